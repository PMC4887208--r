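#' Single-breakpoint scan for phylogenetic incongruence
#'
#' Asks whether the alignment is better explained by two independent trees
#' on either side of a breakpoint than by one tree throughout -- the
#' phylogenetic signature of recombination or gene conversion. For each
#' candidate position on a codon-rounded grid, independent HKY85 ML trees
#' are fitted to the left and right segments (warm-started from the
#' full-alignment tree); each two-tree model and the single-tree model are
#' scored by small-sample AICc, converted to Akaike weights, and the summed
#' weight of the breakpoint models is the model-averaged support. A
#' permutation p-value is obtained by re-running the scan on
#' column-shuffled alignments (shuffling destroys positional signal while
#' preserving the site-pattern pool, under which the full-alignment tree --
#' and hence the single-tree model score -- is unchanged); the permuted
#' statistic is the AICc advantage of the best two-tree model, which is
#' monotone in the support but does not saturate at 100% the way Akaike
#' weights do, so ties cannot blunt the test.
#'
#' @param aln a `codon_aln` with >= 4 sequences.
#' @param grid_nt spacing of candidate breakpoints (default 60 nt = 20
#'   codons); candidates are rounded to codon boundaries.
#' @param min_segment minimum segment length in alignment columns.
#' @param n_perm permutation replicates for the p-value (0 = skip).
#' @param seed RNG seed for the permutations.
#' @param kappa fixed kappa, or `NULL` to estimate per fit.
#' @return object of class `breakpoint_scan`: `candidates` data.frame
#'   (`position`, `loglik_left`, `loglik_right`, `k`, `AICc`, `weight`),
#'   `aicc_single`, `weight_single`, `model_averaged_support` (%),
#'   `best_position`, `p_value`, `fit_full`, `fit_left`, `fit_right`.
#' @export
scan_single_breakpoint <- function(aln, grid_nt = 60, min_segment = 300,
                                   n_perm = 99, seed = 1, kappa = NULL) {
  L <- aln_length(aln)
  if (L < 2 * min_segment) {
    stop("alignment length ", L, " < 2 x min_segment (", 2 * min_segment,
         ")")
  }
  if (length(aln$seqs) < 4) stop("need >= 4 sequences")
  cands <- candidate_grid(L, grid_nt, min_segment)
  if (length(cands) == 0) stop("no admissible candidate positions")

  full <- fit_tree(aln, kappa = kappa)
  obs <- bp_support(aln, cands, full, kappa)

  p_value <- NA_real_
  if (n_perm > 0) {
    set.seed(seed)
    null_delta <- vapply(seq_len(n_perm), function(i) {
      perm <- resample_columns(aln, sample.int(L, L))
      bp_support(perm, cands, full, kappa)$delta_aicc
    }, 0)
    p_value <- (1 + sum(null_delta >= obs$delta_aicc)) / (n_perm + 1)
  }

  best <- obs$best_position
  res <- list(candidates = obs$candidates, aicc_single = obs$aicc_single,
              weight_single = obs$weight_single,
              model_averaged_support = obs$support,
              delta_aicc = obs$delta_aicc, best_position = best,
              p_value = p_value, n_perm = n_perm,
              fit_full = full,
              fit_left = obs$fits[[as.character(best)]]$left,
              fit_right = obs$fits[[as.character(best)]]$right)
  class(res) <- "breakpoint_scan"
  res
}

candidate_grid <- function(L, grid_nt, min_segment) {
  pos <- seq(min_segment, L - min_segment, by = grid_nt)
  pos <- unique(pmax(3L, 3L * round(pos / 3)))
  pos[pos >= min_segment & pos <= L - min_segment]
}

# the model-averaged support machinery shared by the observed scan and its
# permutation replicates; the single-tree fit is supplied because it is
# invariant under column permutation
bp_support <- function(aln, cands, full, kappa) {
  L <- aln_length(aln)
  nb1 <- nrow(full$tree$edge)
  k1 <- nb1 + 1
  aicc <- function(ll, k, n) {
    if (n - k - 1 <= 0) return(Inf)
    -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  }
  aicc_single <- aicc(full$loglik, k1, L)
  fits <- list()
  rows <- lapply(cands, function(cc) {
    fl <- fit_tree(aln, region = c(0, cc), start_tree = full$tree,
                   kappa = kappa)
    fr <- fit_tree(aln, region = c(cc, L), start_tree = full$tree,
                   kappa = kappa)
    fits[[as.character(cc)]] <<- list(left = fl, right = fr)
    k2 <- (nrow(fl$tree$edge) + 1) + (nrow(fr$tree$edge) + 1)
    data.frame(position = cc, loglik_left = fl$loglik,
               loglik_right = fr$loglik, k = k2,
               AICc = aicc(fl$loglik + fr$loglik, k2, L))
  })
  cd <- do.call(rbind, rows)
  all_aicc <- c(aicc_single, cd$AICc)
  delta <- all_aicc - min(all_aicc)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  cd$weight <- w[-1]
  list(candidates = cd, aicc_single = aicc_single, weight_single = w[1],
       support = 100 * (1 - w[1]),
       delta_aicc = aicc_single - min(cd$AICc),
       best_position = cd$position[which.min(cd$AICc)], fits = fits)
}

#' Re-scan a sub-region for a secondary breakpoint
#'
#' Runs [scan_single_breakpoint()] on an alignment sub-region (typically 3'
#' of an established breakpoint) to ask whether any further breakpoint is
#' supported. Positions in the result are reported in the coordinates of
#' the original alignment.
#'
#' @inheritParams scan_single_breakpoint
#' @param region 0-based half-open column interval to scan.
#' @return a `breakpoint_scan` (positions offset back to full-alignment
#'   coordinates; the region is recorded in `$region`).
#' @export
confirm_no_secondary <- function(aln, region, grid_nt = 60,
                                 min_segment = 300, n_perm = 99, seed = 1,
                                 kappa = NULL) {
  sub <- aln_region(aln, region[1], region[2])
  res <- scan_single_breakpoint(sub, grid_nt = grid_nt,
                                min_segment = min_segment, n_perm = n_perm,
                                seed = seed, kappa = kappa)
  res$candidates$position <- res$candidates$position + region[1]
  res$best_position <- res$best_position + region[1]
  res$region <- region
  res
}

#' @export
print.breakpoint_scan <- function(x, ...) {
  cat(sprintf(
    "breakpoint scan: support %.1f%% for a breakpoint at %d (%d candidates)",
    x$model_averaged_support, x$best_position, nrow(x$candidates)))
  if (!is.na(x$p_value)) cat(sprintf(", permutation p = %.4g", x$p_value))
  cat("\n")
  invisible(x)
}
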