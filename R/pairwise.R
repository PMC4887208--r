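#' Percent nucleotide identity between two aligned rows
#'
#' Identity is computed over comparable columns only (neither row gapped);
#' a column containing `N` in either row counts as a mismatch.
#'
#' @param aln a `codon_aln`.
#' @param a,b record ids of the two rows.
#' @param region optional 0-based half-open column interval `c(start, end)`;
#'   default whole alignment.
#' @return percent identity in `[0, 100]`.
#' @export
percent_identity <- function(aln, a, b, region = NULL) {
  rows <- get_rows(aln, a, b, region)
  comp <- rows$a != "-" & rows$b != "-"
  if (!any(comp)) stop("no comparable (gap-free in both rows) columns")
  x <- rows$a[comp]; y <- rows$b[comp]
  matches <- x == y & x != "N" & y != "N"
  100 * sum(matches) / sum(comp)
}

get_rows <- function(aln, a, b, region = NULL) {
  if (!is.null(region)) aln <- aln_region(aln, region[1], region[2])
  m <- as.matrix(aln)
  if (!all(c(a, b) %in% rownames(m))) {
    stop("rows not in alignment: ",
         paste(setdiff(c(a, b), rownames(m)), collapse = ", "))
  }
  list(a = m[a, ], b = m[b, ])
}

#' Nei--Gojobori (1986) synonymous divergence with Jukes--Cantor correction
#'
#' Synonymous site counts average, over both sequences, the fraction of the
#' three possible changes at each codon position that are synonymous
#' (changes to stop codons count as nonsynonymous). Codons differing at
#' several positions are scored by averaging over all minimal mutational
#' paths, excluding paths that pass through a stop codon unless all do.
#' The proportion `pS = syn_diffs / S` is corrected as
#' `dS = -3/4 log(1 - 4 pS / 3)`; when the log argument is non-positive
#' (`pS >= 3/4`) the estimate is flagged saturated and `dS` is `Inf`.
#'
#' Only complete codon triplets fully inside `region` are used; codons
#' containing a gap, `N`, or a stop in either row are skipped.
#'
#' @inheritParams percent_identity
#' @return list with `dS`, `dN`, `pS`, `pN`, `S_sites`, `N_sites`,
#'   `syn_diffs`, `nonsyn_diffs`, `n_codons`, `saturated`.
#' @export
ng86_ds <- function(aln, a, b, region = NULL) {
  if (is.null(region)) region <- c(0L, aln_length(aln))
  rows <- get_rows(aln, a, b)
  cstart <- ceiling(region[1] / 3)
  cend <- floor(region[2] / 3)
  if (cend <= cstart) stop("no complete codons in region")
  S <- N <- sd <- nd <- 0
  used <- 0L
  for (ci in cstart:(cend - 1L)) {
    idx <- (3L * ci + 1L):(3L * ci + 3L)
    c1 <- paste(rows$a[idx], collapse = "")
    c2 <- paste(rows$b[idx], collapse = "")
    if (grepl("[^ACGT]", c1) || grepl("[^ACGT]", c2)) next
    a1 <- codon_aa(c1); a2 <- codon_aa(c2)
    if (a1 == "*" || a2 == "*") next
    S <- S + (syn_sites(c1) + syn_sites(c2)) / 2
    N <- N + 3 - (syn_sites(c1) + syn_sites(c2)) / 2
    dd <- codon_path_diffs(c1, c2)
    sd <- sd + dd[1]; nd <- nd + dd[2]
    used <- used + 1L
  }
  if (used == 0L) stop("no scorable codons in region")
  pS <- if (S > 0) sd / S else 0
  pN <- if (N > 0) nd / N else 0
  jc <- function(p) {
    arg <- 1 - 4 * p / 3
    if (arg <= 0) Inf else -0.75 * log(arg)
  }
  list(dS = jc(pS), dN = jc(pN), pS = pS, pN = pN,
       S_sites = S, N_sites = N, syn_diffs = sd, nonsyn_diffs = nd,
       n_codons = used, saturated = !is.finite(jc(pS)))
}

# fraction-of-synonymous-changes site count for one sense codon
syn_sites <- local({
  cache <- new.env(parent = emptyenv())
  function(codon) {
    hit <- cache[[codon]]
    if (!is.null(hit)) return(hit)
    aa <- codon_aa(codon)
    s <- 0
    for (p in 1:3) {
      for (nuc in setdiff(.NUC, substr(codon, p, p))) {
        mut <- codon
        substr(mut, p, p) <- nuc
        if (codon_aa(mut) == aa) s <- s + 1 / 3 # "*" != aa: stop = nonsyn
      }
    }
    cache[[codon]] <- s
    s
  }
})

# average (syn, nonsyn) difference counts over minimal mutational paths
# between two sense codons; stop-passing paths dropped when avoidable
codon_path_diffs <- local({
  cache <- new.env(parent = emptyenv())
  function(c1, c2) {
    key <- paste0(c1, c2)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    d <- length(pos)
    out <- if (d == 0L) {
      c(0, 0)
    } else {
      perms <- permutations(pos)
      scored <- lapply(perms, function(ord) {
        cur <- c1
        s <- n <- 0
        through_stop <- FALSE
        for (p in ord) {
          nxt <- cur
          substr(nxt, p, p) <- substr(c2, p, p)
          aa1 <- codon_aa(cur); aa2 <- codon_aa(nxt)
          if (aa2 == "*") through_stop <- TRUE
          if (aa1 == aa2) s <- s + 1 else n <- n + 1
          cur <- nxt
        }
        list(s = s, n = n, stop = through_stop)
      })
      ok <- !vapply(scored, `[[`, TRUE, "stop")
      if (!any(ok)) ok <- rep(TRUE, length(scored))
      c(mean(vapply(scored[ok], `[[`, 0, "s")),
        mean(vapply(scored[ok], `[[`, 0, "n")))
    }
    cache[[key]] <- out
    out
  }
})

permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutations(v[-i])) {
      out[[length(out) + 1L]] <- c(v[i], rest)
    }
  }
  out
}

#' Sliding-window identity and synonymous divergence
#'
#' Tiles the alignment with fixed-size windows (default 200 nt, the display
#' convention for pairwise paralog scans) and computes percent identity and
#' NG86 dS in each. Windows with fewer than half their columns comparable
#' are flagged missing; dS uses only complete codons inside the window, so
#' a window size that is not a multiple of 3 effectively rounds down to the
#' nearest codon multiple (a warning notes this).
#'
#' @inheritParams percent_identity
#' @param window_nt window size in alignment nucleotides.
#' @param step_nt step between window starts (default 100; overlapping
#'   windows sharpen localisation relative to abutting ones).
#' @return data.frame of class `window_track`: `start`, `end` (0-based
#'   half-open), `identity`, `comparable`, `dS`, `pS`, `S_sites`,
#'   `syn_diffs`, `saturated`, `missing`.
#' @export
window_scan <- function(aln, a, b, window_nt = 200, step_nt = 100) {
  L <- aln_length(aln)
  if (L < window_nt) stop("alignment shorter than one window")
  if (window_nt %% 3 != 0) {
    warning("window of ", window_nt, " nt is not a codon multiple; dS uses ",
            "the ", 3 * (window_nt %/% 3), " nt spanned by complete codons")
  }
  starts <- seq(0L, L - window_nt, by = step_nt)
  rows <- get_rows(aln, a, b)
  res <- lapply(starts, function(s) {
    reg <- c(s, s + window_nt)
    ra <- rows$a[(s + 1):(s + window_nt)]
    rb <- rows$b[(s + 1):(s + window_nt)]
    comp <- sum(ra != "-" & rb != "-")
    idn <- if (comp > 0) {
      ok <- ra != "-" & rb != "-"
      100 * sum(ra[ok] == rb[ok] & ra[ok] != "N" & rb[ok] != "N") / comp
    } else NA_real_
    ds <- tryCatch(ng86_ds(aln, a, b, region = reg), error = function(e) NULL)
    data.frame(start = s, end = s + window_nt, identity = idn,
               comparable = comp,
               dS = if (is.null(ds)) NA_real_ else ds$dS,
               pS = if (is.null(ds)) NA_real_ else ds$pS,
               S_sites = if (is.null(ds)) NA_real_ else ds$S_sites,
               syn_diffs = if (is.null(ds)) NA_real_ else ds$syn_diffs,
               saturated = if (is.null(ds)) NA else ds$saturated,
               missing = comp < window_nt / 2)
  })
  out <- do.call(rbind, res)
  class(out) <- c("window_track", "data.frame")
  attr(out, "window_nt") <- window_nt
  attr(out, "step_nt") <- step_nt
  attr(out, "pair") <- c(a, b)
  out
}

#' Identity-dichotomy change point
#'
#' Finds the column boundary that best splits the pairwise alignment into a
#' high-identity and a low-identity segment, by maximising the two-segment
#' Bernoulli likelihood of the per-column match/mismatch data over
#' comparable columns. Ties break to the smallest position. Significance,
#' when requested, comes from permuting the column match labels.
#'
#' @inheritParams percent_identity
#' @param min_segment_nt minimum segment length in alignment columns.
#' @param n_perm number of label permutations for the null distribution of
#'   the contrast score (0 = no test).
#' @param seed optional RNG seed for the permutation test.
#' @return list of class `changepoint`: `position_nt` (0-based boundary:
#'   columns `[0, position)` are the 5' segment), `left_identity`,
#'   `right_identity`, `left_dS`, `right_dS`, `score` (likelihood-ratio
#'   statistic), `p_value` (or `NA`).
#' @export
identity_changepoint <- function(aln, a, b, min_segment_nt = 300,
                                 n_perm = 0, seed = NULL) {
  L <- aln_length(aln)
  if (L < 2 * min_segment_nt) {
    stop("alignment (", L, " nt) shorter than two minimum segments")
  }
  rows <- get_rows(aln, a, b)
  comp <- which(rows$a != "-" & rows$b != "-")
  x <- as.integer(rows$a[comp] == rows$b[comp] &
                    rows$a[comp] != "N" & rows$b[comp] != "N")
  pos <- comp - 1L # 0-based alignment positions of comparable columns
  n <- length(x)
  # candidate split after comparable column k; boundary = pos[k] + 1
  ks <- which(pos + 1L >= min_segment_nt & pos + 1L <= L - min_segment_nt)
  if (length(ks) == 0) stop("no admissible change point positions")
  best <- cp_score(x, ks)
  boundary <- pos[best$k] + 1L
  p_value <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    null_scores <- vapply(seq_len(n_perm), function(i) {
      cp_score(sample(x), ks)$score
    }, 0)
    p_value <- (1 + sum(null_scores >= best$score)) / (n_perm + 1)
  }
  left <- c(0L, boundary); right <- c(boundary, L)
  res <- list(position_nt = boundary,
              left_identity = percent_identity(aln, a, b, left),
              right_identity = percent_identity(aln, a, b, right),
              left_dS = ng86_ds(aln, a, b, left)$dS,
              right_dS = ng86_ds(aln, a, b, right)$dS,
              score = best$score, p_value = p_value, n_perm = n_perm)
  class(res) <- "changepoint"
  res
}

# maximum two-segment Bernoulli LRT over candidate split indices
cp_score <- function(x, ks) {
  n <- length(x)
  cs <- cumsum(x)
  m <- cs[n]
  bll <- function(mm, nn) {
    p <- mm / nn
    out <- numeric(length(mm))
    ok <- nn > 0
    pin <- pmin(pmax(p[ok], 1e-12), 1 - 1e-12)
    out[ok] <- mm[ok] * log(pin) + (nn[ok] - mm[ok]) * log(1 - pin)
    out
  }
  llL <- bll(cs[ks], ks)
  llR <- bll(m - cs[ks], n - ks)
  ll0 <- bll(m, n)
  sc <- 2 * (llL + llR - ll0)
  i <- which.max(sc) # which.max takes the first (smallest position) on ties
  list(k = ks[i], score = sc[i])
}

#' @export
print.changepoint <- function(x, ...) {
  cat(sprintf(
    "change point at column %d (1-based %d): identity %.1f%% | %.1f%%, score %.1f",
    x$position_nt, x$position_nt + 1L, x$left_identity, x$right_identity,
    x$score))
  if (!is.na(x$p_value)) cat(sprintf(", permutation p = %.4g", x$p_value))
  cat("\n")
  invisible(x)
}
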