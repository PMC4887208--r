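#' Evolve a coding sequence along a branch under HKY85
#'
#' Exact continuous-time simulation: substitution events are drawn one at a
#' time from the HKY85 rate matrix (scaled to one expected substitution per
#' site per unit branch length at stationarity), so the sequence is explicit
#' at every instant -- a requirement for editing gene-conversion tracts into
#' it. Selection on the protein is approximated by thinning: a proposed
#' substitution that changes the encoded amino acid is accepted with
#' probability `omega`; with `omega = 1` the process is exactly neutral HKY85
#' and the expected number of substitutions per site equals `branch_length`.
#'
#' When `omega < 1` the gene is treated as intact: proposals creating an
#' internal stop codon are rejected outright, and an input that already
#' carries an internal stop is an error (pseudogenes evolve with
#' `omega = 1`, where stops are ordinary codons).
#'
#' @param seq nucleotide string; length must be a multiple of 3.
#' @param branch_length expected substitutions per site (>= 0).
#' @param kappa transition/transversion rate ratio (> 0).
#' @param base_freqs stationary frequencies (piA, piC, piG, piT), summing
#'   to 1.
#' @param omega nonsynonymous/synonymous acceptance ratio in (0, 1].
#' @return the evolved nucleotide string (same length).
#' @export
evolve_sequence <- function(seq, branch_length, kappa = 4,
                            base_freqs = c(0.3, 0.2, 0.2, 0.3), omega = 1) {
  stopifnot(branch_length >= 0, kappa > 0, omega > 0, omega <= 1,
            length(base_freqs) == 4, all(base_freqs > 0))
  base_freqs <- base_freqs / sum(base_freqs)
  seq <- normalize_nuc(seq)
  L <- nchar(seq)
  if (L == 0L) stop("empty sequence")
  if (omega < 1 && L %% 3L != 0L) {
    stop("sequence length must be a multiple of 3 when omega < 1, got ", L)
  }
  if (omega < 1 && has_internal_stop(seq)) {
    stop("sequence has an internal stop codon; evolve with omega = 1 ",
         "(pseudogene) or repair the frame")
  }
  if (branch_length == 0) return(seq)

  x <- seq_to_int(seq)
  rt <- hky_site_rates(kappa, base_freqs) # per-state total leave rate
  # conditional target distribution for each current state (rows)
  tp <- hky_target_probs(kappa, base_freqs)

  t <- 0
  rates <- rt[x]
  total <- sum(rates)
  repeat {
    t <- t + rexp(1L, total)
    if (t > branch_length) break
    i <- sample.int(L, 1L, prob = rates)
    y <- sample.int(4L, 1L, prob = tp[x[i], ])
    if (omega < 1) {
      ci <- (i - 1L) %/% 3L            # codon index, 0-based
      pos <- ci * 3L + 1:3
      old <- int_to_seq(x[pos])
      newx <- x[pos]
      newx[i - ci * 3L] <- y
      new <- int_to_seq(newx)
      aa_old <- codon_aa(old)
      aa_new <- codon_aa(new)
      if (aa_new == "*" && !(aa_old == "*")) next       # no new stops
      if (aa_new != aa_old && runif(1L) > omega) next   # thinned
    }
    total <- total - rates[i]
    x[i] <- y
    rates[i] <- rt[y]
    total <- total + rates[i]
  }
  int_to_seq(x)
}

# total leave rate per current state, scaled so the stationary mean rate = 1
hky_site_rates <- function(kappa, pi) {
  q <- hky_q(kappa, pi)
  -diag(q)
}

# row-stochastic matrix of substitution targets given a substitution occurs
hky_target_probs <- function(kappa, pi) {
  q <- hky_q(kappa, pi)
  diag(q) <- 0
  q / rowSums(q)
}

# scaled HKY85 rate matrix, order A C G T
hky_q <- function(kappa, pi) {
  ts <- matrix(c(NA, 1, kappa, 1,
                 1, NA, 1, kappa,
                 kappa, 1, NA, 1,
                 1, kappa, 1, NA), 4, 4, byrow = TRUE)
  q <- sweep(ts, 2, pi, `*`)
  diag(q) <- 0
  diag(q) <- -rowSums(q)
  mu <- -sum(pi * diag(q))
  q / mu
}

# random stationary coding sequence with no internal stop codon
stationary_cds <- function(n_codons, base_freqs = c(0.3, 0.2, 0.2, 0.3)) {
  base_freqs <- base_freqs / sum(base_freqs)
  draw <- function(k) sample(.NUC, 3L * k, replace = TRUE, prob = base_freqs)
  cods <- apply(matrix(draw(n_codons), nrow = 3L), 2,
                paste, collapse = "")
  bad <- which(codon_aa(cods) == "*")
  while (length(bad) > 0L) {
    cods[bad] <- apply(matrix(draw(length(bad)), nrow = 3L), 2,
                       paste, collapse = "")
    bad <- bad[codon_aa(cods[bad]) == "*"]
  }
  paste(cods, collapse = "")
}
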