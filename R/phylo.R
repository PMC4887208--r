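#' HKY85 log-likelihood of a tree
#'
#' Felsenstein pruning over site patterns (compressed before computation),
#' with gaps and `N` treated as missing data and per-node scaling against
#' underflow. The rate matrix is scaled to one expected substitution per
#' site per unit branch length at stationarity.
#'
#' @param tree `phylo` whose tip labels are a subset of the alignment rows;
#'   branch lengths are required and must be non-negative.
#' @param aln a `codon_aln`.
#' @param region optional 0-based half-open column interval.
#' @param kappa transition/transversion rate ratio.
#' @param base_freqs stationary frequencies; default empirical frequencies
#'   of the alignment region.
#' @return log-likelihood (finite).
#' @export
hky_loglik <- function(tree, aln, region = NULL, kappa = 4,
                       base_freqs = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree needs branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  pw <- build_patterns(aln, region, tips = tree$tip.label)
  if (is.null(base_freqs)) base_freqs <- pw$freqs
  cpp_hky_loglik(tree$edge, tree$edge.length, length(tree$tip.label),
                 kappa, base_freqs, pw$pat, pw$wt)
}

# site-pattern compression; rows ordered to match `tips`
build_patterns <- function(aln, region = NULL, tips = NULL) {
  if (!is.null(region)) aln <- aln_region(aln, region[1], region[2])
  m <- as.matrix(aln)
  if (!is.null(tips)) {
    miss <- setdiff(tips, rownames(m))
    if (length(miss)) stop("tree tips not in alignment: ",
                           paste(miss, collapse = ", "))
    m <- m[tips, , drop = FALSE]
  }
  codes <- matrix(match(m, .NUC, nomatch = 0L), nrow = nrow(m),
                  dimnames = dimnames(m))
  codes[is.na(codes)] <- 0L
  key <- do.call(paste, c(as.data.frame(t(codes)), sep = ","))
  uk <- unique(key)
  idx <- match(uk, key)
  pat <- codes[, idx, drop = FALSE]
  wt <- as.numeric(table(factor(key, levels = uk)))
  cnt <- tabulate(codes[codes > 0L], nbins = 4L)
  freqs <- (cnt + 0.01) / sum(cnt + 0.04)
  list(pat = pat, wt = wt, labels = rownames(codes), freqs = freqs,
       nsites = ncol(codes))
}

# pairwise maximum-likelihood HKY distances (for the NJ starting tree)
ml_distances <- function(pw, kappa, freqs, max_t = 10) {
  labs <- pw$labels
  n <- length(labs)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    xi <- pw$pat[i, ]; xj <- pw$pat[j, ]
    ok <- xi > 0L & xj > 0L
    if (!any(ok)) { d[i, j] <- d[j, i] <- max_t; next }
    cnt <- matrix(0, 4, 4)
    tab <- stats::xtabs(pw$wt[ok] ~ factor(xi[ok], levels = 1:4) +
                          factor(xj[ok], levels = 1:4))
    cnt[, ] <- tab
    if (sum(cnt) - sum(diag(cnt)) == 0) { d[i, j] <- d[j, i] <- 1e-8; next }
    nll <- function(t) {
      P <- cpp_hky_pmat(t, kappa, freqs)
      -sum(cnt * log(pmax(freqs * P, 1e-300)))
    }
    opt <- stats::optimize(nll, c(1e-8, max_t))
    d[i, j] <- d[j, i] <- opt$minimum
  }
  stats::as.dist(d)
}

#' Fit an HKY85 maximum-likelihood tree
#'
#' Starts from a neighbour-joining tree on pairwise ML distances, then
#' alternates per-branch 1-D branch-length optimisation with
#' nearest-neighbour-interchange topology moves (first improvement, in a
#' deterministic edge order) until no move improves the log-likelihood by
#' more than `tol`. Base frequencies are empirical; `kappa` is estimated by
#' 1-D optimisation unless supplied. With fewer than three distinct
#' sequences a star tree is returned with a warning.
#'
#' @inheritParams hky_loglik
#' @param kappa fixed transition/transversion ratio, or `NULL` to estimate.
#' @param nni logical; perform NNI topology search.
#' @param start_tree optional `phylo` to warm-start the search (its topology
#'   is used instead of the NJ tree; branch lengths are re-optimised).
#' @param tol minimum log-likelihood gain for accepting an NNI move.
#' @return object of class `hky_fit`: list with `tree` (unrooted `phylo`),
#'   `loglik`, `kappa`, `freqs`, `nsites`.
#' @export
fit_tree <- function(aln, region = NULL, kappa = NULL, nni = TRUE,
                     start_tree = NULL, tol = 1e-4) {
  pw <- build_patterns(aln, region)
  n <- length(pw$labels)
  if (n < 3) stop("need >= 3 sequences to fit a tree")
  freqs <- pw$freqs
  est_kappa <- is.null(kappa)
  if (est_kappa) kappa <- 4

  seq_keys <- do.call(paste, c(as.data.frame(pw$pat), sep = ","))
  if (length(unique(seq_keys)) < 3) {
    warning("fewer than 3 distinct sequences; returning a star tree")
    star <- ape::read.tree(text = paste0(
      "(", paste(pw$labels, collapse = ","), ");"))
    star$edge.length <- rep(1e-8, nrow(star$edge))
    ob <- cpp_hky_optim_bl(star$edge, star$edge.length, n, kappa, freqs,
                           pw$pat, pw$wt)
    star$edge.length <- ob$el
    return(structure(list(tree = star, loglik = ob$loglik, kappa = kappa,
                          freqs = freqs, nsites = pw$nsites),
                     class = "hky_fit"))
  }

  if (is.null(start_tree)) {
    d <- ml_distances(pw, kappa, freqs)
    tr <- ape::nj(d)
  } else {
    tr <- start_tree
    if (!setequal(tr$tip.label, pw$labels)) {
      stop("start_tree tips do not match alignment rows")
    }
  }
  tr <- ape::unroot(tr)
  tr$edge.length <- pmax(tr$edge.length, 1e-8)
  tr$node.label <- NULL

  search <- function(tr, kappa) {
    if (nni) {
      res <- cpp_hky_nni_search(tr$edge, tr$edge.length, n, kappa, freqs,
                                pw$pat, pw$wt, tol = tol)
      tr$edge <- res$edge
    } else {
      res <- cpp_hky_optim_bl(tr$edge, tr$edge.length, n, kappa, freqs,
                              pw$pat, pw$wt, tol = tol)
    }
    tr$edge.length <- res$el
    list(tree = tr, loglik = res$loglik)
  }
  opt_kappa <- function(tr, kappa) {
    if (!est_kappa) return(kappa)
    f <- function(lk) -cpp_hky_loglik(tr$edge, tr$edge.length, n, exp(lk),
                                      freqs, pw$pat, pw$wt)
    exp(stats::optimize(f, log(c(0.2, 100)))$minimum)
  }

  cur <- search(tr, kappa)
  if (est_kappa) {
    kappa <- opt_kappa(cur$tree, kappa)
    cur <- search(cur$tree, kappa)
    kappa <- opt_kappa(cur$tree, kappa)
    ob <- cpp_hky_optim_bl(cur$tree$edge, cur$tree$edge.length, n, kappa,
                           freqs, pw$pat, pw$wt, tol = tol)
    cur$tree$edge.length <- ob$el
    cur$loglik <- ob$loglik
  }
  structure(list(tree = cur$tree, loglik = cur$loglik, kappa = kappa,
                 freqs = freqs, nsites = pw$nsites), class = "hky_fit")
}

#' @export
print.hky_fit <- function(x, ...) {
  cat(sprintf("HKY85 ML fit: %d tips, logL = %.3f, kappa = %.3f\n",
              length(x$tree$tip.label), x$loglik, x$kappa))
  invisible(x)
}

#' Nonparametric bootstrap supports for an HKY85 tree
#'
#' Resamples alignment columns with replacement, refits the tree for each
#' replicate with the same search settings, and reports for every internal
#' bipartition of the point-estimate tree the percentage of replicate trees
#' that contain it. Deterministic given `seed`.
#'
#' @inheritParams fit_tree
#' @param B number of bootstrap replicates (the pipeline default is 100;
#'   set 1000 to match the classical convention).
#' @param seed RNG seed.
#' @param fit optional precomputed point fit (skips refitting).
#' @return an `hky_fit` whose `tree$node.label` holds the supports (%) and
#'   with a `support` vector attached.
#' @export
bootstrap_tree <- function(aln, region = NULL, B = 100, seed = 1,
                           kappa = NULL, nni = TRUE, fit = NULL) {
  stopifnot(B >= 1)
  if (is.null(fit)) fit <- fit_tree(aln, region, kappa = kappa, nni = nni)
  if (!is.null(region)) aln <- aln_region(aln, region[1], region[2])
  L <- aln_length(aln)
  set.seed(seed)
  boots <- vector("list", B)
  for (b in seq_len(B)) {
    cols <- sample.int(L, L, replace = TRUE)
    baln <- resample_columns(aln, cols)
    bf <- tryCatch(fit_tree(baln, kappa = kappa, nni = nni),
                   error = function(e) NULL)
    boots[[b]] <- if (is.null(bf)) NULL else bf$tree
  }
  boots <- Filter(Negate(is.null), boots)
  class(boots) <- "multiPhylo"
  cnt <- ape::prop.clades(fit$tree, boots, rooted = FALSE)
  cnt[is.na(cnt)] <- 0
  supp <- 100 * cnt / length(boots)
  fit$tree$node.label <- round(supp, 1)
  fit$support <- supp
  fit$B <- length(boots)
  fit
}

resample_columns <- function(aln, cols) {
  m <- as.matrix(aln)[, cols, drop = FALSE]
  seqs <- setNames(apply(m, 1, paste, collapse = ""), rownames(m))
  codon_aln(seqs, aln$meta)
}
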