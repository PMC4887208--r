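# Independent oracles used across the suite. These deliberately reimplement
# the quantities they check by different routes (eigendecomposition instead
# of closed forms, explicit enumeration instead of pruning/recursion).

NUC <- c("A", "C", "G", "T")
GC <- Biostrings::GENETIC_CODE

# HKY85 transition probabilities via eigendecomposition of the rate matrix
oracle_pmat <- function(t, kappa, pi) {
  ts <- matrix(c(0, 1, kappa, 1,
                 1, 0, 1, kappa,
                 kappa, 1, 0, 1,
                 1, kappa, 1, 0), 4, 4, byrow = TRUE)
  Q <- sweep(ts, 2, pi, `*`)
  diag(Q) <- -rowSums(Q)
  Q <- Q / -sum(pi * diag(Q))
  # symmetrise: S = diag(sqrt(pi)) Q diag(1/sqrt(pi)) is symmetric
  D <- diag(sqrt(pi)); Di <- diag(1 / sqrt(pi))
  S <- D %*% Q %*% Di
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  Di %*% e$vectors %*% diag(exp(t * e$values)) %*% t(e$vectors) %*% D
}

# tree log-likelihood by brute-force enumeration of internal node states
oracle_tree_loglik <- function(tree, seqs, kappa, pi) {
  ntip <- length(tree$tip.label)
  nnode <- max(tree$edge)
  internals <- (ntip + 1):nnode
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  L <- nchar(seqs[[1]])
  Pm <- lapply(seq_len(nrow(tree$edge)), function(e)
    oracle_pmat(tree$edge.length[e], kappa, pi))
  chars <- lapply(tree$tip.label, function(tp)
    match(strsplit(seqs[[tp]], "")[[1]], NUC)) # NA = missing
  ll <- 0
  grid <- as.matrix(expand.grid(rep(list(1:4), length(internals))))
  for (s in seq_len(L)) {
    tot <- 0
    for (g in seq_len(nrow(grid))) {
      state <- integer(nnode)
      state[internals] <- grid[g, ]
      for (i in seq_len(ntip)) state[i] <- chars[[i]][s]
      # missing tip: sum over its states
      pr_edges <- function(tips_assign) {
        pr <- pi[state[root]]
        for (e in seq_len(nrow(tree$edge))) {
          a <- state[tree$edge[e, 1]]; b <- state[tree$edge[e, 2]]
          pr <- pr * Pm[[e]][a, b]
        }
        pr
      }
      miss <- which(is.na(state[seq_len(ntip)]))
      if (length(miss) == 0) {
        tot <- tot + pr_edges()
      } else {
        sub <- as.matrix(expand.grid(rep(list(1:4), length(miss))))
        for (r in seq_len(nrow(sub))) {
          state[miss] <- sub[r, ]
          tot <- tot + pr_edges()
        }
      }
    }
    ll <- ll + log(tot)
  }
  ll
}

# --- NG86 path-enumeration oracle ----------------------------------------

oracle_syn_sites <- function(codon) {
  aa <- GC[[codon]]
  s <- 0
  for (p in 1:3) {
    orig <- substr(codon, p, p)
    for (nuc in NUC[NUC != orig]) {
      mut <- codon
      substr(mut, p, p) <- nuc
      if (GC[[mut]] == aa) s <- s + 1
    }
  }
  s / 3
}

# all orderings of the differing positions, built iteratively (not the
# package's recursive generator)
all_orders <- function(pos) {
  out <- list(integer(0))
  for (k in seq_along(pos)) {
    nxt <- list()
    for (o in out) {
      remaining <- setdiff(pos, o)
      for (r in remaining) nxt[[length(nxt) + 1L]] <- c(o, r)
    }
    out <- nxt
  }
  out[lengths(out) == length(pos)]
}

oracle_path_diffs <- function(c1, c2) {
  v1 <- strsplit(c1, "")[[1]]; v2 <- strsplit(c2, "")[[1]]
  pos <- which(v1 != v2)
  if (length(pos) == 0) return(c(0, 0))
  paths <- all_orders(pos)
  score <- lapply(paths, function(ord) {
    cur <- v1
    s <- n <- 0; hit_stop <- FALSE
    for (p in ord) {
      nxt <- cur; nxt[p] <- v2[p]
      aa1 <- GC[[paste(cur, collapse = "")]]
      aa2 <- GC[[paste(nxt, collapse = "")]]
      if (aa2 == "*") hit_stop <- TRUE
      if (aa1 == aa2) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    c(s = s, n = n, stop = as.numeric(hit_stop))
  })
  m <- do.call(rbind, score)
  keep <- m[, "stop"] == 0
  if (!any(keep)) keep <- rep(TRUE, nrow(m))
  c(mean(m[keep, "s"]), mean(m[keep, "n"]))
}

sense_codons <- function() {
  all <- apply(expand.grid(NUC, NUC, NUC), 1, paste, collapse = "")
  all[GC[all] != "*"]
}

# --- misc helpers ---------------------------------------------------------

# alignment object straight from equal-length sequences (no gaps)
raw_aln <- function(seqs, species = NULL, locus = NULL) {
  ids <- names(seqs)
  if (is.null(species)) species <- ids
  if (is.null(locus)) locus <- ids
  codon_aln(seqs, data.frame(id = ids, species = species, locus = locus,
                             is_pseudogene = FALSE))
}

rand_cds <- function(n_codons) paraclade:::stationary_cds(n_codons)
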