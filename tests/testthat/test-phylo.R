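test_that("degenerate likelihoods take their closed-form values", {
  # one site, two identical leaves, zero branch lengths: L = log pi_X
  aln <- raw_aln(c(a = "G", b = "G"))
  tr <- ape::read.tree(text = "(a:0,b:0);")
  pi <- c(0.3, 0.2, 0.2, 0.3)
  ll <- hky_loglik(tr, aln, kappa = 2, base_freqs = pi)
  expect_equal(ll, log(0.2), tolerance = 1e-9)
  # kappa = 1, equal frequencies: 2-leaf likelihood is the Jukes-Cantor form
  set.seed(3)
  s1 <- rand_cds(100)
  s2 <- evolve_sequence(s1, 0.2, kappa = 1, base_freqs = rep(0.25, 4),
                        omega = 1)
  aln2 <- raw_aln(c(a = s1, b = s2))
  t <- 0.17
  tr2 <- ape::read.tree(text = sprintf("(a:%f,b:0);", t))
  ll2 <- hky_loglik(tr2, aln2, kappa = 1, base_freqs = rep(0.25, 4))
  v1 <- strsplit(s1, "")[[1]]; v2 <- strsplit(s2, "")[[1]]
  n_same <- sum(v1 == v2); n_diff <- sum(v1 != v2)
  p_same <- 1 / 4 + 3 / 4 * exp(-4 * t / 3)
  ll_jc <- n_same * log(0.25 * p_same) +
    n_diff * log(0.25 * (1 - p_same) / 3)
  expect_equal(ll2, ll_jc, tolerance = 1e-8)
})

test_that("pruning equals brute-force ancestral-state enumeration on random
           4-leaf instances", {
  set.seed(9)
  for (i in 1:8) {
    tr <- ape::unroot(ape::rtree(4))
    tr$edge.length <- runif(nrow(tr$edge), 0.01, 1)
    pi <- rexp(4) + 0.2; pi <- pi / sum(pi)
    kappa <- runif(1, 0.5, 8)
    seqs <- setNames(replicate(4, paste(
      sample(c(NUC, "N", "-"), 12, replace = TRUE,
             prob = c(rep(0.23, 4), 0.04, 0.04)), collapse = "")),
      tr$tip.label)
    aln <- raw_aln(seqs)
    ll <- hky_loglik(tr, aln, kappa = kappa, base_freqs = pi)
    ll_brute <- oracle_tree_loglik(tr, as.list(seqs), kappa, pi)
    expect_equal(ll, ll_brute, tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to re-rooting, leaf order, and the
           pulley principle, and pattern compression is exact", {
  set.seed(17)
  tr <- sim_species_tree(5, 0.3)
  sim <- simulate_family(tr, evolver_config(
    conversion_rate = 0, loss_rate = 0, pseudo_rate = 0,
    gene_length_codons = 120, seed = 3))
  aln <- align_family_codon(sim$records)
  ids <- names(aln$seqs)
  phy <- ape::unroot(ape::rtree(length(ids), tip.label = ids))
  phy$edge.length <- runif(nrow(phy$edge), 0.05, 0.4)
  pi <- c(0.3, 0.2, 0.2, 0.3)
  ll0 <- hky_loglik(phy, aln, kappa = 3, base_freqs = pi)
  # re-root at an internal edge
  rr <- ape::root(phy, outgroup = ids[4], resolve.root = TRUE)
  expect_equal(hky_loglik(rr, aln, kappa = 3, base_freqs = pi), ll0,
               tolerance = 1e-6)
  # pulley: shift length between the root's two daughter branches
  root_edges <- which(rr$edge[, 1] == length(ids) + 1)
  sh <- rr
  eps <- min(0.03, sh$edge.length[root_edges[1]])
  sh$edge.length[root_edges[1]] <- sh$edge.length[root_edges[1]] - eps
  sh$edge.length[root_edges[2]] <- sh$edge.length[root_edges[2]] + eps
  expect_equal(hky_loglik(sh, aln, kappa = 3, base_freqs = pi), ll0,
               tolerance = 1e-6)
  # leaf order permutation of the alignment rows
  perm <- sample(length(aln$seqs))
  aln_perm <- codon_aln(aln$seqs[perm], aln$meta[perm, ])
  expect_equal(hky_loglik(phy, aln_perm, kappa = 3, base_freqs = pi), ll0,
               tolerance = 1e-9)
  # compression against an explicit per-site computation
  pw <- paraclade:::build_patterns(aln, tips = phy$tip.label)
  m <- as.matrix(aln)[phy$tip.label, ]
  codes <- matrix(match(m, NUC, nomatch = 0L), nrow = nrow(m))
  codes[is.na(codes)] <- 0L
  ll_uncomp <- paraclade:::cpp_hky_loglik(
    phy$edge, phy$edge.length, length(ids), 3, pi, codes,
    rep(1, ncol(codes)))
  expect_equal(ll0, ll_uncomp, tolerance = 1e-8)
})

test_that("negative branch lengths are rejected", {
  aln <- raw_aln(c(a = "ACG", b = "ACG"))
  tr <- ape::read.tree(text = "(a:-0.1,b:0.1);")
  expect_error(hky_loglik(tr, aln), "negative")
})

test_that("three leaves recover simulated pairwise distances within 20%", {
  set.seed(25)
  tr <- ape::read.tree(text = "((a:0.15,b:0.25):0.0,c:0.3);")
  root <- rand_cds(3400) # ~10 kb
  seqs <- c(a = evolve_sequence(root, 0.15, omega = 1),
            b = evolve_sequence(root, 0.25, omega = 1),
            c = evolve_sequence(root, 0.30, omega = 1))
  aln <- raw_aln(seqs)
  fit <- fit_tree(aln)
  pd_fit <- ape::cophenetic.phylo(fit$tree)
  pd_true <- ape::cophenetic.phylo(tr)
  for (p in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    expect_lt(abs(pd_fit[p[1], p[2]] / pd_true[p[1], p[2]] - 1), 0.2)
  }
})

test_that("kappa is recovered within 15% at 10 kb", {
  set.seed(71)
  errs <- replicate(8, {
    root <- rand_cds(3400)
    aln <- raw_aln(c(a = evolve_sequence(root, 0.05, kappa = 4, omega = 1),
                     b = evolve_sequence(root, 0.3, kappa = 4, omega = 1),
                     c = evolve_sequence(root, 0.1, kappa = 4, omega = 1)))
    fit_tree(aln)$kappa / 4 - 1
  })
  expect_lt(median(abs(errs)), 0.15)
})

test_that("a duplicated sequence joins as a zero-length cherry without
           disturbing the remaining topology", {
  set.seed(41)
  tr <- sim_species_tree(6, 0.3)
  sim <- simulate_family(tr, evolver_config(
    conversion_rate = 0, loss_rate = 0, pseudo_rate = 0,
    gene_length_codons = 200, seed = 10))
  aln <- align_family_codon(sim$records)
  fit0 <- fit_tree(aln)
  dup_id <- "dup|copy"
  seqs2 <- c(aln$seqs, setNames(aln$seqs[1], dup_id))
  meta2 <- rbind(aln$meta, data.frame(id = dup_id, species = "dup",
                                      locus = "copy",
                                      is_pseudogene = FALSE))
  fit2 <- fit_tree(codon_aln(seqs2, meta2))
  d <- ape::cophenetic.phylo(fit2$tree)[names(aln$seqs)[1], dup_id]
  expect_lt(d, 1e-4)
  pruned <- ape::drop.tip(fit2$tree, dup_id)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(pruned),
                                         ape::unroot(fit0$tree))), 0)
})

test_that("clean simulated data recover the true 8-leaf topology with
           strong bootstrap support", {
  set.seed(52)
  # a resolvable case: every internal edge long enough to leave signal
  repeat {
    tr <- sim_species_tree(8, 0.3)
    internal <- tr$edge[, 2] > length(tr$tip.label)
    if (min(tr$edge.length[internal]) >= 0.015) break
  }
  sim <- simulate_family(tr, evolver_config(
    conversion_rate = 0, loss_rate = 0, pseudo_rate = 0, dup_time = 0,
    locus_names = c("L1", "L1b"), gene_length_codons = 1667, seed = 13))
  rec <- sim$records[sim$records$locus == "L1", ]
  aln <- align_family_codon(rec)
  bs <- bootstrap_tree(aln, B = 50, seed = 2)
  truth <- true_gene_tree(tr, rec)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(bs$tree),
                                         ape::unroot(truth))), 0)
  expect_true(all(bs$support > 80))
})

test_that("bootstrap supports behave at the edges: B = 1 gives 0/100 and a
           duplicated half-alignment reproduces single-half supports", {
  set.seed(61)
  tr <- sim_species_tree(6, 0.35)
  sim <- simulate_family(tr, evolver_config(
    conversion_rate = 0, loss_rate = 0, pseudo_rate = 0, dup_time = 0,
    locus_names = c("A", "B"), gene_length_codons = 300, seed = 19))
  rec <- sim$records[sim$records$locus == "A", ]
  aln <- align_family_codon(rec)
  b1 <- bootstrap_tree(aln, B = 1, seed = 5)
  expect_true(all(b1$support %in% c(0, 100)))
  half <- bootstrap_tree(aln, B = 40, seed = 7)
  dbl_seqs <- setNames(paste0(aln$seqs, aln$seqs), names(aln$seqs))
  dbl <- bootstrap_tree(codon_aln(dbl_seqs, aln$meta), B = 40, seed = 7)
  # same bipartitions; supports agree within sampling error
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(half$tree),
                                         ape::unroot(dbl$tree))), 0)
  expect_lt(mean(abs(sort(half$support) - sort(dbl$support))), 15)
})
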