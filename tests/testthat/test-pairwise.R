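test_that("percent identity handles exact and simple mismatch cases and is
           symmetric", {
  aln <- raw_aln(c(a = "ACGTACGT", b = "ACGAACGT"))
  expect_equal(percent_identity(aln, "a", "b"), 87.5)
  expect_equal(percent_identity(aln, "a", "a"), 100)
  expect_equal(percent_identity(aln, "b", "a"),
               percent_identity(aln, "a", "b"))
  # N counts as a mismatch; gap columns are excluded from the denominator
  aln2 <- raw_aln(c(a = "ACGN-CGT", b = "ACGA-CGT"))
  expect_equal(percent_identity(aln2, "a", "b"), 100 * 6 / 7)
  aln3 <- raw_aln(c(a = "---", b = "AAA"))
  expect_error(percent_identity(aln3, "a", "b"), "comparable")
})

test_that("NG86 dS reproduces the hand-computed single-change example", {
  aln <- raw_aln(c(a = strrep("AAA", 10),
                   b = paste0(strrep("AAA", 9), "AAG")))
  ds <- ng86_ds(aln, "a", "b")
  expect_equal(ds$S_sites, 10 / 3, tolerance = 1e-12)
  expect_equal(ds$pS, 0.3, tolerance = 1e-12)
  expect_equal(ds$dS, -0.75 * log(0.6), tolerance = 1e-12)
  expect_false(ds$saturated)
  ident <- ng86_ds(aln, "a", "a")
  expect_equal(ident$dS, 0)
})

test_that("NG86 counting matches the exhaustive path-enumeration oracle on
           every sense-codon pair with <= 2 differences", {
  cods <- sense_codons()
  n_checked <- 0
  for (c1 in cods) {
    v1 <- strsplit(c1, "")[[1]]
    for (c2 in cods) {
      d <- sum(v1 != strsplit(c2, "")[[1]])
      if (d > 2) next
      got <- paraclade:::codon_path_diffs(c1, c2)
      want <- oracle_path_diffs(c1, c2)
      expect_equal(got, want, tolerance = 1e-12,
                   info = paste(c1, c2))
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 1000)
  # site counts against the independent oracle
  for (c1 in cods) {
    expect_equal(paraclade:::syn_sites(c1), oracle_syn_sites(c1),
                 tolerance = 1e-12, info = c1)
  }
})

test_that("NG86 difference counts agree with the oracle on random diverged
           codon sequences, including 3-difference codons", {
  set.seed(20)
  s1 <- rand_cds(300)
  s2 <- evolve_sequence(s1, 1.2, omega = 0.7)
  aln <- raw_aln(c(a = s1, b = s2))
  ds <- ng86_ds(aln, "a", "b")
  c1 <- paraclade:::split_codons(s1)
  c2 <- paraclade:::split_codons(s2)
  keep <- GC[c1] != "*" & GC[c2] != "*"
  o <- rowSums(vapply(which(keep), function(i)
    oracle_path_diffs(c1[i], c2[i]), c(0, 0)))
  expect_equal(ds$syn_diffs, o[1], tolerance = 1e-9)
  expect_equal(ds$nonsyn_diffs, o[2], tolerance = 1e-9)
})

test_that("a whole-alignment window reduces to the global statistics and
           site counts are conserved over a disjoint tiling", {
  set.seed(23)
  s1 <- rand_cds(200)
  s2 <- evolve_sequence(s1, 0.4, omega = 0.5)
  aln <- raw_aln(c(a = s1, b = s2))
  L <- aln_length(aln)
  tr <- window_scan(aln, "a", "b", window_nt = L, step_nt = L)
  expect_equal(nrow(tr), 1L)
  glob <- ng86_ds(aln, "a", "b")
  expect_equal(tr$dS[1], glob$dS)
  expect_equal(tr$identity[1], percent_identity(aln, "a", "b"))
  # disjoint 150-nt tiling conserves synonymous sites and differences
  tiles <- window_scan(aln, "a", "b", window_nt = 150, step_nt = 150)
  expect_equal(sum(tiles$S_sites), glob$S_sites, tolerance = 1e-9)
  expect_equal(sum(tiles$syn_diffs), glob$syn_diffs, tolerance = 1e-9)
})

test_that("windows flag saturation and missing data; non-codon window sizes
           warn and round down", {
  set.seed(2)
  s1 <- rand_cds(100)
  aln <- raw_aln(c(a = s1, b = s1))
  expect_warning(window_scan(aln, "a", "b", window_nt = 200), "codon")
  gappy <- raw_aln(c(a = paste0(strrep("-", 180), substr(s1, 181, 300)),
                     b = s1))
  tr <- suppressWarnings(window_scan(gappy, "a", "b", window_nt = 200))
  expect_true(tr$missing[1])
})

test_that("on a 5'-converted pair the 5' window dS is significantly below
           the 3' window dS", {
  set.seed(33)
  p <- simulate_conversion_pair()
  aln <- raw_aln(setNames(p$records$seq, p$records$id))
  tr <- suppressWarnings(
    window_scan(aln, p$records$id[1], p$records$id[2]))
  pre <- tr$dS[tr$end <= p$breakpoint_nt]
  post <- tr$dS[tr$start >= p$breakpoint_nt]
  wt <- stats::wilcox.test(pre, post, alternative = "less")
  expect_lt(wt$p.value, 0.01)
})

test_that("on a homogeneous pair no window dS strays beyond the binomial
           sampling envelope of the global value", {
  set.seed(44)
  s1 <- rand_cds(472)
  s2 <- evolve_sequence(s1, 0.5, omega = 0.5)
  aln <- raw_aln(c(a = s1, b = s2))
  glob <- ng86_ds(aln, "a", "b")
  tr <- suppressWarnings(window_scan(aln, "a", "b"))
  # envelope on the synonymous-difference proportion per window
  for (i in seq_len(nrow(tr))) {
    se <- sqrt(glob$pS * (1 - glob$pS) / tr$S_sites[i])
    expect_lt(abs(tr$pS[i] - glob$pS), 4 * se)
  }
})

test_that("a hard identity step is located exactly", {
  # perfect identity, then deterministic 50% identity starting with a
  # mismatch at column 600 (0-based): the two-segment optimum is forced
  left <- strrep("ACGTTGCAAC", 60) # 600 nt
  a <- paste0(left, strrep("AC", 300))
  b <- paste0(left, strrep("GC", 300))
  aln <- raw_aln(c(a = a, b = b))
  cp <- identity_changepoint(aln, "a", "b")
  expect_equal(cp$position_nt, 600L)
  expect_equal(cp$left_identity, 100)
  expect_equal(cp$right_identity, 50)
})

test_that("no-conversion pairs show no significant change point;
           converted pairs do", {
  set.seed(66)
  s1 <- rand_cds(472)
  s2 <- evolve_sequence(s1, 0.8, omega = 0.5)
  aln <- raw_aln(c(a = s1, b = s2))
  cp <- identity_changepoint(aln, "a", "b", n_perm = 199, seed = 1)
  expect_gt(cp$p_value, 0.05)
  p <- simulate_conversion_pair()
  aln2 <- raw_aln(setNames(p$records$seq, p$records$id))
  cp2 <- identity_changepoint(aln2, p$records$id[1], p$records$id[2],
                              n_perm = 199, seed = 1)
  expect_lt(cp2$p_value, 0.01)
  expect_lt(abs(cp2$position_nt - p$breakpoint_nt), 60)
  expect_error(identity_changepoint(raw_aln(c(a = "ACGTAG", b = "ACGTAG")),
                                    "a", "b"), "shorter")
})
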