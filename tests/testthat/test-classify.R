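test_that("monophyly is read off bipartitions for clean and violated
           caterpillar trees", {
  tr <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
  labels <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  res <- test_monophyly(tr, labels)
  expect_true(all(res$monophyletic))
  bad <- ape::read.tree(text = "((a1:1,(b1:1,a2:1):1):1,b2:1);")
  res2 <- test_monophyly(bad, labels)
  expect_false(res2$monophyletic[res2$family == "A"])
  expect_warning(test_monophyly(tr, c(labels, z1 = "Z")), "absent")
})

test_that("concordant trees give zero conversion calls; a cat-style
           injected pair gives exactly one", {
  set.seed(120)
  tr <- sim_species_tree(6, 0.3)
  sim <- simulate_family(tr, evolver_config(
    conversion_rate = 0, loss_rate = 0, pseudo_rate = 0, seed = 121))
  aln <- align_family_codon(sim$records)
  L <- aln_length(aln)
  f5 <- fit_tree(aln, region = c(0, 948))
  f3 <- fit_tree(aln, region = c(948, L))
  expect_equal(nrow(call_conversions(f5, f3, aln, 948)), 0L)

  # inject a recently converted within-family pair for a new species:
  # start from one species' L1/L2, overwrite the recipient's 5' tract with
  # the donor's, and let both drift a little
  set.seed(122)
  src <- sim$records[sim$records$species == "sp01", ]
  # sp99 speciates from sp01, then L1 converts L2's 5' tract, then drift
  a <- evolve_sequence(src$seq[src$locus == "L1"], 0.1, omega = 0.2)
  b <- evolve_sequence(src$seq[src$locus == "L2"], 0.1, omega = 0.2)
  b <- paste0(substr(a, 1, 948), substr(b, 949, nchar(b)))
  a <- evolve_sequence(a, 0.04, omega = 0.2)
  b <- evolve_sequence(b, 0.04, omega = 0.2)
  cat_pair <- gene_records(species = "sp99", locus = c("L1", "L2"),
                           seq = c(a, b))
  recs2 <- rbind(sim$records[, c("id", "species", "locus", "seq",
                                 "is_pseudogene")],
                 cat_pair[, c("id", "species", "locus", "seq",
                              "is_pseudogene")])
  aln2 <- raw_aln(setNames(recs2$seq, recs2$id), species = recs2$species,
                  locus = recs2$locus)
  f5b <- fit_tree(aln2, region = c(0, 948))
  f3b <- fit_tree(aln2, region = c(948, L))
  calls <- call_conversions(f5b, f3b, aln2, 948)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$species, "sp99")
  expect_gt(calls$identity_5p, 90)
  expect_lt(calls$identity_3p, 75)

  # leaf-set mismatch is an error
  f3_drop <- f3b
  f3_drop$tree <- ape::drop.tip(f3_drop$tree, "sp99|L1")
  expect_error(call_conversions(f5b, f3_drop, aln2, 948), "leaf")
})

test_that("planted conversions are recalled against the event log with no
           false calls in unconverted species", {
  set.seed(130)
  tr <- sim_species_tree(12, 0.3)
  conv_sp <- sprintf("sp%02d", c(1, 3, 5, 7, 9, 11))
  plant <- data.frame(species = conv_sp, donor = "L1", recipient = "L2",
                      time_frac = 0.85)
  sim <- simulate_family(tr, evolver_config(
    conversion_rate = 0, loss_rate = 0, pseudo_rate = 0, seed = 131),
    plant_conversions = plant)
  aln <- align_family_codon(sim$records)
  L <- aln_length(aln)
  f5 <- fit_tree(aln, region = c(0, 948))
  f3 <- fit_tree(aln, region = c(948, L))
  calls <- call_conversions(f5, f3, aln, 948)
  truth <- unique(sim$log$lineage[sim$log$type == "conversion"])
  recall <- mean(truth %in% calls$species)
  expect_gte(recall, 5 / 6)
  expect_equal(setdiff(calls$species, truth), character(0))
})

test_that("the pseudogene scanner reports frameshifts and nonsense codons
           and accepts intact genes", {
  set.seed(140)
  s <- rand_cds(478)
  ref <- gene_records("ref", "L1", s)
  self <- scan_pseudogene(ref, ref)
  expect_false(self$is_pseudogene)
  expect_equal(nrow(self$evidence), 0L)

  ins <- paste0(substr(s, 1, 300), "T", substr(s, 301, nchar(s)))
  r_ins <- gene_records("x", "L1", ins, is_pseudogene = TRUE)
  sc <- scan_pseudogene(r_ins, ref)
  expect_true(sc$is_pseudogene)
  expect_true(any(sc$evidence$type == "frameshift_ins" &
                    abs(sc$evidence$position - 300) <= 2))

  # engineer a nonsense mutation at codon index 99 (TGG -> TGA if possible,
  # otherwise overwrite the codon with TAA)
  non <- s
  substr(non, 3 * 99 + 1, 3 * 99 + 3) <- "TAA"
  r_non <- gene_records("y", "L1", non, is_pseudogene = TRUE)
  sc2 <- scan_pseudogene(r_non, ref)
  expect_true(sc2$is_pseudogene)
  expect_true(any(sc2$evidence$type == "nonsense" &
                    sc2$evidence$position == 99))

  # a stop within 15 codons of the reference end is not called
  late <- s
  substr(late, 3 * 470 + 1, 3 * 470 + 3) <- "TAA"
  sc3 <- scan_pseudogene(gene_records("z", "L1", late,
                                      is_pseudogene = TRUE), ref)
  expect_false(any(sc3$evidence$type == "nonsense"))

  expect_error(scan_pseudogene(ref, r_ins), "intact")
})

test_that("simulated pseudogenes are detected from their lesions", {
  set.seed(150)
  tr <- sim_species_tree(8, 0.25)
  sim <- simulate_family(tr, evolver_config(
    conversion_rate = 0, loss_rate = 0, pseudo_rate = 0.25, seed = 151))
  ps <- sim$records[sim$records$is_pseudogene, , drop = FALSE]
  ok <- sim$records[!sim$records$is_pseudogene, , drop = FALSE]
  expect_gt(nrow(ps), 0)
  ref <- ok[1, , drop = FALSE]
  hits <- vapply(seq_len(nrow(ps)), function(i)
    scan_pseudogene(ps[i, , drop = FALSE], ref)$is_pseudogene, TRUE)
  expect_gt(mean(hits), 0.7)
  self_calls <- vapply(seq_len(min(nrow(ok), 6)), function(i)
    scan_pseudogene(ok[i, , drop = FALSE], ref)$is_pseudogene, TRUE)
  expect_false(any(self_calls))
})

test_that("3'-region assignment recovers the true groups; full-length
           trees lose family monophyly under conversion", {
  set.seed(160)
  tr <- sim_species_tree(10, 0.3)
  conv_sp <- sprintf("sp%02d", c(1, 3, 5, 7))
  plant <- data.frame(species = conv_sp, donor = "L1", recipient = "L2",
                      time_frac = 0.85)
  sim <- simulate_family(tr, evolver_config(
    conversion_rate = 0, loss_rate = 0, pseudo_rate = 0, seed = 161),
    plant_conversions = plant)
  aln <- align_family_codon(sim$records)
  L <- aln_length(aln)
  f_full <- fit_tree(aln)
  f3 <- fit_tree(aln, region = c(948, L))
  labels <- setNames(sim$records$group, sim$records$id)
  mono_full <- test_monophyly(f_full, labels)
  mono_3 <- test_monophyly(f3, labels)
  expect_true(all(mono_3$monophyletic))
  expect_false(all(mono_full$monophyletic))
  # exemplar-based assignment from the 3' tree
  ex_ids <- sim$records$id[sim$records$species == "sp02"]
  exemplars <- setNames(sim$records$group[match(ex_ids, sim$records$id)],
                        ex_ids)
  asg <- assign_families(f3, exemplars)
  truth <- labels[asg$id]
  expect_gte(mean(asg$family == truth), 0.95)
})

test_that("the repertoire table reflects copy numbers, pseudogenes and
           losses", {
  calls <- data.frame(
    species = c("sp1", "sp1", "sp2", "sp2", "sp2", "sp3"),
    family = c("L1", "L2", "L1", "L1", "L1", "L1"),
    is_pseudogene = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  tab <- build_repertoire_table(calls)
  get <- function(sp, fam) tab[tab$species == sp & tab$family == fam, ]
  expect_equal(get("sp1", "L1")$n_intact, 1)
  expect_equal(get("sp2", "L1")$n_intact, 3) # mouse-like triplication
  expect_equal(get("sp3", "L1")$status, "pseudogene_only")
  expect_equal(get("sp2", "L2")$status, "lost")
  expect_equal(get("sp3", "L2")$status, "lost")
  tab2 <- build_repertoire_table(
    calls, assembly_complete = c(sp1 = TRUE, sp2 = FALSE, sp3 = TRUE))
  expect_equal(tab2[tab2$species == "sp2" & tab2$family == "L2", ]$status,
               "not_found")
  # simulator truth: losses recorded in the log appear as absences
  set.seed(170)
  tr <- sim_species_tree(6, 0.25)
  sim <- simulate_family(tr, evolver_config(
    conversion_rate = 0, pseudo_rate = 0, loss_rate = 0.15, seed = 171))
  calls_sim <- data.frame(species = sim$records$species,
                          family = sim$records$group,
                          is_pseudogene = sim$records$is_pseudogene)
  tab3 <- build_repertoire_table(calls_sim, species = tr$tip.label)
  absent <- tab3[tab3$status == "lost", ]
  for (i in seq_len(nrow(absent))) {
    expect_equal(sum(sim$records$species == absent$species[i] &
                       sim$records$group == absent$family[i]), 0L)
  }
})
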