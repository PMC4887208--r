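test_that("FASTA round-trips byte-identically after normalisation", {
  recs <- gene_records(c("Felis_catus", "Mustela"), c("IFIT1", "IFIT1B"),
                       c("atgaaacccuuu", "ATGAAACCCTTT"))
  expect_identical(recs$seq[1], "ATGAAACCCTTT") # case and U normalised
  tf <- tempfile(fileext = ".fasta")
  write_gene_fasta(recs, tf)
  back <- read_gene_fasta(tf)
  expect_identical(back$seq, recs$seq)
  expect_identical(back$id, recs$id)
  tf2 <- tempfile(fileext = ".fasta")
  write_gene_fasta(back, tf2)
  expect_identical(readLines(tf), readLines(tf2))
  # pseudogene annotation survives the round trip via a |pseudo header tag
  ps <- gene_records("sp", c("L1", "L2"), c("ATGAAA", "ATGAAATT"),
                     is_pseudogene = c(FALSE, TRUE))
  tf3 <- tempfile(fileext = ".fasta")
  write_gene_fasta(ps, tf3)
  back_ps <- read_gene_fasta(tf3)
  expect_identical(back_ps$id, ps$id)
  expect_identical(back_ps$is_pseudogene, c(FALSE, TRUE))
  tf4 <- tempfile(fileext = ".fasta")
  write_gene_fasta(back_ps, tf4)
  expect_identical(readLines(tf3), readLines(tf4))
})

test_that("headers parse into species and locus with raw-id fallback", {
  tf <- tempfile(fileext = ".fasta")
  writeLines(c(">Felis_catus|IFIT1B", "ATGAAA", ">plainid", "ATGCCC"), tf)
  recs <- read_gene_fasta(tf)
  expect_equal(recs$species[1], "Felis_catus")
  expect_equal(recs$locus[1], "IFIT1B")
  expect_equal(recs$species[2], "plainid")
})

test_that("malformed input is rejected with the offending record named", {
  tf <- tempfile(fileext = ".fasta")
  writeLines(c(">ok|x", "ATGAAA", ">bad|y", "ATGJAA"), tf)
  expect_error(read_gene_fasta(tf), "bad\\|y")
  writeLines(character(0), tf)
  expect_error(read_gene_fasta(tf), "empty")
  expect_error(gene_records(c("a", "a"), c("x", "x"), c("AAA", "CCC")),
               "duplicate")
})

test_that("identical sequences align gap-free at 100% identity", {
  s <- rand_cds(50)
  r <- gene_records(c("a", "b"), c("L", "L"), c(s, s))
  aln <- align_pair_codon(r[1, ], r[2, ])
  expect_false(any(grepl("-", aln$seqs, fixed = TRUE)))
  expect_equal(percent_identity(aln, r$id[1], r$id[2]), 100)
})

test_that("a one-codon insertion aligns as a single codon-sized gap", {
  r <- gene_records(c("a", "b"), c("L", "L"), c("ATGAAA", "ATGAAGAAA"))
  aln <- align_pair_codon(r[1, ], r[2, ])
  short <- aln$seqs[[r$id[1]]]
  expect_equal(nchar(short), 9L)
  expect_equal(nchar(gsub("[^-]", "", short)), 3L) # one codon gap
  m <- regmatches(short, gregexpr("-+", short))[[1]]
  expect_identical(m, "---")
  expect_false(grepl("-", aln$seqs[[r$id[2]]], fixed = TRUE))
})

test_that("emitted protein-space scores survive independent rescoring", {
  set.seed(12)
  B <- paraclade:::blosum62x()
  for (i in 1:5) {
    s1 <- rand_cds(100)
    s2 <- evolve_sequence(s1, 0.6, omega = 0.5)
    # introduce a codon indel
    s2 <- paste0(substr(s2, 1, 150), substr(s2, 157, nchar(s2)))
    r <- gene_records(c("a", "b"), c("L", "L"), c(s1, s2))
    aln <- align_pair_codon(r[1, ], r[2, ])
    # rescore the emitted alignment in protein space
    ca <- strsplit(aln$seqs[[1]], "")[[1]]
    cb <- strsplit(aln$seqs[[2]], "")[[1]]
    ncod <- length(ca) / 3
    sc <- 0; in_gap_a <- FALSE; in_gap_b <- FALSE
    for (k in seq_len(ncod)) {
      cod_a <- paste(ca[(3 * k - 2):(3 * k)], collapse = "")
      cod_b <- paste(cb[(3 * k - 2):(3 * k)], collapse = "")
      if (cod_a == "---") {
        sc <- sc - (if (in_gap_a) 1 else 12) # open 11 + extend 1
        in_gap_a <- TRUE; in_gap_b <- FALSE
      } else if (cod_b == "---") {
        sc <- sc - (if (in_gap_b) 1 else 12)
        in_gap_b <- TRUE; in_gap_a <- FALSE
      } else {
        sc <- sc + B[translate_cds(cod_a), translate_cds(cod_b)]
        in_gap_a <- in_gap_b <- FALSE
      }
    }
    expect_equal(sc, attr(aln, "score"), tolerance = 1e-9)
  }
})

test_that("two records reduce the progressive aligner to the pairwise one", {
  set.seed(4)
  s1 <- rand_cds(80)
  s2 <- evolve_sequence(s1, 0.5, omega = 0.5)
  r <- gene_records(c("a", "b"), c("L1", "L2"), c(s1, s2))
  fam <- align_family_codon(r)
  pair <- align_pair_codon(r[1, ], r[2, ])
  expect_identical(unname(fam$seqs[r$id]), unname(pair$seqs[r$id]))
})

test_that("indel-free simulator families align gap-free, recovering the
           simulated homology", {
  tr <- sim_species_tree(5, 0.3)
  cfg <- evolver_config(conversion_rate = 0, loss_rate = 0,
                        pseudo_rate = 0, gene_length_codons = 150,
                        seed = 6)
  sim <- simulate_family(tr, cfg)
  aln <- align_family_codon(sim$records)
  expect_false(any(grepl("-", aln$seqs, fixed = TRUE)))
  expect_equal(aln_length(aln), 450L)
  # every row ungaps to its input (round-trip invariant)
  expect_identical(unname(paraclade:::ungap(aln$seqs[sim$records$id])),
                   sim$records$seq)
})

test_that("pseudogene rows join in nucleotide space and flag the columns
           they insert", {
  set.seed(9)
  s1 <- rand_cds(60)
  s2 <- evolve_sequence(s1, 0.3, omega = 0.5)
  s3 <- evolve_sequence(s1, 0.3, omega = 0.5)
  # frameshift: 1-nt insertion at position 50
  ps <- paste0(substr(s3, 1, 50), "A", substr(s3, 51, nchar(s3)))
  r <- gene_records(c("a", "b", "c"), c("L1", "L2", "L2"),
                    c(s1, s2, ps), is_pseudogene = c(FALSE, FALSE, TRUE))
  aln <- align_family_codon(r)
  ins <- attr(aln, "col_insert")
  expect_equal(sum(ins), 1L)
  expect_identical(unname(paraclade:::ungap(aln$seqs[[r$id[3]]])), ps)
  # intact rows' gaps (here: only the inserted column) vanish when insert
  # columns are dropped
  keep <- which(!ins)
  intact_rows <- vapply(r$id[1:2], function(id)
    paste(strsplit(aln$seqs[[id]], "")[[1]][keep], collapse = ""), "")
  expect_false(any(grepl("-", intact_rows, fixed = TRUE)))
})

test_that("column maps locate sequence positions through gaps", {
  r <- gene_records(c("a", "b"), c("L", "L"), c("ATGAAA", "ATGAAGAAA"))
  aln <- align_pair_codon(r[1, ], r[2, ])
  cm <- aln_col_map(aln, r$id[1])
  expect_equal(sum(is.na(cm)), 3L)
  expect_identical(cm[!is.na(cm)], 0:5)
})
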