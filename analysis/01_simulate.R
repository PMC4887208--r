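#!/usr/bin/env Rscript
# Stage 1: simulate the canonical gene family.
#
# A 12-species Yule tree (root depth 0.3 substitutions/site), two paralogs
# that duplicated 0.5 substitutions/site before the root, recurrent
# non-reciprocal 5' conversion planted on six terminal branches with the
# shared breakpoint at codon 316 (nt 948 of 1416), plus background loss
# and pseudogenisation. Writes FASTA, the ground-truth event log, and the
# true gene tree under results/run/.

suppressMessages({library(paraclade); library(ape)})
seed <- 20260929L
dir.create("results/run", recursive = TRUE, showWarnings = FALSE)

set.seed(seed)
tree <- sim_species_tree(12, 0.3)
conv_sp <- sample(tree$tip.label, 6)
plant <- data.frame(species = conv_sp, donor = "L1", recipient = "L2",
                    time_frac = 0.85)
cfg <- evolver_config(conversion_rate = 0, loss_rate = 0.05,
                      pseudo_rate = 0.05,
                      locus_names = c("IFIT1", "IFIT1B"), seed = seed)
plant$donor <- "IFIT1"; plant$recipient <- "IFIT1B"
sim <- simulate_family(tree, cfg, plant_conversions = plant)

write_gene_fasta(sim$records, "results/run/family.fasta")
write.table(sim$log, "results/run/eventlog.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.tree(tree, "results/run/species_tree.nwk")
write.tree(true_gene_tree(tree, sim$records), "results/run/true_tree.nwk")

cat("simulated", nrow(sim$records), "genes across",
    length(unique(sim$records$species)), "species\n")
cat("events:", paste(names(table(sim$log$type)), table(sim$log$type),
                     collapse = ", "), "\n")
cat("converted species:", paste(sort(conv_sp), collapse = ", "), "\n")
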