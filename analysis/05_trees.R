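#!/usr/bin/env Rscript
# Stage 5: HKY85 ML trees with bootstrap supports for the full alignment
# and for the 5' and 3' partitions at the inferred breakpoint.

suppressMessages({library(paraclade); library(ape)})
records <- read_gene_fasta("results/run/family.fasta")
arec <- read_gene_fasta("results/run/family.aln.fasta", gapped = TRUE)
keep <- records$id[!records$is_pseudogene]
aln <- codon_aln(setNames(arec$seq[match(keep, arec$id)], keep),
                 records[match(keep, records$id),
                         c("id", "species", "locus", "is_pseudogene")])
L <- aln_length(aln)
bp <- jsonlite::read_json("results/run/breakscan.json")$refined_position

regions <- list(full = c(0, L), `5p` = c(0, bp), `3p` = c(bp, L))
for (nm in names(regions)) {
  fit <- bootstrap_tree(aln, region = regions[[nm]], B = 100,
                        seed = 100 + match(nm, names(regions)))
  write.tree(fit$tree, sprintf("results/run/tree_%s.nwk", nm))
  jsonlite::write_json(
    list(region = regions[[nm]], loglik = fit$loglik, kappa = fit$kappa,
         freqs = as.numeric(fit$freqs), bootstrap = fit$B),
    sprintf("results/run/tree_%s.json", nm), auto_unbox = TRUE,
    digits = NA)
  cat(sprintf("%-4s region [%4d,%4d): logL %.1f, kappa %.2f\n",
              nm, regions[[nm]][1], regions[[nm]][2], fit$loglik,
              fit$kappa))
}
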