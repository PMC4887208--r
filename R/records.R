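#' Construct a set of gene records
#'
#' A gene record is one coding nucleotide sequence tagged with the species
#' and locus it came from. Record sets are plain data frames (one row per
#' gene) so they compose with ordinary R tooling; the constructor validates
#' sequences and enforces unique ids.
#'
#' @param id character vector of unique record ids; if `NULL`, built as
#'   `species|locus`.
#' @param species,locus character vectors naming the source species and the
#'   locus (paralog) of each gene.
#' @param seq character vector of nucleotide sequences over `A C G T N`
#'   (lowercase and `U` are normalised).
#' @param is_pseudogene logical; annotation that the record is a known
#'   pseudogene (frameshifted/nonsense). Pseudogenes are exempt from the
#'   reading-frame checks applied by the codon aligner.
#' @param group optional character vector of true ortholog-group labels
#'   (carried through from the simulator's event log).
#' @return data.frame with columns `id`, `species`, `locus`, `seq`,
#'   `is_pseudogene` and optionally `group`.
#' @export
gene_records <- function(species, locus, seq, id = NULL,
                         is_pseudogene = FALSE, group = NULL,
                         gapped = FALSE) {
  n <- length(seq)
  if (is.null(id)) id <- paste(species, locus, sep = "|")
  seq <- normalize_nuc(seq, id, allow_gaps = gapped)
  if (anyDuplicated(id)) {
    stop("duplicate record ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(!nzchar(seq))) stop("empty sequence in records: ",
                              paste(id[!nzchar(seq)], collapse = ", "))
  out <- data.frame(id = as.character(id), species = as.character(species),
                    locus = as.character(locus), seq = seq,
                    is_pseudogene = rep_len(is_pseudogene, n),
                    stringsAsFactors = FALSE)
  if (!is.null(group)) out$group <- as.character(group)
  out
}

# Uppercase, U->T, and reject non-IUPAC residues (only A,C,G,T,N accepted;
# the gap symbol too when reading aligned FASTA).
normalize_nuc <- function(seq, id = seq_along(seq), allow_gaps = FALSE) {
  seq <- toupper(as.character(seq))
  seq <- gsub("U", "T", seq, fixed = TRUE)
  pat <- if (allow_gaps) "[^ACGTN-]" else "[^ACGTN]"
  bad <- grepl(pat, seq)
  if (any(bad)) {
    ch <- regmatches(seq[bad][1], regexpr(pat, seq[bad][1]))
    stop("non-IUPAC character '", ch, "' in record ", id[bad][1])
  }
  seq
}

## --- genetic code helpers -------------------------------------------------

.NUC <- c("A", "C", "G", "T")

# codon (e.g. "ATG") -> amino acid, "*" for stop; NA for codons containing
# N or gaps. Built once from the standard code shipped with Biostrings.
codon_aa <- function(codons) {
  tab <- Biostrings::GENETIC_CODE
  out <- unname(tab[codons])
  out
}

# split a cds string into codon strings; incomplete tail codon dropped
split_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Translate a coding sequence
#'
#' Standard-code translation; codons containing `N` translate to `X`,
#' stop codons to `*`. The trailing incomplete codon (if any) is dropped.
#'
#' @param seq nucleotide string (length need not be a multiple of 3).
#' @return single amino-acid string.
#' @export
translate_cds <- function(seq) {
  cods <- split_codons(normalize_nuc(seq))
  if (length(cods) == 0L) return("")
  aa <- codon_aa(cods)
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# TRUE if the sequence has an internal stop codon in frame 0 (the last codon
# is allowed to be a stop).
has_internal_stop <- function(seq) {
  cods <- split_codons(seq)
  if (length(cods) < 2L) return(FALSE)
  aa <- codon_aa(cods[-length(cods)])
  any(aa == "*", na.rm = TRUE)
}

seq_to_int <- function(seq) {
  x <- match(strsplit(seq, "", fixed = TRUE)[[1]], .NUC)
  x
}

int_to_seq <- function(x) paste(.NUC[x], collapse = "")
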