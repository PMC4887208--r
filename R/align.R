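#' Codon alignment container
#'
#' Stores aligned nucleotide rows (gap `-`) plus per-record metadata. For
#' intact genes, gaps are codon-sized (inserted in the translated space and
#' back-threaded); pseudogene rows are aligned in nucleotide space, and any
#' columns they insert are flagged in `attr(x, "col_insert")`.
#'
#' @param seqs named character vector of equal-length aligned sequences.
#' @param meta data.frame with columns `id`, `species`, `locus`,
#'   `is_pseudogene` (row order matches `seqs`).
#' @return object of class `codon_aln`.
#' @export
codon_aln <- function(seqs, meta) {
  w <- unique(nchar(seqs))
  if (length(w) != 1) stop("aligned rows must have equal length")
  stopifnot(all(meta$id == names(seqs)))
  structure(list(seqs = seqs, meta = meta), class = "codon_aln")
}

#' @export
print.codon_aln <- function(x, ...) {
  cat("codon alignment:", length(x$seqs), "sequences x",
      nchar(x$seqs[1]), "columns\n")
  invisible(x)
}

#' @export
as.matrix.codon_aln <- function(x, ...) {
  m <- do.call(rbind, strsplit(unname(x$seqs), "", fixed = TRUE))
  rownames(m) <- names(x$seqs)
  m
}

#' Number of columns in a codon alignment
#' @param aln a `codon_aln`.
#' @export
aln_length <- function(aln) nchar(aln$seqs[[1]])

#' Extract a column region of an alignment
#'
#' @param aln a `codon_aln`.
#' @param start,end 0-based half-open column interval `[start, end)`.
#' @return a `codon_aln` over the region.
#' @export
aln_region <- function(aln, start, end) {
  L <- aln_length(aln)
  if (start < 0 || end > L || start >= end) {
    stop("region [", start, ", ", end, ") outside alignment of length ", L)
  }
  out <- aln
  out$seqs <- substring(aln$seqs, start + 1L, end)
  ci <- attr(aln, "col_insert")
  if (!is.null(ci)) attr(out, "col_insert") <- ci[(start + 1L):end]
  out
}

#' Map alignment columns to sequence positions
#'
#' @param aln a `codon_aln`.
#' @param id record id (row name).
#' @return integer vector, one entry per column: the 0-based position in the
#'   ungapped sequence, or `NA` at gap columns.
#' @export
aln_col_map <- function(aln, id) {
  ch <- strsplit(aln$seqs[[id]], "", fixed = TRUE)[[1]]
  pos <- cumsum(ch != "-") - 1L
  pos[ch == "-"] <- NA_integer_
  pos
}

ungap <- function(s) gsub("-", "", s, fixed = TRUE)

# BLOSUM62 with the ambiguity translation X scoring 0 against everything
# (conservative: an N-containing codon neither rewards nor penalises).
blosum62x <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      data("BLOSUM62", package = "Biostrings", envir = environment())
      m <- get("BLOSUM62", envir = environment())
      m["X", ] <- 0L
      m[, "X"] <- 0L
      cache <<- m
    }
    cache
  }
})

aa_string <- function(rec) {
  if (has_internal_stop(rec$seq)) {
    stop("record ", rec$id, " has an internal stop codon; annotate it as a ",
         "pseudogene (see scan_pseudogene) or repair the frame")
  }
  translate_cds(rec$seq)
}

# back-thread one protein-space gapped string to codons of nt sequence
thread_codons <- function(aa_gapped, nt) {
  ch <- strsplit(aa_gapped, "", fixed = TRUE)[[1]]
  cods <- split_codons(nt)
  out <- character(length(ch))
  j <- 0L
  for (i in seq_along(ch)) {
    if (ch[i] == "-") out[i] <- "---"
    else { j <- j + 1L; out[i] <- cods[j] }
  }
  if (j != length(cods)) stop("internal error: codon threading mismatch")
  paste(out, collapse = "")
}

#' Codon-aware global pairwise alignment
#'
#' Translated sequences are aligned end-to-end with BLOSUM62 scoring and
#' affine gap penalties, and the protein alignment is back-threaded to
#' nucleotides so that every gap is codon-sized. If either record is
#' annotated as a pseudogene the pair is aligned in nucleotide space instead
#' (frameshifted genes cannot be translated).
#'
#' @param a,b single gene records (1-row data.frames).
#' @param gap_open,gap_extend affine gap penalties in protein space
#'   (defaults 11 and 1, the common BLOSUM62 pairing).
#' @return a `codon_aln` of the two records, with the protein-space
#'   alignment score in `attr(x, "score")`.
#' @export
align_pair_codon <- function(a, b, gap_open = 11, gap_extend = 1) {
  stopifnot(nrow(a) == 1, nrow(b) == 1)
  if (nchar(a$seq) < 3 || nchar(b$seq) < 3) stop("sequences must be >= 3 nt")
  meta <- rbind(a[, c("id", "species", "locus", "is_pseudogene")],
                b[, c("id", "species", "locus", "is_pseudogene")])
  if (a$is_pseudogene || b$is_pseudogene) {
    al <- align_nt_global(a$seq, b$seq)
    seqs <- setNames(c(al$a, al$b), c(a$id, b$id))
    out <- codon_aln(seqs, meta)
    attr(out, "score") <- al$score
    return(out)
  }
  pa <- aa_string(a); pb <- aa_string(b)
  fit <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa), Biostrings::AAString(pb),
    substitutionMatrix = blosum62x(), gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  ga <- as.character(Biostrings::alignedPattern(fit))
  gb <- as.character(Biostrings::alignedSubject(fit))
  seqs <- setNames(c(thread_codons(ga, a$seq), thread_codons(gb, b$seq)),
                   c(a$id, b$id))
  out <- codon_aln(seqs, meta)
  attr(out, "score") <- Biostrings::score(fit)
  out
}

# plain nucleotide-space global alignment (for pseudogene rows)
align_nt_global <- function(sa, sb) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1)
  fit <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(sa), Biostrings::DNAString(sb),
    substitutionMatrix = mat, gapOpening = 5, gapExtension = 2,
    type = "global")
  list(a = as.character(Biostrings::alignedPattern(fit)),
       b = as.character(Biostrings::alignedSubject(fit)),
       score = Biostrings::score(fit))
}

#' Progressive codon-aware multiple alignment
#'
#' Intact genes are aligned progressively in translated space along a
#' neighbour-joining guide tree built from pairwise protein p-distances,
#' using sum-of-pairs BLOSUM62 profile scores with affine gaps, then
#' back-threaded to codons. Pseudogene records are added afterwards in
#' nucleotide space against the profile consensus; columns they insert are
#' flagged in `attr(x, "col_insert")`. An externally curated alignment can
#' be supplied instead via `external` and is validated against the records.
#'
#' @param records gene records (>= 2 rows).
#' @param gap_open,gap_extend protein-space affine gap penalties.
#' @param external optional path to an aligned FASTA overriding the
#'   progressive aligner (manual curation hook).
#' @return a `codon_aln` over all records.
#' @export
align_family_codon <- function(records, gap_open = 11, gap_extend = 1,
                               external = NULL) {
  if (nrow(records) < 2) stop("need >= 2 records")
  if (!is.null(external)) {
    ext <- read_gene_fasta(external, gapped = TRUE)
    ord <- match(records$id, ext$id)
    if (anyNA(ord)) stop("external alignment is missing records: ",
                         paste(records$id[is.na(ord)], collapse = ", "))
    seqs <- setNames(ext$seq[ord], records$id)
    if (!all(ungap(seqs) == records$seq)) {
      stop("external alignment rows do not ungap to the input sequences")
    }
    return(codon_aln(seqs, records[, c("id", "species", "locus",
                                       "is_pseudogene")]))
  }
  intact <- records[!records$is_pseudogene, , drop = FALSE]
  pseudo <- records[records$is_pseudogene, , drop = FALSE]
  if (nrow(intact) < 2) stop("need >= 2 intact records to build a profile")

  prots <- vapply(seq_len(nrow(intact)), function(i)
    aa_string(intact[i, , drop = FALSE]), "")
  names(prots) <- intact$id

  # progressive merge down an NJ guide tree of protein p-distances
  leaf_profile <- function(id) {
    m <- matrix(strsplit(prots[[id]], "", fixed = TRUE)[[1]], nrow = 1)
    rownames(m) <- id
    m
  }
  prof <- if (nrow(intact) == 2) {
    merge_profiles(leaf_profile(intact$id[1]), leaf_profile(intact$id[2]),
                   gap_open, gap_extend)
  } else {
    guide <- ape::nj(protein_pdist(prots))
    ntip <- length(guide$tip.label)
    align_node <- function(node) {
      if (node <= ntip) return(leaf_profile(guide$tip.label[node]))
      kids <- guide$edge[guide$edge[, 1] == node, 2]
      Reduce(function(a, b) merge_profiles(a, b, gap_open, gap_extend),
             lapply(kids, align_node))
    }
    align_node(guide$edge[1, 1])
  }

  # back-thread to codons, in the input record order
  seqs <- vapply(intact$id, function(id) {
    thread_codons(paste(prof[id, ], collapse = ""),
                  intact$seq[intact$id == id])
  }, "")
  aln <- codon_aln(seqs, intact[, c("id", "species", "locus",
                                    "is_pseudogene")])
  attr(aln, "col_insert") <- rep(FALSE, aln_length(aln))
  for (i in seq_len(nrow(pseudo))) {
    aln <- add_pseudo_row(aln, pseudo[i, , drop = FALSE])
  }
  # restore input record order
  ord <- match(records$id, names(aln$seqs))
  out <- codon_aln(aln$seqs[ord], aln$meta[ord, , drop = FALSE])
  attr(out, "col_insert") <- attr(aln, "col_insert")
  out
}

protein_pdist <- function(prots) {
  n <- length(prots)
  d <- matrix(0, n, n, dimnames = list(names(prots), names(prots)))
  same_len <- length(unique(nchar(prots))) == 1
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (same_len) {
      a <- strsplit(prots[[i]], "")[[1]]; b <- strsplit(prots[[j]], "")[[1]]
      p <- mean(a != b)
    } else {
      fit <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(prots[[i]]), Biostrings::AAString(prots[[j]]),
        substitutionMatrix = blosum62x(), gapOpening = 11, gapExtension = 1,
        type = "global")
      ga <- strsplit(as.character(Biostrings::alignedPattern(fit)), "")[[1]]
      gb <- strsplit(as.character(Biostrings::alignedSubject(fit)), "")[[1]]
      ok <- ga != "-" & gb != "-"
      p <- mean(ga[ok] != gb[ok])
    }
    d[i, j] <- d[j, i] <- p
  }
  stats::as.dist(d)
}

# sum-of-pairs profile-profile alignment via the C++ Gotoh kernel
merge_profiles <- function(pa, pb, gap_open, gap_extend) {
  B <- blosum62x()
  alpha <- rownames(B)
  enc <- function(p) {
    f <- matrix(0, length(alpha), ncol(p))
    for (i in seq_len(nrow(p))) {
      idx <- match(p[i, ], alpha)
      ok <- !is.na(idx)
      f[cbind(idx[ok], which(ok))] <- f[cbind(idx[ok], which(ok))] + 1
    }
    f
  }
  fa <- enc(pa); fb <- enc(pb)
  S <- crossprod(fa, B %*% fb) / (nrow(pa) * nrow(pb))
  path <- cpp_gotoh_profile(S, gap_open, gap_extend)
  ncolm <- length(path$ai)
  out <- matrix("-", nrow(pa) + nrow(pb), ncolm)
  rownames(out) <- c(rownames(pa), rownames(pb))
  out[seq_len(nrow(pa)), path$ai > 0] <- pa[, path$ai[path$ai > 0],
                                            drop = FALSE]
  out[nrow(pa) + seq_len(nrow(pb)), path$bi > 0] <-
    pb[, path$bi[path$bi > 0], drop = FALSE]
  out
}

# align one pseudogene record against the profile consensus in nucleotide
# space and splice it into the alignment; inserted columns are flagged
add_pseudo_row <- function(aln, rec) {
  m <- as.matrix(aln)
  cons <- apply(m, 2, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0) "A" else names(sort(table(col),
                                              decreasing = TRUE))[1]
  })
  cons_nt <- paste(cons, collapse = "")
  al <- align_nt_global(rec$seq, cons_nt)
  ga <- strsplit(al$a, "")[[1]]; gb <- strsplit(al$b, "")[[1]]
  old_insert <- attr(aln, "col_insert")
  ncol_new <- length(ga)
  newm <- matrix("-", nrow(m) + 1, ncol_new)
  rownames(newm) <- c(rownames(m), rec$id)
  col_insert <- logical(ncol_new)
  j <- 0L # consensus (existing alignment) column counter
  for (k in seq_len(ncol_new)) {
    if (gb[k] != "-") {
      j <- j + 1L
      newm[seq_len(nrow(m)), k] <- m[, j]
      col_insert[k] <- old_insert[j]
    } else {
      col_insert[k] <- TRUE # column inserted by this pseudogene
    }
    newm[nrow(m) + 1L, k] <- ga[k]
  }
  seqs <- setNames(apply(newm, 1, paste, collapse = ""), rownames(newm))
  meta <- rbind(aln$meta, rec[, c("id", "species", "locus",
                                  "is_pseudogene")])
  out <- codon_aln(seqs, meta)
  attr(out, "col_insert") <- col_insert
  out
}
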