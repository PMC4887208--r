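#' Test families for monophyly in an inferred tree
#'
#' A family is monophyletic when some bipartition of the (unrooted) tree
#' separates exactly its members from everything else; the reported support
#' is the bootstrap value attached to that bipartition's edge, when the
#' tree carries supports. Singleton families are trivially monophyletic
#' (support `NA`). Families with no members in the tree are skipped with a
#' warning.
#'
#' @param fit an `hky_fit` (or bare `phylo` in `fit$tree` form) whose tips
#'   are gene ids.
#' @param labels named character vector mapping gene id to family label.
#' @return data.frame with columns `family`, `n`, `monophyletic`,
#'   `support`.
#' @export
test_monophyly <- function(fit, labels) {
  tree <- if (inherits(fit, "hky_fit")) fit$tree else fit
  fams <- unique(labels)
  sides <- bipartition_sides(tree)
  res <- lapply(fams, function(fam) {
    mem <- names(labels)[labels == fam]
    inmem <- mem %in% tree$tip.label
    if (!any(inmem)) {
      warning("family ", fam, " absent from tree; skipped")
      return(NULL)
    }
    mem <- mem[inmem]
    if (length(mem) == 1) {
      return(data.frame(family = fam, n = 1L, monophyletic = TRUE,
                        support = NA_real_))
    }
    hit <- NA_integer_
    for (i in seq_along(sides$tips)) {
      s <- sides$tips[[i]]
      if (setequal(s, mem) ||
          setequal(setdiff(tree$tip.label, s), mem)) {
        hit <- i
        break
      }
    }
    data.frame(family = fam, n = length(mem), monophyletic = !is.na(hit),
               support = if (is.na(hit)) NA_real_ else sides$support[hit])
  })
  do.call(rbind, Filter(Negate(is.null), res))
}

# internal-node clades of the stored (arbitrary) rooting, one per internal
# edge, with attached node-label supports when present
bipartition_sides <- function(tree) {
  ntip <- length(tree$tip.label)
  nodes <- (ntip + 1L):max(tree$edge)
  tips <- lapply(nodes, function(v) {
    tree$tip.label[descendant_tips(tree, v)]
  })
  supp <- rep(NA_real_, length(nodes))
  if (!is.null(tree$node.label)) {
    supp <- suppressWarnings(as.numeric(tree$node.label))
  }
  list(nodes = nodes, tips = tips, support = supp)
}

descendant_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (v <= ntip) out <- c(out, v)
    else stack <- c(stack, tree$edge[tree$edge[, 1] == v, 2])
  }
  out
}

#' Assign genes to families from a tree with exemplar labels
#'
#' Each unlabelled gene is assigned by the smallest bipartition side that
#' contains the gene together with at least one exemplar, all of whose
#' exemplars belong to one family; genes for which no such side exists are
#' `"unresolved"`. Run this on the non-recombining (3') region tree, where
#' families form clean clades.
#'
#' @param fit an `hky_fit` (typically bootstrap-annotated).
#' @param exemplars named character vector mapping exemplar gene ids to
#'   family labels.
#' @return data.frame with columns `id`, `family`, `support` (bootstrap of
#'   the assigning bipartition, `NA` if the tree carries no supports).
#' @export
assign_families <- function(fit, exemplars) {
  tree <- if (inherits(fit, "hky_fit")) fit$tree else fit
  sides <- bipartition_sides(tree)
  all_tips <- tree$tip.label
  query <- setdiff(all_tips, names(exemplars))
  both <- c(lapply(sides$tips, identity),
            lapply(sides$tips, function(s) setdiff(all_tips, s)))
  supp2 <- c(sides$support, sides$support)
  res <- lapply(query, function(g) {
    best <- NULL; best_size <- Inf; best_supp <- NA_real_
    for (i in seq_along(both)) {
      s <- both[[i]]
      if (!(g %in% s)) next
      ex <- exemplars[intersect(names(exemplars), s)]
      if (length(ex) == 0 || length(unique(ex)) != 1) next
      if (length(s) < best_size) {
        best <- unique(ex); best_size <- length(s); best_supp <- supp2[i]
      }
    }
    data.frame(id = g,
               family = if (is.null(best)) "unresolved" else best,
               support = best_supp)
  })
  ex_rows <- data.frame(id = names(exemplars), family = unname(exemplars),
                        support = NA_real_)
  rbind(do.call(rbind, res), ex_rows)
}

#' Call gene-conversion events from 5'/3' tree discordance
#'
#' A conversion is called for a within-species locus pair when (i) the pair
#' groups together in the 5'-region tree (the smallest bipartition side
#' containing both holds only genes of that species), (ii) it does not do
#' so in the 3'-region tree, and (iii) the 5' identity exceeds the 3'
#' identity by at least `min_delta` percentage points. Conversion
#' homogenises the tract, so converted pairs look like recent within-
#' species sisters 5' of the breakpoint while retaining their ancient
#' divergence 3' of it.
#'
#' @param fit5,fit3 `hky_fit` trees of the 5' and 3' alignment regions
#'   (identical leaf sets).
#' @param aln the `codon_aln` the trees were fitted to.
#' @param breakpoint 0-based column index separating the regions.
#' @param min_delta minimum 5' minus 3' identity difference (percentage
#'   points) for a call.
#' @return data.frame with one row per called pair: `species`, `locus_a`,
#'   `locus_b`, `id_a`, `id_b`, `identity_5p`, `identity_3p`, `delta`,
#'   `breakpoint`.
#' @export
call_conversions <- function(fit5, fit3, aln, breakpoint, min_delta = 10) {
  t5 <- if (inherits(fit5, "hky_fit")) fit5$tree else fit5
  t3 <- if (inherits(fit3, "hky_fit")) fit3$tree else fit3
  if (!setequal(t5$tip.label, t3$tip.label)) {
    stop("5' and 3' trees have different leaf sets")
  }
  meta <- aln$meta
  L <- aln_length(aln)
  id2sp <- setNames(meta$species, meta$id)
  calls <- list()
  for (sp in unique(meta$species)) {
    ids <- meta$id[meta$species == sp & meta$id %in% t5$tip.label]
    if (length(ids) < 2) next
    prs <- utils::combn(ids, 2)
    for (k in seq_len(ncol(prs))) {
      g1 <- prs[1, k]; g2 <- prs[2, k]
      same5 <- pair_groups_within_species(t5, g1, g2, id2sp)
      if (!same5) next
      same3 <- pair_groups_within_species(t3, g1, g2, id2sp)
      if (same3) next
      i5 <- percent_identity(aln, g1, g2, c(0, breakpoint))
      i3 <- percent_identity(aln, g1, g2, c(breakpoint, L))
      if (i5 - i3 < min_delta) next
      calls[[length(calls) + 1L]] <- data.frame(
        species = sp,
        locus_a = meta$locus[meta$id == g1],
        locus_b = meta$locus[meta$id == g2],
        id_a = g1, id_b = g2, identity_5p = i5, identity_3p = i3,
        delta = i5 - i3, breakpoint = breakpoint)
    }
  }
  if (length(calls) == 0) {
    return(data.frame(species = character(0), locus_a = character(0),
                      locus_b = character(0), id_a = character(0),
                      id_b = character(0), identity_5p = numeric(0),
                      identity_3p = numeric(0), delta = numeric(0),
                      breakpoint = integer(0)))
  }
  do.call(rbind, calls)
}

# smallest bipartition side containing both tips consists solely of genes
# of their (shared) species -- the "sister or same-species clade" test,
# generalised to handle 3+ within-species copies
pair_groups_within_species <- function(tree, g1, g2, id2sp) {
  sides <- bipartition_sides(tree)
  all_tips <- tree$tip.label
  cand <- list(all_tips)
  for (s in sides$tips) {
    if (g1 %in% s && g2 %in% s) cand[[length(cand) + 1L]] <- s
    comp <- setdiff(all_tips, s)
    if (g1 %in% comp && g2 %in% comp) cand[[length(cand) + 1L]] <- comp
  }
  sizes <- vapply(cand, length, 0L)
  smallest <- cand[[which.min(sizes)]]
  all(id2sp[smallest] == id2sp[[g1]])
}

#' Scan a gene for pseudogenising lesions
#'
#' Aligns the record to an intact family exemplar in nucleotide space and
#' reports (i) frameshifts: any indel whose length is not a multiple of 3,
#' and (ii) nonsense mutations: in-frame stop codons at least 15 codons
#' before the reference end (short terminal truncations are tolerated as
#' ordinary stop polymorphism). Nonsense scanning stops at the first
#' frameshift, downstream of which the reading frame is undefined.
#'
#' @param record 1-row gene record to test.
#' @param reference 1-row intact exemplar (no internal stop codons).
#' @return list with `is_pseudogene` and `evidence` (data.frame of `type`
#'   -- `frameshift_ins`, `frameshift_del`, `nonsense` -- and `position`:
#'   0-based nucleotide for frameshifts, 0-based codon index for nonsense).
#' @export
scan_pseudogene <- function(record, reference) {
  stopifnot(nrow(record) == 1, nrow(reference) == 1)
  if (nchar(reference$seq) %% 3 != 0 || has_internal_stop(reference$seq)) {
    stop("reference ", reference$id, " is not an intact single-ORF gene")
  }
  al <- align_nt_global(record$seq, reference$seq)
  ra <- strsplit(al$a, "")[[1]] # record row
  rb <- strsplit(al$b, "")[[1]] # reference row
  ev <- list()
  rec_pos <- 0L
  first_fs <- Inf
  i <- 1L
  while (i <= length(ra)) {
    if (ra[i] == "-" || rb[i] == "-") {
      type <- if (rb[i] == "-") "ins" else "del"
      at <- rec_pos
      len <- 0L
      while (i <= length(ra) &&
             ((type == "ins" && rb[i] == "-" && ra[i] != "-") ||
              (type == "del" && ra[i] == "-" && rb[i] != "-"))) {
        if (type == "ins") rec_pos <- rec_pos + 1L
        len <- len + 1L
        i <- i + 1L
      }
      if (len %% 3 != 0) {
        ev[[length(ev) + 1L]] <- data.frame(
          type = paste0("frameshift_", type), position = at)
        first_fs <- min(first_fs, at)
      }
    } else {
      rec_pos <- rec_pos + 1L
      i <- i + 1L
    }
  }
  # nonsense: in-frame stops upstream of the first frameshift
  n_ref_cod <- nchar(reference$seq) %/% 3L
  cods <- split_codons(record$seq)
  scan_to <- min(length(cods), floor(first_fs / 3))
  if (scan_to >= 1) {
    aa <- codon_aa(cods[seq_len(scan_to)])
    stops <- which(!is.na(aa) & aa == "*") - 1L # 0-based codon index
    stops <- stops[stops <= n_ref_cod - 1L - 15L]
    for (s in stops) {
      ev[[length(ev) + 1L]] <- data.frame(type = "nonsense", position = s)
    }
  }
  evidence <- if (length(ev)) do.call(rbind, ev) else
    data.frame(type = character(0), position = integer(0))
  list(is_pseudogene = nrow(evidence) > 0, evidence = evidence)
}

#' Species-by-family repertoire table
#'
#' Summarises classified genes as per-species counts of intact and
#' pseudogenised copies per family. A family absent from a species is
#' marked `"lost"` when that species' assembly is flagged complete (the
#' family is present in other lineages, so absence is loss), otherwise
#' `"not_found"`.
#'
#' @param calls data.frame with columns `species`, `family`,
#'   `is_pseudogene` (one row per classified gene).
#' @param species optional character vector fixing the species set and row
#'   order (e.g. the species-tree tip order); defaults to the species seen
#'   in `calls`.
#' @param assembly_complete named logical vector per species; default all
#'   `TRUE`.
#' @return data.frame with columns `species`, `family`, `n_intact`,
#'   `n_pseudo`, `status` (`present`, `pseudogene_only`, `lost`,
#'   `not_found`).
#' @export
build_repertoire_table <- function(calls, species = NULL,
                                   assembly_complete = NULL) {
  fams <- sort(unique(calls$family))
  if (is.null(species)) species <- sort(unique(calls$species))
  if (is.null(assembly_complete)) {
    assembly_complete <- setNames(rep(TRUE, length(species)), species)
  }
  rows <- list()
  for (sp in species) for (fam in fams) {
    sub <- calls[calls$species == sp & calls$family == fam, , drop = FALSE]
    ni <- sum(!sub$is_pseudogene)
    np <- sum(sub$is_pseudogene)
    status <- if (ni > 0) "present" else if (np > 0) "pseudogene_only"
      else if (isTRUE(assembly_complete[[sp]])) "lost" else "not_found"
    rows[[length(rows) + 1L]] <- data.frame(
      species = sp, family = fam, n_intact = ni, n_pseudo = np,
      status = status)
  }
  do.call(rbind, rows)
}
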