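#' Configuration for the gene-family evolver
#'
#' Defaults describe the scenario the package is built around: a ~1.4 kb
#' single-exon coding gene (472 codons), an ancient duplication predating the
#' species-tree root, purifying selection on intact copies, and recurrent
#' non-reciprocal 5' gene conversion with a shared breakpoint about
#' two-thirds of the way through the gene (codon 316 = nucleotide 948).
#'
#' @param gene_length_codons gene length in codons (default 472, ~1.4 kb).
#' @param kappa HKY85 transition/transversion rate ratio.
#' @param base_freqs stationary base frequencies (A, C, G, T).
#' @param omega nonsynonymous acceptance probability in (0, 1] for intact
#'   genes; pseudogenes always evolve with omega = 1.
#' @param dup_time time (substitutions/site) by which the ancestral
#'   duplication predates the species-tree root: both paralogs evolve
#'   independently for `dup_time` before reaching the root.
#' @param conversion_rate expected number of conversion events per branch
#'   (Poisson), drawn only on branches carrying at least two loci.
#' @param conversion_breakpoint codon index b; the converted tract is codons
#'   `[0, b)`, i.e. nucleotides `[0, 3b)` (0-based, half-open). Default
#'   `NULL` places it two-thirds of the way through the gene (codon 316 =
#'   nucleotide 948 for the default 472-codon gene).
#' @param jitter_nt half-width of uniform integer noise added to the tract
#'   end per event (the breakpoint is recurrent but not identical).
#' @param loss_rate,pseudo_rate per-branch probabilities of gene loss and of
#'   pseudogenisation (a random frameshift or nonsense lesion after which the
#'   gene evolves neutrally).
#' @param dup_rate expected number of additional lineage-specific
#'   duplications per branch (default 0).
#' @param locus_names names for the two ancestral paralogs.
#' @param seed integer seed recorded in the event log; `NULL` uses the
#'   current RNG state.
#' @return validated list of class `evolver_config`.
#' @export
evolver_config <- function(gene_length_codons = 472, kappa = 4,
                           base_freqs = c(0.3, 0.2, 0.2, 0.3), omega = 0.2,
                           dup_time = 0.5, conversion_rate = 0.15,
                           conversion_breakpoint = NULL, jitter_nt = 0,
                           loss_rate = 0.02, pseudo_rate = 0.02,
                           dup_rate = 0, locus_names = c("L1", "L2"),
                           seed = NULL) {
  if (is.null(conversion_breakpoint)) {
    conversion_breakpoint <- max(1L, round(gene_length_codons * 316 / 472))
  }
  cfg <- list(gene_length_codons = gene_length_codons, kappa = kappa,
              base_freqs = base_freqs / sum(base_freqs), omega = omega,
              dup_time = dup_time, conversion_rate = conversion_rate,
              conversion_breakpoint = conversion_breakpoint,
              jitter_nt = jitter_nt, loss_rate = loss_rate,
              pseudo_rate = pseudo_rate, dup_rate = dup_rate,
              locus_names = locus_names, seed = seed)
  if (gene_length_codons < 1) stop("gene_length_codons must be positive")
  if (conversion_breakpoint <= 0 ||
      conversion_breakpoint >= gene_length_codons) {
    stop("conversion_breakpoint must lie strictly inside the gene (0, ",
         gene_length_codons, ")")
  }
  stopifnot(kappa > 0, all(base_freqs > 0), omega > 0, omega <= 1,
            dup_time >= 0, conversion_rate >= 0, jitter_nt >= 0,
            loss_rate >= 0, loss_rate <= 1, pseudo_rate >= 0,
            pseudo_rate <= 1, dup_rate >= 0, length(locus_names) == 2)
  class(cfg) <- "evolver_config"
  cfg
}

#' Forward-simulate a gene family along a species tree
#'
#' An ancestral gene duplicates `dup_time` substitutions/site before the
#' species-tree root; both copies then descend the tree, accumulating HKY85
#' substitutions (nonsynonymous changes thinned by `omega`), and on each
#' branch optionally suffer loss, pseudogenisation, lineage-specific
#' duplication, and non-reciprocal gene conversion in which the donor's
#' current 5' tract overwrites the recipient's. Every event is recorded in a
#' ground-truth log sufficient to reconstruct the true gene tree.
#'
#' @param tree rooted `phylo` species tree with branch lengths in
#'   substitutions/site (neutral scale) and unique tip labels.
#' @param cfg an [evolver_config()].
#' @param plant_conversions optional data.frame with columns `species`,
#'   `donor`, `recipient`, `time_frac` planting deterministic conversion
#'   events on terminal branches (at `time_frac` of the branch, from its
#'   start) in addition to the Poisson process -- used for ground-truthed
#'   benchmarks with a known number of conversions.
#' @param record_snapshots logical; if `TRUE`, a copy of donor and recipient
#'   sequences immediately after each conversion is attached to the event
#'   log (`attr(log, "snapshots")`) so tract edits can be audited.
#' @return list with elements `records` (gene records, ids
#'   `species|locus|group`) and `log` (event data.frame with attributes
#'   `seed`, `config`, and optionally `snapshots`).
#' @export
simulate_family <- function(tree, cfg = evolver_config(),
                            plant_conversions = NULL,
                            record_snapshots = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("species tree must be rooted")
  if (length(tree$tip.label) < 2) stop("species tree needs >= 2 leaves")
  if (anyDuplicated(tree$tip.label)) stop("species names must be unique")
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    stop("species tree needs non-negative branch lengths")
  }
  if (!inherits(cfg, "evolver_config")) cfg <- do.call(evolver_config, cfg)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  L_nt <- 3L * cfg$gene_length_codons
  events <- list()
  snapshots <- list()
  add_event <- function(type, lineage, time, locus = NA, donor = NA,
                        recipient = NA, tract_start = NA, tract_end = NA,
                        detail = NA) {
    events[[length(events) + 1L]] <<- data.frame(
      type = type, lineage = lineage, time = time, locus = locus,
      donor_locus = donor, recipient_locus = recipient,
      tract_start = tract_start, tract_end = tract_end, detail = detail,
      stringsAsFactors = FALSE)
  }

  # ancestral gene and the root-predating duplication
  g0 <- stationary_cds(cfg$gene_length_codons, cfg$base_freqs)
  add_event("duplication", "stem", -cfg$dup_time,
            donor = "ancestor", recipient = paste(cfg$locus_names,
                                                  collapse = "+"))
  mk_gene <- function(locus, group, seq) {
    list(locus = locus, group = group, seq = seq, pseudo = FALSE)
  }
  root_state <- lapply(cfg$locus_names, function(nm) {
    mk_gene(nm, nm, evolve_sequence(g0, cfg$dup_time, cfg$kappa,
                                    cfg$base_freqs, cfg$omega))
  })

  tree <- stats::reorder(tree) # cladewise: parents before children
  nnode <- max(tree$edge)
  states <- vector("list", nnode)
  root <- tree$edge[1, 1]
  states[[root]] <- root_state
  evolve_gene <- function(g, dt) {
    if (dt <= 0) return(g)
    om <- if (g$pseudo) 1 else cfg$omega
    g$seq <- evolve_sequence(g$seq, dt, cfg$kappa, cfg$base_freqs, om)
    g
  }

  for (e in seq_len(nrow(tree$edge))) {
    u <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    t_br <- tree$edge.length[e]
    is_tip <- v <= length(tree$tip.label)
    lin <- if (is_tip) tree$tip.label[v] else paste0("node", v)
    st <- states[[u]]

    # losses (applied at branch start; time drawn for the record only)
    if (cfg$loss_rate > 0 && length(st) > 0) {
      lost <- runif(length(st)) < cfg$loss_rate
      for (i in which(lost)) {
        add_event("loss", lin, runif(1, 0, t_br), locus = st[[i]]$locus)
      }
      st <- st[!lost]
    }

    # plan the remaining events on this branch
    plan <- list()
    if (cfg$pseudo_rate > 0) {
      for (i in seq_along(st)) {
        if (!st[[i]]$pseudo && runif(1) < cfg$pseudo_rate) {
          plan[[length(plan) + 1L]] <- list(time = runif(1, 0, t_br),
                                            type = "pseudogenization",
                                            locus = st[[i]]$locus)
        }
      }
    }
    if (cfg$conversion_rate > 0 && length(st) >= 2) {
      n_conv <- rpois(1L, cfg$conversion_rate)
      for (k in seq_len(n_conv)) {
        pair <- sample(seq_along(st), 2L)
        plan[[length(plan) + 1L]] <- list(time = runif(1, 0, t_br),
                                          type = "conversion",
                                          donor = st[[pair[1]]]$locus,
                                          recipient = st[[pair[2]]]$locus)
      }
    }
    if (cfg$dup_rate > 0 && length(st) >= 1) {
      n_dup <- rpois(1L, cfg$dup_rate)
      for (k in seq_len(n_dup)) {
        plan[[length(plan) + 1L]] <- list(time = runif(1, 0, t_br),
                                          type = "duplication",
                                          locus = st[[sample(seq_along(st),
                                                             1L)]]$locus)
      }
    }
    if (!is.null(plant_conversions) && is_tip) {
      pc <- plant_conversions[plant_conversions$species == lin, ,
                              drop = FALSE]
      for (k in seq_len(nrow(pc))) {
        plan[[length(plan) + 1L]] <- list(time = pc$time_frac[k] * t_br,
                                          type = "conversion",
                                          donor = pc$donor[k],
                                          recipient = pc$recipient[k])
      }
    }
    if (length(plan) > 1) plan <- plan[order(vapply(plan, `[[`, 0, "time"))]

    cur <- 0
    locus_of <- function(state, nm) {
      idx <- which(vapply(state, `[[`, "", "locus") == nm)
      if (length(idx) == 0L) NA_integer_ else idx[1]
    }
    for (ev in plan) {
      dt <- ev$time - cur
      st <- lapply(st, evolve_gene, dt = dt)
      cur <- ev$time
      if (ev$type == "pseudogenization") {
        i <- locus_of(st, ev$locus)
        if (is.na(i) || st[[i]]$pseudo) next
        st[[i]] <- apply_lesion(st[[i]], lin, ev$time, add_event)
      } else if (ev$type == "conversion") {
        di <- locus_of(st, ev$donor); ri <- locus_of(st, ev$recipient)
        if (is.na(di) || is.na(ri) || di == ri) next
        tract_end <- 3L * cfg$conversion_breakpoint
        if (cfg$jitter_nt > 0) {
          tract_end <- tract_end + sample(-cfg$jitter_nt:cfg$jitter_nt, 1L)
        }
        tract_end <- max(3L, min(tract_end, nchar(st[[di]]$seq),
                                 nchar(st[[ri]]$seq)))
        st[[ri]]$seq <- paste0(substr(st[[di]]$seq, 1L, tract_end),
                               substr(st[[ri]]$seq, tract_end + 1L,
                                      nchar(st[[ri]]$seq)))
        add_event("conversion", lin, ev$time, donor = st[[di]]$locus,
                  recipient = st[[ri]]$locus, tract_start = 0L,
                  tract_end = tract_end)
        # a tract copied from a pseudogene donor can import a lesion:
        # an intact recipient left with an in-frame stop is pseudogenised
        if (!st[[ri]]$pseudo && (nchar(st[[ri]]$seq) %% 3L != 0L ||
                                 has_internal_stop(st[[ri]]$seq))) {
          st[[ri]]$pseudo <- TRUE
          add_event("pseudogenization", lin, ev$time,
                    locus = st[[ri]]$locus, detail = "conversion_imported")
        }
        if (record_snapshots) {
          snapshots[[length(snapshots) + 1L]] <- list(
            lineage = lin, time = ev$time, donor = st[[di]]$locus,
            recipient = st[[ri]]$locus, tract_end = tract_end,
            donor_seq = st[[di]]$seq, recipient_seq = st[[ri]]$seq)
        }
      } else if (ev$type == "duplication") {
        i <- locus_of(st, ev$locus)
        if (is.na(i)) next
        existing <- vapply(st, `[[`, "", "locus")
        k <- 2L
        while (paste0(ev$locus, ".", k) %in% existing) k <- k + 1L
        newname <- paste0(ev$locus, ".", k)
        g <- st[[i]]
        g$locus <- newname
        st[[length(st) + 1L]] <- g
        add_event("duplication", lin, ev$time, donor = ev$locus,
                  recipient = newname)
      }
    }
    st <- lapply(st, evolve_gene, dt = t_br - cur)
    states[[v]] <- st
  }

  recs <- list()
  for (v in seq_along(tree$tip.label)) {
    for (g in states[[v]]) {
      recs[[length(recs) + 1L]] <- data.frame(
        species = tree$tip.label[v], locus = g$locus, seq = g$seq,
        is_pseudogene = g$pseudo, group = g$group, stringsAsFactors = FALSE)
    }
  }
  recs <- do.call(rbind, recs)
  records <- gene_records(species = recs$species, locus = recs$locus,
                          seq = recs$seq,
                          id = paste(recs$species, recs$locus, recs$group,
                                     sep = "|"),
                          is_pseudogene = recs$is_pseudogene,
                          group = recs$group)

  log <- if (length(events)) do.call(rbind, events) else
    data.frame(type = character(0), lineage = character(0),
               time = numeric(0), locus = character(0),
               donor_locus = character(0), recipient_locus = character(0),
               tract_start = integer(0), tract_end = integer(0),
               detail = character(0))
  attr(log, "seed") <- cfg$seed
  attr(log, "config") <- cfg
  if (record_snapshots) attr(log, "snapshots") <- snapshots
  list(records = records, log = log)
}

# random inactivating lesion: 1-nt frameshift (insertion or deletion) or a
# premature stop codon; the gene evolves neutrally afterwards
apply_lesion <- function(g, lin, time, add_event) {
  L <- nchar(g$seq)
  n_cod <- L %/% 3L
  if (runif(1) < 0.5 || n_cod < 32L) {
    pos <- sample.int(L - 1L, 1L)
    if (runif(1) < 0.5) {
      ins <- sample(.NUC, 1L)
      g$seq <- paste0(substr(g$seq, 1L, pos), ins,
                      substr(g$seq, pos + 1L, L))
      add_event("pseudogenization", lin, time, locus = g$locus,
                detail = paste0("frameshift_ins@", pos))
    } else {
      g$seq <- paste0(substr(g$seq, 1L, pos - 1L),
                      substr(g$seq, pos + 1L, L))
      add_event("pseudogenization", lin, time, locus = g$locus,
                detail = paste0("frameshift_del@", pos))
    }
  } else {
    ci <- sample(15:(n_cod - 16L), 1L) # leave a detectable truncation
    stopc <- sample(c("TAA", "TAG", "TGA"), 1L)
    substr(g$seq, 3L * ci + 1L, 3L * ci + 3L) <- stopc
    add_event("pseudogenization", lin, time, locus = g$locus,
              detail = paste0("nonsense@codon", ci))
  }
  g$pseudo <- TRUE
  g
}

#' Random ultrametric species tree for simulations
#'
#' Pure-birth (Yule) topology -- the standard null for species
#' diversification, whose internal edges stay resolvable, unlike a
#' single-population coalescent whose deep edges collapse -- rescaled to a
#' given root-to-tip depth on the neutral substitutions/site scale.
#'
#' @param n_species number of leaves; labelled `sp01`, `sp02`, ...
#' @param depth root-to-tip path length (substitutions/site).
#' @return rooted ultrametric `phylo`.
#' @export
sim_species_tree <- function(n_species, depth = 0.3) {
  tr <- ape::rphylo(n_species, birth = 1, death = 0)
  tr$tip.label <- sprintf("sp%02d", seq_len(n_species))
  h <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * depth / h
  tr
}

#' True gene tree implied by a simulation
#'
#' Reconstructs the expected gene-tree topology from the simulator output:
#' one copy of the species tree per surviving ortholog group, joined at the
#' ancestral duplication; lineage-specific duplicates form within-species
#' clades. Conversion events do not alter the true tree (conversion
#' homogenises sequence, not ancestry).
#'
#' @param tree the species tree used for the simulation.
#' @param records the simulated gene records (with `group` column).
#' @return rooted `phylo` with the gene record ids as tip labels.
#' @export
true_gene_tree <- function(tree, records) {
  stopifnot(!is.null(records$group))
  groups <- unique(records$group)
  sub_nwk <- function(group) {
    recs <- records[records$group == group, , drop = FALSE]
    build <- function(node) {
      if (node <= length(tree$tip.label)) {
        ids <- recs$id[recs$species == tree$tip.label[node]]
        if (length(ids) == 0) return(NULL)
        if (length(ids) == 1) return(ids)
        return(paste0("(", paste(ids, collapse = ","), ")"))
      }
      kids <- tree$edge[tree$edge[, 1] == node, 2]
      parts <- Filter(Negate(is.null), lapply(kids, build))
      if (length(parts) == 0) return(NULL)
      if (length(parts) == 1) return(parts[[1]])
      paste0("(", paste(unlist(parts), collapse = ","), ")")
    }
    build(tree$edge[1, 1])
  }
  parts <- Filter(Negate(is.null), lapply(groups, sub_nwk))
  if (length(parts) < 1) stop("no surviving genes")
  txt <- if (length(parts) == 1) paste0(parts[[1]], ";") else
    paste0("(", paste(unlist(parts), collapse = ","), ");")
  ape::read.tree(text = txt)
}

#' Simulate a cat-style converted paralog pair
#'
#' Two paralogs diverge for `divergence` substitutions/site in total, the 5'
#' tract of one is then overwritten by the other (non-reciprocal
#' conversion), and both accumulate a further `residual` substitutions/site.
#' With the defaults the pair reproduces the signature this package is built
#' to detect: ~97% identity 5' of the breakpoint (nucleotide 948 of 1416)
#' and ~63% identity 3' of it, ~86% whole-gene.
#'
#' @param divergence total pre-conversion paralog divergence
#'   (substitutions/site on the neutral scale; default 1.6, calibrated so the realized 3' identity matches the printed cat value).
#' @param residual total post-conversion divergence (default 0.08).
#' @param conversion_breakpoint codon index of the tract end (default 316).
#' @param gene_length_codons,kappa,base_freqs,omega as [evolver_config()].
#' @param species species name used in the record ids.
#' @return list with `records` (two gene records) and `breakpoint_nt`
#'   (true tract end, 0-based alignment nucleotide).
#' @export
simulate_conversion_pair <- function(divergence = 1.6, residual = 0.08,
                                     conversion_breakpoint = 316,
                                     gene_length_codons = 472, kappa = 4,
                                     base_freqs = c(0.3, 0.2, 0.2, 0.3),
                                     omega = 0.2, species = "spA") {
  g0 <- stationary_cds(gene_length_codons, base_freqs)
  a <- evolve_sequence(g0, divergence / 2, kappa, base_freqs, omega)
  b <- evolve_sequence(g0, divergence / 2, kappa, base_freqs, omega)
  bp <- 3L * conversion_breakpoint
  b <- paste0(substr(a, 1L, bp), substr(b, bp + 1L, nchar(b)))
  a <- evolve_sequence(a, residual / 2, kappa, base_freqs, omega)
  b <- evolve_sequence(b, residual / 2, kappa, base_freqs, omega)
  recs <- gene_records(species = species, locus = c("L1", "L2"),
                       seq = c(a, b))
  list(records = recs, breakpoint_nt = bp)
}
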