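#' Run the full analysis pipeline
#'
#' Chains the stages simulate (or load) -> align -> pairwise scan ->
#' breakpoint scan -> region trees (full / 5' / 3') -> classification, and
#' writes every stage's outputs plus a JSON manifest (parameters, file
#' hashes, seeds, wall times) under `out_dir`. Stages whose inputs are
#' unchanged (matching stamp hash) are resumed from their cached outputs.
#'
#' The configuration is a nested list (or path to a YAML file) with keys:
#' \describe{
#'   \item{out_dir}{output directory.}
#'   \item{seed}{integer; threaded through simulation, scans, bootstrap.}
#'   \item{input}{either `list(fasta = path)` or `list(simulate =
#'     list(n_species =, depth =, config = <evolver_config args>))`.}
#'   \item{align}{optional `list(external = path)` to override the
#'     aligner with a curated alignment.}
#'   \item{breakscan}{optional `list(grid_nt =, min_segment =, n_perm =)`.}
#'   \item{regions}{optional `list(five_prime = c(s,e), three_prime =
#'     c(s,e))`; default split at the breakpoint scan's best position.}
#'   \item{trees}{optional `list(bootstrap = B)`; B = 0 skips supports.}
#'   \item{classify}{optional `list(exemplar_species = name, min_delta =)`.}
#' }
#'
#' @param config nested list or path to a YAML file.
#' @return the manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  stopifnot(!is.null(cfg$out_dir))
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  manifest <- list(config = cfg, seed = seed, stages = list())
  t_all <- proc.time()[["elapsed"]]

  stage <- function(name, inputs, outputs, fun) {
    stamp <- file.path(out, paste0(".stamp_", name, ".json"))
    in_hash <- stage_hash(inputs)
    if (file.exists(stamp) && all(file.exists(outputs))) {
      old <- tryCatch(jsonlite::read_json(stamp), error = function(e) NULL)
      if (!is.null(old) && identical(old$hash, in_hash)) {
        manifest$stages[[name]] <<- list(cached = TRUE, outputs = outputs,
                                         hash = in_hash)
        return(invisible(NULL))
      }
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
    secs <- proc.time()[["elapsed"]] - t0
    jsonlite::write_json(list(hash = in_hash), stamp, auto_unbox = TRUE)
    manifest$stages[[name]] <<- list(
      cached = FALSE, outputs = outputs,
      output_md5 = unname(tools::md5sum(outputs[file.exists(outputs)])),
      hash = in_hash, seconds = round(secs, 2))
    invisible(res)
  }

  ## 1. input: simulate or load -------------------------------------------
  fam_fa <- file.path(out, "family.fasta")
  log_tsv <- file.path(out, "eventlog.tsv")
  true_nwk <- file.path(out, "true_tree.nwk")
  if (!is.null(cfg$input$simulate)) {
    sim_cfg <- cfg$input$simulate
    stage("simulate", list(sim_cfg, seed), c(fam_fa, log_tsv, true_nwk),
          function() {
      set.seed(seed)
      tree <- if (!is.null(sim_cfg$tree)) ape::read.tree(sim_cfg$tree) else
        sim_species_tree(sim_cfg$n_species %||% 12,
                         sim_cfg$depth %||% 0.3)
      ecfg <- do.call(evolver_config, c(sim_cfg$config, list(seed = seed)))
      sim <- simulate_family(tree, ecfg)
      write_gene_fasta(sim$records, fam_fa)
      write.table(sim$log, log_tsv, sep = "\t", row.names = FALSE,
                  quote = FALSE)
      ape::write.tree(true_gene_tree(tree, sim$records), true_nwk)
      ape::write.tree(tree, file.path(out, "species_tree.nwk"))
    })
  } else if (!is.null(cfg$input$fasta)) {
    fam_fa <- cfg$input$fasta
  } else stop("config$input must provide either $simulate or $fasta")
  records <- read_gene_fasta(fam_fa)

  ## 2. align ---------------------------------------------------------------
  aln_fa <- file.path(out, "family.aln.fasta")
  stage("align", list(tools::md5sum(fam_fa), cfg$align), aln_fa, function() {
    aln <- align_family_codon(records, external = cfg$align$external)
    write_gene_fasta(data.frame(id = names(aln$seqs), seq = unname(aln$seqs)),
                     aln_fa)
  })
  aln_rec <- read_gene_fasta(aln_fa, gapped = TRUE)
  ord <- match(records$id, aln_rec$id)
  aln <- codon_aln(setNames(aln_rec$seq[ord], records$id),
                   records[, c("id", "species", "locus", "is_pseudogene")])
  L <- aln_length(aln)

  ## 3. breakpoint scan ------------------------------------------------------
  bs <- cfg$breakscan
  scan_json <- file.path(out, "breakscan.json")
  scan_tsv <- file.path(out, "breakscan_candidates.tsv")
  stage("breakscan", list(tools::md5sum(aln_fa), bs, seed),
        c(scan_json, scan_tsv), function() {
    scan <- scan_single_breakpoint(
      aln, grid_nt = bs$grid_nt %||% 60,
      min_segment = bs$min_segment %||% 300,
      n_perm = bs$n_perm %||% 99, seed = seed)
    write.table(scan$candidates, scan_tsv, sep = "\t", row.names = FALSE,
                quote = FALSE)
    jsonlite::write_json(list(
      best_position = scan$best_position,
      model_averaged_support = scan$model_averaged_support,
      p_value = scan$p_value, weight_single = scan$weight_single),
      scan_json, auto_unbox = TRUE, digits = NA)
    ape::write.tree(scan$fit_left$tree, file.path(out, "tree_left.nwk"))
    ape::write.tree(scan$fit_right$tree, file.path(out, "tree_right.nwk"))
  })
  scan_info <- jsonlite::read_json(scan_json)
  bp <- scan_info$best_position

  ## regions ----------------------------------------------------------------
  r5 <- unlist(cfg$regions$five_prime %||% c(0, bp))
  r3 <- unlist(cfg$regions$three_prime %||% c(bp, L))
  if (identical(r5, r3)) stop("5' and 3' regions are identical")

  ## 4. pairwise scans of within-species locus pairs -------------------------
  pair_tsv <- file.path(out, "pairscan.tsv")
  stage("pairscan", list(tools::md5sum(aln_fa), r5, r3), pair_tsv,
        function() {
    rows <- list()
    for (sp in unique(records$species)) {
      ids <- records$id[records$species == sp]
      if (length(ids) < 2) next
      prs <- utils::combn(ids, 2)
      for (k in seq_len(ncol(prs))) {
        a <- prs[1, k]; b <- prs[2, k]
        cp <- tryCatch(identity_changepoint(aln, a, b),
                       error = function(e) NULL)
        rows[[length(rows) + 1L]] <- data.frame(
          species = sp, id_a = a, id_b = b,
          identity_whole = percent_identity(aln, a, b),
          identity_5p = percent_identity(aln, a, b, r5),
          identity_3p = percent_identity(aln, a, b, r3),
          dS_5p = ng86_ds(aln, a, b, r5)$dS,
          dS_3p = ng86_ds(aln, a, b, r3)$dS,
          changepoint = if (is.null(cp)) NA else cp$position_nt)
      }
    }
    tab <- if (length(rows)) do.call(rbind, rows) else
      data.frame(species = character(0))
    write.table(tab, pair_tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  })

  ## 5. region trees ----------------------------------------------------------
  B <- cfg$trees$bootstrap %||% 100
  tree_files <- file.path(out, c("tree_full.nwk", "tree_5p.nwk",
                                 "tree_3p.nwk"))
  stage("trees", list(tools::md5sum(aln_fa), r5, r3, B, seed), tree_files,
        function() {
    fits <- list(full = c(0, L), `5p` = r5, `3p` = r3)
    for (i in seq_along(fits)) {
      fit <- if (B > 0) {
        bootstrap_tree(aln, region = fits[[i]], B = B, seed = seed + i)
      } else fit_tree(aln, region = fits[[i]])
      ape::write.tree(fit$tree, tree_files[i])
      jsonlite::write_json(
        list(loglik = fit$loglik, kappa = fit$kappa,
             freqs = as.numeric(fit$freqs)),
        sub("\\.nwk$", ".json", tree_files[i]), auto_unbox = TRUE,
        digits = NA)
    }
  })

  ## 6. classify ---------------------------------------------------------------
  cls <- cfg$classify
  calls_json <- file.path(out, "conversion_calls.json")
  rep_tsv <- file.path(out, "repertoire.tsv")
  assign_tsv <- file.path(out, "assignments.tsv")
  stage("classify", list(tools::md5sum(unlist(tree_files)), cls, r5, r3),
        c(calls_json, rep_tsv, assign_tsv), function() {
    t5 <- ape::read.tree(tree_files[2])
    t3 <- ape::read.tree(tree_files[3])
    ex_sp <- cls$exemplar_species %||% exemplar_species_default(records)
    ex_ids <- records$id[records$species == ex_sp & !records$is_pseudogene]
    exemplars <- setNames(records$locus[match(ex_ids, records$id)], ex_ids)
    asg <- assign_families(structure(list(tree = t3), class = "hky_fit"),
                           exemplars)
    asg$species <- records$species[match(asg$id, records$id)]
    asg$is_pseudogene <- records$is_pseudogene[match(asg$id, records$id)]
    write.table(asg, assign_tsv, sep = "\t", row.names = FALSE,
                quote = FALSE)
    conv <- call_conversions(structure(list(tree = t5), class = "hky_fit"),
                             structure(list(tree = t3), class = "hky_fit"),
                             aln, breakpoint = r3[1],
                             min_delta = cls$min_delta %||% 10)
    jsonlite::write_json(conv, calls_json, dataframe = "rows", digits = NA)
    rep <- build_repertoire_table(
      data.frame(species = asg$species, family = asg$family,
                 is_pseudogene = asg$is_pseudogene))
    write.table(rep, rep_tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  })

  manifest$seconds_total <- round(proc.time()[["elapsed"]] - t_all, 2)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                      auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_hash <- function(inputs) {
  digest_input <- paste(utils::capture.output(utils::str(inputs)),
                        collapse = "\n")
  tf <- tempfile()
  writeLines(digest_input, tf)
  unname(tools::md5sum(tf))
}

exemplar_species_default <- function(records) {
  tab <- table(records$species[!records$is_pseudogene])
  names(tab)[which.max(tab)]
}

#' Pairwise identity/dS panel
#'
#' ggplot2 rendering of a [window_scan()] track in the style of a pairwise
#' conversion panel: per-window identity (top), dS with saturated windows
#' capped at 3 (bottom), and an arrow marking a breakpoint.
#'
#' @param track a `window_track`.
#' @param breakpoint optional 0-based column position to mark.
#' @param ds_cap display cap for saturated/large dS values.
#' @return a ggplot object.
#' @export
plot_pair_panel <- function(track, breakpoint = NULL, ds_cap = 3) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  df <- as.data.frame(track)
  df$mid <- (df$start + df$end) / 2
  df$dS_plot <- pmin(df$dS, ds_cap)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = mid)) +
    ggplot2::geom_line(ggplot2::aes(y = identity / 100 * ds_cap),
                       colour = "grey30") +
    ggplot2::geom_segment(ggplot2::aes(x = start, xend = end, y = dS_plot,
                                       yend = dS_plot), colour = "red") +
    ggplot2::scale_y_continuous(
      name = "dS (red)", limits = c(0, ds_cap),
      sec.axis = ggplot2::sec_axis(~ . / ds_cap * 100,
                                   name = "% identity (grey)")) +
    ggplot2::labs(x = "alignment position (nt)") +
    ggplot2::theme_minimal()
  if (!is.null(breakpoint)) {
    p <- p + ggplot2::geom_vline(xintercept = breakpoint, colour = "red",
                                 linetype = 2)
  }
  p
}
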