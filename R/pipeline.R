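# End-to-end orchestration: classify -> typical enhancers -> targets ->
# enrichment -> methylation -> signal loss, over one dataset (in-memory
# list or a directory written by write_dataset()), with a machine-readable
# report.

#' Run the full eCGI workflow on one dataset
#'
#' Executes every stage on a dataset in the shape produced by
#' [generate_dataset()] / [read_dataset()] and returns a structured report:
#' per-class CGI counts, typical-enhancer count, target assignments and
#' multiplicity, eCGI-vs-typical-enhancer interaction-strength contrast,
#' regulator permutation test, hypermethylated-eCGI selection, eCGI-vs-pCGI
#' methylation contrast, target silencing, enhancer-mark signal loss and
#' TSG/oncogene Fisher enrichment. Every random step (the permutation test)
#' is driven by `seed`.
#'
#' @param dataset Dataset list, or a directory path for [read_dataset()].
#' @param flank Promoter half-width in bp (default 1000).
#' @param min_tags ChIA-PET tag-count filter (default 3).
#' @param n_perm Permutations for the regulator test (default 1000).
#' @param dm_threshold Hypermethylation threshold on mean region dm
#'   (default 0.5, the cell-line contrast threshold; use 0.1 for clinical
#'   group-mean contrasts).
#' @param seed Integer seed for the permutation stage.
#' @param stages Character vector of optional stages to run; default all of
#'   `"enrichment"`, `"methylation"`, `"signal"`.
#' @return List of per-stage results plus a `summary` list of scalar
#'   quantities; see the individual stage functions for field meanings.
#' @export
run_pipeline <- function(dataset, flank = 1000, min_tags = 3, n_perm = 1000,
                         dm_threshold = 0.5, seed = 1,
                         stages = c("enrichment", "methylation", "signal")) {
  if (is.character(dataset)) dataset <- read_dataset(dataset)
  for (nm in c("cgis", "genes", "h3k27ac_peaks", "dhs_peaks", "cage_tss",
               "denovo_tss")) {
    if (is.null(dataset[[nm]]))
      stop("configuration error: dataset is missing required input '",
           nm, "'")
  }
  report <- list()

  # -- classification -------------------------------------------------------
  classified <- classify_cgis(dataset$cgis, dataset$genes,
                              dataset$h3k27ac_peaks, dataset$dhs_peaks,
                              dataset$cage_tss, dataset$denovo_tss, flank)
  class_counts <- table(classified$label)
  typical <- call_typical_enhancers(dataset$h3k27ac_peaks, dataset$dhs_peaks,
                                    dataset$cage_tss, dataset$denovo_tss,
                                    dataset$cgis, flank)
  report$classification <- list(cgis = classified,
                                class_counts = c(class_counts),
                                typical_enhancers = typical)
  ecgis <- classified[classified$label == "eCGI", , drop = FALSE]
  ecgis$name <- ecgis$cgi_id

  # -- targets --------------------------------------------------------------
  flinks <- if (!is.null(dataset$links))
    filter_links(dataset$links, min_tags) else NULL
  ecgi_assign <- NULL
  if (!is.null(flinks) && nrow(ecgis)) {
    ecgi_assign <- assign_targets(ecgis, flinks, dataset$genes, flank)
    typ_named <- typical
    typ_named$name <- typical$source_peak_id
    typ_assign <- assign_targets(typ_named, flinks, dataset$genes, flank)
    report$targets <- list(
      ecgi = ecgi_assign, typical = typ_assign,
      multiplicity = if (nrow(ecgi_assign)) target_multiplicity(ecgi_assign),
      link_strength = if (nrow(ecgi_assign) && nrow(typ_assign))
        compare_link_strength(ecgi_assign$tag_count, typ_assign$tag_count))
  }

  # -- regulator permutation enrichment -------------------------------------
  if ("enrichment" %in% stages && !is.null(flinks) && nrow(ecgis) &&
      length(dataset$gene_sets$regulators)) {
    report$regulator_permutation <- permutation_enrichment(
      ecgis, flinks, dataset$genes, dataset$gene_sets$regulators,
      dataset$chrom_sizes, n_perm = n_perm, seed = seed, flank = flank)
  }

  # -- methylation ----------------------------------------------------------
  if ("methylation" %in% stages && !is.null(dataset$beta_normal)) {
    sites <- suppressMessages(
      differential_methylation(dataset$beta_normal, dataset$beta_tumor))
    ecgi_dm <- suppressMessages(aggregate_region_dm(sites, ecgis))
    pcgis <- classified[classified$label == "pCGI", , drop = FALSE]
    pcgis$name <- pcgis$cgi_id
    pcgi_dm <- suppressMessages(aggregate_region_dm(sites, pcgis))
    hyper <- select_hypermethylated(ecgi_dm, dm_threshold)
    meth <- list(ecgi_dm = ecgi_dm, pcgi_dm = pcgi_dm, hyper = hyper,
                 contrast = if (nrow(ecgi_dm) && nrow(pcgi_dm))
                   class_dm_contrast(ecgi_dm, pcgi_dm))
    # target silencing: ChIA evidence when links exist, nearest gene
    # otherwise (the fallback used when no interactome is available)
    if (!is.null(dataset$expr_normal) && nrow(hyper)) {
      assign_tbl <- if (!is.null(ecgi_assign) && nrow(ecgi_assign))
        ecgi_assign
      else data.frame(region_id = ecgis$cgi_id,
                      gene_id = nearest_gene(ecgis, dataset$genes),
                      tag_count = NA_real_, evidence = "nearest",
                      stringsAsFactors = FALSE)
      targeted <- assign_tbl$region_id %in% hyper$region_id
      if (any(targeted)) {
        meth$silencing <- target_silencing(
          hyper$region_id, assign_tbl, dataset$expr_normal,
          dataset$expr_tumor)
        hit_genes <- unique(assign_tbl$gene_id[targeted])
        universe <- dataset$genes$gene_id[dataset$genes$coding]
        hit_genes <- intersect(hit_genes, universe)
        if (length(dataset$gene_sets$tsg))
          meth$fisher_tsg <- fisher_enrichment(
            hit_genes, intersect(dataset$gene_sets$tsg, universe), universe)
        if (length(dataset$gene_sets$oncogene))
          meth$fisher_oncogene <- fisher_enrichment(
            hit_genes, intersect(dataset$gene_sets$oncogene, universe),
            universe)
      }
    }
    report$methylation <- meth
    # enhancer-mark loss at hypermethylated eCGIs
    if ("signal" %in% stages && !is.null(dataset$coverage) &&
        nrow(hyper) >= 2) {
      hy <- ecgis[ecgis$cgi_id %in% hyper$region_id, , drop = FALSE]
      report$signal_loss <- list(
        dhs = signal_loss_test(hy, dataset$coverage$dhs_normal,
                               dataset$coverage$dhs_tumor),
        h3k27ac = signal_loss_test(hy, dataset$coverage$h3k27ac_normal,
                                   dataset$coverage$h3k27ac_tumor))
    }
  }

  report$summary <- pipeline_summary(report)
  report
}

#' Scalar summary of a pipeline report
#'
#' Flattens the headline quantities of [run_pipeline()] output into a list
#' of scalars suitable for JSON serialization.
#'
#' @param report A [run_pipeline()] result.
#' @return Named list of scalar counts, fractions and p-values.
#' @export
pipeline_summary <- function(report) {
  s <- as.list(report$classification$class_counts)
  names(s) <- paste0("n_", names(s))
  s$n_typical_enhancers <- nrow(report$classification$typical_enhancers)
  if (!is.null(report$targets)) {
    s$n_ecgi_target_pairs <- nrow(report$targets$ecgi)
    if (!is.null(report$targets$multiplicity)) {
      s$fraction_single <- report$targets$multiplicity$fraction_single
      s$fraction_multiple <- report$targets$multiplicity$fraction_multiple
    }
    if (!is.null(report$targets$link_strength))
      s$link_strength_p <- report$targets$link_strength$p_greater
  }
  if (!is.null(report$regulator_permutation)) {
    s$regulator_observed <- report$regulator_permutation$observed
    s$regulator_null_mean <- mean(report$regulator_permutation$null_counts)
    s$regulator_perm_p <- report$regulator_permutation$p_value
  }
  if (!is.null(report$methylation)) {
    m <- report$methylation
    s$n_hyper_ecgis <- nrow(m$hyper)
    if (!is.null(m$contrast)) {
      s$ecgi_median_dm <- m$contrast$median_a
      s$pcgi_median_dm <- m$contrast$median_b
      s$dm_contrast_p <- m$contrast$p_greater
    }
    if (!is.null(m$silencing)) {
      s$median_silencing_fold <- m$silencing$median_fold
      s$silencing_p <- m$silencing$p_down
    }
    if (!is.null(m$fisher_tsg)) s$fisher_tsg_p <- m$fisher_tsg$p_value
    if (!is.null(m$fisher_oncogene))
      s$fisher_oncogene_p <- m$fisher_oncogene$p_value
  }
  if (!is.null(report$signal_loss)) {
    s$dhs_loss_p <- report$signal_loss$dhs$p_value
    s$h3k27ac_loss_p <- report$signal_loss$h3k27ac$p_value
  }
  s
}

#' Write a pipeline report summary as JSON
#' @param report A [run_pipeline()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report$summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
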