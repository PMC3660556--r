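# End-to-end orchestration: filter cascade, spectrum and summary statistics,
# depth calibration, catalogue and curated-list screens, gene-level
# copy-number calls and the de novo recurrence screen, bundled into one
# report with a reproducibility manifest.

#' Run the full characterization pipeline
#'
#' Executes every stage on a cohort bundle (in memory from
#' [generate_cohort()], or a directory written by [write_cohort()]): HQ-SNV
#' filtering, per-sample summary and substitution spectrum, WES-vs-array
#' concordance with depth-threshold selection, catalogue matching, curated
#' list screening with per-class NS/S counts, special-state annotation,
#' recurrence and de novo screens, gene-level copy-number calls, catalogue
#' deletion confirmation and compound mutation-plus-loss events. Stage
#' outputs are identical to calling the stage functions individually.
#'
#' @param cohort A `melanoma_cohort` or a directory path.
#' @param config A [scope_config()].
#' @param out_dir Optional directory; when given, all tables are written via
#'   [write_report()].
#' @return An object of class `melanoma_report`: a named list of result
#'   tables plus `manifest`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_variants = 300, array_sites = 150, seed = 3))
#' rep <- run_pipeline(cohort)
#' rep$summary
#' @export
run_pipeline <- function(cohort, config = scope_config(), out_dir = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "melanoma_cohort"))
  config <- as_scope_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  hq <- stage("hq_filter",
              apply_hq_filter(cohort$variants, cohort$genes, cohort$blacklist,
                              config))
  summary_tbl <- stage("summary", build_summary(cohort$variants, hq))
  spectrum_tbl <- stage("spectrum", mutation_spectrum(hq$variants, by_sample = TRUE))

  pairs <- stage("concordance",
                 match_sites(cohort$array_wes, cohort$array_genotypes, config))
  curve <- stage("concordance", concordance_by_depth(pairs))
  depth_threshold <- stage("concordance",
                           suppressWarnings(select_depth_threshold(curve, config)))

  ann <- stage("screen", annotate_states(hq$variants))
  matches <- stage("screen", match_catalogue(ann, cohort$catalogue))
  screened <- stage("screen", screen_curated(ann, cohort$curated_genes))
  class_counts <- stage("screen", curated_class_counts(screened))
  recurrent <- stage("screen",
                     find_recurrent(hq$variants, config$recurrence_min_samples))
  de_novo <- stage("screen",
                   find_de_novo(hq$variants,
                                unique(c(cohort$catalogue$gene_id, cohort$cosmic_deleted)),
                                unique(cohort$curated_genes$gene_id),
                                config$recurrence_min_samples))

  cn_calls <- stage("cna", gene_cn_calls(cohort$genes, cohort$segments, config))
  cosmic_del <- stage("cna", cosmic_deleted_genes(cn_calls, cohort$cosmic_deleted))
  compounds <- stage("cna", compound_events(hq$variants, cn_calls))

  manifest <- list(
    package_version = as.character(packageVersion("melascope")),
    seed = if (!is.null(cohort$spec)) cohort$spec$seed,
    config = unclass(config),
    config_hash = hash(unclass(config)),
    n_samples = length(unique(cohort$variants$sample_id)),
    stage_counts = list(
      variants_in = nrow(cohort$variants),
      hq_snvs = nrow(hq$variants),
      concordance_pairs = nrow(pairs),
      catalogue_matches = sum(matches$matched),
      cn_gene_calls = nrow(cn_calls)
    ),
    depth_threshold = as.integer(depth_threshold)
  )

  report <- structure(list(
    summary = summary_tbl,
    spectrum = spectrum_tbl,
    concordance = curve,
    depth_threshold = as.integer(depth_threshold),
    hq_attrition = hq$attrition,
    hq_variants = hq$variants,
    catalogue_matches = filter(matches, .data$matched),
    curated_screen = screened,
    curated_class_counts = class_counts,
    recurrent_genes = recurrent,
    de_novo_genes = de_novo,
    cn_gene_calls = filter(cn_calls, .data$status != "neutral"),
    cosmic_deleted = cosmic_del$calls,
    compound_events = compounds,
    manifest = manifest
  ), class = "melanoma_report")

  if (!is.null(out_dir)) {
    tables <- report[vapply(report, is.data.frame, TRUE)]
    write_report(c(tables, list(manifest = manifest)), out_dir)
  }
  report
}

#' @export
print.melanoma_report <- function(x, ...) {
  m <- x$manifest
  cat("<melanoma_report>\n")
  cat(sprintf("  samples: %d   variants in: %d   HQ-SNVs: %d\n",
              m$n_samples, m$stage_counts$variants_in, m$stage_counts$hq_snvs))
  cat(sprintf("  depth threshold: %s   catalogue matches: %d   CN calls: %d\n",
              m$depth_threshold, m$stage_counts$catalogue_matches,
              nrow(x$cn_gene_calls)))
  g <- glance.sample_summary(x$summary)
  cat(sprintf("  cohort NS/S: %s (total NS %d / S %d)\n",
              format(g$ns_s), g$total_ns, g$total_s))
  invisible(x)
}

#' @describeIn run_pipeline One-row cohort-level summary of a report.
#' @param x A `melanoma_report`.
#' @param ... Unused.
#' @method glance melanoma_report
#' @export
glance.melanoma_report <- function(x, ...) {
  g <- glance.sample_summary(x$summary)
  dplyr::bind_cols(g, tibble(
    depth_threshold = x$depth_threshold,
    n_catalogue_matches = nrow(x$catalogue_matches),
    n_recurrent = nrow(x$recurrent_genes),
    n_de_novo = nrow(x$de_novo_genes),
    n_compound_events = nrow(x$compound_events)
  ))
}
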