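# The high-quality SNV (HQ-SNV) selection cascade.
#
# Starting from raw per-sample calls, variants are filtered in a fixed stage
# order -- known sites, coding overlap, blacklist, in-house database, read
# depth, call quality, allele fraction -- to a sub-selection of novel,
# highly confident coding variants. The final set is order-independent (the
# stages are conjunctive predicates); the order only shapes the attrition
# accounting.

#' Which variants fall in coding sequence?
#'
#' A position is coding iff it lies within a CDS interval of some gene;
#' intronic positions between CDS blocks of the same gene are not coding.
#' The containing gene (first in gene-model order on ties) is assigned.
#'
#' @param variants Variant tibble.
#' @param genes Gene model tibble.
#' @return The input with columns `coding` (logical) and `gene_id`
#'   (overwritten with the containing gene, `NA` when non-coding).
#' @export
is_coding <- function(variants, genes) {
  cds <- unnest_cds(genes)
  coding <- logical(nrow(variants))
  gene <- rep(NA_character_, nrow(variants))
  for (cur in unique(cds$chrom)) {
    qi <- which(variants$chrom == cur)
    if (length(qi) == 0) next
    ci <- which(cds$chrom == cur)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = variants$pos[qi], width = 1L),
      IRanges::IRanges(start = cds$start[ci], end = cds$end[ci]),
      select = "first"
    )
    hit <- !is.na(hits)
    coding[qi] <- hit
    gene[qi[hit]] <- cds$gene_id[ci][hits[hit]]
  }
  variants$coding <- coding
  variants$gene_id <- gene
  variants
}

#' Which variants fall in blacklisted regions?
#'
#' Blacklist intervals (HLA-like loci, homologous repeated genes) are closed:
#' both boundary positions are inside.
#'
#' @param variants Variant tibble.
#' @param blacklist Tibble with `chrom`, `start`, `end` (1-based inclusive),
#'   or `NULL` for an empty blacklist.
#' @return Logical vector, one element per variant.
#' @export
in_blacklist <- function(variants, blacklist) {
  if (is.null(blacklist) || nrow(blacklist) == 0) {
    return(logical(nrow(variants)))
  }
  positions_in_regions(variants$chrom, variants$pos, blacklist)
}

#' Classify zygosity from the allele fraction
#'
#' Nominal allele fractions are 0.5 for heterozygous and 1 for homozygous
#' calls; observed fractions are noisy, so a single configurable cutoff is
#' used: homozygous iff `af >= hom_af_cutoff`.
#'
#' @param af Numeric vector of allele fractions.
#' @param config A [scope_config()].
#' @return Character vector, `"heterozygous"` or `"homozygous"`.
#' @export
classify_zygosity <- function(af, config = scope_config()) {
  config <- as_scope_config(config)
  ifelse(af >= config$hom_af_cutoff, "homozygous", "heterozygous")
}

HQ_STAGES <- c("known", "coding", "blacklist", "in_house", "depth", "quality", "af")

hq_stage_keep <- function(variants, stage, blacklist, config) {
  switch(stage,
    known = !variants$known,
    coding = variants$coding & variants$consequence %in% CODING_CONSEQUENCES,
    blacklist = !in_blacklist(variants, blacklist),
    in_house = !variants$in_house,
    depth = variants$depth >= config$min_depth,   # minimum depth is inclusive
    quality = variants$quality > config$min_quality,  # strictly above
    af = variants$af > config$min_af                  # strictly above
  )
}

#' Apply the HQ-SNV filter cascade
#'
#' Filters raw SNV calls to novel, coding, high-confidence variants: known
#' and in-house sites removed, coding (CDS) overlap required, blacklisted
#' regions excluded, then read depth `>= min_depth`, call quality
#' `> min_quality` and non-reference allele fraction `> min_af`. Survivors
#' are assigned their containing gene and a zygosity class.
#'
#' @param variants Variant tibble (see [read_variants()]).
#' @param genes Gene model tibble.
#' @param blacklist Blacklist region tibble or `NULL`.
#' @param config A [scope_config()].
#' @return An object of class `hq_filter`: list with `variants` (the HQ-SNV
#'   tibble, with `gene_id` and `zygosity`), `attrition` (per-stage counts in
#'   fixed stage order: `stage`, `n_in`, `n_removed`, `n_out`) and `config`.
#'   `tidy()` returns the survivors, `glance()` a one-row summary.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_variants = 300, array_sites = 0, seed = 2))
#' hq <- apply_hq_filter(cohort$variants, cohort$genes, cohort$blacklist)
#' hq$attrition
#' @export
apply_hq_filter <- function(variants, genes, blacklist = NULL,
                            config = scope_config()) {
  config <- as_scope_config(config)
  validate_variants(variants)
  stop_if_missing_cols(variants, c("known", "in_house", "consequence"),
                       "variant table")
  v <- is_coding(variants, genes)
  attr_rows <- vector("list", length(HQ_STAGES))
  for (i in seq_along(HQ_STAGES)) {
    stage <- HQ_STAGES[[i]]
    keep <- hq_stage_keep(v, stage, blacklist, config)
    attr_rows[[i]] <- tibble(stage = stage, n_in = nrow(v),
                             n_removed = sum(!keep), n_out = sum(keep))
    v <- v[keep, , drop = FALSE]
  }
  v$zygosity <- classify_zygosity(v$af, config)
  v$coding <- NULL
  structure(list(
    variants = as_tibble(v),
    attrition = bind_rows(attr_rows),
    config = config
  ), class = "hq_filter")
}

#' @export
print.hq_filter <- function(x, ...) {
  cat("<hq_filter>\n")
  cat(sprintf("  %d variants in, %d HQ-SNVs out\n",
              x$attrition$n_in[[1]], x$attrition$n_out[[nrow(x$attrition)]]))
  print(x$attrition)
  invisible(x)
}

#' @describeIn apply_hq_filter Survivor table.
#' @param x An `hq_filter` object.
#' @param ... Unused.
#' @method tidy hq_filter
#' @export
tidy.hq_filter <- function(x, ...) x$variants

#' @describeIn apply_hq_filter One-row summary: input count, per-stage
#'   removals (`removed_<stage>`), and the HQ-SNV count.
#' @method glance hq_filter
#' @export
glance.hq_filter <- function(x, ...) {
  wide <- setNames(as.list(x$attrition$n_removed),
                   paste0("removed_", x$attrition$stage))
  as_tibble(c(list(n_in = x$attrition$n_in[[1]]), wide,
              list(n_hq = x$attrition$n_out[[nrow(x$attrition)]])))
}

#' @describeIn apply_hq_filter Attrition waterfall plot.
#' @param object An `hq_filter` object.
#' @method autoplot hq_filter
#' @export
autoplot.hq_filter <- function(object, ...) {
  att <- object$attrition
  att$stage <- factor(att$stage, levels = HQ_STAGES)
  ggplot2::ggplot(att, ggplot2::aes(x = .data$stage, y = .data$n_out)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_out), vjust = -0.4, size = 3) +
    ggplot2::labs(x = "filter stage", y = "variants remaining",
                  title = "HQ-SNV filter attrition") +
    ggplot2::theme_minimal()
}
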