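# Transcribed reference tables from the published whole-exome
# characterization of six metastatic melanoma cell lines (Me01-Me12), shipped
# as plain-text fixtures under inst/extdata/. They carry the printed summary
# statistics (per-sample SNV counts and NS/S ratios, confirmed catalogue
# mutations and deletions, curated-class NS/S counts, recurrent de novo
# genes) and are used for regression tests and the reproduction script. Any
# genomic coordinates attached to them (via the synthetic gene model) are
# synthetic: the underlying raw data are not publicly deposited.

ref_path <- function(file) {
  system.file("extdata", file, package = "melascope", mustWork = TRUE)
}

read_ref <- function(file) {
  readr::read_tsv(ref_path(file), show_col_types = FALSE, progress = FALSE)
}

#' Reference per-sample SNV summary
#'
#' The published per-sample variant accounting for the six-cell-line cohort:
#' total calls, novel calls, novel coding calls, HQ-SNVs with their
#' non-synonymous/synonymous split and NS/S ratio. Returned as a
#' `sample_summary`, so [glance()] yields the cohort totals (3,325 HQ-SNVs,
#' 2,172 NS, 1,153 S, NS/S 1.88).
#'
#' @return A `sample_summary` tibble with one row per cell line.
#' @export
ref_snv_summary <- function() {
  x <- read_ref("ref_table1_snv_summary.tsv")
  for (col in c("n_total", "n_novel", "n_novel_coding", "n_hq", "n_ns", "n_s")) {
    x[[col]] <- as.integer(x[[col]])
  }
  class(x) <- c("sample_summary", class(x))
  x
}

#' Reference confirmed catalogue mutations
#'
#' Sample-level catalogue mutation confirmations (13 entries over 9 distinct
#' genes) with their truncating / homozygous annotations.
#'
#' @return A tibble with `sample_id`, `gene_id`, `truncating`, `homozygous`.
#' @export
ref_cosmic_mutations <- function() read_ref("ref_table2_cosmic_mutations.tsv")

#' Reference confirmed catalogue deletions
#'
#' Gene deletions spanning the entire locus and confirmed in the cancer
#' deletion catalogue (10 distinct genes across five samples), with the
#' homozygous-deletion flag.
#'
#' @return A tibble with `sample_id`, `gene_id`, `homozygous_deletion`.
#' @export
ref_cosmic_deletions <- function() read_ref("ref_table2_cosmic_deletions.tsv")

#' Reference curated-class NS/S counts
#'
#' Per functional class (signalling cascade or molecular function), the
#' non-synonymous and synonymous counts over curated-list member genes.
#'
#' @return A tibble with `class`, `n_ns`, `n_s`.
#' @export
ref_curated_class_counts <- function() read_ref("ref_table3_curated_counts.tsv")

#' Reference curated-list mutated genes
#'
#' Gene-per-sample entries of the curated melanoma-list screen with their
#' annotation flags (truncating, double-mutated, homozygous, and compound
#' mutation-plus-one-copy-loss).
#'
#' @return A tibble with `class`, `sample_id`, `gene_id` and four flags.
#' @export
ref_curated_genes <- function() read_ref("ref_table3_curated_genes.tsv")

#' Reference recurrent de novo genes
#'
#' The ten genes mutated in at least two samples while absent from both the
#' cancer catalogue and the curated list, with carrier samples and
#' non-synonymous mutation counts.
#'
#' @return A tibble with `gene_id`, `n_samples`, `samples`, `n_ns`.
#' @export
ref_de_novo_genes <- function() read_ref("ref_table4_de_novo.tsv")

#' All reference tables
#' @return Named list of the five reference tables.
#' @export
ref_tables <- function() {
  list(
    snv_summary = ref_snv_summary(),
    cosmic_mutations = ref_cosmic_mutations(),
    cosmic_deletions = ref_cosmic_deletions(),
    curated_class_counts = ref_curated_class_counts(),
    curated_genes = ref_curated_genes(),
    de_novo_genes = ref_de_novo_genes()
  )
}

#' Expand reference catalogue confirmations into variant records
#'
#' Reconstructs HQ-SNV-like records for the confirmed catalogue mutations by
#' anchoring each (sample, gene) entry at the synthetic catalogue position of
#' its gene, so exact-position matching can be exercised against
#' [synthetic_catalogue()]. Truncating entries become nonsense consequences,
#' homozygous entries get allele fraction 1.
#'
#' @param genes Gene model tibble (default [synthetic_gene_model()]).
#' @return A variant tibble with `zygosity` and annotation columns.
#' @export
ref_cosmic_variant_records <- function(genes = synthetic_gene_model()) {
  m <- ref_cosmic_mutations()
  cat <- synthetic_catalogue(genes)
  k <- match(m$gene_id, cat$gene_id)
  tibble(
    sample_id = m$sample_id, chrom = cat$chrom[k], pos = cat$pos[k],
    ref = cat$ref_allele[k], alt = cat$alt_allele[k],
    depth = 60L, quality = 500,
    af = ifelse(m$homozygous, 1, 0.5),
    known = FALSE, in_house = FALSE,
    gene_id = m$gene_id,
    consequence = ifelse(m$truncating, "nonsense", "missense"),
    zygosity = ifelse(m$homozygous, "homozygous", "heterozygous")
  )
}

#' Expand reference de novo rows into variant records
#'
#' Reconstructs per-sample non-synonymous variant records for the recurrent
#' de novo genes (mutation counts distributed evenly over the listed carrier
#' samples), anchored at synthetic gene-model positions, for exercising the
#' recurrence and de novo screens.
#'
#' @param genes Gene model tibble (default [synthetic_gene_model()]).
#' @return A variant tibble with `sample_id`, `gene_id`, positional fields
#'   and `consequence`.
#' @export
ref_de_novo_variant_records <- function(genes = synthetic_gene_model()) {
  d <- ref_de_novo_genes()
  pos <- catalogue_position(genes, d$gene_id)
  rows <- lapply(seq_len(nrow(d)), function(i) {
    samples <- strsplit(d$samples[[i]], ",", fixed = TRUE)[[1]]
    per <- rep(d$n_ns[[i]] %/% length(samples), length(samples))
    extra <- d$n_ns[[i]] - sum(per)
    if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
    tibble(
      sample_id = rep(samples, per),
      gene_id = d$gene_id[[i]],
      chrom = pos$chrom[[i]],
      pos = pos$pos[[i]] + sequence(per) - 1L,
      consequence = "missense"
    )
  })
  bind_rows(rows)
}
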