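# Screening HQ-SNVs against cancer catalogues and the curated melanoma list:
# exact-position confirmation, functional-class grouping, special mutation
# states, recurrence and de novo gene discovery.

#' Match variants against a cancer mutation catalogue
#'
#' Confirms variants that hit a catalogued mutation at the exact genomic
#' position (and, by default, with identical ref/alt alleles; position-only
#' matching inflates confirmations and is opt-in). Each variant is matched to
#' at most one catalogue entry, the first after sorting the catalogue by
#' gene, chromosome, position and source label.
#'
#' @param variants HQ-SNV tibble.
#' @param catalogue Catalogue tibble (see [read_catalogue()]).
#' @param require_allele_match Require identical alleles (default `TRUE`)?
#' @return The input with `matched` (logical), `catalogue_gene` and
#'   `catalogue_source` columns.
#' @export
match_catalogue <- function(variants, catalogue, require_allele_match = TRUE) {
  cat_sorted <- arrange(catalogue, .data$gene_id, .data$chrom, .data$pos,
                        .data$source_label)
  by <- if (require_allele_match) {
    cat_sorted <- cat_sorted[!duplicated(cat_sorted[c("chrom", "pos", "ref_allele",
                                                      "alt_allele")]), ]
    c("chrom", "pos", "ref" = "ref_allele", "alt" = "alt_allele")
  } else {
    cat_sorted <- cat_sorted[!duplicated(cat_sorted[c("chrom", "pos")]), ]
    c("chrom", "pos")
  }
  hit <- cat_sorted |>
    rename(catalogue_gene = "gene_id", catalogue_source = "source_label")
  out <- left_join(variants, hit, by = by)
  out$matched <- !is.na(out$catalogue_gene)
  if (!require_allele_match) {
    out$ref_allele <- NULL; out$alt_allele <- NULL
  }
  out
}

#' Annotate special mutation states
#'
#' Flags the states called out in per-gene reporting: truncating (stop codon,
#' i.e. nonsense consequence), homozygous (allele fraction at the homozygous
#' level), and double-mutated (at least two distinct non-synonymous variants
#' in the same gene and sample).
#'
#' @param variants HQ-SNV tibble with `consequence`, `zygosity`, `gene_id`.
#' @return The input with logical columns `is_truncating`, `is_homozygous`,
#'   `is_double_mutated`.
#' @export
annotate_states <- function(variants) {
  stop_if_missing_cols(variants, c("gene_id", "consequence", "zygosity"),
                       "variant table")
  ns <- variants$consequence %in% NS_CONSEQUENCES
  key <- paste(variants$sample_id, variants$gene_id)
  ns_per_key <- table(key[ns & !is.na(variants$gene_id)])
  variants$is_truncating <- variants$consequence == "nonsense"
  variants$is_homozygous <- variants$zygosity == "homozygous"
  variants$is_double_mutated <- ns & !is.na(variants$gene_id) &
    key %in% names(ns_per_key)[ns_per_key >= 2]
  variants
}

#' Group variants by curated functional class
#'
#' Restricts variants to genes on a curated list and replicates each variant
#' into every functional class its gene belongs to (a gene in k families
#' contributes to all k groups). Synonymous variants are retained: per-class
#' NS/S counts are computed over all member-gene variants.
#'
#' @param variants HQ-SNV tibble with `gene_id` and `consequence`.
#' @param gene_list Long-format curated list (`gene_id`, `class`).
#' @return The screened variants with a `class` column (one row per variant
#'   and class).
#' @export
screen_curated <- function(variants, gene_list) {
  stop_if_missing_cols(gene_list, c("gene_id", "class"), "gene list")
  inner_join(variants, gene_list, by = "gene_id",
             relationship = "many-to-many")
}

#' Per-class NS/S counts for screened variants
#'
#' @param screened Output of [screen_curated()].
#' @return A tibble with `class`, `n_ns`, `n_s`, `ns_s` (class-level ratio,
#'   1 decimal), sorted by class.
#' @export
curated_class_counts <- function(screened) {
  screened |>
    group_by(class = .data$class) |>
    summarise(
      n_ns = sum(.data$consequence %in% NS_CONSEQUENCES),
      n_s = sum(.data$consequence == "synonymous"),
      .groups = "drop"
    ) |>
    mutate(ns_s = ns_s_ratio(.data$n_ns, .data$n_s, digits = 1)) |>
    arrange(.data$class)
}

#' Find recurrently mutated genes
#'
#' Genes carrying non-synonymous variants in at least `min_samples` distinct
#' samples, with the carrier samples and the total non-synonymous mutation
#' count; sorted by decreasing sample count, then gene.
#'
#' @param variants HQ-SNV tibble (`sample_id`, `gene_id`, `consequence`).
#' @param min_samples Minimum number of distinct mutated samples (default 2).
#' @return A tibble with `gene_id`, `n_samples`, `samples` (comma-separated,
#'   sorted) and `n_ns_mutations`.
#' @export
find_recurrent <- function(variants, min_samples = 2) {
  variants |>
    filter(.data$consequence %in% NS_CONSEQUENCES, !is.na(.data$gene_id)) |>
    group_by(gene_id = .data$gene_id) |>
    summarise(
      n_samples = n_distinct(.data$sample_id),
      samples = paste(sort(unique(.data$sample_id)), collapse = ","),
      n_ns_mutations = dplyr::n(),
      .groups = "drop"
    ) |>
    filter(.data$n_samples >= min_samples) |>
    arrange(desc(.data$n_samples), .data$gene_id)
}

#' Find recurrent de novo genes
#'
#' The de novo screen: recurrently mutated genes that are reported neither in
#' the cancer mutation catalogue nor on the curated melanoma-related list.
#' Only non-synonymous variants are counted.
#'
#' @param variants HQ-SNV tibble.
#' @param cosmic_genes Character vector of catalogue gene identifiers.
#' @param curated_genes Character vector of curated-list gene identifiers.
#' @param min_samples Minimum number of distinct mutated samples (default 2).
#' @return As [find_recurrent()], restricted to genes outside both sets.
#' @export
find_de_novo <- function(variants, cosmic_genes, curated_genes, min_samples = 2) {
  rec <- find_recurrent(variants, min_samples = min_samples)
  rec[!(rec$gene_id %in% union(cosmic_genes, curated_genes)), , drop = FALSE]
}

#' Mutation frequency of a gene across samples
#'
#' Carrier fraction of a gene over the cohort, with the percentage
#' floor-rounded as conventionally printed (4 of 6 carriers is reported as
#' 66%).
#'
#' @param variants Tibble with `sample_id` and `gene_id` (any per-sample
#'   mutation record; non-synonymous HQ-SNVs in pipeline use).
#' @param gene_id Gene to query.
#' @param n_samples Cohort size (must be >= 1).
#' @return One-row tibble: `gene_id`, `n_carriers`, `n_samples`, `fraction`,
#'   `percent` (floored integer).
#' @examples
#' x <- tibble::tibble(sample_id = c("a", "b", "c", "d"), gene_id = "BRAF")
#' driver_frequency(x, "BRAF", 6)
#' @export
driver_frequency <- function(variants, gene_id, n_samples) {
  if (n_samples < 1) abort("driver_frequency: n_samples must be >= 1")
  carriers <- unique(variants$sample_id[variants$gene_id %in% gene_id])
  frac <- length(carriers) / n_samples
  tibble(
    gene_id = gene_id, n_carriers = length(carriers),
    n_samples = as.integer(n_samples), fraction = frac,
    percent = as.integer(floor(100 * frac))
  )
}

#' Samples mutated in two genes
#'
#' Exact co-occurrence accounting for a gene pair, the data behind mutual
#' exclusivity statements: which samples carry non-synonymous variants in
#' both genes, in exactly one, or in neither.
#'
#' @param variants HQ-SNV tibble.
#' @param gene_a,gene_b Genes to compare.
#' @param sample_ids Full cohort sample set (defaults to samples observed in
#'   `variants`).
#' @return A list with character vectors `both`, `only_a`, `only_b`,
#'   `neither`.
#' @export
co_mutated_samples <- function(variants, gene_a, gene_b,
                               sample_ids = unique(variants$sample_id)) {
  ns <- variants[variants$consequence %in% NS_CONSEQUENCES, , drop = FALSE]
  a <- unique(ns$sample_id[ns$gene_id %in% gene_a])
  b <- unique(ns$sample_id[ns$gene_id %in% gene_b])
  list(
    both = sort(intersect(a, b)),
    only_a = sort(setdiff(a, b)),
    only_b = sort(setdiff(b, a)),
    neither = sort(setdiff(sample_ids, union(a, b)))
  )
}
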