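# Strand-collapsed substitution spectrum and cohort summary statistics.

#' Collapsed substitution class of a base change
#'
#' A substitution and its reverse complement are counted together, giving six
#' classes keyed by the pyrimidine-reference member and displayed with both
#' members (`"C>T/G>A"`, the UV-signature class, etc.).
#'
#' @param ref,alt Character vectors of single bases (A/C/G/T), elementwise
#'   `ref != alt`.
#' @return Factor with the six class levels.
#' @examples
#' substitution_class(c("C", "G", "A"), c("T", "A", "T"))
#' @export
substitution_class <- function(ref, alt) {
  if (length(ref) != length(alt)) abort("ref and alt must have equal length")
  if (length(ref) == 0) return(factor(character(), levels = SPECTRUM_LEVELS))
  if (!all(ref %in% DNA_BASES) || !all(alt %in% DNA_BASES)) {
    abort("substitution_class: bases must be A/C/G/T")
  }
  if (any(ref == alt)) abort("substitution_class: ref must differ from alt")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  purine <- ref %in% c("A", "G")
  r <- ifelse(purine, comp[ref], ref)
  a <- ifelse(purine, comp[alt], alt)
  key <- paste0(r, ">", a)
  labels <- c("C>T" = "C>T/G>A", "C>A" = "C>A/G>T", "C>G" = "C>G/G>C",
              "T>C" = "T>C/A>G", "T>A" = "T>A/A>T", "T>G" = "T>G/A>C")
  factor(unname(labels[key]), levels = SPECTRUM_LEVELS)
}

#' Substitution spectrum of a variant set
#'
#' Counts variants per collapsed substitution class; counts always sum to the
#' number of variants, and complementing every variant's alleles leaves the
#' spectrum unchanged.
#'
#' @param variants Variant tibble with `ref` and `alt` columns (optionally
#'   grouped per sample via `by_sample`).
#' @param by_sample Count per sample as well as per class?
#' @return A `mutation_spectrum` tibble: (`sample_id`,) `class`, `n`,
#'   `fraction`.
#' @export
mutation_spectrum <- function(variants, by_sample = FALSE) {
  cls <- substitution_class(variants$ref, variants$alt)
  if (by_sample) {
    out <- tibble(sample_id = variants$sample_id, class = cls) |>
      count(.data$sample_id, .data$class, .drop = FALSE) |>
      group_by(.data$sample_id) |>
      mutate(fraction = if (sum(n) > 0) .data$n / sum(.data$n) else NA_real_) |>
      ungroup()
  } else {
    out <- tibble(class = cls) |>
      count(.data$class, .drop = FALSE) |>
      mutate(fraction = if (sum(n) > 0) .data$n / sum(.data$n) else NA_real_)
  }
  class(out) <- c("mutation_spectrum", class(out))
  out
}

#' Non-synonymous to synonymous ratio
#'
#' The NS/S ratio over non-negative counts, rounded to a documented number of
#' decimals (2 for whole-dataset and per-sample ratios, 1 for functional-class
#' ratios). A zero synonymous count gives `NA` (undefined), never infinity.
#'
#' @param n_ns,n_s Non-negative integer counts.
#' @param digits Decimals to round to (default 2).
#' @return Numeric ratio or `NA_real_`.
#' @examples
#' ns_s_ratio(2172, 1153)  # 1.88
#' ns_s_ratio(8, 3, digits = 1)  # 2.7
#' @export
ns_s_ratio <- function(n_ns, n_s, digits = 2) {
  if (any(n_ns < 0) || any(n_s < 0)) abort("ns_s_ratio: counts must be non-negative")
  ifelse(n_s == 0, NA_real_, round(n_ns / n_s, digits))
}

#' Per-sample summary across filtering stages
#'
#' Builds the per-sample summary table: total calls, novel calls, novel
#' coding calls, HQ-SNVs, their non-synonymous (missense + nonsense) and
#' synonymous split, and the NS/S ratio. Cohort aggregates (column totals,
#' the whole-dataset NS/S ratio and integer-rounded per-sample means) are
#' available through [glance()].
#'
#' @param variants Full variant tibble (all calls, with `known` and
#'   `consequence`).
#' @param hq An `hq_filter` result, or the HQ-SNV tibble itself.
#' @return A `sample_summary` tibble with columns `sample_id`, `n_total`,
#'   `n_novel`, `n_novel_coding`, `n_hq`, `n_ns`, `n_s`, `ns_s`.
#' @export
build_summary <- function(variants, hq) {
  hqv <- if (inherits(hq, "hq_filter")) hq$variants else hq
  base <- variants |>
    group_by(sample_id = .data$sample_id) |>
    summarise(
      n_total = dplyr::n(),
      n_novel = sum(!.data$known),
      n_novel_coding = sum(!.data$known & .data$consequence %in% CODING_CONSEQUENCES),
      .groups = "drop"
    )
  hqs <- hqv |>
    group_by(sample_id = .data$sample_id) |>
    summarise(
      n_hq = dplyr::n(),
      n_ns = sum(.data$consequence %in% NS_CONSEQUENCES),
      n_s = sum(.data$consequence == "synonymous"),
      .groups = "drop"
    )
  out <- left_join(base, hqs, by = "sample_id") |>
    mutate(
      n_hq = dplyr::coalesce(.data$n_hq, 0L),
      n_ns = dplyr::coalesce(.data$n_ns, 0L),
      n_s = dplyr::coalesce(.data$n_s, 0L),
      ns_s = ns_s_ratio(.data$n_ns, .data$n_s)
    ) |>
    arrange(.data$sample_id)
  if (any(out$n_hq != out$n_ns + out$n_s)) {
    abort("build_summary: HQ-SNVs must split into non-synonymous + synonymous")
  }
  if (any(out$n_hq > out$n_novel_coding | out$n_novel_coding > out$n_novel |
            out$n_novel > out$n_total)) {
    abort("build_summary: stage counts must nest (hq <= novel coding <= novel <= total)")
  }
  class(out) <- c("sample_summary", class(out))
  out
}

#' Cohort aggregates of a per-sample summary
#'
#' Column totals, the whole-dataset NS/S ratio (2 decimals) and per-sample
#' means of the NS and S counts (rounded to integers). Works on any table
#' with the [build_summary()] columns, including transcribed reference
#' tables.
#'
#' @param x A `sample_summary` tibble (or any tibble with its count columns).
#' @param ... Unused.
#' @return A one-row tibble with `n_samples`, `total_hq`, `total_ns`,
#'   `total_s`, `ns_s`, `mean_ns`, `mean_s`.
#' @method glance sample_summary
#' @export
glance.sample_summary <- function(x, ...) {
  tibble(
    n_samples = nrow(x),
    total_hq = sum(x$n_hq),
    total_ns = sum(x$n_ns),
    total_s = sum(x$n_s),
    ns_s = ns_s_ratio(sum(x$n_ns), sum(x$n_s)),
    mean_ns = as.integer(round(mean(x$n_ns))),
    mean_s = as.integer(round(mean(x$n_s)))
  )
}

#' @describeIn mutation_spectrum Bar chart of the collapsed spectrum
#'   (per-sample facets when the spectrum was computed per sample).
#' @param object A `mutation_spectrum`.
#' @param ... Unused.
#' @method autoplot mutation_spectrum
#' @export
autoplot.mutation_spectrum <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$class, y = .data$n)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(x = "substitution class (strand-collapsed)", y = "variants",
                  title = "Nucleotide substitution pattern") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if ("sample_id" %in% names(object)) {
    p <- p + ggplot2::facet_wrap(~sample_id)
  }
  p
}

#' @describeIn build_summary NS/S bar chart per sample.
#' @param object A `sample_summary`.
#' @param ... Unused.
#' @method autoplot sample_summary
#' @export
autoplot.sample_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(object[c("sample_id", "n_ns", "n_s")],
                              c("n_ns", "n_s"),
                              names_to = "class", values_to = "n")
  long$class <- ifelse(long$class == "n_ns", "non-synonymous", "synonymous")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$n,
                                     fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "HQ-SNVs", fill = NULL,
                  title = "Coding HQ-SNVs per sample") +
    ggplot2::theme_minimal()
}
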