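# WES-versus-array genotype concordance and read-depth calibration.
#
# Genotype calls derived from sequencing allele fractions are compared with
# orthogonal SNP-array calls, stratified by array genotype and read depth.
# Homozygous strata stay near-perfect at any depth; the heterozygous stratum
# improves with depth, and the smallest depth sustaining a target concordance
# (90% by default) is adopted as the minimum read depth for SNV calling.

#' Call a genotype from an allele fraction
#'
#' The AF-threshold caller: homozygous reference below `min_af`, homozygous
#' alternate at or above `hom_af_cutoff`, heterozygous in between.
#'
#' @param af Numeric vector of non-reference allele fractions.
#' @param config A [scope_config()].
#' @return Character vector in `hom_ref` / `het` / `hom_alt`.
#' @export
call_genotype <- function(af, config = scope_config()) {
  config <- as_scope_config(config)
  ifelse(af < config$min_af, "hom_ref",
         ifelse(af >= config$hom_af_cutoff, "hom_alt", "het"))
}

#' Pair WES evidence with array genotype calls
#'
#' Joins WES-side evidence (read depth and allele fraction per site; allele
#' fraction 0 encodes covered non-variant sites, the homozygous-reference
#' evidence a VCF omits) with array genotype calls on (sample, chrom, pos).
#' Sites without WES coverage (depth 0) yield no pair; pairs whose ref/alt
#' alleles disagree between platforms are excluded and counted.
#'
#' @param wes Tibble with `sample_id`, `chrom`, `pos`, `depth`, `af` and
#'   optionally `ref`, `alt`.
#' @param array Array genotype tibble (see [read_array_genotypes()]).
#' @param config A [scope_config()] (drives the WES genotype caller).
#' @return A pair tibble with `sample_id`, `chrom`, `pos`, `depth`,
#'   `array_genotype`, `wes_genotype`, `concordant`; the number of
#'   allele-mismatched sites is attached as attribute `n_allele_mismatch`.
#' @export
match_sites <- function(wes, array, config = scope_config()) {
  config <- as_scope_config(config)
  stop_if_missing_cols(wes, c("sample_id", "chrom", "pos", "depth", "af"), "wes")
  stop_if_missing_cols(array, c("sample_id", "chrom", "pos", "genotype"), "array")
  pairs <- inner_join(
    wes, array,
    by = c("sample_id", "chrom", "pos"), suffix = c("", ".array"),
    relationship = "many-to-many"
  )
  n_mismatch <- 0L
  if (all(c("ref", "alt", "ref.array", "alt.array") %in% names(pairs))) {
    mism <- !is.na(pairs$ref) & !is.na(pairs$ref.array) &
      (pairs$ref != pairs$ref.array | pairs$alt != pairs$alt.array)
    n_mismatch <- sum(mism)
    if (n_mismatch > 0) {
      inform(sprintf("match_sites: excluded %d pair(s) with mismatched alleles",
                     n_mismatch))
      pairs <- pairs[!mism, , drop = FALSE]
    }
  }
  pairs <- pairs[pairs$depth > 0, , drop = FALSE]
  out <- tibble(
    sample_id = pairs$sample_id, chrom = pairs$chrom, pos = pairs$pos,
    depth = pairs$depth,
    array_genotype = pairs$genotype,
    wes_genotype = call_genotype(pairs$af, config)
  )
  out$concordant <- out$array_genotype == out$wes_genotype
  attr(out, "n_allele_mismatch") <- n_mismatch
  out
}

#' Concordance by read depth, stratified by array genotype
#'
#' @param pairs Pair tibble from [match_sites()].
#' @param depth_bins Integer depth values to report (default 1:50); pairs at
#'   other depths are ignored.
#' @param min_sites Bins with fewer sites than this are reported with
#'   concordance `NA` (undefined), never 0.
#' @return A `concordance_curve` tibble: `depth`, `stratum`, `n`,
#'   `concordance`.
#' @export
concordance_by_depth <- function(pairs, depth_bins = 1:50, min_sites = 25) {
  if (nrow(pairs) == 0) abort("concordance_by_depth: no pairs")
  if (any(diff(depth_bins) <= 0)) abort("depth_bins must be strictly increasing")
  grid <- tidyr::expand_grid(depth = as.integer(depth_bins),
                             stratum = c("hom_ref", "het", "hom_alt"))
  obs <- pairs |>
    filter(.data$depth %in% depth_bins) |>
    group_by(depth = .data$depth, stratum = .data$array_genotype) |>
    summarise(n = dplyr::n(), n_conc = sum(.data$concordant), .groups = "drop")
  out <- left_join(grid, obs, by = c("depth", "stratum")) |>
    mutate(
      n = dplyr::coalesce(.data$n, 0L),
      concordance = if_else(.data$n >= min_sites, .data$n_conc / .data$n,
                            NA_real_)
    ) |>
    select("depth", "stratum", "n", "concordance")
  class(out) <- c("concordance_curve", class(out))
  out
}

#' Select the minimum read depth from a concordance curve
#'
#' Finds the smallest depth bin at which heterozygous concordance reaches the
#' plateau level and stays at or above it for every defined bin from there on
#' (a sustained crossing, so a later dip below the level pushes the threshold
#' past the dip).
#'
#' @param curve A `concordance_curve` from [concordance_by_depth()].
#' @param config A [scope_config()]; `plateau_level` sets the target.
#' @return The selected depth (integer). When no bin sustains the level, an
#'   `NA` with attribute `reached = FALSE` and a warning.
#' @export
select_depth_threshold <- function(curve, config = scope_config()) {
  config <- as_scope_config(config)
  het <- curve[curve$stratum == "het" & !is.na(curve$concordance), , drop = FALSE]
  if (nrow(het) == 0) {
    warn("select_depth_threshold: no defined heterozygous bins")
    return(structure(NA_integer_, reached = FALSE))
  }
  het <- het[order(het$depth), , drop = FALSE]
  ok <- rev(cumprod(rev(het$concordance >= config$plateau_level)) == 1)
  if (!any(ok)) {
    warn(sprintf("heterozygous concordance never sustains %.0f%%",
                 100 * config$plateau_level))
    return(structure(NA_integer_, reached = FALSE))
  }
  structure(as.integer(het$depth[which(ok)[1]]), reached = TRUE)
}

#' Simulate depth-stratified heterozygous concordance pairs
#'
#' Generates array-vs-WES pairs at fixed read depths for truly heterozygous
#' (and optionally homozygous-alternate) sites under the chosen
#' allele-sampling model, for calibration curves with equal site counts per
#' depth bin.
#'
#' @param depths Integer vector of read depths.
#' @param n_per_bin Sites simulated per depth.
#' @param af_model `"betabinom"` or `"binomial"` (see [cohort_spec()]).
#' @param af_shape1,af_shape2 Beta parameters for the beta-binomial model.
#' @param stratum True genotype of the simulated sites (`"het"` or
#'   `"hom_alt"`).
#' @param config A [scope_config()] for the WES caller.
#' @return A pair tibble as from [match_sites()].
#' @export
simulate_concordance_pairs <- function(depths, n_per_bin,
                                       af_model = c("betabinom", "binomial"),
                                       af_shape1 = 12, af_shape2 = 7.5,
                                       stratum = c("het", "hom_alt"),
                                       config = scope_config()) {
  af_model <- match.arg(af_model)
  stratum <- match.arg(stratum)
  config <- as_scope_config(config)
  depth <- rep(as.integer(depths), each = n_per_bin)
  n <- length(depth)
  alt <- if (stratum == "hom_alt") {
    depth
  } else if (af_model == "betabinom") {
    rbinom(n, depth, rbeta(n, af_shape1, af_shape2))
  } else {
    rbinom(n, depth, 0.5)
  }
  af <- alt / depth
  out <- tibble(
    sample_id = "SIM", chrom = "chrSIM", pos = seq_len(n), depth = depth,
    array_genotype = stratum,
    wes_genotype = call_genotype(af, config)
  )
  out$concordant <- out$array_genotype == out$wes_genotype
  out
}

#' @describeIn concordance_by_depth Concordance-by-depth plot with one line
#'   per stratum and the plateau level marked.
#' @param object A `concordance_curve`.
#' @param config A [scope_config()] for the plateau reference line.
#' @param ... Unused.
#' @method autoplot concordance_curve
#' @export
autoplot.concordance_curve <- function(object, config = scope_config(), ...) {
  config <- as_scope_config(config)
  dat <- object[!is.na(object$concordance), , drop = FALSE]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$depth, y = .data$concordance,
                                    colour = .data$stratum)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = config$plateau_level, linetype = "dashed") +
    ggplot2::labs(x = "read depth (reads)", y = "genotype concordance",
                  title = "WES vs array genotype concordance by read depth") +
    ggplot2::theme_minimal()
}

#' @describeIn concordance_by_depth One-row summary: pair counts per stratum
#'   and the selected depth threshold.
#' @param x A `concordance_curve`.
#' @param ... Unused.
#' @method glance concordance_curve
#' @export
glance.concordance_curve <- function(x, ...) {
  thr <- tryCatch(suppressWarnings(select_depth_threshold(x)),
                  error = function(e) NA_integer_)
  tibble(
    n_sites = sum(x$n),
    n_het_sites = sum(x$n[x$stratum == "het"]),
    depth_threshold = as.integer(thr),
    threshold_reached = isTRUE(attr(thr, "reached"))
  )
}
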