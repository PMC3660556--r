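#' Analysis configuration
#'
#' Bundles every numeric threshold used by the pipeline into a single
#' validated object so that one configuration drives filtering, zygosity
#' classification, copy-number calling, depth calibration and recurrence
#' screening alike.
#'
#' @param min_depth Minimum read depth (reads) at a site for a variant call to
#'   be retained; the boundary is inclusive (a depth of exactly `min_depth`
#'   passes). Default 15.
#' @param min_quality Minimum variant call quality score; strict (a quality of
#'   exactly `min_quality` is rejected). Default 150.
#' @param min_af Minimum non-reference allele fraction, strict. Default 0.20.
#' @param amp_cn Copy-number value above which a segment is called amplified
#'   (strict). Default 2.3.
#' @param del_cn Copy-number value below which a segment is called deleted
#'   (strict), covering both one- and two-copy losses. Default 1.3.
#' @param hd_cn Copy-number value below which a deletion is considered a
#'   homozygous (two-copy) deletion. No published boundary separates one- from
#'   two-copy losses below `del_cn`; 0.7 splits cn ~ 1 from cn ~ 0
#'   symmetrically and is exposed here precisely because it is a choice.
#' @param hom_af_cutoff Allele fraction at or above which a call is classified
#'   homozygous rather than heterozygous. Nominal allele fractions are 0.5
#'   (het) and 1 (hom); 0.85 tolerates sampling noise around them.
#' @param plateau_level Concordance level defining the heterozygous-call
#'   plateau used to select the minimum read depth. Default 0.90.
#' @param recurrence_min_samples Minimum number of distinct mutated samples
#'   for a gene to count as recurrent. Default 2.
#'
#' @return An object of class `scope_config` (a named list).
#' @examples
#' cfg <- scope_config()
#' cfg$min_depth
#' @export
scope_config <- function(min_depth = 15L,
                         min_quality = 150,
                         min_af = 0.20,
                         amp_cn = 2.3,
                         del_cn = 1.3,
                         hd_cn = 0.7,
                         hom_af_cutoff = 0.85,
                         plateau_level = 0.90,
                         recurrence_min_samples = 2L) {
  cfg <- list(
    min_depth = as.integer(min_depth),
    min_quality = as.numeric(min_quality),
    min_af = as.numeric(min_af),
    amp_cn = as.numeric(amp_cn),
    del_cn = as.numeric(del_cn),
    hd_cn = as.numeric(hd_cn),
    hom_af_cutoff = as.numeric(hom_af_cutoff),
    plateau_level = as.numeric(plateau_level),
    recurrence_min_samples = as.integer(recurrence_min_samples)
  )
  if (!(cfg$min_af > 0 && cfg$min_af < cfg$hom_af_cutoff && cfg$hom_af_cutoff <= 1)) {
    stop("scope_config: need 0 < min_af < hom_af_cutoff <= 1", call. = FALSE)
  }
  if (!(cfg$hd_cn < cfg$del_cn && cfg$del_cn < cfg$amp_cn)) {
    stop("scope_config: need hd_cn < del_cn < amp_cn", call. = FALSE)
  }
  if (!(cfg$plateau_level > 0 && cfg$plateau_level <= 1)) {
    stop("scope_config: need 0 < plateau_level <= 1", call. = FALSE)
  }
  if (cfg$min_depth < 0 || cfg$min_quality < 0) {
    stop("scope_config: depth and quality thresholds must be non-negative", call. = FALSE)
  }
  if (cfg$recurrence_min_samples < 1) {
    stop("scope_config: recurrence_min_samples must be >= 1", call. = FALSE)
  }
  structure(cfg, class = "scope_config")
}

#' @export
print.scope_config <- function(x, ...) {
  cat("<scope_config>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

as_scope_config <- function(config) {
  if (inherits(config, "scope_config")) return(config)
  if (is.list(config)) return(do.call(scope_config, config))
  stop("config must be a scope_config or a named list", call. = FALSE)
}
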