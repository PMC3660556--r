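# Gene-level copy-number calls from continuous copy-number segments.
#
# Segments are classified against fixed thresholds (amplified above amp_cn,
# deleted below del_cn, with two-copy losses below hd_cn), then lifted to
# gene-level calls under an entire-locus rule: a gene is only called deleted
# (or amplified) when a deletion- (amplification-) classified run of segments
# fully contains its span; partial overlap is reported as such, never as a
# deletion.

#' Classify copy-number segments
#'
#' @param segments Segment tibble (`sample_id`, `chrom`, `start`, `end`, `cn`).
#' @param config A [scope_config()].
#' @return The input with `status` (`amplified` / `deletion` / `neutral`) and
#'   `hd` (logical two-copy-loss flag, `cn < hd_cn`).
#' @examples
#' segs <- tibble::tibble(sample_id = "s", chrom = "chr1",
#'                        start = c(1, 101, 201), end = c(100, 200, 300),
#'                        cn = c(2.4, 1.2, 0))
#' classify_segments(segs)
#' @export
classify_segments <- function(segments, config = scope_config()) {
  config <- as_scope_config(config)
  if (any(segments$cn < 0)) abort("classify_segments: cn must be non-negative")
  segments$status <- ifelse(segments$cn > config$amp_cn, "amplified",
                            ifelse(segments$cn < config$del_cn, "deletion",
                                   "neutral"))
  segments$hd <- segments$cn < config$hd_cn
  segments
}

# Merge adjacent same-status segments (segmentation breakpoints are
# arbitrary, so a gene spanned by several touching deletion segments counts
# as fully covered). Returns runs with min/max cn over their members.
merge_status_runs <- function(segments) {
  segments <- segments[order(segments$sample_id, segments$chrom, segments$start), ]
  key <- paste(segments$sample_id, segments$chrom, segments$status)
  new_run <- c(TRUE, key[-1] != key[-nrow(segments)] |
                 segments$start[-1] != segments$end[-nrow(segments)] + 1L)
  run_id <- cumsum(new_run)
  segments |>
    mutate(run_id = run_id) |>
    group_by(.data$run_id) |>
    summarise(
      sample_id = first(.data$sample_id), chrom = first(.data$chrom),
      status = first(.data$status),
      start = min(.data$start), end = max(.data$end),
      .groups = "drop"
    )
}

#' Gene-level copy-number calls
#'
#' Derives one call per gene and sample. A gene fully contained in a merged
#' amplification run is `amplified`; fully contained in a merged deletion run
#' it is `homozygous_deletion` when every overlapping segment is below the
#' two-copy-loss boundary (`hd_cn`), otherwise `one_copy_loss`; a gene only
#' partly covered by non-neutral segments is `partial_overlap`; everything
#' else is `neutral`. The supporting `cn_value` is the extreme copy number
#' over the gene span (maximum for deletions, minimum for amplifications), so
#' the call invariants hold: homozygous deletions have `cn_value < hd_cn`,
#' one-copy losses `hd_cn <= cn_value < del_cn`, amplifications
#' `cn_value > amp_cn`.
#'
#' @param genes Gene model tibble.
#' @param segments Segment tibble.
#' @param config A [scope_config()].
#' @return A tibble with `sample_id`, `gene_id`, `status`, `cn_value`.
#' @export
gene_cn_calls <- function(genes, segments, config = scope_config()) {
  config <- as_scope_config(config)
  validate_segments(segments)
  seg <- classify_segments(segments, config)
  runs <- merge_status_runs(seg)
  out <- list()
  for (sid in unique(seg$sample_id)) {
    s_seg <- seg[seg$sample_id == sid, , drop = FALSE]
    s_run <- runs[runs$sample_id == sid, , drop = FALSE]
    for (cur in unique(genes$chrom)) {
      g <- genes[genes$chrom == cur, , drop = FALSE]
      if (nrow(g) == 0) next
      r <- s_run[s_run$chrom == cur, , drop = FALSE]
      e <- s_seg[s_seg$chrom == cur, , drop = FALSE]
      gr <- IRanges::IRanges(start = g$start, end = g$end)
      status <- rep("neutral", nrow(g))
      cn_value <- rep(NA_real_, nrow(g))
      if (nrow(e) > 0) {
        er <- IRanges::IRanges(start = e$start, end = e$end)
        ov <- IRanges::findOverlaps(gr, er)
        # containing run, if any, per gene
        if (nrow(r) > 0) {
          rr <- IRanges::IRanges(start = r$start, end = r$end)
          within <- IRanges::findOverlaps(gr, rr, type = "within", select = "first")
        } else {
          within <- rep(NA_integer_, nrow(g))
        }
        for (i in seq_len(nrow(g))) {
          segs_i <- S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i]
          if (length(segs_i) == 0) next
          cns <- e$cn[segs_i]
          run_i <- within[i]
          run_status <- if (!is.na(run_i)) r$status[run_i] else NA_character_
          if (!is.na(run_status) && run_status == "amplified") {
            status[i] <- "amplified"
            cn_value[i] <- min(cns)
          } else if (!is.na(run_status) && run_status == "deletion") {
            status[i] <- if (max(cns) < config$hd_cn) "homozygous_deletion" else "one_copy_loss"
            cn_value[i] <- max(cns)
          } else if (any(e$status[segs_i] != "neutral")) {
            status[i] <- "partial_overlap"
            cn_value[i] <- cns[which(e$status[segs_i] != "neutral")[1]]
          } else {
            status[i] <- "neutral"
            cn_value[i] <- cns[[1]]
          }
        }
      }
      out[[paste(sid, cur)]] <- tibble(sample_id = sid, gene_id = g$gene_id,
                                       status = status, cn_value = cn_value)
    }
  }
  arrange(bind_rows(out), .data$sample_id, .data$gene_id)
}

#' Deleted genes confirmed in a cancer deletion catalogue
#'
#' Restricts gene-level deletion calls (one-copy losses and homozygous
#' deletions) to a catalogue of genes reported as deleted in cancer and
#' summarises per sample and over distinct genes.
#'
#' @param calls Gene-level calls from [gene_cn_calls()].
#' @param cosmic_deleted Character vector of catalogued deleted genes.
#' @return A list with `calls` (the confirmed deletion calls), `per_sample`
#'   (tibble `sample_id`, `n_genes`), `distinct_genes` (sorted character) and
#'   `n_distinct` (its length).
#' @export
cosmic_deleted_genes <- function(calls, cosmic_deleted) {
  del <- calls |>
    filter(.data$status %in% c("one_copy_loss", "homozygous_deletion"),
           .data$gene_id %in% cosmic_deleted) |>
    arrange(.data$sample_id, .data$gene_id)
  list(
    calls = del,
    per_sample = count(del, .data$sample_id, name = "n_genes"),
    distinct_genes = sort(unique(del$gene_id)),
    n_distinct = length(unique(del$gene_id))
  )
}

#' Compound mutation-plus-deletion events
#'
#' One event per (sample, gene) carrying at least one non-synonymous HQ-SNV
#' together with a one-copy-loss call on the same gene: the mutation affects
#' one allele and the other is lost.
#'
#' @param variants HQ-SNV tibble.
#' @param calls Gene-level calls from [gene_cn_calls()].
#' @return A tibble `sample_id`, `gene_id`, `n_ns_variants`, `cn_value`.
#' @export
compound_events <- function(variants, calls) {
  ns <- variants |>
    filter(.data$consequence %in% NS_CONSEQUENCES, !is.na(.data$gene_id)) |>
    count(.data$sample_id, .data$gene_id, name = "n_ns_variants")
  loss <- calls |> filter(.data$status == "one_copy_loss")
  inner_join(ns, loss[c("sample_id", "gene_id", "cn_value")],
             by = c("sample_id", "gene_id")) |>
    arrange(.data$sample_id, .data$gene_id)
}
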