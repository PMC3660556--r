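# Segment classification thresholds, the entire-locus rule for gene-level
# calls, catalogue deletion summaries and compound events.

seg <- function(sample_id, chrom, start, end, cn) {
  tibble::tibble(sample_id = sample_id, chrom = chrom,
                 start = as.integer(start), end = as.integer(end), cn = cn)
}

test_that("segments classify against the fixed thresholds", {
  s <- seg("s1", "chr1", c(1, 101, 201, 301), c(100, 200, 300, 400),
           c(2.4, 1.2, 2.0, 0))
  cl <- classify_segments(s)
  expect_equal(cl$status, c("amplified", "deletion", "neutral", "deletion"))
  expect_equal(cl$hd, c(FALSE, FALSE, FALSE, TRUE))
  s$cn[1] <- -1
  expect_error(classify_segments(s), "non-negative")
})

test_that("gene calls follow the entire-locus rule", {
  genes <- make_test_genes()   # G1 chrA:100-399, G2 chrA:1000-1299
  # G1 fully inside a cn=0 segment; G2 half-covered by a deletion
  segs <- dplyr::bind_rows(
    seg("s1", "chrA", 1, 500, 0),
    seg("s1", "chrA", 501, 1100, 1.0),
    seg("s1", "chrA", 1101, 5000, 2),
    seg("s1", "chrB", 1, 5000, 2)
  )
  calls <- gene_cn_calls(genes, segs)
  expect_equal(calls$status[calls$gene_id == "G1"], "homozygous_deletion")
  expect_equal(calls$status[calls$gene_id == "G2"], "partial_overlap")
  expect_equal(calls$status[calls$gene_id == "G3"], "neutral")
})

test_that("adjacent deletion segments merge before the containment test", {
  genes <- make_test_genes()
  # two touching one-copy segments jointly cover G1
  segs <- dplyr::bind_rows(
    seg("s1", "chrA", 1, 250, 1.0),
    seg("s1", "chrA", 251, 600, 0.9),
    seg("s1", "chrA", 601, 5000, 2),
    seg("s1", "chrB", 1, 5000, 2)
  )
  calls <- gene_cn_calls(genes, segs)
  expect_equal(calls$status[calls$gene_id == "G1"], "one_copy_loss")
  expect_equal(calls$cn_value[calls$gene_id == "G1"], 1.0)
  # a merged run mixing one- and two-copy losses is not a homozygous deletion
  segs$cn[1] <- 0.2
  calls2 <- gene_cn_calls(genes, segs)
  expect_equal(calls2$status[calls2$gene_id == "G1"], "one_copy_loss")
  # but a run entirely below the two-copy boundary is
  segs$cn[2] <- 0.1
  calls3 <- gene_cn_calls(genes, segs)
  expect_equal(calls3$status[calls3$gene_id == "G1"], "homozygous_deletion")
})

test_that("shrinking a deletion below full gene coverage demotes the call", {
  genes <- make_test_genes()
  full <- dplyr::bind_rows(
    seg("s1", "chrA", 50, 450, 1.0),
    seg("s1", "chrA", 451, 5000, 2),
    seg("s1", "chrB", 1, 5000, 2)
  )
  expect_equal(gene_cn_calls(genes, full)$status[1], "one_copy_loss")
  shrunk <- dplyr::bind_rows(
    seg("s1", "chrA", 50, 398, 1.0),   # one base short of the G1 end
    seg("s1", "chrA", 399, 5000, 2),
    seg("s1", "chrB", 1, 5000, 2)
  )
  expect_equal(gene_cn_calls(genes, shrunk)$status[1], "partial_overlap")
})

test_that("amplification calls use the same entire-locus rule", {
  genes <- make_test_genes()
  segs <- dplyr::bind_rows(
    seg("s1", "chrA", 1, 500, 3.5),
    seg("s1", "chrA", 501, 5000, 2),
    seg("s1", "chrB", 1, 5000, 2)
  )
  calls <- gene_cn_calls(genes, segs)
  expect_equal(calls$status[calls$gene_id == "G1"], "amplified")
  expect_equal(calls$cn_value[calls$gene_id == "G1"], 3.5)
})

test_that("planted cn=0 genes are recovered with no false positives", {
  spec <- cohort_spec(seed = 67)
  segs <- generate_cn_segments(spec)
  genes <- synthetic_gene_model()
  calls <- gene_cn_calls(genes, segs)
  hd <- calls[calls$status == "homozygous_deletion", ]
  ev <- default_cn_events()
  planted <- ev[ev$cn < scope_config()$hd_cn, ]
  expect_setequal(paste(hd$sample_id, hd$gene_id),
                  paste(planted$sample_id, planted$gene_id))
  # diploid background: every untouched gene is neutral
  touched <- paste(ev$sample_id, ev$gene_id)
  bg <- calls[!(paste(calls$sample_id, calls$gene_id) %in% touched), ]
  expect_true(all(bg$status == "neutral"))
})

test_that("catalogue deletion summaries count distinct genes and per-sample loads", {
  spec <- cohort_spec(seed = 71)
  calls <- gene_cn_calls(synthetic_gene_model(), generate_cn_segments(spec))
  s <- cosmic_deleted_genes(calls, cosmic_deleted_gene_set())
  expect_equal(s$n_distinct, 10L)
  expect_equal(nrow(s$per_sample), 5L)   # five affected samples
  expect_equal(s$per_sample$n_genes[s$per_sample$sample_id == "Me05"], 8L)
  empty <- cosmic_deleted_genes(calls, character(0))
  expect_equal(empty$n_distinct, 0L)
  expect_equal(nrow(empty$calls), 0L)
})

test_that("compound events equal a brute-force join of NS variants and losses", {
  withr::with_seed(73, {
    v <- random_variants(300, seed = 77)
    v$gene_id <- sample(c("G1", "G2", "G3", NA), 300, replace = TRUE)
    calls <- tidyr::expand_grid(sample_id = c("s1", "s2", "s3"),
                                gene_id = c("G1", "G2", "G3")) |>
      dplyr::mutate(status = sample(c("one_copy_loss", "neutral",
                                      "homozygous_deletion"), 9, replace = TRUE),
                    cn_value = 1)
  })
  ev <- compound_events(v, calls)
  for (i in seq_len(nrow(calls))) {
    ns_here <- sum(v$consequence %in% c("missense", "nonsense") &
                     v$sample_id == calls$sample_id[i] &
                     v$gene_id %in% calls$gene_id[i])
    in_ev <- any(ev$sample_id == calls$sample_id[i] &
                   ev$gene_id == calls$gene_id[i])
    expect_equal(in_ev, calls$status[i] == "one_copy_loss" && ns_here > 0)
    if (in_ev) {
      expect_equal(ev$n_ns_variants[ev$sample_id == calls$sample_id[i] &
                                      ev$gene_id == calls$gene_id[i]], ns_here)
    }
  }
})
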