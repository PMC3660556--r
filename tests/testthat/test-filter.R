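# HQ-SNV filter cascade: threshold boundaries, overlap oracles, attrition
# accounting and zygosity classification.

base_variant <- function(...) {
  fields <- list(
    sample_id = "s1", chrom = "chrA", pos = 150L, ref = "C", alt = "T",
    depth = 15L, quality = 151, af = 0.25, known = FALSE, in_house = FALSE,
    gene_id = NA_character_, consequence = "missense"
  )
  args <- list(...)
  fields[names(args)] <- args
  tibble::as_tibble(fields)   # recycles scalars against any vector override
}

test_that("depth threshold is inclusive, quality and AF thresholds are strict", {
  genes <- make_test_genes()
  keep <- function(v) nrow(apply_hq_filter(v, genes)$variants)
  expect_equal(keep(base_variant()), 1L)                 # 15x / 151 / 0.25 passes
  expect_equal(keep(base_variant(depth = 14L)), 0L)
  expect_equal(keep(base_variant(quality = 150)), 0L)    # exactly 150 rejected
  expect_equal(keep(base_variant(af = 0.20)), 0L)        # exactly 20% rejected
  expect_equal(keep(base_variant(known = TRUE)), 0L)
  expect_equal(keep(base_variant(in_house = TRUE)), 0L)
})

test_that("coding means CDS overlap: introns of the same gene do not count", {
  genes <- make_test_genes()
  v <- base_variant(pos = c(150L, 250L, 399L))  # CDS, intron, CDS boundary
  v$sample_id <- "s1"
  out <- is_coding(v, genes)
  expect_equal(out$coding, c(TRUE, FALSE, TRUE))
  expect_equal(out$gene_id, c("G1", NA, "G1"))
})

test_that("CDS and blacklist overlap agree with a brute-force linear scan", {
  genes <- make_test_genes()
  bl <- make_test_blacklist()
  v <- random_variants(200, seed = 7)
  got <- is_coding(v, genes)
  ora <- oracle_coding(v$chrom, v$pos, genes)
  expect_equal(got$coding, ora$coding)
  expect_equal(got$gene_id, ora$gene_id)
  expect_equal(in_blacklist(v, bl), oracle_in_regions(v$chrom, v$pos, bl))
})

test_that("blacklist intervals are closed and an empty blacklist never hits", {
  bl <- make_test_blacklist()   # chrA:1000-1299
  v <- base_variant(pos = c(1000L, 1299L, 999L, 1300L))
  expect_equal(in_blacklist(v, bl), c(TRUE, TRUE, FALSE, FALSE))
  expect_false(any(in_blacklist(v, NULL)))
  expect_false(any(in_blacklist(v, bl[0, ])))
})

test_that("the cascade equals the brute-force per-variant predicate", {
  genes <- make_test_genes()
  bl <- make_test_blacklist()
  cfg <- scope_config()
  v <- random_variants(1000, seed = 13)
  res <- apply_hq_filter(v, genes, bl, cfg)
  keep <- oracle_hq_keep(v, genes, bl, cfg)
  expect_equal(sort(variant_key(res$variants)), sort(variant_key(v[keep, ])))
  # conservation: survivors + per-stage removals = input
  expect_equal(sum(res$attrition$n_removed) + nrow(res$variants), nrow(v))
  expect_equal(res$attrition$stage,
               c("known", "coding", "blacklist", "in_house", "depth",
                 "quality", "af"))
  # empty input
  empty <- apply_hq_filter(v[0, ], genes, bl, cfg)
  expect_equal(nrow(empty$variants), 0L)
  expect_true(all(empty$attrition$n_removed == 0L))
})

test_that("tightening any threshold never adds a survivor (nested sets)", {
  genes <- make_test_genes()
  bl <- make_test_blacklist()
  v <- random_variants(800, seed = 21)
  base <- apply_hq_filter(v, genes, bl, scope_config())$variants
  tighter <- list(
    scope_config(min_depth = 20),
    scope_config(min_quality = 200),
    scope_config(min_af = 0.3),
    scope_config(min_depth = 25, min_quality = 250, min_af = 0.35)
  )
  for (cfg in tighter) {
    surv <- apply_hq_filter(v, genes, bl, cfg)$variants
    expect_true(all(variant_key(surv) %in% variant_key(base)))
  }
})

test_that("zygosity classification uses a single AF cutoff", {
  cfg <- scope_config()
  expect_equal(classify_zygosity(c(1, 0.5, 0.85, 0.8499), cfg),
               c("homozygous", "heterozygous", "homozygous", "heterozygous"))
})

test_that("filter summaries expose attrition through tidy and glance", {
  genes <- make_test_genes()
  v <- random_variants(300, seed = 3)
  res <- apply_hq_filter(v, genes, make_test_blacklist())
  expect_identical(tidy(res), res$variants)
  g <- glance(res)
  expect_equal(g$n_in, 300L)
  expect_equal(g$n_hq, nrow(res$variants))
})

test_that("configuration invariants are enforced", {
  expect_error(scope_config(min_af = 0.9, hom_af_cutoff = 0.85), "min_af")
  expect_error(scope_config(hd_cn = 1.5), "hd_cn")
  expect_error(scope_config(plateau_level = 0), "plateau")
})
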