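make_table <- function(counts) {
  meta <- data.frame(sample_id = rownames(counts),
                     individual = sub("_.*", "", rownames(counts)),
                     fraction = sub(".*_", "", rownames(counts)))
  validate_count_table(counts, meta)
}

test_that("sheath rule removes exactly the sheath-only ASVs", {
  counts <- rbind(
    I01_Whole = c(a = 12L, b = 0L, c = 3L),
    I01_HNA = c(a = 5L, b = 7L, c = 1L),
    I01_Sheath = c(a = 5L, b = 5L, c = 0L))
  tab <- make_table(counts)
  res <- remove_sheath_contaminants(tab)
  # b: sheath reads, absent from Whole -> removed; a: in Whole -> kept
  expect_equal(res$report$removed_asvs, "b")
  expect_equal(colnames(res$table$counts), c("a", "c"))
  expect_false("I01_Sheath" %in% rownames(res$table$counts))
  # idempotence (no sheath samples remain, rule becomes a no-op)
  expect_warning(res2 <- remove_sheath_contaminants(res$table), "skipped")
  expect_equal(res2$table$counts, res$table$counts)
})

test_that("generator-injected contaminants are removed with precision and recall 1", {
  co <- simulate_cohort(small_config(seed = 6))
  tab <- validate_count_table(co$counts, co$metadata)
  res <- remove_sheath_contaminants(tab)
  expect_setequal(res$report$removed_asvs, co$truth$contaminant_ids)
  # read totals reconcile exactly
  expect_equal(rowSums(tab$counts)[rownames(res$table$counts)],
               rowSums(res$table$counts) +
                 res$report$reads_removed_per_sample[rownames(res$table$counts)])
})

test_that("phylum and named-taxon filters drop the right columns", {
  counts <- rbind(I01_Whole = c(x = 5L, y = 6L, z = 7L),
                  I01_HNA = c(x = 1L, y = 8L, z = 9L))
  tab <- make_table(counts)
  taxo <- data.frame(asv = c("x", "y", "z"),
                     phylum = c("Firmicutes", "", NA))
  res <- drop_unassigned_phylum(tab, taxo)
  expect_equal(colnames(res$table$counts), "x")
  # all assigned -> identity
  taxo2 <- data.frame(asv = c("x", "y", "z"), phylum = "Firmicutes")
  expect_equal(drop_unassigned_phylum(tab, taxo2)$table$counts, tab$counts)
  expect_warning(r2 <- remove_named_taxa(tab, c("x", "nope")), "skipped")
  expect_equal(colnames(r2$table$counts), c("y", "z"))
  expect_equal(remove_named_taxa(tab, character(0))$table$counts, tab$counts)
})

test_that("prevalence filter implements >= min_reads in >= min_samples", {
  counts <- rbind(s1_Whole = c(keep1 = 6L, drop1 = 6L, keep2 = 7L),
                  s2_Whole = c(keep1 = 6L, drop1 = 5L, keep2 = 6L),
                  s3_Whole = c(keep1 = 0L, drop1 = 5L, keep2 = 1L))
  tab <- make_table(counts)
  res <- prevalence_filter(tab, min_reads = 6, min_samples = 2)
  expect_setequal(colnames(res$table$counts), c("keep1", "keep2"))
  expect_equal(res$report$removed_asvs, "drop1")
  expect_error(prevalence_filter(tab, min_reads = 0), ">= 1")
})

test_that("the VST uses median-of-ratios size factors", {
  counts <- rbind(A = c(10L, 20L, 40L), B = c(20L, 40L, 80L))
  colnames(counts) <- paste0("t", 1:3)
  v <- vst_transform(counts)
  sf <- attr(v, "size_factors")
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-12)
  expect_equal(v["A", ], v["B", ], tolerance = 1e-12)  # same composition
  # identical samples: unit size factors, identical columns
  eq <- rbind(A = c(5L, 9L, 2L), B = c(5L, 9L, 2L))
  v2 <- vst_transform(eq)
  expect_equal(unname(attr(v2, "size_factors")), c(1, 1))
  # monotone within a sample
  expect_true(all(diff(v2["A", order(eq["A", ])]) >= 0))
})

test_that("size factors agree with the DESeq2 median-of-ratios estimator", {
  skip_if_not_installed("DESeq2")
  co <- simulate_cohort(small_config(seed = 9))
  counts <- co$counts[1:12, colSums(co$counts[1:12, ]) > 0]
  sf <- attr(vst_transform(counts), "size_factors")
  ref <- DESeq2::estimateSizeFactorsForMatrix(t(counts))
  expect_equal(unname(sf), unname(ref), tolerance = 1e-8)
})

test_that("VST falls back to library-size factors without an always-present ASV", {
  counts <- rbind(A = c(10L, 0L), B = c(0L, 30L))
  colnames(counts) <- c("t1", "t2")
  expect_warning(v <- vst_transform(counts), "library-size")
  expect_equal(unname(attr(v, "size_factors")), c(0.5, 1.5))
})

test_that("rarefaction subsamples to exact depth, deterministically", {
  co <- simulate_cohort(small_config(seed = 3))
  # sheath controls sit below the depth and are dropped with a warning
  expect_warning(r1 <- rarefy_counts(co$counts, depth = 1000, seed = 11),
                 "dropping")
  expect_true(all(rowSums(r1) == 1000))
  expect_true(all(r1 <= co$counts[rownames(r1), ]))
  expect_identical(r1, suppressWarnings(
    rarefy_counts(co$counts, depth = 1000, seed = 11)))
  # a sample already at depth is returned unchanged
  x <- matrix(c(600L, 400L), 1, 2, dimnames = list("s", c("a", "b")))
  expect_equal(suppressWarnings(rarefy_counts(x, depth = 1000, seed = 1)), x)
  w <- capture_warnings(rarefy_counts(rbind(x, low = c(3L, 2L)), 1000,
                                      seed = 1))
  expect_match(w, "dropping", all = FALSE)
  expect_error(rarefy_counts(x, depth = 2000), "below the rarefaction depth")
})

test_that("the filter cascade reconciles and is ordered", {
  co <- simulate_cohort(small_config(seed = 7))
  tab <- validate_count_table(co$counts, co$metadata)
  pp <- preprocess_counts(tab, taxonomy = co$taxonomy, min_reads = 2,
                          min_samples = 2)
  expect_named(pp$reports, c("sheath", "phylum", "prevalence"))
  removed <- unlist(lapply(pp$reports, function(r) r$removed_asvs))
  expect_equal(anyDuplicated(removed), 0)  # rules remove disjoint sets
  expect_equal(ncol(tab$counts), ncol(pp$table$counts) + length(removed))
})
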