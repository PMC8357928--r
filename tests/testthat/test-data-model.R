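# Typed containers, TSV round-trips, alignment, and abundance transforms.

make_abundance <- function() {
  v <- matrix(c(0.5, 0.3, 0.2,
                0.0, 0.6, 0.4,
                0.9, 0.0, 0.1), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), c("taxA", "taxB", "taxC")))
  abundance_table(v, group = c("rural", "urban", "urban"))
}

test_that("abundance round-trips through TSV to high precision", {
  ab <- make_abundance()
  f <- tempfile(fileext = ".tsv")
  write_table(ab, f, header_comment = "fixture")
  back <- read_table(f, "abundance")
  expect_equal(back$values, ab$values, tolerance = 1e-12)
  expect_equal(unname(back$group), unname(ab$group))
})

test_that("taxa-by-samples orientation (merged profiler table) is accepted", {
  ab <- make_abundance()
  f <- tempfile(fileext = ".tsv")
  df <- data.frame(taxon_id = colnames(ab$values), t(ab$values), check.names = FALSE)
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_table(f, "abundance", orientation = "taxa_by_samples")
  expect_equal(back$values[rownames(ab$values), colnames(ab$values)], ab$values,
               tolerance = 1e-12)
})

test_that("validators name the offending record", {
  v <- matrix(0.1, 2, 2, dimnames = list(c("a", "a"), c("t1", "t2")))
  expect_error(abundance_table(v), "duplicate sample ID: 'a'")
  v2 <- matrix(c(0.1, -0.2, 0.3, 0.4), 2, dimnames = list(c("a", "b"), c("t1", "t2")))
  expect_error(abundance_table(v2), "negative abundance")
  expect_error(subject_metadata(data.frame(subject_id = c("x", "x"), age = 1,
                                           sex = 0, residency = "r")),
               "duplicate subject ID")
})

test_that("percent-scale abundances are detected and rescaled", {
  v <- matrix(c(60, 40, 30, 70), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("t1", "t2")))
  expect_message(ab <- abundance_table(v), "percentages")
  expect_equal(rowSums(ab$values), c(a = 1, b = 1))
})

test_that("nonpositive cytokine concentrations are dropped with a count", {
  df <- data.frame(subject_id = c("a", "a", "b"), cytokine = "IL-6",
                   stimulus = c("LPS", "E.coli", "LPS"),
                   concentration = c(10, -1, NA))
  expect_message(cm <- cytokine_measurements(df), "2 cytokine record")
  expect_equal(nrow(cm), 1L)
  expect_equal(attr(cm, "n_dropped"), 2L)
  dup <- data.frame(subject_id = "a", cytokine = "IL-6", stimulus = "LPS",
                    concentration = c(1, 2))
  expect_error(cytokine_measurements(dup), "duplicate")
})

test_that("cohort alignment intersects, reports drops, and is idempotent", {
  ab <- make_abundance()
  md <- subject_metadata(data.frame(subject_id = c("s1", "s2", "s3", "s4"),
                                    age = c(30, 40, 50, 60), sex = c(0, 1, 0, 1),
                                    residency = "urban"))
  al <- align_cohort(abundance = ab, metadata = md)
  expect_equal(al$ids, c("s1", "s2", "s3"))
  expect_equal(unname(al$dropped), c(0L, 1L))
  al2 <- align_cohort(abundance = al$abundance, metadata = al$metadata)
  expect_equal(al2$abundance$values, al$abundance$values)
  expect_equal(unname(al2$dropped), c(0L, 0L))
  md_disjoint <- subject_metadata(data.frame(subject_id = "zz", age = 1, sex = 0,
                                             residency = "r"))
  expect_error(align_cohort(abundance = ab, metadata = md_disjoint), "no samples shared")
})

test_that("prevalence is the strict detection fraction", {
  ab <- make_abundance()
  expect_equal(prevalence(ab, "taxA"), 2 / 3)
  expect_equal(prevalence(ab, "taxC"), 1)
  zero <- abundance_table(matrix(0, 2, 1, dimnames = list(c("a", "b"), "t")))
  expect_equal(prevalence(zero, "t"), 0)
  expect_error(prevalence(ab, "nope"), "unknown taxon")
})

test_that("zero-anchored rank transform follows the stated rule", {
  expect_equal(rank_transform_abundance(c(0, 0.5, 0.2, 0)), c(0, 3, 2, 0))
  expect_equal(rank_transform_abundance(rep(0, 5)), rep(0, 5))
  # n = 299 with a unique maximum: max gets 298, zeros get 0
  set.seed(9)
  v <- c(rep(0, 50), runif(248), 2)
  r <- rank_transform_abundance(v)
  expect_equal(r[299], 298)
  expect_true(all(r[1:50] == 0))
  expect_equal(sort(unique(r)), c(0, 50:298))
  # scale invariance and permutation-with-ties structure
  expect_equal(rank_transform_abundance(v * 17.3), r)
  expect_error(rank_transform_abundance(c(-1, 2)), "nonnegative")
})

test_that("mid-ranks are used for tied nonzero abundances", {
  r <- rank_transform_abundance(c(0, 0.2, 0.2, 0.7))
  expect_equal(r, c(0, 1.5, 1.5, 3))
})

test_that("fold change is a guarded ratio", {
  expect_equal(fold_change(1.1, 0.2), 5.5)
  expect_equal(fold_change(3, 3), 1)
  expect_equal(fold_change(0, 1), 0)
  expect_error(fold_change(1, 0), "positive")
})

test_that("pathway copy tables validate depth coverage", {
  df <- data.frame(sample_id = c("a", "b"), species_id = "sp1",
                   pathway_id = "pwy1", copies = c(1, 2))
  expect_error(pathway_copy_table(df, read_depth = c(a = 1e6)), "no read depth")
  pt <- pathway_copy_table(df, read_depth = c(a = 1e6, b = 2e6))
  f <- tempfile(fileext = ".tsv")
  write_table(pt, f)
  back <- read_table(f, "pathway")
  expect_equal(back$records$copies, pt$records$copies, tolerance = 1e-12)
  expect_equal(back$read_depth[c("a", "b")], pt$read_depth[c("a", "b")])
})
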