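# Metabolome integration: per-species effects, distribution comparisons,
# correlation tallies, and ARI-selected clustering.

test_that("a strictly monotone species-metabolite pair yields E_s = 1", {
  set.seed(1)
  n <- 20
  ab <- abundance_table(matrix(runif(n, 0.01, 0.5), n, 1,
                               dimnames = list(sprintf("s%02d", 1:n), "spA")))
  peaks <- cbind(mono = exp(ab$values[, 1]) * 100,
                 noise = runif(n))
  rownames(peaks) <- rownames(ab$values)
  mt <- metabolite_table(peaks)
  res <- species_metabolome_effects(ab, mt)
  row <- res$effects[res$effects$species_id == "spA", ]
  expect_equal(row$max_abs_rho, 1)
  expect_equal(row$best_metabolite, "mono")
  expect_true(row$significant)
})

test_that("the hand-computed spearman pair is reproduced as a best pair", {
  samples <- sprintf("s%d", 1:5)
  ab <- abundance_table(matrix((1:5) / 10, 5, 1, dimnames = list(samples, "spA")))
  mt <- metabolite_table(matrix(c(2, 1, 4, 3, 5), 5, 1, dimnames = list(samples, "pk")))
  res <- species_metabolome_effects(ab, mt)
  expect_equal(res$effects$max_abs_rho, 0.8, tolerance = 1e-12)
})

test_that("constant peaks are skipped, not fatal", {
  set.seed(2)
  samples <- sprintf("s%d", 1:10)
  ab <- abundance_table(matrix(runif(10, 0, 0.5), 10, 1, dimnames = list(samples, "spA")))
  mt <- metabolite_table(cbind(flat = rep(1, 10), ok = runif(10)) |>
                           `rownames<-`(samples))
  expect_message(res <- species_metabolome_effects(ab, mt), "skipped")
  expect_equal(res$effects$best_metabolite, "ok")
})

test_that("effect-distribution comparison separates lifted positive species", {
  eff <- data.frame(species_id = sprintf("s%d", 1:12),
                    max_abs_rho = c(0.95, 0.9, 0.85, runif(9, 0.1, 0.3)),
                    effect_class = c(rep("positive", 3), rep("neutral", 9)))
  cmp <- compare_effect_distributions(eff)
  # all positive E_s above the neutral maximum: minimal one-sided p = 1/C(12,3)
  expect_equal(cmp$positive_vs_neutral$p_value, 1 / choose(12, 3), tolerance = 1e-10)
  expect_message(
    cmp2 <- compare_effect_distributions(eff[eff$effect_class != "positive", ]),
    "skipped")
  expect_null(cmp2$positive_vs_neutral)
})

test_that("metabolite-cytokine screen flags a planted coupling and respects pair n", {
  set.seed(3)
  n <- 60
  subjects <- sprintf("s%02d", 1:n)
  latent <- rnorm(n)
  cy <- cytokine_measurements(data.frame(
    subject_id = rep(subjects, 2),
    cytokine = rep(c("IL-6", "TNF-a"), each = n),
    stimulus = "LPS",
    concentration = exp(c(latent + rnorm(n, 0, 0.4), rnorm(n)))))
  peaks <- cbind(coupled = exp(latent + rnorm(n, 0, 0.4)),
                 junk1 = runif(n), junk2 = runif(n))
  rownames(peaks) <- subjects
  mt <- metabolite_table(peaks)
  res <- metabolite_cytokine_correlations(mt, cy)
  hit <- res$pairs[res$pairs$peak_id == "coupled" & res$pairs$cytokine == "IL-6", ]
  expect_true(hit$significant)
  expect_equal(hit$n, n)
  expect_true(res$per_peak$any_significant[res$per_peak$peak_id == "coupled"])
})

test_that("pathway tallies count correlations by sign and apply the floors", {
  ann <- pathway_annotation(
    enzymes = list(pwy1 = sprintf("K%02d", 1:12), pwy2 = sprintf("K%02d", 1:9)),
    compounds = list(pwy1 = c("c1", "c2", "c3"), pwy2 = "c4"))
  peak_ann <- data.frame(peak_id = c("p1", "p2", "p3", "p4"),
                         pathway_ids = c("pwy1", "pwy1", "pwy1", "pwy2"))
  cyto_pairs <- data.frame(peak_id = c("p1", "p2", "p3", "p4"),
                           rho = c(0.5, 0.4, -0.3, 0.2),
                           significant = c(TRUE, TRUE, TRUE, FALSE))
  sp_pairs <- data.frame(species_id = "spX", peak_id = c("p1", "p2", "p3"))
  eff <- data.frame(species_id = "spX", classification = "positive")
  tl <- tally_pathways(ann, peak_ann, cyto_pairs, sp_pairs, eff)
  p1 <- tl[tl$pathway_id == "pwy1", ]
  expect_equal(p1$n_positive_assoc, 2L)
  expect_equal(p1$n_negative_assoc, 1L)
  expect_equal(p1$n_immunomod_metabolites, 3L)
  expect_true(p1$pass_enzyme_floor)       # 12 >= 10
  expect_true(p1$pass_metabolite_floor)   # 3 >= 3
  p2 <- tl[tl$pathway_id == "pwy2", ]
  expect_false(p2$pass_enzyme_floor)      # 9 < 10
  expect_equal(p2$n_positive_assoc, 0L)   # p4 not significant
  # additivity over disjoint annotations
  expect_equal(p1$n_positive_assoc + p2$n_positive_assoc, 2L)
})

test_that("ARI matches the pair-counting oracle and the worked example", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_equal(adjusted_rand_index(1:6, 1:6), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(5, 5, 9, 9)), 1)  # label-invariant
  set.seed(4)
  for (i in 1:25) {
    a <- sample(3, 12, replace = TRUE)
    b <- sample(4, 12, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), oracle_ari(a, b), tolerance = 1e-10)
  }
})

test_that("ARI agrees with the established implementation", {
  skip_if_not_installed("mclust")
  set.seed(5)
  for (i in 1:10) {
    a <- sample(4, 30, replace = TRUE)
    b <- sample(3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-10)
  }
})

test_that("k selection is deterministic and ties break toward smaller k", {
  set.seed(6)
  n <- 40
  f <- matrix(rnorm(n * 3), n, 3)
  cls <- rep(1:3, length.out = 24)
  peaks <- sapply(seq_len(24), function(j) f[, cls[j]] + rnorm(n, 0, 0.1))
  dimnames(peaks) <- list(sprintf("s%02d", 1:n), sprintf("pk%02d", 1:24))
  ann <- data.frame(peak_id = colnames(peaks),
                    molecular_class = paste0("cl", cls))
  mt <- metabolite_table(exp(peaks), annotation = ann)
  c1 <- cluster_metabolites(mt, k_range = 2:6, seed = 99)
  c2 <- cluster_metabolites(mt, k_range = 2:6, seed = 99)
  expect_identical(c1$k, c2$k)
  expect_identical(c1$partition, c2$partition)
  expect_equal(c1$k, 3)
  expect_gt(c1$ari[["3"]], 0.9)
  expect_equal(sort(unique(unname(c1$cluster_classes))), c("cl1", "cl2", "cl3"))
})

test_that("E_s is invariant under strictly monotone transforms of intensities", {
  set.seed(7)
  n <- 15
  samples <- sprintf("s%02d", 1:n)
  ab <- abundance_table(matrix(runif(n, 0, 0.5), n, 1, dimnames = list(samples, "spA")))
  raw <- matrix(runif(n * 3, 1, 10), n, 3, dimnames = list(samples, c("a", "b", "c")))
  r1 <- species_metabolome_effects(ab, metabolite_table(raw))
  r2 <- species_metabolome_effects(ab, metabolite_table(raw^3))
  expect_equal(r1$effects$max_abs_rho, r2$effects$max_abs_rho, tolerance = 1e-12)
})
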