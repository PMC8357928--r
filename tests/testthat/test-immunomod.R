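# Pooled log-linear cytokine model and immunomodulatory classification.

small_cytokine_fixture <- function() {
  subjects <- c("a", "b", "c", "d")
  grid <- expand.grid(subject_id = subjects,
                      cytokine = c("IL-6", "TNF-a"),
                      stimulus = c("LPS", "E.coli", "Poly:IC"),
                      stringsAsFactors = FALSE)
  grid$concentration <- exp(rnorm(nrow(grid), 3, 1))
  md <- subject_metadata(data.frame(subject_id = subjects,
                                    age = c(20, 30, 40, 50), sex = c(0, 1, 0, 1),
                                    residency = "urban"))
  v <- matrix(runif(8, 0.1, 0.4), 4, 2,
              dimnames = list(subjects, c("sp1", "sp2")))
  list(cy = cytokine_measurements(grid), md = md, ab = abundance_table(v))
}

test_that("observation grid counts follow the stimulus set", {
  set.seed(1)
  fx <- small_cytokine_fixture()
  obs <- build_observation_table(fx$cy, fx$md, fx$ab)
  # Poly:IC excluded by default: 4 subjects x 2 cytokines x 2 stimuli
  expect_equal(nrow(obs$obs), 16L)
  expect_equal(obs$grid_size, 16L)
  obs_all <- build_observation_table(fx$cy, fx$md, fx$ab, excluded_stimuli = character(0))
  expect_equal(nrow(obs_all$obs), 24L)
  # one record absent from a 2x2x2 grid leaves 7 rows
  cy7 <- fx$cy[!(fx$cy$subject_id == "a" & fx$cy$cytokine == "IL-6" &
                   fx$cy$stimulus == "LPS"), ]
  cy7 <- cy7[cy7$stimulus != "Poly:IC" & cy7$subject_id %in% c("a", "b"), ]
  obs7 <- build_observation_table(cytokine_measurements(cy7), fx$md, fx$ab)
  expect_equal(nrow(obs7$obs), 7L)
})

test_that("noiseless planted effects are recovered to machine precision", {
  cfg <- tiny_config(noise_sd = 0, missing_fraction = 0,
                     immunomod_spec = data.frame(species = 5, beta = 0.005))
  md <- simulate_metadata(cfg, 2)
  ab <- simulate_abundances(cfg, 2, md)
  cy <- simulate_cytokines(ab$table, md, cfg, 2)
  obs <- build_observation_table(cy$table, md, ab$table)
  eff <- fit_species_effect(obs, "sp005")
  expect_equal(eff$beta_m, 0.005, tolerance = 1e-10)
  expect_equal(eff$p_raw, 0)
})

test_that("the FWL species scan equals the full per-species least-squares fit", {
  cfg <- tiny_config()
  md <- simulate_metadata(cfg, 3)
  ab <- simulate_abundances(cfg, 3, md)
  cy <- simulate_cytokines(ab$table, md, cfg, 3)
  obs <- build_observation_table(cy$table, md, ab$table)
  scan <- fit_species_effects(obs, species = c("sp002", "sp010", "sp020"))
  for (s in scan$species_id) {
    single <- fit_species_effect(obs, s)
    row <- scan[scan$species_id == s, ]
    expect_equal(row$beta_m, single$beta_m, tolerance = 1e-10, info = s)
    expect_equal(row$std_error, single$std_error, tolerance = 1e-10, info = s)
    expect_equal(row$p_raw, single$p_raw, tolerance = 1e-10, info = s)
  }
})

test_that("beta is invariant to the dummy reference level and to response shifts", {
  set.seed(4)
  fx <- small_cytokine_fixture()
  obs <- build_observation_table(fx$cy, fx$md, fx$ab)
  base <- fit_species_effect(obs, "sp1")
  # reorder the (cytokine, stimulus) labels so a different level is reference
  obs2 <- obs
  obs2$obs$cytokine <- factor(obs$obs$cytokine, levels = c("TNF-a", "IL-6"))
  ref_switched <- fit_species_effect(obs2, "sp1")
  expect_equal(ref_switched$beta_m, base$beta_m, tolerance = 1e-10)
  expect_equal(ref_switched$p_raw, base$p_raw, tolerance = 1e-10)
  # adding a constant to all log responses moves only the intercept
  obs3 <- obs
  obs3$obs$log_response <- obs$obs$log_response + 7
  shifted <- fit_species_effect(obs3, "sp1")
  expect_equal(shifted$beta_m, base$beta_m, tolerance = 1e-10)
})

test_that("a constant rank vector yields an undefined, flagged effect", {
  set.seed(5)
  fx <- small_cytokine_fixture()
  fx$ab$values[, "sp2"] <- 0
  obs <- build_observation_table(fx$cy, fx$md, fx$ab)
  eff <- fit_species_effects(obs, "sp2")
  expect_false(eff$defined)
  expect_true(is.na(eff$beta_m))
})

test_that("classification applies the bonferroni threshold, prevalence floor and sign", {
  eff <- data.frame(species_id = c("s1", "s2", "s3", "s4"),
                    beta_m = c(0.01, -0.02, 0.01, 0.005),
                    p_raw = c(1e-6, 1e-6, 0.01, 1e-6),
                    prevalence = c(0.5, 0.5, 0.9, 0.1),
                    defined = TRUE)
  cl <- classify_species(eff, n_tested = 111)
  expect_equal(cl$effects$classification, c("positive", "negative", "neutral", "neutral"))
  # p = 0.01 over 111 tests bonferroni-saturates at 1
  expect_equal(cl$effects$p_bonferroni[3], 1)
  expect_equal(unname(cl$counts), c(1L, 1L, 2L))
})

test_that("subject-clustered standard errors restore classification under strong planted effects", {
  # the pooled model treats repeated per-subject observations as independent;
  # omitted planted species then act as clustered noise that inflates plain
  # OLS t-statistics of null species. The subject-clustered (CR0) diagnostic
  # accounts for this: planted species are recovered with correct signs and
  # false positives are rare.
  fp <- 0L; missed <- 0L
  for (s in 1:5) {
    cfg <- sim_config(immunomod_spec = data.frame(species = 7:13,
                                                  beta = c(rep(0.004, 4), rep(-0.004, 3))))
    md <- simulate_metadata(cfg, s)
    ab <- simulate_abundances(cfg, s, md)
    cy <- simulate_cytokines(ab$table, md, cfg, s)
    obs <- build_observation_table(cy$table, md, ab$table)
    eff <- fit_species_effects(obs, se = "cluster")
    tested <- eff$defined & eff$prevalence > 0.2
    cl <- classify_species(eff[tested, ], n_tested = sum(tested))
    e <- cl$effects
    pos <- e$species_id[e$classification == "positive"]
    neg <- e$species_id[e$classification == "negative"]
    want_pos <- sprintf("sp%03d", 7:10)
    want_neg <- sprintf("sp%03d", 11:13)
    missed <- missed + length(setdiff(want_pos, pos)) + length(setdiff(want_neg, neg))
    fp <- fp + length(setdiff(c(pos, neg), c(want_pos, want_neg)))
  }
  expect_equal(missed, 0L)
  expect_lte(fp, 10L)
})
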