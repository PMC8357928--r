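# Per-microbe pooled log-linear model of ex vivo cytokine responses:
#
#   ln y[c,s,i] = b0 + b[c,s] + b_age * age_i + b_sex * sex_i
#               + b_m * rank(abundance of microbe m in subject i) + noise
#
# fit once per microbe over all (cytokine, stimulus, subject) observations
# pooled, with a two-sided t-test on b_m. Species are then classified
# positive / negative / neutral under a Bonferroni threshold and a
# prevalence floor.

#' Assemble the pooled observation table
#'
#' One row per available (subject, cytokine, stimulus) record with the natural
#' log of the concentration, subject age and sex, plus a subjects x species
#' matrix of zero-anchored abundance ranks computed over the included
#' subjects. Records for excluded stimuli are removed; nonpositive
#' concentrations were already dropped at table construction.
#'
#' @param cytokines A [cytokine_measurements] table.
#' @param metadata A [subject_metadata] table.
#' @param abundances An [abundance_table].
#' @param excluded_stimuli Stimuli excluded from modeling (default the
#'   viral TLR3 ligand "Poly:IC", whose responses do not correlate with the
#'   rest of the panel).
#' @return Object of class `observation_table`: list with `obs` (data frame:
#'   subject_id, cytokine, stimulus, log_response, age, sex), `ranks`
#'   (subjects x species), `subjects`, and `grid_size` (the full
#'   cytokines x stimuli x subjects grid count).
#' @export
build_observation_table <- function(cytokines, metadata, abundances,
                                    excluded_stimuli = "Poly:IC") {
  stopifnot(inherits(abundances, "abundance_table"))
  cy <- as.data.frame(cytokines)
  cy <- cy[!cy$stimulus %in% excluded_stimuli, , drop = FALSE]
  subjects <- intersect(intersect(unique(cy$subject_id), metadata$subject_id),
                        rownames(abundances$values))
  if (length(subjects) == 0L) stop("no subject has cytokines, metadata and a microbial profile", call. = FALSE)
  cy <- cy[cy$subject_id %in% subjects, , drop = FALSE]
  md <- metadata[match(cy$subject_id, metadata$subject_id), ]
  obs <- data.frame(subject_id = cy$subject_id,
                    cytokine = cy$cytokine,
                    stimulus = cy$stimulus,
                    log_response = log(cy$concentration),
                    age = md$age, sex = md$sex,
                    stringsAsFactors = FALSE)
  ranks <- apply(abundances$values[subjects, , drop = FALSE], 2L,
                 rank_transform_abundance)
  rownames(ranks) <- subjects
  structure(
    list(obs = obs, ranks = ranks, subjects = subjects,
         grid_size = length(unique(obs$cytokine)) *
           length(unique(obs$stimulus)) * length(subjects)),
    class = "observation_table"
  )
}

#' @export
print.observation_table <- function(x, ...) {
  cat(sprintf("<observation_table> %d observations (%d of full grid %d), %d subjects, %d species\n",
              nrow(x$obs), nrow(x$obs), x$grid_size, length(x$subjects), ncol(x$ranks)))
  invisible(x)
}

# common covariate design: intercept, cytokine x stimulus dummies (one
# reference level), age, sex
immunomod_design <- function(obs) {
  cs <- interaction(obs$cytokine, obs$stimulus, drop = TRUE)
  stats::model.matrix(~ cs + age + sex, data = cbind(obs, cs = cs))
}

#' Fit the pooled cytokine model for one microbe
#'
#' Single least-squares fit with design columns: intercept,
#' cytokine x stimulus interaction dummies (one reference level), age, sex,
#' and the zero-anchored rank abundance of microbe `species`. Returns the
#' microbial coefficient with its two-sided t-test.
#'
#' @param obs An [observation_table].
#' @param species Species (column of `obs$ranks`) to test.
#' @return One-row data frame of class `species_effect`: species_id, beta_m,
#'   std_error, t_value, p_raw, prevalence, n_obs, defined (FALSE when the
#'   rank vector is constant and the effect is not estimable).
#' @export
fit_species_effect <- function(obs, species) {
  stopifnot(inherits(obs, "observation_table"))
  if (!species %in% colnames(obs$ranks)) stop(sprintf("unknown species '%s'", species), call. = FALSE)
  X <- immunomod_design(obs$obs)
  mic <- obs$ranks[obs$obs$subject_id, species]
  design <- cbind(X, mic = mic)
  fit <- fit_linear_model(design, obs$obs$log_response)
  beta <- fit$coefficients[["mic"]]
  defined <- !is.na(beta) && !is.na(fit$p_values[["mic"]])
  out <- data.frame(species_id = species,
                    beta_m = beta,
                    std_error = fit$std_errors[["mic"]],
                    t_value = fit$t_values[["mic"]],
                    p_raw = fit$p_values[["mic"]],
                    prevalence = mean(obs$ranks[, species] > 0),
                    n_obs = fit$n_obs,
                    defined = defined,
                    stringsAsFactors = FALSE)
  class(out) <- c("species_effect", "data.frame")
  out
}

#' Fit the pooled cytokine model for every species
#'
#' Equivalent to calling [fit_species_effect] per species, but the shared
#' covariate block (intercept, cytokine x stimulus dummies, age, sex) is
#' QR-factorized once and each microbe's rank vector and the response are
#' residualized against it (Frisch-Waugh-Lovell), giving identical
#' coefficients, standard errors and t-tests at a fraction of the cost.
#'
#' With `se = "cluster"`, subject-clustered (CR0 sandwich) standard errors
#' replace the OLS ones as a diagnostic for the pooled design's independence
#' assumption: repeated observations of one subject share any unmodeled
#' subject-level signal, which plain OLS understates. Coefficients are
#' unchanged; t-tests then use n_subjects - 1 degrees of freedom.
#'
#' @param obs An [observation_table].
#' @param species Species to test (default: all columns of `obs$ranks`).
#' @param se "ols" (primary inference, as the original model) or "cluster"
#'   (subject-clustered robust diagnostic).
#' @return Data frame with one row per species (fields as in
#'   [fit_species_effect]).
#' @export
fit_species_effects <- function(obs, species = colnames(obs$ranks),
                                se = c("ols", "cluster")) {
  stopifnot(inherits(obs, "observation_table"))
  se <- match.arg(se)
  X <- immunomod_design(obs$obs)
  y <- obs$obs$log_response
  qx <- qr(X)
  p_full <- qx$rank + 1L  # + the microbe column
  n <- length(y)
  df <- n - p_full
  ry <- qr.resid(qx, y)
  idx <- match(obs$obs$subject_id, rownames(obs$ranks))
  out <- lapply(species, function(s) {
    mic <- obs$ranks[idx, s]
    rm_ <- qr.resid(qx, mic)
    ss_m <- sum(rm_^2)
    if (ss_m < 1e-10 || df <= 0) {
      return(data.frame(species_id = s, beta_m = NA_real_, std_error = NA_real_,
                        t_value = NA_real_, p_raw = NA_real_,
                        prevalence = mean(obs$ranks[, s] > 0), n_obs = n,
                        defined = FALSE, stringsAsFactors = FALSE))
    }
    beta <- sum(rm_ * ry) / ss_m
    if (se == "ols") {
      rss <- sum(ry^2) - beta^2 * ss_m
      sd_b <- sqrt(max(rss, 0) / df / ss_m)
      df_t <- df
    } else {
      eh <- ry - beta * rm_
      scores <- tapply(rm_ * eh, obs$obs$subject_id, sum)
      sd_b <- sqrt(sum(scores^2)) / ss_m
      df_t <- length(scores) - 1L
    }
    tv <- beta / sd_b
    data.frame(species_id = s, beta_m = beta, std_error = sd_b, t_value = tv,
               p_raw = 2 * stats::pt(-abs(tv), df = df_t),
               prevalence = mean(obs$ranks[, s] > 0), n_obs = n,
               defined = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("species_effect", "data.frame")
  out
}

#' Classify species as positive / negative / neutral immunomodulators
#'
#' Bonferroni-adjusts the raw per-microbe p-values over the number of tested
#' species, then classifies: positive if adjusted p < `p_threshold`,
#' prevalence > `prevalence_min`, and the coefficient is positive; negative
#' symmetrically; neutral otherwise.
#'
#' @param effects Data frame from [fit_species_effects].
#' @param n_tested Bonferroni denominator: the number of species fitted
#'   (defaults to the number of rows with a defined effect).
#' @param p_threshold Bonferroni-adjusted significance threshold (default 0.005).
#' @param prevalence_min Strict prevalence floor (default 0.20).
#' @return List with `effects` (input plus `p_bonferroni` and
#'   `classification`) and `counts` (named positive/negative/neutral totals).
#' @export
classify_species <- function(effects, n_tested = sum(effects$defined),
                             p_threshold = 0.005, prevalence_min = 0.20) {
  stopifnot(is.data.frame(effects), n_tested >= 1)
  effects$p_bonferroni <- pmin(1, effects$p_raw * n_tested)
  sig <- !is.na(effects$p_bonferroni) &
    effects$p_bonferroni < p_threshold &
    effects$prevalence > prevalence_min
  effects$classification <- ifelse(!sig, "neutral",
                                   ifelse(effects$beta_m > 0, "positive", "negative"))
  counts <- c(positive = sum(effects$classification == "positive"),
              negative = sum(effects$classification == "negative"),
              neutral = sum(effects$classification == "neutral"))
  list(effects = effects, counts = counts)
}
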