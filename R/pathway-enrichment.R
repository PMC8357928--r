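# Per-pathway log-linear model of species-stratified pathway copy numbers:
#
#   ln y[p,m,i] = b0 + b_depth * ln(reads_i) + b_mic * abundance[m,i]
#               + b_e[class(m)] + noise
#
# where class(m) is the microbe's immunomodulatory classification (positive /
# negative / neutral, neutral as the reference level absorbed by the
# intercept). A significant positive-class or negative-class coefficient
# reveals over- or under-representation of the pathway's gene copies in
# immunomodulatory genomes. Unlike the cytokine model, abundance enters as
# the raw relative fraction, not a rank.

#' Assemble pathway copy-number observations
#'
#' One row per (pathway, species, sample) with positive copies: log copies,
#' log read depth, the species' relative abundance in the sample, and the
#' species' immunomodulatory class. Species missing from the classification
#' default to neutral (with a message).
#'
#' @param copies A [pathway_copy_table].
#' @param abundances An [abundance_table] covering the table's samples.
#' @param effects Classified effects data frame (from [classify_species]),
#'   with columns species_id and classification.
#' @return Data frame of class `pathway_observations`: pathway_id, species_id,
#'   sample_id, log_copies, log_depth, rel_abundance, effect_class.
#' @export
build_pathway_observations <- function(copies, abundances, effects) {
  stopifnot(inherits(copies, "pathway_copy_table"), inherits(abundances, "abundance_table"))
  rec <- copies$records
  rec <- rec[rec$copies > 0, , drop = FALSE]
  if (nrow(rec) == 0L) stop("no positive copy-number records", call. = FALSE)
  if (any(copies$read_depth[as.character(rec$sample_id)] <= 0)) {
    stop("zero read depth", call. = FALSE)
  }
  cls <- stats::setNames(effects$classification, effects$species_id)
  unknown <- setdiff(unique(rec$species_id), names(cls))
  if (length(unknown)) {
    message(sprintf("%d species without effect classification treated as neutral", length(unknown)))
  }
  eff <- unname(cls[as.character(rec$species_id)])
  eff[is.na(eff)] <- "neutral"
  missing_sp <- setdiff(unique(rec$species_id), colnames(abundances$values))
  if (length(missing_sp)) {
    stop(sprintf("species without abundance profile: %s",
                 paste(utils::head(missing_sp, 3L), collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(
    pathway_id = rec$pathway_id,
    species_id = rec$species_id,
    sample_id = rec$sample_id,
    log_copies = log(rec$copies),
    log_depth = log(copies$read_depth[as.character(rec$sample_id)]),
    rel_abundance = abundances$values[cbind(as.character(rec$sample_id),
                                            as.character(rec$species_id))],
    effect_class = factor(eff, levels = c("neutral", "positive", "negative")),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("pathway_observations", "data.frame")
  out
}

#' Fit the copy-number enrichment model for one pathway
#'
#' Least-squares fit of log copies on intercept, log depth, relative
#' abundance, and positive/negative class dummies (neutral reference), with
#' two-sided t-tests per dummy. A class with no contributing species leaves
#' that coefficient undefined (NA), flagged rather than raised. Significance
#' stars follow the raw p-value: * p < 0.1, ** p < 0.01, *** p < 0.001.
#'
#' @param obs Rows of a `pathway_observations` frame for a single pathway.
#' @return One-row data frame of class `pathway_effect`: pathway_id, n_obs,
#'   beta_e_positive, p_positive, stars_positive, beta_e_negative, p_negative,
#'   stars_negative, beta_depth, beta_mic, n_classes.
#' @export
fit_pathway_effect <- function(obs) {
  stopifnot(is.data.frame(obs))
  pid <- unique(as.character(obs$pathway_id))
  if (length(pid) != 1L) stop("fit_pathway_effect expects observations for exactly one pathway", call. = FALSE)
  present <- unique(as.character(obs$effect_class))
  if (length(present) < 2L) {
    return(data.frame(pathway_id = pid, n_obs = nrow(obs),
                      beta_e_positive = NA_real_, p_positive = NA_real_, stars_positive = "",
                      beta_e_negative = NA_real_, p_negative = NA_real_, stars_negative = "",
                      beta_depth = NA_real_, beta_mic = NA_real_,
                      n_classes = length(present), stringsAsFactors = FALSE))
  }
  design <- cbind(`(Intercept)` = 1,
                  log_depth = obs$log_depth,
                  rel_abundance = obs$rel_abundance)
  if ("positive" %in% present) design <- cbind(design, positive = as.numeric(obs$effect_class == "positive"))
  if ("negative" %in% present) design <- cbind(design, negative = as.numeric(obs$effect_class == "negative"))
  fit <- fit_linear_model(design, obs$log_copies)
  star <- function(p) {
    if (is.na(p)) "" else if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.1) "*" else ""
  }
  getc <- function(name, field) {
    if (name %in% names(fit$coefficients)) fit[[field]][[name]] else NA_real_
  }
  bp <- getc("positive", "coefficients"); pp <- getc("positive", "p_values")
  bn <- getc("negative", "coefficients"); pn <- getc("negative", "p_values")
  data.frame(pathway_id = pid, n_obs = nrow(obs),
             beta_e_positive = bp, p_positive = pp, stars_positive = star(pp),
             beta_e_negative = bn, p_negative = pn, stars_negative = star(pn),
             beta_depth = getc("log_depth", "coefficients"),
             beta_mic = getc("rel_abundance", "coefficients"),
             n_classes = length(present), stringsAsFactors = FALSE)
}

#' Fit the enrichment model across all pathways
#'
#' @param obs A `pathway_observations` frame (from
#'   [build_pathway_observations]).
#' @param fdr Also add BH-adjusted p-values across pathways (off by default;
#'   per-pathway raw p stars are the primary readout).
#' @return Data frame with one row per pathway (fields of [fit_pathway_effect],
#'   plus p_positive_fdr / p_negative_fdr when `fdr = TRUE`).
#' @export
fit_pathway_effects <- function(obs, fdr = FALSE) {
  stopifnot(inherits(obs, "pathway_observations"))
  out <- do.call(rbind, lapply(split(obs, obs$pathway_id), fit_pathway_effect))
  rownames(out) <- NULL
  if (fdr) {
    out$p_positive_fdr <- adjust_pvalues(out$p_positive, "BH")
    out$p_negative_fdr <- adjust_pvalues(out$p_negative, "BH")
  }
  out
}
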