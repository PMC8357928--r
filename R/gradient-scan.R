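# Three-group "double Wilcoxon" monotone-change screen over species.
#
# A species changes along an ordering of the three cohorts (e.g. rural ->
# urban -> external) if both consecutive pairwise rank-sum tests reject, with
# the combined p-value taken as the LARGER of the two, and the two pairwise
# shifts sharing a direction.

ordering_levels <- function(ordering) {
  switch(ordering,
    RUN = c("rural", "urban", "external"),
    URN = c("urban", "rural", "external"),
    RNU = c("rural", "external", "urban"),
    stop(sprintf("unknown ordering '%s' (use RUN, URN or RNU)", ordering), call. = FALSE)
  )
}

#' Double Wilcoxon gradient test for one species
#'
#' Runs two two-sided rank-sum tests on the consecutive group pairs of the
#' ordering and combines them as the maximum of the two p-values. The
#' direction ("increasing"/"decreasing" along the ordering) is defined only
#' when both pairwise shifts share a sign; otherwise the result is flagged
#' inconsistent.
#'
#' @param species_values Numeric abundance vector.
#' @param groups Character/factor of group labels ("rural", "urban",
#'   "external"), same length.
#' @param ordering "RUN", "URN", or "RNU".
#' @return List of class `gradient_result`: p_first, p_second, p_combined,
#'   direction ("increasing", "decreasing" or NA), consistent flag.
#' @export
double_wilcoxon <- function(species_values, groups, ordering = "RUN") {
  lv <- ordering_levels(ordering)
  groups <- as.character(groups)
  gs <- lapply(lv, function(g) species_values[groups == g])
  if (any(vapply(gs, length, 1L) == 0L)) {
    stop(sprintf("missing group(s): %s",
                 paste(lv[vapply(gs, length, 1L) == 0L], collapse = ", ")), call. = FALSE)
  }
  t1 <- wilcoxon_rank_sum(gs[[1L]], gs[[2L]])
  t2 <- wilcoxon_rank_sum(gs[[2L]], gs[[3L]])
  # step sign: positive when the later group in the ordering is higher
  s1 <- -t1$direction
  s2 <- -t2$direction
  consistent <- s1 != 0 && s1 == s2
  direction <- if (!consistent) NA_character_ else if (s1 > 0) "increasing" else "decreasing"
  structure(
    list(ordering = ordering,
         p_first = t1$p_value, p_second = t2$p_value,
         p_combined = max(t1$p_value, t2$p_value),
         direction = direction, consistent = consistent),
    class = "gradient_result"
  )
}

#' Scan all species for monotone gradient changes
#'
#' Species below the prevalence floor are excluded before any testing. Within
#' each ordering, Benjamini-Hochberg correction is applied across the tested
#' species to the combined (max) p-values. Direction-inconsistent species are
#' retained in the output, flagged, and counted as non-significant in the
#' summary.
#'
#' @param table An [abundance_table] with 3-level group labels.
#' @param orderings Character vector of orderings to test.
#' @param prevalence_min Strict prevalence floor (default 0.20: tested species
#'   must be detected in more than 20% of samples).
#' @param fdr_alpha BH significance level for the summary counts.
#' @return List with `results` (one data frame per ordering: species_id,
#'   prevalence, p_first, p_second, p_combined, p_fdr, direction, consistent,
#'   significant) and `summary` (per-ordering counts of uncorrected and
#'   FDR-significant direction-consistent species, plus n_tested).
#' @export
scan_gradient <- function(table, orderings = c("RUN", "URN", "RNU"),
                          prevalence_min = 0.20, fdr_alpha = 0.05) {
  stopifnot(inherits(table, "abundance_table"))
  if (is.null(table$group)) stop("abundance table carries no group labels", call. = FALSE)
  prev <- colMeans(table$values > 0)
  tested <- names(prev)[prev > prevalence_min]
  if (length(tested) == 0L) {
    warning("no species passes the prevalence filter")
    return(list(results = stats::setNames(vector("list", length(orderings)), orderings),
                summary = data.frame(ordering = orderings, n_tested = 0L,
                                     n_uncorrected = 0L, n_fdr = 0L)))
  }
  results <- list()
  summary <- data.frame(ordering = orderings, n_tested = length(tested),
                        n_uncorrected = 0L, n_fdr = 0L)
  for (k in seq_along(orderings)) {
    ord <- orderings[k]
    rows <- lapply(tested, function(s) {
      r <- double_wilcoxon(table$values[, s], table$group, ord)
      data.frame(species_id = s, prevalence = prev[[s]],
                 p_first = r$p_first, p_second = r$p_second,
                 p_combined = r$p_combined,
                 direction = if (is.na(r$direction)) NA_character_ else r$direction,
                 consistent = r$consistent, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    df$p_fdr <- adjust_pvalues(df$p_combined, "BH")
    df$significant <- df$consistent & df$p_fdr < fdr_alpha
    rownames(df) <- NULL
    results[[ord]] <- df
    summary$n_uncorrected[k] <- sum(df$consistent & df$p_combined < 0.05)
    summary$n_fdr[k] <- sum(df$significant)
  }
  list(results = results, summary = summary)
}
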