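# Metabolome integration: per-species metabolome effects (max absolute
# Spearman over all peaks), effect-distribution comparisons, metabolite ~
# cytokine correlation tallies stratified by pathway, and ARI-selected
# k-means clustering of peaks.

# columnwise Spearman grid between two matrices sharing rows; returns rho and
# t-approximation p matrices (NA for constant columns)
spearman_grid <- function(A, B) {
  stopifnot(nrow(A) == nrow(B))
  n <- nrow(A)
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)
  RA <- apply(A, 2L, rank)
  RB <- apply(B, 2L, rank)
  constA <- apply(A, 2L, function(v) length(unique(v)) == 1L)
  constB <- apply(B, 2L, function(v) length(unique(v)) == 1L)
  rho <- suppressWarnings(stats::cor(RA, RB))
  rho[constA, ] <- NA
  rho[, constB] <- NA
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-300))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[!is.na(rho) & abs(rho) >= 1 - 1e-15] <- 0
  list(rho = rho, p = p, n = n)
}

#' Per-species metabolome effect sizes
#'
#' Computes Spearman correlations between every species' relative abundance
#' and every metabolite peak over the shared samples, applies BH correction
#' globally over the whole species x metabolite grid, and summarizes each
#' species by its maximum absolute correlation (its metabolome effect E_s),
#' the identity of that best peak, and whether the best pair passes the global
#' FDR threshold. Constant peaks (or species) are skipped.
#'
#' @param abundances An [abundance_table].
#' @param metabolites A [metabolite_table] on the same samples.
#' @param effects Optional classified species effects (adds `effect_class`).
#' @param alpha BH significance level (default 0.05).
#' @return List with `effects` (per-species data frame: species_id,
#'   best_metabolite, max_abs_rho, best_rho, best_pair_p_fdr, significant,
#'   effect_class) and `pairs` (all BH-significant species-peak pairs). The
#'   `rho_threshold` attribute on `effects` records the smallest |rho| among
#'   significant pairs (the significance line on an effect-size axis).
#' @export
species_metabolome_effects <- function(abundances, metabolites, effects = NULL,
                                       alpha = 0.05) {
  stopifnot(inherits(abundances, "abundance_table"), inherits(metabolites, "metabolite_table"))
  samples <- intersect(rownames(abundances$values), rownames(metabolites$intensities))
  if (length(samples) < 3L) stop("need at least 3 shared samples", call. = FALSE)
  A <- abundances$values[samples, , drop = FALSE]
  B <- metabolites$intensities[samples, , drop = FALSE]
  g <- spearman_grid(A, B)
  n_skipped <- sum(is.na(g$rho))
  if (n_skipped > 0) message(sprintf("%d constant species-peak pair(s) skipped", n_skipped))
  p_fdr <- matrix(adjust_pvalues(as.vector(g$p), "BH"), nrow(g$p), ncol(g$p),
                  dimnames = dimnames(g$p))
  per_species <- lapply(colnames(A), function(s) {
    r <- stats::setNames(g$rho[s, ], colnames(g$rho))  # names survive 1-peak tables
    if (all(is.na(r))) {
      return(data.frame(species_id = s, best_metabolite = NA_character_,
                        max_abs_rho = NA_real_, best_rho = NA_real_,
                        best_pair_p_fdr = NA_real_, significant = FALSE,
                        stringsAsFactors = FALSE))
    }
    j <- which.max(abs(r))
    data.frame(species_id = s, best_metabolite = names(j),
               max_abs_rho = abs(r[[j]]), best_rho = r[[j]],
               best_pair_p_fdr = p_fdr[s, j],
               significant = p_fdr[s, j] < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_species)
  if (!is.null(effects)) {
    out$effect_class <- effects$classification[match(out$species_id, effects$species_id)]
    out$effect_class[is.na(out$effect_class)] <- "neutral"
  }
  sig_idx <- which(p_fdr < alpha, arr.ind = TRUE)
  pairs <- data.frame(species_id = rownames(p_fdr)[sig_idx[, 1L]],
                      peak_id = colnames(p_fdr)[sig_idx[, 2L]],
                      rho = g$rho[sig_idx], p_fdr = p_fdr[sig_idx],
                      stringsAsFactors = FALSE)
  attr(out, "rho_threshold") <- if (nrow(pairs)) min(abs(pairs$rho)) else NA_real_
  list(effects = out, pairs = pairs)
}

#' Compare metabolome effect distributions between species classes
#'
#' One-sided rank-sum tests (alternative: greater) of the per-species maximum
#' absolute Spearman effect E_s: positive vs neutral species and negative vs
#' neutral species. A contrast with an empty class is skipped with a note.
#'
#' @param effects Per-species data frame from [species_metabolome_effects]
#'   (must carry `effect_class`).
#' @return Named list of [test_result]s ("positive_vs_neutral",
#'   "negative_vs_neutral"); skipped contrasts are NULL with a message.
#' @export
compare_effect_distributions <- function(effects) {
  stopifnot("effect_class" %in% names(effects))
  es <- effects$max_abs_rho
  cls <- effects$effect_class
  run <- function(a) {
    x <- es[cls == a & !is.na(es)]
    y <- es[cls == "neutral" & !is.na(es)]
    if (length(x) < 2L || length(y) < 2L) {
      message(sprintf("contrast %s vs neutral skipped: too few species", a))
      return(NULL)
    }
    wilcoxon_rank_sum(x, y, alternative = "greater")
  }
  list(positive_vs_neutral = run("positive"),
       negative_vs_neutral = run("negative"))
}

#' Metabolite-cytokine correlation screen
#'
#' Spearman correlation of every peak against every (cytokine, stimulus)
#' log response over the subjects with both measured, BH-corrected across all
#' pairs. Pairs with fewer than 3 complete observations or a constant peak
#' are skipped.
#'
#' @param metabolites A [metabolite_table].
#' @param cytokines A [cytokine_measurements] table.
#' @param alpha BH significance level.
#' @return List with `pairs` (data frame: peak_id, cytokine, stimulus, rho,
#'   n, p, p_fdr, significant) and `per_peak` (data frame: peak_id,
#'   any_significant, n_significant).
#' @export
metabolite_cytokine_correlations <- function(metabolites, cytokines, alpha = 0.05) {
  stopifnot(inherits(metabolites, "metabolite_table"))
  cy <- as.data.frame(cytokines)
  subjects <- intersect(rownames(metabolites$intensities), unique(cy$subject_id))
  if (length(subjects) < 3L) stop("need at least 3 shared subjects", call. = FALSE)
  cy <- cy[cy$subject_id %in% subjects, , drop = FALSE]
  combo <- interaction(cy$cytokine, cy$stimulus, sep = "\r", drop = TRUE)
  resp <- matrix(NA_real_, length(subjects), nlevels(combo),
                 dimnames = list(subjects, levels(combo)))
  resp[cbind(cy$subject_id, as.character(combo))] <- log(cy$concentration)
  M <- metabolites$intensities[subjects, , drop = FALSE]

  n_resp <- colSums(!is.na(resp))  # peaks have no NAs, so pair n is per-response
  rho <- suppressWarnings(stats::cor(M, resp, use = "pairwise.complete.obs",
                                     method = "spearman"))
  const_peak <- apply(M, 2L, function(v) length(unique(v)) == 1L)
  rho[const_peak, ] <- NA
  nn <- matrix(n_resp, nrow = ncol(M), ncol = ncol(resp), byrow = TRUE)
  rho[nn < 3L] <- NA
  tt <- rho * sqrt((nn - 2) / pmax(1 - rho^2, 1e-300))
  p <- 2 * stats::pt(-abs(tt), df = pmax(nn - 2, 1))
  p[!is.na(rho) & abs(rho) >= 1 - 1e-15] <- 0
  p_fdr <- matrix(adjust_pvalues(as.vector(p), "BH"), nrow(p), ncol(p))

  cs <- do.call(rbind, strsplit(colnames(resp), "\r", fixed = TRUE))
  keep <- which(!is.na(rho), arr.ind = TRUE)
  pairs <- data.frame(peak_id = rownames(rho)[keep[, 1L]],
                      cytokine = cs[keep[, 2L], 1L],
                      stimulus = cs[keep[, 2L], 2L],
                      rho = rho[keep], n = nn[keep],
                      p = p[keep], p_fdr = p_fdr[keep],
                      stringsAsFactors = FALSE)
  pairs$significant <- pairs$p_fdr < alpha
  agg <- tapply(pairs$significant, pairs$peak_id, sum)
  per_peak <- data.frame(peak_id = names(agg),
                         n_significant = as.integer(agg),
                         any_significant = as.integer(agg) > 0L,
                         stringsAsFactors = FALSE)
  list(pairs = pairs, per_peak = per_peak)
}

#' Tally pathway-level association counts
#'
#' For each pathway passing the detected-enzyme floor, counts significant
#' metabolite-cytokine correlations among the pathway's peaks split by rho
#' sign; separately flags pathways whose peaks include at least
#' `metabolite_floor` peaks significantly correlated with an immunomodulatory
#' (positive/negative) species.
#'
#' @param annotation A [pathway_annotation] (pathway -> enzyme sets used for
#'   the floor; only enzymes also in `detected_enzymes` count when supplied).
#' @param peak_annotation Data frame with peak_id and comma-separated
#'   pathway_ids (the metabolite table's annotation).
#' @param cyto_pairs Pair table from [metabolite_cytokine_correlations].
#' @param species_pairs Significant species-peak pairs from
#'   [species_metabolome_effects], with an `effect_class` column or joined
#'   classified effects via `species_effects`.
#' @param species_effects Optional classified species effects used to restrict
#'   `species_pairs` to immunomodulatory species.
#' @param detected_enzymes Optional named list pathway -> detected enzyme IDs;
#'   defaults to the annotation's full enzyme sets.
#' @param enzyme_floor Minimum number of detected microbial enzymes (default 10).
#' @param metabolite_floor Minimum number of immunomodulatory-correlated peaks
#'   (default 3).
#' @return Data frame: pathway_id, n_enzymes_detected, n_metabolites,
#'   n_positive_assoc, n_negative_assoc, n_immunomod_metabolites,
#'   pass_enzyme_floor, pass_metabolite_floor.
#' @export
tally_pathways <- function(annotation, peak_annotation, cyto_pairs,
                           species_pairs = NULL, species_effects = NULL,
                           detected_enzymes = NULL,
                           enzyme_floor = 10, metabolite_floor = 3) {
  stopifnot(inherits(annotation, "pathway_annotation"))
  pwy <- names(annotation$enzymes)
  det <- detected_enzymes %||% annotation$enzymes
  pwy_col <- peak_annotation$pathway_ids %||% rep("", nrow(peak_annotation))
  peak_pwys <- strsplit(pwy_col, ",", fixed = TRUE)
  names(peak_pwys) <- peak_annotation$peak_id

  imm_peaks <- character(0)
  if (!is.null(species_pairs) && nrow(species_pairs) > 0) {
    sp <- species_pairs
    if (!is.null(species_effects)) {
      cls <- species_effects$classification[match(sp$species_id, species_effects$species_id)]
      sp <- sp[!is.na(cls) & cls != "neutral", , drop = FALSE]
    }
    imm_peaks <- unique(sp$peak_id)
  }
  sig_cyto <- cyto_pairs[cyto_pairs$significant, , drop = FALSE]

  rows <- lapply(pwy, function(p) {
    members <- names(peak_pwys)[vapply(peak_pwys, function(v) p %in% v, TRUE)]
    n_enz <- length(intersect(annotation$enzymes[[p]], det[[p]] %||% character(0)))
    sc <- sig_cyto[sig_cyto$peak_id %in% members, , drop = FALSE]
    data.frame(pathway_id = p,
               n_enzymes_detected = n_enz,
               n_metabolites = length(members),
               n_positive_assoc = sum(sc$rho > 0),
               n_negative_assoc = sum(sc$rho < 0),
               n_immunomod_metabolites = length(intersect(members, imm_peaks)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$pass_enzyme_floor <- out$n_enzymes_detected >= enzyme_floor
  out$pass_metabolite_floor <- out$n_immunomod_metabolites >= metabolite_floor
  out
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement: 1 for identical partitions, ~0 for random
#' agreement, negative for worse-than-chance.
#'
#' @param a,b Vectors of cluster labels, same length.
#' @return The ARI (scalar).
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length", call. = FALSE)
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(if (sum_ij == expected) 1 else 0)
  (sum_ij - expected) / (maxi - expected)
}

#' Cluster metabolite peaks by k-means with ARI-selected k
#'
#' Peaks are z-scored across samples and clustered (peaks as points, samples
#' as features) by seeded k-means with multiple restarts for each candidate k.
#' The chosen k maximizes the adjusted Rand index between the partition and
#' the peaks' molecular-class labels, ties broken toward smaller k. Each
#' cluster is annotated with its most prevalent molecular class.
#'
#' @param metabolites A [metabolite_table] whose annotation carries
#'   `molecular_class`.
#' @param k_range Candidate cluster counts (values exceeding the number of
#'   peaks are skipped).
#' @param restarts k-means restarts per k (best within-SS solution kept).
#' @param seed Integer seed.
#' @return List: `k` (chosen), `partition` (named cluster labels per peak),
#'   `ari` (named ARI per candidate k), `cluster_classes` (dominant molecular
#'   class per cluster).
#' @export
cluster_metabolites <- function(metabolites, k_range = 2:10, restarts = 25, seed = 1) {
  stopifnot(inherits(metabolites, "metabolite_table"))
  ann <- metabolites$annotation
  if (is.null(ann) || !"molecular_class" %in% names(ann)) {
    stop("metabolite annotation with molecular_class required", call. = FALSE)
  }
  M <- t(metabolites$intensities)  # peaks x samples
  sds <- apply(M, 1L, stats::sd)
  Z <- (M - rowMeans(M)) / ifelse(sds > 0, sds, 1)
  classes <- ann$molecular_class[match(rownames(Z), ann$peak_id)]
  k_range <- k_range[k_range <= nrow(Z)]
  if (length(k_range) == 0L) stop("no feasible k in k_range", call. = FALSE)

  fits <- with_seed(seed, {
    lapply(k_range, function(k) {
      # infeasible k (more centers than distinct points) is skipped
      tryCatch(stats::kmeans(Z, centers = k, nstart = restarts, iter.max = 50),
               error = function(e) NULL)
    })
  })
  ok <- !vapply(fits, is.null, TRUE)
  k_range <- k_range[ok]
  fits <- fits[ok]
  if (length(fits) == 0L) stop("k-means failed for every k in k_range", call. = FALSE)
  aris <- vapply(fits, function(f) adjusted_rand_index(f$cluster, classes), 1)
  names(aris) <- as.character(k_range)
  best <- which(aris >= max(aris) - 1e-12)[1L]  # ties toward smaller k
  part <- fits[[best]]$cluster
  dominant <- vapply(split(classes, part), function(cl) {
    names(sort(table(cl), decreasing = TRUE))[1L]
  }, character(1))
  list(k = k_range[best], partition = part, ari = aris, cluster_classes = dominant)
}
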