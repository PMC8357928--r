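# Compositional distances, the dendrogram merge-height cluster-count rule,
# one-factor PERMANOVA on an arbitrary distance matrix, and metadata
# association screens.

#' Jensen-Shannon divergence matrix between samples
#'
#' JSD(p, q) = KL(p || m)/2 + KL(q || m)/2 with m = (p + q)/2, natural
#' logarithm, and the convention 0 * log 0 = 0; bounded in \[0, ln 2\].
#' Sample vectors are renormalized to sum to 1 first.
#'
#' @param table An [abundance_table]; no sample may be all-zero.
#' @return Symmetric matrix of class `dist_matrix` with zero diagonal and
#'   sample IDs as dimnames.
#' @export
jensen_shannon_matrix <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  V <- table$values
  rs <- rowSums(V)
  if (any(rs == 0)) {
    stop(sprintf("all-zero sample: '%s'", rownames(V)[which(rs == 0)[1L]]), call. = FALSE)
  }
  P <- V / rs
  n <- nrow(P)
  xlogx <- function(M) {
    out <- M * log(M)
    out[M == 0] <- 0
    out
  }
  H <- -rowSums(xlogx(P))  # Shannon entropies, nats
  D <- matrix(0, n, n, dimnames = list(rownames(P), rownames(P)))
  for (i in seq_len(max(n - 1L, 0L))) {
    rest <- (i + 1L):n
    Mid <- (P[rest, , drop = FALSE] + matrix(P[i, ], length(rest), ncol(P), byrow = TRUE)) / 2
    Hm <- -rowSums(xlogx(Mid))
    d <- Hm - (H[rest] + H[i]) / 2  # JSD = H(m) - (H(p)+H(q))/2
    D[i, rest] <- D[rest, i] <- pmax(d, 0)
  }
  class(D) <- c("dist_matrix", "matrix", "array")
  D
}

#' Cluster count from descending dendrogram merge heights
#'
#' Scans the merge heights from the top of the tree downwards and cuts where
#' two subsequent height cutoffs first differ by less than `ratio`-fold:
#' k = j + 1 for the smallest j with h_j / h_(j+1) < ratio. If no such step
#' exists, every sample is its own cluster (k = n_samples). k is always >= 2.
#'
#' @param merge_heights Positive merge heights in descending order
#'   (length n_samples - 1, as from rev(hclust(..)$height)).
#' @param n_samples Number of leaves.
#' @param ratio Fold threshold (default 2).
#' @return Integer cluster count k.
#' @export
cluster_count_by_height <- function(merge_heights, n_samples, ratio = 2.0) {
  if (any(merge_heights <= 0)) stop("merge heights must be positive", call. = FALSE)
  if (is.unsorted(rev(merge_heights))) stop("merge heights must be descending", call. = FALSE)
  if (length(merge_heights) != n_samples - 1L) {
    stop("need n_samples - 1 merge heights", call. = FALSE)
  }
  for (j in seq_len(length(merge_heights) - 1L)) {
    if (merge_heights[j] / merge_heights[j + 1L] < ratio) return(j + 1L)
  }
  n_samples
}

#' One-factor PERMANOVA on a distance matrix
#'
#' Distance-based sums of squares: SS_total = sum of squared distances over
#' all pairs / n; SS_within = the same within each group scaled by the group
#' size; SS_between = SS_total - SS_within. pseudo-F =
#' (SS_between/(a-1)) / (SS_within/(n-a)); R^2 = SS_between / SS_total. The
#' p-value comes from label permutations: full enumeration of all n!
#' orderings when n! <= 10,000, otherwise `n_perm` random permutations with
#' the +1 convention.
#'
#' @param dist Symmetric distance matrix (class `dist_matrix`, `dist`, or
#'   plain matrix).
#' @param labels Group labels per sample (>= 2 groups, each nonempty).
#' @param n_perm Number of random permutations when enumeration is infeasible.
#' @param seed Integer seed for the random permutations.
#' @return List of class `permanova_result`: pseudo_F, r_squared, p_perm,
#'   n_permutations, exact (flag), ss (named components).
#' @export
permanova <- function(dist, labels, n_perm = 999, seed = 1) {
  D <- as.matrix(dist)
  n <- nrow(D)
  labels <- as.character(labels)
  if (length(labels) != n) stop("labels must match distance matrix size", call. = FALSE)
  groups <- unique(labels)
  a <- length(groups)
  if (a < 2L) stop("need at least two groups", call. = FALSE)
  D2 <- D^2

  ss_stats <- function(lab) {
    ss_w <- 0
    for (g in groups) {
      idx <- which(lab == g)
      ng <- length(idx)
      if (ng > 1L) ss_w <- ss_w + sum(D2[idx, idx]) / 2 / ng
    }
    ss_w
  }
  ss_total <- sum(D2) / 2 / n
  ss_within <- ss_stats(labels)
  ss_between <- ss_total - ss_within
  f_of <- function(ss_w) {
    if (ss_w <= 0) return(Inf)
    ((ss_total - ss_w) / (a - 1)) / (ss_w / (n - a))
  }
  f_obs <- f_of(ss_within)

  exact <- factorial(n) <= 10000
  if (exact) {
    perms <- permutations_of(n)
    f_perm <- apply(perms, 1L, function(idx) f_of(ss_stats(labels[idx])))
    p <- mean(f_perm >= f_obs - 1e-12)
    n_used <- nrow(perms)
  } else {
    f_perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(k) f_of(ss_stats(sample(labels))), 1)
    })
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }
  structure(
    list(pseudo_F = f_obs, r_squared = ss_between / ss_total, p_perm = p,
         n_permutations = n_used, exact = exact,
         ss = c(total = ss_total, within = ss_within, between = ss_between)),
    class = "permanova_result"
  )
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("<permanova> pseudo-F = %.4g, R^2 = %.4f, p = %.4g (%s, %d permutations)\n",
              x$pseudo_F, x$r_squared, x$p_perm,
              if (x$exact) "exact enumeration" else "Monte Carlo", x$n_permutations))
  invisible(x)
}

#' Cut a sample set into clusters by JSD + average linkage + the height rule
#'
#' Convenience wrapper: hierarchical clustering (average linkage by default)
#' on the Jensen-Shannon matrix, cluster count from
#' [cluster_count_by_height], and the resulting partition.
#'
#' @param table An [abundance_table].
#' @param linkage hclust agglomeration method.
#' @param ratio Fold threshold for the height rule.
#' @return List: `k`, `clusters` (named integer labels), `heights`
#'   (descending merge heights), `hclust` (the tree).
#' @export
cluster_samples <- function(table, linkage = "average", ratio = 2.0) {
  D <- jensen_shannon_matrix(table)
  hc <- stats::hclust(stats::as.dist(D), method = linkage)
  heights <- rev(hc$height)
  k <- cluster_count_by_height(heights, n_samples = nrow(D), ratio = ratio)
  list(k = k, clusters = stats::cutree(hc, k = k), heights = heights, hclust = hc)
}

#' Equal-frequency binning
#'
#' Splits a numeric vector into `n_bins` groups of (near-)equal size by rank
#' order, ties resolved by first occurrence (stable). Bin sizes differ by at
#' most one.
#'
#' @param x Numeric vector.
#' @param n_bins Number of bins (default 3).
#' @return Integer bin labels 1..n_bins.
#' @export
equal_frequency_bins <- function(x, n_bins = 3) {
  n <- length(x)
  ord <- order(x)  # stable: ties keep input order
  bin_sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0) bin_sizes[seq_len(extra)] <- bin_sizes[seq_len(extra)] + 1L
  bins <- integer(n)
  bins[ord] <- rep(seq_len(n_bins), times = bin_sizes)
  bins
}

#' Associate a sample grouping with metadata variables
#'
#' Categorical variables are tested against the grouping with the chi-square
#' test (Yates correction only for 2x2 tables); ordinal or continuous
#' variables (e.g. weekly consumption frequencies) with Kruskal-Wallis. Age is
#' first converted to three equal-frequency bins and tested as categorical.
#' Variables with a single observed level are skipped.
#'
#' @param groups Cluster or group labels per subject (named by subject ID, or
#'   aligned with `metadata` rows).
#' @param metadata A [subject_metadata] table.
#' @param variables Character vector of metadata columns to test.
#' @param ordinal Character vector naming which of `variables` are
#'   ordinal/continuous (Kruskal-Wallis route). "age" is always handled by the
#'   binning route.
#' @return Data frame: variable, test, statistic, p_value (NA for skipped
#'   variables, with `note`).
#' @export
metadata_association <- function(groups, metadata, variables,
                                 ordinal = character(0)) {
  if (!is.null(names(groups))) {
    metadata <- metadata[match(names(groups), metadata$subject_id), ]
  }
  stopifnot(length(groups) == nrow(metadata))
  g <- as.character(groups)
  rows <- lapply(variables, function(v) {
    if (!v %in% names(metadata)) {
      return(data.frame(variable = v, test = NA_character_, statistic = NA_real_,
                        p_value = NA_real_, note = "missing variable"))
    }
    x <- metadata[[v]]
    if (identical(v, "age")) x <- equal_frequency_bins(x, 3)
    if (v %in% ordinal && !identical(v, "age")) {
      grp_vals <- split(as.numeric(x), g)
      r <- kruskal_wallis(grp_vals)
      return(data.frame(variable = v, test = "kruskal_wallis",
                        statistic = r$statistic, p_value = r$p_value, note = ""))
    }
    if (length(unique(x)) < 2L) {
      return(data.frame(variable = v, test = NA_character_, statistic = NA_real_,
                        p_value = NA_real_, note = "single level, skipped"))
    }
    tab <- table(x, g)
    r <- contingency_chi_square(as.matrix(tab))
    data.frame(variable = v, test = "chi_square",
               statistic = r$statistic, p_value = r$p_value, note = "")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
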