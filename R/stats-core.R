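# Shared statistical primitives. Each is a thin, validated layer over the
# corresponding base-R routine, returning a uniform `test_result` record so
# downstream stages never touch htest objects directly.

#' Construct a test result record
#'
#' @param statistic Test statistic.
#' @param p_value P-value in \[0, 1\].
#' @param direction Sign of the effect: -1, 0 or +1 (NA when undefined).
#' @param method_note Short free-text note (e.g. "exact" vs "normal approximation").
#' @param ... Extra named fields carried along (e.g. `estimate`).
#' @return An object of class `test_result`.
#' @export
test_result <- function(statistic, p_value, direction, method_note, ...) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1 + 1e-12))
  structure(
    list(statistic = unname(statistic),
         p_value = unname(min(p_value, 1)),
         direction = direction,
         method_note = method_note,
         ...),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> statistic = %.6g, p = %.4g, direction = %s (%s)\n",
              x$statistic, x$p_value,
              ifelse(is.na(x$direction), "NA", format(x$direction)),
              x$method_note))
  invisible(x)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sample rank-sum test with mid-ranks for ties. The p-value is exact
#' (full enumeration of the rank-sum distribution) when the combined sample
#' size is at most 20 and no ties are present; otherwise the tie-corrected
#' normal approximation with continuity correction is used. The reported
#' direction is the sign of the rank-biserial correlation, i.e. the sign of
#' U - mn/2.
#'
#' @param x,y Numeric vectors, each nonempty.
#' @param alternative One of "two.sided", "less", "greater".
#' @return A [test_result] with the Mann-Whitney U statistic (of `x` vs `y`).
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) < 1L || length(y) < 1L) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  if (any(!is.finite(c(x, y)))) stop("non-finite values in input", call. = FALSE)
  m <- length(x); n <- length(y)
  combined <- c(x, y)
  ties <- anyDuplicated(combined) > 0L

  # U statistic from mid-ranks (counts pairs x > y, ties as 1/2)
  r <- rank(combined)
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  rb <- 2 * u / (m * n) - 1  # rank-biserial correlation

  if (length(unique(combined)) == 1L) {
    # fully degenerate: no information
    return(test_result(u, 1, 0L, "degenerate (all values tied)", rank_biserial = 0))
  }

  exact <- (m + n) <= 20 && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative,
                       exact = exact, correct = TRUE)
  )
  p <- ht$p.value
  dir <- as.integer(sign(rb))
  test_result(u, p, dir,
              if (exact) "exact enumeration" else "normal approximation, tie-corrected, continuity-corrected",
              rank_biserial = rb)
}

#' Spearman rank correlation test
#'
#' Rho is computed by average-rank transform followed by Pearson correlation
#' on the ranks. By default the p-value comes from the t approximation
#' t = rho * sqrt((n-2)/(1-rho^2)) with n-2 degrees of freedom; with
#' `exact = TRUE` (small n only) it is computed by full enumeration of all
#' permutations of one vector's ranks.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param exact Use full permutation enumeration for the p-value
#'   (requires n <= 8).
#' @return A [test_result]; `statistic` is rho, extra field `rho`.
#'   When either vector is constant, rho is undefined: the result is flagged
#'   via `method_note` and carries `rho = NA`.
#' @export
spearman_correlation <- function(x, y, exact = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values in input", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(test_result(NA_real_, NA_real_, NA_integer_,
                       "undefined: constant input vector", rho = NA_real_))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (exact) {
    if (n > 8L) stop("exact permutation enumeration limited to n <= 8", call. = FALSE)
    perms <- permutations_of(n)
    rhos <- apply(perms, 1L, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    return(test_result(rho, p, as.integer(sign(rho)),
                       "exact permutation enumeration", rho = rho))
  }
  if (abs(rho) >= 1 - 1e-15) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  test_result(rho, p, as.integer(sign(rho)), "t approximation", rho = rho)
}

# all n! permutations of 1:n as rows (n small)
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    for (i in seq_len(nrow(sub))) {
      rest <- seq_len(n)[-k]
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up ("BH") or Bonferroni adjusted p-values,
#' clipped at 1. NA entries are propagated and do not count toward m.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method "BH" or "bonferroni".
#' @return Adjusted p-values, same length and order as input.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  assert_prob(p[!is.na(p)], "p")
  stats::p.adjust(p, method = method)
}

#' Pearson chi-square test on a contingency table
#'
#' @param table Matrix of nonnegative integer counts, at least 2x2, with all
#'   row and column margins positive.
#' @param continuity_correction Apply the Yates correction (only meaningful
#'   for 2x2 tables). Default: on for 2x2, ignored otherwise.
#' @return A [test_result] with the chi-square statistic; extra field `df`.
#' @export
contingency_chi_square <- function(table, continuity_correction = NULL) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L) stop("table must be at least 2x2", call. = FALSE)
  if (any(table < 0) || any(table != round(table))) {
    stop("table must contain nonnegative integer counts", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("all table margins must be positive", call. = FALSE)
  }
  is2x2 <- nrow(table) == 2L && ncol(table) == 2L
  correct <- if (is.null(continuity_correction)) is2x2 else (continuity_correction && is2x2)
  ht <- suppressWarnings(stats::chisq.test(table, correct = correct))
  test_result(ht$statistic, ht$p.value, 0L,
              if (correct) "Pearson chi-square, Yates-corrected" else "Pearson chi-square",
              df = unname(ht$parameter))
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with a chi-square reference (df = k - 1).
#' When every observation is identical the tie correction degenerates;
#' by convention H = 0 and p = 1.
#'
#' @param groups List of >= 2 nonempty numeric vectors.
#' @return A [test_result] with H; extra field `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need a list of >= 2 groups", call. = FALSE)
  if (any(vapply(groups, length, 1L) == 0L)) stop("all groups must be nonempty", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(values))) stop("non-finite values in input", call. = FALSE)
  k <- length(groups)
  if (length(unique(values)) == 1L) {
    return(test_result(0, 1, 0L, "degenerate (all values tied)", df = k - 1L))
  }
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  ht <- stats::kruskal.test(values, g)
  test_result(ht$statistic, ht$p.value, 0L, "tie-corrected H, chi-square reference",
              df = unname(ht$parameter))
}

#' Ordinary least squares with per-coefficient t-tests
#'
#' Fits response ~ design (no implicit intercept: include a column of ones if
#' wanted) by QR least squares. Rank-deficient designs are flagged and the
#' aliased coefficients are NA. Standard errors come from the residual
#' variance and (X'X)^-1 on the identified columns; p-values are two-sided
#' t-tests on n - rank degrees of freedom.
#'
#' @param design Numeric matrix with column names.
#' @param response Numeric vector, length nrow(design).
#' @return An object of class `linear_fit`: list with `coefficients`,
#'   `std_errors`, `t_values`, `p_values` (named vectors), `residual_variance`,
#'   `df_residual`, `n_obs`, `rank_deficient`, `residuals`, `fitted`.
#' @export
fit_linear_model <- function(design, response) {
  design <- as.matrix(design)
  if (is.null(colnames(design))) {
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  }
  n <- nrow(design)
  if (n != length(response)) stop("design rows must match response length", call. = FALSE)
  if (any(!is.finite(design)) || any(!is.finite(response))) {
    stop("non-finite values in design or response", call. = FALSE)
  }
  qx <- qr(design)
  r <- qx$rank
  p <- ncol(design)
  coefs <- qr.coef(qx, response)          # NA for aliased columns
  fitted <- qr.fitted(qx, response)
  resid <- response - fitted
  df_res <- n - r
  rank_def <- r < p

  se <- tv <- pv <- rep(NA_real_, p)
  names(se) <- names(tv) <- names(pv) <- colnames(design)
  sigma2 <- if (df_res > 0) sum(resid^2) / df_res else NA_real_
  if (df_res > 0) {
    used <- qx$pivot[seq_len(r)]
    R <- qr.R(qx)[seq_len(r), seq_len(r), drop = FALSE]
    xtx_inv <- chol2inv(R)
    se[used] <- sqrt(pmax(diag(xtx_inv), 0) * sigma2)
    tv[used] <- coefs[used] / se[used]
    pv[used] <- 2 * stats::pt(-abs(tv[used]), df = df_res)
  }
  structure(
    list(coefficients = coefs, std_errors = se, t_values = tv, p_values = pv,
         residual_variance = sigma2, df_residual = df_res, n_obs = n,
         rank_deficient = rank_def, residuals = resid, fitted = fitted),
    class = "linear_fit"
  )
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit> n = %d, residual df = %d%s\n", x$n_obs, x$df_residual,
              if (x$rank_deficient) " (rank deficient)" else ""))
  tab <- data.frame(estimate = x$coefficients, std_error = x$std_errors,
                    t = x$t_values, p = x$p_values)
  print(utils::head(tab, 12L))
  if (nrow(tab) > 12L) cat(sprintf("... %d more coefficients\n", nrow(tab) - 12L))
  invisible(x)
}
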