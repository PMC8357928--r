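# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's code paths (and base R's test functions) wherever the
# package result is being checked.

# exact two-sided rank-sum p by enumerating all C(m+n, m) label assignments
oracle_wilcoxon_p <- function(x, y) {
  m <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(m)])
  combos <- utils::combn(n, m)
  ws <- apply(combos, 2L, function(idx) sum(r[idx]))
  mu <- m * (n + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# Spearman rho by the textbook d^2 formula (tie-free inputs only)
oracle_spearman_rho <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# exact permutation p for |rho| by recursion over all n! orderings
oracle_spearman_perm_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  perms <- all_perms(n)
  rhos <- apply(perms, 1L, function(idx) stats::cor(rx, ry[idx]))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

# BH step-up by the textbook recursion (sort, cummin from the largest)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(p[o] * m / rank(p, ties.method = "max")[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Jensen-Shannon divergence by direct KL arithmetic
oracle_jsd <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    s <- a > 0
    sum(a[s] * log(a[s] / b[s]))
  }
  kl(p, m) / 2 + kl(q, m) / 2
}

# ARI from pair-counting first principles: agreement over all sample pairs
oracle_ari <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  n11 <- sum(same_a & same_b); n00 <- sum(!same_a & !same_b)
  n10 <- sum(same_a & !same_b); n01 <- sum(!same_a & same_b)
  np <- n11 + n10; nq <- n11 + n01; tot <- n * (n - 1) / 2
  exp_idx <- np * nq / tot
  max_idx <- (np + nq) / 2
  if (max_idx == exp_idx) return(if (n11 == exp_idx) 1 else 0)
  (n11 - exp_idx) / (max_idx - exp_idx)
}

# PERMANOVA by definition: SS from the distance matrix, exhaustive label
# permutations (independent loop-based implementation)
oracle_permanova <- function(D, labels) {
  D <- as.matrix(D)
  n <- nrow(D)
  groups <- unique(labels)
  a <- length(groups)
  ss_t <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) ss_t <- ss_t + D[i, j]^2
  ss_t <- ss_t / n
  ssw <- function(lab) {
    s2 <- 0
    for (g in groups) {
      idx <- which(lab == g)
      if (length(idx) > 1) {
        acc <- 0
        for (ii in seq_len(length(idx) - 1)) for (jj in (ii + 1):length(idx)) {
          acc <- acc + D[idx[ii], idx[jj]]^2
        }
        s2 <- s2 + acc / length(idx)
      }
    }
    s2
  }
  f_of <- function(lab) {
    sw <- ssw(lab)
    ((ss_t - sw) / (a - 1)) / (sw / (n - a))
  }
  f_obs <- f_of(labels)
  perms <- all_perms(n)
  fs <- apply(perms, 1L, function(idx) f_of(labels[idx]))
  list(pseudo_F = f_obs, r_squared = (ss_t - ssw(labels)) / ss_t,
       p = mean(fs >= f_obs - 1e-12))
}

# small planted cohort for recovery-style tests (kept light); overrides win
tiny_config <- function(...) {
  defaults <- list(n_rural = 20, n_urban = 40, n_external = 60, n_species = 30,
                   n_metabolites = 40, n_pathways = 5, n_gradient_species = 3,
                   species_per_pathway = 10)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}
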