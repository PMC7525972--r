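#' Alpha-diversity estimators for one sample
#'
#' Computes three count-based estimators:
#' * `np_shannon` -- the coverage-adjusted (Chao-Shen) non-parametric Shannon
#'   index: with sample coverage `C = 1 - F1/n` (F1 = singletons, n = total
#'   reads) and adjusted proportions `p~ = C p`, it is
#'   `-sum(p~ log p~ / (1 - (1 - p~)^n))`.
#' * `inv_simpson` -- inverse Simpson concentration `1 / sum(p_i^2)`.
#' * `chao1` -- `S_obs + F1^2 / (2 F2)`, with the standard correction
#'   `S_obs + F1 (F1 - 1) / 2` when there are no doubletons (F2 = 0).
#'
#' @param counts non-negative integer count vector for one sample, total > 0.
#' @return named numeric vector `c(np_shannon, inv_simpson, chao1)`.
#' @export
alpha_diversity <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || any(!is.finite(counts)))
    abort("counts must be finite and non-negative")
  if (any(abs(counts - round(counts)) > 1e-8))
    abort("counts must be integers (estimators are count-based)")
  counts <- round(counts[counts > 0])
  n <- sum(counts)
  if (n <= 0) abort("sample total must be positive")
  p <- counts / n
  s_obs <- length(counts)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  cover <- 1 - f1 / n
  if (cover <= 0) cover <- 1 - (f1 - 1) / n  # all-singleton guard
  pa <- cover * p
  np_shannon <- -sum(pa * log(pa) / (1 - (1 - pa)^n))
  inv_simpson <- 1 / sum(p^2)
  chao1 <- if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
  c(np_shannon = np_shannon, inv_simpson = inv_simpson, chao1 = chao1)
}

#' Alpha diversity for every sample of a table
#'
#' @param x an [abundance_table()].
#' @return data.frame: sample metadata plus the three index columns.
#' @export
alpha_diversity_table <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  idx <- t(apply(x$counts, 1, alpha_diversity))
  cbind(x$metadata, as.data.frame(idx))
}

#' Permutation two-sample t-test
#'
#' Pooled-variance two-sample t statistic; the null distribution is obtained
#' by randomly permuting group labels. The p-value uses the add-one estimator
#' `(1 + #{|t_perm| >= |t_obs|}) / (1 + n_perm)`. When one group is constant
#' but means differ, |t| is infinite and only permutations reproducing a
#' perfect separation count as extreme; when the pooled data are constant the
#' statistic is undefined and p = 1 is returned with a warning.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @param n_perm number of label permutations (>= 99; default 9999).
#' @param seed integer seed (NULL = ambient RNG).
#' @return p-value in (0, 1].
#' @export
permutation_t_test <- function(values_a, values_b, n_perm = 9999, seed = NULL) {
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (length(a) < 2L || length(b) < 2L) abort("each group needs >= 2 values")
  n_perm <- assert_count(n_perm, "n_perm", min = 99L)
  pooled <- c(a, b)
  if (max(pooled) == min(pooled)) {
    warning("pooled data are constant; t statistic undefined, returning p = 1")
    return(1)
  }
  na <- length(a); nb <- length(b)
  tstat <- function(x, y) {
    s2 <- ((na - 1) * stats::var(x) + (nb - 1) * stats::var(y)) / (na + nb - 2)
    d <- mean(x) - mean(y)
    if (s2 == 0) return(if (d == 0) 0 else Inf)
    abs(d) / sqrt(s2 * (1 / na + 1 / nb))
  }
  obs <- tstat(a, b)
  maybe_with_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample.int(na + nb, na)
      if (tstat(pooled[idx], pooled[-idx]) >= obs) hits <- hits + 1L
    }
    (1 + hits) / (1 + n_perm)
  })
}
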