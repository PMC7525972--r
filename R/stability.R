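#' Cooperation/competition stability profile of one group
#'
#' For every ensemble member, the fractions of positive and negative fitted
#' off-diagonal interaction coefficients (exact zeros are excluded from the
#' denominator, so the two proportions sum to 1). Network-level extremes --
#' the largest positive and smallest negative consensus-edge mean strength --
#' are reported separately, in the coefficient's strength units.
#'
#' @param ensemble a [infer_ensemble()] result.
#' @param network the matching [consensus_network()].
#' @param group group label (default: the ensemble's).
#' @return object of class `stability_profile`: `members` data.frame
#'   (member, proportion_positive, proportion_negative), strength extremes,
#'   and consensus edge sign counts.
#' @export
stability_profile <- function(ensemble, network, group = ensemble$group) {
  stopifnot(inherits(ensemble, "glv_ensemble"),
            inherits(network, "consensus_network"))
  if (!identical(sort(ensemble$taxa), sort(network$taxa)))
    abort("ensemble and network taxa differ")
  M <- dim(ensemble$a)[3]
  off <- row(ensemble$a[, , 1]) != col(ensemble$a[, , 1])
  props <- t(vapply(seq_len(M), function(m) {
    v <- ensemble$a[, , m][off]
    nz <- v[v != 0]
    if (!length(nz)) return(c(NA_real_, NA_real_))
    c(mean(nz > 0), mean(nz < 0))
  }, numeric(2)))
  e <- network$edges
  pos <- e$mean_strength[e$sign == "+"]
  neg <- e$mean_strength[e$sign == "-"]
  if (!nrow(e)) warning("empty consensus network; strength extremes absent")
  structure(list(
    group = group,
    members = data.frame(member = seq_len(M),
                         proportion_positive = props[, 1],
                         proportion_negative = props[, 2]),
    max_positive_strength = if (length(pos)) max(pos) else NA_real_,
    min_negative_strength = if (length(neg)) min(neg) else NA_real_,
    edge_sign_counts = c(positive = sum(e$sign == "+"),
                         negative = sum(e$sign == "-"))),
    class = "stability_profile")
}

#' @export
print.stability_profile <- function(x, ...) {
  cat(sprintf(
    "stability profile [%s]: %d members, median prop(+) %.3f; edges %d+/%d-\n",
    x$group, nrow(x$members), stats::median(x$members$proportion_positive),
    x$edge_sign_counts[1], x$edge_sign_counts[2]))
  invisible(x)
}

#' Compare cooperation/competition balance between two groups
#'
#' Shapiro-Wilk normality checks on each group's per-member positive
#' proportions, then two-sided Wilcoxon rank-sum tests on the positive and
#' negative proportions. `direction` names the group whose positive
#' proportion is stochastically larger (by median; `"none"` on exact tie).
#'
#' @param profile_a,profile_b [stability_profile()] objects with >= 3
#'   members each.
#' @param seed accepted for interface symmetry; the exact tests used here
#'   are deterministic, so it is ignored.
#' @return list: shapiro_p_a, shapiro_p_b, wilcoxon_p_positive,
#'   wilcoxon_p_negative, direction, and the group labels.
#' @export
compare_stability <- function(profile_a, profile_b, seed = NULL) {
  stopifnot(inherits(profile_a, "stability_profile"),
            inherits(profile_b, "stability_profile"))
  pa <- profile_a$members$proportion_positive
  pb <- profile_b$members$proportion_positive
  na_ <- profile_a$members$proportion_negative
  nb_ <- profile_b$members$proportion_negative
  if (length(pa) < 3L || length(pb) < 3L) abort("each profile needs >= 3 members")
  shap <- function(v) tryCatch(stats::shapiro.test(v)$p.value,
                               error = function(e) NA_real_)
  wil <- function(x, y) {
    if (max(c(x, y)) == min(c(x, y))) {
      warning("all values tied; Wilcoxon p = 1")
      return(1)
    }
    suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
  }
  direction <- if (stats::median(pb) > stats::median(pa)) profile_b$group
  else if (stats::median(pa) > stats::median(pb)) profile_a$group
  else "none"
  list(group_a = profile_a$group, group_b = profile_b$group,
       shapiro_p_a = shap(pa), shapiro_p_b = shap(pb),
       wilcoxon_p_positive = wil(pa, pb),
       wilcoxon_p_negative = wil(na_, nb_),
       direction = direction)
}
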