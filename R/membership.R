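#' Classify taxa into abundance and coreness membership classes
#'
#' Partitions taxa by mean relative abundance into high (> `high_cutoff`),
#' rare (< `rare_cutoff`) and low (the closed interval in between), and into
#' core (present in every evaluated sample) versus non-core. The mean is the
#' average of per-sample relative abundances, which is robust to library-size
#' variation. Boundary values (exactly 1% or 0.1%) fall in the low class.
#'
#' @param x an [abundance_table()].
#' @param high_cutoff,rare_cutoff fractions with 0 < rare < high < 1;
#'   defaults 0.01 and 0.001 (1% and 0.1%).
#' @param scope `"per_group"` (classify within each group's sample set,
#'   the default) or `"all_samples"`.
#' @return data.frame with columns `taxon`, `group` (or `"all"`),
#'   `mean_relative_abundance`, `prevalence`, `abundance_class`
#'   (high/low/rare) and `coreness` (core/non_core).
#' @export
classify_membership <- function(x, high_cutoff = 0.01, rare_cutoff = 0.001,
                                scope = c("per_group", "all_samples")) {
  stopifnot(inherits(x, "abundance_table"))
  scope <- match.arg(scope)
  assert_fraction(high_cutoff, "high_cutoff", open_lo = TRUE, open_hi = TRUE)
  assert_fraction(rare_cutoff, "rare_cutoff", open_lo = TRUE, open_hi = TRUE)
  if (rare_cutoff >= high_cutoff) abort("need rare_cutoff < high_cutoff")
  if (nrow(x$counts) == 0L) abort("empty abundance table")
  sets <- if (scope == "per_group") {
    gs <- unique(x$metadata$group)
    stats::setNames(lapply(gs, function(g) x$metadata$group == g), gs)
  } else list(all = rep(TRUE, nrow(x$counts)))
  out <- lapply(names(sets), function(nm) {
    keep <- sets[[nm]]
    rel <- to_relative(x$counts[keep, , drop = FALSE])
    mu <- colMeans(rel)
    prev <- colMeans(x$counts[keep, , drop = FALSE] > 0)
    cls <- ifelse(mu > high_cutoff, "high",
                  ifelse(mu < rare_cutoff, "rare", "low"))
    data.frame(taxon = x$taxa, group = nm,
               mean_relative_abundance = unname(mu),
               prevalence = unname(prev),
               abundance_class = cls,
               coreness = ifelse(prev == 1, "core", "non_core"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
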