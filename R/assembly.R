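#' Enumerate or subsample replicate-assembly index vectors
#'
#' An assembly picks, for each of K time points, which of R replicate animals
#' supplies the sample, giving R^K composite time series per group (3^11 =
#' 177,147 for the reference design). `mode = "full"` returns all R^K
#' assemblies in lexicographic order (guarded by `ceiling`); `mode =
#' "subsample"` returns a seeded draw without replacement.
#'
#' @param n_replicates R, replicates per group.
#' @param n_timepoints K, time points per series.
#' @param mode `"full"` or `"subsample"`.
#' @param n_subsample draws for subsample mode (default 2000). If it meets or
#'   exceeds R^K the full enumeration is returned.
#' @param seed integer seed for subsampling.
#' @param ceiling largest R^K admitted in full mode (default 2e5).
#' @return integer matrix, one assembly per row, K columns, values in 1..R.
#' @export
enumerate_assemblies <- function(n_replicates, n_timepoints,
                                 mode = c("full", "subsample"),
                                 n_subsample = 2000, seed = NULL,
                                 ceiling = 2e5) {
  R <- assert_count(n_replicates, "n_replicates")
  K <- assert_count(n_timepoints, "n_timepoints")
  mode <- match.arg(mode)
  total <- R^as.numeric(K)
  expand <- function(idx0) {
    # idx0: 0-based assembly indices; most significant digit first gives
    # lexicographic order
    m <- matrix(0L, length(idx0), K)
    for (k in seq_len(K))
      m[, k] <- as.integer((idx0 %/% R^(K - k)) %% R) + 1L
    m
  }
  if (mode == "full") {
    if (total > ceiling)
      abort(paste0("full enumeration would need %s assemblies ",
                   "(ceiling %s); use mode = 'subsample'"),
            format(total, big.mark = ","), format(ceiling, big.mark = ","))
    return(expand(seq_len(total) - 1))
  }
  n_subsample <- assert_count(n_subsample, "n_subsample")
  if (n_subsample >= total) {
    if (total > ceiling)
      abort("n_subsample >= R^K but R^K exceeds the full-mode ceiling")
    message(sprintf("n_subsample >= R^K = %s; returning the full enumeration",
                    format(total, big.mark = ",")))
    return(expand(seq_len(total) - 1))
  }
  maybe_with_seed(seed, {
    if (total <= .Machine$integer.max) {
      expand(sample.int(as.integer(total), n_subsample) - 1)
    } else {
      # R^K too large to index: draw digit vectors and deduplicate
      rows <- matrix(0L, 0L, K)
      while (nrow(rows) < n_subsample) {
        fresh <- matrix(sample.int(R, 2L * n_subsample * K, replace = TRUE),
                        ncol = K)
        rows <- unique(rbind(rows, fresh))
      }
      rows[seq_len(n_subsample), , drop = FALSE]
    }
  })
}

#' Build one composite relative-abundance time series from an assembly
#'
#' Column k of the result is the relative-abundance profile of replicate
#' `assembly[k]` of `group` at the group's k-th sampling day.
#'
#' @param table an [abundance_table()].
#' @param group group label.
#' @param assembly integer vector, one replicate choice per time point.
#' @return taxon x time matrix of relative abundances (columns sum to 1),
#'   with attribute `time_grid`.
#' @export
assemble_series <- function(table, group, assembly) {
  stopifnot(inherits(table, "abundance_table"))
  meta <- table$metadata
  in_group <- meta$group == group
  if (!any(in_group)) abort("unknown group '%s'", group)
  reps <- sort(unique(meta$mouse[in_group]))
  days <- sort(unique(meta$day[in_group]))
  K <- length(days)
  assembly <- as.integer(assembly)
  if (length(assembly) != K)
    abort("assembly has length %d but group '%s' has %d time points",
          length(assembly), group, K)
  if (any(assembly < 1L) || any(assembly > length(reps)))
    abort("assembly choices must lie in 1..%d", length(reps))
  rel <- to_relative(table)
  out <- matrix(NA_real_, ncol(rel), K,
                dimnames = list(table$taxa, days))
  for (k in seq_len(K)) {
    hit <- which(in_group & meta$mouse == reps[assembly[k]] &
                   meta$day == days[k])
    if (length(hit) != 1L)
      abort("no unique sample for (group %s, replicate %s, day %s)",
            group, reps[assembly[k]], format(days[k]))
    out[, k] <- rel[hit, ]
  }
  attr(out, "time_grid") <- days
  out
}
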