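#' Generalized Lotka-Volterra parameter set
#'
#' Bundles a per-taxon intrinsic growth-rate vector `b` (1/day) with a
#' taxon-by-taxon interaction matrix `A`, where entry `A[i, j]` is the effect
#' of taxon j's abundance on taxon i's per-capita growth rate
#' (1/(day * abundance)). The community evolves by the discrete log-space
#' Euler update
#' `ln x_i(t[k+1]) = ln x_i(t[k]) + dt_k * (b_i + sum_j A[i,j] x_j(t[k]))`.
#'
#' @param growth numeric vector of intrinsic growth rates, one per taxon.
#' @param interactions square numeric matrix of interaction coefficients.
#' @param taxa character vector of unique taxon labels.
#' @return an object of class `glv_params`.
#' @export
glv_params <- function(growth, interactions,
                       taxa = paste0("Taxon_", seq_along(growth))) {
  interactions <- as.matrix(interactions)
  n <- length(growth)
  if (!is.numeric(growth) || n < 1L) abort("'growth' must be a numeric vector")
  if (nrow(interactions) != n || ncol(interactions) != n)
    abort("'interactions' must be a %d x %d matrix", n, n)
  if (any(!is.finite(growth)) || any(!is.finite(interactions)))
    abort("gLV parameters must be finite")
  if (length(taxa) != n || anyDuplicated(taxa))
    abort("'taxa' must be %d unique labels", n)
  taxa <- as.character(taxa)
  dimnames(interactions) <- list(taxa, taxa)
  names(growth) <- taxa
  structure(list(growth = growth, interactions = interactions, taxa = taxa),
            class = "glv_params")
}

#' @export
print.glv_params <- function(x, ...) {
  nz <- sum(x$interactions[row(x$interactions) != col(x$interactions)] != 0)
  cat(sprintf("gLV parameter set: %d taxa, %d non-zero off-diagonal interactions\n",
              length(x$taxa), nz))
  invisible(x)
}

#' Default sampling-day grid
#'
#' The eleven-point fecal-collection grid used by default: one baseline day
#' before surgery, the surgery day itself, and nine post-surgery days with a
#' 0.4-day sub-daily sample (day 1.4) and a final gap to day 14.
#'
#' @return numeric vector of 11 strictly increasing days.
#' @export
default_time_grid <- function() c(-1, 0, 1, 1.4, 2, 3, 4, 5, 6, 7, 14)

#' Study design for the synthetic-community generator
#'
#' @param n_groups number of treatment groups (default 2).
#' @param replicates_per_group animals per group (default 3).
#' @param time_grid strictly increasing sampling days; default
#'   [default_time_grid()] (11 points).
#' @param n_taxa number of genus-level taxa (default 20, a desk-scale stand-in
#'   for the 59-genus study; set 59 for full scale).
#' @param library_size reads per sample (default 1e4; full scale ~2e5).
#' @param noise_sd per-step log-abundance process noise (default 0.05).
#' @param init_sdlog log-normal sd of between-replicate initial-abundance
#'   spread around the community equilibrium (default 0.5).
#' @param seed integer seed recorded with the design.
#' @return an object of class `study_design`.
#' @export
study_design <- function(n_groups = 2L, replicates_per_group = 3L,
                         time_grid = default_time_grid(), n_taxa = 20L,
                         library_size = 1e4, noise_sd = 0.05,
                         init_sdlog = 0.5, seed = NULL) {
  n_groups <- assert_count(n_groups, "n_groups")
  replicates_per_group <- assert_count(replicates_per_group, "replicates_per_group")
  n_taxa <- assert_count(n_taxa, "n_taxa")
  library_size <- assert_count(library_size, "library_size")
  if (!is.numeric(time_grid) || length(time_grid) < 2L ||
      any(diff(time_grid) <= 0))
    abort("'time_grid' must be strictly increasing with >= 2 points")
  assert_scalar_number(noise_sd, "noise_sd")
  if (noise_sd < 0) abort("'noise_sd' must be >= 0")
  structure(list(n_groups = n_groups,
                 replicates_per_group = replicates_per_group,
                 time_grid = as.numeric(time_grid), n_taxa = n_taxa,
                 library_size = library_size, noise_sd = noise_sd,
                 init_sdlog = init_sdlog, seed = seed),
            class = "study_design")
}

#' Draw a random ground-truth gLV parameter set
#'
#' Off-diagonal interactions are non-zero with probability `density`; a
#' non-zero entry is positive with probability `positive_fraction` and has
#' magnitude |N(0, strength_scale^2)|. Diagonal entries are negative
#' (self-limitation) drawn uniformly from `-self_limitation`. Growth rates are
#' set as `b = -A x*` for a log-normally drawn positive equilibrium `x*`, so
#' the community has a feasible fixed point by construction.
#'
#' @param n_taxa number of taxa (> 0).
#' @param density probability an off-diagonal interaction is non-zero.
#' @param strength_scale sd of non-zero off-diagonal magnitudes
#'   (1/(day*abundance)); default 0.05, i.e. pairwise effects a few times
#'   weaker than self-limitation.
#' @param positive_fraction probability a non-zero interaction is positive
#'   (cooperative); raise it to emulate cooperation-dominated communities.
#' @param seed integer seed (NULL = ambient RNG).
#' @param self_limitation length-2 positive range for |diagonal| (1/day per
#'   unit abundance); default c(0.1, 0.3) keeps the stiffest relaxation rate
#'   compatible with the 7-day final sampling gap.
#' @param equilibrium_sdlog log-normal spread of equilibrium abundances.
#' @return a [glv_params()] object with attribute `equilibrium`.
#' @export
generate_interaction_matrix <- function(n_taxa, density = 0.15,
                                        strength_scale = 0.05,
                                        positive_fraction = 0.5,
                                        seed = NULL,
                                        self_limitation = c(0.1, 0.3),
                                        equilibrium_sdlog = 1) {
  n_taxa <- assert_count(n_taxa, "n_taxa")
  assert_fraction(density, "density")
  assert_fraction(positive_fraction, "positive_fraction")
  assert_scalar_number(strength_scale, "strength_scale")
  maybe_with_seed(seed, {
    a <- matrix(0, n_taxa, n_taxa)
    off <- which(row(a) != col(a))
    nz <- off[stats::runif(length(off)) < density]
    sgn <- ifelse(stats::runif(length(nz)) < positive_fraction, 1, -1)
    a[nz] <- sgn * abs(stats::rnorm(length(nz), 0, strength_scale))
    diag(a) <- -stats::runif(n_taxa, self_limitation[1], self_limitation[2])
    x_star <- stats::rlnorm(n_taxa, meanlog = 0, sdlog = equilibrium_sdlog)
    # enforce diagonal dominance at the equilibrium so the fixed point is
    # stable (Gershgorin) and cooperative loops cannot blow up; rescaling
    # preserves every interaction's sign
    for (i in seq_len(n_taxa)) {
      load <- sum(abs(a[i, -i]) * x_star[-i])
      cap <- 0.7 * abs(a[i, i]) * x_star[i]
      if (load > cap) a[i, -i] <- a[i, -i] * cap / load
    }
    b <- as.numeric(-a %*% x_star)
    p <- glv_params(b, a, taxa = sprintf("Taxon_%02d", seq_len(n_taxa)))
    attr(p, "equilibrium") <- stats::setNames(x_star, p$taxa)
    p
  })
}

#' Simulate a gLV trajectory on a (possibly uneven) day grid
#'
#' Applies the discrete multiplicative update (see [glv_params()]) once per
#' interval of `time_grid`, adding N(0, noise_sd^2) log-abundance noise per
#' taxon and step. Abundances stay strictly positive.
#'
#' @param params a [glv_params()] object.
#' @param initial_abundances strictly positive vector, one per taxon.
#' @param time_grid strictly increasing sampling days (first entry = t0).
#' @param noise_sd per-step log-scale noise sd (0 = deterministic).
#' @param seed integer seed (NULL = ambient RNG).
#' @return taxon x time matrix of abundances, columns named by day.
#' @export
simulate_glv_series <- function(params, initial_abundances,
                                time_grid = default_time_grid(),
                                noise_sd = 0, seed = NULL) {
  stopifnot(inherits(params, "glv_params"))
  n <- length(params$taxa)
  x0 <- as.numeric(initial_abundances)
  if (length(x0) != n) abort("'initial_abundances' must have length %d", n)
  if (any(!is.finite(x0)) || any(x0 <= 0))
    abort("initial abundances must be strictly positive")
  if (any(diff(time_grid) <= 0)) abort("'time_grid' must be strictly increasing")
  K <- length(time_grid)
  maybe_with_seed(seed, {
    out <- matrix(NA_real_, n, K, dimnames = list(params$taxa, time_grid))
    logx <- log(x0)
    out[, 1] <- x0
    for (k in seq_len(K - 1L)) {
      dt <- time_grid[k + 1L] - time_grid[k]
      x <- exp(logx)
      logx <- logx + dt * (params$growth + as.numeric(params$interactions %*% x))
      if (noise_sd > 0) logx <- logx + stats::rnorm(n, 0, noise_sd)
      bad <- which(!is.finite(logx) | logx > 250)
      if (length(bad))
        abort("divergent gLV dynamics: taxon '%s' overflowed at step %d (day %s)",
              params$taxa[bad[1]], k, format(time_grid[k + 1L]))
      out[, k + 1L] <- exp(logx)
    }
    out
  })
}

#' Multinomially sample sequencing counts from an abundance trajectory
#'
#' Emulates compositional amplicon sequencing: each time point's abundances
#' are normalized to proportions and `library_size` reads are drawn
#' multinomially, so per-sample counts sum exactly to the library size.
#'
#' @param abundance_matrix taxon x time matrix of non-negative abundances,
#'   each column with positive total.
#' @param library_size reads per sample.
#' @param seed integer seed (NULL = ambient RNG).
#' @return sample (time point) x taxon integer count matrix.
#' @export
sample_counts <- function(abundance_matrix, library_size, seed = NULL) {
  m <- as.matrix(abundance_matrix)
  library_size <- assert_count(library_size, "library_size")
  if (any(m < 0)) abort("abundances must be non-negative")
  tot <- colSums(m)
  if (any(tot <= 0))
    abort("all-zero abundance column at time point %d", which(tot <= 0)[1])
  maybe_with_seed(seed, {
    counts <- apply(m, 2, function(col) stats::rmultinom(1, library_size, col))
    counts <- t(counts)
    dimnames(counts) <- list(colnames(m), rownames(m))
    storage.mode(counts) <- "integer"
    counts
  })
}

#' Generate a full two-group synthetic study with known ground truth
#'
#' Replicates within a group share one gLV parameter set but differ in
#' initial abundances (log-normal spread around the group equilibrium) and in
#' process-noise draws, emulating between-animal variation. Counts are
#' multinomial at the design's library size.
#'
#' @param design a [study_design()].
#' @param group_params list of one [glv_params()] per group (NULL = draw one
#'   per group with [generate_interaction_matrix()] defaults).
#' @param group_labels character labels; defaults to Sham/SNI for two groups.
#' @param seed integer seed; defaults to `design$seed`.
#' @return list of class `glv_study` with elements `table` (an
#'   [abundance_table()]), `params` (ground truth per group), `abundances`
#'   (list of latent taxon x time matrices per group/replicate) and `design`.
#' @export
generate_study <- function(design, group_params = NULL, group_labels = NULL,
                           seed = design$seed) {
  stopifnot(inherits(design, "study_design"))
  G <- design$n_groups
  R <- design$replicates_per_group
  K <- length(design$time_grid)
  labels <- group_labels %||%
    (if (G == 2L) c("Sham", "SNI") else sprintf("Group%d", seq_len(G)))
  if (length(labels) != G) abort("'group_labels' must have length %d", G)
  if (!is.null(group_params) && length(group_params) != G)
    abort("need one gLV parameter set per group (%d given, %d groups)",
          length(group_params), G)
  maybe_with_seed(seed, {
    if (is.null(group_params))
      group_params <- lapply(seq_len(G), function(g)
        generate_interaction_matrix(design$n_taxa))
    for (p in group_params)
      if (length(p$taxa) != design$n_taxa)
        abort("group parameter set has %d taxa but design declares %d",
              length(p$taxa), design$n_taxa)
    names(group_params) <- labels
    taxa <- group_params[[1]]$taxa
    counts <- NULL
    meta <- NULL
    latent <- list()
    for (g in seq_len(G)) {
      p <- group_params[[g]]
      x_star <- attr(p, "equilibrium") %||% rep(1, design$n_taxa)
      for (r in seq_len(R)) {
        x0 <- x_star * stats::rlnorm(design$n_taxa, 0, design$init_sdlog)
        traj <- simulate_glv_series(p, x0, design$time_grid,
                                    noise_sd = design$noise_sd)
        latent[[sprintf("%s_m%d", labels[g], r)]] <- traj
        cnt <- sample_counts(traj, design$library_size)
        ids <- sprintf("%s_m%d_t%02d", labels[g], r, seq_len(K))
        rownames(cnt) <- ids
        counts <- rbind(counts, cnt)
        meta <- rbind(meta, data.frame(sample = ids, group = labels[g],
                                       mouse = r, day = design$time_grid,
                                       stringsAsFactors = FALSE))
      }
    }
    colnames(counts) <- taxa
    structure(list(table = abundance_table(counts, meta),
                   params = group_params, abundances = latent,
                   design = design),
              class = "glv_study")
  })
}

#' @export
print.glv_study <- function(x, ...) {
  cat(sprintf("synthetic gLV study: %d groups x %d replicates x %d time points, %d taxa\n",
              x$design$n_groups, x$design$replicates_per_group,
              length(x$design$time_grid), x$design$n_taxa))
  invisible(x)
}
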