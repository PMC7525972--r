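#' Configuration for the per-series gLV regression
#'
#' @param regression backend: `"pls"` (partial least squares, the default --
#'   the only workable choice when taxa outnumber transitions), `"ridge"`, or
#'   `"ols"` (for small fully identified recovery settings).
#' @param n_components PLS components (clipped to the data rank; default 2).
#' @param lambda ridge penalty (default 0.01).
#' @param pseudocount replacement for zero relative abundances before taking
#'   logs; NULL (default) = half the smallest non-zero value in the series.
#' @return list of class `glv_fit_config`.
#' @export
glv_fit_config <- function(regression = c("pls", "ridge", "ols"),
                           n_components = 2L, lambda = 1e-2,
                           pseudocount = NULL) {
  regression <- match.arg(regression)
  n_components <- assert_count(n_components, "n_components")
  assert_scalar_number(lambda, "lambda")
  if (lambda < 0) abort("'lambda' must be >= 0")
  if (!is.null(pseudocount)) {
    assert_scalar_number(pseudocount, "pseudocount")
    if (pseudocount <= 0) abort("'pseudocount' must be positive")
  }
  structure(list(regression = regression, n_components = n_components,
                 lambda = lambda, pseudocount = pseudocount),
            class = "glv_fit_config")
}

# PLS1 (NIPALS) regression coefficients for one centered/scaled response;
# returns c(intercept, beta) on the original predictor scale
pls1_coef <- function(X, y, ncomp, scale. = TRUE) {
  n <- nrow(X); p <- ncol(X)
  xm <- colMeans(X); ym <- mean(y)
  xs <- if (scale.) apply(X, 2, stats::sd) else rep(1, p)
  xs[xs == 0 | !is.finite(xs)] <- 1
  Xr <- sweep(sweep(X, 2, xm), 2, xs, "/")
  yr <- y - ym
  ncomp <- min(ncomp, n - 1L, p)
  W <- P <- matrix(0, p, max(ncomp, 1L)); q <- numeric(max(ncomp, 1L))
  used <- 0L
  for (h in seq_len(ncomp)) {
    w <- crossprod(Xr, yr)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) break
    w <- w / wn
    tt <- Xr %*% w
    t2 <- sum(tt^2)
    if (t2 < 1e-12) break
    pl <- crossprod(Xr, tt) / t2
    qh <- sum(yr * tt) / t2
    Xr <- Xr - tt %*% t(pl)
    yr <- yr - qh * as.numeric(tt)
    used <- used + 1L
    W[, used] <- w; P[, used] <- pl; q[used] <- qh
  }
  beta <- if (used == 0L) rep(0, p) else {
    Wu <- W[, seq_len(used), drop = FALSE]
    Pu <- P[, seq_len(used), drop = FALSE]
    as.numeric(Wu %*% solve(crossprod(Pu, Wu), q[seq_len(used)]))
  }
  beta <- beta / xs
  c(ym - sum(xm * beta), beta)
}

#' Fit the discrete gLV regression to one taxon-by-time series
#'
#' For each taxon i the response over transitions k is
#' `y_i(k) = (ln x_i(t[k+1]) - ln x_i(t[k])) / dt_k` and the predictors are
#' the abundances `x_j(t[k])` of all taxa plus an intercept; the intercept
#' estimates the intrinsic growth `b_i` and the slopes the interaction row
#' `A[i, ]`. Zeros are replaced by a pseudocount before taking logs.
#'
#' @param series taxon x time matrix of (relative) abundances >= 0.
#' @param time_grid sampling days; defaults to `attr(series, "time_grid")`
#'   or numeric column names.
#' @param config a [glv_fit_config()].
#' @return list of class `glv_fit` with `growth` (length-n vector) and
#'   `interactions` (n x n matrix, row = target taxon).
#' @export
fit_glv_series <- function(series, time_grid = NULL,
                           config = glv_fit_config()) {
  series <- as.matrix(series)
  stopifnot(inherits(config, "glv_fit_config"))
  time_grid <- time_grid %||% attr(series, "time_grid") %||%
    suppressWarnings(as.numeric(colnames(series)))
  if (is.null(time_grid) || any(!is.finite(time_grid)))
    abort("no usable time grid: pass 'time_grid' or name the columns by day")
  K <- ncol(series)
  if (length(time_grid) != K) abort("time grid length != number of columns")
  if (K < 2L) abort("need at least 2 time points")
  dt <- diff(time_grid)
  if (any(dt == 0)) abort("zero time step at index %d", which(dt == 0)[1])
  if (any(dt < 0)) abort("'time_grid' must be increasing")
  if (any(series < 0)) abort("abundances must be non-negative")
  taxa <- rownames(series) %||% paste0("Taxon_", seq_len(nrow(series)))
  pc <- config$pseudocount
  if (any(series == 0)) {
    if (is.null(pc)) {
      pos <- series[series > 0]
      if (!length(pos)) abort("series is identically zero")
      pc <- min(pos) / 2
    }
    series[series == 0] <- pc
  }
  n <- nrow(series)
  logx <- log(series)
  Y <- sweep(logx[, -1L, drop = FALSE] - logx[, -K, drop = FALSE], 2, dt, "/")
  X <- t(series[, -K, drop = FALSE])          # transitions x taxa
  coefs <- switch(config$regression,
    ols = {
      Xd <- cbind(`(Intercept)` = 1, X)
      if (nrow(Xd) < ncol(Xd))
        warning("ols is underdetermined here (", nrow(Xd), " transitions, ",
                ncol(Xd), " coefficients); consider pls or ridge")
      qrX <- qr(Xd)
      t(apply(Y, 1, function(y) {
        co <- qr.coef(qrX, y)
        co[is.na(co)] <- 0
        co
      }))
    },
    ridge = {
      xm <- colMeans(X)
      Xc <- sweep(X, 2, xm)
      G <- crossprod(Xc) + config$lambda * diag(n)
      t(apply(Y, 1, function(y) {
        beta <- solve(G, crossprod(Xc, y - mean(y)))
        c(mean(y) - sum(xm * beta), beta)
      }))
    },
    pls = t(apply(Y, 1, function(y) pls1_coef(X, y, config$n_components)))
  )
  growth <- stats::setNames(coefs[, 1L], taxa)
  interactions <- coefs[, -1L, drop = FALSE]
  dimnames(interactions) <- list(taxa, taxa)
  structure(list(growth = growth, interactions = interactions, taxa = taxa,
                 config = config),
            class = "glv_fit")
}
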