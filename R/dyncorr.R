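#' Quadrature weights of the time-averaged inner product
#'
#' The dynamical inner product of two trajectories is the time average
#' `(1/(tN - t1)) * integral(u v dt)` approximated on the sampling knots:
#' `<u, v> = sum_k w_k u_k v_k` with interior weights
#' `w_k = (t_{k+1} - t_{k-1}) / (2 (t_N - t_1))` and trapezoid endpoint
#' weights `w_1 = (t_2 - t_1) / (2 (t_N - t_1))`,
#' `w_N = (t_N - t_{N-1}) / (2 (t_N - t_1))`. The weights sum to one, so
#' constants have unit norm.
#'
#' @param grid strictly increasing numeric vector of times (hours), length
#'   at least 2.
#' @return Numeric vector of weights summing to 1.
#' @export
dynamical_weights <- function(grid) {
  n <- length(grid)
  if (n < 2 || any(diff(grid) <= 0))
    abort("grid must be strictly increasing with at least 2 points")
  span <- grid[n] - grid[1]
  w <- c(grid[2] - grid[1],
         if (n > 2) grid[3:n] - grid[1:(n - 2)] else NULL,
         grid[n] - grid[n - 1]) / (2 * span)
  w
}

#' @rdname dynamical_weights
#' @param u,v numeric vectors of trajectory values on `grid`.
#' @return `dynamical_inner_product()`: the scalar `sum_k w_k u_k v_k`.
#' @export
dynamical_inner_product <- function(u, v, grid) {
  if (length(u) != length(grid) || length(v) != length(grid))
    abort("u, v and grid must have equal length")
  sum(dynamical_weights(grid) * u * v)
}

#' Cubic-spline interpolation of replicated series to a uniform grid
#'
#' Each replicate of each variable is interpolated independently with a
#' cubic spline onto the uniform grid `seq(span[1], span[2], by = step)`.
#' For the default span of 0--24 h at 0.5 h resolution the grid has 49
#' points. End conditions are those of R's standard cubic interpolant
#' (`stats::spline`, FMM).
#'
#' @param series long-format tibble with columns `variable`, `replicate`,
#'   `time_h`, `value` (extra columns such as `layer` and `unit_id` are
#'   carried through).
#' @param step grid resolution in hours.
#' @param span two-element numeric, the time window in hours.
#' @param grid optional explicit target grid (overrides `step`/`span`);
#'   e.g. the union of the native layer grids, which preserves the
#'   information content of the design better than a fine uniform grid.
#' @return A tibble in the same long format on the target grid.
#' @export
interpolate_to_grid <- function(series, step = 0.5, span = c(0, 24),
                                grid = NULL) {
  series <- as_tibble(series)
  stopifnot(all(c("variable", "replicate", "time_h", "value") %in%
                  names(series)))
  if (is.null(grid)) grid <- seq(span[1], span[2], by = step)
  span <- range(grid)
  meta_cols <- intersect(c("layer", "unit_id"), names(series))
  meta <- series |> distinct(across(all_of(c("variable", meta_cols))))
  out <- series |>
    group_by(.data$variable, .data$replicate) |>
    group_modify(function(df, key) {
      if (nrow(df) < 4)
        abort(sprintf(
          "variable '%s': cubic spline interpolation needs at least 4 native points (got %d)",
          key$variable, nrow(df)))
      if (min(df$time_h) > span[1] || max(df$time_h) < span[2])
        abort(sprintf("variable '%s': native grid does not cover the span",
                      key$variable))
      sp <- stats::spline(df$time_h, df$value, xout = grid)
      tibble(time_h = sp$x, value = sp$y)
    }) |>
    ungroup()
  left_join(out, meta, by = "variable")
}

# arrange long series into a [variable, replicate, time] array on a common
# grid; errors if the grid or replicate structure is ragged
dyn_arrange <- function(series, nodes = NULL) {
  series <- as_tibble(series)
  if (!is.null(nodes)) series <- filter(series, .data$variable %in% nodes)
  vars <- sort(unique(series$variable))
  if (!is.null(nodes)) {
    missing <- setdiff(nodes, vars)
    if (length(missing) > 0)
      abort(paste0("series missing for: ", paste(missing, collapse = ", ")))
    vars <- nodes
  }
  grid <- sort(unique(series$time_h))
  reps <- sort(unique(series$replicate))
  M <- length(reps); N <- length(grid)
  if (nrow(series) != length(vars) * M * N)
    abort("series must be complete over a common grid and replicate set")
  arr <- array(NA_real_, dim = c(length(vars), M, N),
               dimnames = list(vars, reps, grid))
  arr[cbind(match(series$variable, vars),
            match(series$replicate, reps),
            match(series$time_h, grid))] <- series$value
  if (anyNA(arr)) abort("series must be complete over a common grid")
  list(values = arr, vars = vars, reps = reps, grid = grid, M = M, N = N)
}

# centering, pooled variance and standardization shared by the correlation
# and the normality screen; replicates are centered by the grand mean over
# replicates of the per-replicate time averages
dyn_standardize <- function(arr) {
  w <- dynamical_weights(arr$grid)
  M <- arr$M
  tavg <- apply(arr$values, c(1, 2), mean)            # plain time average
  grand <- rowMeans(tavg)
  cent <- sweep(arr$values, 1, grand, "-")
  denom <- max(M - 1, 1)
  wcube <- aperm(array(w, dim = c(arr$N, length(arr$vars), M)), c(2, 3, 1))
  variance <- apply(cent^2 * wcube, 1, sum) / denom
  if (any(variance <= 0)) {
    bad <- arr$vars[variance <= 0]
    abort(paste0("constant series (zero pooled variance): ",
                 paste(bad, collapse = ", ")))
  }
  std <- sweep(cent, 1, sqrt(variance), "/")
  list(cent = cent, std = std, variance = variance, grand = grand,
       weights = w, denom = denom)
}

#' Sample dynamical correlation for replicated time series
#'
#' Computes the replicate-pooled sample dynamical covariance and correlation
#' of a collection of series sharing one grid and one replicate count M.
#' Each replicate is centered by the grand mean (over replicates) of the
#' per-replicate time averages; the pooled variance is
#' `Var_i = (1/(M-1)) sum_r <x_ir^C, x_ir^C>` (for M = 1 the single inner
#' product); standardized trajectories `x^S = x^C / sqrt(Var)` then give
#' `R_ij = (1/(M-1)) sum_r <x_ir^S, x_jr^S>`. The sign is positive when two
#' series sit mostly on the same side of their time averages, negative when
#' on opposite sides. R has unit diagonal, entries in `[-1, 1]`, and is
#' positive semidefinite by construction (it is a Gram matrix of weighted
#' standardized trajectories).
#'
#' @inheritParams interpolate_to_grid
#' @param nodes optional character vector restricting (and ordering) the
#'   variables.
#' @return An object of class `pcu_dyncorr`: list with `R`, `Sigma`,
#'   `variances`, `means`, `nodes`, `M`, `grid`.
#' @export
dynamical_correlation <- function(series, nodes = NULL) {
  arr <- dyn_arrange(series, nodes)
  st <- dyn_standardize(arr)
  sw <- sqrt(st$weights / st$denom)
  nv <- length(arr$vars)
  flat <- function(a) {
    # [var, rep, time] -> [var, rep*time] with weight-scaled columns
    m <- matrix(aperm(a, c(1, 3, 2)), nrow = nv)
    m * rep(rep(sw, times = arr$M), each = nv)
  }
  Zs <- flat(st$std)
  Zc <- flat(st$cent)
  R <- Zs %*% t(Zs)
  Sigma <- Zc %*% t(Zc)
  dimnames(R) <- dimnames(Sigma) <- list(arr$vars, arr$vars)
  structure(
    list(R = R, Sigma = Sigma,
         variances = setNames(st$variance, arr$vars),
         means = setNames(st$grand, arr$vars),
         nodes = arr$vars, M = arr$M, grid = arr$grid),
    class = "pcu_dyncorr")
}

#' @export
print.pcu_dyncorr <- function(x, ...) {
  cat(sprintf(
    "<pcu_dyncorr> %d variables, M = %d replicates, %d grid points\n",
    length(x$nodes), x$M, length(x$grid)))
  invisible(x)
}

#' @describeIn dynamical_correlation long tibble of the upper-triangle
#'   correlations and covariances.
#' @param x a `pcu_dyncorr` object.
#' @param ... unused.
#' @method tidy pcu_dyncorr
#' @export
tidy.pcu_dyncorr <- function(x, ...) {
  idx <- which(upper.tri(x$R), arr.ind = TRUE)
  tibble(
    var1 = x$nodes[idx[, 1]],
    var2 = x$nodes[idx[, 2]],
    correlation = x$R[idx],
    covariance = x$Sigma[idx]
  )
}

#' @describeIn dynamical_correlation one-row summary (dimensions, minimum
#'   eigenvalue of R).
#' @method glance pcu_dyncorr
#' @export
glance.pcu_dyncorr <- function(x, ...) {
  tibble(
    n_variables = length(x$nodes),
    n_replicates = x$M,
    n_grid = length(x$grid),
    min_eigenvalue = min(eigen(x$R, symmetric = TRUE,
                               only.values = TRUE)$values)
  )
}

#' Kolmogorov-Smirnov normality screen for detrended series
#'
#' Time-series omics data are neither stationary nor Gaussian, but the
#' detrended, standardized trajectories `x^S` used by the dynamical
#' correlation are far closer to normal. This screen pools the
#' standardized values of each variable over replicates and grid points
#' and runs a one-sample Kolmogorov-Smirnov test against the standard
#' normal.
#'
#' @inheritParams dynamical_correlation
#' @param alpha rejection level (default 0.01).
#' @return Tibble with one row per variable: `variable`, `statistic`,
#'   `p_value`, `reject`.
#' @export
detrended_normality_test <- function(series, nodes = NULL, alpha = 0.01) {
  stopifnot(alpha > 0, alpha <= 1)
  arr <- dyn_arrange(series, nodes)
  st <- dyn_standardize(arr)
  purrr::map(seq_along(arr$vars), function(i) {
    vals <- as.vector(st$std[i, , ])
    kt <- suppressWarnings(stats::ks.test(vals, "pnorm"))
    tibble(variable = arr$vars[i], statistic = unname(kt$statistic),
           p_value = kt$p.value, reject = kt$p.value < alpha)
  }) |>
    bind_rows()
}
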