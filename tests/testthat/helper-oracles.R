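# Independent oracles used across the suite. These deliberately take
# different computational routes than the package implementation.

# random DAG on n nodes as an upper-triangular edge table
ora_random_dag <- function(n, p_edge = 0.4) {
  nodes <- sprintf("n%d", seq_len(n))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(idx)) < p_edge
  data.frame(from = nodes[idx[keep, 1]], to = nodes[idx[keep, 2]],
             stringsAsFactors = FALSE)
}

# covariance of a generic linear-Gaussian SEM on the DAG: x = W^T x + e
ora_sem_sigma <- function(edges, nodes) {
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges) > 0)
    W[cbind(match(edges$from, nodes), match(edges$to, nodes))] <-
      stats::runif(nrow(edges), 0.5, 1.5) *
      sample(c(-1, 1), nrow(edges), TRUE)
  A <- solve(diag(n) - t(W))
  v <- stats::runif(n, 0.5, 1.5)
  S <- A %*% diag(v) %*% t(A)
  dimnames(S) <- list(nodes, nodes)
  S
}

# partial correlation via the Schur complement (conditional covariance),
# an independent route from the package's precision-matrix formula
ora_pcor_schur <- function(S, x, y, C) {
  if (length(C) == 0) {
    return(S[x, y] / sqrt(S[x, x] * S[y, y]))
  }
  xy <- c(x, y)
  Scc <- S[C, C, drop = FALSE]
  Sc <- S[xy, xy] - S[xy, C, drop = FALSE] %*%
    solve(Scc, S[C, xy, drop = FALSE])
  Sc[1, 2] / sqrt(Sc[1, 1] * Sc[2, 2])
}

# exhaustive simple-cycle enumeration with sign products (DFS); the
# implementation under test uses BFS gauge propagation instead
ora_all_cycles_balanced <- function(sgn) {
  n <- nrow(sgn)
  balanced <- TRUE
  visit <- function(path, prod) {
    v <- path[length(path)]
    for (u in seq_len(n)) {
      if (sgn[v, u] == 0) next
      if (u == path[1] && length(path) >= 3) {
        if (prod * sgn[v, u] < 0) balanced <<- FALSE
      } else if (!(u %in% path) && u > path[1]) {
        visit(c(path, u), prod * sgn[v, u])
      }
    }
  }
  for (s in seq_len(n)) visit(s, 1)
  balanced
}

# random signed symmetric adjacency (with unit diagonal as weights)
ora_random_signed <- function(n, p_edge = 0.6) {
  A <- matrix(0, n, n)
  idx <- which(upper.tri(A), arr.ind = TRUE)
  val <- ifelse(stats::runif(nrow(idx)) < p_edge,
                stats::runif(nrow(idx), 0.2, 1) *
                  sample(c(-1, 1), nrow(idx), TRUE), 0)
  A[idx] <- val
  A <- A + t(A)
  diag(A) <- 1
  rownames(A) <- colnames(A) <- sprintf("v%d", seq_len(n))
  A
}

# long-format series tibble from a [rep x time] value matrix
ora_series_tbl <- function(values_by_var, grid, reps = NULL) {
  M <- nrow(values_by_var[[1]])
  reps <- reps %||% sprintf("r%d", seq_len(M))
  purrr::imap(values_by_var, function(m, v) {
    tidyr::crossing(replicate = reps, time_h = grid) |>
      dplyr::arrange(replicate, time_h) |>
      dplyr::mutate(variable = v,
                    value = as.vector(t(m)))
  }) |> dplyr::bind_rows()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# native union grid of the default simulation design
ora_union_grid <- function(config = simulation_config())
  sort(unique(unlist(config$grids)))

# unit id of a simulated variable
ora_unit_of <- function(vars) sub("^(u[0-9]+).*$", "\\1", vars)

# shared small synthetic study, memoized per test run
ora_default_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(n_units = 10, seed = 42)
      st <- simulate_pcu_study(cfg)
      ug <- ora_union_grid(cfg)
      interp <- interpolate_to_grid(st$series, grid = ug)
      dc <- dynamical_correlation(interp)
      cache <<- list(config = cfg, truth = st$truth, series = st$series,
                     interp = interp, dyncorr = dc)
    }
    cache
  }
})
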