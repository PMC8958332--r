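#' Configuration of the synthetic protein-coding-unit study
#'
#' The generator emulates the design of the motivating study: ATAC and
#' RNA layers sampled at 0, 0.5, 1, 2, 6 and 24 h, the protein layer at
#' 0, 1, 2, 6 and 24 h (a late 120 h point is not part of the analysis
#' window and is not generated), and 3 biological replicates throughout.
#' Signals are smooth functions of time built from cubic B-spline bases
#' with random coefficients, propagated through the unit's DAG by linear
#' structural equations with signed weights; optional planted extra
#' `a -> s` edges and hidden confounders violate the assumed DAG while
#' leaving it unchanged as the analysis model.
#'
#' @param n_units number of protein-coding units.
#' @param peaks_per_unit,splices_per_unit integer range `c(min, max)`;
#'   counts drawn uniformly.
#' @param edge_weight_magnitude positive scale of the structural weights;
#'   magnitudes are drawn uniformly in `[0.5, 1.5] *
#'   edge_weight_magnitude`, bounded away from zero so that true edges are
#'   detectable.
#' @param negative_edge_prob probability that a weight's sign is flipped.
#' @param noise_sd standard deviation of the smooth structural noise added
#'   to every splice and protein signal.
#' @param replicate_sd standard deviation of white observation noise added
#'   independently per replicate and time point.
#' @param n_replicates number of replicates (M).
#' @param grids named list of per-layer sampling times in hours.
#' @param n_basis number of smooth basis functions per latent signal.
#'   Latent signals are cardinal cubic splines through independent standard
#'   normal values at a set of control times; by default (`NULL`) the
#'   control times are the union of the layer grids, so the signal carries
#'   exactly as many degrees of freedom as the sampling design can resolve.
#'   A numeric value places that many evenly spaced control times instead.
#' @param planted_extra_edge_rate per-unit probability of planting a direct
#'   `a -> s` edge absent from the assumed DAG.
#' @param confounder_rate per-unit probability of a hidden smooth factor
#'   loading on two or more splices.
#' @param global_trend_sd scale of the loadings of a shared smooth trend
#'   onto every root peak signal (default 0 = no shared trend). A positive
#'   value emulates a population-wide response -- such as a differentiation
#'   program -- that couples otherwise unrelated units.
#' @param seed integer seed; all generator randomness derives from it.
#' @return A validated list of class `pcu_sim_config`.
#' @export
simulation_config <- function(n_units = 20,
                              peaks_per_unit = c(1, 3),
                              splices_per_unit = c(1, 4),
                              edge_weight_magnitude = 1,
                              negative_edge_prob = 0.2,
                              noise_sd = 0.25,
                              replicate_sd = 0.1,
                              n_replicates = 3,
                              grids = list(
                                a = c(0, 0.5, 1, 2, 6, 24),
                                s = c(0, 0.5, 1, 2, 6, 24),
                                p = c(0, 1, 2, 6, 24)),
                              n_basis = NULL,
                              planted_extra_edge_rate = 0,
                              confounder_rate = 0,
                              global_trend_sd = 0,
                              seed = 1) {
  chk_range <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 2 || any(x < 1) || x[1] > x[2] ||
        any(x != floor(x)))
      abort(sprintf("'%s' must be an integer range c(min, max) with min >= 1",
                    nm))
  }
  chk_range(peaks_per_unit, "peaks_per_unit")
  chk_range(splices_per_unit, "splices_per_unit")
  probs <- c(negative_edge_prob, planted_extra_edge_rate, confounder_rate)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (edge_weight_magnitude <= 0) abort("edge_weight_magnitude must be > 0")
  if (noise_sd < 0 || replicate_sd < 0 || global_trend_sd < 0)
    abort("noise sds must be >= 0")
  if (n_replicates < 1) abort("n_replicates must be >= 1")
  for (g in grids)
    if (g[1] != 0 || any(diff(g) <= 0))
      abort("grids must be strictly increasing and start at 0")
  if (!is.null(n_basis) && n_basis < 2) abort("n_basis must be >= 2")
  structure(
    list(n_units = n_units, peaks_per_unit = peaks_per_unit,
         splices_per_unit = splices_per_unit,
         edge_weight_magnitude = edge_weight_magnitude,
         negative_edge_prob = negative_edge_prob,
         noise_sd = noise_sd, replicate_sd = replicate_sd,
         n_replicates = n_replicates, grids = grids, n_basis = n_basis,
         planted_extra_edge_rate = planted_extra_edge_rate,
         confounder_rate = confounder_rate,
         global_trend_sd = global_trend_sd, seed = as.integer(seed)),
    class = "pcu_sim_config")
}

draw_weight <- function(n, config) {
  mag <- runif(n, 0.5, 1.5) * config$edge_weight_magnitude
  sgn <- ifelse(runif(n) < config$negative_edge_prob, -1, 1)
  mag * sgn
}

#' Generate a population of protein-coding-unit DAGs with ground truth
#'
#' Draws `n_units` three-layer DAGs. Each splice receives one peak parent
#' uniformly at random; peaks left without children are attached to a
#' random splice (so some splices carry several peak parents). Every
#' splice feeds the unit's single protein. Structural weights are drawn
#' per edge. If the config requests planted violations or confounders,
#' [plant_violations()] is applied.
#'
#' @param config a [simulation_config()].
#' @return An object of class `pcu_truth`: list with `dags` (named list of
#'   [pcu_dag]), `weights` (tibble `dag_id`, `from`, `to`, `weight`),
#'   `planted` (same shape), `confounders` (list), `config`.
#' @export
generate_dag_population <- function(config) {
  stopifnot(inherits(config, "pcu_sim_config"))
  set.seed(config$seed)
  units <- sprintf("u%03d", seq_len(config$n_units))
  dags <- list()
  weights <- list()
  for (u in units) {
    n_a <- sample(config$peaks_per_unit[1]:config$peaks_per_unit[2], 1)
    n_s <- sample(config$splices_per_unit[1]:config$splices_per_unit[2], 1)
    a_ids <- sprintf("%s_a%d", u, seq_len(n_a))
    s_ids <- sprintf("%s_s%d", u, seq_len(n_s))
    p_id <- sprintf("%s_p", u)
    # every splice gets one peak parent; childless peaks adopt a splice
    pa_of_s <- sample(a_ids, n_s, replace = TRUE)
    orphans <- setdiff(a_ids, pa_of_s)
    as_edges <- tibble(from = pa_of_s, to = s_ids)
    if (length(orphans) > 0)
      as_edges <- bind_rows(as_edges,
        tibble(from = orphans,
               to = sample(s_ids, length(orphans), replace = TRUE)))
    as_edges <- distinct(as_edges)
    edges <- bind_rows(as_edges, tibble(from = s_ids, to = p_id))
    nodes <- tibble(
      id = c(a_ids, s_ids, p_id),
      layer = c(rep("a", n_a), rep("s", n_s), "p"),
      unit_id = u)
    dags[[u]] <- pcu_dag(nodes, edges, dag_id = u)
    weights[[u]] <- edges |>
      mutate(dag_id = u, weight = draw_weight(nrow(edges), config)) |>
      select("dag_id", "from", "to", "weight")
  }
  all_roots <- bind_rows(purrr::map(dags, "nodes")) |>
    filter(.data$layer == "a")
  global_loadings <- tibble(
    dag_id = all_roots$unit_id, node = all_roots$id,
    loading = if (config$global_trend_sd > 0)
      rnorm(nrow(all_roots), sd = config$global_trend_sd) else
      rep(0, nrow(all_roots)))
  truth <- structure(
    list(dags = dags, weights = bind_rows(weights),
         planted = tibble(dag_id = character(), from = character(),
                          to = character(), weight = double()),
         confounders = list(), global_loadings = global_loadings,
         config = config),
    class = "pcu_truth")
  if (config$planted_extra_edge_rate > 0 || config$confounder_rate > 0)
    truth <- plant_violations(truth, config)
  truth
}

#' @export
print.pcu_truth <- function(x, ...) {
  cat(sprintf(
    "<pcu_truth> %d units, %d weighted edges, %d planted edge(s), %d confounder(s)\n",
    length(x$dags), nrow(x$weights), nrow(x$planted),
    length(x$confounders)))
  invisible(x)
}

#' Plant causal violations into the generating equations
#'
#' Adds direct `a -> s` edges between non-adjacent pairs and hidden smooth
#' confounders to the data-generating equations, while leaving the assumed
#' DAGs (`truth$dags`) untouched: downstream analyses still test the clean
#' model, so planted conditions should come out non-verified. Everything
#' planted is recorded in the truth ledger.
#'
#' @param truth a `pcu_truth` from [generate_dag_population()].
#' @param config the same [simulation_config()] (rates must be positive for
#'   an effect).
#' @return The updated `pcu_truth`.
#' @export
plant_violations <- function(truth, config) {
  stopifnot(inherits(truth, "pcu_truth"))
  set.seed(config$seed + 1L)
  planted <- list()
  confounders <- list()
  for (u in names(truth$dags)) {
    dag <- truth$dags[[u]]
    if (config$planted_extra_edge_rate > 0 &&
        runif(1) < config$planted_extra_edge_rate) {
      a_ids <- dag$nodes$id[dag$nodes$layer == "a"]
      s_ids <- dag$nodes$id[dag$nodes$layer == "s"]
      cand <- crossing(from = a_ids, to = s_ids) |>
        anti_join(dag$edges, by = c("from", "to"))
      if (nrow(cand) == 0) {
        warn(sprintf("unit %s: no non-adjacent a-s pair; skipping plant", u))
      } else {
        pick <- cand[sample(nrow(cand), 1), ]
        planted[[length(planted) + 1]] <- pick |>
          mutate(dag_id = u, weight = draw_weight(1, config)) |>
          select("dag_id", "from", "to", "weight")
      }
    }
    if (config$confounder_rate > 0 && runif(1) < config$confounder_rate) {
      s_ids <- dag$nodes$id[dag$nodes$layer == "s"]
      if (length(s_ids) >= 2) {
        k <- sample(2:length(s_ids), 1)
        loaded <- sample(s_ids, k)
        confounders[[length(confounders) + 1]] <- list(
          id = sprintf("f_%s_%d", u, length(confounders) + 1),
          dag_id = u, splices = loaded,
          loadings = setNames(draw_weight(k, config), loaded))
      }
    }
  }
  truth$planted <- bind_rows(truth$planted, bind_rows(planted))
  truth$confounders <- c(truth$confounders, confounders)
  truth
}

# cardinal cubic-spline basis: column j is the spline interpolating the
# j-th unit vector at the control times, evaluated on the grid. A latent
# signal B %*% coef is then the smooth curve through iid control values --
# the richest signal the native sampling design can resolve.
basis_on_grid <- function(grid, control_times) {
  nb <- length(control_times)
  B <- matrix(0, length(grid), nb)
  for (j in seq_len(nb)) {
    e <- numeric(nb); e[j] <- 1
    B[, j] <- stats::spline(control_times, e, xout = grid)$y
  }
  B
}

sim_control_times <- function(config) {
  ct <- sort(unique(unlist(config$grids)))
  if (!is.null(config$n_basis) && config$n_basis != length(ct))
    ct <- seq(min(ct), max(ct), length.out = config$n_basis)
  ct
}

# linear structural propagation in basis-coefficient space for one unit and
# one replicate; returns coefficient matrix [node, basis]
unit_coefficients <- function(dag, wmap, planted, confs, config, nb,
                              gcoef = NULL, gload = NULL) {
  a_ids <- dag$nodes$id[dag$nodes$layer == "a"]
  s_ids <- dag$nodes$id[dag$nodes$layer == "s"]
  p_ids <- dag$nodes$id[dag$nodes$layer == "p"]
  co <- matrix(0, nrow(dag$nodes), nb, dimnames = list(dag$nodes$id, NULL))
  for (a in a_ids) {
    co[a, ] <- rnorm(nb)
    if (!is.null(gcoef) && !is.null(gload[[a]]) && gload[[a]] != 0)
      co[a, ] <- co[a, ] + gload[[a]] * gcoef
  }
  fco <- lapply(confs, function(cf) rnorm(nb))
  names(fco) <- purrr::map_chr(confs, "id")
  for (s in s_ids) {
    acc <- rep(0, nb)
    for (a in dag_parents(dag, s))
      acc <- acc + wmap[[paste(a, s)]] * co[a, ]
    pl <- planted[planted$to == s, ]
    if (nrow(pl) > 0)
      for (i in seq_len(nrow(pl)))
        acc <- acc + pl$weight[i] * co[pl$from[i], ]
    for (cf in confs)
      if (s %in% cf$splices)
        acc <- acc + cf$loadings[[s]] * fco[[cf$id]]
    co[s, ] <- acc + config$noise_sd * rnorm(nb)
  }
  for (p in p_ids) {
    acc <- rep(0, nb)
    for (s in dag_parents(dag, p))
      acc <- acc + wmap[[paste(s, p)]] * co[s, ]
    co[p, ] <- acc + config$noise_sd * rnorm(nb)
  }
  co
}

#' Simulate replicated multi-omics time series for a DAG population
#'
#' Each replicate is an independent realization of the structural system:
#' root peak signals draw fresh B-spline coefficients, splices and proteins
#' are signed weighted sums of their parents plus smooth structural noise
#' (and any planted edges or hidden confounders recorded in the truth
#' ledger), and white observation noise is added per time point. Signals
#' are sampled on each layer's native grid. Output is deterministic given
#' the config seed.
#'
#' @param truth a `pcu_truth`.
#' @param config the [simulation_config()] used to generate it.
#' @return Long tibble: `variable`, `unit_id`, `layer`, `replicate`,
#'   `time_h`, `value`.
#' @export
simulate_unit_timeseries <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "pcu_truth"))
  set.seed(config$seed + 2L)
  ct <- sim_control_times(config)
  B <- lapply(config$grids, basis_on_grid, control_times = ct)
  gload <- if (!is.null(truth$global_loadings))
    setNames(as.list(truth$global_loadings$loading),
             truth$global_loadings$node) else list()
  gcoefs <- purrr::map(seq_len(config$n_replicates),
                       ~ rnorm(length(ct)))
  out <- vector("list", length(truth$dags) * config$n_replicates)
  k <- 0
  for (u in names(truth$dags)) {
    dag <- truth$dags[[u]]
    w <- truth$weights |> filter(.data$dag_id == u)
    wmap <- setNames(as.list(w$weight), paste(w$from, w$to))
    planted <- truth$planted |> filter(.data$dag_id == u)
    confs <- purrr::keep(truth$confounders, ~ .x$dag_id == u)
    for (r in seq_len(config$n_replicates)) {
      co <- unit_coefficients(dag, wmap, planted, confs, config,
                              length(ct), gcoefs[[r]], gload)
      vals <- purrr::map(seq_len(nrow(dag$nodes)), function(i) {
        id <- dag$nodes$id[i]; layer <- dag$nodes$layer[i]
        grid <- config$grids[[layer]]
        y <- as.vector(B[[layer]] %*% co[id, ]) +
          config$replicate_sd * rnorm(length(grid))
        tibble(variable = id, unit_id = u, layer = layer,
               replicate = sprintf("r%d", r), time_h = grid, value = y)
      })
      k <- k + 1
      out[[k]] <- bind_rows(vals)
    }
  }
  bind_rows(out)
}

#' One-call synthetic study
#'
#' Convenience wrapper: generates the DAG population (with any configured
#' violations) and simulates its replicated time series.
#'
#' @inheritParams generate_dag_population
#' @return List with elements `truth` and `series`.
#' @export
simulate_pcu_study <- function(config = simulation_config()) {
  truth <- generate_dag_population(config)
  list(truth = truth, series = simulate_unit_timeseries(truth, config))
}

#' Population covariance implied by the generating equations
#'
#' Exact covariance of one unit's variables under the scalar linear
#' structural equation model that the generator applies coordinate-wise in
#' basis space: roots have unit variance, every non-root adds structural
#' noise of variance `noise_sd^2`, planted edges and confounders are
#' included (they act on the data, not on the assumed DAG), and white
#' observation noise `replicate_sd^2` sits on the diagonal. Serves as the
#' independent oracle for conditional-independence checks: pairs
#' d-separated in the assumed DAG have exactly zero partial correlation
#' here whenever no violation touches them.
#'
#' @param truth a `pcu_truth`.
#' @param dag_id unit to evaluate.
#' @param include_violations include planted edges and confounders
#'   (default `TRUE`).
#' @return Covariance matrix over the unit's node ids.
#' @export
population_covariance <- function(truth, dag_id, include_violations = TRUE) {
  dag <- truth$dags[[dag_id]]
  if (is.null(dag)) abort(sprintf("unknown dag_id '%s'", dag_id))
  config <- truth$config
  w <- truth$weights |> filter(.data$dag_id == !!dag_id)
  wmap <- setNames(as.list(w$weight), paste(w$from, w$to))
  planted <- if (include_violations)
    truth$planted |> filter(.data$dag_id == !!dag_id)
  else truth$planted[0, ]
  confs <- if (include_violations)
    purrr::keep(truth$confounders, ~ .x$dag_id == dag_id) else list()

  ids <- dag$nodes$id
  lay <- dag_layers(dag)
  a_ids <- ids[lay[ids] == "a"]
  s_ids <- ids[lay[ids] == "s"]
  p_ids <- ids[lay[ids] == "p"]
  # sources: one per root, one structural-noise per non-root, one per factor
  src <- c(a_ids, paste0("eps_", c(s_ids, p_ids)),
           purrr::map_chr(confs, "id"), "global_trend")
  L <- matrix(0, length(ids), length(src), dimnames = list(ids, src))
  gl <- truth$global_loadings
  for (a in a_ids) {
    L[a, a] <- 1
    if (!is.null(gl)) {
      lo <- gl$loading[gl$node == a]
      if (length(lo) == 1 && lo != 0) L[a, "global_trend"] <- lo
    }
  }
  for (s in s_ids) {
    for (a in dag_parents(dag, s))
      L[s, ] <- L[s, ] + wmap[[paste(a, s)]] * L[a, ]
    if (nrow(planted) > 0) {
      pl <- planted[planted$to == s, ]
      for (i in seq_len(nrow(pl)))
        L[s, ] <- L[s, ] + pl$weight[i] * L[pl$from[i], ]
    }
    for (cf in confs)
      if (s %in% cf$splices)
        L[s, cf$id] <- L[s, cf$id] + cf$loadings[[s]]
    L[s, paste0("eps_", s)] <- config$noise_sd
  }
  for (p in p_ids) {
    for (s in dag_parents(dag, p))
      L[p, ] <- L[p, ] + wmap[[paste(s, p)]] * L[s, ]
    L[p, paste0("eps_", p)] <- config$noise_sd
  }
  L %*% t(L) + diag(config$replicate_sd^2, length(ids))
}
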