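#' Verification test configuration
#'
#' @param alpha significance level of the Fisher z test (default 0.05).
#' @param N effective sample size. The default 147 is the study
#'   convention: 49 interpolated time points times 3 replicates. Spline
#'   interpolation inflates the effective sample size (the native design
#'   carries far fewer informative samples), so `N` is exposed: analyses of
#'   synthetic data generated on the native grids are better served by
#'   `N = native points x replicates`.
#' @param per_card if `TRUE` (default) the threshold uses the
#'   conditioning-set cardinality in the degrees of freedom; if `FALSE` a
#'   single global threshold at `card = 0` is used for all conditions.
#' @param null_reps number of resamples per condition in the null-model
#'   benchmark.
#' @param condition_tol maximum condition number (2-norm) tolerated when
#'   inverting correlation submatrices.
#' @param theta optional fixed global threshold overriding the Fisher z
#'   computation, e.g. one calibrated on an empirical null with
#'   [null_calibrated_theta()].
#' @param seed seed for null-model resampling.
#' @return List of class `pcu_test_config`.
#' @export
test_config <- function(alpha = 0.05, N = 147, per_card = TRUE,
                        null_reps = 20, condition_tol = 1e10,
                        theta = NULL, seed = 1) {
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1)")
  if (N <= 4) abort("N too small for any Fisher z test")
  if (!is.null(theta) && (theta <= 0 || theta >= 1))
    abort("theta must lie in (0, 1)")
  structure(list(alpha = alpha, N = N, per_card = per_card,
                 null_reps = null_reps, condition_tol = condition_tol,
                 theta = theta, seed = as.integer(seed)),
            class = "pcu_test_config")
}

#' Fisher z threshold for partial correlations
#'
#' The largest absolute (partial) correlation that does not reject
#' independence at level `alpha` with `N` samples and `card_C` conditioning
#' variables: the z transform `Z = atanh(R)` satisfies
#' `sqrt(N - card_C - 3) * |Z|` ~ standard normal under independence, so
#' `theta = tanh(qnorm(1 - alpha/2) / sqrt(N - card_C - 3))`. With the
#' study convention N = 147 and an empty conditioning set this gives
#' theta of about 0.16.
#'
#' @param N sample size.
#' @param card_C conditioning-set cardinality.
#' @param alpha significance level.
#' @return The threshold theta in (0, 1).
#' @export
fisher_threshold <- function(N, card_C = 0, alpha = 0.05) {
  df <- N - card_C - 3
  if (any(df <= 0)) abort("non-positive degrees of freedom (N - |C| - 3)")
  tanh(qnorm(1 - alpha / 2) / sqrt(df))
}

theta_for <- function(card_C, config) {
  if (!is.null(config$theta)) return(rep(config$theta, length(card_C)))
  eff <- if (isTRUE(config$per_card)) card_C else 0
  fisher_threshold(config$N, eff, config$alpha)
}

#' Null-calibrated verification threshold
#'
#' The Fisher z threshold presumes N independent samples, but replicated
#' short time series carry far fewer: spline interpolation adds no
#' information and irregular sampling concentrates the quadrature weight
#' on few knots, so the null distribution of the sample dynamical
#' correlation is much wider than the nominal one. This calibrates the
#' threshold directly on an empirical null: pairs of variables known (or
#' safely assumed) to be independent -- e.g. variables of different,
#' unlinked protein-coding units -- whose absolute correlations provide
#' the null quantile at level `alpha`.
#'
#' @param dyncorr a `pcu_dyncorr` (or correlation matrix).
#' @param units named character vector mapping variable ids to unit ids;
#'   null pairs are sampled across distinct units.
#' @param alpha intended test size (default 0.05); the returned theta is
#'   the `1 - alpha` quantile of the null `|R|`.
#' @param n_pairs number of cross-unit pairs sampled.
#' @param seed sampling seed.
#' @return A single threshold value in (0, 1).
#' @export
null_calibrated_theta <- function(dyncorr, units, alpha = 0.05,
                                  n_pairs = 500, seed = 1) {
  R <- if (inherits(dyncorr, "pcu_dyncorr")) dyncorr$R else dyncorr
  vars <- intersect(rownames(R), names(units))
  if (length(unique(units[vars])) < 2)
    abort("need variables from at least two units")
  set.seed(seed)
  vals <- numeric(0)
  guard <- 0
  while (length(vals) < n_pairs && guard < 50 * n_pairs) {
    guard <- guard + 1
    pair <- sample(vars, 2)
    if (units[[pair[1]]] != units[[pair[2]]])
      vals <- c(vals, abs(R[pair[1], pair[2]]))
  }
  unname(quantile(vals, 1 - alpha))
}

#' Partial correlation from a correlation matrix
#'
#' Restricts `R` to `{x, y} union C`, inverts, and applies
#' `R_xy.C = -[R^-1]_xy / sqrt([R^-1]_xx [R^-1]_yy)`. An empty `C` returns
#' the marginal correlation. Ill-conditioned submatrices (2-norm condition
#' number above `condition_tol`) raise an error rather than being
#' pseudo-inverted.
#'
#' @param R correlation (or covariance) matrix with dimnames.
#' @param x,y variable names.
#' @param C character vector of conditioning variable names.
#' @param condition_tol condition-number tolerance.
#' @return The partial correlation, a scalar in `[-1, 1]`.
#' @export
partial_correlation <- function(R, x, y, C = character(),
                                condition_tol = 1e10) {
  vars <- c(x, y, C)
  missing <- setdiff(vars, rownames(R))
  if (length(missing) > 0)
    abort(paste0("variables not in R: ", paste(missing, collapse = ", ")))
  if (length(C) == 0) return(R[x, y])
  S <- R[vars, vars, drop = FALSE]
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > condition_tol)
    abort(sprintf("ill-conditioned submatrix for (%s, %s | %s)",
                  x, y, paste(C, collapse = ",")))
  K <- solve(S)
  -K[1, 2] / sqrt(K[1, 1] * K[2, 2])
}

#' Verify Markov conditions against sample dynamical correlations
#'
#' For each enumerated condition `x` _|_ `y` | `C`, computes the sample
#' partial correlation from the dynamical correlation matrix and compares
#' it to the Fisher z threshold at that conditioning-set cardinality:
#' the condition is verified when `|R_xy.C| < theta`. Records also carry
#' the marginal correlation and whether conditioning contracted it
#' (`|R_xy.C| <= |R_xy|`). Conditions whose submatrix is ill-conditioned
#' are returned with `NA` partial correlation and flagged in `skipped`.
#'
#' @param conditions tibble from [enumerate_markov_conditions()] (columns
#'   `dag_id`, `x`, `y`, `C` list-column, `card_C`, `klass`).
#' @param dyncorr a `pcu_dyncorr` from [dynamical_correlation()] covering
#'   all condition variables.
#' @param config a [test_config()].
#' @return Tibble of verification records: the condition columns plus
#'   `r_xy`, `r_xy_C`, `theta`, `verified`, `contraction`, `skipped`.
#' @export
verify_conditions <- function(conditions, dyncorr, config = test_config()) {
  R <- if (inherits(dyncorr, "pcu_dyncorr")) dyncorr$R else dyncorr
  recs <- conditions |>
    mutate(
      r_xy = purrr::map2_dbl(.data$x, .data$y, ~ R[.x, .y]),
      r_xy_C = purrr::pmap_dbl(
        list(.data$x, .data$y, .data$C),
        function(x, y, C) {
          tryCatch(partial_correlation(R, x, y, C,
                                       config$condition_tol),
                   error = function(e) NA_real_)
        }),
      theta = theta_for(.data$card_C, config),
      verified = abs(.data$r_xy_C) < .data$theta,
      contraction = abs(.data$r_xy_C) <= abs(.data$r_xy),
      skipped = is.na(.data$r_xy_C))
  n_skip <- sum(recs$skipped)
  if (n_skip > 0)
    inform(sprintf("%d condition(s) skipped (ill-conditioned submatrix)",
                   n_skip))
  recs
}

#' Aggregate verification records
#'
#' `records_by_klass()` reproduces the layout of the headline
#' predicted/verified table: one row per condition class with totals.
#' `records_by_node()` gives the per-node verified/predicted ratio (the
#' quantity histogrammed per DAG node), `records_by_dag()` the per-DAG
#' ratio.
#'
#' @param records tibble from [verify_conditions()].
#' @return A tibble of counts and ratios.
#' @export
records_by_klass <- function(records) {
  records |>
    filter(!.data$skipped) |>
    group_by(.data$klass) |>
    summarise(total = n(), rate = mean(.data$verified),
              verified = sum(.data$verified), .groups = "drop") |>
    mutate(non_verified = .data$total - .data$verified) |>
    select("klass", "total", "verified", "non_verified", "rate")
}

#' @rdname records_by_klass
#' @export
records_by_node <- function(records) {
  records |>
    filter(!.data$skipped) |>
    tidyr::pivot_longer(c("x", "y"), values_to = "node") |>
    group_by(.data$node) |>
    summarise(predicted = n(), ratio = mean(.data$verified),
              verified = sum(.data$verified), .groups = "drop") |>
    select("node", "predicted", "verified", "ratio")
}

#' @rdname records_by_klass
#' @export
records_by_dag <- function(records) {
  records |>
    filter(!.data$skipped) |>
    group_by(.data$dag_id) |>
    summarise(predicted = n(), ratio = mean(.data$verified),
              verified = sum(.data$verified), .groups = "drop") |>
    select("dag_id", "predicted", "verified", "ratio")
}

#' Dominant splice variant of a protein-coding unit
#'
#' Searches, on a DAG with at least two splices, for an isoform `s_i` such
#' that every other isoform satisfies `s_j` _|_ `p` | `s_i`, i.e.
#' `|R_{s_j p . s_i}| < theta`. The dominant candidate maximizes the number
#' of explained isoforms; ties are broken by the smaller maximum residual
#' partial correlation. `explained_fraction` is that count over `n - 1`,
#' and a unit has a single dominant isoform when the fraction is 1.
#'
#' @param dag a [pcu_dag] with one protein.
#' @param dyncorr `pcu_dyncorr` covering the unit's splices and protein.
#' @param config a [test_config()].
#' @return One-row tibble: `dag_id`, `dominant`, `n_splices`,
#'   `explained`, `explained_fraction`, `single_dominant`, `max_residual`.
#'   Units with fewer than two splices return `NA` results with
#'   `eligible = FALSE`.
#' @export
dominant_splice <- function(dag, dyncorr, config = test_config()) {
  R <- if (inherits(dyncorr, "pcu_dyncorr")) dyncorr$R else dyncorr
  s_ids <- dag$nodes$id[dag$nodes$layer == "s"]
  p_id <- dag$nodes$id[dag$nodes$layer == "p"][1]
  n <- length(s_ids)
  if (n < 2)
    return(tibble(dag_id = dag$dag_id, dominant = NA_character_,
                  n_splices = n, explained = NA_integer_,
                  explained_fraction = NA_real_, single_dominant = NA,
                  max_residual = NA_real_, eligible = FALSE))
  theta <- theta_for(1L, config)
  stats <- purrr::map(s_ids, function(si) {
    others <- setdiff(s_ids, si)
    resid <- purrr::map_dbl(others, function(sj)
      tryCatch(partial_correlation(R, sj, p_id, si, config$condition_tol),
               error = function(e) NA_real_))
    tibble(candidate = si,
           explained = sum(abs(resid) < theta, na.rm = TRUE),
           max_resid = max(abs(resid), na.rm = TRUE))
  }) |> bind_rows()
  best <- stats |>
    arrange(desc(.data$explained), .data$max_resid) |>
    slice(1)
  tibble(dag_id = dag$dag_id, dominant = best$candidate, n_splices = n,
         explained = best$explained,
         explained_fraction = best$explained / (n - 1),
         single_dominant = best$explained == n - 1,
         max_residual = best$max_resid, eligible = TRUE)
}

#' @rdname dominant_splice
#' @param dags list of [pcu_dag] objects.
#' @export
dominant_splice_all <- function(dags, dyncorr, config = test_config()) {
  purrr::map(dags, dominant_splice, dyncorr = dyncorr, config = config) |>
    bind_rows()
}

#' Null-model benchmark for condition verification
#'
#' Compares the per-node distribution of verification successes of the
#' true Markov conditions against two null models: (1) the partner `y` is
#' replaced by a node drawn uniformly from all nodes of all DAGs (same
#' conditioning set), and (2) both `y` and `C` are replaced by random
#' draws, `|C_r| = |C|`. The first null measures how much of the
#' information on `x` the tailored conditioning set captures; the second
#' the probability of a chance conditional independence. Distributions are
#' compared by two-sample t tests.
#'
#' @param conditions enumerated conditions (see
#'   [enumerate_markov_conditions()]).
#' @param dyncorr `pcu_dyncorr` over the global series collection (all
#'   nodes of all DAGs).
#' @param config a [test_config()]; `null_reps` resamples per condition,
#'   seeded by `config$seed`.
#' @param layer_matched if `TRUE`, null draws are restricted to nodes of
#'   the same layer as the node they replace.
#' @return List with `distributions` (tibble: `model`, `node`,
#'   `success_rate`), `means` (named numeric), and `tests` (tibble of
#'   pairwise t statistics and p values).
#' @export
null_model_benchmark <- function(conditions, dyncorr,
                                 config = test_config(),
                                 layer_matched = FALSE) {
  R <- if (inherits(dyncorr, "pcu_dyncorr")) dyncorr$R else dyncorr
  pool <- rownames(R)
  if (length(pool) < 5) abort("too few nodes to sample null models")
  layer_of <- function(v) sub("^.*_([asp])[0-9]*$", "\\1", v)
  pool_layer <- layer_of(pool)
  set.seed(config$seed)
  pcor_ok <- function(x, y, C) {
    tryCatch(abs(partial_correlation(R, x, y, C, config$condition_tol)),
             error = function(e) NA_real_)
  }
  rows <- purrr::pmap(
    list(conditions$x, conditions$y, conditions$C, conditions$card_C),
    function(x, y, C, card) {
      theta <- theta_for(card, config)
      true_s <- pcor_ok(x, y, C) < theta
      n1 <- logical(config$null_reps); n2 <- logical(config$null_reps)
      for (i in seq_len(config$null_reps)) {
        cand <- setdiff(pool, c(x, C))
        if (layer_matched) cand <- cand[layer_of(cand) == layer_of(y)]
        yr <- sample(cand, 1)
        n1[i] <- isTRUE(pcor_ok(x, yr, C) < theta)
        cand2 <- setdiff(pool, x)
        yr2 <- sample(cand2, 1)
        Cr <- if (card > 0) sample(setdiff(pool, c(x, yr2)), card)
              else character()
        n2[i] <- isTRUE(pcor_ok(x, yr2, Cr) < theta)
      }
      tibble(node = x,
             true_success = isTRUE(true_s),
             null1 = mean(n1), null2 = mean(n2))
    }) |> bind_rows()
  per_node <- rows |>
    group_by(.data$node) |>
    summarise(true = mean(.data$true_success), null_y = mean(.data$null1),
              null_yC = mean(.data$null2), .groups = "drop")
  distributions <- per_node |>
    tidyr::pivot_longer(c("true", "null_y", "null_yC"),
                        names_to = "model", values_to = "success_rate")
  means <- c(true = mean(per_node$true), null_y = mean(per_node$null_y),
             null_yC = mean(per_node$null_yC))
  safe_t <- function(a, b) {
    tryCatch({
      tt <- t.test(a, b)
      tibble(statistic = unname(tt$statistic), p_value = tt$p.value)
    }, error = function(e) tibble(statistic = NA_real_, p_value = NA_real_))
  }
  tests <- bind_rows(
    mutate(safe_t(per_node$true, per_node$null_y),
           comparison = "true_vs_null_y"),
    mutate(safe_t(per_node$null_y, per_node$null_yC),
           comparison = "null_y_vs_null_yC"),
    mutate(safe_t(per_node$true, per_node$null_yC),
           comparison = "true_vs_null_yC")) |>
    select("comparison", "statistic", "p_value")
  list(distributions = distributions, means = means, tests = tests)
}

#' Enrichment of verified conditions in a unit subset
#'
#' Cross-tabulates verified / non-verified conditions against membership of
#' their DAG in a unit subset (for example the T-cell or T_H_1 related gene
#' lists shipped with the package) and runs a two-sided Fisher exact test.
#'
#' @param records verification records.
#' @param subset character vector of unit (dag) ids.
#' @return List with `table` (2x2 matrix) and `p_value`.
#' @export
subset_enrichment <- function(records, subset) {
  if (length(subset) == 0) abort("subset must be nonempty")
  records <- filter(records, !.data$skipped)
  in_sub <- records$dag_id %in% subset
  tab <- table(
    factor(ifelse(records$verified, "verified", "non_verified"),
           levels = c("verified", "non_verified")),
    factor(ifelse(in_sub, "in_subset", "background"),
           levels = c("in_subset", "background")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warn("degenerate margin in enrichment table; p = 1")
    return(list(table = tab, p_value = 1))
  }
  list(table = tab, p_value = fisher.test(tab)$p.value)
}

#' Compare a numeric covariate between verified and non-verified conditions
#'
#' Two-sample t test of a per-condition covariate (for example the number
#' of putative transcription-factor binding sites of the splices involved
#' in s-s conditions) between verified and non-verified records.
#'
#' @param records verification records.
#' @param covariate numeric vector aligned with `records` rows.
#' @return Tibble with group means, t statistic and p value.
#' @export
covariate_comparison <- function(records, covariate) {
  stopifnot(length(covariate) == nrow(records))
  keep <- !records$skipped & !is.na(covariate)
  v <- covariate[keep & records$verified]
  nv <- covariate[keep & !records$verified]
  if (length(v) < 2 || length(nv) < 2)
    abort("need at least two records per group")
  tt <- t.test(v, nv)
  tibble(mean_verified = mean(v), mean_non_verified = mean(nv),
         statistic = unname(tt$statistic), p_value = tt$p.value)
}

appris_rank_levels <- c("PRINCIPAL:1", "PRINCIPAL:2", "PRINCIPAL:3",
                        "PRINCIPAL:4", "PRINCIPAL:5", "ALTERNATIVE:1",
                        "ALTERNATIVE:2", "MINOR", "NON-CODING", "ABSENT")

appris_rank <- function(label) {
  r <- match(label, appris_rank_levels)
  r[is.na(r)] <- match("ABSENT", appris_rank_levels)
  r
}

#' Agreement between dominant splices and isoform annotation ranks
#'
#' Compares the inferred dominant isoforms with an APPRIS-style annotation
#' table: the fraction of dominant splices carrying the top rank
#' (PRINCIPAL:1), the per-DAG median rank of the dominant splice versus the
#' DAG-wide median, and a Fisher exact test of top-rank hits against the
#' expectation under a uniformly random in-DAG choice. Transcripts missing
#' from the annotation count as ABSENT (lowest rank).
#'
#' @param dominants tibble from [dominant_splice_all()].
#' @param annotation tibble with columns `transcript_id`, `label` (APPRIS
#'   vocabulary: PRINCIPAL:1..5, ALTERNATIVE:1..2, MINOR, NON-CODING,
#'   ABSENT).
#' @param dags list of the corresponding [pcu_dag] objects (named by dag
#'   id), used to count the splices per unit.
#' @return List with `per_dag` tibble, `top_rank_fraction`,
#'   `random_baseline`, and `p_value`.
#' @export
annotation_agreement <- function(dominants, annotation, dags) {
  if (nrow(annotation) == 0)
    warn("empty annotation table: all transcripts ranked ABSENT")
  rank_of <- function(tx) {
    lab <- annotation$label[match(tx, annotation$transcript_id)]
    lab[is.na(lab)] <- "ABSENT"
    appris_rank(lab)
  }
  elig <- filter(dominants, .data$eligible)
  if (nrow(elig) == 0) abort("no eligible units")
  per_dag <- elig |>
    mutate(
      dominant_rank = rank_of(.data$dominant),
      dag_splices = purrr::map(.data$dag_id, function(u) {
        d <- dags[[u]]; d$nodes$id[d$nodes$layer == "s"]
      }),
      median_rank = purrr::map_dbl(.data$dag_splices,
                                   ~ median(rank_of(.x))),
      n_top_in_dag = purrr::map_int(.data$dag_splices,
                                    ~ sum(rank_of(.x) == 1L)),
      dominant_is_top = .data$dominant_rank == 1L) |>
    select(-"dag_splices")
  frac <- mean(per_dag$dominant_is_top)
  baseline <- mean(per_dag$n_top_in_dag / per_dag$n_splices)
  expected_hits <- round(baseline * nrow(per_dag))
  tab <- matrix(c(sum(per_dag$dominant_is_top),
                  nrow(per_dag) - sum(per_dag$dominant_is_top),
                  expected_hits, nrow(per_dag) - expected_hits), 2)
  p <- tryCatch(fisher.test(tab)$p.value, error = function(e) NA_real_)
  list(per_dag = per_dag, top_rank_fraction = frac,
       random_baseline = baseline, p_value = p)
}

#' Packaged differentiation gene lists
#'
#' Returns the gene lists distributed with the package: `"th1"` for genes
#' annotated to T-helper-1 differentiation and its regulation, `"tcell"`
#' for the broader T-cell differentiation/activation list that contains it.
#'
#' @param which `"th1"` or `"tcell"`.
#' @return Character vector of gene symbols.
#' @export
gene_list <- function(which = c("th1", "tcell")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   paste0(which, "_genes.txt"), package = "pcunet")
  readLines(f)
}
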