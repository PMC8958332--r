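test_that("the Fisher z threshold matches its closed form", {
  expect_equal(fisher_threshold(147, 0, 0.05), 0.1619, tolerance = 1e-3)
  expect_equal(fisher_threshold(147, 1, 0.05),
               tanh(qnorm(0.975) / sqrt(143)), tolerance = 1e-12)
  # alpha -> 1 drives theta to zero
  expect_lt(fisher_threshold(147, 0, 0.999), 1e-3)
  expect_error(fisher_threshold(4, 1, 0.05), "degrees of freedom")
  # the two formulations of the test agree exactly
  N <- 147
  for (card in 0:3) {
    theta <- fisher_threshold(N, card, 0.05)
    r <- seq(-0.9, 0.9, by = 0.05)
    lhs <- abs(r) < theta
    rhs <- sqrt(N - card - 3) * abs(atanh(r)) < qnorm(0.975)
    expect_equal(lhs, rhs)
  }
})

test_that("partial correlation reproduces the triangle formula", {
  R <- matrix(c(1, 0.5, 0.6,
                0.5, 1, 0.6,
                0.6, 0.6, 1), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  expect_equal(partial_correlation(R, "x", "y", "z"),
               (0.5 - 0.36) / (sqrt(1 - 0.36) * sqrt(1 - 0.36)))
  expect_equal(partial_correlation(R, "x", "y", "z"), 0.21875)
  # empty conditioning set returns the marginal
  expect_equal(partial_correlation(R, "x", "y"), 0.5)
  # equicorrelated triangle contracts 0.5 to 1/3
  Re <- matrix(0.5, 3, 3, dimnames = dimnames(R)); diag(Re) <- 1
  expect_equal(partial_correlation(Re, "x", "y", "z"), 1 / 3)
  expect_error(partial_correlation(R, "x", "q"), "not in R")
})

test_that("matrix inversion agrees with Schur and regression oracles", {
  set.seed(21)
  # triangle formula on all random 3-node instances
  for (i in 1:50) {
    S <- ora_sem_sigma(ora_random_dag(3, 0.7), c("n1", "n2", "n3"))
    R <- stats::cov2cor(S)
    tri <- (R[1, 2] - R[1, 3] * R[2, 3]) /
      (sqrt(1 - R[1, 3]^2) * sqrt(1 - R[2, 3]^2))
    expect_equal(partial_correlation(R, "n1", "n2", "n3"), tri,
                 tolerance = 1e-12)
  }
  # Schur-complement and residual oracles on random 6-node instances
  for (i in 1:25) {
    nodes <- sprintf("n%d", 1:6)
    S <- ora_sem_sigma(ora_random_dag(6, 0.5), nodes)
    R <- stats::cov2cor(S)
    C <- sample(nodes[3:6], sample(1:3, 1))
    expect_equal(partial_correlation(R, "n1", "n2", C),
                 ora_pcor_schur(R, "n1", "n2", C), tolerance = 1e-8)
  }
  # residuals of sample data give the sample partial correlation
  set.seed(22)
  X <- matrix(rnorm(50 * 4), 50, 4,
              dimnames = list(NULL, c("x", "y", "z1", "z2")))
  X[, "y"] <- X[, "y"] + 0.8 * X[, "z1"]
  X[, "x"] <- X[, "x"] + 0.5 * X[, "z1"] - 0.3 * X[, "z2"]
  Rs <- stats::cor(X)
  res_x <- stats::resid(stats::lm(x ~ z1 + z2, data = as.data.frame(X)))
  res_y <- stats::resid(stats::lm(y ~ z1 + z2, data = as.data.frame(X)))
  expect_equal(partial_correlation(Rs, "x", "y", c("z1", "z2")),
               stats::cor(res_x, res_y), tolerance = 1e-8)
})

test_that("verification respects the threshold and is monotone in theta", {
  d <- pcu_example_dag()
  mc <- enumerate_markov_conditions(d)
  st <- ora_default_study()
  R <- st$dyncorr$R[1:6, 1:6]
  dimnames(R) <- list(d$nodes$id, d$nodes$id)
  rec_small <- verify_conditions(mc, R, test_config(theta = 0.2))
  rec_large <- verify_conditions(mc, R, test_config(theta = 0.7))
  expect_true(all(rec_small$verified <= rec_large$verified))
  # record fields are internally consistent
  expect_equal(rec_small$verified,
               abs(rec_small$r_xy_C) < rec_small$theta)
  expect_equal(rec_small$contraction,
               abs(rec_small$r_xy_C) <= abs(rec_small$r_xy))
  # Fisher mode: theta depends on card through the degrees of freedom
  rec_f <- verify_conditions(mc, R, test_config(N = 147))
  expect_equal(rec_f$theta,
               fisher_threshold(147, rec_f$card_C, 0.05))
  rec_g <- verify_conditions(mc, R, test_config(N = 147, per_card = FALSE))
  expect_equal(unique(rec_g$theta), fisher_threshold(147, 0, 0.05))
})

test_that("aggregation identities hold", {
  st <- ora_default_study()
  conds <- enumerate_markov_conditions_all(st$truth$dags)
  rec <- verify_conditions(conds, st$dyncorr, test_config(theta = 0.6))
  bk <- records_by_klass(rec)
  expect_equal(bk$verified + bk$non_verified, bk$total)
  expect_equal(sum(bk$total), sum(!rec$skipped))
  bd <- records_by_dag(rec)
  expect_equal(sum(bd$verified), sum(bk$verified))
  bn <- records_by_node(rec)
  expect_equal(sum(bn$predicted), 2 * sum(bk$total))
})

test_that("dominant splice detection finds the driving isoform", {
  # s1 drives p; s2 is a noisy copy of s1
  set.seed(23)
  grid <- c(0, 0.5, 1, 2, 6, 24)
  M <- 3
  a1 <- matrix(rnorm(M * 6), M)
  s1 <- a1 + 0.1 * matrix(rnorm(M * 6), M)
  s2 <- s1 + 0.4 * matrix(rnorm(M * 6), M)
  p <- s1 + 0.05 * matrix(rnorm(M * 6), M)
  df <- ora_series_tbl(list(a1 = a1, s1 = s1, s2 = s2, p = p), grid)
  dc <- dynamical_correlation(df)
  d <- pcu_dag(
    nodes = tibble::tibble(id = c("a1", "s1", "s2", "p"),
                           layer = c("a", "s", "s", "p"), unit_id = "u"),
    edges = tibble::tibble(from = c("a1", "a1", "s1", "s2"),
                           to = c("s1", "s2", "p", "p")))
  res <- dominant_splice(d, dc, test_config(theta = 0.6))
  expect_true(res$eligible)
  expect_equal(res$dominant, "s1")
  expect_equal(res$explained_fraction, 1)
  expect_true(res$single_dominant)
  # a single-splice unit is flagged ineligible
  res1 <- dominant_splice(pcu_chain_dag(), dc, test_config(theta = 0.6))
  expect_false(res1$eligible)
  # n = 2 tie: both explain the other; smaller residual wins
  res2 <- dominant_splice(d, dc, test_config(theta = 0.99))
  r_s2p_s1 <- abs(partial_correlation(dc$R, "s2", "p", "s1"))
  r_s1p_s2 <- abs(partial_correlation(dc$R, "s1", "p", "s2"))
  expect_equal(res2$dominant,
               if (r_s2p_s1 <= r_s1p_s2) "s1" else "s2")
})

test_that("independently driving splices are not fully explained", {
  set.seed(24)
  grid <- c(0, 0.5, 1, 2, 6, 24)
  M <- 3
  s1 <- matrix(rnorm(M * 6), M)
  s2 <- matrix(rnorm(M * 6), M)
  p <- s1 + s2 + 0.05 * matrix(rnorm(M * 6), M)
  a1 <- s1 + 0.1 * matrix(rnorm(M * 6), M)
  df <- ora_series_tbl(list(a1 = a1, s1 = s1, s2 = s2, p = p), grid)
  dc <- dynamical_correlation(df)
  d <- pcu_dag(
    nodes = tibble::tibble(id = c("a1", "s1", "s2", "p"),
                           layer = c("a", "s", "s", "p"), unit_id = "u"),
    edges = tibble::tibble(from = c("a1", "a1", "s1", "s2"),
                           to = c("s1", "s2", "p", "p")))
  res <- dominant_splice(d, dc, test_config(theta = 0.5))
  expect_equal(res$explained_fraction, 0)
})

test_that("subset enrichment reduces to the hypergeometric closed form", {
  rec <- tibble::tibble(
    dag_id = rep(c("in1", "out1"), each = 10),
    verified = rep(c(TRUE, FALSE), each = 10),
    skipped = FALSE)
  out <- subset_enrichment(rec, "in1")
  expect_equal(out$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  # equal proportions give p = 1
  rec2 <- tibble::tibble(
    dag_id = rep(c("in1", "out1"), 10),
    verified = rep(c(TRUE, FALSE), each = 10),
    skipped = FALSE)
  expect_equal(subset_enrichment(rec2, "in1")$p_value, 1)
  # degenerate margins warn and return 1
  rec3 <- tibble::tibble(dag_id = "in1", verified = TRUE, skipped = FALSE)
  expect_warning(out3 <- subset_enrichment(rec3, "in1"), "margin")
  expect_equal(out3$p_value, 1)
  expect_error(subset_enrichment(rec, character()), "nonempty")
})

test_that("random subset labels give calibrated enrichment p values", {
  st <- ora_default_study()
  conds <- enumerate_markov_conditions_all(st$truth$dags)
  rec <- verify_conditions(conds, st$dyncorr, test_config(theta = 0.6))
  set.seed(31)
  ps <- purrr::map_dbl(1:40, function(i) {
    subset <- sample(names(st$truth$dags), 5)
    subset_enrichment(rec, subset)$p_value
  })
  # conservative calibration check: not systematically small
  expect_gt(mean(ps > 0.05), 0.75)
})

test_that("covariate comparison runs a two-sample t test", {
  rec <- tibble::tibble(verified = rep(c(TRUE, FALSE), each = 20),
                        skipped = FALSE)
  cov <- c(rnorm(20, 5), rnorm(20, 0))
  out <- covariate_comparison(rec, cov)
  expect_lt(out$p_value, 1e-4)
  expect_gt(out$mean_verified, out$mean_non_verified)
})

test_that("null models preserve conditioning-set cardinality", {
  st <- ora_default_study()
  conds <- enumerate_markov_conditions_all(st$truth$dags)
  # spy on the partial correlation calls through a tiny pool check:
  # run the benchmark and confirm it returns one row per condition node
  nm <- null_model_benchmark(conds[1:20, ], st$dyncorr,
                             test_config(theta = 0.6, null_reps = 5,
                                         seed = 2))
  expect_setequal(unique(nm$distributions$model),
                  c("true", "null_y", "null_yC"))
  expect_equal(nrow(nm$tests), 3)
  expect_true(all(nm$distributions$success_rate >= 0 &
                  nm$distributions$success_rate <= 1))
})

test_that("annotation agreement recovers top-ranked drivers", {
  st <- ora_default_study()
  doms <- dominant_splice_all(st$truth$dags, st$dyncorr,
                              test_config(theta = 0.6))
  ann <- tibble::tibble(
    transcript_id = unlist(purrr::map(st$truth$dags,
                                      ~ .x$nodes$id[.x$nodes$layer == "s"])),
    label = "MINOR")
  # mark each unit's dominant (when present) as PRINCIPAL:1
  ann$label[ann$transcript_id %in% stats::na.omit(doms$dominant)] <-
    "PRINCIPAL:1"
  out <- annotation_agreement(doms, ann, st$truth$dags)
  expect_equal(out$top_rank_fraction, 1)
  expect_lt(out$random_baseline, 1)
  # all splices identically ranked: agreement equals the random baseline
  ann2 <- dplyr::mutate(ann, label = "PRINCIPAL:1")
  out2 <- annotation_agreement(doms, ann2, st$truth$dags)
  expect_equal(out2$top_rank_fraction, out2$random_baseline)
  # an empty annotation degenerates to ABSENT ranks with a warning
  expect_warning(
    out3 <- annotation_agreement(doms, ann[0, ], st$truth$dags),
    "empty")
  expect_equal(out3$top_rank_fraction, 0)
})

test_that("packaged gene lists load and nest correctly", {
  th1 <- gene_list("th1")
  tc <- gene_list("tcell")
  expect_length(th1, 34)
  expect_length(tc, 148)
  expect_true(all(th1 %in% tc))
  expect_true("TBX21" %in% th1)
})
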