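signed_triangle <- function(s12, s13, s23) {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- s12 * 0.5
  R[1, 3] <- R[3, 1] <- s13 * 0.5
  R[2, 3] <- R[3, 2] <- s23 * 0.5
  rownames(R) <- colnames(R) <- c("x", "y", "z")
  R
}

test_that("triangles follow the classic balance rules", {
  # the enemy of my enemy is my friend: (+, -, -) is balanced
  b <- is_balanced(signed_triangle(1, -1, -1))
  expect_true(b$balanced)
  expect_equal(unname(b$gauge[1] * b$gauge[2]), 1)
  # one negative edge is unbalanced
  u <- is_balanced(signed_triangle(1, 1, -1))
  expect_false(u$balanced)
  expect_gte(length(u$conflict_cycle), 3)
  # two-node graphs have no cycles
  R2 <- matrix(c(1, -0.4, -0.4, 1), 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  expect_true(is_balanced(R2)$balanced)
  expect_true(is_inverse_balanced(R2)$balanced)
})

test_that("gauge propagation agrees with the exhaustive cycle oracle", {
  set.seed(41)
  for (i in 1:120) {
    n <- sample(3:7, 1)
    A <- ora_random_signed(n, p_edge = runif(1, 0.3, 0.9))
    got <- is_balanced(A)
    want <- ora_all_cycles_balanced(sign(A) * (abs(A) >= 1e-8) -
                                      diag(n))
    expect_equal(got$balanced, want)
    if (got$balanced) {
      # gauge witness: D A D has nonnegative present off-diagonals
      D <- diag(got$gauge)
      G <- D %*% A %*% D
      off <- G[upper.tri(G)]
      expect_true(all(off >= -1e-12 | abs(off) < 1e-8))
    } else {
      # the reported conflict cycle has negative sign product
      cyc <- got$conflict_cycle
      prod <- 1
      for (k in seq_along(cyc)) {
        a <- cyc[k]; b <- cyc[(k %% length(cyc)) + 1]
        prod <- prod * sign(A[a, b])
      }
      expect_equal(prod, -1)
    }
  }
})

test_that("inverse balance works the concentration graph", {
  # equicorrelated rho = 0.5: K off-diagonals all negative -> M-matrix
  Re <- matrix(0.5, 3, 3); diag(Re) <- 1
  rownames(Re) <- colnames(Re) <- c("x", "y", "z")
  cg <- concentration_graph(Re)
  expect_true(all(cg$K[upper.tri(cg$K)] < 0))
  expect_true(is_inverse_balanced(Re)$balanced)
  expect_equal(unname(diag(cg$P)), rep(1, 3))
  expect_equal(cg$P[1, 2],
               -cg$K[1, 2] / sqrt(cg$K[1, 1] * cg$K[2, 2]))
  expect_error(concentration_graph(matrix(c(1, 1, 1, 1), 2)),
               "positive definite")
})

test_that("inverse balance implies balance, never forced conversely", {
  set.seed(42)
  n_inv <- 0
  n_bal_not_inv <- 0
  for (i in 1:300) {
    n <- sample(3:6, 1)
    S <- ora_sem_sigma(ora_random_dag(n, 0.6), sprintf("n%d", 1:n))
    R <- stats::cov2cor(S)
    b <- is_balanced(R)$balanced
    ib <- is_inverse_balanced(R)$balanced
    if (ib) {
      n_inv <- n_inv + 1
      expect_true(b)
    }
    if (b && !ib) n_bal_not_inv <- n_bal_not_inv + 1
  }
  expect_gt(n_inv, 0)
  expect_gt(n_bal_not_inv, 0)
})

test_that("signed-MTP2 matrices are inverse balanced and contract", {
  set.seed(43)
  n_checked <- 0
  for (i in 1:1000) {
    n <- sample(3:6, 1)
    R <- random_mtp2_correlation(n)
    nodes <- rownames(R)
    pair <- sample(nodes, 2)
    C <- setdiff(nodes, pair)
    C <- if (length(C) > 0) sample(C, sample(1:length(C), 1)) else
      character()
    r0 <- R[pair[1], pair[2]]
    rC <- partial_correlation(R, pair[1], pair[2], C)
    expect_lte(abs(rC), abs(r0) + 1e-10)
    n_checked <- n_checked + 1
    if (i <= 50)
      expect_true(is_inverse_balanced(R)$balanced)
  }
  expect_equal(n_checked, 1000)
})

test_that("covariance contraction holds exactly under signed MTP2", {
  set.seed(44)
  for (i in 1:200) {
    R <- random_mtp2_correlation(sample(3:6, 1))
    S <- R * 4   # any positive scaling of a covariance
    nodes <- rownames(R)
    pair <- sample(nodes, 2)
    C <- sample(setdiff(nodes, pair), 1)
    xy <- c(pair, C)
    Sc <- S[pair, pair] - S[pair, C, drop = FALSE] %*%
      solve(S[C, C, drop = FALSE], S[C, pair, drop = FALSE])
    expect_lte(abs(Sc[1, 2]), abs(S[pair[1], pair[2]]) + 1e-10)
  }
})

test_that("unbalanced triangles can expand upon conditioning", {
  R <- matrix(c(1, 0.1, 0.6,
                0.1, 1, -0.6,
                0.6, -0.6, 1), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  expect_false(is_balanced(R)$balanced)
  rC <- partial_correlation(R, "x", "y", "z")
  expect_gt(abs(rC), abs(R["x", "y"]))
})

test_that("motif classification labels records and stratifies contraction", {
  st <- ora_default_study()
  conds <- enumerate_markov_conditions_all(st$truth$dags)
  rec <- verify_conditions(conds, st$dyncorr, test_config(theta = 0.6))
  lab <- classify_condition_motifs(rec, st$dyncorr)
  expect_true(all(c("balanced", "inverse_balanced") %in% names(lab)))
  # empty conditioning sets are balanced by convention
  expect_true(all(lab$balanced[lab$card_C == 0]))
  expect_true(all(lab$inverse_balanced[lab$card_C == 0], na.rm = TRUE))
  # implication chain on real records
  ok <- !is.na(lab$inverse_balanced)
  expect_true(all(!lab$inverse_balanced[ok] | lab$balanced[ok]))
  cs <- contraction_stats(lab)
  expect_setequal(cs$stratum, c("all", "balanced", "unbalanced",
                                "inverse_balanced", "inverse_unbalanced"))
  inv <- cs$contraction_fraction[cs$stratum == "inverse_balanced"]
  if (cs$n[cs$stratum == "inverse_balanced"] > 0)
    expect_equal(inv, 1)
  tab <- balance_table(lab)
  expect_equal(sum(tab), sum(!lab$skipped))
})

test_that("the threshold sweep reproduces classification limits", {
  set.seed(45)
  # perfectly separated scores give AUC 1
  rec <- tibble::tibble(
    r_xy_C = c(runif(50, 0, 0.2), runif(50, 0.6, 1)) *
      sample(c(-1, 1), 100, TRUE),
    balanced = rep(c(TRUE, FALSE), each = 50),
    skipped = FALSE)
  roc <- threshold_roc(rec)
  expect_equal(roc$auc_roc, 1, tolerance = 2e-3)
  # labels independent of score give AUC about one half
  rec2 <- tibble::tibble(
    r_xy_C = runif(10000, -1, 1),
    balanced = sample(c(TRUE, FALSE), 10000, TRUE),
    skipped = FALSE)
  roc2 <- threshold_roc(rec2)
  expect_equal(roc2$auc_roc, 0.5, tolerance = 0.05)
  # single-class truth is an error
  rec3 <- dplyr::mutate(rec, balanced = TRUE)
  expect_error(threshold_roc(rec3), "single-class")
})

test_that("ROC AUC equals the rank-sum concordance statistic", {
  set.seed(46)
  rec <- tibble::tibble(
    r_xy_C = rbeta(500, 1.2, 2) * sample(c(-1, 1), 500, TRUE),
    balanced = runif(500) < 0.5 - 0.3 * abs(rbeta(500, 1.2, 2)),
    skipped = FALSE)
  rec$balanced[1:2] <- c(TRUE, FALSE)   # both classes present
  roc <- threshold_roc(rec, n_grid = 4001)
  s <- abs(rec$r_xy_C)
  pos <- s[rec$balanced]; neg <- s[!rec$balanced]
  conc <- mean(outer(pos, neg, "<") + 0.5 * outer(pos, neg, "=="))
  expect_equal(roc$auc_roc, conc, tolerance = 0.01)
  # and matches the Wilcoxon rank-sum route
  w <- stats::wilcox.test(neg, pos)$statistic / (length(pos) *
                                                   length(neg))
  expect_equal(conc, unname(w), tolerance = 1e-10)
})
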