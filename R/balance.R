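#' Structural balance of a signed correlation graph
#'
#' A signed graph is balanced (frustration-free) when every cycle carries
#' an even number of negative edges; equivalently, when a signature vector
#' `d` in `{-1, +1}^n` exists with `sign(R_ij) = d_i d_j` on every present
#' edge (a gauge rendering all edges positive). The test propagates spins
#' by breadth-first traversal per connected component and reports either
#' the gauge or a violating cycle (the path between the conflicting pair
#' in the traversal tree, closed by the conflicting edge).
#'
#' Entries with `|R_ij|` below `zero_tol` are treated as absent edges:
#' sample correlations are essentially never exactly zero, so the cutoff
#' only guards degenerate cases.
#'
#' @param R symmetric matrix of signed weights (typically a correlation
#'   submatrix, unit diagonal).
#' @param zero_tol absolute threshold below which an entry is no edge.
#' @return List with `balanced` (logical), `gauge` (named +/-1 vector if
#'   balanced, otherwise `NULL`) and `conflict_cycle` (vector of node
#'   names, `NULL` if balanced).
#' @export
is_balanced <- function(R, zero_tol = 1e-8) {
  R <- as.matrix(R)
  if (!isTRUE(all.equal(R, t(R), tolerance = 1e-8,
                        check.attributes = FALSE)))
    abort("R must be symmetric")
  n <- nrow(R)
  nm <- rownames(R) %||% as.character(seq_len(n))
  sgn <- sign(R) * (abs(R) >= zero_tol)
  diag(sgn) <- 0
  d <- rep(NA_integer_, n)
  parent <- rep(NA_integer_, n)
  for (start in seq_len(n)) {
    if (!is.na(d[start])) next
    d[start] <- 1L
    queue <- start
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (u in which(sgn[v, ] != 0)) {
        want <- d[v] * sgn[v, u]
        if (is.na(d[u])) {
          d[u] <- want
          parent[u] <- v
          queue <- c(queue, u)
        } else if (d[u] != want) {
          # conflict: close the cycle through the BFS tree
          path_to_root <- function(i) {
            p <- i
            while (!is.na(parent[i])) { i <- parent[i]; p <- c(p, i) }
            p
          }
          pv <- path_to_root(v); pu <- path_to_root(u)
          common <- intersect(pv, pu)[1]
          cyc <- c(rev(pu[seq_len(match(common, pu))]),
                   pv[seq_len(match(common, pv) - 1)])
          return(list(balanced = FALSE, gauge = NULL,
                      conflict_cycle = nm[cyc]))
        }
      }
    }
  }
  list(balanced = TRUE, gauge = setNames(d, nm), conflict_cycle = NULL)
}

#' Concentration graph and inverse balance (signed MTP2)
#'
#' `concentration_graph()` inverts a positive-definite correlation matrix
#' `R` into `K = R^-1`, normalizes `H_ij = K_ij / sqrt(K_ii K_jj)` and
#' forms the partial correlation matrix `P = 2I - H` (unit diagonal,
#' `P_ij = -K_ij / sqrt(K_ii K_jj)`). A variable set is inverse balanced
#' when the signed graph of `P` is balanced -- equivalently, when some
#' signature matrix `D` makes `DKD` an M-matrix (all off-diagonal entries
#' non-positive), the signed analogue of multivariate total positivity of
#' order 2. Inverse balance implies balance of `G(R)`, never conversely.
#'
#' @param R positive-definite correlation matrix with dimnames.
#' @param zero_tol edge-presence threshold, as in [is_balanced()].
#' @return `concentration_graph()`: list with `K`, `H`, `P`.
#'   `is_inverse_balanced()`: as [is_balanced()], applied to `G(P)`.
#' @export
concentration_graph <- function(R) {
  R <- as.matrix(R)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) abort("R must be positive definite")
  K <- solve(R)
  s <- 1 / sqrt(diag(K))
  H <- K * tcrossprod(s)
  P <- 2 * diag(nrow(R)) - H
  dimnames(K) <- dimnames(H) <- dimnames(P) <- dimnames(R)
  list(K = K, H = H, P = P)
}

#' @rdname concentration_graph
#' @export
is_inverse_balanced <- function(R, zero_tol = 1e-8) {
  cg <- concentration_graph(R)
  is_balanced(cg$P, zero_tol = zero_tol)
}

#' Label verification records with balance and inverse balance
#'
#' For each condition, the complete signed subgraph of the sample
#' correlation graph on `{x, y} union C` (including the x-y edge itself)
#' is classified as balanced or unbalanced, and the concentration graph on
#' the same variable set as inverse balanced or not. Conditions with an
#' empty conditioning set have two-node motifs without cycles and are
#' balanced by convention.
#'
#' @param records tibble from [verify_conditions()].
#' @param dyncorr `pcu_dyncorr` (or correlation matrix) covering the
#'   variables.
#' @param zero_tol edge-presence threshold.
#' @return `records` with added logical columns `balanced` and
#'   `inverse_balanced`.
#' @export
classify_condition_motifs <- function(records, dyncorr, zero_tol = 1e-8) {
  R <- if (inherits(dyncorr, "pcu_dyncorr")) dyncorr$R else dyncorr
  lab <- purrr::pmap(
    list(records$x, records$y, records$C),
    function(x, y, C) {
      vars <- c(x, y, C)
      S <- R[vars, vars, drop = FALSE]
      b <- is_balanced(S, zero_tol)$balanced
      ib <- tryCatch(is_inverse_balanced(S, zero_tol)$balanced,
                     error = function(e) NA)
      tibble(balanced = b, inverse_balanced = ib)
    }) |> bind_rows()
  bind_cols(records, lab)
}

#' Contraction of correlations upon conditioning
#'
#' Conditioning on a balanced motif typically shrinks the correlation,
#' `|R_xy.C| <= |R_xy|`; under inverse balance (signed MTP2) the
#' contraction holds systematically. Summarizes the fraction of records
#' obeying the contraction, stratified by the balance and inverse-balance
#' labels.
#'
#' @param records records labelled by [classify_condition_motifs()].
#' @return Tibble with one row per stratum: `stratum`, `n`,
#'   `contraction_fraction`.
#' @export
contraction_stats <- function(records) {
  records <- filter(records, !.data$skipped)
  strat <- function(keep, name) {
    r <- records[keep & !is.na(keep), ]
    tibble(stratum = name, n = nrow(r),
           contraction_fraction = if (nrow(r) > 0)
             mean(r$contraction) else NA_real_)
  }
  bind_rows(
    strat(rep(TRUE, nrow(records)), "all"),
    strat(records$balanced, "balanced"),
    strat(!records$balanced, "unbalanced"),
    strat(records$inverse_balanced, "inverse_balanced"),
    strat(!records$inverse_balanced, "inverse_unbalanced"))
}

#' Cross-tabulation of verification against balance
#'
#' @param records labelled records.
#' @param label `"balanced"` or `"inverse_balanced"`.
#' @return 2x2 table of verified/non-verified by balanced/unbalanced.
#' @export
balance_table <- function(records, label = c("balanced",
                                             "inverse_balanced")) {
  label <- match.arg(label)
  records <- filter(records, !.data$skipped, !is.na(.data[[label]]))
  table(
    factor(ifelse(records$verified, "verified", "non_verified"),
           levels = c("verified", "non_verified")),
    factor(ifelse(records[[label]], label, paste0("un", label)),
           levels = c(label, paste0("un", label))))
}

#' ROC and precision-recall sweep of the verification threshold
#'
#' Takes balance (or inverse balance) of the motif as the ground truth and
#' "verified at threshold theta" (`|R_xy.C| < theta`) as the prediction,
#' sweeping theta over a uniform grid on `[0, 1]`: TP = balanced and
#' verified, FP = unbalanced and verified, FN = balanced and non-verified,
#' TN = unbalanced and non-verified. Returns the ROC curve (FPR, TPR), the
#' precision-recall curve, and trapezoid AUCs.
#'
#' @param records labelled records.
#' @param truth_label `"balanced"` or `"inverse_balanced"`.
#' @param n_grid number of thresholds (default 1001).
#' @return Object of class `pcu_roc`: list with `curve` (tibble: `theta`,
#'   `tpr`, `fpr`, `precision`, `recall`), `auc_roc`, `auc_pr`,
#'   `truth_label`.
#' @export
threshold_roc <- function(records, truth_label = c("balanced",
                                                   "inverse_balanced"),
                          n_grid = 1001) {
  truth_label <- match.arg(truth_label)
  records <- filter(records, !.data$skipped, !is.na(.data[[truth_label]]))
  truth <- records[[truth_label]]
  if (length(unique(truth)) < 2)
    abort("single-class truth: AUC undefined")
  score <- abs(records$r_xy_C)
  thetas <- seq(0, 1, length.out = n_grid)
  P <- sum(truth); Ntv <- sum(!truth)
  curve <- purrr::map(thetas, function(th) {
    pred <- score < th
    tp <- sum(pred & truth); fp <- sum(pred & !truth)
    tibble(theta = th, tpr = tp / P, fpr = fp / Ntv,
           precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
           recall = tp / P)
  }) |> bind_rows()
  trap <- function(x, y) {
    keep <- !is.na(x) & !is.na(y)
    x <- x[keep]; y <- y[keep]
    o <- order(x)
    sum(diff(x[o]) * (head(y[o], -1) + tail(y[o], -1)) / 2)
  }
  structure(
    list(curve = curve,
         auc_roc = trap(curve$fpr, curve$tpr),
         auc_pr = trap(curve$recall, curve$precision),
         truth_label = truth_label),
    class = "pcu_roc")
}

#' @export
print.pcu_roc <- function(x, ...) {
  cat(sprintf("<pcu_roc> truth = %s | ROC AUC %.3f, PR AUC %.3f\n",
              x$truth_label, x$auc_roc, x$auc_pr))
  invisible(x)
}

#' @describeIn threshold_roc the sweep curve as a tibble.
#' @param x a `pcu_roc`.
#' @param ... unused.
#' @method tidy pcu_roc
#' @export
tidy.pcu_roc <- function(x, ...) x$curve

#' @describeIn threshold_roc one-row AUC summary.
#' @method glance pcu_roc
#' @export
glance.pcu_roc <- function(x, ...) {
  tibble(truth_label = x$truth_label, auc_roc = x$auc_roc,
         auc_pr = x$auc_pr)
}

#' Random inverse-balanced (signed MTP2) correlation matrices
#'
#' Generates a gauged M-matrix `K` (diagonally dominant, off-diagonal
#' signs set by a random signature vector) and returns the implied
#' correlation matrix. By construction the result is inverse balanced,
#' hence balanced; used to exercise the systematic contraction law.
#'
#' @param n number of variables.
#' @param density probability an off-diagonal entry of K is nonzero.
#' @return Correlation matrix with dimnames `v1..vn`.
#' @export
random_mtp2_correlation <- function(n, density = 0.8) {
  B <- matrix(0, n, n)
  up <- upper.tri(B)
  vals <- runif(sum(up), 0.1, 1) * (runif(sum(up)) < density)
  B[up] <- vals
  B <- B + t(B)
  K <- -B
  diag(K) <- rowSums(B) + runif(n, 0.1, 0.5)
  d <- sample(c(-1, 1), n, replace = TRUE)
  K <- K * tcrossprod(d)
  S <- solve(K)
  R <- stats::cov2cor(S)
  dimnames(R) <- list(paste0("v", seq_len(n)), paste0("v", seq_len(n)))
  R
}
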