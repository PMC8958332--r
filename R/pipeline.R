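#' Schema-checked TSV input and output
#'
#' Round-trip-stable readers and writers for the package's flat tables.
#' `read_table_checked()` validates a column-type schema and reports the
#' offending column and row on failure; unknown extra columns are kept
#' with a warning.
#'
#' @param path file path.
#' @param schema named character vector mapping required column names to
#'   `"character"`, `"numeric"`, `"integer"` or `"logical"`.
#' @return A tibble.
#' @export
read_table_checked <- function(path, schema) {
  if (!file.exists(path)) abort(sprintf("input not found: %s", path))
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  miss <- setdiff(names(schema), names(df))
  if (length(miss) > 0)
    abort(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  extra <- setdiff(names(df), names(schema))
  if (length(extra) > 0)
    warn(paste0("unknown column(s) preserved: ",
                paste(extra, collapse = ", ")))
  for (col in names(schema)) {
    type <- schema[[col]]
    if (type == "character") next
    raw <- df[[col]]
    conv <- switch(type,
      numeric = suppressWarnings(as.numeric(raw)),
      integer = suppressWarnings(as.integer(raw)),
      logical = as.logical(raw))
    bad <- which(!is.na(raw) & is.na(conv))
    if (length(bad) > 0)
      abort(sprintf("column '%s', row %d: cannot parse '%s' as %s",
                    col, bad[1], raw[bad[1]], type))
    df[[col]] <- conv
  }
  df
}

series_schema <- c(variable = "character", replicate = "character",
                   time_h = "numeric", value = "numeric")

#' @rdname read_table_checked
#' @param series long-format series tibble.
#' @export
write_series_tsv <- function(series, path) {
  readr::write_tsv(series, path)
  invisible(path)
}

#' @rdname read_table_checked
#' @export
read_series_tsv <- function(path) read_table_checked(path, series_schema)

#' @rdname read_table_checked
#' @param records verification records (list-column `C` is pipe-joined on
#'   disk).
#' @export
write_records_tsv <- function(records, path) {
  readr::write_tsv(conditions_flat(records), path)
  invisible(path)
}

#' @rdname read_table_checked
#' @export
read_records_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  conditions_unflat(df)
}

#' @rdname read_table_checked
#' @param m square matrix with dimnames (correlation or covariance).
#' @export
write_matrix_tsv <- function(m, path) {
  df <- as_tibble(m, rownames = "id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname read_table_checked
#' @export
read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$id
  m
}

#' Pipeline configuration
#'
#' Exactly one input mode must be active: `sim` (a [simulation_config()];
#' the study is generated) or `series` plus `dags` (observed long-format
#' series and pre-built DAGs).
#'
#' @param sim optional [simulation_config()].
#' @param series optional long-format series tibble or TSV path.
#' @param dags optional named list of [pcu_dag] objects.
#' @param test a [test_config()].
#' @param stages character subset of
#'   `c("balance", "dominant", "nullmodel", "roc")`.
#' @param merge_shared_peaks merge units sharing peaks into joint DAGs.
#' @param complex_pairs optional tibble (`p1`, `p2`) of complex couplings.
#' @param subset optional character vector of unit ids for enrichment.
#' @param interpolation_step,interpolation_span grid for
#'   [interpolate_to_grid()].
#' @param out_dir optional output directory for TSV reports.
#' @param seed integer seed for any stage randomness.
#' @return List of class `pcu_pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, series = NULL, dags = NULL,
                            test = test_config(),
                            stages = c("balance", "dominant"),
                            merge_shared_peaks = FALSE,
                            complex_pairs = NULL,
                            subset = NULL,
                            interpolation_step = 0.5,
                            interpolation_span = c(0, 24),
                            out_dir = NULL, seed = 1) {
  simulate_mode <- !is.null(sim)
  if (simulate_mode == (!is.null(series) && !is.null(dags)))
    abort("exactly one of simulate mode (sim) or table mode (series + dags) must be active")
  bad <- setdiff(stages, c("balance", "dominant", "nullmodel", "roc"))
  if (length(bad) > 0)
    abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  if ("roc" %in% stages && !"balance" %in% stages)
    abort("the 'roc' stage requires the 'balance' stage")
  structure(
    list(sim = sim, series = series, dags = dags, test = test,
         stages = stages, merge_shared_peaks = merge_shared_peaks,
         complex_pairs = complex_pairs, subset = subset,
         interpolation_step = interpolation_step,
         interpolation_span = interpolation_span,
         out_dir = out_dir, seed = as.integer(seed)),
    class = "pcu_pipeline_config")
}

#' Run the verification pipeline end to end
#'
#' Build (or simulate) the protein-coding-unit DAGs, interpolate the
#' replicated series to the common grid, compute the dynamical
#' correlation, enumerate the Markov conditions, verify them with the
#' Fisher z threshold, and run the optional balance, dominant-splice,
#' null-model and ROC stages. All randomness is seeded from the config.
#' When `out_dir` is set, every table is written as TSV together with a
#' JSON run manifest (config hash, package and R versions, stage counts).
#'
#' @param config a [pipeline_config()].
#' @return List of class `pcu_report`: `dags`, `conditions`, `records`,
#'   `by_klass`, `by_node`, `by_dag`, plus stage outputs (`balance_tab`,
#'   `inverse_balance_tab`, `contraction`, `dominant`, `nullmodel`,
#'   `roc_balance`, `roc_inverse`, `subset_enrichment`), the `dyncorr`
#'   object, and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pcu_pipeline_config"))
  stage_fail <- function(stage, e)
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)))
  if (!is.null(config$sim)) {
    study <- tryCatch(simulate_pcu_study(config$sim),
                      error = function(e) stage_fail("simulate", e))
    dags <- study$truth$dags
    series <- study$series
    truth <- study$truth
  } else {
    series <- config$series
    if (is.character(series)) series <- read_series_tsv(series)
    dags <- config$dags
    truth <- NULL
  }
  if (isTRUE(config$merge_shared_peaks))
    dags <- tryCatch(merge_shared_peak_units(dags),
                     error = function(e) stage_fail("merge", e))
  if (!is.null(config$complex_pairs))
    dags <- tryCatch(add_complex_edges(dags, config$complex_pairs),
                     error = function(e) stage_fail("complexes", e))
  interp <- tryCatch(
    interpolate_to_grid(series, step = config$interpolation_step,
                        span = config$interpolation_span),
    error = function(e) stage_fail("interpolate", e))
  dyncorr <- tryCatch(dynamical_correlation(interp),
                      error = function(e) stage_fail("correlate", e))
  conditions <- tryCatch(enumerate_markov_conditions_all(dags),
                         error = function(e) stage_fail("enumerate", e))
  inform(sprintf("pipeline: %d DAG(s), %d condition(s) enumerated",
                 length(dags), nrow(conditions)))
  records <- tryCatch(verify_conditions(conditions, dyncorr, config$test),
                      error = function(e) stage_fail("verify", e))
  out <- list(dags = dags, conditions = conditions, records = records,
              dyncorr = dyncorr, truth = truth)
  if ("balance" %in% config$stages) {
    records <- tryCatch(classify_condition_motifs(records, dyncorr),
                        error = function(e) stage_fail("balance", e))
    out$records <- records
    out$balance_tab <- balance_table(records, "balanced")
    out$inverse_balance_tab <- balance_table(records, "inverse_balanced")
    out$contraction <- contraction_stats(records)
  }
  out$by_klass <- records_by_klass(records)
  out$by_node <- records_by_node(records)
  out$by_dag <- records_by_dag(records)
  if ("dominant" %in% config$stages)
    out$dominant <- tryCatch(
      dominant_splice_all(dags, dyncorr, config$test),
      error = function(e) stage_fail("dominant", e))
  if ("nullmodel" %in% config$stages) {
    tc <- config$test
    tc$seed <- config$seed
    out$nullmodel <- tryCatch(
      null_model_benchmark(conditions, dyncorr, tc),
      error = function(e) stage_fail("nullmodel", e))
  }
  if ("roc" %in% config$stages) {
    out$roc_balance <- tryCatch(
      threshold_roc(out$records, "balanced"),
      error = function(e) stage_fail("roc", e))
    out$roc_inverse <- tryCatch(
      threshold_roc(out$records, "inverse_balanced"),
      error = function(e) stage_fail("roc", e))
  }
  if (!is.null(config$subset))
    out$subset_enrichment <- subset_enrichment(out$records, config$subset)
  out$manifest <- list(
    package = "pcunet",
    version = as.character(utils::packageVersion("pcunet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    seed = config$seed,
    n_dags = length(dags),
    n_conditions = nrow(conditions),
    n_verified = sum(out$records$verified, na.rm = TRUE))
  class(out) <- "pcu_report"
  if (!is.null(config$out_dir)) write_report(out, config$out_dir)
  out
}

#' @export
print.pcu_report <- function(x, ...) {
  cat(sprintf(
    "<pcu_report> %d DAG(s), %d condition(s), %d verified (%.1f%%)\n",
    x$manifest$n_dags, x$manifest$n_conditions, x$manifest$n_verified,
    100 * x$manifest$n_verified / max(x$manifest$n_conditions, 1)))
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(name) file.path(out_dir, name)
  write_records_tsv(report$records, f("records.tsv"))
  readr::write_tsv(report$by_klass, f("by_klass.tsv"))
  readr::write_tsv(report$by_node, f("by_node.tsv"))
  readr::write_tsv(report$by_dag, f("by_dag.tsv"))
  write_matrix_tsv(report$dyncorr$R, f("correlation.tsv"))
  if (!is.null(report$contraction))
    readr::write_tsv(report$contraction, f("contraction.tsv"))
  if (!is.null(report$balance_tab)) {
    readr::write_tsv(as.data.frame.matrix(report$balance_tab) |>
                       as_tibble(rownames = "status"),
                     f("balance_table.tsv"))
    readr::write_tsv(as.data.frame.matrix(report$inverse_balance_tab) |>
                       as_tibble(rownames = "status"),
                     f("inverse_balance_table.tsv"))
  }
  if (!is.null(report$dominant))
    readr::write_tsv(report$dominant, f("dominant.tsv"))
  if (!is.null(report$nullmodel)) {
    readr::write_tsv(report$nullmodel$distributions,
                     f("nullmodel_distributions.tsv"))
    readr::write_tsv(report$nullmodel$tests, f("nullmodel_tests.tsv"))
  }
  if (!is.null(report$roc_balance)) {
    readr::write_tsv(report$roc_balance$curve, f("roc_balance.tsv"))
    readr::write_tsv(report$roc_inverse$curve, f("roc_inverse.tsv"))
  }
  jsonlite::write_json(report$manifest, f("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
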