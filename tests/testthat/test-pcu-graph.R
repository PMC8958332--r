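test_that("peaks associate with promoters by window overlap", {
  skip_if_not_installed("GenomicRanges")
  tx <- tibble::tibble(
    chrom = "chr1", start = c(1100, 1100, 1000), end = c(9000, 9000, 8000),
    strand = c("+", "+", "+"),
    transcript_id = c("t1", "t2", "t3"))
  peaks <- tibble::tibble(
    chrom = "chr1",
    start = c(1000, 10000, 3900),
    end = c(1200, 10200, 4200),
    peak_id = c("pk_contains_tss", "pk_far", "pk_edge"))
  out <- assign_peaks_to_transcripts(peaks, tx)
  # peak [1000,1200] contains the TSS at 1100
  expect_true(any(out$peak_id == "pk_contains_tss" &
                  out$transcript_id == "t1"))
  # gap beyond the 3000 bp half-width: not associated
  expect_false(any(out$peak_id == "pk_far" & out$transcript_id == "t1"))
  # overlap exactly at the window edge TSS + 3000 = 4000 for TSS 1000
  expect_true(any(out$peak_id == "pk_edge" & out$transcript_id == "t3"))
  # strand-aware TSS: minus-strand transcript has its TSS at `end`
  tx_minus <- tibble::tibble(chrom = "chr1", start = 1100, end = 9000,
                             strand = "-", transcript_id = "tm")
  out_m <- assign_peaks_to_transcripts(
    tibble::tibble(chrom = "chr1", start = 1000, end = 1200,
                   peak_id = "pk"), tx_minus)
  expect_equal(nrow(out_m), 0)  # promoter sits around 9000, not 1100
  expect_error(
    assign_peaks_to_transcripts(
      tibble::tibble(chrom = "chr1", start = -5, end = 10, peak_id = "z"),
      tx),
    "malformed")
})

test_that("the flank pre-filter removes distant candidates", {
  skip_if_not_installed("GenomicRanges")
  tx <- tibble::tibble(chrom = "chr1", start = 1000, end = 20000,
                       strand = "+", transcript_id = "t1")
  pk <- tibble::tibble(chrom = "chr1", start = 3500, end = 3600,
                       peak_id = "pk")
  # TSS distance ~2.5 kb: in window, within flank
  expect_equal(nrow(assign_peaks_to_transcripts(pk, tx)), 1)
  # tighten the flank below the distance
  expect_equal(nrow(assign_peaks_to_transcripts(pk, tx, flank = 2000)), 0)
})

test_that("unit DAGs are built and filtered from association tables", {
  peak_tx <- readr::read_tsv(
    system.file("extdata", "example_peak_tx.tsv", package = "pcunet"),
    show_col_types = FALSE)
  tx_prot <- readr::read_tsv(
    system.file("extdata", "example_tx_protein.tsv", package = "pcunet"),
    show_col_types = FALSE)
  dags <- build_unit_dags(peak_tx, tx_prot)
  expect_length(dags, 1)
  d <- dags[["p"]]
  expect_setequal(paste(d$edges$from, d$edges$to),
                  c("a1 s1", "a2 s2", "a2 s3", "s1 p", "s2 p", "s3 p"))
  # non-coding transcripts are removed
  flags <- tibble::tibble(transcript_id = "s1", coding = FALSE)
  d2 <- build_unit_dags(peak_tx, tx_prot, coding_flags = flags)[["p"]]
  expect_false("s1" %in% d2$nodes$id)
  expect_false("a1" %in% d2$nodes$id)  # its only splice is gone
  # series availability filter
  idx <- c("a2", "s2", "s3", "p")
  d3 <- build_unit_dags(peak_tx, tx_prot, series_index = idx)[["p"]]
  expect_setequal(d3$nodes$id, idx)
  # empty tables give an empty list
  expect_length(build_unit_dags(peak_tx[0, ], tx_prot), 0)
  # protein with no surviving splice is omitted with a message
  expect_message(
    out <- build_unit_dags(peak_tx, tx_prot,
                           series_index = c("a1", "a2", "p")),
    "omitted")
  expect_length(out, 0)
})

make_unit <- function(u, peaks, splices) {
  s_ids <- sprintf("%s_s%d", u, seq_len(splices))
  p_id <- paste0(u, "_p")
  pa <- rep(peaks, length.out = splices)
  pcu_dag(
    nodes = tibble::tibble(
      id = c(unique(peaks), s_ids, p_id),
      layer = c(rep("a", length(unique(peaks))),
                rep("s", splices), "p"),
      unit_id = u),
    edges = dplyr::bind_rows(
      tibble::tibble(from = pa, to = s_ids),
      tibble::tibble(from = s_ids, to = p_id)),
    dag_id = u)
}

test_that("shared peaks merge units transitively and idempotently", {
  d1 <- make_unit("u1", c("pkA", "pkB"), 2)
  d2 <- make_unit("u2", c("pkB", "pkC"), 2)
  d3 <- make_unit("u3", c("pkC"), 1)
  d4 <- make_unit("u4", c("pkZ"), 1)
  merged <- merge_shared_peak_units(list(d1, d2, d3, d4))
  expect_length(merged, 2)
  joint <- merged[["u1+u2+u3"]]
  expect_equal(joint$provenance, "shared-peak-joint")
  expect_equal(sum(joint$nodes$id == "pkB"), 1)
  expect_setequal(unique(joint$nodes$unit_id), c("u1", "u2", "u3"))
  expect_identical(merged[["u4"]], d4)
  # order independence
  merged_rev <- merge_shared_peak_units(list(d4, d3, d2, d1))
  expect_equal(names(merged_rev), names(merged))
  expect_setequal(merged_rev[["u1+u2+u3"]]$nodes$id, joint$nodes$id)
  # idempotence
  again <- merge_shared_peak_units(merged)
  expect_equal(names(again), names(merged))
  # no sharing: output equals input
  solo <- list(v1 = make_unit("v1", "x1", 1), v2 = make_unit("v2", "x2", 1))
  expect_identical(merge_shared_peak_units(solo), solo)
  pcunet:::assert_acyclic(joint)
})

test_that("complex pairs add undirected p-p edges", {
  d1 <- make_unit("u1", "pk1", 2)
  d2 <- make_unit("u2", "pk2", 1)
  dags <- list(u1 = d1, u2 = d2)
  out <- add_complex_edges(dags, tibble::tibble(p1 = "u1_p", p2 = "u2_p"))
  joint <- out[[which(purrr::map_chr(out, "provenance") ==
                        "complex-joint")]]
  expect_equal(nrow(joint$pp_edges), 1)
  # the coupled proteins are adjacent: no p-p condition across them
  mc <- enumerate_markov_conditions(joint)
  expect_false("p-p" %in% mc$klass)
  # empty pair table is the identity
  expect_identical(add_complex_edges(dags, tibble::tibble(p1 = character(),
                                                          p2 = character())),
                   dags)
  # unknown proteins are skipped with a message
  expect_message(
    out2 <- add_complex_edges(dags,
                              tibble::tibble(p1 = "u1_p", p2 = "nope")),
    "skipped")
  expect_identical(out2, dags)
  # a pair inside an existing shared-peak joint DAG annotates that DAG
  s1 <- make_unit("w1", "pkS", 1)
  s2 <- make_unit("w2", "pkS", 1)
  shared <- merge_shared_peak_units(list(w1 = s1, w2 = s2))
  out3 <- add_complex_edges(shared,
                            tibble::tibble(p1 = "w1_p", p2 = "w2_p"))
  expect_length(out3, 1)
  expect_equal(nrow(out3[[1]]$pp_edges), 1)
  expect_setequal(unique(out3[[1]]$nodes$unit_id), c("w1", "w2"))
})

test_that("series_index applies the missing-points filter", {
  grid <- c(0, 0.5, 1, 2, 6, 24)
  full <- ora_series_tbl(list(ok = matrix(rnorm(18), 3)), grid)
  gappy <- full |>
    dplyr::mutate(variable = "gap") |>
    dplyr::filter(!(replicate == "r1" & time_h %in% c(0.5, 1)))
  onegap <- full |>
    dplyr::mutate(variable = "one") |>
    dplyr::filter(!(replicate == "r2" & time_h == 6))
  idx <- series_index(dplyr::bind_rows(full, gappy, onegap), grid)
  expect_setequal(idx, c("ok", "one"))
})
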