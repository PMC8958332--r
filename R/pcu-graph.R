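#' Assign chromatin peaks to transcript promoters
#'
#' A peak is associated with a transcript when the peak interval overlaps
#' the transcript's promoter window, defined as TSS +/- `promoter_halfwidth`
#' bp (strand-aware TSS). Candidate transcripts are pre-filtered to those
#' whose TSS lies within `flank` bp of the peak. One peak may map to many
#' transcripts and vice versa.
#'
#' Inputs may be file paths (BED for peaks, GTF/GFF for transcripts, read
#' with `rtracklayer`) or data frames: peaks in the BED dialect (0-based
#' half-open; columns `chrom`, `start`, `end`, `peak_id`), transcripts in
#' the GTF dialect (1-based closed; columns `chrom`, `start`, `end`,
#' `strand`, `transcript_id`).
#'
#' @param peaks BED file path or data frame of peak intervals.
#' @param transcripts GTF file path or data frame of transcript records.
#' @param promoter_halfwidth promoter half-width in bp (default 3000).
#' @param flank candidate pre-filter on peak-to-TSS distance in bp
#'   (default 5000).
#' @return Tibble with columns `peak_id`, `transcript_id`.
#' @export
assign_peaks_to_transcripts <- function(peaks, transcripts,
                                        promoter_halfwidth = 3000,
                                        flank = 5000) {
  for (pkg in c("GenomicRanges", "IRanges", "S4Vectors"))
    if (!requireNamespace(pkg, quietly = TRUE))
      abort(sprintf("package '%s' is required for peak assignment", pkg))
  peaks_gr <- ranges_from_input(peaks, kind = "peaks")
  tx_gr <- ranges_from_input(transcripts, kind = "transcripts")
  tss <- GenomicRanges::resize(tx_gr, width = 1, fix = "start")
  prom <- suppressWarnings(
    GenomicRanges::promoters(tss, upstream = promoter_halfwidth,
                             downstream = promoter_halfwidth + 1))
  prom <- GenomicRanges::trim(prom)
  hits <- GenomicRanges::findOverlaps(peaks_gr, prom, ignore.strand = TRUE)
  out <- tibble(
    peak_id = peaks_gr$peak_id[S4Vectors::queryHits(hits)],
    transcript_id = tx_gr$transcript_id[S4Vectors::subjectHits(hits)])
  if (is.finite(flank)) {
    d <- GenomicRanges::distance(
      peaks_gr[S4Vectors::queryHits(hits)],
      tss[S4Vectors::subjectHits(hits)], ignore.strand = TRUE)
    out <- out[!is.na(d) & d <= flank, ]
  }
  distinct(out)
}

# normalize BED-dialect / GTF-dialect inputs to GRanges (1-based closed)
ranges_from_input <- function(x, kind) {
  if (is.character(x) && length(x) == 1) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      abort("package 'rtracklayer' is required to read interval files")
    gr <- tryCatch(rtracklayer::import(x),
                   error = function(e)
                     abort(sprintf("failed to parse '%s': %s", x,
                                   conditionMessage(e))))
    if (kind == "peaks") {
      gr$peak_id <- if (!is.null(gr$name)) gr$name
                    else sprintf("peak_%d", seq_along(gr))
    } else {
      if (!is.null(gr$type)) gr <- gr[gr$type == "transcript"]
      gr$transcript_id <- gr$transcript_id %||%
        sprintf("tx_%d", seq_along(gr))
    }
    return(gr)
  }
  x <- as_tibble(x)
  if (kind == "peaks") {
    need <- c("chrom", "start", "end", "peak_id")
    miss <- setdiff(need, names(x))
    if (length(miss) > 0)
      abort(paste0("peak table missing column(s): ",
                   paste(miss, collapse = ", ")))
    if (any(x$start < 0 | x$end < x$start))
      abort("malformed peak interval (negative or inverted coordinates)")
    GenomicRanges::GRanges(
      seqnames = x$chrom,
      ranges = IRanges::IRanges(start = x$start + 1, end = x$end),
      peak_id = x$peak_id)
  } else {
    need <- c("chrom", "start", "end", "strand", "transcript_id")
    miss <- setdiff(need, names(x))
    if (length(miss) > 0)
      abort(paste0("transcript table missing column(s): ",
                   paste(miss, collapse = ", ")))
    if (any(x$start < 1 | x$end < x$start))
      abort("malformed transcript interval")
    GenomicRanges::GRanges(
      seqnames = x$chrom,
      ranges = IRanges::IRanges(start = x$start, end = x$end),
      strand = x$strand,
      transcript_id = x$transcript_id)
  }
}

#' Index of usable time series
#'
#' Applies the missing-data filter: a variable is kept when, in every
#' replicate, at most `max_missing_per_replicate` of the native time
#' points of `grid` are absent or NA.
#'
#' @param series long-format series tibble (`variable`, `replicate`,
#'   `time_h`, `value`).
#' @param grid native time grid the series should cover.
#' @param max_missing_per_replicate tolerated missing points (default 1).
#' @return Character vector of surviving variable ids.
#' @export
series_index <- function(series, grid, max_missing_per_replicate = 1) {
  series |>
    filter(!is.na(.data$value), .data$time_h %in% grid) |>
    count(.data$variable, .data$replicate) |>
    group_by(.data$variable) |>
    summarise(worst = min(.data$n), .groups = "drop") |>
    filter(length(grid) - .data$worst <= max_missing_per_replicate) |>
    pull(.data$variable)
}

#' Build protein-coding-unit DAGs from association tables
#'
#' One DAG per protein: splices are dropped when flagged non-coding,
#' missing from the series index, or left without any surviving peak;
#' peaks are dropped when missing from the index or when all their splices
#' are dropped; units without at least one surviving splice and one peak
#' (or whose protein series is missing) are omitted with a message.
#'
#' @param peak_tx tibble with columns `peak_id`, `transcript_id`.
#' @param tx_protein tibble with columns `transcript_id`, `protein_id`.
#' @param series_index character vector of variable ids with usable time
#'   series; `NULL` disables the availability filter.
#' @param coding_flags optional tibble (`transcript_id`, `coding` logical);
#'   transcripts absent from it are treated as coding.
#' @return List of [pcu_dag] objects sorted by unit id.
#' @export
build_unit_dags <- function(peak_tx, tx_protein, series_index = NULL,
                            coding_flags = NULL) {
  peak_tx <- as_tibble(peak_tx)
  tx_protein <- as_tibble(tx_protein)
  if (nrow(peak_tx) == 0 || nrow(tx_protein) == 0) return(list())
  assoc <- inner_join(peak_tx, tx_protein, by = "transcript_id")
  if (!is.null(coding_flags)) {
    nc <- coding_flags$transcript_id[!coding_flags$coding]
    assoc <- filter(assoc, !.data$transcript_id %in% nc)
  }
  if (!is.null(series_index)) {
    assoc <- assoc |>
      filter(.data$peak_id %in% series_index,
             .data$transcript_id %in% series_index,
             .data$protein_id %in% series_index)
  }
  dropped <- setdiff(unique(tx_protein$protein_id),
                     unique(assoc$protein_id))
  if (length(dropped) > 0)
    inform(sprintf("%d protein(s) omitted (no surviving splice with a peak)",
                   length(dropped)))
  units <- sort(unique(assoc$protein_id))
  purrr::map(units, function(u) {
    au <- filter(assoc, .data$protein_id == u)
    s_ids <- sort(unique(au$transcript_id))
    a_ids <- sort(unique(au$peak_id))
    nodes <- tibble(
      id = c(a_ids, s_ids, u),
      layer = c(rep("a", length(a_ids)), rep("s", length(s_ids)), "p"),
      unit_id = u)
    edges <- bind_rows(
      distinct(tibble(from = au$peak_id, to = au$transcript_id)),
      tibble(from = s_ids, to = u))
    pcu_dag(nodes, edges, dag_id = u)
  }) |>
    setNames(units)
}

#' Merge units that share chromatin peaks into joint DAGs
#'
#' Units sharing at least one peak are merged (transitive closure of the
#' sharing relation) into a joint DAG in which each shared peak appears
#' once, with its children in every member unit. Units sharing nothing
#' pass through unchanged. Merging is idempotent and independent of input
#' order.
#'
#' @param dags list of [pcu_dag] objects.
#' @return List of [pcu_dag] objects; merged ones carry provenance
#'   `"shared-peak-joint"`.
#' @export
merge_shared_peak_units <- function(dags) {
  if (length(dags) <= 1) return(dags)
  units <- purrr::map_chr(dags, "dag_id")
  peak_sets <- purrr::map(dags, ~ .x$nodes$id[.x$nodes$layer == "a"])
  # union-find over units
  parent <- seq_along(dags)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  peak_owner <- list()
  for (i in seq_along(dags)) {
    for (pk in peak_sets[[i]]) {
      j <- peak_owner[[pk]]
      if (is.null(j)) peak_owner[[pk]] <- i
      else parent[find(i)] <- find(j)
    }
  }
  comp <- vapply(seq_along(dags), find, integer(1))
  out <- purrr::map(unique(comp), function(cid) {
    members <- which(comp == cid)
    if (length(members) == 1) return(dags[[members]])
    nodes <- bind_rows(purrr::map(dags[members], "nodes")) |>
      distinct(.data$id, .keep_all = TRUE)
    edges <- bind_rows(purrr::map(dags[members], "edges")) |> distinct()
    pcu_dag(nodes, edges, provenance = "shared-peak-joint")
  })
  ord <- order(purrr::map_chr(out, "dag_id"))
  out <- out[ord]
  setNames(out, purrr::map_chr(out, "dag_id"))
}

#' Couple protein-coding units through protein-complex membership
#'
#' For every complex pair whose two proteins are present in the DAG set,
#' the containing DAGs are merged (if distinct) and an undirected `p - p`
#' edge is added, producing a mixed graph flagged `"complex-joint"`. Pairs
#' referencing unknown proteins are skipped with a message; an empty pair
#' table returns the input unchanged.
#'
#' @param dags list of [pcu_dag] objects.
#' @param complex_pairs tibble with columns `p1`, `p2` (protein node ids).
#' @return List of [pcu_dag] objects.
#' @export
add_complex_edges <- function(dags, complex_pairs) {
  complex_pairs <- as_tibble(complex_pairs)
  if (nrow(complex_pairs) == 0) return(dags)
  owner <- function(p)
    which(purrr::map_lgl(dags, ~ p %in% .x$nodes$id))[1]
  keep <- logical(nrow(complex_pairs))
  o1 <- o2 <- integer(nrow(complex_pairs))
  for (i in seq_len(nrow(complex_pairs))) {
    o1[i] <- owner(complex_pairs$p1[i])
    o2[i] <- owner(complex_pairs$p2[i])
    keep[i] <- !is.na(o1[i]) && !is.na(o2[i])
  }
  if (any(!keep))
    inform(sprintf("%d complex pair(s) skipped (unknown protein)",
                   sum(!keep)))
  complex_pairs <- complex_pairs[keep, ]
  o1 <- o1[keep]; o2 <- o2[keep]
  if (nrow(complex_pairs) == 0) return(dags)
  parent <- seq_along(dags)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(nrow(complex_pairs)))
    parent[find(o1[i])] <- find(o2[i])
  comp <- vapply(seq_along(dags), find, integer(1))
  touched <- unique(c(o1, o2))
  out <- purrr::map(unique(comp), function(cid) {
    members <- which(comp == cid)
    if (length(members) == 1 && !(members %in% touched))
      return(dags[[members]])
    nodes <- bind_rows(purrr::map(dags[members], "nodes")) |>
      distinct(.data$id, .keep_all = TRUE)
    edges <- bind_rows(purrr::map(dags[members], "edges")) |> distinct()
    pp_prev <- bind_rows(purrr::map(dags[members], "pp_edges"))
    in_comp <- complex_pairs$p1 %in% nodes$id &
      complex_pairs$p2 %in% nodes$id
    pp <- bind_rows(pp_prev, complex_pairs[in_comp, c("p1", "p2")]) |>
      distinct()
    pcu_dag(nodes, edges, pp_edges = pp, provenance = "complex-joint")
  })
  ord <- order(purrr::map_chr(out, "dag_id"))
  out <- out[ord]
  setNames(out, purrr::map_chr(out, "dag_id"))
}
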