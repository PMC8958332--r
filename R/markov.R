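#' d-separation test
#'
#' Checks whether a conditioning set `C` d-separates nodes `x` and `y` in a
#' DAG, using the standard reduction: restrict the graph to the ancestors of
#' `{x, y} \\U C`, moralize (connect co-parents, drop directions), delete
#' `C`, and test whether `x` and `y` are disconnected. Under any
#' distribution that factorizes over the DAG -- in particular a
#' linear-Gaussian structural equation model -- d-separation implies the
#' conditional independence `x` _|_ `y` | `C` (zero partial correlation).
#'
#' For mixed graphs carrying undirected protein-protein complex edges, the
#' test is run on the directed part only; the undirected edges are treated
#' purely as adjacencies when conditions are enumerated.
#'
#' @param dag a [pcu_dag], or a data frame of directed edges with columns
#'   `from` and `to`.
#' @param x,y node ids, distinct, neither contained in `C`.
#' @param C character vector of conditioning node ids (possibly empty).
#' @param nodes optional character vector of node ids (to declare isolated
#'   nodes when `dag` is an edge table).
#' @return `TRUE` if `C` d-separates `x` and `y`.
#' @export
d_separated <- function(dag, x, y, C = character(), nodes = NULL) {
  if (inherits(dag, "pcu_dag")) {
    edges <- dag$edges
    nodes <- dag$nodes$id
  } else {
    edges <- as_tibble(dag)[, c("from", "to")]
    nodes <- union(nodes, union(edges$from, edges$to))
  }
  C <- as.character(C)
  if (x == y) abort("x and y must be distinct")
  if (x %in% C || y %in% C) abort("x and y must not be in C")
  missing <- setdiff(c(x, y, C), nodes)
  if (length(missing) > 0)
    abort(paste0("unknown node id(s): ", paste(missing, collapse = ", ")))

  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(id = nodes))
  anc <- unique(unlist(lapply(c(x, y, C), function(v)
    names(igraph::subcomponent(g, v, mode = "in")))))
  sub <- igraph::induced_subgraph(g, anc)
  # moralize: join co-parents of every node
  el <- igraph::as_edgelist(sub)
  extra <- list()
  for (v in igraph::V(sub)$name) {
    pa <- el[el[, 2] == v, 1]
    if (length(pa) >= 2) {
      cmb <- utils::combn(sort(pa), 2)
      extra[[v]] <- t(cmb)
    }
  }
  m <- igraph::as_undirected(sub, mode = "collapse")
  if (length(extra) > 0) {
    em <- do.call(rbind, extra)
    nm <- igraph::V(m)$name
    idx <- rbind(match(em[, 1], nm), match(em[, 2], nm))
    m <- igraph::add_edges(m, as.vector(idx))
    m <- igraph::simplify(m)
  }
  m <- igraph::delete_vertices(m, C[C %in% igraph::V(m)$name])
  d <- igraph::distances(m, v = x, to = y)
  is.infinite(d[1, 1])
}

#' Moral graph of a protein-coding-unit DAG
#'
#' Adds undirected edges between co-parents of every node (moral edges) and
#' drops edge directions. In a protein-coding unit every splice pair of a
#' unit is a moral edge, because all splices converge on the protein in a
#' v-structure `s1 -> p <- s2`; peak pairs become moral edges only when two
#' peaks feed the same splice.
#'
#' @param dag a [pcu_dag].
#' @return A tibble of undirected edges with columns `from`, `to` and
#'   `moral` (`TRUE` for added co-parent edges, `FALSE` for skeleton edges
#'   of the DAG).
#' @export
moral_graph <- function(dag) {
  assert_acyclic(dag)
  skel <- tibble(
    from = pmin(dag$edges$from, dag$edges$to),
    to = pmax(dag$edges$from, dag$edges$to),
    moral = FALSE) |>
    distinct()
  targets <- unique(dag$edges$to)
  moral <- purrr::map(targets, function(v) {
    pa <- sort(dag_parents(dag, v))
    if (length(pa) < 2) return(NULL)
    cmb <- t(utils::combn(pa, 2))
    tibble(from = cmb[, 1], to = cmb[, 2])
  }) |>
    bind_rows()
  if (nrow(moral) > 0) {
    moral <- moral |>
      distinct() |>
      anti_join(skel, by = c("from", "to")) |>
      mutate(moral = TRUE)
  }
  bind_rows(skel, moral) |> arrange(.data$from, .data$to)
}

# layer-pair class of a non-adjacent pair; NA for pairs that are not
# enumerated (cross-unit s-p in joint DAGs)
classify_pair <- function(dag, x, y) {
  lay <- dag_layers(dag)
  un <- setNames(dag$nodes$unit_id, dag$nodes$id)
  lx <- lay[[x]]; ly <- lay[[y]]
  same_unit <- un[[x]] == un[[y]]
  key <- paste(sort(c(lx, ly)), collapse = "")
  if (!same_unit) {
    if (key == "ss") return("s-between")
    if (key == "pp") return("p-p")
    if (key %in% c("as", "ap", "aa")) {
      # peaks are unit-agnostic roots: shared peaks make cross-unit a-s /
      # a-p / a-a pairs meaningful only in joint DAGs; the enumeration keeps
      # a-a (marginal), and treats a-s / a-p like within-unit pairs
      return(switch(key, aa = "a-a", as = "a->s", ap = "a->p"))
    }
    return(NA_character_)
  }
  switch(key,
    aa = "a-a", ss = "s-s", as = "a->s", ap = "a->p",
    pp = "p-p", NA_character_)
}

#' Canonical conditioning set of a Markov condition
#'
#' Returns, for a non-adjacent pair of nodes, the conditioning set used by
#' the verification pipeline. The conventions reproduce the worked
#' three-layer examples: peak pairs are marginally independent (empty set);
#' for a peak and a splice it does not feed, the splice's peak parents; for
#' two splices of the same unit, the union of their peak parents; for a
#' peak and a protein, the splices the peak feeds (plus any other peak
#' parent of those splices, needed so that the set always d-separates when
#' a splice has several peak parents); for splices of different units,
#' their common peaks; for two proteins, the full splice set of the
#' first (by unit id) protein.
#'
#' @inheritParams d_separated
#' @param minimal if `TRUE`, greedily prune the canonical set to a minimal
#'   d-separator (the conditioning-set cardinality feeds the Fisher z
#'   degrees of freedom, so the choice matters for verification).
#' @return Character vector of node ids (possibly empty), sorted.
#' @export
canonical_conditioning_set <- function(dag, x, y, minimal = FALSE) {
  stopifnot(inherits(dag, "pcu_dag"))
  if (dag_adjacent(dag, x, y)) abort("x and y are adjacent: no condition")
  lay <- dag_layers(dag)
  # orient so that x has the earlier layer (a < s < p)
  ord <- c(a = 1, s = 2, p = 3)
  if (ord[[lay[[x]]]] > ord[[lay[[y]]]]) { tmp <- x; x <- y; y <- tmp }
  klass <- classify_pair(dag, x, y)
  if (is.na(klass))
    abort("pair is not of an enumerated class (cross-unit s-p)")
  C <- switch(klass,
    "a-a" = character(),
    "a->s" = dag_parents(dag, y),
    "s-s" = union(dag_parents(dag, x), dag_parents(dag, y)),
    "a->p" = {
      ch <- dag_children(dag, x)
      cop <- setdiff(unlist(lapply(ch, function(s) dag_parents(dag, s))), x)
      union(ch, cop)
    },
    "s-between" = intersect(dag_parents(dag, x), dag_parents(dag, y)),
    "p-p" = {
      un <- setNames(dag$nodes$unit_id, dag$nodes$id)
      first <- if (un[[x]] <= un[[y]]) x else y
      dag_parents(dag, first)
    })
  C <- sort(unique(C))
  if (!d_separated(dag, x, y, C))
    abort(sprintf("internal error: canonical set does not d-separate %s, %s",
                  x, y))
  if (minimal && length(C) > 0) {
    for (v in rev(C)) {
      trial <- setdiff(C, v)
      if (d_separated(dag, x, y, trial)) C <- trial
    }
  }
  sort(C)
}

#' Enumerate the Markov conditions of a protein-coding-unit DAG
#'
#' Missing edges of a Bayesian network correspond to (conditional)
#' independencies. For three-layer protein-coding units, nodes can be
#' ordered so that local (parent-conditioning) and global (d-separation)
#' Markov conditions coincide, and one condition is emitted per non-adjacent
#' unordered pair, with the canonical conditioning set of
#' [canonical_conditioning_set()] and a layer-pair class label. The class
#' `s -> p` never occurs: every splice is connected to its protein. In joint
#' DAGs, cross-unit pairs contribute the two additional classes
#' `s-between` (splices of different units given their common peaks) and
#' `p-p` (proteins given the full splice set of the first protein);
#' cross-unit splice-protein pairs are not enumerated.
#'
#' @inheritParams canonical_conditioning_set
#' @return A tibble with one row per condition: `dag_id`, `x`, `y`, `C`
#'   (list-column of character vectors), `card_C`, `klass`.
#' @export
enumerate_markov_conditions <- function(dag, minimal = FALSE) {
  stopifnot(inherits(dag, "pcu_dag"))
  assert_acyclic(dag)
  ids <- dag$nodes$id
  lay <- dag_layers(dag)
  ord <- c(a = 1, s = 2, p = 3)
  if (length(ids) < 2)
    return(tibble(dag_id = character(), x = character(), y = character(),
                  C = list(), card_C = integer(), klass = character()))
  pairs <- t(utils::combn(ids, 2))
  rows <- purrr::map(seq_len(nrow(pairs)), function(i) {
    x <- pairs[i, 1]; y <- pairs[i, 2]
    if (dag_adjacent(dag, x, y)) return(NULL)
    # orient by layer so x is the upstream side
    if (ord[[lay[[x]]]] > ord[[lay[[y]]]] ||
        (lay[[x]] == lay[[y]] && x > y)) { tmp <- x; x <- y; y <- tmp }
    klass <- classify_pair(dag, x, y)
    if (is.na(klass)) return(NULL)
    C <- canonical_conditioning_set(dag, x, y, minimal = minimal)
    card <- length(C)
    tibble(dag_id = dag$dag_id, x = x, y = y, C = list(C),
           card_C = card, klass = klass)
  })
  bind_rows(rows)
}

#' Enumerate Markov conditions for a list of DAGs
#'
#' @param dags list of [pcu_dag] objects.
#' @inheritParams enumerate_markov_conditions
#' @return Row-bound tibble of conditions (see
#'   [enumerate_markov_conditions()]).
#' @export
enumerate_markov_conditions_all <- function(dags, minimal = FALSE) {
  purrr::map(dags, enumerate_markov_conditions, minimal = minimal) |>
    bind_rows()
}

# pipe-join the conditioning set for flat TSV output
conditions_flat <- function(conditions) {
  conditions |>
    mutate(C = purrr::map_chr(.data$C, paste, collapse = "|"))
}

conditions_unflat <- function(df) {
  df |>
    mutate(C = purrr::map(.data$C, function(s) {
      if (is.na(s) || s == "") character() else strsplit(s, "|", fixed = TRUE)[[1]]
    }))
}
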