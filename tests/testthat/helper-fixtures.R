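# Shared toy builders and independent oracles.

# Build a pathway_graph from a compact edge string like "R -a M; M -i E".
toy_graph <- function(spec, pathway_id = "TOY", genes = NULL,
                      extra_nodes = NULL) {
  if (nzchar(spec)) {
    parts <- strsplit(strsplit(spec, ";")[[1]], "\\s+")
    parts <- lapply(parts, function(p) p[nzchar(p)])
    edges <- tibble::tibble(
      source = vapply(parts, `[[`, "", 1),
      target = vapply(parts, `[[`, "", 3),
      sign = ifelse(vapply(parts, `[[`, "", 2) == "-i",
                    "inhibition", "activation")
    )
  } else {
    edges <- tibble::tibble(source = character(), target = character(),
                            sign = character())
  }
  ids <- unique(c(edges$source, edges$target, extra_nodes))
  if (is.null(genes)) genes <- lapply(ids, function(n) paste0("g", n))
  nodes <- tibble::tibble(node_id = ids, genes = genes, label = ids)
  pathway_graph(pathway_id, nodes, edges)
}

# One-circuit helper: extract the circuit ending at `effector`.
toy_circuit <- function(spec, effector = NULL, ...) {
  g <- toy_graph(spec, ...)
  circ <- extract_circuits(g)
  if (is.null(effector)) return(circ[[1]])
  circ[[paste0(g$pathway_id, ":", effector)]]
}

# Independent oracle: union of nodes over exhaustive simple-path enumeration
# from every receptor to the effector (igraph path enumerator, not the
# package's reachability intersection).
path_union_oracle <- function(graph, receptors, effector) {
  ig <- igraph::graph_from_data_frame(
    graph$edges[, c("source", "target")], directed = TRUE,
    vertices = data.frame(name = graph$nodes$node_id))
  members <- character()
  for (r in receptors) {
    ps <- igraph::all_simple_paths(ig, from = r, to = effector, mode = "out")
    for (p in ps) members <- union(members, names(p))
    if (r == effector) members <- union(members, r)
  }
  sort(members)
}

# Independent oracle: memoized recursive evaluation of the propagation rule
# on an acyclic circuit (no topological sort, no matrices).
recursive_propagation_oracle <- function(circuit, v) {
  memo <- new.env()
  ed <- circuit$member_edges
  eval_node <- function(n) {
    if (!is.null(memo[[n]])) return(memo[[n]])
    inc <- ed[ed$target == n, , drop = FALSE]
    if (n %in% circuit$receptor_nodes) {
      act <- 1
    } else {
      a_par <- inc$source[inc$sign == "activation"]
      act <- if (length(a_par) == 0) 1 else
        1 - prod(vapply(a_par, function(p) 1 - eval_node(p), 1.0))
    }
    i_par <- inc$source[inc$sign == "inhibition"]
    inh <- if (length(i_par) == 0) 1 else
      prod(vapply(i_par, function(p) 1 - eval_node(p), 1.0))
    memo[[n]] <- unname(v[n]) * act * inh
    memo[[n]]
  }
  eval_node(circuit$effector_node)
}

# Random DAG pathway_graph on n nodes (single-gene nodes).
random_dag_graph <- function(n, p_edge = 0.4, p_inh = 0.25,
                             pathway_id = "RND") {
  repeat {
    pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    keep <- stats::runif(nrow(pairs)) < p_edge
    if (!any(keep)) next
    ids <- paste0("n", seq_len(n))
    edges <- tibble::tibble(
      source = ids[pairs[keep, "row"]],
      target = ids[pairs[keep, "col"]],
      sign = ifelse(stats::runif(sum(keep)) < p_inh, "inhibition",
                    "activation"))
    g <- pathway_graph(pathway_id,
                       tibble::tibble(node_id = ids,
                                      genes = as.list(paste0("g", ids)),
                                      label = ids),
                       edges)
    circ <- suppressWarnings(extract_circuits(g))
    if (length(circ) > 0) return(g)
  }
}

# Brute-force Rand index by looping over all cell pairs.
rand_index_bruteforce <- function(a, b) {
  n <- length(a)
  agree <- 0L; total <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      same_a <- a[i] == a[j]; same_b <- b[i] == b[j]
      agree <- agree + as.integer(same_a == same_b)
      total <- total + 1L
    }
  }
  agree / total
}

# Small two-group expression toy with named genes/cells.
toy_expr <- function(values, genes, cells) {
  matrix(values, nrow = length(genes), byrow = TRUE,
         dimnames = list(genes, cells))
}

# Is a circuit subgraph acyclic? (independent of package internals)
circuit_is_dag_public <- function(cc) {
  ig <- igraph::graph_from_data_frame(cc$member_edges[, c("source", "target")],
                                      directed = TRUE,
                                      vertices = data.frame(name = cc$member_nodes))
  igraph::is_dag(ig)
}
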