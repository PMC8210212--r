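#' Read signed pathway graphs from plain-text edge and node tables
#'
#' Pathway topologies are consumed as two UTF-8 TSV files, a portable
#' stand-in for KGML exports. The edge file has columns
#' `pathway_id, source, sign, target`; the node file has
#' `pathway_id, node_id, genes` (comma-separated gene symbols) and optional
#' logical columns `is_receptor` / `is_effector` carrying curated role
#' annotations. Lines starting with `#` are ignored in both files.
#'
#' A node may carry several genes: signal-transducer families (e.g. the
#' growth-factor ligands that share one receptor node) are modelled as one
#' multi-gene node whose expression is summarized by [node_values()].
#'
#' @param edge_file Path to the TSV edge list.
#' @param node_file Path to the TSV node attribute table.
#' @return A named list of `pathway_graph` objects, one per `pathway_id`, in
#'   order of first appearance. Each holds a `nodes` tibble
#'   (`node_id`, `genes` list-column, `label`, `is_receptor`, `is_effector`)
#'   and an `edges` tibble (`source`, `target`, `sign`).
#' @export
read_pathways <- function(edge_file, node_file) {
  nodes <- read_commented_tsv(node_file)
  edges <- read_commented_tsv(edge_file)

  need_n <- c("pathway_id", "node_id", "genes")
  if (!all(need_n %in% names(nodes))) {
    stop("node file ", node_file, " must have columns: ",
         paste(need_n, collapse = ", "), call. = FALSE)
  }
  need_e <- c("pathway_id", "source", "sign", "target")
  if (nrow(edges) > 0 && !all(need_e %in% names(edges))) {
    stop("edge file ", edge_file, " must have columns: ",
         paste(need_e, collapse = ", "), call. = FALSE)
  }

  dup <- nodes %>%
    dplyr::count(.data$pathway_id, .data$node_id) %>%
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate node id(s) in ", node_file, ": ",
         paste(unique(dup$node_id), collapse = ", "), call. = FALSE)
  }

  bad_sign <- which(!(edges$sign %in% c("activation", "inhibition")))
  if (length(bad_sign) > 0) {
    stop("unknown sign token '", edges$sign[bad_sign[1]], "' in ",
         edge_file, " line ", attr(edges, "line_numbers")[bad_sign[1]],
         call. = FALSE)
  }

  graphs <- list()
  for (pid in unique(nodes$pathway_id)) {
    nd <- nodes[nodes$pathway_id == pid, , drop = FALSE]
    ed_idx <- which(edges$pathway_id == pid)
    ed <- edges[ed_idx, , drop = FALSE]

    declared <- nd$node_id
    for (i in seq_len(nrow(ed))) {
      for (col in c("source", "target")) {
        if (!(ed[[col]][i] %in% declared)) {
          stop("edge file ", edge_file, " line ",
               attr(edges, "line_numbers")[ed_idx[i]],
               ": undeclared node id '", ed[[col]][i],
               "' in pathway '", pid, "'", call. = FALSE)
        }
      }
    }
    graphs[[pid]] <- pathway_graph(
      pathway_id = pid,
      nodes = tibble::tibble(
        node_id = nd$node_id,
        genes = strsplit(trimws(nd$genes), "\\s*,\\s*"),
        label = if ("label" %in% names(nd)) nd$label else nd$node_id,
        is_receptor = parse_flag(nd, "is_receptor"),
        is_effector = parse_flag(nd, "is_effector")
      ),
      edges = tibble::tibble(source = ed$source, target = ed$target,
                             sign = ed$sign)
    )
  }
  leftover <- setdiff(unique(edges$pathway_id), unique(nodes$pathway_id))
  if (length(leftover) > 0) {
    stop("edge file references pathway(s) with no declared nodes: ",
         paste(leftover, collapse = ", "), call. = FALSE)
  }
  graphs
}

# Read a TSV keeping original line numbers so parse errors can name them.
read_commented_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- which(!grepl("^\\s*#", raw) & nzchar(trimws(raw)))
  if (length(keep) == 0) stop("no header row in ", path, call. = FALSE)
  header <- strsplit(raw[keep[1]], "\t", fixed = TRUE)[[1]]
  data_lines <- keep[-1]
  rows <- lapply(raw[data_lines], function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    # strsplit drops trailing empty fields; restore them from the tab count
    nf <- length(gregexpr("\t", l, fixed = TRUE)[[1]])
    if (!grepl("\t", l, fixed = TRUE)) nf <- 0
    length(f) <- nf + 1
    f[is.na(f)] <- ""
    f
  })
  bad <- which(vapply(rows, length, 1L) != length(header))
  if (length(bad) > 0) {
    stop("ragged row in ", path, " line ", data_lines[bad[1]],
         " (expected ", length(header), " fields)", call. = FALSE)
  }
  if (length(rows) == 0) {
    out <- tibble::as_tibble(stats::setNames(
      replicate(length(header), character(0), simplify = FALSE), header))
  } else {
    out <- tibble::as_tibble(
      stats::setNames(as.data.frame(do.call(rbind, rows),
                                    stringsAsFactors = FALSE),
                      header),
      .name_repair = "minimal"
    )
  }
  attr(out, "line_numbers") <- data_lines
  out
}

parse_flag <- function(df, col) {
  if (!col %in% names(df)) return(rep(NA, nrow(df)))
  tolower(trimws(df[[col]])) %in% c("true", "t", "1", "yes")
}

#' Construct a pathway graph
#'
#' Validates the invariants of a signed directed pathway graph: unique node
#' ids, non-empty gene lists, declared edge endpoints, signs from
#' `{activation, inhibition}` and no self-loops.
#'
#' @param pathway_id Pathway identifier.
#' @param nodes Tibble with `node_id`, `genes` (list of character vectors),
#'   optional `label`, `is_receptor`, `is_effector`.
#' @param edges Tibble with `source`, `target`, `sign`.
#' @return A `pathway_graph` object.
#' @export
pathway_graph <- function(pathway_id, nodes, edges) {
  stopifnot(is.character(pathway_id), length(pathway_id) == 1)
  if (anyDuplicated(nodes$node_id)) {
    stop("duplicate node id in pathway '", pathway_id, "'", call. = FALSE)
  }
  if (any(lengths(nodes$genes) == 0)) {
    stop("node with empty gene list in pathway '", pathway_id, "'",
         call. = FALSE)
  }
  if (nrow(edges) > 0) {
    if (!all(edges$sign %in% c("activation", "inhibition"))) {
      stop("edge sign must be 'activation' or 'inhibition'", call. = FALSE)
    }
    missing_ep <- setdiff(c(edges$source, edges$target), nodes$node_id)
    if (length(missing_ep) > 0) {
      stop("edge endpoint(s) not declared as nodes: ",
           paste(missing_ep, collapse = ", "), call. = FALSE)
    }
    if (any(edges$source == edges$target)) {
      stop("self-loop edge(s) rejected in pathway '", pathway_id, "'",
           call. = FALSE)
    }
  }
  if (!"label" %in% names(nodes)) nodes$label <- nodes$node_id
  if (!"is_receptor" %in% names(nodes)) nodes$is_receptor <- NA
  if (!"is_effector" %in% names(nodes)) nodes$is_effector <- NA
  structure(
    list(pathway_id = pathway_id,
         nodes = tibble::as_tibble(nodes),
         edges = tibble::as_tibble(edges)),
    class = "pathway_graph"
  )
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat("<pathway_graph> ", x$pathway_id, ": ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

as_igraph <- function(graph) {
  g <- igraph::graph_from_data_frame(
    d = if (nrow(graph$edges) > 0) graph$edges[, c("source", "target", "sign")]
        else data.frame(source = character(), target = character(),
                        sign = character()),
    directed = TRUE,
    vertices = data.frame(name = graph$nodes$node_id)
  )
  g
}

#' Extract effector-centric signaling circuits from a pathway graph
#'
#' A circuit is the sub-network connecting every possible receptor node to
#' one effector node: one circuit per effector, whose member set is the union
#' of nodes and edges lying on directed routes from any receptor to that
#' effector. Receptors default to curated `is_receptor` annotations when the
#' node table carries any, otherwise to source nodes (no incoming edges);
#' effectors likewise default to annotations or sink nodes. On acyclic graphs
#' the member set equals the union over all simple receptor-to-effector
#' paths; on cyclic graphs it is the reachability intersection
#' (reachable from some receptor, and co-reachable to the effector), the
#' natural generalization.
#'
#' @param graph A `pathway_graph`.
#' @param receptors Optional explicit character vector of receptor node ids.
#' @param effectors Optional explicit character vector of effector node ids.
#' @return List of `circuit` objects, one per effector reachable from at
#'   least one receptor. Unreachable effectors are dropped with a warning.
#' @export
extract_circuits <- function(graph, receptors = NULL, effectors = NULL) {
  stopifnot(inherits(graph, "pathway_graph"))
  nd <- graph$nodes
  indeg <- table(factor(graph$edges$target, levels = nd$node_id))
  outdeg <- table(factor(graph$edges$source, levels = nd$node_id))

  if (is.null(receptors)) {
    receptors <- if (any(nd$is_receptor %in% TRUE)) {
      nd$node_id[nd$is_receptor %in% TRUE]
    } else {
      nd$node_id[indeg == 0]
    }
  }
  if (is.null(effectors)) {
    effectors <- if (any(nd$is_effector %in% TRUE)) {
      nd$node_id[nd$is_effector %in% TRUE]
    } else {
      nd$node_id[outdeg == 0]
    }
  }
  bad <- setdiff(c(receptors, effectors), nd$node_id)
  if (length(bad) > 0) {
    stop("unknown node id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(receptors) == 0) {
    stop("pathway '", graph$pathway_id,
         "' has no source nodes and no explicit receptor list; ",
         "cannot define circuits", call. = FALSE)
  }

  ig <- as_igraph(graph)
  # nodes reachable from any receptor (receptors included)
  reach <- unique(unlist(lapply(receptors, function(r) {
    names(igraph::subcomponent(ig, r, mode = "out"))
  })))

  circuits <- list()
  for (eff in effectors) {
    coreach <- names(igraph::subcomponent(ig, eff, mode = "in"))
    members <- intersect(reach, coreach)
    if (!(eff %in% members)) {
      warning("effector '", eff, "' in pathway '", graph$pathway_id,
              "' is unreachable from every receptor; no circuit defined",
              call. = FALSE)
      next
    }
    keep_e <- graph$edges$source %in% members & graph$edges$target %in% members
    circuits[[paste0(graph$pathway_id, ":", eff)]] <- structure(
      list(circuit_id = paste0(graph$pathway_id, ":", eff),
           pathway_id = graph$pathway_id,
           effector_node = eff,
           receptor_nodes = sort(intersect(receptors, members)),
           member_nodes = sort(members),
           member_edges = graph$edges[keep_e, , drop = FALSE],
           node_genes = stats::setNames(nd$genes, nd$node_id)[sort(members)]),
      class = "circuit"
    )
  }
  circuits
}

#' @export
print.circuit <- function(x, ...) {
  cat("<circuit> ", x$circuit_id, ": ", length(x$member_nodes),
      " nodes (receptors: ", paste(x$receptor_nodes, collapse = ", "),
      " -> effector: ", x$effector_node, ")\n", sep = "")
  invisible(x)
}

#' Genes carried by a set of circuits
#'
#' @param circuits List of `circuit` objects.
#' @return Tibble with one row per (circuit, node, gene).
#' @export
circuit_genes <- function(circuits) {
  purrr::map_dfr(circuits, function(cc) {
    tibble::tibble(
      circuit_id = cc$circuit_id,
      node_id = rep(names(cc$node_genes), lengths(cc$node_genes)),
      gene = unlist(cc$node_genes, use.names = FALSE)
    )
  })
}
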