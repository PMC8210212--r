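#' Summarize per-cell node expression for multi-gene nodes
#'
#' Each pathway node carries one or more gene symbols; its normalized
#' expression \eqn{v_n \in [0,1]} is a summary of those genes' values in the
#' cell. Genes absent from the expression matrix contribute
#' `missing_default`; matching of gene symbols against matrix row names is
#' case-insensitive. Single-gene nodes return that gene's value under every
#' rule.
#'
#' @param expr Normalized expression matrix (genes x cells, values in
#'   \[0,1\]) or a named per-cell vector.
#' @param genes Character vector of gene symbols carried by the node.
#' @param rule Summarization rule: `"mean"` (default), `"min"`, or
#'   `"percentile90"` (type-7 90th percentile).
#' @param missing_default Value in \[0,1\] substituted for genes not present
#'   in `expr`, or `NULL` to require all genes measurable.
#' @return A numeric vector of node values, one per cell (or a scalar for a
#'   vector `expr`).
#' @export
node_values <- function(expr, genes,
                        rule = c("mean", "min", "percentile90"),
                        missing_default = 0.5) {
  rule <- match.arg(rule)
  scalar <- is.null(dim(expr))
  if (scalar) expr <- matrix(expr, ncol = 1, dimnames = list(names(expr), "cell"))
  idx <- match(toupper(genes), toupper(rownames(expr)))
  n_missing <- sum(is.na(idx))
  if (n_missing > 0 && is.null(missing_default)) {
    stop("gene(s) absent from expression matrix with no missing_default: ",
         paste(genes[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  vals <- matrix(missing_default %||% NA_real_,
                 nrow = length(genes), ncol = ncol(expr))
  hit <- !is.na(idx)
  vals[hit, ] <- expr[idx[hit], , drop = FALSE]
  out <- switch(rule,
    mean = colMeans(vals),
    min = apply(vals, 2, min),
    percentile90 = apply(vals, 2, stats::quantile, probs = 0.9,
                         type = 7, names = FALSE)
  )
  if (scalar) out <- unname(out[1])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Activation/inhibition factors for one node given incoming signal rows.
# S: nodes x cells signal matrix; edges within the circuit.
prop_factors <- function(node, S, edges, is_receptor) {
  inc <- edges[edges$target == node, , drop = FALSE]
  act_parents <- inc$source[inc$sign == "activation"]
  inh_parents <- inc$source[inc$sign == "inhibition"]
  if (is_receptor) {
    # receptors carry one implicit activation of 1: factor is exactly 1
    act <- rep(1, ncol(S))
  } else if (length(act_parents) == 0) {
    # no activating input but (necessarily) inhibitors: pass-through factor
    act <- rep(1, ncol(S))
  } else {
    one_minus <- 1 - S[act_parents, , drop = FALSE]
    act <- 1 - apply(one_minus, 2, prod)
  }
  if (length(inh_parents) == 0) {
    inh <- rep(1, ncol(S))
  } else {
    inh <- apply(1 - S[inh_parents, , drop = FALSE], 2, prod)
  }
  list(act = act, inh = inh)
}

circuit_is_dag <- function(circuit) {
  ig <- igraph::graph_from_data_frame(
    d = if (nrow(circuit$member_edges) > 0)
          circuit$member_edges[, c("source", "target")]
        else data.frame(source = character(), target = character()),
    directed = TRUE,
    vertices = data.frame(name = circuit$member_nodes))
  list(dag = igraph::is_dag(ig), graph = ig)
}

#' Propagate signal through one circuit
#'
#' Implements the recursive signal-propagation rule: a node's transduced
#' signal is
#' \deqn{S_n = v_n \cdot \Big(1 - \prod_{s_a \in A}(1 - s_a)\Big) \cdot
#'       \prod_{s_i \in I}(1 - s_i)}
#' where \eqn{A} and \eqn{I} are the activating and inhibiting signals
#' arriving on the circuit's edges. Receptor nodes receive one implicit
#' activation of 1, so \eqn{S_{receptor} = v_{receptor}} in the absence of
#' inhibitors; a node with inhibitors but no activating edge uses activation
#' factor 1. Acyclic circuits are evaluated exactly in topological order;
#' cyclic circuits are iterated synchronously from all-zero signals to a
#' fixed point.
#'
#' @param circuit A `circuit` object.
#' @param v Named numeric vector (or nodes x cells matrix) of node
#'   expression values \eqn{v_n \in [0,1]}; names must cover
#'   `circuit$member_nodes`.
#' @param tol Fixed-point convergence tolerance (max absolute change).
#' @param max_iter Maximum fixed-point iterations for cyclic circuits.
#' @param method `"auto"` (topological order when the circuit is acyclic,
#'   fixed point otherwise) or `"iterative"` to force fixed-point
#'   iteration.
#' @return A list with `effector` (signal at the effector node, per cell),
#'   `states` (nodes x cells matrix of all \eqn{S_n}), `converged`, and
#'   `iterations` (0 for exact topological evaluation).
#' @export
propagate <- function(circuit, v, tol = 1e-6, max_iter = 100L,
                      method = c("auto", "iterative")) {
  method <- match.arg(method)
  stopifnot(inherits(circuit, "circuit"))
  nodes <- circuit$member_nodes
  scalar <- is.null(dim(v))
  if (scalar) v <- matrix(v, ncol = 1, dimnames = list(names(v), "cell"))
  if (!all(nodes %in% rownames(v))) {
    stop("v lacks values for node(s): ",
         paste(setdiff(nodes, rownames(v)), collapse = ", "), call. = FALSE)
  }
  v <- v[nodes, , drop = FALSE]
  if (any(v < 0 | v > 1)) stop("node values must lie in [0,1]", call. = FALSE)
  edges <- circuit$member_edges
  receptors <- circuit$receptor_nodes
  dg <- circuit_is_dag(circuit)

  S <- matrix(0, nrow = length(nodes), ncol = ncol(v),
              dimnames = list(nodes, colnames(v)))
  if (dg$dag && method == "auto") {
    ord <- names(igraph::topo_sort(dg$graph, mode = "out"))
    for (n in ord) {
      f <- prop_factors(n, S, edges, n %in% receptors)
      S[n, ] <- v[n, ] * f$act * f$inh
    }
    res <- list(converged = TRUE, iterations = 0L, residual = 0)
  } else {
    it <- 0L
    repeat {
      S_new <- S
      for (n in nodes) {
        f <- prop_factors(n, S, edges, n %in% receptors)
        S_new[n, ] <- v[n, ] * f$act * f$inh
      }
      delta <- max(abs(S_new - S))
      S <- S_new
      it <- it + 1L
      if (delta < tol) { res <- list(converged = TRUE, iterations = it,
                                     residual = delta); break }
      if (it >= max_iter) {
        stop("fixed-point propagation did not converge in ", max_iter,
             " iterations (last residual ", signif(delta, 4), ") for circuit ",
             circuit$circuit_id, call. = FALSE)
      }
    }
  }
  eff <- S[circuit$effector_node, ]
  if (scalar) eff <- unname(eff[1])
  c(list(effector = eff, states = S), res)
}

#' Compute the circuit-by-cell activity matrix
#'
#' Evaluates every circuit's effector signal in every cell of a normalized
#' expression matrix, yielding the activity matrix downstream differential
#' and perturbation analyses operate on.
#'
#' @param expr Normalized expression matrix (genes x cells, values in
#'   \[0,1\]), e.g. from [normalize_expression()].
#' @param circuits List of `circuit` objects (see [extract_circuits()]).
#' @param rule Multi-gene node summarization rule, see [node_values()].
#' @param missing_default Value substituted for unmeasured genes; `NULL`
#'   makes circuits with unmeasurable nodes an error.
#' @param tol,max_iter Fixed-point controls for cyclic circuits, see
#'   [propagate()].
#' @return A `circuit_activity` matrix (circuits x cells, values in \[0,1\])
#'   with the propagation settings attached as attributes.
#' @export
circuit_activities <- function(expr, circuits, rule = "mean",
                               missing_default = 0.5, tol = 1e-6,
                               max_iter = 100L) {
  expr <- as_expression_matrix(expr)
  if (any(expr < 0 - 1e-12) || any(expr > 1 + 1e-12)) {
    stop("expression must be normalized to [0,1] before computing ",
         "circuit activities; see normalize_expression()", call. = FALSE)
  }
  if (length(circuits) == 0) stop("no circuits supplied", call. = FALSE)
  if (is.null(names(circuits))) {
    names(circuits) <- vapply(circuits, function(cc) cc$circuit_id, "")
  }
  if (is.null(missing_default)) {
    genes_up <- toupper(rownames(expr))
    for (cc in circuits) {
      cg <- toupper(unique(unlist(cc$node_genes)))
      if (!any(cg %in% genes_up)) {
        stop("circuit ", cc$circuit_id, " references zero measurable genes ",
             "and missing_default is unset", call. = FALSE)
      }
      if (!all(cg %in% genes_up)) {
        stop("circuit ", cc$circuit_id, " has unmeasured gene(s) and ",
             "missing_default is unset", call. = FALSE)
      }
    }
  }
  acts <- matrix(NA_real_, nrow = length(circuits), ncol = ncol(expr),
                 dimnames = list(names(circuits), colnames(expr)))
  iters <- integer(length(circuits))
  for (i in seq_along(circuits)) {
    cc <- circuits[[i]]
    V <- do.call(rbind, lapply(cc$node_genes, function(g) {
      node_values(expr, g, rule = rule, missing_default = missing_default)
    }))
    rownames(V) <- names(cc$node_genes)
    if (is.null(dim(V))) V <- matrix(V, nrow = length(cc$node_genes),
                                     dimnames = list(names(cc$node_genes), colnames(expr)))
    pr <- propagate(cc, V, tol = tol, max_iter = max_iter)
    acts[i, ] <- pr$effector
    iters[i] <- pr$iterations
  }
  structure(acts,
            class = c("circuit_activity", "matrix", "array"),
            settings = list(rule = rule, missing_default = missing_default,
                            tol = tol, max_iter = max_iter),
            iterations = iters)
}

#' @export
print.circuit_activity <- function(x, ...) {
  cat("<circuit_activity> ", nrow(x), " circuits x ", ncol(x), " cells; ",
      "range [", signif(min(x), 3), ", ", signif(max(x), 3), "]\n", sep = "")
  invisible(x)
}

#' Tidy a circuit activity matrix into long form
#'
#' @param x A `circuit_activity` matrix.
#' @param ... Unused.
#' @return Tibble with columns `circuit_id`, `cell`, `activity`.
#' @method tidy circuit_activity
#' @export
tidy.circuit_activity <- function(x, ...) {
  m <- unclass(x)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  tibble::as_tibble(m, rownames = "circuit_id") %>%
    tidyr::pivot_longer(-"circuit_id", names_to = "cell",
                        values_to = "activity")
}
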