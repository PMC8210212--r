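#' Read a drug-target table
#'
#' TSV with header `drug  gene  action`; actions come from the closed
#' vocabulary `{inhibitor, antagonist, agonist}`.
#'
#' @param path Path to the TSV.
#' @return Tibble with columns `drug`, `gene`, `action`.
#' @export
read_drug_table <- function(path) {
  tab <- read_commented_tsv(path)
  need <- c("drug", "gene", "action")
  if (!all(need %in% names(tab))) {
    stop("drug table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!(tab$action %in% c("inhibitor", "antagonist", "agonist")))
  if (length(bad) > 0) {
    stop("unknown action '", tab$action[bad[1]], "' in ", path, " line ",
         attr(tab, "line_numbers")[bad[1]], call. = FALSE)
  }
  tibble::tibble(drug = tab$drug, gene = tab$gene, action = tab$action)
}

#' Build a drug specification
#'
#' @param drug Drug name.
#' @param genes Target gene symbols (>= 1).
#' @param actions Action per target: `"inhibitor"`, `"antagonist"` or
#'   `"agonist"` (recycled if length 1).
#' @return One-drug tibble usable wherever a drug table row set is expected.
#' @export
drug_spec <- function(drug, genes, actions = "inhibitor") {
  if (length(genes) < 1) stop("a drug needs >= 1 target", call. = FALSE)
  actions <- rep_len(actions, length(genes))
  if (!all(actions %in% c("inhibitor", "antagonist", "agonist"))) {
    stop("actions must be inhibitor, antagonist or agonist", call. = FALSE)
  }
  tibble::tibble(drug = drug, gene = genes, action = actions)
}

#' Apply a simulated drug perturbation to a normalized expression matrix
#'
#' Creates the simulated profile the knockdown model compares against
#' baseline: inhibitor/antagonist target genes are set to a low value
#' (default 0) and agonist targets to a high value (default 1) in every
#' cell; all other genes are untouched. A fractional-knockdown mode
#' (`efficacy < 1`) instead multiplies inhibited targets by `1 - efficacy`
#' and moves agonist targets the same fraction of the way to the agonism
#' value. Targets absent from the matrix are skipped with a warning and
#' recorded in the `skipped_targets` attribute.
#'
#' @param expr Normalized expression matrix (genes x cells) or data frame.
#' @param drug Drug rows (tibble `drug`, `gene`, `action`), e.g. from
#'   [drug_spec()] or one drug's rows of [read_drug_table()].
#' @param inhibition_value Value assigned to inhibited targets (default 0).
#' @param agonism_value Value assigned to agonized targets (default 1).
#' @param efficacy Fraction of full effect in \[0,1\] (default 1 = full).
#' @return Perturbed matrix with attribute `skipped_targets`.
#' @export
apply_perturbation <- function(expr, drug, inhibition_value = 0,
                               agonism_value = 1, efficacy = 1) {
  m <- as_expression_matrix(expr)
  stopifnot(inhibition_value >= 0, inhibition_value <= 1,
            agonism_value >= 0, agonism_value <= 1,
            efficacy >= 0, efficacy <= 1)
  skipped <- character()
  for (i in seq_len(nrow(drug))) {
    g <- drug$gene[i]
    row <- match(toupper(g), toupper(rownames(m)))
    if (is.na(row)) {
      warning("target gene '", g, "' absent from expression matrix; skipped",
              call. = FALSE)
      skipped <- c(skipped, g)
      next
    }
    target_value <- if (drug$action[i] == "agonist") agonism_value
                    else inhibition_value
    m[row, ] <- m[row, ] + efficacy * (target_value - m[row, ])
  }
  attr(m, "skipped_targets") <- skipped
  m
}

#' Circuits whose member nodes carry a given gene
#'
#' @param circuits List of `circuit` objects.
#' @param gene Gene symbol (matched case-insensitively).
#' @return Character vector of circuit ids.
#' @export
circuits_with_gene <- function(circuits, gene) {
  hit <- vapply(circuits, function(cc) {
    toupper(gene) %in% toupper(unlist(cc$node_genes, use.names = FALSE))
  }, TRUE)
  unname(vapply(circuits[hit], function(cc) cc$circuit_id, ""))
}

#' Per-cell impact of a perturbation on circuit activities
#'
#' Quantifies, per cell, how much the simulated drug changed the circuits
#' the target participates in: the log2 fold change
#' \eqn{\mathrm{LFC}(c,j) = \log_2((A'_{cj}+\epsilon)/(A_{cj}+\epsilon))}
#' between perturbed and baseline activity (pseudocount \eqn{\epsilon}
#' keeps total shutdowns finite), and an impact score aggregating
#' \eqn{|\mathrm{LFC}|} over the target circuits (mean by default).
#'
#' @param baseline,perturbed `circuit_activity` matrices (or plain
#'   matrices) of identical dimensions.
#' @param target_circuits Circuit ids the impact aggregates over, normally
#'   [circuits_with_gene()] of the drug targets.
#' @param eps Pseudocount on the \[0,1\] activity scale (default 1e-3).
#' @param aggregate `"mean"` (default), `"sum"` or `"max"` of the absolute
#'   LFC over target circuits.
#' @return A `perturbation_result`: `$lfc` (circuits x cells), `$impact`
#'   tibble (`cell`, `impact`), `$target_circuits`.
#' @export
perturbation_impact <- function(baseline, perturbed, target_circuits,
                                eps = 1e-3,
                                aggregate = c("mean", "sum", "max")) {
  aggregate <- match.arg(aggregate)
  b <- if (inherits(baseline, "circuit_activity")) m_strip(unclass(baseline))
       else as.matrix(baseline)
  p <- if (inherits(perturbed, "circuit_activity")) m_strip(unclass(perturbed))
       else as.matrix(perturbed)
  if (!identical(dim(b), dim(p)) || !identical(dimnames(b), dimnames(p))) {
    stop("baseline and perturbed activity matrices do not match", call. = FALSE)
  }
  lfc <- log2((p + eps) / (b + eps))
  missing_tc <- setdiff(target_circuits, rownames(lfc))
  if (length(missing_tc) > 0) {
    stop("target circuit(s) not in activity matrix: ",
         paste(missing_tc, collapse = ", "), call. = FALSE)
  }
  if (length(target_circuits) == 0) {
    impact <- rep(0, ncol(lfc))
  } else {
    sub <- abs(lfc[target_circuits, , drop = FALSE])
    impact <- switch(aggregate,
                     mean = colMeans(sub),
                     sum = colSums(sub),
                     max = apply(sub, 2, max))
  }
  structure(list(
    lfc = lfc,
    impact = tibble::tibble(cell = colnames(lfc), impact = unname(impact)),
    target_circuits = target_circuits,
    eps = eps, aggregate = aggregate
  ), class = "perturbation_result")
}

#' Classify cells into responders and low-responders
#'
#' Splits the per-cell impact scores into two groups with 1-D k-means
#' (k = 2); the higher-mean component is labeled `responder`. The reported
#' threshold is the midpoint of the two component means, and a mean
#' silhouette width over the split is returned as a bimodality diagnostic
#' (values below 0.5 flag a weak split). If all scores are identical a
#' single all-responder group is returned with a warning.
#'
#' @param impact Per-cell scores: the `$impact` tibble of
#'   [perturbation_impact()], a named numeric vector, or a
#'   `perturbation_result`.
#' @param seed Integer seed for the k-means initialization.
#' @return Tibble (`cell`, `impact`, `label`) with attributes `threshold`,
#'   `silhouette` and `weak_bimodality`.
#' @export
classify_responders <- function(impact, seed = 1L) {
  if (inherits(impact, "perturbation_result")) impact <- impact$impact
  if (is.data.frame(impact)) {
    scores <- stats::setNames(impact$impact, impact$cell)
  } else {
    scores <- impact
    if (is.null(names(scores))) names(scores) <- paste0("cell", seq_along(scores))
  }
  if (length(scores) < 2) stop("need >= 2 cells", call. = FALSE)
  out <- tibble::tibble(cell = names(scores), impact = unname(scores))
  if (stats::sd(scores) == 0) {
    warning("all impact scores identical; labeling every cell a responder",
            call. = FALSE)
    out$label <- "responder"
    return(structure(out, threshold = unname(scores[1]), silhouette = NA_real_,
                     weak_bimodality = TRUE))
  }
  old <- .Random.seed_exists()
  set.seed(seed)
  km <- stats::kmeans(matrix(scores, ncol = 1), centers = 2, nstart = 10)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  hi <- which.max(km$centers[, 1])
  out$label <- ifelse(km$cluster == hi, "responder", "low_responder")
  sil <- cluster::silhouette(km$cluster, stats::dist(matrix(scores, ncol = 1)))
  mean_sil <- mean(sil[, "sil_width"])
  structure(out,
            threshold = mean(km$centers[, 1]),
            silhouette = mean_sil,
            weak_bimodality = mean_sil < 0.5)
}

#' Simulate one drug end to end
#'
#' Convenience wrapper: perturb the expression matrix, recompute circuit
#' activities, score per-cell impact over the circuits containing any
#' target gene, and classify responders.
#'
#' @inheritParams apply_perturbation
#' @inheritParams perturbation_impact
#' @param circuits List of `circuit` objects.
#' @param baseline Optional precomputed baseline `circuit_activity` (saves
#'   recomputation across drugs).
#' @param seed Seed for the responder split.
#' @param ... Passed to [circuit_activities()].
#' @return A `perturbation_result` with an extra `$responders` tibble and
#'   `$drug` name.
#' @export
simulate_drug <- function(expr, drug, circuits, baseline = NULL,
                          inhibition_value = 0, agonism_value = 1,
                          efficacy = 1, eps = 1e-3, aggregate = "mean",
                          seed = 1L, ...) {
  m <- as_expression_matrix(expr)
  if (is.null(baseline)) baseline <- circuit_activities(m, circuits, ...)
  pert_expr <- apply_perturbation(m, drug, inhibition_value, agonism_value,
                                  efficacy)
  perturbed <- circuit_activities(pert_expr, circuits, ...)
  target_circuits <- unique(unlist(lapply(unique(drug$gene), function(g) {
    circuits_with_gene(circuits, g)
  })))
  res <- perturbation_impact(baseline, perturbed, target_circuits,
                             eps = eps, aggregate = aggregate)
  res$responders <- classify_responders(res, seed = seed)
  res$drug <- drug$drug[1]
  res$skipped_targets <- attr(pert_expr, "skipped_targets")
  res
}

#' @export
print.perturbation_result <- function(x, ...) {
  cat("<perturbation_result>", if (!is.null(x$drug)) paste0(" drug: ", x$drug),
      "; ", length(x$target_circuits), " target circuits, ",
      ncol(x$lfc), " cells\n", sep = "")
  if (!is.null(x$responders)) print(table(x$responders$label))
  invisible(x)
}

#' @rdname perturbation_impact
#' @param x A `perturbation_result`.
#' @param ... Unused.
#' @method tidy perturbation_result
#' @export
tidy.perturbation_result <- function(x, ...) {
  out <- if (!is.null(x$responders)) x$responders else x$impact
  tibble::as_tibble(out)
}

#' Per-drug report of targeted circuits and affected hallmarks
#'
#' For every (drug, target) pair: the number of circuits the target gene
#' participates in, and how many of those circuits are annotated to each
#' hallmark — the tabular summary used to compare candidate drugs. Targets
#' present in zero circuits yield an all-zero row.
#'
#' @param drugs Drug table (`drug`, `gene`, `action`).
#' @param circuits List of `circuit` objects.
#' @param circuit_hallmarks Tibble (`circuit_id`, `hallmark`), e.g. from
#'   [annotate_circuits()].
#' @return Tibble: `drug`, `gene`, `action`, `circuits`, then one count
#'   column per hallmark.
#' @export
drug_report <- function(drugs, circuits, circuit_hallmarks) {
  hallmark_levels <- sort(unique(circuit_hallmarks$hallmark))
  rows <- purrr::pmap_dfr(drugs, function(drug, gene, action) {
    ids <- circuits_with_gene(circuits, gene)
    counts <- circuit_hallmarks %>%
      dplyr::filter(.data$circuit_id %in% ids) %>%
      dplyr::count(.data$hallmark)
    wide <- stats::setNames(rep(0L, length(hallmark_levels)), hallmark_levels)
    wide[counts$hallmark] <- counts$n
    dplyr::bind_cols(
      tibble::tibble(drug = drug, gene = gene, action = action,
                     circuits = length(ids)),
      tibble::as_tibble_row(as.list(wide))
    )
  })
  rows
}
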