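#' Read a gene expression matrix
#'
#' Two formats are supported, chosen by extension or `format`:
#' * **tsv** — genes as rows, a header row of cell ids, first column the
#'   gene symbol.
#' * **mtx** — MatrixMarket sparse matrix with plain-text sidecars
#'   `<stem>.genes.txt` and `<stem>.cells.txt` (one name per line).
#'
#' Duplicate gene symbols, non-numeric entries and ragged rows are parse
#' errors naming the offender.
#'
#' @param path Path to the matrix file.
#' @param format `"auto"` (by extension), `"tsv"` or `"mtx"`.
#' @return Numeric genes x cells matrix.
#' @export
read_expression <- function(path, format = c("auto", "tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "tsv"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "tsv") {
    tab <- read_commented_tsv(path)
    genes <- tab[[1]]
    m <- as.matrix(tab[, -1, drop = FALSE])
    suppressWarnings(storage.mode(m) <- "double")
    if (anyNA(m)) {
      bad <- which(is.na(m), arr.ind = TRUE)[1, ]
      stop("non-numeric entry at gene '", genes[bad[1]], "', column ",
           colnames(m)[bad[2]], " in ", path, call. = FALSE)
    }
    rownames(m) <- genes
  } else {
    sm <- Matrix::readMM(path)
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    gfile <- paste0(stem, ".genes.txt"); cfile <- paste0(stem, ".cells.txt")
    for (f in c(gfile, cfile)) {
      if (!file.exists(f)) stop("missing MTX sidecar: ", f, call. = FALSE)
    }
    m <- as.matrix(sm)
    rownames(m) <- readLines(gfile, warn = FALSE)
    colnames(m) <- readLines(cfile, warn = FALSE)
  }
  as_expression_matrix(m)
}

#' Write a gene expression (or activity) matrix
#'
#' TSV output writes genes as rows with a leading `gene` column; `.mtx`
#' output writes a MatrixMarket file plus `<stem>.genes.txt` /
#' `<stem>.cells.txt` sidecars.
#'
#' @param m Matrix with row and column names.
#' @param path Output path; extension `.mtx` selects MatrixMarket.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  m <- if (is.data.frame(m)) as_expression_matrix(m) else m
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    Matrix::writeMM(Matrix::Matrix(unname(as.matrix(m)), sparse = TRUE), path)
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    writeLines(rownames(m), paste0(stem, ".genes.txt"))
    writeLines(colnames(m), paste0(stem, ".cells.txt"))
  } else {
    df <- tibble::as_tibble(as.matrix(m), rownames = "gene")
    readr::write_tsv(df, path)
  }
  invisible(path)
}

#' Write pathway graphs to the edge/node TSV pair
#'
#' @param graphs Named list of `pathway_graph` objects.
#' @param edge_file,node_file Output paths.
#' @return `edge_file`, invisibly.
#' @export
write_pathways <- function(graphs, edge_file, node_file) {
  edges <- purrr::map_dfr(graphs, function(g) {
    dplyr::mutate(g$edges, pathway_id = g$pathway_id, .before = 1)
  })
  nodes <- purrr::map_dfr(graphs, function(g) {
    tibble::tibble(pathway_id = g$pathway_id,
                   node_id = g$nodes$node_id,
                   genes = vapply(g$nodes$genes, paste, "", collapse = ","),
                   label = g$nodes$label,
                   is_receptor = ifelse(is.na(g$nodes$is_receptor), "",
                                        tolower(g$nodes$is_receptor)),
                   is_effector = ifelse(is.na(g$nodes$is_effector), "",
                                        tolower(g$nodes$is_effector)))
  })
  readr::write_tsv(edges[, c("pathway_id", "source", "sign", "target")],
                   edge_file)
  readr::write_tsv(nodes, node_file)
  invisible(edge_file)
}

#' Write / read cluster or group labels as two-column TSV
#'
#' @param labels Named vector (names = cells) or tibble (`cell`, `label`).
#' @param path TSV path.
#' @return For the writer, `path` invisibly; for the reader, a named vector.
#' @export
write_labels <- function(labels, path) {
  if (is.data.frame(labels)) {
    df <- labels[, 1:2]
    names(df) <- c("cell", "label")
  } else {
    df <- tibble::tibble(cell = names(labels), label = unclass(unname(labels)))
  }
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  tab <- read_commented_tsv(path)
  lab <- tab[[2]]
  suppressWarnings(num <- as.numeric(lab))
  if (!anyNA(num)) lab <- as.integer(num)
  stats::setNames(lab, tab[[1]])
}

#' Run the full analysis pipeline on files
#'
#' Orchestrates the stages end to end: read counts, impute dropouts,
#' normalize, load pathways and extract circuits, compute circuit
#' activities, cluster cells (reporting Rand agreement against reference
#' labels when provided), test differential activity per contrast,
#' summarize by hallmark, and simulate each drug. All inputs are validated
#' before any computation; every output is written under `out_dir` along
#' with a JSON manifest of versions, seeds and parameters.
#'
#' @param expression Path to the count matrix (TSV or MTX).
#' @param pathways Character vector: `c(edge_file, node_file)`.
#' @param out_dir Output directory.
#' @param hallmarks Optional GMT path.
#' @param drugs Optional drug table path.
#' @param reference_labels Optional TSV of curated cell labels.
#' @param contrasts Optional list of length-2 label vectors to test; when
#'   omitted and reference labels are present, each label is contrasted
#'   against all others pooled.
#' @param impute Logical: run dropout imputation first.
#' @param k Clusters for [cluster_cells()].
#' @param k_grid,q,rule,missing_default,tol,alpha,eps,seed Stage parameters
#'   passed through to the respective functions.
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(expression, pathways, out_dir,
                         hallmarks = NULL, drugs = NULL,
                         reference_labels = NULL, contrasts = NULL,
                         impute = TRUE, k = 3, k_grid = 2:8, q = 0.99,
                         rule = "mean", missing_default = 0.5, tol = 1e-6,
                         alpha = 0.05, eps = 1e-3, seed = 1L) {
  paths <- c(expression, pathways, hallmarks, drugs, reference_labels)
  missing_f <- paths[!file.exists(paths)]
  if (length(missing_f) > 0) {
    stop("input file(s) not found: ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()

  counts <- read_expression(expression)
  message("loaded ", nrow(counts), " genes x ", ncol(counts), " cells")
  imp <- if (impute) impute_dropouts(counts, k_grid = k_grid, seed = seed)
         else counts
  norm <- normalize_expression(imp, q = q)
  write_expression(norm, file.path(out_dir, "normalized.tsv"))

  graphs <- read_pathways(pathways[1], pathways[2])
  circuits <- unlist(lapply(graphs, extract_circuits), recursive = FALSE)
  names(circuits) <- vapply(circuits, function(cc) cc$circuit_id, "")
  message(length(circuits), " circuits from ", length(graphs), " pathways")

  acts <- circuit_activities(norm, circuits, rule = rule,
                             missing_default = missing_default, tol = tol)
  write_expression(m_strip(unclass(acts)), file.path(out_dir, "activities.tsv"))
  results$activities <- acts

  clusters <- cluster_cells(acts, k = k, seed = seed)
  write_labels(clusters, file.path(out_dir, "clusters.tsv"))
  results$clusters <- clusters

  ref <- NULL
  if (!is.null(reference_labels)) {
    ref <- read_labels(reference_labels)
    ri <- rand_index(clusters, ref)
    readr::write_tsv(ri, file.path(out_dir, "rand_index.tsv"))
    results$rand_index <- ri
  }

  diffs <- list()
  if (!is.null(ref)) {
    if (is.null(contrasts)) {
      contrasts <- lapply(sort(unique(ref)), function(g) c(g, "rest"))
    }
    for (ct in contrasts) {
      lab <- ifelse(ref == ct[1], as.character(ct[1]),
                    if (identical(ct[2], "rest")) "rest" else NA)
      if (!identical(ct[2], "rest")) {
        lab[ref == ct[2]] <- as.character(ct[2])
      }
      keep <- !is.na(lab)
      dd <- differential_circuits(
        m_strip(unclass(acts))[, keep, drop = FALSE],
        stats::setNames(lab[keep], names(ref)[keep]),
        alpha = alpha, group_order = unique(c(ct[1], setdiff(unique(lab[keep]),
                                                             ct[1]))))
      nm <- paste(ct[1], "vs", ct[2])
      diffs[[nm]] <- dd
      readr::write_tsv(dd$table,
                       file.path(out_dir, paste0("diff_", ct[1], ".tsv")))
    }
    results$differential <- diffs
  }

  if (!is.null(hallmarks)) {
    ann <- read_hallmarks_gmt(hallmarks)
    ch <- annotate_circuits(circuits, ann)
    results$circuit_hallmarks <- ch
    if (length(diffs) > 0) {
      hs <- hallmark_summary(diffs, ch)
      readr::write_tsv(hs$counts, file.path(out_dir, "hallmark_counts.tsv"))
      readr::write_tsv(hs$partition,
                       file.path(out_dir, "hallmark_partition.tsv"))
      results$hallmark_summary <- hs
    }
  }

  if (!is.null(drugs)) {
    dtab <- read_drug_table(drugs)
    baseline <- acts
    pert <- list()
    for (dn in unique(dtab$drug)) {
      pr <- simulate_drug(norm, dtab[dtab$drug == dn, ], circuits,
                          baseline = baseline, eps = eps, seed = seed,
                          rule = rule, missing_default = missing_default,
                          tol = tol)
      readr::write_tsv(pr$responders,
                       file.path(out_dir, paste0("perturbation_", dn, ".tsv")))
      pert[[dn]] <- pr
    }
    results$perturbations <- pert
    if (!is.null(results$circuit_hallmarks)) {
      rep_tab <- drug_report(dtab, circuits, results$circuit_hallmarks)
      readr::write_tsv(rep_tab, file.path(out_dir, "drug_report.tsv"))
      results$drug_report <- rep_tab
    }
  }

  manifest <- list(
    package = "sccircuits",
    version = as.character(utils::packageVersion("sccircuits")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    seed = seed,
    parameters = list(impute = impute, k = k, k_grid = k_grid, q = q,
                      rule = rule, missing_default = missing_default,
                      tol = tol, alpha = alpha, eps = eps),
    inputs = list(expression = expression, pathways = pathways,
                  hallmarks = hallmarks, drugs = drugs,
                  reference_labels = reference_labels),
    counts = list(genes = nrow(counts), cells = ncol(counts),
                  pathways = length(graphs), circuits = length(circuits))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(results)
}
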