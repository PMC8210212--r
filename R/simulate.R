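#' Configuration for the synthetic single-cell signaling study
#'
#' Bundles every knob of the generator: pathway topology (random signed
#' DAGs with multi-gene nodes), clustered negative-binomial counts with
#' expression-dependent dropout, planted differentially active circuits,
#' and a planted drug-resistant subpopulation in which the drug target is
#' lowly expressed but a co-node ligand compensates.
#'
#' Defaults describe a compact but realistic study: 6 pathways of 10 nodes,
#' 3 cell types of 60 cells, negative-binomial counts (dispersion size 3)
#' with a double-exponential dropout model tuned to the 60-80% zero regime
#' typical of plate-based single-cell data, planted circuit shifts of 2.5
#' log2 units on 4 circuits per non-reference type, and a 15% resistant
#' fraction whose target-gene mean is scaled x0.05 while the compensator
#' gene in the same receptor node is scaled x5.
#'
#' @param n_pathways,nodes_per_pathway,edge_density,p_inhibition,genes_per_node
#'   Pathway topology: number of graphs, nodes each, probability of a
#'   forward edge, probability an edge is inhibitory, and the (min, max)
#'   genes carried per node.
#' @param n_background_genes Non-pathway genes carrying the cell-type
#'   clustering signal.
#' @param n_cell_types,cells_per_type Population structure.
#' @param base_mean_log,base_mean_sd Log-normal prior on per-gene baseline
#'   negative-binomial means.
#' @param nb_size Negative-binomial dispersion (size) parameter.
#' @param marker_fraction,marker_log2fc Fraction of background genes
#'   upregulated per cell type and their log2 fold change.
#' @param delta_log2fc Log2 shift applied to the member genes of each
#'   planted circuit in its cell type.
#' @param circuits_per_type Planted differentially active circuits per
#'   non-reference cell type.
#' @param libsize_sd SD of the log-normal library-size factors.
#' @param dropout_lambda Dropout decay: a count with underlying mean
#'   \eqn{\mu} is zeroed with probability
#'   \eqn{\exp(-\lambda \log(1+\mu)^2)}.
#' @param resistant_fraction Fraction of the last cell type planted as
#'   drug-resistant.
#' @param target_gene,compensator_gene Symbols placed together in the
#'   receptor node of the designated drug pathway.
#' @param target_mean,compensator_mean Baseline means of those two genes.
#' @param target_scale,compensator_scale Mean multipliers applied in
#'   resistant cells.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_pathways = 6, nodes_per_pathway = 10,
                              edge_density = 0.25, p_inhibition = 0.15,
                              genes_per_node = c(1, 3),
                              n_background_genes = 300,
                              n_cell_types = 3, cells_per_type = 60,
                              base_mean_log = log(4), base_mean_sd = 1,
                              nb_size = 3,
                              marker_fraction = 0.1, marker_log2fc = 1.5,
                              delta_log2fc = 2.5, circuits_per_type = 4,
                              libsize_sd = 0.2, dropout_lambda = 0.12,
                              resistant_fraction = 0.15,
                              target_gene = "VEGFA",
                              compensator_gene = "PDGFD",
                              target_mean = 30, compensator_mean = 10,
                              target_scale = 0.05, compensator_scale = 5) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_pathways >= 1, cfg$nodes_per_pathway >= 3,
            cfg$edge_density > 0, cfg$edge_density <= 1,
            cfg$p_inhibition >= 0, cfg$p_inhibition <= 1,
            length(cfg$genes_per_node) == 2,
            cfg$n_cell_types >= 1, cfg$cells_per_type >= 2,
            cfg$dropout_lambda >= 0,
            cfg$resistant_fraction >= 0, cfg$resistant_fraction <= 1)
  structure(cfg, class = "simulation_config")
}

#' Generate random signed pathway graphs
#'
#' Draws `n_pathways` random DAGs (nodes ordered, forward edges with the
#' configured density, inhibition signs with probability `p_inhibition`),
#' each with at least one source, one sink, and one sink reachable from a
#' source so circuit extraction always yields a circuit. The first pathway
#' is the designated drug pathway: its first node is a source carrying both
#' the target and the compensator gene, wired by activation edges into the
#' rest of the graph (the structure in which a co-node ligand can
#' substitute the drugged gene's signaling role).
#'
#' @param cfg A [simulation_config()].
#' @param seed Integer seed.
#' @param max_retries Redraws allowed per pathway before erroring.
#' @return Named list of `pathway_graph` objects.
#' @export
generate_pathways <- function(cfg, seed, max_retries = 100) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(seed)
  graphs <- list()
  for (p in seq_len(cfg$n_pathways)) {
    pid <- sprintf("PW%02d", p)
    for (attempt in seq_len(max_retries)) {
      m <- cfg$nodes_per_pathway
      ids <- sprintf("N%02d", seq_len(m))
      pairs <- which(upper.tri(matrix(TRUE, m, m)), arr.ind = TRUE)
      keep <- stats::runif(nrow(pairs)) < cfg$edge_density
      ed <- tibble::tibble(
        source = ids[pairs[keep, "row"]],
        target = ids[pairs[keep, "col"]],
        sign = ifelse(stats::runif(sum(keep)) < cfg$p_inhibition,
                      "inhibition", "activation")
      )
      if (p == 1) {
        # drug pathway: node 1 must feed the graph via activation edges
        if (!any(ed$source == ids[1])) {
          ed <- dplyr::bind_rows(
            ed, tibble::tibble(source = ids[1], target = ids[2],
                               sign = "activation"))
        }
        ed$sign[ed$source == ids[1]] <- "activation"
      }
      ed <- dplyr::distinct(ed, .data$source, .data$target, .keep_all = TRUE)
      indeg <- ids %in% ed$target
      outdeg <- ids %in% ed$source
      sources <- ids[!indeg]
      sinks <- ids[!outdeg]
      if (length(sources) == 0 || length(sinks) == 0 || nrow(ed) == 0) next
      ig <- igraph::graph_from_data_frame(ed[, c("source", "target")],
                                          directed = TRUE,
                                          vertices = data.frame(name = ids))
      reach <- unique(unlist(lapply(sources, function(s) {
        names(igraph::subcomponent(ig, s, mode = "out"))
      })))
      if (!any(sinks %in% reach)) next

      ng <- sample(seq(cfg$genes_per_node[1], cfg$genes_per_node[2]),
                   m, replace = TRUE)
      genes <- lapply(seq_len(m), function(n) {
        sprintf("%sN%02dG%d", pid, n, seq_len(ng[n]))
      })
      if (p == 1) genes[[1]] <- c(cfg$target_gene, cfg$compensator_gene)
      nodes <- tibble::tibble(
        node_id = ids,
        genes = genes,
        label = ids,
        is_receptor = NA, is_effector = NA
      )
      graphs[[pid]] <- pathway_graph(pid, nodes, ed)
      break
    }
    if (is.null(graphs[[pid]])) {
      stop("could not generate a pathway with a source-reachable sink in ",
           max_retries, " attempts; raise edge_density", call. = FALSE)
    }
  }
  graphs
}

#' Generate clustered single-cell counts with full ground truth
#'
#' Simulates the count matrix the pipeline starts from. Per-gene baseline
#' means are log-normal; each cell type upregulates its own random subset
#' of background genes (the clustering signal) and the member genes of its
#' planted circuits (the differential-activity signal, injected on gene
#' means so the propagation model is genuinely exercised). Counts are
#' negative binomial with log-normal library-size factors; dropout zeroes
#' each entry with probability \eqn{\exp(-\lambda\log(1+\mu)^2)}, so
#' lowly expressed genes drop out most. A configured fraction of the last
#' cell type is planted drug-resistant: the target gene's mean is scaled
#' down and the co-node compensator's mean scaled up.
#'
#' @param cfg A [simulation_config()].
#' @param graphs Pathway graphs from [generate_pathways()].
#' @param seed Integer seed.
#' @return A `sc_simulation` list: `counts` (genes x cells, post-dropout),
#'   and `truth` with `cell_types`, `resistant_cells`, `planted`
#'   (type x circuit), `pre_dropout` matrix, `dropout_mask`, `circuits`,
#'   `hallmarks`, `drugs`, and the config.
#' @export
generate_cells <- function(cfg, graphs, seed) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(seed + 1L)
  circuits <- unlist(lapply(graphs, extract_circuits), recursive = FALSE)
  names(circuits) <- vapply(circuits, function(cc) cc$circuit_id, "")

  pw_genes <- unique(unlist(lapply(graphs, function(g) unlist(g$nodes$genes))))
  bg_genes <- sprintf("BG%03d", seq_len(cfg$n_background_genes))
  genes <- c(pw_genes, bg_genes)
  n_genes <- length(genes)

  types <- paste0("type", seq_len(cfg$n_cell_types))
  cells <- sprintf("cell%04d", seq_len(cfg$n_cell_types * cfg$cells_per_type))
  cell_types <- stats::setNames(rep(types, each = cfg$cells_per_type), cells)

  base_mu <- stats::setNames(
    stats::rlnorm(n_genes, meanlog = cfg$base_mean_log,
                  sdlog = cfg$base_mean_sd), genes)
  base_mu[cfg$target_gene] <- cfg$target_mean
  base_mu[cfg$compensator_gene] <- cfg$compensator_mean

  # per-type mean multipliers: background markers + planted circuit genes
  type_factor <- matrix(1, n_genes, cfg$n_cell_types,
                        dimnames = list(genes, types))
  n_marker <- round(cfg$marker_fraction * cfg$n_background_genes)
  for (t in seq_len(cfg$n_cell_types)) {
    markers <- sample(bg_genes, n_marker)
    type_factor[markers, t] <- type_factor[markers, t] * 2^cfg$marker_log2fc
  }

  # planted circuits: non-reference types get shifted circuit genes,
  # drawn from non-drug pathways so the drug signal stays clean
  plantable <- circuits[vapply(circuits, function(cc)
    cc$pathway_id != names(graphs)[1], TRUE)]
  planted <- tibble::tibble(type = character(), circuit_id = character())
  if (cfg$n_cell_types > 1 && cfg$circuits_per_type > 0 &&
      length(plantable) > 0) {
    pool <- sample(names(plantable))
    idx <- 1L
    for (t in seq(2, cfg$n_cell_types)) {
      take <- pool[((idx - 1) %% length(pool)) + seq_len(
        min(cfg$circuits_per_type, length(pool))) ]
      take <- take[!is.na(take)]
      idx <- idx + length(take)
      for (cid in take) {
        cg <- unique(unlist(circuits[[cid]]$node_genes))
        cg <- setdiff(cg, c(cfg$target_gene, cfg$compensator_gene))
        type_factor[cg, t] <- type_factor[cg, t] * 2^cfg$delta_log2fc
        planted <- dplyr::add_row(planted, type = types[t], circuit_id = cid)
      }
    }
  }

  # resistant subpopulation of the last type
  n_res <- round(cfg$resistant_fraction * cfg$cells_per_type)
  res_cells <- sample(cells[cell_types == types[cfg$n_cell_types]], n_res)

  libsize <- stats::setNames(
    stats::rlnorm(length(cells), meanlog = 0, sdlog = cfg$libsize_sd), cells)

  mu <- base_mu * type_factor[, match(cell_types, types), drop = FALSE]
  colnames(mu) <- cells
  mu[cfg$target_gene, res_cells] <- mu[cfg$target_gene, res_cells] *
    cfg$target_scale
  mu[cfg$compensator_gene, res_cells] <- mu[cfg$compensator_gene, res_cells] *
    cfg$compensator_scale
  mu <- sweep(mu, 2, libsize, `*`)

  counts <- matrix(
    stats::rnbinom(length(mu), mu = as.vector(mu), size = cfg$nb_size),
    nrow = n_genes, dimnames = list(genes, cells))
  pre_dropout <- counts
  # lambda = 0 means no dropout (the decay formula's degenerate limit)
  p_drop <- if (cfg$dropout_lambda == 0) 0 else
    exp(-cfg$dropout_lambda * log1p(mu)^2)
  mask <- matrix(stats::runif(length(mu)) < p_drop, nrow = n_genes,
                 dimnames = list(genes, cells))
  counts[mask] <- 0

  hallmarks <- generate_hallmarks(graphs, seed = seed + 2L)
  drugs <- drug_spec(paste0("anti_", cfg$target_gene), cfg$target_gene,
                     "inhibitor")

  structure(list(
    counts = counts,
    truth = list(cell_types = cell_types,
                 resistant_cells = res_cells,
                 planted = planted,
                 pre_dropout = pre_dropout,
                 dropout_mask = mask & pre_dropout > 0,
                 circuits = circuits,
                 hallmarks = hallmarks,
                 drugs = drugs,
                 libsize = libsize,
                 config = cfg,
                 seed = seed)
  ), class = "sc_simulation")
}

#' Random effector-gene hallmark annotation
#'
#' Assigns each pathway effector-node gene, with probability 0.7, one or
#' two of the ten canonical cancer hallmarks, producing the GMT-shaped
#' annotation the hallmark summary consumes.
#'
#' @param graphs Pathway graphs.
#' @param seed Integer seed.
#' @return `hallmark_annotation` tibble (`hallmark`, `gene`).
#' @export
generate_hallmarks <- function(graphs, seed) {
  set.seed(seed)
  hm <- c("Sustaining proliferative signaling", "Evading growth suppressors",
          "Resisting cell death", "Enabling replicative immortality",
          "Inducing angiogenesis", "Activating invasion and metastasis",
          "Genome instability and mutation", "Tumor promoting inflammation",
          "Deregulating cellular energetics", "Avoiding immune destruction")
  circuits <- unlist(lapply(graphs, extract_circuits), recursive = FALSE)
  eff_genes <- unique(unlist(lapply(circuits, function(cc) {
    cc$node_genes[[cc$effector_node]]
  })))
  rows <- purrr::map_dfr(eff_genes, function(g) {
    if (stats::runif(1) > 0.7) return(NULL)
    tibble::tibble(hallmark = sample(hm, sample(1:2, 1)), gene = g)
  })
  structure(dplyr::distinct(rows), class = c("hallmark_annotation",
                                             class(rows)))
}

#' Run the full synthetic study generator
#'
#' @param cfg A [simulation_config()] (default configuration if omitted).
#' @param seed Integer seed (mandatory; the single source of randomness).
#' @return A `sc_simulation`, see [generate_cells()].
#' @export
simulate_study <- function(cfg = simulation_config(), seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  graphs <- generate_pathways(cfg, seed)
  sim <- generate_cells(cfg, graphs, seed)
  sim$graphs <- graphs
  sim
}

#' @export
print.sc_simulation <- function(x, ...) {
  cat("<sc_simulation> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " cells; ", length(unique(x$truth$cell_types)), " cell types, ",
      length(x$truth$circuits), " circuits, ",
      length(x$truth$resistant_cells), " resistant cells; ",
      round(100 * mean(x$counts == 0)), "% zeros\n", sep = "")
  invisible(x)
}

#' Write a complete synthetic fixture set to a directory
#'
#' Emits every input the pipeline reads: expression (TSV and MatrixMarket
#' with row/column sidecars), pathway edge and node TSVs, the hallmark GMT,
#' the drug table, and a ground-truth JSON (cell types, planted circuits,
#' resistant cells).
#'
#' @param sim A `sc_simulation` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "sc_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(sim$counts, file.path(dir, "counts.tsv"))
  write_expression(sim$counts, file.path(dir, "counts.mtx"))
  write_pathways(sim$graphs, file.path(dir, "pathway_edges.tsv"),
                 file.path(dir, "pathway_nodes.tsv"))
  write_hallmarks_gmt(sim$truth$hallmarks, file.path(dir, "hallmarks.gmt"))
  readr::write_tsv(sim$truth$drugs, file.path(dir, "drugs.tsv"))
  truth <- list(
    cell_types = as.list(sim$truth$cell_types),
    resistant_cells = sim$truth$resistant_cells,
    planted = sim$truth$planted,
    seed = sim$truth$seed
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
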