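#' Read effector-gene to cancer-hallmark annotations from a GMT file
#'
#' GMT is the tab-delimited gene-set format: set name, description, then
#' member gene symbols. Here each set is a cancer hallmark (or free-form
#' cell function) and its members are effector genes. Hallmark names are
#' normalized (trimmed, internal whitespace collapsed); gene symbols are
#' kept verbatim but matched case-insensitively downstream.
#'
#' @param path Path to the GMT file.
#' @return A `hallmark_annotation`: tibble with columns `hallmark`, `gene`.
#' @export
read_hallmarks_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  rows <- purrr::map_dfr(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop("malformed GMT line (need name, description, >=1 gene): ",
           substr(l, 1, 60), call. = FALSE)
    }
    tibble::tibble(hallmark = normalize_hallmark(f[1]),
                   gene = f[-(1:2)][nzchar(f[-(1:2)])])
  })
  structure(dplyr::distinct(rows), class = c("hallmark_annotation",
                                             class(rows)))
}

normalize_hallmark <- function(x) gsub("\\s+", " ", trimws(x))

#' Write a hallmark annotation to GMT
#'
#' @param ann Tibble with `hallmark`, `gene` columns.
#' @param path Output path.
#' @export
write_hallmarks_gmt <- function(ann, path) {
  sets <- split(ann$gene, ann$hallmark)
  lines <- vapply(names(sets), function(h) {
    paste(c(h, "na", sets[[h]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Annotate circuits with cancer hallmarks via their effector genes
#'
#' A circuit inherits the union of the hallmarks annotated to the genes in
#' its effector node (effector-only linkage); circuits whose effector genes
#' carry no annotation map to the empty set and are excluded from hallmark
#' tables. Gene matching is case-insensitive.
#'
#' @param circuits List of `circuit` objects.
#' @param ann Hallmark annotation tibble (`hallmark`, `gene`), e.g. from
#'   [read_hallmarks_gmt()].
#' @return Tibble with columns `circuit_id`, `hallmark` (zero rows for
#'   unannotated circuits).
#' @export
annotate_circuits <- function(circuits, ann) {
  gene_up <- toupper(ann$gene)
  purrr::map_dfr(circuits, function(cc) {
    eff_genes <- toupper(cc$node_genes[[cc$effector_node]])
    hits <- unique(ann$hallmark[gene_up %in% eff_genes])
    if (length(hits) == 0) return(tibble::tibble(circuit_id = character(),
                                                 hallmark = character()))
    tibble::tibble(circuit_id = cc$circuit_id, hallmark = hits)
  })
}

#' Summarize differentially active circuits by cancer hallmark
#'
#' Produces the per-group hallmark breakdown of significant circuits: the
#' circuits significant in every group ("common"), each group's extra
#' circuits beyond the common core ("specific" = significant in that group
#' minus common to all, not exclusive-to-group), and both percentage views
#' (share of the group's significant annotated circuits, and share of all
#' circuits annotated to that hallmark). A circuit annotated to k hallmarks
#' contributes to k table cells; direction (UP/DOWN) is retained per
#' circuit for heatmap-style output.
#'
#' @param diff_tables Named list: group name -> `circuit_diff` object or a
#'   tidy differential table with `circuit_id` and `significant` columns.
#' @param circuit_hallmarks Tibble (`circuit_id`, `hallmark`) covering all
#'   circuits, e.g. from [annotate_circuits()].
#' @return A `hallmark_summary` object: `$counts` (group x hallmark counts
#'   and percentages), `$partition` (hallmark x common/group-specific
#'   counts), `$details` (per circuit x hallmark x group significance and
#'   direction), plus the interpretation note in `$meta`.
#' @export
hallmark_summary <- function(diff_tables, circuit_hallmarks) {
  if (length(diff_tables) < 1) stop("need >= 1 group", call. = FALSE)
  if (is.null(names(diff_tables))) {
    names(diff_tables) <- paste0("group", seq_along(diff_tables))
  }
  tabs <- purrr::map(diff_tables, function(x) {
    if (inherits(x, "circuit_diff")) x$table else tibble::as_tibble(x)
  })
  sig_sets <- purrr::map(tabs, ~ .x$circuit_id[.x$significant])
  common <- Reduce(intersect, sig_sets)

  ann_by_circuit <- circuit_hallmarks
  annotated_totals <- ann_by_circuit %>% dplyr::count(.data$hallmark,
                                                      name = "n_annotated")

  details <- purrr::imap_dfr(tabs, function(tab, grp) {
    tab %>%
      dplyr::inner_join(ann_by_circuit, by = "circuit_id") %>%
      dplyr::mutate(group = grp) %>%
      dplyr::select("group", "circuit_id", "hallmark", "direction",
                    "significant")
  })

  counts <- details %>%
    dplyr::filter(.data$significant) %>%
    dplyr::count(.data$group, .data$hallmark, name = "n_significant")
  sig_annotated_per_group <- details %>%
    dplyr::filter(.data$significant) %>%
    dplyr::distinct(.data$group, .data$circuit_id) %>%
    dplyr::count(.data$group, name = "n_sig_annotated")
  counts <- counts %>%
    dplyr::left_join(sig_annotated_per_group, by = "group") %>%
    dplyr::left_join(annotated_totals, by = "hallmark") %>%
    dplyr::mutate(
      pct_of_group_significant = 100 * .data$n_significant /
        .data$n_sig_annotated,
      pct_of_annotated = 100 * .data$n_significant / .data$n_annotated
    )

  partition <- details %>%
    dplyr::filter(.data$significant) %>%
    dplyr::mutate(class = ifelse(.data$circuit_id %in% common, "common",
                                 .data$group)) %>%
    dplyr::distinct(.data$class, .data$circuit_id, .data$hallmark) %>%
    dplyr::count(.data$hallmark, .data$class, name = "n") %>%
    tidyr::pivot_wider(names_from = "class", values_from = "n",
                       values_fill = 0L)

  structure(list(
    counts = counts,
    partition = partition,
    details = details,
    common_circuits = common,
    meta = list(specific_definition =
                  "significant in group minus common-to-all-groups")
  ), class = "hallmark_summary")
}

#' @export
print.hallmark_summary <- function(x, ...) {
  cat("<hallmark_summary> ", length(unique(x$counts$group)), " group(s), ",
      length(unique(x$counts$hallmark)), " hallmark(s); ",
      length(x$common_circuits), " circuits significant in all groups\n",
      sep = "")
  print(x$partition)
  invisible(x)
}

#' @rdname hallmark_summary
#' @param x A `hallmark_summary` object.
#' @param ... Unused.
#' @method tidy hallmark_summary
#' @export
tidy.hallmark_summary <- function(x, ...) x$counts
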