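#' Coerce expression input to a genes x cells numeric matrix
#'
#' Accepts a matrix with gene row names, or a data frame whose first column
#' holds gene symbols (remaining columns one per cell), the tabular form the
#' readers return. Duplicate gene symbols and negative values are rejected.
#'
#' @param x Matrix or data frame.
#' @return Numeric matrix, genes as rows.
#' @export
as_expression_matrix <- function(x) {
  if (is.data.frame(x)) {
    genes <- as.character(x[[1]])
    m <- as.matrix(x[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- genes
    x <- m
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expression must be a numeric matrix or a data frame with a gene ",
         "column first", call. = FALSE)
  }
  if (is.null(rownames(x))) stop("expression matrix needs gene row names",
                                 call. = FALSE)
  dup <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup) > 0) {
    stop("duplicate gene symbol(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(x < 0)) stop("negative expression values are not allowed",
                       call. = FALSE)
  x
}

#' Impute dropout zeros by consensus-cluster averaging
#'
#' Single-cell counts are riddled with dropout events: zeros recorded for
#' transcripts that were expressed but not captured. Because the propagation
#' model treats a zero as a switched-off node, distinguishing unmeasured from
#' unexpressed is crucial. This imputer follows the consensus-clustering
#' recipe: cells are clustered several ways (every `k` in `k_grid`, crossed
#' with Euclidean-on-log-counts and Spearman correlation distances, using
#' Ward linkage), and each zero entry is replaced by the average over all
#' clusterings of the within-cluster mean of that gene (cluster means include
#' the observed zeros). Nonzero entries are never altered, so an all-zero
#' gene stays all-zero.
#'
#' @param counts Count matrix (genes x cells) or equivalent data frame.
#' @param k_grid Integer vector of cluster numbers to average over.
#' @param seed Integer seed (the hierarchical clusterings are deterministic;
#'   the seed is recorded for provenance and future stochastic backends).
#' @return Imputed matrix, same dimensions, `stage` attribute `"imputed"`.
#' @export
impute_dropouts <- function(counts, k_grid = 2:8, seed = 1L) {
  m <- as_expression_matrix(counts)
  if (length(k_grid) == 0) stop("k_grid must be non-empty", call. = FALSE)
  if (any(k_grid >= ncol(m))) {
    stop("k_grid contains k >= number of cells (", ncol(m), ")",
         call. = FALSE)
  }
  if (any(k_grid < 1)) stop("k_grid must be positive", call. = FALSE)
  zeros <- m == 0
  if (!any(zeros)) {
    out <- m
    attr(out, "stage") <- "imputed"
    return(out)
  }

  lg <- log1p(m)
  d_euc <- stats::dist(t(lg))
  suppressWarnings(cs <- stats::cor(m, method = "spearman"))
  cs[!is.finite(cs)] <- 0
  d_spe <- stats::as.dist(1 - cs)

  imputed_sum <- matrix(0, nrow(m), ncol(m))
  n_clusterings <- 0L
  for (d in list(d_euc, d_spe)) {
    hc <- stats::hclust(d, method = "ward.D2")
    for (k in k_grid) {
      cl <- stats::cutree(hc, k = k)
      # per-gene per-cluster means, expanded back to cells
      for (g in seq_len(max(cl))) {
        cells_g <- which(cl == g)
        mu <- rowMeans(m[, cells_g, drop = FALSE])
        imputed_sum[, cells_g] <- imputed_sum[, cells_g] + mu
      }
      n_clusterings <- n_clusterings + 1L
    }
  }
  fill <- imputed_sum / n_clusterings
  out <- m
  out[zeros] <- fill[zeros]
  attr(out, "stage") <- "imputed"
  out
}

#' Normalize expression for the propagation model
#'
#' Applies the preprocessing the activity model requires: `log(1+x)`
#' transform, truncation at the `q` quantile (type-7, linear interpolation;
#' values above the quantile are set to it), then min-max scaling to
#' \[0,1\]. Truncation and scaling are per gene by default so that every
#' gene's dynamic range is usable by the model; `per_gene = FALSE` switches
#' both to matrix-global. Constant genes map to all-zero rows.
#'
#' @param m Count or imputed matrix (genes x cells) or data frame.
#' @param q Truncation quantile in (0, 1\]; default 0.99.
#' @param per_gene Truncate and scale per gene (default) or globally.
#' @return Matrix with values in \[0,1\], `stage` attribute `"normalized"`.
#' @export
normalize_expression <- function(m, q = 0.99, per_gene = TRUE) {
  m <- as_expression_matrix(m)
  if (!(q > 0 && q <= 1)) stop("q must be in (0, 1]", call. = FALSE)
  lg <- log1p(m)
  if (per_gene) {
    caps <- apply(lg, 1, stats::quantile, probs = q, type = 7, names = FALSE)
    lg <- pmin(lg, caps)
    rmin <- apply(lg, 1, min)
    rmax <- apply(lg, 1, max)
    rng <- rmax - rmin
    rng[rng == 0] <- 1  # constant genes -> all zeros
    out <- (lg - rmin) / rng
  } else {
    cap <- stats::quantile(lg, probs = q, type = 7, names = FALSE)
    lg <- pmin(lg, cap)
    rng <- max(lg) - min(lg)
    if (rng == 0) rng <- 1
    out <- (lg - min(lg)) / rng
  }
  dimnames(out) <- dimnames(m)
  attr(out, "stage") <- "normalized"
  out
}

#' Cluster cells on a low-dimensional embedding
#'
#' Embeds cells in two dimensions and k-means-clusters the embedding. The
#' default embedding is the first two principal components, which is
#' deterministic; any externally computed cells x 2 embedding (e.g. t-SNE
#' coordinates) is accepted instead.
#'
#' @param m Expression or activity matrix (features x cells) or data frame.
#' @param k Number of clusters (1 <= k <= n cells).
#' @param seed Integer seed for the k-means initialization.
#' @param embedding `"pca"` or a cells x 2 numeric matrix/data frame with
#'   cell row names (or a `cell` column).
#' @param nstart Random restarts for k-means.
#' @return Integer cluster labels named by cell, with attributes `k`,
#'   `seed`, and the `embedding` used.
#' @export
cluster_cells <- function(m, k, seed = 1L, embedding = "pca", nstart = 10L) {
  if (is.character(embedding) && identical(embedding, "pca")) {
    m <- if (inherits(m, "circuit_activity")) unclass(m) else
      as_expression_matrix(m)
    if (k > ncol(m)) stop("k (", k, ") exceeds number of cells (", ncol(m),
                          ")", call. = FALSE)
    keep <- apply(m, 1, stats::var) > 0
    pc <- stats::prcomp(t(m[keep, , drop = FALSE]), center = TRUE,
                        scale. = FALSE, rank. = 2)
    emb <- pc$x[, 1:2, drop = FALSE]
  } else {
    emb <- embedding
    if (is.data.frame(emb)) {
      if ("cell" %in% names(emb)) {
        rn <- emb$cell
        emb <- as.matrix(emb[, setdiff(names(emb), "cell"), drop = FALSE])
        rownames(emb) <- rn
      } else emb <- as.matrix(emb)
    }
    if (ncol(emb) != 2) stop("external embedding must be cells x 2",
                             call. = FALSE)
    if (k > nrow(emb)) stop("k exceeds number of cells", call. = FALSE)
  }
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k == 1) {
    labels <- stats::setNames(rep(1L, nrow(emb)), rownames(emb))
  } else {
    old <- .Random.seed_exists()
    set.seed(seed)
    km <- stats::kmeans(emb, centers = k, nstart = nstart, iter.max = 50)
    labels <- stats::setNames(as.integer(km$cluster), rownames(emb))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  structure(labels, k = as.integer(k), seed = as.integer(seed),
            embedding = emb, class = c("cell_clusters", "integer"))
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

#' @export
print.cell_clusters <- function(x, ...) {
  cat("<cell_clusters> ", length(x), " cells in ", attr(x, "k"),
      " clusters\n", sep = "")
  print(table(unclass(x)))
  invisible(x)
}

#' Rand index and adjusted Rand index between two partitions
#'
#' The Rand index is the fraction of cell pairs treated consistently by two
#' partitions (grouped together in both, or apart in both) out of all
#' \eqn{\binom{n}{2}} pairs; the adjusted version corrects for chance
#' agreement. Both are label-permutation invariant.
#'
#' @param a,b Cluster labels: named integer vectors (e.g. from
#'   [cluster_cells()]) over the same cell set, or unnamed vectors of equal
#'   length taken to be in matching order.
#' @return One-row tibble with `rand_index` and `adjusted_rand`.
#' @export
rand_index <- function(a, b) {
  a_v <- unclass(a); b_v <- unclass(b)
  if (!is.null(names(a_v)) && !is.null(names(b_v))) {
    if (!setequal(names(a_v), names(b_v))) {
      stop("partitions cover different cell sets", call. = FALSE)
    }
    b_v <- b_v[names(a_v)]
  } else if (length(a_v) != length(b_v)) {
    stop("partitions cover different cell sets", call. = FALSE)
  }
  n <- length(a_v)
  if (n < 2) stop("need at least 2 cells", call. = FALSE)
  tab <- table(a_v, b_v)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  total <- ch2(n)
  ri <- (total + 2 * sum_ij - sum_a - sum_b) / total
  expected <- sum_a * sum_b / total
  max_idx <- (sum_a + sum_b) / 2
  ari <- if (max_idx == expected) 1 else (sum_ij - expected) / (max_idx - expected)
  tibble::tibble(rand_index = ri, adjusted_rand = ari)
}
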