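#' Fit an empirical-Bayes prior to per-circuit sample variances
#'
#' Method-of-moments fit of a scaled inverse-chi-squared prior
#' \eqn{s_0^2, d_0} to the observed sample variances, working on the log
#' scale: if \eqn{s_g^2 \sim s_0^2 \chi^2_{d}/d} then
#' \eqn{e_g = \log s_g^2 - \psi(d/2) + \log(d/2)} has mean
#' \eqn{\log s_0^2 + \psi(d_0/2) - \log(d_0/2)} and excess variance
#' \eqn{\psi'(d_0/2)} over \eqn{\psi'(d/2)}. When the observed variances
#' show no excess dispersion the prior degrees of freedom are infinite and
#' every variance shrinks completely to \eqn{s_0^2}. No intensity trend is
#' fitted (simple moments only).
#'
#' @param sample_variances Per-circuit sample variances (>= 2 positive).
#' @param residual_df Residual degrees of freedom of each variance
#'   (scalar, e.g. \eqn{n_1+n_2-2}).
#' @return List with `d0` (prior df, possibly `Inf`) and `s0_sq`.
#' @export
fit_eb_prior <- function(sample_variances, residual_df) {
  s2 <- sample_variances[is.finite(sample_variances) & sample_variances > 0]
  if (sum(sample_variances > 0, na.rm = TRUE) < 2) {
    stop("need at least 2 circuits with positive variance", call. = FALSE)
  }
  d <- residual_df
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  e_mean <- mean(e)
  e_var <- stats::var(e)
  excess <- e_var - trigamma(d / 2)
  if (!is.finite(excess) || excess <= 0) {
    # no excess dispersion: infinite prior df, prior variance = mean variance
    return(list(d0 = Inf, s0_sq = mean(s2)))
  }
  d0 <- 2 * trigamma_inverse(excess)
  s0_sq <- exp(e_mean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

# Solve trigamma(x) = y by Newton iteration on 1/trigamma (monotone convex).
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Moderated two-sample t test for one circuit
#'
#' Pooled two-sample t statistic whose variance is shrunk toward the
#' empirical-Bayes prior:
#' \eqn{\tilde{s}^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)} with
#' \eqn{d_g = n_1 + n_2 - 2}, \eqn{t = \Delta \bar{x} /
#' \sqrt{\tilde{s}^2 (1/n_1 + 1/n_2)}}, two-sided p from a t distribution
#' with \eqn{d_0 + d_g} degrees of freedom. With `d0 = 0` this is exactly
#' the classical pooled t test; with `d0 = Inf` the variance is replaced by
#' `s0_sq` and the reference distribution is normal.
#'
#' @param g1,g2 Numeric activity vectors for the two groups (each length
#'   >= 2).
#' @param d0 Prior degrees of freedom (>= 0, may be `Inf`).
#' @param s0_sq Prior variance.
#' @param var_floor Lower bound applied to the shrunk variance.
#' @return List with `t`, `p`, `delta` (mean of `g1` minus mean of `g2`),
#'   `s2_pooled` and `s2_post`.
#' @export
moderated_t <- function(g1, g2, d0 = 0, s0_sq = 0, var_floor = 1e-12) {
  n1 <- length(g1); n2 <- length(g2)
  if (n1 < 2 || n2 < 2) stop("each group needs >= 2 cells", call. = FALSE)
  dg <- n1 + n2 - 2
  delta <- mean(g1) - mean(g2)
  s2 <- (sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)) / dg
  if (is.infinite(d0)) {
    s2_post <- s0_sq
    df <- Inf
  } else {
    s2_post <- (d0 * s0_sq + dg * s2) / (d0 + dg)
    df <- d0 + dg
  }
  if (s2_post <= var_floor) {
    if (abs(delta) < .Machine$double.eps^0.5) {
      return(list(t = 0, p = 1, delta = delta, s2_pooled = s2,
                  s2_post = s2_post))
    }
    s2_post <- var_floor
  }
  tval <- delta / sqrt(s2_post * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(tval), df = df)
  list(t = tval, p = p, delta = delta, s2_pooled = s2, s2_post = s2_post)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement; input order is
#' preserved.
#'
#' @param pvals Numeric p-values in \[0,1\].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0,1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Differentially active circuits between two cell groups
#'
#' Runs the moderated-t workflow over a circuit activity matrix: the
#' empirical-Bayes variance prior is fitted across all circuits
#' ([fit_eb_prior()]), each circuit is tested with the moderated t
#' ([moderated_t()]), and p-values are FDR-adjusted ([bh_fdr()]). Circuits
#' constant in both groups with equal means get p = 1 by convention.
#'
#' @param acts `circuit_activity` matrix (circuits x cells) or plain matrix
#'   with circuit row names.
#' @param labels Two-group labels over the matrix columns: a named vector
#'   (names = cells) or a vector in column order; exactly two distinct
#'   values, each with >= 2 cells.
#' @param alpha FDR significance level (default 0.05).
#' @param group_order Optional length-2 vector fixing which label is group 1
#'   (differences are group1 - group2); defaults to sorted label order.
#' @return A `circuit_diff` object; `tidy()` returns the per-circuit table
#'   (`circuit_id`, `delta`, `t`, `p`, `q`, `direction`, `significant`),
#'   `glance()` the prior fit and call counts.
#' @export
differential_circuits <- function(acts, labels, alpha = 0.05,
                                  group_order = NULL) {
  m <- if (inherits(acts, "circuit_activity")) unclass(m_strip(acts)) else
    as.matrix(acts)
  lab <- unclass(labels)
  if (!is.null(names(lab))) {
    if (!setequal(names(lab), colnames(m))) {
      stop("label names do not match activity matrix cells", call. = FALSE)
    }
    lab <- lab[colnames(m)]
  } else if (length(lab) != ncol(m)) {
    stop("labels length does not match number of cells", call. = FALSE)
  }
  groups <- if (is.null(group_order)) sort(unique(lab)) else group_order
  if (length(unique(lab)) != 2 || length(groups) != 2) {
    stop("exactly two groups required", call. = FALSE)
  }
  i1 <- which(lab == groups[1]); i2 <- which(lab == groups[2])
  if (length(i1) < 2 || length(i2) < 2) {
    stop("each group needs >= 2 cells", call. = FALSE)
  }
  n1 <- length(i1); n2 <- length(i2); dg <- n1 + n2 - 2

  g1m <- m[, i1, drop = FALSE]; g2m <- m[, i2, drop = FALSE]
  mu1 <- rowMeans(g1m); mu2 <- rowMeans(g2m)
  ss1 <- rowSums((g1m - mu1)^2); ss2 <- rowSums((g2m - mu2)^2)
  s2 <- (ss1 + ss2) / dg
  if (all(s2 <= 0)) stop("all circuit variances are zero; degenerate data",
                         call. = FALSE)
  prior <- fit_eb_prior(s2, dg)

  res <- lapply(seq_len(nrow(m)), function(i) {
    moderated_t(g1m[i, ], g2m[i, ], d0 = prior$d0, s0_sq = prior$s0_sq)
  })
  p <- vapply(res, `[[`, 1.0, "p")
  delta <- mu1 - mu2
  q <- bh_fdr(p)
  table <- tibble::tibble(
    circuit_id = rownames(m) %||% as.character(seq_len(nrow(m))),
    delta = delta,
    t = vapply(res, `[[`, 1.0, "t"),
    p = p,
    q = q,
    direction = ifelse(delta >= 0, "UP", "DOWN"),
    significant = q < alpha
  )
  structure(list(table = table, prior = prior, alpha = alpha,
                 groups = as.character(groups),
                 n = c(n1 = n1, n2 = n2)),
            class = "circuit_diff")
}

m_strip <- function(x) {
  attributes(x) <- attributes(x)[c("dim", "dimnames")]
  x
}

#' @export
print.circuit_diff <- function(x, ...) {
  cat("<circuit_diff> ", nrow(x$table), " circuits; ",
      sum(x$table$significant), " significant at FDR < ", x$alpha,
      " (", x$groups[1], " vs ", x$groups[2], ")\n", sep = "")
  cat("  prior: d0 = ", signif(x$prior$d0, 4), ", s0^2 = ",
      signif(x$prior$s0_sq, 4), "\n", sep = "")
  invisible(x)
}

#' @rdname differential_circuits
#' @param x A `circuit_diff` object.
#' @param ... Unused.
#' @method tidy circuit_diff
#' @export
tidy.circuit_diff <- function(x, ...) x$table

#' @rdname differential_circuits
#' @method glance circuit_diff
#' @export
glance.circuit_diff <- function(x, ...) {
  tibble::tibble(
    n_circuits = nrow(x$table),
    n_significant = sum(x$table$significant),
    n_up = sum(x$table$significant & x$table$direction == "UP"),
    n_down = sum(x$table$significant & x$table$direction == "DOWN"),
    d0 = x$prior$d0,
    s0_sq = x$prior$s0_sq,
    alpha = x$alpha
  )
}
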