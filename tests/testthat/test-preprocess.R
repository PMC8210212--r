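test_that("imputation fills a dropout with the group mean on a 4-cell toy", {
  # two perfectly separated groups; gene g1 zeroed in cell c2 of group 1.
  # For every k = 2 clustering that separates the groups, the imputed value
  # is the group-1 mean of g1 *including the observed zero*: (40+0)/2 = 20.
  m <- matrix(c(40,  0,  0,  0,   # g1: dropout at c2
                30, 30,  0,  0,   # g2: group-1 marker
                 0,  0, 50, 50,   # g3: group-2 marker
                10, 12, 11,  9),  # g4: housekeeping
              nrow = 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), paste0("c", 1:4)))
  imp <- impute_dropouts(m, k_grid = 2, seed = 1)
  expect_equal(imp["g1", "c2"], 20)
  # group-2 cells get the group-2 mean of g1, which is 0
  expect_equal(unname(imp["g1", c("c3", "c4")]), c(0, 0))
  # nonzero entries never change
  expect_identical(imp[m > 0], m[m > 0])
})

test_that("imputation is a no-op without zeros and keeps all-zero genes", {
  set.seed(1)
  m <- matrix(stats::rpois(60, 10) + 1, nrow = 6,
              dimnames = list(paste0("g", 1:6), paste0("c", 1:10)))
  expect_equal(unname(unclass(impute_dropouts(m, k_grid = 2:3))[, ]),
               unname(m))
  m2 <- rbind(m, gz = 0)
  imp <- impute_dropouts(m2, k_grid = 2:3)
  expect_true(all(imp["gz", ] == 0))
})

test_that("imputation never raises the zero count and validates k", {
  set.seed(2)
  m <- matrix(stats::rnbinom(400, mu = 3, size = 1), nrow = 20,
              dimnames = list(paste0("g", 1:20), paste0("c", 1:20)))
  imp <- impute_dropouts(m, k_grid = 2:5)
  expect_lte(sum(imp == 0), sum(m == 0))
  expect_identical(imp[m > 0], m[m > 0])
  expect_error(impute_dropouts(m, k_grid = c(2, 20)), "k_grid")
  expect_error(impute_dropouts(m, k_grid = integer()), "non-empty")
})

test_that("normalization truncates at the type-7 quantile then scales", {
  m <- matrix(1:10, nrow = 1, dimnames = list("g1", paste0("c", 1:10)))
  # hand-computed: log1p, cap at the row median of the logs (type-7
  # interpolated), then min-max
  lg <- log1p(1:10)
  cap <- unname(stats::quantile(lg, 0.5, type = 7))
  expected <- pmin(lg, cap)
  expected <- (expected - min(expected)) / (max(expected) - min(expected))
  norm <- normalize_expression(m, q = 0.5)
  expect_equal(unname(norm[1, ]), expected)

  # on the raw scale the capped values correspond to counts capped at 5.5
  expect_equal(unname(expm1(pmin(lg, unname(stats::quantile(lg, 0.5))))),
               pmin(1:10, expm1(cap)))
})

test_that("normalization maps constant genes to zero and bounds to [0,1]", {
  set.seed(3)
  m <- rbind(matrix(stats::rpois(50, 20), nrow = 5), const = 7)
  rownames(m) <- c(paste0("g", 1:5), "const")
  colnames(m) <- paste0("c", 1:10)
  norm <- normalize_expression(m)
  expect_true(all(norm >= 0 & norm <= 1))
  expect_true(all(norm["const", ] == 0))
  nonconst <- norm[paste0("g", 1:5), ]
  expect_equal(unname(apply(nonconst, 1, min)), rep(0, 5))
  expect_equal(unname(apply(nonconst, 1, max)), rep(1, 5))
  expect_error(normalize_expression(m, q = 0), "q must be")
  expect_error(normalize_expression(m - 10), "negative")
})

test_that("global normalization uses one cap and one range", {
  m <- matrix(c(1, 2, 3, 100), nrow = 2,
              dimnames = list(c("a", "b"), c("c1", "c2")))
  ng <- normalize_expression(m, q = 1, per_gene = FALSE)
  expect_equal(max(ng), 1)
  expect_equal(min(ng), 0)
  # rows keep their relative scale instead of each spanning [0,1]
  expect_lt(max(ng["a", ]), 1)
})

test_that("well-separated blobs are recovered by embedding + k-means", {
  set.seed(5)
  n <- 40
  centers <- matrix(c(0, 8), nrow = 2)  # two gene-space centers
  truth <- rep(1:2, each = n / 2)
  m <- sapply(truth, function(t) stats::rnorm(10, centers[t], 0.5)) + 10
  dimnames(m) <- list(paste0("g", 1:10), paste0("c", 1:n))
  cl <- cluster_cells(m, k = 2, seed = 9)
  expect_equal(rand_index(unclass(cl),
                          stats::setNames(truth, colnames(m)))$adjusted_rand,
               1)
  # nearest-centroid oracle on the true centers agrees up to label swap
  oracle <- apply(m, 2, function(x) which.min(abs(mean(x[1:10]) - (centers + 10))))
  expect_true(rand_index(unclass(cl), stats::setNames(oracle, colnames(m)))$rand_index == 1)
})

test_that("clustering edge cases: k = 1, determinism, k validation", {
  set.seed(6)
  m <- matrix(stats::runif(50), nrow = 5,
              dimnames = list(paste0("g", 1:5), paste0("c", 1:10)))
  expect_true(all(cluster_cells(m, k = 1) == 1L))
  a <- cluster_cells(m, k = 3, seed = 4)
  b <- cluster_cells(m, k = 3, seed = 4)
  expect_identical(unclass(a)[], unclass(b)[])
  expect_error(cluster_cells(m, k = 11), "exceeds")
})

test_that("an external embedding is accepted in place of PCA", {
  emb <- rbind(matrix(stats::rnorm(20, 0), ncol = 2),
               matrix(stats::rnorm(20, 10), ncol = 2))
  rownames(emb) <- paste0("c", 1:20)
  cl <- cluster_cells(NULL, k = 2, seed = 1, embedding = emb)
  expect_equal(unname(table(unclass(cl))), c(10L, 10L), ignore_attr = TRUE)
})

test_that("Rand index matches brute-force pair counting", {
  expect_equal(rand_index(c(1, 1, 2, 2), c(1, 2, 2, 2))$rand_index, 0.5)
  expect_equal(rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2))$rand_index, 1)
  # label permutation invariance
  expect_equal(rand_index(c(1, 1, 2, 3), c(3, 3, 1, 2))$rand_index, 1)
  expect_equal(rand_index(c(1, 1, 2, 3), c(3, 3, 1, 2))$adjusted_rand, 1)

  set.seed(8)
  for (rep in 1:40) {
    n <- sample(5:50, 1)
    a <- sample(1:4, n, replace = TRUE)
    b <- sample(1:4, n, replace = TRUE)
    expect_equal(rand_index(a, b)$rand_index, rand_index_bruteforce(a, b))
    # symmetry
    expect_equal(rand_index(a, b), rand_index(b, a))
  }
})

test_that("adjusted Rand agrees with the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(10:50, 1)
    a <- sample(1:3, n, replace = TRUE)
    b <- sample(1:5, n, replace = TRUE)
    expect_equal(rand_index(a, b)$adjusted_rand,
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("partitions over different cell sets are rejected", {
  a <- stats::setNames(c(1, 2), c("x", "y"))
  b <- stats::setNames(c(1, 2), c("x", "z"))
  expect_error(rand_index(a, b), "different cell sets")
  expect_error(rand_index(1:3, 1:4), "different cell sets")
})
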