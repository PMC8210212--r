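test_that("node summarization follows the stated rules", {
  e <- toy_expr(c(0.7), "VEGFA", "c1")
  expect_equal(node_values(e, "VEGFA", rule = "mean"), 0.7)
  expect_equal(node_values(e, "VEGFA", rule = "min"), 0.7)
  expect_equal(node_values(e, "VEGFA", rule = "percentile90"), 0.7)

  e2 <- toy_expr(c(0.2, 0.8), c("G1", "G2"), "c1")
  expect_equal(node_values(e2, c("G1", "G2"), rule = "mean"), 0.5)

  # only G1 measured; G2, G3 take the missing default 0.5
  e3 <- toy_expr(0.2, "G1", "c1")
  expect_equal(node_values(e3, c("G1", "G2", "G3"), rule = "min",
                           missing_default = 0.5), 0.2)
  expect_equal(node_values(e3, c("G1", "G2", "G3"), rule = "mean",
                           missing_default = 0.5), 0.4)
  expect_error(node_values(e3, c("G1", "G2"), missing_default = NULL),
               "G2")
})

test_that("gene symbol matching is case-insensitive", {
  e <- toy_expr(0.3, "Vegfa", "c1")
  expect_equal(node_values(e, "VEGFA"), 0.3)
})

test_that("hand-evaluated propagation cases are exact", {
  # two activators (0.8, 0.5) and one inhibitor (0.5) into v = 0.5:
  # S = 0.5 * (1 - 0.2*0.5) * 0.5 = 0.225
  cc <- toy_circuit("A1 -a N; A2 -a N; I1 -i N", effector = "N")
  v <- c(A1 = 0.8, A2 = 0.5, I1 = 0.5, N = 0.5)
  expect_equal(propagate(cc, v)$effector, 0.225, tolerance = 1e-15)

  # chain R(0.8) -act-> M(1.0) -inh-> E(0.6): S_E = 0.6*(1-0.8) = 0.12
  chain <- toy_circuit("R -a M; M -i E", effector = "E")
  pr <- propagate(chain, c(R = 0.8, M = 1.0, E = 0.6))
  expect_equal(pr$states["R", 1], 0.8)
  expect_equal(pr$states["M", 1], 0.8)
  expect_equal(pr$effector, 0.12, tolerance = 1e-15)

  # a saturated inhibitor annihilates the signal
  cc2 <- toy_circuit("A -a N; I -i N", effector = "N")
  expect_equal(propagate(cc2, c(A = 1, I = 1, N = 0.9))$effector, 0)
})

test_that("propagation matches the recursive oracle on random DAG circuits", {
  set.seed(11)
  for (rep in 1:40) {
    g <- random_dag_graph(sample(4:12, 1))
    circ <- suppressWarnings(extract_circuits(g))
    cc <- circ[[sample(length(circ), 1)]]
    v <- stats::setNames(stats::runif(length(cc$member_nodes)),
                         cc$member_nodes)
    expect_equal(propagate(cc, v)$effector,
                 recursive_propagation_oracle(cc, v),
                 tolerance = 1e-12, info = cc$circuit_id)
  }
})

test_that("fixed-point iteration agrees with topological evaluation on DAGs", {
  set.seed(12)
  for (rep in 1:15) {
    g <- random_dag_graph(sample(4:10, 1))
    circ <- suppressWarnings(extract_circuits(g))
    cc <- circ[[1]]
    v <- stats::setNames(stats::runif(length(cc$member_nodes)),
                         cc$member_nodes)
    topo <- propagate(cc, v)
    iter <- propagate(cc, v, method = "iterative", tol = 1e-10)
    expect_equal(iter$effector, topo$effector, tolerance = 1e-8)
    expect_gt(iter$iterations, 0)
  }
})

test_that("cyclic circuits converge to a fixed point in [0,1]", {
  g <- toy_graph("R -a A; A -a B; B -a A; A -a E")
  cc <- extract_circuits(g)[["TOY:E"]]
  expect_false(circuit_is_dag_public(cc))
  v <- c(R = 0.9, A = 0.8, B = 0.7, E = 0.6)
  pr <- propagate(cc, v)
  expect_true(pr$converged)
  expect_true(all(pr$states >= 0 & pr$states <= 1))
  # the fixed point satisfies the propagation equations
  S <- pr$states[, 1]
  expect_equal(S[["A"]],
               v[["A"]] * (1 - (1 - S[["R"]]) * (1 - S[["B"]])),
               tolerance = 1e-4)
  expect_equal(S[["B"]], v[["B"]] * S[["A"]], tolerance = 1e-4)
  expect_equal(S[["E"]], v[["E"]] * S[["A"]], tolerance = 1e-4)
  expect_error(propagate(cc, v, max_iter = 1), "converge")
})

test_that("signals stay in [0,1] and respect monotonicity", {
  set.seed(13)
  for (rep in 1:25) {
    g <- random_dag_graph(sample(4:10, 1))
    circ <- suppressWarnings(extract_circuits(g))
    cc <- circ[[sample(length(circ), 1)]]
    nodes <- cc$member_nodes
    v <- stats::setNames(stats::runif(length(nodes)), nodes)
    base <- propagate(cc, v)
    expect_true(all(base$states >= 0 & base$states <= 1))
  }

  # monotonicity of the update rule: raising an activation input or the
  # node's own expression never decreases its signal; raising an inhibition
  # input never increases it (star circuits feeding one node)
  set.seed(14)
  for (rep in 1:40) {
    n_act <- sample(1:3, 1); n_inh <- sample(0:3, 1)
    spec <- paste(c(paste0("A", seq_len(n_act), " -a N"),
                    if (n_inh > 0) paste0("I", seq_len(n_inh), " -i N")),
                  collapse = "; ")
    cc <- toy_circuit(spec, effector = "N")
    v <- stats::setNames(stats::runif(length(cc$member_nodes)),
                         cc$member_nodes)
    base <- propagate(cc, v)$effector
    up <- function(x) min(1, x + stats::runif(1, 0, 1 - x + 1e-9))
    v_a <- v; v_a[["A1"]] <- up(v[["A1"]])
    expect_gte(propagate(cc, v_a)$effector + 1e-12, base)
    v_n <- v; v_n[["N"]] <- up(v[["N"]])
    expect_gte(propagate(cc, v_n)$effector + 1e-12, base)
    if (n_inh > 0) {
      v_i <- v; v_i[["I1"]] <- up(v[["I1"]])
      expect_lte(propagate(cc, v_i)$effector - 1e-12, base)
    }
  }
})

test_that("activity matrices equal per-cell scalar propagation", {
  g <- toy_graph("R -a M; M -a E; R -a X; X -i E",
                 genes = list("gR", c("gM1", "gM2"), "gE", "gX"))
  circ <- extract_circuits(g)
  set.seed(3)
  expr <- matrix(stats::runif(5 * 3), nrow = 5,
                 dimnames = list(c("gR", "gM1", "gM2", "gE", "gX"),
                                 paste0("c", 1:3)))
  am <- circuit_activities(expr, circ)
  for (j in 1:3) {
    for (cc in circ) {
      v <- vapply(cc$node_genes, function(gg) {
        node_values(expr[, j, drop = FALSE], gg)
      }, 1.0)
      expect_equal(am[cc$circuit_id, j], propagate(cc, v)$effector,
                   tolerance = 1e-12)
    }
  }
})

test_that("saturated and silent inputs give the boundary activities", {
  g <- toy_graph("R -a M; M -a E")
  circ <- extract_circuits(g)
  genes <- c("gR", "gM", "gE")
  ones <- matrix(1, 3, 2, dimnames = list(genes, c("c1", "c2")))
  zeros <- matrix(0, 3, 2, dimnames = list(genes, c("c1", "c2")))
  expect_true(all(circuit_activities(ones, circ) == 1))
  expect_true(all(circuit_activities(zeros, circ) == 0))
})

test_that("identical inputs give bit-identical activity matrices", {
  set.seed(4)
  g <- random_dag_graph(8)
  circ <- suppressWarnings(extract_circuits(g))
  genes <- paste0("g", g$nodes$node_id)
  expr <- matrix(stats::runif(length(genes) * 4), nrow = length(genes),
                 dimnames = list(genes, paste0("c", 1:4)))
  expect_identical(unclass(circuit_activities(expr, circ)),
                   unclass(circuit_activities(expr, circ)))
})

test_that("unmeasurable circuits error when no missing default is set", {
  g <- toy_graph("R -a E")
  circ <- extract_circuits(g)
  expr <- matrix(0.5, 1, 1, dimnames = list("OTHER", "c1"))
  expect_error(circuit_activities(expr, circ, missing_default = NULL),
               "TOY:E")
  expect_silent(circuit_activities(expr, circ, missing_default = 0.5))
})
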