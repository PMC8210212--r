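test_that("drug actions rewrite only their target genes", {
  m <- toy_expr(c(0.9, 0.9, 0.2, 0.4, 0.3, 0.5),
                c("VEGFA", "TLR7", "OTHER"), c("c1", "c2"))
  inh <- apply_perturbation(m, drug_spec("bev", "VEGFA", "inhibitor"))
  expect_equal(unname(inh["VEGFA", ]), c(0, 0))
  expect_equal(inh["OTHER", ], m["OTHER", ])
  expect_equal(inh["TLR7", ], m["TLR7", ])

  ago <- apply_perturbation(m, drug_spec("imi", "TLR7", "agonist"))
  expect_equal(unname(ago["TLR7", ]), c(1, 1))

  # fractional knockdown moves targets part way
  frac <- apply_perturbation(m, drug_spec("bev", "VEGFA", "inhibitor"),
                             efficacy = 0.5)
  expect_equal(unname(frac["VEGFA", ]), c(0.45, 0.45))
})

test_that("absent targets are skipped with a warning and recorded", {
  m <- toy_expr(c(0.5, 0.5), "GENE1", c("c1", "c2"))
  expect_warning(out <- apply_perturbation(m, drug_spec("d", "MISSING")),
                 "MISSING")
  expect_equal(out[, ], m[, ])
  expect_equal(attr(out, "skipped_targets"), "MISSING")
})

test_that("impact is zero when nothing changes and LFC matches by hand", {
  base <- matrix(c(0.48, 0.3), 2, 1,
                 dimnames = list(c("P:E", "P:F"), "c1"))
  same <- perturbation_impact(base, base, target_circuits = "P:E")
  expect_true(all(same$lfc == 0))
  expect_equal(same$impact$impact, 0)

  # chain R(0.8) -> E(0.6): baseline S_E = 0.48; knockdown of R gives 0.
  # LFC = log2(eps / (0.48 + eps)) with eps = 1e-3
  g <- toy_graph("R -a E", genes = list("gR", "gE"))
  circ <- extract_circuits(g)
  expr <- toy_expr(c(0.8, 0.6), c("gR", "gE"), "c1")
  b <- circuit_activities(expr, circ)
  p <- circuit_activities(apply_perturbation(expr, drug_spec("d", "gR")), circ)
  expect_equal(b["TOY:E", "c1"], 0.48, tolerance = 1e-12)
  expect_equal(p["TOY:E", "c1"], 0)
  pr <- perturbation_impact(b, p, "TOY:E")
  expect_equal(pr$lfc["TOY:E", "c1"], log2(1e-3 / 0.481), tolerance = 1e-10)
  expect_equal(pr$impact$impact, abs(log2(1e-3 / 0.481)), tolerance = 1e-10)
  expect_error(perturbation_impact(b, p[, c(1, 1)], "TOY:E"), "do not match")
})

test_that("a co-node compensator dampens the knockdown impact", {
  # receptor node carries the target plus a compensator ligand
  g <- toy_graph("R -a E", genes = list(c("TGT", "CMP"), "gE"))
  circ <- extract_circuits(g)
  drug <- drug_spec("d", "TGT")
  # compensated cell: high CMP; exposed cell: CMP low, node relies on TGT
  expr <- matrix(c(0.9, 0.9,   # TGT
                   0.9, 0.05,  # CMP
                   0.8, 0.8),  # gE
                 nrow = 3, byrow = TRUE,
                 dimnames = list(c("TGT", "CMP", "gE"), c("comp", "naked")))
  b <- circuit_activities(expr, circ)
  p <- circuit_activities(apply_perturbation(expr, drug), circ)
  pr <- perturbation_impact(b, p, names(circ))
  lfc <- abs(pr$lfc[1, ])
  expect_lt(lfc[["comp"]], lfc[["naked"]])
})

test_that("cells with an already-silent target are barely affected", {
  g <- toy_graph("R -a E", genes = list("TGT", "gE"))
  circ <- extract_circuits(g)
  expr <- toy_expr(c(0, 0.01, 0.9, 0.8, 0.8, 0.8), c("TGT", "gE"),
                   c("silent", "low", "high"))
  b <- circuit_activities(expr, circ)
  p <- circuit_activities(apply_perturbation(expr, drug_spec("d", "TGT")),
                          circ)
  pr <- perturbation_impact(b, p, names(circ))
  imp <- stats::setNames(pr$impact$impact, pr$impact$cell)
  expect_equal(imp[["silent"]], 0)
  expect_lt(imp[["low"]], imp[["high"]] / 2)
  expect_gt(imp[["high"]], 5)
})

test_that("knocking down a gene in zero circuits changes nothing", {
  g <- toy_graph("R -a M; M -a E",
                 genes = list("gR", "gM", "gE"))
  circ <- extract_circuits(g)
  set.seed(41)
  expr <- matrix(stats::runif(4 * 6), nrow = 4,
                 dimnames = list(c("gR", "gM", "gE", "BYSTANDER"),
                                 paste0("c", 1:6)))
  b <- circuit_activities(expr, circ)
  p <- circuit_activities(apply_perturbation(expr, drug_spec("d", "BYSTANDER")),
                          circ)
  expect_equal(circuits_with_gene(circ, "BYSTANDER"), character(0))
  pr <- perturbation_impact(b, p, circuits_with_gene(circ, "BYSTANDER"))
  expect_true(all(pr$lfc == 0))
  expect_true(all(pr$impact$impact == 0))
})

test_that("inhibitor effects are monotone through activation edges only", {
  set.seed(42)
  expr <- matrix(stats::runif(3 * 8, 0.3, 0.9), nrow = 3,
                 dimnames = list(c("gR", "gM", "gE"), paste0("c", 1:8)))
  # activation-only chain: knockdown can only lower activity
  circ_act <- extract_circuits(toy_graph("R -a M; M -a E",
                                         genes = list("gR", "gM", "gE")))
  b <- circuit_activities(expr, circ_act)
  p <- circuit_activities(apply_perturbation(expr, drug_spec("d", "gR")),
                          circ_act)
  expect_true(all(p <= b + 1e-12))
  # target feeding an inhibition edge: knockdown RAISES the effector
  circ_inh <- extract_circuits(toy_graph("R -a E; X -i E",
                                         genes = list("gR", "gX", "gE")))
  expr2 <- rbind(expr, gX = stats::runif(ncol(expr), 0.3, 0.9))
  b2 <- circuit_activities(expr2, circ_inh)
  p2 <- circuit_activities(apply_perturbation(expr2, drug_spec("d", "gX")),
                           circ_inh)
  expect_true(all(p2["TOY:E", ] >= b2["TOY:E", ] - 1e-12))
})

test_that("clearly separated impact modes split into the stated labels", {
  scores <- stats::setNames(c(rep(0.01, 10), rep(2, 10)), paste0("c", 1:20))
  lab <- classify_responders(scores, seed = 1)
  expect_equal(sum(lab$label == "low_responder"), 10)
  expect_equal(sum(lab$label == "responder"), 10)
  expect_true(all(lab$label[lab$impact > 1] == "responder"))
  expect_gt(attr(lab, "threshold"), 0.01)
  expect_lt(attr(lab, "threshold"), 2)
  expect_false(attr(lab, "weak_bimodality"))
})

test_that("degenerate and weakly bimodal impact vectors are flagged", {
  expect_warning(lab <- classify_responders(rep(1, 5)), "identical")
  expect_true(all(lab$label == "responder"))
  set.seed(43)
  blob <- stats::rnorm(100, 1, 0.2)  # unimodal: split exists but is weak
  lab2 <- classify_responders(stats::setNames(pmax(blob, 0), paste0("c", 1:100)))
  expect_true(attr(lab2, "silhouette") < 0.7)
  expect_error(classify_responders(1), ">= 2 cells")
})

test_that("the drug report counts target circuits and their hallmarks", {
  g <- toy_graph("R -a A; R -a B; A -a E1; B -a E2; A -a E3",
                 genes = list("TGT", "gA", "gB", "eff1", "eff2", "eff3"))
  circ <- extract_circuits(g)
  ch <- tibble::tibble(circuit_id = c("TOY:E1", "TOY:E3"), hallmark = "H")
  drugs <- dplyr::bind_rows(
    drug_spec("drugA", "TGT"),
    drug_spec("drugB", c("TGT", "NOWHERE"), c("inhibitor", "antagonist")))
  rep_tab <- drug_report(drugs, circ, ch)
  # TGT is in the receptor node of every circuit (3 effectors)
  expect_equal(rep_tab$circuits[rep_tab$drug == "drugA"], 3)
  expect_equal(rep_tab$H[rep_tab$drug == "drugA"], 2L)
  # absent target -> all-zero row
  nw <- rep_tab[rep_tab$gene == "NOWHERE", ]
  expect_equal(nw$circuits, 0)
  expect_equal(nw$H, 0L)
  # two drugs sharing a target get identical circuit counts
  expect_equal(rep_tab$circuits[rep_tab$gene == "TGT"], c(3, 3))
})

test_that("drug tables parse and validate their action vocabulary", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("drug\tgene\taction", "bev\tVEGFA\tinhibitor",
               "imi\tTLR7\tagonist"), path)
  tab <- read_drug_table(path)
  expect_equal(nrow(tab), 2)
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("drug\tgene\taction", "x\tG\tblocker"), bad)
  expect_error(read_drug_table(bad), "blocker")
  expect_error(drug_spec("d", character()), ">= 1 target")
})

test_that("simulate_drug ties the stages together deterministically", {
  set.seed(44)
  g <- toy_graph("R -a M; M -a E", genes = list(c("TGT", "CMP"), "gM", "gE"))
  circ <- extract_circuits(g)
  expr <- matrix(stats::runif(4 * 30), nrow = 4,
                 dimnames = list(c("TGT", "CMP", "gM", "gE"),
                                 paste0("c", 1:30)))
  r1 <- simulate_drug(expr, drug_spec("d", "TGT"), circ, seed = 5)
  r2 <- simulate_drug(expr, drug_spec("d", "TGT"), circ, seed = 5)
  expect_identical(tidy(r1), tidy(r2))
  expect_setequal(r1$responders$label, c("responder", "low_responder"))
  expect_equal(r1$target_circuits, "TOY:E")
})
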