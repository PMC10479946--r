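test_that("gene weights count decades of FDR below the threshold", {
  de <- data.frame(gene = c("a", "b", "c", "d"),
                   FDR = c(0.25, 0.025, 0.0025, 0.5))
  w <- gene_weights(de, p_th = 0.25)
  # the boundary gene (FDR = p_th) and the non-significant one drop out
  expect_setequal(w$gene, c("b", "c"))
  expect_equal(w$W[w$gene == "b"], 1)
  expect_equal(w$W[w$gene == "c"], 2)
  expect_error(gene_weights(data.frame(gene = "x", FDR = 0)), "floor")
  # smaller FDR always means larger weight
  fdrs <- 10^seq(-6, -1)
  ws <- gene_weights(data.frame(gene = paste0("g", 1:6), FDR = fdrs))$W
  expect_true(all(diff(ws[order(fdrs)]) < 0))
})

test_that("genes map to exactly the reactions whose rules cite them", {
  m <- toy()
  rmap <- map_genes_to_reactions(m, c("g2", "g4", "ghost"))
  expect_identical(rmap$g2, "R_ox")
  expect_identical(rmap$g4, "R_ferm")
  expect_false("ghost" %in% names(rmap))
  expect_identical(attr(rmap, "unmapped"), "ghost")
  # a gene cited by two rules maps to both reactions
  m2 <- m
  m2$reactions$gpr[m2$reactions$id == "R_upper"] <- "g1 or g2"
  rmap2 <- map_genes_to_reactions(m2, "g2")
  expect_setequal(rmap2$g2, c("R_upper", "R_ox"))
})

test_that("membership rules partition reactions as specified", {
  m <- toy()
  vref <- pfba_state(m)
  de <- data.frame(gene = c("g2", "g3", "g4"), FC = c(0.5, 0.5, 2),
                   log2FC = c(-1, -1, 1), pvalue = 1e-3, FDR = 1e-3)
  meas <- data.frame(parameter = "OCR", reaction = "EX_O2", mean = 2.5, sd = 0.1)
  qp <- assemble_qp(m, vref, de, measurements = meas)
  cls <- split(qp$terms$reaction, qp$terms$class)
  expect_setequal(cls$measured, "EX_O2")
  expect_setequal(unique(cls$de), c("R_ox", "R_ferm"))
  expect_setequal(cls$unchanged,
                  setdiff(m$reactions$id, c("EX_O2", "R_ox", "R_ferm")))
  # no DE genes and no measurements: everything is an unchanged-term
  qp0 <- assemble_qp(m, vref, identity_de(m))
  expect_identical(unique(qp0$terms$class), "unchanged")
  expect_equal(qp0$terms$a, 1 / pmax(abs(qp0$terms$target), 1e-6))
  # FC = 1 genes contribute nothing even when significant
  de1 <- data.frame(gene = "g4", FC = 1, log2FC = 0, pvalue = 1e-4, FDR = 1e-4)
  qp1 <- assemble_qp(m, vref, de1)
  expect_false("de" %in% qp1$terms$class)
})

test_that("a measured reaction overrides its DE gene targets", {
  m <- toy()
  vref <- pfba_state(m)
  de <- data.frame(gene = c("g2", "g3"), FC = 4, log2FC = 2,
                   pvalue = 1e-4, FDR = 1e-4)
  meas <- data.frame(parameter = "flux", reaction = "R_ox",
                     mean = vref[["R_ox"]], sd = 0.01)
  qp <- assemble_qp(m, vref, de, measurements = meas)
  rox <- qp$terms[qp$terms$reaction == "R_ox", ]
  expect_identical(unique(rox$class), "measured")
  expect_true("R_ox" %in% qp$notes$measured_overrides)
})

test_that("identity inputs return the reference flux unchanged", {
  for (m in toy_fleet(1:3)) {
    vref <- pfba_state(m)
    fit <- qmta(m, vref, identity_de(m))
    expect_identical(fit$status, "optimal")
    expect_lt(max(abs(coef(fit) - as.numeric(vref))), 1e-6)
    expect_lt(fit$objective, 1e-10)
    expect_true(all(abs(fit$log2fc$log2fc) < 1e-6))
  }
})

test_that("mass balance propagates a single-gene fold change along a chain", {
  # unbranched 2-reaction chain: doubling the gene of reaction 1 must
  # double both reactions (they are stoichiometrically locked)
  m <- metabolic_model(
    "chain", data.frame(id = "X", compartment = "c"),
    data.frame(id = c("R1", "R2"), lower_bound = 0, upper_bound = 100,
               gpr = c("gA", ""), objective_coef = c(0, 1)),
    list(R1 = c(X = 1), R2 = c(X = -1)))
  vref <- flux_distribution(c(R1 = 5, R2 = 5), m)
  de <- data.frame(gene = "gA", FC = 2, log2FC = 1, pvalue = 1e-3, FDR = 1e-3)
  fit <- qmta(m, vref, de)
  orc <- oracle_qp(fit$qp$terms, m$S, m$reactions$lower_bound,
                   m$reactions$upper_bound, m$reactions$id)
  expect_equal(fit$objective, orc$objective, tolerance = 1e-6)
  expect_lt(max(abs(coef(fit) - orc$v)), 1e-4)
  expect_gt(coef(fit)[["R1"]], 5)
  expect_equal(coef(fit)[["R1"]], coef(fit)[["R2"]], tolerance = 1e-9)
})

test_that("tight measurements pull the compromise toward the measured value", {
  m <- toy()
  vref <- pfba_state(m)
  # DE wants fermentation x4; a near-exact measurement nails it at v_ref
  de <- data.frame(gene = c("g4", "g5"), FC = 4, log2FC = 2,
                   pvalue = 1e-4, FDR = 1e-4)
  meas <- data.frame(parameter = "ferm", reaction = "EX_D",
                     mean = vref[["EX_D"]], sd = 1e-3)
  fit <- qmta(m, vref, de, measurements = meas)
  orc <- oracle_qp(fit$qp$terms, m$S, m$reactions$lower_bound,
                   m$reactions$upper_bound, m$reactions$id)
  expect_equal(fit$objective, orc$objective, tolerance = 1e-6)
  expect_lt(max(abs(coef(fit) - orc$v)), 1e-4)
  # the measured drain barely moves; the un-measured twin absorbs the pull
  expect_lt(abs(coef(fit)[["EX_D"]] - vref[["EX_D"]]), 0.1)
  expect_gt(coef(fit)[["R_ferm"]], vref[["R_ferm"]])
})

test_that("the quadprog route matches the interior-point oracle across seeds", {
  for (seed in 1:10) {
    scen <- ground_truth_scenario(seed = seed)
    fit <- qmta(scen$model, scen$v_control, scen$de_table,
                scen$measurements)
    expect_identical(fit$status, "optimal")
    orc <- oracle_qp(fit$qp$terms, scen$model$S,
                     scen$model$reactions$lower_bound,
                     scen$model$reactions$upper_bound,
                     scen$model$reactions$id)
    expect_equal(fit$objective, orc$objective, tolerance = 1e-6)
    expect_lt(max(abs(coef(fit) - orc$v)), 1e-4)
    expect_lt(max_infeasibility(coef(fit), scen$model), 1e-6)
  }
})

test_that("the objective decomposition sums to the reported objective", {
  scen <- ground_truth_scenario(seed = 5)
  fit <- qmta(scen$model, scen$v_control, scen$de_table, scen$measurements)
  expect_equal(sum(fit$decomposition), fit$objective, tolerance = 1e-10)
  expect_setequal(names(fit$decomposition), c("de", "measured", "unchanged"))
})

test_that("shrinking a gene's FDR pulls its reactions closer to target", {
  m <- toy()
  vref <- pfba_state(m)
  dist_at <- function(fdr) {
    de <- data.frame(gene = c("g4", "g5"), FC = 1.6, log2FC = log2(1.6),
                     pvalue = fdr, FDR = fdr)
    fit <- qmta(m, vref, de)
    abs(coef(fit)[["R_ferm"]] - 1.6 * vref[["R_ferm"]])
  }
  gaps <- vapply(c(0.2, 0.05, 1e-3, 1e-6), dist_at, numeric(1))
  expect_true(all(diff(gaps) <= 1e-9))
})

test_that("flux log2 fold changes report magnitude ratios and sign flips", {
  out <- flux_log2fc(c(R1 = 1, R2 = 2, R3 = 0.5),
                     c(R1 = 2, R2 = 2, R3 = -0.5))
  expect_equal(out$log2fc[out$reaction == "R1"], 1, tolerance = 1e-5)
  expect_equal(out$log2fc[out$reaction == "R2"], 0)
  expect_equal(out$log2fc[out$reaction == "R3"], 0, tolerance = 1e-9)
  expect_identical(out$sign_flip, c(FALSE, FALSE, TRUE))
})

test_that("the pathway report groups deterministically by subsystem", {
  scen <- ground_truth_scenario(seed = 2)
  fit <- qmta(scen$model, scen$v_control, scen$de_table, scen$measurements)
  rep <- pathway_report(fit)
  expect_identical(names(rep),
                   c("subsystem", "reaction", "log2fc", "v_mta", "direction"))
  glyc <- rep$reaction[rep$subsystem == "Glycolysis-like"]
  expect_setequal(glyc, c("R_upper", "R_ferm"))
  expect_false(is.unsorted(rep$subsystem))
  expect_true(all(rep$direction %in% c("up", "down", "unchanged")))
  # report is identical across repeated calls (deterministic ordering)
  expect_identical(rep, pathway_report(fit))
})

test_that("both denominator-exponent variants solve and differ as expected", {
  scen <- ground_truth_scenario(seed = 4)
  lit <- qmta(scen$model, scen$v_control, scen$de_table,
              config = qmta_config(de_denom_squared = TRUE))
  alt <- qmta(scen$model, scen$v_control, scen$de_table,
              config = qmta_config(de_denom_squared = FALSE,
                                   ru_denom_squared = TRUE))
  expect_identical(lit$status, "optimal")
  expect_identical(alt$status, "optimal")
  expect_false(isTRUE(all.equal(coef(lit), coef(alt))))
})
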