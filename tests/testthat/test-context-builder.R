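make_profile <- function(model, control, treated = control) {
  genes <- model$genes
  m <- cbind(ctrl_1 = control[genes], ctrl_2 = control[genes],
             trt_1 = treated[genes], trt_2 = treated[genes])
  rownames(m) <- genes
  expression_profile(m, c(ctrl_1 = "control", ctrl_2 = "control",
                          trt_1 = "treated", trt_2 = "treated"))
}

test_that("reaction expression folds condition means through the GPR", {
  m <- toy()
  prof <- make_profile(m, c(g1 = 0.4, g2 = 3, g3 = 0.2, g4 = 1, g5 = 8))
  s <- reaction_expression(m, prof, "control")
  expect_equal(s[["R_upper"]], 0.4)        # single gene passes through
  expect_equal(s[["R_ox"]], 0.2)           # complex: limiting subunit
  expect_equal(s[["R_ferm"]], 8)           # isozymes: best alternative
  expect_true(is.na(s[["EX_A"]]))          # no gene association: absent
})

test_that("globally silent reactions are removed only when guards allow", {
  m <- toy()
  # R_ox silent everywhere; fermentation can still reach 20%*20 = 4 demand
  prof <- make_profile(m, c(g1 = 10, g2 = 0.5, g3 = 0.5, g4 = 10, g5 = 10))
  res <- prune_globally_silent(m, prof)
  expect_false("R_ox" %in% res$model$reactions$id)
  acts <- vapply(res$log, `[[`, "", "action")
  expect_identical(acts, "removed")
  expect_gte(fba(res$model)$objective, res$floor - 1e-9)

  # R_upper silent but essential: its loss cuts demand to 2*5=10 via R_ox
  # only if B were still produced — it is not, so biomass collapses
  prof2 <- make_profile(m, c(g1 = 0.5, g2 = 10, g3 = 10, g4 = 10, g5 = 10))
  res2 <- prune_globally_silent(m, prof2)
  expect_true("R_upper" %in% res2$model$reactions$id)
  expect_match(res2$log[[1]]$reason, "essential|infeasible")

  # boundary: a score of exactly 1.0 is not "under" the threshold
  prof3 <- make_profile(m, c(g1 = 10, g2 = 1.0, g3 = 1.0, g4 = 10, g5 = 10))
  res3 <- prune_globally_silent(m, prof3)
  expect_true("R_ox" %in% res3$model$reactions$id)
  expect_length(res3$log, 0)
})

test_that("silence in one condition only is not grounds for global pruning", {
  m <- toy()
  prof <- make_profile(m,
                       control = c(g1 = 10, g2 = 5, g3 = 5, g4 = 10, g5 = 10),
                       treated = c(g1 = 10, g2 = 0.2, g3 = 0.2, g4 = 10, g5 = 10))
  res <- prune_globally_silent(m, prof)
  expect_true("R_ox" %in% res$model$reactions$id)
})

test_that("condition-specific pruning gates on FDR and both expression sides", {
  m <- toy()
  prof <- make_profile(m,
                       control = c(g1 = 10, g2 = 4.2, g3 = 4.2, g4 = 10, g5 = 10),
                       treated = c(g1 = 10, g2 = 0.3, g3 = 0.3, g4 = 10, g5 = 10))
  de <- function(fdr) data.frame(gene = c("g2", "g3"), FDR = fdr)
  hit <- prune_condition_specific(m, de(0.01), prof, "treated", "control")
  expect_false("R_ox" %in% hit$model$reactions$id)
  # FDR gate: not significant, retained
  miss <- prune_condition_specific(m, de(0.2), prof, "treated", "control")
  expect_true("R_ox" %in% miss$model$reactions$id)
  # expression gate: still expressed under drug, retained
  prof2 <- make_profile(m,
                        control = c(g1 = 10, g2 = 4.2, g3 = 4.2, g4 = 10, g5 = 10),
                        treated = c(g1 = 10, g2 = 2.0, g3 = 2.0, g4 = 10, g5 = 10))
  miss2 <- prune_condition_specific(m, de(0.01), prof2, "treated", "control")
  expect_true("R_ox" %in% miss2$model$reactions$id)
  expect_error(prune_condition_specific(m, data.frame(gene = "g2", FDR = 0),
                                        prof, "treated", "control"),
               "FDR")
})

test_that("medium application closes unlisted uptakes conservatively", {
  m <- toy()
  med <- medium_spec(c(EX_A = 10))
  mm <- apply_medium(m, med)
  expect_equal(mm$reactions$upper_bound[mm$reactions$id == "EX_O2"], 0)
  expect_equal(fba(mm)$objective, 10)  # oxidative branch starved of O2
  # empty medium: nothing can be taken up, optimum collapses to zero
  m0 <- apply_medium(m, medium_spec(stats::setNames(numeric(), character())))
  expect_equal(fba(m0)$objective, 0, tolerance = 1e-12)
  # a medium asking for more than the template allows is clipped, logged
  mc <- apply_medium(m, medium_spec(c(EX_A = 50, EX_O2 = 5)))
  expect_equal(mc$reactions$upper_bound[mc$reactions$id == "EX_A"], 10)
  acts <- vapply(mc$log, `[[`, "", "action")
  expect_true("uptake_clipped_to_template" %in% acts)
  expect_error(apply_medium(m, medium_spec(c(R_upper = 5))), "non-exchange")
})

test_that("measured rates intersect bounds, with k_sd = 0 fixing the flux", {
  m <- toy()
  meas <- data.frame(parameter = "OCR", reaction = "EX_O2", mean = 4, sd = 0.5)
  m2 <- apply_measurements(m, meas, k_sd = 2)
  i <- which(m2$reactions$id == "EX_O2")
  expect_equal(c(m2$reactions$lower_bound[i], m2$reactions$upper_bound[i]),
               c(3, 5))
  m0 <- apply_measurements(m, meas, k_sd = 0)
  i <- which(m0$reactions$id == "EX_O2")
  expect_equal(c(m0$reactions$lower_bound[i], m0$reactions$upper_bound[i]),
               c(4, 4))
  bad <- data.frame(parameter = "OCR", reaction = "EX_O2", mean = 9, sd = 0.5)
  expect_error(apply_measurements(m, bad, k_sd = 2), "OCR.*not intersect")
})

test_that("context build keeps the full toy when everything is expressed", {
  m <- toy()
  prof <- make_profile(m, c(g1 = 10, g2 = 10, g3 = 10, g4 = 10, g5 = 10))
  ctx <- build_context_model(m, prof,
                             de_tables = list(treated = identity_de(m)),
                             untreated = "control")
  expect_equal(nrow(ctx$models$control$reactions), 8)
  expect_equal(nrow(ctx$models$treated$reactions), 8)
})

test_that("an isozyme-backed reaction survives silencing of one isozyme", {
  m <- toy()
  # g5 off everywhere, but g4 covers R_ferm through the OR rule
  prof <- make_profile(m, c(g1 = 10, g2 = 10, g3 = 10, g4 = 10, g5 = 0.1))
  ctx <- build_context_model(m, prof,
                             de_tables = list(treated = identity_de(m)))
  expect_true("R_ferm" %in% ctx$models$treated$reactions$id)
})

test_that("a drug-silenced complex is dropped from that condition's model only", {
  m <- toy()
  prof <- make_profile(m,
                       control = c(g1 = 10, g2 = 5, g3 = 5, g4 = 10, g5 = 10),
                       treated = c(g1 = 10, g2 = 0.2, g3 = 5, g4 = 10, g5 = 10))
  de <- data.frame(gene = "g2", FDR = 1e-4)
  ctx <- build_context_model(m, prof, de_tables = list(treated = de))
  expect_true("R_ox" %in% ctx$models$control$reactions$id)
  expect_false("R_ox" %in% ctx$models$treated$reactions$id)
  # and the guard held: the treated model still reaches the biomass floor
  expect_gte(fba(ctx$models$treated)$objective,
             0.2 * ctx$template_optimum - 1e-9)
})

test_that("pruning is deterministic and never starves the biomass floor", {
  for (seed in 1:6) {
    m <- toy_network(list(n_mid = 2, n_branch = 2, seed = seed))
    genes <- m$genes
    set.seed(seed + 100)
    ctrl <- stats::setNames(stats::runif(length(genes), 0, 3), genes)
    trt <- stats::setNames(stats::runif(length(genes), 0, 3), genes)
    prof <- make_profile(m, ctrl, trt)
    opt0 <- fba(m)$objective
    scores <- sapply(c("control", "treated"),
                     function(cc) reaction_expression(m, prof, cc))
    res <- prune_globally_silent(m, prof)
    # guard: biomass floor always preserved
    expect_gte(fba(res$model)$objective, 0.2 * opt0 - 1e-9)
    # no reaction at/above threshold in any condition was touched
    removed <- vapply(Filter(function(r) r$action == "removed", res$log),
                      `[[`, "", "reaction")
    if (length(removed)) {
      expect_true(all(apply(scores[removed, , drop = FALSE], 1,
                            function(s) all(!is.na(s) & s < 1))))
    }
    # determinism: identical inputs give identical models and logs
    res2 <- prune_globally_silent(m, prof)
    expect_identical(res$model$reactions, res2$model$reactions)
    expect_identical(res$log, res2$log)
  }
})

test_that("medium-listed exchanges are never pruned", {
  m <- toy()
  # every gene silent: all gene-associated reactions become candidates
  prof <- make_profile(m, c(g1 = 0.1, g2 = 0.1, g3 = 0.1, g4 = 0.1, g5 = 0.1))
  med <- medium_spec(c(EX_A = 10, EX_O2 = 5))
  ctx <- build_context_model(m, prof, de_tables = list(),
                             medium = med)
  expect_true(all(c("EX_A", "EX_O2") %in% ctx$models$control$reactions$id))
})

test_that("expression profile round-trips through TSV + condition JSON", {
  m <- toy()
  prof <- make_profile(m, c(g1 = 1.5, g2 = 2, g3 = 0.25, g4 = 4, g5 = 8))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_expression_tsv(prof, tsv, js)
  prof2 <- read_expression_tsv(tsv, js)
  expect_equal(prof2$fpkm, prof$fpkm)
  expect_identical(prof2$conditions, prof$conditions)
})
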