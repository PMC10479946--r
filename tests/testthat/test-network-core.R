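test_that("GPR parsing round-trips and rejects malformed rules", {
  cases <- c("g1", "g1 and g2", "g1 or g2", "(g1 and g2) or g3",
             "g1 and (g2 or g3) and g4")
  for (txt in cases) {
    tree <- gpr_parse(txt)
    expect_identical(gpr_deparse(gpr_parse(gpr_deparse(tree))),
                     gpr_deparse(tree))
  }
  expect_null(gpr_parse(""))
  expect_setequal(gpr_genes(gpr_parse("(g1 and g2) or g1")), c("g1", "g2"))
  expect_error(gpr_parse("g1 and"), "malformed")
  expect_error(gpr_parse("(g1 or g2"), "malformed")
  expect_error(gpr_parse("g1 && g2"), "malformed")
})

test_that("GPR evaluation applies min for complexes and max/sum for isozymes", {
  s <- c(g1 = 5, g2 = 2, g3 = 1)
  expect_equal(evaluate_gpr("g1 and g2", s), 2)
  expect_equal(evaluate_gpr("g1 or g2", s), 5)
  expect_equal(evaluate_gpr("(g1 and g2) or g3", s), 2)
  expect_equal(evaluate_gpr("g1 or g2", s, or_rule = "sum"), 7)
  expect_true(is.na(evaluate_gpr("", s)))
  # absent propagation: complex with an unscored subunit is absent,
  # isozyme set falls back to the scored alternative
  expect_true(is.na(evaluate_gpr("g1 and gX", s)))
  expect_equal(evaluate_gpr("g1 or gX", s), 5)
  expect_equal(evaluate_gpr("g1 and gX", s, absent_and = "ignore"), 5)
})

test_that("GPR evaluation is monotone in every gene score", {
  rules <- c("g1 and g2", "(g1 and g2) or g3", "g1 or (g2 and g3)")
  set.seed(42)
  for (rule in rules) for (or_rule in c("max", "sum")) {
    for (rep in 1:20) {
      s <- stats::setNames(stats::runif(3, 0, 20), c("g1", "g2", "g3"))
      base <- evaluate_gpr(rule, s, or_rule = or_rule)
      g <- sample(names(s), 1)
      s2 <- s; s2[g] <- s2[g] + stats::runif(1, 0, 10)
      expect_gte(evaluate_gpr(rule, s2, or_rule = or_rule), base)
    }
  }
})

test_that("model construction enforces structural invariants", {
  expect_error(
    metabolic_model("m", data.frame(id = "A", compartment = "c"),
                    data.frame(id = "R1", lower_bound = 0, upper_bound = 1),
                    list(R1 = c(B = 1))),
    "undeclared metabolite")
  expect_error(
    metabolic_model("m", data.frame(id = c("A", "A"), compartment = "c"),
                    data.frame(id = "R1", lower_bound = 0, upper_bound = 1),
                    list(R1 = c(A = 1))),
    "duplicate")
  expect_error(
    metabolic_model("m", data.frame(id = "A", compartment = "c"),
                    data.frame(id = "R1", lower_bound = 2, upper_bound = 1),
                    list(R1 = c(A = 1))),
    "lower_bound")
})

test_that("JSON round trip is the identity on all model fields", {
  m <- toy()
  p <- withr::local_tempfile(fileext = ".json")
  save_model(m, p)
  m2 <- load_model(p)
  expect_identical(m2$reactions, m$reactions)
  expect_identical(m2$metabolites, m$metabolites)
  expect_identical(m2$genes, m$genes)
  expect_equal(as.matrix(m2$S), as.matrix(m$S))
  # and save(load(x)) is byte-stable
  p2 <- withr::local_tempfile(fileext = ".json")
  save_model(m2, p2)
  expect_identical(readLines(p), readLines(p2))
})

test_that("SBML round trip preserves stoichiometry, bounds and GPR semantics", {
  m <- toy()
  p <- withr::local_tempfile(fileext = ".xml")
  save_model(m, p)
  m2 <- load_model(p)
  expect_equal(as.matrix(m2$S), as.matrix(m$S))
  expect_equal(m2$reactions$lower_bound, m$reactions$lower_bound)
  expect_equal(m2$reactions$upper_bound, m$reactions$upper_bound)
  expect_identical(m2$reactions$gpr, m$reactions$gpr)
  expect_identical(m2$reactions$subsystem, m$reactions$subsystem)
  expect_identical(m2$genes, m$genes)
  expect_equal(m2$reactions$objective_coef, m$reactions$objective_coef)
})

test_that("SBML citing an undeclared species is a validation error", {
  m <- toy()
  p <- withr::local_tempfile(fileext = ".xml")
  save_model(m, p)
  txt <- readLines(p)
  txt <- sub('species="B_c"', 'species="GHOST_c"', txt)
  writeLines(txt, p)
  expect_error(load_model(p), "undeclared species.*GHOST", ignore.case = TRUE)
})

test_that("FBA finds the hand-derived optima of the toy network", {
  m <- toy()
  # substrate cap 10 yields 10 ATP in the upper branch; the O2 cap of 5
  # allows 5 flux through oxidation at 2 ATP each: optimum 10 + 10 = 20
  res <- fba(m)
  expect_equal(res$objective, 20, tolerance = 1e-9)
  expect_true(attr(res$flux, "feasible"))
  # halving uptake: 5 + 2 * min(5, 5) = 15
  expect_equal(fba(set_bounds(m, "EX_A", ub = 5))$objective, 15,
               tolerance = 1e-9)
  # closing all exchanges leaves only the zero flux
  m0 <- m
  for (ex in exchange_reactions(m0)) m0 <- set_bounds(m0, ex, ub = 0)
  expect_equal(fba(m0)$objective, 0, tolerance = 1e-12)
})

test_that("FBA reports infeasibility as a status, not a partial flux", {
  m <- toy()
  m <- set_bounds(m, "DM_ATP", lb = 30)  # demand above the attainable 20
  res <- fba(m)
  expect_identical(res$status, "infeasible")
  expect_null(res$flux)
  expect_true(is.na(res$objective))
})

test_that("FBA objective agrees with an independent ridge-QP route on the fleet", {
  for (m in toy_fleet(1:3)) {
    obj <- m$reactions$objective_coef
    mine <- fba(m, "max")$objective
    orc <- oracle_lp_min(-obj, m$S, m$reactions$lower_bound,
                         pmin(m$reactions$upper_bound, 1e6))
    expect_equal(mine, -orc$objective, tolerance = 1e-5)
  }
})

test_that("FVA brackets the optimum flux and detects blocked reactions", {
  m <- toy()
  mfix <- set_bounds(m, "DM_ATP", lb = 20)  # demand fixed at its optimum
  rng <- fva(mfix, c("R_ox", "R_upper"))
  # at optimum the O2 limit forces the oxidative branch to exactly 5
  expect_equal(rng$min[rng$reaction == "R_ox"], 5, tolerance = 1e-8)
  expect_equal(rng$max[rng$reaction == "R_ox"], 5, tolerance = 1e-8)
  expect_equal(rng[rng$reaction == "R_upper", c("min", "max")],
               data.frame(min = 10, max = 10, row.names = 4L),
               tolerance = 1e-8, ignore_attr = TRUE)
  # a reaction uncoupled from everything spans exactly its bounds
  m2 <- metabolic_model(
    "free", data.frame(id = "X", compartment = "c"),
    data.frame(id = c("R_in", "R_out"), lower_bound = 0,
               upper_bound = c(10, 1000),
               objective_coef = c(0, 1)),
    list(R_in = c(X = 1), R_out = c(X = -1)))
  expect_equal(fva(m2, "R_in"), data.frame(reaction = "R_in", min = 0, max = 10),
               tolerance = 1e-9)
  # blocked: sever the fermentation drain, then R_ferm cannot carry flux
  mb <- set_bounds(m, "EX_D", ub = 0)
  rngb <- fva(mb, "R_ferm")
  expect_equal(c(rngb$min, rngb$max), c(0, 0), tolerance = 1e-9)
})

test_that("FVA ranges contain the FBA solution", {
  for (m in toy_fleet(1:3)) {
    sol <- fba(m)
    mfix <- fix_objective(m, 1)
    rng <- fva(mfix)
    v <- as.numeric(sol$flux[rng$reaction])
    expect_true(all(v >= rng$min - 1e-6 & v <= rng$max + 1e-6))
  }
})

test_that("splitting reversible reactions preserves the FBA optimum", {
  m <- toy()
  # add a reversible transport to exercise the split
  mets <- rbind(m$metabolites,
                data.frame(id = "B_m", name = "B_m", compartment = "m"))
  rxns <- rbind(m$reactions,
                data.frame(id = "T_B", lower_bound = -10, upper_bound = 10,
                           gpr = "", subsystem = "Transport",
                           objective_coef = 0))
  S <- rbind(cbind(as.matrix(m$S)), B_m = 0)
  S <- cbind(S, T_B = 0)
  S["B_c", "T_B"] <- -1; S["B_m", "T_B"] <- 1
  mr <- metabolic_model("toy-rev", mets, rxns, S, genes = m$genes,
                        compartments = c(m$compartments))
  sp <- split_reversible(mr)
  expect_equal(sp$model$reactions$lower_bound[
    sp$model$reactions$id %in% c("T_B__fwd", "T_B__bwd")], c(0, 0))
  expect_equal(sp$model$reactions$upper_bound[
    sp$model$reactions$id == "T_B__bwd"], 10)
  expect_equal(fba(sp$model)$objective, fba(mr)$objective, tolerance = 1e-6)
  # irreversible model: identity mapping, unchanged model
  sp0 <- split_reversible(m)
  expect_identical(sp0$model$reactions, m$reactions)
  expect_true(all(is.na(sp0$map$backward)))
  # split fluxes map back to a feasible original flux
  v_split <- fba(sp$model)$flux
  v <- fluxshift:::unsplit_flux(v_split, sp$map)
  expect_lt(max_infeasibility(v, mr), 1e-6)
})

test_that("general constraint rows restrict the polytope as stated", {
  m <- toy()
  # cap total uptake of A and O2 at 6: optimum drops accordingly
  mc <- add_constraint(m, c(EX_A = 1, EX_O2 = 1), lb = 0, ub = 6)
  expect_lt(fba(mc)$objective, fba(m)$objective)
  expect_error(add_constraint(mc, c(EX_A = 1), lb = 0, ub = 1,
                              id = "penalty_budget"), NA)
})

test_that("flux TSV export carries reaction metadata", {
  m <- toy()
  sol <- fba(m)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_flux_tsv(sol$flux, m, p)
  df <- read.delim(p)
  expect_identical(names(df), c("reaction_id", "flux", "lb", "ub", "subsystem"))
  expect_identical(df$reaction_id, m$reactions$id)
})
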