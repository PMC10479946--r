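# Synthetic-data module: toy networks with known optima, ground-truth flux
# perturbations, expression/DE tables consistent with them, and noisy flux
# measurements, so every pipeline stage is testable without any download.

#' Build a toy metabolic network
#'
#' The canonical fixture `"glyc-ox-8"` is an 8-reaction, 6-metabolite
#' caricature of glycolysis plus oxidative phosphorylation: substrate A is
#' taken up (`EX_A`, cap 10) and split to B with 1 ATP (`R_upper`, gene g1);
#' B is either oxidized with O2 (`EX_O2`, cap 5) to C yielding 2 further ATP
#' (`R_ox`, complex "g2 and g3") or fermented to D (`R_ferm`, isozymes
#' "g4 or g5"); C and D are secreted and ATP is drained by the demand
#' `DM_ATP`, the model objective (its maximum is 10 + 2*5 = 20). The ATP
#' demand doubles as the biomass stand-in.
#'
#' Alternatively a randomized feasible network can be generated from
#' parameters; infeasible draws are regenerated with the next seed.
#'
#' @param spec either the string `"glyc-ox-8"` or a list with elements
#'   `n_mid` (number of chained intermediates, >= 1), `n_branch` (number of
#'   alternative drain branches, >= 1) and `seed`.
#' @param max_retries retry budget for randomized specs.
#' @return a `metabolic_model`.
#' @export
toy_network <- function(spec = "glyc-ox-8", max_retries = 10L) {
  if (identical(spec, "glyc-ox-8")) return(toy_glyc_ox_8())
  stopifnot(is.list(spec), !is.null(spec$seed))
  n_mid <- spec$n_mid %||% 3L
  n_branch <- spec$n_branch %||% 2L
  for (k in seq_len(max_retries)) {
    model <- random_toy_network(n_mid, n_branch, spec$seed + k - 1L)
    opt <- fba(model, "max")
    if (opt$status == "optimal" && opt$objective > 1e-6) return(model)
  }
  stop("could not generate a feasible toy network in ", max_retries, " tries")
}

toy_glyc_ox_8 <- function() {
  mets <- data.frame(
    id = c("A_c", "B_c", "C_c", "D_c", "O2_m", "ATP_c"),
    name = c("substrate A", "intermediate B", "oxidation product C",
             "fermentation product D", "oxygen", "ATP"),
    compartment = c("c", "c", "c", "c", "m", "c"),
    stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("EX_A", "EX_O2", "R_upper", "R_ox", "R_ferm", "EX_C", "EX_D", "DM_ATP"),
    lower_bound = c(0, 0, 0, 0, 0, 0, 0, 0),
    upper_bound = c(10, 5, 1000, 1000, 1000, 1000, 1000, 1000),
    gpr = c("", "", "g1", "g2 and g3", "g4 or g5", "", "", ""),
    subsystem = c("Exchange", "Exchange", "Glycolysis-like", "OxPhos-like",
                  "Glycolysis-like", "Exchange", "Exchange", "Demand"),
    objective_coef = c(0, 0, 0, 0, 0, 0, 0, 1),
    stringsAsFactors = FALSE)
  stoich <- list(
    EX_A = c(A_c = 1), EX_O2 = c(O2_m = 1),
    R_upper = c(A_c = -1, B_c = 1, ATP_c = 1),
    R_ox = c(B_c = -1, O2_m = -1, C_c = 1, ATP_c = 2),
    R_ferm = c(B_c = -1, D_c = 1),
    EX_C = c(C_c = -1), EX_D = c(D_c = -1), DM_ATP = c(ATP_c = -1))
  metabolic_model("glyc-ox-8", mets, rxns, stoich)
}

random_toy_network <- function(n_mid, n_branch, seed) {
  with_seed(seed, {
    mets <- c("A_c", paste0("M", seq_len(n_mid), "_c"), "ATP_c",
              paste0("P", seq_len(n_branch), "_c"))
    chain_ids <- paste0("R_chain", seq_len(n_mid + 1L))
    chain_genes <- paste0("gc", seq_len(n_mid + 1L))
    stoich <- list(EX_A = c(A_c = 1))
    nodes <- c("A_c", paste0("M", seq_len(n_mid), "_c"), "ATP_c")
    rid <- character(); glist <- character(); sub <- character()
    for (i in seq_len(n_mid + 1L)) {
      coefs <- stats::setNames(c(-1, 1), c(nodes[i], nodes[i + 1L]))
      stoich[[chain_ids[i]]] <- coefs
      rid <- c(rid, chain_ids[i]); glist <- c(glist, chain_genes[i])
      sub <- c(sub, "Chain")
    }
    last_mid <- nodes[n_mid + 1L]
    for (j in seq_len(n_branch)) {
      bid <- paste0("R_branch", j)
      stoich[[bid]] <- stats::setNames(c(-1, 1), c(last_mid, paste0("P", j, "_c")))
      stoich[[paste0("EX_P", j)]] <- stats::setNames(-1, paste0("P", j, "_c"))
      rid <- c(rid, bid, paste0("EX_P", j))
      glist <- c(glist, paste0("gb", j), "")
      sub <- c(sub, "Branch", "Exchange")
    }
    stoich[["DM_ATP"]] <- c(ATP_c = -1)
    all_ids <- c("EX_A", rid, "DM_ATP")
    all_gpr <- c("", glist, "")
    all_sub <- c("Exchange", sub, "Demand")
    ub <- stats::setNames(rep(1000, length(all_ids)), all_ids)
    ub["EX_A"] <- stats::runif(1, 2, 20)
    for (j in seq_len(n_branch)) {
      ub[paste0("R_branch", j)] <- stats::runif(1, 0.5, 10)
    }
    rxns <- data.frame(id = all_ids, lower_bound = 0,
                       upper_bound = as.numeric(ub[all_ids]),
                       gpr = all_gpr, subsystem = all_sub,
                       objective_coef = as.numeric(all_ids == "DM_ATP"),
                       stringsAsFactors = FALSE)
    met_df <- data.frame(id = mets, name = mets,
                         compartment = sub("^.*_", "", mets),
                         stringsAsFactors = FALSE)
    metabolic_model(paste0("rand-toy-", seed), met_df, rxns,
                    stoich[all_ids])
  })
}

# Run code under a local RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Project a requested flux perturbation onto the feasible set
#'
#' Takes a feasible control flux vector and a plan of per-reaction
#' multipliers (e.g. `list(R_ferm = 2, R_ox = 0.5)`), forms the target
#' `v_control * multiplier` and solves the QP `min sum w_i (v_i -
#' target_i)^2` subject to `S v = 0` and the model bounds. Planned
#' reactions carry unit weight; unplanned reactions carry only a weak
#' ridge toward the control state (`soft_weight`), enough to pin an
#' otherwise-degenerate projection without diluting the requested shift.
#' The achieved fold changes, not the requested ones, are the ground truth
#' reported for downstream recovery tests.
#'
#' @param model a `metabolic_model`.
#' @param v_control feasible named flux vector.
#' @param plan named list/vector of multipliers.
#' @param zero_tol fluxes with `|v_control|` below this get no defined fold
#'   change (`NA` in `achieved_fc`).
#' @param soft_weight ridge weight on unplanned reactions (default 1e-2).
#' @return list: `v_treated` (a [flux_distribution()]), `achieved_fc`
#'   (named vector, `NA` where undefined), `requested_fc`.
#' @export
perturb_fluxes <- function(model, v_control, plan = list(), zero_tol = 1e-9,
                           soft_weight = 1e-2) {
  ids <- model$reactions$id
  v_control <- v_control[ids]
  mult <- stats::setNames(rep(1, length(ids)), ids)
  if (length(plan)) {
    rxn_index(model, names(plan))  # validates ids
    mult[names(plan)] <- unlist(plan)
  }
  target <- as.numeric(v_control) * mult
  wts <- ifelse(ids %in% names(plan), 1, soft_weight)
  sol <- solve_qp_box(Dvec = wts, target = target,
                      S = model$S, lb = model$reactions$lower_bound,
                      ub = model$reactions$upper_bound)
  if (sol$status != "optimal") {
    stop("perturbation projection failed (", sol$status, "); binding constraints: ",
         paste(ids[sol$binding %||% integer()], collapse = ", "))
  }
  v_treated <- flux_distribution(stats::setNames(sol$x, ids), model)
  achieved <- ifelse(abs(as.numeric(v_control)) > zero_tol,
                     as.numeric(v_treated) / as.numeric(v_control), NA_real_)
  list(v_treated = v_treated,
       achieved_fc = stats::setNames(achieved, ids),
       requested_fc = mult)
}

# min sum(Dvec_i * (x_i - target_i)^2)  s.t.  S x = 0, lb <= x <= ub.
# Thin wrapper over quadprog::solve.QP with box bounds as inequality rows.
solve_qp_box <- function(Dvec, target, S, lb, ub, scale = TRUE) {
  n <- length(target)
  d <- pmax(Dvec, 0)
  sc <- if (scale) max(d, 1e-12) else 1
  Dmat <- diag(2 * d / sc, n)
  dvec <- 2 * d * target / sc
  Seq <- as.matrix(S)
  lb <- pmax(lb, -LP_BIG); ub <- pmin(ub, LP_BIG)
  Amat <- cbind(t(Seq), diag(n), -diag(n))
  bvec <- c(rep(0, nrow(Seq)), lb, -ub)
  res <- tryCatch(
    quadprog::solve.QP(Dmat, dvec, Amat, bvec, meq = nrow(Seq)),
    error = function(e) e)
  if (inherits(res, "error")) {
    status <- if (grepl("no solution|constraints are inconsistent",
                        conditionMessage(res))) "infeasible" else "solver_error"
    return(list(status = status, x = NULL, message = conditionMessage(res)))
  }
  x <- pmin(pmax(res$solution, lb), ub)
  list(status = "optimal", x = x,
       objective = sum(d * (x - target)^2), message = "ok")
}

#' Simulate expression profiles and a DE table from a flux perturbation
#'
#' Per-gene baseline FPKM is drawn log-normally (median 10). Each gene
#' inherits the achieved flux fold change of its reaction (the reaction with
#' the largest control flux magnitude, when a gene serves several), so at
#' `noise_cv = 0` the expression fold change equals the flux fold change
#' exactly — recovery failures downstream then implicate the pipeline, not
#' the generator. Samples get multiplicative log-normal noise of the given
#' coefficient of variation.
#'
#' The DE table reports the ratio-of-means fold change and an FDR from a
#' two-sample t statistic on log values (BH-adjusted). With `noise_cv = 0`
#' the t statistic is undefined and the table uses a labeling convention:
#' FDR `1e-9` for any gene whose fold change differs from 1, FDR 1 otherwise.
#' This FDR is a convention for exercising significance weighting in tests,
#' not a statistical claim about real RNA-seq.
#'
#' @param model a `metabolic_model`.
#' @param v_control,v_treated feasible flux vectors (control/treated).
#' @param noise_cv per-sample multiplicative noise CV (default 0.1).
#' @param n_samples samples per condition (default 4, a typical donor count).
#' @param seed RNG seed.
#' @param conditions labels for the two conditions.
#' @return list: `profile` (an [expression_profile()] covering both
#'   conditions), `de_table` (data.frame gene, log2FC, FC, pvalue, FDR),
#'   `gene_fc` (named true fold changes).
#' @export
synth_expression <- function(model, v_control, v_treated, noise_cv = 0.1,
                             n_samples = 4L, seed = 1L,
                             conditions = c("control", "treated")) {
  genes <- model$genes
  ids <- model$reactions$id
  achieved <- ifelse(abs(v_control[ids]) > 1e-9,
                     as.numeric(v_treated[ids]) / as.numeric(v_control[ids]),
                     NA_real_)
  names(achieved) <- ids
  gene_fc <- stats::setNames(rep(1, length(genes)), genes)
  for (g in genes) {
    owners <- ids[vapply(model$reactions$gpr,
                         function(r) g %in% gpr_genes(gpr_parse(r)), logical(1))]
    if (!length(owners)) next
    main <- owners[which.max(abs(v_control[owners]))]
    fc <- achieved[[main]]
    if (!is.na(fc)) gene_fc[g] <- abs(fc)
  }
  with_seed(seed, {
    base <- stats::rlnorm(length(genes), meanlog = log(10), sdlog = 1)
    names(base) <- genes
    sdlog <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) else 0
    draw <- function(mean_fpkm) {
      if (sdlog == 0) return(matrix(rep(mean_fpkm, n_samples), ncol = n_samples))
      matrix(mean_fpkm * stats::rlnorm(length(mean_fpkm) * n_samples,
                                       meanlog = -sdlog^2 / 2, sdlog = sdlog),
             ncol = n_samples)
    }
    ctrl <- draw(base)
    trt <- draw(base * gene_fc)
    fpkm <- cbind(ctrl, trt)
    rownames(fpkm) <- genes
    colnames(fpkm) <- c(paste0(conditions[1], "_", seq_len(n_samples)),
                        paste0(conditions[2], "_", seq_len(n_samples)))
    cond_map <- stats::setNames(rep(conditions, each = n_samples), colnames(fpkm))
    fc_obs <- rowMeans(trt) / rowMeans(ctrl)
    if (sdlog == 0) {
      p <- ifelse(abs(log2(fc_obs)) > 1e-12, 1e-9, 1)
    } else {
      p <- vapply(seq_along(genes), function(i) {
        stats::t.test(log(trt[i, ] + 1e-12), log(ctrl[i, ] + 1e-12))$p.value
      }, numeric(1))
      p <- pmax(p, 1e-12)
    }
    de <- data.frame(gene = genes, log2FC = log2(fc_obs), FC = fc_obs,
                     pvalue = p, FDR = pmin(stats::p.adjust(p, "BH"), 1),
                     stringsAsFactors = FALSE)
    list(profile = expression_profile(fpkm, cond_map),
         de_table = de, gene_fc = gene_fc)
  })
}

#' Simulate noisy flux measurements
#'
#' Emulates respiration-style measured rates: for each requested reaction
#' the reported mean is the true flux perturbed by relative Gaussian noise
#' of size `cv`, and the reported standard deviation is `cv * |mean|`
#' floored at `1e-3`. Oxygen-exchange and ATP-demand reactions are labeled
#' OCR and ATP_production respectively.
#'
#' @param v_true named true flux vector.
#' @param reactions reaction ids to "measure".
#' @param cv relative noise / reported CV (default 0.05). `cv = 0` reports
#'   the true flux exactly.
#' @param seed RNG seed.
#' @return data.frame with columns `parameter`, `reaction`, `mean`, `sd`,
#'   `units`, `conversion` (a measurements table for [apply_measurements()]).
#' @export
synth_measurements <- function(v_true, reactions, cv = 0.05, seed = 1L) {
  missing <- setdiff(reactions, names(v_true))
  if (length(missing)) stop("unknown reaction(s): ", paste(missing, collapse = ", "))
  with_seed(seed, {
    truth <- as.numeric(v_true[reactions])
    mean_v <- truth * (1 + stats::rnorm(length(truth), 0, cv))
    sd_v <- pmax(cv * abs(mean_v), 1e-3)
    param <- ifelse(grepl("O2", reactions), "OCR",
                    ifelse(grepl("ATP", reactions), "ATP_production", reactions))
    data.frame(parameter = param, reaction = reactions, mean = mean_v,
               sd = sd_v, units = "model_flux", conversion = 1,
               stringsAsFactors = FALSE)
  })
}

#' Generate a complete ground-truth scenario
#'
#' Bundles everything one pipeline run consumes, with a known answer: the
#' toy model, a control flux state (minimal-total-flux FBA optimum), a
#' feasible perturbed state from `plan`, expression/DE tables consistent
#' with the achieved fold changes, and measurements of the treated state.
#'
#' @param seed master seed.
#' @param spec forwarded to [toy_network()].
#' @param plan perturbation plan. The default (fermentation x1.6,
#'   oxidation x0.4) is the classic drug-induced glycolytic shift, sized so
#'   the requested state is exactly feasible on the canonical toy (the
#'   branch fluxes re-balance the fixed substrate supply: 5*1.6 + 5*0.4 =
#'   10), making requested and achieved fold changes coincide.
#' @param noise_cv expression noise CV (default 0: noiseless, exact truth).
#' @param measurement_cv measurement noise (default 0).
#' @param measure reaction ids to measure (default oxygen exchange + ATP
#'   demand when present).
#' @param biomass_fraction demand floor used for the control state
#'   (default 1: the control is the minimal-total-flux state at the full
#'   growth optimum, so both the oxidative and fermentative branches carry
#'   flux and perturbing either is observable).
#' @return object of class `flux_scenario`.
#' @export
ground_truth_scenario <- function(seed = 1L, spec = "glyc-ox-8",
                                  plan = list(R_ferm = 1.6, R_ox = 0.4),
                                  noise_cv = 0, measurement_cv = 0,
                                  measure = NULL,
                                  biomass_fraction = 1) {
  model <- toy_network(spec)
  plan <- plan[names(plan) %in% model$reactions$id]
  pen0 <- stats::setNames(rep(0, nrow(model$reactions)), model$reactions$id)
  ctrl_fit <- gim3e_minimize(model, pen0, biomass_fraction = biomass_fraction,
                             uniform_fallback = 1)
  v_control <- ctrl_fit$flux
  pert <- perturb_fluxes(model, v_control, plan)
  expr <- synth_expression(model, v_control, pert$v_treated,
                           noise_cv = noise_cv, seed = seed)
  if (is.null(measure)) {
    measure <- intersect(c("EX_O2", "DM_ATP"), model$reactions$id)
  }
  meas <- if (length(measure)) {
    synth_measurements(pert$v_treated, measure, cv = measurement_cv,
                       seed = seed + 1L)
  } else NULL
  structure(list(model = model, v_control = v_control,
                 v_treated = pert$v_treated, achieved_fc = pert$achieved_fc,
                 profile = expr$profile, de_table = expr$de_table,
                 gene_fc = expr$gene_fc, measurements = meas,
                 plan = plan, seed = seed),
            class = "flux_scenario")
}

#' @export
print.flux_scenario <- function(x, ...) {
  cat("<flux_scenario> model=", x$model$id, " seed=", x$seed, "\n", sep = "")
  shown <- x$achieved_fc[!is.na(x$achieved_fc) & abs(x$achieved_fc - 1) > 1e-9]
  if (length(shown)) {
    cat("  achieved flux fold changes:\n")
    for (i in seq_along(shown)) {
      cat(sprintf("    %-10s x%.3f\n", names(shown)[i], shown[i]))
    }
  } else cat("  identity perturbation\n")
  invisible(x)
}

#' Write a scenario's files to a directory
#'
#' Emits exactly the formats the pipeline consumes — model JSON, expression
#' TSV + condition-map JSON, DE TSV, measurements JSON — plus
#' `ground_truth.json` (true flux vectors, achieved fold changes, seed).
#'
#' @param scenario a `flux_scenario`.
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(model = file.path(dir, "model.json"),
             expression = file.path(dir, "expression.tsv"),
             conditions = file.path(dir, "conditions.json"),
             de = file.path(dir, "de_treated.tsv"),
             measurements = file.path(dir, "measurements.json"),
             truth = file.path(dir, "ground_truth.json"))
  save_model(scenario$model, paths[["model"]], format = "json")
  write_expression_tsv(scenario$profile, paths[["expression"]], paths[["conditions"]])
  utils::write.table(scenario$de_table, paths[["de"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meas <- scenario$measurements
  jsonlite::write_json(if (is.null(meas)) list() else meas,
                       paths[["measurements"]], auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  jsonlite::write_json(
    list(seed = scenario$seed,
         v_control = as.list(stats::setNames(as.numeric(scenario$v_control),
                                             names(scenario$v_control))),
         v_treated = as.list(stats::setNames(as.numeric(scenario$v_treated),
                                             names(scenario$v_treated))),
         achieved_fc = as.list(stats::setNames(as.numeric(scenario$achieved_fc),
                                               names(scenario$achieved_fc)))),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
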