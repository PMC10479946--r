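# Context builder: condition-specific model construction from a template
# model plus expression (FPKM), medium composition and measured rates.

#' Construct an expression profile
#'
#' @param fpkm numeric matrix, genes x samples, of FPKM values (>= 0).
#' @param conditions named character vector mapping sample (column) name to
#'   condition label; every condition needs at least one sample.
#' @return object of class `expression_profile`.
#' @export
expression_profile <- function(fpkm, conditions) {
  fpkm <- as.matrix(fpkm)
  if (any(fpkm < 0)) stop("FPKM values must be non-negative")
  if (anyDuplicated(rownames(fpkm))) stop("duplicate gene ids")
  if (is.null(names(conditions)) || !setequal(names(conditions), colnames(fpkm))) {
    stop("conditions must be named by the FPKM column (sample) names")
  }
  conditions <- conditions[colnames(fpkm)]
  structure(list(fpkm = fpkm, conditions = conditions),
            class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat("<expression_profile> ", nrow(x$fpkm), " genes x ", ncol(x$fpkm),
      " samples; conditions: ",
      paste(unique(x$conditions), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Per-gene mean FPKM within one condition
#'
#' @param profile an `expression_profile`.
#' @param condition condition label.
#' @return named numeric vector of per-gene means.
#' @export
condition_means <- function(profile, condition) {
  cols <- names(profile$conditions)[profile$conditions == condition]
  if (!length(cols)) stop("unknown condition: ", condition)
  rowMeans(profile$fpkm[, cols, drop = FALSE])
}

#' Map condition-level gene expression onto reactions through GPR rules
#'
#' Folds per-gene mean FPKM through each reaction's GPR with
#' [evaluate_gpr()]. Reactions with no gene association score `NA`
#' ("absent") and are exempt from expression-based decisions downstream.
#'
#' @param model a `metabolic_model`.
#' @param profile an `expression_profile`.
#' @param condition condition label.
#' @param and_rule,or_rule forwarded to [evaluate_gpr()].
#' @return named numeric vector (reaction -> score, `NA` = absent).
#' @export
reaction_expression <- function(model, profile, condition,
                                and_rule = "min", or_rule = "max") {
  means <- condition_means(profile, condition)
  scores <- vapply(model$reactions$gpr, function(g) {
    evaluate_gpr(g, means, and_rule = and_rule, or_rule = or_rule)
  }, numeric(1), USE.NAMES = FALSE)
  stats::setNames(scores, model$reactions$id)
}

#' Construct a growth-medium specification
#'
#' @param uptake named numeric vector: exchange reaction id -> maximal
#'   uptake rate (model flux units, >= 0).
#' @param secretion named numeric vector of secretion caps; defaults to
#'   unlimited for all listed exchanges.
#' @return data.frame of class `medium_spec` (columns `reaction`, `uptake`,
#'   `secretion`).
#' @export
medium_spec <- function(uptake, secretion = NULL) {
  if (any(uptake < 0)) stop("uptake bounds must be >= 0")
  out <- data.frame(reaction = as.character(names(uptake) %||% character()),
                    uptake = as.numeric(uptake),
                    secretion = rep(LP_BIG, length(uptake)),
                    stringsAsFactors = FALSE)
  if (!is.null(secretion)) {
    if (any(secretion < 0)) stop("secretion bounds must be >= 0")
    out$secretion[match(names(secretion), out$reaction)] <- as.numeric(secretion)
  }
  class(out) <- c("medium_spec", "data.frame")
  out
}

# Exchange orientation: the flux direction that produces the single
# metabolite is "uptake" (source into the network). Returns +1 when the
# metabolite coefficient is positive (uptake = positive flux), -1 when
# negative (uptake = negative flux, the common "A ->" convention).
exchange_orientation <- function(model, id) {
  col <- model$S[, rxn_index(model, id)]
  nz <- which(col != 0)
  if (length(nz) != 1L) stop("'", id, "' is not an exchange reaction")
  sign(col[nz])
}

#' Apply medium constraints to a model
#'
#' Every exchange reaction not listed in the medium is closed for uptake
#' (secretion stays as in the template). Listed exchanges get their uptake
#' bound set to the minimum of the medium value and the template's own
#' capacity (the conservative choice when the medium asks for more than the
#' template allows; such clips are logged).
#'
#' @param model a `metabolic_model`.
#' @param medium a [medium_spec()].
#' @return the constrained model (provenance appended to `model$log`).
#' @export
apply_medium <- function(model, medium) {
  ex <- exchange_reactions(model)
  bad <- setdiff(medium$reaction, ex)
  if (length(bad)) {
    stop("medium lists non-exchange reaction(s): ", paste(bad, collapse = ", "))
  }
  for (id in ex) {
    orient <- exchange_orientation(model, id)
    i <- rxn_index(model, id)
    row <- medium[medium$reaction == id, ]
    if (nrow(row) == 0L) {  # not in medium: close uptake
      if (orient > 0) model$reactions$upper_bound[i] <- min(model$reactions$upper_bound[i], 0)
      else model$reactions$lower_bound[i] <- max(model$reactions$lower_bound[i], 0)
      model <- log_event(model, stage = "medium", reaction = id,
                         action = "uptake_closed")
    } else {
      if (orient > 0) {
        cap <- model$reactions$upper_bound[i]
        model$reactions$upper_bound[i] <- min(cap, row$uptake)
        model$reactions$lower_bound[i] <- max(model$reactions$lower_bound[i],
                                              -row$secretion)
      } else {
        cap <- -model$reactions$lower_bound[i]
        model$reactions$lower_bound[i] <- -min(cap, row$uptake)
        model$reactions$upper_bound[i] <- min(model$reactions$upper_bound[i],
                                              row$secretion)
      }
      clipped <- row$uptake > cap
      model <- log_event(model, stage = "medium", reaction = id,
                         action = if (clipped) "uptake_clipped_to_template" else "uptake_set",
                         requested = row$uptake, applied = min(cap, row$uptake))
    }
  }
  model
}

#' Constrain a model with measured rates
#'
#' Intersects each mapped reaction's bounds with the measurement interval
#' `mean +/- k_sd * sd` (after unit conversion). `k_sd = 0` fixes the
#' reaction to the measured mean.
#'
#' @param model a `metabolic_model`.
#' @param measurements data.frame with columns `parameter`, `reaction`,
#'   `mean`, `sd` and optionally `conversion` (factor to model flux units,
#'   default 1) — the shape produced by [synth_measurements()].
#' @param k_sd half-width of the accepted interval in standard deviations
#'   (default 2).
#' @return the constrained model.
#' @export
apply_measurements <- function(model, measurements, k_sd = 2) {
  if (is.null(measurements) || nrow(measurements) == 0L) return(model)
  if (is.null(measurements$conversion)) measurements$conversion <- 1
  for (j in seq_len(nrow(measurements))) {
    m <- measurements[j, ]
    i <- rxn_index(model, m$reaction)
    ctr <- m$mean * m$conversion
    half <- k_sd * m$sd * m$conversion
    lo <- max(model$reactions$lower_bound[i], ctr - half)
    hi <- min(model$reactions$upper_bound[i], ctr + half)
    if (lo > hi + 1e-12) {
      stop("measurement '", m$parameter, "' (reaction ", m$reaction,
           "): interval [", ctr - half, ", ", ctr + half,
           "] does not intersect bounds [",
           model$reactions$lower_bound[i], ", ",
           model$reactions$upper_bound[i], "]")
    }
    model$reactions$lower_bound[i] <- lo
    model$reactions$upper_bound[i] <- max(hi, lo)
    model <- log_event(model, stage = "measurements", reaction = m$reaction,
                       parameter = m$parameter, lb = lo, ub = hi)
  }
  model
}

#' Context-builder configuration
#'
#' @param fpkm_threshold expression floor: reactions scoring strictly below
#'   it are pruning candidates (default 1 FPKM).
#' @param biomass_fraction feasibility guard: pruning must preserve at least
#'   this fraction of the template's biomass optimum (default 0.2).
#' @param de_fdr_threshold FDR gate for condition-specific removal
#'   (default 0.05).
#' @param biomass_reaction id of the biomass (or stand-in demand) reaction;
#'   `NULL` uses the model objective.
#' @param k_sd measurement interval half-width (default 2).
#' @return list of class `context_config`.
#' @export
context_config <- function(fpkm_threshold = 1, biomass_fraction = 0.2,
                           de_fdr_threshold = 0.05, biomass_reaction = NULL,
                           k_sd = 2) {
  stopifnot(fpkm_threshold > 0, biomass_fraction > 0, biomass_fraction <= 1,
            de_fdr_threshold > 0)
  structure(list(fpkm_threshold = fpkm_threshold,
                 biomass_fraction = biomass_fraction,
                 de_fdr_threshold = de_fdr_threshold,
                 biomass_reaction = biomass_reaction, k_sd = k_sd),
            class = "context_config")
}

# Biomass optimum of `model` maximizing the designated reaction.
biomass_optimum <- function(model, config) {
  m <- model
  if (!is.null(config$biomass_reaction)) {
    m$reactions$objective_coef <- as.numeric(m$reactions$id == config$biomass_reaction)
  }
  fba(m, "max")
}

# Greedy guarded removal shared by both pruning rules. `candidates` is a
# data.frame(reaction, score_key) pre-filtered by the caller's rule;
# removal proceeds in ascending score_key order (ties by id) and each step
# is kept only if the reduced model still reaches `floor_value` of biomass
# (measurement bounds are already part of the model, so feasibility at the
# floor implies the measured rates remain attainable).
guarded_removal <- function(model, candidates, floor_value, config, rule) {
  protected <- unique(c(
    if (!is.null(config$biomass_reaction)) config$biomass_reaction,
    objective_ids(model)))
  log <- list()
  ord <- order(candidates$score_key, candidates$reaction)
  for (k in ord) {
    id <- candidates$reaction[k]
    if (!(id %in% model$reactions$id)) next
    if (id %in% protected) {
      log[[length(log) + 1L]] <- list(stage = rule, reaction = id,
                                      action = "retained", reason = "protected")
      next
    }
    trial <- remove_reactions(model, id)
    opt <- biomass_optimum(trial, config)
    ok <- opt$status == "optimal" && opt$objective >= floor_value - 1e-9
    if (ok) {
      model <- trial
      log[[length(log) + 1L]] <- list(stage = rule, reaction = id,
                                      action = "removed",
                                      score = candidates$score_key[k],
                                      biomass_after = opt$objective)
    } else {
      log[[length(log) + 1L]] <- list(
        stage = rule, reaction = id, action = "retained",
        reason = if (opt$status != "optimal") "infeasible" else "essential",
        biomass_after = if (opt$status == "optimal") opt$objective else NA)
    }
  }
  model$log <- c(model$log, log)
  list(model = model, log = log)
}

#' Remove reactions silent in every condition
#'
#' Pruning rule for globally unexpressed enzymes: a reaction is a candidate
#' when its GPR score is strictly below `fpkm_threshold` in *all*
#' conditions (reactions with no gene association are exempt). Candidates
#' are removed greedily in ascending order of their maximum
#' across-condition score (ties by reaction id), and each removal is kept
#' only if the model still attains `biomass_fraction` of the template
#' optimum while satisfying any measurement bounds already applied.
#'
#' @param model a `metabolic_model` (medium/measurement constraints already
#'   applied).
#' @param profile an `expression_profile` covering all conditions.
#' @param config a [context_config()].
#' @return list: `model` (pruned), `log` (one record per candidate
#'   decision), `floor` (the biomass floor enforced).
#' @export
prune_globally_silent <- function(model, profile, config = context_config()) {
  opt0 <- biomass_optimum(model, config)
  if (opt0$status != "optimal") {
    stop("template model infeasible before pruning (status ", opt0$status, ")")
  }
  floor_value <- config$biomass_fraction * opt0$objective
  conds <- unique(profile$conditions)
  scores <- sapply(conds, function(cc) reaction_expression(model, profile, cc))
  scores <- matrix(scores, ncol = length(conds),
                   dimnames = list(model$reactions$id, conds))
  silent <- apply(scores, 1, function(s) all(!is.na(s) & s < config$fpkm_threshold))
  cand <- data.frame(reaction = rownames(scores)[silent],
                     score_key = apply(scores[silent, , drop = FALSE], 1, max),
                     stringsAsFactors = FALSE)
  res <- guarded_removal(model, cand, floor_value, config, "global_prune")
  c(res, list(floor = floor_value))
}

#' Remove enzymes switched off by a treatment
#'
#' Condition-specific rule: reactions whose GPR contains a differentially
#' expressed gene (FDR below `de_fdr_threshold`), scoring below
#' `fpkm_threshold` in the treated condition but at or above it untreated,
#' are removed from that condition's model — under the same biomass /
#' measurement feasibility guard as [prune_globally_silent()].
#'
#' @param model the (already globally pruned) `metabolic_model`.
#' @param de_table data.frame with columns `gene` and `FDR`.
#' @param profile an `expression_profile`.
#' @param condition treated condition label.
#' @param untreated untreated condition label.
#' @param config a [context_config()].
#' @return list: `model`, `log`, `floor`.
#' @export
prune_condition_specific <- function(model, de_table, profile, condition,
                                     untreated, config = context_config()) {
  if (any(de_table$FDR <= 0 | de_table$FDR > 1)) {
    stop("FDR values must lie in (0, 1]")
  }
  opt0 <- biomass_optimum(model, config)
  if (opt0$status != "optimal") stop("model infeasible before pruning")
  floor_value <- config$biomass_fraction * opt0$objective
  de_genes <- de_table$gene[de_table$FDR < config$de_fdr_threshold]
  s_trt <- reaction_expression(model, profile, condition)
  s_ctl <- reaction_expression(model, profile, untreated)
  has_de <- vapply(model$reactions$gpr, function(g) {
    length(intersect(gpr_genes(gpr_parse(g)), de_genes)) > 0
  }, logical(1), USE.NAMES = FALSE)
  hit <- has_de & !is.na(s_trt) & s_trt < config$fpkm_threshold &
    !is.na(s_ctl) & s_ctl >= config$fpkm_threshold
  cand <- data.frame(reaction = model$reactions$id[hit],
                     score_key = s_trt[hit], stringsAsFactors = FALSE)
  res <- guarded_removal(model, cand, floor_value, config, "condition_prune")
  c(res, list(floor = floor_value))
}

#' Build condition-specific models
#'
#' Orchestrates the full construction: medium constraints, measured-rate
#' bounds, removal of globally silent enzymes (shared by all conditions),
#' then per-treatment removal of enzymes switched off by that treatment.
#' One model per condition is returned together with a machine-readable
#' provenance log of every decision.
#'
#' @param template the template `metabolic_model`.
#' @param profile an `expression_profile` covering all conditions.
#' @param de_tables named list of DE tables, one per treated condition
#'   (names are condition labels); the untreated condition needs none.
#' @param medium optional [medium_spec()].
#' @param measurements optional measurements table (see
#'   [apply_measurements()]).
#' @param config a [context_config()].
#' @param untreated label of the untreated/control condition (default
#'   `"control"`).
#' @return list of class `context_models`: `models` (named list of
#'   per-condition models), `provenance` (list of decision records),
#'   `template_optimum`.
#' @export
build_context_model <- function(template, profile, de_tables = list(),
                                medium = NULL, measurements = NULL,
                                config = context_config(),
                                untreated = "control") {
  model <- template
  if (!is.null(medium)) model <- apply_medium(model, medium)
  model <- apply_measurements(model, measurements, k_sd = config$k_sd)
  opt0 <- biomass_optimum(model, config)
  if (opt0$status != "optimal") {
    stop("template infeasible after medium/measurement constraints")
  }
  shared <- prune_globally_silent(model, profile, config)
  models <- list()
  models[[untreated]] <- shared$model
  prov <- shared$model$log
  for (cond in names(de_tables)) {
    if (!(cond %in% profile$conditions)) {
      # no expression samples for this condition: the expression-gated
      # removal rule cannot fire, so the shared model is used as-is
      models[[cond]] <- shared$model
      prov <- c(prov, list(list(stage = "condition_prune", condition = cond,
                                action = "skipped",
                                reason = "no expression samples")))
      next
    }
    sp <- prune_condition_specific(shared$model, de_tables[[cond]], profile,
                                   cond, untreated, config)
    models[[cond]] <- sp$model
    prov <- c(prov, sp$log)
  }
  structure(list(models = models, provenance = prov,
                 template_optimum = opt0$objective, config = config),
            class = "context_models")
}

#' @export
print.context_models <- function(x, ...) {
  cat("<context_models> template optimum ",
      format(x$template_optimum, digits = 6), "\n", sep = "")
  for (nm in names(x$models)) {
    cat("  ", nm, ": ", nrow(x$models[[nm]]$reactions), " reactions\n", sep = "")
  }
  invisible(x)
}

#' Write expression profile to TSV (+ JSON condition map)
#'
#' @param profile an `expression_profile`.
#' @param path TSV destination (gene x sample).
#' @param conditions_path JSON sidecar destination.
#' @export
write_expression_tsv <- function(profile, path, conditions_path) {
  df <- data.frame(gene = rownames(profile$fpkm), profile$fpkm,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(profile$conditions), conditions_path,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read an expression profile from TSV (+ JSON condition map)
#'
#' @param path TSV with a `gene` column then one column per sample.
#' @param conditions_path JSON mapping sample name to condition.
#' @return an `expression_profile`.
#' @export
read_expression_tsv <- function(path, conditions_path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  fpkm <- as.matrix(df[, -1, drop = FALSE])
  rownames(fpkm) <- df[[1]]
  conds <- unlist(jsonlite::read_json(conditions_path))
  expression_profile(fpkm, conds)
}
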