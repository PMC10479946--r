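# LP layer: all flux-balance LPs go through solve_lp(), which shifts
# variables by their lower bounds (x = v - lb >= 0) and hands the
# resulting standard-form problem to the package's Bland-rule simplex.

LP_BIG <- 1e6  # stand-in for infinite bounds; model caps are ~1e3

solve_lp <- function(obj, S, lb, ub, sense = c("max", "min"), tol = 1e-9) {
  sense <- match.arg(sense)
  lb <- pmax(lb, -LP_BIG); ub <- pmin(ub, LP_BIG)
  n <- length(obj)
  rng <- ub - lb
  cc <- if (sense == "max") -obj else obj
  res <- lp_simplex(cc, as.matrix(S), as.numeric(-S %*% lb), rng, tol = tol)
  if (res$status != "optimal") {
    return(list(status = res$status, x = NULL, objective = NA_real_,
                message = res$status))
  }
  x <- pmin(pmax(res$x, 0), rng)  # snap round-off into the box
  v <- x + lb
  list(status = "optimal", x = v,
       objective = sum(obj * v), message = "ok")
}

#' Flux balance analysis
#'
#' Optimizes the model's linear objective over the steady-state flux cone
#' `S v = 0`, `lb <= v <= ub`.
#'
#' @param model a `metabolic_model` with a non-empty objective.
#' @param sense `"max"` (default) or `"min"`.
#' @return list of class `fba_result`: `objective` (optimal value), `flux`
#'   (a [flux_distribution()] at one optimum), `status` (`"optimal"`,
#'   `"infeasible"` or `"unbounded"`).
#' @export
fba <- function(model, sense = c("max", "min")) {
  sense <- match.arg(sense)
  obj <- model$reactions$objective_coef
  if (all(obj == 0)) stop("model has no objective reaction")
  res <- solve_lp(obj, model$S, model$reactions$lower_bound,
                  model$reactions$upper_bound, sense)
  flux <- if (res$status == "optimal") {
    flux_distribution(stats::setNames(res$x, model$reactions$id), model)
  } else NULL
  structure(list(objective = res$objective, flux = flux,
                 status = res$status, sense = sense, model_id = model$id),
            class = "fba_result")
}

#' @export
print.fba_result <- function(x, ...) {
  cat("<fba_result> ", x$sense, " objective on ", x$model_id,
      ": status=", x$status, sep = "")
  if (x$status == "optimal") cat(", value=", format(x$objective, digits = 8), sep = "")
  cat("\n")
  invisible(x)
}

#' Flux variability analysis
#'
#' Computes, for each queried reaction, the minimum and maximum flux it can
#' carry under the model's current constraints. Any objective-value
#' restriction (e.g. a fraction-of-optimum floor) must already be encoded in
#' the model's bounds or constraint rows — see [fix_objective()].
#'
#' @param model a `metabolic_model`.
#' @param reactions reaction ids to query (default: all).
#' @return data.frame with columns `reaction`, `min`, `max`.
#' @export
fva <- function(model, reactions = NULL) {
  if (is.null(reactions)) reactions <- model$reactions$id
  idx <- rxn_index(model, reactions)
  lb <- model$reactions$lower_bound; ub <- model$reactions$upper_bound
  out <- data.frame(reaction = reactions, min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(idx)) {
    obj <- numeric(nrow(model$reactions)); obj[idx[k]] <- 1
    lo <- solve_lp(obj, model$S, lb, ub, "min")
    hi <- solve_lp(obj, model$S, lb, ub, "max")
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("FVA ", lo$status, " for reaction '", reactions[k], "'")
    }
    out$min[k] <- lo$objective; out$max[k] <- hi$objective
  }
  # round-off can invert near-fixed ranges by ~1e-12
  swap <- out$min > out$max
  if (any(swap)) {
    mid <- (out$min[swap] + out$max[swap]) / 2
    out$min[swap] <- mid; out$max[swap] <- mid
  }
  out
}

#' Constrain the objective to a fraction of its optimum
#'
#' Runs FBA, then raises the objective reaction's lower bound (for a single
#' positive-coefficient objective) or adds a constraint row so the objective
#' value must stay at or above `fraction` times the optimum.
#'
#' @param model a `metabolic_model`.
#' @param fraction fraction of the optimal objective value in (0, 1].
#' @return the constrained model, with attribute `"objective_optimum"`.
#' @export
fix_objective <- function(model, fraction = 1) {
  stopifnot(fraction > 0, fraction <= 1)
  opt <- fba(model, "max")
  if (opt$status != "optimal") stop("cannot fix objective: FBA status ", opt$status)
  obj <- model$reactions$objective_coef
  pos <- which(obj != 0)
  if (length(pos) == 1 && obj[pos] > 0) {
    model$reactions$lower_bound[pos] <-
      max(model$reactions$lower_bound[pos], fraction * opt$objective / obj[pos])
  } else {
    model <- add_constraint(model,
                            stats::setNames(obj[pos], model$reactions$id[pos]),
                            lb = fraction * opt$objective, ub = LP_BIG,
                            id = "objective_floor")
  }
  attr(model, "objective_optimum") <- opt$objective
  model
}

#' Add a general linear constraint row to a model
#'
#' Encodes `lb <= sum(coefs * v) <= ub` with the standard pseudo-metabolite
#' trick: a new balance row plus a slack "reaction" bounded by `[lb, ub]`,
#' so downstream LP/sampling code keeps seeing only `S v = 0` and box
#' bounds. The slack column is tagged with subsystem `"_constraint"`.
#'
#' @param model a `metabolic_model`.
#' @param coefs named numeric vector (names = reaction ids).
#' @param lb,ub bounds for the linear form.
#' @param id label used for the pseudo-metabolite and slack reaction.
#' @return the augmented model.
#' @export
add_constraint <- function(model, coefs, lb, ub, id = "cns") {
  idx <- rxn_index(model, names(coefs))
  met_id <- paste0("_", id, "_bal")
  slack_id <- paste0("_", id, "_slack")
  if (met_id %in% model$metabolites$id) stop("constraint id '", id, "' already used")
  model$metabolites <- rbind(model$metabolites,
                             data.frame(id = met_id, name = met_id,
                                        compartment = model$compartments[1],
                                        stringsAsFactors = FALSE))
  model$reactions <- rbind(model$reactions,
                           data.frame(id = slack_id, lower_bound = lb,
                                      upper_bound = ub, gpr = "",
                                      subsystem = "_constraint",
                                      objective_coef = 0,
                                      stringsAsFactors = FALSE))
  S <- Matrix::Matrix(0, nrow(model$metabolites), nrow(model$reactions),
                      sparse = TRUE,
                      dimnames = list(model$metabolites$id, model$reactions$id))
  S[seq_len(nrow(model$S)), seq_len(ncol(model$S))] <- model$S
  S[met_id, names(coefs)] <- as.numeric(coefs)
  S[met_id, slack_id] <- -1
  model$S <- S
  rownames(model$reactions) <- NULL; rownames(model$metabolites) <- NULL
  validate_model(model)
  model
}

#' Split reversible reactions into irreversible forward/backward pairs
#'
#' Every reaction with a negative lower bound becomes a forward copy with
#' bounds `[0, max(ub, 0)]` and a backward copy (negated stoichiometry) with
#' bounds `[0, -lb]`; `v = v_fwd - v_bwd` recovers the original flux, and
#' the objective value is preserved. Needed to express weighted `|v|`
#' penalties as an LP.
#'
#' @param model a `metabolic_model`.
#' @return list: `model` (irreversible), `map` (data.frame `original`,
#'   `forward`, `backward`; `backward` is `NA` for reactions left untouched).
#' @export
split_reversible <- function(model) {
  r <- model$reactions
  rev_idx <- which(r$lower_bound < 0)
  map <- data.frame(original = r$id, forward = r$id,
                    backward = NA_character_, stringsAsFactors = FALSE)
  if (!length(rev_idx)) {
    return(list(model = model, map = map))
  }
  new_rxns <- list(); new_cols <- list()
  for (i in seq_len(nrow(r))) {
    col <- model$S[, i]
    if (i %in% rev_idx) {
      fwd <- paste0(r$id[i], "__fwd"); bwd <- paste0(r$id[i], "__bwd")
      map$forward[i] <- fwd; map$backward[i] <- bwd
      new_rxns[[length(new_rxns) + 1L]] <-
        data.frame(id = fwd, lower_bound = 0, upper_bound = max(r$upper_bound[i], 0),
                   gpr = r$gpr[i], subsystem = r$subsystem[i],
                   objective_coef = r$objective_coef[i], stringsAsFactors = FALSE)
      new_cols[[length(new_cols) + 1L]] <- col
      new_rxns[[length(new_rxns) + 1L]] <-
        data.frame(id = bwd, lower_bound = 0, upper_bound = -r$lower_bound[i],
                   gpr = r$gpr[i], subsystem = r$subsystem[i],
                   objective_coef = -r$objective_coef[i], stringsAsFactors = FALSE)
      new_cols[[length(new_cols) + 1L]] <- -col
    } else {
      new_rxns[[length(new_rxns) + 1L]] <- r[i, , drop = FALSE]
      new_cols[[length(new_cols) + 1L]] <- col
    }
  }
  rxns <- do.call(rbind, new_rxns)
  S <- do.call(cbind, lapply(new_cols, as.numeric))
  split <- metabolic_model(id = paste0(model$id, "_irrev"),
                           metabolites = model$metabolites,
                           reactions = rxns, stoichiometry = S,
                           genes = model$genes,
                           compartments = model$compartments)
  list(model = split, map = map)
}

# Map a flux vector in split space back to the original reaction space.
unsplit_flux <- function(v_split, map) {
  fwd <- v_split[map$forward]
  bwd <- ifelse(is.na(map$backward), 0, v_split[map$backward])
  bwd[is.na(bwd)] <- 0
  stats::setNames(as.numeric(fwd) - as.numeric(bwd), map$original)
}
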