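# Reference flux estimation: expression-weighted flux minimization
# (GIM3E-style), restriction of the solution space to within a small slack
# of the weighted-penalty optimum, artificially-centered hit-and-run
# sampling, and the sample mean as the reference distribution.

#' Derive flux-minimization penalties from reaction expression
#'
#' GIM3E-style penalties: on the log2(FPKM + 1) scale, every scored
#' reaction pays `s_max - s_i` per unit of absolute flux, so lowly
#' expressed reactions are the most expensive to use and the most highly
#' expressed reaction is free. Reactions without a score (no gene
#' association) get penalty 0. A linear-FPKM variant is available.
#'
#' @param model a `metabolic_model`.
#' @param reaction_scores named score vector from [reaction_expression()].
#' @param form `"log2"` (default: penalties on log2(score + 1)) or
#'   `"linear"` (penalties on the raw score).
#' @return named non-negative penalty vector over all reactions.
#' @export
expression_penalties <- function(model, reaction_scores,
                                 form = c("log2", "linear")) {
  form <- match.arg(form)
  ids <- model$reactions$id
  s <- reaction_scores[ids]
  s <- if (form == "log2") log2(s + 1) else s
  s_max <- suppressWarnings(max(s, na.rm = TRUE))
  if (!is.finite(s_max)) s_max <- 0
  pen <- pmax(0, s_max - s)
  pen[is.na(pen)] <- 0
  stats::setNames(as.numeric(pen), ids)
}

#' Expression-weighted flux minimization
#'
#' Minimizes `sum_i w_i |v_i|` over the steady-state flux space, subject to
#' producing at least `biomass_fraction` of the optimal biomass (and to any
#' measured-rate bounds already present in the model). Weights are
#' `w_i = penalty_i + uniform_fallback`; the uniform fallback keeps the LP
#' bounded (and, alone, reduces the problem to parsimonious minimal-total-
#' flux FBA). Absolute values are handled by splitting reversible
#' reactions.
#'
#' @param model a `metabolic_model` (constraints already applied).
#' @param penalties named penalty vector from [expression_penalties()].
#' @param biomass_fraction fraction of the biomass optimum to enforce
#'   (default 0.2).
#' @param uniform_fallback constant added to every weight (default 1e-3).
#' @param biomass_reaction biomass reaction id; `NULL` uses the objective.
#' @return list of class `gim3e_fit`: `P_star` (optimal weighted flux sum),
#'   `flux` (one optimal [flux_distribution()] in the original reaction
#'   space), `weights`, `biomass_floor`, `biomass_optimum`, `status`.
#' @export
gim3e_minimize <- function(model, penalties, biomass_fraction = 0.2,
                           uniform_fallback = 1e-3, biomass_reaction = NULL) {
  stopifnot(biomass_fraction > 0, biomass_fraction <= 1)
  if (uniform_fallback <= 0 && any(penalties <= 0)) {
    stop("uniform_fallback must be > 0 when some penalties are zero, ",
         "otherwise the minimization is unbounded over free cycles")
  }
  ids <- model$reactions$id
  w <- stats::setNames(as.numeric(penalties[ids]) + uniform_fallback, ids)
  work <- model
  if (!is.null(biomass_reaction)) {
    work$reactions$objective_coef <- as.numeric(ids == biomass_reaction)
  }
  opt <- fba(work, "max")
  if (opt$status != "optimal") {
    return(structure(list(P_star = NA_real_, flux = NULL, weights = w,
                          status = opt$status), class = "gim3e_fit"))
  }
  work <- fix_objective(work, biomass_fraction)
  sp <- split_reversible(work)
  w_split <- w[sp$map$original]
  obj <- stats::setNames(rep(0, nrow(sp$model$reactions)), sp$model$reactions$id)
  obj[sp$map$forward] <- w_split
  obj[stats::na.omit(sp$map$backward)] <- w_split[!is.na(sp$map$backward)]
  res <- solve_lp(as.numeric(obj), sp$model$S,
                  sp$model$reactions$lower_bound,
                  sp$model$reactions$upper_bound, "min")
  if (res$status != "optimal") {
    return(structure(list(P_star = NA_real_, flux = NULL, weights = w,
                          status = res$status), class = "gim3e_fit"))
  }
  v_split <- stats::setNames(res$x, sp$model$reactions$id)
  v <- unsplit_flux(v_split, sp$map)
  structure(list(P_star = res$objective,
                 flux = flux_distribution(v, model),
                 model_floored = work,
                 weights = w,
                 biomass_fraction = biomass_fraction,
                 biomass_floor = biomass_fraction * opt$objective,
                 biomass_optimum = opt$objective,
                 uniform_fallback = uniform_fallback,
                 status = "optimal"),
            class = "gim3e_fit")
}

#' @export
print.gim3e_fit <- function(x, ...) {
  cat("<gim3e_fit> status=", x$status, sep = "")
  if (x$status == "optimal") {
    cat(", P*=", format(x$P_star, digits = 8),
        ", biomass floor=", format(x$biomass_floor, digits = 6), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Restrict the flux space to within a slack of the weighted optimum
#'
#' Adds the constraint `sum_i w_i |v_i| <= (1 + slack) * P_star` to the
#' (split, biomass-floored) model and computes per-reaction FVA bounds
#' under it. The resulting polytope — all constraints now equalities plus
#' box bounds, thanks to the slack-variable encoding — is what the ACHR
#' sampler explores.
#'
#' @param model the `metabolic_model` passed to [gim3e_minimize()].
#' @param fit the `gim3e_fit` returned by it.
#' @param slack relative slack on the optimum (default 0.01, i.e. the
#'   solution space within 99% optimality).
#' @return list of class `flux_space`: `model_split` (augmented split
#'   model), `map`, `fva` (original-space bounds), `fva_split`, `bound`,
#'   `slack`.
#' @export
solution_space <- function(model, fit, slack = 0.01) {
  stopifnot(inherits(fit, "gim3e_fit"), fit$status == "optimal", slack >= 0)
  ids <- model$reactions$id
  # reuse the biomass-floored model from the fit so any custom biomass
  # designation carries over unchanged
  work <- fit$model_floored %||% fix_objective(model, fit$biomass_fraction)
  sp <- split_reversible(work)
  w_split <- fit$weights[sp$map$original]
  coefs <- stats::setNames(rep(0, nrow(sp$model$reactions)),
                           sp$model$reactions$id)
  coefs[sp$map$forward] <- w_split
  coefs[stats::na.omit(sp$map$backward)] <- w_split[!is.na(sp$map$backward)]
  bound <- (1 + slack) * fit$P_star
  aug <- add_constraint(sp$model, coefs[coefs != 0], lb = 0, ub = bound,
                        id = "penalty_budget")
  fva_split <- fva(aug)
  # original-space ranges: optimize v_fwd - v_bwd per original reaction
  orig_rng <- data.frame(reaction = ids, min = NA_real_, max = NA_real_,
                         stringsAsFactors = FALSE)
  n_aug <- nrow(aug$reactions)
  for (k in seq_along(ids)) {
    obj <- numeric(n_aug)
    obj[match(sp$map$forward[k], aug$reactions$id)] <- 1
    if (!is.na(sp$map$backward[k])) {
      obj[match(sp$map$backward[k], aug$reactions$id)] <- -1
    }
    lo <- solve_lp(obj, aug$S, aug$reactions$lower_bound,
                   aug$reactions$upper_bound, "min")
    hi <- solve_lp(obj, aug$S, aug$reactions$lower_bound,
                   aug$reactions$upper_bound, "max")
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("solution-space FVA failed for '", ids[k], "' (", lo$status, ")")
    }
    orig_rng$min[k] <- min(lo$objective, hi$objective)
    orig_rng$max[k] <- max(lo$objective, hi$objective)
  }
  structure(list(model_split = aug, map = sp$map, fva = orig_rng,
                 fva_split = fva_split, bound = bound, slack = slack,
                 weights = fit$weights, P_star = fit$P_star),
            class = "flux_space")
}

#' @export
print.flux_space <- function(x, ...) {
  cat("<flux_space> ", nrow(x$fva), " reactions, penalty budget <= ",
      format(x$bound, digits = 8), " (slack ", x$slack, ")\n", sep = "")
  invisible(x)
}

#' Sampling configuration
#'
#' @param n_samples number of samples to emit (default 5000).
#' @param thinning chain iterations per emitted sample (default 100).
#' @param n_warmup cap on the number of warmup points (default 100).
#' @param seed RNG seed (`NULL`: use the current stream).
#' @param tolerance numeric tolerance for degenerate directions (default
#'   1e-9).
#' @return list of class `sampling_config`.
#' @export
sampling_config <- function(n_samples = 5000L, thinning = 100L,
                            n_warmup = 100L, seed = NULL, tolerance = 1e-9) {
  stopifnot(n_samples >= 1, thinning >= 1, n_warmup >= 2)
  structure(list(n_samples = as.integer(n_samples),
                 thinning = as.integer(thinning),
                 n_warmup = as.integer(n_warmup),
                 seed = seed, tolerance = tolerance),
            class = "sampling_config")
}

#' Sample the restricted flux space by artificially-centered hit-and-run
#'
#' Warmup points are the FVA vertex solutions of the restricted polytope
#' (two per unblocked dimension, capped at `n_warmup`). Each iteration
#' picks a random stored point, draws the direction through the running
#' center (the "artificial centering" that adapts proposals to the
#' polytope's shape), computes the feasible chord from the box bounds and
#' steps to a uniform point on it; the center is updated as a running mean.
#' Every `thinning` iterations a sample is emitted. Directions live in the
#' affine subspace `S v = 0` by construction, so emitted samples satisfy
#' all constraints up to round-off.
#'
#' @param space a `flux_space` from [solution_space()].
#' @param config a [sampling_config()].
#' @return numeric matrix, `n_samples` x reactions (original reaction
#'   space). Attribute `"warmup_used"` records the warmup count. If the
#'   polytope is a single point, that point is returned in every row with
#'   a warning.
#' @export
achr_sample <- function(space, config = sampling_config()) {
  aug <- space$model_split
  lb <- aug$reactions$lower_bound; ub <- aug$reactions$upper_bound
  tol <- config$tolerance
  # warmup: FVA optima of the restricted polytope
  warm <- achr_warmup(aug, config$n_warmup)
  if (max(space$fva_split$max - space$fva_split$min) < 1e-8) {
    warning("solution space is a single point; returning it for every sample")
    v0 <- unsplit_flux(stats::setNames(warm[, 1], aug$reactions$id), space$map)
    out <- matrix(rep(v0, each = config$n_samples), nrow = config$n_samples,
                  dimnames = list(NULL, space$map$original))
    attr(out, "warmup_used") <- ncol(warm)
    return(out)
  }
  with_seed(config$seed, {
    n <- nrow(warm)
    pts <- warm                      # columns are stored points
    center <- rowMeans(pts)
    x <- center
    n_stored <- ncol(pts)
    samples <- matrix(NA_real_, config$n_samples, n)
    emitted <- 0L; iter <- 0L
    while (emitted < config$n_samples) {
      iter <- iter + 1L
      p <- pts[, sample.int(n_stored, 1L)]
      d <- p - center
      nd <- sqrt(sum(d * d))
      if (nd < tol) next
      d <- d / nd
      # chord: lb <= x + a*d <= ub
      hi_a <- (ub - x)[abs(d) > tol] / d[abs(d) > tol]
      lo_a <- (lb - x)[abs(d) > tol] / d[abs(d) > tol]
      amax <- min(pmax(hi_a, lo_a)); amin <- max(pmin(hi_a, lo_a))
      if (!is.finite(amin) || !is.finite(amax) || amax - amin < tol) next
      a <- stats::runif(1, amin, amax)
      x <- pmin(pmax(x + a * d, lb), ub)
      center <- center + (x - center) / (n_stored + iter)
      if (iter %% config$thinning == 0L) {
        emitted <- emitted + 1L
        samples[emitted, ] <- x
      }
    }
    colnames(samples) <- aug$reactions$id
    out <- t(apply(samples, 1, function(row) {
      unsplit_flux(stats::setNames(row, aug$reactions$id), space$map)
    }))
    colnames(out) <- space$map$original
    attr(out, "warmup_used") <- n_stored
    out
  })
}

# FVA solutions of the augmented split model as warmup points (columns).
achr_warmup <- function(aug, n_warmup) {
  lb <- aug$reactions$lower_bound; ub <- aug$reactions$upper_bound
  pts <- list()
  n <- nrow(aug$reactions)
  take <- seq_len(min(n, ceiling(n_warmup / 2)))
  for (k in take) {
    obj <- numeric(n); obj[k] <- 1
    for (sense in c("min", "max")) {
      sol <- solve_lp(obj, aug$S, lb, ub, sense)
      if (sol$status == "optimal") pts[[length(pts) + 1L]] <- sol$x
      if (length(pts) >= n_warmup) break
    }
    if (length(pts) >= n_warmup) break
  }
  if (length(pts) < 2L) stop("could not obtain 2 warmup points")
  do.call(cbind, pts)
}

#' Reference flux distribution from a sample matrix
#'
#' The componentwise sample mean; as a convex combination of feasible
#' points it remains feasible, which is re-checked and recorded. Fluxes
#' with magnitude below `clamp` are set to exactly 0 to stabilize the
#' downstream reference-scaled divisions.
#'
#' @param samples matrix from [achr_sample()] (samples x reactions).
#' @param model the original `metabolic_model`.
#' @param clamp zero-clamp threshold (default 1e-9).
#' @return a [flux_distribution()].
#' @export
reference_distribution <- function(samples, model, clamp = 1e-9) {
  v <- colMeans(samples)
  v[abs(v) < clamp] <- 0
  flux_distribution(v[model$reactions$id], model)
}

#' Estimate the reference flux state of a condition
#'
#' Convenience wrapper chaining [expression_penalties()],
#' [gim3e_minimize()], [solution_space()], [achr_sample()] and
#' [reference_distribution()].
#'
#' @param model the condition's `metabolic_model`.
#' @param reaction_scores expression scores from [reaction_expression()].
#' @param biomass_fraction,uniform_fallback,slack forwarded to the stages.
#' @param sampling a [sampling_config()].
#' @param penalty_form forwarded to [expression_penalties()].
#' @return list of class `reference_result`: `v_ref`, `samples`, `space`,
#'   `fit`, `config`.
#' @export
estimate_reference <- function(model, reaction_scores,
                               biomass_fraction = 0.2,
                               uniform_fallback = 1e-3, slack = 0.01,
                               sampling = sampling_config(),
                               penalty_form = "log2") {
  pen <- expression_penalties(model, reaction_scores, form = penalty_form)
  fit <- gim3e_minimize(model, pen, biomass_fraction = biomass_fraction,
                        uniform_fallback = uniform_fallback)
  if (fit$status != "optimal") {
    stop("weighted flux minimization failed: status ", fit$status)
  }
  space <- solution_space(model, fit, slack = slack)
  samples <- achr_sample(space, sampling)
  v_ref <- reference_distribution(samples, model)
  structure(list(v_ref = v_ref, samples = samples, space = space, fit = fit,
                 config = sampling),
            class = "reference_result")
}

#' @export
print.reference_result <- function(x, ...) {
  cat("<reference_result> ", ncol(x$samples), " reactions, ",
      nrow(x$samples), " samples; P*=",
      format(x$fit$P_star, digits = 8), "\n", sep = "")
  invisible(x)
}
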