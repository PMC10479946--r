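#' Construct a metabolic model
#'
#' A `metabolic_model` is an in-memory stoichiometric network: metabolites,
#' reactions with flux bounds and gene-protein-reaction (GPR) rules, a sparse
#' stoichiometric matrix S (rows = metabolites, columns = reactions) and a
#' single linear objective (typically a biomass or energy-demand reaction).
#'
#' @param id model identifier.
#' @param metabolites data.frame with columns `id`, `name`, `compartment`.
#' @param reactions data.frame with columns `id`, `lower_bound`,
#'   `upper_bound`, `gpr` (string GPR rule, `""` for none), `subsystem`,
#'   `objective_coef`.
#' @param stoichiometry either a sparse/dense matrix (metabolites x reactions)
#'   or a named list mapping reaction id to a named numeric vector of
#'   metabolite coefficients.
#' @param genes optional character vector of gene ids; defaults to the union
#'   of GPR leaves.
#' @param compartments optional declared compartment tags; defaults to those
#'   used by the metabolites.
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, metabolites, reactions, stoichiometry,
                            genes = NULL, compartments = NULL) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$compartment)) metabolites$compartment <- ""
  if (is.null(reactions$gpr)) reactions$gpr <- ""
  if (is.null(reactions$subsystem)) reactions$subsystem <- ""
  if (is.null(reactions$objective_coef)) reactions$objective_coef <- 0

  if (is.list(stoichiometry) && !is.matrix(stoichiometry) &&
      !inherits(stoichiometry, "Matrix")) {
    S <- Matrix::Matrix(0, nrow(metabolites), nrow(reactions), sparse = TRUE,
                        dimnames = list(metabolites$id, reactions$id))
    for (rid in names(stoichiometry)) {
      coefs <- stoichiometry[[rid]]
      bad <- setdiff(names(coefs), metabolites$id)
      if (length(bad)) {
        stop("reaction '", rid, "' references undeclared metabolite(s): ",
             paste(bad, collapse = ", "))
      }
      S[names(coefs), rid] <- coefs
    }
  } else {
    S <- Matrix::Matrix(stoichiometry, sparse = TRUE)
    dimnames(S) <- list(metabolites$id, reactions$id)
  }

  gpr_leaf_genes <- unique(unlist(lapply(reactions$gpr, function(g) {
    gpr_genes(gpr_parse(g))
  })))
  if (is.null(genes)) genes <- gpr_leaf_genes
  genes <- sort(unique(c(genes, gpr_leaf_genes)))
  if (is.null(compartments)) {
    compartments <- sort(unique(metabolites$compartment))
  }

  model <- structure(
    list(id = id, metabolites = metabolites, reactions = reactions,
         S = S, genes = genes, compartments = compartments, log = list()),
    class = "metabolic_model")
  validate_model(model)
  model
}

#' Validate a metabolic model's structural invariants
#'
#' Checks id uniqueness, matrix dimensions, bound ordering, compartment
#' membership and that every objective reaction exists. Called by the
#' constructor and after structural edits.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly; stops with a descriptive error otherwise.
#' @export
validate_model <- function(model) {
  m <- model$metabolites; r <- model$reactions
  if (anyDuplicated(m$id)) stop("duplicate metabolite ids")
  if (anyDuplicated(r$id)) stop("duplicate reaction ids")
  if (any(!nzchar(m$id)) || any(!nzchar(r$id))) stop("empty ids not allowed")
  if (!all(dim(model$S) == c(nrow(m), nrow(r)))) {
    stop("stoichiometric matrix dimensions do not match metabolite/reaction counts")
  }
  if (any(r$lower_bound > r$upper_bound)) {
    bad <- r$id[r$lower_bound > r$upper_bound]
    stop("lower_bound > upper_bound for: ", paste(bad, collapse = ", "))
  }
  if (!all(m$compartment %in% model$compartments)) {
    stop("metabolite compartment outside the declared compartment set")
  }
  leaves <- unique(unlist(lapply(r$gpr, function(g) gpr_genes(gpr_parse(g)))))
  if (!all(leaves %in% model$genes)) {
    stop("GPR references gene(s) missing from the model gene list: ",
         paste(setdiff(leaves, model$genes), collapse = ", "))
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n", sep = "")
  cat("  metabolites: ", nrow(x$metabolites),
      "  reactions: ", nrow(x$reactions),
      "  genes: ", length(x$genes), "\n", sep = "")
  obj <- objective_ids(x)
  if (length(obj)) cat("  objective: ", paste(obj, collapse = " + "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.metabolic_model <- function(x) dim(x$S)

objective_ids <- function(model) {
  model$reactions$id[model$reactions$objective_coef != 0]
}

rxn_index <- function(model, ids) {
  i <- match(ids, model$reactions$id)
  if (anyNA(i)) stop("unknown reaction(s): ", paste(ids[is.na(i)], collapse = ", "))
  i
}

#' Set flux bounds for one reaction
#'
#' @param model a `metabolic_model`.
#' @param id reaction id.
#' @param lb,ub new bounds; `NULL` leaves a bound unchanged.
#' @return the modified model.
#' @export
set_bounds <- function(model, id, lb = NULL, ub = NULL) {
  i <- rxn_index(model, id)
  if (!is.null(lb)) model$reactions$lower_bound[i] <- lb
  if (!is.null(ub)) model$reactions$upper_bound[i] <- ub
  if (model$reactions$lower_bound[i] > model$reactions$upper_bound[i]) {
    stop("bounds for '", id, "' are inverted")
  }
  model
}

#' Remove reactions (and any metabolites left orphaned) from a model
#'
#' @param model a `metabolic_model`.
#' @param ids reaction ids to delete.
#' @return the reduced model.
#' @export
remove_reactions <- function(model, ids) {
  if (!length(ids)) return(model)
  keep <- !(model$reactions$id %in% ids)
  model$reactions <- model$reactions[keep, , drop = FALSE]
  model$S <- model$S[, keep, drop = FALSE]
  used <- Matrix::rowSums(model$S != 0) > 0
  model$metabolites <- model$metabolites[used, , drop = FALSE]
  model$S <- model$S[used, , drop = FALSE]
  rownames(model$reactions) <- NULL
  rownames(model$metabolites) <- NULL
  validate_model(model)
  model
}

#' Identify exchange (boundary) reactions
#'
#' An exchange reaction touches exactly one metabolite; it sources material
#' into, or drains it from, the network.
#'
#' @param model a `metabolic_model`.
#' @return character vector of reaction ids.
#' @export
exchange_reactions <- function(model) {
  n_mets <- Matrix::colSums(model$S != 0)
  model$reactions$id[n_mets <= 1]
}

# Append a provenance record to the model's running log.
log_event <- function(model, ...) {
  model$log[[length(model$log) + 1L]] <- list(...)
  model
}

#' Construct a flux distribution
#'
#' A reaction-indexed flux vector tied to a model. Feasibility (mass balance
#' `|S v| <= tol` and bound satisfaction within `tol`) is checked at
#' construction and stored.
#'
#' @param values named numeric vector of fluxes (names = reaction ids) or an
#'   unnamed vector in model reaction order.
#' @param model the `metabolic_model` the fluxes refer to.
#' @param tolerance feasibility tolerance (default `1e-6`).
#' @return numeric vector of class `flux_distribution` with attributes
#'   `model_id`, `feasible` and `tolerance`.
#' @export
flux_distribution <- function(values, model, tolerance = 1e-6) {
  ids <- model$reactions$id
  if (is.null(names(values))) {
    stopifnot(length(values) == length(ids))
    names(values) <- ids
  } else {
    values <- values[ids]
  }
  resid <- max(abs(as.numeric(model$S %*% values)), 0)
  within <- all(values >= model$reactions$lower_bound - tolerance) &&
    all(values <= model$reactions$upper_bound + tolerance)
  structure(as.numeric(`names<-`(values, ids)),
            names = ids,
            model_id = model$id,
            feasible = (resid <= tolerance) && within,
            mass_balance_residual = resid,
            tolerance = tolerance,
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat("<flux_distribution> model=", attr(x, "model_id"),
      " feasible=", attr(x, "feasible"),
      " (|S v|max=", format(attr(x, "mass_balance_residual"), digits = 3),
      ")\n", sep = "")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Export a flux distribution as a TSV table
#'
#' Columns: reaction_id, flux, lb, ub, subsystem.
#'
#' @param flux a `flux_distribution`.
#' @param model the owning model (for bounds/subsystems).
#' @param path output file.
#' @export
write_flux_tsv <- function(flux, model, path) {
  df <- data.frame(reaction_id = model$reactions$id,
                   flux = as.numeric(flux[model$reactions$id]),
                   lb = model$reactions$lower_bound,
                   ub = model$reactions$upper_bound,
                   subsystem = model$reactions$subsystem,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
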