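# qMTA: quadratic metabolic transformation. Fits a treated flux state
# v_MTA to (i) reference fluxes rescaled by differential-expression fold
# changes for reactions of significant genes, (ii) the reference itself
# for untouched reactions, and (iii) measured rates, as one convex QP over
# the steady-state polytope.

#' Significance weights for differentially expressed genes
#'
#' `W_m = log10(p_th) - log10(p_m)`: one unit of weight per decade of FDR
#' below the threshold. Genes at or above the threshold carry no weight
#' and are excluded from the differentially-expressed set.
#'
#' @param de_table data.frame with columns `gene` and `FDR` (adjusted
#'   p-values in (0, 1]; exact zeros must be floored upstream).
#' @param p_th significance threshold (default 0.25).
#' @return data.frame `gene`, `FDR`, `W` for genes with `FDR < p_th`.
#' @export
gene_weights <- function(de_table, p_th = 0.25) {
  stopifnot(p_th > 0, p_th < 1)
  if (any(de_table$FDR <= 0)) {
    stop("FDR of 0 is not representable (log10 undefined); floor upstream")
  }
  if (any(de_table$FDR > 1)) stop("FDR values must be <= 1")
  keep <- de_table$FDR < p_th
  data.frame(gene = de_table$gene[keep], FDR = de_table$FDR[keep],
             W = log10(p_th) - log10(de_table$FDR[keep]),
             stringsAsFactors = FALSE)
}

#' Map genes to the reactions whose GPR rules contain them
#'
#' @param model a `metabolic_model`.
#' @param genes gene ids.
#' @return named list gene -> character vector of reaction ids. Genes
#'   absent from every GPR map to nothing and are listed in attribute
#'   `"unmapped"`.
#' @export
map_genes_to_reactions <- function(model, genes) {
  leaves <- lapply(model$reactions$gpr, function(g) gpr_genes(gpr_parse(g)))
  out <- lapply(genes, function(g) {
    model$reactions$id[vapply(leaves, function(l) g %in% l, logical(1))]
  })
  names(out) <- genes
  unmapped <- genes[lengths(out) == 0]
  out <- out[lengths(out) > 0]
  attr(out, "unmapped") <- unmapped
  out
}

#' qMTA configuration
#'
#' @param p_th FDR threshold defining the differentially expressed set
#'   (default 0.25).
#' @param epsilon_ref floor for `|v_ref|` in denominators (default 1e-6).
#' @param epsilon_fc genes with `|FC - 1|` below this contribute nothing
#'   (their target equals the reference; default 1e-6).
#' @param de_denom_squared if `TRUE` (default) the DE-term divisor
#'   `v_ref (FC - 1)` is squared; `FALSE` selects the unsquared variant.
#' @param ru_denom_squared if `FALSE` (default) the unchanged-term divisor
#'   `v_ref` enters unsquared (as `|v_ref|`); `TRUE` squares it.
#' @param log2fc_epsilon pseudo-flux for reporting flux log2 fold changes.
#' @return list of class `qmta_config`.
#' @export
qmta_config <- function(p_th = 0.25, epsilon_ref = 1e-6, epsilon_fc = 1e-6,
                        de_denom_squared = TRUE, ru_denom_squared = FALSE,
                        log2fc_epsilon = 1e-6) {
  stopifnot(p_th > 0, p_th < 1, epsilon_ref > 0, epsilon_fc > 0)
  structure(list(p_th = p_th, epsilon_ref = epsilon_ref,
                 epsilon_fc = epsilon_fc,
                 de_denom_squared = de_denom_squared,
                 ru_denom_squared = ru_denom_squared,
                 log2fc_epsilon = log2fc_epsilon),
            class = "qmta_config")
}

#' Assemble the qMTA quadratic program
#'
#' Builds the objective
#' `sum_{m in DExp} W_m sum_{i in R_m} ((v_i_ref FC_m - v_i) / (v_i_ref (FC_m - 1)))^2
#'  + sum_{i in Ru} (v_i_ref - v_i)^2 / |v_i_ref|
#'  + sum_{j in Rexp} (E_j - v_j)^2 / sigma_j`
#' over `S v = 0`, `lb <= v <= ub`. Membership: a measured reaction is in
#' `Rexp` (measured data overrides any DE gene mapping to it, logged); else
#' a reaction any weighted DE gene maps to is DE-targeted; all remaining
#' reactions form `Ru`, whose flux change from the reference is simply
#' minimized. Both reference-scaled denominators are floored at
#' `epsilon_ref`; a DE-targeted reaction with zero reference flux falls
#' back to an unscaled `W_m (target - v)^2` term.
#'
#' @param model the treated condition's `metabolic_model`.
#' @param v_ref reference [flux_distribution()] (from the control model;
#'   reactions absent from this model are ignored).
#' @param de_table data.frame with columns `gene`, `FC` (linear fold
#'   change) and `FDR`.
#' @param weights optional precomputed [gene_weights()]; derived from
#'   `de_table` when `NULL`.
#' @param measurements optional measurements table (columns `reaction`,
#'   `mean`, `sd`, optional `conversion`).
#' @param config a [qmta_config()].
#' @return list of class `qmta_qp`: quadratic coefficients per term
#'   (`terms`: data.frame reaction, a, target, class, gene, weight),
#'   `model`, `v_ref`, `notes` (membership overrides and fallbacks).
#' @export
assemble_qp <- function(model, v_ref, de_table, weights = NULL,
                        measurements = NULL, config = qmta_config()) {
  ids <- model$reactions$id
  vref <- stats::setNames(as.numeric(v_ref[ids]), ids)
  if (anyNA(vref)) {
    stop("v_ref lacks values for: ",
         paste(ids[is.na(vref)], collapse = ", "))
  }
  if (is.null(weights)) weights <- gene_weights(de_table, config$p_th)
  notes <- list()
  eps <- config$epsilon_ref

  measured_ids <- character(0)
  terms <- list()
  if (!is.null(measurements) && nrow(measurements) > 0) {
    if (is.null(measurements$conversion)) measurements$conversion <- 1
    for (j in seq_len(nrow(measurements))) {
      m <- measurements[j, ]
      if (!(m$reaction %in% ids)) next
      measured_ids <- c(measured_ids, m$reaction)
      terms[[length(terms) + 1L]] <- data.frame(
        reaction = m$reaction, a = 1 / max(m$sd * m$conversion, eps),
        target = m$mean * m$conversion, class = "measured",
        gene = NA_character_, weight = NA_real_, stringsAsFactors = FALSE)
    }
  }

  de_targeted <- character(0)
  if (nrow(weights) > 0) {
    fc <- stats::setNames(de_table$FC, de_table$gene)
    rmap <- map_genes_to_reactions(model, weights$gene)
    if (length(attr(rmap, "unmapped"))) {
      notes$unmapped_genes <- attr(rmap, "unmapped")
    }
    for (g in names(rmap)) {
      FCm <- fc[[g]]
      if (is.na(FCm) || FCm <= 0) {
        stop("gene '", g, "' has no positive linear fold change")
      }
      if (abs(FCm - 1) < config$epsilon_fc) next  # target == reference
      Wm <- weights$W[weights$gene == g]
      for (rid in rmap[[g]]) {
        if (rid %in% measured_ids) {
          notes$measured_overrides <- unique(c(notes$measured_overrides, rid))
          next
        }
        de_targeted <- c(de_targeted, rid)
        vr <- vref[[rid]]
        target <- vr * FCm
        if (abs(vr) < eps) {
          # zero-reference fallback: unscaled squared deviation
          a <- Wm
          notes$zero_ref_fallback <- unique(c(notes$zero_ref_fallback, rid))
        } else {
          denom <- abs(vr * (FCm - 1))
          denom <- max(denom, eps)
          a <- if (config$de_denom_squared) Wm / denom^2 else Wm / denom
        }
        terms[[length(terms) + 1L]] <- data.frame(
          reaction = rid, a = a, target = target, class = "de",
          gene = g, weight = Wm, stringsAsFactors = FALSE)
      }
    }
  }

  ru <- setdiff(ids, union(measured_ids, de_targeted))
  if (length(ru)) {
    d <- pmax(abs(vref[ru]), eps)
    a_ru <- if (config$ru_denom_squared) 1 / d^2 else 1 / d
    terms[[length(terms) + 1L]] <- data.frame(
      reaction = ru, a = as.numeric(a_ru), target = as.numeric(vref[ru]),
      class = "unchanged", gene = NA_character_, weight = NA_real_,
      stringsAsFactors = FALSE)
  }
  terms <- do.call(rbind, terms)
  structure(list(model = model, v_ref = vref, terms = terms,
                 config = config, notes = notes),
            class = "qmta_qp")
}

#' Solve an assembled qMTA program
#'
#' The objective is separable-quadratic, so the Hessian is diagonal and
#' strictly positive (every reaction carries at least its unchanged-term
#' coefficient); the QP is convex and is solved with the dual active-set
#' method of `quadprog`, with the steady-state equalities and flux bounds
#' as hard constraints. The Hessian is rescaled by its largest entry for
#' conditioning (the argmin is unchanged).
#'
#' @param qp a `qmta_qp` from [assemble_qp()].
#' @return object of class `qmta`: `v_ref`, `v_mta`
#'   ([flux_distribution()]), `log2fc` table (see [flux_log2fc()]),
#'   `objective`, `decomposition` (named DE/unchanged/measured sums),
#'   `status`, `qp`.
#' @export
solve_qmta <- function(qp) {
  model <- qp$model
  ids <- model$reactions$id
  n <- length(ids)
  A <- stats::setNames(rep(0, n), ids)    # diagonal quadratic coefs
  L <- stats::setNames(rep(0, n), ids)    # linear coefs: sum 2 a t
  for (k in seq_len(nrow(qp$terms))) {
    tm <- qp$terms[k, ]
    A[tm$reaction] <- A[tm$reaction] + tm$a
    L[tm$reaction] <- L[tm$reaction] + tm$a * tm$target
  }
  sc <- max(A)
  Dmat <- diag(2 * A / sc, n)
  dvec <- 2 * L / sc
  lb <- pmax(model$reactions$lower_bound, -LP_BIG)
  ub <- pmin(model$reactions$upper_bound, LP_BIG)
  Seq <- as.matrix(model$S)
  Amat <- cbind(t(Seq), diag(n), -diag(n))
  bvec <- c(rep(0, nrow(Seq)), lb, -ub)
  res <- tryCatch(quadprog::solve.QP(Dmat, dvec, Amat, bvec, meq = nrow(Seq)),
                  error = function(e) e)
  if (inherits(res, "error")) {
    return(structure(list(v_ref = qp$v_ref, v_mta = NULL, log2fc = NULL,
                          objective = NA_real_, decomposition = NULL,
                          status = "solver_error",
                          message = conditionMessage(res), qp = qp),
                     class = "qmta"))
  }
  v <- pmin(pmax(res$solution, lb), ub)
  names(v) <- ids
  obj_terms <- qp$terms$a * (v[qp$terms$reaction] - qp$terms$target)^2
  decomp <- tapply(obj_terms, qp$terms$class, sum)
  decomp <- stats::setNames(as.numeric(decomp), names(decomp))
  v_mta <- flux_distribution(v, model)
  structure(list(v_ref = qp$v_ref, v_mta = v_mta,
                 log2fc = flux_log2fc(qp$v_ref, v_mta,
                                      epsilon = qp$config$log2fc_epsilon),
                 objective = sum(obj_terms), decomposition = decomp,
                 status = "optimal", qp = qp),
            class = "qmta")
}

#' Fit a treated flux state to differential expression (qMTA)
#'
#' The main entry point: derives gene weights from the DE table, assembles
#' the quadratic program against the reference flux distribution and
#' solves it.
#'
#' @inheritParams assemble_qp
#' @return an object of class `qmta`; see [solve_qmta()].
#' @seealso [flux_log2fc()], [pathway_report()]
#' @examples
#' scen <- ground_truth_scenario(seed = 1)
#' fit <- qmta(scen$model, scen$v_control, scen$de_table, scen$measurements)
#' head(fit$log2fc)
#' @export
qmta <- function(model, v_ref, de_table, measurements = NULL,
                 config = qmta_config()) {
  qp <- assemble_qp(model, v_ref, de_table, weights = NULL,
                    measurements = measurements, config = config)
  solve_qmta(qp)
}

#' @export
print.qmta <- function(x, ...) {
  cat("<qmta> status=", x$status, sep = "")
  if (x$status == "optimal") {
    cat(", objective=", format(x$objective, digits = 6), sep = "")
    moved <- sum(abs(x$log2fc$log2fc) > 0.1)
    cat("; ", moved, "/", nrow(x$log2fc),
        " reactions shifted by >0.1 log2 units", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
summary.qmta <- function(object, ...) {
  cat("qMTA flux transformation\n")
  cat("  status: ", object$status, "\n", sep = "")
  if (object$status != "optimal") return(invisible(object))
  cat("  objective: ", format(object$objective, digits = 8), "\n", sep = "")
  cat("  decomposition:\n")
  for (nm in names(object$decomposition)) {
    cat(sprintf("    %-10s %g\n", nm, object$decomposition[[nm]]))
  }
  tab <- object$log2fc[order(-abs(object$log2fc$log2fc)), ]
  cat("  largest flux shifts:\n")
  print(utils::head(tab, 8), row.names = FALSE)
  invisible(object)
}

#' @export
coef.qmta <- function(object, ...) {
  if (is.null(object$v_mta)) return(NULL)
  stats::setNames(as.numeric(object$v_mta), names(object$v_mta))
}

#' @export
residuals.qmta <- function(object, ...) {
  tm <- object$qp$terms
  v <- object$v_mta
  stats::setNames(sqrt(tm$a) * (as.numeric(v[tm$reaction]) - tm$target),
                  paste0(tm$reaction, ifelse(is.na(tm$gene), "",
                                             paste0(":", tm$gene))))
}

#' @export
plot.qmta <- function(x, ...) {
  tab <- x$log2fc[order(x$log2fc$log2fc), ]
  cols <- ifelse(tab$log2fc > 0, "firebrick", "steelblue")
  graphics::barplot(tab$log2fc, names.arg = tab$reaction, horiz = TRUE,
                    col = cols, las = 1, xlab = "flux log2 fold change",
                    main = "qMTA predicted flux shifts", ...)
  invisible(x)
}

#' Per-reaction flux log2 fold change
#'
#' `log2((|v_mta| + eps) / (|v_ref| + eps))`, with a flag for reactions
#' whose predicted flux reversed direction (magnitude comparisons hide
#' sign flips, so they are reported separately).
#'
#' @param v_ref,v_mta named flux vectors over the same reactions.
#' @param epsilon pseudo-flux stabilizing zero references (default 1e-6).
#' @return data.frame `reaction`, `v_ref`, `v_mta`, `log2fc`, `sign_flip`.
#' @export
flux_log2fc <- function(v_ref, v_mta, epsilon = 1e-6) {
  ids <- names(v_ref)
  vr <- as.numeric(v_ref); vm <- as.numeric(v_mta[ids])
  data.frame(reaction = ids, v_ref = vr, v_mta = vm,
             log2fc = log2((abs(vm) + epsilon) / (abs(vr) + epsilon)),
             sign_flip = (vm * vr) < 0,
             stringsAsFactors = FALSE)
}

#' Pathway-grouped report of predicted flux shifts
#'
#' Groups the per-reaction log2 fold changes by model subsystem, the
#' layout used to annotate flux maps (up in red, down in blue). Ordering
#' is deterministic (subsystem, then reaction id); empty subsystems are
#' omitted.
#'
#' @param result a solved `qmta` object.
#' @param model the model supplying subsystem labels (default: the one in
#'   the fit).
#' @param threshold absolute log2FC below which a reaction counts as
#'   unchanged (default 1e-6).
#' @return data.frame `subsystem`, `reaction`, `log2fc`, `v_mta`,
#'   `direction` (`"up"`, `"down"`, `"unchanged"`).
#' @export
pathway_report <- function(result, model = result$qp$model,
                           threshold = 1e-6) {
  stopifnot(result$status == "optimal")
  tab <- result$log2fc
  sub <- model$reactions$subsystem[match(tab$reaction, model$reactions$id)]
  out <- data.frame(subsystem = ifelse(nzchar(sub), sub, "(none)"),
                    reaction = tab$reaction, log2fc = tab$log2fc,
                    v_mta = tab$v_mta,
                    direction = ifelse(abs(tab$log2fc) <= threshold, "unchanged",
                                       ifelse(tab$log2fc > 0, "up", "down")),
                    stringsAsFactors = FALSE)
  out[order(out$subsystem, out$reaction), , drop = FALSE]
}
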