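# Shared fixtures and independent oracles for the test suite.

toy <- function() toy_network("glyc-ox-8")

# A fleet of small networks: the canonical fixture plus randomized chained
# networks. Used by invariant/property tests.
toy_fleet <- function(seeds = 1:5) {
  c(list(toy()),
    lapply(seeds, function(s) toy_network(list(n_mid = 2, n_branch = 2, seed = s))))
}

# Uniform expression profile: every gene at `fpkm` in every sample.
flat_profile <- function(model, fpkm = 10, conditions = c("control", "treated"),
                         n_per_cond = 2) {
  samples <- paste0(rep(conditions, each = n_per_cond), "_",
                    seq_len(n_per_cond))
  m <- matrix(fpkm, nrow = length(model$genes), ncol = length(samples),
              dimnames = list(model$genes, samples))
  expression_profile(m, stats::setNames(rep(conditions, each = n_per_cond),
                                        samples))
}

# Independent brute-force QP oracle: minimizes sum_i a_i (v_i - t_i)^2
# over S v = 0, lb <= v <= ub by exhaustive active-set enumeration — every
# assignment of each variable to {free, at-lb, at-ub} is tried, the
# equality-restricted KKT system solved directly, and the best
# primal-feasible candidate returned. Exact up to linear-algebra round-off
# and algorithmically unrelated to the iterative dual active-set method
# the package uses. Only viable for the <= ~10-reaction instances it is
# applied to (3^n candidates).
oracle_qp <- function(terms, S, lb, ub, ids, tol = 1e-8) {
  n <- length(ids)
  stopifnot(n <= 12)
  A <- stats::setNames(rep(0, n), ids)
  L <- stats::setNames(rep(0, n), ids)
  for (k in seq_len(nrow(terms))) {
    A[terms$reaction[k]] <- A[terms$reaction[k]] + terms$a[k]
    L[terms$reaction[k]] <- L[terms$reaction[k]] + terms$a[k] * terms$target[k]
  }
  sc <- max(A)
  A <- A / sc; L <- L / sc
  Sm <- as.matrix(S)
  ubc <- pmin(ub, 1e6)
  best <- NULL; best_obj <- Inf
  states <- expand.grid(rep(list(0:2), n))  # 0 free, 1 at lb, 2 at ub
  for (row in seq_len(nrow(states))) {
    st <- as.integer(states[row, ])
    v <- numeric(n)
    fixed <- st != 0L
    v[st == 1L] <- lb[st == 1L]
    v[st == 2L] <- ubc[st == 2L]
    F <- which(!fixed)
    if (length(F)) {
      SF <- Sm[, F, drop = FALSE]
      rhs_eq <- -as.numeric(Sm[, fixed, drop = FALSE] %*% v[fixed])
      qrS <- qr(t(SF))
      keep <- qrS$pivot[seq_len(qrS$rank)]
      K <- rbind(cbind(diag(2 * A[F], length(F)), t(SF[keep, , drop = FALSE])),
                 cbind(SF[keep, , drop = FALSE],
                       matrix(0, length(keep), length(keep))))
      rhs <- c(2 * L[F], rhs_eq[keep])
      sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      v[F] <- sol[seq_along(F)]
    }
    if (any(v < lb - tol) || any(v > ubc + tol)) next
    if (max(abs(Sm %*% v)) > tol) next
    obj <- sum(A * v^2 - 2 * L * v)
    if (obj < best_obj) { best_obj <- obj; best <- v }
  }
  stopifnot(!is.null(best))
  names(best) <- ids
  list(v = best,
       objective = sum(terms$a * (best[terms$reaction] - terms$target)^2))
}

# Independent LP cross-check: minimize c'v over S v = 0, lb <= v <= ub by
# the proximal-point method (a short sequence of strictly convex QPs,
# min c'v + rho ||v - v_k||^2, which converges finitely for polyhedral
# problems). A different algorithm from the package's tableau simplex.
oracle_lp_min <- function(cc, S, lb, ub, iters = 6, rho = 1e-4) {
  n <- length(cc)
  Sm <- as.matrix(S)
  Amat <- cbind(t(Sm), diag(n), -diag(n))
  bvec <- c(rep(0, nrow(Sm)), lb, -ub)
  v <- numeric(n)
  for (i in seq_len(iters)) {
    Dmat <- diag(2 * rho, n)
    dvec <- -cc + 2 * rho * v
    v <- quadprog::solve.QP(Dmat, dvec, Amat, bvec, meq = nrow(Sm))$solution
    v <- pmin(pmax(v, lb), ub)
  }
  list(v = v, objective = sum(cc * v))
}

# Feasibility check used across sampling/qMTA tests.
max_infeasibility <- function(v, model) {
  ids <- model$reactions$id
  vv <- as.numeric(v[ids])
  max(max(abs(as.numeric(model$S %*% vv))),
      max(model$reactions$lower_bound - vv, 0),
      max(vv - model$reactions$upper_bound, 0))
}

# Parsimonious control state shared by qMTA tests: minimal-total-flux
# vertex at the full demand optimum.
pfba_state <- function(model) {
  pen0 <- stats::setNames(rep(0, nrow(model$reactions)), model$reactions$id)
  gim3e_minimize(model, pen0, biomass_fraction = 1, uniform_fallback = 1)$flux
}

# DE table stating "nothing changed" for every gene of a model.
identity_de <- function(model) {
  data.frame(gene = model$genes, log2FC = 0, FC = 1,
             pvalue = 1, FDR = 1, stringsAsFactors = FALSE)
}
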