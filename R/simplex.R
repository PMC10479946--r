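# Dense two-phase tableau simplex with Bland's anti-cycling rule.
# Flux-balance LPs are small (tens of variables) but highly degenerate;
# Bland's rule guarantees termination and the explicit tableau avoids the
# singular-basis factorizations that trip up general-purpose solvers on
# these instances. Solves
#     min c'x   s.t.  A x = b,  0 <= x <= u
# (upper bounds are folded in as slack rows x_i + s_i = u_i).

lp_simplex <- function(cc, A, b, u, tol = 1e-9, max_pivots = NULL) {
  n <- length(cc); m <- nrow(A)
  finite_u <- is.finite(u)
  nu <- sum(finite_u)
  # standard form: z = [x, s_u]; rows = [A x = b ; x_i + s_i = u_i]
  nz <- n + nu
  M <- matrix(0, m + nu, nz)
  M[seq_len(m), seq_len(n)] <- A
  rhs <- c(b, u[finite_u])
  if (nu > 0) {
    ui <- which(finite_u)
    for (k in seq_len(nu)) {
      M[m + k, ui[k]] <- 1
      M[m + k, n + k] <- 1
    }
  }
  neg <- rhs < 0
  M[neg, ] <- -M[neg, , drop = FALSE]
  rhs[neg] <- -rhs[neg]
  mm <- m + nu
  # phase I: artificial basis
  Tab <- cbind(M, diag(mm), rhs)
  basis <- nz + seq_len(mm)
  cost1 <- c(rep(0, nz), rep(1, mm))
  res <- simplex_iterate(Tab, basis, cost1, nz + mm, tol, max_pivots)
  Tab <- res$Tab; basis <- res$basis
  phase1_obj <- sum(cost1[basis] * Tab[, ncol(Tab)])
  if (phase1_obj > 1e-7) {
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  }
  # drive remaining artificials out of the basis where possible
  for (r in which(basis > nz)) {
    piv <- which(abs(Tab[r, seq_len(nz)]) > tol)
    if (length(piv)) {
      Tab <- pivot_tableau(Tab, r, piv[1])
      basis[r] <- piv[1]
    }
  }
  keep_rows <- basis <= nz
  Tab <- Tab[keep_rows, c(seq_len(nz), ncol(Tab)), drop = FALSE]
  basis <- basis[keep_rows]
  # phase II
  cost2 <- c(cc, rep(0, nu))
  res <- simplex_iterate(Tab, basis, cost2, nz, tol, max_pivots)
  if (res$status == "unbounded") {
    return(list(status = "unbounded", x = NULL, objective = NA_real_))
  }
  Tab <- res$Tab; basis <- res$basis
  x <- numeric(nz)
  x[basis] <- Tab[, ncol(Tab)]
  x <- x[seq_len(n)]
  list(status = "optimal", x = x, objective = sum(cc * x))
}

simplex_iterate <- function(Tab, basis, cost, nvar, tol, max_pivots = NULL) {
  if (is.null(max_pivots)) max_pivots <- 2000L + 50L * nvar
  ncolT <- ncol(Tab)
  for (it in seq_len(max_pivots)) {
    cb <- cost[basis]
    # reduced costs over structural columns
    red <- cost[seq_len(nvar)] - as.numeric(crossprod(cb, Tab[, seq_len(nvar), drop = FALSE]))
    enter <- which(red < -tol)
    if (!length(enter)) return(list(Tab = Tab, basis = basis, status = "optimal"))
    j <- enter[1]                       # Bland: smallest index
    col <- Tab[, j]
    pos <- which(col > tol)
    if (!length(pos)) return(list(Tab = Tab, basis = basis, status = "unbounded"))
    ratio <- Tab[pos, ncolT] / col[pos]
    rmin <- min(ratio)
    cand <- pos[ratio <= rmin + tol]
    r <- cand[which.min(basis[cand])]   # Bland on the leaving variable
    Tab <- pivot_tableau(Tab, r, j)
    basis[r] <- j
  }
  stop("simplex did not terminate in ", max_pivots, " pivots")
}

pivot_tableau <- function(Tab, r, j) {
  Tab[r, ] <- Tab[r, ] / Tab[r, j]
  other <- setdiff(seq_len(nrow(Tab)), r)
  Tab[other, ] <- Tab[other, , drop = FALSE] -
    outer(Tab[other, j], Tab[r, ])
  Tab
}
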