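# Numeric rank with a relative singular-value cutoff; the constraint matrix
# mixes exact small integers with user-supplied reals, so 1e-10 * sigma_max
# separates structural rank from round-off.
RANK_TOL <- 1e-10

effective_system <- function(cs) {
  A <- cs$A[, cs$free_params, drop = FALSE]
  list(A = A, c = cs$c)
}

numeric_rank <- function(M) {
  if (nrow(M) == 0L || ncol(M) == 0L) return(0L)
  s <- svd(M, nu = 0, nv = 0)$d
  sum(s > RANK_TOL * max(s, .Machine$double.xmin))
}

#' Classify a constraint system
#'
#' Compares `rank(A)` with `rank([A | c])` over the effective (non
#' zero-fixed) parameters: equal ranks with full column rank means a unique
#' solution (no optimization needed); equal ranks below full column rank
#' means an affine solution set of dimension `d = J_eff - rank(A)`;
#' an augmented rank excess (or a row requiring a zero-fixed parameter)
#' means the constraints are mutually inconsistent.
#'
#' @param cs a `constraint_system` from [assemble_constraints()].
#' @return list with `status` (`"unique"`, `"underdetermined"`,
#'   `"infeasible"`), `rank`, and `d` (null-space dimension; 0 unless
#'   underdetermined).
#' @export
feasibility_check <- function(cs) {
  stopifnot(inherits(cs, "constraint_system"))
  eff <- effective_system(cs)
  rk <- numeric_rank(eff$A)
  if (any(cs$row_provenance$contradictory) ||
      (nrow(eff$A) > 0L && numeric_rank(cbind(eff$A, eff$c)) > rk)) {
    return(list(status = "infeasible", rank = rk, d = 0L))
  }
  d <- ncol(eff$A) - rk
  list(status = if (d == 0L) "unique" else "underdetermined",
       rank = rk, d = as.integer(d))
}

# Greedy search for a small set of mutually conflicting rows: drop each row
# in turn and keep only those whose removal is necessary for infeasibility.
conflicting_rows <- function(cs) {
  keep <- seq_len(nrow(cs$A))
  is_inf <- function(rows) {
    sub <- cs
    sub$A <- cs$A[rows, , drop = FALSE]
    sub$c <- cs$c[rows]
    sub$row_provenance <- cs$row_provenance[rows, ]
    feasibility_check(sub)$status == "infeasible"
  }
  for (r in rev(seq_along(keep))) {
    trial <- keep[-r]
    if (length(trial) > 0L && is_inf(trial)) keep <- trial
  }
  keep
}

#' Minimum-distance particular solution of the constraints
#'
#' Finds `kappa0 = argmin ||kappa - kappa_ref||_2` subject to
#' `A %*% kappa = c` -- the feasible log-parameter vector closest (least
#' squares) to a reference such as a published, possibly infeasible,
#' parameter set.  Computed by projecting the reference residual through the
#' Moore-Penrose pseudoinverse of the effective constraint matrix.
#'
#' @param cs a `constraint_system`.
#' @param kappa_ref named numeric vector of reference log parameters; must
#'   be finite on every non-zero-fixed parameter.
#' @return named numeric vector `kappa0` of length J, `NA` on zero-fixed
#'   parameters (those re-enter as exact zeros on the value scale).
#' @export
particular_solution <- function(cs, kappa_ref) {
  fc <- feasibility_check(cs)
  if (fc$status == "infeasible") {
    stop("constraint system is infeasible; conflicting rows: ",
         paste(conflicting_rows(cs), collapse = ", "), call. = FALSE)
  }
  ref <- kappa_ref[cs$free_params]
  stopifnot(all(is.finite(ref)))
  eff <- effective_system(cs)
  k0_eff <- ref
  if (nrow(eff$A) > 0L) {
    sv <- svd(eff$A)
    pos <- sv$d > RANK_TOL * max(sv$d, .Machine$double.xmin)
    resid <- eff$c - as.numeric(eff$A %*% ref)
    corr <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], resid)) / sv$d[pos])
    k0_eff <- ref + as.numeric(corr)
    ach <- as.numeric(eff$A %*% k0_eff) - eff$c
    if (max(abs(ach)) > 1e-8 * max(1, max(abs(eff$c))))
      stop("particular solution does not satisfy the constraints", call. = FALSE)
  }
  k0 <- stats::setNames(rep(NA_real_, length(cs$param_ids)), cs$param_ids)
  k0[cs$free_params] <- k0_eff
  k0
}

#' Orthonormal basis of the feasible directions
#'
#' Columns form an orthonormal basis of the null space of the effective
#' constraint matrix, computed from a singular value decomposition (a
#' deterministic rank-revealing decomposition; each column's sign is fixed
#' so its largest-magnitude entry is positive).  Moving along any
#' combination of these directions preserves every constraint.
#'
#' @param cs a `constraint_system`.
#' @return a J x d matrix `B` (rows over all parameters; zero rows on
#'   zero-fixed parameters) with `A %*% B = 0` and `t(B) %*% B = I`.
#' @export
feasible_basis <- function(cs) {
  eff <- effective_system(cs)
  Jeff <- ncol(eff$A)
  if (nrow(eff$A) == 0L) {
    Beff <- diag(Jeff)
  } else {
    sv <- svd(eff$A, nu = 0, nv = Jeff)
    rk <- sum(sv$d > RANK_TOL * max(sv$d, .Machine$double.xmin))
    Beff <- sv$v[, seq_len(Jeff) > rk, drop = FALSE]
  }
  if (ncol(Beff) > 0L) {
    for (j in seq_len(ncol(Beff))) {
      i <- which.max(abs(Beff[, j]))
      if (Beff[i, j] < 0) Beff[, j] <- -Beff[, j]
    }
  }
  B <- matrix(0, length(cs$param_ids), ncol(Beff),
              dimnames = list(cs$param_ids, NULL))
  B[cs$free_params, ] <- Beff
  B
}

#' Affine reparameterization of the feasible manifold
#'
#' Bundles the particular solution and null-space basis so that the feasible
#' set `{kappa : A kappa = c}` is exactly `{kappa0 + B v : v in R^d}`.
#' Optimizing over `v` is then unconstrained: every visited point is
#' feasible by construction, and the search space has dimension `d` instead
#' of J.
#'
#' @param cs a `constraint_system`.
#' @param kappa_ref reference log parameters used to pick `kappa0` (see
#'   [particular_solution()]); typically the model's current/published
#'   values, or the user's initial guess for a de-novo model.
#' @return a `reparameterization` with fields `kappa0`, `B`, `d`,
#'   `param_ids`, `zero_fixed_params`, `reference`.
#' @export
reparameterization <- function(cs, kappa_ref) {
  k0 <- particular_solution(cs, kappa_ref)
  B <- feasible_basis(cs)
  structure(
    list(kappa0 = k0, B = B, d = ncol(B),
         param_ids = cs$param_ids,
         free_params = cs$free_params,
         zero_fixed_params = cs$zero_fixed_params,
         reference = kappa_ref),
    class = "reparameterization"
  )
}

#' @export
print.reparameterization <- function(x, ...) {
  cat("<reparameterization> J = ", length(x$param_ids), " parameters, d = ",
      x$d, " free directions (", length(x$zero_fixed_params),
      " fixed to zero)\n", sep = "")
  invisible(x)
}

#' Map reduced coordinates to log parameters and back
#'
#' `to_kappa()` returns `kappa0 + B %*% v` (feasible for every `v`; `NA` on
#' zero-fixed parameters).  `to_v()` inverts it by orthogonal projection,
#' `t(B) %*% (kappa - kappa0)`, so `to_v(to_kappa(v)) == v`.
#'
#' @param v length-d numeric vector.
#' @param rep a [reparameterization()].
#' @return `to_kappa()`: named length-J vector; `to_v()`: length-d vector.
#' @export
to_kappa <- function(v, rep) {
  stopifnot(inherits(rep, "reparameterization"), length(v) == rep$d)
  k <- rep$kappa0
  if (rep$d > 0L) k <- k + as.numeric(rep$B %*% v)
  k
}

#' @rdname to_kappa
#' @param kappa named length-J log-parameter vector (values on zero-fixed
#'   parameters are ignored).
#' @export
to_v <- function(kappa, rep) {
  stopifnot(inherits(rep, "reparameterization"))
  diff <- kappa[rep$free_params] - rep$kappa0[rep$free_params]
  as.numeric(crossprod(rep$B[rep$free_params, , drop = FALSE], diff))
}

#' Apply a log-parameter vector to a network
#'
#' Writes `exp(kappa)` into the network's parameter table, re-inserting
#' zero-fixed parameters as exact zeros on the value scale.
#'
#' @param network a `reaction_network`.
#' @param kappa named length-J log-parameter vector (e.g. from [to_kappa()]).
#' @return the updated network.
#' @export
apply_log_parameters <- function(network, kappa) {
  pt <- network$parameters
  vals <- exp(kappa[pt$id])
  vals[pt$id %in% names(kappa)[is.na(kappa)]] <- 0
  vals[pt$fixed_zero] <- 0
  set_parameters(network, stats::setNames(vals, pt$id))
}
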