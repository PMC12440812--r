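## Charge equilibration: minimize the quadratic charge energy
##   U_Qeq(Q) = U_Coul(Q) + sum_i [ chi_i Q_i + (J_i/2) Q_i^2 ]
## subject to 1^T Q = Q_tot, via the bordered KKT linear system.

#' Bundle per-atom Qeq parameters
#'
#' @param chi Per-atom electronegativities [eV/e].
#' @param hardness Per-atom chemical hardnesses [eV/e^2], strictly positive.
#' @param gamma Per-atom Gaussian charge radii [Angstrom], strictly positive.
#' @param total_charge Total charge constraint [e].
#' @return An object of class `qeq_parameters`.
#' @export
qeq_parameters <- function(chi, hardness, gamma, total_charge = 0) {
  n <- length(chi)
  if (length(hardness) != n || length(gamma) != n)
    stop("chi, hardness and gamma must have equal length")
  if (any(hardness <= 0)) stop("hardness must be strictly positive")
  if (any(gamma <= 0)) stop("gamma must be strictly positive")
  structure(list(chi = as.numeric(chi), hardness = as.numeric(hardness),
                 gamma = as.numeric(gamma),
                 total_charge = as.numeric(total_charge)),
            class = "qeq_parameters")
}

#' Charge-equilibration energy
#'
#' `U_Qeq = U_Coul + sum_i [chi_i Q_i + (J_i/2) Q_i^2]` with
#' `U_Coul = (1/2) Q^T M Q` from the supplied Coulomb operator.
#'
#' @param params A [qeq_parameters()] object.
#' @param charges Per-atom charges [e].
#' @param op A [coulomb_operator()] built for the same system.
#' @return Energy in eV.
#' @export
qeq_energy <- function(params, charges, op) {
  n <- length(params$chi)
  if (length(charges) != n || nrow(op$matrix) != n)
    stop("inconsistent shapes between params, charges and operator")
  0.5 * drop(crossprod(charges, op$matrix %*% charges)) +
    sum(params$chi * charges + 0.5 * params$hardness * charges^2)
}

# assemble and factor the bordered KKT system [[H, 1], [1^T, 0]]
.kkt_solve <- function(h, rhs) {
  n <- nrow(h)
  a <- rbind(cbind(h, 1), c(rep(1, n), 0))
  if (anyNA(a)) stop("NaN in Qeq inputs")
  z <- tryCatch(solve(a, rhs), error = function(e) {
    ev <- tryCatch(min(eigen(h, symmetric = TRUE, only.values = TRUE)$values),
                   error = function(e2) NA_real_)
    stop(sprintf(paste0("Qeq KKT system is singular or ill-conditioned ",
                        "(smallest hardness-matrix eigenvalue ~ %.3e); ",
                        "hardness may be too small relative to the Coulomb ",
                        "coupling"), ev), call. = FALSE)
  })
  list(a = a, z = z)
}

#' Solve the constrained charge equilibration problem
#'
#' Returns the unique minimizer of the Qeq energy under the total-charge
#' constraint by solving the `(N+1) x (N+1)` bordered KKT system
#' `[[M + diag(J), 1], [1^T, 0]] [Q; lambda] = [-chi; Q_tot]`.
#'
#' @param params A [qeq_parameters()] object.
#' @param op A [coulomb_operator()] for the same system.
#' @return An object of class `qeq_solution` with fields `charges`,
#'   `energy_coul`, `energy_qeq`, and `multiplier` (the KKT dual variable,
#'   interpretable as the negative equilibrated electronegativity).
#' @export
solve_qeq <- function(params, op) {
  n <- length(params$chi)
  if (nrow(op$matrix) != n) stop("operator size does not match parameters")
  if (anyNA(params$chi) || anyNA(params$hardness))
    stop("NaN in Qeq inputs")
  h <- op$matrix + diag(params$hardness, n)
  sol <- .kkt_solve(h, c(-params$chi, params$total_charge))
  q <- sol$z[1:n]
  lam <- sol$z[n + 1]
  # iterative refinement: one residual-correction step keeps the charge sum
  # and stationarity tight even for poorly scaled systems
  res <- c(-params$chi, params$total_charge) - sol$a %*% sol$z
  corr <- solve(sol$a, res)
  q <- q + corr[1:n]
  lam <- lam + corr[n + 1]
  ucoul <- 0.5 * drop(crossprod(q, op$matrix %*% q))
  structure(list(charges = q,
                 energy_coul = ucoul,
                 energy_qeq = ucoul + sum(params$chi * q +
                                            0.5 * params$hardness * q^2),
                 multiplier = lam),
            class = "qeq_solution")
}

#' @export
print.qeq_solution <- function(x, ...) {
  cat(sprintf("qeq_solution: %d charges, sum = %+.6f e, U_Qeq = %.6f eV\n",
              length(x$charges), sum(x$charges), x$energy_qeq))
  invisible(x)
}

#' Brute-force Qeq oracle by projected gradient descent
#'
#' Independent reference solver: eliminates the constraint by
#' `Q_N = Q_tot - sum_{i<N} Q_i` and minimizes the reduced unconstrained
#' quadratic with gradient descent. Intended for test-scale systems
#' (N <= 50).
#'
#' @param params A [qeq_parameters()] object.
#' @param op A [coulomb_operator()] for the same system.
#' @param steps Maximum number of descent steps.
#' @param tolerance Convergence threshold on the reduced-gradient norm.
#' @return The converged charge vector.
#' @export
brute_force_qeq <- function(params, op, steps = 200000L, tolerance = 1e-12) {
  n <- length(params$chi)
  if (n > 50) stop("brute_force_qeq is a test oracle; use solve_qeq for N > 50")
  h <- op$matrix + diag(params$hardness, n)
  chi <- params$chi
  qtot <- params$total_charge
  if (n == 1) return(qtot)
  # q = q0 + B t with q0 = (0,...,0,qtot), B maps t (length n-1) to the
  # constraint surface: q_i = t_i (i < n), q_n = -sum t
  b <- rbind(diag(1, n - 1), rep(-1, n - 1))
  hb <- crossprod(b, h %*% b)
  q0 <- c(rep(0, n - 1), qtot)
  g0 <- crossprod(b, h %*% q0 + chi)
  lr <- 1 / max(eigen(hb, symmetric = TRUE, only.values = TRUE)$values)
  t <- rep(0, n - 1)
  for (s in seq_len(steps)) {
    g <- hb %*% t + g0
    if (sqrt(sum(g^2)) < tolerance) return(drop(q0 + b %*% t))
    t <- t - lr * g
  }
  stop("brute_force_qeq did not converge in ", steps, " steps")
}

#' Sensitivities of equilibrated charges by implicit differentiation
#'
#' Differentiates the KKT system of [solve_qeq()]: with
#' `A = [[H, 1], [1^T, 0]]` and `B = A^{-1}`, the solution responds as
#' `dQ/dchi = -B_QQ`, `dQ_a/dJ_b = -B_ab Q_b`, and
#' `dQ/dR = -B_QQ (dM/dR) Q`. Only open-boundary operators carry position
#' sensitivities.
#'
#' @param params A [qeq_parameters()] object.
#' @param op A [coulomb_operator()].
#' @param system The [atomic_system()] the operator was built for (needed for
#'   position derivatives; may be omitted to skip them).
#' @return A list with `charges`, `dq_dchi` (N x N), `dq_dhardness` (N x N),
#'   and, when `system` is given and open, `dq_dpos` (N x N x 3 array;
#'   `[a, b, k]` is the derivative of charge `a` w.r.t. coordinate `k` of
#'   atom `b`).
#' @export
qeq_jacobians <- function(params, op, system = NULL) {
  n <- length(params$chi)
  h <- op$matrix + diag(params$hardness, n)
  sol <- solve_qeq(params, op)
  q <- sol$charges
  a <- rbind(cbind(h, 1), c(rep(1, n), 0))
  binv <- solve(a)
  bqq <- binv[1:n, 1:n, drop = FALSE]
  out <- list(charges = q,
              dq_dchi = -bqq,
              dq_dhardness = -sweep(bqq, 2, q, "*"))
  if (!is.null(system)) {
    if (op$boundary != "open")
      stop("position sensitivities are implemented for open boundaries only")
    gm <- .coulomb_matrix_position_grad(system, params$gamma)
    dq_dpos <- array(0, c(n, n, 3))
    for (k in 1:3) {
      for (b in 1:n) {
        dm <- gm[[k]][[b]]           # dM/dR_{b,k}, an N x N matrix
        dq_dpos[, b, k] <- -bqq %*% (dm %*% q)
      }
    }
    out$dq_dpos <- dq_dpos
  }
  out
}

# dM/dR for the open-boundary operator: returns, per coordinate k, a list of
# N sparse-ish dense matrices dM/dR_{b,k}. Used by qeq_jacobians (the model's
# force path uses a fused adjoint instead).
.coulomb_matrix_position_grad <- function(system, gamma) {
  n <- n_atoms(system)
  ke <- celliq_constants$ke
  pos <- system$positions
  dx <- outer(pos[, 1], pos[, 1], "-")
  dy <- outer(pos[, 2], pos[, 2], "-")
  dz <- outer(pos[, 3], pos[, 3], "-")
  r <- sqrt(dx^2 + dy^2 + dz^2)
  amat <- matrix(gauss_alpha(rep(gamma, n), rep(gamma, each = n)), n, n)
  off <- row(r) != col(r)
  # d/dr [erf(ar)/r] = 2a/sqrt(pi) exp(-a^2 r^2)/r - erf(ar)/r^2
  dk <- matrix(0, n, n)
  dk[off] <- ke * (2 * amat[off] / sqrt(pi) * exp(-(amat[off] * r[off])^2) /
                     r[off] - .erf(amat[off] * r[off]) / r[off]^2)
  lapply(1:3, function(k) {
    dd <- list(dx, dy, dz)[[k]]
    lapply(1:n, function(b) {
      dm <- matrix(0, n, n)
      # entry (a, c) depends on R_b only if a == b or c == b;
      # dr_ac/dR_{b,k} = (delta_ab - delta_cb) (R_a - R_c)_k / r_ac
      dm[b, ] <- dk[b, ] * dd[b, ] / pmax(r[b, ], 1e-300)
      dm[b, b] <- 0
      dm[, b] <- dm[b, ]          # symmetry of M
      dm
    })
  })
}
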