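# Constrained charge equilibration: energy, solver, oracle, sensitivities.

ke <- celliq_constants$ke

test_that("qeq_energy matches closed forms and a naive scalar loop", {
  one <- atomic_system(11, matrix(0, 1, 3))
  gam <- 1.1; chi <- 2.5; jj <- 6
  p <- qeq_parameters(chi, jj, gam, total_charge = 0.4)
  op <- coulomb_operator(one, gam)
  expect_equal(qeq_energy(p, 0, op), 0)
  q <- 0.4
  expect_equal(qeq_energy(p, q, op),
               ke * q^2 / (gam * sqrt(pi)) + chi * q + jj / 2 * q^2,
               tolerance = 1e-12)
  # random 4-atom system against explicit term-by-term summation
  set.seed(21)
  inp <- random_qeq_inputs(4)
  q <- rnorm(4)
  m <- inp$op$matrix
  u_loop <- 0
  for (i in 1:4) {
    u_loop <- u_loop + inp$params$chi[i] * q[i] +
      0.5 * inp$params$hardness[i] * q[i]^2 + 0.5 * m[i, i] * q[i]^2
    for (j in seq_len(4)) if (j > i) u_loop <- u_loop + m[i, j] * q[i] * q[j]
  }
  expect_equal(qeq_energy(inp$params, q, inp$op), u_loop, tolerance = 1e-12)
})

test_that("symmetric dimers split the charge evenly at any separation", {
  for (r in c(1.5, 3, 8)) {
    sys <- atomic_system(c(11, 11), rbind(c(0, 0, 0), c(r, 0, 0)))
    p <- qeq_parameters(c(3, 3), c(5, 5), c(1, 1), total_charge = 0.8)
    sol <- solve_qeq(p, coulomb_operator(sys, p$gamma))
    expect_equal(sol$charges, c(0.4, 0.4), tolerance = 1e-12)
  }
})

test_that("uniform electronegativity only shifts the multiplier", {
  set.seed(22)
  inp <- random_qeq_inputs(6)
  inp$params$total_charge <- 0
  base <- qeq_parameters(rep(2.5, 6), inp$params$hardness, inp$params$gamma, 0)
  sol <- solve_qeq(base, inp$op)
  expect_lt(max(abs(sol$charges)), 1e-12)
  shifted <- base; shifted$chi <- base$chi + 1.7
  sol2 <- solve_qeq(shifted, inp$op)
  expect_lt(max(abs(sol2$charges - sol$charges)), 1e-10)
  expect_equal(sol2$multiplier - sol$multiplier, -1.7, tolerance = 1e-10)
})

test_that("heteronuclear dimer matches the analytically eliminated quadratic", {
  set.seed(23)
  for (i in 1:20) {
    r <- runif(1, 1.5, 6)
    sys <- atomic_system(c(11, 17), rbind(c(0, 0, 0), c(r, 0, 0)))
    gam <- runif(2, 0.5, 1.5)
    p <- qeq_parameters(rnorm(2, 0, 4), runif(2, 3, 10), gam, 0)
    op <- coulomb_operator(sys, gam)
    h <- op$matrix + diag(p$hardness)
    q1 <- (p$chi[2] - p$chi[1]) / (h[1, 1] + h[2, 2] - 2 * h[1, 2])
    sol <- solve_qeq(p, op)
    expect_equal(sol$charges, c(q1, -q1), tolerance = 1e-10)
  }
})

test_that("solver agrees with the brute-force oracle and conserves charge", {
  set.seed(24)
  worst <- 0; worst_sum <- 0
  for (i in 1:30) {
    inp <- random_qeq_inputs(sample(2:12, 1))
    sol <- solve_qeq(inp$params, inp$op)
    qo <- brute_force_qeq(inp$params, inp$op)
    worst <- max(worst, max(abs(sol$charges - qo)))
    worst_sum <- max(worst_sum, abs(sum(sol$charges) - inp$params$total_charge))
    # stationarity of the KKT system
    resid <- inp$op$matrix %*% sol$charges +
      inp$params$hardness * sol$charges + inp$params$chi + sol$multiplier
    expect_lt(max(abs(resid)), 1e-8)
  }
  expect_lt(worst, 1e-8)
  expect_lt(worst_sum, 1e-10)
})

test_that("single atom charge is fixed by the constraint", {
  one <- atomic_system(17, matrix(0, 1, 3))
  p <- qeq_parameters(4, 8, 0.9, total_charge = -1)
  expect_equal(brute_force_qeq(p, coulomb_operator(one, 0.9)), -1)
  expect_equal(solve_qeq(p, coulomb_operator(one, 0.9))$charges, -1,
               tolerance = 1e-12)
})

test_that("the solution is optimal among constraint-satisfying perturbations", {
  set.seed(25)
  for (i in 1:5) {
    inp <- random_qeq_inputs(sample(3:8, 1))
    n <- length(inp$params$chi)
    sol <- solve_qeq(inp$params, inp$op)
    u0 <- qeq_energy(inp$params, sol$charges, inp$op)
    for (k in 1:50) {
      d <- rnorm(n); d <- d - mean(d)
      d <- d / sqrt(sum(d^2)) * 1e-3
      expect_gte(qeq_energy(inp$params, sol$charges + d, inp$op), u0)
    }
  }
})

test_that("charges are invariant under rigid rotation and translation", {
  set.seed(26)
  inp <- random_qeq_inputs(7)
  sol <- solve_qeq(inp$params, inp$op)
  rot <- random_rotation()
  moved <- inp$sys
  moved$positions <- inp$sys$positions %*% t(rot) + rep(1, 7) %o% c(3, -2, 5)
  sol2 <- solve_qeq(inp$params, coulomb_operator(moved, inp$params$gamma))
  expect_lt(max(abs(sol$charges - sol2$charges)), 1e-10)
})

test_that("solver reports NaN inputs and ill-conditioning", {
  inp <- random_qeq_inputs(3)
  bad <- inp$params; bad$chi[1] <- NaN
  expect_error(solve_qeq(bad, inp$op), "NaN")
})

test_that("charge sensitivities obey conservation and symmetry", {
  sys <- atomic_system(c(11, 11), rbind(c(0, 0, 0), c(2.5, 0, 0)))
  p <- qeq_parameters(c(3, 3), c(6, 6), c(1, 1), 0)
  jac <- qeq_jacobians(p, coulomb_operator(sys, p$gamma), sys)
  # perturbing chi cannot change the total charge
  expect_lt(max(abs(colSums(jac$dq_dchi))), 1e-12)
  # symmetric dimer antisymmetry
  expect_equal(jac$dq_dchi[1, 1], -jac$dq_dchi[1, 2], tolerance = 1e-12)
})

test_that("sensitivities match central finite differences", {
  set.seed(27)
  inp <- random_qeq_inputs(4)
  jac <- qeq_jacobians(inp$params, inp$op, inp$sys)
  h <- 1e-5
  for (b in 1:4) {
    pp <- inp$params; pp$chi[b] <- pp$chi[b] + h
    pm <- inp$params; pm$chi[b] <- pm$chi[b] - h
    fd <- (solve_qeq(pp, inp$op)$charges - solve_qeq(pm, inp$op)$charges) / (2 * h)
    expect_equal(jac$dq_dchi[, b], fd, tolerance = 1e-5)
    pp <- inp$params; pp$hardness[b] <- pp$hardness[b] + h
    pm <- inp$params; pm$hardness[b] <- pm$hardness[b] - h
    fd <- (solve_qeq(pp, inp$op)$charges - solve_qeq(pm, inp$op)$charges) / (2 * h)
    expect_equal(jac$dq_dhardness[, b], fd, tolerance = 1e-5)
    for (k in 1:3) {
      sp <- inp$sys; sp$positions[b, k] <- sp$positions[b, k] + h
      sm <- inp$sys; sm$positions[b, k] <- sm$positions[b, k] - h
      fd <- (solve_qeq(inp$params, coulomb_operator(sp, inp$params$gamma))$charges -
             solve_qeq(inp$params, coulomb_operator(sm, inp$params$gamma))$charges) / (2 * h)
      expect_equal(jac$dq_dpos[, b, k], fd, tolerance = 1e-5,
                   info = paste("atom", b, "coord", k))
    }
  }
})
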