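# Shared fixtures: small random systems and toy potentials used across tests.

# random open-boundary cluster with a minimum-separation guard; the box
# grows with the atom count so the rejection loop stays fast
random_cluster <- function(n, species = c(11L, 17L), qtot = 0, spread = 3.5,
                           min_sep = 1.6) {
  spread <- max(spread, 2.6 * n^(1 / 3))
  repeat {
    pos <- matrix(stats::runif(3 * n, 0, spread), n, 3)
    d <- if (n > 1) min(stats::dist(pos)) else Inf
    if (d > min_sep) break
  }
  atomic_system(rep(species, length.out = n), pos, total_charge = qtot)
}

random_qeq_inputs <- function(n) {
  sys <- random_cluster(n)
  gam <- stats::runif(n, 0.6, 1.4)
  params <- qeq_parameters(chi = stats::rnorm(n, 0, 3),
                           hardness = stats::runif(n, 3, 10),
                           gamma = gam,
                           total_charge = sample(c(-1, 0, 0, 1), 1))
  list(sys = sys, params = params, op = coulomb_operator(sys, gam))
}

random_rotation <- function() {
  qr.Q(qr(matrix(stats::rnorm(9), 3, 3))) * sample(c(-1, 1), 1)
}

# a tiny model with every gradient path active (non-zero readout, residual
# weights and charge-layer couplings)
active_model <- function(seed = 3, ...) {
  m <- potential_model(c(11L, 17L), seed = seed, ...)
  set.seed(seed + 1000)
  m$params$readout <- stats::rnorm(length(m$params$readout), 0, 0.3)
  for (l in seq_along(m$params$layers))
    m$params$layers[[l]]$beta <- stats::runif(1, 0.3, 0.8)
  m
}

# analytic harmonic-dimer surrogate potential for the MD oracle tests
harmonic_model <- function(k = 5, r0 = 2.5) {
  structure(list(k = k, r0 = r0), class = "harmonic_dimer")
}

# registered in helper so S3 dispatch finds it during tests
predict.harmonic_dimer <- function(object, system, forces = TRUE, ...) {
  d <- system$positions[2, ] - system$positions[1, ]
  r <- sqrt(sum(d^2))
  u <- 0.5 * object$k * (r - object$r0)^2
  f <- NULL
  if (forces) {
    g <- object$k * (r - object$r0) * d / r
    f <- rbind(g, -g)
  }
  list(energy = u, forces = f, charges = NULL)
}
registerS3method("predict", "harmonic_dimer", predict.harmonic_dimer)

# zero-force potential (free particles)
zero_model <- function() structure(list(), class = "zero_potential")
predict.zero_potential <- function(object, system, forces = TRUE, ...) {
  list(energy = 0,
       forces = if (forces) matrix(0, nrow(system$positions), 3) else NULL,
       charges = NULL)
}
registerS3method("predict", "zero_potential", predict.zero_potential)

# Morse-dimer surrogate for the energy-drift check
morse_model <- function(de = 0.8, a = 1.6, re = 2.35) {
  structure(list(de = de, a = a, re = re), class = "morse_dimer")
}
predict.morse_dimer <- function(object, system, forces = TRUE, ...) {
  d <- system$positions[2, ] - system$positions[1, ]
  r <- sqrt(sum(d^2))
  ex <- exp(-object$a * (r - object$re))
  u <- object$de * ((1 - ex)^2 - 1)
  f <- NULL
  if (forces) {
    dudr <- 2 * object$de * object$a * ex * (1 - ex)
    g <- dudr * d / r
    f <- rbind(g, -g)
  }
  list(energy = u, forces = f, charges = NULL)
}
registerS3method("predict", "morse_dimer", predict.morse_dimer)
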