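# The charge-equilibration block: softplus, species embeddings, environment
# electronegativity, charge embedding, full composition.

test_that("generalized softplus handles its landmark values", {
  expect_equal(generalized_softplus(0), log(2), tolerance = 1e-15)
  expect_equal(generalized_softplus(), 0)
  expect_equal(generalized_softplus(50), 50, tolerance = 1e-12)
  expect_equal(generalized_softplus(-745), 0, tolerance = 1e-12) # no underflow blowup
  # independent extended evaluation of the two-argument form
  expect_equal(generalized_softplus(1, 2), log(1 + exp(1) + exp(2)),
               tolerance = 1e-14)
})

test_that("species hardness is positive and reduces correctly", {
  expect_equal(species_hardness(0), log(2))
  expect_equal(species_hardness(c(0, 0), env_hardness = FALSE), rep(log(2), 2))
  # equal species => equal hardness when the environment term is off
  expect_equal(species_hardness(c(1.3, 1.3), c(9, -9), env_hardness = FALSE),
               rep(generalized_softplus(1.3), 2))
  expect_equal(species_hardness(1, 2, env_hardness = TRUE),
               log(1 + exp(1) + exp(2)), tolerance = 1e-14)
  expect_gt(species_hardness(-100), 0)
})

test_that("species radii scale covalent radii with a positive factor", {
  expect_equal(species_radii(0, 1.55), 1.55)          # exact at s~ = 0
  expect_equal(species_radii(1, 2), log(1 + exp(1)) / log(2) * 2,
               tolerance = 1e-14)
  expect_lt(species_radii(-40, 1.55), 1e-10)          # monotone lower bound
  expect_gt(species_radii(-40, 1.55), 0)
  expect_error(species_radii(0, -1), "positive")
})

test_that("environment electronegativity sums directed edges per atom", {
  m <- active_model(seed = 11)
  sys <- atomic_system(c(11, 17, 11), rbind(c(0, 0, 0), c(2.3, 0, 0),
                                            c(4.6, 0, 0)))
  nb <- build_neighbor_list(sys, m$config$cutoff)
  x <- embed_edges(sys, nb, m$config, m$params)
  cp <- m$params$celli
  emb <- environment_embedding(x, sys, nb, cp)
  # hand computation: chi_i = f * sum of MLP_R outputs over edges leaving i
  out <- celliq:::.mlp_forward(cp$mlp_r, x)$out
  for (i in 1:3) {
    sel <- nb$edges[, 1] == i
    expect_equal(emb$chi[i], cp$f * sum(out[sel, 1]), tolerance = 1e-12)
    expect_equal(emb$j_env[i], sum(out[sel, 2]), tolerance = 1e-12)
  }
  # f = 0 kills the electronegativity
  cp0 <- cp; cp0$f <- 0
  expect_equal(environment_embedding(x, sys, nb, cp0)$chi, rep(0, 3))
  # mirror-symmetric atoms get identical chi
  expect_equal(emb$chi[1], emb$chi[3], tolerance = 1e-10)
})

test_that("isolated atoms get zero electronegativity and still carry charge", {
  m <- potential_model(c(11L, 17L), seed = 12)
  iso <- atomic_system(c(11, 17), rbind(c(0, 0, 0), c(50, 0, 0)),
                       total_charge = 1)
  pr <- predict(m, iso, forces = FALSE)
  expect_equal(sum(pr$charges), 1, tolerance = 1e-10)
})

test_that("charge embedding vanishes at the cutoff and matches hand math", {
  m <- active_model(seed = 13)
  cfg <- m$config
  cp <- m$params$celli
  r <- cfg$cutoff - 1e-6
  two <- atomic_system(c(11, 17), rbind(c(0, 0, 0), c(r, 0, 0)))
  nb <- build_neighbor_list(two, cfg$cutoff)
  x <- embed_edges(two, nb, cfg, m$params)
  upd <- charge_embedding_update(x, c(0.4, -0.4), two, nb, cfg, cp)
  expect_lt(max(abs(upd)), 1e-15)    # envelope kills the edge
  # hand computation at a normal distance
  two2 <- atomic_system(c(11, 17), rbind(c(0, 0, 0), c(2.2, 0, 0)))
  nb2 <- build_neighbor_list(two2, cfg$cutoff)
  x2 <- embed_edges(two2, nb2, cfg, m$params)
  q <- c(0.4, -0.4)
  upd2 <- charge_embedding_update(x2, q, two2, nb2, cfg, cp)
  zi <- match(two2$species, cfg$species)
  for (e in 1:2) {
    i <- nb2$edges[e, 1]; j <- nb2$edges[e, 2]
    y <- celliq:::.mlp_forward(cp$mlp_q,
                               rbind(c(q[i], q[j], cp$ctx[zi[i], ], cp$ctx[zi[j], ])))$out
    want <- celliq:::.mlp_forward(cp$mlp_x, cbind(y, rbind(x2[e, ])))$out *
      envelope(nb2$distances[e], cfg$cutoff, cfg$envelope_p)
    expect_equal(upd2[e, ], drop(want), tolerance = 1e-12)
  }
})

test_that("full block composition equals the chained sub-operations", {
  set.seed(41)
  m <- active_model(seed = 14)
  cfg <- m$config
  cp <- m$params$celli
  sys <- random_cluster(6, qtot = 1)
  nb <- build_neighbor_list(sys, cfg$cutoff)
  x <- embed_edges(sys, nb, cfg, m$params)
  x1 <- interaction_layer(x, sys, nb, cfg, m$params$layers[[1]])
  out <- celli_forward(x1, sys, nb, cfg, cfg$celli, cp)
  # manual chain
  emb <- environment_embedding(x1, sys, nb, cp)
  zi <- match(sys$species, cfg$species)
  hard <- species_hardness(cp$jz[zi], emb$j_env, cfg$celli$env_hardness)
  gam <- species_radii(cp$stilde[zi], covalent_radius(sys$species))
  op <- coulomb_operator(sys, gam)
  sol <- solve_qeq(qeq_parameters(emb$chi, hard, gam, 1), op)
  upd <- charge_embedding_update(x1, sol$charges, sys, nb, cfg, cp)
  expect_equal(out$charges, sol$charges, tolerance = 1e-12)
  expect_equal(out$u_coul, sol$energy_coul, tolerance = 1e-12)
  expect_equal(out$latents, upd, tolerance = 1e-12)
  # and the fused model forward agrees with the op-by-op composition
  pr <- predict(m, sys, forces = FALSE)
  expect_equal(pr$charges, sol$charges, tolerance = 1e-10)
  expect_equal(pr$u_coul, sol$energy_coul, tolerance = 1e-10)
})

test_that("every forward pass conserves charge, including charged inputs", {
  set.seed(42)
  m <- potential_model(c(11L, 17L), seed = 15)
  worst <- 0
  for (i in 1:60) {
    sys <- random_cluster(sample(2:9, 1), qtot = sample(c(-1, 0, 1), 1))
    pr <- predict(m, sys, forces = FALSE)
    worst <- max(worst, abs(sum(pr$charges) - sys$total_charge))
  }
  expect_lt(worst, 1e-10)
})

test_that("homonuclear symmetric clusters get exactly symmetric charges", {
  m <- potential_model(c(11L, 17L), seed = 16)
  # equilateral triangle of one species: all charges equal by symmetry
  tri <- atomic_system(rep(11, 3),
                       rbind(c(0, 0, 0), c(2.4, 0, 0),
                             c(1.2, 2.4 * sqrt(3) / 2, 0)),
                       total_charge = 0)
  pr <- predict(m, tri, forces = FALSE)
  expect_lt(max(abs(pr$charges)), 1e-10)
  tri$total_charge <- 1
  pr1 <- predict(m, tri, forces = FALSE)
  expect_equal(pr1$charges, rep(1 / 3, 3), tolerance = 1e-10)
})

test_that("the charge state changes the electrostatics but not a baseline", {
  set.seed(43)
  m <- active_model(seed = 17)
  sys0 <- random_cluster(6, qtot = 0)
  sys1 <- sys0; sys1$total_charge <- 1
  pr0 <- predict(m, sys0, forces = FALSE)
  pr1 <- predict(m, sys1, forces = FALSE)
  expect_gt(abs(pr1$u_coul - pr0$u_coul), 1e-6)
  expect_gt(max(abs(pr1$charges - pr0$charges)), 1e-6)
  expect_gt(abs(pr1$delta_u - pr0$delta_u), 0)  # charges feed the latents
  # the charge-blind baseline is bit-identical across charge states
  mb <- potential_model(c(11L, 17L), use_celli = FALSE, seed = 17)
  set.seed(1017)
  mb$params$readout <- rnorm(length(mb$params$readout), 0, 0.3)
  b0 <- predict(mb, sys0, forces = FALSE)
  b1 <- predict(mb, sys1, forces = FALSE)
  expect_identical(b0$energy, b1$energy)
})

test_that("rotating a structure leaves the charges unchanged", {
  set.seed(44)
  m <- active_model(seed = 18)
  sys <- random_cluster(7, qtot = 1)
  pr <- predict(m, sys, forces = FALSE)
  rot <- random_rotation()
  moved <- sys; moved$positions <- sys$positions %*% t(rot)
  pr2 <- predict(m, moved, forces = FALSE)
  expect_lt(max(abs(pr$charges - pr2$charges)), 1e-8)
})

test_that("cold start: zeroed heads and f = 0 give uniform charges", {
  m <- potential_model(c(11L, 17L), seed = 19)
  m$params$celli$f <- 0
  m$params$celli$mlp_r$w3[] <- 0; m$params$celli$mlp_r$b3[] <- 0
  # regular tetrahedron: all atoms equivalent by symmetry
  hom <- atomic_system(rep(11, 4),
                       1.25 * rbind(c(1, 1, 1), c(1, -1, -1),
                                    c(-1, 1, -1), c(-1, -1, 1)),
                       total_charge = 1)
  pr <- predict(hom, object = m, forces = FALSE)
  expect_equal(pr$charges, rep(0.25, 4), tolerance = 1e-10)
  expect_equal(pr$delta_u, 0)   # readout is zero-initialized
})
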