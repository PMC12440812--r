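# Envelope, radial basis, edge embedding, interaction layers, readout,
# node-adapter mode.

test_that("envelope hits its boundary values and is smooth at the cutoff", {
  rc <- 4
  expect_equal(envelope(0, rc), 1)
  expect_equal(envelope(rc, rc), 0)
  expect_equal(envelope(5, rc), 0)
  ev <- envelope(rc - 1e-9, rc, deriv = TRUE)
  expect_lt(abs(ev$grad), 1e-6)     # first derivative vanishes at r_c
  expect_error(envelope(-1, rc), "non-negative")
  # direct extended evaluation of the polynomial at r_c/2, p = 6
  u <- 0.5; p <- 6
  want <- 1 - (p + 1) * (p + 2) / 2 * u^p + p * (p + 2) * u^(p + 1) -
    p * (p + 1) / 2 * u^(p + 2)
  expect_equal(envelope(2, 4, p = 6), want, tolerance = 1e-15)
})

test_that("envelope derivative matches finite differences", {
  rc <- 4
  r <- seq(0.2, 3.9, by = 0.3)
  ev <- envelope(r, rc, deriv = TRUE)
  h <- 1e-6
  fd <- (envelope(r + h, rc) - envelope(r - h, rc)) / (2 * h)
  expect_equal(ev$grad, fd, tolerance = 1e-8)
})

test_that("Bessel basis vanishes at the cutoff and derivatives check out", {
  rc <- 4
  b <- radial_basis(rc - 1e-10, rc, count = 6)
  expect_lt(max(abs(b)), 1e-8)
  r <- c(0.7, 1.9, 3.2)
  rb <- radial_basis(r, rc, count = 5, deriv = TRUE)
  h <- 1e-6
  fd <- (radial_basis(r + h, rc, 5) - radial_basis(r - h, rc, 5)) / (2 * h)
  expect_equal(rb$grad, fd, tolerance = 1e-7)
})

test_that("edge embedding is a function of local data only and reproducible", {
  m <- potential_model(c(11L, 17L), seed = 4)
  # two AB edges at the same distance must embed identically
  sys <- atomic_system(c(11, 17, 11, 17),
                       rbind(c(0, 0, 0), c(2.2, 0, 0),
                             c(10, 0, 0), c(12.2, 0, 0)))
  nb <- build_neighbor_list(sys, m$config$cutoff)
  x0 <- embed_edges(sys, nb, m$config, m$params)
  e1 <- which(nb$edges[, 1] == 1 & nb$edges[, 2] == 2)
  e2 <- which(nb$edges[, 1] == 3 & nb$edges[, 2] == 4)
  expect_equal(x0[e1, ], x0[e2, ], tolerance = 1e-14)
  # identical seeds give identical features
  m2 <- potential_model(c(11L, 17L), seed = 4)
  expect_identical(embed_edges(sys, nb, m2$config, m2$params), x0)
  # unknown species fail loudly
  bad <- atomic_system(c(11, 79), rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_error(predict(m, bad), "species")
})

test_that("interaction layer is invariant to neighbor order and handles a
           single-edge node", {
  m <- active_model(seed = 9)
  cfg <- m$config
  sys <- atomic_system(c(11, 17, 11), rbind(c(0, 0, 0), c(2.3, 0, 0),
                                            c(0, 2.7, 0)))
  nb <- build_neighbor_list(sys, cfg$cutoff)
  x0 <- embed_edges(sys, nb, cfg, m$params)
  x1 <- interaction_layer(x0, sys, nb, cfg, m$params$layers[[1]])
  expect_true(all(is.finite(x1)))
  # hand-unrolled environment sum: w_ij = A(x_ij) * sum_k B(x_ik), then
  # U(w, x) with the weighted residual
  lp <- m$params$layers[[1]]
  a_out <- celliq:::.mlp_forward(lp$A, x0)$out
  b_out <- celliq:::.mlp_forward(lp$B, x0)$out
  e <- 1  # first edge; source atom nb$edges[1, 1]
  ksel <- which(nb$edges[, 1] == nb$edges[e, 1])
  w_e <- a_out[e, ] * colSums(b_out[ksel, , drop = FALSE])
  u_e <- celliq:::.mlp_forward(lp$U, rbind(c(w_e, x0[e, ])))$out
  want <- (x0[e, ] + lp$beta * drop(u_e)) / sqrt(1 + lp$beta^2)
  expect_equal(x1[e, ], want, tolerance = 1e-12)
  # a dimer: every node has one incident edge, W acts on (x_ij, x_ij)
  dim2 <- atomic_system(c(11, 17), rbind(c(0, 0, 0), c(2.3, 0, 0)))
  nb2 <- build_neighbor_list(dim2, cfg$cutoff)
  xd <- embed_edges(dim2, nb2, cfg, m$params)
  xd1 <- interaction_layer(xd, dim2, nb2, cfg, lp)
  ad <- celliq:::.mlp_forward(lp$A, xd)$out
  bd <- celliq:::.mlp_forward(lp$B, xd)$out
  ud <- celliq:::.mlp_forward(lp$U, cbind(ad * bd, xd))$out
  expect_equal(xd1, (xd + lp$beta * ud) / sqrt(1 + lp$beta^2),
               tolerance = 1e-12)
})

test_that("zero readout weights give zero correction energy", {
  m <- potential_model(c(11L, 17L), seed = 5)  # readout zero-initialized
  sys <- random_cluster(5)
  nb <- build_neighbor_list(sys, m$config$cutoff)
  pr <- predict(m, sys, forces = FALSE)
  expect_equal(pr$delta_u, 0)
})

test_that("correction energy is extensive over non-interacting copies", {
  set.seed(31)
  # strictly local baseline: exact extensivity (the charge-equilibrated
  # model couples the copies through the global solve by design)
  m <- potential_model(c(11L, 17L), use_celli = FALSE, seed = 6)
  set.seed(1006)
  m$params$readout <- rnorm(length(m$params$readout), 0, 0.3)
  m$params$pair_readout[] <- rnorm(length(m$params$pair_readout), 0, 0.1)
  sys <- random_cluster(4)
  pr1 <- predict(m, sys, forces = FALSE)
  double <- atomic_system(rep(sys$species, 2),
                          rbind(sys$positions, sys$positions + 50))
  pr2 <- predict(m, double, forces = FALSE)
  expect_equal(pr2$delta_u, 2 * pr1$delta_u, tolerance = 1e-10)
  expect_lt(abs(pr2$delta_u - 2 * pr1$delta_u), 1e-10)
})

test_that("backbone latents depend on atoms beyond the receptive field by
           exactly 0", {
  # edge (1,2) in a small cluster, plus one distant atom far beyond
  # n_layers * cutoff; for the strictly local backbone (no charge layer)
  # moving the distant atom must leave the edge latents bit-identical
  sys <- atomic_system(c(11, 17, 11, 17),
                       rbind(c(0, 0, 0), c(2.3, 0, 0), c(3.5, 0, 0),
                             c(30, 0, 0)))
  moved <- sys
  moved$positions[4, ] <- c(35, 2, -1)
  mb <- potential_model(c(11L, 17L), use_celli = FALSE, seed = 7)
  set.seed(1007)
  mb$params$readout <- rnorm(length(mb$params$readout), 0, 0.3)
  probe_b <- function(s) {
    geom <- celliq:::.geometry(s, cfg = mb$config)
    fwd <- celliq:::.model_forward(mb, geom)
    sel <- geom$src == 1 & geom$dst == 2
    fwd$x_final[sel, ]
  }
  expect_identical(probe_b(sys), probe_b(moved))
})

test_that("rotating and translating a system leaves the latents' energy fixed", {
  set.seed(32)
  m <- active_model(seed = 8)
  sys <- random_cluster(6)
  pr1 <- predict(m, sys, forces = FALSE)
  rot <- random_rotation()
  moved <- sys
  moved$positions <- sys$positions %*% t(rot) + rep(1, 6) %o% c(4, 4, -2)
  pr2 <- predict(m, moved, forces = FALSE)
  expect_equal(pr1$energy, pr2$energy, tolerance = 1e-8)
})

test_that("node-adapter updates behave at the degenerate points", {
  set.seed(33)
  sys <- random_cluster(4)
  nb <- build_neighbor_list(sys, 4)
  h <- matrix(rnorm(4 * 6), 4, 6)
  eo <- matrix(rnorm(nrow(nb$edges) * 6), nrow(nb$edges), 6)
  expect_equal(node_mode_update(h, eo, nb, 0), h)
  # isolated node: no incident edges, stays unchanged
  iso <- atomic_system(c(11, 17, 11), rbind(c(0, 0, 0), c(2.2, 0, 0),
                                            c(40, 0, 0)))
  nbi <- build_neighbor_list(iso, 4)
  hi <- matrix(rnorm(3 * 2), 3, 2)
  eoi <- matrix(1, nrow(nbi$edges), 2)
  upd <- node_mode_update(hi, eoi, nbi, 0.5)
  expect_equal(upd[3, ], hi[3, ])
  # two-node graph with explicit tiny weights matches hand computation
  two <- atomic_system(c(11, 17), rbind(c(0, 0, 0), c(2, 0, 0)))
  nb2 <- build_neighbor_list(two, 4)
  h2 <- rbind(c(1, 2), c(3, 4))
  e2 <- rbind(c(0.1, 0.2), c(0.3, 0.4))   # edges (1,2) and (2,1)
  want <- h2 + 0.5 * rbind(e2[1, ], e2[2, ])
  expect_equal(node_mode_update(h2, e2, nb2, 0.5), want)
  expect_error(node_mode_update(h2, e2[, 1, drop = FALSE], nb2, 0.5), "width")
})

test_that("adapter edge features concatenate enveloped node features and rbf", {
  two <- atomic_system(c(11, 17), rbind(c(0, 0, 0), c(2, 0, 0)))
  nb <- build_neighbor_list(two, 4)
  h <- rbind(c(1, -1), c(2, 0.5))
  x <- adapter_edge_features(h, nb, cutoff = 4, n_bessel = 3)
  expect_equal(dim(x), c(2, 5))
  en <- envelope(2, 4)
  expect_equal(x[1, 1:2], h[1, ] * en)
  expect_equal(x[2, 1:2], h[2, ] * en)
  expect_equal(x[, 3:5], radial_basis(nb$distances, 4, 3))
})
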