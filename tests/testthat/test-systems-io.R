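# Structure data model, extended XYZ round trips, neighbor lists.

test_that("atomic_system enforces its invariants", {
  expect_error(atomic_system(c(11, 17), matrix(0, 3, 3)), "one row per atom")
  expect_error(atomic_system(11, matrix(0, 1, 3), charges = 0.5,
                             total_charge = 0), "sum to")
  expect_error(atomic_system(11, matrix(0, 1, 3), pbc = c(TRUE, TRUE, TRUE)),
               "cell")
  expect_error(atomic_system(11, matrix(0, 1, 3), cell = matrix(0, 3, 3),
                             pbc = rep(TRUE, 3)), "singular")
  sys <- atomic_system(c(11, 17), rbind(c(0, 0, 0), c(2, 0, 0)),
                       total_charge = 1, charges = c(0.6, 0.4))
  expect_s3_class(sys, "atomic_system")
})

test_that("a minimal unlabeled frame reads with absent labels", {
  f <- withr::local_tempfile(fileext = ".extxyz")
  writeLines(c("2", "Properties=species:S:1:pos:R:3 total_charge=0",
               "Na 0 0 0", "Cl 2.5 0 0"), f)
  sys <- read_extxyz(f)
  expect_length(sys, 1)
  expect_null(sys[[1]]$energy)
  expect_null(sys[[1]]$forces)
  expect_null(sys[[1]]$charges)
  expect_equal(sys[[1]]$species, c(11L, 17L))
})

test_that("a hand-written periodic frame parses field by field", {
  f <- withr::local_tempfile(fileext = ".extxyz")
  writeLines(c(
    "1",
    paste0('Lattice="10 0 0 0 11 0 0 0 12" Properties=species:S:1:pos:R:3 ',
           'energy=-1.25 total_charge=0 pbc="T T T"'),
    "Na 0.5 0.25 0.125"), f)
  sys <- read_extxyz(f)[[1]]
  expect_equal(sys$cell, diag(c(10, 11, 12)))
  expect_true(all(sys$pbc))
  expect_equal(sys$energy, -1.25)
  expect_equal(sys$positions[1, ], c(0.5, 0.25, 0.125))
})

test_that("write/read round trip is the identity on all fields", {
  set.seed(7)
  systems <- list(
    random_cluster(4),
    atomic_system(c(11, 17, 11), matrix(runif(9, 0, 5), 3, 3),
                  cell = diag(8, 3) + matrix(runif(9, 0, 0.1), 3),
                  pbc = rep(TRUE, 3), total_charge = 1,
                  energy = -3.21789456123,
                  forces = matrix(rnorm(9), 3, 3),
                  charges = c(0.312, 0.41, 0.278)))
  f <- withr::local_tempfile(fileext = ".extxyz")
  write_extxyz(systems, f)
  back <- read_extxyz(f)
  for (i in seq_along(systems)) {
    for (field in c("species", "positions", "cell", "pbc", "total_charge",
                    "energy", "forces", "charges")) {
      expect_equal(back[[i]][[field]], systems[[i]][[field]],
                   tolerance = 0, info = paste("frame", i, field))
    }
  }
})

test_that("empty list writes an empty file; headers reflect the labels", {
  f <- withr::local_tempfile(fileext = ".extxyz")
  write_extxyz(list(), f)
  expect_length(readLines(f), 0)
  sys <- atomic_system(11, matrix(1, 1, 3), total_charge = 0,
                       forces = matrix(0.5, 1, 3), charges = 0)
  write_extxyz(sys, f)
  hdr <- readLines(f)[2]
  expect_match(hdr, "forces:R:3")
  expect_match(hdr, "charge:R:1")
  expect_false(grepl("Lattice", hdr))
})

test_that("malformed files fail with the offending line", {
  f <- withr::local_tempfile(fileext = ".extxyz")
  writeLines(c("2", "Properties=species:S:1:pos:R:3 total_charge=0",
               "Na 0 0 0", "Cl 2.5 0"), f)
  expect_error(read_extxyz(f), "line 4")
  writeLines(c("1", "Properties=species:S:1:pos:R:3:charge:R:1 total_charge=0",
               "Na 0 0 0 0.7"), f)
  expect_error(read_extxyz(f), "total_charge")
})

test_that("neighbor list matches the trivial two-atom cases", {
  far <- atomic_system(c(11, 11), rbind(c(0, 0, 0), c(10, 0, 0)))
  expect_equal(nrow(build_neighbor_list(far, 6)$edges), 0)
  near <- atomic_system(c(11, 11), rbind(c(0, 0, 0), c(2, 0, 0)))
  nb <- build_neighbor_list(near, 6)
  expect_equal(nb$edges, cbind(i = c(1L, 2L), j = c(2L, 1L)))
  expect_equal(nb$distances, c(2, 2))
})

test_that("minimum image works across a periodic boundary", {
  sys <- atomic_system(c(11, 17), rbind(c(0.5, 5, 5), c(9.5, 5, 5)),
                       cell = diag(10, 3), pbc = rep(TRUE, 3))
  nb <- build_neighbor_list(sys, 3)
  expect_equal(nb$distances, c(1, 1))
  # brute-force scan over all 27 image shifts agrees
  sh <- as.matrix(expand.grid(-1:1, -1:1, -1:1)) * 10
  d <- min(sqrt(rowSums((rep(1, 27) %o% (sys$positions[2, ] - sys$positions[1, ]) + sh)^2)))
  expect_equal(nb$distances[1], d)
})

test_that("neighbor list agrees with a brute-force oracle on random systems", {
  set.seed(42)
  for (rep in 1:6) {
    n <- sample(3:20, 1)
    periodic <- rep %% 2 == 0
    if (periodic) {
      cell <- diag(runif(3, 8, 12))
      pos <- matrix(runif(3 * n), n, 3) %*% cell
      sys <- atomic_system(rep(c(11, 17), length.out = n), pos, cell = cell,
                           pbc = rep(TRUE, 3))
      cutoff <- 3.5
    } else {
      sys <- random_cluster(n, min_sep = 0.9, spread = 6)
      cutoff <- 4
    }
    nb <- build_neighbor_list(sys, cutoff)
    # O(N^2)-over-images oracle
    shifts <- if (periodic)
      as.matrix(expand.grid(-1:1, -1:1, -1:1)) %*% sys$cell
    else matrix(0, 1, 3)
    want <- list()
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      dmin <- min(sqrt(colSums((t(shifts) + (sys$positions[j, ] - sys$positions[i, ]))^2)))
      if (dmin < cutoff) want[[length(want) + 1]] <- c(i, j, dmin)
    }
    want <- do.call(rbind, want)
    expect_equal(nrow(nb$edges), NROW(want))
    if (NROW(want)) {
      expect_equal(unname(nb$edges), unname(want[, 1:2, drop = FALSE]))
      expect_equal(nb$distances, want[, 3], tolerance = 1e-12)
    }
  }
})

test_that("distances equal displacement norms and survive rigid translation", {
  set.seed(8)
  sys <- random_cluster(8, min_sep = 0.9, spread = 5)
  nb <- build_neighbor_list(sys, 4)
  expect_lt(max(abs(sqrt(rowSums(nb$displacements^2)) - nb$distances)), 1e-12)
  moved <- sys
  moved$positions <- sys$positions + rep(1, 8) %o% c(11, -4, 7)
  nb2 <- build_neighbor_list(moved, 4)
  expect_lt(max(abs(nb$distances - nb2$distances)), 1e-12)
})

test_that("oversized cutoffs on periodic cells are rejected with advice", {
  sys <- atomic_system(c(11, 17), rbind(c(0, 0, 0), c(2, 0, 0)),
                       cell = diag(8, 3), pbc = rep(TRUE, 3))
  expect_error(build_neighbor_list(sys, 5), "replicate")
})
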