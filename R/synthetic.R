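## Exact synthetic reference data: a fixed-parameter Qeq model plus a
## short-range Morse pair potential labels generated structures with
## energies, forces, and equilibrated charges analytically. Used in place of
## quantum-mechanical reference data so that every training and evaluation
## path can be tested against an exact ground truth.

#' Synthetic reference model
#'
#' Ground truth `U = U_Qeq(Q*) + sum_pairs Morse(r) p_env(r)`: equilibrated
#' Qeq charges from fixed per-species electronegativities, hardnesses and
#' Gaussian radii, plus a smoothly cut-off Morse pair potential
#' `D_e ((1 - exp(-a (r - r_e)))^2 - 1)`. The default parameters describe
#' two fictitious ionic species "A" and "B" (stored as Z = 11 and Z = 17)
#' with an NaCl-flavored electronegativity gap.
#'
#' @param species Atomic numbers of the two species.
#' @param chi,hardness,gamma Named per-species Qeq parameters (names are
#'   atomic numbers); hardness and gamma strictly positive.
#' @param morse Data frame with columns `zi`, `zj`, `de`, `a`, `re`
#'   (one row per unordered species pair).
#' @param sr_cutoff Smooth cutoff radius of the pair potential [Angstrom].
#' @param envelope_p Envelope degree of the smooth cutoff.
#' @param noise Named list `sigma_u`, `sigma_f`, `sigma_q` of optional
#'   Gaussian label-noise standard deviations (defaults 0).
#' @return An object of class `reference_model`.
#' @export
reference_model <- function(
    species = c(11L, 17L),
    chi = c("11" = 2.8, "17" = 8.5),
    hardness = c("11" = 4.6, "17" = 9.9),
    gamma = c("11" = 1.2, "17" = 0.9),
    morse = data.frame(zi = c(11, 11, 17), zj = c(11, 17, 17),
                       de = c(0.15, 0.8, 0.1), a = c(1.2, 1.6, 1.2),
                       re = c(3.2, 2.35, 3.4)),
    sr_cutoff = 4.0, envelope_p = 6,
    noise = list(sigma_u = 0, sigma_f = 0, sigma_q = 0)) {
  if (any(hardness <= 0) || any(gamma <= 0))
    stop("reference hardness and gamma must be strictly positive")
  structure(list(species = as.integer(species), chi = chi,
                 hardness = hardness, gamma = gamma, morse = morse,
                 sr_cutoff = sr_cutoff, envelope_p = envelope_p,
                 noise = noise),
            class = "reference_model")
}

# Morse pair energy with smooth cutoff, and its derivative
.morse_pair <- function(r, de, a, re, rc, p) {
  ex <- exp(-a * (r - re))
  v <- de * ((1 - ex)^2 - 1)
  dv <- 2 * de * a * ex * (1 - ex)
  en <- envelope(r, rc, p, deriv = TRUE)
  list(value = v * en$value, grad = dv * en$value + v * en$grad)
}

# short-range pair energy and per-atom gradient of a structure
.sr_energy <- function(ref, sys) {
  n <- n_atoms(sys)
  u <- 0
  g <- matrix(0, n, 3)
  if (n < 2) return(list(energy = u, grad = g))
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  dif <- sys$positions[pr[, 1], , drop = FALSE] -
         sys$positions[pr[, 2], , drop = FALSE]
  r <- sqrt(rowSums(dif^2))
  keep <- r < ref$sr_cutoff
  if (!any(keep)) return(list(energy = u, grad = g))
  pr <- pr[keep, , drop = FALSE]; dif <- dif[keep, , drop = FALSE]; r <- r[keep]
  key <- paste(pmin(sys$species[pr[, 1]], sys$species[pr[, 2]]),
               pmax(sys$species[pr[, 1]], sys$species[pr[, 2]]))
  mkey <- paste(pmin(ref$morse$zi, ref$morse$zj), pmax(ref$morse$zi, ref$morse$zj))
  row <- match(key, mkey)
  if (anyNA(row)) stop("no Morse parameters for species pair ",
                       key[which(is.na(row))[1]])
  mp <- .morse_pair(r, ref$morse$de[row], ref$morse$a[row], ref$morse$re[row],
                    ref$sr_cutoff, ref$envelope_p)
  u <- sum(mp$value)
  dudr <- mp$grad
  for (k in 1:3) {
    c1 <- dudr * dif[, k] / r
    g[, k] <- drop(.rowsum_to(matrix(c1, ncol = 1), pr[, 1], n)) -
              drop(.rowsum_to(matrix(c1, ncol = 1), pr[, 2], n))
  }
  list(energy = u, grad = g)
}

# per-atom reference Qeq parameter lookup
.ref_qeq_params <- function(ref, sys) {
  key <- as.character(sys$species)
  if (!all(key %in% names(ref$chi)))
    stop("reference model does not cover species Z = ",
         paste(setdiff(unique(key), names(ref$chi)), collapse = ", "))
  qeq_parameters(ref$chi[key], ref$hardness[key], ref$gamma[key],
                 sys$total_charge)
}

#' Label structures with the exact reference model
#'
#' Charges come from the constrained Qeq solve with the reference
#' parameters; the energy is `U_Qeq` at the solution plus the short-range
#' pair sum; forces are the exact analytic negative gradient (the charge
#' response term vanishes at the constrained optimum because the reference
#' electronegativities do not depend on positions). Optional Gaussian noise
#' is added after labeling; the noiseless labels are kept in the
#' `"noiseless"` attribute of each system.
#'
#' @param structures List of [atomic_system()]s (open boundaries).
#' @param ref A [reference_model()].
#' @param seed Seed for the label noise (only used when noise > 0).
#' @return The list with `energy`, `forces`, `charges` filled in. Structures
#'   on which the Qeq solve fails are dropped with a warning.
#' @export
label_structures <- function(structures, ref, seed = 0) {
  oldseed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, .GlobalEnv))
  set.seed(seed)
  out <- list()
  for (i in seq_along(structures)) {
    sys <- structures[[i]]
    lab <- tryCatch(.label_one(sys, ref), error = function(e) {
      warning("dropping structure ", i, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(lab)) next
    sigu <- ref$noise$sigma_u; sigf <- ref$noise$sigma_f; sigq <- ref$noise$sigma_q
    sys$energy <- lab$energy + if (sigu > 0) stats::rnorm(1, 0, sigu) else 0
    sys$forces <- lab$forces + if (sigf > 0)
      matrix(stats::rnorm(3 * n_atoms(sys), 0, sigf), ncol = 3) else 0
    qn <- lab$charges
    if (sigq > 0) {
      dq <- stats::rnorm(n_atoms(sys), 0, sigq)
      qn <- qn + dq - mean(dq)   # keep the charge sum exact
    }
    sys$charges <- qn
    attr(sys, "noiseless") <- lab
    out[[length(out) + 1L]] <- sys
  }
  out
}

.label_one <- function(sys, ref) {
  if (any(sys$pbc)) stop("reference labeling supports open boundaries only")
  params <- .ref_qeq_params(ref, sys)
  mc <- .m_open_forward(.geometry_dfull(sys), params$gamma)
  n <- n_atoms(sys)
  a <- rbind(cbind(mc$m + diag(params$hardness, n), 1), c(rep(1, n), 0))
  z <- solve(a, c(-params$chi, params$total_charge))
  q <- z[1:n]
  uqeq <- 0.5 * sum(q * (mc$m %*% q)) +
    sum(params$chi * q + 0.5 * params$hardness * q^2)
  sr <- .sr_energy(ref, sys)
  # dU_Qeq/dR at fixed Q (envelope theorem at the constrained optimum)
  bm <- .m_open_backward(mc, 0.5 * tcrossprod(q))
  gpos <- matrix(0, n, 3)
  sgd <- bm$gd + t(bm$gd)
  dd <- array(0, c(n, n, 3))
  for (k in 1:3) dd[, , k] <- outer(sys$positions[, k], sys$positions[, k], "-")
  r <- pmax(mc$r, 1e-300)
  for (k in 1:3) gpos[, k] <- rowSums(sgd * dd[, , k] / r)
  list(energy = uqeq + sr$energy,
       forces = -(gpos + sr$grad),
       charges = q)
}

.geometry_dfull <- function(sys) {
  pos <- sys$positions
  dx <- outer(pos[, 1], pos[, 1], "-")
  dy <- outer(pos[, 2], pos[, 2], "-")
  dz <- outer(pos[, 3], pos[, 3], "-")
  sqrt(dx^2 + dy^2 + dz^2)
}

## ---- structure generation ----------------------------------------------

.min_dist <- function(pos) {
  n <- nrow(pos)
  if (n < 2) return(Inf)
  d <- as.matrix(stats::dist(pos))
  min(d[upper.tri(d)])
}

#' Generate unlabeled synthetic structures
#'
#' Three geometry families:
#' \describe{
#'   \item{chain}{Linear alternating two-species chains with jittered bond
#'     lengths and transverse displacements; total charge 0 or +1.}
#'   \item{ionic_cluster}{Rock-salt-like fragments (with extra-cation and
#'     vacancy variants) emitted as geometry-identical twins in the two
#'     total-charge states 0 and +1 (`info$twin` pairs them).}
#'   \item{dimer_scan}{A rock-salt fragment plus one cation displaced along
#'     a fixed outward path (`info$scan_d` records the displacement), in
#'     both charge states.}
#' }
#'
#' @param recipe One of `"chain"`, `"ionic_cluster"`, `"dimer_scan"`.
#' @param n Number of structures.
#' @param size_range For chains: atom-count range; for clusters: ignored
#'   (variants are cycled); for scans: displacement range [Angstrom].
#' @param seed Integer seed (same seed, same structures).
#' @param species Two atomic numbers (cation first).
#' @param spacing Nearest-neighbor lattice/bond scale [Angstrom].
#' @param jitter Positional jitter amplitude [Angstrom].
#' @param max_retries Regeneration attempts before giving up on overlaps.
#' @return A list of unlabeled [atomic_system()]s.
#' @export
generate_structures <- function(recipe = c("chain", "ionic_cluster", "dimer_scan"),
                                n, size_range = NULL, seed = 0,
                                species = c(11L, 17L), spacing = 2.6,
                                jitter = 0.1, max_retries = 50L) {
  recipe <- match.arg(recipe)
  if (n == 0) return(list())
  oldseed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, .GlobalEnv))
  set.seed(seed)
  draw <- switch(recipe,
    chain = function(i) .draw_chain(size_range, species, jitter),
    ionic_cluster = function(i) .draw_cluster(i, species, spacing, jitter),
    dimer_scan = function(i) .draw_scan(i, n, size_range, species, spacing))
  out <- vector("list", n)
  i <- 1L
  pend <- list()   # second members of twin pairs
  while (i <= n) {
    if (length(pend)) {
      out[[i]] <- pend[[1]]; pend <- pend[-1]; i <- i + 1L; next
    }
    made <- NULL
    for (try in seq_len(max_retries)) {
      cand <- draw(i)
      if (.min_dist(cand[[1]]$positions) >= 0.7) { made <- cand; break }
    }
    if (is.null(made))
      stop("could not generate a non-overlapping structure after ",
           max_retries, " retries")
    out[[i]] <- made[[1]]
    if (length(made) > 1) pend <- made[-1]
    i <- i + 1L
  }
  out
}

.draw_chain <- function(size_range, species, jitter) {
  if (is.null(size_range)) size_range <- c(4, 8)
  na <- sample(size_range[1]:size_range[2], 1)
  bonds <- 2.35 + stats::runif(na - 1, -0.15, 0.15)
  x <- c(0, cumsum(bonds))
  pos <- cbind(x, stats::runif(na, -jitter, jitter),
               stats::runif(na, -jitter, jitter))
  z <- rep(species, length.out = na)
  qtot <- sample(c(0, 1), 1)
  list(atomic_system(z, pos, total_charge = qtot))
}

# rock-salt fragments; returns a geometry-identical twin pair (Q_tot 0 / +1)
.draw_cluster <- function(i, species, spacing, jitter) {
  grid <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * spacing
  par <- (rowSums(grid / spacing) %% 2) == 0
  z <- ifelse(par, species[1], species[2])
  variant <- sample(3, 1)
  pos <- grid
  if (variant == 2) {           # extra cation on top
    pos <- rbind(grid, c(spacing / 2, spacing / 2, 2 * spacing))
    z <- c(z, species[1])
  } else if (variant == 3) {    # anion vacancy
    drop <- sample(which(z == species[2]), 1)
    pos <- grid[-drop, , drop = FALSE]
    z <- z[-drop]
  }
  pos <- pos + matrix(stats::runif(length(pos), -jitter, jitter), ncol = 3)
  twin <- sprintf("pair%06d", i)
  lapply(c(0, 1), function(q)
    atomic_system(z, pos, total_charge = q, info = list(twin = twin)))
}

# fixed cube + one cation pulled outward along the body diagonal
.draw_scan <- function(i, n, size_range, species, spacing) {
  if (is.null(size_range)) size_range <- c(2.0, 6.0)
  npts <- max(1L, n %/% 2L)
  d <- seq(size_range[1], size_range[2], length.out = npts)[(i + 1) %/% 2]
  grid <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * spacing
  par <- (rowSums(grid / spacing) %% 2) == 0
  z <- c(ifelse(par, species[1], species[2]), species[1])
  dir <- c(1, 1, 1) / sqrt(3)
  pos <- rbind(grid, spacing + dir * d)
  twin <- sprintf("scan%06d", (i + 1) %/% 2)
  lapply(c(0, 1), function(q)
    atomic_system(z, pos, total_charge = q,
                  info = list(twin = twin, scan_d = format(d))))
}

#' Build a labeled benchmark suite on disk
#'
#' Generates chains and ionic clusters, labels them with the reference
#' model, splits 80/10/10 into train/validation/test, and writes
#' `train.extxyz`, `val.extxyz`, `test.extxyz`, a `twins_test.extxyz` of
#' geometry-identical charge-state pairs, and a `scan_test.extxyz` path.
#' Byte-identical output for a fixed seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_chain,n_cluster Structures per family.
#' @param n_twins Frames in the twin test set (even).
#' @param n_scan Frames in the scan test set.
#' @param ref A [reference_model()].
#' @return Invisibly, a named list of the written file paths.
#' @export
make_benchmark_suite <- function(out_dir, seed = 0, n_chain = 1000,
                                 n_cluster = 1000, n_twins = 40, n_scan = 40,
                                 ref = reference_model()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pool <- c(generate_structures("chain", n_chain, seed = seed + 1),
            generate_structures("ionic_cluster", n_cluster, seed = seed + 2))
  pool <- label_structures(pool, ref, seed = seed + 3)
  oldseed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed + 4)
  ord <- sample(length(pool))
  if (!is.null(oldseed)) assign(".Random.seed", oldseed, .GlobalEnv)
  ntr <- floor(0.8 * length(pool)); nva <- floor(0.1 * length(pool))
  splits <- list(train = pool[ord[seq_len(ntr)]],
                 val = pool[ord[ntr + seq_len(nva)]],
                 test = pool[ord[(ntr + nva + 1):length(pool)]])
  twins <- label_structures(
    generate_structures("ionic_cluster", n_twins, seed = seed + 5), ref,
    seed = seed + 6)
  scan <- label_structures(
    generate_structures("dimer_scan", n_scan, seed = seed + 7), ref,
    seed = seed + 8)
  paths <- list()
  for (nm in names(splits)) {
    paths[[nm]] <- file.path(out_dir, paste0(nm, ".extxyz"))
    write_extxyz(splits[[nm]], paths[[nm]])
  }
  paths$twins <- file.path(out_dir, "twins_test.extxyz")
  write_extxyz(twins, paths$twins)
  paths$scan <- file.path(out_dir, "scan_test.extxyz")
  write_extxyz(scan, paths$scan)
  invisible(paths)
}
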