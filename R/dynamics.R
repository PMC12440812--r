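## Langevin molecular dynamics (BAOAB splitting) with trained potentials
## plus trajectory stability diagnostics: overlapping particles, broken
## bonds, non-finite values, and the kinetic-temperature trace.

#' Molecular dynamics configuration
#'
#' @param dt Timestep [fs], > 0.
#' @param temperature Thermostat temperature [K], >= 0.
#' @param friction Langevin friction [1/ps], >= 0 (0 gives velocity Verlet).
#' @param n_steps Number of integration steps.
#' @param seed Seed for the thermostat noise and initial velocities.
#' @param report_every Trajectory frame interval (steps).
#' @return A named list of class `md_config`.
#' @export
md_config <- function(dt = 0.5, temperature = 300, friction = 100,
                      n_steps = 1000, seed = 0, report_every = 100) {
  if (dt <= 0) stop("dt must be positive")
  if (temperature < 0) stop("temperature must be non-negative")
  if (friction < 0) stop("friction must be non-negative")
  structure(list(dt = dt, temperature = temperature, friction = friction,
                 n_steps = as.integer(n_steps), seed = seed,
                 report_every = as.integer(report_every)),
            class = "md_config")
}

#' Run Langevin dynamics
#'
#' BAOAB-discretized Langevin integration: half kick, half drift, exact
#' Ornstein-Uhlenbeck velocity update, half drift, half kick. With zero
#' friction and temperature the scheme reduces to velocity Verlet.
#' Deterministic for a fixed seed.
#'
#' Passing a list of starting structures runs independent replica
#' simulations batched through one fused force evaluation per step (the
#' replicas are disjoint graphs with separate charge-equilibration solves,
#' so their dynamics are exactly independent).
#'
#' @param model A [potential_model()] (or any object with a compatible
#'   `predict` method returning `$forces` and `$energy`).
#' @param system Starting [atomic_system()] (open boundaries), or a list of
#'   them for batched replicas.
#' @param cfg An [md_config()].
#' @param velocities Optional initial N x 3 velocity matrix [Angstrom/fs]
#'   (or a list for replicas); default is a Maxwell-Boltzmann draw at the
#'   thermostat temperature.
#' @return A list with `trajectory` (list of [atomic_system()] frames,
#'   including the initial one), `report` (a `stability_report`), and
#'   `velocities` (final); for replica input, a list of such lists.
#' @export
simulate_md <- function(model, system, cfg, velocities = NULL) {
  single <- inherits(system, "atomic_system")
  systems <- if (single) list(system) else system
  ns <- length(systems)
  natoms <- vapply(systems, n_atoms, 1L)
  offset <- c(0L, cumsum(natoms))
  aslice <- lapply(seq_len(ns), function(s) (offset[s] + 1L):offset[s + 1L])
  n_tot <- sum(natoms)
  mass <- unlist(lapply(systems, function(s) atomic_mass(s$species)))
  kb <- celliq_constants$kb
  acc <- celliq_constants$acc
  oldseed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, .GlobalEnv))
  set.seed(cfg$seed)

  pos <- do.call(rbind, lapply(systems, function(s) s$positions))
  if (is.null(velocities)) {
    sig <- sqrt(kb * cfg$temperature / mass * acc)     # Angstrom/fs
    velocities <- matrix(stats::rnorm(3 * n_tot), n_tot, 3) * sig
    if (cfg$temperature == 0) velocities[] <- 0
  } else if (!single) {
    velocities <- do.call(rbind, velocities)
  }
  v <- velocities
  gfs <- cfg$friction * 1e-3                           # 1/ps -> 1/fs
  cf <- exp(-gfs * cfg$dt)
  sigv <- sqrt(kb * cfg$temperature / mass * acc)
  ou_noise <- sqrt(1 - cf^2) * sigv

  # forces for all replicas: the fused pass keeps the structures fully
  # independent (disjoint graphs, one Qeq solve per structure) while
  # amortizing the per-call overhead
  fused <- inherits(model, "potential_model")
  getf <- function(p) {
    if (fused) {
      cur <- systems
      for (s in seq_len(ns)) cur[[s]]$positions <- p[aslice[[s]], , drop = FALSE]
      geom <- .geometry(cur, model$config, need_grad = TRUE)
      fwd <- .model_forward(model, geom)
      bw <- .model_backward(model, geom, fwd, gu = rep(1, ns),
                            want_pos = TRUE, want_params = FALSE)
      list(f = -bw$gpos, u = fwd$u)
    } else {
      out <- lapply(seq_len(ns), function(s) {
        s2 <- systems[[s]]; s2$positions <- p[aslice[[s]], , drop = FALSE]
        predict(model, s2, forces = TRUE)
      })
      list(f = do.call(rbind, lapply(out, `[[`, "forces")),
           u = vapply(out, `[[`, 1.0, "energy"))
    }
  }
  fr <- getf(pos)
  bonds <- lapply(systems, .initial_bonds)
  mind <- vapply(seq_len(ns), function(s) .min_dist(pos[aslice[[s]], , drop = FALSE]), 1.0)
  maxstretch <- vapply(seq_len(ns), function(s)
    .bond_stretch(pos[aslice[[s]], , drop = FALSE], bonds[[s]]), 1.0)
  ktrace <- vector("list", ns)
  nonfinite_step <- NA_integer_
  traj <- lapply(seq_len(ns), function(s)
    list(.frame(systems[[s]], pos[aslice[[s]], , drop = FALSE], fr$u[s])))

  for (step in seq_len(cfg$n_steps)) {
    v <- v + 0.5 * cfg$dt * acc * fr$f / mass          # B
    pos <- pos + 0.5 * cfg$dt * v                      # A
    if (gfs > 0 || cfg$temperature > 0)                # O
      v <- cf * v + ou_noise * matrix(stats::rnorm(3 * n_tot), n_tot, 3)
    pos <- pos + 0.5 * cfg$dt * v                      # A
    fr <- getf(pos)
    if (!all(is.finite(fr$f)) || !all(is.finite(fr$u))) {
      nonfinite_step <- step
      break
    }
    v <- v + 0.5 * cfg$dt * acc * fr$f / mass          # B
    for (s in seq_len(ns)) {
      at <- aslice[[s]]
      ke <- 0.5 * sum(mass[at] * rowSums(v[at, , drop = FALSE]^2)) / acc
      ktrace[[s]] <- c(ktrace[[s]], 2 * ke / (3 * natoms[s] * kb))
      mind[s] <- min(mind[s], .min_dist(pos[at, , drop = FALSE]))
      maxstretch[s] <- max(maxstretch[s],
                           .bond_stretch(pos[at, , drop = FALSE], bonds[[s]]))
      if (step %% cfg$report_every == 0)
        traj[[s]][[length(traj[[s]]) + 1L]] <-
          .frame(systems[[s]], pos[at, , drop = FALSE], fr$u[s])
    }
  }
  results <- lapply(seq_len(ns), function(s) {
    report <- structure(list(
      min_distance_seen = mind[s],
      max_bond_stretch_ratio = maxstretch[s],
      any_nonfinite = !is.na(nonfinite_step),
      nonfinite_step = nonfinite_step,
      temperature_trace = ktrace[[s]]
    ), class = "stability_report")
    list(trajectory = traj[[s]], report = report,
         velocities = v[aslice[[s]], , drop = FALSE])
  })
  if (single) results[[1]] else results
}

.frame <- function(system, pos, u) {
  f <- system
  f$positions <- pos
  f$energy <- u
  f$forces <- NULL; f$charges <- NULL
  f
}

# bonded pairs of the initial frame: within 1.25 x the species-pair Morse
# minimum when the model carries one, else 1.25 x the covalent-radius sum
.initial_bonds <- function(system, model = NULL) {
  n <- n_atoms(system)
  if (n < 2) return(cbind(i = integer(0), j = integer(0), r0 = numeric(0)))
  rsum <- outer(covalent_radius(system$species), covalent_radius(system$species), "+")
  thresh <- 1.25 * rsum
  d <- as.matrix(stats::dist(system$positions))
  # ionic synthetic species bind beyond covalent-radius sums; use a floor of
  # 1.25 x the observed nearest-neighbor distance so bonds are never empty
  thresh <- pmax(thresh, 1.25 * min(d[upper.tri(d)]))
  sel <- which(upper.tri(d) & d < thresh, arr.ind = TRUE)
  cbind(i = sel[, 1], j = sel[, 2], r0 = d[sel])
}

# rebuild a stability report from a bare frame list (first frame defines
# the bond set)
.report_from_frames <- function(frames) {
  bonds <- .initial_bonds(frames[[1]])
  mind <- Inf; maxstretch <- 0; nonfin <- NA_integer_
  for (k in seq_along(frames)) {
    p <- frames[[k]]$positions
    if (!all(is.finite(p))) { nonfin <- k; break }
    mind <- min(mind, .min_dist(p))
    maxstretch <- max(maxstretch, .bond_stretch(p, bonds))
  }
  structure(list(min_distance_seen = mind,
                 max_bond_stretch_ratio = maxstretch,
                 any_nonfinite = !is.na(nonfin), nonfinite_step = nonfin,
                 temperature_trace = numeric(0)),
            class = "stability_report")
}

.bond_stretch <- function(pos, bonds) {
  if (!nrow(bonds)) return(0)
  d <- sqrt(rowSums((pos[bonds[, 1], , drop = FALSE] -
                       pos[bonds[, 2], , drop = FALSE])^2))
  max(d / bonds[, 3])
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(paste0("stability_report: min distance %.3f Angstrom, max bond ",
                     "stretch %.2fx, nonfinite: %s\n"),
              x$min_distance_seen, x$max_bond_stretch_ratio,
              if (x$any_nonfinite) paste("step", x$nonfinite_step) else "none"))
  if (length(x$temperature_trace))
    cat(sprintf("  mean kinetic temperature: %.1f K\n",
                mean(x$temperature_trace)))
  invisible(x)
}

#' Check a trajectory / stability report against thresholds
#'
#' Fails if any interatomic distance dropped below `min_distance`, any
#' initial bond stretched beyond `max_stretch` times its starting length, or
#' any non-finite energy/force occurred.
#'
#' @param result The list returned by [simulate_md()], its `report`, or a
#'   plain list of trajectory frames ([atomic_system()]s).
#' @param min_distance Minimum allowed distance [Angstrom].
#' @param max_stretch Maximum allowed bond stretch ratio.
#' @return A list with `pass` (logical) and `reasons` (character vector).
#' @export
stability_check <- function(result, min_distance = 0.5, max_stretch = 2.0) {
  rep <- if (inherits(result, "stability_report")) result
         else if (!is.null(result$report)) result$report
         else if (length(result) && inherits(result[[1]], "atomic_system"))
           .report_from_frames(result)
         else NULL
  if (is.null(rep)) stop("empty trajectory: nothing to check")
  reasons <- character(0)
  if (rep$any_nonfinite)
    reasons <- c(reasons, sprintf("non-finite values at step %d",
                                  rep$nonfinite_step))
  if (rep$min_distance_seen < min_distance)
    reasons <- c(reasons, sprintf("overlap: minimum distance %.3f < %.3f",
                                  rep$min_distance_seen, min_distance))
  if (rep$max_bond_stretch_ratio > max_stretch)
    reasons <- c(reasons, sprintf("broken bond: stretch %.2fx > %.2fx",
                                  rep$max_bond_stretch_ratio, max_stretch))
  list(pass = length(reasons) == 0, reasons = reasons)
}
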