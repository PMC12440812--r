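## Full potential model: backbone + one charge-equilibration block +
## readout + per-species energy shifts. One fused forward pass and one
## hand-written reverse pass provide both parameter gradients (training) and
## position gradients (forces), including the implicit differentiation of
## the constrained Qeq solve.

#' Assemble a potential model
#'
#' The model predicts `U = U_Coul + Delta U`, forces `F = -dU/dR` (with the
#' full sensitivity of the equilibrated charges to positions), and partial
#' charges `Q`. Exactly one charge-equilibration block sits at a
#' configurable position among the interaction layers; without it
#' (`use_celli = FALSE`) the block is replaced by an additional interaction
#' layer, yielding the strictly local, charge-blind baseline.
#'
#' @param species Integer vector of atomic numbers the model covers.
#' @param cutoff Graph cutoff radius [Angstrom].
#' @param n_layers Number of interaction layers.
#' @param feature_width,n_bessel,envelope_p,hidden Backbone controls, see
#'   [backbone_config()].
#' @param celli A [celli_config()] list.
#' @param use_celli Include the charge-equilibration block (default `TRUE`).
#' @param seed Integer seed for parameter initialization.
#' @return An object of class `potential_model`.
#' @export
potential_model <- function(species, cutoff = 4, n_layers = 2,
                            feature_width = 16, n_bessel = 8, envelope_p = 6,
                            hidden = 32, celli = celli_config(),
                            use_celli = TRUE, seed = 0) {
  if (!use_celli) n_layers <- n_layers + 1  # replacement convention
  cfg <- backbone_config(species, cutoff = cutoff, n_layers = n_layers,
                         feature_width = feature_width, n_bessel = n_bessel,
                         envelope_p = envelope_p, hidden = hidden,
                         seed = seed)
  if (is.null(celli$placement)) celli$placement <- floor(n_layers / 2)
  if (celli$placement < 0 || celli$placement > n_layers)
    stop("celli placement must lie between 0 and n_layers")
  cfg$celli <- celli
  cfg$use_celli <- use_celli
  oldseed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  rng <- function(n) stats::rnorm(n)
  params <- .init_backbone(cfg, rng)
  if (use_celli) params$celli <- .init_celli(celli, cfg, rng)
  if (!is.null(oldseed)) assign(".Random.seed", oldseed, .GlobalEnv)
  structure(list(
    config = cfg,
    params = params,
    shifts = stats::setNames(numeric(length(cfg$species)),
                             as.character(cfg$species)),
    gamma_exp = covalent_radius(cfg$species)
  ), class = "potential_model")
}

#' @export
print.potential_model <- function(x, ...) {
  cat(sprintf(paste0("potential_model: %d interaction layers, width %d, ",
                     "cutoff %.2f Angstrom, %s\n"),
              x$config$n_layers, x$config$feature_width, x$config$cutoff,
              if (isTRUE(x$config$use_celli))
                sprintf("charge-equilibration block at position %d",
                        x$config$celli$placement)
              else "no charge block (baseline)"))
  cat("  species:", paste(.z_to_symbol(x$config$species), collapse = " "), "\n")
  invisible(x)
}

## ---- Coulomb matrix (open) with backward hooks --------------------------

.m_open_forward <- function(dfull, gam) {
  n <- length(gam)
  ke <- celliq_constants$ke
  ssum <- outer(gam^2, gam^2, "+")
  amat <- 1 / sqrt(2 * ssum)
  m <- matrix(0, n, n)
  if (n > 1) {
    off <- row(m) != col(m)
    m[off] <- ke * .erf(amat[off] * dfull[off]) / dfull[off]
  }
  diag(m) <- ke * 2 / (sqrt(pi) * gam)
  list(m = m, amat = amat, ssum = ssum, r = dfull, gam = gam)
}

.m_open_backward <- function(cache, gm) {
  ke <- celliq_constants$ke
  n <- length(cache$gam)
  r <- cache$r; a <- cache$amat
  gd <- matrix(0, n, n)
  ggam <- numeric(n)
  if (n > 1) {
    off <- row(gd) != col(gd)
    e2 <- exp(-(a * r)^2)
    dmdr <- matrix(0, n, n)
    dmdr[off] <- ke * (2 * a[off] / sqrt(pi) * e2[off] / r[off] -
                         .erf(a[off] * r[off]) / r[off]^2)
    gd <- gm * dmdr
    ga <- matrix(0, n, n)
    ga[off] <- gm[off] * ke * 2 / sqrt(pi) * e2[off]
    # alpha_ab = (2(g_a^2 + g_b^2))^(-1/2), so
    # d alpha_ab / d g_a = -alpha_ab g_a / (g_a^2 + g_b^2); the entry (a, b)
    # contributes through both its row and its column atom
    kmat <- ga * (-a / cache$ssum)
    ggam <- cache$gam * (rowSums(kmat) + colSums(kmat))
  }
  ggam <- ggam + diag(gm) * (-ke * 2 / (sqrt(pi) * cache$gam^2))
  list(ggam = ggam, gd = gd)
}

## ---- short-range core repulsion -----------------------------------------

# Fixed screened nuclear-core baseline k_e Z_i Z_j erfc(r/d)/r with
# d = 0.2 (R_i^cov + R_j^cov): negligible beyond ~70% of the covalent-radius
# sum, a steep wall below it. Keeps molecular dynamics from collapsing into
# the unconstrained-extrapolation region below the sampled distances; within
# the training data range its contribution is orders of magnitude below the
# fit accuracy. Per directed edge, so the 1/2 removes double counting.
.core_energy <- function(geom, deriv = FALSE) {
  if (!length(geom$r)) {
    z <- numeric(length(geom$r))
    return(list(value = z, grad = z))
  }
  ke <- celliq_constants$ke
  zz <- geom$z[geom$src] * geom$z[geom$dst]
  d <- 0.2 * (covalent_radius(geom$z[geom$src]) +
                covalent_radius(geom$z[geom$dst]))
  r <- geom$r
  val <- 0.5 * ke * zz * .erfc(r / d) / r
  out <- list(value = val)
  if (deriv)
    out$grad <- 0.5 * ke * zz * (-2 / (d * sqrt(pi)) * exp(-(r / d)^2) / r -
                                   .erfc(r / d) / r^2)
  out
}

## ---- fused forward ------------------------------------------------------

# geom: merged geometry from .geometry(); returns energies per structure,
# charges per atom, and all caches needed for the reverse pass
.model_forward <- function(model, geom) {
  p <- model$params
  cfg <- model$config
  use_celli <- isTRUE(cfg$use_celli)
  pl <- if (use_celli) cfg$celli$placement else cfg$n_layers

  emb <- .embed_forward(p, geom)
  x <- emb$x
  lc <- vector("list", cfg$n_layers)
  for (l in seq_len(pl)) {
    lc[[l]] <- .layer_forward(p$layers[[l]], x, geom)
    x <- lc[[l]]$x
  }

  celli_cache <- NULL
  q <- rep(0, geom$n_tot)
  ucoul <- numeric(geom$ns)
  lambda <- rep(NA_real_, geom$ns)
  if (use_celli) {
    cp <- p$celli
    mr <- .mlp_forward(cp$mlp_r, x)
    chisum <- drop(.rowsum_to(mr$out[, 1, drop = FALSE], geom$src, geom$n_tot))
    chi <- cp$f * chisum
    jenv <- drop(.rowsum_to(mr$out[, 2, drop = FALSE], geom$src, geom$n_tot))
    jzr <- cp$jz[geom$zidx]
    jj <- species_hardness(jzr, jenv, cfg$celli$env_hardness)
    gam <- generalized_softplus(cp$stilde[geom$zidx]) / log(2) *
      model$gamma_exp[geom$zidx]
    mcache <- vector("list", geom$ns)
    kkt <- vector("list", geom$ns)
    for (s in seq_len(geom$ns)) {
      at <- (geom$offset[s] + 1L):geom$offset[s + 1L]
      if (geom$periodic[s]) {
        sys <- geom$systems[[s]]
        ew <- .ewald_setup(sys, gam[at], list())
        mm <- .ewald_operator_matrix(sys, gam[at], ew)
        mcache[[s]] <- list(m = mm, periodic = TRUE)
      } else {
        mcache[[s]] <- .m_open_forward(geom$dfull[[s]], gam[at])
      }
      m <- mcache[[s]]$m
      n <- length(at)
      a <- rbind(cbind(m + diag(jj[at], n), 1), c(rep(1, n), 0))
      z <- solve(a, c(-chi[at], geom$qtot[s]))
      q[at] <- z[1:n]
      lambda[s] <- z[n + 1]
      ucoul[s] <- 0.5 * sum(q[at] * (m %*% q[at]))
      kkt[[s]] <- a
    }
    cu <- .charge_update_forward(cp, x, q, geom)
    celli_cache <- list(mr = mr, chisum = chisum, chi = chi, jenv = jenv,
                        jzr = jzr, jj = jj, gam = gam, mcache = mcache,
                        kkt = kkt, cu = cu, x_in = x)
    x <- cu$x
  }
  for (l in seq.int(pl + 1L, length.out = cfg$n_layers - pl)) {
    lc[[l]] <- .layer_forward(p$layers[[l]], x, geom)
    x <- lc[[l]]$x
  }
  sc <- drop(x %*% p$readout) +
    rowSums(geom$rb * p$pair_readout[geom$pidx, , drop = FALSE])
  du <- drop(.rowsum_to(matrix(sc * geom$env, ncol = 1), geom$esid, geom$ns))
  ucore <- drop(.rowsum_to(matrix(.core_energy(geom)$value, ncol = 1),
                           geom$esid, geom$ns))
  list(u = ucoul + du + ucore, u_coul = ucoul, delta_u = du, u_core = ucore,
       q = q, lambda = lambda,
       emb = emb, lc = lc, celli = celli_cache, x_final = x, pl = pl)
}

## ---- fused backward -----------------------------------------------------

# gu: per-structure upstream dL/dU; gq_ext: per-atom upstream dL/dQ (or NULL)
.model_backward <- function(model, geom, fwd, gu, gq_ext = NULL,
                            want_pos = FALSE, want_params = TRUE) {
  p <- model$params
  cfg <- model$config
  use_celli <- isTRUE(cfg$use_celli)
  pl <- fwd$pl
  gp <- if (want_params) .zero_like(p) else NULL
  gr_edge <- numeric(length(geom$r))

  # readout (latent channel + species-pair radial channel)
  gu_e <- gu[geom$esid]
  pr_e <- p$pair_readout[geom$pidx, , drop = FALSE]
  sc <- drop(fwd$x_final %*% p$readout) + rowSums(geom$rb * pr_e)
  if (want_params) {
    gp$readout <- colSums(fwd$x_final * (gu_e * geom$env))
    gp$pair_readout <- .rowsum_to(geom$rb * (gu_e * geom$env), geom$pidx,
                                  nrow(p$pair_readout))
  }
  gx <- outer(gu_e * geom$env, p$readout)
  if (want_pos)
    gr_edge <- gr_edge + gu_e *
      (sc * geom$denv + geom$env * rowSums(geom$drb * pr_e) +
         .core_energy(geom, deriv = TRUE)$grad)

  # layers above the block
  for (l in rev(seq.int(pl + 1L, length.out = cfg$n_layers - pl))) {
    bl <- .layer_backward(p$layers[[l]], fwd$lc[[l]], geom, gx, want_params)
    gx <- bl$gx
    if (want_params) gp$layers[[l]] <- bl$gp
  }

  if (use_celli) {
    cc <- fwd$celli
    cp <- p$celli
    # charge embedding update
    bu <- .charge_update_backward(cp, cc$cu, geom, gx, want_pos = want_pos,
                                  want_params = want_params)
    gx <- bu$gx
    if (want_params) {
      gp$celli$mlp_q <- bu$gp$mlp_q
      gp$celli$mlp_x <- bu$gp$mlp_x
      gp$celli$ctx <- bu$gp$ctx
    }
    if (want_pos) gr_edge <- gr_edge + bu$gr
    gq <- bu$gq
    if (!is.null(gq_ext)) gq <- gq + gq_ext

    gchi <- numeric(geom$n_tot)
    gjj <- numeric(geom$n_tot)
    ggam <- numeric(geom$n_tot)
    gd_list <- vector("list", geom$ns)
    for (s in seq_len(geom$ns)) {
      at <- (geom$offset[s] + 1L):geom$offset[s + 1L]
      n <- length(at)
      qs <- fwd$q[at]
      m <- cc$mcache[[s]]$m
      # explicit U_Coul dependence
      gqs <- gq[at] + gu[s] * drop(m %*% qs)
      gm <- gu[s] * 0.5 * tcrossprod(qs)
      # implicit function theorem through the bordered KKT system
      uadj <- solve(cc$kkt[[s]], c(gqs, 0))[1:n]
      gchi[at] <- -uadj
      gh <- -tcrossprod(uadj, qs)
      gjj[at] <- gjj[at] + diag(gh)
      gm <- gm + gh
      if (isTRUE(cc$mcache[[s]]$periodic)) {
        stop("gradients through the periodic Coulomb operator are not ",
             "implemented; train and differentiate on open-boundary systems")
      } else {
        bm <- .m_open_backward(cc$mcache[[s]], gm)
        ggam[at] <- ggam[at] + bm$ggam
        gd_list[[s]] <- bm$gd
      }
    }

    # radii depend on species only, so their gradient is training-only
    if (want_params) {
      sp <- .sigmoid(cp$stilde[geom$zidx])
      gst <- ggam * sp / log(2) * model$gamma_exp[geom$zidx]
      gp$celli$stilde <- drop(.rowsum_to(matrix(gst, ncol = 1), geom$zidx,
                                         length(cp$stilde)))
      gjz_at <- gjj * exp(cc$jzr - cc$jj)
      gp$celli$jz <- drop(.rowsum_to(matrix(gjz_at, ncol = 1), geom$zidx,
                                     length(cp$jz)))
      gp$celli$f <- sum(gchi * cc$chisum)
    }
    # environment-hardness sums flow back into the edge features
    gjenv <- if (isTRUE(cfg$celli$env_hardness)) gjj * exp(cc$jenv - cc$jj)
             else numeric(geom$n_tot)
    # electronegativity path into the environment MLP
    gchie <- cp$f * gchi[geom$src]
    gjre <- gjenv[geom$src]
    br <- if (want_params) .mlp_backward(cp$mlp_r, cc$mr, cbind(gchie, gjre))
          else .mlp_backward_x(cp$mlp_r, cc$mr, cbind(gchie, gjre))
    if (want_params) gp$celli$mlp_r <- br$gp
    gx <- gx + br$gx
  } else {
    gd_list <- NULL
  }

  for (l in rev(seq_len(pl))) {
    bl <- .layer_backward(p$layers[[l]], fwd$lc[[l]], geom, gx, want_params)
    gx <- bl$gx
    if (want_params) gp$layers[[l]] <- bl$gp
  }
  be <- .embed_backward(p, geom, fwd$emb, gx,
                        gpos = if (want_pos) TRUE else NULL,
                        want_params = want_params)
  if (want_params) {
    gp$pair_embed <- be$gp$pair_embed
    gp$w_rb <- be$gp$w_rb
  }
  if (want_pos) gr_edge <- gr_edge + be$gr

  gpos <- NULL
  if (want_pos) {
    gpos <- matrix(0, geom$n_tot, 3)
    if (length(geom$src)) {
      for (k in 1:3) {
        contrib <- gr_edge * geom$u[, k]
        gpos[, k] <- gpos[, k] +
          drop(.rowsum_to(matrix(contrib, ncol = 1), geom$dst, geom$n_tot)) -
          drop(.rowsum_to(matrix(contrib, ncol = 1), geom$src, geom$n_tot))
      }
    }
    if (use_celli) {
      for (s in seq_len(geom$ns)) {
        gd <- gd_list[[s]]
        if (is.null(gd)) next
        at <- (geom$offset[s] + 1L):geom$offset[s + 1L]
        sgd <- gd + t(gd)
        r <- pmax(fwd$celli$mcache[[s]]$r, 1e-300)
        for (k in 1:3) {
          gpos[at, k] <- gpos[at, k] +
            rowSums(sgd * geom$ddisp[[s]][, , k] / r)
        }
      }
    }
  }
  list(gp = gp, gpos = gpos)
}

## ---- prediction ---------------------------------------------------------

#' Predict energy, forces and charges
#'
#' @param object A [potential_model()].
#' @param system An [atomic_system()].
#' @param forces Compute forces `-dU/dR` (open boundaries only).
#' @param absolute Add the per-species energy shifts back, reporting
#'   absolute rather than shifted energies.
#' @param ... Unused.
#' @return A list with `energy` [eV], `forces` [eV/Angstrom] (or `NULL`),
#'   `charges` [e], `u_coul`, `delta_u` (the learned correction), and
#'   `u_core` (the fixed screened nuclear-core repulsion baseline, which is
#'   negligible at bonded distances and prevents collapse in dynamics).
#' @export
predict.potential_model <- function(object, system, forces = TRUE,
                                    absolute = FALSE, ...) {
  geom <- .geometry(system, object$config, need_grad = forces)
  fwd <- tryCatch(.model_forward(object, geom), error = function(e)
    stop("prediction failed for structure: ", conditionMessage(e),
         call. = FALSE))
  u <- fwd$u
  if (absolute) {
    cnt <- table(factor(as.character(system$species),
                        levels = names(object$shifts)))
    u <- u + sum(object$shifts * as.numeric(cnt))
  }
  fo <- NULL
  if (forces) {
    bw <- .model_backward(object, geom, fwd, gu = 1, want_pos = TRUE,
                          want_params = FALSE)
    fo <- -bw$gpos
  }
  list(energy = u, forces = fo,
       charges = if (isTRUE(object$config$use_celli)) fwd$q else NULL,
       u_coul = fwd$u_coul, delta_u = fwd$delta_u, u_core = fwd$u_core)
}

#' Save / load a potential model
#'
#' The on-disk representation round-trips to a bit-identical predictor.
#'
#' @param model A [potential_model()].
#' @param path File path.
#' @return `load_model` returns the model; `save_model` returns `path`
#'   invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "potential_model")) stop("not a saved potential model")
  m
}
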