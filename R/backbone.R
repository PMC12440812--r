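## Strictly local scalar edge network: radial/species embeddings, the
## polynomial cutoff envelope, directed-edge interaction layers with
## environment sums, the per-edge energy readout, and the node-feature
## adapter mode for message-passing hosts.
##
## Directed edge features x_ij never propagate along the graph: each layer
## only mixes x_ij with the features of edges leaving the same source atom i,
## so the receptive field of an edge stays within one cutoff radius per
## environment sum.

#' Smooth polynomial cutoff envelope
#'
#' `p_env(u) = 1 - (p+1)(p+2)/2 u^p + p(p+2) u^(p+1) - p(p+1)/2 u^(p+2)`
#' with `u = r / r_c`: equals 1 at `r = 0`, vanishes with zero first and
#' second derivative at `r = r_c`, and is 0 beyond.
#'
#' @param r Distances [Angstrom], >= 0.
#' @param cutoff Cutoff radius `r_c` [Angstrom].
#' @param p Polynomial degree parameter (integer >= 2), default 6.
#' @param deriv If `TRUE`, also return the derivative w.r.t. `r`.
#' @return Envelope values in `[0, 1]`, or a list `(value, grad)` when
#'   `deriv = TRUE`.
#' @export
envelope <- function(r, cutoff, p = 6, deriv = FALSE) {
  if (any(r < 0)) stop("distances must be non-negative")
  u <- pmin(r / cutoff, 1)
  c1 <- (p + 1) * (p + 2) / 2
  c2 <- p * (p + 2)
  c3 <- p * (p + 1) / 2
  val <- 1 - c1 * u^p + c2 * u^(p + 1) - c3 * u^(p + 2)
  val[r >= cutoff] <- 0
  if (!deriv) return(val)
  g <- (-c1 * p * u^(p - 1) + c2 * (p + 1) * u^p - c3 * (p + 2) * u^(p + 1)) / cutoff
  g[r >= cutoff] <- 0
  list(value = val, grad = g)
}

#' Bessel radial basis
#'
#' `b_n(r) = sqrt(2 / r_c) sin(n pi r / r_c) / r` for `n = 1, ..., count`.
#'
#' @param r Distances [Angstrom], > 0.
#' @param cutoff Cutoff radius [Angstrom].
#' @param count Number of basis functions.
#' @param deriv If `TRUE`, also return derivatives w.r.t. `r`.
#' @return An `length(r) x count` matrix (or a list `(value, grad)`).
#' @export
radial_basis <- function(r, cutoff, count = 8, deriv = FALSE) {
  if (any(r <= 0)) stop("radial basis requires positive distances")
  n <- seq_len(count)
  arg <- outer(r, n * pi / cutoff)
  norm <- sqrt(2 / cutoff)
  val <- norm * sin(arg) / r
  if (!deriv) return(val)
  g <- norm * (sweep(cos(arg), 2, n * pi / cutoff, "*") - sin(arg) / r) / r
  list(value = val, grad = g)
}

#' Default backbone configuration
#'
#' @param species Integer vector of atomic numbers the model covers.
#' @param cutoff Graph cutoff radius [Angstrom].
#' @param n_layers Number of interaction layers.
#' @param feature_width Width of the per-edge latent feature vectors.
#' @param n_bessel Number of Bessel radial basis functions.
#' @param envelope_p Envelope degree parameter.
#' @param hidden Hidden width of the layer MLPs.
#' @param mode `"edge"` (strictly local directed-edge net) or
#'   `"node_adapter"` (features for a message-passing host).
#' @param seed Seed for parameter initialization.
#' @return A named list of configuration values.
#' @export
backbone_config <- function(species, cutoff = 4, n_layers = 2,
                            feature_width = 16, n_bessel = 8, envelope_p = 6,
                            hidden = 32, mode = c("edge", "node_adapter"),
                            seed = 0) {
  mode <- match.arg(mode)
  list(species = sort(unique(as.integer(species))), cutoff = cutoff,
       n_layers = n_layers, feature_width = feature_width,
       n_bessel = n_bessel, envelope_p = envelope_p, hidden = hidden,
       mode = mode, seed = seed)
}

# initialize backbone parameters from the config's seed
.init_backbone <- function(cfg, rng) {
  s <- length(cfg$species)
  w <- cfg$feature_width
  layers <- lapply(seq_len(cfg$n_layers), function(l) {
    list(A = .mlp_init(w, cfg$hidden, w, rng),
         B = .mlp_init(w, cfg$hidden, w, rng),
         U = .mlp_init(2 * w, cfg$hidden, w, rng),
         beta = 0.0)
  })
  list(
    pair_embed = matrix(rng(s * s * w), s * s, w),
    w_rb = matrix(rng(cfg$n_bessel * w) / sqrt(cfg$n_bessel), cfg$n_bessel, w),
    layers = layers,
    readout = numeric(w),     # zero-initialized: untrained correction is 0
    # direct species-pair radial channel of the readout (a learnable pair
    # potential in the Bessel basis); zero-initialized as well
    pair_readout = matrix(0, s * s, cfg$n_bessel)
  )
}

## ---- geometry cache -----------------------------------------------------

# Precompute everything geometry-dependent for one or more systems merged
# into a single disjoint graph: edge lists, radial features, edge-pair
# aggregation indices, and full per-structure distance matrices for the
# Coulomb operator.
.geometry <- function(systems, cfg, need_grad = FALSE) {
  if (inherits(systems, "atomic_system")) systems <- list(systems)
  spec_idx <- function(z) {
    m <- match(z, cfg$species)
    if (anyNA(m))
      stop("species outside the configured table: Z = ",
           paste(unique(z[is.na(m)]), collapse = ", "))
    m
  }
  natoms <- vapply(systems, n_atoms, 1L)
  offset <- c(0L, cumsum(natoms))
  ns <- length(systems)
  src <- integer(0); dst <- integer(0)
  r <- numeric(0); uvec <- matrix(0, 0, 3); esid <- integer(0)
  dfull <- vector("list", ns); ddisp <- vector("list", ns)
  for (s in seq_len(ns)) {
    sys <- systems[[s]]
    if (!any(sys$pbc)) {
      # open system: one all-pairs pass feeds both the neighbor list and
      # the full distance matrix of the Coulomb operator
      pos <- sys$positions
      n <- natoms[s]
      dd <- array(0, c(n, n, 3))
      for (k in 1:3) dd[, , k] <- outer(pos[, k], pos[, k], "-")
      dall <- sqrt(dd[, , 1]^2 + dd[, , 2]^2 + dd[, , 3]^2)
      dfull[[s]] <- dall
      ddisp[[s]] <- dd
      sel <- which(dall < cfg$cutoff & row(dall) != col(dall), arr.ind = TRUE)
      if (nrow(sel)) {
        ord <- order(sel[, 1], sel[, 2])
        sel <- sel[ord, , drop = FALSE]
        idx <- (sel[, 2] - 1) * n + sel[, 1]
        re <- dall[idx]
        src <- c(src, sel[, 1] + offset[s])
        dst <- c(dst, sel[, 2] + offset[s])
        r <- c(r, re)
        # displacement R_j - R_i = -dd[i, j, ]
        uvec <- rbind(uvec, cbind(-dd[, , 1][idx], -dd[, , 2][idx],
                                  -dd[, , 3][idx]) / re)
        esid <- c(esid, rep.int(s, length(re)))
      }
    } else {
      nb <- build_neighbor_list(sys, cfg$cutoff)
      ne <- nrow(nb$edges)
      if (ne) {
        src <- c(src, nb$edges[, 1] + offset[s])
        dst <- c(dst, nb$edges[, 2] + offset[s])
        r <- c(r, nb$distances)
        uvec <- rbind(uvec, nb$displacements / nb$distances)
        esid <- c(esid, rep.int(s, ne))
      }
    }
  }
  n_tot <- sum(natoms)
  zidx <- unlist(lapply(systems, function(s) spec_idx(s$species)))
  z_all <- unlist(lapply(systems, function(s) s$species))
  asid <- rep.int(seq_len(ns), natoms)
  if (length(r)) {
    en <- envelope(r, cfg$cutoff, cfg$envelope_p, deriv = need_grad)
    bb <- radial_basis(r, cfg$cutoff, cfg$n_bessel, deriv = need_grad)
    if (!need_grad) { en <- list(value = en); bb <- list(value = bb) }
  } else {
    en <- list(value = numeric(0), grad = numeric(0))
    bb <- list(value = matrix(0, 0, cfg$n_bessel),
               grad = matrix(0, 0, cfg$n_bessel))
  }
  sw <- length(cfg$species)
  pidx <- (zidx[src] - 1L) * sw + zidx[dst]
  list(systems = systems, natoms = natoms, offset = offset, n_tot = n_tot,
       ns = ns, src = src, dst = dst, r = r, u = uvec, esid = esid,
       asid = asid, zidx = zidx, z = z_all, pidx = pidx,
       env = en$value, denv = en$grad, rb = bb$value, drb = bb$grad,
       dfull = dfull, ddisp = ddisp,
       qtot = vapply(systems, function(s) s$total_charge, 1.0),
       periodic = vapply(systems, function(s) any(s$pbc), TRUE))
}

## ---- exported single ops ------------------------------------------------

#' Initial edge embedding (layer 0)
#'
#' Concatenation-free formulation: a learned species-pair embedding for
#' `(Z_i, Z_j)` plus a linear map of the envelope-weighted Bessel features of
#' `r_ij`.
#'
#' @param system An [atomic_system()].
#' @param nbrs Its [build_neighbor_list()] (built with the config cutoff).
#' @param cfg A [backbone_config()].
#' @param params Backbone parameters (from [potential_model()]'s `params`).
#' @return An E x width matrix of layer-0 edge features.
#' @export
embed_edges <- function(system, nbrs, cfg, params) {
  geom <- .geometry(system, cfg)
  .embed_forward(params, geom)$x
}

.embed_forward <- function(params, geom) {
  rbw <- geom$rb * geom$env
  x <- params$pair_embed[geom$pidx, , drop = FALSE] + rbw %*% params$w_rb
  list(x = x, rbw = rbw)
}

.embed_backward <- function(params, geom, cache, gx, gpos = NULL,
                            want_params = TRUE) {
  gp <- NULL
  if (want_params)
    gp <- list(
      pair_embed = .rowsum_to(gx, geom$pidx, nrow(params$pair_embed)),
      w_rb = crossprod(cache$rbw, gx)
    )
  gr <- NULL
  if (!is.null(gpos)) {
    grbw <- gx %*% t(params$w_rb)
    gr <- rowSums(grbw * (geom$drb * geom$env + geom$rb * geom$denv))
  }
  list(gp = gp, gr = gr)
}

# Environment sum with the factorized two-argument map
# W(x_ij, x_ik) = A(x_ij) * B(x_ik) (elementwise), so
# w_ij = A(x_ij) * sum_{k in N(i)} B(x_ik) costs edge-level work only.
.layer_forward <- function(lp, x, geom) {
  ma <- .mlp_forward(lp$A, x)
  mb <- .mlp_forward(lp$B, x)
  senv <- .rowsum_to(mb$out, geom$src, geom$n_tot)
  senv_e <- senv[geom$src, , drop = FALSE]
  wij <- ma$out * senv_e
  mu <- .mlp_forward(lp$U, cbind(wij, x))
  s <- sqrt(1 + lp$beta^2)
  xn <- (x + lp$beta * mu$out) / s
  list(x = xn, ma = ma, mb = mb, mu = mu, senv_e = senv_e, xin = x, s = s)
}

.layer_backward <- function(lp, cache, geom, gxn, want_params = TRUE) {
  mlpb <- if (want_params) .mlp_backward else .mlp_backward_x
  s <- cache$s
  gx <- gxn / s
  gxu <- lp$beta * gxn / s
  bu <- mlpb(lp$U, cache$mu, gxu)
  w <- ncol(cache$xin)
  gwij <- bu$gx[, 1:w, drop = FALSE]
  gx <- gx + bu$gx[, (w + 1):(2 * w), drop = FALSE]
  ga_out <- gwij * cache$senv_e
  gsenv_e <- gwij * cache$ma$out
  gb_out <- .rowsum_to(gsenv_e, geom$src, geom$n_tot)[geom$src, , drop = FALSE]
  ba <- mlpb(lp$A, cache$ma, ga_out)
  bb <- mlpb(lp$B, cache$mb, gb_out)
  gx <- gx + ba$gx + bb$gx
  gp <- NULL
  if (want_params) {
    gbeta <- sum(gxn * (cache$mu$out / s - cache$x * lp$beta / s^2))
    gp <- list(A = ba$gp, B = bb$gp, U = bu$gp, beta = gbeta)
  }
  list(gx = gx, gp = gp)
}

#' One strictly local interaction layer
#'
#' Environment sum `w_ij = sum_{k in N(i)} W(x_ij, x_ik)` with the learned
#' two-argument map factorized as `W(a, b) = A(a) * B(b)` (elementwise
#' product of two MLP embeddings, so the sum over the environment costs
#' edge-level work), followed by the update `U(w_ij, x_ij)` and a
#' variance-preserving weighted residual
#' `x' = (x + beta * update) / sqrt(1 + beta^2)`.
#'
#' @param latents E x width matrix of edge features at layer `l`.
#' @param system,nbrs The structure and its neighbor list.
#' @param cfg A [backbone_config()].
#' @param layer_params One element of the backbone's `layers` list.
#' @return Updated E x width matrix.
#' @export
interaction_layer <- function(latents, system, nbrs, cfg, layer_params) {
  geom <- .geometry(system, cfg)
  .layer_forward(layer_params, latents, geom)$x
}

#' Per-edge energy readout
#'
#' Linear map of the final-layer features to a per-edge scalar, multiplied by
#' the cutoff envelope, summed over all directed edges.
#'
#' @param latents Final-layer E x width edge features.
#' @param system,nbrs Structure and neighbor list.
#' @param cfg A [backbone_config()].
#' @param weights Readout weight vector (length width).
#' @return Correction energy `Delta U` in eV.
#' @export
readout_energy <- function(latents, system, nbrs, cfg, weights) {
  geom <- .geometry(system, cfg)
  sum(drop(latents %*% weights) * geom$env)
}

#' Residual node update for message-passing hosts
#'
#' `h_i' = h_i + epsilon * sum_{j in N(i)} x_ij` aggregates per-edge outputs
#' of a charge-equilibration block in adapter mode back onto the nodes.
#'
#' @param nodes N x width matrix of node features.
#' @param edge_out E x width matrix of per-edge block outputs.
#' @param nbrs The neighbor list defining the aggregation.
#' @param epsilon Learnable aggregation weight (scalar).
#' @return Updated N x width node-feature matrix.
#' @export
node_mode_update <- function(nodes, edge_out, nbrs, epsilon) {
  if (ncol(nodes) != ncol(edge_out))
    stop("node and edge feature widths differ")
  nodes + epsilon * .rowsum_to(edge_out, nbrs$edges[, 1], nrow(nodes))
}

#' Adapter-mode edge construction
#'
#' Builds layer-0 edge features for a message-passing host:
#' `x_ij = (p_env(r_ij) h_i || e_rbf,ij)`.
#'
#' @param nodes N x width matrix of scalar node features.
#' @param nbrs Neighbor list.
#' @param cutoff,n_bessel,envelope_p Radial embedding controls.
#' @return E x (width + n_bessel) matrix.
#' @export
adapter_edge_features <- function(nodes, nbrs, cutoff, n_bessel = 8,
                                  envelope_p = 6) {
  en <- envelope(nbrs$distances, cutoff, envelope_p)
  cbind(nodes[nbrs$edges[, 1], , drop = FALSE] * en,
        radial_basis(nbrs$distances, cutoff, n_bessel))
}
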