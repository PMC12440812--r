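## The charge-equilibration layer: maps latent edge features to per-atom Qeq
## parameters (electronegativity from the environment, hardness and charge
## radii from the species), solves the constrained charge equilibration, and
## embeds the equilibrated charges back into the latent features.

#' Generalized softplus
#'
#' `sigma_+(x_1, ..., x_k) = log(1 + exp(x_1) + ... + exp(x_k))`, computed
#' overflow-safely. With no arguments the empty sum gives `log(1) = 0`.
#'
#' @param ... Numeric scalars or vectors (recycled elementwise).
#' @return Positive numeric vector (non-negative; 0 only for the empty call).
#' @export
generalized_softplus <- function(...) {
  args <- list(...)
  if (!length(args)) return(0)
  x <- do.call(cbind, args)
  m <- pmax(0, apply(x, 1, max))
  s <- rowSums(exp(x - m))
  # at m = 0 use log1p so tiny sums are not rounded away
  ifelse(m == 0, log1p(s), m + log(exp(-m) + s))
}

#' Configuration of the charge-equilibration layer
#'
#' @param placement Index of the interaction layer after which the block
#'   sits (0 = before the first layer). Default: central,
#'   `floor(n_layers / 2)`.
#' @param env_hardness Use environment-dependent hardness contributions
#'   `J^R` in addition to the species term (default off).
#' @param hidden Hidden width of the block's MLPs.
#' @param context_width Width of the species context features `c(Z)`.
#' @param y_width Width of the charge-dependent edge features `y_ij`.
#' @param f_init Initial value of the species-invariant scale factor `f`.
#' @return A named list.
#' @export
celli_config <- function(placement = NULL, env_hardness = FALSE, hidden = 16,
                         context_width = 4, y_width = 8, f_init = 0.5) {
  list(placement = placement, env_hardness = env_hardness, hidden = hidden,
       context_width = context_width, y_width = y_width, f_init = f_init)
}

# initialize the block's parameters for a species table
.init_celli <- function(ccfg, cfg, rng) {
  s <- length(cfg$species)
  w <- cfg$feature_width
  list(
    mlp_r = .mlp_init(w, ccfg$hidden, 2, rng),
    f = ccfg$f_init,
    jz = rng(s) * 0.1 + 1,          # pre-softplus species hardness
    stilde = numeric(s),            # 0 => gamma = covalent radius exactly
    ctx = matrix(rng(s * ccfg$context_width), s, ccfg$context_width),
    mlp_q = .mlp_init(2 + 2 * ccfg$context_width, ccfg$hidden, ccfg$y_width, rng),
    mlp_x = .mlp_init(ccfg$y_width + w, ccfg$hidden, w, rng)
  )
}

#' Per-atom electronegativities from the edge environment
#'
#' Applies the block's environment MLP to every directed edge feature and
#' sums the first output channel over all edges leaving each atom:
#' `chi_i = f * sum_{k in N(i)} chi~_ik`. The second channel carries the
#' optional environment hardness contributions, returned as per-atom sums.
#' Atoms without any incident edge get `chi_i = 0`.
#'
#' @param latents E x width matrix of edge features at the block's layer.
#' @param system,nbrs Structure and neighbor list.
#' @param cp CELLI parameter list (fields `mlp_r`, `f`).
#' @return A list with `chi` (length N) and `j_env` (length N).
#' @export
environment_embedding <- function(latents, system, nbrs, cp) {
  n <- n_atoms(system)
  out <- .mlp_forward(cp$mlp_r, latents)$out
  chi <- cp$f * drop(.rowsum_to(out[, 1, drop = FALSE], nbrs$edges[, 1], n))
  jenv <- drop(.rowsum_to(out[, 2, drop = FALSE], nbrs$edges[, 1], n))
  list(chi = chi, j_env = jenv)
}

#' Strictly positive per-atom hardness
#'
#' `J_i = sigma_+(J~^Z_i, sum_j J~^R_ij)`; without environment hardness the
#' second argument is dropped and `J` depends on the species alone.
#'
#' @param jz_raw Per-atom pre-softplus species hardness `J~^Z`.
#' @param j_env Per-atom environment sums (ignored unless `env_hardness`).
#' @param env_hardness Logical toggle.
#' @return Per-atom hardness in eV/e^2, strictly positive.
#' @export
species_hardness <- function(jz_raw, j_env = NULL, env_hardness = FALSE) {
  if (env_hardness) {
    if (is.null(j_env)) stop("env_hardness requires environment sums")
    generalized_softplus(jz_raw, j_env)
  } else {
    generalized_softplus(jz_raw)
  }
}

#' Per-atom Gaussian charge radii
#'
#' `gamma_i = sigma_+(s~_i) / log(2) * gamma_i^exp`: a learned positive
#' species scaling of tabulated single-bond covalent radii. At `s~ = 0` the
#' factor is exactly 1.
#'
#' @param stilde_raw Per-atom pre-softplus scale parameter.
#' @param gamma_exp Per-atom covalent radii [Angstrom].
#' @return Per-atom radii in Angstrom, strictly positive.
#' @export
species_radii <- function(stilde_raw, gamma_exp) {
  if (any(gamma_exp <= 0)) stop("covalent radii must be positive")
  generalized_softplus(stilde_raw) / log(2) * gamma_exp
}

#' Charge embedding and latent feature update
#'
#' `y_ij = MLP_Q(Q_i, Q_j, c_i, c_j)` followed by
#' `x'_ij = MLP_x(y_ij, x_ij) * p_env(r_ij)`: the equilibrated charge
#' environment is written back into the latent edge features so that
#' downstream layers can condition short-range terms on the charge state.
#'
#' @param latents E x width matrix at the block's layer.
#' @param charges Equilibrated per-atom charges [e].
#' @param system,nbrs Structure and neighbor list.
#' @param cfg Backbone config (for the envelope).
#' @param cp CELLI parameter list (`ctx`, `mlp_q`, `mlp_x`).
#' @return Updated E x width matrix.
#' @export
charge_embedding_update <- function(latents, charges, system, nbrs, cfg, cp) {
  geom <- .geometry(system, cfg)
  .charge_update_forward(cp, latents, charges, geom)$x
}

.charge_update_forward <- function(cp, x, q, geom) {
  ci <- cp$ctx[geom$zidx[geom$src], , drop = FALSE]
  cj <- cp$ctx[geom$zidx[geom$dst], , drop = FALSE]
  mq <- .mlp_forward(cp$mlp_q, cbind(q[geom$src], q[geom$dst], ci, cj))
  mx <- .mlp_forward(cp$mlp_x, cbind(mq$out, x))
  list(x = mx$out * geom$env, mq = mq, mx = mx, raw = mx$out)
}

.charge_update_backward <- function(cp, cache, geom, gx, want_pos = FALSE,
                                    want_params = TRUE) {
  mlpb <- if (want_params) .mlp_backward else .mlp_backward_x
  graw <- gx * geom$env
  gr <- if (want_pos) rowSums(gx * cache$raw) * geom$denv else NULL
  bx <- mlpb(cp$mlp_x, cache$mx, graw)
  wy <- ncol(cache$mq$out)
  gy <- bx$gx[, 1:wy, drop = FALSE]
  gxin <- bx$gx[, (wy + 1):ncol(bx$gx), drop = FALSE]
  bq <- mlpb(cp$mlp_q, cache$mq, gy)
  n <- geom$n_tot
  gq <- drop(.rowsum_to(bq$gx[, 1, drop = FALSE], geom$src, n)) +
        drop(.rowsum_to(bq$gx[, 2, drop = FALSE], geom$dst, n))
  gp <- NULL
  if (want_params) {
    wc <- ncol(cp$ctx)
    gctx <- .rowsum_to(bq$gx[, 3:(2 + wc), drop = FALSE],
                       geom$zidx[geom$src], nrow(cp$ctx)) +
            .rowsum_to(bq$gx[, (3 + wc):(2 + 2 * wc), drop = FALSE],
                       geom$zidx[geom$dst], nrow(cp$ctx))
    gp <- list(mlp_q = bq$gp, mlp_x = bx$gp, ctx = gctx)
  }
  list(gx = gxin, gq = gq, gr = gr, gp = gp)
}

#' Full forward pass of the charge-equilibration block
#'
#' Composes the environment embedding, species hardness and radii, the
#' constrained Qeq solve, and the charge embedding update.
#'
#' @param latents E x width matrix at the block's layer.
#' @param system,nbrs Structure and neighbor list.
#' @param cfg Backbone config.
#' @param ccfg [celli_config()].
#' @param cp CELLI parameter list.
#' @param op Optional precomputed [coulomb_operator()]; by default it is
#'   built from the learned radii.
#' @return A list with `latents` (updated features), `u_coul` [eV],
#'   `charges` [e], and `multiplier`.
#' @export
celli_forward <- function(latents, system, nbrs, cfg, ccfg, cp, op = NULL) {
  emb <- environment_embedding(latents, system, nbrs, cp)
  zi <- match(system$species, cfg$species)
  if (anyNA(zi)) stop("species outside the configured table")
  hard <- species_hardness(cp$jz[zi], emb$j_env, ccfg$env_hardness)
  gam <- species_radii(cp$stilde[zi], covalent_radius(system$species))
  if (is.null(op)) op <- coulomb_operator(system, gam)
  params <- qeq_parameters(emb$chi, hard, gam, system$total_charge)
  sol <- solve_qeq(params, op)
  geom <- .geometry(system, cfg)
  upd <- .charge_update_forward(cp, latents, sol$charges, geom)
  list(latents = upd$x, u_coul = sol$energy_coul, charges = sol$charges,
       multiplier = sol$multiplier)
}
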