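## Force-matching training: per-species energy shifts by ridge regression,
## the weighted loss over energies / forces / charges, and stochastic
## minibatch optimization (Adam, polynomial step-size schedule, decoupled
## weight decay) with validation-based checkpoint selection.

#' Loss weights for force-matching training
#'
#' @param gamma_U Energy weight [1/eV^2].
#' @param gamma_F Force weight [(Angstrom/eV)^2].
#' @param gamma_Q Charge weight [1/e^2].
#' @return A named list of class `loss_weights`.
#' @export
loss_weights <- function(gamma_U = 1, gamma_F = 0, gamma_Q = 1) {
  if (gamma_U < 0 || gamma_F < 0 || gamma_Q < 0)
    stop("loss weights must be non-negative")
  if (gamma_U == 0 && gamma_F == 0 && gamma_Q == 0)
    stop("at least one loss weight must be positive")
  structure(list(gamma_U = gamma_U, gamma_F = gamma_F, gamma_Q = gamma_Q),
            class = "loss_weights")
}

# per-structure species counts against a reference species ordering
.composition <- function(systems, species) {
  matrix(vapply(systems, function(s)
    as.numeric(table(factor(s$species, levels = species))),
    numeric(length(species))),
    nrow = length(systems), ncol = length(species), byrow = TRUE)
}

#' Fit per-species energy shifts by ridge regression
#'
#' Solves `U_s = argmin sum_i (U_i - sum_s U_s N_{s,i})^2 + lambda ||U_s||^2`
#' where `N_{s,i}` counts species `s` in sample `i`. Species present in the
#' table but absent from the data get shift 0 with a warning.
#'
#' @param dataset List of labeled [atomic_system()]s (energies required).
#' @param species Integer vector: the species ordering of the model table.
#' @param ridge_lambda Ridge penalty (>= 0).
#' @return Named numeric vector of shifts [eV], names are atomic numbers.
#' @export
fit_shifts <- function(dataset, species, ridge_lambda = 1e-8) {
  if (ridge_lambda < 0) stop("ridge_lambda must be non-negative")
  u <- vapply(dataset, function(s) {
    if (is.null(s$energy)) stop("every sample needs an energy label")
    s$energy
  }, 1.0)
  x <- .composition(dataset, species)
  absent <- colSums(x) == 0
  if (any(absent))
    warning("species absent from data get shift 0: ",
            paste(species[absent], collapse = ", "))
  shifts <- numeric(length(species))
  if (any(!absent)) {
    xs <- x[, !absent, drop = FALSE]
    a <- crossprod(xs) + diag(ridge_lambda, ncol(xs))
    shifts[!absent] <- drop(solve(a, crossprod(xs, u)))
  }
  stats::setNames(shifts, as.character(species))
}

# reference energy on the shifted scale
.shifted_energy <- function(sys, shifts, species) {
  cnt <- as.numeric(table(factor(sys$species, levels = species)))
  sys$energy - sum(shifts * cnt)
}

#' Force-matching loss
#'
#' `L = (1/D) sum_i [ gamma_U ||U - U_hat||^2 + gamma_F/(3 N_i) ||F - F_hat||^2
#'      + gamma_Q/N_i ||Q - Q_hat||^2 ]` with reference energies on the
#' shifted scale of the model's per-species shifts.
#'
#' @param model A [potential_model()].
#' @param batch List of labeled [atomic_system()]s.
#' @param weights A [loss_weights()] object.
#' @return Scalar loss.
#' @export
fm_loss <- function(model, batch, weights) {
  species <- model$config$species
  tot <- 0
  for (i in seq_along(batch)) {
    sys <- batch[[i]]
    need_f <- weights$gamma_F > 0
    if (weights$gamma_U > 0 && is.null(sys$energy))
      stop("sample ", i, " lacks an energy label")
    if (need_f && is.null(sys$forces))
      stop("sample ", i, " lacks force labels")
    if (weights$gamma_Q > 0 && is.null(sys$charges))
      stop("sample ", i, " lacks charge labels")
    pr <- predict(model, sys, forces = need_f)
    n <- n_atoms(sys)
    li <- 0
    if (weights$gamma_U > 0)
      li <- li + weights$gamma_U *
        (pr$energy - .shifted_energy(sys, model$shifts, species))^2
    if (need_f)
      li <- li + weights$gamma_F / (3 * n) * sum((pr$forces - sys$forces)^2)
    if (weights$gamma_Q > 0)
      li <- li + weights$gamma_Q / n * sum((pr$charges - sys$charges)^2)
    tot <- tot + li
  }
  tot / length(batch)
}

# energy/charge loss and parameter gradient for one precomputed batch
.batch_loss_grad <- function(model, bg, weights) {
  fwd <- .model_forward(model, bg$geom)
  ns <- bg$geom$ns
  du <- fwd$u - bg$uhat
  gu <- 2 * weights$gamma_U * du / ns
  loss <- weights$gamma_U * sum(du^2) / ns
  gq <- NULL
  if (weights$gamma_Q > 0) {
    dq <- fwd$q - bg$qhat
    wq <- weights$gamma_Q / bg$geom$natoms[bg$geom$asid] / ns
    gq <- 2 * wq * dq
    loss <- loss + sum(wq * dq^2)
  }
  bw <- .model_backward(model, bg$geom, fwd, gu = gu, gq_ext = gq)
  list(loss = loss, gp = bw$gp)
}

# precompute merged geometry and stacked labels for fixed batches
.prepare_batches <- function(model, dataset, batch_size) {
  species <- model$config$species
  idx <- split(seq_along(dataset),
               ceiling(seq_along(dataset) / batch_size))
  lapply(idx, function(ii) {
    systems <- dataset[ii]
    geom <- .geometry(systems, model$config)
    uhat <- vapply(systems, .shifted_energy, 1.0,
                   shifts = model$shifts, species = species)
    qhat <- unlist(lapply(systems, function(s)
      if (is.null(s$charges)) rep(NA_real_, n_atoms(s)) else s$charges))
    list(geom = geom, uhat = uhat, qhat = qhat)
  })
}

#' Train a potential by stochastic force matching
#'
#' Minimizes the energy and charge terms of the force-matching loss with
#' Adam, a polynomial step-size schedule
#' `lr(t) = lr0 (1 - t/T)^kappa`, decoupled weight decay, and global
#' gradient-norm clipping. The checkpoint with the lowest validation loss is
#' returned. Reference energies are compared on the shifted scale of
#' `model$shifts` (fit them first with [fit_shifts()]).
#'
#' Gradients for a non-zero force weight would require second-order
#' differentiation and are not supported by the trainer; use the force term
#' via [fm_loss()] for evaluation only.
#'
#' @param model A [potential_model()].
#' @param train_set,val_set Disjoint lists of labeled systems.
#' @param weights A [loss_weights()] with `gamma_F = 0`.
#' @param n_epochs Number of passes over the training set.
#' @param batch_size Structures per minibatch.
#' @param lr0 Initial step size.
#' @param kappa Polynomial decay exponent.
#' @param weight_decay Decoupled weight-decay coefficient.
#' @param clip Global gradient-norm clip.
#' @param seed Seed controlling shuffling (training is bit-reproducible for
#'   a fixed seed on a fixed platform).
#' @param verbose Print per-epoch progress.
#' @return A list with `model` (best-validation checkpoint) and `history`
#'   (one row per epoch: train loss, validation loss and metrics).
#' @export
train_potential <- function(model, train_set, val_set,
                            weights = loss_weights(), n_epochs = 30,
                            batch_size = 32, lr0 = 5e-3, kappa = 1,
                            weight_decay = 1e-5, clip = 100, seed = 0,
                            verbose = FALSE) {
  if (weights$gamma_F > 0)
    stop("training gradients for the force term are not supported; ",
         "set gamma_F = 0 (see ?train_potential)")
  history <- data.frame()
  if (n_epochs <= 0) return(list(model = model, history = history))
  oldseed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, .GlobalEnv))
  set.seed(seed)

  batches <- .prepare_batches(model, train_set, batch_size)
  vb <- .prepare_batches(model, val_set, length(val_set))
  val_eval <- function(m) {
    fwd <- .model_forward(m, vb[[1]]$geom)
    du <- fwd$u - vb[[1]]$uhat
    nat <- vb[[1]]$geom$natoms
    loss <- weights$gamma_U * mean(du^2)
    qrmse <- NA_real_
    if (weights$gamma_Q > 0) {
      dq <- fwd$q - vb[[1]]$qhat
      wq <- weights$gamma_Q / nat[vb[[1]]$geom$asid]
      loss <- loss + sum(wq * dq^2) / length(nat)
      qrmse <- sqrt(mean(dq^2))
    }
    list(loss = loss, u_mae_atom = mean(abs(du) / nat), q_rmse = qrmse)
  }

  theta <- unlist(model$params)
  madam <- vadam <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  tmax <- n_epochs * length(batches)
  t <- 0L
  best <- list(loss = Inf, theta = theta)
  for (ep in seq_len(n_epochs)) {
    ord <- sample(length(batches))
    ep_loss <- 0
    for (bi in ord) {
      t <- t + 1L
      lg <- .batch_loss_grad(model, batches[[bi]], weights)
      if (!is.finite(lg$loss))
        stop("non-finite loss at optimization step ", t)
      g <- unlist(lg$gp)
      gn <- sqrt(sum(g^2))
      if (gn > clip) g <- g * (clip / gn)
      madam <- b1 * madam + (1 - b1) * g
      vadam <- b2 * vadam + (1 - b2) * g^2
      lr <- lr0 * (1 - (t - 1) / tmax)^kappa
      step <- lr * (madam / (1 - b1^t)) /
        (sqrt(vadam / (1 - b2^t)) + eps)
      theta <- theta - step - lr * weight_decay * theta
      model$params <- utils::relist(theta, model$params)
      ep_loss <- ep_loss + lg$loss
    }
    ve <- val_eval(model)
    if (ve$loss <= best$loss) best <- list(loss = ve$loss, theta = theta)
    history <- rbind(history, data.frame(
      epoch = ep, train_loss = ep_loss / length(batches),
      val_loss = ve$loss,
      val_u_mae_mev_atom = 1000 * ve$u_mae_atom,
      val_q_rmse_me = 1000 * ve$q_rmse))
    if (verbose)
      message(sprintf("epoch %3d  train %.5g  val %.5g  U %.2f meV/atom  Q %.2f me",
                      ep, ep_loss / length(batches), ve$loss,
                      1000 * ve$u_mae_atom, 1000 * ve$q_rmse))
  }
  model$params <- utils::relist(best$theta, model$params)
  list(model = model, history = history)
}
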