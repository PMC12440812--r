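## Evaluation and reporting surface: metrics in the field's customary
## units (meV/atom, meV/Angstrom, me), charge export, and run-configuration
## loading with fail-fast validation.

#' Evaluate a model on a labeled dataset
#'
#' Reports energy RMSE/MAE in meV/atom, force RMSE/MAE in meV/Angstrom, and
#' charge RMSE in me. When twin metadata (`info$twin`) pairs
#' geometry-identical structures in different total-charge states, the
#' twin-set energy-difference error (RMSE of the predicted vs reference
#' pairwise energy difference, meV) is reported as well. Metrics whose
#' labels are absent are omitted with a notice.
#'
#' @param model A [potential_model()].
#' @param dataset List of labeled [atomic_system()]s.
#' @param forces Include force metrics (requires force labels).
#' @return A one-row data frame of metrics.
#' @export
evaluate_model <- function(model, dataset, forces = FALSE) {
  species <- model$config$species
  n <- vapply(dataset, n_atoms, 1L)
  has_u <- all(vapply(dataset, function(s) !is.null(s$energy), TRUE))
  has_q <- all(vapply(dataset, function(s) !is.null(s$charges), TRUE))
  has_f <- all(vapply(dataset, function(s) !is.null(s$forces), TRUE))
  preds <- lapply(dataset, predict, object = model, forces = forces && has_f)
  out <- list(n_structures = length(dataset))
  if (has_u) {
    du <- mapply(function(p, s) p$energy - .shifted_energy(s, model$shifts,
                                                           species),
                 preds, dataset) / n
    out$u_rmse_mev_atom <- 1000 * sqrt(mean(du^2))
    out$u_mae_mev_atom <- 1000 * mean(abs(du))
  } else message("energy labels absent: energy metrics omitted")
  if (forces && has_f) {
    df <- unlist(mapply(function(p, s) p$forces - s$forces, preds, dataset,
                        SIMPLIFY = FALSE))
    out$f_rmse_mev_a <- 1000 * sqrt(mean(df^2))
    out$f_mae_mev_a <- 1000 * mean(abs(df))
  } else if (forces) message("force labels absent: force metrics omitted")
  if (has_q && isTRUE(model$config$use_celli)) {
    dq <- unlist(mapply(function(p, s) p$charges - s$charges, preds, dataset,
                        SIMPLIFY = FALSE))
    out$q_rmse_me <- 1000 * sqrt(mean(dq^2))
  } else if (has_q) message("model predicts no charges: charge metric omitted")
  else message("charge labels absent: charge metric omitted")
  twins <- vapply(dataset, function(s)
    if (is.null(s$info$twin)) NA_character_ else s$info$twin, "x")
  if (has_u && any(!is.na(twins))) {
    ids <- unique(twins[!is.na(twins)])
    dd <- vapply(ids, function(id) {
      k <- which(twins == id)
      if (length(k) != 2) return(NA_real_)
      dref <- dataset[[k[2]]]$energy - dataset[[k[1]]]$energy
      dprd <- (preds[[k[2]]]$energy + .shift_sum(dataset[[k[2]]], model)) -
              (preds[[k[1]]]$energy + .shift_sum(dataset[[k[1]]], model))
      dprd - dref
    }, 1.0)
    out$twin_du_rmse_mev <- 1000 * sqrt(mean(dd^2, na.rm = TRUE))
  }
  as.data.frame(out)
}

.shift_sum <- function(sys, model) {
  cnt <- as.numeric(table(factor(sys$species, levels = model$config$species)))
  sum(model$shifts * cnt)
}

#' Predict and export partial charges
#'
#' Reads frames, augments them with the model's equilibrated charges, and
#' writes them back as extended XYZ. The charge column of every frame sums
#' to the frame's declared total charge.
#'
#' @param model A [potential_model()].
#' @param input Path to an extended XYZ file.
#' @param output Output path.
#' @return Invisibly, the list of augmented systems.
#' @export
predict_charges <- function(model, input, output) {
  systems <- read_extxyz(input)
  out <- lapply(systems, function(sys) {
    pr <- predict(model, sys, forces = FALSE)
    sys$charges <- pr$charges
    sys
  })
  write_extxyz(out, output)
  invisible(out)
}

## ---- run configuration --------------------------------------------------

.config_schema <- list(
  data = c("train", "val", "test", "out_dir"),
  backbone = c("cutoff", "n_layers", "feature_width", "n_bessel",
               "envelope_p", "hidden", "mode", "species"),
  celli = c("enabled", "placement", "env_hardness", "hidden",
            "context_width", "y_width", "f_init"),
  electrostatics = c("boundary", "ewald_accuracy", "splitting_width"),
  training = c("gamma_u", "gamma_f", "gamma_q", "n_epochs", "batch_size",
               "lr0", "kappa", "weight_decay", "clip"),
  md = c("dt", "temperature", "friction", "n_steps", "report_every"),
  seed = NULL, version = NULL
)

#' Read and validate a run configuration file
#'
#' YAML configuration with sections `data`, `backbone`, `celli`,
#' `electrostatics`, `training`, `md` plus top-level `seed` and `version`.
#' Unknown sections or keys are rejected (fail-fast).
#'
#' @param path Path to a YAML file.
#' @param overrides Named list of `section.key` overrides (e.g. from
#'   command-line flags); overrides take precedence over file values.
#' @return The validated configuration as a nested list.
#' @export
read_run_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  for (nm in names(overrides)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) == 2) cfg[[parts[1]]][[parts[2]]] <- overrides[[nm]]
    else cfg[[nm]] <- overrides[[nm]]
  }
  unknown <- setdiff(names(cfg), names(.config_schema))
  if (length(unknown))
    stop("unknown configuration section(s): ", paste(unknown, collapse = ", "))
  for (sec in names(cfg)) {
    allowed <- .config_schema[[sec]]
    if (is.null(allowed)) next
    bad <- setdiff(names(cfg[[sec]]), allowed)
    if (length(bad))
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "))
  }
  cfg
}

#' Write the resolved configuration next to a run's outputs
#'
#' @param cfg A configuration list.
#' @param path Output YAML path.
#' @return Invisibly, `path`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# timestamped log line; suppressed when quiet
.log <- function(..., quiet = FALSE) {
  if (!quiet)
    message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " celliq ",
            utils::packageVersion("celliq"), " | ", ...)
  invisible(NULL)
}
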