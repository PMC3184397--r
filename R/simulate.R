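#' Perturbation protocol configuration
#'
#' Settings of the oxidative-perturbation experiment: a subject's network is
#' brought to its pre-perturbation steady state, a hydrogen-peroxide dose is
#' applied at `t = 0`, and the system is observed while it recovers.
#'
#' @param h2o2_dose Perturbation dose (uM; default 100, i.e. 0.1 mM).
#' @param window Observation window (s; default 1800, i.e. 30 min).
#' @param dose_mode `"bolus_internal"` (default): the intracellular H2O2
#'   concentration is raised instantaneously by the dose at `t = 0`.
#'   `"clamp_external"`: the extracellular H2O2 concentration is clamped at
#'   the dose from `t = 0` onward and enters through the diffusion reaction.
#' @param record_step Recording step of the trajectory (s).
#' @param theta Recovery threshold: the ratio counts as recovered once it
#'   re-attains `theta` times its pre-perturbation value (default 0.99).
#' @param rtol,atol Relative / absolute integrator tolerances.
#' @param ss_tol Steady-state residual tolerance (uM/s, infinity norm).
#' @return A list of class `protocol_config`.
#' @export
protocol_config <- function(h2o2_dose = 100, window = 1800,
                            dose_mode = c("bolus_internal", "clamp_external"),
                            record_step = 1, theta = 0.99,
                            rtol = 1e-8, atol = 1e-10, ss_tol = 1e-8) {
  dose_mode <- match.arg(dose_mode)
  if (h2o2_dose < 0 || window <= 0 || record_step <= 0 ||
      theta <= 0 || theta >= 1) {
    rlang::abort("require dose >= 0, window > 0, record_step > 0, 0 < theta < 1",
                 class = "redoxrbc_parameter_error")
  }
  structure(list(h2o2_dose = h2o2_dose, window = window, dose_mode = dose_mode,
                 record_step = record_step, theta = theta,
                 rtol = rtol, atol = atol, ss_tol = ss_tol),
            class = "protocol_config")
}

# Integrate the dynamic species; returns deSolve matrix with flux columns.
integrate_model <- function(y0, times, model, kin, parms, rtol, atol) {
  if (identical(model$engine, "compiled")) {
    deSolve::lsoda(y = y0, times = times, func = "redox_derivs",
                   parms = parms, dllname = "redoxrbc",
                   initfunc = "redox_initmod", nout = 11,
                   outnames = flux_names(), rtol = rtol, atol = atol,
                   maxsteps = 50000)
  } else {
    dyn <- names(y0)
    fn <- function(t, y, p) {
      r <- rhs_at(stats::setNames(y, dyn), model, kin)
      list(r$deriv, r$flux)
    }
    deSolve::lsoda(y = y0, times = times, func = fn, parms = NULL,
                   rtol = rtol, atol = atol, maxsteps = 50000)
  }
}

#' Find the pre-perturbation steady state
#'
#' Integrates the network from the model-file initial concentrations over a
#' long horizon and then polishes the endpoint with damped Newton iterations
#' on the conservation-constrained system (the glutathione and nicotinamide
#' moiety totals of the initial state replace the two redundant balance
#' equations).
#'
#' @param model A `network_model`.
#' @param kin A [patient_kinetics()] row.
#' @param cfg A [protocol_config()].
#' @param state0 Optional named initial concentrations overriding the model
#'   file.
#' @return A list of class `steady_state`: `state` (full named vector),
#'   `residual_norm` (uM/s), `ratio_gsh_gssg`, `ratio_nadph_nadp`, `totals`.
#' @export
#' @examples
#' \donttest{
#' m <- default_redox_model()
#' ctrl <- dplyr::filter(reference_patients(), label == "Control")
#' find_steady_state(m, ctrl)$ratio_gsh_gssg
#' }
find_steady_state <- function(model, kin, cfg = protocol_config(),
                              state0 = NULL) {
  full0 <- initial_state(model, state0)
  dyn <- model$species$name[!model$species$clamped]
  y0 <- full0[dyn]
  parms <- if (identical(model$engine, "compiled")) {
    model_parms_vector(model, kin, state = full0)
  } else NULL
  totals0 <- conserved_totals(full0, model)

  sol <- integrate_model(y0, times = c(0, 10, 100, 1e3, 1e4, 1e5),
                         model, kin, parms, rtol = cfg$rtol, atol = cfg$atol)
  y <- pmax(sol[nrow(sol), dyn], 0)

  y <- newton_polish(y, model, kin, parms, totals0)
  r <- rhs_at(y, model, kin, parms)
  res <- max(abs(r$deriv))
  if (!is.finite(res) || res > cfg$ss_tol) {
    rlang::abort(sprintf("steady state did not converge (residual %.3e uM/s)", res),
                 class = "redoxrbc_convergence_error")
  }
  full <- full0
  full[dyn] <- y
  has_gsh <- all(c("gsh", "gssg") %in% names(full))
  has_nadp <- all(c("nadph", "nadp") %in% names(full))
  if (has_gsh && full[["gssg"]] <= 0) {
    rlang::abort("steady state has non-positive GSSG; ratio undefined",
                 class = "redoxrbc_convergence_error")
  }
  structure(list(state = full, residual_norm = res,
                 ratio_gsh_gssg = if (has_gsh) full[["gsh"]] / full[["gssg"]] else NA_real_,
                 ratio_nadph_nadp = if (has_nadp) full[["nadph"]] / full[["nadp"]] else NA_real_,
                 totals = conserved_totals(full, model),
                 fluxes = r$flux),
            class = "steady_state")
}

# Damped Newton on f(y) = (balance equations with the glutathione and
# nicotinamide rows replaced by moiety constraints). Forward-difference
# Jacobian; step halving keeps all concentrations non-negative.
newton_polish <- function(y, model, kin, parms, totals0, max_iter = 40) {
  dyn <- names(y)
  has_moieties <- all(c("glutathione", "nicotinamide") %in% names(totals0)) &&
    all(c("gsh", "gssg", "nadph", "nadp") %in% dyn)
  fval <- function(y) {
    d <- rhs_at(y, model, kin, parms)$deriv
    if (has_moieties) {
      d[["gsh"]] <- (y[["gsh"]] + 2 * y[["gssg"]] - totals0[["glutathione"]])
      d[["nadph"]] <- (y[["nadph"]] + y[["nadp"]] - totals0[["nicotinamide"]])
    }
    d
  }
  f <- fval(y)
  for (it in seq_len(max_iter)) {
    if (max(abs(f)) < 1e-13) break
    n <- length(y)
    J <- matrix(0, n, n)
    for (j in seq_len(n)) {
      h <- max(1e-8 * abs(y[j]), 1e-10)
      yp <- y; yp[j] <- yp[j] + h
      J[, j] <- (fval(yp) - f) / h
    }
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      y_new <- y + lambda * step
      if (all(y_new >= 0)) {
        f_new <- fval(y_new)
        if (all(is.finite(f_new)) &&
            (max(abs(f_new)) < max(abs(f)) || lambda < 1e-3)) break
      }
      lambda <- lambda / 2
      if (lambda < 1e-6) { y_new <- y; f_new <- f; break }
    }
    if (identical(y_new, y)) break
    y <- y_new; f <- f_new
  }
  y
}

#' Run the H2O2 perturbation experiment
#'
#' Applies the dose at `t = 0` to a steady state (per the configured dose
#' mode) and integrates over the observation window, recording every species
#' concentration, every reaction flux, and the derived GSH/GSSG and
#' NADPH/NADP ratio series.
#'
#' @param model A `network_model`.
#' @param kin A [patient_kinetics()] row.
#' @param ss A `steady_state` from [find_steady_state()]; computed on the fly
#'   when omitted.
#' @param cfg A [protocol_config()].
#' @return A tibble of class `redox_trajectory`: columns `time`, the species,
#'   `flux_*` for each reaction, `ratio_gsh_gssg`, `ratio_nadph_nadp`.
#'   Attributes: `initial_ratio`, `theta`, `window`, `dose`.
#' @export
run_perturbation <- function(model, kin, ss = NULL, cfg = protocol_config()) {
  if (is.null(ss)) ss <- find_steady_state(model, kin, cfg)
  stopifnot(inherits(ss, "steady_state"))
  full0 <- ss$state
  dyn <- model$species$name[!model$species$clamped]
  y0 <- full0[dyn]
  if (cfg$dose_mode == "bolus_internal") {
    y0[["h2o2"]] <- y0[["h2o2"]] + cfg$h2o2_dose
  } else {
    full0[["h2o2_ext"]] <- cfg$h2o2_dose
  }
  parms <- if (identical(model$engine, "compiled")) {
    model_parms_vector(model, kin, state = full0)
  } else {
    # clamp_external must reach the R evaluator too
    model$species$initial[model$species$name == "h2o2_ext"] <- full0[["h2o2_ext"]]
    NULL
  }
  times <- seq(0, cfg$window, by = cfg$record_step)
  sol <- integrate_model(y0, times, model, kin, parms,
                         rtol = cfg$rtol, atol = cfg$atol)
  if (nrow(sol) < length(times)) {
    rlang::abort(sprintf("integration failed at t = %.3f s", sol[nrow(sol), "time"]),
                 class = "redoxrbc_integration_error")
  }
  conc <- sol[, dyn, drop = FALSE]
  if (min(conc) < -1e-6) {
    rlang::abort(sprintf("negative concentration beyond tolerance (min %.3e uM)",
                         min(conc)),
                 class = "redoxrbc_integration_error")
  }
  conc[conc < 0] <- 0   # clip solver noise for reporting only
  out <- tibble::as_tibble(as.data.frame(conc))
  out$time <- sol[, "time"]
  clamped <- model$species$name[model$species$clamped]
  for (s in clamped) out[[s]] <- full0[[s]]
  fx <- sol[, flux_names(), drop = FALSE]
  colnames(fx) <- paste0("flux_", flux_names())
  out <- dplyr::bind_cols(out, tibble::as_tibble(as.data.frame(fx)))
  out$ratio_gsh_gssg <- out$gsh / out$gssg
  out$ratio_nadph_nadp <- out$nadph / out$nadp
  out <- dplyr::relocate(out, "time")
  structure(out,
            class = c("redox_trajectory", class(tibble::tibble())),
            initial_ratio = ss$ratio_gsh_gssg,
            theta = cfg$theta, window = cfg$window, dose = cfg$h2o2_dose,
            steady_fluxes = ss$fluxes)
}

#' Enzyme activity (flux) time courses
#'
#' Extracts flux-through-reaction series for the named enzymes from a
#' perturbation trajectory, in long (tidy) form.
#'
#' @param traj A `redox_trajectory`.
#' @param enzymes Character vector of reaction names (default the five
#'   antioxidant-relevant enzymes).
#' @return A tibble with columns `time`, `enzyme`, `flux`.
#' @export
enzyme_activity_series <- function(traj,
                                   enzymes = c("G6PD", "CAT", "GSHpx",
                                               "SOD", "GR")) {
  unknown <- setdiff(enzymes, flux_names())
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown enzyme(s): ", paste(unknown, collapse = ", "),
                        "; available: ", paste(flux_names(), collapse = ", ")),
                 class = "redoxrbc_argument_error")
  }
  cols <- paste0("flux_", enzymes)
  out <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(traj), "time", dplyr::all_of(cols)),
    cols = dplyr::all_of(cols), names_to = "enzyme", values_to = "flux",
    names_prefix = "flux_")
  out$enzyme <- factor(out$enzyme, levels = enzymes)
  out
}
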