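#' @importFrom rlang .data
NULL

dynamic_species_names <- function() {
  c("h2o2", "o2minus", "gsh", "gssg", "nadph", "nadp", "g6p", "gl6p")
}

flux_names <- function() {
  c("h2o2_influx", "o2minus_generation", "SOD", "CAT", "GSHpx", "GR",
    "G6PD", "ppp_second_step", "g6p_supply", "g6p_drain", "nadph_drain")
}

#' Read a kinetic network model from a YAML definition file
#'
#' The model definition lists species (name, initial concentration in uM,
#' clamped flag), reactions (name, rate-law id, stoichiometry, parameters)
#' and conserved moieties (named linear combinations of species). Available
#' rate laws: `constant_flux` (v), `mass_action` (k times the product of the
#' listed substrates), `saturating_mass_action` (mass action times a
#' Michaelis factor in the `saturating` species), `michaelis_2s`
#' (two-substrate Michaelis form), `diffusion` (k * (source - target)), and
#' `g6pd_eq1` (the patient-specific G6PD law of [g6pd_rate()]).
#'
#' @param path Path to a YAML model definition.
#' @return A validated `network_model` object (a list with elements
#'   `name`, `species`, `reactions`, `moieties`, `engine`).
#' @seealso [default_redox_model()] for the packaged calibrated network.
#' @export
read_model <- function(path) {
  raw <- yaml::read_yaml(path)
  species <- purrr::map_dfr(raw$species, function(s) {
    tibble::tibble(name = s$name, initial = as.numeric(s$initial),
                   clamped = isTRUE(s$clamped))
  })
  reactions <- purrr::map(raw$reactions, function(r) {
    list(name = r$name, law = r$law,
         stoich = unlist(r$stoich),
         substrates = as.character(r$substrates %||% character()),
         params = r$params %||% list())
  })
  moieties <- purrr::map(raw$moieties, unlist)
  model <- structure(
    list(name = raw$name %||% "model", species = species,
         reactions = reactions, moieties = moieties),
    class = "network_model")
  validate_model(model)
  model$engine <- if (is_default_network(model)) "compiled" else "r"
  model
}

#' The calibrated default redox network
#'
#' Loads the reduced erythrocyte redox network shipped with the package:
#' H2O2 diffusion and basal superoxide generation, SOD, catalase, glutathione
#' peroxidase, glutathione reductase, the patient-specific G6PD reaction, a
#' lumped second oxidative-PPP step, a constant G6P supply with first-order
#' glycolytic drain, and a basal NADPH drain. ATP, 2,3-BPG, glucose and
#' extracellular H2O2 are clamped. Rate constants were calibrated so that the
#' healthy control reaches a pre-perturbation steady state with GSH/GSSG
#' close to 700 (see the methods vignette).
#'
#' @return A `network_model` object whose right-hand side is evaluated in
#'   compiled code during integration.
#' @export
#' @examples
#' m <- default_redox_model()
#' m$name
default_redox_model <- function() {
  read_model(system.file("extdata", "redox_network.yaml",
                         package = "redoxrbc", mustWork = TRUE))
}

#' Validate a network model
#'
#' Checks that every reaction references known species with finite
#' stoichiometry, that clamped species never change, and that each declared
#' conserved moiety lies in the left null space of the stoichiometry matrix
#' restricted to non-clamped species.
#'
#' @param model A `network_model`.
#' @return The model, invisibly; aborts with class
#'   `redoxrbc_configuration_error` on an inconsistent definition.
#' @export
validate_model <- function(model) {
  sp <- model$species
  stopifnot(is.data.frame(sp), all(c("name", "initial", "clamped") %in% names(sp)))
  if (anyDuplicated(sp$name)) {
    rlang::abort("duplicated species names", class = "redoxrbc_configuration_error")
  }
  for (r in model$reactions) {
    unknown <- setdiff(c(names(r$stoich), r$substrates), sp$name)
    if (length(unknown) > 0) {
      rlang::abort(paste0("reaction '", r$name, "' references unknown species: ",
                          paste(unknown, collapse = ", ")),
                   class = "redoxrbc_configuration_error")
    }
    if (any(!is.finite(r$stoich))) {
      rlang::abort(paste0("reaction '", r$name, "' has non-finite stoichiometry"),
                   class = "redoxrbc_configuration_error")
    }
    if (any(sp$clamped[match(names(r$stoich), sp$name)])) {
      rlang::abort(paste0("reaction '", r$name, "' changes a clamped species"),
                   class = "redoxrbc_configuration_error")
    }
  }
  S <- stoichiometry_matrix(model)
  for (m in names(model$moieties)) {
    w <- model$moieties[[m]]
    unknown <- setdiff(names(w), sp$name)
    if (length(unknown) > 0) {
      rlang::abort(paste0("moiety '", m, "' references unknown species: ",
                          paste(unknown, collapse = ", ")),
                   class = "redoxrbc_configuration_error")
    }
    wv <- stats::setNames(numeric(nrow(S)), rownames(S))
    wv[names(w)] <- w
    if (max(abs(drop(wv %*% S))) > 1e-12) {
      rlang::abort(paste0("moiety '", m, "' is not conserved by the stoichiometry"),
                   class = "redoxrbc_configuration_error")
    }
  }
  invisible(model)
}

#' Stoichiometry matrix of the non-clamped species
#'
#' @param model A `network_model`.
#' @return A species-by-reaction matrix of stoichiometric coefficients,
#'   restricted to non-clamped species.
#' @export
stoichiometry_matrix <- function(model) {
  dyn <- model$species$name[!model$species$clamped]
  S <- matrix(0, nrow = length(dyn), ncol = length(model$reactions),
              dimnames = list(dyn, purrr::map_chr(model$reactions, "name")))
  for (j in seq_along(model$reactions)) {
    st <- model$reactions[[j]]$stoich
    keep <- intersect(names(st), dyn)
    S[keep, j] <- st[keep]
  }
  S
}

#' Initial model state
#'
#' @param model A `network_model`.
#' @param overrides Optional named numeric vector of concentrations (uM) to
#'   replace model-file initial values.
#' @return Named numeric vector over all species (clamped included).
#' @export
initial_state <- function(model, overrides = NULL) {
  state <- stats::setNames(model$species$initial, model$species$name)
  if (!is.null(overrides)) {
    unknown <- setdiff(names(overrides), names(state))
    if (length(unknown) > 0) {
      rlang::abort(paste0("unknown species in overrides: ",
                          paste(unknown, collapse = ", ")),
                   class = "redoxrbc_configuration_error")
    }
    state[names(overrides)] <- overrides
  }
  if (any(state < 0)) {
    rlang::abort("concentrations must be non-negative",
                 class = "redoxrbc_parameter_error")
  }
  state
}

#' G6PD reaction velocity
#'
#' Product-inhibited ordered rate law of the G6PD reaction
#' (G6P + NADP -> GL6P + NADPH):
#' \deqn{v = \frac{V_{max}[NADP][G6P]}{K_{mNADP} K_{mG6P}\left(1 +
#'   \frac{[NADP]}{K_{mNADP}}\left(1 + \frac{[G6P]}{K_{mG6P}}\right) +
#'   \frac{[NADPH]}{K_{iNADPH}} + \frac{[ATP]}{K_{iATP}} +
#'   \frac{[2,3BPG]}{K_{i2,3BPG}}\right)}}
#' The velocity is zero exactly when `[NADP][G6P] = 0`, is strictly below
#' `vmax` everywhere, increases in each substrate and decreases in each
#' inhibitor.
#'
#' @param state Named numeric vector with at least `g6p`, `nadp`, `nadph`,
#'   `atp`, `bpg23` (uM, all >= 0).
#' @param kin A [patient_kinetics()] row (or any list with the six kinetic
#'   parameters).
#' @return Reaction velocity (same units as `vmax`).
#' @export
#' @examples
#' ctrl <- patient_kinetics(64, 67, 3.7, 3.1, 749, 2289, label = "Control")
#' g6pd_rate(c(g6p = 40, nadp = 2, nadph = 60, atp = 1600, bpg23 = 5000), ctrl)
g6pd_rate <- function(state, kin) {
  p <- purrr::map_dbl(kinetic_parameter_names(), ~ as.numeric(kin[[.x]]))
  names(p) <- kinetic_parameter_names()
  if (any(!is.finite(p)) || any(p <= 0)) {
    rlang::abort("kinetic constants must be finite and strictly positive",
                 class = "redoxrbc_parameter_error")
  }
  need <- c("g6p", "nadp", "nadph", "atp", "bpg23")
  if (!all(need %in% names(state))) {
    rlang::abort(paste0("state must name: ", paste(need, collapse = ", ")),
                 class = "redoxrbc_parameter_error")
  }
  if (any(state[need] < 0)) {
    rlang::abort("concentrations must be non-negative",
                 class = "redoxrbc_parameter_error")
  }
  g6p <- state[["g6p"]]; nadp <- state[["nadp"]]
  den <- p[["km_nadp"]] * p[["km_g6p"]] *
    (1 + (nadp / p[["km_nadp"]]) * (1 + g6p / p[["km_g6p"]]) +
       state[["nadph"]] / p[["ki_nadph"]] +
       state[["atp"]] / p[["ki_atp"]] +
       state[["bpg23"]] / p[["ki_23bpg"]])
  p[["vmax"]] * nadp * g6p / den
}

# Evaluate one reaction's rate law at a full (clamped-included) state.
reaction_rate <- function(r, state, kin) {
  pr <- r$params
  v <- switch(
    r$law,
    constant_flux = pr$v,
    mass_action = pr$k * prod(state[r$substrates]),
    saturating_mass_action = {
      s <- state[[pr$saturating]]
      pr$k * prod(state[r$substrates]) * s / (pr$km + s)
    },
    michaelis_2s = {
      a <- state[[r$substrates[1]]]; b <- state[[r$substrates[2]]]
      pr$vmax * a / (pr$km_a + a) * b / (pr$km_b + b)
    },
    diffusion = pr$k * (state[[pr$source]] - state[[pr$target]]),
    g6pd_eq1 = {
      if (is.null(kin)) {
        rlang::abort("model contains a G6PD reaction but no patient kinetics were supplied",
                     class = "redoxrbc_configuration_error")
      }
      g6pd_rate(state, kin)
    },
    rlang::abort(paste0("unknown rate law '", r$law, "' in reaction '", r$name, "'"),
                 class = "redoxrbc_configuration_error")
  )
  as.numeric(v)
}

#' Reaction fluxes at a state
#'
#' Evaluates every reaction's rate law at the given state. For the default
#' network this yields the named velocities of the H2O2 influx, superoxide
#' generation, SOD, CAT, GSHpx, GR, G6PD, second PPP step, G6P supply/drain
#' and basal NADPH drain.
#'
#' @param state Named numeric state vector over all species (uM).
#' @param model A `network_model`.
#' @param kin Patient kinetics; required when the model contains a
#'   `g6pd_eq1` reaction.
#' @return Named numeric vector of reaction velocities.
#' @export
reaction_fluxes <- function(state, model, kin = NULL) {
  v <- purrr::map_dbl(model$reactions, reaction_rate, state = state, kin = kin)
  stats::setNames(v, purrr::map_chr(model$reactions, "name"))
}

#' Antioxidant and housekeeping reaction velocities
#'
#' Convenience wrapper around [reaction_fluxes()] returning the non-G6PD
#' velocities of the default network.
#'
#' @inheritParams reaction_fluxes
#' @return Named numeric vector of the non-G6PD reaction velocities.
#' @export
antioxidant_rates <- function(state, model, kin = NULL) {
  keep <- purrr::keep(model$reactions, ~ .x$law != "g6pd_eq1")
  v <- purrr::map_dbl(keep, reaction_rate, state = state, kin = kin)
  stats::setNames(v, purrr::map_chr(keep, "name"))
}

#' ODE right-hand side
#'
#' Time derivative of every species: the stoichiometry matrix applied to the
#' reaction-rate vector. Clamped species have derivative exactly zero.
#'
#' @param state Named numeric state vector over all species (uM).
#' @param model A `network_model`.
#' @param kin Patient kinetics (required if the model has a G6PD reaction).
#' @return Named numeric vector of derivatives (uM/s) over all species, with
#'   the flux vector attached as attribute `fluxes`.
#' @export
ode_rhs <- function(state, model, kin = NULL) {
  v <- reaction_fluxes(state, model, kin)
  if (any(!is.finite(v))) {
    bad <- names(v)[!is.finite(v)][1]
    rlang::abort(paste0("non-finite rate in reaction '", bad, "'"),
                 class = "redoxrbc_integration_error")
  }
  S <- stoichiometry_matrix(model)
  d <- stats::setNames(numeric(length(state)), names(state))
  d[rownames(S)] <- drop(S %*% v)
  attr(d, "fluxes") <- v
  d
}

#' Conserved moiety totals
#'
#' @param state Named numeric state vector.
#' @param model A `network_model` defining moieties (for the default network,
#'   glutathione `GSH + 2 GSSG` and nicotinamide `NADP + NADPH`).
#' @return Named numeric vector of totals (uM).
#' @export
#' @examples
#' m <- default_redox_model()
#' conserved_totals(initial_state(m), m)
conserved_totals <- function(state, model) {
  purrr::map_dbl(model$moieties, function(w) {
    unknown <- setdiff(names(w), names(state))
    if (length(unknown) > 0) {
      rlang::abort(paste0("moiety references unknown species: ",
                          paste(unknown, collapse = ", ")),
                   class = "redoxrbc_configuration_error")
    }
    sum(w * state[names(w)])
  })
}

# ---- compiled-engine plumbing -------------------------------------------

# TRUE when the model matches the network shape hard-wired in src/redox.c:
# same species (and order), same reactions (names, laws, stoichiometries).
is_default_network <- function(model) {
  sp_ok <- identical(model$species$name,
                     c(dynamic_species_names(),
                       "h2o2_ext", "atp", "bpg23", "glc")) &&
    identical(model$species$clamped, c(rep(FALSE, 8), rep(TRUE, 4)))
  if (!sp_ok) return(FALSE)
  if (length(model$reactions) != 11L) return(FALSE)
  ref <- default_network_signature()
  for (i in seq_len(11L)) {
    r <- model$reactions[[i]]
    q <- ref[[i]]
    if (!identical(r$name, q$name) || !identical(r$law, q$law)) return(FALSE)
    if (!setequal(names(r$stoich), names(q$stoich))) return(FALSE)
    if (any(as.numeric(r$stoich[names(q$stoich)]) != as.numeric(q$stoich))) return(FALSE)
  }
  TRUE
}

default_network_signature <- function() {
  list(
    list(name = "h2o2_influx", law = "diffusion", stoich = c(h2o2 = 1)),
    list(name = "o2minus_generation", law = "constant_flux", stoich = c(o2minus = 1)),
    list(name = "SOD", law = "mass_action", stoich = c(o2minus = -2, h2o2 = 1)),
    list(name = "CAT", law = "mass_action", stoich = c(h2o2 = -2)),
    list(name = "GSHpx", law = "michaelis_2s",
         stoich = c(h2o2 = -1, gsh = -2, gssg = 1)),
    list(name = "GR", law = "michaelis_2s",
         stoich = c(gssg = -1, nadph = -1, gsh = 2, nadp = 1)),
    list(name = "G6PD", law = "g6pd_eq1",
         stoich = c(g6p = -1, nadp = -1, gl6p = 1, nadph = 1)),
    list(name = "ppp_second_step", law = "saturating_mass_action",
         stoich = c(gl6p = -1, nadp = -1, nadph = 1)),
    list(name = "g6p_supply", law = "constant_flux", stoich = c(g6p = 1)),
    list(name = "g6p_drain", law = "mass_action", stoich = c(g6p = -1)),
    list(name = "nadph_drain", law = "mass_action", stoich = c(nadph = -1, nadp = 1))
  )
}

# 24-slot parameter vector consumed by the compiled right-hand side.
model_parms_vector <- function(model, kin, state = initial_state(model)) {
  rp <- function(reaction, param) {
    r <- purrr::detect(model$reactions, ~ .x$name == reaction)
    as.numeric(r$params[[param]])
  }
  kv <- purrr::map_dbl(kinetic_parameter_names(), ~ as.numeric(kin[[.x]]))
  c(state[["h2o2_ext"]], state[["atp"]], state[["bpg23"]],
    rp("h2o2_influx", "k"), rp("o2minus_generation", "v"),
    rp("SOD", "k"), rp("CAT", "k"),
    rp("GSHpx", "vmax"), rp("GSHpx", "km_a"), rp("GSHpx", "km_b"),
    rp("GR", "vmax"), rp("GR", "km_a"), rp("GR", "km_b"),
    rp("ppp_second_step", "k"), rp("ppp_second_step", "km"),
    rp("g6p_supply", "v"), rp("g6p_drain", "k"), rp("nadph_drain", "k"),
    kv)
}

# Fast rhs evaluation at a dynamic-species state (compiled when possible).
rhs_at <- function(y_dyn, model, kin, parms = NULL) {
  if (identical(model$engine, "compiled")) {
    if (is.null(parms)) parms <- model_parms_vector(model, kin)
    out <- .Call(C_redox_rhs, as.numeric(y_dyn), as.numeric(parms))
    list(deriv = stats::setNames(out$deriv, dynamic_species_names()),
         flux = stats::setNames(out$flux, flux_names()))
  } else {
    full <- stats::setNames(model$species$initial, model$species$name)
    full[names(y_dyn)] <- y_dyn
    d <- ode_rhs(full, model, kin)
    dyn <- model$species$name[!model$species$clamped]
    list(deriv = d[dyn], flux = attr(d, "fluxes"))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
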