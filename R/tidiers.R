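#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a steady state into a species table
#'
#' @param x A `steady_state`.
#' @param ... Unused.
#' @return A tibble with one row per species: `species`, `concentration`
#'   (uM), `clamped`.
#' @method tidy steady_state
#' @export
tidy.steady_state <- function(x, ...) {
  tibble::tibble(species = names(x$state),
                 concentration = unname(x$state),
                 clamped = names(x$state) %in%
                   c("h2o2_ext", "atp", "bpg23", "glc"))
}

#' One-row summary of a steady state
#'
#' @param x A `steady_state`.
#' @param ... Unused.
#' @return A one-row tibble: the two redox ratios, the conserved totals and
#'   the residual norm.
#' @method glance steady_state
#' @export
glance.steady_state <- function(x, ...) {
  tibble::tibble(ratio_gsh_gssg = x$ratio_gsh_gssg,
                 ratio_nadph_nadp = x$ratio_nadph_nadp,
                 glutathione_total = x$totals[["glutathione"]],
                 nicotinamide_total = x$totals[["nicotinamide"]],
                 residual_norm = x$residual_norm)
}

#' Tidy a subject simulation into its indicator row
#'
#' @param x A `redox_sim` from [simulate_subject()].
#' @param ... Unused.
#' @return The one-row indicator tibble of [compute_indicators()].
#' @method tidy redox_sim
#' @export
tidy.redox_sim <- function(x, ...) x$indicators

#' One-row summary of a subject simulation
#'
#' @param x A `redox_sim`.
#' @param ... Unused.
#' @return A one-row tibble joining the kinetic parameters with the
#'   indicators and the steady-state residual.
#' @method glance redox_sim
#' @export
glance.redox_sim <- function(x, ...) {
  dplyr::bind_cols(x$kinetics,
                   dplyr::select(x$indicators, -"label"),
                   tibble::tibble(residual_norm = x$steady_state$residual_norm))
}

#' @export
print.redox_sim <- function(x, ...) {
  cat("<redox_sim> subject:", x$kinetics$label, "\n")
  cat(sprintf("  initial GSH/GSSG %.2f | min %.2f | amount of change %.4f\n",
              x$indicators$initial_ratio, x$indicators$min_ratio,
              x$indicators$amount_of_change))
  if (x$indicators$recovered) {
    cat(sprintf("  recovery time %.2f s (theta = %.2f)\n",
                x$indicators$recovery_time, x$indicators$theta))
  } else {
    cat(sprintf("  NOT RECOVERED within window (theta = %.2f)\n",
                x$indicators$theta))
  }
  invisible(x)
}

#' @export
print.steady_state <- function(x, ...) {
  cat("<steady_state>\n")
  cat(sprintf("  GSH/GSSG %.2f | NADPH/NADP %.3f | residual %.2e uM/s\n",
              x$ratio_gsh_gssg, x$ratio_nadph_nadp, x$residual_norm))
  invisible(x)
}
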