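#' Initial (steady-state) GSH/GSSG ratio
#'
#' @param ss A `steady_state` (or any list with a `state` element naming
#'   `gsh` and `gssg`).
#' @return The dimensionless ratio `[GSH]/[GSSG]` at steady state.
#' @export
initial_ratio <- function(ss) {
  st <- if (inherits(ss, "steady_state")) ss$state else ss$state %||% ss
  gsh <- st[["gsh"]]; gssg <- st[["gssg"]]
  if (gssg == 0) {
    rlang::abort("GSSG is zero: GSH/GSSG undefined",
                 class = "redoxrbc_ratio_error")
  }
  gsh / gssg
}

#' Amount of change of GSH/GSSG
#'
#' Fractional dip of the redox ratio during the observation period:
#' `(initial - minimum) / initial`, in `[0, 1]`. The indicator is invariant
#' to rescaling GSH and GSSG by a common factor.
#'
#' @param initial Pre-perturbation ratio (> 0).
#' @param minimum Minimum ratio during the observation period
#'   (`0 <= minimum <= initial`).
#' @return Dimensionless fraction in `[0, 1]`.
#' @export
#' @examples
#' amount_of_change(700.38, 560.304)
amount_of_change <- function(initial, minimum) {
  if (!is.finite(initial) || initial <= 0) {
    rlang::abort("`initial` must be positive", class = "redoxrbc_argument_error")
  }
  if (!is.finite(minimum) || minimum < 0 || minimum > initial) {
    rlang::abort("`minimum` must satisfy 0 <= minimum <= initial (the ratio dipped, not rose)",
                 class = "redoxrbc_argument_error")
  }
  (initial - minimum) / initial
}

# Ratio channel of a trajectory: prefers the GSH/GSSG series.
trajectory_ratio <- function(traj) {
  col <- intersect(c("ratio_gsh_gssg", "ratio"), names(traj))[1]
  if (is.na(col)) {
    rlang::abort("trajectory carries no ratio channel",
                 class = "redoxrbc_argument_error")
  }
  list(time = traj$time, ratio = traj[[col]])
}

# Minimum of the ratio series with parabolic refinement around the discrete
# minimum (vertex of the quadratic through the three bracketing samples).
ratio_minimum <- function(traj) {
  ch <- trajectory_ratio(traj)
  i <- which.min(ch$ratio)
  r_min <- ch$ratio[i]
  t_min <- ch$time[i]
  if (i > 1 && i < length(ch$ratio)) {
    t3 <- ch$time[(i - 1):(i + 1)]; r3 <- ch$ratio[(i - 1):(i + 1)]
    fit <- try(stats::lm.fit(cbind(1, t3, t3^2), r3)$coefficients, silent = TRUE)
    if (!inherits(fit, "try-error") && is.finite(fit[3]) && fit[3] > 0) {
      tv <- -fit[2] / (2 * fit[3])
      if (tv >= t3[1] && tv <= t3[3]) {
        rv <- fit[1] + fit[2] * tv + fit[3] * tv^2
        if (is.finite(rv) && rv <= r_min) { t_min <- tv; r_min <- rv }
      }
    }
  }
  list(time = t_min, ratio = r_min)
}

#' Recovery time of the GSH/GSSG ratio
#'
#' The time required for the ratio to re-attain a threshold fraction `theta`
#' of its pre-perturbation value after the post-perturbation minimum: the
#' smallest `t` past the minimum with `ratio(t) >= theta * initial`, located
#' by linear interpolation between recorded samples. A trajectory that never
#' drops below the threshold has recovery time 0; one that never re-attains
#' it within the window is not recovered (`NA` with attribute).
#'
#' @param traj A trajectory tibble (a `redox_trajectory` or the output of
#'   [synth_ratio_trajectory()]).
#' @param theta Recovery threshold in (0, 1); defaults to the trajectory's
#'   recorded protocol value, else 0.99.
#' @param window Observation window (s); defaults to the trajectory's.
#' @param initial Pre-perturbation ratio; defaults to the trajectory's
#'   `initial_ratio` attribute.
#' @return Recovery time in seconds, or `NA_real_` when not recovered within
#'   the window.
#' @export
#' @examples
#' tr <- synth_ratio_trajectory(700, a = 0.2, tau = 60)
#' recovery_time(tr, theta = 0.99)  # ~ 60 * log(20)
recovery_time <- function(traj, theta = NULL, window = NULL, initial = NULL) {
  theta <- theta %||% attr(traj, "theta") %||% 0.99
  initial <- initial %||% attr(traj, "initial_ratio")
  window <- window %||% attr(traj, "window") %||% max(traj$time)
  if (is.null(initial)) {
    rlang::abort("pre-perturbation ratio unknown: supply `initial`",
                 class = "redoxrbc_argument_error")
  }
  if (theta <= 0 || theta >= 1) {
    rlang::abort("`theta` must lie in (0, 1)", class = "redoxrbc_argument_error")
  }
  ch <- trajectory_ratio(traj)
  if (max(ch$time) < window - 1e-9) {
    rlang::abort("trajectory does not cover the observation window",
                 class = "redoxrbc_argument_error")
  }
  keep <- ch$time <= window + 1e-9
  tt <- ch$time[keep]; rr <- ch$ratio[keep]
  thr <- theta * initial
  if (min(rr) >= thr) return(0)
  i_min <- which.min(rr)
  above <- which(rr >= thr & seq_along(rr) > i_min)
  if (length(above) == 0) {
    return(structure(NA_real_, not_recovered = TRUE))
  }
  j <- above[1]
  # linear interpolation between sample j-1 (below) and j (at/above)
  t0 <- tt[j - 1]; t1 <- tt[j]; r0 <- rr[j - 1]; r1 <- rr[j]
  if (r1 == r0) t1 else t0 + (thr - r0) / (r1 - r0) * (t1 - t0)
}

#' Indicators of redox imbalance for one subject
#'
#' Computes the three indicators from a perturbation trajectory: the initial
#' (pre-perturbation) GSH/GSSG, the recovery time, and the amount of change,
#' plus the refined ratio minimum.
#'
#' @param traj A `redox_trajectory` (or a ratio trajectory with an
#'   `initial_ratio` attribute).
#' @param theta,window See [recovery_time()].
#' @param label Subject identifier carried into the output.
#' @return A one-row tibble: `label`, `initial_ratio`, `min_ratio`,
#'   `amount_of_change`, `recovery_time` (`NA` if not recovered),
#'   `recovered`, `theta`.
#' @export
compute_indicators <- function(traj, theta = NULL, window = NULL,
                               label = "subject") {
  theta <- theta %||% attr(traj, "theta") %||% 0.99
  window <- window %||% attr(traj, "window") %||% max(traj$time)
  r0 <- attr(traj, "initial_ratio")
  if (is.null(r0)) {
    rlang::abort("trajectory lacks an `initial_ratio` attribute",
                 class = "redoxrbc_argument_error")
  }
  mn <- ratio_minimum(traj)
  rt <- recovery_time(traj, theta = theta, window = window, initial = r0)
  tibble::tibble(
    label = label,
    initial_ratio = r0,
    min_ratio = min(mn$ratio, r0),
    amount_of_change = amount_of_change(r0, min(mn$ratio, r0)),
    recovery_time = as.numeric(rt),
    recovered = !isTRUE(attr(rt, "not_recovered")),
    theta = theta
  )
}
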