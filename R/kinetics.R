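#' Construct a patient G6PD kinetic parameter set
#'
#' A patient — real or virtual — is identified by the six kinetic parameters
#' of their G6PD variant: the maximal velocity and the Michaelis constants for
#' G6P and NADP, plus the inhibition constants for NADPH, ATP and
#' 2,3-bisphosphoglycerate that enter the product-inhibited G6PD rate law
#' (see [g6pd_rate()]).
#'
#' @param vmax Maximal G6PD velocity (model velocity units, treated as uM/s).
#' @param km_g6p,km_nadp Michaelis constants for G6P and NADP (uM).
#' @param ki_nadph,ki_atp,ki_23bpg Inhibition constants for NADPH, ATP and
#'   2,3-BPG (uM).
#' @param label Subject identifier (non-empty string).
#' @return A one-row tibble of class `patient_kinetics` with columns `label`,
#'   `vmax`, `km_g6p`, `km_nadp`, `ki_nadph`, `ki_atp`, `ki_23bpg`.
#' @export
#' @examples
#' patient_kinetics(64, 67, 3.7, 3.1, 749, 2289, label = "Control")
patient_kinetics <- function(vmax, km_g6p, km_nadp, ki_nadph, ki_atp,
                             ki_23bpg, label = "subject") {
  vals <- c(vmax = vmax, km_g6p = km_g6p, km_nadp = km_nadp,
            ki_nadph = ki_nadph, ki_atp = ki_atp, ki_23bpg = ki_23bpg)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    rlang::abort("all six G6PD kinetic parameters must be finite and strictly positive",
                 class = "redoxrbc_parameter_error")
  }
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    rlang::abort("`label` must be a non-empty string",
                 class = "redoxrbc_parameter_error")
  }
  out <- tibble::tibble(label = label, vmax = vmax, km_g6p = km_g6p,
                        km_nadp = km_nadp, ki_nadph = ki_nadph,
                        ki_atp = ki_atp, ki_23bpg = ki_23bpg)
  class(out) <- c("patient_kinetics", class(out))
  out
}

kinetic_parameter_names <- function() {
  c("vmax", "km_g6p", "km_nadp", "ki_nadph", "ki_atp", "ki_23bpg")
}

#' Validate a cohort data frame of patient kinetics
#'
#' @param patients A data frame with a `label` column and the six kinetic
#'   parameter columns (see [patient_kinetics()]).
#' @return The input as a tibble, invisibly checked.
#' @keywords internal
as_patient_table <- function(patients) {
  need <- c("label", kinetic_parameter_names())
  missing <- setdiff(need, names(patients))
  if (length(missing) > 0) {
    rlang::abort(paste0("patient table is missing column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "redoxrbc_parameter_error")
  }
  pars <- as.matrix(patients[kinetic_parameter_names()])
  if (any(!is.finite(pars)) || any(pars <= 0)) {
    rlang::abort("all kinetic parameters must be finite and strictly positive",
                 class = "redoxrbc_parameter_error")
  }
  tibble::as_tibble(patients)
}

#' Reference G6PD-deficient subjects
#'
#' The eleven reference subjects used throughout: ten G6PD-deficient patients
#' characterised biochemically in the clinical literature plus one healthy
#' control, each given by the six kinetic parameters of their G6PD variant.
#'
#' @return A tibble with 11 rows (`Patient 1` .. `Patient 10`, `Control`) and
#'   the kinetic parameter columns of [patient_kinetics()].
#' @export
#' @examples
#' reference_patients()
reference_patients <- function() {
  tibble::tribble(
    ~label,       ~vmax, ~km_g6p, ~km_nadp, ~ki_nadph, ~ki_atp, ~ki_23bpg,
    "Patient 1",    1.1,     152,      3.8,      0.62,     180,       520,
    "Patient 2",   36.7,     140,      115,      33.6,    4687,      8515,
    "Patient 3",    0.8,       7,      4.1,       8.9,     952,      1071,
    "Patient 4",    0.8,      43,      155,        56,   11000,     35000,
    "Patient 5",   37.1,      57,     30.5,       3.7,    5016,      5507,
    "Patient 6",   14.5,      66,      3.5,       1.1,     212,       532,
    "Patient 7",    8.9,      80,      3.6,         1,     125,       586,
    "Patient 8",    0.8,      68,      1.4,       0.9,     500,      2000,
    "Patient 9",    0.6,      40,      4.8,       6.9,     314,      3784,
    "Patient 10",  18.9,      79,        3,       4.1,     407,      2200,
    "Control",       64,      67,      3.7,       3.1,     749,      2289
  )
}

#' Sampling ranges for virtual patients
#'
#' Closed intervals from which the six G6PD kinetic parameters of a virtual
#' patient are drawn. The defaults span the minimum-to-maximum values observed
#' across the deficient reference patients.
#'
#' @return A tibble with columns `parameter`, `lower`, `upper` (uM except
#'   `vmax`, which is in model velocity units).
#' @export
sampling_ranges <- function() {
  tibble::tribble(
    ~parameter, ~lower, ~upper,
    "vmax",          1,     64,
    "km_g6p",        7,    152,
    "km_nadp",       3,    155,
    "ki_nadph",      1,     56,
    "ki_atp",      125,  11000,
    "ki_23bpg",    520,  35000
  )
}

#' Draw a cohort of virtual patients
#'
#' Each kinetic parameter is drawn independently and uniformly from its
#' sampling interval (optionally log-uniformly, which spreads draws more
#' evenly over the wide inhibition-constant ranges). The random stream is
#' isolated: the caller's RNG state is untouched, and a given seed always
#' yields the same cohort.
#'
#' @param n Number of virtual patients (>= 0).
#' @param ranges A tibble as returned by [sampling_ranges()].
#' @param seed Integer seed for the cohort draw.
#' @param log_uniform Draw log-uniformly instead of uniformly (default FALSE).
#' @return A tibble of `n` patients with labels `V0001`, `V0002`, ...
#' @export
#' @examples
#' sample_virtual_patients(3, seed = 1)
sample_virtual_patients <- function(n, ranges = sampling_ranges(), seed,
                                    log_uniform = FALSE) {
  if (length(n) != 1L || is.na(n) || n < 0 || n != floor(n)) {
    rlang::abort("`n` must be a single non-negative integer",
                 class = "redoxrbc_argument_error")
  }
  stopifnot(all(c("parameter", "lower", "upper") %in% names(ranges)))
  if (any(ranges$lower >= ranges$upper) || any(ranges$lower <= 0)) {
    rlang::abort("sampling ranges must satisfy 0 < lower < upper",
                 class = "redoxrbc_parameter_error")
  }
  n <- as.integer(n)
  draws <- withr::with_seed(seed, {
    purrr::map(seq_len(nrow(ranges)), function(i) {
      lo <- ranges$lower[i]; hi <- ranges$upper[i]
      if (log_uniform) exp(stats::runif(n, log(lo), log(hi)))
      else stats::runif(n, lo, hi)
    })
  })
  names(draws) <- ranges$parameter
  out <- tibble::as_tibble(c(list(label = sprintf("V%04d", seq_len(n))), draws))
  # hard bound guarantee, not merely statistical
  for (i in seq_len(nrow(ranges))) {
    p <- ranges$parameter[i]
    out[[p]] <- pmin(pmax(out[[p]], ranges$lower[i]), ranges$upper[i])
  }
  out
}

#' Synthetic exponential-recovery ratio trajectory
#'
#' Generates a GSH/GSSG-ratio trajectory of known closed form,
#' `r(t) = r0 * (1 - a * exp(-t / tau))`: the ratio starts at its minimum
#' `r0 * (1 - a)` at `t = 0` and recovers monotonically toward the
#' pre-perturbation value `r0`. Used as ground truth when testing the
#' recovery-time indicator, whose threshold-crossing time has the closed form
#' `tau * log(a / (1 - theta))`.
#'
#' @param r0 Pre-perturbation ratio (> 0).
#' @param a Dip fraction in \[0, 1\] (0 gives a flat trajectory).
#' @param tau Recovery time constant (s).
#' @param step Sampling step (s).
#' @param window Window length (s).
#' @return A tibble with columns `time` and `ratio`, carrying the
#'   pre-perturbation ratio as attribute `initial_ratio`.
#' @export
#' @examples
#' synth_ratio_trajectory(700, a = 0.2, tau = 60)
synth_ratio_trajectory <- function(r0, a, tau, step = 1, window = 1800) {
  if (r0 <= 0 || a < 0 || a > 1 || tau <= 0 || step <= 0 || window <= 0) {
    rlang::abort("require r0 > 0, 0 <= a <= 1, tau > 0, step > 0, window > 0",
                 class = "redoxrbc_parameter_error")
  }
  tt <- seq(0, window, by = step)
  out <- tibble::tibble(time = tt, ratio = r0 * (1 - a * exp(-tt / tau)))
  attr(out, "initial_ratio") <- r0
  out
}
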