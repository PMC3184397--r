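#' Run the perturbation protocol for one subject
#'
#' Convenience wrapper: steady state, perturbation, indicators.
#'
#' @param kin A [patient_kinetics()] row (or a one-row patient table).
#' @param model A `network_model` (default the calibrated network).
#' @param cfg A [protocol_config()].
#' @return A list of class `redox_sim` with elements `kinetics`,
#'   `steady_state`, `trajectory`, `indicators`.
#' @export
#' @examples
#' \donttest{
#' ctrl <- dplyr::filter(reference_patients(), label == "Control")
#' sim <- simulate_subject(ctrl)
#' sim$indicators
#' }
simulate_subject <- function(kin, model = default_redox_model(),
                             cfg = protocol_config()) {
  kin <- as_patient_table(kin)
  stopifnot(nrow(kin) == 1L)
  ss <- find_steady_state(model, kin, cfg)
  traj <- run_perturbation(model, kin, ss, cfg)
  ind <- compute_indicators(traj, label = kin$label)
  structure(list(kinetics = kin, steady_state = ss, trajectory = traj,
                 indicators = ind),
            class = "redox_sim")
}

#' Evaluate a cohort of patients through the full protocol
#'
#' Runs steady state + perturbation + indicators for every patient. Failures
#' on individual subjects are recorded per row (in the `error` column), not
#' fatal, unless every row fails.
#'
#' @param patients A patient table (`label` + the six kinetic parameters),
#'   e.g. [reference_patients()] or [sample_virtual_patients()].
#' @param model A `network_model`.
#' @param cfg A [protocol_config()].
#' @param provenance `"real"`, `"virtual"` or `"grid"` tag carried per row.
#' @param run Trial-run index carried per row.
#' @return A `cohort_table` tibble: kinetic parameters joined with the
#'   indicator columns of [compute_indicators()], plus `provenance`, `run`
#'   and `error` (NA when the subject evaluated cleanly).
#' @export
evaluate_cohort <- function(patients, model = default_redox_model(),
                            cfg = protocol_config(), provenance = "real",
                            run = 1L) {
  patients <- as_patient_table(patients)
  if (nrow(patients) == 0) {
    rlang::abort("`patients` must contain at least one row",
                 class = "redoxrbc_argument_error")
  }
  if (anyDuplicated(patients$label)) {
    rlang::abort("duplicated subject labels within a run",
                 class = "redoxrbc_argument_error")
  }
  rows <- purrr::map(seq_len(nrow(patients)), function(i) {
    kin <- patients[i, ]
    res <- tryCatch({
      sim <- simulate_subject(kin, model, cfg)
      dplyr::mutate(sim$indicators, error = NA_character_)
    }, error = function(e) {
      tibble::tibble(label = kin$label, initial_ratio = NA_real_,
                     min_ratio = NA_real_, amount_of_change = NA_real_,
                     recovery_time = NA_real_, recovered = NA,
                     theta = cfg$theta, error = conditionMessage(e))
    })
    dplyr::bind_cols(kin, dplyr::select(res, -"label"))
  })
  out <- dplyr::bind_rows(rows)
  if (all(!is.na(out$error))) {
    rlang::abort("every subject in the cohort failed to evaluate",
                 class = "redoxrbc_cohort_error")
  }
  out$provenance <- provenance
  out$run <- as.integer(run)
  class(out) <- c("cohort_table", class(out))
  out
}

#' Repeated virtual-patient trial runs
#'
#' Draws and evaluates `runs` independent cohorts of `n` virtual patients.
#' Per-run seeds are derived deterministically from `seed` (seed, seed + 1,
#' ...), so a fixed seed reproduces every table bit-identically.
#'
#' @param n Patients per trial run (study default 500).
#' @param runs Number of trial runs (study default 15).
#' @param seed Base integer seed.
#' @param ranges Sampling ranges, see [sampling_ranges()].
#' @param model,cfg Passed to [evaluate_cohort()].
#' @param log_uniform Passed to [sample_virtual_patients()].
#' @return A `cohort_table` with `runs * n` rows and a `run` index column.
#' @export
virtual_cohort <- function(n = 500, runs = 15, seed = 1,
                           ranges = sampling_ranges(),
                           model = default_redox_model(),
                           cfg = protocol_config(), log_uniform = FALSE) {
  out <- purrr::map(seq_len(runs), function(r) {
    pats <- sample_virtual_patients(n, ranges, seed = seed + r - 1L,
                                    log_uniform = log_uniform)
    evaluate_cohort(pats, model, cfg, provenance = "virtual", run = r)
  })
  dplyr::bind_rows(out)
}

#' Pairwise Pearson correlations among the redox-imbalance indicators
#'
#' Correlates `initial_ratio`, `recovery_time` and `amount_of_change`
#' pairwise across a cohort. Subjects whose ratio did not recover inside the
#' observation window carry no finite recovery time; the `not_recovered`
#' policy either caps them at the window length (`"window_cap"`, default) or
#' drops them (`"drop"`) before computing correlations involving recovery
#' time.
#'
#' @param table A `cohort_table` (or any data frame with the three indicator
#'   columns; a `recovered` logical column marks non-recovering subjects).
#' @param not_recovered One of `"window_cap"`, `"drop"`.
#' @param window Cap value in seconds (default 1800).
#' @return A tibble with one row per pair: `var_x`, `var_y`, `estimate`,
#'   `n_used`, `defined` (FALSE when a column had zero variance).
#' @export
indicator_correlations <- function(table,
                                   not_recovered = c("window_cap", "drop"),
                                   window = 1800) {
  not_recovered <- match.arg(not_recovered)
  vars <- c("initial_ratio", "recovery_time", "amount_of_change")
  stopifnot(all(vars %in% names(table)))
  df <- tibble::as_tibble(table)[c(vars, intersect("recovered", names(table)))]
  nr <- if ("recovered" %in% names(df)) !df$recovered %in% TRUE & is.na(df$recovery_time)
        else is.na(df$recovery_time)
  if (not_recovered == "window_cap") {
    df$recovery_time[nr] <- window
  } else {
    df <- df[!nr, ]
  }
  pairs <- utils::combn(vars, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(p) {
    x <- df[[p[1]]]; y <- df[[p[2]]]
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3) {
      rlang::abort("need at least 3 usable rows for a correlation",
                   class = "redoxrbc_argument_error")
    }
    defined <- stats::sd(x) > 0 && stats::sd(y) > 0
    tibble::tibble(var_x = p[1], var_y = p[2],
                   estimate = if (defined) stats::cor(x, y) else NA_real_,
                   n_used = length(x), defined = defined)
  })
}

#' Indicator surfaces over a Vmax x KmG6P grid
#'
#' Evaluates the full protocol on a grid of (Vmax, KmG6P) pairs with the four
#' remaining kinetic parameters fixed (defaults: the healthy-control values).
#' Axis values of zero are replaced by a small positive floor, since a zero
#' maximal velocity or Michaelis constant makes the steady-state problem
#' degenerate; the substitution is recorded in the output.
#'
#' @param vmax_values,km_g6p_values Grid axes (defaults: Vmax 0..64 step 1,
#'   KmG6P even values 0..200).
#' @param fixed Named list of the four fixed parameters `km_nadp`,
#'   `ki_nadph`, `ki_atp`, `ki_23bpg`.
#' @param model,cfg Passed to the protocol.
#' @param floor Positive floor replacing zero axis values (default 0.01).
#' @return A long tibble: `vmax`, `km_g6p` (as requested), `vmax_used`,
#'   `km_g6p_used` (after flooring), the indicator columns, and `error`.
#' @export
vmax_km_grid <- function(vmax_values = seq(0, 64, by = 1),
                         km_g6p_values = seq(0, 200, by = 2),
                         fixed = list(km_nadp = 3.7, ki_nadph = 3.1,
                                      ki_atp = 749, ki_23bpg = 2289),
                         model = default_redox_model(),
                         cfg = protocol_config(), floor = 0.01) {
  stopifnot(length(vmax_values) > 0, length(km_g6p_values) > 0, floor > 0)
  if (any(unlist(fixed) <= 0)) {
    rlang::abort("fixed kinetic parameters must be positive",
                 class = "redoxrbc_parameter_error")
  }
  cells <- tidyr::expand_grid(vmax = vmax_values, km_g6p = km_g6p_values)
  cells$vmax_used <- pmax(cells$vmax, floor)
  cells$km_g6p_used <- pmax(cells$km_g6p, floor)
  pats <- tibble::tibble(
    label = sprintf("grid_v%g_k%g", cells$vmax, cells$km_g6p),
    vmax = cells$vmax_used, km_g6p = cells$km_g6p_used,
    km_nadp = fixed$km_nadp, ki_nadph = fixed$ki_nadph,
    ki_atp = fixed$ki_atp, ki_23bpg = fixed$ki_23bpg)
  res <- evaluate_cohort(pats, model, cfg, provenance = "grid")
  dplyr::bind_cols(
    cells,
    dplyr::select(res, "initial_ratio", "min_ratio", "amount_of_change",
                  "recovery_time", "recovered", "error"))
}

#' Stratified indicator summary
#'
#' Splits a cohort into four strata (low/high Vmax crossed with low/high
#' KmG6P) and summarises each indicator's dispersion per stratum, flagging
#' subjects whose recovery exceeded the observation window.
#'
#' @param table A `cohort_table`.
#' @param vmax_cut,km_cut Cut points defining "low" (< cut) vs "high".
#' @param window Observation window used to flag abnormal recovery (s).
#' @return A tibble with one row per stratum x indicator: counts, quartiles
#'   (`q25`, `median`, `q75`), `iqr`, and `n_abnormal` (recovery beyond the
#'   window or not recovered).
#' @export
trend_summary <- function(table, vmax_cut = 10, km_cut = 100, window = 1800) {
  stopifnot(all(c("vmax", "km_g6p") %in% names(table)))
  df <- tibble::as_tibble(table)
  df$vmax_stratum <- ifelse(df$vmax < vmax_cut, "low_vmax", "high_vmax")
  df$km_stratum <- ifelse(df$km_g6p < km_cut, "low_km", "high_km")
  long <- tidyr::pivot_longer(
    df, cols = c("initial_ratio", "recovery_time", "amount_of_change"),
    names_to = "indicator", values_to = "value")
  dplyr::summarise(
    dplyr::group_by(long, .data$vmax_stratum, .data$km_stratum, .data$indicator),
    n = dplyr::n(),
    n_abnormal = sum((.data$indicator == "recovery_time") &
                       (is.na(.data$value) | .data$value > window)),
    q25 = stats::quantile(.data$value, 0.25, na.rm = TRUE, names = FALSE),
    median = stats::median(.data$value, na.rm = TRUE),
    q75 = stats::quantile(.data$value, 0.75, na.rm = TRUE, names = FALSE),
    iqr = q75 - q25,
    .groups = "drop")
}

#' Published indicator table of the reference subjects
#'
#' The packaged fixture of published per-subject indicator values (initial
#' GSH/GSSG, recovery time — missing for the non-recovering patient 1 — and
#' amount of change) for the ten deficient patients and the healthy control,
#' used for the correlation cross-check in [table3_check()].
#'
#' @return A tibble with 11 rows: `label`, `vmax`, `initial_ratio`,
#'   `recovery_time` (NA = not recovered), `amount_of_change`, `recovered`.
#' @export
reference_indicator_table <- function() {
  path <- system.file("extdata", "reference_indicators.csv",
                      package = "redoxrbc", mustWork = TRUE)
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  df$recovered <- !is.na(df$recovery_time)
  df
}
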