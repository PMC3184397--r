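#' Write a trajectory to CSV
#'
#' @param traj A `redox_trajectory`.
#' @param path Output file.
#' @param format `"wide"` (one column per series) or `"long"` (tidy
#'   time/variable/value).
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, format = c("wide", "long")) {
  format <- match.arg(format)
  df <- tibble::as_tibble(traj)
  if (format == "long") {
    df <- tidyr::pivot_longer(df, cols = -"time",
                              names_to = "variable", values_to = "value")
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a cohort table
#'
#' Lossless CSV round trip of a `cohort_table` (empty recovery-time cells
#' encode non-recovering subjects).
#'
#' @param table A `cohort_table`.
#' @param path CSV file path.
#' @return `write_cohort_csv()` the path invisibly; `read_cohort_csv()` a
#'   `cohort_table` tibble.
#' @export
write_cohort_csv <- function(table, path) {
  utils::write.csv(tibble::as_tibble(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if ("error" %in% names(df)) df$error <- as.character(df$error)
  if ("recovered" %in% names(df)) df$recovered <- as.logical(df$recovered)
  class(df) <- c("cohort_table", class(df))
  df
}

#' Run one subject and write its outputs
#'
#' Runs the steady-state + perturbation protocol for a labelled reference
#' subject (or a supplied kinetics row), writing the trajectory (wide and
#' long CSV), the indicator row, and a run manifest echoing the
#' configuration.
#'
#' @param subject A label found in [reference_patients()], or a
#'   [patient_kinetics()] row.
#' @param out_dir Output directory (created if needed).
#' @param model,cfg Protocol inputs.
#' @return The `redox_sim` object, invisibly; files `trajectory.csv`,
#'   `trajectory_long.csv`, `indicators.csv`, `manifest.yaml` in `out_dir`.
#' @export
run_subject <- function(subject, out_dir, model = default_redox_model(),
                        cfg = protocol_config()) {
  if (is.character(subject)) {
    refs <- reference_patients()
    if (!subject %in% refs$label) {
      rlang::abort(paste0("unknown subject '", subject, "'; available: ",
                          paste(refs$label, collapse = ", ")),
                   class = "redoxrbc_argument_error")
    }
    subject <- refs[refs$label == subject, ]
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_subject(subject, model, cfg)
  write_trajectory_csv(sim$trajectory, file.path(out_dir, "trajectory.csv"))
  write_trajectory_csv(sim$trajectory, file.path(out_dir, "trajectory_long.csv"),
                       format = "long")
  utils::write.csv(sim$indicators, file.path(out_dir, "indicators.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, list(command = "simulate",
                               subject = sim$kinetics$label, config = unclass(cfg)))
  invisible(sim)
}

#' Run a cohort and write its outputs
#'
#' @param mode `"reference"` (the 11 packaged subjects), `"virtual"`
#'   (Monte-Carlo patients) or `"grid"` (Vmax x KmG6P surfaces).
#' @param out_dir Output directory.
#' @param n,runs,seed Virtual-cohort settings (defaults 500 patients x 15
#'   runs).
#' @param model,cfg Protocol inputs.
#' @param ... Extra arguments passed to [vmax_km_grid()] when `mode = "grid"`.
#' @return The cohort (or grid) tibble, invisibly; per-run CSVs, a pooled
#'   correlation report and a manifest are written to `out_dir`.
#' @export
run_cohort <- function(mode = c("reference", "virtual", "grid"), out_dir,
                       n = 500, runs = 15, seed = 1,
                       model = default_redox_model(), cfg = protocol_config(),
                       ...) {
  mode <- match.arg(mode)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (mode == "reference") {
    tab <- evaluate_cohort(reference_patients(), model, cfg, provenance = "real")
    write_cohort_csv(tab, file.path(out_dir, "cohort_reference.csv"))
  } else if (mode == "virtual") {
    tab <- virtual_cohort(n = n, runs = runs, seed = seed, model = model,
                          cfg = cfg)
    for (r in unique(tab$run)) {
      write_cohort_csv(dplyr::filter(tab, .data$run == r),
                       file.path(out_dir, sprintf("cohort_run%02d.csv", r)))
    }
  } else {
    tab <- vmax_km_grid(model = model, cfg = cfg, ...)
    utils::write.csv(tab, file.path(out_dir, "grid_surfaces.csv"),
                     row.names = FALSE)
    long <- tidyr::pivot_longer(
      tab, cols = c("initial_ratio", "recovery_time", "amount_of_change"),
      names_to = "indicator", values_to = "value")
    utils::write.csv(long[c("vmax", "km_g6p", "indicator", "value")],
                     file.path(out_dir, "grid_surfaces_long.csv"),
                     row.names = FALSE)
  }
  if (mode != "grid") {
    rep <- indicator_correlations(tab, window = cfg$window)
    utils::write.csv(rep, file.path(out_dir, "correlations.csv"),
                     row.names = FALSE)
  }
  write_manifest(out_dir, list(command = "cohort", mode = mode, n = n,
                               runs = runs, seed = seed,
                               config = unclass(cfg)))
  invisible(tab)
}

write_manifest <- function(out_dir, info) {
  info$package_version <- as.character(utils::packageVersion("redoxrbc"))
  info$r_version <- as.character(getRversion())
  yaml::write_yaml(info, file.path(out_dir, "manifest.yaml"))
  invisible(info)
}

#' Correlation cross-check against the published indicator table
#'
#' Recomputes the two published indicator correlations from the packaged
#' reference indicator table: (i) Pearson correlation of initial GSH/GSSG
#' with amount of change over the ten subjects with finite recovery time,
#' and (ii) the magnitude of the Pearson correlation of recovery time with
#' amount of change over all eleven subjects, the non-recovering subject
#' capped at the observation window. Fails loudly if either value, rounded
#' to two decimals, deviates from the published 0.99 / 0.91.
#'
#' @param window Cap for the non-recovering subject (s, default 1800).
#' @param strict Abort on mismatch (default TRUE).
#' @param table Indicator table to check (defaults to the packaged fixture);
#'   any perturbation of the published values makes the check fail.
#' @return A tibble with the two correlations, their published counterparts
#'   and the subject counts used.
#' @export
#' @examples
#' table3_check()
table3_check <- function(window = 1800, strict = TRUE,
                         table = reference_indicator_table()) {
  tab <- table
  fin <- tab[!is.na(tab$recovery_time), ]
  r1 <- stats::cor(fin$initial_ratio, fin$amount_of_change)
  rec_cap <- ifelse(is.na(tab$recovery_time), window, tab$recovery_time)
  r2 <- abs(stats::cor(rec_cap, tab$amount_of_change))
  out <- tibble::tibble(
    check = c("initial_ratio vs amount_of_change (finite recovery)",
              "|recovery_time vs amount_of_change| (window cap)"),
    estimate = c(r1, r2),
    published = c(0.99, 0.91),
    n_used = c(nrow(fin), nrow(tab)))
  if (strict && any(round(out$estimate, 2) != out$published)) {
    rlang::abort(paste0(
      "reference indicator table failed the published-correlation check: ",
      paste(sprintf("%s = %.4f (published %.2f)", out$check, out$estimate,
                    out$published), collapse = "; ")),
      class = "redoxrbc_check_error")
  }
  out
}

#' Calibrate the glutathione-reductase capacity
#'
#' Bisection on the glutathione-reductase `vmax` so that the healthy
#' control's steady-state GSH/GSSG hits a target value. Used once to fix the
#' packaged default (see `scripts/calibrate.R`); exposed so alternative
#' networks can be recalibrated.
#'
#' @param model A `network_model`.
#' @param target Target control steady-state ratio (default 700.38).
#' @param interval Search interval for the reductase `vmax` (uM/s).
#' @param tol Relative tolerance on the achieved ratio.
#' @param cfg A [protocol_config()].
#' @return The model with the calibrated reductase `vmax`, with the achieved
#'   ratio in attribute `calibrated_ratio`.
#' @export
calibrate_reductase <- function(model = default_redox_model(), target = 700.38,
                                interval = c(0.5, 50), tol = 1e-4,
                                cfg = protocol_config()) {
  ctrl <- reference_patients()[reference_patients()$label == "Control", ]
  set_vgr <- function(m, v) {
    i <- which(purrr::map_chr(m$reactions, "name") == "GR")
    m$reactions[[i]]$params$vmax <- v
    m
  }
  ratio_at <- function(v) {
    find_steady_state(set_vgr(model, v), ctrl, cfg)$ratio_gsh_gssg
  }
  f <- function(v) ratio_at(v) - target
  root <- stats::uniroot(f, interval = interval, tol = tol)
  out <- set_vgr(model, root$root)
  attr(out, "calibrated_ratio") <- root$f.root + target
  out
}
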