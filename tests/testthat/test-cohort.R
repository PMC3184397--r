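test_that("the reference cohort reproduces the published severity structure", {
  tab <- fix_reference_cohort()
  expect_equal(nrow(tab), 11L)
  expect_true(all(is.na(tab$error)))
  expect_false(anyDuplicated(tab$label) > 0)

  # the healthy control has the largest pre-perturbation GSH/GSSG
  expect_equal(tab$label[which.max(tab$initial_ratio)], "Control")
  # patients 1, 4 and 8 have the three smallest initial ratios
  worst <- tab$label[order(tab$initial_ratio)][1:3]
  expect_setequal(worst, c("Patient 1", "Patient 4", "Patient 8"))
  # ... and the three longest recoveries
  rec <- ifelse(is.na(tab$recovery_time), Inf, tab$recovery_time)
  slowest <- tab$label[order(-rec)][1:3]
  expect_setequal(slowest, c("Patient 1", "Patient 4", "Patient 8"))
})

test_that("failures are isolated per row, not fatal", {
  pats <- reference_patients()[1:3, ]
  real_sim <- simulate_subject
  local_mocked_bindings(
    simulate_subject = function(kin, model, cfg) {
      if (kin$label == "Patient 2") stop("synthetic failure")
      real_sim(kin, model, cfg)
    })
  tab <- evaluate_cohort(pats, fix_model())
  expect_equal(nrow(tab), 3L)
  expect_match(tab$error[tab$label == "Patient 2"], "synthetic failure")
  expect_true(all(is.na(tab$error[tab$label != "Patient 2"])))
  expect_true(all(is.finite(tab$initial_ratio[tab$label != "Patient 2"])))

  local_mocked_bindings(
    simulate_subject = function(kin, model, cfg) stop("all fail"))
  expect_error(evaluate_cohort(pats, fix_model()),
               class = "redoxrbc_cohort_error")
})

test_that("indicator correlations: oracle agreement, policies, degeneracies", {
  withr::local_seed(5)
  # random tables match a textbook two-pass Pearson computation
  for (rep in 1:5) {
    tab <- tibble::tibble(initial_ratio = runif(20, 100, 700),
                          recovery_time = runif(20, 50, 600),
                          amount_of_change = runif(20),
                          recovered = TRUE)
    res <- indicator_correlations(tab)
    for (i in seq_len(nrow(res))) {
      expect_equal(res$estimate[i],
                   pearson_two_pass(tab[[res$var_x[i]]], tab[[res$var_y[i]]]),
                   tolerance = 1e-12)
    }
  }

  # exactly collinear indicators give 1
  lin <- tibble::tibble(initial_ratio = 1:10,
                        recovery_time = 2 * (1:10) + 5,
                        amount_of_change = 0.1 * (1:10),
                        recovered = TRUE)
  res <- indicator_correlations(lin)
  expect_true(all(abs(res$estimate - 1) < 1e-12))

  # zero variance flags the pair as undefined
  zv <- lin; zv$amount_of_change <- 0.5
  res <- indicator_correlations(zv)
  expect_true(all(!res$defined[res$var_x == "amount_of_change" |
                                 res$var_y == "amount_of_change"]))

  # the two sentinel policies differ only through non-recovered rows
  tab <- lin
  tab$recovered[3] <- FALSE
  tab$recovery_time[3] <- NA
  cap <- indicator_correlations(tab, "window_cap", window = 1800)
  drp <- indicator_correlations(tab, "drop")
  expect_equal(drp$n_used[drp$var_x == "recovery_time" |
                            drp$var_y == "recovery_time"], c(9L, 9L))
  expect_equal(cap$n_used, rep(10L, 3))
  no_sentinel <- indicator_correlations(lin, "window_cap")
  expect_equal(indicator_correlations(lin, "drop"), no_sentinel)

  expect_error(indicator_correlations(lin[1:2, ]),
               class = "redoxrbc_argument_error")
})

test_that("grid evaluation equals batched single-subject runs and is order-independent", {
  m <- fix_model()
  cfg <- protocol_config(record_step = 2)
  g <- vmax_km_grid(vmax_values = c(8, 32), km_g6p_values = c(40, 120),
                    model = m, cfg = cfg)
  expect_equal(nrow(g), 4L)
  for (i in seq_len(nrow(g))) {
    kin <- patient_kinetics(g$vmax[i], g$km_g6p[i], 3.7, 3.1, 749, 2289,
                            label = "cell")
    sim <- simulate_subject(kin, m, cfg)
    expect_equal(g$initial_ratio[i], sim$indicators$initial_ratio,
                 tolerance = 1e-10)
    expect_equal(g$recovery_time[i], sim$indicators$recovery_time,
                 tolerance = 1e-10)
  }
  # permuting the axis order permutes, but does not change, the surfaces
  g2 <- vmax_km_grid(vmax_values = c(32, 8), km_g6p_values = c(120, 40),
                     model = m, cfg = cfg)
  key <- function(d) d[order(d$vmax, d$km_g6p),
                       c("vmax", "km_g6p", "initial_ratio", "recovery_time")]
  expect_equal(key(g), key(g2), ignore_attr = TRUE)

  # a zero axis value is floored and the substitution is recorded
  g0 <- vmax_km_grid(vmax_values = 0, km_g6p_values = 40, model = m, cfg = cfg)
  expect_equal(g0$vmax, 0)
  expect_equal(g0$vmax_used, 0.01)
  expect_true(is.finite(g0$initial_ratio))
})

test_that("trend summaries stratify dispersion by vmax and km cuts", {
  # degenerate cut collapses to a whole-cohort summary
  tab <- fix_reference_cohort()
  one <- trend_summary(tab, vmax_cut = -Inf, km_cut = -Inf)
  expect_equal(unique(one$vmax_stratum), "high_vmax")
  expect_equal(unique(one$km_stratum), "high_km")
  expect_equal(unique(one$n), 11L)

  # constructed effect: indicator driven by vmax only
  withr::local_seed(8)
  synth <- tibble::tibble(
    label = sprintf("s%02d", 1:40),
    vmax = runif(40, 1, 64), km_g6p = runif(40, 7, 152),
    km_nadp = 3.7, ki_nadph = 3.1, ki_atp = 749, ki_23bpg = 2289,
    initial_ratio = 10 + 5 * (runif(40, 1, 64) < 10),
    recovery_time = 100 + 600 / sqrt(runif(40, 1, 64)),
    amount_of_change = 0.2)
  synth$recovery_time <- 100 + 600 / sqrt(synth$vmax)
  s <- trend_summary(synth, vmax_cut = 10, km_cut = 80)
  rec <- s[s$indicator == "recovery_time", ]
  med_by_vmax <- tapply(rec$median, rec$vmax_stratum, mean)
  expect_gt(med_by_vmax[["low_vmax"]], med_by_vmax[["high_vmax"]])
})

test_that("the packaged reference indicator fixture is intact", {
  tab <- reference_indicator_table()
  expect_equal(nrow(tab), 11L)
  expect_equal(sum(is.na(tab$recovery_time)), 1L)
  expect_equal(tab$label[is.na(tab$recovery_time)], "Patient 1")
  expect_equal(tab$initial_ratio[tab$label == "Control"], 700.38)
})
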