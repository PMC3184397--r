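test_that("steady state of a one-species relaxation model is its analytic fixed point", {
  toy <- read_model(write_toy_model(k = 0.2, a = 3, x0 = 0.5))
  ss <- find_steady_state(toy, NULL)
  expect_equal(ss$state[["x"]], 3, tolerance = 1e-8)
  expect_lt(ss$residual_norm, 1e-8)
})

test_that("steady state satisfies its residual and conservation postconditions", {
  m <- fix_model()
  ss <- fix_control_ss()
  expect_lt(ss$residual_norm, 1e-8)
  # residual re-evaluated through the R rate-law path agrees
  d <- ode_rhs(ss$state, m, fix_control())
  expect_lt(max(abs(d)), 1e-8)
  # conserved totals match those of the model-file initial state
  tot0 <- conserved_totals(initial_state(m), m)
  expect_equal(ss$totals[["glutathione"]], tot0[["glutathione"]],
               tolerance = 1e-6)
  expect_equal(ss$totals[["nicotinamide"]], tot0[["nicotinamide"]],
               tolerance = 1e-6)
  expect_gt(ss$ratio_gsh_gssg, 0)
})

test_that("zero-dose runs stay at steady state across the whole window", {
  m <- fix_model()
  ss <- fix_control_ss()
  tr <- run_perturbation(m, fix_control(), ss,
                         protocol_config(h2o2_dose = 0, window = 1800,
                                         record_step = 10))
  for (sp in dynamic_species) {
    expect_lt(max(abs(tr[[sp]] - ss$state[[sp]])) /
                max(ss$state[[sp]], 1e-12), 1e-6)
  }
})

test_that("the oxidative dose produces a dip-and-recover ratio excursion", {
  tr <- fix_control_traj()
  r0 <- attr(tr, "initial_ratio")
  expect_equal(tr$ratio_gsh_gssg[1], r0, tolerance = 1e-6)
  expect_lt(min(tr$ratio_gsh_gssg), 0.95 * r0)          # a real dip
  n <- nrow(tr)
  expect_gt(tr$ratio_gsh_gssg[n], 0.99 * r0)            # recovery inside window
  i_min <- which.min(tr$ratio_gsh_gssg)
  expect_true(i_min > 1 && i_min < n)
})

test_that("conserved moieties drift below 1e-6 along perturbation trajectories", {
  m <- fix_model()
  for (lab in c("Control", "Patient 1", "Patient 5")) {
    kin <- fix_patient(lab)
    tr <- run_perturbation(m, kin, cfg = protocol_config(record_step = 5))
    gt <- tr$gsh + 2 * tr$gssg
    nt <- tr$nadph + tr$nadp
    expect_lt(max(abs(gt - gt[1])) / gt[1], 1e-6)
    expect_lt(max(abs(nt - nt[1])) / nt[1], 1e-6)
  }
})

test_that("halving integrator tolerances leaves recorded series unchanged to 1e-5", {
  m <- fix_model()
  ss <- fix_control_ss()
  a <- run_perturbation(m, fix_control(), ss, protocol_config(record_step = 5))
  b <- run_perturbation(m, fix_control(), ss,
                        protocol_config(record_step = 5,
                                        rtol = 5e-9, atol = 5e-11))
  for (sp in dynamic_species) {
    expect_lt(max(abs(a[[sp]] - b[[sp]]) / pmax(abs(b[[sp]]), 1e-8)), 1e-5)
  }
})

test_that("integration is deterministic: identical config, identical series", {
  m <- fix_model()
  ss <- find_steady_state(m, fix_control())
  a <- run_perturbation(m, fix_control(), ss)
  b <- run_perturbation(m, fix_control(), ss)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("the post-perturbation ratio minimum is non-increasing in dose", {
  m <- fix_model()
  ss <- fix_control_ss()
  mins <- vapply(c(50, 100, 200), function(d) {
    min(run_perturbation(m, fix_control(), ss,
                         protocol_config(h2o2_dose = d,
                                         record_step = 2))$ratio_gsh_gssg)
  }, 0)
  expect_true(all(diff(mins) < 0))
})

test_that("both dose modes perturb the system", {
  m <- fix_model()
  ss <- fix_control_ss()
  bol <- run_perturbation(m, fix_control(), ss,
                          protocol_config(window = 300, record_step = 2))
  expect_equal(bol$h2o2[1], ss$state[["h2o2"]] + 100, tolerance = 1e-9)
  cl <- run_perturbation(m, fix_control(), ss,
                         protocol_config(dose_mode = "clamp_external",
                                         window = 300, record_step = 2))
  expect_equal(cl$h2o2_ext[1], 100)
  expect_lt(min(cl$ratio_gsh_gssg), 0.95 * ss$ratio_gsh_gssg)
})

test_that("enzyme activity series re-evaluate to the recorded rate laws", {
  m <- fix_model()
  tr <- fix_control_traj()
  long <- enzyme_activity_series(tr)
  expect_named(long, c("time", "enzyme", "flux"))
  expect_error(enzyme_activity_series(tr, "nosuch"),
               class = "redoxrbc_argument_error")

  # re-evaluation oracle at a handful of recorded states (R rate-law path)
  idx <- c(1, 11, 61, 301, nrow(tr))
  for (i in idx) {
    st <- unlist(tr[i, c(dynamic_species, "h2o2_ext", "atp", "bpg23", "glc")])
    v <- reaction_fluxes(st, m, fix_control())
    for (e in c("G6PD", "CAT", "GSHpx", "SOD", "GR")) {
      expect_equal(tr[[paste0("flux_", e)]][i], v[[e]], tolerance = 1e-6)
    }
  }

  # zero dose: all activity series constant
  tr0 <- run_perturbation(m, fix_control(), fix_control_ss(),
                          protocol_config(h2o2_dose = 0, window = 300,
                                          record_step = 5))
  l0 <- enzyme_activity_series(tr0)
  spread <- tapply(l0$flux, l0$enzyme, function(x) diff(range(x)) / max(abs(x)))
  expect_true(all(spread < 1e-6))

  # CAT and GSHpx rise after the dose and relax back toward baseline
  base <- attr(tr, "steady_fluxes")
  for (e in c("CAT", "GSHpx")) {
    f <- tr[[paste0("flux_", e)]]
    expect_gt(max(f) / base[[e]], 2)
    expect_lt(f[nrow(tr)] / base[[e]], 1.05)
  }
})
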