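test_that("G6PD rate law: limits, frozen value, and error guards", {
  ctrl <- fix_control()
  base <- c(g6p = 40, nadp = 2, nadph = 60, atp = 1600, bpg23 = 5000)

  # zero substrate annihilates the numerator
  expect_identical(g6pd_rate(replace(base, "g6p", 0), ctrl), 0)
  expect_identical(g6pd_rate(replace(base, "nadp", 0), ctrl), 0)

  # double-saturation, zero-inhibitor limit approaches vmax
  sat <- c(g6p = 1e6 * 67, nadp = 1e6 * 3.7, nadph = 0, atp = 0, bpg23 = 0)
  expect_equal(g6pd_rate(sat, ctrl), 64, tolerance = 1e-4)

  # frozen independent arithmetic evaluation of the rate law
  expect_equal(g6pd_rate(base, ctrl), 0.8087155824, tolerance = 1e-9)

  bad <- ctrl; bad$ki_atp <- 0
  expect_error(g6pd_rate(base, bad), class = "redoxrbc_parameter_error")
  expect_error(g6pd_rate(base[-1], ctrl), class = "redoxrbc_parameter_error")
  expect_error(g6pd_rate(replace(base, "g6p", -1), ctrl),
               class = "redoxrbc_parameter_error")
})

test_that("G6PD rate is bounded by vmax and monotone in every effector", {
  withr::local_seed(7)
  ctrl <- fix_control()
  n <- 10000
  st <- list(g6p = runif(n, 0, 500), nadp = runif(n, 0, 200),
             nadph = runif(n, 0, 200), atp = runif(n, 0, 3000),
             bpg23 = runif(n, 0, 10000))
  v <- vapply(seq_len(n), function(i) {
    g6pd_rate(vapply(st, `[[`, 0, i), ctrl)
  }, 0)
  expect_true(all(v >= 0))
  expect_true(all(v < 64))
  expect_true(all((v == 0) == (st$g6p * st$nadp == 0)))

  bump <- function(var, delta) {
    vapply(seq_len(n), function(i) {
      s <- vapply(st, `[[`, 0, i)
      s[var] <- s[var] + delta
      g6pd_rate(s, ctrl)
    }, 0)
  }
  expect_true(all(bump("g6p", 10) >= v - 1e-12))
  expect_true(all(bump("nadp", 10) >= v - 1e-12))
  expect_true(all(bump("nadph", 10) <= v + 1e-12))
  expect_true(all(bump("atp", 100) <= v + 1e-12))
  expect_true(all(bump("bpg23", 100) <= v + 1e-12))
})

test_that("antioxidant rate laws match independent re-evaluation", {
  m <- fix_model()
  ctrl <- fix_control()
  st <- c(h2o2 = 0.5, o2minus = 0.2, gsh = 3000, gssg = 10, nadph = 50,
          nadp = 12, g6p = 35, gl6p = 0.4, h2o2_ext = 100, atp = 1600,
          bpg23 = 5000, glc = 5000)
  v <- antioxidant_rates(st, m)
  pr <- function(rxn) {
    r <- m$reactions[[which(vapply(m$reactions, `[[`, "", "name") == rxn)]]
    r$params
  }
  # hand re-evaluation of every stated rate law
  expect_equal(v[["h2o2_influx"]], pr("h2o2_influx")$k * (100 - 0.5))
  expect_equal(v[["o2minus_generation"]], pr("o2minus_generation")$v)
  expect_equal(v[["SOD"]], pr("SOD")$k * 0.2)
  expect_equal(v[["CAT"]], pr("CAT")$k * 0.5)
  gpx <- pr("GSHpx")
  expect_equal(v[["GSHpx"]],
               gpx$vmax * 0.5 / (gpx$km_a + 0.5) * 3000 / (gpx$km_b + 3000))
  gr <- pr("GR")
  expect_equal(v[["GR"]],
               gr$vmax * 10 / (gr$km_a + 10) * 50 / (gr$km_b + 50))
  p2 <- pr("ppp_second_step")
  expect_equal(v[["ppp_second_step"]], p2$k * 0.4 * 12 / (p2$km + 12))
  expect_equal(v[["g6p_drain"]], pr("g6p_drain")$k * 35)
  expect_equal(v[["nadph_drain"]], pr("nadph_drain")$k * 50)

  # every concentration-driven velocity vanishes at the zero state;
  # the constant source fluxes stay at their configured values
  z <- st; z[] <- 0
  vz <- antioxidant_rates(z, m)
  const <- c("o2minus_generation", "g6p_supply")
  expect_true(all(vz[setdiff(names(vz), const)] == 0))
  expect_equal(vz[["o2minus_generation"]], pr("o2minus_generation")$v)

  # GSHpx and GR sanity at depleted substrates
  expect_equal(antioxidant_rates(replace(st, "gsh", 0), m)[["GSHpx"]], 0)
  expect_equal(antioxidant_rates(replace(st, "nadph", 0), m)[["GR"]], 0)
})

test_that("ode_rhs equals the brute-force per-reaction accumulation oracle", {
  m <- fix_model()
  ctrl <- fix_control()
  withr::local_seed(11)
  for (rep in 1:20) {
    st <- random_state()
    d <- ode_rhs(st, m, ctrl)
    v <- attr(d, "fluxes")
    # brute force: loop reactions, accumulate stoich * rate
    acc <- setNames(numeric(length(st)), names(st))
    for (r in m$reactions) {
      for (sp in names(r$stoich)) {
        acc[sp] <- acc[sp] + r$stoich[[sp]] * v[[r$name]]
      }
    }
    expect_equal(unname(d[dynamic_species]), unname(acc[dynamic_species]),
                 tolerance = 1e-12)
    # clamped derivatives are exactly zero
    expect_identical(unname(d[c("h2o2_ext", "atp", "bpg23", "glc")]),
                     rep(0, 4))
    # glutathione moiety is untouched by the stoichiometry
    expect_equal(d[["gsh"]] + 2 * d[["gssg"]], 0, tolerance = 1e-12)
    expect_equal(d[["nadph"]] + d[["nadp"]], 0, tolerance = 1e-12)
  }
})

test_that("conserved totals and their definitions", {
  m <- fix_model()
  st <- initial_state(m, c(gsh = 3200, gssg = 4, nadph = 60, nadp = 2))
  tot <- conserved_totals(st, m)
  expect_equal(tot[["glutathione"]], 3208)
  expect_equal(tot[["nicotinamide"]], 62)
  bad <- m
  bad$moieties$glutathione <- c(gsh = 1, nosuch = 2)
  expect_error(conserved_totals(st, bad),
               class = "redoxrbc_configuration_error")
})

test_that("model definitions validate and the default engine is compiled", {
  m <- fix_model()
  expect_identical(m$engine, "compiled")
  expect_silent(validate_model(m))

  bad <- m
  bad$reactions[[5]]$stoich <- c(h2o2 = -1, nosuch = 1)
  expect_error(validate_model(bad), class = "redoxrbc_configuration_error")

  bad2 <- m
  bad2$moieties$glutathione <- c(gsh = 1, gssg = 1)  # not in the null space
  expect_error(validate_model(bad2), class = "redoxrbc_configuration_error")

  # unknown rate law surfaces as a configuration error
  bad3 <- m
  bad3$reactions[[2]]$law <- "mystery"
  expect_error(reaction_fluxes(initial_state(m), bad3, fix_control()),
               class = "redoxrbc_configuration_error")

  # a structurally different model falls back to the R evaluator
  toy <- read_model(write_toy_model())
  expect_identical(toy$engine, "r")
})

test_that("compiled and R evaluators agree on derivatives and fluxes", {
  m <- fix_model()
  mr <- m; mr$engine <- "r"
  ctrl <- fix_control()
  withr::local_seed(3)
  for (rep in 1:10) {
    st <- random_state()
    st[c("h2o2_ext", "atp", "bpg23", "glc")] <- c(0, 1600, 5000, 5000)
    y <- st[dynamic_species]
    a <- redoxrbc:::rhs_at(y, m, ctrl)
    b <- redoxrbc:::rhs_at(y, mr, ctrl)
    expect_equal(a$deriv, b$deriv, tolerance = 1e-14)
    expect_equal(unname(a$flux), unname(b$flux[names(a$flux)]),
                 tolerance = 1e-14)
  }
})
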