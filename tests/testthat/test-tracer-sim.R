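test_that("network construction reflects the scenario's branch structure", {
  net <- build_network(flux_scenario(f_mpc = 0.8, f_gln = 0.5,
                                     f_reductive = 0.2))
  expect_true(all(c("succinate", "fumarate") %in% net$symmetric_pools))
  expect_true(net$reactions$active[net$reactions$id == "red_idh"])

  off <- build_network(flux_scenario(f_mpc = 0, f_reductive = 0))
  expect_false(off$reactions$active[off$reactions$id == "red_idh"])
  expect_false(off$reactions$active[off$reactions$id == "pdh"])
})

test_that("unlabeled tracer leaves every pool at M+0", {
  net <- build_network(flux_scenario(f_mpc = 0.8, f_gln = 0.6,
                                     f_reductive = 0.3,
                                     f_anaplerotic_pc = 0.1))
  mids <- simulate_steady_state(net, tracer_spec("glucose", "U",
                                                 enrichment = 0))
  for (m in names(mids)) expect_equal(mids[[m]][1], 1)
})

test_that("every simulated MID is a valid distribution", {
  set.seed(42)
  for (i in 1:5) {
    sc <- flux_scenario(f_mpc = runif(1), f_gln = runif(1),
                        f_reductive = runif(1),
                        f_anaplerotic_pc = runif(1), dilution = runif(1, 0, 0.5))
    tr <- tracer_spec(sample(c("glucose", "glutamine"), 1), "U",
                      enrichment = runif(1))
    mids <- simulate_steady_state(build_network(sc), tr)
    for (m in names(mids)) {
      expect_true(all(mids[[m]] >= -1e-12))
      expect_equal(sum(mids[[m]]), 1, tolerance = 1e-9)
    }
  }
})

test_that("MPC loss abolishes glucose-derived M+2 in TCA intermediates", {
  sc <- flux_scenario(f_mpc = 0, f_gln = 0.85, f_reductive = 0.45,
                      f_anaplerotic_pc = 0, dilution = 0.25)
  mids <- simulate_steady_state(build_network(sc),
                                tracer_spec("glucose", "U"))
  for (m in c("citrate", "succinate", "malate", "aspartate"))
    expect_equal(mids[[m]][3], 0, tolerance = 1e-9)
})

test_that("without reductive flux, [1-13C]glutamine leaves C4 pools at M+0", {
  sc <- flux_scenario(f_mpc = 0, f_gln = 1, f_reductive = 0,
                      f_anaplerotic_pc = 0)
  mids <- simulate_steady_state(build_network(sc),
                                tracer_spec("glutamine", 1))
  for (m in c("succinate", "malate", "aspartate"))
    expect_equal(mids[[m]][2], 0, tolerance = 1e-9)
})

test_that("aspartate M+1 under [1-13C]glutamine rises with reductive flux", {
  vals <- vapply(c(0, 0.2, 0.5, 0.8), function(fr) {
    sc <- flux_scenario(f_mpc = 0, f_gln = 0.85, f_reductive = fr,
                        dilution = 0.25)
    simulate_steady_state(build_network(sc),
                          tracer_spec("glutamine", 1))$aspartate[2]
  }, 0)
  expect_true(all(diff(vals) > 0))
})

test_that("citrate M+2 under [U-13C]glucose is non-decreasing in f_mpc", {
  vals <- vapply(c(0, 0.3, 0.6, 0.9), function(fm) {
    sc <- flux_scenario(f_mpc = fm, f_gln = 0.7, f_reductive = 0.1,
                        dilution = 0.25)
    simulate_steady_state(build_network(sc),
                          tracer_spec("glucose", "U"))$citrate[3]
  }, 0)
  expect_true(all(diff(vals) >= 0))
})

test_that("one oxidative pass of [U-13C]glutamine gives pure succinate M+4", {
  sc <- flux_scenario(f_mpc = 0, f_gln = 1, f_reductive = 0)
  mids <- simulate_steady_state(build_network(sc),
                                tracer_spec("glutamine", "U"),
                                single_pass = TRUE)
  expect_equal(mids$akg, c(0, 0, 0, 0, 0, 1))   # alpha-KG fully labeled
  expect_equal(mids$succinate, c(0, 0, 0, 0, 1)) # loses one labeled CO2
})

test_that("single-pass simulator equals exhaustive atom-placement enumeration", {
  cases <- list(
    list(substrate = "glucose", positions = 1:6, e = 1,
         f_mpc = 1, f_gln = 0, f_red = 0, f_pc = 0),
    list(substrate = "glucose", positions = 1:6, e = 0.6,
         f_mpc = 0.7, f_gln = 0.3, f_red = 0.2, f_pc = 0.3),
    list(substrate = "glucose", positions = c(1, 2), e = 1,
         f_mpc = 0.5, f_gln = 0, f_red = 0.5, f_pc = 0.5),
    list(substrate = "glutamine", positions = 1:5, e = 1,
         f_mpc = 0, f_gln = 1, f_red = 0, f_pc = 0),
    list(substrate = "glutamine", positions = 1:5, e = 0.8,
         f_mpc = 0.2, f_gln = 0.9, f_red = 0.4, f_pc = 0.1),
    list(substrate = "glutamine", positions = 1, e = 1,
         f_mpc = 0, f_gln = 1, f_red = 1, f_pc = 0),
    list(substrate = "glutamine", positions = 1, e = 1,
         f_mpc = 0.3, f_gln = 0.8, f_red = 0.6, f_pc = 0.2))
  for (cs in cases) {
    sc <- flux_scenario(f_mpc = cs$f_mpc, f_gln = cs$f_gln,
                        f_reductive = cs$f_red,
                        f_anaplerotic_pc = cs$f_pc)
    sim <- simulate_steady_state(
      build_network(sc),
      tracer_spec(cs$substrate, cs$positions, enrichment = cs$e),
      single_pass = TRUE)
    oracle <- oracle_single_pass(cs$substrate, cs$positions, cs$e,
                                 f_mpc = cs$f_mpc, f_gln = cs$f_gln,
                                 f_reductive = cs$f_red, f_pc = cs$f_pc)
    for (m in names(oracle))
      expect_equal(unname(sim[[m]]), oracle[[m]], tolerance = 1e-12,
                   label = sprintf("%s (%s)", m, cs$substrate))
  }
})

test_that("succinate/fumarate orientation assignment does not change MIDs", {
  # a positionally asymmetric tracer must give results identical to the
  # oracle in which both end-to-end orientations of succinate and fumarate
  # are enumerated explicitly with equal weight
  oracle <- oracle_single_pass("glutamine", c(1, 2), 1,
                               f_mpc = 0.4, f_gln = 0.8,
                               f_reductive = 0.3, f_pc = 0.1)
  sim <- simulate_steady_state(build_network(
    flux_scenario(f_mpc = 0.4, f_gln = 0.8, f_reductive = 0.3,
                  f_anaplerotic_pc = 0.1)),
    tracer_spec("glutamine", c(1, 2)), single_pass = TRUE)
  for (m in c("succinate", "fumarate", "malate", "oaa", "aspartate"))
    expect_equal(unname(sim[[m]]), oracle[[m]], tolerance = 1e-12)
})

test_that("non-convergence and invalid inputs raise clear errors", {
  sc <- flux_scenario(f_mpc = 0.9, f_gln = 0.5, name = "tight")
  expect_error(
    simulate_steady_state(build_network(sc), tracer_spec("glucose", "U"),
                          tol = 1e-12, max_iter = 2L),
    "tight")
  expect_error(flux_scenario(f_mpc = 1.2), "\\[0, 1\\]")
  expect_error(tracer_spec("glutamine", 7), "within 1..5")
})
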