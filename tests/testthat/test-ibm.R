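test_that("config validation enforces the simulator's invariants", {
  expect_error(ibm_config(1, 100, seed = 1), "n_patches")
  expect_error(ibm_config(10, 100, seed = 1, mutation_rate = 0.1,
                          mutation_sd = 0), "mutation_sd")
  expect_error(ibm_config(10, 100), "seed")
  expect_error(ibm_config(10, 100, seed = 1, burn_in = 100), "burn_in")
  p <- protection_params()
  expect_error(run_ibm(p, ibm_config(10, 50, seed = 1, z0 = 0.01)), "z0")
})

test_that("without mutation a monomorphic population never moves", {
  p <- mating_params()
  r <- run_ibm(p, ibm_config(40, 80, seed = 3, mutation_rate = 0,
                             mutation_sd = 0, z0 = 0.4))
  expect_lt(max(abs(r$trajectory$z - 0.4)), 1e-12)
  expect_lt(max(abs(r$trajectory$phen_f - 0.4)), 1e-12)
})

test_that("identical seeds give bit-identical trajectories", {
  p <- mating_params()
  cfg <- ibm_config(60, 150, seed = 99)
  r1 <- run_ibm(p, cfg)
  r2 <- run_ibm(p, cfg)
  expect_identical(r1$trajectory, r2$trajectory)
  r3 <- run_ibm(p, ibm_config(60, 150, seed = 100))
  expect_false(identical(r1$trajectory, r3$trajectory))
})

test_that("purely beneficial sleep evolves upward from the midpoint", {
  p <- panel_params(a = 0, c_f = 0, c_m = 0)
  r <- run_ibm(p, ibm_config(250, 1200, seed = 5, z0 = 0.5))
  tr <- r$trajectory
  expect_gt(utils::tail(tr$z, 1), 0.9)
  expect_gt(mean(utils::tail(tr$z, 20)), mean(utils::head(tr$z, 20)))
})

test_that("neutral configurations drift with no directional trend", {
  p <- panel_params(a = 0, c_f = 0, c_m = 0, b_f = 0, b_m = 0)
  slopes <- vapply(1:10, function(s) {
    r <- run_ibm(p, ibm_config(150, 500, seed = 1000 + s, z0 = 0.5))
    tr <- r$trajectory
    unname(stats::coef(stats::lm(z ~ generation, tr))[2])
  }, numeric(1))
  # one-sample t-test across independent seeds
  expect_gt(stats::t.test(slopes)$p.value, 0.01)
})

test_that("summaries report batch-mean errors and honour burn-in", {
  p <- mating_params()
  r <- run_ibm(p, ibm_config(100, 800, seed = 12))
  s <- summarize_ibm(r)
  expect_setequal(s$class, c("z", "phen_f", "phen_m"))
  expect_true(all(s$se >= 0))
  expect_error(summarize_ibm(r, burn_in = 800), "burn_in")
  # constant trajectory: SE exactly 0
  rf <- run_ibm(p, ibm_config(40, 100, seed = 4, mutation_rate = 0,
                              mutation_sd = 0, z0 = 0.6))
  sf <- summarize_ibm(rf)
  expect_equal(sf$mean, rep(0.6, 3), tolerance = 1e-12)
  expect_equal(sf$se, rep(0, 3), tolerance = 1e-12)
})

test_that("two seeds of one configuration agree within combined error", {
  p <- mating_params()
  s1 <- summarize_ibm(run_ibm(p, ibm_config(300, 2500, seed = 21)))
  s2 <- summarize_ibm(run_ibm(p, ibm_config(300, 2500, seed = 22)))
  z1 <- s1[s1$class == "z", ]; z2 <- s2[s2$class == "z", ]
  expect_lt(abs(z1$mean - z2$mean), 3 * sqrt(z1$se^2 + z2$se^2) + 0.01)
})

test_that("a population that cannot survive the night goes extinct loudly", {
  p <- protection_params()  # a = 1
  expect_error(run_ibm(p, ibm_config(20, 50, seed = 2, mutation_rate = 0,
                                     mutation_sd = 0, z0 = 1)),
               "extinct")
})

test_that("expression modes wire the right components to the phenotype", {
  p <- mating_params()
  # sex-specific: female component frozen at its start when only males
  # are under selection would still mutate, so just check bounds and
  # class naming
  r <- run_ibm(p, ibm_config(50, 100, seed = 8,
                             expression_mode = "sex_specific"))
  expect_setequal(setdiff(names(r$trajectory), "generation"),
                  c("z_f", "z_m", "phen_f", "phen_m"))
  expect_true(all(r$trajectory$z_f >= p$m & r$trajectory$z_f <= 1))
  r2 <- run_ibm(p, ibm_config(50, 100, seed = 8,
                              expression_mode = "maternal_expressed",
                              z0 = c(0.3, 0.8)))
  expect_setequal(setdiff(names(r2$trajectory), "generation"),
                  c("z_mat", "z_pat", "phen_f", "phen_m"))
  # maternal expression: phenotype tracks the maternal class mean
  expect_lt(max(abs(r2$trajectory$phen_f + r2$trajectory$phen_m -
                    2 * r2$trajectory$z_mat)), 0.05)
})
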