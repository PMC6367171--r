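test_that("survival and competitive-weight kernels match their forms", {
  p <- protection_params()
  expect_equal(group_survival(1, p), 1)
  expect_equal(group_survival(0.5, p), 0.5)      # a = 1
  expect_equal(group_survival(0, mating_params()), 1)  # a = 0

  expect_equal(competitive_weight(1, "f", p), p$b_f)
  expect_equal(competitive_weight(0.4, "m", p, "viability"), 0.4)
  expect_equal(competitive_weight(0.4, "m", p, "contest"), 1)  # c_m = 0
  pm <- mating_params()
  expect_equal(competitive_weight(0.4, "f", pm, "contest"), 1 - 0.4)
  # b = 0 means no viability differences
  p0 <- panel_params(a = 0, c_f = 1, c_m = 1, b_f = 0, b_m = 0)
  expect_equal(competitive_weight(c(0.2, 0.9), "f", p0), c(1, 1))
})

test_that("fitness is exactly 1 at any resident strategy", {
  for (res in list(0.3,
                   sleep_strategy("sex_specific", z_f = 0.9, z_m = 0.4),
                   sleep_strategy("parent_of_origin", z_mat = 0.3,
                                  z_pat = 0.8))) {
    for (p in list(protection_params(0.3), mating_params(0.7))) {
      ph <- sleepkin:::resolve_phenotypes(
        if (is.numeric(res)) sleep_strategy("monomorphic", z = res) else res)
      expect_equal(expected_fitness("f", ph[["f"]], resident = res,
                                    params = p), 1, tolerance = 1e-12)
      expect_equal(expected_fitness("m", ph[["m"]], resident = res,
                                    params = p), 1, tolerance = 1e-12)
    }
  }
})

test_that("fitness increases in own sleep when sleep is purely beneficial", {
  p <- panel_params(a = 0, c_f = 0, c_m = 0)
  zz <- seq(0.1, 1, by = 0.1)
  wf <- vapply(zz, function(z) expected_fitness("f", z, resident = 0.5,
                                                params = p), numeric(1))
  wm <- vapply(zz, function(z) expected_fitness("m", z, resident = 0.5,
                                                params = p), numeric(1))
  expect_true(all(diff(wf) > 0))
  expect_true(all(diff(wm) > 0))
})

test_that("selection vanishes when no social force is active", {
  p_neutral <- panel_params(a = 0, c_f = 0, c_m = 0, b_f = 0, b_m = 0)
  expect_equal(unname(selection_gradient(0.5, p_neutral)), 0,
               tolerance = 1e-9)
  # b = c with a = 0: the two channels exactly offset is no longer a
  # neutral knife-edge (viability and contest are distinct channels), but
  # a patch where nothing depends on z stays neutral
  expect_equal(unname(selection_gradient(0.21, p_neutral)), 0,
               tolerance = 1e-9)
})

test_that("sleep is purely favoured when only benefits act", {
  p <- panel_params(a = 0, c_f = 0, c_m = 0)
  for (z in c(0.2, 0.5, 0.9)) {
    expect_gt(unname(selection_gradient(z, p)), 0)
  }
})

test_that("central-difference slope of fitness matches the direct term", {
  p <- protection_params()
  rel <- patch_relatedness(p)
  z <- 0.5
  h <- 1e-4
  slope <- (expected_fitness("f", z + h, resident = z, params = p) -
            expected_fitness("f", z - h, resident = z, params = p)) / (2 * h)
  dv <- sleepkin:::fitness_derivatives(p, sleep_strategy("monomorphic",
                                                         z = z))
  expect_equal(slope, dv$f[["self"]], tolerance = 1e-6)
})

test_that("neighbour-modulated and actor-centric accountings agree", {
  # the actor-centric (inclusive-fitness) sum distributes one actor's
  # per-recipient effects over all recipients; with exchangeable roles it
  # must equal the neighbour-modulated assembly term by term
  set.seed(42)
  for (rep in 1:20) {
    p <- panel_params(a = runif(1), c_f = runif(1), c_m = runif(1),
                      d_f = runif(1), d_m = runif(1), d_B = runif(1))
    z <- runif(1, p$m, 1)
    rel <- patch_relatedness(p)
    g_nm <- unname(selection_gradient(z, p, rel = rel))
    dv <- sleepkin:::fitness_derivatives(p, sleep_strategy("monomorphic",
                                                           z = z))
    n_f <- p$n_f; n_m <- p$n_m
    u_f <- n_f / (n_f + n_m); u_m <- n_m / (n_f + n_m)
    # one actor's marginal effect on each single recipient
    per_fF <- dv$f[["oF"]] / (n_f - 1)  # female actor -> one other female
    per_fM <- dv$m[["oF"]] / n_f        # female actor -> one male
    per_mF <- dv$f[["oM"]] / n_m        # male actor -> one female
    per_mM <- dv$m[["oM"]] / (n_m - 1)  # male actor -> one other male
    g_incl <-
      u_f * (dv$f[["self"]] +
             (n_f - 1) * per_fF * rel$r_ff + n_m * per_fM * rel$r_fm) +
      u_m * (dv$m[["self"]] +
             (n_m - 1) * per_mM * rel$r_mm + n_f * per_mF * rel$r_mf)
    if (is.finite(g_nm)) expect_equal(g_incl, g_nm, tolerance = 1e-8)
  }
})

test_that("origin-ignorant gradient is the mean of the origin classes", {
  for (p in list(protection_params(0.7), mating_params(0.3))) {
    res <- sleep_strategy("parent_of_origin", z_mat = 0.4, z_pat = 0.7)
    g <- selection_gradient(res, p,
                            actor_class = c("z_mat", "z_pat", "z_naive"))
    expect_equal(unname(g[["z_naive"]]),
                 unname((g[["z_mat"]] + g[["z_pat"]]) / 2),
                 tolerance = 1e-10)
  }
})

test_that("Hamilton decomposition reconstructs the gradient exactly", {
  for (p in list(protection_params(), mating_params())) {
    for (z in c(0.3, 0.6, 0.9)) {
      h <- hamilton_decomposition(z, p)
      g <- unname(selection_gradient(z, p))
      expect_equal(-h$C + h$B * h$r_eff, g, tolerance = 1e-8)
    }
  }
})

test_that("sleeping more is selfish under protection, altruistic under mating", {
  hp <- hamilton_decomposition(0.9, protection_params())
  expect_lt(hp$C, 0); expect_lt(hp$B, 0)
  expect_identical(hp$classification, "selfish_sleep")
  hm <- hamilton_decomposition(0.55, mating_params())
  expect_gt(hm$C, 0); expect_gt(hm$B, 0)
  expect_identical(hm$classification, "altruistic_sleep")
})
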