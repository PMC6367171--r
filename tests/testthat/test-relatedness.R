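test_that("co-natal probability covers the dispersal limits", {
  p <- panel_params(a = 0, c_f = 0, c_m = 0, d_f = 0, d_m = 0, d_B = 0)
  expect_equal(conatal_probability("f", "m", p), 1)

  p <- panel_params(a = 0, c_f = 0, c_m = 0, d_f = 1, d_m = 1, d_B = 0)
  expect_equal(conatal_probability("f", "f", p), 0)

  p <- panel_params(a = 0, c_f = 0, c_m = 0, d_f = 1, d_m = 1, d_B = 1)
  expect_equal(conatal_probability("m", "m", p), 1)

  p <- panel_params(a = 0, c_f = 0, c_m = 0, d_f = 0.3, d_m = 0.6, d_B = 0.5)
  expect_equal(conatal_probability("f", "m", p),
               0.7 * 0.4 + 0.3 * 0.6 * 0.5)
})

test_that("full independent mixing gives zero relatedness and inbreeding", {
  p <- panel_params(a = 1, c_f = 0, c_m = 0, d_f = 1, d_m = 1, d_B = 0)
  cons <- solve_consanguinities(p)
  expect_lt(max(abs(c(cons$Q_ff, cons$Q_mm, cons$Q_fm, cons$F_f))), 1e-10)
  rel <- relatedness_coefficients(cons)
  expect_lt(max(abs(c(rel$r_ff, rel$r_mm, rel$r_fm))), 1e-10)
  expect_equal(rel$r_f, 1 / 8)   # only self remains in the group average
})

test_that("a fully closed lineage fixes identity by descent", {
  p <- sleep_params(d_f = 0, d_m = 0, d_B = 0, n_f = 1, n_m = 1, m = 0,
                    b_f = 1, b_m = 1, a = 0, c_f = 0, c_m = 0)
  cons <- solve_consanguinities(p)
  expect_equal(cons$Q_fm, 1, tolerance = 1e-9)
  expect_equal(cons$F_f, 1, tolerance = 1e-9)
})

test_that("self-consanguinity and origin-mean identities hold exactly", {
  for (d_f in c(0.2, 0.8)) {
    cons <- solve_consanguinities(protection_params(d_f))
    expect_equal(cons$Q_self_f, (1 + cons$F_f) / 2)
    rel <- relatedness_coefficients(cons)
    expect_equal(rel$r_f, (rel$r_mat_f + rel$r_pat_f) / 2)
    expect_equal(rel$r_m, (rel$r_mat_m + rel$r_pat_m) / 2)
    expect_equal(rel$r_ff, (rel$r_ff_mat + rel$r_ff_pat) / 2)
  }
})

test_that("unbiased dispersal with equal sex numbers removes origin asymmetry", {
  for (d in c(0.25, 0.6)) {
    rel <- patch_relatedness(panel_params(a = 1, c_f = 0, c_m = 0,
                                          d_f = d, d_m = d, d_B = 0.5))
    expect_lt(abs(rel$r_mat_f - rel$r_pat_f), 1e-10)
    expect_lt(abs(rel$r_mat_m - rel$r_pat_m), 1e-10)
    expect_lt(abs(rel$r_f - rel$r_m), 1e-10)
  }
})

test_that("female-biased dispersal orders sexes and parental origins", {
  rel <- patch_relatedness(protection_params(d_f = 0.8))
  expect_lt(rel$r_f, rel$r_m)          # females less related to the group
  expect_gt(rel$r_pat_f, rel$r_mat_f)  # paternal-origin relatedness higher
  expect_gt(rel$r_pat_m, rel$r_mat_m)
})

test_that("consanguinities decrease in each dispersal rate without budding", {
  grid <- seq(0, 1, length.out = 11)
  qff <- qmm <- qfm <- numeric(length(grid))
  for (i in seq_along(grid)) {
    cons <- solve_consanguinities(
      panel_params(a = 1, c_f = 0, c_m = 0, d_f = grid[i], d_m = 0.2,
                   d_B = 0))
    qff[i] <- cons$Q_ff; qmm[i] <- cons$Q_mm; qfm[i] <- cons$Q_fm
  }
  expect_true(all(diff(qff) <= 1e-12))
  expect_true(all(diff(qmm) <= 1e-12))
  expect_true(all(diff(qfm) <= 1e-12))
  for (i in seq_along(grid)) {
    cons <- solve_consanguinities(
      panel_params(a = 1, c_f = 0, c_m = 0, d_f = 0.2, d_m = grid[i],
                   d_B = 0))
    qmm[i] <- cons$Q_mm
  }
  expect_true(all(diff(qmm) <= 1e-12))
})

test_that("the pedigree oracle reproduces classical outbred values", {
  # well-mixed population: parent-offspring consanguinity 1/4 is the
  # juvenile-level share through each parent; between distinct adults
  # everything vanishes, and inbreeding is zero
  p <- panel_params(a = 0, c_f = 0, c_m = 0, d_f = 1, d_m = 1, d_B = 0)
  orc <- pedigree_oracle(p, n_patches = 600, generations = 120, seed = 7,
                         burn_in = 60, sample_every = 20)
  expect_lt(abs(orc$est[["Q_ff"]]), 3 * orc$se[["Q_ff"]] + 1e-12)
  expect_lt(abs(orc$est[["F"]]), 3 * orc$se[["F"]] + 1e-12)
})

test_that("analytic consanguinities match a small pedigree simulation", {
  p <- sleep_params(d_f = 0.5, d_m = 0, d_B = 1, n_f = 4, n_m = 4,
                    m = 0.05, b_f = 1, b_m = 1, a = 1, c_f = 0, c_m = 0)
  cons <- solve_consanguinities(p)
  orc <- pedigree_oracle(p, n_patches = 800, generations = 160, seed = 11,
                         burn_in = 80, sample_every = 20)
  cmp <- compare_oracle(cons, orc)
  expect_true(all(cmp$z <= 3))
})

test_that("relatedness serialises with parameter provenance", {
  rel <- patch_relatedness(protection_params(0.4))
  path <- tempfile(fileext = ".json")
  write_relatedness_json(rel, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$values$r_f, rel$r_f, tolerance = 1e-12)
  expect_equal(back$params$d_f, 0.4)
})
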