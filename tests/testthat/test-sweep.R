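test_that("sweep specs validate the swept parameter and grid", {
  p <- protection_params()
  expect_error(sweep_spec(p, "monomorphic", swept = "q"), "not a model")
  expect_error(sweep_spec(p, "monomorphic", grid = c(0, 1.5)), "d_f")
  s <- sweep_spec(p, "monomorphic", grid = seq(0, 1, length.out = 5))
  expect_s3_class(s, "sweep_spec")
})

test_that("the four qualitative panel shapes hold on coarse grids", {
  grid <- seq(0, 1, length.out = 11)
  t1a <- sweep_optima(sweep_spec(preset_params("fig1a")$params,
                                 "monomorphic", grid = grid))
  expect_identical(unname(attr(t1a, "monotonicity")["z"]), "non-decreasing")
  t1b <- sweep_optima(sweep_spec(preset_params("fig1b")$params,
                                 "monomorphic", grid = grid))
  expect_identical(unname(attr(t1b, "monotonicity")["z"]), "non-increasing")
  t2a <- sweep_optima(sweep_spec(preset_params("fig2a")$params,
                                 "sex_specific", grid = grid))
  ok <- !is.na(t2a$z_f)
  expect_true(all(t2a$z_f[ok] >= t2a$z_m[ok] - 1e-8))
  t2b <- sweep_optima(sweep_spec(preset_params("fig2b")$params,
                                 "sex_specific", grid = grid))
  ok <- !is.na(t2b$z_f)
  expect_true(all(abs(t2b$z_f[ok] - 1) < 1e-8))
})

test_that("relatedness columns ride along and agree with the solver", {
  tab <- sweep_optima(sweep_spec(protection_params(), "monomorphic",
                                 grid = c(0.2, 0.8)))
  rel <- patch_relatedness(protection_params(0.8))
  expect_equal(tab$r_f[2], rel$r_f, tolerance = 1e-12)
  expect_equal(tab$r_pat_m[2], rel$r_pat_m, tolerance = 1e-12)
})

test_that("sweep tables round-trip through CSV", {
  tab <- sweep_optima(sweep_spec(preset_params("fig3b")$params,
                                 "parent_of_origin",
                                 grid = c(0.3, 0.6, 0.9)))
  path <- tempfile(fileext = ".csv")
  write_table_csv(tab, path)
  back <- utils::read.csv(path)
  expect_equal(back$z_mat, tab$z_mat, tolerance = 1e-12)
  expect_identical(back$scenario, tab$scenario)
})

test_that("prediction table is complete, consistent and swap-symmetric", {
  mk <- function(a, c_f, c_m, d_f = 0.5, d_m = 0) {
    panel_params(a = a, c_f = c_f, c_m = c_m, d_f = d_f, d_m = d_m)
  }
  tab <- figure4_table(mk(1, 0, 0), mk(0, 1, 1))
  expect_identical(nrow(tab), 24L)
  expect_identical(sort(unique(tab$perturbation)), sort(perturbation_kinds()))
  # silenced-allele deletions never change the phenotype
  silenced_del <- (tab$perturbation == "deletion_maternal" &
                   tab$silenced_allele == "maternal") |
                  (tab$perturbation == "deletion_paternal" &
                   tab$silenced_allele == "paternal")
  expect_true(all(tab$phenotype[silenced_del] == "unchanged"))
  # male-biased dispersal swaps every maternal/paternal entry
  tabM <- figure4_table(mk(1, 0, 0, d_f = 0, d_m = 0.5),
                        mk(0, 1, 1, d_f = 0, d_m = 0.5))
  swap <- function(x) ifelse(x == "maternal", "paternal",
                             ifelse(x == "paternal", "maternal", x))
  expect_identical(tabM$expressed_allele, swap(tab$expressed_allele))
  expect_identical(tabM$silenced_allele, swap(tab$silenced_allele))
  # per 6-row block: deletions and UPDs swap partners, epimutations keep
  # their outcome (they act on "the expressed/silenced allele" whichever
  # parent that is)
  idx <- as.vector(vapply(0:3, function(b) b * 6L + c(2L, 1L, 3L, 4L, 6L, 5L),
                          integer(6)))
  expect_identical(tabM$phenotype, tab$phenotype[idx])
  # scenario guardrails
  expect_error(figure4_table(mk(0, 1, 1), mk(0, 1, 1)), "protection")
})
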