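test_that("purely beneficial sleep drives every mode to full sleep", {
  p <- panel_params(a = 0, c_f = 0, c_m = 0)
  for (mode in c("monomorphic", "sex_specific", "parent_of_origin")) {
    o <- solve_optimum(p, mode)
    vals <- o$z_star[strategy_classes(mode)]
    expect_true(all(abs(vals - 1) < 1e-9), info = mode)
    expect_true(all(o$stable[strategy_classes(mode)]))
  }
})

test_that("interior monomorphic optima are genuine stable roots", {
  for (p in list(protection_params(0.5), mating_params(0.5))) {
    o <- solve_optimum(p, "monomorphic")
    z <- o$z_star[["z"]]
    expect_identical(o$solutions[[1]]$boundary[["z"]], "interior")
    expect_true(o$stable[["z"]])
    expect_lt(abs(unname(selection_gradient(z, p))), 1e-7)
    # gradient decreasing through the root
    expect_gt(unname(selection_gradient(z - 1e-3, p)), 0)
    expect_lt(unname(selection_gradient(z + 1e-3, p)), 0)
  }
})

test_that("stability checker flags attracting boundaries and interior roots", {
  p <- panel_params(a = 0, c_f = 0, c_m = 0)
  o <- solve_optimum(p, "monomorphic")
  expect_identical(o$solutions[[1]]$boundary[["z"]], "at_1")
  expect_true(check_convergence_stability(o)[[1]][["z"]])
  o2 <- solve_optimum(protection_params(), "monomorphic")
  expect_true(check_convergence_stability(o2)[[1]][["z"]])
})

test_that("a fully closed population has no defined optimum", {
  p <- protection_params(d_f = 0)   # d_m = 0 too: no gene flow at all
  o <- solve_optimum(p, "monomorphic")
  expect_true(is.na(o$z_star[["z"]]))
  expect_identical(o$solutions[[1]]$boundary[["z"]], "neutral")
})

test_that("protection favours more sleep at higher female dispersal", {
  z_lo <- solve_optimum(protection_params(0.1), "monomorphic")$z_star[["z"]]
  z_hi <- solve_optimum(protection_params(0.9), "monomorphic")$z_star[["z"]]
  expect_gt(z_hi, z_lo)
})

test_that("sex-specific solve matches the sex-differences panels", {
  # protection: females (less related) sacrifice less sleep than males
  oa <- solve_optimum(protection_params(0.5), "sex_specific")
  expect_gte(oa$z_star[["z_f"]], oa$z_star[["z_m"]])
  # male-only mating gains: females sleep fully, males sacrifice
  ob <- solve_optimum(panel_params(a = 0, c_f = 0, c_m = 1), "sex_specific")
  expect_equal(ob$z_star[["z_f"]], 1)
  expect_lt(ob$z_star[["z_m"]], 1)
  expect_true(all(ob$stable))
})

test_that("parent-of-origin optima bracket the origin-ignorant gene", {
  for (p in list(protection_params(0.3), protection_params(0.7),
                 mating_params(0.3), mating_params(0.7))) {
    o <- solve_optimum(p, "parent_of_origin")
    v <- o$z_star
    expect_gte(v[["z_naive"]], min(v[["z_mat"]], v[["z_pat"]]) - 1e-8)
    expect_lte(v[["z_naive"]], max(v[["z_mat"]], v[["z_pat"]]) + 1e-8)
  }
})

test_that("origin conflict direction follows the scenario", {
  # female-biased dispersal: relatedness higher through paternal-origin
  # genes; under protection they favour less sleep, under mating more
  oa <- solve_optimum(protection_params(0.5), "parent_of_origin")
  expect_gte(oa$z_star[["z_mat"]], oa$z_star[["z_pat"]])
  ob <- solve_optimum(mating_params(0.5), "parent_of_origin")
  expect_gte(ob$z_star[["z_pat"]], ob$z_star[["z_mat"]])
})

test_that("allelic co-expression escalates toward opposite extremes", {
  esc <- solve_allelic_escalation(mating_params(0.5))
  v <- esc[[1]]$values
  o <- solve_optimum(mating_params(0.5), "parent_of_origin")
  # the tug-of-war spreads the allelic values far beyond the favoured
  # levels of the two classes
  expect_lt(v[["z_mat"]], o$z_star[["z_mat"]])
  expect_gt(v[["z_pat"]], o$z_star[["z_pat"]] - 1e-9)
})

test_that("loudest voice picks the right allele for each locus type", {
  op <- solve_optimum(protection_params(0.5), "parent_of_origin")
  pp <- predict_imprinting(op, "promoter")
  expect_identical(pp$expressed_allele, "maternal")
  expect_identical(pp$silenced_allele, "paternal")
  expect_equal(pp$expression_level, op$z_star[["z_mat"]])
  pi_ <- predict_imprinting(op, "inhibitor")
  expect_identical(pi_$expressed_allele, "paternal")

  om <- solve_optimum(mating_params(0.5), "parent_of_origin")
  expect_identical(predict_imprinting(om, "promoter")$expressed_allele,
                   "paternal")
  expect_identical(predict_imprinting(om, "inhibitor")$expressed_allele,
                   "maternal")
})

test_that("no conflict means no imprinting", {
  o <- solve_optimum(panel_params(a = 1, c_f = 0, c_m = 0, d_f = 0.4,
                                  d_m = 0.4, d_B = 0.3),
                     "parent_of_origin")
  pred <- predict_imprinting(o, "promoter")
  expect_identical(pred$expressed_allele, "both")
  expect_identical(pred$perturbation_phenotypes[["hypo_methylation"]],
                   "unchanged")
  expect_identical(pred$perturbation_phenotypes[["UPD_maternal"]],
                   "unchanged")
  expect_identical(pred$perturbation_phenotypes[["deletion_maternal"]],
                   "less_sleep")
})

test_that("perturbation dosage logic matches independent enumeration", {
  op <- solve_optimum(protection_params(0.5), "parent_of_origin")
  # independent enumeration: track active copies per parental origin
  enumerate <- function(expressed, locus, perturbation, convention) {
    base <- switch(expressed, maternal = c(1, 0), paternal = c(0, 1))
    if (convention == "activation") {
      perturbation <- switch(perturbation,
                             hypo_methylation = "hyper_methylation",
                             hyper_methylation = "hypo_methylation",
                             perturbation)
    }
    active <- switch(perturbation,
      deletion_maternal = base[2],
      deletion_paternal = base[1],
      hypo_methylation = 2,
      hyper_methylation = 0,
      UPD_maternal = 2 * base[1],
      UPD_paternal = 2 * base[2])
    d <- active - sum(base)
    if (d == 0) "unchanged"
    else if ((d > 0) == (locus == "promoter")) "more_sleep"
    else "less_sleep"
  }
  for (locus in c("promoter", "inhibitor")) {
    for (conv in c("silencing", "activation")) {
      pred <- predict_imprinting(op, locus, methylation_convention = conv)
      for (k in perturbation_kinds()) {
        expect_identical(
          predict_perturbation(pred, k),
          enumerate(pred$expressed_allele, locus, k, conv),
          info = paste(locus, conv, k))
      }
    }
  }
  expect_error(predict_perturbation(predict_imprinting(op, "promoter"),
                                    "inversion"), "unknown perturbation")
})

test_that("methylation conventions swap the epimutation outcomes only", {
  op <- solve_optimum(mating_params(0.5), "parent_of_origin")
  sil <- predict_imprinting(op, "promoter", "silencing")
  act <- predict_imprinting(op, "promoter", "activation")
  expect_identical(sil$perturbation_phenotypes[["hypo_methylation"]],
                   act$perturbation_phenotypes[["hyper_methylation"]])
  expect_identical(sil$perturbation_phenotypes[["hyper_methylation"]],
                   act$perturbation_phenotypes[["hypo_methylation"]])
  same <- setdiff(perturbation_kinds(),
                  c("hypo_methylation", "hyper_methylation"))
  expect_identical(sil$perturbation_phenotypes[same],
                   act$perturbation_phenotypes[same])
})
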