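#' Convergence-stable sleep optima
#'
#' Finds the convergence-stable resident strategies of the model for a
#' given trait architecture. For the monomorphic mode the selection
#' gradient is evaluated on a uniform grid over the strategy space
#' `[m, 1]` (1001 points), sign changes are bracketed and refined by
#' bisection to `1e-10`, and a boundary is assigned when no interior root
#' attracts (gradient negative at `m`, or positive at 1). For the
#' sex-specific mode, simultaneous zeros are found by damped iterated
#' best response (each class's 1-D root holding the other fixed, damping
#' 0.5) to a fixed point at tolerance `1e-8`, with a multi-start over
#' `{m, (m + 1)/2, 1}` per class to detect multiplicity; all distinct
#' convergence-stable points are reported, sorted.
#'
#' For the parent-of-origin mode, `z_mat*` and `z_pat*` are the levels of
#' sleep *favoured by* the maternal- and paternal-origin gene classes:
#' each class is solved under full phenotypic control (its gradient with
#' a monomorphic resident), which is exactly the state an imprinted locus
#' expressed from that slot evolves to, since after loudest-voice
#' silencing the expressed allele alone sets the phenotype. The optimum
#' of a gene ignorant of its parental origin (`z_naive`, whole-genome
#' relatedness) is solved alongside and lies between the two class
#' optima. The joint best-response dynamics of allelic values under
#' additive co-expression — the escalating tug-of-war that motivates the
#' imprinting resolution — is available separately as
#' [solve_allelic_escalation].
#'
#' @param params A [sleep_params] object.
#' @param mode `"monomorphic"`, `"sex_specific"`, or `"parent_of_origin"`.
#' @param grid_n Grid resolution for 1-D scans (default 1001).
#' @param tol Fixed-point tolerance for best-response iteration.
#' @param max_iter Best-response iteration cap (non-convergence from every
#'   start is an error with diagnostics).
#' @return An object of class `sleep_optimum`: list with `mode`, `params`,
#'   and `solutions` — a list of solutions, each holding `values` (named
#'   sleep levels per class, including `z_naive` for parent-of-origin),
#'   `boundary` (per class: `"interior"`, `"at_m"`, or `"at_1"`), and
#'   `stable` (per-class convergence-stability flags, via
#'   [check_convergence_stability]). The first solution is also exposed as
#'   `z_star` for convenience.
#' @examples
#' p <- preset_params("fig1a", d_f = 0.5)$params
#' solve_optimum(p, "monomorphic")$z_star
#' @export
solve_optimum <- function(params, mode = c("monomorphic", "sex_specific",
                                           "parent_of_origin"),
                          grid_n = 1001, tol = 1e-8, max_iter = 200) {
  stopifnot(inherits(params, "sleep_params"))
  mode <- match.arg(mode)
  rel <- patch_relatedness(params)

  solutions <- switch(mode,
    monomorphic = solve_monomorphic(params, rel, grid_n),
    sex_specific = solve_multiclass(params, rel, mode, grid_n, tol, max_iter),
    parent_of_origin = solve_po_fullcontrol(params, rel, grid_n))
  out <- structure(list(mode = mode, params = params, rel = rel,
                        solutions = solutions,
                        z_star = solutions[[1]]$values),
                   class = "sleep_optimum")
  out$solutions <- lapply(out$solutions, function(s) {
    s$stable <- check_convergence_stability_one(s, out)
    s
  })
  # report convergence-stable points; repellors found by multi-start are
  # dropped unless nothing else was found
  keep <- vapply(out$solutions, function(s) {
    !any(s$stable[strategy_classes(mode)] %in% FALSE)
  }, logical(1))
  if (any(keep)) out$solutions <- out$solutions[keep]
  out$z_star <- out$solutions[[1]]$values
  out$stable <- out$solutions[[1]]$stable
  out
}

# Gradient of one class as a function of its own resident value, all other
# class values held fixed. With full_control = TRUE the class value sets the
# whole resident phenotype (a monomorphic resident): this is the "level
# favoured by" that gene class -- the state an imprinted locus expressed
# from that class's slot evolves to, since the expressed allele then
# controls the entire phenotype.
class_gradient_fn <- function(params, rel, mode, cl, fixed,
                              full_control = FALSE) {
  force(cl)
  # evaluation points stay one finite-difference stencil inside the
  # strategy space: within the margin the fitness expressions would be
  # evaluated at unphysical sleep levels (z > 1 or z < m - h), which next
  # to a degenerate state (e.g. S -> 0 at z = 1 under a = 1) produces
  # arbitrarily wrong values
  margin <- 2e-6
  clamp <- function(z) min(max(z, params$m + margin), 1 - margin)
  if (full_control) {
    return(function(z) {
      res <- sleep_strategy("monomorphic", z = clamp(z))
      unname(selection_gradient(res, params, actor_class = cl, rel = rel))
    })
  }
  function(z) {
    vals <- fixed
    vals[cl] <- clamp(z)
    res <- make_strategy(mode, vals)
    unname(selection_gradient(res, params, actor_class = cl, rel = rel))
  }
}

# Parent-of-origin favoured levels: each origin class solved under full
# phenotypic control, plus the origin-ignorant gene (whole-genome
# relatedness). The classes decouple, so the 1-D scans are independent;
# multiple stable roots per class (rare) yield the cross product.
solve_po_fullcontrol <- function(params, rel, grid_n) {
  classes <- c("z_mat", "z_pat", "z_naive")
  per_class <- lapply(classes, function(cl) {
    g <- class_gradient_fn(params, rel, "parent_of_origin", cl,
                           fixed = NULL, full_control = TRUE)
    scan_roots(g, params$m, grid_n)
  })
  names(per_class) <- classes
  idx <- expand.grid(lapply(per_class, seq_along))
  lapply(seq_len(nrow(idx)), function(k) {
    vals <- vapply(classes, function(cl) {
      per_class[[cl]][[idx[k, cl]]]$z
    }, numeric(1))
    bnd <- vapply(classes, function(cl) {
      per_class[[cl]][[idx[k, cl]]]$boundary
    }, character(1))
    list(values = vals, boundary = bnd,
         stable = stats::setNames(rep(NA, length(classes)), classes))
  })
}

make_strategy <- function(mode, vals) {
  switch(mode,
    monomorphic = sleep_strategy(mode, z = vals[["z"]]),
    sex_specific = sleep_strategy(mode, z_f = vals[["z_f"]],
                                  z_m = vals[["z_m"]]),
    parent_of_origin = sleep_strategy(mode, z_mat = vals[["z_mat"]],
                                      z_pat = vals[["z_pat"]]))
}

# Best response of one class in the direction selection pushes from the
# current value: follow the sign of the gradient to the attractor (an
# interior root or a boundary). This is the attractor gradual evolution
# reaches from the current state; multiplicity is covered by multi-start.
directional_best_response <- function(params, rel, mode, cl, vals, m,
                                      full_control = FALSE) {
  g <- class_gradient_fn(params, rel, mode, cl, vals, full_control)
  eps <- 1e-8
  z <- vals[[cl]]
  gz <- g(z)
  # a non-finite gradient can only come from a degenerate resident state
  # set by the *other* classes (whole-patch phenotype at a lethal corner)
  if (!is.finite(gz)) return(z)
  if (abs(gz) < eps) return(z)  # below the noise floor: no selection here
  dir <- sign(gz)
  bound <- if (dir > 0) 1 else m
  if ((dir > 0 && z >= bound) || (dir < 0 && z <= bound)) return(bound)
  # walk toward the boundary until the gradient changes sign, then refine
  # (g is evaluated on the clamped stencil, so every value is physical)
  x <- z; gx <- gz
  repeat {
    xn <- if (dir > 0) min(x + 0.1, bound) else max(x - 0.1, bound)
    gn <- g(xn)
    if (!is.finite(gn)) return(x)
    if (dir * gn < -eps) {
      lo <- min(x, xn); hi <- max(x, xn)
      return(stats::uniroot(g, c(lo, hi),
                            f.lower = if (dir > 0) gx else gn,
                            f.upper = if (dir > 0) gn else gx,
                            tol = 1e-10)$root)
    }
    if (abs(gn) <= eps) return(xn)          # selection plateau
    if (dir > 0 && xn >= bound - 1e-12) return(bound)
    if (dir < 0 && xn <= bound + 1e-12) return(bound)
    x <- xn; gx <- gn
  }
}

# 1-D solve: attracting roots of g on [m, 1] (sign change + to -), plus
# attracting boundaries. Returns list of list(z, boundary).
scan_roots <- function(g, m, grid_n, eps = 1e-8) {
  zz <- seq(m, 1, length.out = grid_n)
  gv <- vapply(zz, g, numeric(1))
  # sign classification with a noise floor: finite-difference noise is
  # ~1e-10, real selection is orders of magnitude larger; |g| < eps counts
  # as zero. Signed infinities mark degenerate resident states (e.g.
  # S = 0 at z = 1 under a = 1) and carry their sign.
  sg <- integer(grid_n)
  sg[gv > eps] <- 1L
  sg[gv < -eps] <- -1L
  nz <- which(sg != 0L)
  # selection can vanish over the whole strategy space (e.g. a fully
  # closed population, d_f = d_m = 0, where every fate is shared); the
  # bulk of the grid then carries only noise, possibly amplified near a
  # degenerate endpoint, so the test is on the median magnitude
  if (length(nz) == 0L ||
      stats::median(abs(gv[is.finite(gv)])) < eps) {
    return(list(list(z = NA_real_, boundary = "neutral")))
  }
  sols <- list()
  if (length(nz) > 1L) {
    for (k in seq_len(length(nz) - 1L)) {
      i <- nz[k]; j <- nz[k + 1L]
      if (sg[i] == 1L && sg[j] == -1L && is.finite(gv[i]) &&
          is.finite(gv[j])) {
        root <- tryCatch(
          stats::uniroot(g, c(zz[i], zz[j]), f.lower = gv[i],
                         f.upper = gv[j], tol = 1e-10)$root,
          error = function(e) (zz[i] + zz[j]) / 2)
        sols <- c(sols, list(list(z = root, boundary = "interior")))
      }
    }
  }
  if (sg[nz[1L]] == -1L && is.finite(gv[nz[1L]])) {
    sols <- c(sols, list(list(z = m, boundary = "at_m")))
  }
  if (sg[nz[length(nz)]] == 1L && is.finite(gv[nz[length(nz)]])) {
    sols <- c(sols, list(list(z = 1, boundary = "at_1")))
  }
  if (length(sols) == 0L) {
    return(list(list(z = NA_real_, boundary = "neutral")))
  }
  sols[order(vapply(sols, `[[`, numeric(1), "z"))]
}

solve_monomorphic <- function(params, rel, grid_n) {
  g <- class_gradient_fn(params, rel, "monomorphic", "z",
                         c(z = NA_real_))
  sols <- scan_roots(g, params$m, grid_n)
  lapply(sols, function(s) {
    list(values = c(z = s$z), boundary = c(z = s$boundary),
         stable = c(z = NA))
  })
}

solve_multiclass <- function(params, rel, mode, grid_n, tol, max_iter) {
  classes <- strategy_classes(mode)
  m <- params$m
  starts <- expand.grid(rep(list(c(m, (m + 1) / 2, 1)), length(classes)))
  names(starts) <- classes
  best_response <- function(cl, vals) {
    directional_best_response(params, rel, mode, cl, vals, m)
  }

  # configurations with no selection on any class (e.g. a fully closed
  # population, d_f = d_m = 0) have no optimum to report
  mid <- stats::setNames(rep((m + 1) / 2, length(classes)), classes)
  gmag <- unlist(lapply(classes, function(cl) {
    g <- class_gradient_fn(params, rel, mode, cl, mid)
    vapply(seq(m, 1, length.out = 21), g, numeric(1))
  }))
  if (stats::median(abs(gmag[is.finite(gmag)])) < 1e-8) {
    return(list(list(
      values = stats::setNames(rep(NA_real_, length(classes)), classes),
      boundary = stats::setNames(rep("neutral", length(classes)), classes),
      stable = stats::setNames(rep(NA, length(classes)), classes))))
  }

  found <- list()
  diag <- character()
  for (k in seq_len(nrow(starts))) {
    vals <- stats::setNames(as.numeric(starts[k, ]), classes)
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      new_vals <- vals
      for (cl in classes) {
        br <- best_response(cl, new_vals)
        new_vals[cl] <- 0.5 * new_vals[cl] + 0.5 * br
      }
      if (max(abs(new_vals - vals)) < tol) {
        vals <- new_vals
        ok <- TRUE
        break
      }
      vals <- new_vals
    }
    if (!ok) {
      diag <- c(diag, sprintf("start (%s) did not converge in %d iterations",
                              paste(signif(as.numeric(starts[k, ]), 3),
                                    collapse = ", "), max_iter))
      next
    }
    # undamped polish: land each class exactly on its best response
    for (polish in 1:3) {
      for (cl in classes) vals[cl] <- best_response(cl, vals)
    }
    boundary <- vapply(classes, function(cl) {
      if (abs(vals[cl] - m) < 1e-7) "at_m"
      else if (abs(vals[cl] - 1) < 1e-7) "at_1"
      else "interior"
    }, character(1))
    dup <- any(vapply(found, function(f) {
      max(abs(f$values[classes] - vals)) < 1e-6
    }, logical(1)))
    if (!dup) {
      found <- c(found, list(list(values = vals, boundary = boundary,
                                  stable = stats::setNames(
                                    rep(NA, length(classes)), classes))))
    }
  }
  if (length(found) == 0) {
    stop("best-response iteration failed to converge from every start:\n  ",
         paste(diag, collapse = "\n  "), call. = FALSE)
  }
  found[order(vapply(found, function(f) f$values[1], numeric(1)))]
}

#' Escalation equilibrium of parent-of-origin allelic values
#'
#' Under additive, unimprinted expression the phenotype is the mean of the
#' maternal- and paternal-origin allelic values, so when the two classes
#' favour different phenotypes each drags its own allelic value toward its
#' side: maternal- and paternal-origin values escalate in opposite
#' directions until a class's 1-D root (holding the other fixed) or a
#' boundary of the strategy space stops them — the tug-of-war that the
#' loudest-voice-prevails argument resolves into imprinting. This solves
#' that joint system by damped iterated best response with a
#' `{m, (m + 1)/2, 1}^2` multi-start.
#'
#' @inheritParams solve_optimum
#' @return A list of solutions as in [solve_optimum] (values `z_mat`,
#'   `z_pat` of the escalated allelic system; the implied resident
#'   phenotype is their mean).
#' @export
solve_allelic_escalation <- function(params, grid_n = 1001, tol = 1e-8,
                                     max_iter = 200) {
  stopifnot(inherits(params, "sleep_params"))
  rel <- patch_relatedness(params)
  solve_multiclass(params, rel, "parent_of_origin", grid_n, tol, max_iter)
}

#' Convergence stability of solved optima
#'
#' Re-derives the per-class convergence-stability flags of a
#' [solve_optimum] result: an interior class value is convergence stable
#' when the selection gradient decreases through zero in the resident
#' direction (numeric slope, step `1e-4`); a boundary value when the
#' gradient points outward; and for multi-class modes the spectral radius
#' of the numeric best-response Jacobian must be below 1.
#'
#' @param opt A `sleep_optimum`.
#' @param params The generating [sleep_params] (defaults to those stored
#'   in `opt`).
#' @return A list (one element per solution) of named logical vectors, one
#'   flag per class.
#' @export
check_convergence_stability <- function(opt, params = opt$params) {
  stopifnot(inherits(opt, "sleep_optimum"))
  lapply(opt$solutions, check_convergence_stability_one, opt = opt)
}

check_convergence_stability_one <- function(sol, opt, h = 1e-4) {
  params <- opt$params
  rel <- opt$rel
  mode <- opt$mode
  classes <- strategy_classes(mode)
  m <- params$m
  vals <- sol$values
  extra <- setdiff(names(vals), classes)   # z_naive rides along

  full_control <- mode == "parent_of_origin"
  flag_one <- function(cl, all_classes_vals) {
    g <- if (cl == "z_naive" || full_control) {
      class_gradient_fn(params, rel, mode,
                        if (cl == "z_naive" && !full_control) "z" else cl,
                        fixed = NULL, full_control = TRUE)
    } else {
      class_gradient_fn(params, rel, mode, cl, all_classes_vals)
    }
    z <- vals[[cl]]
    b <- sol$boundary[[cl]]
    if (b == "at_m") return(g(m + h) < 0)
    if (b == "at_1") return(g(1 - h) > 0)
    if (b == "neutral") return(NA)
    slope <- (g(min(z + h, 1)) - g(max(z - h, m))) / (min(z + h, 1) -
                                                      max(z - h, m))
    slope < 0
  }

  flags <- vapply(classes, function(cl) flag_one(cl, vals), logical(1))
  for (cl in extra) flags[cl] <- flag_one(cl, vals)

  interior <- classes[sol$boundary[classes] == "interior"]
  if (!full_control && length(interior) >= 2 && all(flags[interior])) {
    # best-response Jacobian: BR_i depends on the other classes only
    br <- function(cl, v) {
      directional_best_response(params, rel, mode, cl, v, m)
    }
    J <- matrix(0, length(interior), length(interior),
                dimnames = list(interior, interior))
    for (j in interior) {
      vp <- vals[classes]; vp[j] <- vals[[j]] + h
      vm_ <- vals[classes]; vm_[j] <- vals[[j]] - h
      for (i in setdiff(interior, j)) {
        J[i, j] <- (br(i, vp) - br(i, vm_)) / (2 * h)
      }
    }
    if (max(abs(eigen(J, only.values = TRUE)$values)) >= 1) {
      flags[interior] <- FALSE
    }
  }
  flags
}

#' @export
print.sleep_optimum <- function(x, ...) {
  cat(sprintf("Convergence-stable sleep optima (%s mode, scenario: %s)\n",
              x$mode, classify_scenario(x$params)))
  for (i in seq_along(x$solutions)) {
    s <- x$solutions[[i]]
    cat(sprintf("  solution %d:\n", i))
    for (cl in names(s$values)) {
      cat(sprintf("    %-8s = %.6f  [%s%s]\n", cl, s$values[[cl]],
                  s$boundary[[cl]],
                  if (isTRUE(s$stable[[cl]])) ", stable"
                  else if (isFALSE(s$stable[[cl]])) ", UNSTABLE" else ""))
    }
  }
  invisible(x)
}

#' Genomic-imprinting prediction from parent-of-origin optima
#'
#' Resolves the intralocus conflict between maternal- and paternal-origin
#' genes by the loudest-voice-prevails principle: at a locus whose
#' expression promotes sleep, the allele favouring *more* sleep silences
#' its homologue and sets expression to its own optimum, so the expressed
#' allele is the parental origin with the larger `z*`; at a locus whose
#' expression inhibits sleep the logic is reversed and the origin with the
#' smaller `z*` is expressed. Equal optima (within `tie_tol`) mean no
#' conflict and both alleles stay expressed.
#'
#' @param opt A `sleep_optimum` solved in `"parent_of_origin"` mode.
#' @param locus_type `"promoter"` (expression increases sleep) or
#'   `"inhibitor"` (expression decreases sleep).
#' @param methylation_convention `"silencing"` (default; methylation
#'   silences, the usual mammalian case) or `"activation"`. Only the
#'   interpretation of epimutations depends on this; see
#'   [predict_perturbation].
#' @param tie_tol Tolerance within which the two optima count as equal.
#' @return An object of class `imprint_prediction`: list with `scenario`,
#'   `dispersal_bias`, `locus_type`, `expressed_allele`
#'   (`"maternal"`, `"paternal"`, or `"both"`), `silenced_allele`,
#'   `methylation_convention`, `z_mat`, `z_pat`, `expression_level` (the
#'   winner's optimum), and `perturbation_phenotypes` (named map over the
#'   six perturbation kinds).
#' @export
predict_imprinting <- function(opt, locus_type = c("promoter", "inhibitor"),
                               methylation_convention = c("silencing",
                                                          "activation"),
                               tie_tol = 1e-8) {
  stopifnot(inherits(opt, "sleep_optimum"))
  if (opt$mode != "parent_of_origin") {
    stop("predict_imprinting needs a parent_of_origin optimum", call. = FALSE)
  }
  locus_type <- match.arg(locus_type)
  methylation_convention <- match.arg(methylation_convention)
  z_mat <- opt$z_star[["z_mat"]]
  z_pat <- opt$z_star[["z_pat"]]
  p <- opt$params
  bias <- if (p$d_f > p$d_m) "female_biased"
          else if (p$d_m > p$d_f) "male_biased" else "unbiased"

  expressed <- if (abs(z_mat - z_pat) <= tie_tol) "both"
    else if (locus_type == "promoter") {
      if (z_mat > z_pat) "maternal" else "paternal"
    } else {
      if (z_mat < z_pat) "maternal" else "paternal"
    }
  silenced <- switch(expressed, maternal = "paternal",
                     paternal = "maternal", both = "none")
  pred <- structure(list(
    scenario = classify_scenario(p),
    dispersal_bias = bias,
    locus_type = locus_type,
    expressed_allele = expressed,
    silenced_allele = silenced,
    methylation_convention = methylation_convention,
    z_mat = z_mat, z_pat = z_pat,
    expression_level = switch(expressed, maternal = z_mat,
                              paternal = z_pat, both = (z_mat + z_pat) / 2),
    params = p
  ), class = "imprint_prediction")
  pred$perturbation_phenotypes <- vapply(perturbation_kinds(),
                                         function(k) {
                                           predict_perturbation(pred, k)
                                         }, character(1))
  pred
}

#' The six perturbation kinds of the prediction table
#' @return Character vector of perturbation names.
#' @export
perturbation_kinds <- function() {
  c("deletion_maternal", "deletion_paternal",
    "hypo_methylation", "hyper_methylation",
    "UPD_maternal", "UPD_paternal")
}

#' Phenotypic direction of a genetic or epigenetic perturbation
#'
#' Applies dosage logic to an imprinting prediction. The unperturbed state
#' carries one expressed and one silenced allele (or two expressed when
#' there is no conflict). A deletion removes an allele together with its
#' expression state; hypo-methylation re-activates silenced alleles and
#' hyper-methylation silences expressed ones (under the silencing
#' convention; under the activation convention the two epimutations swap
#' outcomes); a uniparental disomy replaces the genotype with two copies
#' of one parent's allele, each keeping that allele's epigenetic state.
#' The phenotype direction compares the number of active copies with the
#' unperturbed number: for a sleep promoter, more active copies mean more
#' sleep and fewer mean less; for a sleep inhibitor the map is mirrored.
#'
#' @param pred An `imprint_prediction` from [predict_imprinting].
#' @param perturbation One of [perturbation_kinds()].
#' @return `"more_sleep"`, `"less_sleep"`, or `"unchanged"`.
#' @export
predict_perturbation <- function(pred, perturbation) {
  stopifnot(inherits(pred, "imprint_prediction"))
  if (!perturbation %in% perturbation_kinds()) {
    stop("unknown perturbation kind '", perturbation, "'", call. = FALSE)
  }
  # active-copy counts per parental origin in the unperturbed state
  base <- switch(pred$expressed_allele,
                 maternal = c(mat = 1L, pat = 0L),
                 paternal = c(mat = 0L, pat = 1L),
                 both = c(mat = 1L, pat = 1L))
  carried <- c(mat = 1L, pat = 1L)

  eff <- perturbation
  if (pred$methylation_convention == "activation") {
    eff <- switch(perturbation,
                  hypo_methylation = "hyper_methylation",
                  hyper_methylation = "hypo_methylation",
                  perturbation)
  }
  active <- switch(eff,
    deletion_maternal = sum(base * c(0L, 1L)),
    deletion_paternal = sum(base * c(1L, 0L)),
    hypo_methylation = sum(carried),          # every carried copy active
    hyper_methylation = 0L,                   # every expressed copy silenced
    UPD_maternal = 2L * base[["mat"]],
    UPD_paternal = 2L * base[["pat"]]
  )
  delta <- active - sum(base)
  if (delta == 0) return("unchanged")
  more_expression <- delta > 0
  if (pred$locus_type == "promoter") {
    if (more_expression) "more_sleep" else "less_sleep"
  } else {
    if (more_expression) "less_sleep" else "more_sleep"
  }
}

#' @export
print.imprint_prediction <- function(x, ...) {
  cat(sprintf("Imprinting prediction (%s scenario, %s dispersal, %s locus)\n",
              x$scenario, x$dispersal_bias, x$locus_type))
  cat(sprintf("  optima: z_mat* = %.4f, z_pat* = %.4f\n", x$z_mat, x$z_pat))
  cat(sprintf("  expressed: %s allele; silenced: %s (methylation = %s)\n",
              x$expressed_allele, x$silenced_allele,
              x$methylation_convention))
  for (k in names(x$perturbation_phenotypes)) {
    cat(sprintf("    %-18s -> %s\n", k, x$perturbation_phenotypes[[k]]))
  }
  invisible(x)
}
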