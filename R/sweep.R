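#' Specification of a parameter sweep
#'
#' Describes a one-dimensional sweep of a model parameter (by default the
#' female dispersal rate, as in the standard panels), solving the
#' convergence-stable optima and relatedness at every grid point.
#'
#' @param params Base [sleep_params]; the swept parameter's value in it is
#'   ignored.
#' @param mode Strategy mode to solve at each point.
#' @param swept Name of the swept parameter (a [sleep_params] field).
#' @param grid Numeric grid of swept values (default: 101 points over the
#'   parameter's legal range).
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(params, mode = c("monomorphic", "sex_specific",
                                        "parent_of_origin"),
                       swept = "d_f", grid = seq(0, 1, length.out = 101)) {
  stopifnot(inherits(params, "sleep_params"))
  mode <- match.arg(mode)
  if (!swept %in% names(params)) {
    stop("swept parameter '", swept, "' is not a model parameter",
         call. = FALSE)
  }
  # every grid value must validate in place
  for (v in range(grid)) {
    raw <- unclass(params)
    raw[[swept]] <- v
    validate_params(raw)
  }
  structure(list(params = params, mode = mode, swept = swept, grid = grid),
            class = "sweep_spec")
}

#' Sweep convergence-stable optima along a parameter grid
#'
#' Runs [solve_optimum] along the grid of a [sweep_spec], warm-starting
#' each grid point from the previous solution (full multi-start at the
#' first point), and returns one row per grid point with the optimum per
#' gene class, the group relatedness coefficients, and stability flags.
#' Monotonicity diagnostics (the direction of each optimum column along
#' the grid) are attached as the `"monotonicity"` attribute.
#'
#' @param spec A [sweep_spec].
#' @return A data frame with columns: the swept parameter, `z_*` per class,
#'   `stable_*` flags, `r_f`, `r_m`, `r_mat_f`, `r_pat_f`, `r_mat_m`,
#'   `r_pat_m`, and a `scenario` column.
#' @export
sweep_optima <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  mode <- spec$mode
  classes <- switch(mode,
                    monomorphic = "z",
                    sex_specific = c("z_f", "z_m"),
                    parent_of_origin = c("z_mat", "z_pat", "z_naive"))
  prev <- NULL
  rows <- vector("list", length(spec$grid))
  for (i in seq_along(spec$grid)) {
    raw <- unclass(spec$params)
    raw[[spec$swept]] <- spec$grid[i]
    p <- validate_params(raw)
    sol <- tryCatch(
      sweep_point(p, mode, classes, prev),
      error = function(e) {
        stop(sprintf("sweep failed at %s = %g: %s", spec$swept,
                     spec$grid[i], conditionMessage(e)), call. = FALSE)
      })
    prev <- sol$values
    rel <- sol$rel
    rows[[i]] <- data.frame(
      swept = spec$grid[i],
      as.list(stats::setNames(sol$values[classes], paste0("", classes))),
      as.list(stats::setNames(as.logical(sol$stable[classes]),
                              paste0("stable_", classes))),
      r_f = rel$r_f, r_m = rel$r_m,
      r_mat_f = rel$r_mat_f, r_pat_f = rel$r_pat_f,
      r_mat_m = rel$r_mat_m, r_pat_m = rel$r_pat_m,
      scenario = classify_scenario(p))
  }
  out <- do.call(rbind, rows)
  names(out)[1] <- spec$swept
  mono <- vapply(classes, function(cl) {
    # neutral grid points (no selection, z* undefined) are skipped
    d <- diff(out[[cl]][!is.na(out[[cl]])])
    if (isTRUE(all(d >= -1e-9))) "non-decreasing"
    else if (isTRUE(all(d <= 1e-9))) "non-increasing"
    else "non-monotone"
  }, character(1))
  attr(out, "monotonicity") <- mono
  out
}

# One grid point: warm-started when prev is available.
sweep_point <- function(params, mode, classes, prev) {
  rel <- patch_relatedness(params)
  m <- params$m
  if (is.null(prev) || any(!is.finite(prev))) {
    o <- solve_optimum(params, mode)
    return(list(values = o$z_star, stable = o$stable, rel = rel))
  }
  if (mode == "monomorphic") {
    z <- directional_best_response(params, rel, mode, "z",
                                   c(z = unname(prev["z"])), m)
    vals <- c(z = z)
  } else if (mode == "parent_of_origin") {
    vals <- vapply(classes, function(cl) {
      directional_best_response(params, rel, "parent_of_origin", cl,
                                stats::setNames(prev[cl], cl), m,
                                full_control = TRUE)
    }, numeric(1))
  } else {
    vals <- prev[classes]
    for (it in 1:60) {
      new_vals <- vals
      for (cl in classes) {
        new_vals[cl] <- directional_best_response(params, rel, mode, cl,
                                                  new_vals, m)
      }
      if (max(abs(new_vals - vals)) < 1e-8) { vals <- new_vals; break }
      vals <- new_vals
    }
  }
  boundary <- vapply(classes, function(cl) {
    if (is.na(vals[cl])) "neutral"
    else if (abs(vals[cl] - m) < 1e-7) "at_m"
    else if (abs(vals[cl] - 1) < 1e-7) "at_1" else "interior"
  }, character(1))
  opt <- structure(list(mode = mode, params = params, rel = rel),
                   class = "sleep_optimum")
  sol <- list(values = vals, boundary = boundary,
              stable = stats::setNames(rep(NA, length(classes)), classes))
  sol$stable <- check_convergence_stability_one(sol, opt)
  list(values = vals, stable = sol$stable, rel = rel)
}

#' The genomic-imprinting prediction table
#'
#' Enumerates the predictions of the loudest-voice resolution for both
#' selective scenarios, both locus types, and all six perturbation kinds:
#' 2 scenarios x 2 locus types x 6 perturbations = 24 rows, with the
#' expressed and silenced alleles and the qualitative sleep phenotype of
#' each perturbation.
#'
#' @param params_protection A [sleep_params] of the protection scenario.
#' @param params_mating A [sleep_params] of the mating-competition
#'   scenario.
#' @param methylation_convention `"silencing"` (default) or
#'   `"activation"`; see [predict_perturbation].
#' @return A data frame with columns `scenario`, `bias`, `locus_type`,
#'   `expressed_allele`, `silenced_allele`, `perturbation`, `phenotype`,
#'   in stable order.
#' @export
figure4_table <- function(params_protection, params_mating,
                          methylation_convention = "silencing") {
  stopifnot(inherits(params_protection, "sleep_params"),
            inherits(params_mating, "sleep_params"))
  if (classify_scenario(params_protection) != "protection") {
    stop("params_protection is not a protection scenario", call. = FALSE)
  }
  if (classify_scenario(params_mating) != "mating_competition") {
    stop("params_mating is not a mating_competition scenario",
         call. = FALSE)
  }
  rows <- list()
  for (sc in c("protection", "mating_competition")) {
    p <- if (sc == "protection") params_protection else params_mating
    opt <- solve_optimum(p, "parent_of_origin")
    for (lt in c("promoter", "inhibitor")) {
      pred <- predict_imprinting(opt, lt,
                                 methylation_convention =
                                   methylation_convention)
      for (k in perturbation_kinds()) {
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = sc,
          bias = pred$dispersal_bias,
          locus_type = lt,
          expressed_allele = pred$expressed_allele,
          silenced_allele = pred$silenced_allele,
          perturbation = k,
          phenotype = pred$perturbation_phenotypes[[k]])
      }
    }
  }
  do.call(rbind, rows)
}

#' Write a sweep or prediction table as CSV
#'
#' Plain RFC-4180 CSV with a header row; [read.csv] round-trips it.
#'
#' @param x A data frame (e.g. from [sweep_optima] or [figure4_table]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
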