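#' Night survival of a patch's brood
#'
#' A patch's entire offspring production survives the night with probability
#' \deqn{S = 1 - a (1 - V),}
#' where `V` is the mean wakefulness of the patch's `n_f + n_m` adults and
#' `a` is the threat level. Full collective vigilance (`V = 1`) guarantees
#' survival; a fully asleep patch survives with probability `1 - a`.
#'
#' @param mean_wakefulness Mean adult wakefulness `V` in `[0, 1]`.
#' @param params A [sleep_params] object.
#' @return Survival probability `S`.
#' @export
group_survival <- function(mean_wakefulness, params) {
  stopifnot(inherits(params, "sleep_params"))
  1 - params$a * (1 - mean_wakefulness)
}

#' Competitive weight components of an adult
#'
#' Sleep and wakefulness act on reproduction through two distinct channels.
#' Sleeping a fraction `z` of the night earns the *viability* benefit
#' \deqn{v_x(z) = b_x z}
#' (an absolute factor multiplying the offspring production credited to a
#' parent of sex `x`; when `b_x = 0` there are no viability differences and
#' the factor is 1). Sacrificing sleep earns the *contest* weight
#' \deqn{w_x(z) = (1 - c_x) + c_x (1 - z) = 1 - c_x z,}
#' a relative mating/fecundity weight contested among same-sex patchmates:
#' `c_x` is the fraction of mating opportunities decided by nighttime
#' effort, with the remainder awarded independently of sleep. A female's
#' share of the patch's fecundity is proportional to her contest weight,
#' and a male's paternity share is his contest weight divided by the summed
#' weight of the patch's males. With `c_x = 0` all shares are equal; with
#' `c_x = 1` shares are fully proportional to wakefulness, so a sleeping
#' individual cedes all contested matings.
#'
#' @param z Sleep level(s).
#' @param sex `"f"` or `"m"`.
#' @param params A [sleep_params] object.
#' @param component `"viability"` (default) or `"contest"`.
#' @return Non-negative weight(s).
#' @export
competitive_weight <- function(z, sex, params,
                               component = c("viability", "contest")) {
  stopifnot(inherits(params, "sleep_params"))
  sex <- match.arg(sex, c("f", "m"))
  component <- match.arg(component)
  b <- if (sex == "f") params$b_f else params$b_m
  cc <- if (sex == "f") params$c_f else params$c_m
  if (component == "viability") {
    if (b > 0) b * z else rep(1, length(z))
  } else {
    1 - cc * z
  }
}

#' Sleep strategies by gene class
#'
#' A resident strategy under one of three trait architectures:
#' `"monomorphic"` (one sleep level `z` expressed by everyone),
#' `"sex_specific"` (levels `z_f`, `z_m` expressed by females and males),
#' or `"parent_of_origin"` (allelic values `z_mat`, `z_pat` conditioned on
#' parental origin; under unimprinted additive expression an individual's
#' phenotype is the mean of its two allelic values).
#'
#' @param mode `"monomorphic"`, `"sex_specific"`, or `"parent_of_origin"`.
#' @param z,z_f,z_m,z_mat,z_pat Sleep levels for the classes the mode uses.
#' @return An object of class `sleep_strategy`.
#' @export
sleep_strategy <- function(mode = c("monomorphic", "sex_specific",
                                    "parent_of_origin"),
                           z = NULL, z_f = NULL, z_m = NULL,
                           z_mat = NULL, z_pat = NULL) {
  mode <- match.arg(mode)
  values <- switch(mode,
    monomorphic = c(z = z),
    sex_specific = c(z_f = z_f, z_m = z_m),
    parent_of_origin = c(z_mat = z_mat, z_pat = z_pat))
  if (length(values) != length(strategy_classes(mode))) {
    stop("mode '", mode, "' requires values for: ",
         paste(strategy_classes(mode), collapse = ", "), call. = FALSE)
  }
  structure(list(mode = mode, values = values), class = "sleep_strategy")
}

#' Gene classes of a strategy mode
#' @param mode A strategy mode.
#' @return Character vector of class names.
#' @export
strategy_classes <- function(mode) {
  switch(mode,
         monomorphic = "z",
         sex_specific = c("z_f", "z_m"),
         parent_of_origin = c("z_mat", "z_pat"),
         stop("unknown mode '", mode, "'", call. = FALSE))
}

# Phenotypes (female, male) implied by a resident strategy.
resolve_phenotypes <- function(strategy) {
  v <- strategy$values
  switch(strategy$mode,
    monomorphic = c(f = unname(v["z"]), m = unname(v["z"])),
    sex_specific = c(f = unname(v["z_f"]), m = unname(v["z_m"])),
    parent_of_origin = {
      ph <- unname((v["z_mat"] + v["z_pat"]) / 2)
      c(f = ph, m = ph)
    })
}

# The direct-fitness kernel. Returns a function W(sex, z_self, z_oF, z_oM)
# giving the reproductive-value-weighted expected number of breeding
# offspring of a focal adult, normalised so the resident value is exactly 1.
# z_oF / z_oM are the common sleep levels of the focal's patchmates of each
# sex (excluding the focal itself); the resident phenotypes come from the
# strategy the kernel is built for.
#
# Structure: brood survival S = 1 - a(1 - V) scales the whole patch's
# offspring mass. Female i takes fecundity share prop. to her contest
# weight w_f(z_i) of the patch's production, scaled by her viability factor
# v_f(z_i); fathers are drawn per contest share w_m(z_j)/sum, and each
# father's brood is scaled by his viability v_m(z_j). Offspring of sex x
# stay home with probability 1 - d_x and compete for the natal patch's n_x
# slots against its philopatric juveniles plus an immigrant mass d_x D_r
# from the resident world; with probability d_x d_B they leave in the
# patch's bud, which takes over the entire immigration of a single resident
# patch (co-bud juveniles, mass d_x D, compete against that patch's
# philopatric mass (1 - d_x) D_r); with probability d_x (1 - d_B) they
# scatter into patches whose juvenile competition is entirely resident,
# mass D_r.
fitness_kernel <- function(params, resident) {
  p <- params
  n_f <- p$n_f; n_m <- p$n_m
  ph <- resolve_phenotypes(resident)
  z_rF <- ph[["f"]]; z_rM <- ph[["m"]]

  vf <- function(z) if (p$b_f > 0) p$b_f * z else 1
  vm <- function(z) if (p$b_m > 0) p$b_m * z else 1
  wf <- function(z) 1 - p$c_f * z
  wm <- function(z) 1 - p$c_m * z

  V_r <- (n_f * (1 - z_rF) + n_m * (1 - z_rM)) / (n_f + n_m)
  S_r <- 1 - p$a * (1 - V_r)
  D_r <- (S_r / 2) * n_f * vf(z_rF) * vm(z_rM)  # resident juvenile mass/sex

  v_f <- 1 / (2 * n_f)
  v_m <- 1 / (2 * n_m)

  function(sex, z_self, z_oF, z_oM) {
    if (sex == "f") {
      females <- c(z_self, rep(z_oF, n_f - 1))
      males <- rep(z_oM, n_m)
      wake <- sum(1 - females) + sum(1 - males)
    } else {
      females <- rep(z_oF, n_f)
      males <- c(z_self, rep(z_oM, n_m - 1))
      wake <- sum(1 - females) + sum(1 - males)
    }
    V <- wake / (n_f + n_m)
    S <- 1 - p$a * (1 - V)

    # all-zero contest weights (c = 1, everyone fully asleep): shares are
    # uniform in that limit
    w_F <- wf(females); sum_wF <- sum(w_F)
    if (sum_wF <= 0) { w_F <- rep(1, n_f); sum_wF <- n_f }
    w_M <- wm(males);   sum_wM <- sum(w_M)
    if (sum_wM <= 0) { w_M <- rep(1, n_m); sum_wM <- n_m }
    fec <- vf(females) * n_f * w_F / sum_wF      # per-female fecundity
    Phi_m <- sum(w_M * vm(males)) / sum_wM       # mean paternal viability
    D <- (S / 2) * sum(fec) * Phi_m              # focal-patch mass per sex

    route <- function(d_x, n_x) {
      C_home <- (1 - d_x) * D + d_x * D_r
      C_bud  <- (1 - d_x) * D_r + d_x * D
      C_scat <- D_r
      (1 - d_x) * n_x / C_home +
        d_x * (p$d_B * n_x / C_bud + (1 - p$d_B) * n_x / C_scat)
    }
    P_f <- route(p$d_f, n_f)
    P_m <- route(p$d_m, n_m)

    own <- if (sex == "f") {
      (S / 2) * fec[1] * Phi_m
    } else {
      (S / 2) * sum(fec) * w_M[1] * vm(z_self) / sum_wM
    }
    n_x <- if (sex == "f") n_f else n_m
    n_x * (v_f * own * P_f + v_m * own * P_m)
  }
}

#' Expected fitness of a focal adult
#'
#' Expected number of offspring of a focal adult that secure adult breeding
#' slots, weighted by offspring-class reproductive value (`v_f = 1/(2 n_f)`
#' per daughter slot, `v_m = 1/(2 n_m)` per son slot, so each sex class
#' carries total reproductive value 1/2) and normalised so that the value at
#' the resident strategy is exactly 1. Combines the focal's
#' fecundity/paternity share and viability ([competitive_weight]), night
#' survival of the natal brood ([group_survival], the focal's own
#' wakefulness included), dispersal routing via `d_f`, `d_m`, `d_B`, and
#' slot competition on every destination patch against natives and
#' immigrants whose natal patches play the resident strategy.
#'
#' @param focal_sex `"f"` or `"m"`.
#' @param z_self The focal's own sleep level.
#' @param z_patch_f,z_patch_m Common sleep level of the focal's *other*
#'   patchmates of each sex (defaults: the resident phenotype).
#' @param resident A [sleep_strategy] (or a single number, taken as a
#'   monomorphic resident).
#' @param params A [sleep_params] object.
#' @return Expected reproductive-value-weighted offspring count (resident
#'   value 1).
#' @examples
#' p <- preset_params("fig1a", d_f = 0.5)$params
#' expected_fitness("f", 0.5, resident = 0.5, params = p)  # exactly 1
#' @export
expected_fitness <- function(focal_sex, z_self, z_patch_f = NULL,
                             z_patch_m = NULL, resident, params) {
  stopifnot(inherits(params, "sleep_params"))
  if (is.numeric(resident)) {
    resident <- sleep_strategy("monomorphic", z = resident)
  }
  ph <- resolve_phenotypes(resident)
  if (is.null(z_patch_f)) z_patch_f <- ph[["f"]]
  if (is.null(z_patch_m)) z_patch_m <- ph[["m"]]
  W <- fitness_kernel(params, resident)
  W(match.arg(focal_sex, c("f", "m")), z_self, z_patch_f, z_patch_m)
}

# Marginal effects of each actor role on each recipient sex's normalised
# fitness, by central finite differences of the kernel (step h).
# Roles: self (the focal's own level), oF (common level of the focal's
# other female patchmates -- n_f - 1 of them for a female focal, n_f for a
# male focal; the derivative w.r.t. the common value already carries that
# multiplicity), oM likewise for males.
fitness_derivatives <- function(params, resident, h = 1e-6) {
  ph <- resolve_phenotypes(resident)
  zf <- ph[["f"]]; zm <- ph[["m"]]
  W <- fitness_kernel(params, resident)
  cd <- function(f) (f(h) - f(-h)) / (2 * h)
  list(
    f = c(self = cd(function(e) W("f", zf + e, zf, zm)),
          oF   = cd(function(e) W("f", zf, zf + e, zm)),
          oM   = cd(function(e) W("f", zf, zf, zm + e))),
    m = c(self = cd(function(e) W("m", zm + e, zf, zm)),
          oF   = cd(function(e) W("m", zm, zf + e, zm)),
          oM   = cd(function(e) W("m", zm, zf, zm + e)))
  )
}

# Degenerate resident states: no surviving resident brood mass. Happens
# when a = 1 and everyone is fully asleep (night survival S_r = 0; any
# wakeful deviant sweeps, gradient -Inf) or when m = 0, b > 0 and the
# resident sleeps z = 0 (zero viability; any sleeping deviant sweeps,
# gradient +Inf).
degenerate_gradient <- function(params, resident) {
  p <- params
  ph <- resolve_phenotypes(resident)
  n_f <- p$n_f; n_m <- p$n_m
  V_r <- (n_f * (1 - ph[["f"]]) + n_m * (1 - ph[["m"]])) / (n_f + n_m)
  S_r <- 1 - p$a * (1 - V_r)
  if (S_r <= 1e-12) return(-Inf)
  via <- (if (p$b_f > 0) p$b_f * ph[["f"]] else 1) *
         (if (p$b_m > 0) p$b_m * ph[["m"]] else 1)
  if (via <= 1e-12) return(Inf)
  NULL
}

#' Selection gradient on each gene class
#'
#' Inclusive-fitness selection gradient for the gene classes of a resident
#' strategy, assembled by the direct-fitness (neighbour-modulated) method:
#' marginal effects of every actor role on the focal's fitness (central
#' finite differences of [expected_fitness], step `h`), weighted by the
#' relatedness of the focal's class-specific gene to that role and by class
#' reproductive values (each sex totals 1/2). Parent-of-origin classes
#' weight partners by the relatedness computed through the focal's
#' maternal- or paternal-origin gene ([relatedness_coefficients]). These
#' are the exact allele-lineage coefficients once silent-slot gene copies
#' are accounted for: a copy of an origin-conditional (or imprinted)
#' allele that currently sits in the slot where it is not expressed still
#' experiences selection through its correlation with expressed copies —
#' in its own carrier (probability `F`) and in patchmates (the partner's
#' expressed-slot consanguinity); averaging over the two slots a lineage
#' occupies gives self weight 1 and partner weight `r_mat` (or `r_pat`)
#' exactly, because the slot-resolved consanguinity matrix is symmetric.
#' The same weights therefore govern an imprinted locus expressed from
#' that slot, which is how the individual-based simulator checks them.
#' The pseudo-class `"z_naive"` (a gene ignorant of its origin) uses
#' whole-genome relatedness, the mean of the two origin classes, so its
#' gradient is the exact mean of the class gradients.
#'
#' @param resident A [sleep_strategy] (or a single number, taken as
#'   monomorphic).
#' @param params A [sleep_params] object.
#' @param actor_class Gene class(es) to evaluate; default: all classes of
#'   the resident's mode. In `parent_of_origin` mode the pseudo-class
#'   `"z_naive"` (a gene ignorant of its origin) may also be requested.
#' @param rel A precomputed `relatedness_set` for `params` (computed if
#'   missing).
#' @param h Finite-difference step (default `1e-6`).
#' @return Named numeric vector of gradients, one per requested class.
#' @export
selection_gradient <- function(resident, params, actor_class = NULL,
                               rel = NULL, h = 1e-6) {
  stopifnot(inherits(params, "sleep_params"))
  if (is.numeric(resident)) {
    resident <- sleep_strategy("monomorphic", z = resident)
  }
  classes <- actor_class
  if (is.null(classes)) classes <- strategy_classes(resident$mode)
  ok <- c("z", "z_f", "z_m", "z_mat", "z_pat", "z_naive")
  if (!all(classes %in% ok)) {
    stop("actor_class must be among: ", paste(ok, collapse = ", "),
         call. = FALSE)
  }
  dg <- degenerate_gradient(params, resident)
  if (!is.null(dg)) return(stats::setNames(rep(dg, length(classes)), classes))
  if (is.null(rel)) rel <- patch_relatedness(params)
  dv <- fitness_derivatives(params, resident, h = h)
  n_f <- params$n_f; n_m <- params$n_m
  u_f <- n_f / (n_f + n_m); u_m <- n_m / (n_f + n_m)

  # bracket(x): sum over roles of marginal fitness effect x relatedness,
  # for a focal of sex x whose class gene carries weight w_self on its own
  # phenotype and weights wF / wM to a random other patch female / male.
  bracket <- function(sex, w_self, wF, wM) {
    d <- dv[[sex]]
    w_self * d[["self"]] + wF * d[["oF"]] + wM * d[["oM"]]
  }

  grad_one <- function(cl) {
    switch(cl,
      z = u_f * bracket("f", 1, rel$r_ff, rel$r_fm) +
          u_m * bracket("m", 1, rel$r_mf, rel$r_mm),
      z_f = u_f * bracket("f", 1, rel$r_ff, 0) +
            u_m * bracket("m", 0, rel$r_mf, 0),
      z_m = u_m * bracket("m", 1, 0, rel$r_mm) +
            u_f * bracket("f", 0, 0, rel$r_fm),
      z_mat = 0.5 * (u_f * bracket("f", 1, rel$r_ff_mat, rel$r_fm_mat) +
                     u_m * bracket("m", 1, rel$r_fm_mat, rel$r_mm_mat)),
      z_pat = 0.5 * (u_f * bracket("f", 1, rel$r_ff_pat, rel$r_fm_pat) +
                     u_m * bracket("m", 1, rel$r_fm_pat, rel$r_mm_pat)),
      z_naive = 0.5 * (u_f * bracket("f", 1, rel$r_ff, rel$r_fm) +
                       u_m * bracket("m", 1, rel$r_mf, rel$r_mm))
    )
  }
  vapply(stats::setNames(classes, classes), grad_one, numeric(1))
}

#' Hamilton's-rule decomposition of selection on sleep
#'
#' Splits the selection gradient on a monomorphic sleep level into the
#' marginal direct cost and the relatedness-weighted indirect benefit of
#' *sleeping more*: `C` is the loss of the actor's own fitness
#' (`-C` = marginal effect of the actor's sleep on its own fitness), `B`
#' the summed marginal effect on all patch recipients, and `r_eff` the
#' effective relatedness weighting those recipients, so that the gradient
#' is `-C + B * r_eff` exactly. At an interior optimum the two terms
#' cancel, forcing sleeping more to be either selfish (`C < 0`, `B < 0`)
#' or altruistic (`C > 0`, `B > 0`).
#'
#' @param z Monomorphic resident sleep level.
#' @param params A [sleep_params] object.
#' @param rel Optional precomputed `relatedness_set`.
#' @param h Finite-difference step.
#' @param tol Magnitude below which `C` and `B` are treated as zero for
#'   classification.
#' @return An object of class `hamilton_decomposition`: list with `C`, `B`,
#'   `r_eff`, `gradient` (`= -C + B * r_eff`), and `classification`
#'   (`"selfish_sleep"`, `"altruistic_sleep"`, `"neutral"`, or `"mixed"`).
#' @export
hamilton_decomposition <- function(z, params, rel = NULL, h = 1e-6,
                                   tol = 1e-9) {
  stopifnot(inherits(params, "sleep_params"))
  resident <- sleep_strategy("monomorphic", z = z)
  if (is.null(rel)) rel <- patch_relatedness(params)
  dv <- fitness_derivatives(params, resident, h = h)
  n_f <- params$n_f; n_m <- params$n_m
  u_f <- n_f / (n_f + n_m); u_m <- n_m / (n_f + n_m)

  direct <- u_f * dv$f[["self"]] + u_m * dv$m[["self"]]
  B <- u_f * (dv$f[["oF"]] + dv$f[["oM"]]) +
       u_m * (dv$m[["oF"]] + dv$m[["oM"]])
  Br <- u_f * (dv$f[["oF"]] * rel$r_ff + dv$f[["oM"]] * rel$r_fm) +
        u_m * (dv$m[["oF"]] * rel$r_mf + dv$m[["oM"]] * rel$r_mm)
  C <- -direct
  r_eff <- if (abs(B) > tol) Br / B else NA_real_
  classification <-
    if (abs(C) <= tol && abs(B) <= tol) "neutral"
    else if (C < 0 && B < 0) "selfish_sleep"
    else if (C > 0 && B > 0) "altruistic_sleep"
    else "mixed"
  structure(list(C = C, B = B, r_eff = r_eff,
                 gradient = -C + if (is.na(r_eff)) 0 else B * r_eff,
                 classification = classification, z = z, params = params),
            class = "hamilton_decomposition")
}

#' @export
print.hamilton_decomposition <- function(x, ...) {
  cat(sprintf("Hamilton decomposition at z = %g\n", x$z))
  cat(sprintf("  -C = %+.6g (direct), B = %+.6g, r_eff = %.6g\n",
              -x$C, x$B, x$r_eff))
  cat(sprintf("  gradient -C + B r = %+.6g; sleeping more is %s\n",
              x$gradient, x$classification))
  invisible(x)
}
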