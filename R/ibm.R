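#' Configuration for the individual-based simulator
#'
#' @param n_patches Number of patches (at least 2).
#' @param generations Number of generations to simulate.
#' @param seed Integer seed (mandatory; a run is bit-identical for a given
#'   seed and configuration).
#' @param expression_mode Trait architecture and expression:
#'   `"monomorphic"` (one locus, additive, expressed in both sexes),
#'   `"sex_specific"` (one locus with a female-expressed and a
#'   male-expressed component), `"parent_of_origin"` (allele carries a
#'   maternal-role and a paternal-role component, additive unimprinted
#'   expression: phenotype is the mean of the maternal-slot allele's
#'   maternal component and the paternal-slot allele's paternal
#'   component), `"maternal_expressed"` / `"paternal_expressed"`
#'   (imprinted: phenotype is the expressed slot's component alone).
#' @param mutation_rate Mutation probability per allele component per
#'   transmission.
#' @param mutation_sd Standard deviation of the Gaussian mutational step
#'   (reflected into `[m, 1]`).
#' @param burn_in Generations excluded from equilibrium summaries
#'   (default: half the run).
#' @param record_every Thinning interval for the recorded trajectory.
#' @param z0 Initial allelic value(s): a single number, or one per class
#'   component. Default: midpoint of the strategy space.
#' @param brood_mean Expected offspring per unit fecundity per female
#'   before regulation (Poisson mean is `brood_mean` times the female's
#'   fecundity times the patch's mean paternal viability).
#' @return An object of class `ibm_config`.
#' @export
ibm_config <- function(n_patches, generations, seed,
                       expression_mode = c("monomorphic", "sex_specific",
                                           "parent_of_origin",
                                           "maternal_expressed",
                                           "paternal_expressed"),
                       mutation_rate = 0.01, mutation_sd = 0.02,
                       burn_in = floor(generations / 2), record_every = 10,
                       z0 = NULL, brood_mean = 10) {
  expression_mode <- match.arg(expression_mode)
  stopifnot(n_patches >= 2, generations >= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            burn_in < generations, record_every >= 1, brood_mean > 0)
  if (mutation_rate > 0 && mutation_sd <= 0) {
    stop("mutation_sd must be > 0 when mutation_rate > 0", call. = FALSE)
  }
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  structure(list(n_patches = as.integer(n_patches),
                 generations = as.integer(generations),
                 seed = as.numeric(seed),
                 expression_mode = expression_mode,
                 mutation_rate = mutation_rate, mutation_sd = mutation_sd,
                 burn_in = as.integer(burn_in),
                 record_every = as.integer(record_every),
                 z0 = z0, brood_mean = brood_mean),
            class = "ibm_config")
}

ibm_mode_int <- function(expression_mode) {
  match(expression_mode, c("monomorphic", "sex_specific",
                           "parent_of_origin", "maternal_expressed",
                           "paternal_expressed")) - 1L
}

ibm_class_names <- function(expression_mode) {
  switch(expression_mode,
         monomorphic = "z",
         sex_specific = c("z_f", "z_m"),
         c("z_mat", "z_pat"))
}

#' Run the individual-based simulator
#'
#' Stochastic simulation of the full tribe-splitting life cycle with
#' evolving diploid sleep alleles: nightly brood destruction with
#' probability `1 - S`, fecundity- and contest-weighted reproduction,
#' Mendelian inheritance with Gaussian mutation, sex-specific dispersal
#' with budding (a patch's dispersers travel together with probability
#' `d_B` and then take over the immigration of a single destination
#' patch), and uniform regulation to `n_f + n_m` adults per patch
#' (patches short of candidates refill from the global juvenile pool).
#' Deterministic given `config$seed`.
#'
#' @param params A [sleep_params] object.
#' @param config An [ibm_config] object.
#' @return An object of class `ibm_result`: list with `trajectory` (a
#'   data frame: `generation`, one column per allelic class mean, and the
#'   mean expressed phenotype per sex), `params`, and `config`.
#' @seealso [summarize_ibm] for equilibrium means with Monte-Carlo errors.
#' @export
run_ibm <- function(params, config) {
  stopifnot(inherits(params, "sleep_params"), inherits(config, "ibm_config"))
  mode <- ibm_mode_int(config$expression_mode)
  k <- if (config$expression_mode == "monomorphic") 1L else 2L
  z0 <- config$z0
  if (is.null(z0)) z0 <- (params$m + 1) / 2
  if (length(z0) == 1L) z0 <- rep(z0, k)
  if (length(z0) != k || any(z0 < params$m) || any(z0 > 1)) {
    stop("z0 must supply ", k, " value(s) within [m, 1]", call. = FALSE)
  }
  res <- ibm_run_cpp(unclass(params), config$n_patches, config$generations,
                     config$mutation_rate, config$mutation_sd,
                     mode, as.numeric(z0), config$brood_mean,
                     config$record_every, config$seed)
  traj <- as.data.frame(res$trajectory)
  names(traj) <- c(ibm_class_names(config$expression_mode),
                   "phen_f", "phen_m")
  traj <- cbind(generation = seq_len(nrow(traj)) * config$record_every,
                traj)
  structure(list(trajectory = traj, params = params, config = config),
            class = "ibm_result")
}

#' Equilibrium summaries of an IBM run
#'
#' Post-burn-in time averages of every recorded column, with
#' autocorrelation-corrected Monte-Carlo standard errors by the method of
#' batch means (20 batches; a warning is recorded when fewer than 20
#' post-burn-in records are available).
#'
#' @param result An `ibm_result` from [run_ibm].
#' @param burn_in Generations to discard (default: the config's burn-in).
#' @return An object of class `ibm_summary`: data frame with `class`,
#'   `mean`, `se`, `n_records`, plus a `warnings` attribute.
#' @export
summarize_ibm <- function(result, burn_in = result$config$burn_in) {
  stopifnot(inherits(result, "ibm_result"))
  traj <- result$trajectory
  if (burn_in >= max(traj$generation)) {
    stop("burn_in must be smaller than the number of generations",
         call. = FALSE)
  }
  keep <- traj$generation > burn_in
  cols <- setdiff(names(traj), "generation")
  n <- sum(keep)
  warn <- character()
  n_batch <- 20L
  if (n < n_batch) {
    warn <- c(warn, sprintf(
      "only %d post-burn-in records; batch-means SE uses %d batches", n,
      max(2L, n)))
    n_batch <- max(2L, n)
  }
  batch <- cut(seq_len(n), breaks = n_batch, labels = FALSE)
  out <- do.call(rbind, lapply(cols, function(cl) {
    x <- traj[[cl]][keep]
    bm <- tapply(x, batch, mean)
    se <- stats::sd(bm) / sqrt(length(bm))
    data.frame(class = cl, mean = mean(x), se = se, n_records = n)
  }))
  attr(out, "warnings") <- warn
  class(out) <- c("ibm_summary", class(out))
  out
}

#' Neutral pedigree oracle for the identity-by-descent recursions
#'
#' Simulates the exact neutral life cycle (the [run_ibm] engine with
#' selection switched off: uniform mother and father draws, fixed brood
#' sizes, no night-time brood destruction, no mutation) while tracking
#' allele labels that are unique at founding, and estimates the stationary
#' within-patch identity-by-descent probabilities. Within-patch identity
#' is normalised by the measured between-patch background,
#' `(Q_w - Q_b) / (1 - Q_b)`: lineages that escape their patch behave as
#' random global lineages, so this removes the finite-metapopulation
#' background that an infinite-island recursion sets to zero. Standard
#' errors come from the spread across widely spaced sample generations.
#'
#' @param params A [sleep_params] object.
#' @param n_patches Number of patches (default 2000; at least 1000
#'   recommended).
#' @param generations Horizon (default 260).
#' @param seed Integer seed (required).
#' @param burn_in Generations before sampling starts (default 110).
#' @param sample_every Spacing between sample generations (default 25;
#'   wide spacing keeps samples near-independent).
#' @param brood_per_sex Juveniles produced per patch and sex before
#'   regulation (default 40).
#' @return An object of class `pedigree_oracle`: list with `est` and `se`
#'   (named vectors over `Q_ff`, `Q_mm`, `Q_fm`, their `_mat`/`_pat`
#'   origin components, the slot-resolved categories `ff_mm`, ...,
#'   `F`), `n_samples`, `between` (the raw background level), and the
#'   generating parameters.
#' @export
pedigree_oracle <- function(params, n_patches = 2000, generations = 260,
                            seed, burn_in = 110, sample_every = 25,
                            brood_per_sex = 40) {
  stopifnot(inherits(params, "sleep_params"), n_patches >= 2,
            burn_in < generations)
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  raw <- ibm_neutral_cpp(unclass(params), as.integer(n_patches),
                         as.integer(generations), as.integer(burn_in),
                         as.integer(sample_every),
                         as.integer(brood_per_sex), as.numeric(seed))
  s <- raw$samples
  qb <- s[, "between"]
  norm <- (s[, setdiff(colnames(s), "between"), drop = FALSE] - qb) /
    (1 - qb)

  derived <- cbind(
    Q_ff = rowMeans(norm[, c("ff_mm", "ff_mp", "ff_pm", "ff_pp"),
                         drop = FALSE]),
    Q_mm = rowMeans(norm[, c("mm_mm", "mm_mp", "mm_pm", "mm_pp"),
                         drop = FALSE]),
    Q_fm = rowMeans(norm[, c("fm_mm", "fm_mp", "fm_pm", "fm_pp"),
                         drop = FALSE]),
    Q_ff_mat = rowMeans(norm[, c("ff_mm", "ff_mp"), drop = FALSE]),
    Q_ff_pat = rowMeans(norm[, c("ff_pm", "ff_pp"), drop = FALSE]),
    Q_mm_mat = rowMeans(norm[, c("mm_mm", "mm_mp"), drop = FALSE]),
    Q_mm_pat = rowMeans(norm[, c("mm_pm", "mm_pp"), drop = FALSE]),
    Q_fm_mat = rowMeans(norm[, c("fm_mm", "fm_mp"), drop = FALSE]),
    Q_fm_pat = rowMeans(norm[, c("fm_pm", "fm_pp"), drop = FALSE]),
    norm
  )
  est <- colMeans(derived)
  se <- apply(derived, 2, stats::sd) / sqrt(nrow(derived))
  structure(list(est = est, se = se, n_samples = nrow(derived),
                 between = mean(qb), params = params,
                 config = list(n_patches = n_patches,
                               generations = generations, seed = seed,
                               burn_in = burn_in,
                               sample_every = sample_every,
                               brood_per_sex = brood_per_sex)),
            class = "pedigree_oracle")
}

#' @export
print.pedigree_oracle <- function(x, ...) {
  cat(sprintf(
    "Pedigree-oracle IBD estimates (%d patches, %d samples, bg %.2g)\n",
    x$config$n_patches, x$n_samples, x$between))
  for (nm in c("Q_ff", "Q_mm", "Q_fm", "F")) {
    cat(sprintf("  %-5s = %.5f +/- %.5f\n", nm, x$est[[nm]], x$se[[nm]]))
  }
  invisible(x)
}

#' Compare analytic consanguinities with the pedigree oracle
#'
#' @param cons A `consanguinity_set` from [solve_consanguinities].
#' @param oracle A `pedigree_oracle` for the same parameters.
#' @return Data frame with one row per compared quantity: analytic value,
#'   oracle estimate, Monte-Carlo SE, and the absolute z-score.
#' @export
compare_oracle <- function(cons, oracle) {
  stopifnot(inherits(cons, "consanguinity_set"),
            inherits(oracle, "pedigree_oracle"))
  slot_flat <- function(M) c(M["mat", "mat"], M["mat", "pat"],
                             M["pat", "mat"], M["pat", "pat"])
  analytic <- c(
    Q_ff = cons$Q_ff, Q_mm = cons$Q_mm, Q_fm = cons$Q_fm,
    Q_ff_mat = cons$Q_ff_mat, Q_ff_pat = cons$Q_ff_pat,
    Q_mm_mat = cons$Q_mm_mat, Q_mm_pat = cons$Q_mm_pat,
    Q_fm_mat = cons$Q_fm_mat, Q_fm_pat = cons$Q_fm_pat,
    setNames(slot_flat(cons$Q_slot$ff), c("ff_mm", "ff_mp", "ff_pm", "ff_pp")),
    setNames(slot_flat(cons$Q_slot$mm), c("mm_mm", "mm_mp", "mm_pm", "mm_pp")),
    setNames(slot_flat(cons$Q_slot$fm), c("fm_mm", "fm_mp", "fm_pm", "fm_pp")),
    F = cons$F_f
  )
  nm <- names(analytic)
  data.frame(quantity = nm,
             analytic = unname(analytic),
             oracle = unname(oracle$est[nm]),
             se = unname(oracle$se[nm]),
             z = abs(unname(analytic) - unname(oracle$est[nm])) /
               pmax(unname(oracle$se[nm]), 1e-12))
}
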