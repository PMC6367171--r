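#' Model parameters for the tribe-splitting sleep model
#'
#' Constructs and validates the full parameter vector of the group-structured
#' (island) model of sleep evolution with sex-biased and budding dispersal.
#' The population consists of infinitely many patches, each holding `n_f`
#' adult females and `n_m` adult males. Each adult sleeps a fraction
#' `z` of the night, constrained to the interval `[m, 1]`; wakefulness
#' `1 - z` contributes to group vigilance against a night threat of level
#' `a`, and to sex-specific mating/fecundity gains `c_f`, `c_m`, while sleep
#' itself carries direct benefits `b_f`, `b_m`. Offspring disperse with
#' sex-specific probabilities `d_f`, `d_m`; with probability `d_B` all
#' dispersers leaving a patch travel together as a single bud ("tribe
#' splitting"), otherwise they scatter independently.
#'
#' @param d_f Probability of female natal dispersal, in `[0, 1]`.
#' @param d_m Probability of male natal dispersal, in `[0, 1]`.
#' @param d_B Budding-dispersal probability in `[0, 1]`: probability that the
#'   dispersers leaving one patch travel together to a common destination.
#' @param n_f Number of adult females per patch (integer, at least 1).
#' @param n_m Number of adult males per patch (integer, at least 1).
#' @param m Minimum feasible sleep level, in `[0, 1)`. The strategy space for
#'   any sleep level is the closed interval `[m, 1]`.
#' @param b_f,b_m Benefit-of-sleep coefficients (finite, non-negative):
#'   fecundity (females) or mating weight (males) gained per unit of sleep.
#' @param a Night-threat level in `[0, 1]`. A patch's brood survives the night
#'   with probability `1 - a * (1 - V)` where `V` is mean adult wakefulness.
#' @param c_f,c_m Mating-opportunity gain from sleep sacrifice (finite,
#'   non-negative): fecundity (females) or mating weight (males) gained per
#'   unit of wakefulness.
#'
#' @return An object of class `sleep_params`: a named list of the validated
#'   parameters.
#'
#' @examples
#' p <- sleep_params(d_f = 0.5, d_m = 0, d_B = 1, n_f = 4, n_m = 4,
#'                   m = 0.05, b_f = 1, b_m = 1, a = 1, c_f = 0, c_m = 0)
#' classify_scenario(p)
#' @export
sleep_params <- function(d_f, d_m, d_B, n_f, n_m, m, b_f, b_m, a, c_f, c_m) {
  validate_params(list(d_f = d_f, d_m = d_m, d_B = d_B, n_f = n_f, n_m = n_m,
                       m = m, b_f = b_f, b_m = b_m, a = a, c_f = c_f,
                       c_m = c_m))
}

.param_names <- c("d_f", "d_m", "d_B", "n_f", "n_m", "m",
                  "b_f", "b_m", "a", "c_f", "c_m")

#' Validate a raw mapping of model parameters
#'
#' Checks presence, type and range of every model parameter and returns a
#' validated [sleep_params] object. Errors name the offending field and the
#' violated bound.
#'
#' @param raw Named list or named numeric vector supplying every parameter of
#'   [sleep_params].
#' @return A validated `sleep_params` object.
#' @export
validate_params <- function(raw) {
  raw <- as.list(raw)
  missing <- setdiff(.param_names, names(raw))
  if (length(missing) > 0L) {
    stop("missing model parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  p <- lapply(raw[.param_names], function(x) as.numeric(x)[1L])

  chk <- function(name, ok, what) {
    if (!is.finite(p[[name]]) || !ok(p[[name]])) {
      stop(sprintf("parameter %s = %s is invalid: must be %s",
                   name, format(raw[[name]]), what), call. = FALSE)
    }
  }
  for (nm in c("d_f", "d_m", "d_B", "a")) {
    chk(nm, function(x) x >= 0 && x <= 1, "a probability in [0, 1]")
  }
  for (nm in c("n_f", "n_m")) {
    chk(nm, function(x) x >= 1 && x == round(x), "an integer >= 1")
    p[[nm]] <- as.integer(round(p[[nm]]))
  }
  chk("m", function(x) x >= 0 && x < 1, "in [0, 1)")
  for (nm in c("b_f", "b_m")) {
    chk(nm, function(x) x >= 0, "finite and >= 0")
  }
  # c is the fraction of mating opportunities contested by night effort
  for (nm in c("c_f", "c_m")) {
    chk(nm, function(x) x >= 0 && x <= 1, "in [0, 1]")
  }
  structure(p, class = "sleep_params")
}

#' @export
print.sleep_params <- function(x, ...) {
  cat("Tribe-splitting sleep model parameters\n")
  cat(sprintf("  dispersal:  d_f = %g, d_m = %g, budding d_B = %g\n",
              x$d_f, x$d_m, x$d_B))
  cat(sprintf("  patch size: n_f = %d females, n_m = %d males\n",
              x$n_f, x$n_m))
  cat(sprintf("  sleep:      minimum m = %g, benefits b_f = %g, b_m = %g\n",
              x$m, x$b_f, x$b_m))
  cat(sprintf("  wakefulness: threat a = %g, mating gains c_f = %g, c_m = %g\n",
              x$a, x$c_f, x$c_m))
  cat(sprintf("  scenario:   %s\n", classify_scenario(x)))
  invisible(x)
}

#' Classify the selective scenario of a parameter set
#'
#' Labels a parameter set by the social force acting on sleep:
#' `"protection"` when only the night threat is active (`a > 0`,
#' `c_f = c_m = 0`; sleep sacrifice buys group vigilance),
#' `"mating_competition"` when only mating gains are active (`a = 0`,
#' `c_f > 0` or `c_m > 0`; sleep sacrifice buys matings),
#' `"neutral"` when neither is active, and `"mixed"` otherwise.
#'
#' @param params A [sleep_params] object.
#' @return A character scalar, one of `"protection"`,
#'   `"mating_competition"`, `"mixed"`, `"neutral"`.
#' @export
classify_scenario <- function(params) {
  stopifnot(inherits(params, "sleep_params"))
  threat <- params$a > 0
  mating <- params$c_f > 0 || params$c_m > 0
  if (threat && !mating) "protection"
  else if (!threat && mating) "mating_competition"
  else if (!threat && !mating) "neutral"
  else "mixed"
}

#' Read model parameters from a YAML or JSON config file
#'
#' The config is a flat key-value mapping using the model's parameter names
#' (`d_f`, `d_m`, `d_B`, `n_f`, `n_m`, `m`, `b_f`, `b_m`, `a`, `c_f`, `c_m`).
#' Format is chosen by file extension (`.json` vs `.yaml`/`.yml`); anything
#' else is tried as YAML, which is a superset of flat JSON.
#'
#' @param path Path to the config file.
#' @return A validated [sleep_params] object.
#' @export
read_params <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_params(raw)
}

#' Write model parameters as canonical JSON
#'
#' Writes a flat JSON object with alphabetically sorted keys, so that
#' `read_params(write_params(p))` round-trips exactly.
#'
#' @param params A [sleep_params] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "sleep_params"))
  x <- unclass(params)[order(names(params))]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# Figure-default parameter presets. All panels share d_m = 0, d_B = 1,
# n_f = n_m = 4, m = 0.05, b_f = b_m = 1 and sweep d_f; panels differ in the
# threat level a and the mating gains c_f, c_m.
.preset_table <- list(
  fig1a = list(a = 1, c_f = 0, c_m = 0, mode = "monomorphic"),
  fig1b = list(a = 0, c_f = 1, c_m = 1, mode = "monomorphic"),
  fig2a = list(a = 1, c_f = 0, c_m = 0, mode = "sex_specific"),
  fig2b = list(a = 0, c_f = 0, c_m = 1, mode = "sex_specific"),
  fig3a = list(a = 1, c_f = 0, c_m = 0, mode = "parent_of_origin"),
  fig3b = list(a = 0, c_f = 1, c_m = 1, mode = "parent_of_origin")
)

#' Named parameter presets for the standard model panels
#'
#' Returns the parameter set (and associated strategy mode) used by the
#' standard panels of the model: a protection panel (`a = 1`, no mating
#' gains) and a mating-competition panel (`a = 0`) for each of the
#' monomorphic (`fig1a`, `fig1b`), sex-specific (`fig2a`, `fig2b`) and
#' parent-of-origin (`fig3a`, `fig3b`) strategy modes. All presets use
#' `d_m = 0`, `d_B = 1`, `n_f = n_m = 4`, `m = 0.05`, `b_f = b_m = 1`, with
#' the female dispersal rate `d_f` free to be swept.
#'
#' @param name Preset name: one of `"fig1a"`, `"fig1b"`, `"fig2a"`,
#'   `"fig2b"`, `"fig3a"`, `"fig3b"`.
#' @param d_f Female dispersal rate to plug in (default 0.5).
#' @return A list with elements `params` (a [sleep_params]) and `mode`
#'   (the strategy mode the panel is solved under).
#' @export
preset_params <- function(name, d_f = 0.5) {
  if (!name %in% names(.preset_table)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(.preset_table), collapse = ", "), call. = FALSE)
  }
  e <- .preset_table[[name]]
  list(params = sleep_params(d_f = d_f, d_m = 0, d_B = 1, n_f = 4, n_m = 4,
                             m = 0.05, b_f = 1, b_m = 1, a = e$a,
                             c_f = e$c_f, c_m = e$c_m),
       mode = e$mode)
}
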