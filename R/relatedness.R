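#' Probability that two same-patch adults share a natal patch
#'
#' Under the tribe-splitting life cycle, two distinct adults of sexes `x` and
#' `y` breeding on the same patch derive from the same natal patch if both
#' stayed home, or if both dispersed and their dispersers travelled together
#' as a bud:
#' \deqn{\phi_{xy} = (1 - d_x)(1 - d_y) + d_x d_y d_B.}
#' Co-natal pairs carry the natal-patch consanguinity of two random
#' juveniles; all other pairs are unrelated (infinite-island assumption).
#'
#' @param sex_x,sex_y `"f"` or `"m"`, the sexes of the two adults.
#' @param params A [sleep_params] object.
#' @return The co-natal probability, a number in `[0, 1]`.
#' @export
conatal_probability <- function(sex_x, sex_y, params) {
  stopifnot(inherits(params, "sleep_params"))
  d <- c(f = params$d_f, m = params$d_m)
  dx <- d[[match.arg(sex_x, c("f", "m"))]]
  dy <- d[[match.arg(sex_y, c("f", "m"))]]
  (1 - dx) * (1 - dy) + dx * dy * params$d_B
}

#' Solve the neutral identity-by-descent recursions
#'
#' Computes the stationary consanguinity (identity-by-descent, IBD)
#' structure of the tribe-splitting life cycle at neutrality. The state is
#' four adult-level probabilities: `A_ff`, `A_mm`, `A_fm`, the IBD
#' probability between random homologous genes of two distinct same-patch
#' adults (female-female, male-male, female-male), and `F`, the inbreeding
#' coefficient (IBD between an adult's own two gene copies).
#'
#' One generation maps adults to adults as follows. Two distinct juveniles
#' born on the same patch share a mother with probability `1/n_f` and a
#' father with probability `1/n_m` (mothers uniform among the patch's
#' females, fathers drawn independently and uniformly among its males at
#' neutrality). Conditioning the two sampled genes on their parental origin
#' (maternal-origin slot inherited from the mother, paternal-origin slot
#' from the father) gives the juvenile-level, origin-resolved
#' consanguinities
#' \deqn{G^{mm} = (1/n_f)(1+F)/2 + (1 - 1/n_f) A_{ff},}
#' \deqn{G^{pp} = (1/n_m)(1+F)/2 + (1 - 1/n_m) A_{mm},}
#' \deqn{G^{mp} = G^{pm} = A_{fm},}
#' because a parent transmits a random one of its two genes, so e.g. both
#' maternal-origin genes are random genes of the two mothers. Adults of the
#' next generation are random juveniles of their natal patch, co-natal with
#' probability [conatal_probability], so `A'_xy = phi_xy * G` with
#' `G = (G_mm + G_pp + 2 G_mp) / 4`, and the new inbreeding coefficient is
#' `F' = A_fm` (an offspring's two genes are random genes of a same-patch
#' female and male). The system is linear and is solved by damped Jacobi
#' iteration (damping 0.5) to within `tol`.
#'
#' @param params A [sleep_params] object.
#' @param tol Convergence tolerance on the maximum absolute update
#'   (default `1e-12`).
#' @param max_iter Iteration cap; exceeding it signals an error since the
#'   system is contractive.
#' @return An object of class `consanguinity_set`: a list with the adult
#'   pair consanguinities `Q_ff`, `Q_mm`, `Q_fm` (whole-genome), their
#'   origin components `Q_ff_mat`, `Q_ff_pat`, ... (focal's maternal- or
#'   paternal-origin gene versus a random gene of the partner), the fully
#'   slot-resolved matrices `Q_slot` (a 2x2 matrix per pair type, rows =
#'   focal origin, columns = partner origin), inbreeding coefficients
#'   `F_f`, `F_m`, self-consanguinities `Q_self_f`, `Q_self_m`
#'   `= (1 + F)/2`, the co-natal probabilities `phi`, iteration count, and
#'   the generating parameters.
#' @export
solve_consanguinities <- function(params, tol = 1e-12, max_iter = 1e6) {
  stopifnot(inherits(params, "sleep_params"), tol > 0)
  n_f <- params$n_f
  n_m <- params$n_m
  phi <- c(ff = conatal_probability("f", "f", params),
           mm = conatal_probability("m", "m", params),
           fm = conatal_probability("f", "m", params))

  # state: A_ff, A_mm, A_fm, F
  x <- c(0, 0, 0, 0)
  step <- function(x) {
    A_ff <- x[1]; A_mm <- x[2]; A_fm <- x[3]; F <- x[4]
    Qs <- (1 + F) / 2
    G_mm <- Qs / n_f + (1 - 1 / n_f) * A_ff
    G_pp <- Qs / n_m + (1 - 1 / n_m) * A_mm
    G <- (G_mm + G_pp + 2 * A_fm) / 4
    c(phi[["ff"]] * G, phi[["mm"]] * G, phi[["fm"]] * G, A_fm)
  }
  iter <- 0L
  repeat {
    x_new <- 0.5 * x + 0.5 * step(x)
    iter <- iter + 1L
    if (max(abs(x_new - x)) < tol) {
      x <- x_new
      break
    }
    x <- x_new
    if (iter >= max_iter) {
      stop("consanguinity recursion failed to converge after ", max_iter,
           " iterations; this indicates a kernel bug", call. = FALSE)
    }
  }

  A_ff <- x[1]; A_mm <- x[2]; A_fm <- x[3]; F <- x[4]
  Qs <- (1 + F) / 2
  G_mm <- Qs / n_f + (1 - 1 / n_f) * A_ff
  G_pp <- Qs / n_m + (1 - 1 / n_m) * A_mm
  G_mp <- A_fm

  slot <- function(p) {
    matrix(p * c(G_mm, G_mp, G_mp, G_pp), 2, 2, byrow = TRUE,
           dimnames = list(focal = c("mat", "pat"),
                           partner = c("mat", "pat")))
  }
  Q_slot <- list(ff = slot(phi[["ff"]]), mm = slot(phi[["mm"]]),
                 fm = slot(phi[["fm"]]))
  mat_comp <- function(M) mean(M["mat", ])
  pat_comp <- function(M) mean(M["pat", ])

  structure(list(
    Q_ff = phi[["ff"]] * (G_mm + G_pp + 2 * G_mp) / 4,
    Q_mm = phi[["mm"]] * (G_mm + G_pp + 2 * G_mp) / 4,
    Q_fm = phi[["fm"]] * (G_mm + G_pp + 2 * G_mp) / 4,
    Q_ff_mat = mat_comp(Q_slot$ff), Q_ff_pat = pat_comp(Q_slot$ff),
    Q_mm_mat = mat_comp(Q_slot$mm), Q_mm_pat = pat_comp(Q_slot$mm),
    Q_fm_mat = mat_comp(Q_slot$fm), Q_fm_pat = pat_comp(Q_slot$fm),
    Q_slot = Q_slot,
    F_f = F, F_m = F,
    Q_self_f = Qs, Q_self_m = Qs,
    phi = phi,
    iterations = iter,
    params = params
  ), class = "consanguinity_set")
}

#' @export
print.consanguinity_set <- function(x, ...) {
  cat("Neutral identity-by-descent probabilities (stationary)\n")
  cat(sprintf("  F = %.6g, Q_self = %.6g\n", x$F_f, x$Q_self_f))
  cat(sprintf("  Q_ff = %.6g (mat %.6g / pat %.6g)\n",
              x$Q_ff, x$Q_ff_mat, x$Q_ff_pat))
  cat(sprintf("  Q_mm = %.6g (mat %.6g / pat %.6g)\n",
              x$Q_mm, x$Q_mm_mat, x$Q_mm_pat))
  cat(sprintf("  Q_fm = %.6g (mat %.6g / pat %.6g)\n",
              x$Q_fm, x$Q_fm_mat, x$Q_fm_pat))
  invisible(x)
}

#' Relatedness coefficients from a consanguinity set
#'
#' Converts stationary consanguinities into relatedness coefficients under
#' the ratio-of-consanguinities scaling: relatedness of actor `x` to
#' recipient `y` is `Q_xy / Q_self_x`, so relatedness to self alone is 1.
#' Pairwise coefficients (`r_ff`, `r_mm`, `r_fm` to a random *other* patch
#' female/male) are reported alongside the aggregates `r_f`, `r_m`:
#' relatedness of a focal female/male to a random member of its patch,
#' *including itself* (group-wide benefits such as night-time vigilance are
#' shared with self). Every coefficient is also computed through the focal's
#' maternal-origin or paternal-origin gene only; because a random gene of
#' self is IBD to a specific own gene with probability `(1 + F)/2` exactly,
#' the self term is 1 in every origin class, and the whole-genome
#' coefficient is the arithmetic mean of the two origin coefficients.
#'
#' @param cons A `consanguinity_set` from [solve_consanguinities].
#' @param params The [sleep_params] the set was solved for (defaults to the
#'   parameters stored in `cons`).
#' @return An object of class `relatedness_set`: a list with pairwise
#'   coefficients (`r_ff`, `r_mm`, `r_fm`, `r_mf` and origin-specific
#'   variants `r_ff_mat`, ...), group aggregates (`r_f`, `r_m`,
#'   `r_f_mat`, `r_f_pat`, `r_m_mat`, `r_m_pat`), the slot-resolved
#'   matrices `r_slot` (focal origin x partner origin, unnormalised
#'   consanguinities divided by self-consanguinity), and the scaling
#'   convention.
#' @export
relatedness_coefficients <- function(cons, params = cons$params) {
  stopifnot(inherits(cons, "consanguinity_set"))
  Qs <- cons$Q_self_f
  if (Qs <= 0) stop("self-consanguinity is zero; corrupt input", call. = FALSE)
  n_f <- params$n_f
  n_m <- params$n_m
  n <- n_f + n_m

  r_pair <- list(ff = cons$Q_ff / Qs, mm = cons$Q_mm / Qs,
                 fm = cons$Q_fm / Qs)
  r_o <- list(ff_mat = cons$Q_ff_mat / Qs, ff_pat = cons$Q_ff_pat / Qs,
              mm_mat = cons$Q_mm_mat / Qs, mm_pat = cons$Q_mm_pat / Qs,
              fm_mat = cons$Q_fm_mat / Qs, fm_pat = cons$Q_fm_pat / Qs)

  agg <- function(r_same, r_cross, n_same, n_other) {
    (1 + (n_same - 1) * r_same + n_other * r_cross) / n
  }
  structure(list(
    r_ff = r_pair$ff, r_mm = r_pair$mm, r_fm = r_pair$fm, r_mf = r_pair$fm,
    r_ff_mat = r_o$ff_mat, r_ff_pat = r_o$ff_pat,
    r_mm_mat = r_o$mm_mat, r_mm_pat = r_o$mm_pat,
    r_fm_mat = r_o$fm_mat, r_fm_pat = r_o$fm_pat,
    r_f = agg(r_pair$ff, r_pair$fm, n_f, n_m),
    r_m = agg(r_pair$mm, r_pair$fm, n_m, n_f),
    r_mat_f = agg(r_o$ff_mat, r_o$fm_mat, n_f, n_m),
    r_pat_f = agg(r_o$ff_pat, r_o$fm_pat, n_f, n_m),
    r_mat_m = agg(r_o$mm_mat, r_o$fm_mat, n_m, n_f),
    r_pat_m = agg(r_o$mm_pat, r_o$fm_pat, n_m, n_f),
    r_slot = lapply(cons$Q_slot, function(M) M / Qs),
    Q_slot = cons$Q_slot,
    Q_self = Qs,
    scaling = "recipient consanguinity / actor self-consanguinity (self = 1)",
    params = params
  ), class = "relatedness_set")
}

#' @export
print.relatedness_set <- function(x, ...) {
  cat("Relatedness coefficients (self-normalised)\n")
  cat(sprintf("  to whole group (incl. self): r_f = %.6g, r_m = %.6g\n",
              x$r_f, x$r_m))
  cat(sprintf("  by parental origin: female mat %.6g / pat %.6g; ",
              x$r_mat_f, x$r_pat_f))
  cat(sprintf("male mat %.6g / pat %.6g\n", x$r_mat_m, x$r_pat_m))
  cat(sprintf("  pairwise: r_ff = %.6g, r_mm = %.6g, r_fm = %.6g\n",
              x$r_ff, x$r_mm, x$r_fm))
  invisible(x)
}

#' Relatedness of a patch under the model, in one call
#'
#' Convenience wrapper: solves the neutral IBD recursion and converts to
#' relatedness coefficients.
#'
#' @inheritParams solve_consanguinities
#' @return A `relatedness_set`; see [relatedness_coefficients].
#' @export
patch_relatedness <- function(params, tol = 1e-12) {
  relatedness_coefficients(solve_consanguinities(params, tol = tol))
}

#' Serialize consanguinities or relatedness to JSON
#'
#' Writes the numeric content of a `consanguinity_set` or `relatedness_set`
#' together with its generating parameters.
#'
#' @param x A `consanguinity_set` or `relatedness_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_relatedness_json <- function(x, path) {
  flat <- x[vapply(x, function(e) is.numeric(e) && length(e) == 1L,
                   logical(1))]
  out <- list(values = flat,
              params = unclass(x$params))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
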