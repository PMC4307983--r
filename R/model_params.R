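#' Default parameter sets for the GAL network model variants
#'
#' Returns the shipped default kinetic parameters for one of three model
#' variants of the GAL regulatory circuit:
#'
#' * `"repressor"` — the glucose-repressor model: galactose activates the
#'   signal transducer G1 to G1*, which sequesters the repressor G80 away
#'   from the activator G4; glucose converts a repressor pool R to its
#'   active form R*, which represses the *G1* and *G4* promoters.
#' * `"dilution"` — no explicit repressor; glucose instead raises the
#'   first-order decay (dilution) rate of each species by a species-specific
#'   scaling factor `s_i`.
#' * `"gal80_open_loop"` — as `"repressor"` but the *G80* feedback loop is
#'   cut: G80 is produced constitutively at `g80_const`, calibrated so the
#'   steady G80 level is approximately 40% of the fully induced wild-type
#'   level.
#'
#' Units are nM for concentrations and hours for time.  The repressor
#' defaults place a bistable glucose band at `gal = 150` nM inside
#' `glu` in `[10, 1000]` nM, with monostable ON below the band and
#' monostable OFF above it.  The repression constants `K_R1`, `K_R4` are
#' the baseline (wild-type) promoter affinities; scaling both by 1.25
#' gives the reduced-affinity variant (a 20% reduction in affinity).
#'
#' @param variant one of `"repressor"`, `"dilution"`, `"gal80_open_loop"`.
#' @return an object of class `gal_params`: a validated named list of
#'   kinetic constants plus the `variant` label.
#' @examples
#' p <- default_params("repressor")
#' p$K_R1 * 1.25   # reduced-affinity value, 80.8 nM
#' @export
default_params <- function(variant = c("repressor", "dilution", "gal80_open_loop")) {
  variant <- match.arg(variant)
  p <- list(
    alpha1 = 670, alpha80 = 40, alpha4 = 36,
    b1 = 0.5, b80 = 26, b4 = 0.3,
    d = 0.5,
    K_A = 12, n_A = 3,
    K_R1 = 80.8 / 1.25, K_R4 = 40.6 / 1.25, n_R = 2,
    K_gal = 60, m = 2,
    K_seq80 = 0.25, K_seq4 = 0.4,
    k_R = 0.002, k_Rd = 1, R_total = 200,
    g80_const = 0,
    s1 = 0, s80 = 0, s4 = 0, K_g = 1, n_g = 1,
    variant = variant
  )
  if (variant == "gal80_open_loop") {
    # 40% of the fully induced wild-type G80 production (b80 + alpha80)
    p$g80_const <- 0.4 * (p$b80 + p$alpha80)
  }
  if (variant == "dilution") {
    p$s1 <- 6.3; p$s80 <- 0.4; p$s4 <- 2.9
    p$K_g <- 260; p$n_g <- 2
  }
  validate_params(p)
}

#' Construct / validate a GAL model parameter set
#'
#' @param p named list with the fields of [default_params()].
#' @return the list with class `gal_params`, or an error describing the
#'   violated constraint.
#' @export
validate_params <- function(p) {
  stopifnot(is.list(p))
  if (!p$variant %in% c("repressor", "dilution", "gal80_open_loop"))
    stop("unknown variant label: ", p$variant)
  rates <- c("alpha1", "alpha80", "alpha4", "d", "K_A", "K_R1", "K_R4",
             "K_gal", "K_seq80", "K_seq4", "k_R", "k_Rd", "R_total")
  for (f in rates) {
    if (is.null(p[[f]]) || !is.finite(p[[f]]) || p[[f]] <= 0)
      stop("parameter ", f, " must be finite and > 0")
  }
  for (f in c("b1", "b80", "b4", "g80_const", "s1", "s80", "s4")) {
    if (is.null(p[[f]]) || !is.finite(p[[f]]) || p[[f]] < 0)
      stop("parameter ", f, " must be finite and >= 0")
  }
  for (f in c("n_A", "n_R", "m", "n_g")) {
    if (is.null(p[[f]]) || !is.finite(p[[f]]) || p[[f]] < 1)
      stop("Hill coefficient ", f, " must be >= 1")
  }
  structure(p, class = "gal_params")
}

#' @export
print.gal_params <- function(x, ...) {
  cat("GAL model parameters (variant:", x$variant, ")\n")
  num <- vapply(x[setdiff(names(x), "variant")], identity, 0)
  print(round(num, 4))
  invisible(x)
}

# order must match the parameter slots in src/gal_model.c
.parm_order <- c("alpha1", "alpha80", "alpha4", "b1", "b80", "b4", "d",
                 "K_A", "n_A", "K_R1", "K_R4", "n_R", "K_gal", "m",
                 "K_seq80", "K_seq4", "k_R", "k_Rd", "R_total", "g80_const",
                 "s1", "s80", "s4", "K_g", "n_g")

# pack parameters + constant inputs for the compiled rhs
.pack_parms <- function(params, glu, gal) {
  code <- match(params$variant, c("repressor", "dilution", "gal80_open_loop"))
  c(code, unlist(params[.parm_order], use.names = FALSE), glu, gal)
}

# LHS sampling bounds for initial conditions: production/decay balance caps
# each protein at 2*(alpha_i + b_i)/d; R* is bounded by the pool size.
.state_bounds <- function(params) {
  up <- with(params, c(
    g1_total = 2 * (alpha1 + b1) / d,
    g80_total = 2 * (alpha80 + b80) / d,
    g4_total = 2 * (alpha4 + b4) / d,
    r_active = R_total
  ))
  rbind(lower = c(0, 0, 0, 0), upper = up)
}
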