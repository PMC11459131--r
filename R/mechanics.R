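#' Force-extension model parameters
#'
#' Container for the parameters of the saturation-plus-linear-spring model of
#' protein extensibility,
#' \deqn{x(F) = \frac{x_E}{1 + F_{1/2}/F} + \frac{F}{K},}
#' in which `x_E` is the maximal entropic extension (nm), `f_half` is the
#' force at which entropic extension is halfway complete (pN) and `k` is the
#' enthalpic (Hookean) stiffness (pN/nm, numerically identical to mN/m).
#'
#' @param x_e Maximal entropic extension, nm. Must be positive.
#' @param f_half Half-saturation force, pN. Must be positive.
#' @param k Enthalpic stiffness, pN/nm. Must be positive.
#' @param rms Optional residual root-mean-square of a fit, nm.
#' @param n_points Optional number of samples that entered a fit.
#' @return An object of class `"fit_params"`.
#' @seealso [extension_at_force()], [fit_segment()]
#' @examples
#' p <- fit_params(x_e = 39.9, f_half = 1.4, k = 3.7)
#' extension_at_force(p, 1.4)
#' @export
fit_params <- function(x_e, f_half, k, rms = NA_real_, n_points = NA_integer_) {
  for (nm in c("x_e", "f_half", "k")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("'", nm, "' must be a single positive finite number", call. = FALSE)
    }
  }
  if (!is.na(rms) && rms < 0) stop("'rms' must be non-negative", call. = FALSE)
  structure(
    list(x_e = as.numeric(x_e), f_half = as.numeric(f_half), k = as.numeric(k),
         rms = as.numeric(rms), n_points = as.integer(n_points)),
    class = "fit_params"
  )
}

#' @export
print.fit_params <- function(x, ...) {
  cat(sprintf("Force-extension fit: x_E = %.3g nm, F_half = %.3g pN, K = %.3g pN/nm\n",
              x$x_e, x$f_half, x$k))
  if (!is.na(x$rms)) {
    cat(sprintf("  residual RMS %.3g nm over %d samples\n", x$rms, x$n_points))
  }
  invisible(x)
}

.as_fit_params <- function(params) {
  if (inherits(params, "fit_params")) return(params)
  if (is.list(params) && all(c("x_e", "f_half", "k") %in% names(params))) {
    return(fit_params(params$x_e, params$f_half, params$k))
  }
  stop("'params' must be a fit_params object or a list with x_e, f_half, k",
       call. = FALSE)
}

#' Extension of the molecule at a given force
#'
#' Evaluates the saturation-plus-spring model at one or more forces. At
#' `force = 0` the continuous limit 0 is returned (the entropic term vanishes
#' as F goes to 0).
#'
#' @param params A [fit_params()] object (or compatible list).
#' @param force Applied force(s), pN; non-negative and finite.
#' @return End-to-end extension(s), nm; strictly increasing in `force`.
#' @examples
#' p <- fit_params(39.9, 1.4, 3.7)
#' extension_at_force(p, c(0, 1.4, 50))
#' @export
extension_at_force <- function(params, force) {
  p <- .as_fit_params(params)
  if (!is.numeric(force) || any(!is.finite(force)) || any(force < 0)) {
    stop("'force' must be finite and non-negative", call. = FALSE)
  }
  # x_E/(1 + F_half/F) written as x_E F/(F + F_half): continuous at F = 0
  p$x_e * force / (force + p$f_half) + force / p$k
}

#' Force that produces a given extension
#'
#' Inverts [extension_at_force()] by bracketed root finding; the model is
#' strictly monotone so the root is unique.
#'
#' @param params A [fit_params()] object.
#' @param x Target extension(s), nm; non-negative.
#' @param tol Convergence tolerance on extension, nm.
#' @return Force(s), pN, with `extension_at_force(params, F)` within `tol` of `x`.
#' @export
invert_extension <- function(params, x, tol = 1e-9) {
  p <- .as_fit_params(params)
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop("'x' must be finite and non-negative", call. = FALSE)
  }
  vapply(x, function(xi) {
    if (xi == 0) return(0)
    upper <- p$k * xi + 1  # x >= F/K so F <= K x; pad the bracket
    root <- uniroot(function(f) extension_at_force(p, f) - xi,
                    lower = 0, upper = upper, tol = min(tol, 1e-10))
    root$root
  }, numeric(1))
}

#' Stiffness estimate with uncertainty
#'
#' @param value Stiffness, pN/nm (= mN/m). Must be positive.
#' @param sem Standard error of the mean, pN/nm (optional).
#' @param n Number of determinations contributing to the estimate.
#' @return An object of class `"stiffness_value"`.
#' @export
stiffness_value <- function(value, sem = NA_real_, n = NA_integer_) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) || value <= 0) {
    stop("'value' must be a single positive number", call. = FALSE)
  }
  if (!is.na(sem) && sem < 0) stop("'sem' must be non-negative", call. = FALSE)
  structure(list(value = as.numeric(value), sem = as.numeric(sem),
                 n = as.integer(n)),
            class = "stiffness_value")
}

#' @export
print.stiffness_value <- function(x, ...) {
  cat(sprintf("Stiffness %.3g pN/nm", x$value))
  if (!is.na(x$sem)) cat(sprintf(" +/- %.2g (SEM)", x$sem))
  if (!is.na(x$n)) cat(sprintf(", n = %d", x$n))
  cat("\n")
  invisible(x)
}

.stiffness_num <- function(k) {
  v <- if (inherits(k, "stiffness_value")) k$value else k
  if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
    stop("stiffness values must be positive and finite", call. = FALSE)
  }
  v
}

#' Stiffness of springs in series
#'
#' Combined stiffness of elastic elements loaded in series,
#' \eqn{1/K = \sum_i 1/K_i}. For the tip link this composes the PCDH15 and
#' CDH23 dimer stiffnesses into the stiffness of the whole filament.
#'
#' @param ... Two or more stiffnesses (numeric, pN/nm, or
#'   [stiffness_value()] objects); vectors are flattened.
#' @return Combined stiffness, pN/nm; symmetric in its arguments and never
#'   larger than the softest element.
#' @examples
#' series_stiffness(6.4, 6.4 / 2.3)  # tip-link estimate, ~1.9 pN/nm
#' @export
series_stiffness <- function(...) {
  ks <- unlist(lapply(list(...), .stiffness_num))
  if (length(ks) < 2L) stop("need at least two springs", call. = FALSE)
  1 / sum(1 / ks)
}

#' Stiffness rescaled by contour length
#'
#' For filaments of identical material, stiffness is inversely proportional
#' to contour length; a filament `length_ratio` times as long is
#' `1/length_ratio` times as stiff.
#'
#' @param k Reference stiffness, pN/nm.
#' @param length_ratio Length of the target filament relative to the
#'   reference; positive.
#' @return Scaled stiffness, pN/nm.
#' @examples
#' scaled_stiffness(6.4, 2.3)  # CDH23 from PCDH15, ~2.8 pN/nm
#' @export
scaled_stiffness <- function(k, length_ratio) {
  kv <- .stiffness_num(k)
  if (!is.numeric(length_ratio) || any(!is.finite(length_ratio)) ||
      any(length_ratio <= 0)) {
    stop("'length_ratio' must be positive and finite", call. = FALSE)
  }
  kv / length_ratio
}

#' Contour-length gain from unfolding
#'
#' Length released when a structured element of `n_residues` amino acids
#' unfolds: 0.40 nm per residue less the end-to-end length of the folded
#' element (about 4.5 nm for one extracellular-cadherin domain), floored at
#' zero. The folded length is subtracted once per unfolded element.
#'
#' @param n_residues Number of residues in the element; non-negative.
#' @param folded_length End-to-end length of the folded element, nm.
#' @param nm_per_aa Contour length per residue, nm.
#' @return Extension gained on unfolding, nm.
#' @examples
#' contour_gain(100)      # full EC domain, 35.5 nm
#' contour_gain(4, 0)     # short linker, 1.6 nm
#' @export
contour_gain <- function(n_residues, folded_length = 4.5, nm_per_aa = 0.40) {
  if (any(n_residues < 0) || any(folded_length < 0) || any(nm_per_aa < 0)) {
    stop("inputs must be non-negative", call. = FALSE)
  }
  pmax(0, nm_per_aa * n_residues - folded_length)
}

#' Published illustrative fit parameters
#'
#' Parameter sets quoted for illustrative force-ramp cycles of wild-type and
#' V507D PCDH15 dimers at three Ca2+ conditions: per-phase (and, where the
#' cycle was segmented by unfolding events, per-segment) values of the
#' maximal entropic extension and half-saturation force, with the shared
#' per-condition enthalpic stiffness. Useful as realistic inputs for
#' round-trip fitting checks.
#'
#' @return A data frame with columns `construct`, `calcium`, `phase`,
#'   `segment`, `x_e` (nm), `f_half` (pN) and `k` (pN/nm).
#' @export
reference_fit_params <- function() {
  rbind(
    data.frame(construct = "wild-type", calcium = "3 mM",
               phase = c("extension", "relaxation"), segment = 1L,
               x_e = c(39.9, 40.9), f_half = c(1.4, 1.5), k = 3.7),
    data.frame(construct = "wild-type", calcium = "20 uM",
               phase = c("extension", "relaxation"), segment = 1L,
               x_e = c(63.8, 63.1), f_half = c(2.4, 2.4), k = 2.5),
    data.frame(construct = "wild-type", calcium = "0 M EDTA",
               phase = c(rep("extension", 3), "relaxation"),
               segment = c(1:3, 1L),
               x_e = c(55.2, 59.6, 78.8, 84.5),
               f_half = c(rep(4.1, 3), 5.1), k = 2.4),
    data.frame(construct = "V507D", calcium = "3 mM",
               phase = c(rep("extension", 3), "relaxation"),
               segment = c(1:3, 1L),
               x_e = c(34.9, 44.0, 91.6, 99.5),
               f_half = c(rep(2.4, 3), 4.0), k = 3.2),
    data.frame(construct = "V507D", calcium = "20 uM",
               phase = c(rep("extension", 3), "relaxation"),
               segment = c(1:3, 1L),
               x_e = c(48.1, 68.6, 98.6, 110.9),
               f_half = c(rep(2.1, 3), 6.4), k = 2.1),
    data.frame(construct = "V507D", calcium = "0 M EDTA",
               phase = c(rep("extension", 3), "relaxation"),
               segment = c(1:3, 1L),
               x_e = c(130.9, 157.6, 174.0, 188.2),
               f_half = c(rep(3.7, 3), 6.2), k = 1.6)
  )
}

#' Expected fraction of single-molecule tethers
#'
#' Poisson argument for tethering statistics: if a fraction
#' `n_tethered/n_tested` of probe beads forms at least one tether, the number
#' of tethers per bead is Poisson with rate \eqn{\lambda = -\ln(1 - f)}, and
#' the probability that a tethered bead carries exactly one molecule is
#' \eqn{\lambda e^{-\lambda} / (1 - e^{-\lambda})}.
#'
#' @param n_tested Number of beads tested; positive.
#' @param n_tethered Number of beads that formed a tether; in `(0, n_tested)`.
#' @return A list with `lambda` (mean tethers per bead) and
#'   `p_single` (probability a tethered bead is singly tethered).
#' @examples
#' tether_statistics(100, 10)  # sparse tethering: mostly single molecules
#' @export
tether_statistics <- function(n_tested, n_tethered) {
  if (n_tested <= 0 || n_tethered <= 0 || n_tethered > n_tested) {
    stop("require 0 < n_tethered <= n_tested", call. = FALSE)
  }
  if (n_tethered == n_tested) {
    stop("all beads tethered: Poisson rate is unbounded", call. = FALSE)
  }
  f <- n_tethered / n_tested
  lambda <- -log(1 - f)
  list(lambda = lambda, p_single = lambda * exp(-lambda) / (1 - exp(-lambda)))
}
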