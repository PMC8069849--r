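#' Canonicalize a phase angle into [0, 2*pi)
#'
#' Phases of probability amplitudes are angles; two phases that differ by an
#' exact multiple of \eqn{2\pi} describe the same amplitude.
#'
#' @param theta Numeric vector of angles in radians.
#' @return Numeric vector of angles in `[0, 2*pi)`.
#' @export
#' @examples
#' canonical_phase(-pi / 2)    # 3*pi/2
#' canonical_phase(4 * pi)     # 0
canonical_phase <- function(theta) {
  if (!is.numeric(theta) || any(!is.finite(theta))) {
    stop("phase must be a finite numeric value", call. = FALSE)
  }
  theta %% (2 * pi)
}

#' Compare phases modulo 2*pi
#'
#' @param a,b Numeric vectors of angles in radians.
#' @param tol Tolerance for modular equality.
#' @return Logical vector.
#' @export
phase_equal <- function(a, b, tol = 1e-9) {
  d <- (canonical_phase(a) - canonical_phase(b)) %% (2 * pi)
  pmin(d, 2 * pi - d) < tol
}

#' Construct a probability amplitude
#'
#' A probability amplitude is the complex number \eqn{m e^{i\theta}} with
#' magnitude \eqn{m = \sqrt{p}} for some classical probability `p`, so that its
#' squared magnitude (the product with its complex conjugate) recovers `p`.
#' Amplitudes are stored in polar form -- `(magnitude, phase)` -- which avoids
#' the sign ambiguity of the square root; they are converted to rectangular
#' (complex) form whenever amplitudes are summed.
#'
#' @param magnitude Real magnitude in `[0, 1]`.
#' @param phase Phase angle in radians; canonicalized into `[0, 2*pi)`.
#' @return An object of class `"qamp"`.
#' @seealso [amplitude_from_probability()], [to_probability()]
#' @export
qamp <- function(magnitude, phase = 0) {
  if (!is.numeric(magnitude) || any(!is.finite(magnitude))) {
    stop("amplitude magnitude must be finite numeric", call. = FALSE)
  }
  if (any(magnitude < 0 | magnitude > 1)) {
    stop(sprintf("amplitude magnitude %g lies outside [0, 1]",
                 magnitude[which(magnitude < 0 | magnitude > 1)[1]]),
         call. = FALSE)
  }
  structure(list(magnitude = as.numeric(magnitude),
                 phase = canonical_phase(phase)),
            class = "qamp")
}

#' Convert a classical probability into a probability amplitude
#'
#' Returns the amplitude \eqn{\sqrt{p}\,e^{i\theta}}. The squared magnitude of
#' the result reproduces `p` to machine precision (e.g. `p = 0.1` gives
#' magnitude `0.3162` to four decimals).
#'
#' @param p Classical probability in `[0, 1]`.
#' @param theta Phase angle in radians (default 0).
#' @return A [qamp()] object.
#' @export
#' @examples
#' a <- amplitude_from_probability(0.1)
#' round(a$magnitude, 4)  # 0.3162
#' to_probability(a)      # 0.1
amplitude_from_probability <- function(p, theta = 0) {
  if (!is.numeric(p) || any(!is.finite(p))) {
    stop("probability must be finite numeric", call. = FALSE)
  }
  if (any(p < 0 | p > 1)) {
    bad <- p[which(p < 0 | p > 1)[1]]
    stop(sprintf("probability %g lies outside [0, 1]", bad), call. = FALSE)
  }
  qamp(sqrt(p), theta)
}

#' Squared magnitude of an amplitude
#'
#' The classical probability carried by an amplitude is its squared magnitude,
#' independent of phase.
#'
#' @param a A [qamp()] object or a complex vector.
#' @return Numeric vector of probabilities.
#' @export
to_probability <- function(a) {
  if (inherits(a, "qamp")) return(a$magnitude^2)
  if (is.complex(a)) return(Mod(a)^2)
  stop("expected a qamp object or complex vector", call. = FALSE)
}

#' @export
as.complex.qamp <- function(x, ...) {
  complex(modulus = x$magnitude, argument = x$phase)
}

#' @export
print.qamp <- function(x, digits = 4, ...) {
  cat(sprintf("<amplitude> %s * exp(%si)  |.|^2 = %s\n",
              format(x$magnitude, digits = digits),
              format(x$phase, digits = digits),
              format(x$magnitude^2, digits = digits)))
  invisible(x)
}

.as_amp_complex <- function(x) {
  if (inherits(x, "qamp")) return(complex(modulus = x$magnitude, argument = x$phase))
  if (is.complex(x)) return(x)
  if (is.numeric(x)) return(as.complex(x))
  if (is.list(x)) return(vapply(x, .as_amp_complex, complex(1)))
  stop("cannot interpret object as amplitude(s)", call. = FALSE)
}

#' Decompose a coherent sum of amplitudes into classical and interference parts
#'
#' For amplitudes \eqn{\psi_1, \ldots, \psi_n} the coherent probability
#' \eqn{|\sum_i \psi_i|^2} differs from the classical sum
#' \eqn{\sum_i |\psi_i|^2} by the interference term
#' \eqn{2\sum_{i<j} |\psi_i||\psi_j|\cos(\theta_i - \theta_j)}. With equal
#' phases the cross terms are maximally constructive (a coherent probability
#' can exceed 1 before normalization); the interference term vanishes when the
#' pairwise cross terms cancel, e.g. at phase separations of \eqn{\pi/2}.
#'
#' @param amplitudes A list of [qamp()] objects, or a complex vector.
#' @return An object of class `"interference_report"` with fields
#'   `classical_sum`, `coherent_probability`, and `interference_term`
#'   (satisfying `coherent = classical + interference`).
#' @export
#' @examples
#' # two in-phase amplitudes 1/sqrt(2): coherent 2, classical 1, interference +1
#' interfere(complex(modulus = c(1, 1) / sqrt(2), argument = c(0, 0)))
interfere <- function(amplitudes) {
  z <- .as_amp_complex(amplitudes)
  if (length(z) < 1) stop("interfere() needs at least one amplitude", call. = FALSE)
  classical <- sum(Mod(z)^2)
  coherent <- Mod(sum(z))^2
  structure(list(classical_sum = classical,
                 coherent_probability = coherent,
                 interference_term = coherent - classical),
            class = "interference_report")
}

#' @export
print.interference_report <- function(x, digits = 4, ...) {
  cat(sprintf(
    "<interference> classical sum %s | coherent %s | interference %+g\n",
    format(x$classical_sum, digits = digits),
    format(x$coherent_probability, digits = digits),
    signif(x$interference_term, digits)))
  invisible(x)
}
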