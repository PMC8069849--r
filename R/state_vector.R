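#' Construct a Hilbert-space state vector (wave function)
#'
#' A state vector assigns one complex amplitude to each labelled basis state.
#' It must be of unit length: the squared magnitudes of the amplitudes form a
#' valid classical distribution. Vectors violating the normalization tolerance
#' are rejected rather than silently renormalized -- call [renormalize()]
#' explicitly if that is what you mean -- so that mis-entered tables are not
#' masked.
#'
#' @param basis Character vector of unique basis-state labels.
#' @param amplitudes Complex vector (or list of [qamp()] objects) of the same
#'   length as `basis`.
#' @param tol Normalization tolerance on the L2 norm (default `1e-9`).
#' @return An object of class `"state_vector"` with fields `basis` and `amp`.
#' @export
#' @examples
#' psi <- superpose(c(good = 0.5, poor = 0.5))
#' born_probability(psi, projector(psi$basis, "poor"))  # 0.5
state_vector <- function(basis, amplitudes, tol = 1e-9) {
  basis <- as.character(basis)
  if (anyDuplicated(basis)) stop("basis labels must be unique", call. = FALSE)
  amp <- .as_amp_complex(amplitudes)
  if (length(amp) != length(basis)) {
    stop(sprintf("length mismatch: %d basis labels but %d amplitudes",
                 length(basis), length(amp)), call. = FALSE)
  }
  nrm <- sqrt(sum(Mod(amp)^2))
  if (abs(nrm - 1) > tol) {
    stop(sprintf(
      "state vector is not unit length (L2 norm %.12g); call renormalize() if intended",
      nrm), call. = FALSE)
  }
  structure(list(basis = basis, amp = amp), class = "state_vector")
}

#' Renormalize a vector of amplitudes to unit length
#'
#' @param basis Character vector of basis labels.
#' @param amplitudes Complex amplitudes (any nonzero norm).
#' @return A unit-length [state_vector()]; relative phases are preserved.
#' @export
renormalize <- function(basis, amplitudes) {
  amp <- .as_amp_complex(amplitudes)
  nrm <- sqrt(sum(Mod(amp)^2))
  if (nrm == 0) stop("cannot renormalize the zero vector", call. = FALSE)
  state_vector(basis, amp / nrm)
}

#' Build a superposition state from a classical distribution and phases
#'
#' Constructs the wave function with amplitudes
#' \eqn{\psi_i = \sqrt{p_i}\,e^{i\theta_i}} over the given basis, e.g. the
#' two-state habitat superposition \eqn{S = e^{i\theta_g}/\sqrt{2}\,|good\rangle
#' + e^{i\theta_p}/\sqrt{2}\,|poor\rangle} when `probs = c(0.5, 0.5)`. The sum
#' of the squared magnitudes equals 1 for any choice of phases.
#'
#' @param probs Named (or unnamed) numeric distribution summing to 1 within
#'   `1e-9`.
#' @param phases One phase (radians) per state; a scalar is recycled.
#' @param basis Optional basis labels; defaults to `names(probs)` or
#'   `s1, s2, ...`.
#' @return A [state_vector()].
#' @export
superpose <- function(probs, phases = 0, basis = NULL) {
  if (!is.numeric(probs)) stop("probs must be numeric", call. = FALSE)
  if (abs(sum(probs) - 1) > 1e-9) {
    stop(sprintf("probabilities sum to %.12g, not 1", sum(probs)), call. = FALSE)
  }
  if (any(probs < 0)) stop("probabilities must be nonnegative", call. = FALSE)
  if (length(phases) == 1) phases <- rep(phases, length(probs))
  if (length(phases) != length(probs)) {
    stop(sprintf("shape error: %d probabilities but %d phases",
                 length(probs), length(phases)), call. = FALSE)
  }
  if (is.null(basis)) {
    basis <- if (!is.null(names(probs))) names(probs) else paste0("s", seq_along(probs))
  }
  state_vector(basis, complex(modulus = sqrt(probs), argument = phases))
}

#' Projector onto a subspace spanned by basis states
#'
#' @param basis Character vector: the full ordered basis.
#' @param kept Indices or labels of the basis states spanning the subspace.
#' @return An object of class `"projector"` (idempotent by construction).
#' @export
projector <- function(basis, kept) {
  basis <- as.character(basis)
  if (anyDuplicated(basis)) stop("basis labels must be unique", call. = FALSE)
  if (is.character(kept)) {
    idx <- match(kept, basis)
    if (anyNA(idx)) {
      stop(sprintf("unknown basis state(s): %s",
                   paste(kept[is.na(idx)], collapse = ", ")), call. = FALSE)
    }
  } else {
    idx <- as.integer(kept)
    if (any(idx < 1 | idx > length(basis))) {
      stop("projector indices out of range", call. = FALSE)
    }
  }
  idx <- sort(unique(idx))
  if (length(idx) == 0) stop("projector must keep at least one basis state", call. = FALSE)
  structure(list(basis = basis, kept = idx), class = "projector")
}

.check_same_basis <- function(psi, proj) {
  if (!identical(psi$basis, proj$basis)) {
    stop("basis mismatch between state vector and projector", call. = FALSE)
  }
}

#' Apply a projector to a state vector without renormalizing
#'
#' Amplitudes outside the kept subspace are set to zero; the result is in
#' general no longer unit length (its squared norm is the Born probability).
#'
#' @param proj A [projector()].
#' @param psi A [state_vector()].
#' @return Complex amplitude vector of the projected (unnormalized) state.
#' @export
project_amplitudes <- function(proj, psi) {
  .check_same_basis(psi, proj)
  out <- psi$amp
  out[-proj$kept] <- 0i
  out
}

#' Born-rule probability of a measurement outcome
#'
#' \eqn{P = \lVert P_a \psi \rVert^2}: the squared norm of the state vector
#' projected onto the outcome's subspace. Invariant under a global phase shift
#' of `psi`; summing over the projectors of any complete observable gives 1
#' (the quantum analogue of the Law of Total Probability).
#'
#' @param psi A [state_vector()].
#' @param proj A [projector()] on the same basis.
#' @return Probability in `[0, 1]`.
#' @export
born_probability <- function(psi, proj) {
  sum(Mod(project_amplitudes(proj, psi))^2)
}

#' Collapse of the wave function onto an observed subspace
#'
#' Projects `psi` onto the subspace of `proj` and renormalizes to unit length.
#' Relative phases inside the subspace are preserved exactly. Conditioning on
#' an impossible event (Born probability 0) is an error.
#'
#' @param psi A [state_vector()].
#' @param proj A [projector()] on the same basis.
#' @param tol Probabilities below `tol` are treated as impossible.
#' @return The collapsed unit-length [state_vector()].
#' @export
collapse <- function(psi, proj, tol = 1e-12) {
  p <- born_probability(psi, proj)
  if (p <= tol) {
    stop("cannot collapse onto a zero-probability subspace (impossible event)",
         call. = FALSE)
  }
  out <- project_amplitudes(proj, psi) / sqrt(p)
  structure(list(basis = psi$basis, amp = out), class = "state_vector")
}

#' Quantum conditional probability
#'
#' \eqn{P(B \mid A) = \lVert Q_B \psi_A \rVert^2} where \eqn{\psi_A} is the
#' state collapsed on the conditioning subspace: equivalent to
#' `born_probability(collapse(psi, given), then)`.
#'
#' @param psi A [state_vector()].
#' @param given Conditioning [projector()] (must have positive probability).
#' @param then Outcome [projector()].
#' @return Probability in `[0, 1]`.
#' @export
quantum_conditional <- function(psi, given, then) {
  born_probability(collapse(psi, given), then)
}

#' Observable: a Hermitian operator as eigenvalue-weighted projectors
#'
#' An observable \eqn{A = \sum_i a_i P_{a_i}} is represented by its real
#' eigenvalues and the projectors onto the corresponding eigen-subspaces,
#' which must be mutually disjoint and jointly cover the basis.
#'
#' @param projectors List of [projector()] objects on a common basis.
#' @param eigenvalues Real eigenvalues, one per projector; defaults to the
#'   projector ordinals (the paper-level eigenvalues are never used
#'   numerically).
#' @return An object of class `"observable"`.
#' @export
observable <- function(projectors, eigenvalues = seq_along(projectors)) {
  if (length(projectors) < 1) stop("observable needs at least one projector", call. = FALSE)
  basis <- projectors[[1]]$basis
  for (p in projectors) {
    if (!inherits(p, "projector")) stop("projectors must be projector objects", call. = FALSE)
    if (!identical(p$basis, basis)) stop("projectors must share one basis", call. = FALSE)
  }
  kept <- unlist(lapply(projectors, `[[`, "kept"))
  if (anyDuplicated(kept)) stop("observable projectors must be mutually disjoint", call. = FALSE)
  if (length(kept) != length(basis)) {
    stop("observable projectors must jointly cover the basis", call. = FALSE)
  }
  if (length(eigenvalues) != length(projectors) || !is.numeric(eigenvalues)) {
    stop("need one real eigenvalue per projector", call. = FALSE)
  }
  structure(list(eigenvalues = as.numeric(eigenvalues), projectors = projectors),
            class = "observable")
}

#' Outcome distribution of measuring an observable
#'
#' @param psi A [state_vector()].
#' @param obs An [observable()] on the same basis.
#' @return Named numeric vector of Born probabilities (one per eigenvalue),
#'   summing to 1.
#' @export
observable_probabilities <- function(psi, obs) {
  p <- vapply(obs$projectors, function(pr) born_probability(psi, pr), numeric(1))
  names(p) <- as.character(obs$eigenvalues)
  p
}

#' @export
print.state_vector <- function(x, digits = 4, ...) {
  cat(sprintf("<state vector> %d basis states\n", length(x$basis)))
  df <- data.frame(state = x$basis,
                   magnitude = round(Mod(x$amp), digits),
                   phase = round(canonical_phase(Arg(x$amp)), digits),
                   probability = round(Mod(x$amp)^2, digits))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
print.projector <- function(x, ...) {
  cat(sprintf("<projector> keeps {%s} of basis {%s}\n",
              paste(x$basis[x$kept], collapse = ", "),
              paste(x$basis, collapse = ", ")))
  invisible(x)
}
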