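#' Sample initial conditions from the ground-state Wigner distribution
#'
#' For the vibrational ground state of a set of harmonic modes, the Wigner
#' distribution in dimensionless mass-frequency-scaled coordinates is a
#' product of independent Gaussians in q and p, each with mean 0 and
#' variance 1/2.  The expectation of the classical mode energy
#' `omega * (q^2 + p^2) / 2` is then the zero-point energy `omega / 2`.
#' No thermal excitation is applied.
#'
#' A single integer `seed` deterministically streams one sub-seed per
#' sample (recorded on the sample), so any individual trajectory can be
#' re-run in isolation.
#'
#' @param modes list of `sh_mode` objects (only their number matters here).
#' @param n number of phase-space samples (>= 1).
#' @param initial_state state label assigned to every sample (the
#'   reference protocol starts all trajectories in the bright S2 state).
#' @param seed integer master seed.
#' @return list of `sh_phase_point` objects with fields `q`, `p`
#'   (dimensionless, one per mode), `initial_state` and `seed`.
#' @export
sample_wigner <- function(modes, n, initial_state = "S2", seed = 1L) {
  if (length(modes) < 1) stop("sample_wigner: modes must be non-empty")
  if (!is.numeric(n) || n < 1) stop("sample_wigner: n must be >= 1")
  n <- as.integer(n)
  nM <- length(modes)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max, n)
  lapply(seq_len(n), function(i) {
    set.seed(sub_seeds[i])
    structure(list(
      q = stats::rnorm(nM, 0, sqrt(0.5)),
      p = stats::rnorm(nM, 0, sqrt(0.5)),
      initial_state = initial_state,
      seed = sub_seeds[i]
    ), class = "sh_phase_point")
  })
}
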