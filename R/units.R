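#' Physical constants and unit conversions
#'
#' All internal computation in surfhop uses Hartree atomic units
#' (energy in Hartree, time in a.u. of time, length in Bohr, mass in
#' electron masses, hbar = 1).  User-facing interfaces use eV, fs and
#' Angstrom.  These constants are the single source of conversion factors
#' for the whole package.
#'
#' @format A named list with elements
#' \describe{
#'   \item{ev_per_hartree}{27.211386...: eV in one Hartree}
#'   \item{fs_per_autime}{0.0241888...: fs in one atomic unit of time}
#'   \item{hartree_per_cm1}{Hartree in one wavenumber (cm^-1)}
#'   \item{angstrom_per_bohr}{Angstrom in one Bohr}
#'   \item{me_per_amu}{electron masses in one unified atomic mass unit}
#' }
#' @export
sh_units <- list(
  ev_per_hartree   = 27.211386245988,
  fs_per_autime    = 0.02418884326586,
  hartree_per_cm1  = 4.556335252912e-6,
  angstrom_per_bohr = 0.529177210903,
  me_per_amu       = 1822.888486209
)

#' Unit conversion helpers
#'
#' Thin wrappers around the constants in [sh_units].
#'
#' @param x numeric vector to convert.
#' @return converted numeric vector.
#' @name unit-conversions
NULL

#' @rdname unit-conversions
#' @export
ev_to_hartree <- function(x) x / sh_units$ev_per_hartree

#' @rdname unit-conversions
#' @export
hartree_to_ev <- function(x) x * sh_units$ev_per_hartree

#' @rdname unit-conversions
#' @export
cm1_to_hartree <- function(x) x * sh_units$hartree_per_cm1

#' @rdname unit-conversions
#' @export
hartree_to_cm1 <- function(x) x / sh_units$hartree_per_cm1

#' @rdname unit-conversions
#' @export
fs_to_autime <- function(x) x / sh_units$fs_per_autime

#' @rdname unit-conversions
#' @export
autime_to_fs <- function(x) x * sh_units$fs_per_autime

#' @rdname unit-conversions
#' @export
bohr_to_angstrom <- function(x) x * sh_units$angstrom_per_bohr

#' @rdname unit-conversions
#' @export
angstrom_to_bohr <- function(x) x / sh_units$angstrom_per_bohr
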