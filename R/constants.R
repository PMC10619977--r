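#' Physical constants and unit conventions
#'
#' All energies are in kJ/mol, lengths in nm, times in ps, temperatures in K,
#' forces in pN unless a function documents otherwise.
#'
#' @format `ak_constants` is a named list with elements:
#' \describe{
#'   \item{kB}{Boltzmann constant, 0.0083145 kJ/mol/K (equal to the molar gas
#'     constant in kJ/mol/K).}
#'   \item{pN_per_kJmolnm}{Conversion factor from kJ/mol/nm to piconewton,
#'     1.66054 pN per kJ/mol/nm.}
#' }
#' @export
ak_constants <- list(
  kB = 0.0083145,
  pN_per_kJmolnm = 1.66054
)

#' Thermal energy kBT
#'
#' @param temperature Temperature in K.
#' @return kBT in kJ/mol.
#' @examples
#' kBT(300) # about 2.49 kJ/mol
#' @export
kBT <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  ak_constants$kB * temperature
}

#' Derive a child seed from a master seed
#'
#' All stochastic stages draw their seeds through this one scheme so that a
#' single master seed makes an entire multi-stage run reproducible. The child
#' seed is `(master + 7919 * counter) mod (2^31 - 1)`, which stays inside the
#' 32-bit integer range R requires.
#'
#' @param master Master seed (integer).
#' @param counter Non-negative integer counter; distinct counters give
#'   distinct, decorrelated streams.
#' @return An integer seed.
#' @export
derive_seed <- function(master, counter) {
  stopifnot(length(master) == 1, length(counter) == 1, counter >= 0)
  as.integer((as.numeric(master) + 7919 * as.numeric(counter)) %% 2147483647)
}
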