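#' Convert IC50 to pIC50
#'
#' Activity transform used throughout the study: `pIC50 = 6 - log10(IC50)`
#' for IC50 in micromolar, i.e. the negative decadic log of the molar IC50.
#'
#' @param ic50 Half-maximal inhibitory concentration in micromolar; must be
#'   strictly positive.
#' @return pIC50 in log units.
#' @examples
#' ic50_to_pic50(1)      # 6
#' ic50_to_pic50(0.0489) # ~7.31
#' @export
ic50_to_pic50 <- function(ic50) {
  if (!is.numeric(ic50) || any(!is.finite(ic50)) || any(ic50 <= 0)) {
    stop("ic50 must be a positive finite concentration (uM)", call. = FALSE)
  }
  6 - log10(ic50)
}

#' Chemical hardness from frontier-orbital energies
#'
#' Global hardness as half the HOMO-LUMO gap,
#' `eta = (E_LUMO - E_HOMO) / 2`, in the same units as the inputs
#' (Hartree here). Requires a positive gap.
#'
#' @param e_homo Energy of the highest occupied molecular orbital (Hartree).
#' @param e_lumo Energy of the lowest unoccupied molecular orbital (Hartree).
#' @return Hardness in Hartree.
#' @examples
#' hardness_from_orbitals(-0.1961, -0.0486) # 0.07375
#' @export
hardness_from_orbitals <- function(e_homo, e_lumo) {
  if (any(!is.finite(e_homo)) || any(!is.finite(e_lumo))) {
    stop("orbital energies must be finite", call. = FALSE)
  }
  if (any(e_lumo <= e_homo)) {
    stop("non-positive HOMO-LUMO gap: E_LUMO must exceed E_HOMO", call. = FALSE)
  }
  (e_lumo - e_homo) / 2
}
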