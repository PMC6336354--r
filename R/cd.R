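#' Molar ellipticity from raw CD readings
#'
#' Converts an instrument reading in millidegrees to molar ellipticity,
#' \eqn{[\theta] = m\degree \cdot M / (10 L C)} in deg cm^2 dmol^-1, where
#' \eqn{m\degree} is the signal in mdeg, \eqn{M} the molecular weight in
#' g/mol, \eqn{L} the path length in cm and \eqn{C} the mass concentration
#' in g/L. Optionally divides by the number of peptide bonds to report
#' mean residue ellipticity.
#'
#' @param mdeg signal in millidegrees (vectorized, e.g. per wavelength).
#' @param mw molecular weight (g/mol).
#' @param path_cm cuvette path length (cm).
#' @param conc_gl concentration (g/L).
#' @param per_residue divide by \code{n_residues - 1} (default FALSE: the
#'   molar form).
#' @param n_residues residue count, required when \code{per_residue}.
#' @return molar ellipticity in deg cm^2 dmol^-1.
#' @export
molar_ellipticity <- function(mdeg, mw, path_cm, conc_gl,
                              per_residue = FALSE, n_residues = NULL) {
  if (path_cm <= 0 || conc_gl <= 0 || mw <= 0)
    stop("molecular weight, path length and concentration must be positive")
  me <- mdeg * mw / (10 * path_cm * conc_gl)
  if (per_residue) {
    stopifnot(!is.null(n_residues), n_residues >= 2)
    me <- me / (n_residues - 1)
  }
  me
}

#' Convert a CD spectrum with blank subtraction
#'
#' Pointwise subtracts a blank (buffer) spectrum, then converts each
#' wavelength's reading to molar ellipticity.
#'
#' @param spectrum data.frame with columns \code{wavelength_nm},
#'   \code{mdeg}.
#' @param blank optional data.frame with the same columns; must cover every
#'   sample wavelength.
#' @inheritParams molar_ellipticity
#' @return data.frame: \code{wavelength_nm}, \code{mdeg} (blank-corrected),
#'   \code{molar_ellipticity}.
#' @export
cd_spectrum <- function(spectrum, mw, path_cm, conc_gl, blank = NULL,
                        per_residue = FALSE, n_residues = NULL) {
  md <- spectrum$mdeg
  if (!is.null(blank)) {
    i <- match(spectrum$wavelength_nm, blank$wavelength_nm)
    if (anyNA(i)) stop("blank spectrum does not cover all sample wavelengths")
    md <- md - blank$mdeg[i]
  }
  data.frame(wavelength_nm = spectrum$wavelength_nm, mdeg = md,
             molar_ellipticity = molar_ellipticity(md, mw, path_cm, conc_gl,
                                                   per_residue, n_residues))
}
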