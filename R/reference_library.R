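#' Reference chemical-shift library for SSP scoring
#'
#' Returns the packaged reference library used by [secondary_shifts()] and
#' [ssp_profile()]: per (residue type, nucleus) random-coil shifts
#' (\code{rc_ppm}), and the secondary-shift endpoints a nucleus would show in
#' a fully formed alpha helix (\code{d_alpha}) or beta sheet (\code{d_beta}).
#' Random-coil values follow the standard published random-coil compilation
#' for the 20 common amino acids; helix/sheet endpoints are per-nucleus
#' consensus secondary shifts. Glycine carries no CB row and proline no
#' amide (H, N) rows.
#'
#' @return A data.frame with columns \code{residue_type} (one-letter code),
#'   \code{nucleus} (one of \code{"H"}, \code{"N"}, \code{"C"}, \code{"CA"},
#'   \code{"CB"}), \code{rc_ppm}, \code{d_alpha}, \code{d_beta}.
#' @examples
#' lib <- ref_shift_library()
#' subset(lib, residue_type == "A")
#' @export
ref_shift_library <- function() {
  rc <- matrix(c(
    # CA,   CB,    C,     N,     H
    52.5, 19.1, 177.8, 123.8, 8.24,  # A
    56.0, 30.9, 176.3, 120.5, 8.23,  # R
    52.8, 37.9, 175.2, 118.7, 8.40,  # N
    54.2, 41.1, 176.3, 120.4, 8.34,  # D
    58.2, 28.0, 174.6, 118.8, 8.32,  # C
    56.6, 29.2, 176.0, 119.8, 8.32,  # Q
    56.6, 29.9, 176.6, 120.2, 8.42,  # E
    45.1,   NA, 174.9, 108.8, 8.33,  # G
    55.0, 29.0, 174.3, 118.2, 8.42,  # H
    61.1, 38.8, 176.4, 119.9, 8.00,  # I
    55.1, 42.4, 177.6, 121.8, 8.16,  # L
    56.2, 33.1, 176.6, 120.4, 8.29,  # K
    55.4, 32.9, 176.3, 119.6, 8.28,  # M
    57.7, 39.6, 175.8, 120.3, 8.30,  # F
    63.3, 32.1, 177.3,    NA,   NA,  # P
    58.3, 63.8, 174.6, 115.7, 8.31,  # S
    61.8, 69.8, 174.7, 113.6, 8.15,  # T
    57.5, 29.6, 176.1, 121.3, 8.25,  # W
    57.9, 38.8, 175.9, 120.3, 8.12,  # Y
    62.2, 32.9, 176.3, 119.2, 8.03   # V
  ), ncol = 5, byrow = TRUE)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  nuc <- c("CA", "CB", "C", "N", "H")
  # per-nucleus full-helix / full-sheet secondary-shift endpoints (ppm)
  d_alpha <- c(CA = 2.8, CB = -0.5, C = 1.8, N = -1.5, H = -0.25)
  d_beta  <- c(CA = -1.4, CB = 2.2, C = -1.6, N = 2.5, H = 0.35)
  out <- data.frame(
    residue_type = rep(aa, each = length(nuc)),
    nucleus      = rep(nuc, times = length(aa)),
    rc_ppm       = as.vector(t(rc)),
    d_alpha      = rep(unname(d_alpha), times = length(aa)),
    d_beta       = rep(unname(d_beta), times = length(aa)),
    stringsAsFactors = FALSE
  )
  out <- out[!is.na(out$rc_ppm), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @keywords internal
.lib_lookup <- function(library, residue_type, nucleus) {
  i <- match(paste(residue_type, nucleus), paste(library$residue_type, library$nucleus))
  library[i, , drop = FALSE]
}

.NUCLEI <- c("H", "N", "C", "CA", "CB")
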