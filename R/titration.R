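#' Per-residue peak-intensity quenching profile
#'
#' Ratio of bound to free peak heights for each residue of a titration
#' step. Residues whose ratio cannot be obtained (peak overlap, prolines,
#' missing assignment) are carried through with a status flag and no ratio.
#'
#' @param free,bound data.frames with columns \code{residue} and
#'   \code{intensity}.
#' @param statuses optional data.frame (\code{residue}, \code{status}) with
#'   status in \code{c("ok","overlapped","proline","missing")}; residues
#'   not listed default to \code{"ok"}.
#' @param molar_ratio titrant:protein molar ratio label (metadata).
#' @param normalize_region optional integer vector of residue numbers
#'   declared unaffected by binding; when given, ratios are divided by the
#'   mean ok-ratio over that region (corrects inter-sample concentration
#'   differences). Off by default: raw bound/free ratios are reported.
#' @return data.frame of class \code{"quench_profile"}: \code{residue},
#'   \code{ratio} (NA unless status ok), \code{status}; attribute
#'   \code{molar_ratio}.
#' @export
quench_profile <- function(free, bound, statuses = NULL, molar_ratio = NA,
                           normalize_region = NULL) {
  missing_free <- setdiff(bound$residue, free$residue)
  if (length(missing_free))
    stop("residue(s) present in bound but absent in free: ",
         paste(sort(missing_free), collapse = ", "))
  residues <- sort(unique(c(free$residue, bound$residue)))
  status <- rep("ok", length(residues))
  if (!is.null(statuses)) {
    i <- match(statuses$residue, residues)
    status[i[!is.na(i)]] <- statuses$status[!is.na(i)]
  }
  status[!(residues %in% bound$residue)] <- "missing"
  i_free <- free$intensity[match(residues, free$residue)]
  i_bound <- bound$intensity[match(residues, bound$residue)]
  ok <- status == "ok"
  if (any(ok & (is.na(i_free) | i_free <= 0)))
    stop("non-positive or missing free intensity at ok residue(s): ",
         paste(residues[ok & (is.na(i_free) | i_free <= 0)], collapse = ", "))
  ratio <- rep(NA_real_, length(residues))
  ratio[ok] <- i_bound[ok] / i_free[ok]
  if (!is.null(normalize_region)) {
    sel <- ok & residues %in% normalize_region
    if (!any(sel)) stop("no ok residues inside the normalization region")
    ratio <- ratio / mean(ratio[sel])
  }
  if (any(ratio[ok] < 0)) stop("negative intensity ratio encountered")
  out <- data.frame(residue = residues, ratio = ratio, status = status,
                    stringsAsFactors = FALSE)
  attr(out, "molar_ratio") <- molar_ratio
  class(out) <- c("quench_profile", "data.frame")
  out
}

#' Call contiguous binding segments from a quenching profile
#'
#' Finds maximal runs of consecutive ok-residues whose bound/free ratio is
#' at or below \code{threshold}, at least \code{min_length} residues long.
#' A single flagged (overlapped/proline/missing) residue inside a run does
#' not interrupt it (single-gap bridging); gaps of more than one residue
#' do.
#'
#' @param profile a [quench_profile()].
#' @param threshold ratio cutoff in (0, 1) (default 0.5).
#' @param min_length minimum run length in residues (default 3).
#' @return data.frame: \code{start_residue}, \code{end_residue},
#'   \code{mean_ratio} (over ok residues in the segment); zero rows when
#'   nothing is called.
#' @export
call_binding_segments <- function(profile, threshold = 0.5, min_length = 3L) {
  stopifnot(threshold > 0, threshold < 1, min_length >= 1L)
  res <- profile$residue
  ok <- profile$status == "ok"
  below <- ok & !is.na(profile$ratio) & profile$ratio <= threshold
  above <- ok & !is.na(profile$ratio) & profile$ratio > threshold
  # state per residue position: 1 = below, 0 = flagged (bridgeable), -1 = above
  full <- seq(min(res), max(res))
  st <- rep(0L, length(full))                 # unobserved = flagged
  st[match(res[below], full)] <- 1L
  st[match(res[above], full)] <- -1L
  segs <- list()
  i <- 1L
  n <- length(full)
  while (i <= n) {
    if (st[i] == 1L) {
      j <- i
      gap <- 0L
      last_below <- i
      while (j < n) {
        nxt <- st[j + 1L]
        if (nxt == 1L) { j <- j + 1L; last_below <- j; gap <- 0L }
        else if (nxt == 0L && gap == 0L) { j <- j + 1L; gap <- 1L }
        else break
      }
      j <- last_below
      members <- full[i:j]
      ok_members <- members[members %in% res[below]]
      if (j - i + 1L >= min_length)
        segs[[length(segs) + 1L]] <- data.frame(
          start_residue = full[i], end_residue = full[j],
          mean_ratio = mean(profile$ratio[profile$residue %in% ok_members]))
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(segs))
    return(data.frame(start_residue = integer(), end_residue = integer(),
                      mean_ratio = numeric()))
  do.call(rbind, segs)
}
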