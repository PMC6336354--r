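#' @title Synthetic-data generators with attached ground truth
#' @description Every pipeline stage has a generator producing inputs with
#'   the statistical structure that stage assumes: population-weighted
#'   helix/coil chemical shifts, monoexponential intensity decays on the
#'   standard sampling grids, 1:1 Langmuir sensorgrams over the standard
#'   concentration ladder, depletion-corrected binding isotherms,
#'   run-and-pause particle tracks, and puncta-on-background images. Each
#'   generator takes an explicit integer seed and attaches a
#'   \code{"truth"} attribute with the generating parameters; the same
#'   seed reproduces the dataset bit-exactly.
#' @name synthetic_data
NULL

.with_truth <- function(x, generator, seed, params) {
  attr(x, "truth") <- list(generator = generator, seed = seed,
                           params = params)
  x
}

#' Ground truth attached to a synthetic dataset
#' @param x object produced by a generator in this package.
#' @return list with \code{generator}, \code{seed}, \code{params}.
#' @export
synthetic_truth <- function(x) attr(x, "truth")

#' Generate chemical shifts for a partially helical disordered chain
#'
#' Observed shifts follow a two-state population-weighted model:
#' \eqn{\delta_{obs} = \delta_{rc} + p \Delta\delta_\alpha + \epsilon},
#' with per-residue helical population p and Gaussian noise per nucleus.
#'
#' @param sequence one-letter amino-acid string.
#' @param helix_population per-residue helical fraction in \[0, 1\]
#'   (length = nchar(sequence)).
#' @param library reference library ([ref_shift_library()]).
#' @param noise_sd_ppm named numeric, Gaussian noise sd per nucleus
#'   (single value recycled; default 0).
#' @param seed integer seed.
#' @param offset residue number of sequence position 1.
#' @return a [shift_table()] with a \code{"truth"} attribute.
#' @export
gen_idr_shifts <- function(sequence, helix_population,
                           library = ref_shift_library(),
                           noise_sd_ppm = 0, seed = 1L, offset = 1L) {
  seq_chars <- strsplit(toupper(sequence), "")[[1]]
  stopifnot(length(helix_population) == length(seq_chars),
            all(helix_population >= 0 & helix_population <= 1))
  set.seed(as.integer(seed))
  res_nums <- seq_along(seq_chars) + as.integer(offset) - 1L
  rows <- do.call(rbind, lapply(seq_along(seq_chars), function(i) {
    sub <- library[library$residue_type == seq_chars[i], , drop = FALSE]
    if (!nrow(sub)) stop("residue type not in library: ", seq_chars[i])
    sd_i <- if (length(noise_sd_ppm) == 1L) rep(noise_sd_ppm, nrow(sub))
            else noise_sd_ppm[sub$nucleus]
    data.frame(residue_number = res_nums[i], residue_type = seq_chars[i],
               nucleus = sub$nucleus,
               shift = sub$rc_ppm + helix_population[i] * sub$d_alpha +
                       stats::rnorm(nrow(sub), 0, sd_i),
               stringsAsFactors = FALSE)
  }))
  tb <- shift_table(rows$residue_number, rows$residue_type, rows$nucleus,
                    rows$shift)
  .with_truth(tb, "gen_idr_shifts", seed,
              list(sequence = sequence, helix_population = helix_population,
                   noise_sd_ppm = noise_sd_ppm, offset = offset))
}

#' Generate monoexponential intensity decay series
#'
#' @param rates named numeric vector of decay rates per residue (s^-1);
#'   names are residue numbers.
#' @param i0 initial intensity (single value or per residue).
#' @param time_grid sampling times in seconds (default the standard R1
#'   grid, [relaxation_time_grid()]).
#' @param noise_sd Gaussian noise sd (intensity units).
#' @param seed integer seed.
#' @return a \code{long_table} (series_key = residue, x = time, y =
#'   intensity) with a \code{"truth"} attribute.
#' @export
gen_decay_series <- function(rates, i0 = 100,
                             time_grid = relaxation_time_grid("r1"),
                             noise_sd = 0, seed = 1L) {
  stopifnot(all(rates > 0))
  set.seed(as.integer(seed))
  i0 <- rep(i0, length.out = length(rates))
  keys <- if (!is.null(names(rates))) names(rates) else as.character(seq_along(rates))
  out <- do.call(rbind, lapply(seq_along(rates), function(i) {
    data.frame(series_key = keys[i], x = time_grid,
               y = i0[i] * exp(-rates[i] * time_grid) +
                   stats::rnorm(length(time_grid), 0, noise_sd),
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("long_table", "data.frame")
  .with_truth(out, "gen_decay_series", seed,
              list(rates = rates, i0 = i0, time_grid = time_grid,
                   noise_sd = noise_sd))
}

#' Generate a 1:1 Langmuir sensorgram set
#'
#' @param ka,kd,rmax kinetic truth (M^-1 s^-1, s^-1, RU).
#' @param concentrations analyte ladder in M (default the standard
#'   5-point series 50, 11, 4.5, 1.8, 0.3 uM).
#' @param t_a,t_d association and dissociation end times (s; defaults 120
#'   and 720).
#' @param dt sampling interval (s).
#' @param noise_sd Gaussian noise sd (RU).
#' @param seed integer seed.
#' @return data.frame (\code{conc}, \code{time}, \code{response}) with a
#'   \code{"truth"} attribute.
#' @export
gen_sensorgrams <- function(ka, kd, rmax,
                            concentrations = c(50, 11, 4.5, 1.8, 0.3) * 1e-6,
                            t_a = 120, t_d = 720, dt = 1, noise_sd = 0,
                            seed = 1L) {
  stopifnot(ka > 0, kd > 0, rmax > 0, t_a < t_d)
  set.seed(as.integer(seed))
  times <- seq(0, t_d, by = dt)
  out <- do.call(rbind, lapply(concentrations, function(cc) {
    data.frame(conc = cc, time = times,
               response = model_sensorgram(ka, kd, rmax, cc, times, t_a) +
                          stats::rnorm(length(times), 0, noise_sd))
  }))
  .with_truth(out, "gen_sensorgrams", seed,
              list(ka = ka, kd = kd, rmax = rmax,
                   concentrations = concentrations, t_a = t_a, t_d = t_d,
                   dt = dt, noise_sd = noise_sd))
}

#' Generate a depletion-corrected equilibrium isotherm
#'
#' @param kd_m dissociation constant truth (M).
#' @param l0 labeled-species concentration (M, default 10 nM).
#' @param top_concentration highest titrant concentration (M, default
#'   42.5 uM).
#' @param n_points number of capillaries (default 16).
#' @param dilution_factor serial dilution factor (default 2).
#' @param s_free,s_bound free and bound signal levels.
#' @param noise_sd Gaussian noise sd (signal units).
#' @param seed integer seed.
#' @return data.frame (\code{titrant_M}, \code{signal}) with a
#'   \code{"truth"} attribute.
#' @export
gen_isotherm <- function(kd_m, l0 = 10e-9, top_concentration = 42.5e-6,
                         n_points = 16L, dilution_factor = 2,
                         s_free = 800, s_bound = 900, noise_sd = 0,
                         seed = 1L) {
  stopifnot(kd_m > 0, l0 > 0, top_concentration > 0, n_points >= 2L)
  set.seed(as.integer(seed))
  t0 <- top_concentration / dilution_factor^(seq_len(n_points) - 1L)
  fb <- fraction_bound(t0, l0, kd_m)
  out <- data.frame(titrant_M = t0,
                    signal = s_free + (s_bound - s_free) * fb +
                             stats::rnorm(n_points, 0, noise_sd))
  .with_truth(out, "gen_isotherm", seed,
              list(kd_m = kd_m, l0 = l0,
                   top_concentration = top_concentration,
                   n_points = n_points, dilution_factor = dilution_factor,
                   s_free = s_free, s_bound = s_bound, noise_sd = noise_sd))
}

#' Generate run-and-pause particle tracks
#'
#' Discrete-state Markov motility: each frame the particle is anterograde,
#' retrograde, or paused, moving at the state velocity; states evolve by a
#' per-frame transition matrix. Positions are integrated displacements.
#'
#' @param n_tracks number of tracks.
#' @param duration track duration (s).
#' @param dt frame interval (s, default 0.2).
#' @param velocities named numeric: \code{anterograde} (positive um/s),
#'   \code{retrograde} (negative um/s).
#' @param transition 3x3 row-stochastic matrix over states (anterograde,
#'   retrograde, pause), in that order.
#' @param start_state initial state index or \code{"stationary_dist"}
#'   sampling from the uniform distribution over states.
#' @param seed integer seed.
#' @return list of numeric position vectors with a \code{"truth"}
#'   attribute.
#' @export
gen_tracks <- function(n_tracks, duration, dt = 0.2,
                       velocities = c(anterograde = 1, retrograde = -1.2),
                       transition = default_transition_matrix(),
                       start_state = "stationary_dist", seed = 1L) {
  stopifnot(n_tracks >= 1L, duration > dt,
            nrow(transition) == 3L, ncol(transition) == 3L,
            all(abs(rowSums(transition) - 1) < 1e-12))
  set.seed(as.integer(seed))
  n_frames <- floor(duration / dt)
  vel <- c(velocities[["anterograde"]], velocities[["retrograde"]], 0)
  tracks <- lapply(seq_len(n_tracks), function(i) {
    s <- if (identical(start_state, "stationary_dist"))
      sample.int(3L, 1L) else as.integer(start_state)
    states <- integer(n_frames)
    for (f in seq_len(n_frames)) {
      states[f] <- s
      s <- sample.int(3L, 1L, prob = transition[s, ])
    }
    c(0, cumsum(vel[states] * dt))
  })
  .with_truth(tracks, "gen_tracks", seed,
              list(n_tracks = n_tracks, duration = duration, dt = dt,
                   velocities = velocities, transition = transition))
}

#' Default motility transition matrix
#'
#' Per-frame transition probabilities over (anterograde, retrograde,
#' pause) giving persistent runs interrupted by pauses and occasional
#' reversals, typical of organelle transport imaged at 5 frames per
#' second.
#' @return 3x3 row-stochastic matrix.
#' @export
default_transition_matrix <- function() {
  matrix(c(0.92, 0.01, 0.07,
           0.01, 0.92, 0.07,
           0.05, 0.05, 0.90), nrow = 3, byrow = TRUE,
         dimnames = list(c("anterograde", "retrograde", "pause"),
                         c("anterograde", "retrograde", "pause")))
}

#' Generate a puncta-on-background image with ROI masks
#'
#' Gaussian puncta of given integrated intensity on a constant background
#' with optional Gaussian noise. Inner masks cover each punctum out to
#' \code{mask_radius_sigma} standard deviations.
#'
#' @param shape c(rows, cols) in pixels.
#' @param background_level constant background (counts per pixel).
#' @param puncta data.frame: \code{x} (col), \code{y} (row),
#'   \code{integrated_intensity} (counts), \code{width} (Gaussian sigma,
#'   px).
#' @param noise_sd Gaussian noise sd per pixel.
#' @param mask_radius_sigma inner-mask radius in sigmas (default 5).
#' @param seed integer seed.
#' @return list: \code{image} (matrix), \code{masks} (list of logical
#'   matrices, one per punctum), with a \code{"truth"} attribute.
#' @export
gen_roi_image <- function(shape, background_level, puncta = NULL,
                          noise_sd = 0, mask_radius_sigma = 5, seed = 1L) {
  set.seed(as.integer(seed))
  nr <- shape[1]; nc <- shape[2]
  img <- matrix(background_level, nr, nc)
  masks <- list()
  rowc <- matrix(seq_len(nr), nr, nc)
  colc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  if (!is.null(puncta) && nrow(puncta)) {
    for (i in seq_len(nrow(puncta))) {
      p <- puncta[i, ]
      stopifnot(p$x >= 1, p$x <= nc, p$y >= 1, p$y <= nr)
      d2 <- (rowc - p$y)^2 + (colc - p$x)^2
      amp <- p$integrated_intensity / (2 * pi * p$width^2)
      img <- img + amp * exp(-d2 / (2 * p$width^2))
      masks[[i]] <- sqrt(d2) <= mask_radius_sigma * p$width
    }
  }
  if (noise_sd > 0) img <- img + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
  .with_truth(list(image = img, masks = masks), "gen_roi_image", seed,
              list(shape = shape, background_level = background_level,
                   puncta = puncta, noise_sd = noise_sd,
                   mask_radius_sigma = mask_radius_sigma))
}
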