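#' Frame geometry for a simulation task
#'
#' Frames are stored depth-major: row 1 is the shallowest depth (nearest the
#' needle tip), the row index increases with depth Z, and columns span the
#' lateral X axis. Classification frames are 181 (X) x 241 (Z) pixels;
#' distance-regression frames are 241 (X) x 681 (Z) pixels. The physical
#' pixel size is 6.25 um in both directions.
#'
#' @param task `"classify"` or `"regress"`.
#' @param pixel_size_um Physical pixel size in micrometres.
#' @return A list with `task`, `width_px`, `depth_px`, `pixel_size_um`.
#' @export
#' @examples
#' frame_geometry("classify")
frame_geometry <- function(task = c("classify", "regress"), pixel_size_um = 6.25) {
  task <- match.arg(task)
  if (task == "classify") {
    g <- list(task = task, width_px = 181L, depth_px = 241L,
              pixel_size_um = pixel_size_um)
  } else {
    g <- list(task = task, width_px = 241L, depth_px = 681L,
              pixel_size_um = pixel_size_um)
  }
  structure(g, class = "oct_geometry")
}

#' Per-tissue generative appearance parameters
#'
#' One row per tissue layer. The defaults encode the qualitative B-scan
#' signatures of the five layers: the interspinous ligament has the longest
#' attenuation length (deepest penetration) and periodic transverse stripes
#' from its fibre structure; the ligamentum flavum is brightest at the
#' surface with the shallowest penetration; fat and spinal cord have similar
#' intermediate penetration but fat's lateral intensity distribution is much
#' less even; the epidural space shows a dark gap between the needle tip and
#' the dura, with dura/cord-like tissue beyond it.
#'
#' @param confusable If `TRUE`, the spinal-cord appearance is set equal to
#'   the fat appearance, making the two classes statistically
#'   indistinguishable for a five-class classifier while leaving every
#'   adjacent-layer contrast used by the sequential cascade intact.
#' @return A tibble with columns `label`, `surface_brightness`,
#'   `attenuation_length_px`, `stripe_period_px`, `stripe_amplitude`,
#'   `heterogeneity_scale`, `speckle_variance`, `noise_floor`.
#' @export
#' @examples
#' default_appearances()
default_appearances <- function(confusable = FALSE) {
  app <- tibble(
    label = as_tissue_label(tissue_labels()),
    surface_brightness    = c(170, 150, 235, 180, 180),
    attenuation_length_px = c(55,  95,  30,  50,  50),
    stripe_period_px      = c(0,   22,  0,   0,   0),
    stripe_amplitude      = c(0,   0.45, 0,  0,   0),
    heterogeneity_scale   = c(0.35, 0.10, 0.10, 0.10, 0.08),
    speckle_variance      = c(0.30, 0.30, 0.30, 0.30, 0.30),
    noise_floor           = c(18,  18,  18,  18,  18)
  )
  if (confusable) {
    fat <- which(app$label == "fat")
    sc  <- which(app$label == "spinal_cord")
    app[sc, -1] <- app[fat, -1]
  }
  app
}

# numeric appearance columns that per-subject multipliers apply to,
# with the log-normal sdlog of each multiplier
.appearance_sdlog <- c(
  surface_brightness    = 0.10,
  attenuation_length_px = 0.10,
  stripe_period_px      = 0.00,
  stripe_amplitude      = 0.15,
  heterogeneity_scale   = 0.15,
  speckle_variance      = 0.10,
  noise_floor           = 0.05
)

#' Draw per-subject appearance multipliers
#'
#' One log-normal scale factor per appearance parameter, shared across all
#' tissue layers of the subject (a subject-level global effect, e.g. overall
#' brightness), so within-subject class contrasts are preserved while
#' between-subject shifts make subject-grouped validation non-trivial.
#'
#' @param sdlog_scale Overall multiplier on the per-parameter sdlog values;
#'   0 disables subject variability.
#' @return Named numeric vector of multipliers.
#' @keywords internal
.draw_subject_multipliers <- function(sdlog_scale = 1) {
  sdl <- .appearance_sdlog * sdlog_scale
  stats::setNames(rlnorm(length(sdl), 0, sdl), names(sdl))
}

.apply_multipliers <- function(appearances, mult) {
  for (nm in names(mult)) {
    appearances[[nm]] <- appearances[[nm]] * mult[[nm]]
  }
  appearances
}

# one-row appearance for a label
.appearance_row <- function(appearances, label) {
  row <- appearances[appearances$label == as.character(label), ]
  if (nrow(row) != 1) abort(paste0("no appearance row for label ", label))
  row
}

#' Construct an OCT frame object
#'
#' @param pixels Integer matrix, `depth_px` rows x `width_px` columns,
#'   values in 0--255.
#' @param label Tissue label.
#' @param subject_id Subject identifier.
#' @param distance_um Needle-tip-to-dura distance in um; required for
#'   epidural-space frames and disallowed otherwise.
#' @param pixel_size_um Physical pixel size.
#' @return An `oct_frame` object.
#' @export
oct_frame <- function(pixels, label, subject_id = NA_integer_,
                      distance_um = NULL, pixel_size_um = 6.25) {
  label <- as_tissue_label(label)
  stopifnot(is.matrix(pixels))
  if (min(pixels) < 0 || max(pixels) > 255) {
    abort("pixel intensities must lie in [0, 255]")
  }
  is_epi <- label == "epidural_space"
  if (is_epi && is.null(distance_um)) {
    abort("epidural-space frames require a distance_um label")
  }
  if (!is_epi && !is.null(distance_um)) {
    abort("distance_um may only be supplied for epidural-space frames")
  }
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         subject_id = subject_id, label = label,
         distance_um = if (is_epi) distance_um else NA_real_),
    class = "oct_frame"
  )
}

#' @export
print.oct_frame <- function(x, ...) {
  cat(sprintf("<oct_frame> %s, %d x %d px (depth x width), subject %s",
              as.character(x$label), nrow(x$pixels), ncol(x$pixels),
              as.character(x$subject_id)))
  if (!is.na(x$distance_um)) cat(sprintf(", distance %.1f um", x$distance_um))
  cat("\n")
  invisible(x)
}

# separable 3-tap Gaussian blur (PSF stand-in), edge-replicated
.blur3 <- function(m) {
  d <- nrow(m)
  w <- ncol(m)
  m <- 0.25 * m[c(1L, seq_len(d - 1L)), , drop = FALSE] + 0.5 * m +
       0.25 * m[c(seq_len(d - 1L) + 1L, d), , drop = FALSE]
  m <- 0.25 * m[, c(1L, seq_len(w - 1L)), drop = FALSE] + 0.5 * m +
       0.25 * m[, c(seq_len(w - 1L) + 1L, w), drop = FALSE]
  m
}

# smooth unit-variance lateral modulation curve over w columns
.lateral_profile <- function(w) {
  x <- seq_len(w) / w
  freq <- runif(3, 1, 4)
  amp <- runif(3, 0.5, 1)
  phase <- runif(3, 0, 2 * pi)
  s <- amp[1] * sin(2 * pi * freq[1] * x + phase[1]) +
       amp[2] * sin(2 * pi * freq[2] * x + phase[2]) +
       amp[3] * sin(2 * pi * freq[3] * x + phase[3])
  s <- s / max(sd(s), 1e-8)
  pmin(pmax(s, -2), 2)
}

#' Simulate a single OCT B-scan frame
#'
#' Generative model: a background noise floor everywhere, plus, below the
#' tissue surface row, `surface_brightness * exp(-(z - z0) /
#' attenuation_length)` modulated by class-specific depth-periodic stripes
#' (interspinous ligament), low-frequency lateral heterogeneity (strongest
#' for fat) and unit-mean multiplicative gamma speckle; a small separable
#' Gaussian blur stands in for the PSF; the result is clipped and quantised
#' to 8-bit. For non-epidural layers the surface row is jittered uniformly
#' within `surface_jitter`; for epidural-space frames the surface sits at
#' `round(distance_um / pixel_size_um)` background rows, so everything
#' shallower is noise-floor background (the dark gap in front of the needle)
#' and the dura/cord surface begins at that row.
#'
#' @param label Tissue label (see [tissue_labels()]).
#' @param appearances Appearance table as from [default_appearances()].
#' @param geometry Frame geometry from [frame_geometry()], or a task name.
#' @param distance_um Needle-to-dura distance in um; required iff `label` is
#'   `"epidural_space"`, and must not exceed the frame depth extent.
#' @param subject_id Subject identifier stored on the frame.
#' @param surface_jitter Integer range (rows) of the surface-depth jitter
#'   for non-epidural layers.
#' @return An [oct_frame()].
#' @export
#' @examples
#' fr <- simulate_frame("ligamentum_flavum")
#' dim(fr$pixels)
simulate_frame <- function(label, appearances = default_appearances(),
                           geometry = frame_geometry("classify"),
                           distance_um = NULL, subject_id = NA_integer_,
                           surface_jitter = c(4L, 12L)) {
  if (is.character(geometry)) geometry <- frame_geometry(geometry)
  label <- as_tissue_label(label)
  d <- geometry$depth_px
  w <- geometry$width_px
  px <- geometry$pixel_size_um
  is_epi <- label == "epidural_space"

  if (is_epi) {
    if (is.null(distance_um)) {
      abort("epidural-space frames require distance_um")
    }
    if (distance_um < 0 || distance_um > d * px) {
      abort(sprintf(
        "distance_um = %.1f lies outside the frame depth extent [0, %.1f] um",
        distance_um, d * px))
    }
    z0 <- as.integer(round(distance_um / px))
  } else {
    if (!is.null(distance_um)) {
      abort("distance_um may only be supplied for epidural-space frames")
    }
    z0 <- as.integer(round(runif(1, surface_jitter[1], surface_jitter[2])))
  }

  app <- .appearance_row(appearances, label)
  floor_ <- app$noise_floor
  img <- matrix(rnorm(d * w, mean = floor_, sd = floor_ / 4), d, w)

  if (z0 < d) {
    nt <- d - z0
    tloc <- seq_len(nt)
    prof <- app$surface_brightness * exp(-(tloc - 1) / app$attenuation_length_px)
    if (app$stripe_amplitude > 0 && app$stripe_period_px > 0) {
      phase <- runif(1, 0, 2 * pi)
      prof <- prof * (1 + app$stripe_amplitude *
                        sin(2 * pi * tloc / app$stripe_period_px + phase))
    }
    lat <- pmax(1 + app$heterogeneity_scale * .lateral_profile(w), 0.05)
    tis <- outer(prof, lat)
    v <- app$speckle_variance
    if (v > 0) {
      tis <- tis * matrix(rgamma(nt * w, shape = 1 / v, rate = 1 / v), nt, w)
    }
    img[(z0 + 1L):d, ] <- img[(z0 + 1L):d, ] + tis
  }

  img <- .blur3(img)
  # acquisition post-processing: each image is scaled into the 0-255 range,
  # so absolute brightness is only meaningful relative to the in-frame peak
  rng <- range(img)
  img <- (img - rng[1]) / max(rng[2] - rng[1], 1e-8) * 255
  pix <- matrix(as.integer(round(img)), d, w)
  oct_frame(pix, label, subject_id = subject_id,
            distance_um = if (is_epi) distance_um else NULL,
            pixel_size_um = px)
}

# default epidural distance range per task, um; must fit in the frame depth
.default_distance_range <- function(geometry) {
  if (geometry$task == "classify") c(200, 1400) else c(200, 2500)
}

#' Simulate all frames for one subject
#'
#' Generates `frames_per_layer` frames for each of the five tissue layers.
#' A single set of per-subject appearance multipliers (log-normal, one per
#' appearance parameter) is drawn once and applied to every frame of the
#' subject. Epidural-space distances are drawn uniformly from
#' `distance_range_um`.
#'
#' @param subject_id Integer subject identifier.
#' @param frames_per_layer Frames per tissue layer (the acquisition default
#'   is 1000).
#' @param task `"classify"` or `"regress"` frame geometry.
#' @param distance_range_um Length-2 range of epidural distances in um;
#'   defaults to 200--1400 for classification frames and 200--2500 for
#'   regression frames (the range must fit within the frame depth).
#' @param appearances Base appearance table.
#' @param subject_sdlog Overall scale on the per-parameter multiplier
#'   sdlog values; 0 disables subject-level variability.
#' @param layers Tissue layers to generate (default all five); e.g.
#'   `"epidural_space"` alone for a distance-regression dataset.
#' @param seed Optional seed; when supplied the subject is generated under a
#'   private RNG state and is bit-reproducible.
#' @return A tibble with columns `subject_id`, `label`, `distance_um`
#'   (`NA` for non-epidural frames) and a `frame` list-column of
#'   [oct_frame()] objects.
#' @export
#' @examples
#' d <- simulate_subject(1, frames_per_layer = 2, seed = 1)
#' nrow(d)  # 10 frames: 2 per layer
simulate_subject <- function(subject_id, frames_per_layer = 1000,
                             task = c("classify", "regress"),
                             distance_range_um = NULL,
                             appearances = default_appearances(),
                             subject_sdlog = 1, layers = tissue_labels(),
                             seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, simulate_subject(
      subject_id, frames_per_layer, task, distance_range_um,
      appearances, subject_sdlog, layers, seed = NULL)))
  }
  layers <- as.character(as_tissue_label(layers))
  task <- if (inherits(task, "oct_geometry")) task$task else match.arg(task)
  geometry <- frame_geometry(task)
  if (frames_per_layer < 1) abort("frames_per_layer must be >= 1")
  if (is.null(distance_range_um)) {
    distance_range_um <- .default_distance_range(geometry)
  }
  dmax <- geometry$depth_px * geometry$pixel_size_um
  if (distance_range_um[1] < 0 || distance_range_um[2] > dmax) {
    abort(sprintf("distance_range_um must lie within the frame depth [0, %.1f]",
                  dmax))
  }

  mult <- .draw_subject_multipliers(subject_sdlog)
  app <- .apply_multipliers(appearances, mult)

  rows <- purrr::map(layers, function(lab) {
    frames <- vector("list", frames_per_layer)
    dists <- rep(NA_real_, frames_per_layer)
    for (i in seq_len(frames_per_layer)) {
      dist_i <- if (lab == "epidural_space") {
        runif(1, distance_range_um[1], distance_range_um[2])
      } else NULL
      frames[[i]] <- simulate_frame(lab, app, geometry, distance_um = dist_i,
                                    subject_id = subject_id)
      if (!is.null(dist_i)) dists[i] <- dist_i
    }
    tibble(subject_id = subject_id, label = as_tissue_label(lab),
           distance_um = dists, frame = frames)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "geometry") <- geometry
  attr(out, "multipliers") <- mult
  out
}

#' Simulate a multi-subject study dataset
#'
#' @param n_subjects Number of subjects (the study default is 8).
#' @param frames_per_layer Frames per layer per subject.
#' @param seed Seed for the whole study; subject s is generated under seed
#'   `seed + s` so subjects can be regenerated independently.
#' @inheritParams simulate_subject
#' @return Tibble of all subjects' frames (see [simulate_subject()]).
#' @export
simulate_study <- function(n_subjects = 8, frames_per_layer = 1000,
                           task = c("classify", "regress"),
                           distance_range_um = NULL,
                           appearances = default_appearances(),
                           subject_sdlog = 1, layers = tissue_labels(),
                           seed = 1L) {
  task <- match.arg(task)
  out <- dplyr::bind_rows(purrr::map(seq_len(n_subjects), function(s) {
    simulate_subject(s, frames_per_layer, task, distance_range_um,
                     appearances, subject_sdlog, layers,
                     seed = if (is.null(seed)) NULL else seed + s)
  }))
  attr(out, "geometry") <- frame_geometry(task)
  out
}

#' Simulate a needle-insertion B-scan stream
#'
#' Concatenates frames in puncture order with per-frame truth labels. The
#' default segment lengths are 100, 700, 100, 100 and 150 frames for fat,
#' interspinous ligament, ligamentum flavum, epidural space and spinal cord,
#' proportional to the layer widths. Within the epidural segment the
#' needle-to-dura distance decreases monotonically (the needle advancing).
#'
#' @param segment_lengths Five nonnegative frame counts in puncture order.
#' @param appearances Base appearance table.
#' @param task Frame geometry task.
#' @param distance_range_um Range of epidural distances traversed; the
#'   segment runs from the far end to the near end of this range.
#' @param subject_id Subject identifier stamped on the frames.
#' @param subject_sdlog Subject-level variability scale (one multiplier set
#'   for the whole stream).
#' @param seed Optional seed for bit-reproducibility.
#' @return A tibble with columns `t` (frame index), `subject_id`, `label`,
#'   `distance_um`, `frame`.
#' @export
#' @examples
#' seq5 <- simulate_insertion_sequence(c(0, 0, 0, 0, 5), seed = 1)
#' nrow(seq5)
simulate_insertion_sequence <- function(segment_lengths = c(100, 700, 100, 100, 150),
                                        appearances = default_appearances(),
                                        task = c("classify", "regress"),
                                        distance_range_um = NULL,
                                        subject_id = 1L,
                                        subject_sdlog = 1, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, simulate_insertion_sequence(
      segment_lengths, appearances, task, distance_range_um, subject_id,
      subject_sdlog, seed = NULL)))
  }
  task <- match.arg(task)
  geometry <- frame_geometry(task)
  if (length(segment_lengths) != 5 || any(segment_lengths < 0)) {
    abort("segment_lengths must be five nonnegative counts")
  }
  if (is.null(distance_range_um)) {
    distance_range_um <- .default_distance_range(geometry)
  }
  mult <- .draw_subject_multipliers(subject_sdlog)
  app <- .apply_multipliers(appearances, mult)

  labs <- tissue_labels()
  n_epi <- segment_lengths[4]
  epi_dists <- if (n_epi > 0) {
    seq(distance_range_um[2], distance_range_um[1], length.out = n_epi)
  } else numeric(0)

  rows <- purrr::map(1:5, function(k) {
    n <- segment_lengths[k]
    if (n == 0) return(NULL)
    frames <- vector("list", n)
    dists <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      dist_i <- if (k == 4) epi_dists[i] else NULL
      frames[[i]] <- simulate_frame(labs[k], app, geometry,
                                    distance_um = dist_i,
                                    subject_id = subject_id)
      if (!is.null(dist_i)) dists[i] <- dist_i
    }
    tibble(subject_id = subject_id, label = as_tissue_label(labs[k]),
           distance_um = dists, frame = frames)
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out, t = dplyr::row_number(), .before = 1)
  attr(out, "geometry") <- geometry
  out
}
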