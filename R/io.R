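#' Write a dataset as PNG frames plus a CSV manifest
#'
#' Frames are written as 8-bit grayscale PNGs under
#' `dir/subject_<id>/<label>/frame_<n>.png`; the manifest
#' (`dir/manifest.csv`) has columns `subject_id`, `relative_path`,
#' `tissue_label`, `distance_um` (empty for non-epidural frames) and
#' `seed`, enough provenance to regenerate the dataset bit-for-bit.
#'
#' @param data Dataset tibble from [simulate_subject()]/[simulate_study()].
#' @param dir Output directory (created if missing).
#' @param seed The generator seed recorded in the manifest (`NA` for
#'   external data).
#' @return The manifest tibble, invisibly.
#' @export
write_dataset <- function(data, dir, seed = NA_integer_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_in_group <- stats::ave(seq_len(nrow(data)), data$subject_id,
                           as.character(data$label), FUN = seq_along)
  rel <- sprintf("subject_%s/%s/frame_%04d.png",
                 data$subject_id, as.character(data$label), n_in_group)
  for (i in seq_len(nrow(data))) {
    path <- file.path(dir, rel[i])
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    png::writePNG(.frame_pixels(data$frame[[i]]) / 255, path)
  }
  manifest <- tibble(
    subject_id = data$subject_id,
    relative_path = rel,
    tissue_label = as.character(data$label),
    distance_um = data$distance_um,
    seed = seed
  )
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE,
            na = "")
  invisible(manifest)
}

#' Read and validate a dataset manifest
#'
#' Checks the header, that every referenced file resolves, and the
#' distance rule: `distance_um` must be present on epidural-space rows and
#' absent elsewhere. Malformed rows are reported with their row numbers.
#'
#' @param path Path to a `manifest.csv` written by [write_dataset()].
#' @return The manifest tibble with the dataset directory attached as the
#'   `"dir"` attribute; frames load lazily via [load_frames()].
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(paste0("manifest not found: ", path))
  m <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "relative_path", "tissue_label", "distance_um", "seed")
  if (!all(needed %in% names(m))) {
    abort(paste0("bad manifest header; need columns: ",
                 paste(needed, collapse = ", ")))
  }
  m$distance_um <- suppressWarnings(as.numeric(m$distance_um))
  bad_label <- which(!m$tissue_label %in% tissue_labels())
  if (length(bad_label) > 0) {
    abort(paste0("unknown tissue label in manifest row(s): ",
                 paste(bad_label, collapse = ", ")))
  }
  is_epi <- m$tissue_label == "epidural_space"
  bad_dist <- which((is_epi & is.na(m$distance_um)) |
                      (!is_epi & !is.na(m$distance_um)))
  if (length(bad_dist) > 0) {
    abort(paste0("distance_um must be present iff tissue is epidural_space; ",
                 "bad row(s): ", paste(bad_dist, collapse = ", ")))
  }
  dir <- dirname(path)
  missing <- which(!file.exists(file.path(dir, m$relative_path)))
  if (length(missing) > 0) {
    abort(paste0("unresolvable frame path(s) at manifest row(s): ",
                 paste(missing, collapse = ", ")))
  }
  out <- as_tibble(m)
  attr(out, "dir") <- dir
  out
}

#' Load frames referenced by a manifest
#'
#' @param manifest A tibble from [read_manifest()].
#' @param rows Optional row indices to load (default all).
#' @return A dataset tibble with columns `subject_id`, `label`,
#'   `distance_um` and the `frame` list-column.
#' @export
load_frames <- function(manifest, rows = NULL) {
  dir <- attr(manifest, "dir")
  if (is.null(dir)) abort("manifest has no directory attribute; use read_manifest()")
  if (is.null(rows)) rows <- seq_len(nrow(manifest))
  m <- manifest[rows, , drop = FALSE]
  frames <- purrr::map(seq_len(nrow(m)), function(i) {
    img <- png::readPNG(file.path(dir, m$relative_path[i]))
    if (length(dim(img)) == 3) img <- img[, , 1]
    pix <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
    oct_frame(pix, m$tissue_label[i], subject_id = m$subject_id[i],
              distance_um = if (m$tissue_label[i] == "epidural_space")
                m$distance_um[i] else NULL)
  })
  tibble(subject_id = m$subject_id,
         label = as_tissue_label(m$tissue_label),
         distance_um = m$distance_um,
         frame = frames)
}
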