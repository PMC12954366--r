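#' Electrode montage
#'
#' A montage pairs an ordered set of channel names with 3D positions on a
#' unit sphere approximating the head. It is the source of channel
#' adjacency (for searchlight neighbourhoods and spatio-temporal
#' clustering), region-of-interest membership, and the scalp projection
#' used by the synthetic generator's spatial topographies.
#'
#' @param channels character vector of unique channel names.
#' @param positions numeric matrix, one row per channel, columns x
#'   (towards the right ear), y (towards the nasion), z (towards the
#'   vertex).
#' @return An object of class `eeg_montage`.
#' @seealso [biosemi64_montage()], [read_montage()], [build_adjacency()]
#' @export
montage <- function(channels, positions) {
  channels <- as.character(channels)
  positions <- as.matrix(positions)
  if (anyDuplicated(channels)) {
    abort("Montage channel names must be unique.")
  }
  if (nrow(positions) != length(channels) || ncol(positions) != 3L) {
    abort("`positions` must be a length(channels) x 3 matrix.")
  }
  if (!all(is.finite(positions))) {
    abort("Montage positions must be finite.")
  }
  rownames(positions) <- channels
  colnames(positions) <- c("x", "y", "z")
  structure(list(channels = channels, positions = positions),
            class = "eeg_montage")
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d channels: %s ...\n",
              length(x$channels),
              paste(head(x$channels, 6), collapse = ", ")))
  invisible(x)
}

#' Built-in 64-channel montage (10-20 extension)
#'
#' Idealised spherical positions for the standard 64-channel layout used
#' by BioSemi caps (10-10 names). Electrodes are placed on a unit sphere:
#' the outer 10% ring (Fpz, F7, T7, Oz, ...) lies on the equator,
#' midline electrodes are spaced every 18 degrees along the
#' nasion-inion arc, and interior electrodes are spaced uniformly along
#' great-circle arcs between their outer-ring and midline row members.
#' P9/P10 and Iz sit 18 degrees below the equator.
#'
#' These are idealised coordinates, not digitised head measurements; they
#' reproduce the qualitative neighbourhood structure of a real cap (e.g.
#' Cz borders C1, C2, FCz and CPz) which is all the pipeline relies on.
#'
#' @return An `eeg_montage` with 64 channels.
#' @export
#' @examples
#' mon <- biosemi64_montage()
#' length(mon$channels)
biosemi64_montage <- function() {
  eq_point <- function(az_deg, side) {
    a <- az_deg * pi / 180
    c(-side * sin(a), cos(a), 0)
  }
  mid_point <- function(incl_deg, front) {
    b <- incl_deg * pi / 180
    c(0, if (front) sin(b) else -sin(b), cos(b))
  }
  below_point <- function(az_deg, side, incl_deg = 108) {
    a <- az_deg * pi / 180
    b <- incl_deg * pi / 180
    c(-side * sin(a) * sin(b), cos(a) * sin(b), cos(b))
  }
  slerp <- function(p, q, t) {
    w <- acos(max(-1, min(1, sum(p * q))))
    if (w < 1e-12) return(p)
    (sin((1 - t) * w) * p + sin(t * w) * q) / sin(w)
  }

  pos <- list()
  front_mid <- c(Fpz = 90, AFz = 72, Fz = 54, FCz = 36, Cz = 0)
  back_mid <- c(CPz = 36, Pz = 54, POz = 72, Oz = 90)
  for (nm in names(front_mid)) pos[[nm]] <- mid_point(front_mid[[nm]], TRUE)
  for (nm in names(back_mid)) pos[[nm]] <- mid_point(back_mid[[nm]], FALSE)
  pos[["Iz"]] <- mid_point(108, FALSE)

  ring <- c(Fp = 1, AF = 2, F = 3, FT = 4, T = 5, TP = 6, P = 7, PO = 8,
            O = 9)
  ring_names_l <- c("Fp1", "AF7", "F7", "FT7", "T7", "TP7", "P7", "PO7", "O1")
  ring_names_r <- c("Fp2", "AF8", "F8", "FT8", "T8", "TP8", "P8", "PO8", "O2")
  for (i in seq_along(ring)) {
    pos[[ring_names_l[i]]] <- eq_point(ring[[i]] * 18, side = 1)
    pos[[ring_names_r[i]]] <- eq_point(ring[[i]] * 18, side = -1)
  }
  pos[["P9"]] <- below_point(7 * 18, side = 1)
  pos[["P10"]] <- below_point(7 * 18, side = -1)

  rows <- list(
    list(end = c("AF7", "AF8"), mid = "AFz",
         left = c(AF3 = 0.5), right = c(AF4 = 0.5)),
    list(end = c("F7", "F8"), mid = "Fz",
         left = c(F5 = 0.25, F3 = 0.5, F1 = 0.75),
         right = c(F6 = 0.25, F4 = 0.5, F2 = 0.75)),
    list(end = c("FT7", "FT8"), mid = "FCz",
         left = c(FC5 = 0.25, FC3 = 0.5, FC1 = 0.75),
         right = c(FC6 = 0.25, FC4 = 0.5, FC2 = 0.75)),
    list(end = c("T7", "T8"), mid = "Cz",
         left = c(C5 = 0.25, C3 = 0.5, C1 = 0.75),
         right = c(C6 = 0.25, C4 = 0.5, C2 = 0.75)),
    list(end = c("TP7", "TP8"), mid = "CPz",
         left = c(CP5 = 0.25, CP3 = 0.5, CP1 = 0.75),
         right = c(CP6 = 0.25, CP4 = 0.5, CP2 = 0.75)),
    list(end = c("P7", "P8"), mid = "Pz",
         left = c(P5 = 0.25, P3 = 0.5, P1 = 0.75),
         right = c(P6 = 0.25, P4 = 0.5, P2 = 0.75)),
    list(end = c("PO7", "PO8"), mid = "POz",
         left = c(PO3 = 0.5), right = c(PO4 = 0.5))
  )
  for (r in rows) {
    for (nm in names(r$left)) {
      pos[[nm]] <- slerp(pos[[r$end[1]]], pos[[r$mid]], r$left[[nm]])
    }
    for (nm in names(r$right)) {
      pos[[nm]] <- slerp(pos[[r$end[2]]], pos[[r$mid]], r$right[[nm]])
    }
  }

  order64 <- c(
    "Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5", "FC3",
    "FC1", "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3", "CP1", "P1",
    "P3", "P5", "P7", "P9", "PO7", "PO3", "O1", "Iz", "Oz", "POz",
    "Pz", "CPz", "Fpz", "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4",
    "F6", "F8", "FT8", "FC6", "FC4", "FC2", "FCz", "Cz", "C2", "C4",
    "C6", "T8", "TP8", "CP6", "CP4", "CP2", "P2", "P4", "P6", "P8",
    "P10", "PO8", "PO4", "O2")
  montage(order64, do.call(rbind, pos[order64]))
}

#' Read a montage from a plain-text electrode position file
#'
#' Expects one electrode per line: `name x y z`, whitespace-separated
#' (the common .sfp/.elc style). Lines starting with `#` are skipped.
#'
#' @param path file path.
#' @return An `eeg_montage`.
#' @export
read_montage <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) abort("No electrode entries found in file.")
  parts <- strsplit(lines, "[[:space:],]+")
  bad <- vapply(parts, length, 1L) != 4L
  if (any(bad)) {
    abort(sprintf("Malformed electrode line(s): %s",
                  paste(lines[bad], collapse = "; ")))
  }
  nms <- vapply(parts, `[[`, "", 1L)
  xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  if (any(!is.finite(xyz))) abort("Non-numeric electrode coordinates.")
  montage(nms, xyz)
}

#' Write a montage in the same plain-text format
#' @param mon an `eeg_montage`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_montage <- function(mon, path) {
  stopifnot(inherits(mon, "eeg_montage"))
  writeLines(sprintf("%s %.10g %.10g %.10g", mon$channels,
                     mon$positions[, 1], mon$positions[, 2],
                     mon$positions[, 3]), path)
  invisible(path)
}

#' Azimuthal-equidistant projection of a montage onto the plane
#'
#' Projects each electrode from the vertex: the planar radius equals the
#' spherical inclination from the vertex (radians), preserving distances
#' along meridians. This 2D layout underlies the Delaunay adjacency and
#' the synthetic generator's spatial Gaussians.
#'
#' @param mon an `eeg_montage`.
#' @return numeric matrix (channels x 2) with rownames.
#' @export
project_scalp <- function(mon) {
  stopifnot(inherits(mon, "eeg_montage"))
  p <- mon$positions
  nrm <- sqrt(rowSums(p^2))
  if (any(nrm < 1e-12)) abort("Montage contains a zero position.")
  p <- p / nrm
  r <- sqrt(p[, 1]^2 + p[, 2]^2)
  incl <- atan2(r, p[, 3])
  out <- cbind(ifelse(r < 1e-12, 0, incl * p[, 1] / pmax(r, 1e-12)),
               ifelse(r < 1e-12, 0, incl * p[, 2] / pmax(r, 1e-12)))
  dimnames(out) <- list(mon$channels, c("u", "v"))
  out
}

# ROI label rule --------------------------------------------------------

roi_bands <- list(
  anterior = c("Fp", "AF", "F", "FT", "FC"),
  central = c("C", "T", "CP", "TP"),
  posterior = c("P", "PO", "O", "I")
)

# Parse a 10-20 style channel name into prefix and index ("z" for midline).
parse_channel_name <- function(ch) {
  m <- regmatches(ch, regexec("^([A-Za-z]+?)(z|[0-9]+)$", ch))[[1]]
  if (length(m) != 3L) {
    abort(sprintf("Channel name '%s' does not follow the 10-20 naming rule.",
                  ch))
  }
  prefix <- m[2]
  band <- names(roi_bands)[vapply(roi_bands, function(b) prefix %in% b,
                                  logical(1))]
  if (length(band) != 1L) {
    abort(sprintf("Channel name '%s' has unknown row prefix '%s'.",
                  ch, prefix))
  }
  idx <- m[3]
  hemisphere <- if (idx == "z") {
    "midline"
  } else if (as.integer(idx) %% 2L == 1L) {
    "left"
  } else {
    "right"
  }
  list(prefix = prefix, band = band, hemisphere = hemisphere)
}

roi_labels <- as.vector(outer(c("left", "right"),
                              c("anterior", "central", "posterior"),
                              paste, sep = "_"))

#' Channels belonging to one of six scalp regions of interest
#'
#' The scalp is split into six lateral regions crossing hemisphere (left,
#' right) with coronal band (anterior, central, posterior). Membership is
#' determined from the 10-20 channel name: an odd terminal digit is left,
#' even is right, and `z` midline channels belong to no lateral region;
#' row prefixes Fp/AF/F/FT/FC are anterior, C/T/CP/TP central, and
#' P/PO/O/I posterior.
#'
#' @param mon an `eeg_montage`.
#' @param roi one of `"left_anterior"`, `"left_central"`,
#'   `"left_posterior"`, `"right_anterior"`, `"right_central"`,
#'   `"right_posterior"`.
#' @return Character vector of channel names in the region.
#' @export
#' @examples
#' roi_channels(biosemi64_montage(), "left_posterior")
roi_channels <- function(mon, roi) {
  stopifnot(inherits(mon, "eeg_montage"))
  if (!is.character(roi) || length(roi) != 1L || !(roi %in% roi_labels)) {
    abort(sprintf("`roi` must be one of: %s.",
                  paste(roi_labels, collapse = ", ")))
  }
  parts <- strsplit(roi, "_", fixed = TRUE)[[1]]
  hemi <- parts[1]
  band <- parts[2]
  hits <- vapply(mon$channels, function(ch) {
    p <- parse_channel_name(ch)
    p$hemisphere == hemi && p$band == band
  }, logical(1))
  chans <- mon$channels[hits]
  if (length(chans) == 0L) {
    warn(sprintf("ROI '%s' is empty on this montage.", roi))
  }
  chans
}
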