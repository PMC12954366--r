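#' Sensor adjacency from Delaunay triangulation
#'
#' Defines two channels as neighbours when they share an edge in the
#' Delaunay triangulation of the montage's 2D azimuthal-equidistant
#' projection. This is the standard parameter-free sensor-space
#' neighbourhood definition: it adapts to local electrode density and
#' yields a connected planar graph. The diagonal is `TRUE` (every channel
#' is in its own neighbourhood).
#'
#' The triangulation is computed on channels sorted canonically by
#' coordinates, so the result is invariant to the order in which channels
#' are listed in the montage.
#'
#' @param mon an `eeg_montage` with at least 3 channels.
#' @return A symmetric logical channels x channels matrix with `TRUE`
#'   diagonal, dimnames set to the montage's channel names.
#' @export
#' @examples
#' adj <- build_adjacency(biosemi64_montage())
#' names(which(adj["Cz", ]))
build_adjacency <- function(mon) {
  stopifnot(inherits(mon, "eeg_montage"))
  n <- length(mon$channels)
  if (n < 3L) abort("Adjacency needs at least 3 channels.")
  xy <- project_scalp(mon)
  if (anyDuplicated(round(xy, 12))) {
    abort("Degenerate montage: duplicate projected electrode positions.")
  }
  # Canonical ordering makes the triangulation independent of channel order.
  ord <- order(xy[, 1], xy[, 2])
  pts <- xy[ord, , drop = FALSE]
  tri <- tryCatch(
    deldir::deldir(pts[, 1], pts[, 2], suppressMsge = TRUE),
    error = function(e) {
      abort(paste0("Degenerate montage: Delaunay triangulation failed (",
                   conditionMessage(e), ")."))
    })
  adj <- matrix(FALSE, n, n, dimnames = list(mon$channels, mon$channels))
  i <- ord[tri$delsgs$ind1]
  j <- ord[tri$delsgs$ind2]
  adj[cbind(i, j)] <- TRUE
  adj[cbind(j, i)] <- TRUE
  diag(adj) <- TRUE
  if (any(rowSums(adj) < 2L)) {
    abort("Degenerate montage: a channel has no neighbours.")
  }
  adj
}

#' Channel neighbourhood from an adjacency matrix
#'
#' @param adjacency logical adjacency matrix as returned by
#'   [build_adjacency()].
#' @param channel channel name.
#' @return Character vector: the channel and its neighbours, in montage
#'   order.
#' @export
channel_neighborhood <- function(adjacency, channel) {
  if (!channel %in% rownames(adjacency)) {
    abort(sprintf("Channel '%s' is not in the adjacency matrix.", channel))
  }
  colnames(adjacency)[adjacency[channel, ]]
}
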