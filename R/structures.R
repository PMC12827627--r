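#' Construct a bead-resolution structure
#'
#' A bead structure is the coarse-grained analogue of an atomic model: each
#' bead carries a position (in nm), a radius (in nm) and chain/residue/bead
#' identifiers.  It is stored as a tibble with one row per bead, so all the
#' usual dplyr verbs apply, plus a class tag used by the analysis functions.
#'
#' @param x,y,z Numeric bead coordinates in nm.
#' @param radius Bead radii in nm (recycled); must be positive.
#' @param chain_id Character chain identifiers (recycled).
#' @param residue_index Integer residue numbers (recycled).
#' @param residue_name Character residue names (recycled).
#' @param bead_name Character bead names (recycled).
#'
#' @return A `bead_structure`: a tibble with columns `bead_id`, `x`, `y`,
#'   `z`, `radius`, `chain_id`, `residue_index`, `residue_name`,
#'   `bead_name`.
#' @export
#' @examples
#' bead_structure(x = c(0, 1), y = 0, z = 0)
bead_structure <- function(x, y, z, radius = 0.235, chain_id = "A",
                           residue_index = seq_along(x),
                           residue_name = "BEA", bead_name = "BB") {
  tb <- tibble::tibble(
    bead_id = seq_along(x),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    radius = as.numeric(radius),
    chain_id = as.character(chain_id),
    residue_index = as.integer(residue_index),
    residue_name = as.character(residue_name),
    bead_name = as.character(bead_name)
  )
  new_bead_structure(tb)
}

new_bead_structure <- function(tb) {
  validate_bead_structure(tb)
  class(tb) <- c("bead_structure", class(tibble::as_tibble(tb)))
  tb
}

validate_bead_structure <- function(tb) {
  need <- c("bead_id", "x", "y", "z", "radius", "chain_id",
            "residue_index", "residue_name", "bead_name")
  miss <- setdiff(need, names(tb))
  if (length(miss) > 0) {
    stop("bead structure is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(tb) == 0) stop("bead structure has zero beads", call. = FALSE)
  if (!all(is.finite(tb$x) & is.finite(tb$y) & is.finite(tb$z))) {
    stop("bead positions must be finite", call. = FALSE)
  }
  if (!all(is.finite(tb$radius) & tb$radius > 0)) {
    stop("bead radii must be positive", call. = FALSE)
  }
  key <- paste(tb$chain_id, tb$residue_index, tb$bead_name)
  if (anyDuplicated(key)) {
    stop("(chain_id, residue_index, bead_name) must be unique per structure",
         call. = FALSE)
  }
  invisible(tb)
}

#' @export
print.bead_structure <- function(x, ...) {
  cat("# Bead structure:", nrow(x), "beads,",
      length(unique(x$chain_id)), "chain(s)\n")
  NextMethod()
}

#' Extract the coordinate matrix of a structure
#'
#' @param structure A [bead_structure()].
#' @return An `n x 3` numeric matrix of positions in nm.
#' @export
coords_matrix <- function(structure) {
  m <- cbind(structure$x, structure$y, structure$z)
  colnames(m) <- c("x", "y", "z")
  m
}

#' Replace the coordinates of a structure
#'
#' @param structure A [bead_structure()].
#' @param coords An `n x 3` matrix of positions in nm.
#' @return The structure with updated `x`, `y`, `z` columns.
#' @export
set_coords <- function(structure, coords) {
  stopifnot(nrow(coords) == nrow(structure), ncol(coords) == 3)
  structure$x <- coords[, 1]
  structure$y <- coords[, 2]
  structure$z <- coords[, 3]
  structure
}

#' Construct a conformational ensemble
#'
#' An ensemble is an ordered set of frames over a fixed bead topology.  The
#' topology's own coordinates are ignored; frames carry the coordinates.
#'
#' @param topology A [bead_structure()] giving the bead identities.
#' @param frames A list of `n x 3` coordinate matrices (nm), or a
#'   3-dimensional `n x 3 x n_frames` array.
#' @param frame_spacing Time between consecutive frames, ns.
#' @param label Free-text label for the ensemble.
#'
#' @return An `ensemble` object with elements `topology`, `coords`
#'   (an `n x 3 x n_frames` array), `frame_spacing`, `label`.
#' @export
ensemble <- function(topology, frames, frame_spacing = 1, label = "") {
  validate_bead_structure(topology)
  n <- nrow(topology)
  if (is.array(frames) && length(dim(frames)) == 3) {
    coords <- frames
  } else if (is.list(frames)) {
    if (length(frames) == 0) stop("ensemble needs at least one frame",
                                  call. = FALSE)
    bad <- vapply(frames, function(f) nrow(f) != n || ncol(f) != 3, logical(1))
    if (any(bad)) {
      stop("frame ", which(bad)[1], " does not match the topology bead count (",
           n, ")", call. = FALSE)
    }
    coords <- array(0, dim = c(n, 3, length(frames)))
    for (i in seq_along(frames)) coords[, , i] <- frames[[i]]
  } else {
    stop("`frames` must be a list of matrices or an n x 3 x F array",
         call. = FALSE)
  }
  if (dim(coords)[1] != n || dim(coords)[2] != 3) {
    stop("coordinate array must be n_beads x 3 x n_frames", call. = FALSE)
  }
  if (!is.numeric(frame_spacing) || frame_spacing <= 0) {
    stop("frame_spacing must be a positive time in ns", call. = FALSE)
  }
  structure(
    list(topology = topology, coords = coords,
         frame_spacing = as.numeric(frame_spacing),
         label = as.character(label)),
    class = "ensemble"
  )
}

#' @export
print.ensemble <- function(x, ...) {
  cat("# Ensemble", if (nzchar(x$label)) paste0("'", x$label, "'") else "",
      ":", n_frames(x), "frames x", nrow(x$topology), "beads,",
      x$frame_spacing, "ns/frame\n")
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ens An [ensemble()].
#' @return Integer frame count.
#' @export
n_frames <- function(ens) dim(ens$coords)[3]

#' Extract one frame of an ensemble
#' @param ens An [ensemble()].
#' @param i Frame index (1-based).
#' @return An `n x 3` coordinate matrix in nm.
#' @export
frame_coords <- function(ens, i) {
  stopifnot(i >= 1, i <= n_frames(ens))
  m <- ens$coords[, , i]
  dim(m) <- c(dim(ens$coords)[1], 3)
  colnames(m) <- c("x", "y", "z")
  m
}

#' Tidy an ensemble into a long tibble
#'
#' One row per (frame, bead) with coordinates and frame time.
#'
#' @param x An [ensemble()].
#' @param ... Unused.
#' @return A tibble with columns `frame`, `time_ns`, `bead_id`, `chain_id`,
#'   `residue_index`, `x`, `y`, `z`.
#' @method tidy ensemble
#' @export
tidy.ensemble <- function(x, ...) {
  nf <- n_frames(x)
  nb <- nrow(x$topology)
  xs <- as.vector(x$coords[, 1, ])
  ys <- as.vector(x$coords[, 2, ])
  zs <- as.vector(x$coords[, 3, ])
  tibble::tibble(
    frame = rep(seq_len(nf), each = nb),
    time_ns = rep((seq_len(nf) - 1) * x$frame_spacing, each = nb),
    bead_id = rep(x$topology$bead_id, nf),
    chain_id = rep(x$topology$chain_id, nf),
    residue_index = rep(x$topology$residue_index, nf),
    x = xs, y = ys, z = zs
  )
}
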