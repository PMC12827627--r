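#' Read a bead structure from a PDB file
#'
#' Coordinates are converted from the PDB's native angstroms to the
#' package's internal nanometres.  Radii are assigned per bead name from
#' `radius_table`, falling back to `default_radius` for unknown names (the
#' default is half a standard 0.47 nm coarse-grained bead diameter).
#'
#' @param path Path to a PDB file.
#' @param radius_table Named numeric vector of radii in nm, keyed by bead
#'   (atom) name.
#' @param default_radius Radius in nm for bead names not in `radius_table`.
#'
#' @return A [bead_structure()].  For multi-model files only the first
#'   model is used; see [read_ensemble()] for trajectories.
#' @export
read_structure <- function(path, radius_table = NULL,
                           default_radius = 0.235) {
  pdb <- read_pdb_checked(path, multi = FALSE)
  at <- pdb$atom
  bead_structure(
    x = at$x / 10, y = at$y / 10, z = at$z / 10,
    radius = lookup_radius(at$elety, radius_table, default_radius),
    chain_id = ifelse(is.na(at$chain), "A", at$chain),
    residue_index = at$resno,
    residue_name = at$resid,
    bead_name = at$elety
  )
}

read_pdb_checked <- function(path, multi) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = multi, verbose = FALSE),
    error = function(e) stop("could not parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0) {
    stop("PDB file '", path, "' contains no atoms", call. = FALSE)
  }
  pdb
}

lookup_radius <- function(bead_names, radius_table, default_radius) {
  r <- rep(default_radius, length(bead_names))
  if (!is.null(radius_table)) {
    hit <- match(bead_names, names(radius_table))
    r[!is.na(hit)] <- radius_table[hit[!is.na(hit)]]
  }
  r
}

#' Write a bead structure or ensemble to a PDB file
#'
#' Coordinates are converted from nm back to angstroms.  An ensemble is
#' written as a multi-model PDB, one MODEL block per frame.
#'
#' @param x A [bead_structure()] or [ensemble()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "ensemble")) {
    topo <- x$topology
    nf <- n_frames(x)
    xyz <- matrix(0, nrow = nf, ncol = 3 * nrow(topo))
    for (i in seq_len(nf)) {
      xyz[i, ] <- as.vector(t(frame_coords(x, i))) * 10
    }
  } else {
    topo <- x
    xyz <- matrix(as.vector(t(coords_matrix(x))) * 10, nrow = 1)
  }
  bio3d::write.pdb(
    file = path, xyz = xyz,
    resno = topo$residue_index, resid = topo$residue_name,
    chain = topo$chain_id, elety = topo$bead_name
  )
  invisible(path)
}

#' Read a conformational ensemble
#'
#' Accepts either a single multi-model PDB file or an ordered vector of
#' single-frame files (PDB or XYZ, by extension).  All frames must share
#' one topology; the topology (identities and radii) is taken from the
#' first frame.
#'
#' @param paths One multi-model PDB path, or a character vector of
#'   single-frame files in frame order.
#' @param frame_spacing Time between frames, ns.
#' @param label Free-text ensemble label.
#' @inheritParams read_structure
#'
#' @return An [ensemble()].
#' @export
read_ensemble <- function(paths, frame_spacing = 1, label = "",
                          radius_table = NULL, default_radius = 0.235) {
  if (length(paths) == 0) stop("no input files given", call. = FALSE)
  if (length(paths) == 1 && grepl("\\.pdb$", paths, ignore.case = TRUE)) {
    pdb <- read_pdb_checked(paths, multi = TRUE)
    at <- pdb$atom
    topo <- bead_structure(
      x = at$x / 10, y = at$y / 10, z = at$z / 10,
      radius = lookup_radius(at$elety, radius_table, default_radius),
      chain_id = ifelse(is.na(at$chain), "A", at$chain),
      residue_index = at$resno, residue_name = at$resid,
      bead_name = at$elety
    )
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    frames <- lapply(seq_len(nrow(xyz)), function(i) {
      matrix(xyz[i, ], ncol = 3, byrow = TRUE) / 10
    })
  } else {
    read_one <- function(p) {
      if (grepl("\\.xyz$", p, ignore.case = TRUE)) {
        read_xyz(p, radius_table = radius_table,
                 default_radius = default_radius)
      } else {
        read_structure(p, radius_table = radius_table,
                       default_radius = default_radius)
      }
    }
    structs <- lapply(paths, read_one)
    topo <- structs[[1]]
    nb <- vapply(structs, nrow, integer(1))
    if (any(nb != nb[1])) {
      stop("bead-count mismatch across frames: ",
           paste(unique(nb), collapse = " vs "), call. = FALSE)
    }
    frames <- lapply(structs, coords_matrix)
  }
  ensemble(topo, frames, frame_spacing = frame_spacing, label = label)
}
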