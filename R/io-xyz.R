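#' Read a bead structure from an XYZ file
#'
#' Plain chemistry XYZ: an atom count line, a comment line, then one
#' `name x y z` row per bead.  Coordinates are taken to be in angstroms
#' (the format's convention) and converted to nm.  Chain and residue
#' identifiers are synthesised since XYZ carries none.
#'
#' @inheritParams read_structure
#' @return A [bead_structure()].
#' @export
read_xyz <- function(path, radius_table = NULL, default_radius = 0.235) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 3) stop("XYZ file '", path, "' too short",
                              call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1 || length(lines) < n + 2) {
    stop("malformed XYZ header in '", path, "'", call. = FALSE)
  }
  rows <- strsplit(trimws(lines[3:(n + 2)]), "\\s+")
  name <- vapply(rows, `[`, character(1), 1)
  xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  if (any(!is.finite(xyz))) stop("non-numeric coordinate in '", path, "'",
                                 call. = FALSE)
  bead_structure(
    x = xyz[, 1] / 10, y = xyz[, 2] / 10, z = xyz[, 3] / 10,
    radius = lookup_radius(name, radius_table, default_radius),
    chain_id = "A", residue_index = seq_len(n),
    residue_name = "BEA", bead_name = name
  )
}

#' Write a bead structure to an XYZ file
#'
#' @param structure A [bead_structure()].
#' @param path Output file path.
#' @param comment Comment line for the file header.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(structure, path, comment = "") {
  m <- coords_matrix(structure) * 10
  lines <- c(
    as.character(nrow(structure)),
    comment,
    sprintf("%-5s %12.6f %12.6f %12.6f",
            structure$bead_name, m[, 1], m[, 2], m[, 3])
  )
  writeLines(lines, path)
  invisible(path)
}
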