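#' Deterministic quasi-uniform sphere points
#'
#' Golden-spiral (Fibonacci) lattice on the unit sphere.  Deterministic,
#' so surface areas computed from it are exactly reproducible.
#'
#' @param n Number of points (>= 1).
#' @return An `n x 3` matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  k <- seq_len(n)
  z <- 1 - (2 * k - 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  phi <- golden * (k - 1)
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Large-probe accessible surface area
#'
#' Shrake–Rupley-style point-sampled accessible surface area for a subset
#' of beads, with every bead of the structure acting as an occluder.  The
#' probe radius is meant to be large — of the order of an antigen domain
#' (the receptor-derived default elsewhere in the package is 3.5 nm, half
#' the maximum width of the receptor's binding domain) — so the ASA
#' measures whether an antigen-sized sphere can touch the selection, not
#' solvent exposure.
#'
#' For each selected bead i, `n_sphere_points` points are distributed on
#' the sphere of radius r_i + R by a deterministic golden-spiral lattice;
#' a point is exposed if it lies outside every other bead's (r_j + R)
#' sphere, and the bead's area is the exposed fraction of 4 pi (r_i + R)^2.
#'
#' @param structure A [bead_structure()].
#' @param selection Integer bead indices whose area is wanted.
#' @param probe_radius Probe radius R, nm (>= 0).
#' @param n_sphere_points Points per bead (>= 32; default 960).
#'
#' @return An `asa_result`: list with `per_bead` (tibble `bead_id`,
#'   `area`), `total_area` (nm^2), `probe_radius`, `n_sphere_points`.
#' @export
#' @examples
#' s <- bead_structure(x = 0, y = 0, z = 0, radius = 0.235)
#' compute_asa(s, 1, probe_radius = 3.5)$total_area  # 4*pi*3.735^2
compute_asa <- function(structure, selection, probe_radius = 3.5,
                        n_sphere_points = 960) {
  validate_bead_structure(structure)
  selection <- as.integer(selection)
  if (length(selection) == 0) stop("empty selection", call. = FALSE)
  if (probe_radius < 0) stop("probe_radius must be >= 0", call. = FALSE)
  if (n_sphere_points < 32) stop("need at least 32 sphere points",
                                 call. = FALSE)
  xyz <- coords_matrix(structure)
  rad <- structure$radius + probe_radius
  pts <- sphere_points(n_sphere_points)
  area <- asa_areas(xyz, rad, selection, pts)
  structure(
    list(per_bead = tibble::tibble(bead_id = structure$bead_id[selection],
                                   area = area),
         total_area = sum(area), probe_radius = probe_radius,
         n_sphere_points = n_sphere_points),
    class = "asa_result"
  )
}

asa_areas <- function(xyz, rad, selection, pts) {
  n <- nrow(xyz)
  vapply(selection, function(i) {
    ri <- rad[i]
    p <- pts * ri
    p <- sweep(p, 2, xyz[i, ], `+`)
    exposed <- rep(TRUE, nrow(p))
    d_cent <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    near <- which(d_cent < ri + rad & seq_len(n) != i)
    for (j in near) {
      if (!any(exposed)) break
      dx <- p[exposed, 1] - xyz[j, 1]
      dy <- p[exposed, 2] - xyz[j, 2]
      dz <- p[exposed, 3] - xyz[j, 3]
      exposed[exposed] <- dx * dx + dy * dy + dz * dz > rad[j]^2
    }
    mean(exposed) * 4 * pi * ri^2
  }, numeric(1))
}

#' @export
print.asa_result <- function(x, ...) {
  cat("# ASA: probe", x$probe_radius, "nm,", nrow(x$per_bead),
      "beads, total", format(x$total_area, digits = 6), "nm^2\n")
  invisible(x)
}

#' @method tidy asa_result
#' @export
tidy.asa_result <- function(x, ...) x$per_bead

#' @method glance asa_result
#' @export
glance.asa_result <- function(x, ...) {
  tibble::tibble(total_area = x$total_area, probe_radius = x$probe_radius,
                 n_beads = nrow(x$per_bead),
                 n_sphere_points = x$n_sphere_points)
}

#' Per-frame accessible surface area of a named selection
#'
#' Applies [compute_asa()] to one named domain (typically a CDR) in every
#' frame of an ensemble.
#'
#' @param ens An [ensemble()].
#' @param map A [domain_map()] over the ensemble's topology.
#' @param cdr_name Name of the selection in `map`.
#' @inheritParams compute_asa
#'
#' @return A tibble with columns `frame`, `time_ns`, `area` (nm^2).
#' @export
asa_timeseries <- function(ens, map, cdr_name, probe_radius = 3.5,
                           n_sphere_points = 960) {
  if (!cdr_name %in% names(map$domains)) {
    stop("unknown domain: ", cdr_name, call. = FALSE)
  }
  sel <- map$domains[[cdr_name]]
  rad <- ens$topology$radius + probe_radius
  pts <- sphere_points(n_sphere_points)
  nf <- n_frames(ens)
  area <- vapply(seq_len(nf), function(f) {
    sum(asa_areas(frame_coords(ens, f), rad, sel, pts))
  }, numeric(1))
  tibble::tibble(frame = seq_len(nf),
                 time_ns = (seq_len(nf) - 1) * ens$frame_spacing,
                 area = area)
}

#' Maximum and minimum widths of a selection
#'
#' `max_width` is the largest pairwise centre distance within the
#' selection.  `min_width` is the smallest extent of the selection along
#' the three principal axes of its coordinate covariance — a global
#' "thickness" rather than a pairwise minimum.  Half-widths are reported
#' alongside, since the package's probe and threshold conventions (3.5 nm
#' probe, 1.8 nm threshold) are half the maximum and minimum widths of the
#' receptor's binding domain.
#'
#' @param structure A [bead_structure()].
#' @param selection Integer bead indices (>= 2 beads).
#' @return A one-row tibble: `max_width`, `half_max_width`, `min_width`,
#'   `half_min_width` (all nm).
#' @export
domain_widths <- function(structure, selection) {
  selection <- as.integer(selection)
  if (length(selection) < 2) stop("selection needs at least 2 beads",
                                  call. = FALSE)
  xyz <- coords_matrix(structure)[selection, , drop = FALSE]
  max_w <- max(stats::dist(xyz))
  ctr <- sweep(xyz, 2, colMeans(xyz))
  ax <- eigen(crossprod(ctr) / nrow(ctr), symmetric = TRUE)$vectors
  proj <- ctr %*% ax
  extents <- apply(proj, 2, function(v) diff(range(v)))
  min_w <- min(extents)
  tibble::tibble(max_width = max_w, half_max_width = max_w / 2,
                 min_width = min_w, half_min_width = min_w / 2)
}
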