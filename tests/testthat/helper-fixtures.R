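# Shared fixtures and independent brute-force oracles.  The oracles here
# deliberately use plain loops / dense matrices, not the package's
# vectorised or cell-list code paths.

random_structure <- function(n, seed = 1, scale = 3) {
  withr::with_seed(seed, {
    bead_structure(x = rnorm(n, 0, scale), y = rnorm(n, 0, scale),
                   z = rnorm(n, 0, scale))
  })
}

small_toy <- function(n_frames = 20, seed = 7, cone = 40) {
  generate_toy_igm(toy_igm_params(n_frames = n_frames, seed = seed,
                                  hinge_cone_half_angle = cone))
}

# O(N^2) contact count
brute_contacts <- function(frame, sel_a, sel_b, cutoff) {
  n <- 0L
  for (i in sel_a) {
    for (j in sel_b) {
      if (sqrt(sum((frame[i, ] - frame[j, ])^2)) <= cutoff) n <- n + 1L
    }
  }
  n
}

# exhaustive nearest-obstruction recount, one (frame, fab) configuration
# at a time (frame-major order); independent of the package's
# array-vectorised implementation
brute_accessibility <- function(ens, map, threshold) {
  nf <- n_frames(ens)
  nfab <- length(map$fab_ids)
  dists <- numeric(nf * nfab)
  i <- 0L
  for (f in seq_len(nf)) {
    fr <- frame_coords(ens, f)
    for (fab in map$fab_ids) {
      cdr <- map$domains[[map$cdr_of[[fab]]]]
      com <- colMeans(fr[cdr, , drop = FALSE])
      keep <- setdiff(seq_len(nrow(fr)), map$domains[[fab]])
      i <- i + 1L
      dists[i] <- if (length(keep) == 0) Inf else
        sqrt(min(rowSums(sweep(fr[keep, , drop = FALSE], 2, com)^2)))
    }
  }
  list(probability = mean(dists >= threshold), n = length(dists),
       distances = dists)
}

# dense-point ASA estimate, independent of the golden-spiral lattice:
# random points on each sphere, seeded
brute_asa <- function(structure, selection, probe, n_pts, seed = 1) {
  xyz <- coords_matrix(structure)
  rad <- structure$radius + probe
  withr::with_seed(seed, {
    vapply(selection, function(i) {
      p <- matrix(rnorm(n_pts * 3), ncol = 3)
      p <- p / sqrt(rowSums(p^2)) * rad[i]
      p <- sweep(p, 2, xyz[i, ], `+`)
      ok <- rep(TRUE, n_pts)
      for (j in seq_len(nrow(xyz))) {
        if (j == i) next
        d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
          (p[, 3] - xyz[j, 3])^2
        ok <- ok & d2 > rad[j]^2
      }
      mean(ok) * 4 * pi * rad[i]^2
    }, numeric(1))
  })
}

rigid_transform <- function(coords, angle = 0.6, axis = c(0, 0, 1),
                            shift = c(1, -2, 3)) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  sweep(coords %*% t(R), 2, shift, `+`)
}

apply_rigid_to_ensemble <- function(ens, ...) {
  frames <- lapply(seq_len(n_frames(ens)), function(f) {
    rigid_transform(frame_coords(ens, f), ...)
  })
  ensemble(ens$topology, frames, frame_spacing = ens$frame_spacing)
}
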