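test_that("superposition is exact on self and rigid copies", {
  co <- coords_matrix(random_structure(50, seed = 2))
  expect_equal(superpose(co, co)$rmsd, 0, tolerance = 1e-12)
  moved <- rigid_transform(co, angle = 1.2, axis = c(1, 2, 3))
  expect_lt(superpose(moved, co)$rmsd, 1e-6)
  # collinear fit selections are degenerate
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line + 1), "degenerate")
})

test_that("Kabsch RMSD agrees with an independent optimiser", {
  co <- coords_matrix(random_structure(50, seed = 4))
  mob <- coords_matrix(random_structure(50, seed = 5))
  ours <- superpose(mob, co)$rmsd
  # independent route: bio3d's least-squares fit
  inds <- bio3d::atom2xyz(1:50)
  fitted <- bio3d::fit.xyz(as.vector(t(co)), as.vector(t(mob)),
                           fixed.inds = inds, mobile.inds = inds)
  theirs <- sqrt(mean(rowSums(
    (matrix(fitted, ncol = 3, byrow = TRUE) - co)^2)))
  expect_equal(ours, theirs, tolerance = 1e-6)
})

test_that("rmsd_series distinguishes whole-fit from self-fit modes", {
  toy <- small_toy(n_frames = 40, seed = 3)
  ens <- toy$ensemble
  fab <- toy$domain_map$domains$Fab_1

  # static ensemble: all zeros
  static <- ensemble(ens$topology,
                     array(rep(frame_coords(ens, 1), 4),
                           dim = c(nrow(ens$topology), 3, 4)))
  expect_equal(rmsd_series(static)$rmsd, rep(0, 4), tolerance = 1e-12)

  # a rigid arm under arbitrary global motion is zero in self-fit mode
  moved <- apply_rigid_to_ensemble(ens, angle = 0.9, shift = c(3, 1, -2))
  self_fit <- rmsd_series(moved, reference = frame_coords(ens, 1),
                          fit_selection = fab, calc_selection = fab)
  whole_fit <- rmsd_series(moved, reference = frame_coords(ens, 1),
                           calc_selection = fab)
  # arms are internally rigid rods in the toy model: self-fit ~ 0
  expect_lt(max(self_fit$rmsd), 1e-6)
  # whole-fit sees the hinge motion: strictly larger on average
  expect_gt(mean(whole_fit$rmsd), mean(self_fit$rmsd))
})

test_that("rmsf matches the closed form under isotropic jitter", {
  s <- random_structure(60, seed = 6)
  co <- coords_matrix(s)
  nf <- 3000
  arr <- array(rep(co, nf), dim = c(60, 3, nf)) +
    array(withr::with_seed(20, rnorm(60 * 3 * nf, 0, 0.1)),
          dim = c(60, 3, nf))
  r <- rmsf(ensemble(s, arr))
  expect_equal(mean(r$rmsf), 0.1 * sqrt(3), tolerance = 0.05)
  expect_error(rmsf(ensemble(s, arr[, , 1, drop = FALSE])), "2 frames")
})

test_that("rmsf equals the direct formula on pre-aligned frames", {
  toy <- small_toy(n_frames = 25, seed = 9)
  r <- rmsf(toy$ensemble)
  # independent recomputation: same two-pass alignment done longhand
  ens <- toy$ensemble
  ref <- frame_coords(ens, 1)
  al <- lapply(seq_len(25), function(f) {
    superpose(frame_coords(ens, f), ref)$coords
  })
  avg <- Reduce(`+`, al) / 25
  al2 <- lapply(al, function(m) superpose(m, avg)$coords)
  avg2 <- Reduce(`+`, al2) / 25
  msf <- Reduce(`+`, lapply(al2, function(m) rowSums((m - avg2)^2))) / 25
  expect_equal(r$rmsf, sqrt(msf), tolerance = 1e-10)
})

test_that("pca recovers planted mode variances and the trace identity", {
  ms <- random_structure(80, seed = 10)
  V <- qr.Q(qr(withr::with_seed(2, matrix(rnorm(240 * 2), 240, 2))))
  ens <- generate_gaussian_ensemble(ms, V, c(4, 1), n_frames = 4000,
                                    seed = 11)
  p <- suppressWarnings(pca(ens))
  expect_equal(p$variance_fractions[1], 0.8, tolerance = 0.03)
  # eigenvalues descending, fractions normalised, eigenvectors orthonormal
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  expect_equal(sum(p$variance_fractions), 1)
  k <- min(5, ncol(p$eigenvectors))
  expect_equal(crossprod(p$eigenvectors[, 1:k]), diag(k),
               ignore_attr = TRUE, tolerance = 1e-8)
  # trace identity: total variance = mean squared deviation from the mean
  al <- suppressWarnings(pca(ens, selection = 1:80))
  X <- t(vapply(seq_len(n_frames(ens)), function(f) {
    as.vector(frame_coords(ens, f))
  }, numeric(240)))
  # compare against an aligned-free recomputation through projections
  expect_equal(sum(p$eigenvalues),
               sum(apply(p$projections, 2, stats::var)),
               tolerance = 1e-8)
})

test_that("pca mode trajectories interpolate and project back exactly", {
  toy <- small_toy(n_frames = 15, seed = 12)
  p <- suppressWarnings(pca(toy$ensemble))
  tr <- pca_mode_trajectory(p, toy$ensemble$topology, mode = 1,
                            n_interp = 11, amplitude = 2)
  expect_equal(n_frames(tr), 11)
  # endpoints differ by 2 * amplitude * sqrt(lambda) along a unit vector
  span <- sqrt(sum((frame_coords(tr, 11) - frame_coords(tr, 1))^2))
  expect_equal(span, 2 * 2 * sqrt(p$eigenvalues[1]), tolerance = 1e-10)
  # projecting back onto the mode recovers the linear ramp
  v <- p$eigenvectors[, 1]
  mu <- as.vector(p$mean_coordinates)
  proj <- vapply(seq_len(11), function(f) {
    sum((as.vector(frame_coords(tr, f)) - mu) * v)
  }, numeric(1))
  a <- 2 * sqrt(p$eigenvalues[1])
  expect_equal(proj, seq(-a, a, length.out = 11), tolerance = 1e-10)
  # zero amplitude: all frames equal the mean
  tr0 <- pca_mode_trajectory(p, toy$ensemble$topology, mode = 1,
                             n_interp = 3, amplitude = 0)
  expect_equal(frame_coords(tr0, 1), frame_coords(tr0, 3),
               ignore_attr = TRUE)
})

test_that("contact counting honours the cutoff boundary and symmetry", {
  fr <- rbind(c(0, 0, 0), c(0.59, 0, 0))
  expect_equal(contact_count(fr, 1, 2, 0.6), 1)
  fr2 <- rbind(c(0, 0, 0), c(0.61, 0, 0))
  expect_equal(contact_count(fr2, 1, 2, 0.6), 0)
  expect_equal(contact_count(fr, 1, integer(0), 0.6), 0)
  expect_error(contact_count(fr, 1:2, 2, 0.6), "disjoint")

  co <- matrix(withr::with_seed(30, runif(300 * 3, 0, 2.5)), 300, 3)
  expect_equal(contact_count(co, 1:150, 151:300, 0.6),
               contact_count(co, 151:300, 1:150, 0.6))
})

test_that("cell-list contacts equal the O(N^2) loop on random frames", {
  for (seed in 1:4) {
    fr <- matrix(withr::with_seed(seed, runif(200 * 3, 0, 2.5)), 200, 3)
    expect_equal(contact_count(fr, 1:80, 81:200, 0.6),
                 brute_contacts(fr, 1:80, 81:200, 0.6))
  }
})

test_that("per-residue contacts conserve the total and average frames", {
  toy <- small_toy(n_frames = 6, seed = 15)
  ens <- toy$ensemble
  fc <- toy$domain_map$domains$Fc
  arms <- toy$domain_map$domains$Fab_1
  cutoff <- 1.5
  tb <- per_residue_contacts(ens, fc, arms, cutoff)
  total <- mean(vapply(seq_len(6), function(f) {
    contact_count(frame_coords(ens, f), fc, arms, cutoff)
  }, numeric(1)))
  expect_equal(sum(tb$mean_contacts), total)

  # static ensemble: means equal single-frame counts
  static <- ensemble(ens$topology,
                     array(rep(frame_coords(ens, 1), 3),
                           dim = c(nrow(ens$topology), 3, 3)))
  tb1 <- per_residue_contacts(static, fc, arms, cutoff)
  pairs1 <- contact_count(frame_coords(ens, 1), fc, arms, cutoff)
  expect_equal(sum(tb1$mean_contacts), pairs1)
})

test_that("COM distance series matches the hand-rolled definition", {
  s <- bead_structure(x = c(0, 0, 3, 3), y = c(0, 2, 0, 2), z = 0)
  ens <- ensemble(s, list(coords_matrix(s)))
  expect_equal(com_distance_series(ens, 1:2, 3:4)$distance, 3)
  expect_equal(com_distance_series(ens, 1:2, 1:2)$distance, 0)

  toy <- small_toy(n_frames = 8, seed = 16)
  a <- toy$domain_map$domains$CDR_1
  b <- toy$domain_map$domains$Fc
  got <- com_distance_series(toy$ensemble, a, b)$distance
  want <- vapply(seq_len(8), function(f) {
    fr <- frame_coords(toy$ensemble, f)
    sqrt(sum((colMeans(fr[a, , drop = FALSE]) -
                colMeans(fr[b, , drop = FALSE]))^2))
  }, numeric(1))
  expect_equal(got, want)
})

test_that("ensemble metrics are invariant under uniform rigid motion", {
  toy <- small_toy(n_frames = 12, seed = 18)
  moved <- apply_rigid_to_ensemble(toy$ensemble, angle = 0.8,
                                   axis = c(1, 1, 0), shift = c(5, 0, 1))
  expect_equal(rmsd_series(toy$ensemble)$rmsd,
               rmsd_series(moved)$rmsd, tolerance = 1e-8)
  expect_equal(rmsf(toy$ensemble)$rmsf, rmsf(moved)$rmsf,
               tolerance = 1e-8)
  p1 <- suppressWarnings(pca(toy$ensemble))
  p2 <- suppressWarnings(pca(moved))
  expect_equal(p1$eigenvalues, p2$eigenvalues, tolerance = 1e-8)
  f <- 5
  expect_equal(
    contact_count(frame_coords(toy$ensemble, f),
                  toy$domain_map$domains$Fc,
                  toy$domain_map$domains$Fab_1, 1.5),
    contact_count(frame_coords(moved, f),
                  toy$domain_map$domains$Fc,
                  toy$domain_map$domains$Fab_1, 1.5))
  expect_equal(
    com_distance_series(toy$ensemble, 1:5, 20:30)$distance,
    com_distance_series(moved, 1:5, 20:30)$distance, tolerance = 1e-10)
})
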