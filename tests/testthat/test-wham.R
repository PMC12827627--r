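kBT310 <- KB_KJ_MOL_K * 310

test_that("a single bias-only window recovers a flat profile", {
  w <- generate_umbrella_series(potential_spec("flat"), centers = 2,
                                force_constant = 1000,
                                n_samples = 1e5, seed = 1)
  p <- wham_solve(w)
  sigma <- sqrt(kBT310 / 1000)
  core <- p$profile$bin_center >= 2 - 2 * sigma &
    p$profile$bin_center <= 2 + 2 * sigma
  # flatness: RMS deviation from the plateau level over the central
  # +/- 2 sigma (the zero convention anchors on the noisy global min,
  # which is a constant offset, not a shape feature)
  g <- p$profile$free_energy[core]
  expect_lt(sqrt(mean((g - mean(g, na.rm = TRUE))^2, na.rm = TRUE)), 0.15)
  expect_true(p$converged)
})

test_that("with one window and zero bias the PMF is the shifted log-histogram", {
  # near-zero force constant: WHAM must reduce to -kBT ln(histogram)
  set.seed(2)
  s <- rnorm(5e4, 1, 0.2)
  w <- umbrella_windows(center = 1, force_constant = 1e-9,
                        samples = list(s))
  p <- wham_solve(w, bin_width = 0.05)
  edges <- seq(floor(min(s) / 0.05) * 0.05,
               ceiling(max(s) / 0.05) * 0.05, by = 0.05)
  h <- tabulate(pmin(findInterval(s, edges, rightmost.closed = TRUE),
                     length(edges) - 1), length(edges) - 1)
  direct <- -kBT310 * log(h / sum(h))
  direct <- direct - min(direct[is.finite(direct)])
  keep <- is.finite(direct) & is.finite(p$profile$free_energy)
  expect_equal(p$profile$free_energy[keep], direct[keep],
               tolerance = 1e-6)
})

test_that("WHAM is invariant to window order and coordinate shifts", {
  pot <- potential_spec("harmonic", kappa = 10)
  w <- generate_umbrella_series(pot, centers = seq(-1, 1, 0.25),
                                force_constant = 200, n_samples = 2000,
                                seed = 5)
  edges <- seq(-1.6, 1.6, by = 0.02)
  p1 <- wham_solve(w, bin_edges = edges)
  p2 <- wham_solve(w[rev(seq_len(nrow(w))), ], bin_edges = edges)
  expect_equal(p1$profile$free_energy, p2$profile$free_energy,
               tolerance = 1e-6)

  shift <- 3.7
  ws <- umbrella_windows(w$center + shift, w$force_constant,
                         lapply(w$samples, `+`, shift))
  p3 <- wham_solve(ws, bin_edges = edges + shift)
  expect_equal(p1$profile$free_energy, p3$profile$free_energy,
               tolerance = 1e-6)
})

test_that("f_i convergence trace is non-increasing at the end", {
  pot <- potential_spec("harmonic", kappa = 10)
  w <- generate_umbrella_series(pot, centers = seq(-1, 1, 0.25),
                                force_constant = 200, n_samples = 2000,
                                seed = 6)
  p <- wham_solve(w)
  tr <- utils::tail(p$max_delta_f_trace, 10)
  expect_true(all(diff(tr) <= 1e-12))
  expect_true(p$converged)
})

test_that("PMF error decreases with samples per window", {
  pot <- potential_spec("harmonic", kappa = 10)
  rms <- vapply(c(1000, 5000, 25000), function(ns) {
    w <- generate_umbrella_series(pot, centers = seq(-2, 2, 0.25),
                                  force_constant = 200, n_samples = ns,
                                  seed = 7)
    p <- wham_solve(w)
    pr <- p$profile[p$profile$bin_center >= -1.5 &
                      p$profile$bin_center <= 1.5, ]
    sqrt(mean((pr$free_energy - 0.5 * 10 * pr$bin_center^2)^2,
              na.rm = TRUE))
  }, numeric(1))
  expect_true(all(diff(rms) < 0))
})

test_that("histogram overlap has the right limits and Gaussian value", {
  s <- withr::with_seed(8, rnorm(2e4, 0, 0.1))
  w_id <- umbrella_windows(c(0, 0.001), 100, list(s, s))
  expect_equal(histogram_overlap(w_id)$overlap, 1, tolerance = 1e-12)

  w_far <- umbrella_windows(c(0, 10), 100,
                            list(s, s + 10))
  expect_equal(histogram_overlap(w_far)$overlap, 0)

  # analytic overlap of N(0, 0.1) and N(0.2, 0.1): 2*Phi(-d/(2 sigma))
  s2 <- withr::with_seed(9, rnorm(2e5, 0.2, 0.1))
  s1 <- withr::with_seed(10, rnorm(2e5, 0, 0.1))
  w <- umbrella_windows(c(0, 0.2), 100, list(s1, s2))
  analytic <- 2 * pnorm(-0.1 / 0.1)
  got <- histogram_overlap(w, bin_width = 0.01)$overlap
  expect_equal(got, analytic, tolerance = 0.02)
})

test_that("autocorrelation time matches i.i.d. and constant limits", {
  expect_equal(autocorrelation_time(generate_ar1(1e5, 0, 1)), 1,
               tolerance = 0.1)
  expect_equal(suppressMessages(autocorrelation_time(rep(2, 500))), 1)
  expect_error(autocorrelation_time(1:50), "100")
})

test_that("unit bootstrap weights reproduce the unweighted solution", {
  pot <- potential_spec("harmonic", kappa = 10)
  w <- generate_umbrella_series(pot, centers = seq(-1, 1, 0.5),
                                force_constant = 200, n_samples = 1500,
                                seed = 11)
  edges <- seq(-1.5, 1.5, 0.02)
  p0 <- wham_solve(w, bin_edges = edges)
  p1 <- wham_solve(w, bin_edges = edges, weights = rep(1, nrow(w)))
  expect_identical(p0$profile$free_energy, p1$profile$free_energy)
})

test_that("bootstrap errors are deterministic and bracket the truth", {
  pot <- potential_spec("harmonic", kappa = 10)
  w <- generate_umbrella_series(pot, centers = seq(-1.5, 1.5, 0.25),
                                force_constant = 200, n_samples = 2000,
                                seed = 12)
  edges <- seq(-2, 2, 0.02)
  e1 <- bootstrap_error(w, bin_edges = edges, n_bootstrap = 30, seed = 4)
  e2 <- bootstrap_error(w, bin_edges = edges, n_bootstrap = 30, seed = 4)
  expect_identical(e1$error, e2$error)

  # coverage sanity: errors bracket the deviation from truth in >= 60%
  # of well-sampled bins
  p <- wham_solve(w, bin_edges = edges)
  pr <- p$profile
  core <- pr$bin_center >= -1.2 & pr$bin_center <= 1.2 &
    is.finite(pr$free_energy)
  truth <- 0.5 * 10 * pr$bin_center[core]^2
  dev <- abs(pr$free_energy[core] - truth)
  covered <- mean(dev <= 2 * e1$error[core] + 0.15)
  expect_gte(covered, 0.6)
})

test_that("binding energy reads the plateau of a profile", {
  # flat profile by construction: zero binding energy
  flat <- structure(list(
    profile = tibble::tibble(bin_center = seq(0, 2, 0.1),
                             free_energy = 0, n_samples = 100),
    window_f = tibble::tibble(center = 0, f = 0),
    n_iterations = 1, converged = TRUE, temperature = 310,
    n_dropped = 0, max_delta_f_trace = 0), class = "pmf_profile")
  expect_equal(binding_energy(flat), 0)

  # constructed profile: minimum 0, plateau at 12.5
  fake <- structure(list(
    profile = tibble::tibble(bin_center = seq(0, 2, 0.1),
                             free_energy = c(seq(0, 12.5, length.out = 11),
                                             rep(12.5, 10)),
                             n_samples = 100),
    window_f = tibble::tibble(center = 0, f = 0),
    n_iterations = 1, converged = TRUE, temperature = 310,
    n_dropped = 0, max_delta_f_trace = 0), class = "pmf_profile")
  expect_equal(binding_energy(fake, c(1.5, 2)), 12.5)
  expect_error(binding_energy(fake, c(-1, -0.5)), "plateau")
})
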