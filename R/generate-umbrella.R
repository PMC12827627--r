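#' Boltzmann constant in kJ mol^-1 K^-1
#' @export
KB_KJ_MOL_K <- 0.0083144621

#' Specify a one-dimensional reference potential
#'
#' Used by [generate_umbrella_series()] as the known truth behind synthetic
#' umbrella windows.  Three forms are supported:
#' * `flat` — U(x) = 0;
#' * `harmonic` — U(x) = kappa/2 (x - center)^2 with `kappa` in
#'   kJ mol^-1 nm^-2;
#' * `double_well` — U(x) = B ((x - center)^2 - w^2)^2 / w^4, with wells at
#'   center +/- w and barrier height exactly `barrier` = B kJ/mol at the
#'   midpoint.
#'
#' @param form One of `"flat"`, `"harmonic"`, `"double_well"`.
#' @param kappa Harmonic stiffness, kJ mol^-1 nm^-2 (harmonic form).
#' @param center Potential centre, nm.
#' @param barrier Barrier height B, kJ/mol (double-well form).
#' @param half_width Well half-separation w, nm (double-well form).
#' @param temperature Temperature in K (default 310).
#'
#' @return A `potential_spec` object with a callable `U(x)` in kJ/mol.
#' @export
potential_spec <- function(form = c("flat", "harmonic", "double_well"),
                           kappa = 10, center = 0, barrier = 5,
                           half_width = 1, temperature = 310) {
  form <- match.arg(form)
  if (form == "harmonic" && kappa <= 0) {
    stop("harmonic stiffness must be positive", call. = FALSE)
  }
  if (form == "double_well" && (barrier <= 0 || half_width <= 0)) {
    stop("double-well barrier and half_width must be positive",
         call. = FALSE)
  }
  U <- switch(form,
    flat = function(x) rep(0, length(x)),
    harmonic = function(x) 0.5 * kappa * (x - center)^2,
    double_well = function(x) {
      barrier * ((x - center)^2 - half_width^2)^2 / half_width^4
    }
  )
  structure(
    list(form = form, kappa = kappa, center = center, barrier = barrier,
         half_width = half_width, temperature = temperature, U = U),
    class = "potential_spec"
  )
}

#' Generate exact equilibrium umbrella-window samples
#'
#' For each bias centre, draws samples from the equilibrium density
#' proportional to exp(-(U(x) + k/2 (x - x0)^2) / kBT).  For flat and
#' harmonic reference potentials the total potential is quadratic and the
#' draw is an exact Gaussian (harmonic: mean (kappa c + k x0)/(kappa + k),
#' variance kBT/(kappa + k)).  For the double well, rejection sampling
#' against a Gaussian envelope centred on the mode of the total potential
#' is used; the acceptance rate is monitored and a rate below 1% raises an
#' error as a sign of ill-chosen parameters.
#'
#' @param true_potential A [potential_spec()].
#' @param centers Strictly increasing bias centres, nm.
#' @param force_constant Harmonic bias force constant, kJ mol^-1 nm^-2.
#' @param n_samples Samples per window (>= 100).
#' @param seed Integer seed; output is a pure function of the arguments.
#' @param sample_spacing Nominal time between samples, ns.
#'
#' @return An [umbrella_windows()] tibble, one row per centre.
#' @export
#' @examples
#' w <- generate_umbrella_series(potential_spec("flat"),
#'                               centers = c(1, 2), force_constant = 1000,
#'                               n_samples = 200, seed = 7)
#' w$center
generate_umbrella_series <- function(true_potential, centers,
                                     force_constant, n_samples, seed,
                                     sample_spacing = 1) {
  stopifnot(inherits(true_potential, "potential_spec"))
  if (any(diff(centers) <= 0)) {
    stop("bias centers must be strictly increasing", call. = FALSE)
  }
  if (n_samples < 100) stop("n_samples must be >= 100", call. = FALSE)
  if (force_constant <= 0) stop("force_constant must be positive",
                                call. = FALSE)
  kBT <- KB_KJ_MOL_K * true_potential$temperature
  k <- force_constant
  samples <- withr::with_seed(seed, {
    lapply(centers, function(x0) {
      draw_window_samples(true_potential, x0, k, kBT, n_samples)
    })
  })
  umbrella_windows(centers, force_constant, samples,
                   sample_spacing = sample_spacing)
}

draw_window_samples <- function(pot, x0, k, kBT, n) {
  if (pot$form == "flat") {
    return(stats::rnorm(n, mean = x0, sd = sqrt(kBT / k)))
  }
  if (pot$form == "harmonic") {
    prec <- pot$kappa + k
    mu <- (pot$kappa * pot$center + k * x0) / prec
    return(stats::rnorm(n, mean = mu, sd = sqrt(kBT / prec)))
  }
  # double well: rejection against a Gaussian envelope at the mode of the
  # total potential V(x) = U(x) + k/2 (x - x0)^2
  V <- function(x) pot$U(x) + 0.5 * k * (x - x0)^2
  span <- abs(pot$center - x0) + 2 * pot$half_width + 1
  opt <- stats::optimize(V, interval = c(x0 - span, x0 + span))
  xstar <- opt$minimum
  h <- 1e-4
  curv <- (V(xstar - h) - 2 * V(xstar) + V(xstar + h)) / h^2
  sd_env <- 1.5 * sqrt(kBT / max(curv, k))
  grid <- seq(xstar - 8 * sd_env, xstar + 8 * sd_env, length.out = 2001)
  log_ratio <- -(V(grid) - V(xstar)) / kBT -
    stats::dnorm(grid, xstar, sd_env, log = TRUE)
  logM <- max(log_ratio)
  out <- numeric(0)
  tried <- 0
  while (length(out) < n) {
    m <- max(2L * (n - length(out)), 1000L)
    x <- stats::rnorm(m, xstar, sd_env)
    logp <- -(V(x) - V(xstar)) / kBT -
      stats::dnorm(x, xstar, sd_env, log = TRUE) - logM
    keep <- log(stats::runif(m)) < logp
    out <- c(out, x[keep])
    tried <- tried + m
    if (tried > 100 * n && length(out) / tried < 0.01) {
      stop("rejection acceptance rate below 1% for window at x0 = ", x0,
           "; check potential parameters", call. = FALSE)
    }
  }
  out[seq_len(n)]
}

#' Generate a Gaussian-mode ensemble
#'
#' Frames are the mean structure displaced along a small set of
#' orthonormal 3N-dimensional mode vectors with independent Gaussian
#' amplitudes: x_f = mean + sum_m z_m v_m, z_m ~ N(0, sigma_m^2).  The
#' coordinate vector convention is column-major over the `n x 3` matrix
#' (all x, then all y, then all z), matching [pca()].
#'
#' @param mean_structure A [bead_structure()] giving the mean coordinates.
#' @param mode_vectors A `3N x M` matrix with orthonormal columns
#'   (checked to 1e-8).
#' @param mode_variances Length-`M` variances, nm^2.
#' @param n_frames Frames to draw.
#' @param seed Integer seed.
#' @param frame_spacing Time between frames, ns.
#'
#' @return An [ensemble()].
#' @export
generate_gaussian_ensemble <- function(mean_structure, mode_vectors,
                                       mode_variances, n_frames, seed,
                                       frame_spacing = 1) {
  validate_bead_structure(mean_structure)
  n3 <- 3 * nrow(mean_structure)
  V <- as.matrix(mode_vectors)
  stopifnot(nrow(V) == n3, length(mode_variances) == ncol(V),
            all(mode_variances >= 0), n_frames >= 1)
  gram <- crossprod(V)
  if (max(abs(gram - diag(ncol(V)))) > 1e-8) {
    stop("mode_vectors must be orthonormal (tolerance 1e-8)",
         call. = FALSE)
  }
  mu <- as.vector(coords_matrix(mean_structure))
  z <- withr::with_seed(seed, {
    matrix(stats::rnorm(n_frames * ncol(V)), n_frames, ncol(V)) %*%
      diag(sqrt(mode_variances), ncol(V))
  })
  disp <- z %*% t(V)                      # n_frames x 3N
  coords <- array(0, dim = c(nrow(mean_structure), 3, n_frames))
  for (f in seq_len(n_frames)) {
    coords[, , f] <- matrix(mu + disp[f, ], ncol = 3)
  }
  ensemble(mean_structure, coords, frame_spacing = frame_spacing,
           label = "gaussian-mode ensemble")
}

#' Generate a stationary AR(1) series
#'
#' Test fixture for [autocorrelation_time()]: x_t = phi x_(t-1) + e_t with
#' unit-variance innovations and a stationary start, so the integrated
#' autocorrelation time is (1 + phi) / (1 - phi).
#'
#' @param n Series length.
#' @param phi AR(1) coefficient, |phi| < 1.
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @export
generate_ar1 <- function(n, phi, seed) {
  stopifnot(abs(phi) < 1, n >= 1)
  withr::with_seed(seed, {
    e <- stats::rnorm(n)
    x <- numeric(n)
    x[1] <- stats::rnorm(1, sd = 1 / sqrt(1 - phi^2))
    for (t in seq_len(n)[-1]) x[t] <- phi * x[t - 1] + e[t]
    x
  })
}
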