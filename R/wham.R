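#' Weighted histogram analysis of umbrella windows
#'
#' Combines biased window histograms into an unbiased potential of mean
#' force by the standard WHAM self-consistency:
#' \deqn{P(x_b) = \frac{\sum_i h_i(x_b)}{\sum_j N_j \exp[(f_j - w_j(x_b))/k_BT]}}
#' \deqn{f_i = -k_BT \ln \sum_b P(x_b) \exp(-w_i(x_b)/k_BT)}
#' with harmonic biases w_i(x) = k_i/2 (x - x_i0)^2.  Iteration stops when
#' the largest change in any window free energy f_i falls below
#' `tolerance`; the PMF is -kBT ln P, shifted so its minimum is zero, and
#' the f_i are reported with the first window pinned to 0.  Samples
#' outside the bin range are dropped with a count; bins inside the sampled
#' range that receive no samples get `NA` free energy.
#'
#' @param windows An [umbrella_windows()] tibble.
#' @param temperature Temperature, K (default 310).
#' @param bin_edges Bin edges in nm, or `NULL` for automatic bins of width
#'   `bin_width` spanning the samples.
#' @param bin_width Bin width used when `bin_edges` is `NULL`; the default
#'   0.02 nm resolves a typical 0.1 nm window spacing five-fold.
#' @param tolerance Convergence tolerance on max |delta f_i|, kJ/mol.
#' @param max_iterations Iteration cap; non-convergence is flagged, not
#'   fatal.
#' @param weights Optional positive per-window weights (used by the
#'   Bayesian bootstrap); default all 1.
#'
#' @return A `pmf_profile`: list with `profile` (tibble `bin_center`,
#'   `free_energy`, `n_samples`), `window_f` (tibble `center`, `f`),
#'   `n_iterations`, `converged`, `temperature`, `n_dropped`,
#'   `max_delta_f_trace`.
#' @export
#' @examples
#' w <- generate_umbrella_series(potential_spec("flat"),
#'                               centers = seq(0, 1, 0.25),
#'                               force_constant = 500, n_samples = 500,
#'                               seed = 11)
#' p <- wham_solve(w)
#' p$converged
wham_solve <- function(windows, temperature = 310, bin_edges = NULL,
                       bin_width = 0.02, tolerance = 1e-6,
                       max_iterations = 1e5, weights = NULL) {
  stopifnot(nrow(windows) >= 1, tolerance > 0)
  kBT <- KB_KJ_MOL_K * temperature
  if (is.null(bin_edges)) {
    lo <- min(vapply(windows$samples, min, numeric(1)))
    hi <- max(vapply(windows$samples, max, numeric(1)))
    bin_edges <- seq(floor(lo / bin_width) * bin_width,
                     ceiling(hi / bin_width) * bin_width, by = bin_width)
  }
  if (any(diff(bin_edges) <= 0)) {
    stop("bin edges must be strictly increasing", call. = FALSE)
  }
  nw <- nrow(windows)
  nb <- length(bin_edges) - 1
  centers <- (bin_edges[-1] + bin_edges[-(nb + 1)]) / 2
  if (is.null(weights)) weights <- rep(1, nw)
  stopifnot(length(weights) == nw, all(weights > 0))

  h <- matrix(0, nw, nb)
  n_dropped <- 0L
  for (i in seq_len(nw)) {
    s <- windows$samples[[i]]
    inside <- s >= bin_edges[1] & s <= bin_edges[nb + 1]
    n_dropped <- n_dropped + sum(!inside)
    idx <- pmin(findInterval(s[inside], bin_edges,
                             rightmost.closed = TRUE), nb)
    tab <- tabulate(idx, nbins = nb)
    h[i, ] <- tab * weights[i]
  }
  Ni <- rowSums(h)
  if (any(Ni == 0)) {
    stop("window(s) ", paste(which(Ni == 0), collapse = ", "),
         " contribute no in-range samples", call. = FALSE)
  }
  # bias energies at bin centers: nw x nb
  W <- 0.5 * outer(windows$force_constant,
                   rep(1, nb)) * (outer(windows$center, centers, `-`))^2
  numer <- colSums(h)
  expW <- exp(-W / kBT)
  f <- rep(0, nw)
  trace <- numeric(0)
  converged <- FALSE
  it <- 0
  while (it < max_iterations) {
    it <- it + 1
    denom <- colSums(Ni * exp(f / kBT) * expW)
    P <- ifelse(denom > 0, numer / denom, 0)
    P <- P / sum(P)
    f_new <- -kBT * log(as.vector(expW %*% P))
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f))
    trace <- c(trace, delta)
    f <- f_new
    if (delta < tolerance) { converged <- TRUE; break }
  }
  denom <- colSums(Ni * exp(f / kBT) * expW)
  P <- ifelse(denom > 0, numer / denom, 0)
  P <- P / sum(P)
  pmf <- ifelse(P > 0, -kBT * log(P), NA_real_)
  pmf <- pmf - min(pmf, na.rm = TRUE)
  empty_inside <- which(is.na(pmf) & centers > min(centers[P > 0]) &
                          centers < max(centers[P > 0]))
  if (length(empty_inside) > 0) {
    rlang::inform(paste0(length(empty_inside),
                         " empty bin(s) inside the sampled range"),
                  .frequency = "once",
                  .frequency_id = "avidpmf_wham_empty")
  }
  structure(
    list(profile = tibble::tibble(bin_center = centers, free_energy = pmf,
                                  n_samples = numer),
         window_f = tibble::tibble(center = windows$center, f = f),
         n_iterations = it, converged = converged,
         temperature = temperature, n_dropped = n_dropped,
         max_delta_f_trace = trace),
    class = "pmf_profile"
  )
}

#' @export
print.pmf_profile <- function(x, ...) {
  rng <- range(x$profile$free_energy, na.rm = TRUE)
  cat("# PMF profile:", nrow(x$profile), "bins,",
      sprintf("range %.2f-%.2f kJ/mol,", rng[1], rng[2]),
      x$n_iterations, "iterations,",
      if (x$converged) "converged" else "NOT converged", "\n")
  invisible(x)
}

#' @method tidy pmf_profile
#' @export
tidy.pmf_profile <- function(x, ...) x$profile

#' @method glance pmf_profile
#' @export
glance.pmf_profile <- function(x, ...) {
  tibble::tibble(n_bins = nrow(x$profile),
                 n_iterations = x$n_iterations, converged = x$converged,
                 temperature = x$temperature, n_dropped = x$n_dropped)
}

#' Histogram overlap between adjacent umbrella windows
#'
#' Quantifies the visual overlap check: for each pair of consecutive
#' windows (sorted by centre), the overlap is the summed bin-wise minimum
#' of the two normalised histograms, 1 for identical distributions, 0 for
#' disjoint support.  Pairs below `min_overlap` are flagged.
#'
#' @param windows An [umbrella_windows()] tibble (>= 2 rows).
#' @param bin_edges Common histogram bin edges, or `NULL` to span all
#'   samples at `bin_width`.
#' @param bin_width Bin width for automatic edges.
#' @param min_overlap Warning threshold on the overlap fraction (default 0.05).
#'
#' @return A tibble `center_lo`, `center_hi`, `overlap`, `flagged`.
#' @export
histogram_overlap <- function(windows, bin_edges = NULL, bin_width = 0.02,
                              min_overlap = 0.05) {
  stopifnot(nrow(windows) >= 2)
  ord <- order(windows$center)
  if (any(ord != seq_len(nrow(windows)))) {
    rlang::inform("windows were not sorted by center; sorting",
                  .frequency = "once",
                  .frequency_id = "avidpmf_overlap_sort")
    windows <- windows[ord, ]
  }
  if (is.null(bin_edges)) {
    lo <- min(vapply(windows$samples, min, numeric(1)))
    hi <- max(vapply(windows$samples, max, numeric(1)))
    bin_edges <- seq(floor(lo / bin_width) * bin_width,
                     ceiling(hi / bin_width) * bin_width, by = bin_width)
  }
  nb <- length(bin_edges) - 1
  pmat <- t(vapply(windows$samples, function(s) {
    idx <- pmin(findInterval(s, bin_edges, rightmost.closed = TRUE), nb)
    idx <- idx[idx >= 1]
    tabulate(idx, nbins = nb) / length(s)
  }, numeric(nb)))
  ov <- vapply(seq_len(nrow(windows) - 1), function(i) {
    sum(pmin(pmat[i, ], pmat[i + 1, ]))
  }, numeric(1))
  tibble::tibble(center_lo = windows$center[-nrow(windows)],
                 center_hi = windows$center[-1],
                 overlap = ov, flagged = ov < min_overlap)
}

#' Integrated autocorrelation time
#'
#' tau = 1 + 2 sum_t rho(t), with the sum truncated at the first lag where
#' the empirical autocorrelation goes negative (initial-positive-sequence
#' rule).  For a constant series tau is 1 by convention.  The effective
#' sample size of a series of length N is N / tau.
#'
#' @param series Numeric vector (>= 100 samples).
#' @return tau in sample units (>= 1).
#' @export
autocorrelation_time <- function(series) {
  n <- length(series)
  if (n < 100) stop("need at least 100 samples", call. = FALSE)
  if (stats::sd(series) == 0) {
    rlang::inform("constant series: tau = 1 by convention",
                  .frequency = "once", .frequency_id = "avidpmf_tau_const")
    return(1)
  }
  lag_max <- 100L
  repeat {
    rho <- stats::acf(series, lag.max = min(lag_max, n - 1),
                      plot = FALSE, demean = TRUE)$acf[-1]
    first_neg <- which(rho < 0)[1]
    if (!is.na(first_neg) || lag_max >= n - 1) break
    lag_max <- lag_max * 4L
  }
  upto <- if (is.na(first_neg)) length(rho) else first_neg - 1L
  1 + 2 * sum(rho[seq_len(upto)])
}

#' Bayesian bootstrap errors for a WHAM profile
#'
#' Each replicate re-solves WHAM with window histograms scaled by i.i.d.
#' unit-mean exponential weights (one weight per window — the Bayesian
#' bootstrap over complete windows), and the per-bin error is the standard
#' deviation of the min-shifted replicate PMFs.  Unconverged replicates
#' are discarded and counted, not fatal.
#'
#' @inheritParams wham_solve
#' @param n_bootstrap Number of replicates (>= 20).
#' @param seed Integer seed; errors are a pure function of the inputs.
#'
#' @return A tibble `bin_center`, `error` (kJ/mol), with attributes
#'   `n_discarded` and `n_bootstrap`.
#' @export
bootstrap_error <- function(windows, temperature = 310, bin_edges = NULL,
                            bin_width = 0.02, n_bootstrap = 200, seed = 1,
                            tolerance = 1e-6, max_iterations = 1e5) {
  stopifnot(n_bootstrap >= 20)
  if (is.null(bin_edges)) {
    lo <- min(vapply(windows$samples, min, numeric(1)))
    hi <- max(vapply(windows$samples, max, numeric(1)))
    bin_edges <- seq(floor(lo / bin_width) * bin_width,
                     ceiling(hi / bin_width) * bin_width, by = bin_width)
  }
  nw <- nrow(windows)
  reps <- withr::with_seed(seed, {
    lapply(seq_len(n_bootstrap), function(r) {
      w <- stats::rexp(nw)
      w <- w / mean(w)
      prof <- tryCatch(
        wham_solve(windows, temperature = temperature,
                   bin_edges = bin_edges, tolerance = tolerance,
                   max_iterations = max_iterations, weights = w),
        error = function(e) NULL
      )
      if (is.null(prof) || !prof$converged) NULL else
        prof$profile$free_energy
    })
  })
  ok <- !vapply(reps, is.null, logical(1))
  n_disc <- sum(!ok)
  if (!any(ok)) stop("all bootstrap replicates failed to converge",
                     call. = FALSE)
  mat <- do.call(cbind, reps[ok])
  centers <- (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2
  out <- tibble::tibble(bin_center = centers,
                        error = apply(mat, 1, stats::sd, na.rm = TRUE))
  attr(out, "n_discarded") <- n_disc
  attr(out, "n_bootstrap") <- n_bootstrap
  out
}

#' Binding free energy from a PMF plateau
#'
#' The depth of the profile: mean PMF over the dissociated plateau minus
#' the (zero-shifted) bound minimum.  By default the plateau is the last
#' 1.0 nm of the profile.
#'
#' @param profile A [wham_solve()] result.
#' @param plateau_window Length-2 numeric range in nm, or `NULL` for the
#'   default last 1.0 nm.
#' @return Binding free energy, kJ/mol.
#' @export
binding_energy <- function(profile, plateau_window = NULL) {
  stopifnot(inherits(profile, "pmf_profile"))
  pr <- profile$profile
  finite <- is.finite(pr$free_energy)
  if (is.null(plateau_window)) {
    hi <- max(pr$bin_center[finite])
    plateau_window <- c(hi - 1.0, hi)
  }
  inw <- pr$bin_center >= plateau_window[1] &
    pr$bin_center <= plateau_window[2] & finite
  if (sum(inw) < 3) {
    stop("plateau window must contain at least 3 finite bins",
         call. = FALSE)
  }
  mean(pr$free_energy[inw])
}
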