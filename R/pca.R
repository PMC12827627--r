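#' Principal component analysis of ensemble coordinates
#'
#' Frames are superposed onto the time-average structure (as in [rmsf()]),
#' then the covariance of the 3N-dimensional coordinate vector of the
#' selection (column-major: all x, then y, then z) is eigendecomposed.
#' Eigenvalues are reported in nm^2, descending, together with variance
#' fractions, orthonormal eigenvector displacement fields, and per-frame
#' projections.  With fewer frames than 3N the covariance is rank
#' deficient, which is expected and only warned about.
#'
#' The dense eigenproblem is practical up to a few thousand selected beads
#' (3N of order 10^4); larger selections should be subset first.
#'
#' @param ens An [ensemble()] with at least 2 frames.
#' @param selection Beads entering the covariance (default: all).
#' @param fit_selection Beads used for the superposition (default: all).
#'
#' @return A `pca_result`: list with `mean_coordinates` (`n x 3`),
#'   `eigenvalues` (nm^2), `variance_fractions`, `eigenvectors`
#'   (`3n x n_modes`, orthonormal columns), `projections`
#'   (`n_frames x n_modes`, nm), `selection`.
#' @export
#' @examples
#' toy <- generate_toy_igm(toy_igm_params(n_frames = 30, seed = 5))
#' p <- pca(toy$ensemble)
#' head(p$variance_fractions)
pca <- function(ens, selection = NULL, fit_selection = NULL) {
  if (n_frames(ens) < 2) stop("PCA needs at least 2 frames", call. = FALSE)
  nb <- nrow(ens$topology)
  if (is.null(selection)) selection <- seq_len(nb)
  if (is.null(fit_selection)) fit_selection <- seq_len(nb)
  al <- align_to_mean(ens, fit_selection)
  nf <- n_frames(ens)
  n3 <- 3 * length(selection)
  if (nf < n3) {
    rlang::warn(paste0("fewer frames (", nf, ") than coordinates (", n3,
                       "): covariance is rank deficient (expected)"),
                .frequency = "once", .frequency_id = "avidpmf_pca_rank")
  }
  X <- t(vapply(seq_len(nf), function(f) {
    m <- al$coords[selection, , f]
    as.vector(m)
  }, numeric(n3)))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0)
  lambda <- sv$d^2 / (nf - 1)
  keep <- seq_len(min(nf - 1, n3))
  lambda <- lambda[keep]
  V <- sv$v[, keep, drop = FALSE]
  structure(
    list(mean_coordinates = matrix(mu, ncol = 3),
         eigenvalues = lambda,
         variance_fractions = lambda / sum(lambda),
         eigenvectors = V,
         projections = Xc %*% V,
         selection = selection),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat("# PCA:", length(x$eigenvalues), "modes over",
      nrow(x$mean_coordinates), "beads\n")
  k <- seq_len(min(3, length(x$eigenvalues)))
  cat("  top variance fractions:",
      paste(sprintf("%.2f%%", 100 * x$variance_fractions[k]),
            collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy pca_result
#' @export
tidy.pca_result <- function(x, ...) {
  tibble::tibble(mode = seq_along(x$eigenvalues),
                 eigenvalue = x$eigenvalues,
                 variance_fraction = x$variance_fractions)
}

#' @method glance pca_result
#' @export
glance.pca_result <- function(x, ...) {
  tibble::tibble(n_modes = length(x$eigenvalues),
                 total_variance = sum(x$eigenvalues),
                 pc1_fraction = x$variance_fractions[1])
}

#' Interpolated trajectory along one principal mode
#'
#' Builds an ensemble of `n_interp` frames running linearly from
#' mean - amplitude sqrt(lambda) v to mean + amplitude sqrt(lambda) v
#' along the chosen mode — the standard way of visualising a principal
#' motion as a colour-graded morph.
#'
#' @param result A [pca()] result.
#' @param topology The [bead_structure()] matching `result$selection`.
#' @param mode Mode index.
#' @param n_interp Number of frames (default 20).
#' @param amplitude Excursion in multiples of sqrt(eigenvalue), default 2.
#'
#' @return An [ensemble()] over the selected beads.
#' @export
pca_mode_trajectory <- function(result, topology, mode = 1, n_interp = 20,
                                amplitude = 2) {
  stopifnot(inherits(result, "pca_result"))
  if (mode < 1 || mode > length(result$eigenvalues)) {
    stop("mode index out of range", call. = FALSE)
  }
  sel_topo <- topology[result$selection, ]
  sel_topo$bead_id <- seq_len(nrow(sel_topo))
  sel_topo <- new_bead_structure(tibble::as_tibble(sel_topo))
  mu <- as.vector(result$mean_coordinates)
  v <- result$eigenvectors[, mode]
  a <- amplitude * sqrt(result$eigenvalues[mode])
  ramp <- seq(-a, a, length.out = n_interp)
  frames <- lapply(ramp, function(s) matrix(mu + s * v, ncol = 3))
  ensemble(sel_topo, frames, frame_spacing = 1,
           label = paste0("PC", mode, " mode trajectory"))
}
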