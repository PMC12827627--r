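#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD of
#' `mobile` onto `reference` over `fit_selection`, and applies it to all
#' beads of `mobile`.  The rotation is constrained to determinant +1 by
#' the usual sign correction of the smallest singular vector.
#'
#' @param mobile `n x 3` coordinate matrix to move, nm.
#' @param reference `n x 3` coordinate matrix to fit to, nm.
#' @param fit_selection Integer bead indices used for the fit (default:
#'   all); at least 3 non-collinear beads.
#'
#' @return A list with `coords` (transformed `n x 3` matrix) and `rmsd`
#'   (over the fit selection, nm).
#' @export
superpose <- function(mobile, reference, fit_selection = NULL) {
  stopifnot(nrow(mobile) == nrow(reference), ncol(mobile) == 3)
  if (is.null(fit_selection)) fit_selection <- seq_len(nrow(mobile))
  fit_selection <- as.integer(fit_selection)
  if (length(fit_selection) < 3) {
    stop("fit selection needs at least 3 beads", call. = FALSE)
  }
  A <- mobile[fit_selection, , drop = FALSE]
  B <- reference[fit_selection, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  sv <- svd(crossprod(A0, B0))
  if (sv$d[2] < 1e-12) {
    stop("degenerate (collinear or coincident) fit selection",
         call. = FALSE)
  }
  s <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, 1, s))
  R <- sv$u %*% D %*% t(sv$v)
  out <- sweep(sweep(mobile, 2, ca) %*% R, 2, cb, `+`)
  dif <- out[fit_selection, , drop = FALSE] - B
  list(coords = out, rmsd = sqrt(mean(rowSums(dif^2))))
}

rmsd_between <- function(a, b, sel) {
  d <- a[sel, , drop = FALSE] - b[sel, , drop = FALSE]
  sqrt(mean(rowSums(d^2)))
}

#' RMSD time series in either fit mode
#'
#' Per frame, superposes the frame onto the reference over
#' `fit_selection`, then measures RMSD over `calc_selection`.  Setting
#' `fit_selection` to all beads gives the whole-structure fit mode (the
#' deviation of a domain after least-squares fitting the complete
#' assembly); setting `fit_selection = calc_selection` gives the
#' intradomain (self-fit) mode.
#'
#' @param ens An [ensemble()].
#' @param reference Frame index (default 1) or a [bead_structure()] /
#'   `n x 3` matrix.
#' @param fit_selection Beads for the superposition (default: all).
#' @param calc_selection Beads over which RMSD is measured (default: all).
#'
#' @return A tibble with columns `frame`, `time_ns`, `rmsd` (nm).
#' @export
rmsd_series <- function(ens, reference = 1, fit_selection = NULL,
                        calc_selection = NULL) {
  nb <- nrow(ens$topology)
  if (is.null(fit_selection)) fit_selection <- seq_len(nb)
  if (is.null(calc_selection)) calc_selection <- seq_len(nb)
  ref <- resolve_reference(ens, reference)
  nf <- n_frames(ens)
  r <- vapply(seq_len(nf), function(f) {
    fit <- superpose(frame_coords(ens, f), ref, fit_selection)
    rmsd_between(fit$coords, ref, calc_selection)
  }, numeric(1))
  tibble::tibble(frame = seq_len(nf),
                 time_ns = (seq_len(nf) - 1) * ens$frame_spacing,
                 rmsd = r)
}

resolve_reference <- function(ens, reference) {
  if (is.numeric(reference) && length(reference) == 1) {
    frame_coords(ens, reference)
  } else if (inherits(reference, "bead_structure")) {
    coords_matrix(reference)
  } else if (is.matrix(reference)) {
    reference
  } else {
    stop("reference must be a frame index, structure, or matrix",
         call. = FALSE)
  }
}

# two-pass mean-structure alignment shared by rmsf() and pca():
# fit every frame to frame 1, average, then refit to the average
align_to_mean <- function(ens, fit_selection) {
  nf <- n_frames(ens)
  nb <- nrow(ens$topology)
  ref <- frame_coords(ens, 1)
  aligned <- array(0, dim = c(nb, 3, nf))
  for (f in seq_len(nf)) {
    aligned[, , f] <- superpose(frame_coords(ens, f), ref,
                                fit_selection)$coords
  }
  avg <- apply(aligned, c(1, 2), mean)
  for (f in seq_len(nf)) {
    m <- aligned[, , f]; dim(m) <- c(nb, 3)
    aligned[, , f] <- superpose(m, avg, fit_selection)$coords
  }
  list(coords = aligned, mean = apply(aligned, c(1, 2), mean))
}

#' Per-bead root-mean-square fluctuation
#'
#' Frames are superposed onto the time-average structure (two-pass: fit to
#' the first frame, average, refit to the average), then
#' RMSF_i = sqrt(mean_f |x_i(f) - <x_i>|^2).
#'
#' @param ens An [ensemble()] with at least 2 frames.
#' @param selection Beads to report (default: all).
#' @param fit_selection Beads used for the superposition (default: all).
#'
#' @return A tibble with columns `bead_id`, `chain_id`, `residue_index`,
#'   `rmsf` (nm).
#' @export
rmsf <- function(ens, selection = NULL, fit_selection = NULL) {
  if (n_frames(ens) < 2) stop("RMSF needs at least 2 frames",
                              call. = FALSE)
  nb <- nrow(ens$topology)
  if (is.null(selection)) selection <- seq_len(nb)
  if (is.null(fit_selection)) fit_selection <- seq_len(nb)
  al <- align_to_mean(ens, fit_selection)
  dev2 <- sweep(al$coords, c(1, 2), al$mean)^2
  msf <- apply(dev2, 1, sum) / n_frames(ens)   # sums x,y,z and frames
  tibble::tibble(bead_id = ens$topology$bead_id[selection],
                 chain_id = ens$topology$chain_id[selection],
                 residue_index = ens$topology$residue_index[selection],
                 rmsf = sqrt(msf[selection]))
}
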