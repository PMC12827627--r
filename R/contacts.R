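#' Count contacts between two selections in one frame
#'
#' A contact is a pair of beads, one from each selection, whose centre
#' distance is at most `cutoff` (closed comparison; the conventional
#' coarse-grained cutoff is 0.6 nm).  Implemented with a cell list of
#' side `cutoff`, so only the 27 neighbouring cells of each bead are
#' examined.
#'
#' @param frame `n x 3` coordinate matrix, nm.
#' @param sel_a,sel_b Disjoint integer bead index selections.
#' @param cutoff Contact cutoff, nm (default 0.6).
#' @return Integer number of contacting pairs.
#' @export
contact_count <- function(frame, sel_a, sel_b, cutoff = 0.6) {
  pairs <- contact_pairs(frame, sel_a, sel_b, cutoff)
  nrow(pairs)
}

contact_pairs <- function(frame, sel_a, sel_b, cutoff) {
  sel_a <- as.integer(sel_a); sel_b <- as.integer(sel_b)
  if (length(intersect(sel_a, sel_b)) > 0) {
    stop("selections must be disjoint", call. = FALSE)
  }
  empty <- cbind(a = integer(0), b = integer(0))
  if (length(sel_a) == 0 || length(sel_b) == 0) return(empty)
  a <- frame[sel_a, , drop = FALSE]
  b <- frame[sel_b, , drop = FALSE]
  # cell list over b
  cell_b <- floor(b / cutoff)
  key_b <- paste(cell_b[, 1], cell_b[, 2], cell_b[, 3])
  bins <- split(seq_along(sel_b), key_b)
  cell_a <- floor(a / cutoff)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  c2 <- cutoff^2
  out <- vector("list", length(sel_a))
  for (i in seq_along(sel_a)) {
    keys <- paste(cell_a[i, 1] + off[, 1], cell_a[i, 2] + off[, 2],
                  cell_a[i, 3] + off[, 3])
    cand <- unlist(bins[keys], use.names = FALSE)
    if (length(cand) == 0) next
    d2 <- (b[cand, 1] - a[i, 1])^2 + (b[cand, 2] - a[i, 2])^2 +
      (b[cand, 3] - a[i, 3])^2
    hit <- cand[d2 <= c2]
    if (length(hit) > 0) out[[i]] <- cbind(a = sel_a[i], b = sel_b[hit])
  }
  found <- do.call(rbind, out)
  if (is.null(found)) empty else found
}

#' Mean per-residue contact counts over an ensemble
#'
#' Contacts between `sel_a` and `sel_b` (cutoff as in [contact_count()])
#' aggregated by the (chain, residue) of the `sel_a` bead and averaged
#' over frames — e.g. the average number of glycan contacts made by each
#' residue of an antibody.
#'
#' @param ens An [ensemble()].
#' @inheritParams contact_count
#' @return A tibble `chain_id`, `residue_index`, `mean_contacts`, covering
#'   every residue present in `sel_a` (zero where no contacts occur).
#' @export
per_residue_contacts <- function(ens, sel_a, sel_b, cutoff = 0.6) {
  topo <- ens$topology
  nf <- n_frames(ens)
  res_key <- paste(topo$chain_id, topo$residue_index)
  all_res <- unique(res_key[sel_a])
  counts <- matrix(0, nrow = length(all_res), ncol = nf,
                   dimnames = list(all_res, NULL))
  for (f in seq_len(nf)) {
    pr <- contact_pairs(frame_coords(ens, f), sel_a, sel_b, cutoff)
    if (nrow(pr) == 0) next
    tab <- table(res_key[pr[, "a"]])
    counts[names(tab), f] <- as.integer(tab)
  }
  first <- match(all_res, res_key)
  tibble::tibble(chain_id = topo$chain_id[first],
                 residue_index = topo$residue_index[first],
                 mean_contacts = rowMeans(counts))
}

#' Centre-of-mass distance series
#'
#' Per-frame Euclidean distance between the unweighted centres of mass of
#' two selections — e.g. a CDR and its bound receptor.
#'
#' @param ens An [ensemble()].
#' @param sel_a,sel_b Non-empty integer bead selections.
#' @return A tibble `frame`, `time_ns`, `distance` (nm).
#' @export
com_distance_series <- function(ens, sel_a, sel_b) {
  sel_a <- as.integer(sel_a); sel_b <- as.integer(sel_b)
  if (length(sel_a) == 0 || length(sel_b) == 0) {
    stop("selections must be non-empty", call. = FALSE)
  }
  co <- ens$coords
  com_a <- apply(co[sel_a, , , drop = FALSE], c(2, 3), mean)
  com_b <- apply(co[sel_b, , , drop = FALSE], c(2, 3), mean)
  d <- sqrt(colSums((com_a - com_b)^2))
  nf <- n_frames(ens)
  tibble::tibble(frame = seq_len(nf),
                 time_ns = (seq_len(nf) - 1) * ens$frame_spacing,
                 distance = d)
}
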