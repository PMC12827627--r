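#' Nearest-obstruction distance for one Fab in one frame
#'
#' Euclidean distance from the centre of mass of a Fab's CDR (unweighted
#' mean of CDR bead positions, or mass-weighted if masses are given) to
#' the nearest bead centre belonging to any domain not excluded.  The Fab
#' bearing the CDR is always excluded; glycan or other accessory domains
#' are obstructions unless explicitly excluded.  When no obstruction beads
#' remain the distance is `Inf` (always classified accessible).
#'
#' @param frame An `n x 3` coordinate matrix, nm.
#' @param map A [domain_map()].
#' @param fab_name Name of the Fab domain whose CDR is probed.
#' @param exclusions Character vector of additional domain names to drop
#'   from the obstruction set.
#' @param masses Optional per-bead masses for a weighted CDR centre.
#'
#' @return Distance in nm (possibly `Inf`).
#' @export
nearest_obstruction_distance <- function(frame, map, fab_name,
                                         exclusions = character(),
                                         masses = NULL) {
  if (!fab_name %in% names(map$domains)) {
    stop("unknown Fab domain: ", fab_name, call. = FALSE)
  }
  cdr_name <- map$cdr_of[[fab_name]]
  if (is.null(cdr_name)) {
    stop("no CDR selection registered for ", fab_name, call. = FALSE)
  }
  cdr <- map$domains[[cdr_name]]
  com <- selection_com(frame, cdr, masses)
  obst <- obstruction_indices(map, fab_name, exclusions)
  if (length(obst) == 0) return(Inf)
  sqrt(min((frame[obst, 1] - com[1])^2 + (frame[obst, 2] - com[2])^2 +
             (frame[obst, 3] - com[3])^2))
}

selection_com <- function(frame, sel, masses = NULL) {
  if (is.null(masses)) {
    colMeans(frame[sel, , drop = FALSE])
  } else {
    w <- masses[sel] / sum(masses[sel])
    colSums(frame[sel, , drop = FALSE] * w)
  }
}

obstruction_indices <- function(map, fab_name, exclusions) {
  drop <- union(fab_name, exclusions)
  keep <- setdiff(names(map$domains), drop)
  # the Fab's own CDR is inside the Fab, but guard against maps where the
  # CDR is registered as a separate (overlapping) domain name
  cdr_name <- map$cdr_of[[fab_name]]
  keep <- setdiff(keep, cdr_name)
  fab_beads <- map$domains[[fab_name]]
  obst <- unique(unlist(map$domains[keep], use.names = FALSE))
  setdiff(obst, fab_beads)
}

#' Simultaneous-binding accessibility over ensembles
#'
#' For every (ensemble, frame, Fab) configuration, computes the
#' nearest-obstruction distance of the Fab's CDR and classifies the
#' configuration as accessible when the distance is at least `threshold`
#' (closed comparison: ties are accessible).  The pooled fraction of
#' accessible configurations estimates the probability that an
#' antigen-sized receptor can engage a Fab without steric interference —
#' the simultaneous-binding probability.  The receptor-derived default
#' threshold is 1.8 nm, half the minimal width of the receptor's binding
#' domain.
#'
#' @param ensembles An [ensemble()] or list of ensembles sharing one
#'   topology (independent runs are pooled).
#' @param map A [domain_map()] with registered `fab_ids` and CDRs.
#' @param threshold Accessibility threshold, nm (> 0).
#' @param exclusions Extra domain names excluded from obstruction (e.g.
#'   glycan domains).
#'
#' @return An `accessibility_result`: list with `distances` (tibble
#'   `ensemble`, `frame`, `fab`, `distance`, `accessible`), `per_fab`
#'   (tibble `fab`, `probability`, `n`), `overall_probability`,
#'   `n_configurations`, `threshold`.
#' @export
#' @examples
#' toy <- generate_toy_igm(toy_igm_params(n_frames = 20, seed = 3))
#' res <- binding_accessibility(toy$ensemble, toy$domain_map)
#' res$overall_probability
binding_accessibility <- function(ensembles, map, threshold = 1.8,
                                  exclusions = character()) {
  if (inherits(ensembles, "ensemble")) ensembles <- list(ensembles)
  if (length(map$fab_ids) == 0) {
    stop("domain map has no registered Fab domains", call. = FALSE)
  }
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  nb <- nrow(ensembles[[1]]$topology)
  for (e in ensembles) {
    if (nrow(e$topology) != nb) {
      stop("ensembles do not share a topology", call. = FALSE)
    }
  }
  pieces <- lapply(seq_along(ensembles), function(ei) {
    ens <- ensembles[[ei]]
    nf <- n_frames(ens)
    per_fab <- lapply(map$fab_ids, function(fab) {
      d <- fab_distance_series(ens, map, fab, exclusions)
      tibble::tibble(ensemble = ei, frame = seq_len(nf), fab = fab,
                     distance = d)
    })
    dplyr::bind_rows(per_fab)
  })
  distances <- dplyr::bind_rows(pieces)
  distances$accessible <- distances$distance >= threshold
  per_fab <- distances |>
    dplyr::group_by(.data$fab) |>
    dplyr::summarise(probability = mean(.data$accessible),
                     n = dplyr::n(), .groups = "drop")
  structure(
    list(distances = distances, per_fab = per_fab,
         overall_probability = mean(distances$accessible),
         n_configurations = nrow(distances), threshold = threshold),
    class = "accessibility_result"
  )
}

# vectorised over frames: distances for one Fab across a whole ensemble
fab_distance_series <- function(ens, map, fab_name, exclusions) {
  cdr <- map$domains[[map$cdr_of[[fab_name]]]]
  obst <- obstruction_indices(map, fab_name, exclusions)
  nf <- n_frames(ens)
  if (length(obst) == 0) return(rep(Inf, nf))
  co <- ens$coords
  # CDR centre of mass per frame: 3 x nf
  com <- apply(co[cdr, , , drop = FALSE], c(2, 3), mean)
  ox <- co[obst, 1, , drop = FALSE]; dim(ox) <- c(length(obst), nf)
  oy <- co[obst, 2, , drop = FALSE]; dim(oy) <- c(length(obst), nf)
  oz <- co[obst, 3, , drop = FALSE]; dim(oz) <- c(length(obst), nf)
  dx <- sweep(ox, 2, com[1, ])
  dy <- sweep(oy, 2, com[2, ])
  dz <- sweep(oz, 2, com[3, ])
  sqrt(apply(dx * dx + dy * dy + dz * dz, 2, min))
}

#' @export
print.accessibility_result <- function(x, ...) {
  cat("# Binding accessibility:", x$n_configurations,
      "configurations, threshold", x$threshold, "nm\n")
  cat("  pooled probability:",
      sprintf("%.2f%%", 100 * x$overall_probability), "\n")
  invisible(x)
}

#' @method tidy accessibility_result
#' @export
tidy.accessibility_result <- function(x, ...) x$distances

#' @method glance accessibility_result
#' @export
glance.accessibility_result <- function(x, ...) {
  tibble::tibble(overall_probability = x$overall_probability,
                 n_configurations = x$n_configurations,
                 threshold = x$threshold,
                 n_fabs = nrow(x$per_fab))
}
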