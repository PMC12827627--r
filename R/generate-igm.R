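#' Parameters for the toy pentameric antibody generator
#'
#' The toy model abstracts a pentameric IgM into a planar ring of rigid
#' core segments with mobile antigen-binding arms.  Defaults describe an
#' IgM-like geometry: five subunits with two Fab arms each (ten arms), a
#' core ring of roughly 6 nm radius and 7 nm arms, with per-frame arm
#' orientations drawn uniformly within a cone about the outward radial
#' direction.
#'
#' @param n_subunits Number of core subunits (default 5).
#' @param fabs_per_subunit Arms per subunit (default 2).
#' @param core_radius Radius of the planar core ring, nm.
#' @param arm_length Arm length hinge-to-tip, nm.
#' @param beads_per_arm Beads per arm.
#' @param cdr_tip_beads Beads at the arm tip labelled as the CDR.
#' @param hinge_cone_half_angle Half-angle of the hinge cone, degrees
#'   (0 freezes the arms).
#' @param n_frames Frames to generate.
#' @param frame_spacing Time between frames, ns.
#' @param seed Integer seed; the generator is a pure function of
#'   (params, seed).
#'
#' @return A list of validated parameters, class `toy_igm_params`.
#' @export
toy_igm_params <- function(n_subunits = 5, fabs_per_subunit = 2,
                           core_radius = 6, arm_length = 7,
                           beads_per_arm = 10, cdr_tip_beads = 2,
                           hinge_cone_half_angle = 40, n_frames = 100,
                           frame_spacing = 1, seed = 1) {
  p <- list(n_subunits = as.integer(n_subunits),
            fabs_per_subunit = as.integer(fabs_per_subunit),
            core_radius = core_radius, arm_length = arm_length,
            beads_per_arm = as.integer(beads_per_arm),
            cdr_tip_beads = as.integer(cdr_tip_beads),
            hinge_cone_half_angle = hinge_cone_half_angle,
            n_frames = as.integer(n_frames),
            frame_spacing = frame_spacing, seed = as.integer(seed))
  with(p, {
    stopifnot(n_subunits >= 1, fabs_per_subunit >= 1, beads_per_arm >= 1,
              cdr_tip_beads >= 1, n_frames >= 1)
    if (core_radius <= 0 || arm_length <= 0) {
      stop("core_radius and arm_length must be positive", call. = FALSE)
    }
    if (hinge_cone_half_angle < 0 || hinge_cone_half_angle > 90) {
      stop("hinge_cone_half_angle must lie in [0, 90] degrees",
           call. = FALSE)
    }
    if (cdr_tip_beads > beads_per_arm) {
      stop("cdr_tip_beads cannot exceed beads_per_arm", call. = FALSE)
    }
  })
  structure(p, class = "toy_igm_params")
}

#' Generate a toy pentameric antibody ensemble
#'
#' Builds a planar ring of rigid core segments (fixed across frames, plus a
#' small central J-chain-like cluster) with `n_subunits * fabs_per_subunit`
#' arms.  Each arm is a straight chain of beads attached at a hinge on the
#' ring; its axis is redrawn independently per frame, uniformly within a
#' cone of the given half-angle about the outward radial direction.  The
#' last `cdr_tip_beads` beads of arm *k* form the `CDR_k` selection of the
#' returned domain map.
#'
#' @param params A [toy_igm_params()] list.
#' @return A list with elements `ensemble` (an [ensemble()]) and
#'   `domain_map` (a [domain_map()] with `Fc`, `Jchain`, `Fab_k`, `CDR_k`).
#' @export
#' @examples
#' toy <- generate_toy_igm(toy_igm_params(n_frames = 5, seed = 42))
#' toy$ensemble
generate_toy_igm <- function(params) {
  stopifnot(inherits(params, "toy_igm_params"))
  p <- params
  n_arms <- p$n_subunits * p$fabs_per_subunit
  core_per_sub <- 6L
  n_core <- p$n_subunits * core_per_sub
  n_j <- 3L
  n_arm_beads <- n_arms * p$beads_per_arm
  n_beads <- n_core + n_j + n_arm_beads

  # static core ring: core_per_sub beads along each subunit's arc
  sub_arc <- 2 * pi / p$n_subunits
  core_theta <- unlist(lapply(seq_len(p$n_subunits), function(s) {
    (s - 1) * sub_arc + sub_arc * (seq_len(core_per_sub) - 0.5) / core_per_sub
  }))
  core_xyz <- cbind(p$core_radius * cos(core_theta),
                    p$core_radius * sin(core_theta), 0)
  j_xyz <- cbind(c(0, 0.5, -0.5), c(0, 0.3, 0.3), 0)

  # hinge positions: fabs evenly spread within each subunit's arc
  hinge_theta <- unlist(lapply(seq_len(p$n_subunits), function(s) {
    (s - 1) * sub_arc +
      sub_arc * (seq_len(p$fabs_per_subunit) - 0.5) / p$fabs_per_subunit
  }))
  hinge_xyz <- cbind(p$core_radius * cos(hinge_theta),
                     p$core_radius * sin(hinge_theta), 0)

  alpha <- p$hinge_cone_half_angle * pi / 180
  bead_d <- p$arm_length * seq_len(p$beads_per_arm) / p$beads_per_arm
  # rigid zigzag offset perpendicular to the arm axis: arms are
  # three-dimensional rigid bodies, not degenerate rods
  zig <- 0.15 * ((seq_len(p$beads_per_arm) %% 2) * 2 - 1)

  coords <- array(0, dim = c(n_beads, 3, p$n_frames))
  coords[seq_len(n_core), 1, ] <- core_xyz[, 1]
  coords[seq_len(n_core), 2, ] <- core_xyz[, 2]
  coords[n_core + seq_len(n_j), 1, ] <- j_xyz[, 1]
  coords[n_core + seq_len(n_j), 2, ] <- j_xyz[, 2]

  withr::with_seed(p$seed, {
    for (a in seq_len(n_arms)) {
      # uniform-in-solid-angle cone about the outward radial direction
      cos_t <- stats::runif(p$n_frames, cos(alpha), 1)
      phi <- stats::runif(p$n_frames, 0, 2 * pi)
      sin_t <- sqrt(pmax(0, 1 - cos_t^2))
      th <- hinge_theta[a]
      e1 <- c(-sin(th), cos(th), 0)   # in-plane tangent
      e2 <- c(0, 0, 1)                # ring normal
      e3 <- c(cos(th), sin(th), 0)    # outward radial
      # per-frame arm axes, n_frames x 3
      u <- outer(sin_t * cos(phi), e1) + outer(sin_t * sin(phi), e2) +
        outer(cos_t, e3)
      # per-frame perpendicular for the zigzag: u x z, with a fallback
      # for the measure-zero case of u parallel to z
      wv <- cbind(u[, 2], -u[, 1], 0)
      nw <- sqrt(rowSums(wv^2))
      wv <- wv / pmax(nw, 1e-8)
      bad <- nw < 1e-8
      if (any(bad)) wv[bad, ] <- matrix(c(1, 0, 0), sum(bad), 3,
                                        byrow = TRUE)
      row0 <- n_core + n_j + (a - 1) * p$beads_per_arm
      for (l in seq_len(p$beads_per_arm)) {
        coords[row0 + l, 1, ] <- hinge_xyz[a, 1] + bead_d[l] * u[, 1] +
          zig[l] * wv[, 1]
        coords[row0 + l, 2, ] <- hinge_xyz[a, 2] + bead_d[l] * u[, 2] +
          zig[l] * wv[, 2]
        coords[row0 + l, 3, ] <- bead_d[l] * u[, 3] + zig[l] * wv[, 3]
      }
    }
  })

  sub_of_core <- rep(seq_len(p$n_subunits), each = core_per_sub)
  if (n_arms > 26 || p$n_subunits > 9) {
    stop("toy generator supports at most 9 subunits / 26 arms ",
         "(single-character chain ids)", call. = FALSE)
  }
  arm_chain <- letters[seq_len(n_arms)]   # lowercase: cores are uppercase
  topo <- bead_structure(
    x = coords[, 1, 1], y = coords[, 2, 1], z = coords[, 3, 1],
    radius = 0.235,
    chain_id = c(LETTERS[sub_of_core], rep("J", n_j),
                 rep(arm_chain, each = p$beads_per_arm)),
    residue_index = c(rep(seq_len(core_per_sub), p$n_subunits),
                      seq_len(n_j),
                      rep(seq_len(p$beads_per_arm), n_arms)),
    residue_name = c(rep("COR", n_core), rep("JCH", n_j),
                     rep("ARM", n_arm_beads)),
    bead_name = "BB"
  )

  fab_ids <- paste0("Fab_", seq_len(n_arms))
  cdr_ids <- paste0("CDR_", seq_len(n_arms))
  domains <- c(
    list(Fc = seq_len(n_core), Jchain = n_core + seq_len(n_j)),
    stats::setNames(lapply(seq_len(n_arms), function(a) {
      n_core + n_j + (a - 1) * p$beads_per_arm + seq_len(p$beads_per_arm)
    }), fab_ids),
    stats::setNames(lapply(seq_len(n_arms), function(a) {
      n_core + n_j + a * p$beads_per_arm -
        (p$cdr_tip_beads - 1):0
    }), cdr_ids)
  )
  dm <- domain_map(domains, fab_ids = fab_ids,
                   cdr_of = stats::setNames(cdr_ids, fab_ids),
                   topology = topo)

  list(
    ensemble = ensemble(topo, coords, frame_spacing = p$frame_spacing,
                        label = "toy pentameric IgM"),
    domain_map = dm
  )
}
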