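# Synthetic structure and melting-curve generators.  These stand in for the
# inputs the analyses were designed for -- molecular dynamics snapshot
# ensembles of a 7-helix bundle carrying a globular fusion domain, and
# circular dichroism melting curves -- with full control of the planted
# ground truth (rigid-body motions, noise, cluster occupancies, midpoints).
# Geometric realism is not a goal; selection and transform correctness is.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Random proper rotation with normally distributed angle
#'
#' Axis uniform on the sphere, angle drawn from `Normal(0, sd_deg)`
#' (degrees), composed by Rodrigues' formula.  Used for all rigid-body
#' jitter in the generators, so oracles can replay the construction.
#'
#' @param sd_deg standard deviation of the rotation angle, degrees.
#' @return 3x3 rotation matrix.
#' @export
random_rotation <- function(sd_deg) {
  if (sd_deg <= 0) return(diag(3))
  axis <- stats::rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  angle <- stats::rnorm(1, 0, sd_deg) * pi / 180
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# rotate coordinates about their centroid, then translate
jitter_rigid <- function(xyz, rot_sd_deg, trans_sd) {
  R <- random_rotation(rot_sd_deg)
  tr <- if (trans_sd > 0) stats::rnorm(3, 0, trans_sd) else c(0, 0, 0)
  ctr <- colMeans(xyz)
  sweep(sweep(xyz, 2L, ctr) %*% t(R), 2L, -(ctr + tr))
}

#' Build an idealized helix-bundle / fusion-domain complex
#'
#' Constructs a reference conformation mimicking a GPCR-T4L fusion: `n_helices`
#' ideal alpha-helices (rise 1.5 A per residue, 100 degrees twist per
#' residue) stand on a circle of radius 12 A with alternating direction, and
#' a compact pseudo-globular fusion domain sits below the bundle along its
#' axis, built as a self-avoiding random cluster with a 2.5 A minimum
#' CA-CA distance.  Every residue is alanine with backbone N, CA, C and a
#' CB side-chain atom.
#'
#' @param n_helices number of transmembrane helices (default 7).
#' @param residues_per_helix residues per helix (default 20).
#' @param fusion_residues residues in the fusion domain (default 40).
#' @param seed integer seed; the output is a pure function of it.
#' @return list with `frame` (a [structure_frame()]) and `segmap`
#'   (a [segment_map()] labelling `TM1..TMn` and `T4L`).
#' @export
make_bundle <- function(n_helices = 7L, residues_per_helix = 20L,
                        fusion_residues = 40L, seed = 1L) {
  if (n_helices < 1L)
    stop_gpcrstab("need at least one helix", "invalid_parameter_error")
  with_seed(seed, {
    rise <- 1.5; twist <- 100 * pi / 180
    r_ca <- 2.3
    atoms <- list(); xyz <- list()
    res0 <- 0L
    add_res <- function(resseq, base, axis_pts) {
      # axis_pts: named list of atom offsets (already absolute coordinates)
      for (nm in names(axis_pts)) {
        atoms[[length(atoms) + 1L]] <<- data.frame(
          atom_name = nm, element = substr(nm, 1L, 1L), chain = "A",
          resseq = resseq, icode = "", resname = "ALA")
        xyz[[length(xyz) + 1L]] <<- axis_pts[[nm]]
      }
    }
    for (h in seq_len(n_helices)) {
      phi <- 2 * pi * (h - 1) / n_helices
      origin <- c(12 * cos(phi), 12 * sin(phi), 0)
      updown <- if (h %% 2L == 1L) 1 else -1
      for (k in seq_len(residues_per_helix)) {
        th <- twist * (k - 1)
        z <- updown * rise * (k - 1) - updown * rise * residues_per_helix / 2
        helix_pt <- function(dth, dz, rad)
          origin + c(rad * cos(th + dth), rad * sin(th + dth), z + dz * updown)
        add_res(res0 + k, origin, list(
          N = helix_pt(-0.60, -0.55, 1.6),
          CA = helix_pt(0, 0, r_ca),
          C = helix_pt(0.62, 0.55, 1.7),
          CB = helix_pt(0.05, 0.05, r_ca + 1.5)))
      }
      res0 <- res0 + residues_per_helix
    }
    # fusion domain: self-avoiding random CA cluster in a sphere below the
    # bundle, minimum CA-CA separation 2.5 A
    centre <- c(0, 0, -(1.5 * residues_per_helix / 2 + 18))
    placed <- matrix(0, 0, 3)
    while (nrow(placed) < fusion_residues) {
      cand <- centre + stats::runif(3, -9, 9)
      if (!nrow(placed) ||
          min(sqrt(rowSums(sweep(placed, 2L, cand)^2))) >= 2.5)
        placed <- rbind(placed, cand)
    }
    for (k in seq_len(fusion_residues)) {
      ca <- placed[k, ]
      add_res(res0 + k, ca, list(
        N = ca + c(-0.9, 0.5, 0.4), CA = ca,
        C = ca + c(0.9, 0.6, -0.4), CB = ca + c(0.1, -1.2, 0.8)))
    }
    atoms <- do.call(rbind, atoms)
    frame <- structure_frame(atoms, do.call(rbind, xyz))

    segs <- list()
    tm_names <- paste0("TM", seq_len(n_helices))
    for (h in seq_len(n_helices)) {
      segs[[tm_names[h]]] <- data.frame(
        chain = "A", start = (h - 1L) * residues_per_helix + 1L,
        end = h * residues_per_helix)
    }
    segs[["T4L"]] <- data.frame(chain = "A",
                                start = n_helices * residues_per_helix + 1L,
                                end = n_helices * residues_per_helix +
                                  fusion_residues)
    list(frame = frame,
         segmap = segment_map(segs, tm_names = tm_names, fusion_name = "T4L"))
  })
}

#' Motion specification for synthetic ensembles
#'
#' Describes how frames are perturbed around a reference conformation:
#' per-domain rigid jitter (rotation about the domain centroid plus
#' translation), global rigid jitter of the whole complex, isotropic atom
#' noise, and optional planted conformational clusters, each a set of fixed
#' per-domain offset transforms drawn with a set occupancy.
#'
#' @param domain_rot_sd named numeric: rotation jitter sd per segment,
#'   degrees (segments absent default to 0).
#' @param domain_trans_sd named numeric: translation jitter sd per segment,
#'   Angstrom per axis.
#' @param global_rot_sd,global_trans_sd rigid jitter of the whole complex.
#' @param atom_noise_sd isotropic per-coordinate noise, Angstrom.
#' @param clusters optional list of cluster centers; each element a list
#'   with `occupancy` (fractions must sum to 1) and `offsets`, a named list
#'   mapping segment name (or `"ALL"`) to a [rigid_transform()] applied
#'   about the segment centroid.
#' @param seed integer seed driving all randomness.
#' @return object of class `motion_spec`.
#' @export
motion_spec <- function(domain_rot_sd = numeric(), domain_trans_sd = numeric(),
                        global_rot_sd = 0, global_trans_sd = 0,
                        atom_noise_sd = 0, clusters = NULL, seed = 1L) {
  if (any(c(unlist(domain_rot_sd), unlist(domain_trans_sd), global_rot_sd,
            global_trans_sd, atom_noise_sd) < 0))
    stop_gpcrstab("all jitter sd values must be >= 0", "invalid_spec_error")
  if (!is.null(clusters)) {
    occ <- vapply(clusters, `[[`, numeric(1), "occupancy")
    if (abs(sum(occ) - 1) > 1e-9)
      stop_gpcrstab(sprintf("cluster occupancies sum to %.6f, not 1", sum(occ)),
                    "invalid_spec_error")
  }
  structure(list(domain_rot_sd = domain_rot_sd,
                 domain_trans_sd = domain_trans_sd,
                 global_rot_sd = global_rot_sd,
                 global_trans_sd = global_trans_sd,
                 atom_noise_sd = atom_noise_sd,
                 clusters = clusters, seed = as.integer(seed)),
            class = "motion_spec")
}

apply_domain_offset <- function(xyz, idx, transform) {
  sub <- xyz[idx, , drop = FALSE]
  ctr <- colMeans(sub)
  moved <- sweep(sweep(sub, 2L, ctr) %*% t(transform$rotation), 2L,
                 -(ctr + transform$translation))
  xyz[idx, ] <- moved
  xyz
}

#' Draw a synthetic structure ensemble around a reference conformation
#'
#' Each frame is generated by (1) sampling a planted cluster by occupancy
#' (when clusters are present) and applying its per-domain offset
#' transforms, (2) adding per-domain rigid jitter, (3) adding global rigid
#' jitter, and (4) adding isotropic atom noise.  Frames are emitted in the
#' (random) order the cluster labels were drawn.  The planted ground truth
#' is attached as attribute `"truth"`: a list with the per-frame cluster
#' id and the applied global transform of every frame.
#'
#' @param reference a [structure_frame()] (e.g. from [make_bundle()]).
#' @param segmap the matching [segment_map()].
#' @param spec a [motion_spec()].
#' @param n_frames number of frames to draw.
#' @return a [structure_ensemble()] with attribute `"truth"`.
#' @export
make_ensemble <- function(reference, segmap, spec, n_frames) {
  stopifnot(inherits(spec, "motion_spec"))
  dom_idx <- lapply(names(segmap$segments), function(nm)
    select_atom_indices(reference$atoms, segmap, nm, "heavy"))
  names(dom_idx) <- names(segmap$segments)
  all_idx <- sort(unique(unlist(dom_idx)))

  with_seed(spec$seed, {
    cluster_of <- if (is.null(spec$clusters)) rep(0L, n_frames) else
      sample(seq_along(spec$clusters), n_frames, replace = TRUE,
             prob = vapply(spec$clusters, `[[`, numeric(1), "occupancy"))
    frames <- vector("list", n_frames)
    globals <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      xyz <- reference$xyz
      if (cluster_of[f] > 0L) {
        offs <- spec$clusters[[cluster_of[f]]]$offsets
        for (nm in names(offs)) {
          idx <- if (identical(nm, "ALL")) all_idx else dom_idx[[nm]]
          if (is.null(idx))
            stop_gpcrstab(sprintf("cluster offset names unknown segment '%s'", nm),
                          "invalid_spec_error")
          xyz <- apply_domain_offset(xyz, idx, offs[[nm]])
        }
      }
      doms <- union(names(spec$domain_rot_sd), names(spec$domain_trans_sd))
      for (nm in doms) {
        rs <- if (nm %in% names(spec$domain_rot_sd))
          spec$domain_rot_sd[[nm]] else 0
        ts <- if (nm %in% names(spec$domain_trans_sd))
          spec$domain_trans_sd[[nm]] else 0
        if (rs > 0 || ts > 0)
          xyz[dom_idx[[nm]], ] <- jitter_rigid(xyz[dom_idx[[nm]], , drop = FALSE],
                                               rs, ts)
      }
      if (spec$global_rot_sd > 0 || spec$global_trans_sd > 0) {
        Rg <- random_rotation(spec$global_rot_sd)
        tg <- if (spec$global_trans_sd > 0)
          stats::rnorm(3, 0, spec$global_trans_sd) else c(0, 0, 0)
        ctr <- colMeans(xyz)
        xyz <- sweep(sweep(xyz, 2L, ctr) %*% t(Rg), 2L, -(ctr + tg))
        globals[[f]] <- rigid_transform(Rg, as.numeric(ctr + tg - Rg %*% ctr))
      } else {
        globals[[f]] <- rigid_transform()
      }
      if (spec$atom_noise_sd > 0)
        xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, spec$atom_noise_sd),
                            nrow(xyz), 3L)
      frames[[f]] <- xyz
    }
    ens <- structure_ensemble(reference$atoms, frames)
    attr(ens, "truth") <- list(cluster = cluster_of, global = globals,
                               spec = spec)
    ens
  })
}

#' Generate a synthetic melting curve
#'
#' Evaluates the Hill denatured fraction at each temperature and maps it to
#' an ellipticity scale `theta = theta_min + delta_fd * (theta_max -
#' theta_min)` (defaults -20 to -2, a typical 222 nm millidegree range for
#' a helical protein losing signal on unfolding), then adds Gaussian noise
#' on theta.
#'
#' @param tm planted midpoint, degC.
#' @param steepness Hill exponent (> 0).
#' @param temps sampling temperatures (default 25 to 90 degC in 5 degC
#'   steps).
#' @param noise_sd Gaussian noise sd on the ellipticity (same units).
#' @param seed integer seed (only consulted when `noise_sd > 0`).
#' @param theta_min,theta_max ellipticity extremes of the clean curve.
#' @param label construct name.
#' @return a [melt_curve()].
#' @export
make_melting_curve <- function(tm, steepness, temps = seq(25, 90, by = 5),
                               noise_sd = 0, seed = 1L,
                               theta_min = -20, theta_max = -2, label = "") {
  if (steepness <= 0)
    stop_gpcrstab("steepness must be > 0", "invalid_parameter_error")
  fd <- hill_fd(temps, tm, steepness)
  theta <- theta_min + fd * (theta_max - theta_min)
  if (noise_sd > 0)
    theta <- with_seed(seed,
                       theta + stats::rnorm(length(theta), 0, noise_sd))
  melt_curve(temps, theta, label = label)
}
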