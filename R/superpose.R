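#' Rigid-body transforms
#'
#' A rigid transform maps a point `x` to `R x + t` with `R` a proper rotation
#' (`det R = +1`) and `t` a translation in Angstrom.
#'
#' @param rotation 3x3 proper orthogonal matrix.
#' @param translation length-3 numeric vector (Angstrom).
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)))
    stop_gpcrstab("rotation must be 3x3", "invalid_transform_error")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop_gpcrstab("rotation must be proper orthogonal (det = +1)",
                  "invalid_transform_error")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#' @param coords `n x 3` coordinate matrix.
#' @param transform a [rigid_transform()].
#' @return transformed `n x 3` matrix.
#' @export
apply_transform <- function(coords, transform) {
  coords <- as.matrix(coords)
  sweep(coords %*% t(transform$rotation), 2L, -transform$translation)
}

#' Invert a rigid transform
#' @param transform a [rigid_transform()].
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

#' Kabsch superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' matched coordinate sets (reflections excluded), via SVD of the covariance
#' matrix.  The returned transform maps `mobile` onto `reference`.
#'
#' @param mobile,reference matched `n x 3` coordinate matrices (`n >= 3`,
#'   not collinear).
#' @return list with `transform` (a [rigid_transform()]) and `rmsd`
#'   (Angstrom), the global minimum over all rigid motions.
#' @export
kabsch <- function(mobile, reference) {
  P <- as.matrix(mobile); Q <- as.matrix(reference)
  if (nrow(P) != nrow(Q) || ncol(P) != 3L || ncol(Q) != 3L)
    stop_gpcrstab("mobile and reference selections differ in size",
                  "selection_mismatch_error")
  n <- nrow(P)
  if (n < 3L)
    stop_gpcrstab("superposition needs at least 3 atoms",
                  "degenerate_geometry_error")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp); Qc <- sweep(Q, 2L, cq)
  # collinearity check via the 3x3 moment matrix (second singular value of Pc)
  ev <- eigen(crossprod(Pc), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  if (sqrt(ev[2L]) < 1e-9 * max(sqrt(ev[1L]), 1))
    stop_gpcrstab("degenerate (collinear) coordinates", "degenerate_geometry_error")
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- cq - as.numeric(R %*% cp)
  rot <- Pc %*% t(R)
  rmsd <- sqrt(sum((rot - Qc)^2) / n)
  list(transform = rigid_transform(R, tr), rmsd = rmsd)
}

#' Raw (no-refit) RMSD between matched coordinate sets
#' @param a,b matched `n x 3` coordinate matrices.
#' @return RMSD in Angstrom, without superposition.
#' @export
raw_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b))
    stop_gpcrstab("coordinate sets differ in size", "selection_mismatch_error")
  sqrt(sum((a - b)^2) / nrow(a))
}

#' Iterative ensemble-average reference structure
#'
#' Aligns every frame onto the running mean by Kabsch superposition on the
#' heavy atoms of `align_domain`, recomputes the coordinate-wise mean, and
#' repeats until the mean moves by less than `tol` (RMSD) or `max_iter`
#' passes.  The average of a structure ensemble is the reference against
#' which per-frame RMSD observables are measured.
#'
#' @param ensemble a [structure_ensemble()].
#' @param segmap a [segment_map()].
#' @param align_domain domain used for the alignment (default `"ALL"`).
#' @param tol convergence threshold on the mean's displacement (Angstrom).
#' @param max_iter maximum number of passes.
#' @return a [structure_frame()] holding the mean coordinates, with
#'   attributes `converged` (logical) and `iterations`.  Non-convergence
#'   raises a warning; the last mean is still returned.
#' @export
ensemble_average <- function(ensemble, segmap, align_domain = "ALL",
                             tol = 1e-6, max_iter = 100L) {
  idx <- select_atom_indices(ensemble$atoms, segmap, align_domain, "heavy")
  mean_xyz <- ensemble$frames[[1L]]
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    ref_sel <- mean_xyz[idx, , drop = FALSE]
    aligned <- lapply(ensemble$frames, function(f) {
      fit <- kabsch(f[idx, , drop = FALSE], ref_sel)
      apply_transform(f, fit$transform)
    })
    new_mean <- Reduce(`+`, aligned) / length(aligned)
    shift <- raw_rmsd(new_mean, mean_xyz)
    mean_xyz <- new_mean
    if (shift < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warn_gpcrstab(sprintf("ensemble average did not converge in %d iterations",
                          max_iter), "convergence_warning")
  out <- structure_frame(ensemble$atoms, mean_xyz)
  attr(out, "converged") <- converged
  attr(out, "iterations") <- it
  out
}

#' Domain-decomposed RMSD observables of one frame
#'
#' Computes the four stability observables of a receptor-fusion complex
#' against a reference structure (usually the ensemble average):
#' * `rmsd_all` - Kabsch RMSD over all heavy atoms of the complex;
#' * `rmsd_tm` - Kabsch RMSD over the heavy atoms of the pooled
#'   transmembrane segments;
#' * `rmsd_t4l` - Kabsch RMSD over the fusion-domain heavy atoms;
#' * `rmsd_t4l_prime` - raw RMSD of the fusion domain after applying the
#'   transform fitted on the TM domain (no re-fit), which quantifies the
#'   motion of the fusion domain *relative to* the receptor.
#'
#' Kabsch optimality guarantees `rmsd_t4l_prime >= rmsd_t4l`.
#'
#' @param frame,reference [structure_frame()]s sharing one atom table.
#' @param segmap a [segment_map()].
#' @return one-row data.frame with columns `rmsd_all`, `rmsd_tm`,
#'   `rmsd_t4l`, `rmsd_t4l_prime` (Angstrom).
#' @export
rmsd_decomposition <- function(frame, reference, segmap) {
  i_all <- select_atom_indices(frame$atoms, segmap, "ALL", "heavy")
  i_tm <- select_atom_indices(frame$atoms, segmap, "TM", "heavy")
  i_t4l <- select_atom_indices(frame$atoms, segmap, segmap$fusion_name, "heavy")
  f <- frame$xyz; r <- reference$xyz
  fit_tm <- kabsch(f[i_tm, , drop = FALSE], r[i_tm, , drop = FALSE])
  data.frame(
    rmsd_all = kabsch(f[i_all, , drop = FALSE], r[i_all, , drop = FALSE])$rmsd,
    rmsd_tm = fit_tm$rmsd,
    rmsd_t4l = kabsch(f[i_t4l, , drop = FALSE], r[i_t4l, , drop = FALSE])$rmsd,
    rmsd_t4l_prime = raw_rmsd(apply_transform(f[i_t4l, , drop = FALSE],
                                              fit_tm$transform),
                              r[i_t4l, , drop = FALSE]))
}

#' Per-frame RMSD report of a whole ensemble
#'
#' @param ensemble a [structure_ensemble()].
#' @param segmap a [segment_map()].
#' @param reference reference [structure_frame()]; defaults to the iterative
#'   [ensemble_average()] of the ensemble.
#' @return data.frame with columns `frame_index`, `rmsd_all`, `rmsd_tm`,
#'   `rmsd_t4l`, `rmsd_t4l_prime`.
#' @export
rmsd_report <- function(ensemble, segmap, reference = NULL) {
  if (is.null(reference))
    reference <- ensemble_average(ensemble, segmap, "ALL")
  rows <- lapply(seq_len(n_frames(ensemble)), function(i) {
    cbind(frame_index = i,
          rmsd_decomposition(get_frame(ensemble, i), reference, segmap))
  })
  do.call(rbind, rows)
}

#' 7x7 per-helix RMSD matrix
#'
#' Decomposes the structural difference between two conformations of a
#' seven-helix bundle into 49 numbers.  Entry `(i, j)` is the raw RMSD of
#' helix `j`'s backbone after applying the Kabsch transform fitted on helix
#' `i`'s backbone (rows = alignment helix, columns = evaluated helix).  The
#' diagonal `(i, i)` is the Kabsch-minimal RMSD of helix `i` itself and
#' reports deformation *within* that helix; off-diagonal entries report how
#' the helices moved relative to each other, i.e. the packing of the bundle.
#' Alignments use backbone atoms (N, CA, C).
#'
#' @param reference,target [structure_frame()]s with matched atoms for all
#'   TM segments of `segmap`.
#' @param segmap a [segment_map()] whose `tm_names` define the helices.
#' @return `k x k` numeric matrix (k = number of TM segments, normally 7)
#'   with the TM names as dimnames.
#' @export
seven_by_seven <- function(reference, target, segmap) {
  tms <- segmap$tm_names
  sel_r <- lapply(tms, function(nm)
    select_atoms(reference, segmap, nm, "backbone"))
  sel_t <- lapply(tms, function(nm) select_atoms(target, segmap, nm, "backbone"))
  k <- length(tms)
  M <- matrix(0, k, k, dimnames = list(align = tms, evaluate = tms))
  for (i in seq_len(k)) {
    fit <- kabsch(sel_t[[i]], sel_r[[i]])
    for (j in seq_len(k)) {
      M[i, j] <- if (i == j) fit$rmsd else
        raw_rmsd(apply_transform(sel_t[[j]], fit$transform), sel_r[[j]])
    }
  }
  M
}

#' Pooled TM-backbone RMSD between two structures
#'
#' Convenience comparison for whole TM bundles, e.g. between two receptor
#' crystal structures: one Kabsch superposition on the union of the
#' backbone atoms of all TM segments.  The two structures may be different
#' proteins; their segment maps must then select the same number of matched
#' backbone atoms per helix (e.g. equal-length windows around the
#' Ballesteros-Weinstein x.50 anchors).
#'
#' @param frame_a,frame_b [structure_frame()]s.
#' @param segmap_a,segmap_b segment maps for the two structures
#'   (`segmap_b` defaults to `segmap_a`).
#' @return Kabsch RMSD (Angstrom) of the pooled TM backbone.
#' @export
compare_tm_bundles <- function(frame_a, frame_b, segmap_a, segmap_b = segmap_a) {
  a <- select_atoms(frame_a, segmap_a, "TM", "backbone")
  b <- select_atoms(frame_b, segmap_b, "TM", "backbone")
  kabsch(a, b)$rmsd
}
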