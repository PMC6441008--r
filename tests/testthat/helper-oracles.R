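# Independent oracles and small fixture builders shared across the suite.
# Everything here is deliberately written on a different code path from the
# package (quaternion instead of SVD superposition, explicit all-pairs
# clustering) so agreement is evidence, not tautology.

# ---- quaternion (Horn) superposition --------------------------------------
# Proper-rotation least-squares fit via the largest eigenvector of the 4x4
# quaternion matrix; reflections are unrepresentable by construction.
horn_superpose <- function(mobile, reference) {
  P <- as.matrix(mobile); Q <- as.matrix(reference)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  S <- crossprod(Pc, Qc)   # S[i,j] = sum_k p_ki q_kj
  N <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2], S[3,1]-S[1,3], S[1,2]-S[2,1],
    S[2,3]-S[3,2], S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1], S[3,1]+S[1,3],
    S[3,1]-S[1,3], S[1,2]+S[2,1], -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1], S[3,1]+S[1,3], S[2,3]+S[3,2], -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2*(y^2 + z^2), 2*(x*y - w*z),     2*(x*z + w*y),
    2*(x*y + w*z),     1 - 2*(x^2 + z^2), 2*(y*z - w*x),
    2*(x*z - w*y),     2*(y*z + w*x),     1 - 2*(x^2 + y^2)),
    3, 3, byrow = TRUE)
  moved <- Pc %*% t(R)
  list(rotation = R, translation = cq - as.numeric(R %*% cp),
       rmsd = sqrt(sum((moved - Qc)^2) / nrow(P)))
}

horn_apply <- function(coords, fit) {
  sweep(as.matrix(coords) %*% t(fit$rotation), 2, -fit$translation)
}

# per-helix alignment matrix recomputed entirely through the Horn path
seven_by_seven_oracle <- function(reference, target, segmap) {
  tms <- segmap$tm_names
  k <- length(tms)
  M <- matrix(0, k, k)
  for (i in seq_len(k)) {
    ri <- select_atoms(reference, segmap, tms[i], "backbone")
    ti <- select_atoms(target, segmap, tms[i], "backbone")
    fit <- horn_superpose(ti, ri)
    for (j in seq_len(k)) {
      rj <- select_atoms(reference, segmap, tms[j], "backbone")
      tj <- horn_apply(select_atoms(target, segmap, tms[j], "backbone"), fit)
      M[i, j] <- sqrt(sum((tj - rj)^2) / nrow(rj))
    }
  }
  M
}

# ---- brute-force Jarvis-Patrick -------------------------------------------
# Explicit neighbor sets, explicit n x n link matrix, component search by
# repeated expansion of the reachability matrix.
bf_jarvis_patrick <- function(d, M = 10, cutoff = 1.5, P = 3,
                              neighbor_rule = "intersect") {
  n <- nrow(d)
  nbrs <- vector("list", n)
  for (x in seq_len(n)) {
    others <- setdiff(seq_len(n), x)
    by_rank <- others[order(d[x, others], others)]
    nearest <- by_rank[seq_len(min(M, n - 1))]
    close <- others[d[x, others] <= cutoff]
    nbrs[[x]] <- if (neighbor_rule == "intersect")
      intersect(nearest, close) else union(nearest, close)
  }
  link <- diag(n) > 0
  for (x in seq_len(n)) for (y in seq_len(n)) {
    if (x != y && length(intersect(nbrs[[x]], nbrs[[y]])) >= P)
      link[x, y] <- TRUE
  }
  reach <- link
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- integer(n); cid <- 0
  for (x in seq_len(n)) {
    if (comp[x] == 0) { cid <- cid + 1; comp[which(reach[x, ])] <- cid }
  }
  comp
}

# do two partitions (integer label vectors) describe the same clustering?
same_partition <- function(a, b) {
  identical(match(a, unique(a)), match(b, unique(b)))
}

# ---- random rigid motions --------------------------------------------------
random_rotation_matrix <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2 + z^2), 2*(x*y - w*z), 2*(x*z + w*y),
           2*(x*y + w*z), 1 - 2*(x^2 + z^2), 2*(y*z - w*x),
           2*(x*z - w*y), 2*(y*z + w*x), 1 - 2*(x^2 + y^2)),
         3, 3, byrow = TRUE)
}

rigid_move <- function(coords, R = random_rotation_matrix(),
                       tr = stats::rnorm(3, 0, 5)) {
  sweep(as.matrix(coords) %*% t(R), 2, -tr)
}

# minimum rmsd over nrot random proper rotations with centroids matched;
# an upper-bound oracle for the Kabsch global optimum.  Uses the identity
# sum_i |R p_i - q_i|^2 = ss(P) + ss(Q) - 2 tr(R H), H = sum_i p_i q_i^T,
# so one rotation costs a 9-element dot product.
random_rotation_stack <- function(nrot) {
  t(vapply(seq_len(nrot), function(i) as.numeric(random_rotation_matrix()),
           numeric(9)))
}

best_random_rotation_rmsd <- function(mobile, reference, nrot = 10000,
                                      stack = NULL) {
  P <- sweep(as.matrix(mobile), 2, colMeans(mobile))
  Q <- sweep(as.matrix(reference), 2, colMeans(reference))
  if (is.null(stack)) stack <- random_rotation_stack(nrot)
  H <- crossprod(P, Q)                      # sum_i p_i q_i^T
  scores <- as.numeric(stack %*% as.numeric(t(H)))  # tr(R H) per rotation
  sq <- (sum(P^2) + sum(Q^2) - 2 * scores) / nrow(P)
  sqrt(max(0, min(sq)))
}

# ---- tiny fixtures ---------------------------------------------------------
# frame with explicit atoms: spec is a data.frame with atom_name, element,
# resseq, resname, x, y, z (chain A, no icode)
tiny_frame <- function(spec) {
  structure_frame(
    data.frame(atom_name = spec$atom_name, element = spec$element,
               chain = "A", resseq = spec$resseq, icode = "",
               resname = spec$resname),
    cbind(spec$x, spec$y, spec$z))
}

# small bundle + segment map reused by the heavier geometry tests
small_bundle <- function(seed = 1) {
  make_bundle(n_helices = 7, residues_per_helix = 6, fusion_residues = 12,
              seed = seed)
}
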