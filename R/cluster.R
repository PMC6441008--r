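#' Pairwise RMSD matrix of an ensemble
#'
#' Kabsch RMSD between every pair of frames on the heavy atoms of one
#' domain (for conformational clustering this is normally the pooled
#' transmembrane domain, `"TM"`).  Only the upper triangle is computed, so
#' the result is exactly symmetric with a zero diagonal.
#'
#' @param ensemble a [structure_ensemble()] with at least 2 frames.
#' @param segmap a [segment_map()].
#' @param domain segment name, `"TM"` or `"ALL"`.
#' @return symmetric `n x n` numeric matrix (Angstrom).
#' @export
pairwise_rmsd <- function(ensemble, segmap, domain = "TM") {
  n <- n_frames(ensemble)
  if (n < 2L)
    stop_gpcrstab("pairwise RMSD needs at least 2 frames", "empty_input_error")
  idx <- select_atom_indices(ensemble$atoms, segmap, domain, "heavy")
  sel <- lapply(ensemble$frames, function(f) f[idx, , drop = FALSE])
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d[i, j] <- d[j, i] <- kabsch(sel[[i]], sel[[j]])$rmsd
    }
  }
  d
}

# Neighbor lists for Jarvis-Patrick: the up-to-M nearest frames to x,
# restricted ("intersect", default) or united ("union") with the set of all
# frames within `cutoff`.  Self never counts as its own neighbor; ties at
# rank M break toward the lower frame index.
jp_neighbor_lists <- function(d, M, cutoff, neighbor_rule) {
  n <- nrow(d)
  lapply(seq_len(n), function(x) {
    others <- setdiff(seq_len(n), x)
    ord <- others[order(d[x, others], others)]
    nearest <- ord[seq_len(min(M, length(ord)))]
    within <- others[d[x, others] <= cutoff]
    if (neighbor_rule == "intersect") intersect(nearest, within)
    else union(nearest, within)
  })
}

#' Jarvis-Patrick clustering of a distance matrix
#'
#' Shared-nearest-neighbor clustering as used to group trajectory snapshots:
#' the neighbor list of a frame holds its `M` most similar frames within an
#' RMSD `cutoff`; two frames are linked when their neighbor lists share at
#' least `P` frames, and clusters are the connected components of the link
#' graph (`variant = "components"`).  `variant = "accretion"` instead grows
#' clusters frame by frame, joining a frame to the first existing cluster
#' containing a member with `>= P` shared neighbors.  The published
#' criterion ("M most similar structures or all structures within the
#' cutoff") does not fix whether the two neighbor conditions intersect or
#' unite; `neighbor_rule` exposes both, with the intersection as the
#' default (a pure union leaves the cutoff inert for dense ensembles).
#'
#' @param d symmetric distance matrix (Angstrom), zero diagonal.
#' @param M neighbor-list size (default 10).
#' @param cutoff RMSD cutoff in Angstrom (default 1.5).
#' @param P shared-neighbor threshold (default 3).
#' @param neighbor_rule `"intersect"` (default) or `"union"`.
#' @param variant `"components"` (default) or `"accretion"`.
#' @return an object of class `jp_clustering`: list with `assignment`
#'   (integer vector, cluster id per frame), `sizes` (named integer vector,
#'   descending; ties by lowest member index), and `params`.  Cluster ids
#'   are assigned in decreasing size order.
#' @export
jarvis_patrick <- function(d, M = 10L, cutoff = 1.5, P = 3L,
                           neighbor_rule = c("intersect", "union"),
                           variant = c("components", "accretion")) {
  neighbor_rule <- match.arg(neighbor_rule)
  variant <- match.arg(variant)
  d <- as.matrix(d)
  n <- nrow(d)
  if (n != ncol(d) || max(abs(d - t(d))) > 1e-9 || any(diag(d) != 0) ||
      any(d < 0))
    stop_gpcrstab("distance matrix must be symmetric, non-negative, zero-diagonal",
                  "invalid_matrix_error")
  if (M < 1L || P < 1L)
    stop_gpcrstab("M and P must be >= 1", "invalid_parameter_error")

  if (n == 1L) {
    return(new_jp_clustering(1L, M, cutoff, P, neighbor_rule, variant))
  }
  nb <- jp_neighbor_lists(d, M, cutoff, neighbor_rule)
  shared <- function(x, y) length(intersect(nb[[x]], nb[[y]])) >= P

  raw <- integer(n)
  if (variant == "components") {
    # connected components of the >=P shared-neighbor relation
    comp <- 0L
    for (s in seq_len(n)) {
      if (raw[s] > 0L) next
      comp <- comp + 1L
      queue <- s
      raw[s] <- comp
      while (length(queue)) {
        x <- queue[[1L]]; queue <- queue[-1L]
        for (y in which(raw == 0L)) {
          if (shared(x, y)) { raw[y] <- comp; queue <- c(queue, y) }
        }
      }
    }
  } else {
    clusters <- list()
    for (x in seq_len(n)) {
      joined <- FALSE
      for (ci in seq_along(clusters)) {
        if (any(vapply(clusters[[ci]], shared, TRUE, x = x))) {
          clusters[[ci]] <- c(clusters[[ci]], x)
          raw[x] <- ci
          joined <- TRUE
          break
        }
      }
      if (!joined) {
        clusters[[length(clusters) + 1L]] <- x
        raw[x] <- length(clusters)
      }
    }
  }
  new_jp_clustering(raw, M, cutoff, P, neighbor_rule, variant)
}

# Relabel raw cluster ids in decreasing size order (ties by lowest member
# index) and build the size table.
new_jp_clustering <- function(raw, M, cutoff, P, neighbor_rule, variant) {
  sz <- tapply(seq_along(raw), raw, length)
  first <- tapply(seq_along(raw), raw, min)
  ord <- order(-as.integer(sz), as.integer(first))
  relabel <- integer(length(sz))
  relabel[as.integer(names(sz))[ord]] <- seq_along(ord)
  assignment <- relabel[raw]
  sizes <- as.integer(table(assignment))
  names(sizes) <- seq_along(sizes)
  structure(list(assignment = assignment, sizes = sizes,
                 params = list(M = M, cutoff = cutoff, P = P,
                               neighbor_rule = neighbor_rule,
                               variant = variant)),
            class = "jp_clustering")
}

#' @export
print.jp_clustering <- function(x, ...) {
  cat(sprintf("<jp_clustering> %d frames in %d clusters (M=%d, cutoff=%.2f, P=%d)\n",
              length(x$assignment), length(x$sizes), x$params$M,
              x$params$cutoff, x$params$P))
  invisible(x)
}

#' Cumulative occupancy of the k largest clusters
#'
#' Entry `m` is the fraction of all frames held by the `m` largest clusters.
#' When fewer than `k` clusters exist the vector is padded with its final
#' value.  Large leading occupancies indicate an ensemble concentrated in a
#' few stable conformations.
#'
#' @param clustering a [jarvis_patrick()] result (or any object with a
#'   `sizes` integer vector).
#' @param k number of leading clusters (default 5).
#' @return numeric vector of length `k`, non-decreasing, ending at <= 1.
#' @export
cumulative_occupancy <- function(clustering, k = 5L) {
  if (k < 1L)
    stop_gpcrstab("k must be >= 1", "invalid_parameter_error")
  sizes <- sort(as.numeric(clustering$sizes), decreasing = TRUE)
  n <- sum(sizes)
  cum <- cumsum(sizes) / n
  if (length(cum) >= k) cum[seq_len(k)]
  else c(cum, rep(cum[length(cum)], k - length(cum)))
}
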