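# Per-construct generator presets emulating the study conditions of the
# six CXCR1-T4L constructs (wild type and five point mutants).  The
# fluctuation presets realize TM-RMSD medians inside the 2-3 A band with
# the stability ordering L126W < G294A < WT ~ A240D < L81A ~ K154A; the
# cluster presets realize the reported top-5 cumulative occupancies
# (~0.8 for L126W, < 0.4 for L81A and A240D).  Scales were fixed once by
# calibrating jitter sigma against the resulting median and are not tuned
# per run.

#' Construct names of the emulated study
#' @return character vector of the six construct labels.
#' @export
preset_constructs <- function() {
  c("L126W", "G294A", "WT", "A240D", "L81A", "K154A")
}

# target TM-RMSD medians (A); ties WT~A240D and L81A~K154A are 0.05 apart
# (well under the 0.15 tie tolerance), distinct groups >= 0.25 apart
preset_median_targets <- c(L126W = 2.05, G294A = 2.35, WT = 2.60,
                           A240D = 2.65, L81A = 2.90, K154A = 2.95)

# calibrated map from target median TM RMSD to per-helix translation
# jitter sd (A per axis); rotation jitter and atom noise are held fixed
# (2 deg per helix, 0.25 A atom noise, 12 deg / 3 A fusion-domain jitter
# baseline).  See the methods vignette for the calibration.
preset_trans_sd <- function(target_median) 0.722 * target_median - 0.128

#' Fluctuation motion specs emulating the six constructs
#'
#' Continuous per-helix rigid jitter plus atom noise, scaled per construct
#' so the median TM RMSD against the ensemble average reproduces the
#' study's stability ordering; the three constructs with pronounced
#' fusion-domain motion (L81A, K154A, A240D) get a larger T4L rigid jitter.
#'
#' @param segmap segment map of the reference bundle (from [make_bundle()]).
#' @param seed integer seed; each construct spec derives its own sub-seed.
#' @return named list of [motion_spec()]s, one per construct.
#' @export
preset_fluctuation_specs <- function(segmap, seed = 1L) {
  tms <- segmap$tm_names
  fus <- segmap$fusion_name
  mobile_t4l <- c("L81A", "K154A", "A240D")
  specs <- list()
  for (i in seq_along(preset_median_targets)) {
    nm <- names(preset_median_targets)[i]
    tsd <- preset_trans_sd(preset_median_targets[[i]])
    dom_t <- stats::setNames(rep(tsd, length(tms)), tms)
    dom_r <- stats::setNames(rep(2, length(tms)), tms)
    dom_t[fus] <- if (nm %in% mobile_t4l) 6 else 3
    dom_r[fus] <- 12
    specs[[nm]] <- motion_spec(domain_rot_sd = as.list(dom_r),
                               domain_trans_sd = as.list(dom_t),
                               global_rot_sd = 5, global_trans_sd = 2,
                               atom_noise_sd = 0.25,
                               seed = seed * 1000L + i)
  }
  specs
}

# top-5 cumulative occupancy targets per construct
preset_occupancy_targets <- c(L126W = 0.80, G294A = 0.65, WT = 0.55,
                              K154A = 0.45, A240D = 0.38, L81A = 0.38)

#' Clustered motion specs emulating the conformational-substate structure
#'
#' Five major planted clusters holding the construct's target top-5
#' occupancy, the remainder spread over twelve minor centers.  Cluster
#' centers are distinct per-helix rigid displacements (well separated
#' relative to the 1.5 A neighbor cutoff); within-cluster spread is
#' isotropic atom noise.
#'
#' @inheritParams preset_fluctuation_specs
#' @param occupancy_top5 named numeric of top-5 cumulative occupancies;
#'   defaults to the study-condition presets.
#' @return named list of [motion_spec()]s.
#' @export
preset_cluster_specs <- function(segmap, seed = 1L,
                                 occupancy_top5 = preset_occupancy_targets) {
  specs <- list()
  for (i in seq_along(occupancy_top5)) {
    nm <- names(occupancy_top5)[i]
    s5 <- occupancy_top5[[i]]
    occ <- c(s5 * c(0.35, 0.25, 0.18, 0.12, 0.10),
             rep((1 - s5) / 12, 12))
    specs[[nm]] <- motion_spec(
      atom_noise_sd = 0.15,
      clusters = planted_clusters(segmap, occ, seed = seed * 1000L + 500L + i),
      seed = seed * 1000L + i)
  }
  specs
}

#' Planted conformational clusters for [motion_spec()]
#'
#' Each cluster center is a fixed set of per-helix rigid translations drawn
#' once from `Normal(0, 4 A)` per axis (a deterministic function of
#' `seed`), which keeps center-to-center TM RMSD far above the 1.5 A
#' Jarvis-Patrick cutoff.
#'
#' @param segmap segment map naming the helices.
#' @param occupancies numeric vector summing to 1.
#' @param seed integer seed for the center draws.
#' @return list of cluster definitions for [motion_spec()].
#' @export
planted_clusters <- function(segmap, occupancies, seed = 1L) {
  with_seed(seed, {
    lapply(occupancies, function(p) {
      offsets <- lapply(segmap$tm_names, function(nm)
        rigid_transform(diag(3), stats::rnorm(3, 0, 4)))
      names(offsets) <- segmap$tm_names
      list(occupancy = p, offsets = offsets)
    })
  })
}

#' Published melting temperatures emulated by the synthetic curves
#'
#' The five experimentally characterized constructs and their midpoints
#' (degC): WT 53.78, L81A 46.56, L126W 62.15, K154A 57.22, G294A 49.36
#' (A240D expressed too poorly to measure).
#'
#' @return named numeric vector of Tm values, degC.
#' @export
preset_tm_values <- function() {
  c(WT = 53.78, L81A = 46.56, L126W = 62.15, K154A = 57.22, G294A = 49.36)
}
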