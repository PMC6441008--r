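#' Run configuration for the stability pipeline
#'
#' @param constructs named list: construct name -> [structure_ensemble()]
#'   or path to a multi-model PDB file.
#' @param segmap a [segment_map()] or path to a segment-map config file.
#' @param out_dir output directory (created if needed).
#' @param contact_pairs optional list of `list(a = residue_id, b =
#'   residue_id)` pairs to track.
#' @param melt_curves optional named list of [melt_curve()]s or CSV paths;
#'   must include `melt_reference` when given.
#' @param melt_reference reference construct for the Tm table (default
#'   `"WT"`).
#' @param cluster_m,cluster_cutoff,cluster_p Jarvis-Patrick parameters.
#' @param occupancy_k leading clusters reported (default 5).
#' @param tie_tol ranking tie tolerance, Angstrom.
#' @param seed integer seed recorded in the run log (the analyses are
#'   deterministic; the seed matters when configs embed generators).
#' @return object of class `run_config`.
#' @export
run_config <- function(constructs, segmap, out_dir,
                       contact_pairs = NULL, melt_curves = NULL,
                       melt_reference = "WT",
                       cluster_m = 10L, cluster_cutoff = 1.5, cluster_p = 3L,
                       occupancy_k = 5L, tie_tol = 0.15, seed = 1L) {
  if (!length(constructs) || is.null(names(constructs)))
    stop_gpcrstab("constructs must be a non-empty named list", "config_error")
  structure(list(constructs = constructs, segmap = segmap, out_dir = out_dir,
                 contact_pairs = contact_pairs, melt_curves = melt_curves,
                 melt_reference = melt_reference,
                 cluster_m = as.integer(cluster_m),
                 cluster_cutoff = cluster_cutoff,
                 cluster_p = as.integer(cluster_p),
                 occupancy_k = as.integer(occupancy_k),
                 tie_tol = tie_tol, seed = as.integer(seed)),
            class = "run_config")
}

write_csv_file <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  path
}

#' Full per-construct stability workflow
#'
#' For every construct: iterative ensemble average, per-frame RMSD report
#' and box statistics; pairwise TM RMSD matrix, Jarvis-Patrick clustering
#' and cumulative top-k occupancy; configured side-chain contact distances.
#' Then the cross-construct stability ranking on the median TM RMSD, and
#' (when melting curves are supplied) the fitted Tm table with shifts
#' relative to the reference construct.  Every artifact is written as a
#' headered CSV under `cfg$out_dir`, together with a `run.log` (versions,
#' seed, parameters, per-stage wall time) and a `MANIFEST` listing each
#' artifact with its MD5 content hash.  A stage failure aborts with an
#' error naming the stage; artifacts already written stay on disk and the
#' MANIFEST is marked incomplete.
#'
#' @param cfg a [run_config()].
#' @return (invisibly) list with `rmsd` (per-construct reports), `box`
#'   (per-construct [box_stats()] on TM RMSD), `clustering`, `occupancy`,
#'   `contacts`, `ranking`, `melt` and `files`.
#' @export
run_stability_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  log_lines <- c(sprintf("gpcrstab %s", as.character(utils::packageVersion("gpcrstab"))),
                 sprintf("seed %d", cfg$seed),
                 sprintf("params M=%d cutoff=%g P=%d k=%d tie_tol=%g",
                         cfg$cluster_m, cfg$cluster_cutoff, cfg$cluster_p,
                         cfg$occupancy_k, cfg$tie_tol))
  finish <- function(ok) {
    manifest <- c(if (!ok) "# INCOMPLETE RUN",
                  sprintf("%s  %s", unname(tools::md5sum(files)),
                          basename(files)))
    writeLines(manifest, file.path(cfg$out_dir, "MANIFEST"))
    writeLines(log_lines, file.path(cfg$out_dir, "run.log"))
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      finish(ok = FALSE)
      stop_gpcrstab(sprintf("pipeline stage '%s' failed: %s", name,
                            conditionMessage(e)), "pipeline_stage_error")
    })
    log_lines <<- c(log_lines, sprintf("stage %-28s %.2fs", name,
                                       proc.time()[["elapsed"]] - t0))
    out
  }

  segmap <- stage("load-segments", {
    if (inherits(cfg$segmap, "segment_map")) cfg$segmap
    else read_segment_map(cfg$segmap)
  })
  ensembles <- stage("load-ensembles", {
    lapply(cfg$constructs, function(e) {
      if (inherits(e, "structure_ensemble")) e
      else parse_structure(paste(readLines(e, warn = FALSE), collapse = "\n"))
    })
  })

  rmsd <- list(); box <- list(); clustering <- list(); occupancy <- list()
  for (nm in names(ensembles)) {
    ens <- ensembles[[nm]]
    avg <- stage(paste0("average:", nm),
                 ensemble_average(ens, segmap, "ALL"))
    rep_df <- stage(paste0("rmsd:", nm), rmsd_report(ens, segmap, avg))
    files <- c(files, write_csv_file(rep_df,
                                     file.path(cfg$out_dir,
                                               sprintf("rmsd_%s.csv", nm))))
    rmsd[[nm]] <- rep_df
    box[[nm]] <- box_stats(rep_df$rmsd_tm)
    dm <- stage(paste0("pairwise:", nm), pairwise_rmsd(ens, segmap, "TM"))
    cl <- stage(paste0("cluster:", nm),
                jarvis_patrick(dm, M = cfg$cluster_m,
                               cutoff = cfg$cluster_cutoff, P = cfg$cluster_p))
    clustering[[nm]] <- cl
    occupancy[[nm]] <- cumulative_occupancy(cl, cfg$occupancy_k)
    files <- c(files, write_csv_file(
      data.frame(frame_index = seq_along(cl$assignment),
                 cluster_id = cl$assignment),
      file.path(cfg$out_dir, sprintf("clusters_%s.csv", nm))))
  }

  b <- function(field) vapply(box, `[[`, numeric(1), field)
  files <- c(files, write_csv_file(
    data.frame(construct = names(box), n = vapply(box, `[[`, numeric(1), "n"),
               median = b("median"), q1 = b("q1"), q3 = b("q3"),
               whisker_lo = b("whisker_lo"), whisker_hi = b("whisker_hi"),
               n_outliers = vapply(box, function(x) length(x$outliers),
                                   numeric(1)),
               row.names = NULL),
    file.path(cfg$out_dir, "boxstats_rmsd_tm.csv")))
  files <- c(files, write_csv_file(
    data.frame(construct = rep(names(occupancy),
                               each = cfg$occupancy_k),
               k = rep(seq_len(cfg$occupancy_k), length(occupancy)),
               cumulative_fraction = unlist(occupancy, use.names = FALSE)),
    file.path(cfg$out_dir, "occupancy_top_clusters.csv")))

  contacts <- NULL
  if (!is.null(cfg$contact_pairs)) {
    contacts <- stage("contacts", {
      lapply(names(ensembles), function(nm) {
        rows <- lapply(cfg$contact_pairs, function(p) {
          cs <- distance_series(ensembles[[nm]], p$a, p$b)
          data.frame(construct = nm, res_a = cs$pair[1L], res_b = cs$pair[2L],
                     mean = cs$mean, sd = cs$sd)
        })
        do.call(rbind, rows)
      })
    })
    contacts <- do.call(rbind, contacts)
    files <- c(files, write_csv_file(contacts,
                                     file.path(cfg$out_dir, "contacts.csv")))
  }

  ranking <- stage("rank", {
    if (length(ensembles) >= 2L)
      rank_constructs(lapply(rmsd, `[[`, "rmsd_tm"), tie_tol = cfg$tie_tol)
    else NULL
  })
  if (!is.null(ranking)) {
    writeLines(format(ranking), file.path(cfg$out_dir, "ranking.txt"))
    files <- c(files, file.path(cfg$out_dir, "ranking.txt"))
  }

  melt <- NULL
  if (!is.null(cfg$melt_curves)) {
    melt <- stage("melt", {
      curves <- lapply(cfg$melt_curves, function(m) {
        if (inherits(m, "melt_curve")) m else read_melt_curve(m)
      })
      melt_table(curves, reference = cfg$melt_reference)
    })
    files <- c(files, write_csv_file(melt,
                                     file.path(cfg$out_dir, "melting_tm.csv")))
  }

  finish(ok = TRUE)
  invisible(list(rmsd = rmsd, box = box, clustering = clustering,
                 occupancy = occupancy, contacts = contacts,
                 ranking = ranking, melt = melt, files = files))
}
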