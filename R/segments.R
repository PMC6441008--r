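#' Segment maps: named domains over residue ranges
#'
#' A segment map assigns residues to named domains: the seven transmembrane
#' helices (TM1..TM7) of a GPCR, the fusion domain (e.g. T4 lysozyme inserted
#' into intracellular loop 3), and any linkers or loops.  Each segment is a
#' set of inclusive `(chain, start, end)` residue ranges in PDB numbering.
#' Ballesteros-Weinstein labels (generic GPCR residue labels such as "3.41")
#' are optional metadata supplied with the map, never inferred.
#'
#' @param segments named list; each element a data.frame with columns
#'   `chain`, `start`, `end` (inclusive residue ranges).
#' @param tm_names ordered character vector of the transmembrane segment
#'   names, usually `TM1`..`TM7`.
#' @param fusion_name name of the fusion-domain segment, e.g. `"T4L"`.
#' @param bw_labels optional named character vector mapping
#'   `"chain:resseq"` to a Ballesteros-Weinstein label.
#' @return an object of class `segment_map`.
#' @export
segment_map <- function(segments, tm_names, fusion_name, bw_labels = NULL) {
  if (is.null(names(segments)) || any(!nzchar(names(segments))))
    stop_gpcrstab("segments must be a named list", "invalid_segment_map_error")
  segments <- lapply(segments, function(s) {
    s <- as.data.frame(s)
    if (!all(c("chain", "start", "end") %in% names(s)))
      stop_gpcrstab("each segment needs chain/start/end",
                    "invalid_segment_map_error")
    s$start <- as.integer(s$start); s$end <- as.integer(s$end)
    if (any(s$end < s$start))
      stop_gpcrstab("segment range with end < start", "invalid_segment_map_error")
    # ranges within one segment must not overlap (per chain)
    for (ch in unique(s$chain)) {
      r <- s[s$chain == ch, , drop = FALSE]
      r <- r[order(r$start), , drop = FALSE]
      if (nrow(r) > 1L && any(r$start[-1L] <= r$end[-nrow(r)]))
        stop_gpcrstab("overlapping ranges within one segment",
                      "invalid_segment_map_error")
    }
    s[c("chain", "start", "end")]
  })
  missing_tm <- setdiff(tm_names, names(segments))
  if (length(missing_tm))
    stop_gpcrstab(paste0("tm_names absent from segments: ",
                         paste(missing_tm, collapse = ", ")),
                  "invalid_segment_map_error")
  if (!fusion_name %in% names(segments))
    stop_gpcrstab(sprintf("fusion segment '%s' absent from segments", fusion_name),
                  "invalid_segment_map_error")
  structure(list(segments = segments, tm_names = as.character(tm_names),
                 fusion_name = fusion_name, bw_labels = bw_labels),
            class = "segment_map")
}

#' @export
print.segment_map <- function(x, ...) {
  cat(sprintf("<segment_map> %d segments; TM: %s; fusion: %s\n",
              length(x$segments), paste(x$tm_names, collapse = ","),
              x$fusion_name))
  invisible(x)
}

#' Read a segment-map config file
#'
#' Plain-text key-value format with one section per segment:
#' ```
#' tm_order = TM1 TM2 TM3 TM4 TM5 TM6 TM7
#' fusion   = T4L
#'
#' [TM1]
#' chain = A
#' start = 1
#' end   = 20
#'
#' [T4L]
#' chain = A
#' start = 141
#' end   = 180
#' bw    =            # optional 'resseq=label' pairs, whitespace separated
#' ```
#' A segment may repeat `chain/start/end` triples on extra `range = A 5 10`
#' lines for discontinuous segments.
#'
#' @param path file path (or a character vector of config lines via
#'   `text =`).
#' @param text optional character vector of lines, instead of `path`.
#' @return a [segment_map()].
#' @export
read_segment_map <- function(path, text = NULL) {
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else text
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- NA_character_
  top <- list(); segs <- list(); bw <- character()
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      segs[[section]] <- list(chain = character(), start = integer(),
                              end = integer())
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L)
      stop_gpcrstab(sprintf("malformed config line: '%s'", ln), "parse_error")
    key <- trimws(kv[1L]); val <- trimws(paste(kv[-1L], collapse = "="))
    if (is.na(section)) {
      top[[key]] <- val
    } else if (key == "range") {
      f <- strsplit(val, "\\s+")[[1L]]
      segs[[section]]$chain <- c(segs[[section]]$chain, f[1L])
      segs[[section]]$start <- c(segs[[section]]$start, as.integer(f[2L]))
      segs[[section]]$end <- c(segs[[section]]$end, as.integer(f[3L]))
    } else if (key %in% c("chain", "start", "end")) {
      segs[[section]][[key]] <- c(segs[[section]][[key]],
                                  if (key == "chain") val else as.integer(val))
    } else if (key == "bw") {
      for (pair in strsplit(val, "\\s+")[[1L]]) {
        p <- strsplit(pair, "=", fixed = TRUE)[[1L]]
        if (length(p) == 2L) bw[p[1L]] <- p[2L]
      }
    }
  }
  if (is.null(top$tm_order) || is.null(top$fusion))
    stop_gpcrstab("config must define top-level 'tm_order' and 'fusion'",
                  "parse_error")
  seg_dfs <- lapply(segs, function(s) {
    n <- max(length(s$chain), length(s$start), length(s$end))
    data.frame(chain = rep_len(s$chain, n), start = rep_len(s$start, n),
               end = rep_len(s$end, n))
  })
  segment_map(seg_dfs,
              tm_names = strsplit(top$tm_order, "\\s+")[[1L]],
              fusion_name = top$fusion,
              bw_labels = if (length(bw)) bw else NULL)
}

#' Write a segment map in the config format of [read_segment_map()]
#' @param segmap a [segment_map()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_segment_map <- function(segmap, path) {
  out <- c(paste("tm_order =", paste(segmap$tm_names, collapse = " ")),
           paste("fusion =", segmap$fusion_name), "")
  for (nm in names(segmap$segments)) {
    s <- segmap$segments[[nm]]
    out <- c(out, sprintf("[%s]", nm),
             sprintf("range = %s %d %d", s$chain, s$start, s$end), "")
  }
  writeLines(out, path)
  invisible(path)
}
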