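#' Box-plot statistics with the 1.5 IQR rule
#'
#' Quartiles use linear interpolation at rank `1 + p (n - 1)`
#' ([stats::quantile()] type 7).  Whiskers extend to the most extreme data
#' points within 1.5 interquartile ranges of the quartiles; everything
#' beyond those fences is an outlier.
#'
#' @param values numeric vector (finite, length >= 1).
#' @return object of class `box_stats`: list with `n`, `median`, `q1`,
#'   `q3`, `iqr`, `whisker_lo`, `whisker_hi`, `outliers`.
#' @export
box_stats <- function(values) {
  values <- as.numeric(values)
  if (!length(values))
    stop_gpcrstab("box_stats needs at least one value", "empty_input_error")
  if (any(!is.finite(values)))
    stop_gpcrstab("box_stats values must be finite", "invalid_input_error")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3L] - q[1L]
  fence_lo <- q[1L] - 1.5 * iqr
  fence_hi <- q[3L] + 1.5 * iqr
  inside <- values >= fence_lo & values <= fence_hi
  structure(list(n = length(values), median = q[2L], q1 = q[1L], q3 = q[3L],
                 iqr = iqr,
                 whisker_lo = min(values[inside]),
                 whisker_hi = max(values[inside]),
                 outliers = sort(values[!inside])),
            class = "box_stats")
}

#' @export
print.box_stats <- function(x, ...) {
  cat(sprintf("<box_stats> n=%d median=%.3g [q1=%.3g, q3=%.3g] whiskers [%.3g, %.3g], %d outlier(s)\n",
              x$n, x$median, x$q1, x$q3, x$whisker_lo, x$whisker_hi,
              length(x$outliers)))
  invisible(x)
}

#' Rank constructs by conformational stability
#'
#' Constructs are ordered by ascending median of their per-frame TM-domain
#' RMSD values: a smaller median means smaller deviation from the average
#' structure, i.e. a more stable construct.  Adjacent constructs along the
#' sorted chain whose medians differ by at most `tie_tol` are merged into a
#' tie group ("~"); merging is applied transitively along the chain.
#'
#' @param per_construct named list: construct name -> numeric vector of
#'   per-frame RMSD values (Angstrom), or a named numeric vector of
#'   precomputed medians.
#' @param tie_tol tie tolerance on the medians, Angstrom (default 0.15).
#' @return object of class `rank_result`: list with `groups` (list of
#'   character vectors, most stable first), `medians` (named, ascending)
#'   and `criterion`.
#' @export
rank_constructs <- function(per_construct, tie_tol = 0.15) {
  if (length(per_construct) < 2L)
    stop_gpcrstab("ranking needs at least 2 constructs", "invalid_input_error")
  medians <- if (is.numeric(per_construct) && !is.list(per_construct))
    per_construct else vapply(per_construct, stats::median, numeric(1))
  ord <- order(medians, names(medians))
  medians <- medians[ord]
  groups <- list(names(medians)[1L])
  for (i in seq_along(medians)[-1L]) {
    if (medians[i] - medians[i - 1L] <= tie_tol) {
      groups[[length(groups)]] <- c(groups[[length(groups)]],
                                    names(medians)[i])
    } else {
      groups[[length(groups) + 1L]] <- names(medians)[i]
    }
  }
  structure(list(groups = groups, medians = medians,
                 criterion = sprintf("ascending median TM RMSD, tie_tol = %g A",
                                     tie_tol)),
            class = "rank_result")
}

#' Format a stability ranking as "A > B ~ C" text
#' @param x a [rank_constructs()] result.
#' @param ... unused.
#' @return character scalar.
#' @export
format.rank_result <- function(x, ...) {
  paste(vapply(x$groups, paste, character(1), collapse = " ~ "),
        collapse = " > ")
}

#' @export
print.rank_result <- function(x, ...) {
  cat("<rank_result>", format(x), "\n")
  invisible(x)
}
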