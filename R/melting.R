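#' Melting curves
#'
#' A melting curve records circular dichroism ellipticity (typically at
#' 222 nm, reporting alpha-helical content) against temperature, sampled
#' e.g. from 25 to 90 degC in 5 degC steps.
#'
#' @param temperature numeric vector, degC, strictly increasing.
#' @param ellipticity numeric vector of the same length (instrument units,
#'   e.g. millidegrees).
#' @param label construct name.
#' @return object of class `melt_curve`.
#' @export
melt_curve <- function(temperature, ellipticity, label = "") {
  temperature <- as.numeric(temperature)
  ellipticity <- as.numeric(ellipticity)
  if (length(temperature) < 4L)
    stop_gpcrstab("a melting curve needs at least 4 points", "invalid_curve_error")
  if (length(ellipticity) != length(temperature))
    stop_gpcrstab("temperature and ellipticity lengths differ",
                  "invalid_curve_error")
  if (any(diff(temperature) <= 0))
    stop_gpcrstab("temperatures must be strictly increasing", "invalid_curve_error")
  if (any(!is.finite(temperature)) || any(!is.finite(ellipticity)))
    stop_gpcrstab("melting curve values must be finite", "invalid_curve_error")
  structure(list(points = data.frame(temperature = temperature,
                                     ellipticity = ellipticity),
                 label = label), class = "melt_curve")
}

#' Read a melting curve from CSV
#'
#' Expects columns `temperature_C` and `ellipticity` (extra columns are
#' ignored).
#'
#' @param path CSV file path.
#' @param label construct name; defaults to the file name without extension.
#' @return a [melt_curve()].
#' @export
read_melt_curve <- function(path, label = NULL) {
  df <- utils::read.csv(path, check.names = TRUE)
  if (!all(c("temperature_C", "ellipticity") %in% names(df)))
    stop_gpcrstab("melting CSV needs columns temperature_C, ellipticity",
                  "parse_error")
  if (is.null(label))
    label <- tools::file_path_sans_ext(basename(path))
  melt_curve(df$temperature_C, df$ellipticity, label = label)
}

#' Denatured-fraction normalization of a melting curve
#'
#' Maps ellipticity to the fraction of denatured protein,
#' `delta_fD = (theta - theta_min) / (theta_max - theta_min)`, where
#' `theta_min` and `theta_max` are the lowest and highest ellipticity over
#' all temperatures of the curve.  The result runs from 0 to 1 and is
#' invariant under affine rescaling of the raw signal.
#'
#' @param curve a [melt_curve()].
#' @return object of class `normalized_curve`: list with `points`
#'   (`temperature`, `delta_fd`), `theta_min`, `theta_max`, `label`.
#' @export
normalize_delta_fd <- function(curve) {
  th <- curve$points$ellipticity
  theta_min <- min(th); theta_max <- max(th)
  if (theta_max <= theta_min)
    stop_gpcrstab("constant ellipticity: zero normalization range",
                  "zero_range_error")
  structure(list(points = data.frame(temperature = curve$points$temperature,
                                     delta_fd = (th - theta_min) /
                                       (theta_max - theta_min)),
                 theta_min = theta_min, theta_max = theta_max,
                 label = curve$label), class = "normalized_curve")
}

# Model functions on the denatured-fraction scale.  The Hill form
# f(T) = T^n / (Tm^n + T^n) is evaluated in log space to stay finite for
# large exponents.
hill_fd <- function(temp, tm, n) 1 / (1 + exp(n * (log(tm) - log(temp))))
logistic_fd <- function(temp, tm, s) 1 / (1 + exp((tm - temp) / s))

#' Fit a melting temperature to a normalized curve
#'
#' Nonlinear least squares of a sigmoid on the denatured fraction.  Two
#' parameterizations are available, both with their midpoint
#' (`delta_fd = 0.5`) at `T = Tm`:
#' * `hill`: `delta_fd(T) = T^n / (Tm^n + T^n)` (Hill equation, exponent
#'   `n` dimensionless) - the default;
#' * `logistic`: `delta_fd(T) = 1 / (1 + exp((Tm - T)/s))` (width `s` in
#'   degC).
#'
#' The fit is multi-start: `Tm` starts at the sampled temperature whose
#' `delta_fd` is nearest 0.5 and at the curve midrange; the steepness starts
#' at 5/20/60 (`hill`) or 1/3/10 degC (`logistic`).  The best residual sum
#' of squares wins, ties going to the earliest start.  Baselines are fixed
#' at 0 and 1 (the curve is normalized first); `free_baseline = TRUE`
#' additionally fits lower/upper plateaus.  A fitted midpoint outside the
#' sampled temperature range raises an extrapolation warning and marks the
#' fit unconverged.
#'
#' @param norm a [normalized_curve()] (a raw [melt_curve()] is normalized
#'   on the fly).
#' @param model `"hill"` (default) or `"logistic"`.
#' @param free_baseline fit plateau levels too (default `FALSE`).
#' @return object of class `melt_fit`: list with `tm` (degC), `steepness`,
#'   `rss`, `converged`, `model`, `baselines`, `label`.
#' @export
fit_melting <- function(norm, model = c("hill", "logistic"),
                        free_baseline = FALSE) {
  model <- match.arg(model)
  if (inherits(norm, "melt_curve")) norm <- normalize_delta_fd(norm)
  temp <- norm$points$temperature
  fd <- norm$points$delta_fd
  if (length(temp) < 4L)
    stop_gpcrstab("fit needs at least 4 points", "invalid_curve_error")
  if (min(fd) > 0.4 || max(fd) < 0.6)
    warn_gpcrstab("curve does not span both sides of the transition",
                  "extrapolation_warning")

  tm_starts <- unique(c(temp[which.min(abs(fd - 0.5))],
                        (min(temp) + max(temp)) / 2))
  st_starts <- if (model == "hill") c(5, 20, 60) else c(1, 3, 10)
  lo_tm <- min(temp) - 20; hi_tm <- max(temp) + 20

  fdfun <- if (model == "hill") hill_fd else logistic_fd
  predict_fd <- function(p) {
    base <- fdfun(temp, p[["tm"]], p[["st"]])
    if (free_baseline) p[["b0"]] + (p[["b1"]] - p[["b0"]]) * base else base
  }
  rss_of <- function(p) sum((predict_fd(p) - fd)^2)

  best <- NULL
  for (tm0 in tm_starts) {
    for (st0 in st_starts) {
      p0 <- c(tm = tm0, st = st0)
      lower <- c(tm = lo_tm, st = 1e-3)
      upper <- c(tm = hi_tm, st = if (model == "hill") 500 else 100)
      if (free_baseline) {
        p0 <- c(p0, b0 = 0, b1 = 1)
        lower <- c(lower, b0 = -0.5, b1 = 0.5)
        upper <- c(upper, b0 = 0.5, b1 = 1.5)
      }
      fit <- tryCatch({
        res <- minpack.lm::nls.lm(par = p0,
                                  fn = function(p) predict_fd(p) - fd,
                                  lower = lower, upper = upper,
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = 200, ftol = 1e-12, ptol = 1e-12))
        list(par = res$par, rss = sum(res$fvec^2))
      }, error = function(e) NULL)
      if (is.null(fit)) {
        # fall back to direct minimization of the rss
        opt <- tryCatch(stats::optim(p0, rss_of, method = "L-BFGS-B",
                                     lower = lower, upper = upper),
                        error = function(e) NULL)
        if (!is.null(opt)) fit <- list(par = opt$par, rss = opt$value)
      }
      if (!is.null(fit) && (is.null(best) || fit$rss < best$rss - 1e-12))
        best <- fit
    }
  }
  if (is.null(best))
    stop_gpcrstab(sprintf("melting fit failed from all %d starts (model %s, %d points)",
                          length(tm_starts) * length(st_starts), model,
                          length(temp)), "fit_failure_error")
  tm <- unname(best$par[["tm"]])
  converged <- TRUE
  if (tm < min(temp) || tm > max(temp)) {
    warn_gpcrstab(sprintf("fitted midpoint %.2f degC lies outside the sampled range [%g, %g]",
                          tm, min(temp), max(temp)), "extrapolation_warning")
    converged <- FALSE
  }
  structure(list(tm = tm, steepness = unname(best$par[["st"]]),
                 rss = best$rss, converged = converged, model = model,
                 baselines = if (free_baseline)
                   c(unname(best$par[["b0"]]), unname(best$par[["b1"]]))
                 else c(0, 1),
                 label = norm$label),
            class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("<melt_fit> %s: Tm = %.2f degC (%s, steepness %.2f, rss %.3g%s)\n",
              if (nzchar(x$label)) x$label else "curve", x$tm, x$model,
              x$steepness, x$rss,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Melting-temperature shift relative to a reference construct
#'
#' @param fit_mut [fit_melting()] result of the mutant.
#' @param fit_wt [fit_melting()] result of the reference (wild type).
#' @return signed `Tm(mutant) - Tm(wild type)` in degC.
#' @export
delta_tm <- function(fit_mut, fit_wt) {
  if (!isTRUE(fit_mut$converged) || !isTRUE(fit_wt$converged))
    stop_gpcrstab("delta Tm requires two converged fits", "fit_failure_error")
  fit_mut$tm - fit_wt$tm
}

#' Fit and tabulate melting temperatures for several constructs
#'
#' @param curves named list of [melt_curve()]s; the reference construct is
#'   named by `reference`.
#' @param reference name of the wild-type/reference curve.
#' @param model passed to [fit_melting()].
#' @return data.frame with columns `construct`, `tm`, `steepness`, `rss`,
#'   `converged`, `delta_tm` (degC, relative to `reference`).
#' @export
melt_table <- function(curves, reference = "WT", model = "hill") {
  if (!reference %in% names(curves))
    stop_gpcrstab(sprintf("reference construct '%s' missing", reference),
                  "invalid_parameter_error")
  fits <- lapply(curves, function(cu) fit_melting(normalize_delta_fd(cu),
                                                  model = model))
  ref <- fits[[reference]]
  data.frame(construct = names(fits),
             tm = vapply(fits, `[[`, numeric(1), "tm"),
             steepness = vapply(fits, `[[`, numeric(1), "steepness"),
             rss = vapply(fits, `[[`, numeric(1), "rss"),
             converged = vapply(fits, `[[`, logical(1), "converged"),
             delta_tm = vapply(fits, function(f) delta_tm(f, ref), numeric(1)),
             row.names = NULL)
}
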