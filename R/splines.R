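#' Fit a spline through one observed time course
#'
#' With `smoothing = 0` (the default) an interpolating cubic spline with
#' natural boundary conditions is fitted: it passes through every observed
#' point exactly.  With `smoothing > 0` a smoothing spline
#' (`stats::smooth.spline` with `spar = smoothing`) is used instead, for
#' noisy data.  The fitted curve is evaluated only inside the observation
#' window; extrapolation requests are errors, because spline derivatives
#' carry no information outside the data.
#'
#' @param times strictly increasing numeric vector (>= 2 points; >= 4 for a
#'   full cubic fit, fewer points fall back to lower polynomial order via
#'   the spline's own degeneration).
#' @param values numeric vector of observed concentrations.
#' @param smoothing non-negative scalar; 0 = exact interpolation,
#'   otherwise the `spar` smoothing parameter.
#' @param boundary boundary condition for the interpolating spline:
#'   `"natural"` (second derivative zero at the ends, default) or `"fmm"`
#'   (Forsythe-Malcolm-Moler end conditions, close to not-a-knot).
#' @return An object of class `spline_fit` with `$predict(t)` and
#'   `$derivative(t)` evaluators.
#' @examples
#' sf <- fit_spline(0:10, 2 * (0:10))
#' sf$derivative(c(0, 5, 10))  # exactly 2 everywhere
#' @export
fit_spline <- function(times, values, smoothing = 0, boundary = "natural") {
  stopifnot(length(times) == length(values), is.numeric(times),
            is.numeric(values), smoothing >= 0)
  if (length(times) < 2) stop("need at least 2 points to fit a spline")
  if (anyDuplicated(times)) stop("duplicate times")
  if (is.unsorted(times)) stop("times must be increasing")
  boundary <- match.arg(boundary, c("natural", "fmm"))
  rng <- range(times)
  if (smoothing == 0) {
    f <- stats::splinefun(times, values, method = boundary)
    pred <- function(t) f(t)
    dfun <- function(t) f(t, deriv = 1L)
  } else {
    if (length(times) < 4) stop("smoothing spline needs >= 4 points")
    ss <- stats::smooth.spline(times, values, spar = smoothing)
    pred <- function(t) stats::predict(ss, t)$y
    dfun <- function(t) stats::predict(ss, t, deriv = 1L)$y
  }
  check <- function(t) {
    if (any(t < rng[1] - 1e-12) || any(t > rng[2] + 1e-12))
      stop("evaluation outside the observation window [",
           rng[1], ", ", rng[2], "]")
  }
  structure(list(
    predict = function(t) { check(t); pred(t) },
    derivative = function(t) { check(t); dfun(t) },
    times = times, values = values, smoothing = smoothing,
    boundary = boundary, window = rng), class = "spline_fit")
}

#' @export
print.spline_fit <- function(x, ...) {
  cat("Spline fit:", length(x$times), "points on [",
      x$window[1], ",", x$window[2], "], smoothing =", x$smoothing,
      ", boundary =", x$boundary, "\n")
  invisible(x)
}

#' Interpolated time derivatives for a whole dataset
#'
#' Fits one spline per (experiment, species) and evaluates its first
#' derivative at every observation timepoint.  These interpolated
#' derivatives are the left-hand sides that the collocation error terms
#' compare against the ODE right-hand sides.  First and last timepoints are
#' flagged as boundary points, where spline derivatives are least reliable.
#'
#' @param dataset a [time_series_dataset()].
#' @param smoothing passed to [fit_spline()].
#' @param boundary passed to [fit_spline()].
#' @return An object of class `deriv_table`: a list with per-experiment
#'   derivative matrices (`$deriv[[e]]`, same shape as the observations),
#'   smoothed values (`$smooth[[e]]`, equal to the observations when
#'   `smoothing = 0`), and a per-timepoint logical `$is_boundary[[e]]`.
#' @export
interpolated_derivatives <- function(dataset, smoothing = 0,
                                     boundary = "natural") {
  stopifnot(inherits(dataset, "spedre_data"))
  out <- list(deriv = list(), smooth = list(), is_boundary = list())
  for (nm in names(dataset$experiments)) {
    e <- dataset$experiments[[nm]]
    D <- Sm <- e$obs
    for (i in seq_len(ncol(e$obs))) {
      sf <- fit_spline(e$times, e$obs[, i], smoothing = smoothing,
                       boundary = boundary)
      D[, i] <- sf$derivative(e$times)
      Sm[, i] <- sf$predict(e$times)
    }
    if (any(!is.finite(D))) stop("non-finite interpolated derivative")
    flag <- rep(FALSE, length(e$times))
    flag[c(1L, length(flag))] <- TRUE
    out$deriv[[nm]] <- D
    out$smooth[[nm]] <- Sm
    out$is_boundary[[nm]] <- flag
  }
  out$smoothing <- smoothing
  out$boundary <- boundary
  class(out) <- "deriv_table"
  out
}

#' Write interpolated derivatives as CSV (one file per experiment)
#' @param derivs a `deriv_table` from [interpolated_derivatives()].
#' @param dataset the dataset the table was computed from.
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_derivatives_csv <- function(derivs, dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in names(dataset$experiments)) {
    df <- data.frame(time = dataset$experiments[[nm]]$times)
    D <- derivs$deriv[[nm]]
    colnames(D) <- paste0(colnames(D), "_ddt")
    df <- cbind(df, as.data.frame(D))
    p <- file.path(dir, paste0(nm, "_derivatives.csv"))
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
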