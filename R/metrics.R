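#' Species maximum relative error
#'
#' Simulates the network at `params` from each experiment's observed
#' initial condition and reports `100 * max |x_sim - x_obs| / max_j x_obs`,
#' the maximum taken over experiments, species and timepoints, with each
#' species' deviations normalized by that species' observed maximum in the
#' experiment (range normalization).  Values above 100% are possible and
#' indicate an unusable fit.  With `pointwise = TRUE` the deviation at each
#' point is normalized by the observation at that point instead.
#'
#' @inheritParams weighted_sse
#' @param pointwise use pointwise instead of range normalization.
#' @return percentage (scalar, >= 0).
#' @export
species_mre <- function(network, params, dataset, pointwise = FALSE) {
  dataset <- .align_dataset(network, dataset)
  worst <- 0
  for (e in dataset$experiments) {
    sim <- simulate_network(network, params, pmax(e$obs[1, ], 0), e$times)
    S <- as.matrix(sim[, dataset$species, drop = FALSE])
    for (i in seq_along(dataset$species)) {
      mx <- max(e$obs[, i])
      if (mx <= 0) {
        warning("species ", dataset$species[i],
                " observed as all-zero; skipped in MRE")
        next
      }
      rel <- if (pointwise) {
        ok <- e$obs[, i] > 0
        abs(S[ok, i] - e$obs[ok, i]) / e$obs[ok, i]
      } else abs(S[, i] - e$obs[, i]) / mx
      worst <- max(worst, rel)
    }
  }
  100 * worst
}

#' Parameter percentage error
#'
#' `PPE_p = 100 * |estimated_p - nominal_p| / nominal_p`, reported per
#' parameter together with the median (the headline aggregate).  Requires
#' strictly positive nominal values, so it is only available in simulated
#' tests where the truth is known.
#'
#' @param estimated,nominal numeric parameter vectors of equal length.
#' @return list with `$ppe` (named percentages) and `$median` (scalar).
#' @export
parameter_percentage_error <- function(estimated, nominal) {
  stopifnot(length(estimated) == length(nominal))
  if (any(nominal <= 0)) stop("nominal parameters must be strictly positive")
  ppe <- 100 * abs(estimated - nominal) / nominal
  if (is.null(names(ppe)) && !is.null(names(nominal)))
    names(ppe) <- names(nominal)
  list(ppe = ppe, median = stats::median(ppe))
}

#' Full score report for an estimate
#'
#' @inheritParams weighted_sse
#' @param nominal optional true parameter vector (enables PPE).
#' @return An object of class `score_report` with fields `weighted_sse`,
#'   `species_mre`, `ppe`, `median_ppe`.
#' @export
score_report <- function(network, params, dataset, nominal = NULL,
                         weights = NULL) {
  out <- list(weighted_sse = weighted_sse(network, params, dataset, weights),
              species_mre = species_mre(network, params, dataset),
              ppe = NULL, median_ppe = NA_real_)
  if (!is.null(nominal)) {
    pe <- parameter_percentage_error(params, nominal)
    out$ppe <- pe$ppe
    out$median_ppe <- pe$median
  }
  structure(out, class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat("Score report\n")
  cat("  weighted SSE:", format(x$weighted_sse), "\n")
  cat("  species MRE :", format(round(x$species_mre, 3)), "%\n")
  if (!is.null(x$ppe))
    cat("  median PPE  :", format(round(x$median_ppe, 3)), "%\n")
  invisible(x)
}

#' One-line TSV row of a score report (for benchmark tables)
#' @param report a [score_report()].
#' @param label scenario/method label placed in the first column.
#' @return character scalar (tab-separated).
#' @export
score_tsv_row <- function(report, label = "") {
  paste(label, format(report$weighted_sse), format(report$species_mre),
        format(report$median_ppe), sep = "\t")
}
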