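#' Dense time-series concentration datasets
#'
#' The estimator requires the data-rich regime: every species observed at
#' every timepoint of every experiment.  A `spedre_data` object is a list of
#' experiments; each experiment holds a strictly increasing `times` vector
#' and an observation matrix `obs` (timepoints in rows, species in columns,
#' column names = species names).
#'
#' @param experiments a list; each element is either a data frame in
#'   trajectory layout (`time` column first, then one column per species) or
#'   a list with fields `times` and `obs`.
#' @param species optional character vector fixing the species order; by
#'   default taken from the first experiment.
#' @return An object of class `spedre_data`.
#' @export
time_series_dataset <- function(experiments, species = NULL) {
  stopifnot(is.list(experiments), length(experiments) >= 1)
  if (is.data.frame(experiments) ||
      (!is.null(experiments$times) && !is.null(experiments$obs)))
    experiments <- list(experiments)
  exps <- lapply(experiments, function(e) {
    if (is.data.frame(e)) {
      if (names(e)[1] != "time") stop("first column must be 'time'")
      obs <- as.matrix(e[, -1, drop = FALSE])
      list(times = as.numeric(e$time), obs = obs)
    } else {
      list(times = as.numeric(e$times), obs = as.matrix(e$obs))
    }
  })
  if (is.null(species)) species <- colnames(exps[[1]]$obs)
  if (is.null(species)) stop("species names missing")
  for (k in seq_along(exps)) {
    e <- exps[[k]]
    if (is.null(colnames(e$obs))) colnames(e$obs) <- species
    if (!setequal(colnames(e$obs), species))
      stop("data-rich requirement violated: experiment ", k,
           " does not observe every species")
    exps[[k]]$obs <- e$obs[, species, drop = FALSE]
    if (any(diff(e$times) <= 0))
      stop("timepoints must be strictly increasing (experiment ", k, ")")
    if (length(e$times) != nrow(e$obs))
      stop("times/observations mismatch in experiment ", k)
    if (any(!is.finite(e$obs)))
      stop("non-finite observation in experiment ", k)
  }
  if (is.null(names(exps)))
    names(exps) <- paste0("exp", seq_along(exps))
  structure(list(experiments = exps, species = species),
            class = "spedre_data")
}

#' @export
print.spedre_data <- function(x, ...) {
  nt <- vapply(x$experiments, function(e) length(e$times), 1L)
  cat("Dense time-series dataset:", length(x$experiments),
      "experiment(s),", length(x$species), "species,",
      paste(nt, collapse = "/"), "timepoints\n")
  invisible(x)
}

#' @export
as.data.frame.spedre_data <- function(x, ...) {
  do.call(rbind, lapply(names(x$experiments), function(nm) {
    e <- x$experiments[[nm]]
    cbind(data.frame(experiment = nm, time = e$times),
          as.data.frame(e$obs))
  }))
}

#' Number of collocation error terms in a dataset
#'
#' One error term exists per (experiment, species, timepoint) triple.
#' @param dataset a [time_series_dataset()].
#' @return integer count.
#' @export
n_error_terms <- function(dataset) {
  sum(vapply(dataset$experiments,
             function(e) length(e$times) * ncol(e$obs), 1))
}

# Reorder dataset species columns to match the network's species order.
.align_dataset <- function(network, dataset) {
  if (!setequal(dataset$species, network$species))
    stop("dataset species do not match the network (data-rich requirement ",
         "violated)")
  if (identical(dataset$species, network$species)) return(dataset)
  for (k in seq_along(dataset$experiments))
    dataset$experiments[[k]]$obs <-
      dataset$experiments[[k]]$obs[, network$species, drop = FALSE]
  dataset$species <- network$species
  dataset
}

#' Read / write trajectory CSV files
#'
#' Layout: header `time,<species1>,<species2>,...`, one row per timepoint,
#' one file per experiment; comma separator, '.' decimal, UTF-8.
#'
#' @param path file path.
#' @param trajectory a trajectory data frame (`time` column first).
#' @return `read_trajectory_csv` returns a trajectory data frame.
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time") stop("trajectory CSV must start with 'time'")
  df
}

#' @rdname read_trajectory_csv
#' @export
write_trajectory_csv <- function(trajectory, path) {
  utils::write.csv(trajectory, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a dataset from per-experiment CSV files
#' @param paths character vector of trajectory CSV paths.
#' @param species optional species order check (see [time_series_dataset()]).
#' @return A [time_series_dataset()].
#' @export
read_dataset <- function(paths, species = NULL) {
  exps <- lapply(paths, read_trajectory_csv)
  names(exps) <- if (!is.null(names(paths))) names(paths) else
    tools::file_path_sans_ext(basename(paths))
  time_series_dataset(exps, species = species)
}
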