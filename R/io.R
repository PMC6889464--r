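## Plain-text serialization: CSV for trajectories, colony counts,
## competition records and calibration surfaces; JSON for equilibrium and
## regime reports and for generator provenance. Every writer's output is
## re-readable by its paired reader with value equality to 1e-10.

fmt10 <- function(x) formatC(x, digits = 10, format = "g")

#' Write / read a trajectory as CSV
#'
#' Columns `t,x,y,z`, rows ordered by increasing time, floats rendered with
#' 10 significant digits.
#'
#' @param traj A `qs_trajectory`.
#' @param path Output (input) file path.
#' @return `write_trajectory_csv` returns `path` invisibly;
#'   `read_trajectory_csv` returns a `qs_trajectory` (with `params = NULL`,
#'   since the CSV carries no parameters).
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "qs_trajectory"))
  d <- as.data.frame(traj)
  d <- d[order(d$t), ]
  d[] <- lapply(d, fmt10)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(identical(names(d), c("t", "x", "y", "z")))
  structure(list(times = d$t,
                 states = as.matrix(d[, c("x", "y", "z")]),
                 params = NULL),
            class = "qs_trajectory")
}

#' Write / read a colony-count table as CSV
#'
#' Header `cycle,time_h,n_sampled,n_C,n_CD,n_D`.
#'
#' @param counts A colony-count data frame.
#' @param path File path.
#' @export
write_colony_table <- function(counts, path) {
  check_colony_table(counts)
  utils::write.csv(counts[, c("cycle", "time_h", "n_sampled",
                              "n_C", "n_CD", "n_D")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_colony_table
#' @export
read_colony_table <- function(path) {
  check_colony_table(utils::read.csv(path))
}

#' Write / read competition records as CSV
#'
#' Header `pair,x0,x1,v`; fixation rows carry an empty `v` field.
#'
#' @param records A `qs_competition` data frame.
#' @param path File path.
#' @export
write_competition_csv <- function(records, path) {
  stopifnot(is.data.frame(records),
            all(c("pair", "x0", "x1", "v") %in% names(records)))
  d <- data.frame(pair = records$pair, x0 = fmt10(records$x0),
                  x1 = fmt10(records$x1),
                  v = ifelse(is.na(records$v), "", fmt10(records$v)))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_competition_csv
#' @export
read_competition_csv <- function(path) {
  utils::read.csv(path, colClasses = c(pair = "character"))
}

#' Write a calibration surface as CSV
#'
#' One row per grid point with the free-parameter columns and `sse`.
#'
#' @param fit A `qs_calibration`.
#' @param path File path.
#' @export
write_calibration_csv <- function(fit, path) {
  stopifnot(inherits(fit, "qs_calibration"))
  d <- fit$surface
  d[] <- lapply(d, fmt10)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize equilibrium / regime reports as JSON
#'
#' Locations, kinds, eigenvalue real and imaginary parts, stability labels,
#' the regime label (when given a `qs_regime`), and the parameters echoed.
#'
#' @param x A `qs_equilibria` or `qs_regime` object.
#' @param path File path.
#' @param params A [qs_params()] object to echo (taken from the
#'   `qs_equilibria` attribute when absent).
#' @export
write_equilibria_json <- function(x, path, params = NULL) {
  report_list <- function(eqs) {
    lapply(eqs, function(r) list(
      location = as.numeric(r$location),
      kind = r$kind,
      eigenvalues_re = Re(r$eigenvalues),
      eigenvalues_im = Im(r$eigenvalues),
      stability = r$stability))
  }
  if (inherits(x, "qs_regime")) {
    eqs <- x$stable_equilibria
    body <- list(
      regime = x$label,
      stable_equilibria = if (is.data.frame(eqs)) eqs else report_list(eqs))
  } else if (inherits(x, "qs_equilibria")) {
    if (is.null(params)) params <- attr(x, "params")
    body <- list(equilibria = report_list(x))
  } else stop("x must be a qs_equilibria or qs_regime object")
  if (!is.null(params)) body$parameters <- unclass(params)
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write generator provenance as a sidecar JSON
#'
#' Records the seed, game parameters, and design of a synthetic-data
#' generator run next to its CSV output, so every table is traceable to the
#' exact configuration that produced it.
#'
#' @param path Sidecar file path.
#' @param params A [qs_params()] object.
#' @param design The design object (e.g. [assay_design()]) or a named list
#'   of generator arguments.
#' @param seed The seed used.
#' @export
write_provenance_json <- function(path, params, design, seed) {
  jsonlite::write_json(
    list(seed = seed, parameters = unclass(params),
         design = unclass(design)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
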