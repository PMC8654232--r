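# Core data containers.
#
# A grid_field holds daily values of one or more pollutants on a set of planar
# grid points (the exposure source, e.g. a 12 km chemical-transport-model
# grid).  A tract_series holds daily values of pollutants and weather at
# census-tract centroids (the exposure target).  Both store values as
# variable -> matrix[location x day]; missing entries are NA, never silent 0.

#' Construct a daily gridded exposure field
#'
#' @param points numeric matrix with two columns (x, y planar coordinates,
#'   e.g. km); no duplicated coordinates allowed.
#' @param dates strictly increasing Date vector.
#' @param values named list, one element per pollutant, each a numeric matrix
#'   with `nrow(points)` rows and `length(dates)` columns.  Missing entries
#'   must be `NA` (flagged, not zero).
#' @return An object of class `grid_field`.
#' @seealso [idw_interpolate()]
#' @export
grid_field <- function(points, dates, values) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("`points` must have two columns (x, y)", call. = FALSE)
  if (anyDuplicated(points)) stop("duplicate grid coordinates", call. = FALSE)
  dates <- as_date_strict(dates)
  if (length(dates) > 1L && any(diff(dates) <= 0)) {
    stop("`dates` must be strictly increasing", call. = FALSE)
  }
  if (!is.list(values) || is.null(names(values)) || any(names(values) == "")) {
    stop("`values` must be a named list of matrices", call. = FALSE)
  }
  for (v in names(values)) {
    m <- values[[v]]
    if (!is.matrix(m) || nrow(m) != nrow(points) || ncol(m) != length(dates)) {
      stop(sprintf("values$%s must be a %d x %d matrix", v, nrow(points), length(dates)),
           call. = FALSE)
    }
    if (any(is.infinite(m))) stop(sprintf("non-finite values in %s", v), call. = FALSE)
  }
  structure(list(points = points, dates = dates, values = values),
            class = "grid_field")
}

#' @export
print.grid_field <- function(x, ...) {
  cat(sprintf("<grid_field> %d points, %d days (%s .. %s), variables: %s\n",
              nrow(x$points), length(x$dates),
              format(min(x$dates)), format(max(x$dates)),
              paste(names(x$values), collapse = ", ")))
  invisible(x)
}

#' Construct a tract-level daily exposure/weather series
#'
#' @param tract_ids character vector of unique tract identifiers.
#' @param centroids numeric matrix (x, y), one row per tract; population
#'   weighted tract centroids in the same planar units as any source grid.
#' @param dates strictly increasing Date vector.
#' @param values named list of variable -> matrix[tract x day].  Conventional
#'   variable names: `nox` (ppb), `o3` (ppm), `so2` (ppb), `pm25`, `pm10`,
#'   `pm10_25` (ug/m3), `co` (ppm), `temp`, `dewp` (deg C).
#' @return An object of class `tract_series`.
#' @export
tract_series <- function(tract_ids, centroids, dates, values) {
  tract_ids <- as.character(tract_ids)
  if (anyDuplicated(tract_ids)) stop("duplicate tract ids", call. = FALSE)
  centroids <- as.matrix(centroids)
  if (nrow(centroids) != length(tract_ids) || ncol(centroids) != 2L) {
    stop("`centroids` must be a matrix with one (x, y) row per tract", call. = FALSE)
  }
  dates <- as_date_strict(dates)
  if (length(dates) > 1L && any(diff(dates) <= 0)) {
    stop("`dates` must be strictly increasing", call. = FALSE)
  }
  for (v in names(values)) {
    m <- values[[v]]
    if (!is.matrix(m) || nrow(m) != length(tract_ids) || ncol(m) != length(dates)) {
      stop(sprintf("values$%s must be a %d x %d matrix", v,
                   length(tract_ids), length(dates)), call. = FALSE)
    }
  }
  rownames(centroids) <- tract_ids
  structure(list(tract_ids = tract_ids, centroids = centroids,
                 dates = dates, values = values),
            class = "tract_series")
}

#' @export
print.tract_series <- function(x, ...) {
  cat(sprintf("<tract_series> %d tracts, %d days (%s .. %s), variables: %s\n",
              length(x$tract_ids), length(x$dates),
              format(min(x$dates)), format(max(x$dates)),
              paste(names(x$values), collapse = ", ")))
  invisible(x)
}

series_variables <- function(x) names(x$values)

# matrix lookup with checks
series_matrix <- function(x, variable) {
  if (!variable %in% names(x$values)) {
    stop(sprintf("variable '%s' not in series (has: %s)", variable,
                 paste(names(x$values), collapse = ", ")), call. = FALSE)
  }
  x$values[[variable]]
}

#' Convert a tract series to a long data frame
#'
#' @param x a `tract_series`.
#' @param row.names,optional unused, for generic compatibility.
#' @param ... unused.
#' @return data.frame with columns tract_id, date, variable, value.
#' @export
as.data.frame.tract_series <- function(x, row.names = NULL, optional = FALSE, ...) {
  nt <- length(x$tract_ids); nd <- length(x$dates)
  out <- do.call(rbind, lapply(names(x$values), function(v) {
    data.frame(tract_id = rep(x$tract_ids, times = nd),
               date = rep(x$dates, each = nt),
               variable = v,
               value = as.vector(x$values[[v]]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write / read a tract series as long-format CSV
#'
#' Long format: one row per (tract, date, variable) with columns
#' `tract_id, date, variable, value`; dates ISO-8601.  Centroids are stored in
#' a companion `<path>.centroids.csv`.
#'
#' @param x a `tract_series`.
#' @param path CSV file path.
#' @return `write_tract_series()` returns `path` invisibly;
#'   `read_tract_series()` returns a `tract_series`.
#' @export
write_tract_series <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  cent <- data.frame(tract_id = x$tract_ids,
                     x = x$centroids[, 1], y = x$centroids[, 2])
  write.csv(cent, paste0(path, ".centroids.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_tract_series
#' @export
read_tract_series <- function(path) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  cent <- read.csv(paste0(path, ".centroids.csv"), stringsAsFactors = FALSE)
  tract_ids <- cent$tract_id
  dates <- sort(unique(as.Date(long$date)))
  vars <- unique(long$variable)
  ti <- match(long$tract_id, tract_ids)
  di <- match(as.Date(long$date), dates)
  values <- lapply(setNames(vars, vars), function(v) {
    m <- matrix(NA_real_, length(tract_ids), length(dates))
    sel <- long$variable == v
    m[cbind(ti[sel], di[sel])] <- long$value[sel]
    m
  })
  tract_series(tract_ids, as.matrix(cent[, c("x", "y")]), dates, values)
}
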