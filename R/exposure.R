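# Exposure operations: grid-to-tract interpolation and derived quantities.

#' Inverse-distance-weighted interpolation of a grid field to tract centroids
#'
#' For each tract and day the interpolated value is the weighted mean of the
#' `k` nearest grid points carrying finite values that day, with weights
#' d^(-power).  A centroid coinciding with a grid point receives that point's
#' value exactly.  Days on which all `k` usable neighbours are missing yield
#' `NA` (flagged missing, never zero).  Output is a convex combination of the
#' contributing grid values, so it is bounded by their range.
#'
#' @param field a [grid_field()].
#' @param centroids numeric matrix (x, y), one row per tract; rownames (if
#'   present) become tract ids.
#' @param power positive IDW exponent; default 2, the conventional choice.
#' @param k number of nearest neighbours; default 4.
#' @param tract_ids optional character ids, overriding rownames.
#' @return a [tract_series()] with the field's pollutants.
#' @export
idw_interpolate <- function(field, centroids, power = 2, k = 4, tract_ids = NULL) {
  stopifnot(inherits(field, "grid_field"))
  if (!is.numeric(power) || length(power) != 1L || power <= 0) {
    stop("`power` must be a positive number", call. = FALSE)
  }
  centroids <- as.matrix(centroids)
  if (ncol(centroids) != 2L) stop("`centroids` must have two columns", call. = FALSE)
  npts <- nrow(field$points)
  k <- min(as.integer(k), npts)
  if (k < 1L) stop("`k` must be at least 1", call. = FALSE)
  if (is.null(tract_ids)) {
    tract_ids <- rownames(centroids)
    if (is.null(tract_ids)) tract_ids <- sprintf("t%04d", seq_len(nrow(centroids)))
  }

  # tract x point squared distances
  d2 <- outer(rowSums(centroids^2), rep(1, npts)) +
    outer(rep(1, nrow(centroids)), rowSums(field$points^2)) -
    2 * centroids %*% t(field$points)
  d2[d2 < 0] <- 0  # numerical noise
  dist <- sqrt(d2)

  # k nearest points per tract (by distance, ties by index)
  ord <- t(apply(dist, 1L, order))[, seq_len(k), drop = FALSE]
  nd <- length(field$dates)
  nt <- nrow(centroids)
  zero_tol <- 1e-9

  values <- lapply(field$values, function(vm) {
    any_missing_day <- colSums(is.na(vm)) > 0L
    out <- matrix(NA_real_, nt, nd)
    # neighbour value/weight matrices for the common complete-day path
    wmat <- matrix(0, nt, k)
    for (j in seq_len(k)) {
      dj <- dist[cbind(seq_len(nt), ord[, j])]
      wmat[, j] <- ifelse(dj < zero_tol, Inf, dj^(-power))
    }
    exact <- which(is.infinite(wmat[, 1L]))  # centroid on a grid point
    for (day in seq_len(nd)) {
      v <- vm[, day]
      if (!any_missing_day[day]) {
        vn <- matrix(v[ord], nt, k)
        if (length(exact)) {
          out[exact, day] <- vn[exact, 1L]
          rest <- setdiff(seq_len(nt), exact)
        } else rest <- seq_len(nt)
        if (length(rest)) {
          out[rest, day] <- rowSums(wmat[rest, , drop = FALSE] * vn[rest, , drop = FALSE]) /
            rowSums(wmat[rest, , drop = FALSE])
        }
      } else {
        ok <- which(is.finite(v))
        if (!length(ok)) next  # whole day flagged missing
        for (i in seq_len(nt)) {
          di <- dist[i, ok]
          sel <- ok[order(di)[seq_len(min(k, length(ok)))]]
          dsel <- dist[i, sel]
          if (dsel[1L] < zero_tol) { out[i, day] <- v[sel[1L]]; next }
          w <- dsel^(-power)
          out[i, day] <- sum(w * v[sel]) / sum(w)
        }
      }
    }
    out
  })

  tract_series(tract_ids, centroids, field$dates, values)
}

#' Coarse particulate fraction PM10-2.5
#'
#' Elementwise PM10 minus PM2.5.  Independent estimation error in the two
#' parent series can make the difference negative; a mass fraction is
#' physically nonnegative, so negative results are clamped to 0 and counted
#' in the `n_clamped` attribute.
#'
#' @param pm10,pm25 aligned numeric vectors or matrices (same dimensions and,
#'   when matrices with dimnames, the same dimnames).
#' @return object shaped like `pm10` with attribute `n_clamped`.
#' @export
coarse_fraction <- function(pm10, pm25) {
  if (!identical(dim(pm10), dim(pm25)) || length(pm10) != length(pm25)) {
    stop("pm10 and pm25 are not aligned", call. = FALSE)
  }
  dn10 <- dimnames(pm10); dn25 <- dimnames(pm25)
  if (!is.null(dn10) && !is.null(dn25) && !identical(dn10, dn25)) {
    stop("pm10 and pm25 indices do not match", call. = FALSE)
  }
  out <- pm10 - pm25
  neg <- which(out < 0)
  out[neg] <- 0
  attr(out, "n_clamped") <- length(neg)
  out
}

#' 3-day moving average over lags 0, 1, 2
#'
#' The mean of the values on the target date, one day prior, and two days
#' prior.  If any of the three days is absent from the series or carries a
#' missing value, the window is unusable and `NA` is returned so the caller
#' can drop it.
#'
#' @param values numeric vector of daily values.
#' @param dates Date vector aligned with `values`.
#' @param target_date the window's centre (lag-0) date.
#' @return the 3-day mean, or `NA_real_` when the window is incomplete.
#' @examples
#' d <- as.Date("2010-01-01") + 0:4
#' moving_average_3day(c(1, 2, 3, 4, 5), d, as.Date("2010-01-03"))  # 2
#' @export
moving_average_3day <- function(values, dates, target_date) {
  dates <- as_date_strict(dates)
  target_date <- as_date_strict(target_date, "target date")
  idx <- match(target_date - 0:2, dates)
  if (anyNA(idx)) return(NA_real_)
  v <- values[idx]
  if (anyNA(v)) return(NA_real_)
  mean(v)
}

# 3DMA across a tract x day matrix: column d becomes mean of columns d, d-1,
# d-2; first two columns (and any window touching an NA) are NA.
tdma_matrix <- function(m) {
  nd <- ncol(m)
  out <- matrix(NA_real_, nrow(m), nd)
  if (nd >= 3L) {
    out[, 3:nd] <- (m[, 3:nd, drop = FALSE] +
                    m[, 2:(nd - 1L), drop = FALSE] +
                    m[, 1:(nd - 2L), drop = FALSE]) / 3
  }
  out
}

#' Apply the 3-day moving average to every variable of a tract series
#'
#' @param series a [tract_series()].
#' @param variables variables to transform (default all).
#' @return a [tract_series()] of 3DMAs; the first two days are `NA`.
#' @export
rolling_3dma <- function(series, variables = series_variables(series)) {
  stopifnot(inherits(series, "tract_series"))
  vals <- lapply(setNames(variables, variables), function(v) {
    tdma_matrix(series_matrix(series, v))
  })
  tract_series(series$tract_ids, series$centroids, series$dates, vals)
}

#' Season-stratified Spearman correlations of day-of-year collapsed series
#'
#' Each variable is first averaged across tracts for every day, then collapsed
#' over the study period by day of the year (365 bins; February 29 shares the
#' February 28 bin).  The bins falling in the requested season are retained
#' and Spearman rank correlations are computed for every pair of variables.
#' Rank correlation makes the matrix invariant to strictly monotone transforms
#' of any variable.
#'
#' @param series a [tract_series()].
#' @param season one of "winter", "spring", "summer", "fall", or "all".
#' @param variables variables to include (default all).
#' @return symmetric correlation matrix with unit diagonal; entries involving
#'   a constant collapsed series are `NA`.
#' @export
seasonal_spearman <- function(series, season = "all",
                              variables = series_variables(series)) {
  stopifnot(inherits(series, "tract_series"))
  season <- match.arg(season, c("all", season_levels()))
  doy <- day_of_year_365(series$dates)
  if (season != "all") {
    keep_doy <- sort(unique(doy[assign_season(series$dates) == season]))
  } else keep_doy <- sort(unique(doy))
  if (length(keep_doy) < 3L) stop("fewer than 3 distinct days in season", call. = FALSE)

  collapsed <- sapply(variables, function(v) {
    daily <- colMeans(series_matrix(series, v), na.rm = TRUE)  # across tracts
    byd <- tapply(daily, doy, mean, na.rm = TRUE)              # across years
    as.numeric(byd[as.character(keep_doy)])
  })
  cm <- suppressWarnings(
    cor(collapsed, method = "spearman", use = "pairwise.complete.obs"))
  diag(cm) <- 1  # constant series leave NA off-diagonal (undefined pairs)
  dimnames(cm) <- list(variables, variables)
  cm
}

#' Write a correlation matrix as square CSV with variable-name headers
#'
#' @param m square correlation matrix.
#' @param path CSV file path.
#' @export
write_correlation_csv <- function(m, path) {
  write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}
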