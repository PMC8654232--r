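# Case-crossover dataset construction: one case window (y = 1) per visit plus
# up to three matched referent windows (y = 0), 3DMA covariates at the visit's
# tract, a shared year-month-weekday stratum index, centering, and a pairwise
# collinearity screen.

default_covariates <- function(series) {
  intersect(c("nox", "o3", "so2", "pm25", "pm10_25", "co", "temp", "dewp"),
            series_variables(series))
}

#' Build the time-stratified case-crossover row table
#'
#' For every visit, the case window is the 3-day moving average (lags 0-2)
#' of each covariate at the visit's tract centred on the admittance date;
#' referent windows are the 3DMAs centred on up to three dates drawn from the
#' same year, month and day of week ([select_referents()]).  Rows whose 3DMA
#' window is incomplete are dropped: a missing case window drops the whole
#' visit, a missing referent window drops that row only (both counted in
#' attributes).  All rows of a visit share the case date's stratum index and
#' season label.
#'
#' @param visits data.frame with visit_id, date, tract_id (e.g. from
#'   [generate_visits()]); demographic columns are carried through row-wise
#'   lookups are not needed here.
#' @param exposures a [tract_series()] covering all required lag days.
#' @param covariates variables to extract as covariates (default: the
#'   conventional pollutant/weather set present in `exposures`).
#' @param seed integer seed for referent sampling (stored in the result).
#' @return data.frame of class `cco_rows` with columns visit_id, j (window
#'   index, 1 = case), y, window_date, stratum, season and one column per
#'   covariate; attributes `covariates`, `seed`, `study_years`,
#'   `n_dropped_visits`, `n_dropped_referent_rows`.
#' @export
build_rows <- function(visits, exposures, covariates = default_covariates(exposures),
                       seed = 1L) {
  stopifnot(inherits(exposures, "tract_series"))
  if (!all(c("visit_id", "date", "tract_id") %in% names(visits))) {
    stop("`visits` needs visit_id, date and tract_id columns", call. = FALSE)
  }
  if (nrow(visits) == 0L) stop("no visits supplied", call. = FALSE)
  visits$date <- as_date_strict(visits$date, "admittance date")
  if (!all(visits$tract_id %in% exposures$tract_ids)) {
    stop("some visit tracts are absent from the exposure series", call. = FALSE)
  }
  dates <- exposures$dates
  study_years <- sort(unique(date_year(dates)))

  # referent dates: precompute candidates per unique case date, then draw
  set.seed(seed)
  ucd <- sort(unique(visits$date))
  cand_by_date <- lapply(ucd, referent_candidates)
  names(cand_by_date) <- format(ucd)
  n <- nrow(visits)
  ref_list <- vector("list", n)
  ci <- match(format(visits$date), names(cand_by_date))
  for (i in seq_len(n)) {
    cand <- cand_by_date[[ci[i]]]
    ref_list[[i]] <- if (length(cand) > 3L) sort(cand[sample.int(length(cand), 3L)])
                     else cand
  }

  n_ref <- lengths(ref_list)
  vrep <- rep(seq_len(n), n_ref + 1L)
  j <- unlist(lapply(n_ref, function(k) seq_len(k + 1L)), use.names = FALSE)
  window_date <- as.Date(unlist(lapply(seq_len(n), function(i) {
    c(visits$date[i], ref_list[[i]])
  }), use.names = FALSE), origin = "1970-01-01")
  y <- as.integer(j == 1L)

  tract_i <- match(visits$tract_id, exposures$tract_ids)[vrep]
  day_i <- match(window_date, dates)

  X <- matrix(NA_real_, length(vrep), length(covariates),
              dimnames = list(NULL, covariates))
  in_range <- !is.na(day_i)
  for (v in covariates) {
    tm <- tdma_matrix(series_matrix(exposures, v))
    X[in_range, v] <- tm[cbind(tract_i[in_range], day_i[in_range])]
  }

  bad <- !in_range | rowSums(is.na(X)) > 0L
  bad_visit <- unique(vrep[bad & y == 1L])        # case window unusable
  drop_row <- bad | vrep %in% bad_visit
  n_dropped_visits <- length(bad_visit)
  n_dropped_ref <- sum(bad & y == 0L & !(vrep %in% bad_visit))

  keep <- !drop_row
  out <- data.frame(visit_id = visits$visit_id[vrep[keep]],
                    j = j[keep], y = y[keep],
                    window_date = window_date[keep],
                    stringsAsFactors = FALSE)
  case_date <- visits$date[vrep[keep]]
  out$stratum <- stratum_index(case_date, study_years = study_years)
  out$season <- assign_season(case_date)
  out <- cbind(out, as.data.frame(X[keep, , drop = FALSE]))
  rownames(out) <- NULL

  structure(out,
            covariates = covariates, seed = seed, study_years = study_years,
            n_dropped_visits = n_dropped_visits,
            n_dropped_referent_rows = n_dropped_ref,
            class = c("cco_rows", "data.frame"))
}

#' Subset case-crossover rows to one season, preserving attributes
#'
#' @param rows a `cco_rows` table from [build_rows()].
#' @param season season name ("winter", "spring", "summer", "fall").
#' @return `cco_rows` restricted to visits whose case day falls in `season`.
#' @export
season_rows <- function(rows, season) {
  season <- match.arg(season, season_levels())
  keep_attrs <- attributes(rows)[c("covariates", "seed", "study_years",
                                   "n_dropped_visits", "n_dropped_referent_rows")]
  out <- rows[rows$season == season, , drop = FALSE]
  rownames(out) <- NULL
  for (a in names(keep_attrs)) attr(out, a) <- keep_attrs[[a]]
  class(out) <- c("cco_rows", "data.frame")
  out
}

#' Mean-centre covariates and form the temperature-dewpoint interaction
#'
#' Each covariate column is reduced by its mean over all supplied rows (pass
#' the full table for an overall model, a [season_rows()] subset for a
#' seasonal model).  When both temperature and dewpoint are present, the
#' interaction column `temp_dewp` is the product of the centred main effects,
#' itself centred.  All means are stored in the `centering_means` attribute
#' for back-transformation.  The operation is idempotent.
#'
#' @param rows a `cco_rows` table.
#' @param covariates columns to centre (default: the table's covariate set).
#' @return the table with centred covariates (and `temp_dewp` when
#'   applicable) plus attribute `centering_means`.
#' @export
center_covariates <- function(rows, covariates = attr(rows, "covariates")) {
  if (nrow(rows) == 0L) stop("empty row table", call. = FALSE)
  means <- numeric(0)
  for (v in covariates) {
    mu <- mean(rows[[v]])
    rows[[v]] <- rows[[v]] - mu
    means[v] <- mu
  }
  if (all(c("temp", "dewp") %in% covariates)) {
    inter <- rows$temp * rows$dewp
    mu_i <- mean(inter)
    rows$temp_dewp <- inter - mu_i
    means["temp_dewp"] <- mu_i
  }
  attr(rows, "centering_means") <- means
  rows
}

#' Pairwise collinearity screen with a fixed drop-priority list
#'
#' Iteratively removes covariates until no retained pair has absolute Pearson
#' correlation above `threshold`.  At each step the most correlated offending
#' pair is examined: if one (or both) of its members is on the drop-priority
#' list, that member is removed first (mirroring the conventional removals
#' CO before NOx, dewpoint before temperature, SO2 before NOx); otherwise the
#' member with the larger variance inflation factor is removed.
#'
#' @param rows a `cco_rows` table (or any data.frame with the columns).
#' @param covariates candidate covariates (default: the table's covariate
#'   set; the temperature-dewpoint interaction is never screened).
#' @param threshold pairwise absolute-correlation limit, default 0.9.
#' @param priority covariates to drop first when implicated, in order.
#' @return list with `retained` (character), `removed` (character) and
#'   `log` (data.frame: step, dropped, against, r).
#' @export
collinearity_screen <- function(rows, covariates = attr(rows, "covariates"),
                                threshold = 0.9,
                                priority = c("co", "dewp", "so2")) {
  covariates <- setdiff(covariates, "temp_dewp")
  if (length(covariates) < 2L) stop("need at least two covariates", call. = FALSE)
  X <- as.matrix(rows[, covariates, drop = FALSE])
  retained <- covariates
  removed <- character(0)
  log <- data.frame(step = integer(), dropped = character(),
                    against = character(), r = numeric(),
                    stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    if (length(retained) < 2L) {
      warning("all covariates mutually collinear; retaining one")
      break
    }
    cm <- suppressWarnings(cor(X[, retained, drop = FALSE]))
    cm[is.na(cm)] <- 0
    diag(cm) <- 0
    mx <- max(abs(cm))
    if (mx <= threshold) break
    idx <- which(abs(cm) == mx, arr.ind = TRUE)[1L, ]
    pair <- retained[idx]
    in_prio <- pair %in% priority
    drop_var <- if (sum(in_prio) == 1L) {
      pair[in_prio]
    } else if (sum(in_prio) == 2L) {
      pair[which.min(match(pair, priority))]
    } else {
      vifs <- vapply(pair, function(v) vif_of(X, v, retained), numeric(1))
      pair[which.max(vifs)]
    }
    step <- step + 1L
    log <- rbind(log, data.frame(step = step, dropped = drop_var,
                                 against = setdiff(pair, drop_var)[1L],
                                 r = mx, stringsAsFactors = FALSE))
    retained <- setdiff(retained, drop_var)
    removed <- c(removed, drop_var)
  }
  list(retained = retained, removed = removed, log = log)
}

# VIF of `v` given the other retained covariates: 1 / (1 - R^2)
vif_of <- function(X, v, retained) {
  others <- setdiff(retained, v)
  if (!length(others)) return(1)
  yv <- X[, v]
  fit <- stats::lm.fit(cbind(1, X[, others, drop = FALSE]), yv)
  r2 <- 1 - sum(fit$residuals^2) / sum((yv - mean(yv))^2)
  r2 <- min(r2, 1 - 1e-12)
  1 / (1 - r2)
}

#' Write a case-crossover table with a JSON sidecar
#'
#' The CSV holds the rows; the sidecar (`<path>.json`) stores the centering
#' means, the covariate list, the referent-selection seed and the drop
#' counts.
#'
#' @param rows a `cco_rows` table.
#' @param path CSV file path.
#' @export
write_rows <- function(rows, path) {
  write.csv(as.data.frame(rows), path, row.names = FALSE)
  side <- list(covariates = attr(rows, "covariates"),
               seed = attr(rows, "seed"),
               study_years = attr(rows, "study_years"),
               n_dropped_visits = attr(rows, "n_dropped_visits"),
               n_dropped_referent_rows = attr(rows, "n_dropped_referent_rows"),
               centering_means = as.list(attr(rows, "centering_means")))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
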