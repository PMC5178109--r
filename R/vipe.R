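# Age-stratified vital-sign (VIPE) scoring engine.
#
# All numeric thresholds live in a JSON configuration (the bundled default
# reproduces the published table); this file only contains lookup mechanics.

.clariped_env <- new.env(parent = emptyenv())

round_half_up <- function(x) {
  # round half away from zero; measurements are non-negative
  sign(x) * floor(abs(x) + 0.5)
}

#' Load and normalize a VIPE threshold table set
#'
#' Reads the JSON configuration holding the age strata, the per-stratum score
#' bands for respiratory rate (RR), heart rate (HR) and SpO2, the fever
#' correction rule for elevated heart rate, the score-to-color legend and the
#' waiting-time/destination policy. Bands are normalized to closed integer
#' intervals with infinite open ends, then validated: within each
#' (stratum, parameter) the bands must jointly cover the whole measurement
#' axis; overlapping bands are permitted but flagged with a warning (the
#' bundled table contains one printed overlap in the 5-12 y heart-rate row,
#' resolved at lookup time by taking the higher sub-score).
#'
#' @param path Path to the JSON table file. Defaults to the bundled tables.
#' @return An object of class `vipe_tables`: list with elements `strata`
#'   (data.frame), `bands` (nested list of data.frames with columns lo, hi,
#'   score), `temp_correction`, `color_map`, `policy`, `version`, and
#'   `warnings` (character vector of validation flags).
#' @export
load_vipe_tables <- function(path = NULL) {
  default <- is.null(path)
  if (default) {
    cached <- .clariped_env$default_tables
    if (!is.null(cached)) return(cached)
    path <- system.file("extdata", "vipe_tables.json", package = "clariped")
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)

  strata <- do.call(rbind, lapply(raw$strata, function(s) {
    data.frame(
      id = s$id, label = s$label,
      lower_days = s$lower_days,
      upper_days = if (is.null(s$upper_days)) Inf else s$upper_days,
      stringsAsFactors = FALSE
    )
  }))
  if (strata$lower_days[1] != 0) stop("strata must start at age 0 days", call. = FALSE)
  if (nrow(strata) > 1) {
    for (i in 2:nrow(strata)) {
      if (strata$lower_days[i] != strata$upper_days[i - 1] + 1) {
        stop("age strata must be disjoint and contiguous", call. = FALSE)
      }
    }
  }
  if (is.finite(strata$upper_days[nrow(strata)])) {
    stop("last age stratum must be unbounded", call. = FALSE)
  }

  warnings <- character(0)
  domain_hi <- c(RR = 250, HR = 250, SPO2 = 100)
  bands <- lapply(raw$bands, function(stratum_bands) {
    lapply(stratum_bands, function(b) {
      m <- do.call(rbind, lapply(b, function(row) {
        lo <- if (is.null(row[[1]])) -Inf else row[[1]]
        hi <- if (is.null(row[[2]])) Inf else row[[2]]
        c(lo, hi, row[[3]])
      }))
      df <- data.frame(lo = m[, 1], hi = m[, 2], score = as.integer(m[, 3]))
      if (any(df$lo > df$hi)) stop("band with lo > hi", call. = FALSE)
      if (!all(df$score %in% 0:4)) stop("sub-scores must be 0..4", call. = FALSE)
      df
    })
  })
  names(bands) <- names(raw$bands)
  if (!setequal(names(bands), strata$id)) {
    stop("bands must be given for every stratum", call. = FALSE)
  }

  for (sid in names(bands)) {
    for (par in names(bands[[sid]])) {
      df <- bands[[sid]][[par]]
      grid <- 0:domain_hi[[par]]
      nhit <- vapply(grid, function(v) sum(v >= df$lo & v <= df$hi), integer(1))
      if (any(nhit == 0)) {
        stop(sprintf("coverage gap in %s/%s at value %d", sid, par, grid[which(nhit == 0)[1]]),
             call. = FALSE)
      }
      if (any(nhit > 1)) {
        warnings <- c(warnings, sprintf(
          "overlapping bands in %s/%s at value(s) %s; resolved to the higher sub-score",
          sid, par, paste(grid[nhit > 1], collapse = ",")))
      }
      # band shape: exactly one central 0 band, sub-scores non-decreasing
      # moving away from it on each side (SpO2 only has a low side)
      z <- which(df$score == 0)
      if (length(z) != 1 ||
          is.unsorted(rev(df$score[seq_len(z)])) ||
          (z < nrow(df) && is.unsorted(df$score[z:nrow(df)]))) {
        stop(sprintf("malformed band shape in %s/%s", sid, par), call. = FALSE)
      }
    }
  }

  out <- list(
    version = raw$version,
    strata = strata,
    bands = bands,
    temp_correction = raw$temp_correction,
    color_map = do.call(rbind, lapply(raw$color_map, function(r) {
      data.frame(lo = r$lo, hi = r$hi, level = r$level, stringsAsFactors = FALSE)
    })),
    policy = raw$policy,
    warnings = warnings
  )
  class(out) <- "vipe_tables"
  for (w in warnings) warning(w, call. = FALSE)
  if (default) .clariped_env$default_tables <- out
  out
}

#' @export
print.vipe_tables <- function(x, ...) {
  cat("VIPE threshold tables, version", x$version, "\n")
  cat(nrow(x$strata), "age strata;",
      sum(lengths(x$bands)), "parameter band tables;",
      length(x$warnings), "validation flag(s)\n")
  invisible(x)
}

#' Assign an age stratum
#'
#' Maps an age in days to the unique age stratum of the threshold tables.
#' The default strata are newborn to 2 months, 3-11 months, 1-4 years,
#' 5-12 years and over 12 years, with day boundaries at 91, 365, 1826 and
#' 4749 days (1 month = 30.4375 days, 1 year = 365.25 days).
#'
#' @param age_days Non-negative integer age(s) in days.
#' @inheritParams color_from_total
#' @return Character vector of stratum ids.
#' @export
#' @examples
#' assign_stratum(c(10, 200, 800))
assign_stratum <- function(age_days, tables = load_vipe_tables()) {
  if (any(is.na(age_days)) || any(age_days < 0)) {
    stop("age_days must be non-negative", call. = FALSE)
  }
  s <- tables$strata
  idx <- vapply(age_days, function(a) {
    which(a >= s$lower_days & a <= s$upper_days)[1]
  }, integer(1))
  s$id[idx]
}

#' Score one vital-sign parameter
#'
#' Rounds the measured value half away from zero to the integer grid and
#' returns the sub-score of the band containing it. If the printed table
#' makes a value claimable by two bands (one known overlap exists in the
#' default tables), the higher -- more urgent -- sub-score wins.
#'
#' @param value Measured value (breaths/min, beats/min, or percent).
#' @param parameter One of `"RR"`, `"HR"`, `"SPO2"`.
#' @param stratum Stratum id, e.g. from [assign_stratum()].
#' @inheritParams color_from_total
#' @return Integer sub-score in 0..4.
#' @export
#' @examples
#' score_parameter(40, "RR", "NB_2MO")
score_parameter <- function(value, parameter, stratum, tables = load_vipe_tables()) {
  parameter <- toupper(parameter)
  if (!parameter %in% c("RR", "HR", "SPO2")) stop("unknown parameter", call. = FALSE)
  df <- tables$bands[[stratum]][[parameter]]
  if (is.null(df)) stop("unknown stratum: ", stratum, call. = FALSE)
  if (is.na(value) || value < 0) stop("value must be non-negative", call. = FALSE)
  if (parameter == "SPO2" && value > 100) stop("spo2 must be <= 100", call. = FALSE)
  v <- round_half_up(value)
  hits <- df$score[v >= df$lo & v <= df$hi]
  if (length(hits) == 0) {
    stop(sprintf("table configuration error: no band for %s=%s in %s", parameter, v, stratum),
         call. = FALSE)
  }
  as.integer(max(hits))
}

#' Fever correction of the VIPE total
#'
#' When the heart rate is increased (HR sub-score 2, 3 or 4), 1 point is
#' subtracted from the total for an axillary temperature between 37.5 and
#' 38.5 C (both ends inclusive) and 2 points above 38.5 C. No correction is
#' applied when the heart rate is not elevated.
#'
#' @param axtemp Axillary temperature in degrees Celsius.
#' @param hr_score Heart-rate sub-score, integer 0..4.
#' @inheritParams color_from_total
#' @return Integer correction in \{0, -1, -2\}.
#' @export
#' @examples
#' temperature_correction(39.0, 3)   # -2
#' temperature_correction(39.0, 0)   # 0
temperature_correction <- function(axtemp, hr_score, tables = load_vipe_tables()) {
  if (is.na(hr_score) || !hr_score %in% 0:4) stop("hr_score must be in 0..4", call. = FALSE)
  if (is.na(axtemp)) stop("axtemp is missing", call. = FALSE)
  if (axtemp < 30 || axtemp > 43) {
    warning("axillary temperature outside physiologic range 30-43 C: ", axtemp, call. = FALSE)
  }
  tc <- tables$temp_correction
  if (hr_score < tc$hr_score_min) return(0L)
  if (axtemp > tc$minus2_excl_lo) return(-2L)
  if (axtemp >= tc$minus1_lo) return(-1L)
  0L
}

#' Compute the VIPE score and urgency color
#'
#' First classification step: the vital-sign score. Each of RR, HR and SpO2
#' is scored 0-4 against the age stratum's bands; the total is the sum of
#' the three sub-scores plus the fever correction of an elevated heart rate,
#' clamped at zero. The total (0-12) maps to a color through the legend
#' (0 BLUE, 1-2 GREEN, 3-5 YELLOW, 6-9 ORANGE, >=10 RED).
#'
#' @param vitals Named list or vector with elements `rr`, `hr`, `spo2`,
#'   `axtemp` (all four required).
#' @param age_days Non-negative integer age in days.
#' @inheritParams color_from_total
#' @return Object of class `vipe_result`: list with `stratum`, `rr_score`,
#'   `hr_score`, `spo2_score`, `temp_correction`, `total`, `color`.
#' @export
#' @examples
#' vipe_score(list(rr = 40, hr = 120, spo2 = 97, axtemp = 36.5), age_days = 10)
vipe_score <- function(vitals, age_days, tables = load_vipe_tables()) {
  vitals <- as.list(vitals)
  for (f in c("rr", "hr", "spo2", "axtemp")) {
    if (is.null(vitals[[f]]) || is.na(vitals[[f]])) {
      stop("incomplete measurement: vital sign '", f, "' is missing", call. = FALSE)
    }
  }
  stratum <- assign_stratum(age_days, tables)
  rr_score <- score_parameter(vitals$rr, "RR", stratum, tables)
  hr_score <- score_parameter(vitals$hr, "HR", stratum, tables)
  spo2_score <- score_parameter(vitals$spo2, "SPO2", stratum, tables)
  corr <- temperature_correction(vitals$axtemp, hr_score, tables)
  total <- max(0L, rr_score + hr_score + spo2_score + corr)
  out <- list(
    stratum = stratum,
    rr_score = rr_score, hr_score = hr_score, spo2_score = spo2_score,
    temp_correction = corr,
    total = as.integer(total),
    color = color_from_total(total, tables)
  )
  class(out) <- "vipe_result"
  out
}

#' @export
print.vipe_result <- function(x, ...) {
  cat(sprintf("VIPE %d (%s): RR %d + HR %d + SpO2 %d, fever correction %d [stratum %s]\n",
              x$total, x$color, x$rr_score, x$hr_score, x$spo2_score,
              x$temp_correction, x$stratum))
  invisible(x)
}

#' Enumerate attainable VIPE totals
#'
#' Exhaustively enumerates one representative measurement per score band for
#' RR, HR and SpO2 in every age stratum, crossed with the three fever
#' correction regimes (no fever, 37.5-38.5 C, above 38.5 C), scores each
#' combination through [vipe_score()] and returns all attained totals. Used
#' to verify that the attainable score range is exactly 0..12.
#'
#' @inheritParams color_from_total
#' @return data.frame with one row per enumerated combination: `stratum`,
#'   `rr`, `hr`, `spo2`, `axtemp`, `total`, `color`.
#' @export
enumerate_vipe_totals <- function(tables = load_vipe_tables()) {
  band_reps <- function(df, hi_cap) {
    vapply(seq_len(nrow(df)), function(i) {
      lo <- max(df$lo[i], 0)
      hi <- min(df$hi[i], hi_cap)
      floor((lo + hi) / 2)
    }, numeric(1))
  }
  temps <- c(36.5, 38.0, 39.0)  # correction 0 / -1 / -2 when HR elevated
  rows <- list()
  for (sid in names(tables$bands)) {
    age <- tables$strata$lower_days[tables$strata$id == sid]
    rr_vals <- band_reps(tables$bands[[sid]]$RR, 250)
    hr_vals <- band_reps(tables$bands[[sid]]$HR, 250)
    sp_vals <- band_reps(tables$bands[[sid]]$SPO2, 100)
    grid <- expand.grid(rr = rr_vals, hr = hr_vals, spo2 = sp_vals, axtemp = temps)
    res <- lapply(seq_len(nrow(grid)), function(i) {
      v <- vipe_score(grid[i, ], age, tables)
      cbind(stratum = sid, grid[i, ], total = v$total, color = v$color)
    })
    rows[[sid]] <- do.call(rbind, res)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
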