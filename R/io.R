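# CSV readers/writers and the frozen encounter schema.

#' Encounter CSV schema
#'
#' The frozen column set of the encounter CSV dialect. Units: ages in days,
#' RR in breaths/min, HR in beats/min, SpO2 in percent, temperatures in
#' degrees Celsius, CBG in mg/dL, BP in mmHg, injury age in hours. `findings`
#' holds semicolon-separated finding codes from the catalog vocabulary.
#'
#' @return data.frame with columns `column`, `type`, `required`.
#' @export
encounter_schema <- function() {
  data.frame(
    column = c("id", "age_days", "rr", "hr", "spo2", "axtemp_c",
               "pain_level", "general_appearance", "fever_report_max_c",
               "returns_24h", "returns_72h", "findings", "cbg_mg_dl",
               "bp_systolic", "bp_diastolic", "injury_age_hours",
               "burn_category", "resource_count"),
    type = c("character", "integer", "numeric", "numeric", "numeric",
             "numeric", "integer", "character", "numeric", "integer",
             "integer", "character", "numeric", "numeric", "numeric",
             "numeric", "character", "integer"),
    required = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                 FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                 FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

# one data.frame row -> encounter list (findings split, vitals aliased)
row_to_encounter <- function(row) {
  enc <- as.list(row)
  enc <- lapply(enc, function(x) if (length(x) == 1 && is.na(x)) NA else x)
  enc$axtemp <- enc$axtemp_c %||% enc$axtemp
  f <- enc$findings
  enc$findings <- if (is.null(f) || length(f) == 0 || is.na(f) || !nzchar(f)) {
    character(0)
  } else {
    strsplit(as.character(f), ";", fixed = TRUE)[[1]]
  }
  # drop genuinely absent optional scalars so guards see them as missing
  for (nm in names(enc)) {
    if (nm != "findings" && length(enc[[nm]]) == 1 && is.na(enc[[nm]])) enc[[nm]] <- NULL
  }
  enc
}

#' Read an encounter CSV
#'
#' Parses and validates an encounter file against [encounter_schema()].
#' Rows violating field invariants (SpO2 above 100, pain outside 0-10,
#' negative ages or counts, unknown appearance or finding codes) are rejected
#' into an error report; valid rows are returned as a data.frame.
#'
#' @param path CSV file path.
#' @param catalog Catalog used to validate finding codes.
#' @return List with `encounters` (data.frame of valid rows) and `errors`
#'   (data.frame: `row`, `message`).
#' @export
read_encounters <- function(path, catalog = load_catalog()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  schema <- encounter_schema()
  req <- schema$column[schema$required]
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in setdiff(schema$column, names(df))) df[[col]] <- NA
  df <- df[, schema$column]

  errs <- list()
  ok <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    msgs <- character(0)
    r <- df[i, ]
    chk <- function(cond, msg) if (isTRUE(cond)) msgs <<- c(msgs, msg)
    chk(is.na(r$age_days) || r$age_days < 0, "age_days missing or negative")
    for (v in c("rr", "hr", "spo2", "axtemp_c")) {
      chk(is.na(r[[v]]), paste0("missing vital '", v, "'"))
    }
    chk(!is.na(r$spo2) && (r$spo2 < 0 || r$spo2 > 100), "spo2 outside 0-100")
    chk(!is.na(r$rr) && r$rr < 0, "rr negative")
    chk(!is.na(r$hr) && r$hr < 0, "hr negative")
    chk(is.na(r$pain_level) || r$pain_level < 0 || r$pain_level > 10,
        "pain_level missing or outside 0-10")
    chk(is.na(r$general_appearance) ||
          !r$general_appearance %in% c("critical", "very_ill", "ill", "little_ill", "well"),
        "general_appearance missing or unknown")
    for (v in c("returns_24h", "returns_72h", "resource_count")) {
      chk(!is.na(r[[v]]) && r[[v]] < 0, paste0(v, " negative"))
    }
    if (!is.na(r$findings) && nzchar(r$findings)) {
      codes <- strsplit(as.character(r$findings), ";", fixed = TRUE)[[1]]
      bad <- setdiff(codes, catalog$vocabulary)
      chk(length(bad) > 0, paste("unknown finding code(s):", paste(bad, collapse = ", ")))
    }
    if (length(msgs) > 0) {
      ok[i] <- FALSE
      errs[[length(errs) + 1L]] <- data.frame(row = i, message = paste(msgs, collapse = "; "),
                                              stringsAsFactors = FALSE)
    }
  }
  list(
    encounters = df[ok, , drop = FALSE],
    errors = if (length(errs)) do.call(rbind, errs) else
      data.frame(row = integer(0), message = character(0), stringsAsFactors = FALSE)
  )
}

#' Write classification results to CSV
#'
#' @param results data.frame as produced by [classify_batch()]`$results`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(results, path) {
  cols <- c("id", "vipe_total", "vipe_color", "final_level",
            "max_wait_minutes", "destination", "triggered_codes", "fast_path")
  utils::write.csv(results[, cols, drop = FALSE], path, row.names = FALSE,
                   quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read back a classification results CSV
#' @param path CSV path written by [write_results()].
#' @return data.frame.
#' @export
read_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a contingency table to CSV
#'
#' Counts matrix with a leading `level` column and a trailing `missing`
#' record, round-trippable through [read_contingency()].
#'
#' @param table An `urgency_resource_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_contingency <- function(table, path) {
  stopifnot(inherits(table, "urgency_resource_table"))
  df <- data.frame(level = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  df$missing <- c(table$missing_count, rep(NA, nrow(df) - 1))
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a contingency table CSV
#' @param path CSV path written by [write_contingency()], or any CSV with a
#'   `level` column followed by the four bin count columns.
#' @return An `urgency_resource_table`.
#' @export
read_contingency <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, resource_bins()])
  rownames(counts) <- df$level
  storage.mode(counts) <- "integer"
  counts <- counts[urgency_levels(), , drop = FALSE]
  missing <- if ("missing" %in% names(df)) df$missing[1] else 0L
  if (is.na(missing)) missing <- 0L
  out <- list(counts = counts, missing_count = as.integer(missing),
              n_total = sum(counts) + as.integer(missing))
  class(out) <- "urgency_resource_table"
  out
}

#' Read a rater matrix CSV
#'
#' Auto-detects the layout from the header: long form (`case`, `rater`,
#' `category`) is tabulated into a counts matrix; count form (`case` followed
#' by one count column per category) is used as is.
#'
#' @param path CSV path.
#' @return N x k integer counts matrix with category column names.
#' @export
read_ratings <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (all(c("case", "rater", "category") %in% names(df))) {
    counts <- as.matrix(table(df$case, df$category))
    storage.mode(counts) <- "integer"
    return(counts)
  }
  if (!"case" %in% names(df)) {
    stop("ratings file must have a 'case' column (long or count form)", call. = FALSE)
  }
  counts <- as.matrix(df[, setdiff(names(df), "case"), drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$case
  counts
}

#' Write kappa results to JSON
#'
#' @param kappa A `fleiss_kappa` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_kappa <- function(kappa, path) {
  stopifnot(inherits(kappa, "fleiss_kappa"))
  payload <- list(
    overall = kappa$overall,
    per_category = as.list(kappa$per_category),
    se_overall = kappa$se_overall,
    z = kappa$z, p_value = kappa$p_value,
    n_cases = kappa$n_cases, n_raters = kappa$n_raters,
    n_categories = kappa$n_categories
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
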