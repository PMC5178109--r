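# Two-step classification: VIPE color, then discriminator upgrade.

#' Classify one encounter
#'
#' Runs the full two-step classification: (1) the VIPE vital-sign score and
#' its color; (2) evaluation of the mandatory and complaint-triggered
#' discriminators. The final urgency is the maximum of the VIPE color and
#' every triggered discriminator level -- discriminators can only upgrade,
#' never downgrade. The final level maps to a maximum waiting time and a
#' care destination, and encounters triggering any RED (life-threat)
#' discriminator are flagged for the fast path (immediate care before any
#' administrative procedure, classification completed retrospectively).
#'
#' @param enc Encounter: named list with `age_days`, the four vitals (`rr`,
#'   `hr`, `spo2`, `axtemp`), `pain_level`, `general_appearance`, and any of
#'   the optional fields (`fever_report_max_c`, `returns_24h`, `returns_72h`,
#'   `findings`, `cbg_mg_dl`, `bp_systolic`, `bp_diastolic`,
#'   `injury_age_hours`, `burn_category`).
#' @param catalog Discriminator catalog from [load_catalog()].
#' @inheritParams color_from_total
#' @return Object of class `triage_result`: list with `vipe`
#'   (a `vipe_result`), `triggered` (data.frame of code/level), `final_level`,
#'   `max_wait_minutes`, `destination`, `fast_path`,
#'   `retrospective_classification`, `advisories`, and `provenance` (which
#'   rule set won).
#' @export
#' @examples
#' classify(list(age_days = 800, rr = 30, hr = 110, spo2 = 98, axtemp = 36.8,
#'               pain_level = 5, general_appearance = "well"))
classify <- function(enc, catalog = load_catalog(), tables = load_vipe_tables()) {
  enc <- as.list(enc)
  if (is.null(enc$age_days) || is.na(enc$age_days)) {
    stop("incomplete encounter: 'age_days' is missing", call. = FALSE)
  }
  vipe <- vipe_score(enc[c("rr", "hr", "spo2", "axtemp")], enc$age_days, tables)
  mand <- evaluate_mandatory(enc, catalog)
  comp <- evaluate_complaints(enc, catalog)
  triggered <- rbind(mand, comp)
  advisories <- union(attr(mand, "advisories"), attr(comp, "advisories"))

  disc_max <- max_discriminator_level(triggered)
  final_rank <- max(urgency_rank(vipe$color),
                    if (is.na(disc_max)) 1L else urgency_rank(disc_max))
  final_level <- urgency_levels()[final_rank]
  pol <- policy_for_level(final_level, tables)
  fast <- !is.na(disc_max) && any(triggered$level == "RED")

  out <- list(
    vipe = vipe,
    triggered = triggered[, c("code", "level")],
    final_level = final_level,
    max_wait_minutes = pol$max_wait_minutes,
    destination = pol$destination,
    fast_path = fast,
    retrospective_classification = fast,
    advisories = advisories,
    provenance = list(
      vipe_color = vipe$color,
      discriminator_max = disc_max,
      winner = if (is.na(disc_max) || urgency_rank(vipe$color) >= urgency_rank(disc_max))
        "vipe" else "discriminator",
      triggered_codes = triggered$code
    )
  )
  class(out) <- "triage_result"
  out
}

#' @export
print.triage_result <- function(x, ...) {
  cat(sprintf("Final level %s (wait <= %d min, %s)%s\n",
              x$final_level, x$max_wait_minutes, x$destination,
              if (x$fast_path) " [FAST PATH]" else ""))
  cat(sprintf("  VIPE %d -> %s; discriminators: %s\n",
              x$vipe$total, x$vipe$color,
              if (nrow(x$triggered) == 0) "none" else
                paste(x$triggered$code, collapse = ", ")))
  invisible(x)
}

#' Life-threat fast-path check
#'
#' TRUE when any RED-level discriminator (seizure at the time of care,
#' impaired consciousness, apnea, cyanosis, and the other life-threat
#' entries) triggers on the fields available in the encounter. Unlike
#' [classify()], this check has no preconditions: it is meant to run before
#' a complete encounter record exists, so missing fields simply cannot
#' trigger anything.
#'
#' @inheritParams classify
#' @return Logical scalar.
#' @export
#' @examples
#' fast_path_check(list(findings = "apnea"))
fast_path_check <- function(enc, catalog = load_catalog()) {
  enc <- as.list(enc)
  red_hit <- function(mandatory) {
    tr <- evaluate_entries(enc, catalog, mandatory = mandatory)
    any(tr$level == "RED")
  }
  red_hit(FALSE) || red_hit(TRUE)
}

#' Classify a batch of encounters
#'
#' Order-preserving row-wise classification of an encounter data frame
#' (e.g. from [read_encounters()]). Rows that fail validation are collected
#' into an error report instead of aborting the batch.
#'
#' @param encounters data.frame in the encounter schema (see
#'   [encounter_schema()]); a `findings` column holds semicolon-separated
#'   finding codes.
#' @inheritParams classify
#' @return List with `results` (data.frame: `id`, `vipe_total`, `vipe_color`,
#'   `final_level`, `max_wait_minutes`, `destination`, `triggered_codes`,
#'   `fast_path`) and `errors` (data.frame: `row`, `id`, `message`).
#' @export
classify_batch <- function(encounters, catalog = load_catalog(),
                           tables = load_vipe_tables()) {
  stopifnot(is.data.frame(encounters))
  res_rows <- list()
  err_rows <- list()
  for (i in seq_len(nrow(encounters))) {
    enc <- row_to_encounter(encounters[i, , drop = FALSE])
    id <- enc$id %||% i
    r <- tryCatch(classify(enc, catalog, tables), error = function(e) e)
    if (inherits(r, "error")) {
      err_rows[[length(err_rows) + 1L]] <- data.frame(
        row = i, id = as.character(id), message = conditionMessage(r),
        stringsAsFactors = FALSE)
    } else {
      res_rows[[length(res_rows) + 1L]] <- data.frame(
        id = as.character(id),
        vipe_total = r$vipe$total,
        vipe_color = r$vipe$color,
        final_level = r$final_level,
        max_wait_minutes = r$max_wait_minutes,
        destination = r$destination,
        triggered_codes = paste(r$triggered$code, collapse = ";"),
        fast_path = r$fast_path,
        stringsAsFactors = FALSE)
    }
  }
  empty_res <- data.frame(id = character(0), vipe_total = integer(0),
                          vipe_color = character(0), final_level = character(0),
                          max_wait_minutes = numeric(0), destination = character(0),
                          triggered_codes = character(0), fast_path = logical(0),
                          stringsAsFactors = FALSE)
  empty_err <- data.frame(row = integer(0), id = character(0),
                          message = character(0), stringsAsFactors = FALSE)
  list(
    results = if (length(res_rows)) do.call(rbind, res_rows) else empty_res,
    errors = if (length(err_rows)) do.call(rbind, err_rows) else empty_err
  )
}
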