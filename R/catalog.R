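# Data-driven discriminator catalog and guard evaluation.
#
# Guards are data, not code: a guard is a list with optional elements
#   all  - list of conditions, every one must hold
#   any  - list of sub-guards, at least one must hold
#   none - list of sub-guards, none may hold
# and a condition is one of
#   {type = "finding", code}                      finding present
#   {type = "num", field, op in lt/le/gt/ge, value}  numeric comparison
#   {type = "cat", field, value}                  categorical equality
# A condition on an absent optional field does not hold; absence never
# raises. Absent CBG/BP referenced by a guard is additionally reported as a
# "measurement indicated but absent" advisory.

#' Load a discriminator catalog
#'
#' Reads the JSON discriminator catalog (the bundled default encodes the
#' published general/mandatory and complaint-triggered discriminator tables,
#' one entry per non-empty table cell, each carrying a provenance string).
#' Validates entry codes, levels, guard structure and collects the finding
#' vocabulary referenced by the guards.
#'
#' @param path Path to the catalog JSON. Defaults to the bundled catalog.
#' @return Object of class `discriminator_catalog`: list with `entries`
#'   (list of entries), `vocabulary` (character vector of finding codes),
#'   `census` (expected cell counts), `version`.
#' @export
load_catalog <- function(path = NULL) {
  default <- is.null(path)
  if (default) {
    cached <- .clariped_env$default_catalog
    if (!is.null(cached)) return(cached)
    path <- system.file("extdata", "catalog.json", package = "clariped")
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  entries <- raw$entries
  codes <- vapply(entries, `[[`, character(1), "code")
  if (anyDuplicated(codes)) {
    stop("duplicate discriminator codes: ",
         paste(codes[duplicated(codes)], collapse = ", "), call. = FALSE)
  }
  levels_ok <- vapply(entries, function(e) e$level %in% urgency_levels(), logical(1))
  if (!all(levels_ok)) stop("entry with unknown urgency level", call. = FALSE)
  vocab <- sort(unique(unlist(lapply(entries, function(e) guard_findings(e$guard)))))
  for (e in entries) validate_guard(e$guard, e$code)
  out <- list(
    version = raw$version,
    entries = entries,
    vocabulary = vocab,
    census = raw$census
  )
  class(out) <- "discriminator_catalog"
  if (default) .clariped_env$default_catalog <- out
  out
}

#' @export
print.discriminator_catalog <- function(x, ...) {
  n_mand <- sum(vapply(x$entries, `[[`, logical(1), "mandatory"))
  cat("Discriminator catalog, version", x$version, "\n")
  cat(length(x$entries), "entries (", n_mand, "mandatory ),",
      length(x$vocabulary), "finding codes\n")
  invisible(x)
}

# all finding codes referenced anywhere in a guard (recursive)
guard_findings <- function(guard) {
  out <- character(0)
  for (cond in guard$all %||% list()) {
    if (identical(cond$type, "finding")) out <- c(out, cond$code)
  }
  for (g in c(guard$any %||% list(), guard$none %||% list())) {
    out <- c(out, guard_findings(g))
  }
  out
}

guard_fields <- function(guard) {
  out <- character(0)
  for (cond in guard$all %||% list()) {
    if (cond$type %in% c("num", "cat")) out <- c(out, cond$field)
  }
  for (g in c(guard$any %||% list(), guard$none %||% list())) {
    out <- c(out, guard_fields(g))
  }
  out
}

validate_guard <- function(guard, code) {
  known <- c("all", "any", "none")
  if (length(setdiff(names(guard), known)) > 0) {
    stop("entry ", code, ": unknown guard element", call. = FALSE)
  }
  for (cond in guard$all %||% list()) {
    if (is.null(cond$type) ||
        !cond$type %in% c("finding", "num", "cat") ||
        (cond$type == "finding" && is.null(cond$code)) ||
        (cond$type == "num" && (is.null(cond$field) || is.null(cond$value) ||
                                !cond$op %in% c("lt", "le", "gt", "ge"))) ||
        (cond$type == "cat" && (is.null(cond$field) || is.null(cond$value)))) {
      stop("entry ", code, ": malformed condition", call. = FALSE)
    }
  }
  for (g in c(guard$any %||% list(), guard$none %||% list())) validate_guard(g, code)
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fields whose absence under an interested guard warrants a workflow advisory
.advisory_fields <- c("cbg_mg_dl", "bp_systolic", "bp_diastolic")

# evaluate one condition against an encounter environment; returns TRUE/FALSE
# and records advisory field names in `adv` (an environment accumulator)
eval_condition <- function(cond, enc, adv) {
  if (cond$type == "finding") {
    return(cond$code %in% (enc$findings %||% character(0)))
  }
  val <- enc[[cond$field]]
  if (is.null(val) || (length(val) == 1 && is.na(val))) {
    if (cond$field %in% .advisory_fields) {
      adv$fields <- union(adv$fields, cond$field)
    }
    return(FALSE)
  }
  if (cond$type == "num") {
    return(switch(cond$op,
                  lt = val < cond$value, le = val <= cond$value,
                  gt = val > cond$value, ge = val >= cond$value))
  }
  identical(as.character(val), as.character(cond$value))
}

eval_guard <- function(guard, enc, adv) {
  for (cond in guard$all %||% list()) {
    if (!eval_condition(cond, enc, adv)) return(FALSE)
  }
  anyg <- guard$any %||% list()
  if (length(anyg) > 0 && !any(vapply(anyg, eval_guard, logical(1), enc, adv))) {
    return(FALSE)
  }
  noneg <- guard$none %||% list()
  if (length(noneg) > 0 && any(vapply(noneg, eval_guard, logical(1), enc, adv))) {
    return(FALSE)
  }
  TRUE
}

# common evaluation core; BLUE-level entries never assert an upgrade (BLUE is
# the floor), so they are catalogued for completeness but never "trigger"
evaluate_entries <- function(enc, catalog, mandatory) {
  enc <- prepare_encounter_env(enc)
  adv <- new.env(parent = emptyenv())
  adv$fields <- character(0)
  hits <- list()
  for (e in catalog$entries) {
    if (e$mandatory != mandatory) next
    if (e$level == "BLUE") next
    if (eval_guard(e$guard, enc, adv)) {
      hits[[length(hits) + 1L]] <- list(code = e$code, level = e$level,
                                        label = e$label, category = e$category)
    }
  }
  out <- if (length(hits) == 0) {
    data.frame(code = character(0), level = character(0),
               label = character(0), category = character(0),
               stringsAsFactors = FALSE)
  } else {
    data.frame(
      code = vapply(hits, `[[`, character(1), "code"),
      level = vapply(hits, `[[`, character(1), "level"),
      label = vapply(hits, `[[`, character(1), "label"),
      category = vapply(hits, `[[`, character(1), "category"),
      stringsAsFactors = FALSE
    )
  }
  attr(out, "advisories") <- adv$fields
  out
}

# derive guard-visible fields (rr_score for the tachypnea footnote) once
prepare_encounter_env <- function(enc) {
  enc <- as.list(enc)
  if (is.null(enc$rr_score) &&
      !is.null(enc$rr) && !is.null(enc$age_days) &&
      length(enc$rr) == 1 && !is.na(enc$rr) && !is.na(enc$age_days)) {
    enc$rr_score <- tryCatch(
      score_parameter(enc$rr, "RR", assign_stratum(enc$age_days)),
      error = function(e) NULL
    )
  }
  enc
}

#' Evaluate the mandatory general discriminators
#'
#' The five general discriminator families (general appearance, pain, fever
#' report, age, return to the emergency department) are assessed for every
#' patient. Returns the triggered entries; BLUE-level cells (no pain,
#' looks well) are part of the catalog but assert nothing, since BLUE is the
#' classification floor.
#'
#' @param enc Encounter: named list with at least `pain_level` (0-10) and
#'   `general_appearance` (one of critical, very_ill, ill, little_ill, well);
#'   optionally `age_days`, `fever_report_max_c`, `returns_24h`, `returns_72h`.
#' @param catalog A catalog from [load_catalog()].
#' @return data.frame with columns `code`, `level`, `label`, `category`, one
#'   row per triggered discriminator; attribute `advisories` lists optional
#'   measurements a guard wanted but the encounter lacked.
#' @export
#' @examples
#' cat <- load_catalog()
#' evaluate_mandatory(list(pain_level = 8, general_appearance = "well"), cat)
evaluate_mandatory <- function(enc, catalog = load_catalog()) {
  enc <- as.list(enc)
  if (is.null(enc$pain_level) || is.na(enc$pain_level)) {
    stop("incomplete encounter: 'pain_level' is missing", call. = FALSE)
  }
  if (enc$pain_level < 0 || enc$pain_level > 10) {
    stop("pain_level must be in 0..10", call. = FALSE)
  }
  ga <- enc$general_appearance
  if (is.null(ga) || is.na(ga)) {
    stop("incomplete encounter: 'general_appearance' is missing", call. = FALSE)
  }
  if (!ga %in% c("critical", "very_ill", "ill", "little_ill", "well")) {
    stop("unknown general_appearance: ", ga, call. = FALSE)
  }
  evaluate_entries(enc, catalog, mandatory = TRUE)
}

#' Evaluate the complaint-triggered discriminators
#'
#' Evaluates every non-mandatory catalog entry against the encounter. A guard
#' that needs an absent optional measurement (e.g. capillary blood glucose or
#' blood pressure) does not trigger; the absent field is reported in the
#' `advisories` attribute as "measurement indicated but absent".
#'
#' @inheritParams evaluate_mandatory
#' @return Same shape as [evaluate_mandatory()].
#' @export
#' @examples
#' cat <- load_catalog()
#' evaluate_complaints(list(findings = "unconscious"), cat)
evaluate_complaints <- function(enc, catalog = load_catalog()) {
  enc <- as.list(enc)
  findings <- enc$findings %||% character(0)
  unknown <- setdiff(findings, catalog$vocabulary)
  if (length(unknown) > 0) {
    stop("unknown finding code(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  evaluate_entries(enc, catalog, mandatory = FALSE)
}

#' Maximum urgency level asserted by triggered discriminators
#'
#' @param triggered data.frame as returned by the `evaluate_*` functions (only
#'   the `level` column is used).
#' @return The highest level name, or `NA_character_` when nothing triggered.
#' @export
max_discriminator_level <- function(triggered) {
  lv <- if (is.data.frame(triggered)) triggered$level else as.character(triggered)
  if (length(lv) == 0) return(NA_character_)
  urgency_levels()[max(urgency_rank(lv))]
}

#' Lint a discriminator catalog and threshold tables
#'
#' Runs the catalog census and consistency checks: unique codes, provenance
#' string on every entry, guard fields restricted to the encounter schema,
#' entry counts matching the expected number of non-empty table cells, and
#' reports the threshold-table validation flags (including the known printed
#' heart-rate band overlap in the 5-12 y stratum).
#'
#' @param catalog Catalog from [load_catalog()].
#' @inheritParams color_from_total
#' @return Object of class `catalog_lint`: list with `ok` (logical),
#'   `problems` (character), `table_warnings` (character), `counts` (named
#'   vector: mandatory/complaint entries found and expected).
#' @export
catalog_lint <- function(catalog = load_catalog(), tables = load_vipe_tables()) {
  problems <- character(0)
  entries <- catalog$entries
  prov <- vapply(entries, function(e) e$provenance %||% "", character(1))
  if (any(!nzchar(prov))) {
    problems <- c(problems, paste("entries without provenance:",
      paste(vapply(entries[!nzchar(prov)], `[[`, character(1), "code"), collapse = ", ")))
  }
  schema_fields <- c(encounter_schema()$column, "rr_score")
  bad_fields <- setdiff(unique(unlist(lapply(entries, function(e) guard_fields(e$guard)))),
                        schema_fields)
  if (length(bad_fields) > 0) {
    problems <- c(problems, paste("guards reference unknown fields:",
                                  paste(bad_fields, collapse = ", ")))
  }
  n_mand <- sum(vapply(entries, `[[`, logical(1), "mandatory"))
  n_comp <- length(entries) - n_mand
  counts <- c(mandatory = n_mand, complaint = n_comp,
              mandatory_expected = catalog$census$table2_cells,
              complaint_expected = catalog$census$table3_cells)
  if (n_mand != catalog$census$table2_cells) {
    problems <- c(problems, sprintf(
      "mandatory census mismatch: %d entries, %d non-empty cells expected",
      n_mand, catalog$census$table2_cells))
  }
  if (n_comp != catalog$census$table3_cells) {
    problems <- c(problems, sprintf(
      "complaint census mismatch: %d entries, %d non-empty cells expected",
      n_comp, catalog$census$table3_cells))
  }
  out <- list(ok = length(problems) == 0, problems = problems,
              table_warnings = tables$warnings, counts = counts)
  class(out) <- "catalog_lint"
  out
}

#' @export
print.catalog_lint <- function(x, ...) {
  cat("Catalog lint:", if (x$ok) "OK" else "PROBLEMS", "\n")
  cat(sprintf("  mandatory entries: %d (expected %d)\n",
              x$counts["mandatory"], x$counts["mandatory_expected"]))
  cat(sprintf("  complaint entries: %d (expected %d)\n",
              x$counts["complaint"], x$counts["complaint_expected"]))
  for (p in x$problems) cat("  problem:", p, "\n")
  for (w in x$table_warnings) cat("  table flag:", w, "\n")
  invisible(x)
}
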