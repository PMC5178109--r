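# Synthetic encounter cohorts, rater matrices and vignette sets.
#
# The generators invert the scoring tables: vitals are sampled so that the
# VIPE total is exact by construction (and re-verified by re-scoring), and
# urgency upgrades are injected only through single-finding presence
# discriminators so the intended final level is exact as well.

# integer score of every value in the measurement domain, from the bands
score_value_sets <- function(stratum, parameter, tables) {
  df <- tables$bands[[stratum]][[parameter]]
  cap <- if (parameter == "SPO2") 100L else 250L
  grid <- 0:cap
  sc <- rep(-1L, length(grid))
  for (i in seq_len(nrow(df))) {
    hit <- grid >= df$lo[i] & grid <= df$hi[i]
    sc[hit] <- pmax(sc[hit], df$score[i])  # worst-case overlap rule
  }
  split(grid, sc)
}

# all (rr, hr, spo2, correction) decompositions of a target total
vipe_decompositions <- function(target, spo2_scores = c(0L, 1L, 2L, 4L)) {
  out <- expand.grid(rr = 0:4, hr = 0:4, spo2 = spo2_scores, corr = c(0L, -1L, -2L))
  out <- out[out$corr == 0L | out$hr >= 2L, ]
  out <- out[out$rr + out$hr + out$spo2 + out$corr == target, ]
  out
}

#' Synthesize vital signs with an exact VIPE total
#'
#' Draws a uniformly random decomposition of `target_total` into feasible
#' (RR, HR, SpO2, fever-correction) sub-scores for the stratum, then a
#' uniformly random integer measurement inside each chosen band (the
#' axillary temperature is drawn from the matching correction band). The
#' result is re-scored to verify the round trip.
#'
#' @param stratum Stratum id (see [assign_stratum()]).
#' @param target_total Integer in 0..12.
#' @param seed Optional integer seed.
#' @inheritParams color_from_total
#' @return Named list `rr`, `hr`, `spo2`, `axtemp` scoring exactly
#'   `target_total`.
#' @export
#' @examples
#' v <- synth_vitals_for_total("1_4Y", 12, seed = 7)
#' vipe_score(v, age_days = 800)$total  # 12
synth_vitals_for_total <- function(stratum, target_total, seed = NULL,
                                   tables = load_vipe_tables()) {
  if (is.na(target_total) || target_total < 0 || target_total > 12) {
    stop("target_total must be in 0..12", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  sets <- list(
    RR = score_value_sets(stratum, "RR", tables),
    HR = score_value_sets(stratum, "HR", tables),
    SPO2 = score_value_sets(stratum, "SPO2", tables)
  )
  spo2_scores <- as.integer(names(sets$SPO2))
  dec <- vipe_decompositions(target_total, spo2_scores)
  # keep decompositions whose sub-scores have attainable values
  ok <- vapply(seq_len(nrow(dec)), function(i) {
    !is.null(sets$RR[[as.character(dec$rr[i])]]) &&
      !is.null(sets$HR[[as.character(dec$hr[i])]]) &&
      !is.null(sets$SPO2[[as.character(dec$spo2[i])]])
  }, logical(1))
  dec <- dec[ok, ]
  if (nrow(dec) == 0) {
    stop("infeasible decomposition for total ", target_total, " in ", stratum, call. = FALSE)
  }
  d <- dec[sample.int(nrow(dec), 1), ]
  pick <- function(v) if (length(v) == 1) v else sample(v, 1)
  axtemp <- switch(as.character(d$corr),
                   "0" = round(stats::runif(1, 36.0, 37.4), 1),
                   "-1" = round(stats::runif(1, 37.5, 38.5), 1),
                   "-2" = round(stats::runif(1, 38.6, 41.0), 1))
  out <- list(rr = pick(sets$RR[[as.character(d$rr)]]),
              hr = pick(sets$HR[[as.character(d$hr)]]),
              spo2 = pick(sets$SPO2[[as.character(d$spo2)]]),
              axtemp = axtemp)
  age <- tables$strata$lower_days[tables$strata$id == stratum]
  check <- vipe_score(out, age, tables)
  if (check$total != target_total) {
    stop(sprintf("round-trip failure: requested %d, re-scored %d", target_total, check$total),
         call. = FALSE)
  }
  out
}

# VIPE total band per level, from the color legend
totals_for_level <- function(level, tables = load_vipe_tables()) {
  cm <- tables$color_map
  r <- cm[cm$level == level, ]
  seq(r$lo, r$hi)
}

# non-mandatory entries whose guard is a single finding-presence condition
injectable_entries <- function(catalog) {
  keep <- vapply(catalog$entries, function(e) {
    !e$mandatory &&
      is.null(e$guard$any) && is.null(e$guard$none) &&
      length(e$guard$all) == 1 &&
      identical(e$guard$all[[1]]$type, "finding")
  }, logical(1))
  entries <- catalog$entries[keep]
  data.frame(
    code = vapply(entries, `[[`, character(1), "code"),
    level = vapply(entries, `[[`, character(1), "level"),
    finding = vapply(entries, function(e) e$guard$all[[1]]$code, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Validate a cohort specification
#'
#' @param spec Named list with `n` (>= 1), `seed`, `urgency_mix` (length-5
#'   probability vector, BLUE..RED order), `age_mix` (length-5 probability
#'   vector over the age strata), `discriminator_rate` (probability that the
#'   intended level is realized by a finding one level above the VIPE color),
#'   `resource_model` (5 x 4 matrix of per-level probabilities over the
#'   resource bins 0/1/2/>=3, rows BLUE..RED).
#' @return The spec, with defaults filled in, invisibly checked.
#' @export
cohort_spec <- function(spec) {
  spec <- as.list(spec)
  if (is.null(spec$n) || spec$n < 1) stop("n must be >= 1", call. = FALSE)
  spec$discriminator_rate <- spec$discriminator_rate %||% 0
  if (spec$discriminator_rate < 0 || spec$discriminator_rate > 1) {
    stop("discriminator_rate must be in [0, 1]", call. = FALSE)
  }
  spec$urgency_mix <- spec$urgency_mix %||% rep(0.2, 5)
  spec$age_mix <- spec$age_mix %||% rep(0.2, 5)
  for (nm in c("urgency_mix", "age_mix")) {
    v <- spec[[nm]]
    if (length(v) != 5 || any(v < 0) || abs(sum(v) - 1) > 1e-9) {
      stop(nm, " must be a length-5 probability vector summing to 1", call. = FALSE)
    }
  }
  if (is.null(spec$resource_model)) {
    spec$resource_model <- matrix(0.25, 5, 4,
                                  dimnames = list(urgency_levels(), resource_bins()))
  }
  rm_ <- as.matrix(spec$resource_model)
  if (!all(dim(rm_) == c(5, 4)) || any(rm_ < 0) ||
      any(abs(rowSums(rm_) - 1) > 1e-9)) {
    stop("resource_model must be a 5 x 4 matrix with rows summing to 1", call. = FALSE)
  }
  dimnames(rm_) <- list(urgency_levels(), resource_bins())
  spec$resource_model <- rm_
  spec
}

#' Generate a synthetic encounter cohort
#'
#' Each record draws an intended urgency level from `urgency_mix` and an age
#' stratum from `age_mix`. With probability `discriminator_rate` (and when
#' the intended level is above BLUE) the level is realized by a VIPE total
#' one color band *below* it plus a single injected finding that asserts the
#' intended level; otherwise the VIPE total itself is drawn from the intended
#' level's band. Mandatory discriminators are kept silent (no pain, looks
#' well, no fever report, no returns, age above 28 days), so the intended
#' level is exact by construction. A resource-use bin is drawn from the
#' per-level `resource_model`.
#'
#' @inheritParams cohort_spec
#' @return List with `encounters` (data.frame in the encounter schema) and
#'   `labels` (data.frame: `id`, `intended_level`, `resource_bin`,
#'   `resource_count`).
#' @export
#' @examples
#' synth_cohort(list(n = 5, seed = 1))$labels
synth_cohort <- function(spec) {
  spec <- cohort_spec(spec)
  catalog <- load_catalog()
  tables <- load_vipe_tables()
  if (!is.null(spec$seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(spec$seed)
  }
  inj <- injectable_entries(catalog)
  strata <- tables$strata
  n <- spec$n
  lv_idx <- sample.int(5, n, replace = TRUE, prob = spec$urgency_mix)
  st_idx <- sample.int(5, n, replace = TRUE, prob = spec$age_mix)
  use_disc <- stats::runif(n) < spec$discriminator_rate & lv_idx > 1

  rows <- vector("list", n)
  labels <- vector("list", n)
  for (i in seq_len(n)) {
    level <- urgency_levels()[lv_idx[i]]
    sid <- strata$id[st_idx[i]]
    lo <- max(strata$lower_days[st_idx[i]], 29)  # stay above the newborn rule
    hi <- min(strata$upper_days[st_idx[i]], 6574)  # cap at ~18 y
    age <- sample(lo:hi, 1)
    finding <- ""
    if (use_disc[i]) {
      vipe_level <- urgency_levels()[lv_idx[i] - 1L]
      cand <- inj$finding[inj$level == level]
      finding <- sample(cand, 1)
    } else {
      vipe_level <- level
    }
    target <- sample(totals_for_level(vipe_level, tables), 1)
    v <- synth_vitals_for_total(sid, target, tables = tables)
    bin <- sample.int(4, 1, prob = spec$resource_model[level, ])
    resource_count <- c(0L, 1L, 2L, sample(3:5, 1))[bin]
    rows[[i]] <- data.frame(
      id = sprintf("S%05d", i), age_days = age,
      rr = v$rr, hr = v$hr, spo2 = v$spo2, axtemp_c = v$axtemp,
      pain_level = 0L, general_appearance = "well",
      fever_report_max_c = NA_real_, returns_24h = 0L, returns_72h = 0L,
      findings = finding, cbg_mg_dl = NA_real_,
      bp_systolic = NA_real_, bp_diastolic = NA_real_,
      injury_age_hours = NA_real_, burn_category = NA_character_,
      resource_count = resource_count,
      stringsAsFactors = FALSE
    )
    labels[[i]] <- data.frame(
      id = sprintf("S%05d", i), intended_level = level,
      resource_bin = resource_bins()[bin], resource_count = resource_count,
      stringsAsFactors = FALSE
    )
  }
  list(encounters = do.call(rbind, rows), labels = do.call(rbind, labels))
}

#' Generate labeled vignette cases for agreement studies
#'
#' Emulates the design of a hypothetical-case reliability study: `n_cases`
#' cases are drawn from a target urgency mix, each with a synthetic encounter
#' whose classification equals the label. The truth vector feeds
#' [simulate_raters()].
#'
#' @param n_cases Number of cases (>= 1).
#' @param mix Length-5 probability vector over BLUE..RED.
#' @param seed Optional integer seed.
#' @return List with `truth` (character vector of level names), `vignettes`
#'   (encounter data.frame with an `intended_level` column), and
#'   `expected_counts` (the exact multinomial means `n_cases * mix`).
#' @export
#' @examples
#' synth_vignettes(10, mix = c(.08, .08, .31, .42, .11), seed = 1)$truth
synth_vignettes <- function(n_cases, mix = rep(0.2, 5), seed = NULL) {
  if (n_cases < 1) stop("n_cases must be >= 1", call. = FALSE)
  if (length(mix) != 5 || any(mix < 0) || abs(sum(mix) - 1) > 1e-9) {
    stop("mix must be a length-5 probability vector summing to 1", call. = FALSE)
  }
  out <- synth_cohort(list(n = n_cases, seed = seed, urgency_mix = mix,
                           discriminator_rate = 0.3))
  vignettes <- out$encounters
  vignettes$intended_level <- out$labels$intended_level
  list(truth = out$labels$intended_level,
       vignettes = vignettes,
       expected_counts = stats::setNames(n_cases * mix, urgency_levels()))
}
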