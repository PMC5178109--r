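test_that("mandatory discriminators trigger per the general table", {
  cat <- load_catalog()
  m <- evaluate_mandatory(list(pain_level = 8, general_appearance = "well"), cat)
  expect_true(any(m$code == "pain_strong" & m$level == "ORANGE"))

  m <- evaluate_mandatory(list(pain_level = 0, general_appearance = "well",
                               age_days = 20, fever_report_max_c = 38.6), cat)
  expect_true(any(m$code == "fever_lt3mo_ge385" & m$level == "ORANGE"))
  expect_true(any(m$code == "newborn" & m$level == "YELLOW"))

  m <- evaluate_mandatory(list(pain_level = 0, general_appearance = "well",
                               age_days = 1826), cat)
  expect_identical(nrow(m), 0L)

  # appearance ladder and returns
  m <- evaluate_mandatory(list(pain_level = 0, general_appearance = "critical"), cat)
  expect_true(any(m$code == "appearance_critical" & m$level == "RED"))
  m <- evaluate_mandatory(list(pain_level = 0, general_appearance = "well",
                               returns_24h = 1, returns_72h = 2), cat)
  expect_setequal(m$code, c("return_1_24h", "return_2_72h"))

  expect_error(evaluate_mandatory(list(general_appearance = "well"), cat),
               "pain_level")
  expect_error(evaluate_mandatory(list(pain_level = 3), cat),
               "general_appearance")
  expect_error(evaluate_mandatory(list(pain_level = 12, general_appearance = "well"),
                                  cat), "0..10")
})

test_that("complaint discriminators: presence, numeric, age and combination guards", {
  cat <- load_catalog()
  c1 <- evaluate_complaints(list(findings = "unconscious"), cat)
  expect_equal(c1$code, "coma")
  expect_equal(c1$level, "RED")

  c2 <- evaluate_complaints(list(cbg_mg_dl = 50, age_days = 200), cat)
  expect_equal(c2$code, "cbg_low")
  expect_equal(c2$level, "ORANGE")
  # same CBG over 1 year: below the '>1 y' cut -> RED
  c2b <- evaluate_complaints(list(cbg_mg_dl = 50, age_days = 800), cat)
  expect_equal(c2b$code, "cbg_very_low")

  c3 <- evaluate_complaints(list(findings = "tbi_no_loc_vomit",
                                 injury_age_hours = 5), cat)
  expect_equal(c3$code, "tbi_lt12h")
  expect_equal(c3$level, "YELLOW")
  c3b <- evaluate_complaints(list(findings = "tbi_no_loc_vomit",
                                  injury_age_hours = 20), cat)
  expect_equal(c3b$code, "tbi_gt12h")
  expect_equal(c3b$level, "GREEN")

  # age-conditioned findings
  expect_equal(evaluate_complaints(list(findings = "hoarseness", age_days = 400),
                                   cat)$code, "hoarseness_lt2y")
  expect_identical(nrow(evaluate_complaints(list(findings = "hoarseness",
                                                 age_days = 1000), cat)), 0L)

  # combination guards
  c4 <- evaluate_complaints(list(findings = c("urticaria", "stridor_resp_difficulty")), cat)
  expect_true(any(c4$code == "urticaria_stridor_resp" & c4$level == "RED"))
  c5 <- evaluate_complaints(
    list(findings = "edema", bp_systolic = 150, bp_diastolic = 95), cat)
  expect_true(any(c5$code == "edema_hypertension" & c5$level == "RED"))
  expect_false(any(c5$code == "edema_no_hypertension"))
  c6 <- evaluate_complaints(list(findings = "edema", bp_systolic = 120,
                                 bp_diastolic = 70), cat)
  expect_equal(c6$code, "edema_no_hypertension")

  # negated sub-guard: dengue without warning signs
  c7 <- evaluate_complaints(list(findings = "dengue_suspected"), cat)
  expect_equal(c7$code, "dengue_no_warning")
  c8 <- evaluate_complaints(list(findings = c("dengue_suspected", "dengue_warning_sign")), cat)
  expect_equal(c8$code, "dengue_warning")

  expect_error(evaluate_complaints(list(findings = "not_a_code"), cat),
               "not_a_code")
})

test_that("tachypnea needs both the complaint and an elevated RR sub-score", {
  cat <- load_catalog()
  # RR 65 at 2 y scores 3 -> triggers with the finding
  tr <- evaluate_complaints(list(findings = "tachypnea", age_days = 730,
                                 rr = 65), cat)
  expect_true("tachypnea" %in% tr$code)
  # normal RR: the complaint alone does not trigger
  tr <- evaluate_complaints(list(findings = "tachypnea", age_days = 730,
                                 rr = 30), cat)
  expect_false("tachypnea" %in% tr$code)
})

test_that("absent optional measurements never raise and yield advisories", {
  cat <- load_catalog()
  tr <- evaluate_complaints(list(findings = "diabetes"), cat)
  expect_identical(nrow(tr), 0L)
  expect_true("cbg_mg_dl" %in% attr(tr, "advisories"))
  tr <- evaluate_complaints(list(findings = "edema"), cat)
  # edema-without-hypertension holds (the negated BP guard cannot fire)
  expect_equal(tr$code, "edema_no_hypertension")
  expect_true(all(c("bp_systolic") %in% attr(tr, "advisories")))
  # random sparse encounters: evaluation is total
  set.seed(21)
  vocab <- cat$vocabulary
  for (i in 1:50) {
    enc <- list(findings = sample(vocab, sample(0:3, 1)))
    if (runif(1) < 0.5) enc$age_days <- sample(0:6000, 1)
    if (runif(1) < 0.3) enc$cbg_mg_dl <- runif(1, 10, 500)
    expect_no_error(evaluate_complaints(enc, cat))
  }
})

test_that("pain level is monotone and evaluation is deterministic", {
  cat <- load_catalog()
  pain_rank <- vapply(0:10, function(p) {
    m <- evaluate_mandatory(list(pain_level = p, general_appearance = "well"), cat)
    lv <- max_discriminator_level(m[grepl("^pain", m$code), ])
    if (is.na(lv)) 1L else match(lv, urgency_levels())
  }, integer(1))
  expect_false(is.unsorted(pain_rank))

  enc <- list(pain_level = 5, general_appearance = "ill", age_days = 100,
              findings = c("cough", "dengue_suspected"), cbg_mg_dl = 70)
  expect_identical(evaluate_mandatory(enc, cat), evaluate_mandatory(enc, cat))
  expect_identical(evaluate_complaints(enc, cat), evaluate_complaints(enc, cat))
})

test_that("max_discriminator_level is the max of the ordered enum", {
  expect_equal(max_discriminator_level(
    data.frame(level = c("YELLOW", "ORANGE"))), "ORANGE")
  expect_true(is.na(max_discriminator_level(data.frame(level = character(0)))))
  # an encounter carrying every RED presence finding maxes at RED
  cat <- load_catalog()
  red_findings <- unlist(lapply(cat$entries, function(e) {
    if (e$level == "RED" && length(e$guard$all) >= 1 &&
        identical(e$guard$all[[1]]$type, "finding")) e$guard$all[[1]]$code
  }))
  tr <- evaluate_complaints(list(findings = unique(red_findings),
                                 bp_systolic = 150, bp_diastolic = 95,
                                 cbg_mg_dl = 15, age_days = 100,
                                 axtemp_c = 39), cat)
  expect_equal(max_discriminator_level(tr), "RED")
})

test_that("catalog lint passes the census and reports the table overlap", {
  lint <- catalog_lint()
  expect_true(lint$ok)
  expect_equal(unname(lint$counts["mandatory"]),
               unname(lint$counts["mandatory_expected"]))
  expect_equal(unname(lint$counts["complaint"]),
               unname(lint$counts["complaint_expected"]))
  expect_true(any(grepl("5_12Y/HR", lint$table_warnings)))
  # every entry carries provenance (lint would flag otherwise); spot-check shape
  cat <- load_catalog()
  expect_true(all(vapply(cat$entries,
                         function(e) nzchar(e$provenance), logical(1))))
})
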