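# Shared fixtures and independent oracles.

# preload defaults once so the known table-overlap warning does not leak
# into unrelated expectations
suppressWarnings(load_vipe_tables())
load_catalog()

# printed validity table: counts by urgency row and resource bin, 13 missing
table4_counts <- function() {
  rbind(BLUE   = c(4, 0, 0, 0),
        GREEN  = c(17, 14, 1, 1),
        YELLOW = c(9, 17, 12, 1),
        ORANGE = c(0, 1, 2, 3),
        RED    = c(0, 0, 0, 0))
}

# expand the counts into per-visit (level, resource_count) records,
# plus n_missing visits with an unknown resource count
table4_records <- function(n_missing = 13) {
  m <- table4_counts()
  lv <- rep(rownames(m), rowSums(m))
  rc <- unlist(lapply(rownames(m), function(l) rep(0:3, m[l, ])))
  list(levels = c(lv, rep("GREEN", n_missing)),
       counts = c(rc, rep(NA, n_missing)))
}

# from-scratch Fleiss kappa oracle: pair counting over explicit rater
# assignments, independent of the matrix algebra in fleiss_kappa()
oracle_kappa <- function(counts) {
  counts <- as.matrix(counts)
  n <- nrow(counts); k <- ncol(counts); m <- sum(counts[1, ])
  agree_pairs <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      agree_pairs <- agree_pairs + choose(counts[i, j], 2)
    }
  }
  P_bar <- agree_pairs / (n * choose(m, 2))
  p <- colSums(counts) / (n * m)
  Pe <- sum(p^2)
  overall <- (P_bar - Pe) / (1 - Pe)
  per_cat <- rep(NA_real_, k)
  for (j in seq_len(k)) {
    if (p[j] > 0 && p[j] < 1) {
      disagree_j <- sum(counts[, j] * (m - counts[, j]))
      per_cat[j] <- 1 - disagree_j / (n * m * (m - 1) * p[j] * (1 - p[j]))
    }
  }
  list(overall = overall, per_category = per_cat)
}

# minimal complete encounter scoring VIPE total 0 in the 1-4 y stratum
benign_encounter <- function(...) {
  enc <- list(age_days = 800, rr = 30, hr = 110, spo2 = 98, axtemp = 36.8,
              pain_level = 0, general_appearance = "well")
  utils::modifyList(enc, list(...))
}
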