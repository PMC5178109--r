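# Validity analysis: urgency level vs. count of diagnostic/therapeutic
# resources used, binned 0 / 1 / 2 / >=3, with a Pearson chi-square test of
# independence (and an optional Monte-Carlo p under fixed margins).

resource_bins <- function() c("0", "1", "2", ">=3")

#' Build the urgency-by-resource contingency table
#'
#' Bins per-visit resource counts as 0 / 1 / 2 / >=3 and cross-tabulates them
#' against the final urgency level. Visits with a missing resource count are
#' tallied separately and excluded from the matrix.
#'
#' @param levels Character vector of urgency level names, one per visit.
#' @param resource_counts Integer vector of the same length; `NA` = missing.
#' @return Object of class `urgency_resource_table`: list with `counts`
#'   (5 x 4 integer matrix, rows BLUE..RED, columns 0/1/2/>=3),
#'   `missing_count`, `n_total`.
#' @export
#' @examples
#' build_table(c("BLUE", "BLUE", "GREEN"), c(0, 0, 2))
build_table <- function(levels, resource_counts) {
  if (length(levels) != length(resource_counts)) {
    stop("levels and resource_counts must have equal length", call. = FALSE)
  }
  lv <- as_urgency(levels)
  ok_counts <- resource_counts[!is.na(resource_counts)]
  if (any(ok_counts < 0) || any(ok_counts != round(ok_counts))) {
    stop("resource counts must be non-negative integers", call. = FALSE)
  }
  missing <- is.na(resource_counts)
  bin <- pmin(resource_counts, 3L)
  counts <- matrix(0L, nrow = 5, ncol = 4,
                   dimnames = list(urgency_levels(), resource_bins()))
  keep <- !missing & !is.na(lv)
  if (any(keep)) {
    tab <- table(factor(as.character(lv[keep]), levels = urgency_levels()),
                 factor(bin[keep], levels = 0:3))
    counts[] <- as.integer(tab)
  }
  if (sum(counts) == 0) stop("grand total is zero after dropping missing", call. = FALSE)
  out <- list(counts = counts, missing_count = sum(missing),
              n_total = length(levels))
  class(out) <- "urgency_resource_table"
  out
}

#' @export
print.urgency_resource_table <- function(x, ...) {
  cat("Urgency x resource-use table (", sum(x$counts), "visits,",
      x$missing_count, "missing )\n")
  print(x$counts)
  invisible(x)
}

#' Row percentages of a contingency table
#'
#' Cell / row total x 100 for every retained row. Rows with a zero total are
#' dropped with a warning. Values are returned unrounded; round to 1 decimal
#' for display.
#'
#' @param table An `urgency_resource_table` from [build_table()], or a plain
#'   numeric matrix of counts.
#' @return Numeric matrix of percentages, rows summing to 100.
#' @export
row_percentages <- function(table) {
  counts <- if (inherits(table, "urgency_resource_table")) table$counts else as.matrix(table)
  rs <- rowSums(counts)
  if (any(rs == 0)) {
    warning("dropping row(s) with zero total: ",
            paste(rownames(counts)[rs == 0], collapse = ", "), call. = FALSE)
  }
  keep <- rs > 0
  sweep(counts[keep, , drop = FALSE], 1, rs[keep], "/") * 100
}

#' Column percentages of a contingency table
#'
#' Marginal distribution of urgency levels on two bases: the retained total
#' (visits with a known resource count) and the full sample including
#' missing-resource visits.
#'
#' @inheritParams row_percentages
#' @return data.frame with `level`, `n`, `pct_retained`, `pct_full`.
#' @export
level_frequencies <- function(table) {
  stopifnot(inherits(table, "urgency_resource_table"))
  n <- rowSums(table$counts)
  data.frame(
    level = rownames(table$counts),
    n = as.integer(n),
    pct_retained = n / sum(n) * 100,
    pct_full = n / table$n_total * 100,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Pearson chi-square test of independence
#'
#' Drops all-zero rows and columns, computes the Pearson statistic
#' sum((O - E)^2 / E) with df = (r - 1)(c - 1), the analytic upper-tail
#' p-value, and optionally a Monte-Carlo p-value by resampling tables with
#' the observed margins fixed (via `stats::r2dtable`). A warning is attached
#' when any expected cell is below 5 (the Monte-Carlo p is the robust
#' alternative then).
#'
#' @inheritParams row_percentages
#' @param mc_replicates Optional integer; when given, also estimate the
#'   Monte-Carlo p-value with this many fixed-margin resamples.
#' @param seed Optional integer seed for the Monte-Carlo resampling.
#' @return Object of class `chisq_result`: list with `statistic`, `df`,
#'   `p_value`, `expected`, `observed`, `warnings`, and (when requested)
#'   `mc_p_value`, `mc_replicates`, `mc_seed`.
#' @export
chi_square_independence <- function(table, mc_replicates = NULL, seed = NULL) {
  counts <- if (inherits(table, "urgency_resource_table")) table$counts else as.matrix(table)
  counts <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop("degenerate table: need at least 2 non-empty rows and columns", call. = FALSE)
  }
  n <- sum(counts)
  expected <- outer(rowSums(counts), colSums(counts)) / n
  stat <- sum((counts - expected)^2 / expected)
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  warn <- character(0)
  if (any(expected < 5)) {
    warn <- sprintf("%d expected cell(s) below 5; consider the Monte-Carlo p-value",
                    sum(expected < 5))
  }
  out <- list(statistic = stat, df = df, p_value = p,
              expected = expected, observed = counts, warnings = warn)
  if (!is.null(mc_replicates)) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    sims <- stats::r2dtable(mc_replicates, rowSums(counts), colSums(counts))
    stats_sim <- vapply(sims, function(s) sum((s - expected)^2 / expected), numeric(1))
    # add-one estimator, guarantees p in (0, 1]
    out$mc_p_value <- (sum(stats_sim >= stat - 1e-9) + 1) / (mc_replicates + 1)
    out$mc_replicates <- mc_replicates
    out$mc_seed <- seed
  }
  class(out) <- "chisq_result"
  out
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square = %.3f, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  if (!is.null(x$mc_p_value)) {
    cat(sprintf("Monte-Carlo p = %.4g (%d replicates)\n", x$mc_p_value, x$mc_replicates))
  }
  for (w in x$warnings) cat("Warning:", w, "\n")
  invisible(x)
}
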