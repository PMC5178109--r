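# Multi-rater agreement: Fleiss' kappa with per-category components and the
# Fleiss large-sample standard error under the null of chance agreement.

#' Fleiss' kappa for multiple raters
#'
#' Computes overall and per-category chance-corrected agreement for N cases
#' each rated by the same number m of raters into k nominal categories.
#' With x_ij the number of raters placing case i in category j and
#' p_j the category marginals, the per-case agreement is
#' P_i = (sum_j x_ij^2 - m) / (m (m - 1)), the chance agreement is
#' Pe = sum_j p_j^2, and kappa = (mean(P_i) - Pe) / (1 - Pe). Per-category
#' kappa_j = 1 - sum_i x_ij (m - x_ij) / (N m (m-1) p_j (1 - p_j)), reported
#' as NA when category j has zero (or full) marginal. The standard error is
#' the Fleiss large-sample formula under the null of chance agreement, with
#' a one-sided normal test of kappa > 0.
#'
#' @param counts N x k matrix of non-negative integers; row i gives how many
#'   raters assigned case i to each category. All row sums must equal the
#'   (constant) number of raters m >= 2. Column names are used as category
#'   labels.
#' @return Object of class `fleiss_kappa`: list with `overall`,
#'   `per_category` (named numeric, NA where undefined), `se_overall`, `z`,
#'   `p_value`, `n_cases`, `n_raters`, `n_categories`, `marginals`.
#' @export
#' @examples
#' x <- rbind(c(3, 0), c(0, 3), c(2, 1), c(1, 2))
#' fleiss_kappa(x)
fleiss_kappa <- function(counts) {
  counts <- as.matrix(counts)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  n <- nrow(counts)
  k <- ncol(counts)
  if (n < 2 || k < 2) stop("need at least 2 cases and 2 categories", call. = FALSE)
  m <- sum(counts[1, ])
  if (m < 2 || any(rowSums(counts) != m)) {
    stop("all rows must sum to the same number of raters m >= 2", call. = FALSE)
  }

  p <- colSums(counts) / (n * m)
  if (sum(p > 0) < 2) {
    stop("degenerate input: all ratings in a single category (chance agreement is 1)",
         call. = FALSE)
  }
  q <- 1 - p
  P_i <- (rowSums(counts^2) - m) / (m * (m - 1))
  P_bar <- mean(P_i)
  Pe <- sum(p^2)
  overall <- (P_bar - Pe) / (1 - Pe)

  per_cat <- rep(NA_real_, k)
  defined <- p > 0 & p < 1
  per_cat[defined] <- 1 - colSums(counts * (m - counts))[defined] /
    (n * m * (m - 1) * p[defined] * q[defined])
  names(per_cat) <- colnames(counts) %||% paste0("cat", seq_len(k))

  # Fleiss (1971) large-sample SE under the null of chance agreement
  spq <- sum(p * q)
  se <- sqrt(2 / (n * m * (m - 1))) * sqrt(spq^2 - sum(p * q * (q - p))) / spq
  z <- overall / se
  p_value <- stats::pnorm(z, lower.tail = FALSE)

  out <- list(overall = overall, per_category = per_cat,
              se_overall = se, z = z, p_value = p_value,
              n_cases = n, n_raters = m, n_categories = k, marginals = p)
  class(out) <- "fleiss_kappa"
  out
}

#' @export
print.fleiss_kappa <- function(x, digits = 3, ...) {
  cat(sprintf("Fleiss' kappa: %.*f (SE %.*f, z = %.2f, one-sided p = %.3g)\n",
              digits, x$overall, digits, x$se_overall, x$z, x$p_value))
  cat(sprintf("  %d cases x %d raters x %d categories\n",
              x$n_cases, x$n_raters, x$n_categories))
  cat("  per-category kappa:\n")
  print(round(x$per_category, digits))
  invisible(x)
}

#' Simulate a rater matrix around known truth
#'
#' Each of m raters independently reports the true category with probability
#' `fidelity`, otherwise a uniformly random *other* category. Emulates the
#' design of a vignette reliability study (e.g. 36 cases rated by 9
#' professionals into 5 urgency levels).
#'
#' @param truth Character vector of true category labels (urgency level names
#'   by default; any label set drawn from `categories` works).
#' @param m Number of raters per case (>= 2).
#' @param fidelity Probability in \[0, 1\] that a rater reports the truth.
#' @param seed Optional integer seed for reproducibility.
#' @param categories Category label set; defaults to [urgency_levels()].
#' @return N x k integer matrix of rating counts with category column names.
#' @export
#' @examples
#' simulate_raters(c("RED", "BLUE", "RED"), m = 9, fidelity = 0.9, seed = 1)
simulate_raters <- function(truth, m, fidelity, seed = NULL,
                            categories = urgency_levels()) {
  if (length(truth) == 0) stop("truth must be non-empty", call. = FALSE)
  if (fidelity < 0 || fidelity > 1) stop("fidelity must be in [0, 1]", call. = FALSE)
  if (m < 2) stop("need m >= 2 raters", call. = FALSE)
  if (any(!truth %in% categories)) stop("truth labels outside category set", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  k <- length(categories)
  counts <- matrix(0L, nrow = length(truth), ncol = k,
                   dimnames = list(NULL, categories))
  for (i in seq_along(truth)) {
    true_j <- match(truth[i], categories)
    hit <- stats::rbinom(1, m, fidelity)
    counts[i, true_j] <- hit
    if (m - hit > 0 && k > 1) {
      others <- stats::rmultinom(1, m - hit, rep(1 / (k - 1), k - 1))[, 1]
      counts[i, -true_j] <- counts[i, -true_j] + others
    }
  }
  counts
}
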