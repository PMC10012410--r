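#' Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' Computes the Mann-Whitney U statistic of `x` against `y` and a two-tailed
#' p-value. With `method = "auto"` the p-value is exact — by complete
#' enumeration of all choose(m+n, m) group assignments — when
#' `m + n <= 12` and there are no ties, and a tie-corrected normal
#' approximation with continuity correction otherwise. `method = "exact"`
#' forces enumeration (midranks handle ties), `method = "approx"` the
#' normal approximation.
#'
#' @param x,y Numeric samples (each nonempty).
#' @param method `"auto"`, `"exact"` or `"approx"`.
#' @return A list: `U`, `p`, `method` used.
#' @export
rank_sum_test <- function(x, y, method = c("auto", "exact", "approx")) {
  method <- match.arg(method)
  if (length(x) < 1 || length(y) < 1) stop("both samples must be nonempty")
  m <- length(x); n <- length(y); N <- m + n
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  if (method == "auto") method <- if (N <= 12 && !ties) "exact" else "approx"
  if (method == "exact") {
    combs <- utils::combn(N, m)
    mid <- m * n / 2
    u_all <- apply(combs, 2, function(ix) sum(r[ix])) - m * (m + 1) / 2
    p <- mean(abs(u_all - mid) >= abs(U - mid) - 1e-12)
  } else {
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (12 * N * (N - 1))
    sigma <- sqrt(m * n * ((N + 1) / 12 - tie_term))
    if (sigma == 0) {
      p <- 1
    } else {
      z <- (abs(U - m * n / 2) - 0.5) / sigma   # continuity correction
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
  }
  list(U = U, p = p, method = method)
}

#' Region-wise group comparison between cohorts
#'
#' One two-tailed rank-sum test per region between the ictal and postictal
#' cohorts. No multiple-comparison correction is applied by default
#' (region-wise p-values are reported uncorrected); a Benjamini-Hochberg
#' adjusted column can be requested.
#'
#' @param table Long data.frame with columns `subject_id`, `cohort`
#'   (`"ictal"`/`"postictal"`), `region`, `value`.
#' @param adjust If `TRUE`, add a BH-adjusted `p_adj` column.
#' @param method Passed to [rank_sum_test()].
#' @return Data.frame: region, U, p, direction (cohort with the higher
#'   median; `"none"` on exact ties), n_ictal, n_postictal.
#' @export
compare_groups <- function(table, adjust = FALSE, method = "auto") {
  need <- c("subject_id", "cohort", "region", "value")
  if (!all(need %in% names(table))) stop("table must have columns ",
                                         paste(need, collapse = ", "))
  if (!all(c("ictal", "postictal") %in% table$cohort))
    stop("both cohorts must be present")
  out <- NULL
  for (reg in unique(table$region)) {
    tr <- table[table$region == reg, ]
    x <- tr$value[tr$cohort == "ictal"]
    y <- tr$value[tr$cohort == "postictal"]
    if (length(x) == 0 || length(y) == 0) {
      warning("region '", reg, "' missing in one cohort; skipped")
      next
    }
    ts <- rank_sum_test(x, y, method = method)
    md <- stats::median(x) - stats::median(y)
    dir <- if (md > 0) "ictal" else if (md < 0) "postictal" else "none"
    out <- rbind(out, data.frame(region = reg, U = ts$U, p = ts$p,
                                 direction = dir, n_ictal = length(x),
                                 n_postictal = length(y),
                                 stringsAsFactors = FALSE))
  }
  if (adjust && !is.null(out)) out$p_adj <- stats::p.adjust(out$p, "BH")
  out
}

#' Thalamic z-score sign counts
#'
#' Counts subjects with positive / negative intra-individual thalamic
#' z-scores per side and cohort. Subjects with z exactly 0 are counted in
#' neither sign bucket and reported in a third column, preserving the
#' identity `n_pos + n_neg + n_zero = cohort size`.
#'
#' @param z_table Long data.frame with columns `subject_id`, `cohort`,
#'   `name` (ROI name), `hemisphere`, `z`.
#' @param zero_tol z-scores with `|z| <= zero_tol` count as zero (exact
#'   zeros in synthetic data are only zero up to floating-point round-off).
#' @return Data.frame: cohort, side, n_pos, n_neg, n_zero, n, prop_pos,
#'   prop_neg.
#' @export
thalamic_sign_counts <- function(z_table, zero_tol = 1e-8) {
  tt <- z_table[z_table$name == "thalamus", ]
  if (nrow(tt) == 0) stop("no thalamus entries in the z table")
  out <- NULL
  for (ch in unique(tt$cohort)) for (side in c("left", "right")) {
    zz <- tt$z[tt$cohort == ch & tt$hemisphere == side]
    out <- rbind(out, data.frame(
      cohort = ch, side = side,
      n_pos = sum(zz > zero_tol), n_neg = sum(zz < -zero_tol),
      n_zero = sum(abs(zz) <= zero_tol),
      n = length(zz),
      prop_pos = if (length(zz)) sum(zz > zero_tol) / length(zz) else NA_real_,
      prop_neg = if (length(zz)) sum(zz < -zero_tol) / length(zz) else NA_real_,
      stringsAsFactors = FALSE))
  }
  out
}

#' Per-cohort categorical perfusion proportions
#'
#' Fractions of subjects per perfusion category within each cohort, with
#' display percentages rounded to the nearest integer; the sensitivity of
#' hyperperfusion for detecting the ictal state is reported alongside.
#'
#' @param report Data.frame with one row per subject: `subject_id`, `cohort`,
#'   `category` in normal/hypoperfusion/hyperperfusion.
#' @return A list: `proportions` (cohort, category, n, fraction, percent)
#'   and `sensitivity` (hyperperfusion fraction among ictal subjects;
#'   `percent` rounded for display).
#' @export
categorical_proportions <- function(report) {
  if (nrow(report) == 0) stop("empty report")
  bad <- setdiff(unique(report$category), .subject_categories)
  if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "))
  if (anyDuplicated(report$subject_id)) stop("one row per subject required")
  out <- NULL
  for (ch in unique(report$cohort)) {
    rc <- report[report$cohort == ch, ]
    for (cat in .subject_categories) {
      k <- sum(rc$category == cat)
      out <- rbind(out, data.frame(cohort = ch, category = cat, n = k,
                                   fraction = k / nrow(rc),
                                   percent = round(100 * k / nrow(rc)),
                                   stringsAsFactors = FALSE))
    }
  }
  sens <- NA_real_
  if ("ictal" %in% report$cohort) {
    ri <- report[report$cohort == "ictal", ]
    sens <- sum(ri$category == "hyperperfusion") / nrow(ri)
  }
  list(proportions = out,
       sensitivity = list(fraction = sens, percent = round(100 * sens)))
}

#' Pearson chi-square test of independence
#'
#' @param table Two-way contingency table (matrix of counts).
#' @return A list: `chisq`, `df` = (r-1)(c-1), `p`. No continuity
#'   correction is applied.
#' @export
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal in the contingency table")
  res <- stats::chisq.test(table, correct = FALSE)
  list(chisq = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}
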