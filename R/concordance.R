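#' Cohen's kappa
#'
#' Unweighted chance-corrected agreement between two categorical raters,
#' `kappa = (p_o - p_e) / (1 - p_e)` with the chance agreement `p_e` from
#' the marginals of the confusion matrix. When both raters are constant and
#' identical (`p_e = 1`) kappa is undefined and reported as degenerate.
#'
#' @param ratings_a,ratings_b Category vectors over the same items
#'   (length >= 2).
#' @return A list of class `kappa_result`: `kappa`, `p_o`, `p_e`, `n`,
#'   `degenerate`, `confusion`.
#' @export
cohens_kappa <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b))
    stop("rating vectors must cover the same items")
  n <- length(ratings_a)
  if (n < 2) stop("need at least 2 items")
  lev <- sort(unique(c(as.character(ratings_a), as.character(ratings_b))))
  a <- factor(ratings_a, levels = lev)
  b <- factor(ratings_b, levels = lev)
  cm <- table(a, b)
  p_o <- sum(diag(cm)) / n
  p_e <- sum(rowSums(cm) * colSums(cm)) / n^2
  degen <- abs(1 - p_e) < .Machine$double.eps^0.5
  kappa <- if (degen) NA_real_ else (p_o - p_e) / (1 - p_e)
  structure(list(kappa = kappa, p_o = p_o, p_e = p_e, n = n,
                 degenerate = degen, confusion = cm),
            class = "kappa_result")
}

#' Positive specific agreement for one category
#'
#' `2 * |both assign c| / (|a assigns c| + |b assigns c|)` as a percentage:
#' the chance-uncorrected agreement specific to category `c`.
#'
#' @param ratings_a,ratings_b Category vectors over the same items.
#' @param category The category of interest.
#' @return Percentage in `[0, 100]`, or `NA` with a `"flagged"` attribute
#'   when neither rater ever assigns the category.
#' @export
category_agreement <- function(ratings_a, ratings_b, category) {
  if (length(ratings_a) != length(ratings_b))
    stop("rating vectors must cover the same items")
  na <- sum(ratings_a == category)
  nb <- sum(ratings_b == category)
  if (na + nb == 0) {
    out <- NA_real_
    attr(out, "flagged") <- TRUE
    return(out)
  }
  both <- sum(ratings_a == category & ratings_b == category)
  100 * 2 * both / (na + nb)
}

# region-level rating -> asymmetry group: left-sided asymmetry (positive AI)
# is left hyperperfusion or right hypoperfusion; right-sided the mirror
.rating_to_group <- function(category) {
  ifelse(category %in% c("left-hyper", "right-hypo"), "left",
         ifelse(category %in% c("right-hyper", "left-hypo"), "right",
                "normal"))
}

#' Compare quantitative asymmetry to consensus visual lateralization
#'
#' Maps each consensus region rating to a lateralization group
#' (left-asymmetric, right-asymmetric, normal), pools the quantitative AI
#' values per group across subjects and regions, and tests each asymmetric
#' group's AI against the normal group with a two-tailed rank-sum test.
#'
#' @param ai_table Data.frame with columns `subject_id`, `region` (lobe-level
#'   name matching the rated regions) and `ai`.
#' @param ratings Consensus region ratings: data.frame with `subject_id`,
#'   `region`, `category` (normal / left-hyper / right-hyper / left-hypo /
#'   right-hypo).
#' @return A list: `groups` (joined table with a `group` column), `medians`
#'   (named per group), `tests` (left vs normal and right vs normal; a test
#'   is `NULL` with a notice when its group is empty).
#' @export
ai_rating_concordance <- function(ai_table, ratings) {
  need <- c("subject_id", "region")
  if (!all(c(need, "ai") %in% names(ai_table)) ||
      !all(c(need, "category") %in% names(ratings)))
    stop("ai_table needs subject_id/region/ai; ratings need subject_id/region/category")
  bad <- setdiff(unique(ratings$category), .region_categories)
  if (length(bad)) stop("unknown region categories: ", paste(bad, collapse = ", "))
  j <- merge(ai_table, ratings, by = c("subject_id", "region"))
  if (nrow(j) == 0) stop("AI entries and ratings do not join on (subject, region)")
  j$group <- .rating_to_group(j$category)
  j <- j[!is.na(j$ai), ]
  medians <- tapply(j$ai, factor(j$group, levels = c("left", "normal", "right")),
                    stats::median)
  tests <- list(left = NULL, right = NULL)
  norm_ai <- j$ai[j$group == "normal"]
  for (side in c("left", "right")) {
    grp_ai <- j$ai[j$group == side]
    if (length(grp_ai) == 0 || length(norm_ai) == 0) {
      message("no '", side, "'-asymmetric (or no normal) regions; test skipped")
      next
    }
    tests[[side]] <- rank_sum_test(grp_ai, norm_ai)
  }
  list(groups = j, medians = medians, tests = tests)
}

#' Read a rating table from CSV
#'
#' Expects (or maps to) the columns `subject_id`, `rater`, `level`,
#' `region`, `category`. `header_map` renames foreign headers, so
#' supplementary tables exported with different column names (e.g.
#' `ID, reader, scope, roi, rating`) can be ingested directly.
#'
#' @param path CSV file path.
#' @param header_map Named character vector `c(foreign = "canonical")`.
#' @return Data.frame with the canonical columns.
#' @export
read_rating_csv <- function(path, header_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(header_map)) {
    hit <- match(names(df), names(header_map))
    names(df)[!is.na(hit)] <- header_map[hit[!is.na(hit)]]
  }
  need <- c("subject_id", "rater", "level", "region", "category")
  if (!all(need %in% names(df)))
    stop("rating table must provide columns ", paste(need, collapse = ", "))
  df[, need]
}
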