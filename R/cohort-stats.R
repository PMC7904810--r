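#' Two-sided Fisher exact test on a 2x2 table
#'
#' Uses the "sum of probabilities not exceeding the observed table" two-sided
#' convention (the standard R convention), which is required to reproduce
#' published cohort p-values.  The reported odds ratio is the sample odds
#' ratio \code{(a d)/(b c)}; set \code{or = "cmle"} for the conditional
#' maximum-likelihood estimate.
#'
#' @param t 2x2 matrix of non-negative counts, or a length-4 vector
#'   \code{c(a, b, c, d)} filled by row (rows = groups, columns = outcome).
#' @param or "sample" or "cmle".
#' @return list(odds_ratio, p_value).  A zero margin gives p = 1.
#' @examples
#' fisher_exact_two_sided(c(24, 425, 41, 191))
#' @export
fisher_exact_two_sided <- function(t, or = c("sample", "cmle")) {
  or <- match.arg(or)
  m <- as_twobytwo(t)
  p <- stats::fisher.test(m)$p.value
  oratio <- if (or == "cmle") {
    unname(stats::fisher.test(m)$estimate)
  } else {
    (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  }
  list(odds_ratio = oratio, p_value = p)
}

as_twobytwo <- function(t) {
  if (is.matrix(t)) {
    stopifnot(all(dim(t) == c(2, 2)))
    m <- t
  } else {
    stopifnot(length(t) == 4)
    m <- matrix(as.numeric(t), 2, 2, byrow = TRUE)
  }
  if (any(m < 0) || sum(m) == 0) stop("counts must be non-negative, total > 0")
  m
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact-distribution p-value for tie-free samples of combined size at most
#' 50; normal approximation with tie and continuity correction otherwise.
#' Two identical samples (all values equal) give p = 1.
#'
#' @param x,y numeric samples (non-empty).
#' @return The two-sided p-value.
#' @export
wilcoxon_rank_sum_two_sided <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  if (length(unique(c(x, y))) == 1L) return(1.0)
  exact <- (length(x) + length(y) <= 50) && !anyDuplicated(c(x, y))
  stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                     correct = TRUE)$p.value
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks.  Returns NA when either variable has
#' zero variance.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return Spearman's rho, or NA.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Clinical feature counts of the two C-Circle screening cohorts
#'
#' Published clinical feature counts of the population screening cohort
#' (n = 720) and the INFORM relapse cohort (n = 40): per cohort, clinical
#' feature and category, the number of C-Circle positive and negative
#' tumors.  \code{total_n} is the feature's reporting denominator (the
#' cohort size, or the number of tumors with the feature available: risk
#' stratification is missing for 39 screening tumors and MYCN status for 18).
#'
#' @return data.frame: cohort, feature, category, cc_pos, cc_neg, total_n.
#' @export
neuroblastoma_cohort_counts <- function() {
  rows <- list(
    # screening cohort, n = 720 (66 C-Circle positive, 654 negative)
    c("screening", "stage",     "stage 1-3",      25, 391, 720),
    c("screening", "stage",     "stage 4",        41, 180, 720),
    c("screening", "stage",     "stage 4S",        0,  83, 720),
    c("screening", "risk",      "LR/IR",          24, 425, 681),
    c("screening", "risk",      "HR",             41, 191, 681),
    c("screening", "sex",       "male",           39, 358, 720),
    c("screening", "sex",       "female",         27, 296, 720),
    c("screening", "mycn",      "MYCN amp",        0, 114, 702),
    c("screening", "mycn",      "MYCN normal",    66, 522, 702),
    c("screening", "histology", "ganglioneuroma",  0,  11, 720),
    c("screening", "histology", "other",          66, 643, 720),
    # INFORM relapse cohort, n = 40 (19 C-Circle positive, 21 negative)
    c("inform",    "stage",     "stage 1-3",       4,   0,  40),
    c("inform",    "stage",     "stage 4",        14,  20,  40),
    c("inform",    "stage",     "stage 4S",        1,   1,  40),
    c("inform",    "risk",      "LR/IR",           5,   2,  40),
    c("inform",    "risk",      "HR",             14,  19,  40),
    c("inform",    "sex",       "male",           13,  19,  40),
    c("inform",    "sex",       "female",          6,   2,  40),
    c("inform",    "mycn",      "MYCN amp",        2,   9,  40),
    c("inform",    "mycn",      "MYCN normal",    17,  10,  40)
  )
  do.call(rbind, lapply(rows, function(r)
    data.frame(cohort = r[1], feature = r[2], category = r[3],
               cc_pos = as.integer(r[4]), cc_neg = as.integer(r[5]),
               total_n = as.integer(r[6]), stringsAsFactors = FALSE)))
}

#' Cohort feature percentages
#'
#' Reporting-convention percentages for
#' \code{\link{neuroblastoma_cohort_counts}}: each category's share of the
#' feature's reporting denominator (\code{pct_total}) and its share among
#' the cohort's C-Circle positive and negative tumors with the feature
#' available (\code{pct_pos}, \code{pct_neg}).
#'
#' @param counts a counts table in the layout of
#'   \code{\link{neuroblastoma_cohort_counts}} (the default).
#' @return The input with pct_total, pct_pos and pct_neg appended.
#' @export
cohort_percentages <- function(counts = neuroblastoma_cohort_counts()) {
  key <- paste(counts$cohort, counts$feature)
  pos_tot <- stats::ave(counts$cc_pos, key, FUN = sum)
  neg_tot <- stats::ave(counts$cc_neg, key, FUN = sum)
  counts$pct_total <- 100 * (counts$cc_pos + counts$cc_neg) / counts$total_n
  counts$pct_pos <- 100 * counts$cc_pos / pos_tot
  counts$pct_neg <- 100 * counts$cc_neg / neg_tot
  counts
}

#' Clinical contingency tables of the two C-Circle screening cohorts
#'
#' Reduces the per-feature counts to one 2x2 table per clinical contrast:
#' counts of C-Circle positive / negative tumors in each group.  Stage is
#' tested as stage 1-3 vs stage 4, and separately as stage 4S vs all other
#' staged tumors.
#'
#' @param counts a counts table in the layout of
#'   \code{\link{neuroblastoma_cohort_counts}} (the default).
#' @return data.frame with columns cohort, contrast, group1, group2 and the
#'   2x2 cell counts a, b, c, d (a = group1 C-Circle positive, b = group1
#'   negative, c = group2 positive, d = group2 negative).
#' @export
neuroblastoma_cohort_tables <- function(counts = neuroblastoma_cohort_counts()) {
  cell <- function(cohort, category) {
    r <- counts[counts$cohort == cohort & counts$category == category, ]
    c(r$cc_pos[1], r$cc_neg[1])
  }
  out <- list()
  for (co in unique(counts$cohort)) {
    s13 <- cell(co, "stage 1-3"); s4 <- cell(co, "stage 4")
    s4s <- cell(co, "stage 4S")
    out[[length(out) + 1L]] <- data.frame(
      cohort = co, contrast = "stage_1_3_vs_4", group1 = "stage 1-3",
      group2 = "stage 4", a = s13[1], b = s13[2], c = s4[1], d = s4[2])
    out[[length(out) + 1L]] <- data.frame(
      cohort = co, contrast = "stage_4s_vs_rest", group1 = "stage 4S",
      group2 = "other", a = s4s[1], b = s4s[2],
      c = s13[1] + s4[1], d = s13[2] + s4[2])
    two_level <- list(
      c("risk_lrir_vs_hr", "LR/IR", "HR"),
      c("sex", "male", "female"),
      c("mycn", "MYCN amp", "MYCN normal"),
      c("ganglioneuroma", "ganglioneuroma", "other"))
    for (tl in two_level) {
      if (!tl[2] %in% counts$category[counts$cohort == co]) next
      g1 <- cell(co, tl[2]); g2 <- cell(co, tl[3])
      out[[length(out) + 1L]] <- data.frame(
        cohort = co, contrast = tl[1], group1 = tl[2], group2 = tl[3],
        a = g1[1], b = g1[2], c = g2[1], d = g2[2])
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Cohort association tests
#'
#' Runs the two-sided Fisher exact test on each 2x2 contingency table and
#' adds group percentages: for each group the share of C-Circle positive
#' tumors among all positives (\code{pct_pos_g1}) and the share of the group
#' within the contrast total.
#'
#' @param tables contingency tables in the layout of
#'   \code{\link{neuroblastoma_cohort_tables}} (the default).
#' @return The input with columns \code{odds_ratio}, \code{p_value},
#'   \code{pct_g1_of_pos} (group1 share among C-Circle positives, percent)
#'   and \code{pct_g1_of_neg} appended.
#' @examples
#' head(cohort_association_tests())
#' @export
cohort_association_tests <- function(tables = neuroblastoma_cohort_tables()) {
  res <- lapply(seq_len(nrow(tables)), function(i) {
    with(tables[i, ], fisher_exact_two_sided(c(a, b, c, d)))
  })
  tables$odds_ratio <- vapply(res, `[[`, numeric(1), "odds_ratio")
  tables$p_value <- vapply(res, `[[`, numeric(1), "p_value")
  tables$pct_g1_of_pos <- with(tables, 100 * a / (a + c))
  tables$pct_g1_of_neg <- with(tables, 100 * b / (b + d))
  tables
}
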