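# Descriptive-statistics stage: contingency tables of the binary outcome
# against categorical covariates with row prevalences and Pearson chi-square
# tests, unadjusted 2x2 odds ratios, and pooled two-sample t-tests from
# summary statistics.

#' Contingency table of a categorical covariate against the outcome
#'
#' @param data household data.frame with a 0/1 column `y`.
#' @param var name of a categorical column.
#' @return data.frame of class `contingency_table` with columns
#'   `level, n_no, n_yes`.
#' @export
contingency <- function(data, var) {
  f <- factor(data[[var]])
  tab <- table(f, factor(data$y, levels = c(0, 1)))
  structure(data.frame(level = rownames(tab), n_no = as.integer(tab[, 1]),
                       n_yes = as.integer(tab[, 2]), stringsAsFactors = FALSE),
            class = c("contingency_table", "data.frame"), variable = var)
}

as_counts <- function(t) {
  if (is.data.frame(t)) as.matrix(t[, c("n_no", "n_yes")])
  else as.matrix(t)
}

#' Row prevalences of a contingency table
#'
#' `100 * n_yes / (n_no + n_yes)` per row, the percentage of households with
#' the outcome within each covariate level.
#'
#' @param t a [contingency()] table (or a two-column counts matrix,
#'   no/yes order).
#' @param digits rounding for display (half-up, 1 decimal by default);
#'   `digits = NULL` returns unrounded values.
#' @return numeric vector of percentages (`NA` with a warning for zero rows).
#' @export
#' @examples
#' prevalence_rows(cbind(n_no = c(2690, 1120), n_yes = c(958, 475)))
prevalence_rows <- function(t, digits = 1) {
  m <- as_counts(t)
  tot <- rowSums(m)
  raw <- 100 * m[, 2] / tot
  if (any(tot == 0)) {
    warning("zero row total; prevalence undefined for ",
            sum(tot == 0), " row(s)")
    raw[tot == 0] <- NA_real_
  }
  if (is.null(digits)) return(raw)
  # round half-up rather than banker's rounding
  floor(raw * 10^digits + 0.5) / 10^digits
}

#' Pearson chi-square test of independence (no continuity correction)
#'
#' @param t a [contingency()] table or counts matrix.
#' @return list with `statistic`, `df`, `p`.
#' @export
chi_square <- function(t) {
  m <- as_counts(t)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero marginal; chi-square test undefined")
  ct <- suppressWarnings(chisq.test(m, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Unadjusted odds ratio of a 2x2 table with Woolf interval
#'
#' Row 1 is the reference level; `OR = (a d) / (b c)` with the Woolf
#' (log-scale normal) 95% confidence interval.  Zero cells are rejected (no
#' continuity correction by design).
#'
#' @param t a 2x2 [contingency()] table or counts matrix (columns no/yes).
#' @return list with `or`, `ci_low`, `ci_high`.
#' @export
odds_ratio_2x2 <- function(t) {
  m <- as_counts(t)
  if (!all(dim(m) == c(2, 2))) stop("need a 2x2 table")
  if (any(m == 0)) stop("zero cell; odds ratio undefined without correction")
  a <- m[1, 1]; b <- m[1, 2]; c2 <- m[2, 1]; d <- m[2, 2]
  or <- (a * d) / (b * c2)
  se <- sqrt(sum(1 / m))
  z <- qnorm(0.975)
  list(or = or, ci_low = exp(log(or) - z * se), ci_high = exp(log(or) + z * se))
}

#' Pooled two-sample t-test from summary statistics
#'
#' @param m1,s1,n1 mean, SD and size of group 1.
#' @param m2,s2,n2 mean, SD and size of group 2.
#' @return list with `t`, `df = n1 + n2 - 2`, `p` (two-sided).
#' @export
#' @examples
#' t_test_from_summaries(4.32, 2.33, 3810, 4.59, 2.43, 1433)
t_test_from_summaries <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 in both groups")
  if (s1 <= 0 || s2 <= 0) stop("need positive SDs")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  tstat <- (m2 - m1) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df))
}

#' Table-1-style description of a household table
#'
#' For every categorical covariate: counts by outcome, row prevalence, and
#' the Pearson chi-square p-value; for every continuous covariate: group
#' means/SDs and the pooled t-test p-value.
#'
#' @param data household data.frame (see [generate_households()]).
#' @param categorical,continuous covariate names to describe.
#' @return data.frame with columns `variable, level, n_no, n_yes, pct_yes,
#'   test, p` (continuous rows carry `mean (sd)` strings in the count
#'   columns).
#' @export
describe_households <- function(
    data,
    categorical = c("sex", "marital", "residence", "shock", "credit", "wave"),
    continuous = c("family_size", "schooling", "dep_ratio", "asset", "age")) {
  rows <- list()
  for (v in intersect(categorical, names(data))) {
    ct <- contingency(data, v)
    p <- chi_square(ct)$p
    rows[[v]] <- data.frame(
      variable = v, level = ct$level, n_no = as.character(ct$n_no),
      n_yes = as.character(ct$n_yes),
      pct_yes = prevalence_rows(ct),
      test = "chi-square", p = p, stringsAsFactors = FALSE)
  }
  for (v in intersect(continuous, names(data))) {
    x0 <- data[[v]][data$y == 0]; x1 <- data[[v]][data$y == 1]
    tt <- t_test_from_summaries(mean(x0), sd(x0), length(x0),
                                mean(x1), sd(x1), length(x1))
    rows[[v]] <- data.frame(
      variable = v, level = "mean (sd)",
      n_no = sprintf("%.2f (%.2f)", mean(x0), sd(x0)),
      n_yes = sprintf("%.2f (%.2f)", mean(x1), sd(x1)),
      pct_yes = NA_real_, test = "t-test", p = tt$p,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Published food-insecurity contingency cells (Ethiopia Socioeconomic Survey)
#'
#' The cell counts of the published household-level food-insecurity
#' cross-tabulation that motivated this package's defaults: counts of
#' households not insecure / insecure over the last 12 months by covariate
#' level, ESS waves 1-4 (5262 households, 72 zones).  Cell counts are
#' reported as printed; note that some printed row *totals* in the source
#' table disagree with their cell sums, so all computations here use the
#' cells only.
#'
#' @return data.frame with columns `variable, level, n_no, n_yes`.
#' @export
#' @examples
#' t1 <- ess_table1()
#' g <- t1[t1$variable == "gender", ]
#' prevalence_rows(g) # 26.3 (male), 29.8 (female)
ess_table1 <- function() {
  data.frame(
    variable = c("gender", "gender",
                 "marital", "marital", "marital", "marital",
                 "region", "region", "region", "region", "region", "region",
                 "region", "region", "region", "region", "region",
                 "residence", "residence",
                 "shocks", "shocks",
                 "credit", "credit"),
    level = c("male", "female",
              "never_married", "married", "divorced_separated", "widowed",
              "tigray", "afar", "amhara", "oromia", "somalia",
              "benshagul_gumuz", "snnp", "gambelia", "harari",
              "addis_ababa", "diredwa",
              "rural", "urban",
              "yes", "no",
              "yes", "no"),
    n_no = c(2690L, 1120L,
             363L, 2601L, 339L, 488L,
             490L, 106L, 727L, 779L, 177L, 81L, 772L, 110L, 143L, 275L, 150L,
             2168L, 1642L,
             1014L, 2796L,
             2975L, 2690L),
    n_yes = c(958L, 475L,
              52L, 953L, 164L, 253L,
              123L, 29L, 303L, 272L, 113L, 44L, 419L, 17L, 21L, 22L, 71L,
              1139L, 295L,
              882L, 552L,
              484L, 944L),
    stringsAsFactors = FALSE)
}

#' Published continuous-covariate summaries companion to [ess_table1()]
#'
#' Group means and SDs (not insecure / insecure) with the group sizes taken
#' from the gender cell sums (3810 / 1433).
#'
#' @return data.frame with columns `variable, m_no, s_no, n_no, m_yes,
#'   s_yes, n_yes`.
#' @export
ess_table1_summaries <- function() {
  data.frame(
    variable = c("family_size", "schooling", "dep_ratio", "asset", "age"),
    m_no = c(4.32, 7.27, 0.84, 3.11, 41.85),
    s_no = c(2.33, 4.47, 0.87, 1.42, 15.03),
    n_no = 3810L,
    m_yes = c(4.59, 4.89, 1.14, 2.31, 44.44),
    s_yes = c(2.43, 3.20, 1.01, 1.18, 15.51),
    n_yes = 1433L,
    stringsAsFactors = FALSE)
}
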