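#' Five-number length summaries by group
#'
#' Summarises a numeric column per group with Tukey's five numbers: the
#' median uses the midpoint convention for even n and the quartiles are the
#' Tukey hinges (inclusive method). The species attaining the extremes are
#' carried along (first occurrence on ties). Empty groups are skipped with
#' a warning.
#'
#' @param records Data frame of cohort records.
#' @param group_by Name(s) of grouping column(s) (default `protein_class`).
#' @param value_col Numeric column to summarise (default `d2_length`).
#' @param species_col Column naming each record's species.
#' @return Data frame with one row per group: `group`, `n`, `min`, `q1`,
#'   `median`, `q3`, `max`, `min_species`, `max_species`.
#' @export
length_summary <- function(records, group_by = "protein_class",
                           value_col = "d2_length", species_col = "species") {
  key <- interaction(records[group_by], drop = TRUE, sep = "/")
  groups <- split(records, key)
  rows <- lapply(names(groups), function(g) {
    df <- groups[[g]]
    v <- df[[value_col]]
    keep <- !is.na(v)
    if (!any(keep)) {
      warning("empty group '", g, "' skipped", call. = FALSE)
      return(NULL)
    }
    v <- v[keep]; sp <- df[[species_col]][keep]
    fn <- stats::fivenum(v)
    data.frame(group = g, n = length(v), min = fn[1], q1 = fn[2],
               median = fn[3], q3 = fn[4], max = fn[5],
               min_species = sp[which.min(v)], max_species = sp[which.max(v)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(group = character(), n = integer(), min = numeric(),
                      q1 = numeric(), median = numeric(), q3 = numeric(),
                      max = numeric(), min_species = character(),
                      max_species = character(), stringsAsFactors = FALSE)
  out[order(out$group), , drop = FALSE]
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length, n >= 3, each with non-zero
#'   variance. Pairs with missing values are dropped before checking.
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3)
    stop("validation error: need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined-correlation error: zero variance in a margin", call. = FALSE)
  stats::cor(x, y, method = "pearson")
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. In `auto` mode the p-value is exact (full null
#' distribution of U) when `n1 * n2 <= 400` and the pooled sample has no
#' ties, and otherwise uses the tie-corrected normal approximation with
#' continuity correction. U is reported for the first sample (number of
#' (a, b) pairs with a > b, counting ties as 1/2).
#'
#' @param a,b Non-empty numeric samples.
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return List with `U`, `p`, and the `mode` actually used.
#' @export
mann_whitney <- function(a, b, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0)
    stop("validation error: both samples must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0
  if (mode == "auto")
    mode <- if (!ties && length(a) * length(b) <= 400) "exact" else "normal"
  if (mode == "exact" && ties) {
    warning("ties present; falling back to normal approximation", call. = FALSE)
    mode <- "normal"
  }
  wt <- suppressWarnings(stats::wilcox.test(
    a, b, alternative = "two.sided", exact = (mode == "exact"),
    correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value, mode = mode)
}

#' Cohort proportion with integer-percentage reporting
#'
#' Counts how many records satisfying the denominator predicate also
#' satisfy the numerator predicate. The reported percentage is rounded to
#' the nearest integer; the raw fraction is retained.
#'
#' @param numerator,denominator Logical vectors of equal length (`NA`
#'   treated as `FALSE`).
#' @return List with `k`, `n`, `pct` (rounded integer) and `pct_raw`;
#'   `pct` fields are `NA` when `n == 0`.
#' @export
proportion_stats <- function(numerator, denominator = NULL) {
  if (is.null(denominator)) denominator <- rep(TRUE, length(numerator))
  if (length(numerator) != length(denominator))
    stop("validation error: predicate vectors differ in length", call. = FALSE)
  numerator <- !is.na(numerator) & numerator
  denominator <- !is.na(denominator) & denominator
  n <- sum(denominator)
  k <- sum(numerator & denominator)
  if (n == 0) return(list(k = 0L, n = 0L, pct = NA_real_, pct_raw = NA_real_))
  list(k = as.integer(k), n = as.integer(n),
       pct = round(100 * k / n), pct_raw = 100 * k / n)
}

#' Cohort summary bundle
#'
#' Computes, from a cohort record table (one TolA and at most one
#' representative TonB per species), the statistics underpinning the
#' comparative analysis: per-class domain II length summaries, the paired
#' TolA/TonB length correlation, the TolA-vs-TonB length rank test, and the
#' composition-class proportions.
#'
#' @param records Cohort data frame with columns `species`, `protein_class`
#'   (`TolA`/`TonB`), `d2_length`, `helix_pct`, `proline_pct`,
#'   `composition_class`, `lipo_class`.
#' @return List with `length_summaries`, `pearson_r` (NA when fewer than 3
#'   complete pairs), `mann_whitney` (list U, p), and `composition_props`.
#' @export
cohort_summary <- function(records) {
  sums <- length_summary(records)
  tolA <- records[records$protein_class == "TolA", , drop = FALSE]
  tonB <- records[records$protein_class == "TonB", , drop = FALSE]
  paired <- merge(tolA[, c("species", "d2_length")],
                  tonB[, c("species", "d2_length")],
                  by = "species", suffixes = c("_tolA", "_tonB"))
  r <- if (nrow(paired) >= 3)
    tryCatch(pearson(paired$d2_length_tolA, paired$d2_length_tonB),
             error = function(e) NA_real_) else NA_real_
  mw <- if (nrow(tolA) > 0 && nrow(tonB) > 0)
    mann_whitney(tolA$d2_length, tonB$d2_length) else list(U = NA, p = NA)
  comp <- table(factor(records$composition_class,
                       levels = c("alpha_dominant", "proline_dominant",
                                  "mixed", "disordered")),
                records$protein_class)
  list(length_summaries = sums, pearson_r = r, mann_whitney = mw,
       n_pairs = nrow(paired), composition_props = comp)
}
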