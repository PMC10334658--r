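#' Shapiro-Wilk normality test
#'
#' Royston's approximation, as a reported normality screen (the downstream
#' group comparison is rank-based regardless of its outcome).
#'
#' @param x Numeric vector, 3 <= n <= 5000, non-constant.
#' @return List with `statistic` (W) and `p_value`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3L || length(x) > 5000L) {
    abort("Shapiro-Wilk requires 3 <= n <= 5000.")
  }
  if (diff(range(x)) == 0) abort("Shapiro-Wilk is undefined for a constant vector.")
  fit <- stats::shapiro.test(x)
  list(statistic = unname(fit$statistic), p_value = fit$p.value)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided. Uses the exact null distribution when the combined sample size
#' is at most 12 and there are no ties; otherwise the normal approximation
#' with tie and continuity corrections. Ties receive midranks.
#'
#' @param x,y Numeric vectors (both nonempty).
#' @return List with `statistic` (Mann-Whitney W, as `stats::wilcox.test`)
#'   and `p_value`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) abort("Both groups must be nonempty.")
  if (diff(range(c(x, y))) == 0) {
    # fully tied data: no evidence either way
    return(list(statistic = length(x) * length(y) / 2, p_value = 1))
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y) <= 12L) && !ties
  fit <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE)
  )
  list(statistic = unname(fit$statistic), p_value = fit$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up rule `q_(i) = min_{j >= i} m p_(j) / j`, capped at 1, mapped back
#' to the input order.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted q-values in input order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) abort("`p` must be numeric.")
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("All p-values must lie in [0, 1].")
  }
  stats::p.adjust(p, method = "BH")
}

#' Per-taxon differential abundance at a taxonomic level
#'
#' Wilcoxon rank-sum test of relative abundance between case and control per
#' taxon, with one Benjamini-Hochberg family per level and a significance
#' flag at `q < alpha`. A Shapiro-Wilk screen per taxon is reported when
#' computable (constant or oversized vectors yield `NA`); it does not gate
#' the rank test.
#'
#' @param ft A `feature_table` in relative mode with metadata; its level
#'   must match `level` (collapse first if needed).
#' @param level Taxonomic rank of the table.
#' @param alpha FDR significance threshold.
#' @param min_prevalence Optional minimum fraction of samples in which a
#'   taxon must be nonzero to be tested (default 0: test all).
#' @return A `microrewire_da` tibble: `taxon`, `level`, `mean_case`,
#'   `mean_control`, `shapiro_p`, `statistic` (W), `p_value`, `q_value`,
#'   `significant`.
#' @export
diff_abundance_table <- function(ft, level, alpha = 0.05, min_prevalence = 0) {
  stopifnot(inherits(ft, "feature_table"))
  if (ft$mode != "relative") abort("`diff_abundance_table()` requires relative mode.")
  if (is.null(ft$samples)) abort("Sample metadata must be attached.")
  if (is.na(ft$level) || ft$level != level) {
    abort(sprintf("Table level is '%s', not '%s'; collapse first.",
                  ft$level, level))
  }
  grp <- ft$samples$group
  if (!all(c("case", "control") %in% grp)) {
    abort("Both case and control samples are required.")
  }
  v <- ft$values
  keep <- rowMeans(v > 0) >= min_prevalence
  v <- v[keep, , drop = FALSE]
  is_case <- grp == "case"
  recs <- purrr::map_dfr(seq_len(nrow(v)), function(i) {
    x <- v[i, is_case]; y <- v[i, !is_case]
    w <- wilcoxon_rank_sum(x, y)
    sw <- tryCatch(shapiro_wilk(c(x, y))$p_value, error = function(e) NA_real_)
    tibble(
      taxon = rownames(v)[i], level = level,
      mean_case = mean(x), mean_control = mean(y),
      shapiro_p = sw, statistic = w$statistic, p_value = w$p_value
    )
  })
  recs$q_value <- bh_adjust(recs$p_value)
  recs$significant <- recs$q_value < alpha
  class(recs) <- c("microrewire_da", class(recs))
  recs
}
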