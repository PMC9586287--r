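#' Fraction of chemicals where one MoE is more conservative
#'
#' Restricts two MoE tables to their common chemicals and reports the
#' fraction for which the first MoE is strictly smaller than the second
#' (ties count toward neither direction).
#'
#' @param moe_a,moe_b MoE tables with `chem_id` and `moe`.
#' @return A list with `n_common` and `frac_a_lt_b`.
#' @export
conservativeness_fractions <- function(moe_a, moe_b) {
  common <- intersect(moe_a$chem_id, moe_b$chem_id)
  if (length(common) == 0L) stop("the two MoE tables share no chemicals")
  a <- moe_a$moe[match(common, moe_a$chem_id)]
  b <- moe_b$moe[match(common, moe_b$chem_id)]
  list(n_common = length(common), frac_a_lt_b = mean(a < b))
}

#' Coefficient of determination between log10 MoEs
#'
#' Squared Pearson correlation of the log10-transformed MoEs over the common
#' chemicals; symmetric in its arguments. Chemicals with non-positive MoEs
#' are excluded (their count is messaged); zero variance in either vector
#' yields `NA` with a warning.
#'
#' @param moe_a,moe_b MoE tables with `chem_id` and `moe`.
#' @return r-squared in \\[0, 1\\], or `NA` when undefined.
#' @export
log_r2 <- function(moe_a, moe_b) {
  common <- intersect(moe_a$chem_id, moe_b$chem_id)
  a <- moe_a$moe[match(common, moe_a$chem_id)]
  b <- moe_b$moe[match(common, moe_b$chem_id)]
  pos <- a > 0 & b > 0
  if (any(!pos)) {
    message(sum(!pos), " chemical(s) with non-positive MoE excluded from r2")
  }
  a <- log10(a[pos]); b <- log10(b[pos])
  if (length(a) < 3L) stop("need at least 3 common chemicals with positive MoEs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance in log MoEs; r2 undefined")
    return(NA_real_)
  }
  stats::cor(a, b)^2
}

#' Median ratio of two MoE tables
#'
#' Type-2 median (p = 0.5) of the per-chemical ratio numerator/denominator
#' over the common chemicals.
#'
#' @param moe_num,moe_den MoE tables with `chem_id` and `moe`.
#' @return Dimensionless median ratio.
#' @export
median_moe_ratio <- function(moe_num, moe_den) {
  common <- intersect(moe_num$chem_id, moe_den$chem_id)
  if (length(common) == 0L) stop("the two MoE tables share no chemicals")
  num <- moe_num$moe[match(common, moe_num$chem_id)]
  den <- moe_den$moe[match(common, moe_den$chem_id)]
  if (any(den <= 0)) stop("denominator MoEs must be positive")
  quantile_type2(num / den, 0.5)
}

#' Two-sample location and distribution tests
#'
#' Two-sided Wilcoxon rank-sum test for a difference in medians and
#' two-sample Kolmogorov-Smirnov test for a difference in distributions.
#' The rank-sum test uses exact enumeration when both samples have at most
#' 10 observations and no ties, otherwise the normal approximation with
#' continuity and tie correction. The KS statistic is
#' D = sup |ECDF_x - ECDF_y|.
#'
#' @param x,y Numeric samples, each with at least 2 observations.
#' @return A list with `rank_sum` (list: statistic, p_value) and
#'   `ks` (list: statistic, p_value). When a sample is too small the
#'   entry is `NULL` and `computed` is `FALSE`.
#' @export
group_difference_tests <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    return(list(computed = FALSE, rank_sum = NULL, ks = NULL))
  }
  exact <- length(x) <= 10L && length(y) <= 10L &&
    !any(duplicated(c(x, y)))
  w <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  k <- suppressWarnings(
    stats::ks.test(x, y, alternative = "two.sided")
  )
  list(
    computed = TRUE,
    rank_sum = list(statistic = unname(w$statistic), p_value = w$p.value),
    ks = list(statistic = unname(k$statistic), p_value = k$p.value)
  )
}

#' Full comparison summary between MoE tables
#'
#' Computes the conservativeness fractions, log-space r-squared values,
#' median MoE ratios and, when a category column is available, per-category
#' rank-sum and KS tests between the two inputs of each MoE.
#'
#' @param moe_ttc,moe_oed,moe_noael MoE tables from [compute_moe_table()]
#'   (`moe_noael` may be `NULL`).
#' @return A list mirroring the printed comparison metrics: `n_common`,
#'   `frac_ttc_lt_oed`, `frac_ttc_lt_noael`, `frac_oed_lt_noael`,
#'   `r2_log_noael_vs_ttc`, `r2_log_noael_vs_oed`,
#'   `median_ratio_noael_over_oed`, `median_ratio_noael_over_ttc`,
#'   `category_tests`.
#' @export
compare_moe_tables <- function(moe_ttc, moe_oed, moe_noael = NULL) {
  out <- list()
  f_to <- conservativeness_fractions(moe_ttc, moe_oed)
  out$frac_ttc_lt_oed <- f_to$frac_a_lt_b
  out$n_common <- f_to$n_common
  if (!is.null(moe_noael)) {
    out$frac_ttc_lt_noael <-
      conservativeness_fractions(moe_ttc, moe_noael)$frac_a_lt_b
    out$frac_oed_lt_noael <-
      conservativeness_fractions(moe_oed, moe_noael)$frac_a_lt_b
    out$r2_log_noael_vs_ttc <- log_r2(moe_noael, moe_ttc)
    out$r2_log_noael_vs_oed <- log_r2(moe_noael, moe_oed)
    out$median_ratio_noael_over_ttc <- median_moe_ratio(moe_noael, moe_ttc)
    out$median_ratio_noael_over_oed <- median_moe_ratio(moe_noael, moe_oed)
  }
  if ("ttc_category" %in% names(moe_ttc)) {
    cats <- unique(moe_ttc$ttc_category)
    tests <- lapply(cats, function(cc) {
      ids <- moe_ttc$chem_id[moe_ttc$ttc_category == cc]
      x <- moe_ttc$moe[moe_ttc$chem_id %in% ids]
      y <- moe_oed$moe[moe_oed$chem_id %in% ids]
      if (length(x) < 2L || length(y) < 2L) {
        return(list(category = cc, computed = FALSE))
      }
      gt <- group_difference_tests(log10(x), log10(y))
      c(list(category = cc), gt)
    })
    names(tests) <- cats
    out$category_tests <- tests
  }
  out
}
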