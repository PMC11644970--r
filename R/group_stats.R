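# Two-group non-parametric comparison (normality screen, Mann-Whitney U,
# median/IQR summaries).

#' Shapiro-Wilk normality screen
#'
#' @param values Numeric values for one variable.
#' @param group Group labels aligned with `values`.
#' @return Named numeric vector of per-group Shapiro-Wilk p-values (`NA`
#'   for a constant or too-small sample).
#' @export
normality_screen <- function(values, group) {
  vapply(split(values, group), function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 3 || length(unique(v)) == 1) return(NA_real_)
    stats::shapiro.test(v)$p.value
  }, numeric(1))
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. `U` is the statistic of the first sample
#' (number of (a, b) pairs with a > b, ties counting 1/2). For combined
#' n <= `exact_max` with no ties, the p-value comes from the exact null
#' distribution of U; otherwise from the normal approximation with tie
#' correction and continuity correction.
#'
#' @param a,b Numeric samples (non-empty).
#' @param exact_max Largest combined sample size for the exact p-value.
#' @return List with `U`, `p_value`, and `method` ("exact" or "normal").
#' @export
mann_whitney <- function(a, b, exact_max = 12) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("empty group in Mann-Whitney test")
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- any(duplicated(c(a, b)))
  if (na + nb <= exact_max && !ties) {
    # exact: P(|U - mu| >= |u - mu|) under the null (pwilcox enumerates
    # the exact distribution of U)
    mu <- na * nb / 2
    lo <- min(U, na * nb - U)
    p <- stats::pwilcox(lo, na, nb) +
      (1 - stats::pwilcox(na * nb - lo - 1L, na, nb))
    if (lo == mu) p <- 1
    return(list(U = U, p_value = min(1, p), method = "exact"))
  }
  n <- na + nb
  tie_tab <- table(r)
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
  mu <- na * nb / 2
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
  list(U = U, p_value = min(1, 2 * stats::pnorm(-max(z, 0))),
       method = "normal")
}

#' Compare all features between groups
#'
#' One row per feature column: group medians and IQRs (linear-interpolation
#' quartiles), Shapiro-Wilk p-values, Mann-Whitney U and p, and the
#' significance flag at `alpha`. Missing values are excluded pairwise; a
#' variable entirely missing in a group is skipped with a warning.
#'
#' @param cohort_table Data frame from [cohort_features()] (columns
#'   `group` plus numeric features).
#' @param alpha Per-variable significance level.
#' @param holm Apply a Holm correction across rows (off by default, as the
#'   study reported per-variable tests).
#' @return Data frame of comparison rows.
#' @export
compare_all <- function(cohort_table, alpha = 0.05, holm = FALSE) {
  stopifnot("group" %in% names(cohort_table))
  g <- cohort_table$group
  lv <- sort(unique(g))
  stopifnot(length(lv) == 2)
  vars <- setdiff(names(cohort_table), c("subject_id", "group"))
  vars <- vars[vapply(cohort_table[vars], is.numeric, TRUE)]
  rows <- list()
  for (v in vars) {
    x <- cohort_table[[v]]
    a <- x[g == lv[1]]; bb <- x[g == lv[2]]
    a <- a[!is.na(a)]; bb <- bb[!is.na(bb)]
    if (!length(a) || !length(bb)) {
      warning("variable ", v, " entirely missing in one group: skipped")
      next
    }
    mw <- mann_whitney(a, bb)
    sw <- normality_screen(x, g)
    q <- function(z) stats::quantile(z, c(0.25, 0.5, 0.75), names = FALSE,
                                     type = 7)
    qa <- q(a); qb <- q(bb)
    rows[[v]] <- data.frame(
      variable = v,
      median_1 = qa[2], iqr_1 = qa[3] - qa[1],
      median_2 = qb[2], iqr_2 = qb[3] - qb[1],
      shapiro_p_1 = sw[[lv[1]]], shapiro_p_2 = sw[[lv[2]]],
      U = mw$U, p_value = mw$p_value)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (holm) out$p_value <- stats::p.adjust(out$p_value, "holm")
  out$significant <- out$p_value < alpha
  attr(out, "groups") <- lv
  out
}
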