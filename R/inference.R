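#' Kruskal-Wallis omnibus test across pathology groups
#'
#' Rank-based H statistic with tie correction and chi-square p-value
#' (k - 1 df), via [stats::kruskal.test()]. When all observations are
#' identical the test is undefined; the conventional p = 1 is returned
#' with `flag = "degenerate"`.
#'
#' @param data Data frame.
#' @param value Name of the numeric outcome column.
#' @param group Name of the grouping column.
#' @param family Test-family label carried through for stratified FDR.
#' @return One-row tibble: `test`, `statistic`, `df`, `p`, `n`,
#'   `n_groups`, `family`, `flag`.
#' @export
kruskal_wallis <- function(data, value, group, family = NA_character_) {
  v <- data[[value]]; g <- factor(data[[group]])
  ok <- !is.na(v) & !is.na(g)
  v <- v[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2) abort("Need at least two groups.")
  if (length(v) < 3) abort("Need at least three observations in total.")
  if (length(unique(v)) == 1) {
    return(tibble::tibble(test = "kruskal-wallis", statistic = 0,
                          df = nlevels(g) - 1, p = 1, n = length(v),
                          n_groups = nlevels(g), family = family,
                          flag = "degenerate"))
  }
  kt <- kruskal.test(v, g)
  tibble::tibble(test = "kruskal-wallis",
                 statistic = unname(kt$statistic),
                 df = unname(kt$parameter), p = kt$p.value, n = length(v),
                 n_groups = nlevels(g), family = family, flag = NA_character_)
}

#' Pairwise two-sided Mann-Whitney U tests
#'
#' One test per unordered pair of group levels, via [stats::wilcox.test()]
#' (exact enumeration when both groups have n <= 10 and no ties; normal
#' approximation with continuity and tie correction otherwise). The
#' reported statistic is the U count for `group1`.
#'
#' @inheritParams kruskal_wallis
#' @return Tibble with one row per pair: `group1`, `group2`, `statistic`,
#'   `p`, `n1`, `n2`, `direction` (sign of the median difference
#'   group1 - group2), `family`, `flag`.
#' @export
mann_whitney_pairwise <- function(data, value, group, family = NA_character_) {
  v <- data[[value]]; g <- factor(data[[group]])
  ok <- !is.na(v) & !is.na(g)
  v <- v[ok]; g <- droplevels(g[ok])
  lev <- levels(g)
  if (length(lev) < 2) abort("Need at least two groups.")
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    x <- v[g == pr[1]]; y <- v[g == pr[2]]
    degenerate <- length(unique(c(x, y))) == 1
    if (degenerate) {
      return(tibble::tibble(test = "mann-whitney", group1 = pr[1],
                            group2 = pr[2], statistic = length(x) * length(y) / 2,
                            p = 1, n1 = length(x), n2 = length(y),
                            direction = 0, family = family,
                            flag = "degenerate"))
    }
    exact <- length(x) <= 10 && length(y) <= 10 &&
      !any(duplicated(c(x, y)))
    wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
    tibble::tibble(test = "mann-whitney", group1 = pr[1], group2 = pr[2],
                   statistic = unname(wt$statistic), p = wt$p.value,
                   n1 = length(x), n2 = length(y),
                   direction = sign(median(x) - median(y)),
                   family = family, flag = NA_character_)
  })
}

#' Benjamini-Hochberg q-values, stratified by test family
#'
#' Within each family independently, the step-up BH estimate
#' \eqn{q_{(i)} = \min_{j \ge i} (p_{(j)} m / j)} (capped at 1) is computed
#' on the sorted p-values and mapped back to input order. Families are
#' never pooled: changing one family's p-values cannot move another
#' family's q-values.
#'
#' @param p Numeric p-values in [0, 1].
#' @param family Family label per p-value (single value recycled).
#' @return Numeric q-values, same order as `p`.
#' @export
bh_fdr <- function(p, family = "all") {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  family <- rep_len(as.character(family), length(p))
  q <- rep(NA_real_, length(p))
  for (fam in unique(family)) {
    idx <- which(family == fam & !is.na(p))
    if (length(idx) == 0) next
    pv <- p[idx]
    m <- length(pv)
    o <- order(pv)
    qs <- rev(cummin(rev(pv[o] * m / seq_len(m))))
    qs <- pmin(qs, 1)
    q[idx[o]] <- qs
  }
  q
}

#' Add family-stratified q-values to a results table
#'
#' @param results Tibble with a p-value column and a family column.
#' @param p_col,family_col Column names.
#' @return `results` with a `q` column appended.
#' @export
add_fdr <- function(results, p_col = "p", family_col = "family") {
  results$q <- bh_fdr(results[[p_col]], results[[family_col]])
  results
}

#' Dummy-coded group regression (linear or logistic)
#'
#' Fits outcome ~ pathology dummies (+ optional covariates) with the
#' reference level (glioblastoma by default) absorbed into the intercept.
#' Linear models use least squares, logistic models maximum likelihood.
#' Perfect separation in logistic fits is flagged, never silent; a
#' rank-deficient design is an error naming the collinear columns.
#'
#' @param data Data frame.
#' @param outcome Outcome column name (numeric, or 0/1 / logical for
#'   logistic).
#' @param pathology Grouping column name.
#' @param covariates Optional covariate column names (e.g. age, sex).
#' @param family "linear" or "logistic".
#' @param reference Reference pathology level.
#' @return Object of class `fw_regression`; see [tidy.fw_regression()].
#' @export
group_regression <- function(data, outcome, pathology, covariates = NULL,
                             family = c("linear", "logistic"),
                             reference = "glioblastoma") {
  family <- match.arg(family)
  g <- factor(data[[pathology]])
  if (!reference %in% levels(g)) {
    abort(sprintf("Reference level '%s' absent from `%s`.", reference,
                  pathology))
  }
  if (nlevels(droplevels(g)) < 2) abort("Need at least two pathology levels.")
  data[[pathology]] <- stats::relevel(g, ref = reference)
  rhs <- paste(c(pathology, covariates), collapse = " + ")
  fml <- stats::as.formula(paste(outcome, "~", rhs))
  flag <- NA_character_
  if (family == "linear") {
    fit <- lm(fml, data = data)
  } else {
    fit <- suppressWarnings(glm(fml, data = data, family = binomial()))
    mu <- stats::fitted(fit)
    if (any(mu > 1 - 1e-8) || any(mu < 1e-8)) flag <- "possible separation"
  }
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    abort(paste0("Rank-deficient design; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  structure(list(fit = fit, family = family, outcome = outcome,
                 pathology = pathology, covariates = covariates,
                 reference = reference, flag = flag),
            class = "fw_regression")
}

#' @export
print.fw_regression <- function(x, ...) {
  cat(sprintf("<fw_regression> %s model of %s (reference %s)%s\n",
              x$family, x$outcome, x$reference,
              if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""))
  print(tidy(x))
  invisible(x)
}

#' Coefficient table of a group regression
#'
#' @param x An `fw_regression`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std_error`, `statistic`, `p`
#'   (intercept included; the reference pathology level never appears as a
#'   term).
#' @export
tidy.fw_regression <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(sm), estimate = unname(sm[, 1]),
                 std_error = unname(sm[, 2]), statistic = unname(sm[, 3]),
                 p = unname(sm[, 4]))
}

#' @export
glance.fw_regression <- function(x, ...) {
  tibble::tibble(family = x$family, outcome = x$outcome,
                 n = stats::nobs(x$fit), reference = x$reference,
                 flag = x$flag)
}

#' Shapiro-Wilk normality screen
#'
#' @param x Numeric sample, 3 <= n <= 5000.
#' @param family Family label.
#' @return One-row TestResult tibble (constant input yields NA p with
#'   `flag = "degenerate"`).
#' @export
shapiro_wilk <- function(x, family = NA_character_) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || length(x) > 5000) {
    abort("Shapiro-Wilk requires 3 <= n <= 5000.")
  }
  if (length(unique(x)) == 1) {
    return(tibble::tibble(test = "shapiro-wilk", statistic = NA_real_,
                          p = NA_real_, n = length(x), family = family,
                          flag = "degenerate"))
  }
  st <- shapiro.test(x)
  tibble::tibble(test = "shapiro-wilk", statistic = unname(st$statistic),
                 p = st$p.value, n = length(x), family = family,
                 flag = NA_character_)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks with a two-sided p-value
#' (t approximation, appropriate for tied data).
#'
#' @param x,y Equal-length numeric vectors (n >= 3 after NA removal).
#' @return One-row tibble `rho`, `p`, `n`, `flag` (zero-variance input
#'   yields NA rho, flagged).
#' @export
spearman_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("Need at least three complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble::tibble(rho = NA_real_, p = NA_real_, n = length(x),
                          flag = "zero variance"))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  tibble::tibble(rho = unname(ct$estimate), p = ct$p.value, n = length(x),
                 flag = NA_character_)
}
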