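## Diagnostic validation of a dichotomized grading scheme against a binary
## outcome: 2x2 construction, accuracy / DOR / PPV / NPV with confidence
## intervals, chi-square / Fisher association testing, Cramer's V, and
## reclassification matrices between schemes.

OUTCOMES <- c("death", "primary_OM", "any_OM")

#' Construct a labelled 2x2 contingency table
#'
#' Orientation follows the diagnostic-test convention used throughout the
#' package: rows are severity (severe on top), columns the binary outcome
#' (event first).  `a` = severe with event, `b` = severe without event,
#' `c` = mild with event, `d` = mild without event.
#'
#' @param a,b,c,d Nonnegative integer cell counts.
#' @param row_label,col_label Free-text axis labels.
#' @return An object of class `two_by_two`.
#' @export
two_by_two <- function(a, b, c, d, row_label = "severity", col_label = "outcome") {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    trauma_error("trauma_bad_table", "cell counts must be nonnegative integers")
  if (sum(cells) <= 0)
    trauma_error("trauma_empty_table", "2x2 table has no observations")
  structure(list(a = a, b = b, c = c, d = d, n = a + b + c + d,
                 row_label = row_label, col_label = col_label),
            class = "two_by_two")
}

#' @export
as.matrix.two_by_two <- function(x, ...) {
  matrix(c(x$a, x$b, x$c, x$d), nrow = 2, byrow = TRUE,
         dimnames = list(severity = c("severe", "mild"),
                         outcome = c("event", "no_event")))
}

#' @export
print.two_by_two <- function(x, ...) {
  cat(sprintf("<two_by_two> %s x %s (n = %d)\n", x$row_label, x$col_label, x$n))
  print(as.matrix(x))
  invisible(x)
}

outcome_flag <- function(p, outcome) {
  switch(outcome,
         death = isTRUE(p$death_in_hospital),
         primary_OM = identical(p$primary_management, "OM"),
         any_OM = identical(p$primary_management, "OM") || isTRUE(p$secondary_om))
}

#' Build the severity-by-outcome 2x2 table for a cohort
#'
#' Includes every patient whose named organ is gradeable; combined-injury
#' patients therefore enter both organ-specific analyses.  Severity is the
#' mild/severe dichotomy of the grade under `scheme`; `any_OM` is the
#' composite of primary operative management or failure of non-operative
#' management (secondary OM).
#'
#' @param x A [cohort()].
#' @param scheme Grading scheme.
#' @param organ `"spleen"` or `"liver"`.
#' @param outcome `"death"`, `"primary_OM"` or `"any_OM"`.
#' @return A [two_by_two()].
#' @export
build_two_by_two <- function(x, scheme = SCHEMES, organ = ORGANS,
                             outcome = OUTCOMES) {
  scheme <- match.arg(scheme)
  organ <- match.arg(organ)
  outcome <- match.arg(outcome)
  if (length(x$patients) == 0L)
    trauma_error("trauma_empty_table", "cohort is empty")
  a <- b <- cc <- d <- 0L
  field <- paste0(organ, "_findings")
  for (p in x$patients) {
    fnd <- p[[field]]
    if (!is_gradeable(fnd)) next
    severe <- identical(grade_organ(fnd, scheme)$severity, "severe")
    event <- outcome_flag(p, outcome)
    if (severe && event) a <- a + 1L
    else if (severe) b <- b + 1L
    else if (event) cc <- cc + 1L
    else d <- d + 1L
  }
  if (a + b + cc + d == 0L)
    trauma_error("trauma_empty_table",
                 sprintf("no gradeable %s in cohort", organ))
  two_by_two(a, b, cc, d,
             row_label = sprintf("%s %s severity", scheme, organ),
             col_label = outcome)
}

## Metrics ------------------------------------------------------------------

#' Diagnostic metrics of a dichotomized grading against a binary outcome
#'
#' Accuracy `(a+d)/n` with a Wilson score 95% interval; diagnostic odds
#' ratio `ad/(bc)` with a Woolf logit 95% interval
#' `exp(log(DOR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`; positive and
#' negative predictive values; and the association test p value.  If any
#' cell is zero, 0.5 is added to every cell for the DOR and its interval
#' only (Haldane-Anscombe) and `corrected` is set.
#'
#' @param t A [two_by_two()].
#' @param conf_level Confidence level for the intervals (default 0.95).
#' @return An object of class `diagnostic_result`.
#' @export
diagnostic_metrics <- function(t, conf_level = 0.95) {
  stopifnot(inherits(t, "two_by_two"))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  n <- t$n
  acc <- (t$a + t$d) / n
  acc_ci <- as.numeric(suppressWarnings(
    stats::prop.test(t$a + t$d, n, correct = FALSE,
                     conf.level = conf_level))$conf.int)
  cells <- c(t$a, t$b, t$c, t$d)
  corrected <- any(cells == 0)
  dcells <- if (corrected) cells + 0.5 else cells
  dor <- (dcells[1] * dcells[4]) / (dcells[2] * dcells[3])
  se <- sqrt(sum(1 / dcells))
  dor_ci <- exp(log(dor) + c(-1, 1) * z * se)
  ppv <- if (t$a + t$b > 0) t$a / (t$a + t$b) else NA_real_
  npv <- if (t$c + t$d > 0) t$d / (t$c + t$d) else NA_real_
  assoc <- association_test(t)
  structure(list(
    accuracy = acc, accuracy_ci = acc_ci,
    dor = dor, dor_ci = dor_ci,
    ppv = ppv, npv = npv,
    ppv_defined = t$a + t$b > 0, npv_defined = t$c + t$d > 0,
    p_value = assoc$p_value, test_used = assoc$test_used,
    chi_square = assoc$chi_square,
    corrected = corrected, n = n, conf_level = conf_level
  ), class = "diagnostic_result")
}

#' @export
print.diagnostic_result <- function(x, ...) {
  cat(sprintf(
    "<diagnostic_result> n = %d\n accuracy %.1f%% (%.1f-%.1f)\n DOR %.2f (%.2f-%.2f)%s\n PPV %.1f%%  NPV %.1f%%\n p = %.3g (%s)\n",
    x$n, 100 * x$accuracy, 100 * x$accuracy_ci[1], 100 * x$accuracy_ci[2],
    x$dor, x$dor_ci[1], x$dor_ci[2],
    if (x$corrected) " [0.5 zero-cell correction]" else "",
    100 * x$ppv, 100 * x$npv, x$p_value, x$test_used))
  invisible(x)
}

#' Chi-square or Fisher association test for a 2x2 table
#'
#' Test selection follows the "< 5 cases per group" rule: if any observed
#' cell is below 5, a two-sided Fisher exact test (summing hypergeometric
#' outcomes with probability not exceeding the observed table); otherwise
#' the Pearson chi-square on 1 df without continuity correction.  A zero
#' row or column margin is degenerate: p = 1 with a flag.
#'
#' @param t A [two_by_two()] or 2x2 count matrix.
#' @return List with `p_value`, `test_used` (`"chi_square"`/`"fisher"`),
#'   `chi_square` (uncorrected Pearson statistic, `NA` when degenerate) and
#'   `degenerate`.
#' @export
association_test <- function(t) {
  m <- if (inherits(t, "two_by_two")) as.matrix(t) else as.matrix(t)
  if (sum(m) <= 0)
    trauma_error("trauma_empty_table", "table has no observations")
  use_fisher <- any(m < 5)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(list(p_value = 1, test_used = if (use_fisher) "fisher" else "chi_square",
                chi_square = NA_real_, degenerate = TRUE))
  }
  chi <- as.numeric(suppressWarnings(
    stats::chisq.test(m, correct = FALSE)$statistic))
  if (use_fisher) {
    p <- stats::fisher.test(m)$p.value
    list(p_value = p, test_used = "fisher", chi_square = chi, degenerate = FALSE)
  } else {
    p <- stats::pchisq(chi, df = (nrow(m) - 1) * (ncol(m) - 1), lower.tail = FALSE)
    list(p_value = p, test_used = "chi_square", chi_square = chi, degenerate = FALSE)
  }
}

#' Cramer's V association measure
#'
#' `V = sqrt(chi2 / (n * (min(r, c) - 1)))` with the uncorrected Pearson
#' chi-square; for a 2x2 table this equals the absolute phi coefficient
#' `|ad - bc| / sqrt((a+b)(c+d)(a+c)(b+d))`.  A zero margin returns 0 with
#' a flag.  Values above 0.250 are conventionally read as strong
#' association.
#'
#' @param m A count matrix (at least 2x2) or a [two_by_two()].
#' @return An object of class `association_result`: `cramer_v`,
#'   `chi_square`, `p_value`, `test_used`, `degenerate`.
#' @export
cramers_v <- function(m) {
  if (inherits(m, "two_by_two")) m <- as.matrix(m)
  m <- as.matrix(m)
  if (nrow(m) < 2 || ncol(m) < 2)
    trauma_error("trauma_bad_table", "Cramer's V needs at least a 2x2 table")
  n <- sum(m)
  if (n <= 0)
    trauma_error("trauma_empty_table", "table has no observations")
  assoc <- association_test(m)
  if (isTRUE(assoc$degenerate)) {
    v <- 0
    chi <- NA_real_
  } else {
    chi <- assoc$chi_square
    v <- sqrt(chi / (n * (min(dim(m)) - 1)))
  }
  structure(list(cramer_v = v, chi_square = chi, p_value = assoc$p_value,
                 test_used = assoc$test_used, degenerate = assoc$degenerate,
                 n = n),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("<association_result> Cramer V = %.3f (chi2 = %.3g, p = %.3g, %s)\n",
              x$cramer_v, x$chi_square, x$p_value, x$test_used))
  invisible(x)
}

#' Full validation of one scheme/organ/outcome combination
#'
#' Composition of [build_two_by_two()], [diagnostic_metrics()] and
#' [cramers_v()] — one call per panel of the mortality / operative
#' management figures.
#'
#' @inheritParams build_two_by_two
#' @return List with elements `table`, `diagnostics`, `association`.
#' @export
validate_scheme <- function(x, scheme = SCHEMES, organ = ORGANS,
                            outcome = OUTCOMES) {
  t <- build_two_by_two(x, scheme, organ, outcome)
  list(table = t,
       diagnostics = diagnostic_metrics(t),
       association = cramers_v(t))
}

## Reclassification ---------------------------------------------------------

aligned_rank <- function(scheme, value) {
  r <- grade_rank(scheme, value)
  if (scheme == "CTSI") pmin(r, 4L) else r
}

#' Cross-tabulate the grades of two schemes (reclassification matrix)
#'
#' Cell (i, j) counts patients graded i under `scheme_from` and j under
#' `scheme_to`.  "Changed" counts patients off the aligned diagonal: AAST
#' grades align by value, and CTSI IVa/IVb both align with AAST grade IV.
#' Upstage/downstage counts use the mild/severe dichotomy.
#'
#' @param x A [cohort()].
#' @param organ Organ to grade.
#' @param scheme_from,scheme_to The two schemes to compare.
#' @return List with `matrix` (grade-from x grade-to counts),
#'   `n_upstaged_mild_to_severe`, `n_downstaged_severe_to_mild`,
#'   `n_changed`, `n`.
#' @export
reclassification_matrix <- function(x, organ = ORGANS,
                                    scheme_from = SCHEMES, scheme_to = SCHEMES) {
  organ <- match.arg(organ)
  scheme_from <- match.arg(scheme_from, SCHEMES)
  scheme_to <- match.arg(scheme_to, SCHEMES)
  g <- grade_cohort(x, schemes = unique(c(scheme_from, scheme_to)),
                    organs = organ)
  if (is.null(g) || nrow(g) == 0L)
    trauma_error("trauma_empty_table",
                 sprintf("no gradeable %s in cohort", organ))
  gf <- g[g$scheme == scheme_from, ]
  gt <- g[g$scheme == scheme_to, ]
  stopifnot(identical(gf$patient_id, gt$patient_id))
  lev_f <- grade_rank_map(scheme_from)
  lev_t <- grade_rank_map(scheme_to)
  mat <- table(factor(gf$grade, levels = lev_f),
               factor(gt$grade, levels = lev_t))
  names(dimnames(mat)) <- c(scheme_from, scheme_to)
  changed <- aligned_rank(scheme_from, gf$grade) != aligned_rank(scheme_to, gt$grade)
  up <- gf$severity == "mild" & gt$severity == "severe"
  down <- gf$severity == "severe" & gt$severity == "mild"
  list(matrix = unclass(mat),
       n_upstaged_mild_to_severe = sum(up),
       n_downstaged_severe_to_mild = sum(down),
       n_changed = sum(changed),
       n = nrow(gf))
}
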