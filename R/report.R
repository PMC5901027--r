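# Manual-vs-CAP comparison statistics: Mann-Whitney U (tie-aware exact
# enumeration for small samples, normal approximation otherwise),
# Kruskal-Wallis, Pearson correlation with Fisher-z CI, cylinder-model
# estimation error and cohort comparison tables.

#' Mann-Whitney U test
#'
#' `U` counts pairs where a value of `a` exceeds a value of `b` (ties count
#' one half). For `length(a) + length(b) <= 12` the two-sided p-value is
#' computed by exact enumeration of all group assignments of the pooled
#' sample (valid under ties); larger samples use the normal approximation
#' with tie and continuity correction.
#'
#' @param a,b Numeric vectors, each non-empty.
#' @return List with `U`, `p_two_sided` and `method`.
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) == 0 || length(b) == 0)
    stop("both groups must be non-empty")
  u_stat <- function(x, y) {
    d <- outer(x, y, "-")
    sum(d > 0) + 0.5 * sum(d == 0)
  }
  u <- u_stat(a, b)
  n <- length(a) + length(b)
  if (n <= 12) {
    pooled <- c(a, b)
    picks <- combn(n, length(a))
    us <- apply(picks, 2, function(ix) u_stat(pooled[ix], pooled[-ix]))
    p <- min(1, 2 * min(mean(us <= u), mean(us >= u)))
    return(list(U = u, p_two_sided = p, method = "exact enumeration"))
  }
  p <- suppressWarnings(
    wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
  list(U = u, p_two_sided = p,
       method = "normal approximation (tie + continuity corrected)")
}

#' Kruskal-Wallis rank test
#'
#' Standard tie-corrected H with a chi-square reference distribution on
#' k - 1 degrees of freedom. A fully degenerate input (all values
#' identical) returns H = 0, p = 1.
#'
#' @param groups List of non-empty numeric vectors (>= 2 groups).
#' @return List with `H`, `p` and `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least two groups")
  if (any(vapply(groups, length, 0L) == 0))
    stop("all groups must be non-empty")
  vals <- unlist(groups)
  if (length(unique(vals)) == 1)
    return(list(H = 0, p = 1, df = length(groups) - 1))
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  kt <- kruskal.test(vals, g)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter))
}

#' Pearson correlation with a Fisher-z 95% confidence interval
#'
#' @param x,y Numeric vectors, `n >= 3`, neither constant.
#' @return List with `r`, `ci95_lo`, `ci95_hi`, `R2` and `p` (t-test on
#'   n - 2 df).
#' @export
pearson_ci <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for constant input")
  ct <- cor.test(x, y, method = "pearson", conf.level = 0.95)
  r <- unname(ct$estimate)
  ci <- if (!is.null(ct$conf.int)) ct$conf.int else c(NA_real_, NA_real_)
  list(r = r, ci95_lo = ci[1], ci95_hi = ci[2], R2 = r^2,
       p = ct$p.value)
}

#' Cylinder-model estimation error per ROI
#'
#' Signed difference between expected (modeled) and achieved ablated
#' volumes as a percentage of the baseline anatomical volume; positive
#' values mean the cylinder model overestimates.
#'
#' @param expected,achieved `ablation_report` objects sharing ROI roles
#'   and anatomical volumes.
#' @return Data frame with `role` and `error_percent_of_anatomical`.
#' @export
estimation_error <- function(expected, achieved) {
  e <- expected$per_roi; a <- achieved$per_roi
  if (!identical(e$role, a$role))
    stop("expected and achieved reports cover different ROI roles")
  if (max(abs(e$anatomical_volume_mm3 - a$anatomical_volume_mm3)) > 1e-6)
    stop("expected and achieved reports disagree on anatomical volumes")
  err <- ifelse(e$anatomical_volume_mm3 > 0,
                100 * (e$ablated_volume_mm3 - a$ablated_volume_mm3) /
                  e$anatomical_volume_mm3, 0)
  data.frame(role = e$role, error_percent_of_anatomical = err,
             stringsAsFactors = FALSE)
}

#' Compare manual and CAP arms of a cohort
#'
#' Takes a long-format cohort table (one row per case and arm; columns
#' `case_id`, `arm` in `{"manual", "cap"}`, plus numeric metric columns)
#' and produces, per metric, mean and SD per arm with a two-sided
#' Mann-Whitney p-value.
#'
#' @param table Data frame as described.
#' @param metrics Metric column names; defaults to all numeric columns
#'   other than `case_id`/`arm`.
#' @param alpha Significance flag threshold.
#' @return Data frame with one row per metric: `metric`, `manual_mean`,
#'   `manual_sd`, `cap_mean`, `cap_sd`, `p_value`, `significant`.
#' @export
cohort_compare <- function(table, metrics = NULL, alpha = 0.05) {
  stopifnot(all(c("case_id", "arm") %in% names(table)))
  if (!all(table$arm %in% c("manual", "cap")))
    stop("arm must be 'manual' or 'cap'")
  if (anyDuplicated(table[, c("case_id", "arm")]))
    stop("each case_id may appear at most once per arm")
  both <- intersect(table$case_id[table$arm == "manual"],
                    table$case_id[table$arm == "cap"])
  if (length(both) < 2)
    stop("need at least two cases present in both arms")
  if (is.null(metrics)) {
    metrics <- setdiff(names(table)[vapply(table, is.numeric, TRUE)],
                       c("case_id"))
  }
  rows <- lapply(metrics, function(mcol) {
    man <- table[[mcol]][table$arm == "manual"]
    cap <- table[[mcol]][table$arm == "cap"]
    man <- man[!is.na(man)]; cap <- cap[!is.na(cap)]
    mw <- mann_whitney_u(man, cap)
    data.frame(metric = mcol,
               manual_mean = mean(man), manual_sd = sd(man),
               cap_mean = mean(cap), cap_sd = sd(cap),
               p_value = mw$p_two_sided,
               significant = mw$p_two_sided < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
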