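#' Assemble a long-format condition table
#'
#' Per-cell measurements across physiological conditions, one value per
#' (cell, condition, compartment, metric) combination. Conditions typically
#' span `normal`, `hypertonic`, `hypotonic`, `atp_depletion` and `act_d`;
#' compartments `nucleolus`, `nucleoplasm`, `cytoplasm`; metrics `mean_ri`,
#' `volume_um3`, `D_um2s`.
#'
#' @param cell_id,condition,compartment,metric,value Equal-length vectors,
#'   or a data frame with these columns passed as `cell_id`.
#' @return A tibble of class `condition_table`.
#' @export
condition_table <- function(cell_id, condition = NULL, compartment = NULL,
                            metric = NULL, value = NULL) {
  tab <- if (is.data.frame(cell_id)) tibble::as_tibble(cell_id)
         else tibble::tibble(cell_id = cell_id, condition = condition,
                             compartment = compartment, metric = metric,
                             value = value)
  need <- c("cell_id", "condition", "compartment", "metric", "value")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  key <- paste(tab$cell_id, tab$condition, tab$compartment, tab$metric)
  if (anyDuplicated(key))
    stop("duplicate (cell, condition, compartment, metric) entries")
  class(tab) <- c("condition_table", class(tab))
  tab
}

#' Per-group summary statistics
#'
#' Mean, SD, SEM (`SD / sqrt(n)`) and n for every
#' (condition, compartment, metric) group; the form in which grouped cell
#' measurements are reported (mean +/- SEM over n cells).
#'
#' @param table A [condition_table()].
#' @return Tibble with `condition`, `compartment`, `metric`, `n`, `mean`,
#'   `sd`, `sem`.
#' @export
group_summary <- function(table) {
  stopifnot(inherits(table, "condition_table"))
  out <- dplyr::summarise(
    dplyr::group_by(table, .data$condition, .data$compartment, .data$metric),
    n = dplyr::n(), mean = mean(.data$value), sd = sd(.data$value),
    .groups = "drop")
  if (any(out$n < 2))
    stop("every (condition, compartment, metric) group needs n >= 2")
  out$sem <- out$sd / sqrt(out$n)
  out
}

#' Two-sample Student's t-test
#'
#' Pooled-variance two-sided t-test between two groups of cell
#' measurements, the comparison used for condition effects, with `p < alpha`
#' flagged significant. Degenerate input with zero pooled variance and equal
#' means returns `t = 0, p = 1` instead of erroring. Welch's unequal-variance
#' form is available behind `var_equal = FALSE`.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param alpha Significance level; default 0.05.
#' @param var_equal Pool variances (Student's test, default `TRUE`).
#' @return List with `t`, `df`, `p`, `significant`.
#' @export
ttest <- function(group_a, group_b, alpha = 0.05, var_equal = TRUE) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs n >= 2")
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    if (mean(group_a) == mean(group_b))
      return(list(t = 0, df = length(group_a) + length(group_b) - 2,
                  p = 1, significant = FALSE))
    stop("zero variance in both groups with unequal means: t undefined")
  }
  ht <- t.test(group_a, group_b, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, significant = ht$p.value < alpha)
}

#' Condition-versus-baseline comparison report
#'
#' For every non-baseline condition and every (compartment, metric) present
#' in the baseline, reports the percent change of the group mean relative to
#' baseline, the Student's t-test against the baseline group, and a
#' significance star at `p < alpha`. Raw p-values are reported without
#' multiple-testing correction. Combinations missing from a condition are
#' skipped with a warning.
#'
#' @param table A [condition_table()].
#' @param baseline Baseline condition label; default `"normal"`.
#' @param alpha Significance level; default 0.05.
#' @param var_equal Passed to [ttest()].
#' @return Tibble with `condition`, `compartment`, `metric`, `n_baseline`,
#'   `n_condition`, `mean_baseline`, `mean_condition`, `pct_change`, `t`,
#'   `p`, `significant`.
#' @export
condition_report <- function(table, baseline = "normal", alpha = 0.05,
                             var_equal = TRUE) {
  stopifnot(inherits(table, "condition_table"))
  if (!baseline %in% table$condition)
    stop(sprintf("baseline condition '%s' not present", baseline))
  others <- setdiff(unique(table$condition), baseline)
  base <- table[table$condition == baseline, ]
  combos <- unique(base[, c("compartment", "metric")])
  rows <- list()
  for (cond in others) {
    cur <- table[table$condition == cond, ]
    for (j in seq_len(nrow(combos))) {
      cp <- combos$compartment[j]; mt <- combos$metric[j]
      a <- base$value[base$compartment == cp & base$metric == mt]
      b <- cur$value[cur$compartment == cp & cur$metric == mt]
      if (length(b) < 2) {
        warning(sprintf("condition '%s' lacks %s/%s (n = %d); skipped",
                        cond, cp, mt, length(b)))
        next
      }
      tt <- ttest(a, b, alpha = alpha, var_equal = var_equal)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        condition = cond, compartment = cp, metric = mt,
        n_baseline = length(a), n_condition = length(b),
        mean_baseline = mean(a), mean_condition = mean(b),
        pct_change = percent_change(mean(a), mean(b)),
        t = tt$t, p = tt$p, significant = tt$significant)
    }
  }
  if (length(rows)) dplyr::bind_rows(rows)
  else tibble::tibble(condition = character(), compartment = character(),
                      metric = character(), n_baseline = integer(),
                      n_condition = integer(), mean_baseline = numeric(),
                      mean_condition = numeric(), pct_change = numeric(),
                      t = numeric(), p = numeric(), significant = logical())
}
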