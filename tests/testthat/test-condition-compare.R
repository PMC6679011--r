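make_table <- function(shift_act_d = 0.005, n = 20, sd = 0.002, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (cond in c("normal", "hypertonic", "act_d")) {
    for (comp in c("nucleolus", "cytoplasm")) {
      base <- if (comp == "nucleolus") 1.363 else 1.349
      shift <- if (cond == "act_d" && comp == "nucleolus") shift_act_d else 0
      rows[[length(rows) + 1]] <- tibble::tibble(
        cell_id = paste0(cond, "_", seq_len(n)), condition = cond,
        compartment = comp, metric = "mean_ri",
        value = base + shift + rnorm(n, 0, sd))
    }
  }
  condition_table(dplyr::bind_rows(rows))
}

test_that("group summaries report standard moments and SEM", {
  tab <- condition_table(cell_id = c("a", "b", "c"), condition = "normal",
                         compartment = "nucleolus", metric = "mean_ri",
                         value = c(1, 2, 3))
  gs <- group_summary(tab)
  expect_equal(gs$mean, 2)
  expect_equal(gs$sd, 1)
  expect_equal(gs$sem, 1 / sqrt(3))
  expect_identical(gs$n, 3L)

  same <- condition_table(cell_id = c("a", "b"), condition = "normal",
                          compartment = "nucleolus", metric = "mean_ri",
                          value = c(2, 2))
  expect_equal(group_summary(same)$sd, 0)

  single <- condition_table(cell_id = "a", condition = "normal",
                            compartment = "nucleolus", metric = "mean_ri",
                            value = 1)
  expect_error(group_summary(single), "n >= 2")
})

test_that("SEM shrinks as 1/sqrt(n) on resampled synthetic groups", {
  set.seed(42)
  sems <- sapply(c(5, 10, 20), function(n) {
    mean(replicate(60, {
      tab <- condition_table(cell_id = seq_len(n), condition = "normal",
                             compartment = "nucleolus", metric = "mean_ri",
                             value = 1.363 + rnorm(n, 0, 0.003))
      group_summary(tab)$sem
    }))
  })
  expect_lt(abs(sems[1] / sems[3] - 2), 0.2)          # sqrt(20/5) = 2
  expect_lt(abs(sems[2] / sems[3] - sqrt(2)), 0.15)   # sqrt(20/10)
})

test_that("the t-test matches the pooled-variance closed form", {
  a <- c(1, 2, 3, 4, 5); b <- c(3, 4, 5, 6, 7)
  tt <- ttest(a, b)
  # independent brute-force computation of Student's statistic
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  p_oracle <- 2 * pt(-abs(t_oracle), length(a) + length(b) - 2)
  expect_equal(tt$t, t_oracle)
  expect_equal(tt$df, 8)
  expect_equal(tt$p, p_oracle)
  expect_false(tt$significant)

  # symmetry: swapping groups flips t, keeps p
  sw <- ttest(b, a)
  expect_equal(sw$t, -tt$t)
  expect_equal(sw$p, tt$p)
})

test_that("degenerate and high-power t-test cases behave as contracted", {
  # identical groups with zero variance: t = 0, p = 1
  z <- ttest(c(2, 2, 2), c(2, 2, 2))
  expect_equal(z$t, 0)
  expect_equal(z$p, 1)
  expect_false(z$significant)
  expect_error(ttest(c(2, 2), c(3, 3)), "undefined")
  expect_error(ttest(1, c(1, 2)), "n >= 2")

  # a 3-SD shift with n = 20 is detected
  set.seed(7)
  a <- rnorm(20, 0, 1); b <- rnorm(20, 3, 1)
  expect_true(ttest(a, b)$significant)

  # Welch variant available
  w <- ttest(c(1, 2, 3), c(2, 4, 9, 12), var_equal = FALSE)
  expect_lt(w$df, 5)
})

test_that("condition report flags the shifted condition only", {
  tab <- make_table(shift_act_d = 0.005)
  rep <- condition_report(tab, baseline = "normal")
  nuc <- rep[rep$compartment == "nucleolus", ]
  expect_true(nuc$significant[nuc$condition == "act_d"])
  expect_false(nuc$significant[nuc$condition == "hypertonic"])
  expect_gt(nuc$pct_change[nuc$condition == "act_d"], 0)
  expect_identical(unique(rep$n_baseline), 20L)
})

test_that("condition report contracts: baseline, empties, missing metrics", {
  base_only <- condition_table(cell_id = 1:3, condition = "normal",
                               compartment = "nucleolus", metric = "mean_ri",
                               value = c(1, 2, 3))
  expect_identical(nrow(condition_report(base_only)), 0L)
  expect_error(condition_report(base_only, baseline = "hypertonic"),
               "not present")

  # a metric absent from one condition is skipped with a warning
  tab <- dplyr::bind_rows(
    tibble::tibble(cell_id = 1:5, condition = "normal",
                   compartment = "nucleolus", metric = "mean_ri",
                   value = 1.363 + (1:5) / 1e4),
    tibble::tibble(cell_id = 1:5, condition = "normal",
                   compartment = "nucleolus", metric = "D_um2s",
                   value = 10 + (1:5) / 10),
    tibble::tibble(cell_id = 1:5, condition = "act_d",
                   compartment = "nucleolus", metric = "mean_ri",
                   value = 1.368 + (1:5) / 1e4))
  tab <- condition_table(tab)
  expect_warning(rep <- condition_report(tab), "skipped")
  expect_identical(rep$metric, "mean_ri")

  dup <- tibble::tibble(cell_id = c(1, 1), condition = "normal",
                        compartment = "nucleolus", metric = "mean_ri",
                        value = c(1, 2))
  expect_error(condition_table(dup), "duplicate")
})
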