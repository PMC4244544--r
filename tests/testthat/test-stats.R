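test_that("paired t reproduces the hand-computed statistic", {
  out <- group_compare(c(2, 3, 5), c(1, 2, 3), "paired_t")
  expect_equal(out$statistic, 4, tolerance = 1e-12)
  expect_equal(out$df, 2)
  degen <- group_compare(c(1, 2, 3), c(1, 2, 3), "paired_t")
  expect_match(degen$flag, "degenerate")
  expect_true(is.na(degen$p_value))
  expect_error(group_compare(1:3, 1:4, "paired_t"), "equal lengths")
})

test_that("Mann-Whitney equals exhaustive enumeration for all sizes <= 6", {
  out <- group_compare(c(1, 2, 3), c(4, 5, 6), "mann_whitney")
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 0.1, tolerance = 1e-12)
  set.seed(31)
  for (rep in 1:20) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    x <- round(stats::rnorm(n1), 1)   # rounding induces occasional ties
    y <- round(stats::rnorm(n2, 0.5), 1)
    got <- group_compare(x, y, "mann_whitney")$p_value
    expect_equal(got, mw_oracle(x, y), tolerance = 1e-12)
  }
  # tie-free case also matches wilcox.test's exact p
  x <- c(0.3, 1.2, 2.2, 3.1); y <- c(0.9, 1.8, 2.7, 4.4)
  expect_equal(group_compare(x, y, "mann_whitney")$p_value,
               stats::wilcox.test(x, y, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("Steel-Dwass: degenerate groups, multiplicity, input validation", {
  same <- steel_dwass(list(a = c(1, 1, 1), b = c(1, 1, 1), c = c(1, 1, 1)))
  expect_true(all(same$p_adjusted >= 0.99))
  expect_error(steel_dwass(list(1:4, 2:5)), "at least 3 groups")
  expect_error(steel_dwass(list(1:2, 2:5, 3:6)), "at least 3 observations")
  # adjusted p >= the unadjusted pairwise Mann-Whitney p for every pair
  set.seed(17)
  for (rep in 1:10) {
    g <- list(a = stats::rnorm(5), b = stats::rnorm(5, 0.8),
              c = stats::rnorm(5, 1.6))
    sd_tab <- steel_dwass(g)
    pairs_ <- utils::combn(names(g), 2)
    for (q in seq_len(ncol(pairs_))) {
      mw <- group_compare(g[[pairs_[1, q]]], g[[pairs_[2, q]]], "mann_whitney")
      row <- sd_tab[sd_tab$group1 == pairs_[1, q] &
                      sd_tab$group2 == pairs_[2, q], ]
      expect_gte(row$p_adjusted + 1e-9, mw$p_value)
    }
  }
})

test_that("Steel-Dwass holds its nominal size under the null", {
  set.seed(99)
  rejections <- 0L; trials <- 200L
  for (i in seq_len(trials)) {
    g <- list(a = stats::rnorm(8), b = stats::rnorm(8), c = stats::rnorm(8))
    rejections <- rejections + any(steel_dwass(g)$p_adjusted < 0.05)
  }
  # family-wise error ~5%: allow a 3-sigma binomial band
  expect_lt(rejections / trials, 0.05 + 3 * sqrt(0.05 * 0.95 / trials))
})

test_that("summary table: mean/SD conventions and per-subject CVR", {
  coh <- tibble::tibble(
    institution = "A", subject = rep(1:3, each = 2), region = "mca",
    condition = rep(c("rest", "acz"), 3),
    cbf = c(1, 2, 2, 3, 3, 5)
  )
  st <- summary_table(coh)
  a <- st[st$institution == "A", ]
  expect_equal(a$rest_mean, 2); expect_equal(a$rest_sd, 1)
  # CVR per subject then averaged: (100, 50, 200/3)/3
  expect_equal(a$cvr_mean, mean(c(100, 50, 200 / 3)), tolerance = 1e-12)
  # not equal to the CVR of the group means
  expect_false(isTRUE(all.equal(a$cvr_mean,
                                100 * (a$acz_mean - a$rest_mean) / a$rest_mean)))
  single <- summary_table(coh[coh$subject == 1, ])
  expect_equal(single$rest_sd, c(0, 0))
  expect_match(single$flag, "single subject")
  expect_error(summary_table(dplyr::mutate(coh, cbf = -cbf)), "negative")
})
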