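test_that("Kaplan-Meier estimate matches the hand-computed product limit", {
  d <- tibble::tibble(os_months = c(1, 2, 3), event = 1)
  km <- km_estimate(d)
  curve <- tidy(km)
  expect_equal(curve$estimate, c(2 / 3, 1 / 3, 0))
  expect_equal(unname(km_median(km)), 2)

  # all censored: flat at 1, median not reached
  cens <- km_estimate(tibble::tibble(os_months = c(5, 7, 9), event = 0))
  expect_true(all(tidy(cens)$estimate == 1))
  expect_true(is.na(km_median(cens)))

  expect_error(km_estimate(tibble::tibble(os_months = numeric(0), event = integer(0))),
               "empty")
  expect_error(km_estimate(tibble::tibble(os_months = -1, event = 1)), ">= 0")
})

test_that("KM equals the empirical survival function without censoring", {
  withr::with_seed(14, {
    tt <- round(rexp(60, 0.1), 2)
    d <- tibble::tibble(os_months = tt, event = 1)
    curve <- tidy(km_estimate(d))
    for (i in seq_len(nrow(curve))) {
      expect_equal(curve$estimate[i], mean(tt > curve$time[i]),
                   tolerance = 1e-12)
    }
  })
})

test_that("log-rank statistic agrees with a brute-force observed/expected oracle", {
  # independent implementation: loop over distinct event times, expected
  # events and hypergeometric variance per group
  brute_logrank <- function(time, event, group) {
    g <- factor(group)
    k <- nlevels(g)
    times <- sort(unique(time[event == 1]))
    O <- E <- rep(0, k); V <- matrix(0, k, k)
    for (t in times) {
      at_risk <- time >= t
      n_t <- sum(at_risk)
      d_t <- sum(event == 1 & time == t)
      for (j in 1:k) {
        n_jt <- sum(at_risk & g == levels(g)[j])
        O[j] <- O[j] + sum(event == 1 & time == t & g == levels(g)[j])
        E[j] <- E[j] + d_t * n_jt / n_t
      }
      if (n_t > 1) {
        for (j in 1:k) for (l in 1:k) {
          n_jt <- sum(at_risk & g == levels(g)[j])
          n_lt <- sum(at_risk & g == levels(g)[l])
          V[j, l] <- V[j, l] + d_t * (n_t - d_t) / (n_t - 1) *
            (n_jt * ((j == l) * n_t - n_lt)) / n_t^2
        }
      }
    }
    z <- (O - E)[-1]
    drop(t(z) %*% solve(V[-1, -1, drop = FALSE]) %*% z)
  }
  withr::with_seed(8, {
    d <- tibble::tibble(
      os_months = c(rexp(25, 0.05), rexp(25, 0.15), rexp(25, 0.3)),
      event = rbinom(75, 1, 0.8),
      group = rep(c("a", "b", "c"), each = 25)
    )
  })
  got <- logrank_test(d)
  expect_equal(got$statistic,
               brute_logrank(d$os_months, d$event, d$group),
               tolerance = 1e-8)
  expect_equal(got$df, 2)

  # identical groups duplicated: statistic 0, p 1
  same <- tibble::tibble(os_months = rep(c(1, 2, 3, 4), 2),
                         event = 1, group = rep(c("x", "y"), each = 4))
  lr <- logrank_test(same)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)
  expect_error(logrank_test(dplyr::mutate(same, group = "x")), ">= 2")
})

test_that("log-rank detects a fourfold hazard ratio reliably", {
  withr::with_seed(99, {
    rejected <- vapply(1:60, function(i) {
      d <- tibble::tibble(
        os_months = c(rexp(200, log(2) / 32), rexp(200, log(2) / 8)),
        event = 1, group = rep(c("slow", "fast"), each = 200)
      )
      logrank_test(d)$p_value < 0.05
    }, logical(1))
    expect_gte(mean(rejected), 0.95)
  })
})

test_that("contingency test switches methods and matches printed associations", {
  # male/female x TC-positivity in the ADC reference table
  res <- contingency_test(matrix(c(45, 41, 41, 9), 2, byrow = TRUE))
  expect_lt(res$p_value, 0.001)
  expect_equal(res$method_used, "chisq")

  flat <- contingency_test(matrix(c(5, 5, 5, 5), 2))
  expect_equal(flat$p_value, 1)
  # expected counts are exactly 5, not below it: the chi-square branch
  expect_equal(flat$method_used, "chisq")

  small <- contingency_test(matrix(c(2, 8, 7, 1), 2, byrow = TRUE))
  expect_equal(small$method_used, "fisher")
  expect_equal(small$p_value,
               fisher.test(matrix(c(2, 8, 7, 1), 2, byrow = TRUE))$p.value)

  big <- contingency_test(matrix(c(30, 20, 15, 35), 2, byrow = TRUE))
  expect_equal(big$method_used, "chisq")
  expect_equal(big$p_value,
               chisq.test(matrix(c(30, 20, 15, 35), 2, byrow = TRUE),
                          correct = FALSE)$p.value)
  corr <- contingency_test(matrix(c(30, 20, 15, 35), 2, byrow = TRUE),
                           correct = TRUE)
  expect_equal(corr$method_used, "chisq_corrected")
  expect_gt(corr$p_value, big$p_value)

  expect_error(contingency_test(matrix(c(0, 0, 3, 4), 2)), "degenerate")
  expect_error(contingency_test(matrix(0, 2, 2)), "all-zero")
})

test_that("Spearman correlation matches a brute-force midrank oracle", {
  expect_equal(spearman_corr(1:10, (1:10)^2)$rho, 1)
  x <- c(1, 2, 2, 3, 5, 5, 5, 8)
  y <- c(3, 1, 4, 4, 6, 2, 7, 9)
  brute_rho <- {
    rx <- rank(x); ry <- rank(y)
    sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  }
  expect_equal(spearman_corr(x, y)$rho, brute_rho, tolerance = 1e-12)
  expect_error(spearman_corr(rep(1, 5), 1:5), "constant")
  expect_error(spearman_corr(1:2, 1:2), "at least 3")
})

test_that("independent draws show near-zero rank correlation", {
  withr::with_seed(4, {
    ok <- vapply(1:40, function(i) {
      abs(spearman_corr(rnorm(1000), rnorm(1000))$rho) < 0.1
    }, logical(1))
    expect_gte(mean(ok), 0.95)
  })
})

test_that("Kruskal-Wallis/Dunn results match hand computation on a small instance", {
  d <- tibble::tibble(
    value = c(1, 3, 5, 2, 4, 6, 10, 12, 14),
    group = rep(c("a", "b", "c"), each = 3)
  )
  res <- kruskal_dunn(d)
  expect_equal(res$kw$statistic, kruskal.test(d$value, factor(d$group))$statistic |> unname())
  expect_equal(nrow(res$pairwise), 3)  # k(k-1)/2

  # hand-computed Dunn z for groups a vs c (no ties): ranks 1..9,
  # mean ranks a = (1+3+5)/3 = 3, c = (7+8+9)/3 = 8, sigma2 = 9*10/12
  z_ac <- (3 - 8) / sqrt((9 * 10 / 12) * (1 / 3 + 1 / 3))
  got <- res$pairwise[res$pairwise$group1 == "a" & res$pairwise$group2 == "c", ]
  expect_equal(got$z, z_ac, tolerance = 1e-12)
  expect_equal(got$p_value, 2 * pnorm(-abs(z_ac)), tolerance = 1e-12)

  # identical groups: statistic ~ 0
  same <- tibble::tibble(value = rep(c(1, 2, 3), 3),
                         group = rep(c("a", "b", "c"), each = 3))
  expect_lt(kruskal_dunn(same)$kw$statistic, 1e-10)

  # Bonferroni adjustment scales the pairwise p-values
  adj <- kruskal_dunn(d, p_adjust = "bonferroni")
  expect_equal(adj$pairwise$p_adjusted,
               pmin(1, adj$pairwise$p_value * 3))
})

test_that("three shifted groups are detected at moderate sample size", {
  withr::with_seed(3, {
    d <- tibble::tibble(
      value = c(rnorm(100, 0), rnorm(100, 0.5), rnorm(100, 1)),
      group = rep(c("a", "b", "c"), each = 100)
    )
  })
  expect_lt(kruskal_dunn(d)$kw$p_value, 0.001)
})
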