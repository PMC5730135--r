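test_that("ICC(A,1) matches a from-scratch ANOVA computation", {
  set.seed(8)
  s1 <- rnorm(8, 5, 2)
  s2 <- s1 + rnorm(8, 0, 0.1)
  got <- icc_repeatability(s1, s2)
  df <- data.frame(y = c(s1, s2), subj = factor(rep(1:8, 2)),
                   sess = factor(rep(1:2, each = 8)))
  ms <- summary(stats::aov(y ~ subj + sess, df))[[1]]$"Mean Sq"
  want <- (ms[1] - ms[3]) / (ms[1] + ms[3] + (2 / 8) * (ms[2] - ms[3]))
  expect_lt(abs(got$icc - want), 1e-10)
  expect_identical(got$n, 8L)
  expect_true(got$ci95[1] <= got$icc && got$icc <= got$ci95[2])
  expect_match(got$model_tag, "absolute agreement")
})

test_that("ICC is exactly 1 for duplicated data and penalizes a constant offset", {
  x <- c(2.1, 3.7, 1.5, 4.2, 2.8, 3.3, 1.9, 4.8)
  expect_identical(icc_repeatability(x, x)$icc, 1)
  off <- icc_repeatability(x, x + 1)
  expect_lt(off$icc, 1)
  expect_error(icc_repeatability(rep(1, 5), rep(1, 5)), "zero variance")
})

test_that("ICC decreases monotonically as re-measurement jitter grows", {
  set.seed(14)
  base <- rnorm(10, 5, 2)
  iccs <- vapply(c(0.01, 0.1, 0.3, 0.8, 2), function(sd) {
    mean(replicate(30, icc_repeatability(base, base + rnorm(10, 0, sd))$icc))
  }, 0)
  expect_true(all(diff(iccs) < 0))
})

test_that("difference reports reproduce hand-computed summaries", {
  t1 <- tibble::tibble(subject = paste0("S", 1:4),
                       A = c(1, 2, 3, 4), B = c(2, 2, 2, 2) + c(1, 2, 3, 4))
  # identical sessions: all zeros, CI [0, 0] (ICC on area B is defined)
  same <- difference_report(t1, t1)
  expect_true(all(same$mean == 0 & same$sd == 0 & same$min == 0))
  expect_true(all(same$ci_lo == 0 & same$ci_hi == 0))
  # constant difference 0.1: mean 0.1, sd 0, degenerate CI
  t2 <- t1; t2$A <- t2$A + 0.1; t2$B <- t2$B + 0.1
  const <- difference_report(t1, t2)
  expect_equal(const$mean, c(0.1, 0.1))
  expect_equal(const$sd, c(0, 0))
  expect_equal(const$ci_lo, c(0.1, 0.1))
  # differences {-0.1, 0, 0.1, 0.2}: t-based CI from first principles
  t3 <- t1; t3$A <- t3$A + c(-0.1, 0, 0.1, 0.2)
  rep3 <- difference_report(t1, t3)
  d <- c(-0.1, 0, 0.1, 0.2)
  half <- stats::qt(0.975, 3) * stats::sd(d) / 2
  expect_equal(rep3$mean[1], 0.05)
  expect_equal(rep3$sd[1], stats::sd(d))
  expect_equal(rep3$ci_lo[1], 0.05 - half)
  expect_equal(rep3$ci_hi[1], 0.05 + half)
})

test_that("descriptive statistics are exact sample statistics", {
  t <- tibble::tibble(subject = c("a", "b"), Pogonion = c(6.08, 15.72))
  d <- descriptives(t)
  expect_equal(d$min, 6.08)
  expect_equal(d$max, 15.72)
  expect_equal(d$mean, 10.9)
  one <- descriptives(tibble::tibble(subject = "a", A = 3))
  expect_equal(one$min, one$max)
  expect_true(is.na(one$sd))
  flat <- descriptives(tibble::tibble(subject = c("a", "b"), A = c(2, 2)))
  expect_equal(flat$sd, 0)
})

test_that("Spearman handles monotone extremes and matches the exact reference", {
  expect_equal(spearman(1:8, exp(1:8))$rho, 1)
  expect_equal(spearman(1:8, -(1:8)^3)$rho, -1)
  s <- spearman(1:8, (1:8)^3)
  expect_identical(s$method, "exact permutation")
  expect_equal(s$p_value, 2 / 40320)
  set.seed(19)
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(8)
    got <- spearman(x, y)
    ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                            exact = TRUE))
    expect_equal(got$rho, unname(ref$estimate))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
  expect_error(spearman(rep(1, 5), 1:5), "zero rank variance")
  expect_identical(spearman(1:15, rnorm(15))$method, "t approximation")
})

test_that("Spearman is invariant to monotone transforms and rank replacement", {
  set.seed(23)
  x <- rnorm(9); y <- rnorm(9)
  base <- spearman(x, y)
  expect_equal(spearman(exp(x), y)$rho, base$rho)
  expect_equal(spearman(x, 2 * y + 5)$p_value, base$p_value)
  expect_equal(spearman(rank(x), rank(y))$rho, base$rho)
})

test_that("exact permutation p stays near the t approximation for moderate rho", {
  # enumerate the entire tie-free null support at n = 8: the worst-case
  # discrepancy between the exact and t-approximate two-sided p over
  # |rho| < 0.7 is 0.0240, so the approximation is a sanity cross-check,
  # not a substitute
  null <- dispquant:::null_abs_rho(8)
  nn <- length(null)
  rhos <- sort(unique(round(null, 12)))
  rhos <- rhos[rhos < 0.7]
  worst <- max(vapply(rhos, function(r) {
    p_exact <- (nn - findInterval(r - 1e-12, null)) / nn
    tt <- r * sqrt(6 / (1 - r^2))
    abs(p_exact - 2 * stats::pt(-abs(tt), 6))
  }, 0))
  expect_lt(worst, 0.025)
  expect_gt(worst, 0.02)  # the approximation really is this coarse at n = 8
})

test_that("correlation matrices render the lower-r/upper-p layout", {
  set.seed(37)
  hard <- rnorm(8, 5, 2)
  tab <- tibble::tibble(subject = paste0("S", 1:8),
                        A = hard, B = 0.9 * hard, C = 0.7 * hard)
  cm <- correlation_matrix(tab, c("A", "B", "C"))
  expect_true(all(cm$r[lower.tri(cm$r)] == 1))
  expect_true(all(cm$significant[lower.tri(cm$significant)]))
  txt <- format(cm)
  expect_identical(txt[2, 1], "1.00*")   # r below
  expect_identical(txt[1, 2], "<0.01*")  # p above
  expect_identical(unname(diag(txt)), rep("-", 3))
  expect_error(correlation_matrix(tab, c("A", "Nope")), "Nope")
  long <- tidy(cm)
  expect_identical(nrow(long), 3L)
  expect_true(all(long$significant))
})

test_that("tidiers return one-row summaries for fitted objects", {
  set.seed(41)
  x <- rnorm(8); y <- x + rnorm(8, 0, 0.3)
  ti <- tidy(spearman(x, y))
  expect_identical(names(ti), c("estimate", "p.value", "n", "method"))
  ic <- icc_repeatability(x, x + rnorm(8, 0, 0.05))
  gl <- glance(ic)
  expect_identical(nrow(gl), 1L)
  expect_true(gl$conf.low <= gl$estimate)
})
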