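test_that("perfect duplicate controls are selected by the matcher", {
  cases <- match_frame(c("A1", "A2"), "case", c(60, 50), c(24.1, 24.5))
  pool <- match_frame(sprintf("P%d", 1:8), "pool",
                      c(60, 60, 50, 50, 80, 80, 30, 30),
                      c(24.1, 24.1, 24.5, 24.5, 25.0, 25.0, 23.0, 23.0))
  res <- match_controls(cases, pool, k = 2, rng_seed = 1)
  expect_setequal(res$control_eye_id[res$case_eye_id == "A1"], c("P1", "P2"))
  expect_setequal(res$control_eye_id[res$case_eye_id == "A2"], c("P3", "P4"))
  expect_identical(anyDuplicated(res$control_eye_id), 0L)
})

test_that("22 cases with a pool of 44 perfect matches use all 44 controls", {
  cases <- match_frame(sprintf("C%02d", 1:22), "case",
                       seq(40, 82, by = 2), rep(24.2, 22))
  pool <- match_frame(sprintf("P%02d", 1:44), "pool",
                      rep(seq(40, 82, by = 2), each = 2), rep(24.2, 44))
  res <- match_controls(cases, pool, k = 2, rng_seed = 3)
  expect_identical(nrow(res), 44L)
  expect_identical(anyDuplicated(res$control_eye_id), 0L)
})

test_that("an exhausted pool names the unmatched case", {
  cases <- match_frame(c("A1", "A2"), "case", c(60, 60), c(24, 24))
  pool <- match_frame(c("P1", "P2", "P3"), "pool", c(60, 60, 60), c(24, 24, 24))
  expect_error(match_controls(cases, pool, k = 2, rng_seed = 1),
               "matching failure.*A2")
})

test_that("matching is invariant to row order given the seed", {
  set.seed(99)
  cases <- match_frame(sprintf("C%d", 1:6), "case",
                       rnorm(6, 60, 10), rnorm(6, 24.2, 0.3))
  pool <- match_frame(sprintf("P%02d", 1:40), "pool",
                      rnorm(40, 60, 10), rnorm(40, 24.2, 0.3))
  a <- match_controls(cases, pool, k = 2, rng_seed = 5)
  perm_c <- cases[sample(nrow(cases)), ]
  perm_p <- pool[sample(nrow(pool)), ]
  b <- match_controls(perm_c, perm_p, k = 2, rng_seed = 5)
  expect_equal(a[order(a$case_eye_id, a$rank), c("case_eye_id", "control_eye_id")],
               b[order(b$case_eye_id, b$rank), c("case_eye_id", "control_eye_id")],
               ignore_attr = TRUE)
})

test_that("2x2 chi-square matches closed-form and published arithmetic", {
  sex <- chi_square_2x2(matrix(c(3, 12, 21, 23), 2))
  expect_equal(round(sex$statistic, 2), 3.56)
  expect_equal(round(sex$p_value, 3), 0.059)
  bal <- chi_square_2x2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(bal$statistic, 0)
  expect_equal(bal$p_value, 1)
  # closed form n (ad - bc)^2 / (r1 r2 c1 c2)
  diag <- chi_square_2x2(matrix(c(5, 0, 0, 5), 2))
  expect_equal(diag$statistic, 10)
  expect_equal(diag$p_value, stats::pchisq(10, 1, lower.tail = FALSE))
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2)), "margin")
  expect_error(chi_square_2x2(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("bonferroni threshold is alpha over m", {
  expect_equal(round(bonferroni_threshold(0.05, 12), 4), 0.0042)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 5), 0.002)
  expect_error(bonferroni_threshold(1.2, 3), "alpha")
  expect_error(bonferroni_threshold(0.05, 0), "positive integer")
})

test_that("identical groups give zero difference and p = 1", {
  d <- data.frame(value = rep(5, 8),
                  group = rep(c("control", "siod"), each = 4),
                  subject_id = sprintf("s%d", 1:8))
  cmp <- clustered_group_difference(d)
  expect_equal(cmp$difference, 0)
  expect_equal(cmp$p_value, 1)
})

test_that("the sandwich SE matches explicit cluster algebra on a fixture", {
  # 6 rows, 4 clusters; cluster B and D have paired observations
  d <- data.frame(value = c(10, 14, 12, 20, 24, 22),
                  group = rep(c("control", "siod"), each = 3),
                  subject_id = c("a", "b", "b", "c", "d", "d"))
  cmp <- clustered_group_difference(d)
  # hand algebra: group means, per-cluster residual sums
  m1 <- mean(c(10, 14, 12)); m2 <- mean(c(20, 24, 22))
  u1 <- c(10 - m1, (14 - m1) + (12 - m1))
  u2 <- c(20 - m2, (24 - m2) + (22 - m2))
  se1 <- sqrt(sum(u1^2)) / 3
  se2 <- sqrt(sum(u2^2)) / 3
  expect_equal(cmp$means, c(control = m1, siod = m2))
  expect_equal(cmp$ses, c(control = se1, siod = se2))
  expect_equal(cmp$difference, m1 - m2)
  expect_equal(cmp$se_difference, sqrt(se1^2 + se2^2))
})

test_that("with singleton clusters the SE reduces to the independence SE", {
  set.seed(1)
  y <- rnorm(30)
  d <- data.frame(value = y, group = rep(c("control", "siod"), each = 15),
                  subject_id = sprintf("s%02d", 1:30))
  cmp <- clustered_group_difference(d)
  y1 <- y[1:15]
  se_indep <- sqrt(sum((y1 - mean(y1))^2)) / 15
  expect_equal(unname(cmp$ses["control"]), se_indep)
})

test_that("cluster-robust means agree with the sandwich package oracle", {
  set.seed(7)
  n_sub <- 12
  d <- do.call(rbind, lapply(1:n_sub, function(i) {
    k <- sample(1:2, 1)
    data.frame(value = rnorm(k, ifelse(i <= 6, 0, 1)) + rnorm(1, 0, 0.5),
               group = ifelse(i <= 6, "control", "siod"),
               subject_id = sprintf("s%02d", i))
  }))
  cmp <- clustered_group_difference(d)
  fit <- stats::lm(value ~ 0 + group, data = d)
  vc <- sandwich::vcovCL(fit, cluster = d$subject_id, type = "HC0",
                         cadjust = FALSE)
  expect_equal(unname(cmp$ses),
               unname(sqrt(diag(vc))), tolerance = 1e-10)
  expect_equal(cmp$se_difference,
               unname(sqrt(sum(diag(vc)))), tolerance = 1e-10)
})

test_that("a single-subject group is rejected", {
  d <- data.frame(value = 1:4, group = c("control", "control", "siod", "siod"),
                  subject_id = c("a", "b", "c", "c"))
  expect_error(clustered_group_difference(d), "fewer than 2 subjects")
})

test_that("identical condition data yields unit p-values and no sector flags", {
  base <- expand.grid(subject_id = sprintf("s%d", 1:6), hour = 1:12,
                      stringsAsFactors = FALSE)
  base$value <- 80
  long <- do.call(rbind, lapply(c("control", "siod", "siod_repositioned"),
                                function(cn) transform(base, condition = cn)))
  tab <- sector_comparison_table(long, value = "value")
  expect_identical(nrow(tab), 12L)
  expect_true(all(tab$p_control_vs_siod == 1))
  expect_false(any(tab$sig_control_vs_siod))
  expect_error(sector_comparison_table(long[long$condition != "siod", ],
                                       value = "value"), "missing condition")
})

test_that("permuting condition labels within subjects gives null p-values", {
  set.seed(42)
  n_sub <- 30
  reps <- 200
  conds <- c("control", "siod", "siod_repositioned")
  pvals <- replicate(reps, {
    d <- expand.grid(subject_id = sprintf("s%02d", 1:n_sub),
                     condition = conds, stringsAsFactors = FALSE)
    d$value <- rnorm(nrow(d)) + rep(rnorm(n_sub, 0, 0.7), times = 3)
    # permute condition labels within subject: exchangeable under the null
    for (s in unique(d$subject_id)) {
      idx <- which(d$subject_id == s)
      d$condition[idx] <- sample(d$condition[idx])
    }
    fit <- siodscan:::cluster_robust_cellmeans(d$value, factor(d$condition, conds),
                                               d$subject_id)
    cn <- c(1, -1, 0)
    est <- sum(cn * fit$means)
    se <- sqrt(drop(t(cn) %*% fit$vcov %*% cn))
    siodscan:::wald_p(est, se)
  })
  # p-values approximately uniform: rejection rate near 0.05, mean near 0.5
  expect_lt(mean(pvals < 0.05), 0.12)
  expect_gt(mean(pvals), 0.4)
  expect_lt(mean(pvals), 0.6)
})
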