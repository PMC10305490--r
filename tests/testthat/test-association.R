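test_that("bh_fdr matches step-up arithmetic and reference implementation", {
  # brute-force step-up on [0.01, 0.02, 0.03, 0.04]:
  # q_(i) = min_j>=i (4 * p_(j) / j) = 0.04 for every rank
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.07, 5)), rep(0.07, 5))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_equal(bh_fdr(numeric(0)), numeric(0))

  set.seed(53)
  for (rep in 1:20) {
    p <- stats::runif(sample(1:200, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), stats::p.adjust(p, "BH"))
    # permutation equivariance
    o <- sample(length(p))
    expect_equal(bh_fdr(p[o]), bh_fdr(p)[o])
    expect_true(all(bh_fdr(p) <= 1 & bh_fdr(p) >= p * 0))
  }
})

test_that("per-bin OLS matches a normal-equations oracle on a fixture", {
  # 6-sample fixture, solved independently via solve(X'X) X'y
  cn <- data.frame(sample_id = paste0("s", 1:6),
                   cn = c(150, 210, 180, 260, 120, 240))
  covars <- data.frame(sample_id = paste0("s", 1:6),
                       age = c(30, 41, 35, 60, 28, 55),
                       sex = c(0, 1, 0, 1, 0, 1))
  bins <- data.frame(sample_id = paste0("s", 1:6),
                     start = 1, end = 200,
                     mean_meth = c(22, 31, 24, 39, 18, 36),
                     pass = TRUE)
  res <- per_bin_regression(cn, bins, covars, min_samples = 5)
  X <- cbind(1, bins$mean_meth, covars$age, covars$sex)
  y <- cn$cn
  beta <- solve(t(X) %*% X, t(X) %*% y)
  resid <- y - X %*% beta
  s2 <- sum(resid^2) / (6 - 4)
  se <- sqrt(diag(solve(t(X) %*% X)) * s2)
  tval <- beta[2] / se[2]
  expect_equal(res$beta, beta[2], tolerance = 1e-10)
  expect_equal(res$se, se[2], tolerance = 1e-10)
  expect_equal(res$p_value, 2 * stats::pt(abs(tval), 2, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(res$q_value, res$p_value)  # single bin family
})

test_that("per-bin regression agrees with lm() across random bins", {
  set.seed(59)
  n <- 20
  covars <- data.frame(sample_id = sprintf("s%02d", 1:n),
                       age = round(stats::runif(n, 25, 75)),
                       sex = stats::rbinom(n, 1, 0.5),
                       group = rep(0:1, each = n / 2))
  cn <- data.frame(sample_id = covars$sample_id,
                   cn = stats::rlnorm(n, log(200), 0.3))
  bins <- do.call(rbind, lapply(1:6, function(b)
    data.frame(sample_id = covars$sample_id,
               start = (b - 1) * 200 + 1, end = b * 200,
               mean_meth = 20 + 0.05 * cn$cn * (b > 3) + stats::rnorm(n, 0, 2),
               pass = TRUE)))
  res <- per_bin_regression(cn, bins, covars)
  expect_equal(nrow(res), 6L)
  for (b in 1:6) {
    d <- merge(merge(cn, covars), bins[bins$start == (b - 1) * 200 + 1, ])
    fit <- summary(stats::lm(cn ~ mean_meth + age + sex + group, data = d))
    expect_equal(res$beta[b], fit$coefficients["mean_meth", 1],
                 tolerance = 1e-8)
    expect_equal(res$p_value[b], fit$coefficients["mean_meth", 4],
                 tolerance = 1e-8)
  }
  expect_equal(res$q_value, stats::p.adjust(res$p_value, "BH"))

  # adding a constant to every sample's methylation moves only the intercept
  bins2 <- bins
  bins2$mean_meth <- bins2$mean_meth + 7.5
  res2 <- per_bin_regression(cn, bins2, covars)
  expect_equal(res2$beta, res$beta, tolerance = 1e-8)
  expect_equal(res2$p_value, res$p_value, tolerance = 1e-8)
})

test_that("degenerate bins are skipped with a reason, not an error", {
  cn <- data.frame(sample_id = paste0("s", 1:6), cn = c(1, 2, 3, 4, 5, 6))
  covars <- data.frame(sample_id = paste0("s", 1:6),
                       age = c(30, 41, 35, 60, 28, 55), sex = rep(0:1, 3))
  few <- data.frame(sample_id = paste0("s", 1:3), start = 1, end = 200,
                    mean_meth = c(10, 20, 30), pass = TRUE)
  res <- per_bin_regression(cn, few, covars)
  expect_equal(res$reason, "too_few_samples")
  # constant methylation is collinear with the intercept
  const <- data.frame(sample_id = paste0("s", 1:6), start = 1, end = 200,
                      mean_meth = 50, pass = TRUE)
  res2 <- per_bin_regression(cn, const, covars, min_samples = 5)
  expect_equal(res2$reason, "collinear")
  # missing covariates for regressed samples error clearly
  covars$age[2] <- NA
  bins <- data.frame(sample_id = paste0("s", 1:6), start = 1, end = 200,
                     mean_meth = 1:6 * 10, pass = TRUE)
  expect_error(per_bin_regression(cn, bins, covars), "s2")
})

test_that("group comparison handles effects, nulls and degeneracies", {
  set.seed(61)
  n <- 50
  covars <- data.frame(sample_id = sprintf("s%02d", 1:n),
                       age = round(stats::runif(n, 25, 75)),
                       sex = stats::rbinom(n, 1, 0.5),
                       group = rep(0:1, each = n / 2))
  # strong (but overlapping) shift: detected
  cn_shift <- data.frame(sample_id = covars$sample_id,
                         cn = 200 + 60 * covars$group +
                           stats::rnorm(n, 0, 40))
  g <- group_comparison(cn_shift, covars, segment = "18S")
  expect_true(g$estimable)
  expect_lt(g$p_value, 0.05)
  # constant CN: flagged non-estimable
  cn_const <- data.frame(sample_id = covars$sample_id, cn = 200)
  expect_false(group_comparison(cn_const, covars)$estimable)
  # one group only
  covars1 <- covars
  covars1$group <- 0
  expect_false(group_comparison(cn_shift, covars1)$estimable)
  # too few samples
  expect_false(group_comparison(cn_shift[1:5, ], covars[1:5, ])$estimable)
  # null: rejection rate near nominal over replicates
  rej <- vapply(1:60, function(i) {
    cn0 <- data.frame(sample_id = covars$sample_id,
                      cn = stats::rlnorm(n, log(200), 0.3))
    group_comparison(cn0, covars)$p_value < 0.05
  }, logical(1))
  expect_lt(mean(rej), 0.15)
})

test_that("platform correlation matches a rank-based oracle", {
  a <- data.frame(sample_id = letters[1:6], cn = c(1, 2, 3, 4, 5, 6))
  b <- data.frame(sample_id = letters[1:6], cn = c(10, 20, 25, 40, 55, 70))
  expect_equal(platform_correlation(a, b)$spearman_r, 1)
  b_rev <- data.frame(sample_id = letters[1:6], cn = rev(b$cn))
  expect_equal(platform_correlation(a, b_rev)$spearman_r, -1)
  expect_error(platform_correlation(a, b[1:4, ]), "unmatched")
  expect_error(platform_correlation(a[1:3, ], b[1:3, ]), "4 matched")

  # oracle: Pearson correlation of average ranks, ties included
  set.seed(67)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    x <- data.frame(sample_id = sprintf("s%02d", 1:n),
                    cn = sample(round(stats::rlnorm(n, 5, 0.4))))
    y <- data.frame(sample_id = x$sample_id,
                    cn = sample(round(stats::rlnorm(n, 5, 0.4))))
    pc <- platform_correlation(x, y)
    expect_equal(pc$spearman_r,
                 stats::cor(rank(x$cn), rank(y$cn)), tolerance = 1e-12)
    expect_equal(pc$pearson_r2, stats::cor(x$cn, y$cn)^2)
    expect_true(pc$spearman_p >= 0 && pc$spearman_p <= 1)
  }
})
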