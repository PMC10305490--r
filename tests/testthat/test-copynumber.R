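test_that("window CVs follow the population-SD definition", {
  # two samples; first 150 bp window means {100, 100}, second {100, 300}
  t1 <- depth_track("rDNA", 1L, rep(100, 300))
  t2 <- depth_track("rDNA", 1L, c(rep(100, 150), rep(300, 150)))
  ws <- window_scan(list(a = t1, b = t2), segment = c(1, 300),
                    window_len = 150L, step = 150L)
  expect_equal(ws$start, c(1, 151))
  expect_equal(ws$mean_cv[1], 0)
  expect_equal(ws$mean_cv[2], 0.5)  # pop SD 100 / mean 200
  expect_equal(select_window(ws)$start, 1)

  # constant depth across samples: every CV is zero
  ws0 <- window_scan(list(a = ct(7, 400), b = ct(7, 400)), c(1, 400))
  expect_true(all(ws0$mean_cv == 0))
})

test_that("windows overlapping the exclusion zone are absent", {
  trks <- list(a = ct(10, 2000), b = ct(12, 2000))
  ws <- window_scan(trks, segment = c(1, 2000), exclusion = c(1, 900))
  expect_true(all(ws$start > 900))
  ws2 <- window_scan(trks, segment = c(1, 2000), exclusion = c(500, 900))
  expect_true(all(ws2$end < 500 | ws2$start > 900))
  # zero-mean windows are skipped, not returned
  z <- depth_track("rDNA", 1L, c(rep(0, 200), rep(10, 300)))
  z2 <- depth_track("rDNA", 1L, c(rep(0, 200), rep(12, 300)))
  wsz <- window_scan(list(a = z, b = z2), c(1, 500))
  expect_true(all(wsz$start > 200 - 150 + 1))
  expect_gt(attr(wsz, "n_skipped"), 0)
})

test_that("per-group CVs are averaged unweighted across groups", {
  t1 <- ct(100, 150); t2 <- ct(100, 150)   # group X: CV 0
  t3 <- ct(100, 150); t4 <- ct(300, 150)   # group Y: CV 0.5
  ws <- window_scan(list(a = t1, b = t2, c = t3, d = t4), c(1, 150),
                    groups = c(a = "X", b = "X", c = "Y", d = "Y"))
  expect_equal(ws$cv_X, 0)
  expect_equal(ws$cv_Y, 0.5)
  expect_equal(ws$mean_cv, 0.25)
})

test_that("select_window equals a brute-force argmin with leftmost ties", {
  set.seed(19)
  for (rep in 1:10) {
    n <- sample(50:300, 1)
    tracks <- lapply(1:4, function(i)
      depth_track("r", 1L, stats::rpois(n + 160, 40) + 1))
    names(tracks) <- letters[1:4]
    ws <- window_scan(tracks, c(1, n + 160), window_len = 150L)
    # independent oracle: recompute each window's mean CV naively
    oracle_cv <- vapply(seq_len(nrow(ws)), function(k) {
      m <- vapply(tracks, function(tr)
        mean(tr$depths[ws$start[k]:ws$end[k]]), numeric(1))
      sqrt(mean((m - mean(m))^2)) / mean(m)
    }, numeric(1))
    expect_equal(ws$mean_cv, oracle_cv)
    best <- which(oracle_cv == min(oracle_cv))[1]
    sel <- select_window(ws)
    expect_equal(sel$start, ws$start[best])
  }
  expect_error(select_window(data.frame()), "no windows")
})

test_that("trimmed_mean_depth matches the sort-drop-average oracle", {
  expect_equal(trimmed_mean_depth(1:100, 0.05), mean(1:95))  # = 48
  expect_equal(trimmed_mean_depth(rep(10, 20)), 10)
  expect_equal(trimmed_mean_depth(c(3, 1, 2), 0), 2)
  expect_error(trimmed_mean_depth(numeric(0)), "empty")
  expect_error(trimmed_mean_depth(1:5, 1), "upper_fraction")
  set.seed(23)
  for (rep in 1:20) {
    x <- stats::rpois(sample(3:500, 1), 30)
    f <- stats::runif(1, 0, 0.3)
    s <- sort(x)
    keep <- length(x) - ceiling(length(x) * f)
    expect_equal(trimmed_mean_depth(x, f), mean(s[seq_len(keep)]))
  }
})

test_that("compute_brd pools regions and averages the two trimmed means", {
  # ARD exons 100, ARD introns 80 -> BRD 90 (constant depths survive trim)
  b <- compute_brd(list(ct(100, 50, "e1")), list(ct(80, 50, "i1")))
  expect_equal(b$brd, 90)
  expect_equal(compute_brd(list(ct(10, 30)), list(ct(10, 30)))$brd, 10)
  expect_error(compute_brd(list(), list(ct(10, 30))), "exon")

  # independent two-step oracle on random multi-region tracks
  set.seed(29)
  for (rep in 1:5) {
    ex <- lapply(1:3, function(i) depth_track("e", 1L,
                                              stats::rpois(80, 25)))
    inn <- lapply(1:2, function(i) depth_track("i", 1L,
                                               stats::rpois(120, 25)))
    pool_trim <- function(tracks) {
      v <- sort(unlist(lapply(tracks, `[[`, "depths")))
      mean(v[seq_len(length(v) - ceiling(0.05 * length(v)))])
    }
    expect_equal(compute_brd(ex, inn)$brd,
                 (pool_trim(ex) + pool_trim(inn)) / 2)
  }
})

test_that("estimate_cn is the ARD/BRD ratio and scale-invariant", {
  tr <- ct(300, 200)
  est <- estimate_cn(tr, c(1, 150), brd = 2, sample_id = "s", segment = "18S")
  expect_equal(est$cn, 150)
  expect_equal(est$ard, 300)
  expect_error(estimate_cn(tr, c(1, 150), brd = 0), "positive")
  # multiplying all depths (rDNA and background) by a constant leaves CN fixed
  set.seed(37)
  d <- stats::rpois(500, 50)
  bgd <- stats::rpois(400, 30)
  for (k in c(2, 7.5)) {
    cn1 <- estimate_cn(depth_track("r", 1L, d), c(10, 159),
                       compute_brd(list(depth_track("e", 1L, bgd)),
                                   list(depth_track("i", 1L, bgd)))$brd)$cn
    cn2 <- estimate_cn(depth_track("r", 1L, k * d), c(10, 159),
                       compute_brd(list(depth_track("e", 1L, k * bgd)),
                                   list(depth_track("i", 1L, k * bgd)))$brd)$cn
    expect_equal(cn2, cn1, tolerance = 1e-12)
  }
})

test_that("stability_profile reproduces unthinned estimates at fraction 1", {
  cfg <- tiny_config(n_samples = 2L)
  sim <- simulate_cohort(cfg)
  s <- sim$samples[[1]]
  ex <- s$background[sim$regions$kind == "exon"]
  inn <- s$background[sim$regions$kind == "intron"]
  wins <- cfg$reference$default_windows
  tab <- stability_profile(s$rdna, ex, inn, wins, cov = s$cov,
                           fractions = c(1, 0.5), seed = 4L)
  brd <- compute_brd(ex, inn)$brd
  expect_equal(tab$cn_18S[1], estimate_cn(s$rdna, wins$`18S`, brd)$cn)
  expect_equal(tab$global_meth[1], global_methylation(s$cov))
  expect_true(all(c("cn_18S", "cn_28S", "global_meth") %in% names(tab)))
  expect_error(stability_profile(s$rdna, ex, inn, wins,
                                 fractions = c(1, 0)), "fractions")
})
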