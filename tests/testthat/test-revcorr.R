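test_that("z-normalization is exact, missing-aware, and idempotent", {
  expect_equal(znormalize(c(1, 2, 3)), c(-1, 0, 1))
  x <- c(1, 2, NA, 4, 5)
  z <- znormalize(x)
  expect_true(is.na(z[3]))
  expect_equal(mean(z, na.rm = TRUE), 0, tolerance = 1e-12)
  expect_equal(sd(z, na.rm = TRUE), 1, tolerance = 1e-12)
  expect_equal(znormalize(z), z, tolerance = 1e-12)
  expect_error(znormalize(c(2, 2, 2)), "zero variance")
  expect_error(znormalize(c(1, NA, NA)), "non-missing")
})

test_that("per-TR tests match t.test and events need two consecutive TRs", {
  withr::with_seed(31, Z <- matrix(rnorm(12 * 40), 12, 40))
  ev <- detect_events(Z, alpha = 0.2)
  for (j in c(1, 7, 25)) {
    ht <- t.test(Z[, j], mu = 0, alternative = "greater")
    expect_equal(ev$p[j], ht$p.value, tolerance = 1e-12)
  }

  # planted response: one event spanning the planted TRs
  withr::with_seed(32, {
    G <- matrix(rnorm(30 * 40), 30, 40)
    G[, 10:12] <- G[, 10:12] + 1.5
  })
  ev2 <- detect_events(G)
  hit <- ev2$intervals$start_tr <= 10 & ev2$intervals$end_tr >= 12
  expect_true(any(hit))

  # a single isolated significant TR yields no event
  Z0 <- matrix(rnorm(30 * 20, sd = 0.1), 30, 20)
  Z0[, 5] <- Z0[, 5] + 2
  ev3 <- detect_events(Z0)
  expect_true(ev3$significant[5])
  expect_equal(nrow(ev3$intervals), 0)

  # all-zero data: no events (and no error)
  expect_equal(nrow(detect_events(matrix(0, 5, 10))$intervals), 0)

  # TRs with fewer than 3 contributing subjects are never significant
  Gna <- matrix(5, 10, 6)
  Gna[3:10, 2] <- NA
  expect_false(detect_events(Gna)$significant[2])
})

test_that("event extraction ignores appended non-significant padding", {
  withr::with_seed(33, {
    G <- matrix(rnorm(30 * 20), 30, 20)
    G[, 8:10] <- G[, 8:10] + 2
  })
  ev <- detect_events(G)
  Gpad <- cbind(matrix(-5 + rnorm(30 * 4, sd = .1), 30, 4), G,
                matrix(-5 + rnorm(30 * 3, sd = .1), 30, 3))
  evp <- detect_events(Gpad)
  expect_equal(evp$intervals$start_tr, ev$intervals$start_tr + 4)
  expect_equal(evp$intervals$end_tr, ev$intervals$end_tr + 4)
})

test_that("event response magnitudes average over event TRs only", {
  ev <- structure(list(intervals = data.frame(start_tr = c(3, 8),
                                              end_tr = c(4, 9))),
                  class = "event_set")
  tc <- rep(0, 10)
  tc[c(3, 4)] <- 1; tc[c(8, 9)] <- -1
  expect_equal(event_response(tc, ev), 0)
  tc2 <- rep(-7, 10); tc2[c(3, 4, 8, 9)] <- 1
  expect_equal(event_response(tc2, ev), 1)
  tc3 <- rep(1, 10); tc3[c(3, 4, 8, 9)] <- NA
  expect_true(is.na(event_response(tc3, ev)))
  empty <- structure(list(intervals = data.frame(start_tr = integer(0),
                                                 end_tr = integer(0))),
                     class = "event_set")
  expect_warning(expect_true(is.na(event_response(tc, empty))), "empty")
})

test_that("Spearman partials match the closed-form on ranks", {
  withr::with_seed(40, {
    x <- rnorm(50)
    y <- exp(x) + 0            # strictly increasing in x
    z <- rnorm(50)
  })
  res <- spearman_partial(x, y, z)
  expect_gt(res$r_s, 0.95)
  expect_lt(res$p, 1e-6)

  # closed form r_xy.z = (r_xy - r_xz r_yz) / sqrt((1-r_xz^2)(1-r_yz^2))
  withr::with_seed(41, {
    x2 <- rnorm(40); y2 <- 0.5 * x2 + rnorm(40); z2 <- 0.3 * x2 + rnorm(40)
  })
  rx <- rank(x2); ry <- rank(y2); rz <- rank(z2)
  rxy <- cor(rx, ry); rxz <- cor(rx, rz); ryz <- cor(ry, rz)
  closed <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(spearman_partial(x2, y2, z2)$r_s, closed, tolerance = 1e-12)

  # covariate identical to x: everything is partialled out
  expect_lt(abs(spearman_partial(x2, y2, x2)$r_s), 1e-10)
  expect_error(spearman_partial(rep(1, 10), rnorm(10), rnorm(10)),
               "constant")
  expect_error(spearman_partial(1:4, 1:4, 1:4), "at least 5")
})

test_that("the per-TR null calibration matches alpha and the run model", {
  res <- null_calibration_revcorr(n_seeds = 200, seed = 77)
  expect_gte(res$sig_rate, 0.03)
  expect_lte(res$sig_rate, 0.07)
  expect_lt(abs(res$event_count_mean - res$event_count_expected),
            res$event_count_mc_halfwidth)
})

test_that("age trends in event responses survive the motion covariate", {
  for (seed in 1:5) {
    withr::with_seed(100 + seed, {
      n <- 60
      ages <- runif(n, 3, 12)
      motion <- rpois(n, 8)
      adultZ <- matrix(rnorm(30 * 60), 30, 60)
      adultZ[, 20:25] <- adultZ[, 20:25] + 2
      ev <- detect_events(adultZ)
      resp <- vapply(seq_len(n), function(i) {
        tc <- rnorm(60, sd = 0.3)
        tc[event_trs(ev)] <- tc[event_trs(ev)] + 0.1 * ages[i]
        event_response(tc, ev)
      }, numeric(1))
    })
    res <- spearman_partial(ages, resp, motion)
    expect_gt(res$r_s, 0)
    expect_lt(res$p, 0.05)
  }
})
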