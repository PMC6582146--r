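# Batch-culture metrics: spherical volume, VCV, cumulative cell days,
# window-selected growth rate and specific productivity, ddCt, Dunnett flags.

test_that("cell volume assumes a perfect sphere", {
  expect_equal(volumePerCell(2), 4 * pi / 3)
  expect_equal(volumePerCell(15), 1767.1459, tolerance = 1e-7)
  expect_error(volumePerCell(0), class = "DomainError")
  expect_error(volumePerCell(-3), class = "DomainError")
})

test_that("VCV converts um^3 x cells/ml to mm^3/ml and is linear in VCD", {
  expect_equal(viableCellVolume(1e6, 1000), 1.0)
  expect_equal(viableCellVolume(0, 1000), 0)
  expect_equal(viableCellVolume(2e6, 1000), 2 * viableCellVolume(1e6, 1000))
})

test_that("CCD interval terms follow the log-mean formula and its limit", {
  # doubling from 1e5 over 24 h: term = 1e5 * 24 / (ln 2 * 24)
  ccd <- cumulativeCellDays(c(0, 24), c(1e5, 2e5))
  expect_equal(ccd, c(0, 1e5 / log(2)))
  expect_equal(ccd[2], 144269.5, tolerance = 1e-6)
  # degenerate interval: VCD constant -> V * dt / 24
  ccd2 <- cumulativeCellDays(c(0, 24), c(3e5, 3e5))
  expect_equal(ccd2[2], 3e5 * 1.0)
  expect_error(cumulativeCellDays(c(0, 24), c(1e5, 0)), class = "DomainError")
  expect_error(cumulativeCellDays(c(24, 0), c(1e5, 2e5)), class = "DomainError")
})

test_that("CCD equals the analytic integral on exact exponentials", {
  mu <- 0.027
  v0 <- 2.4e5
  t <- seq(0, 192, by = 24)
  v <- v0 * exp(mu * t)
  ccd <- cumulativeCellDays(t, v)
  expect_equal(ccd, (v - v0) / (mu * 24), tolerance = 1e-12)
  # additivity: inserting a point on the same exponential changes nothing
  t2 <- sort(c(t, 100))
  v2 <- v0 * exp(mu * t2)
  ccd2 <- cumulativeCellDays(t2, v2)
  expect_equal(ccd2[match(t, t2)], ccd, tolerance = 1e-12)
})

test_that("the VCD/VCV unit chain is dimensionally consistent", {
  t <- seq(0, 120, by = 24)
  v <- 3e5 * exp(0.03 * t)
  d <- 15
  vcv <- viableCellVolume(v, volumePerCell(d))     # mm^3/ml
  # CCD_CV built from constant diameter equals the scaled cell-based CCD
  ccd_cv <- cumulativeCellDays(t, vcv * 1e-3)      # cm^3 * days
  ccd_cd <- cumulativeCellDays(t, v)
  expect_equal(ccd_cv, volumePerCell(d) * 1e-12 * ccd_cd, tolerance = 1e-12)
})

test_that("replicates combine onto a common anchored trajectory", {
  t <- seq(0, 96, by = 24)
  a <- 3e5 * exp(0.03 * t)
  two <- data.frame(replicate = rep(1:2, each = length(t)), t = c(t, t),
                    value = c(a, a))
  cmb <- combineCultureReplicates(two)
  expect_equal(cmb$value, a)
  # replicate B = 2 x A: anchored to A's first measurement, both collapse onto A
  twob <- data.frame(replicate = rep(1:2, each = length(t)), t = c(t, t),
                     value = c(a, 2 * a))
  cmb2 <- combineCultureReplicates(twob, reference = a[1])
  expect_equal(cmb2$value, a)
  expect_warning(one <- combineCultureReplicates(
    data.frame(replicate = 1, t = t, value = a)), "single replicate")
  expect_equal(one$value, a)
  expect_error(combineCultureReplicates(
    data.frame(replicate = rep(1:2, each = 2), t = c(0, 24, 0, 24),
               value = c(0, 1, 1, 2))), class = "DomainError")
})

test_that("growth rate recovers a noiseless exponential with TPXY at the end", {
  t <- seq(0, 192, by = 24)                 # 9 daily points
  v <- 2e5 * exp(0.03 * t)
  g <- growthRate(t, v)
  expect_equal(g$rate, 0.03, tolerance = 1e-9)
  expect_gte(g$r_max, 1 - 1e-9)
  expect_equal(g$tpxy, length(t))
})

test_that("a hard plateau caps the window at the exponential phase", {
  t <- seq(0, 192, by = 24)
  v <- 2e5 * exp(0.03 * t)
  v[6:9] <- v[5]                            # exponential for 5 points, then flat
  g <- growthRate(t, v)
  expect_equal(g$tpxy, 5L)
  expect_equal(g$rate, 0.03, tolerance = 1e-9)
})

test_that("the common window end is the minimum TPXY over treatments", {
  t <- seq(0, 216, by = 24)
  mk <- function(nexp) {
    v <- 2e5 * exp(0.03 * t)
    if (nexp < length(t)) v[(nexp + 1):length(t)] <- v[nexp]
    v
  }
  res <- growthRates(list(mock = list(t = t, value = mk(6)),
                          kd = list(t = t, value = mk(4))))
  expect_equal(unique(res$window_end), 4L)
  expect_equal(res$tpxy, c(6L, 4L))
  expect_equal(res$rate, c(0.03, 0.03), tolerance = 1e-9)
})

test_that("specific productivity recovers a planted qP and its invariances", {
  t <- seq(0, 216, by = 24)
  v <- 2.5e5 * exp(0.028 * t)
  ccd <- cumulativeCellDays(t, v)
  qp_true <- 20                              # pg/(cell*day)
  titer <- qp_true * 1e-6 * ccd              # ug/ml
  f <- specificProductivity(t, ccd, titer)
  expect_equal(f$qp, qp_true, tolerance = 1e-9)
  # production stopped: constant titer -> slope 0
  f0 <- specificProductivity(t, ccd, rep(3.5, length(t)))
  expect_equal(f0$qp, 0)
  # product present at t0: additive offset leaves the slope unchanged
  f1 <- specificProductivity(t, ccd, titer + 2.2)
  expect_equal(f1$qp, qp_true, tolerance = 1e-9)
  expect_error(specificProductivity(t[1:4], ccd[1:4], titer[1:4]),
               class = "DomainError")
})

test_that("fold changes follow the 2^-ddCt method", {
  out <- ddctFoldChange(22, 15, calibrator_target_ct = 20,
                        calibrator_reference_ct = 15)
  expect_equal(out$ddct, 2)
  expect_equal(out$fold_change, 0.25)
  expect_equal(out$knockdown_pct, 75)
  same <- ddctFoldChange(c(20, 20), c(15, 15), calibrator_dct = 5)
  expect_equal(same$fold_change, 1.0)
  up <- ddctFoldChange(19, 15, calibrator_dct = 5)
  expect_equal(up$fold_change, 2.0)
})

test_that("Dunnett comparison flags shifted arms and not identical ones", {
  d_same <- data.frame(arm = rep(c("mock", "kd"), each = 3), value = 1)
  out <- compareToControl(d_same)
  expect_equal(out$flag, "")
  set.seed(8)
  base <- rnorm(3, 10, 0.5)
  d_shift <- data.frame(arm = rep(c("mock", "kd"), each = 3),
                        value = c(base, rnorm(3, 10 + 10 * 0.5, 0.5)))
  out2 <- compareToControl(d_shift)
  expect_equal(out2$flag, "+")
  # single replicate arms are skipped with a status
  d_one <- data.frame(arm = c("mock", "mock", "kd"), value = c(1, 1.1, 3))
  out3 <- compareToControl(d_one)
  expect_equal(out3$status, "skipped")
})

test_that("the Dunnett comparison holds its nominal type-I level under the null", {
  set.seed(2024)
  alpha <- 0.05
  n_rep <- 2000
  rejections <- 0L
  for (i in seq_len(n_rep)) {
    d <- data.frame(arm = rep(c("mock", "kd"), each = 3), value = rnorm(6))
    p <- compareToControl(d)$p_value
    if (p < alpha) rejections <- rejections + 1L
  }
  rate <- rejections / n_rep
  # Monte-Carlo error ~ sqrt(0.05 * 0.95 / 2000) ~ 0.005
  expect_lt(abs(rate - alpha), 0.02)
})
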