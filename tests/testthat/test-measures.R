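test_that("movingAverageDetrend removes trends with the nearest-available edge rule", {
  expect_equal(movingAverageDetrend(rep(4.2, 600), 501), rep(0, 600))

  # slow line + fast sinusoid: interior output is the sinusoid
  n <- 1200L; w <- 101L
  tt <- (0:(n - 1)) / 120
  trend <- 0.5 + 2 * tt
  fast <- sin(2 * pi * 6 * tt)
  out <- movingAverageDetrend(trend + fast, w)
  interior <- (w + 1):(n - w)
  # centered MA of a line is the line itself; MA of the 6 Hz tone ~ 0
  expect_equal(out[interior], fast[interior], tolerance = 0.01)

  x <- rnorm(50)
  expect_equal(movingAverageDetrend(x, 1L), rep(0, 50))
  expect_error(movingAverageDetrend(x, 10L), "odd")
  expect_error(movingAverageDetrend(x, 501L), "longer")

  # edge rule: first half-window subtracts the first fully-defined average
  y <- seq_len(20) * 1.0
  o <- movingAverageDetrend(y, 5L)
  ma_first <- mean(y[1:5])
  expect_equal(o[1:2], y[1:2] - ma_first)
  ma_last <- mean(y[16:20])
  expect_equal(o[19:20], y[19:20] - ma_last)
})

test_that("butterworthLowpass is zero-phase with unit DC gain and sharp rolloff", {
  expect_equal(butterworthLowpass(rep(2.5, 500)), rep(2.5, 500),
               tolerance = 1e-8)

  rate <- 120; n <- 12 * rate
  tt <- (0:(n - 1)) / rate
  pass <- butterworthLowpass(sin(2 * pi * 1 * tt), 7, 6, rate)
  mid <- (2 * rate):(10 * rate)
  expect_equal(max(abs(pass[mid])), 1, tolerance = 0.01)
  # no phase shift: filtered 1 Hz tone stays aligned with the input
  expect_gt(cor(pass[mid], sin(2 * pi * 1 * tt)[mid]), 0.9999)

  stopb <- butterworthLowpass(sin(2 * pi * 30 * tt), 7, 6, rate)
  expect_lt(max(abs(stopb[mid])), 0.03)

  expect_error(butterworthLowpass(tt, cutoff = 80, rate = 120), "cutoff")
})

test_that("powerFraction matches Parseval on constructed tones", {
  rate <- 128; n <- 1024
  tt <- (0:(n - 1)) / rate
  expect_equal(powerFraction(sin(2 * pi * 1 * tt), rate, 3), 1.0,
               tolerance = 1e-10)
  expect_lt(powerFraction(sin(2 * pi * 10 * tt), rate, 7), 1e-10)
  two <- sin(2 * pi * 1 * tt) + sin(2 * pi * 10 * tt)  # equal power
  expect_equal(powerFraction(two, rate, 7), 0.5, tolerance = 1e-6)
  expect_error(powerFraction(tt[1:100], rate, 3), "256")
})

test_that("sampleEntropy matches the exhaustive-pair oracle and its conventions", {
  # short printed sequence, hand-checkable parameters
  x <- c(1, 2, 3, 2, 1, 2, 3, 2, 1, 2, 3, 2, 1)
  orc <- sampenOracle(x, m = 2, tau = 1, r_coeff = 0.2)
  got <- sampleEntropy(x, entropyParams(m = 2, r_coeff = 0.2, tau = 1))
  expect_equal(got, unname(orc["saen"]), tolerance = 1e-12)

  # scale invariance: r follows the SD
  set.seed(15)
  y <- rnorm(300)
  p <- entropyParams(tau = 3)
  expect_equal(sampleEntropy(5 * y, p), sampleEntropy(y, p), tolerance = 1e-12)
  expect_equal(sampleEntropy(-2 * y + 7, p), sampleEntropy(y, p),
               tolerance = 1e-12)

  expect_error(sampleEntropy(rep(1, 100), p), "constant")
  expect_error(sampleEntropy(y[1:20], entropyParams(tau = 12)), "short")

  # iid noise is more irregular than a sinusoid of equal SD
  tt <- (0:1199) / 120
  sine <- sin(2 * pi * 0.7 * tt); sine <- sine / sd(sine)
  p120 <- entropyParams()
  worse <- vapply(1:20, function(s) {
    set.seed(s)
    sampleEntropy(rnorm(1200), p120) > sampleEntropy(sine, p120)
  }, logical(1))
  expect_true(all(worse))
})

test_that("sampleEntropy flags undefined cases instead of failing silently", {
  # find a small series with m-matches but no (m+1)-matches: Inf sentinel
  p <- entropyParams(m = 2, r_coeff = 0.05, tau = 1)
  found <- FALSE
  for (s in 1:500) {
    set.seed(s)
    x <- rnorm(24)
    cnt <- sampenOracle(x, 2, 1, 0.05)
    if (cnt["B"] > 0 && cnt["A"] == 0) {
      expect_warning(v <- sampleEntropy(x, p), "m\\+1")
      expect_identical(v, Inf)
      found <- TRUE
      break
    }
    if (cnt["B"] == 0) {
      expect_warning(v <- sampleEntropy(x, p), "dimension m")
      expect_true(is.na(v))
    }
  }
  expect_true(found)
})

test_that("sampleEntropy equals the oracle on random series (property)", {
  set.seed(99)
  for (i in 1:25) {
    n <- sample(60:400, 1)
    m <- sample(1:3, 1)
    tau <- sample(c(1L, 2L, 5L, 12L), 1)
    if (n < (m + 1) * tau + 10) tau <- 1L
    x <- cumsum(rnorm(n))  # correlated series give nontrivial match counts
    orc <- sampenOracle(x, m, tau, 0.2)
    if (!is.finite(orc["saen"])) next
    got <- sampleEntropy(x, entropyParams(m = m, r_coeff = 0.2, tau = tau))
    expect_equal(got, unname(orc["saen"]), tolerance = 1e-12)
  }
})

test_that("zeroCrossings counts sign changes with the zero-handling convention", {
  rate <- 120; T <- 60
  tt <- (0:(T * rate - 1)) / rate
  # 2fT up to the +-1 boundary crossing of the finite window
  expect_lte(abs(zeroCrossings(sin(2 * pi * 1 * tt)) - 2 * 1 * T), 1)

  expect_equal(zeroCrossings(abs(rnorm(100)) + 0.1), 0)
  expect_equal(zeroCrossings(c(1, 0, -1)), 1)
  expect_equal(zeroCrossings(c(1, 0, 1)), 0)
  expect_equal(zeroCrossings(c(0, 0, -1, 1)), 1)  # leading zeros take next sign
  expect_equal(zeroCrossings(c(1, 0, 0, -1)), 1)  # zero run = one crossing
  expect_warning(z <- zeroCrossings(rep(0, 10)), "all-zero")
  expect_equal(z, 0L)
  expect_error(zeroCrossings(1), "2 samples")

  set.seed(31)
  x <- diff(cumsum(rnorm(1001)))
  expect_equal(zeroCrossings(x), zeroCrossOracle(x))

  # positive scaling leaves the count unchanged
  expect_equal(zeroCrossings(3.7 * x), zeroCrossings(x))
})

test_that("intercrossingSD measures timing variability of crossings", {
  rate <- 120
  tt <- (0:(60 * rate - 1)) / rate
  # equispaced crossings: residual SD is sampling quantization only,
  # far below the 0.4 s crossing interval
  expect_lt(intercrossingSD(sin(2 * pi * 1.25 * tt), rate), 0.01)

  # crossings at 1, 2, 4, 8 s -> intervals 1, 2, 4 -> SD = 1.5275
  x <- rep(1, 10 * rate)
  flips <- c(1, 2, 4, 8) * rate + 1
  sgn <- 1
  for (i in seq_along(flips)) {
    x[flips[i]:length(x)] <- -sgn
    sgn <- -sgn
  }
  expect_equal(intercrossingSD(x, rate), sd(c(1, 2, 4)), tolerance = 1e-12)
  expect_equal(sd(c(1, 2, 4)), 1.5275, tolerance = 1e-4)

  expect_warning(v <- intercrossingSD(c(rep(1, 50), rep(-1, 50)), rate),
                 "fewer than 3")
  expect_true(is.na(v))

  # jittered crossings: SD of intervals -> sqrt(2) * jitter SD
  set.seed(44)
  J <- 0.02
  times <- seq(0.5, 100, by = 0.5) + rnorm(200, sd = J)
  n <- 101 * rate
  sig <- rep(1, n)
  s <- 1
  for (ti in times) {
    idx <- ceiling(ti * rate)
    sig[idx:n] <- -s
    s <- -s
  }
  expect_equal(intercrossingSD(sig, rate), sqrt(2) * J, tolerance = 0.15)
})

test_that("computeMeasures builds the long table and propagates sentinels", {
  spec <- tinySpec(n_per_group = c(2L, 2L), duration = 12, seed = 19L)
  out <- runPipeline(runConfig("synthetic", spec = spec, cut_s = 1,
                               target_rate = 120))
  tab <- out$measures
  expect_setequal(names(tab),
                  c("subject_id", "group", "condition", "pm", "saen_pp",
                    "saen_pa", "n", "sigma"))
  expect_equal(nrow(tab), 20 * length(out$retained))
  expect_true(all(is.finite(tab$saen_pp)))
  expect_true(all(tab$n >= 0))

  # single trial, one PM -> one row
  sc <- out$scores[[1]]
  one <- computeMeasures(list(sc), retained = 1L,
                         params = entropyParams(rate = 120))
  expect_equal(nrow(one), 1L)

  # constant PA in one PM -> sentinel cell, others intact
  pa <- principalAccelerations(sc)
  pa[, 2] <- 0
  broken <- new("PMScores", pp = principalPositions(sc),
                pv = principalVelocities(sc), pa = pa,
                rate = sampleRate(sc), meta = trialMeta(sc))
  tb <- computeMeasures(list(broken), retained = 1:2,
                        params = entropyParams(rate = 120))
  expect_true(is.na(tb$saen_pa[2]))
  expect_true(is.na(tb$sigma[2]))
  expect_equal(tb$n[2], 0)
  expect_true(is.finite(tb$saen_pp[2]))
  expect_true(is.finite(tb$saen_pa[1]))
})

test_that("planted regularity gradient shows up in the measured sample entropies", {
  spec <- tinySpec(n_per_group = c(4L, 4L), duration = 12, seed = 23L,
                   base_regularity = 0.3, effect_shape = "monotone",
                   effect_amplitude = 2)
  out <- runPipeline(runConfig("synthetic", spec = spec, cut_s = 1,
                               target_rate = 120))
  tab <- out$measures[out$measures$pm == 1, ]
  cond_means <- tapply(tab$saen_pp, tab$condition, mean)
  cond_means <- cond_means[c("ST", "DT1", "DT2", "DT3", "DT4")]
  # monotone knob: last condition clearly more irregular than the first,
  # ranks increasing overall
  expect_gt(cond_means["DT4"], cond_means["ST"])
  expect_gt(cor(seq_along(cond_means), cond_means, method = "spearman"), 0.5)
})
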