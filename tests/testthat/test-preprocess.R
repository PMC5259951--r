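test_that("background correction subtracts the per-sample quantile and clamps", {
  probes <- toy_probes(ng = 1, np = 10, seed = 21)
  withr::local_seed(21)
  v <- round(runif(10, 50, 800), 1)
  x <- toy_intensities(probes, list(home = list(v, v + 5)))

  # method = none is the identity
  expect_equal(background_correct(x, method = "none"), x)

  out <- background_correct(x, q = 0.02, floor = 1, rel_floor = 0)
  # sorting oracle for the per-sample 2% quantile (type-7)
  q_oracle <- quantile(v, 0.02, names = FALSE)
  got <- out$intensity[out$sample_id == "home_r1"]
  expect_equal(got, pmax(v - q_oracle, 1))

  # constant matrix: quantile equals the value, everything clamps to floor
  xc <- toy_intensities(probes, list(home = list(rep(100, 10), rep(100, 10))))
  outc <- background_correct(xc, floor = 1, rel_floor = 0)
  expect_true(all(outc$intensity == 1))
  # with a proportional floor the clamp level is rel_floor * background
  outc2 <- background_correct(xc, floor = 1, rel_floor = 0.05)
  expect_true(all(outc2$intensity == 5))
})

test_that("masking flags the right probes and excludes them from statistics", {
  probes <- toy_probes(ng = 3, np = 4, seed = 22)
  withr::local_seed(22)
  x <- toy_intensities(probes, list(home = list(runif(12, 100, 200),
                                                runif(12, 100, 200))))
  expect_equal(mask_probes(x, character()), x)

  out <- suppressMessages(mask_probes(x, "^ps02"))
  expect_true(all(out$masked[out$probeset_id == "ps02_at"]))
  expect_false(any(out$masked[out$probeset_id != "ps02_at"]))
  expect_equal(dim(out), dim(x))

  # masked probes drop out of downstream means: recompute excluding rows
  bg <- background_correct(out, q = 0.02)
  m_all <- mean(bg$intensity[bg$sample_id == "home_r1"])
  m_unmasked <- mean(bg$intensity[bg$sample_id == "home_r1" & !bg$masked])
  manual <- mean(bg$intensity[bg$sample_id == "home_r1" &
                                bg$probeset_id != "ps02_at"])
  expect_equal(m_unmasked, manual)
  expect_false(isTRUE(all.equal(m_all, m_unmasked)))
})

test_that("glog2 matches log2 asymptotically and inverts exactly", {
  x <- c(0.01, 1, 10, 1e3, 1e6)
  expect_equal(glog2_inv(glog2(x)), x, tolerance = 1e-10)
  # h(x) - log2(x) tends to a constant (0 for this parameterisation)
  expect_lt(abs(glog2(1e6) - log2(1e6)), 1e-10)
  expect_lt(abs(glog2(1e3) - log2(1e3)), 1e-5)
})

test_that("identical replicates normalise to identical values", {
  probes <- toy_probes(ng = 2, np = 5, seed = 23)
  withr::local_seed(23)
  v <- runif(10, 50, 1000)
  x <- toy_intensities(probes, list(home = list(v, v)))
  out <- normalize_within_species(x)
  a <- out$normalized[out$sample_id == "home_r1"]
  b <- out$normalized[out$sample_id == "home_r2"]
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("a doubled replicate is calibrated back with half the scale", {
  probes <- toy_probes(ng = 5, np = 8, seed = 24)
  withr::local_seed(24)
  v <- exp(rnorm(40, log(300), 0.7))
  x <- toy_intensities(probes, list(home = list(v, 2 * v)))
  out <- normalize_within_species(x)
  p <- norm_params(out)
  b1 <- p$b[p$sample_id == "home_r1"]
  b2 <- p$b[p$sample_id == "home_r2"]
  expect_equal(b2, b1 / 2, tolerance = 1e-8)
  med1 <- median(out$normalized[out$sample_id == "home_r1"])
  med2 <- median(out$normalized[out$sample_id == "home_r2"])
  expect_equal(med1, med2, tolerance = 1e-6)
})

test_that("normalisation preserves within-sample rank order", {
  probes <- toy_probes(ng = 4, np = 6, seed = 25)
  withr::local_seed(25)
  x <- toy_intensities(probes, list(home = list(runif(24, 10, 2000),
                                                runif(24, 10, 2000))))
  out <- normalize_within_species(x)
  for (s in unique(out$sample_id)) {
    raw <- out$intensity[out$sample_id == s]
    nrm <- out$normalized[out$sample_id == s]
    expect_equal(order(raw), order(nrm))
  }
})

test_that("replicate SD of normalised values is stable across intensity deciles", {
  # multiplicative replicate noise: the glog scale should give roughly
  # constant between-replicate spread over the intensity range
  withr::local_seed(26)
  n <- 2000
  true <- 2^runif(n, 5, 12)
  probes <- tibble::tibble(probeset_id = sprintf("p%04d_at", 1:n),
                           probe_index = 1L, gene_id = sprintf("g%04d", 1:n),
                           sequence = NA_character_)
  mk <- function() true * 2^rnorm(n, 0, 0.25)
  x <- toy_intensities(probes, list(home = list(mk(), mk())))
  out <- normalize_within_species(x)
  d <- out$normalized[out$sample_id == "home_r1"] -
    out$normalized[out$sample_id == "home_r2"]
  dec <- cut(rank(true), 10)
  sds <- tapply(d, dec, sd)
  expect_lt(max(sds) / min(sds), 1.6)
})

test_that("normalisation demands replicates and non-negative input", {
  probes <- toy_probes(ng = 1, np = 3, seed = 27)
  x1 <- toy_intensities(probes, list(home = list(c(10, 20, 30))))
  expect_error(normalize_within_species(x1), ">= 2 replicate")
  x2 <- toy_intensities(probes, list(home = list(c(10, -1, 30),
                                                 c(10, 20, 30))))
  expect_error(normalize_within_species(x2), "negative")
})
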