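make_ref_tables <- function(h_vals, i_vals, k_vals) {
  n <- length(h_vals)
  probes <- tibble::tibble(probeset_id = sprintf("r%03d_at", seq_len(n)),
                           probe_index = 1L)
  mk <- function(v, sp) dplyr::bind_rows(lapply(1:2, function(r) {
    tibble::tibble(probeset_id = probes$probeset_id, probe_index = 1L,
                   sample_id = sprintf("%s_r%d", sp, r), species = sp,
                   replicate = r, intensity = v, masked = FALSE,
                   linear = v)
  }))
  list(home = mk(h_vals, "home"), het = mk(i_vals, "het"),
       mm = tibble::tibble(probeset_id = probes$probeset_id,
                           probe_index = 1L, k = k_vals, species = "het"))
}

test_that("S_k is the arithmetic mean of H/I ratios per mismatch stratum", {
  # two probes per k so min_probes is satisfied without interpolation
  k <- rep(0:4, each = 2)
  h <- rep(100, 10)
  i <- rep(100, 10)
  tbl <- make_ref_tables(h, i, k)
  sf <- scaling_factors(tbl$home, tbl$het, tbl$mm)
  expect_equal(sf$s_k, rep(1, 5))           # H = I -> S_k = 1
  expect_equal(sf$n_probes, rep(2L, 5))

  # probes with k = 1 all have H = 2 I -> S_1 = 2
  i2 <- i
  i2[k == 1] <- 50
  # the non-monotone hand-made sequence triggers the plateau warning
  expect_warning(
    sf2 <- scaling_factors(tbl$home, make_ref_tables(h, i2, k)$het, tbl$mm),
    "non-decreasing")
  expect_equal(sf2$s_k[sf2$k == 1], 2)

  # two k = 2 probes with ratios 2 and 4 -> arithmetic mean 3
  i3 <- i
  i3[k == 2] <- c(50, 25)
  sf3 <- suppressWarnings(
    scaling_factors(tbl$home, make_ref_tables(h, i3, k)$het, tbl$mm))
  expect_equal(sf3$s_k[sf3$k == 2], 3)
})

test_that("global factor is the truncated binomial-weighted sum", {
  k <- rep(0:4, each = 2)
  tbl <- make_ref_tables(rep(100, 10), rep(100, 10), k)
  sf <- scaling_factors(tbl$home, tbl$het, tbl$mm)
  m <- mismatch_model(25, 0.06, 4)

  # all S_k = 1, literal weights: S = sum of P(k), k = 0..4
  s_literal <- global_factor(global_scaling_factor(sf, m))
  partial_sum_oracle <- sum(dbinom(0:4, 25, 0.06))  # binomial partial sum
  expect_equal(s_literal, partial_sum_oracle, tolerance = 1e-12)
  expect_equal(s_literal, 0.985, tolerance = 5e-4)

  # renormalised weights: unit factors map to exactly 1
  expect_equal(global_factor(global_scaling_factor(sf, m, renormalize = TRUE)),
               1.0, tolerance = 1e-12)

  # S_1 = 2, others 1: S = sum P(k) + P(1), by hand
  sf_mod <- sf
  sf_mod$s_k[sf_mod$k == 1] <- 2
  s2 <- global_factor(global_scaling_factor(sf_mod, m))
  expect_equal(s2, partial_sum_oracle + dbinom(1, 25, 0.06), tolerance = 1e-12)
})

test_that("missing strata are interpolated with a warning, or fail when impossible", {
  k <- c(0, 0, 1, 1, 3, 3, 4, 4)            # k = 2 absent
  tbl <- make_ref_tables(rep(100, 8), rep(100, 8) / c(1, 1, 2, 2, 4, 4, 5, 5), k)
  expect_warning(sf <- scaling_factors(tbl$home, tbl$het, tbl$mm),
                 "interpolation")
  # linear interpolation between S_1 = 2 and S_3 = 4
  expect_equal(sf$s_k[sf$k == 2], 3)

  k_bad <- rep(0, 8)
  tbl_bad <- make_ref_tables(rep(100, 8), rep(100, 8), k_bad)
  expect_error(suppressWarnings(
    scaling_factors(tbl_bad$home, tbl_bad$het, tbl_bad$mm)),
    "cannot interpolate")
})

test_that("apply_scaling multiplies linear values and shifts log2 values", {
  probes <- toy_probes(ng = 1, np = 3, seed = 41)
  x <- toy_intensities(probes, list(het = list(c(10, 20, 30), c(11, 21, 31))))
  expect_equal(apply_scaling(x, 1)$intensity, x$intensity)
  expect_equal(apply_scaling(x, 2)$intensity, 2 * x$intensity)
  xl <- x
  xl$intensity <- log2(xl$intensity)
  expect_equal(apply_scaling(xl, 2, scale = "log2")$intensity,
               log2(x$intensity) + 1)
  expect_error(apply_scaling(x, -1), "positive")
  # masked probes are not scaled
  xm <- x
  xm$masked[1] <- TRUE
  out <- apply_scaling(xm, 2)
  expect_equal(out$intensity[1], x$intensity[1])
})

test_that("planted attenuation is recovered as S_k ~ 1/alpha_k", {
  alpha <- attenuation_profile()
  rp <- simulate_reference_probes(n_per_k = 200, seed = 55)
  home <- normalize_within_species(rp$home)
  het <- normalize_within_species(rp$het)
  sf <- scaling_factors(home, het, rp$mismatch)
  rel_err <- abs(sf$s_k * alpha[sf$k + 1] - 1)
  expect_true(all(rel_err < 0.05))
  # with attenuation the fitted sequence is non-decreasing in k
  expect_true(all(diff(sf$s_k) >= 0))
})

test_that("scaling factors serialise to YAML for audit", {
  k <- rep(0:4, each = 2)
  tbl <- make_ref_tables(rep(100, 10), rep(50, 10), k)
  sf <- global_scaling_factor(scaling_factors(tbl$home, tbl$het, tbl$mm))
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_scaling_factors(sf, tmp)
  y <- yaml::read_yaml(tmp)
  expect_equal(y$S, global_factor(sf), tolerance = 1e-6)
  expect_length(y$per_k, 5)
  expect_false(y$renormalized)
})
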