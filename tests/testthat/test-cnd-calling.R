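make_ratio_tbl <- function(ng, np, nr, fc = 0, sd = 0) {
  x <- tidyr::expand_grid(probeset_id = sprintf("g%03d_at", seq_len(ng)),
                          probe_index = seq_len(np),
                          replicate = seq_len(nr))
  x$log2_ratio <- fc + if (sd > 0) rnorm(nrow(x), 0, sd) else 0
  x
}

test_that("probe log2 ratios match the element-wise division oracle", {
  probes <- toy_probes(ng = 2, np = 3, seed = 61)
  withr::local_seed(61)
  hv <- list(runif(6, 100, 500), runif(6, 100, 500))
  iv <- list(runif(6, 100, 500), runif(6, 100, 500))
  home <- toy_intensities(probes, list(home = hv))
  het <- toy_intensities(probes, list(het = iv))
  r <- probe_log2_ratios(home, het)
  oracle <- c(log2(iv[[1]] / hv[[1]]), log2(iv[[2]] / hv[[2]]))
  got <- dplyr::arrange(r, replicate, probeset_id, probe_index)$log2_ratio
  want <- c(log2(iv[[1]] / hv[[1]])[order(probes$probeset_id, probes$probe_index)],
            log2(iv[[2]] / hv[[2]])[order(probes$probeset_id, probes$probe_index)])
  expect_equal(sort(got), sort(oracle))
  expect_equal(got, want)

  # het = home -> all zero; het = 4x home -> all 2
  expect_true(all(probe_log2_ratios(home, home |>
    dplyr::mutate(species = "het", sample_id = sub("home", "het", sample_id))
  )$log2_ratio == 0))
  het4 <- home |>
    dplyr::mutate(species = "het", sample_id = sub("home", "het", sample_id),
                  intensity = intensity * 4)
  expect_true(all(abs(probe_log2_ratios(home, het4)$log2_ratio - 2) < 1e-12))

  # mismatched probe universes are an error
  expect_error(probe_log2_ratios(home, het[het$probe_index != 3, ]),
               "universes differ")
})

test_that("degenerate probesets give the boundary p-values", {
  # all ratios exactly zero -> fc 0, p ~ 1
  r0 <- make_ratio_tbl(5, 11, 2, fc = 0)
  f0 <- test_probesets(r0)
  expect_true(all(f0$probesets$log2_fc == 0))
  expect_true(all(f0$probesets$p_raw > 0.99))

  # all ratios exactly one with tiny within-probe variance -> fc 1, p ~ 0
  withr::local_seed(62)
  r1 <- make_ratio_tbl(5, 11, 2, fc = 1, sd = 1e-4)
  f1 <- test_probesets(r1)
  expect_equal(f1$probesets$log2_fc, rep(1, 5), tolerance = 1e-3)
  expect_true(all(f1$probesets$p_raw < 1e-6))
})

test_that("null probeset p-values are uniform", {
  withr::local_seed(63)
  r <- make_ratio_tbl(2000, 11, 2, fc = 0, sd = 0.25)
  fit <- test_probesets(r)
  ks <- ks.test(fit$probesets$p_raw, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("moderated test agrees with an independent moderated-variance fit", {
  # cross-check: limma's eBayes on the same probe-level ratio matrix
  skip_if_not_installed("limma")
  withr::local_seed(64)
  ng <- 300; np <- 8; nr <- 2
  fc_true <- sample(c(0, 0, 0, 1), ng, replace = TRUE)
  r <- make_ratio_tbl(ng, np, nr, fc = 0, sd = 0.3)
  r$log2_ratio <- r$log2_ratio + fc_true[as.integer(factor(r$probeset_id))]
  fit <- test_probesets(r)

  y <- matrix(r$log2_ratio[order(r$probeset_id, r$probe_index, r$replicate)],
              nrow = ng, byrow = TRUE)   # gene x (probe x rep)
  # limma treats each probeset's observations as one gene's samples
  lf <- limma::eBayes(limma::lmFit(y))
  p_lim <- lf$p.value[, 1]
  p_ours <- fit$probesets$p_raw[order(fit$probesets$probeset_id)]
  # strong rank agreement between the two moderated tests
  expect_gt(cor(-log10(p_ours), -log10(p_lim), method = "spearman"), 0.95)
  # both recover essentially the same positives at FDR 0.1
  call_ours <- p.adjust(p_ours, "BH") <= 0.1
  call_lim <- p.adjust(p_lim, "BH") <= 0.1
  expect_gt(mean(call_ours == call_lim), 0.95)
})

test_that("BH adjustment matches the textbook step-up procedure", {
  bh_oracle <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
  }
  # hand-derived case: (0.01, 0.02, 0.03, 0.04) all adjust to 0.04
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  withr::local_seed(65)
  for (n in c(10, 100, 10000)) {
    p <- runif(n)
    expect_equal(p.adjust(p, "BH"), bh_oracle(p))
  }
})

test_that("call_cnd applies the log2 and FDR thresholds exactly", {
  tab <- tibble::tibble(
    probeset_id = c("pcr_like", "near_miss", "down", "flat", "uncallable"),
    log2_fc = c(1.69, 0.99, -1.4, 0.1, 2.0),
    p_raw = c(1e-6, 1e-5, 1e-6, 0.5, NA)
  )
  calls <- call_cnd(tab, up = 1, down = -1, alpha = 0.1)
  got <- setNames(calls$cnd_class, calls$probeset_id)
  # a gene at log2 ratio 1.69 with p_adj ~ 0 is expanded
  expect_equal(got[["pcr_like"]], "CNE")
  # 0.99 sits below the threshold no matter how significant
  expect_equal(got[["near_miss"]], "neutral")
  expect_equal(got[["down"]], "CNR")
  expect_equal(got[["flat"]], "neutral")
  expect_true(is.na(got[["uncallable"]]))
  # classes are exhaustive and mutually exclusive over callable genes
  expect_true(all(calls$cnd_class[!is.na(calls$p_raw)] %in%
                    c("CNE", "CNR", "neutral")))
})

test_that("intersect_species is a per-class set intersection", {
  mk <- function(ids, cls) {
    x <- tibble::tibble(probeset_id = ids, log2_fc = 1, p_raw = 0.001,
                        p_adj = 0.001, cnd_class = cls)
    class(x) <- c("cnd_calls", class(x))
    x
  }
  a <- mk(c("a", "b", "c", "d"), c("CNE", "CNE", "CNR", "neutral"))
  b <- mk(c("a", "b", "c", "d"), c("CNE", "CNR", "CNR", "CNE"))
  shared <- intersect_species(a, b)
  expect_equal(shared$probeset_id[shared$cnd_class == "CNE"], "a")
  expect_equal(shared$probeset_id[shared$cnd_class == "CNR"], "c")
  # identical call sets intersect to themselves; disjoint sets to nothing
  expect_equal(nrow(intersect_species(a, a)), 3)
  expect_equal(nrow(intersect_species(mk("x", "CNE"), mk("y", "CNE"))), 0)
})

test_that("planted duplications are recovered with few false positives", {
  ds <- shared_sim()
  ref <- make_reference_subset(ds, n_genes = 40, seed = 421)
  res <- suppressWarnings(
    run_cnd_pipeline(ds$intensities, ref$mismatch, gene_map = ds$probes))
  cm <- confusion_metrics(res$calls, ds$truth, "CNE")
  expect_gte(cm$sensitivity, 90)
  neutral <- ds$truth$gene_id[ds$truth$status == "single_copy"]
  cls <- res$calls$cnd_class[match(neutral, res$calls$gene_id)]
  expect_lte(mean(cls != "neutral"), 0.01)
})
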