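# Independent oracles and heavier shared fixtures used by several
# test files, including the acceptance checks.

# exact hypergeometric upper-tail oracle by multiplicative recurrence,
# independent of dhyper/fisher.test internals
hyper_tail_oracle <- function(a, b, c, d) {
  # P(X >= a) for X ~ Hypergeom drawing (a+b) from (a+c) successes of N
  N <- a + b + c + d
  K <- a + c
  n <- a + b
  lo <- max(0, n - (N - K)); hi <- min(n, K)
  # build pmf by recurrence from x = lo upward, then normalise
  x <- lo:hi
  logw <- numeric(length(x))
  for (j in seq_along(x)[-1]) {
    i <- x[j]
    # P(i)/P(i-1) = (K-i+1)(n-i+1) / (i (N-K-n+i))
    logw[j] <- logw[j - 1] + log(K - i + 1) + log(n - i + 1) -
      log(i) - log(N - K - n + i)
  }
  w <- exp(logw - max(logw))
  p <- w / sum(w)
  sum(p[x >= a])
}

# brute-force per-window, per-base overlap recount
window_oracle <- function(genes, len, window = 20000, step = 10000,
                          min_cov = 5000) {
  starts <- seq(0, len, by = step)
  starts <- starts[starts + window / 2 <= len]
  covered <- function(cls, ws, we) {
    g <- genes[genes$cnd_class == cls, , drop = FALSE]
    if (nrow(g) == 0) return(0L)
    base <- rep(FALSE, we - ws)
    for (i in seq_len(nrow(g))) {
      lo <- max(g$start[i], ws); hi <- min(g$end[i], we)
      if (hi > lo) base[(lo - ws + 1):(hi - ws)] <- TRUE
    }
    sum(base)
  }
  out <- lapply(starts, function(ws) {
    we <- min(ws + window, len)
    cne <- covered("CNE", ws, we)
    cnr <- covered("CNR", ws, we)
    sgn <- if (cne >= min_cov && cnr >= min_cov) "none"
    else if (cne >= min_cov) "CNE"
    else if (cnr >= min_cov) "CNR" else "none"
    data.frame(start = ws, cne_bases = cne, cnr_bases = cnr,
               sign_class = sgn)
  })
  do.call(rbind, out)
}

random_toy_genes <- function(n = 50, len = 3e5) {
  s <- sort(sample(0:(len - 8000), n))
  tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(n)),
    chrom = "chr1", start = s, end = s + sample(1500:8000, n, replace = TRUE),
    cnd_class = sample(c("CNE", "CNR", "neutral"), n, replace = TRUE,
                       prob = c(0.35, 0.35, 0.3))
  )
}

# independent table-lookup oracle for the nearest-neighbour free energy
dg37_oracle <- function(seq) {
  stacks <- c(AA = -1.00, TT = -1.00, AT = -0.88, TA = -0.58,
              CA = -1.45, TG = -1.45, GT = -1.44, AC = -1.44,
              CT = -1.28, AG = -1.28, GA = -1.30, TC = -1.30,
              CG = -2.17, GC = -2.24, GG = -1.84, CC = -1.84)
  init <- c(A = 1.03, T = 1.03, G = 0.98, C = 0.98)
  b <- strsplit(seq, "")[[1]]
  total <- init[[b[1]]] + init[[b[length(b)]]]
  for (i in seq_len(length(b) - 1)) {
    total <- total + stacks[[paste0(b[i], b[i + 1])]]
  }
  total
}

baseline_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- simulate_dataset(sim_config(n_genes = 250), seed = 113)
      bc <- background_correct(ds$intensities)
      cache <<- list(
        ds = ds,
        home = dplyr::filter(bc, species == "home"),
        het = dplyr::filter(bc, species == "het"),
        truth_ps = dplyr::mutate(ds$truth,
                                 gene_id = paste0(gene_id, "_at")),
        conserved = paste0(
          ds$truth$gene_id[ds$truth$status == "single_copy"], "_at")
      )
    }
    cache
  }
})

no_divergence_pair <- function(fx) {
  # het replaced by an exact copy of home values
  het <- fx$home |>
    dplyr::mutate(species = "het", sample_id = sub("home", "het", sample_id))
  list(home = fx$home, het = het)
}
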