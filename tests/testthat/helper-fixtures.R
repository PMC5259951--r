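# Shared fixtures: tiny in-code datasets used across test files.

random_25mer <- function(n = 1) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE), collapse = "")
  }, character(1))
}

# mutate a sequence at exactly `k` random positions
mutate_kmer <- function(seq, k) {
  b <- strsplit(seq, "")[[1]]
  pos <- sample(length(b), k)
  for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1)
  paste(b, collapse = "")
}

# minimal probe annotation: ng genes x np probes
toy_probes <- function(ng = 3, np = 4, seed = 1) {
  withr::local_seed(seed)
  tibble::tibble(
    probeset_id = rep(sprintf("ps%02d_at", seq_len(ng)), each = np),
    probe_index = rep(seq_len(np), times = ng),
    sequence = random_25mer(ng * np),
    gene_id = rep(sprintf("g%02d", seq_len(ng)), each = np)
  )
}

# long intensity tibble from a named list: values[[species]][[replicate]]
# is a numeric vector over the probes of `probes`
toy_intensities <- function(probes, values) {
  rows <- list()
  for (sp in names(values)) {
    for (r in seq_along(values[[sp]])) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        probeset_id = probes$probeset_id,
        probe_index = probes$probe_index,
        sample_id = sprintf("%s_r%d", sp, r),
        species = sp, replicate = r,
        intensity = values[[sp]][[r]],
        masked = FALSE
      )
    }
  }
  dplyr::bind_rows(rows)
}

# small simulated dataset shared by several heavier tests (cached per run)
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_dataset(sim_config(n_genes = 400), seed = 420)
    }
    cache
  }
})
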