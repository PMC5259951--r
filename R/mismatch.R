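#' Count probe-target mismatches
#'
#' Hamming distance between a probe sequence and the aligned target
#' subsequence of equal length. Vectorised over pairs.
#'
#' @param probe,target Character vectors of equal-length DNA sequences over
#'   A/C/G/T. Ambiguity codes are rejected: the caller must resolve or mask
#'   them upstream.
#' @return Integer vector of mismatch counts.
#' @export
#' @examples
#' count_mismatches("ACGTACGTACGTACGTACGTACGTA", "ACGTACGTACGTACGTACGTACGTA")
count_mismatches <- function(probe, target) {
  probe <- str_to_upper(probe)
  target <- str_to_upper(target)
  if (length(probe) != length(target)) {
    abort("probe and target vectors must have equal length")
  }
  if (any(nchar(probe) != nchar(target))) {
    abort("probe and target sequences must be the same length")
  }
  if (any(!grepl("^[ACGT]+$", probe)) || any(!grepl("^[ACGT]+$", target))) {
    abort("sequences must contain only A/C/G/T (no ambiguity codes)")
  }
  mapply(function(a, b) sum(charToRaw(a) != charToRaw(b)),
         probe, target, USE.NAMES = FALSE)
}

#' Build a mismatch table from probes and their heterologous targets
#'
#' @param probes Probe annotation tibble (`probeset_id`, `probe_index`,
#'   `sequence`).
#' @param targets Tibble (`probeset_id`, `probe_index`, `target`) giving the
#'   aligned heterologous target 25-mer for each probe (the alignment itself
#'   is upstream input).
#' @param species Species label recorded in the table.
#' @return Tibble (`probeset_id`, `probe_index`, `k`, `species`).
#' @export
mismatch_table <- function(probes, targets, species = "het") {
  x <- inner_join(probes[, c("probeset_id", "probe_index", "sequence")],
                  targets, by = c("probeset_id", "probe_index"))
  if (nrow(x) == 0) abort("no probes in common between probes and targets")
  tibble(probeset_id = x$probeset_id, probe_index = x$probe_index,
         k = count_mismatches(x$sequence, x$target), species = species)
}

#' Read heterologous target sequences from FASTA
#'
#' Record names must follow `probeset_id|probe_index`.
#'
#' @param path FASTA file path.
#' @return Tibble (`probeset_id`, `probe_index`, `target`).
#' @export
read_targets_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("reading FASTA requires the Biostrings package")
  }
  seqs <- Biostrings::readDNAStringSet(path)
  parts <- str_split(names(seqs), stringr::fixed("|"), n = 2)
  if (any(lengths(parts) != 2)) {
    abort("FASTA names must be 'probeset_id|probe_index'")
  }
  tibble(probeset_id = map_chr(parts, 1),
         probe_index = as.integer(map_chr(parts, 2)),
         target = as.character(seqs))
}

#' Binomial model for per-probe mismatch counts
#'
#' Each of the `n` positions of a probe either matches or mismatches its
#' heterologous target, so the mismatch count per probe follows
#' Binomial(`n`, `p`), with `p` the per-base divergence (default 0.06, i.e.
#' 94% average nucleotide identity between the hybridised species pair).
#' `kmax` is the truncation used when the per-mismatch correction factors
#' are combined into a global scaling factor.
#'
#' @param n Probe length (default 25).
#' @param p Per-base mismatch probability in `[0, 1]`.
#' @param kmax Truncation for the global scaling sum, in `[0, n]`.
#' @return An object of class `mismatch_model`.
#' @export
mismatch_model <- function(n = 25L, p = 0.06, kmax = 4L) {
  n <- as.integer(n); kmax <- as.integer(kmax)
  if (n < 1) abort("n must be >= 1")
  if (p < 0 || p > 1) abort("p must be in [0, 1]")
  if (kmax < 0 || kmax > n) abort("kmax must be in [0, n]")
  structure(list(n = n, p = p, kmax = kmax), class = "mismatch_model")
}

#' @export
print.mismatch_model <- function(x, ...) {
  cat(sprintf("<mismatch_model> Binomial(n = %d, p = %g), kmax = %d\n",
              x$n, x$p, x$kmax))
  invisible(x)
}

#' Probability of k mismatches under the binomial model
#'
#' @param model A [mismatch_model()].
#' @param k Integer vector of mismatch counts, each in `[0, n]`.
#' @return `choose(n, k) p^k (1-p)^(n-k)` for each `k`.
#' @export
mismatch_pmf <- function(model, k) {
  stopifnot(inherits(model, "mismatch_model"))
  if (any(k < 0 | k > model$n)) {
    abort(sprintf("k must be in [0, %d]", model$n))
  }
  dbinom(k, size = model$n, prob = model$p)
}

#' Chi-square goodness of fit of an observed mismatch histogram
#'
#' Compares observed mismatch counts against the binomial expectation,
#' pooling the upper tail (`k >= pool_at`) into one bin so that expected
#' counts stay away from zero. The statistic is the usual Pearson
#' \eqn{\sum (O-E)^2/E} with `df = bins - 1` and an upper-tail p-value.
#'
#' @param observed Either a tibble with columns `k` and `count`, or a named
#'   numeric vector of counts with names giving `k`.
#' @param model A [mismatch_model()].
#' @param pool_at Pool all counts with `k >= pool_at` (default 4, giving
#'   bins 0, 1, 2, 3, >=4).
#' @return One-row tibble (`chi2`, `df`, `p`).
#' @export
mismatch_gof <- function(observed, model, pool_at = 4L) {
  if (is.data.frame(observed)) {
    kk <- as.integer(observed$k); cnt <- as.numeric(observed$count)
  } else {
    kk <- as.integer(names(observed)); cnt <- as.numeric(observed)
  }
  if (any(is.na(kk)) || any(cnt < 0)) abort("observed counts must be named, non-negative")
  n_total <- sum(cnt)
  if (n_total <= 0) abort("observed histogram is empty")
  pool_at <- as.integer(pool_at)
  if (pool_at < 1 || pool_at > model$n) abort("pool_at must be in [1, n]")
  bin_of <- function(k) pmin(k, pool_at)
  obs <- tapply(cnt, bin_of(kk), sum)
  bins <- 0:pool_at
  o <- setNames(numeric(length(bins)), bins)
  o[names(obs)] <- obs
  p_bin <- c(dbinom(0:(pool_at - 1), model$n, model$p),
             1 - pbinom(pool_at - 1, model$n, model$p))
  e <- n_total * p_bin
  if (any(e == 0)) {
    abort("a bin has expected count 0; re-bin with a smaller pool_at")
  }
  chi2 <- sum((o - e)^2 / e)
  df <- length(bins) - 1L
  tibble(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}
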