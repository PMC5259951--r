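#' Sliding-window scan for large copy-number divergent regions
#'
#' Moves a fixed-width window (default 20 kb) along each chromosome in
#' steps (default 10 kb) and scores every window by how many of its bases
#' are covered by gene bodies of one concordant call class. Gene intervals
#' of a class are merged first, so overlapping genes are not
#' double-counted. A window is positive for CNE or CNR when the merged
#' coverage of that class reaches `min_cov` (default 5 kb); if both
#' classes reach it, the window is ambiguous and scored `none` with a
#' warning.
#'
#' Windows are anchored at position 0 of each chromosome and always span
#' `window` bases; a final window running past the chromosome end is kept
#' only while at least half of it lies on the chromosome.
#'
#' @param cnd_genes Tibble with `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open) and `cnd_class`; only CNE/CNR rows contribute.
#' @param chrom_lengths Tibble (`chrom`, `length`).
#' @param window Window width in bases (default 20000).
#' @param step Step size in bases (default 10000); must be `<= window`.
#' @param min_cov Minimum covered bases for a positive call (default
#'   5000).
#' @return Tibble (`chrom`, `start`, `end`, `cne_bases`, `cnr_bases`,
#'   `sign_class`), one row per window.
#' @export
window_scan <- function(cnd_genes, chrom_lengths, window = 20000L,
                        step = 10000L, min_cov = 5000L) {
  if (step > window) abort("step must not exceed the window size (windows must overlap or tile)")
  bad_chrom <- setdiff(unique(cnd_genes$chrom), chrom_lengths$chrom)
  if (length(bad_chrom) > 0) {
    abort(sprintf("unknown chromosome(s): %s", paste(bad_chrom, collapse = ", ")))
  }
  cnd <- filter(cnd_genes, cnd_class %in% c("CNE", "CNR"))
  ambiguous <- 0L
  out <- map(seq_len(nrow(chrom_lengths)), function(ci) {
    chr <- chrom_lengths$chrom[ci]
    len <- chrom_lengths$length[ci]
    starts <- seq(0L, by = as.integer(step),
                  length.out = max(1L, floor((len - window / 2) / step) + 1L))
    starts <- starts[starts + window / 2 <= len]
    if (length(starts) == 0) starts <- 0L
    merged <- function(cls) {
      g <- filter(cnd, chrom == chr, cnd_class == cls)
      if (nrow(g) == 0) return(IRanges::IRanges())
      IRanges::reduce(IRanges::IRanges(start = g$start + 1L, end = g$end))
    }
    cov_in <- function(rng, ws, we) {
      if (length(rng) == 0) return(rep(0L, length(ws)))
      vapply(seq_along(ws), function(j) {
        r <- IRanges::restrict(rng, start = ws[j] + 1L, end = we[j])
        sum(IRanges::width(r))
      }, integer(1))
    }
    wend <- pmin(starts + as.integer(window), as.integer(len))
    cne <- cov_in(merged("CNE"), starts, wend)
    cnr <- cov_in(merged("CNR"), starts, wend)
    both <- cne >= min_cov & cnr >= min_cov
    ambiguous <<- ambiguous + sum(both)
    sign_class <- ifelse(both, "none",
                  ifelse(cne >= min_cov, "CNE",
                  ifelse(cnr >= min_cov, "CNR", "none")))
    tibble(chrom = chr, start = as.integer(starts),
           end = as.integer(starts + window),
           cne_bases = cne, cnr_bases = cnr, sign_class = sign_class)
  })
  if (ambiguous > 0) {
    warn(sprintf("%d window(s) reached min_cov for both classes; scored 'none'", ambiguous))
  }
  bind_rows(out)
}

#' Merge consecutive concordant windows into segment calls
#'
#' Maximal runs of at least `min_consecutive` step-adjacent windows with
#' the same positive class become one segment spanning the union of the
#' run's windows (so a run of 3 windows at 10-kb steps with 20-kb width
#' spans 40 kb). Shorter runs and discordant neighbours produce no
#' segment.
#'
#' @param windows Window tibble from [window_scan()], ordered by
#'   chromosome and start.
#' @param min_consecutive Minimum run length (default 3).
#' @return Tibble (`chrom`, `start`, `end`, `sign_class`, `n_windows`).
#' @export
merge_segments <- function(windows, min_consecutive = 3L) {
  windows <- arrange(windows, chrom, start)
  out <- windows |>
    group_by(chrom) |>
    group_map(function(w, key) {
      if (nrow(w) == 0) return(NULL)
      step <- if (nrow(w) > 1) min(diff(w$start)) else w$end[1] - w$start[1]
      # run id increments when the class changes or windows are not step-adjacent
      brk <- c(TRUE, w$sign_class[-1] != w$sign_class[-nrow(w)] |
                 diff(w$start) != step)
      run <- cumsum(brk)
      w |>
        mutate(run = run) |>
        group_by(run) |>
        summarise(chrom = key$chrom, start = min(start), end = max(end),
                  sign_class = sign_class[1], n_windows = n(),
                  .groups = "drop") |>
        filter(sign_class != "none", n_windows >= min_consecutive) |>
        select(chrom, start, end, sign_class, n_windows)
    }) |>
    bind_rows()
  if (nrow(out) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  sign_class = character(), n_windows = integer()))
  }
  arrange(out, chrom, start)
}

#' Write segment calls as BED
#'
#' BED columns: chrom, start, end (0-based half-open), name = call class,
#' score = number of windows in the run.
#'
#' @param segments Segment tibble from [merge_segments()].
#' @param path Output path.
#' @return `segments`, invisibly.
#' @export
write_segments_bed <- function(segments, path) {
  bed <- tibble(chrom = segments$chrom, start = segments$start,
                end = segments$end, name = segments$sign_class,
                score = segments$n_windows)
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(segments)
}
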