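#' Generalised log2 transform and its inverse
#'
#' `glog2(y) = log2(y + sqrt(y^2 + 1)) - 1`, an arsinh-family transform that
#' behaves like `log2(y)` for large `y` (the difference tends to 0) while
#' remaining defined and smooth through zero. `glog2_inv()` is its exact
#' inverse.
#'
#' @param y,h Numeric vectors.
#' @return Numeric vector.
#' @export
glog2 <- function(y) asinh(y) / log(2) - 1

#' @rdname glog2
#' @export
glog2_inv <- function(h) sinh((h + 1) * log(2))

#' Background-correct raw intensities
#'
#' Subtracts a per-sample background estimate — the `q`-quantile of the
#' unmasked probe intensities of that sample — and clamps the result at a
#' small positive floor so that subsequent log-family transforms are
#' defined. With chip geometry unavailable in tabulated data, a low-quantile
#' floor stands in for zone-based background estimation: it removes the
#' additive offset while preserving positivity. Masked probes are excluded
#' from background estimation but still receive the correction.
#'
#' The clamp is proportional to the sample's own background level,
#' `max(floor, rel_floor * background)`: a probe below background is set
#' to the same small *fraction* of background in every sample, so that a
#' sub-background probe keeps a comparable value in a dim (heterologous)
#' and a bright (homologous) hybridisation instead of collapsing onto one
#' absolute constant, which would fabricate large cross-species ratios at
#' the low end.
#'
#' @param x Long intensity tibble.
#' @param method `"quantile_floor"` or `"none"` (returns input unchanged).
#' @param q Background quantile in `(0, 0.5)`; default 0.02.
#' @param floor Absolute lower bound of the clamp (default 1).
#' @param rel_floor Clamp as a fraction of the per-sample background
#'   estimate (default 0.05).
#' @return Intensity tibble with corrected `intensity`.
#' @export
background_correct <- function(x, method = c("quantile_floor", "none"),
                               q = 0.02, floor = 1.0, rel_floor = 0.05) {
  method <- match.arg(method)
  if (method == "none") return(x)
  if (q <= 0 || q >= 0.5) abort("background quantile q must be in (0, 0.5)")
  if (floor <= 0) abort("floor must be positive")
  if (rel_floor < 0 || rel_floor >= 1) abort("rel_floor must be in [0, 1)")
  if (all(x$masked)) abort("all probes are masked; cannot estimate background")
  x |>
    group_by(sample_id) |>
    mutate(intensity = {
      if (all(masked)) abort("all probes masked in a sample")
      bg <- quantile(intensity[!masked], probs = q, names = FALSE, type = 7)
      pmax(intensity - bg, max(floor, rel_floor * bg))
    }) |>
    ungroup()
}

#' Mask probes by probeset-id pattern
#'
#' Flags probes whose `probeset_id` matches any of the given regular
#' expressions (e.g. organellar, control or known multi-copy probesets).
#' Matrix dimensions are unchanged; masked probes are excluded from all
#' downstream statistics. An empty match is legal and reported.
#'
#' @param x Long intensity tibble.
#' @param exclude Character vector of regular expressions (possibly empty).
#' @return Intensity tibble with updated `masked` column.
#' @export
mask_probes <- function(x, exclude = character()) {
  if (length(exclude) == 0) return(x)
  hit <- Reduce(`|`, lapply(exclude, function(p) str_detect(x$probeset_id, p)))
  n_sets <- length(unique(x$probeset_id[hit]))
  inform(sprintf("mask_probes: %d probeset(s) matched the exclusion patterns", n_sets))
  x$masked <- x$masked | hit
  x
}

#' Within-species variance-stabilising normalisation
#'
#' Calibrates the replicate hybridisations of one species onto a common
#' scale and applies a generalised-log transform. Per sample `s` an affine
#' calibration `y = a_s + b_s x` is fitted robustly: `b_s` equalises the MAD
#' (so a replicate measured at twice the gain gets half the scale factor)
#' and `a_s` then matches the medians; `glog2` of the calibrated values is
#' the normalised, log-like signal. The transform is monotone increasing,
#' so within-sample rank order is preserved.
#'
#' @param x Long intensity tibble (background-corrected, non-negative).
#' @param species Species to normalise; `NULL` (default) normalises every
#'   species in the table separately.
#' @param floor Positive clamp for the calibrated linear values (log2 of
#'   `linear` must be defined downstream).
#' @return The tibble with added columns `linear` (calibrated linear-scale
#'   intensity) and `normalized` (glog2 scale), and an attribute
#'   `norm_params`: a tibble (`sample_id`, `species`, `a`, `b`).
#' @export
normalize_within_species <- function(x, species = NULL, floor = 1e-3) {
  if (any(x$intensity < 0)) {
    abort("negative intensities: apply background_correct() first")
  }
  todo <- species %||% unique(x$species)
  params <- list()
  x$linear <- NA_real_
  x$normalized <- NA_real_
  for (sp in todo) {
    rows_sp <- x$species == sp
    ids <- unique(x$sample_id[rows_sp])
    if (length(ids) < 2) {
      abort(sprintf("species '%s' needs >= 2 replicate samples", sp))
    }
    stats_s <- map(ids, function(s) {
      v <- x$intensity[rows_sp & x$sample_id == s & !x$masked]
      c(med = median(v), mad = mad(v))
    })
    meds <- map_dbl(stats_s, "med")
    mads <- map_dbl(stats_s, "mad")
    if (any(mads <= 0)) {
      abort(sprintf("species '%s': a sample has zero spread; cannot calibrate", sp))
    }
    med_ref <- median(meds)
    mad_ref <- exp(mean(log(mads)))
    b <- mad_ref / mads
    a <- med_ref - b * meds
    for (i in seq_along(ids)) {
      rows <- rows_sp & x$sample_id == ids[i]
      y <- a[i] + b[i] * x$intensity[rows]
      x$linear[rows] <- pmax(y, floor)
      x$normalized[rows] <- glog2(y)
    }
    params[[sp]] <- tibble(sample_id = ids, species = sp, a = a, b = b)
  }
  keep <- !x$species %in% todo
  if (any(keep)) {
    # untouched species keep raw values on both scales
    x$linear[keep] <- pmax(x$intensity[keep], floor)
    x$normalized[keep] <- glog2(x$intensity[keep])
  }
  attr(x, "norm_params") <- bind_rows(params)
  x
}

#' Extract normalisation parameters
#'
#' @param x Result of [normalize_within_species()].
#' @return Tibble (`sample_id`, `species`, `a`, `b`).
#' @export
norm_params <- function(x) {
  p <- attr(x, "norm_params")
  if (is.null(p)) abort("no normalisation parameters attached")
  p
}
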