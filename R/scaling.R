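#' Incremental correction factors per mismatch count
#'
#' For every mismatch count `k` up to `kmax`, the incremental correction
#' factor is the arithmetic mean, over the `N_k` reference-dataset probes
#' carrying exactly `k` mismatches, of the ratio of homologous to
#' heterologous signal: `S_k = (1/N_k) * sum_i H_ik / I_ik`. Replicate
#' values are averaged per probe before the ratio is formed (ratios of
#' means, which damps low-intensity noise). A `k` stratum with fewer than
#' `min_probes` probes is filled by linear interpolation from its
#' neighbours, with a warning; a fitted sequence that decreases in `k`
#' (attenuation should not lessen with more mismatches) also triggers a
#' warning, not an error, since measured curves plateau.
#'
#' @param home Normalised intensity tibble of the homologous (reference)
#'   species, restricted to (or containing) the reference-dataset probes.
#' @param het Normalised intensity tibble of the heterologous species.
#' @param mm Mismatch table (`probeset_id`, `probe_index`, `k`) for the
#'   reference-dataset probes.
#' @param kmax Largest mismatch count used (default 4).
#' @param min_probes Minimum probes per stratum (default 2).
#' @param value_col Intensity column used for the ratios; default
#'   `"linear"` (calibrated linear scale) falling back to `"intensity"`.
#' @return Tibble (`k`, `n_probes`, `s_k`, `estimated`) of class
#'   `scaling_factors`.
#' @export
scaling_factors <- function(home, het, mm, kmax = 4L, min_probes = 2L,
                            value_col = NULL) {
  value_col <- value_col %||% (if ("linear" %in% names(home)) "linear" else "intensity")
  kmax <- as.integer(kmax)
  per_probe <- function(x) {
    x |>
      filter(!masked) |>
      semi_join(mm, by = c("probeset_id", "probe_index")) |>
      group_by(probeset_id, probe_index) |>
      summarise(value = mean(.data[[value_col]]), .groups = "drop")
  }
  h <- per_probe(home)
  i <- per_probe(het)
  x <- inner_join(h, i, by = c("probeset_id", "probe_index"),
                  suffix = c("_h", "_i")) |>
    inner_join(mm[, c("probeset_id", "probe_index", "k")],
               by = c("probeset_id", "probe_index"))
  if (nrow(x) == 0) abort("no reference probes shared between home, het and mm")
  if (any(x$value_i <= 0)) {
    abort("zero or negative heterologous intensity; apply a positive floor upstream")
  }
  est <- x |>
    filter(k <= kmax) |>
    group_by(k) |>
    summarise(n_probes = n(), s_k = mean(value_h / value_i), .groups = "drop")
  out <- tibble(k = 0:kmax) |>
    left_join(est, by = "k") |>
    mutate(n_probes = ifelse(is.na(n_probes), 0L, n_probes),
           estimated = n_probes >= min_probes,
           s_k = ifelse(estimated, s_k, NA_real_))
  if (any(!out$estimated)) {
    ok <- which(out$estimated)
    if (length(ok) < 2) {
      abort("fewer than two mismatch strata are adequately populated; cannot interpolate")
    }
    warn(sprintf(
      "S_k for k = %s had < %d probes; filled by linear interpolation",
      paste(out$k[!out$estimated], collapse = ", "), min_probes))
    out$s_k <- stats::approx(out$k[ok], out$s_k[ok], xout = out$k,
                             rule = 2)$y
  }
  if (any(diff(out$s_k) < 0)) {
    warn("fitted S_k sequence is not non-decreasing in k (attenuation plateau or noise)")
  }
  class(out) <- c("scaling_factors", class(out))
  out
}

#' Global scaling factor from incremental factors
#'
#' Combines the incremental factors into a single species-specific global
#' scaling factor: the binomial-probability-weighted sum
#' `S = sum_{k=0}^{kmax} S_k * P_n(k)`, truncated at `kmax`. The truncated
#' weights sum to slightly less than 1 (about 0.985 for n = 25, p = 0.06,
#' kmax = 4), so all-unit `S_k` give `S ~ 0.985`, not 1; setting
#' `renormalize = TRUE` divides the weights by their sum so that unit
#' factors map to exactly 1.
#'
#' @param per_k A `scaling_factors` tibble from [scaling_factors()].
#' @param model A [mismatch_model()].
#' @param renormalize Renormalise the truncated binomial weights to sum
#'   to 1 (default `FALSE`: the literal weighted sum).
#' @return `per_k` with attributes `S` (the global factor), `renormalized`
#'   and `model`; retrieve the number with [global_factor()].
#' @export
global_scaling_factor <- function(per_k, model = mismatch_model(),
                                  renormalize = FALSE) {
  kk <- 0:model$kmax
  if (!all(kk %in% per_k$k) || any(is.na(per_k$s_k[match(kk, per_k$k)]))) {
    abort(sprintf("S_k must be available for every k in 0..%d", model$kmax))
  }
  w <- mismatch_pmf(model, kk)
  if (renormalize) w <- w / sum(w)
  s <- sum(per_k$s_k[match(kk, per_k$k)] * w)
  if (s <= 0) abort("global scaling factor must be positive")
  attr(per_k, "S") <- s
  attr(per_k, "renormalized") <- renormalize
  attr(per_k, "model") <- model
  per_k
}

#' @rdname global_scaling_factor
#' @param sf A `scaling_factors` object carrying the `S` attribute.
#' @export
global_factor <- function(sf) {
  s <- attr(sf, "S")
  if (is.null(s)) abort("run global_scaling_factor() first")
  s
}

#' Apply the global scaling factor to heterologous intensities
#'
#' Multiplies every unmasked heterologous intensity by `S` on the linear
#' scale (equivalently, adds `log2(S)` when the values are on a log2
#' scale). The homologous species is left untouched by construction: pass
#' only the heterologous table.
#'
#' @param het Heterologous intensity tibble.
#' @param S Positive global scaling factor (a number or a
#'   `scaling_factors` object carrying one).
#' @param scale `"linear"` (multiply) or `"log2"` (add `log2(S)`).
#' @param value_col Column to scale; defaults to `"linear"` if present,
#'   else `"intensity"` (for `scale = "log2"`, the column is assumed to
#'   already hold log2-scale values).
#' @return The tibble with the scaled column.
#' @export
apply_scaling <- function(het, S, scale = c("linear", "log2"),
                          value_col = NULL) {
  scale <- match.arg(scale)
  if (inherits(S, "scaling_factors")) S <- global_factor(S)
  if (!is.numeric(S) || length(S) != 1 || S <= 0) {
    abort("S must be a single positive number")
  }
  value_col <- value_col %||% (if ("linear" %in% names(het)) "linear" else "intensity")
  v <- het[[value_col]]
  het[[value_col]] <- ifelse(het$masked, v,
                             if (scale == "linear") v * S else v + log2(S))
  het
}

#' Serialise scaling factors to YAML
#'
#' Writes `k`, `N_k`, `S_k`, the global `S` and the renormalisation flag
#' for audit.
#'
#' @param sf A `scaling_factors` object (after [global_scaling_factor()]).
#' @param path Output YAML path.
#' @return `sf`, invisibly.
#' @export
write_scaling_factors <- function(sf, path) {
  yaml::write_yaml(list(
    S = attr(sf, "S"),
    renormalized = isTRUE(attr(sf, "renormalized")),
    per_k = lapply(seq_len(nrow(sf)), function(i) {
      list(k = sf$k[i], n_probes = sf$n_probes[i], s_k = sf$s_k[i])
    })
  ), path)
  invisible(sf)
}

#' @export
print.scaling_factors <- function(x, ...) {
  cat("<scaling_factors>\n")
  print(as_tibble(unclass(x)))
  s <- attr(x, "S")
  if (!is.null(s)) {
    cat(sprintf("global S = %.4f (renormalized = %s)\n", s,
                isTRUE(attr(x, "renormalized"))))
  }
  invisible(x)
}

#' Diagnostic plot of incremental correction factors
#'
#' @param object A `scaling_factors` object.
#' @param ... Unused.
#' @return A ggplot: `S_k` against `k`, with the global factor as a
#'   horizontal reference when available.
#' @exportS3Method ggplot2::autoplot
autoplot.scaling_factors <- function(object, ...) {
  p <- ggplot(as_tibble(unclass(object)), aes(x = k, y = s_k)) +
    geom_line(colour = "grey50") +
    geom_point(aes(colour = estimated), size = 2) +
    scale_colour_manual(values = c(`TRUE` = "black", `FALSE` = "tomato"),
                        name = "directly estimated") +
    labs(x = "mismatches per probe (k)",
         y = expression(S[k]),
         title = "Incremental signal correction factors") +
    theme_bw()
  s <- attr(object, "S")
  if (!is.null(s)) p <- p + geom_hline(yintercept = s, linetype = 2)
  p
}
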