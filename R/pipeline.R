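#' End-to-end copy-number divergence pipeline
#'
#' Runs the full two-step analysis on a pair of species: background
#' correction and probe masking, within-species variance-stabilising
#' normalisation, estimation of the incremental correction factors from
#' the reference-dataset probes and of the global scaling factor, scaling
#' of the heterologous intensities, probe-level log2 ratios, the
#' moderated per-probeset test, and CNE/CNR classification.
#'
#' @param intensities Long raw intensity tibble holding both species.
#' @param reference_mm Mismatch table (`probeset_id`, `probe_index`, `k`)
#'   of the reference-dataset probes.
#' @param home_species,het_species Species labels in `intensities`.
#' @param model A [mismatch_model()].
#' @param mask_patterns Probeset-id patterns to mask (regular
#'   expressions).
#' @param config Analysis configuration ([default_config()] /
#'   [read_config()]); thresholds and background settings are taken from
#'   it unless overridden.
#' @param up,down,alpha Calling thresholds (default from `config`).
#' @param gene_map Optional (`probeset_id`, `gene_id`) map attached to
#'   the calls.
#' @return List of class `cnd_pipeline`: `calls` (a `cnd_calls` tibble),
#'   `fit` (`cnd_fit`), `scaling` (`scaling_factors` with global S),
#'   `ratios`, and the normalised per-species tables `home`, `het`.
#' @export
run_cnd_pipeline <- function(intensities, reference_mm,
                             home_species = "home", het_species = "het",
                             model = mismatch_model(),
                             mask_patterns = character(),
                             config = default_config(),
                             up = config$thresholds$up,
                             down = config$thresholds$down,
                             alpha = config$thresholds$alpha,
                             gene_map = NULL) {
  x <- intensities |>
    background_correct(method = config$background$method,
                       q = config$background$q,
                       floor = config$background$floor,
                       rel_floor = config$background$rel_floor) |>
    mask_probes(mask_patterns) |>
    normalize_within_species()
  params <- norm_params(x)
  home <- filter(x, species == home_species)
  het <- filter(x, species == het_species)
  if (nrow(home) == 0 || nrow(het) == 0) {
    abort("home or het species absent from the intensity table")
  }
  sf <- scaling_factors(home, het, reference_mm, kmax = model$kmax,
                        min_probes = config$scaling$min_probes) |>
    global_scaling_factor(model = model,
                          renormalize = config$scaling$renormalize)
  het_scaled <- apply_scaling(het, sf)
  ratios <- probe_log2_ratios(home, het_scaled)
  fit <- test_probesets(ratios)
  calls <- call_cnd(fit, up = up, down = down, alpha = alpha,
                    gene_map = gene_map)
  structure(list(calls = calls, fit = fit, scaling = sf, ratios = ratios,
                 home = home, het = het_scaled, norm_params = params),
            class = "cnd_pipeline")
}

#' @export
print.cnd_pipeline <- function(x, ...) {
  n_cne <- sum(x$calls$cnd_class == "CNE", na.rm = TRUE)
  n_cnr <- sum(x$calls$cnd_class == "CNR", na.rm = TRUE)
  cat(sprintf("<cnd_pipeline> %d probesets tested; global S = %.4f\n",
              nrow(x$calls), global_factor(x$scaling)))
  cat(sprintf("calls: %d CNE, %d CNR\n", n_cne, n_cnr))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cnd_pipeline <- function(x, ...) as_tibble(x$calls)

#' @exportS3Method generics::glance
glance.cnd_pipeline <- function(x, ...) {
  tibble(n_probesets = nrow(x$calls),
         n_cne = sum(x$calls$cnd_class == "CNE", na.rm = TRUE),
         n_cnr = sum(x$calls$cnd_class == "CNR", na.rm = TRUE),
         global_s = global_factor(x$scaling),
         d0 = x$fit$d0, s0_sq = x$fit$s0_sq)
}
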