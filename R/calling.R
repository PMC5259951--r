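#' Probe-level log2 ratios between species
#'
#' Pairs the heterologous (scaled) and homologous replicates by replicate
#' number (replicate 1 vs 1, 2 vs 2) and returns per-probe, per-replicate
#' `log2(het / home)` on the calibrated linear scale. Probes masked in
#' either species are dropped; a probe present in only one matrix is an
#' error.
#'
#' @param home,het_scaled Normalised intensity tibbles (het after
#'   [apply_scaling()]).
#' @param value_col Intensity column; defaults to `"linear"` if present.
#' @return Tibble (`probeset_id`, `probe_index`, `replicate`,
#'   `log2_ratio`).
#' @export
probe_log2_ratios <- function(home, het_scaled, value_col = NULL) {
  value_col <- value_col %||% (if ("linear" %in% names(home)) "linear" else "intensity")
  pick <- function(x) {
    x |>
      filter(!masked) |>
      select(probeset_id, probe_index, replicate,
             value = all_of(value_col))
  }
  h <- pick(home)
  i <- pick(het_scaled)
  probes_h <- unique(paste(h$probeset_id, h$probe_index))
  probes_i <- unique(paste(i$probeset_id, i$probe_index))
  if (!setequal(probes_h, probes_i)) {
    abort(sprintf("probe universes differ between species (%d vs %d probes; %d shared)",
                  length(probes_h), length(probes_i),
                  length(intersect(probes_h, probes_i))))
  }
  x <- inner_join(h, i, by = c("probeset_id", "probe_index", "replicate"),
                  suffix = c("_home", "_het"))
  if (any(x$value_home <= 0 | x$value_het <= 0)) {
    abort("non-positive intensities; a positive floor must be applied upstream")
  }
  x |>
    transmute(probeset_id, probe_index, replicate,
              log2_ratio = log2(value_het / value_home)) |>
    arrange(probeset_id, probe_index, replicate)
}

#' Moderated per-probeset test of differential signal
#'
#' For each probeset the gene-level log2 fold change is the mean of its
#' probe-level log2 ratios over probes and replicates, and the null
#' hypothesis "mean ratio = 0" is tested with a linear model treating probe
#' as a blocking factor: the residual variance `s^2` is the within-probe,
#' between-replicate variance on `d = n_obs - n_probes` degrees of freedom.
#' Across probesets the variances are shrunk empirical-Bayes style towards
#' a common prior, `s2_mod = (d0 s0^2 + d s^2) / (d0 + d)`, with `(d0,
#' s0^2)` estimated by method of moments from the marginal scaled-F
#' distribution of the `s^2`; the moderated t statistic is referred to a t
#' distribution on `d0 + d` degrees of freedom. Probesets with fewer than
#' `min_probes` probes get `NA` p-values and are excluded from calling.
#'
#' @param ratios Probe-level ratio tibble from [probe_log2_ratios()].
#' @param min_probes Minimum unmasked probes per probeset (default 3).
#' @return An object of class `cnd_fit`: a list with elements `probesets`
#'   (per-gene results tibble), `d0` and `s0_sq` (shrinkage
#'   hyperparameters). Use [tidy()] / [glance()] to extract.
#' @export
test_probesets <- function(ratios, min_probes = 3L) {
  per_gene <- ratios |>
    group_by(probeset_id) |>
    summarise(
      n_probes = n_distinct(probe_index),
      n_obs = n(),
      log2_fc = mean(log2_ratio),
      s2 = {
        dev <- log2_ratio - ave(log2_ratio, probe_index)
        d <- n() - n_distinct(probe_index)
        if (d > 0) sum(dev^2) / d else NA_real_
      },
      .groups = "drop"
    ) |>
    mutate(df_resid = n_obs - n_probes)
  usable <- !is.na(per_gene$s2) & per_gene$df_resid > 0
  if (!any(usable)) abort("no probeset has replicate degrees of freedom")
  hyper <- moment_shrinkage(per_gene$s2[usable], per_gene$df_resid[usable])
  d0 <- hyper$d0; s0 <- hyper$s0_sq
  per_gene <- per_gene |>
    mutate(
      s2_mod = ifelse(is.finite(d0),
                      (d0 * s0 + df_resid * s2) / (d0 + df_resid),
                      s0),
      df_total = ifelse(is.finite(d0), d0 + df_resid, Inf),
      se = sqrt(s2_mod / n_obs),
      t = ifelse(se > 0, log2_fc / se, ifelse(log2_fc == 0, 0, Inf * sign(log2_fc))),
      p_raw = ifelse(n_probes >= min_probes,
                     ifelse(is.finite(t), 2 * pt(-abs(t), df_total),
                            ifelse(t == 0, 1, 0)),
                     NA_real_)
    )
  structure(list(probesets = per_gene, d0 = d0, s0_sq = s0,
                 min_probes = as.integer(min_probes)),
            class = "cnd_fit")
}

# Method-of-moments fit of the scaled inverse-chi-square prior for the
# per-probeset variances: marginally s2 ~ s0^2 * F(d, d0), so
# Var/E^2 = 2 (d + d0 - 2) / (d (d0 - 4)). Degenerate estimates collapse
# to complete pooling (d0 = Inf).
moment_shrinkage <- function(s2, d) {
  m <- mean(s2)
  v <- var(s2)
  dbar <- mean(d)
  if (!is.finite(v) || v <= 0 || m <= 0) {
    return(list(d0 = Inf, s0_sq = max(m, .Machine$double.eps)))
  }
  r <- v / m^2
  denom <- r * dbar - 2
  if (denom <= 0) {
    return(list(d0 = Inf, s0_sq = m))
  }
  d0 <- (2 * dbar - 4 + 4 * r * dbar) / denom
  if (!is.finite(d0) || d0 <= 4) {
    # moments unstable below d0 = 4; fall back to a weakly informative prior
    d0 <- 4.001
  }
  s0_sq <- m * (d0 - 2) / d0
  list(d0 = d0, s0_sq = max(s0_sq, .Machine$double.eps))
}

#' @export
print.cnd_fit <- function(x, ...) {
  cat(sprintf("<cnd_fit> %d probesets; prior df d0 = %.2f, prior variance s0^2 = %.4g\n",
              nrow(x$probesets), x$d0, x$s0_sq))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cnd_fit <- function(x, ...) {
  x$probesets |>
    select(probeset_id, n_probes, n_obs, log2_fc, s2, s2_mod, t, p_raw)
}

#' @exportS3Method generics::glance
glance.cnd_fit <- function(x, ...) {
  tibble(n_probesets = nrow(x$probesets),
         n_callable = sum(!is.na(x$probesets$p_raw)),
         d0 = x$d0, s0_sq = x$s0_sq)
}

#' Classify genes as copy-number expanded, reduced or neutral
#'
#' Benjamini-Hochberg adjustment is applied across all callable probesets;
#' a gene is called CNE (copy-number expanded) when `log2_fc >= up` and
#' `p_adj <= alpha`, CNR (reduced) when `log2_fc <= down` and
#' `p_adj <= alpha`, otherwise neutral. Defaults follow the log2-ratio
#' threshold of 1 and corrected p-value cut-off of 0.1 used for
#' cross-species array-CGH calling.
#'
#' @param fit A `cnd_fit`, or a tibble with `probeset_id`, `log2_fc` and
#'   `p_raw`.
#' @param up,down Log2 fold-change thresholds (default +1 / -1).
#' @param alpha BH-adjusted p-value cut-off (default 0.1).
#' @param gene_map Optional tibble (`probeset_id`, `gene_id`) to attach
#'   gene identifiers.
#' @return Tibble of class `cnd_calls`: `probeset_id`, (`gene_id`),
#'   `log2_fc`, `p_raw`, `p_adj`, `cnd_class` (`"CNE"`, `"CNR"`,
#'   `"neutral"`, or `NA` for non-callable probesets).
#' @export
call_cnd <- function(fit, up = 1, down = -1, alpha = 0.1, gene_map = NULL) {
  x <- if (inherits(fit, "cnd_fit")) fit$probesets else as_tibble(fit)
  if (nrow(x) == 0) abort("no probesets to call")
  if (!all(c("probeset_id", "log2_fc", "p_raw") %in% names(x))) {
    abort("need columns probeset_id, log2_fc, p_raw")
  }
  callable <- !is.na(x$p_raw)
  x$p_adj <- NA_real_
  x$p_adj[callable] <- p.adjust(x$p_raw[callable], method = "BH")
  x$cnd_class <- ifelse(!callable, NA_character_,
                 ifelse(x$log2_fc >= up & x$p_adj <= alpha, "CNE",
                 ifelse(x$log2_fc <= down & x$p_adj <= alpha, "CNR",
                        "neutral")))
  out <- x |> select(probeset_id, log2_fc, p_raw, p_adj, cnd_class)
  if (!is.null(gene_map)) {
    out <- left_join(out, distinct(gene_map[, c("probeset_id", "gene_id")]),
                     by = "probeset_id") |>
      relocate(gene_id, .after = probeset_id)
  }
  class(out) <- c("cnd_calls", class(out))
  out
}

#' Calls shared between two heterologous species
#'
#' @param calls_a,calls_b `cnd_calls` tibbles over the same gene universe.
#' @return Tibble (`probeset_id`, `cnd_class`) of probesets with the same
#'   CNE or CNR call in both species.
#' @export
intersect_species <- function(calls_a, calls_b) {
  pick <- function(x) filter(x, cnd_class %in% c("CNE", "CNR")) |>
    select(probeset_id, cnd_class)
  inner_join(pick(calls_a), pick(calls_b),
             by = c("probeset_id", "cnd_class")) |>
    arrange(cnd_class, probeset_id)
}

#' Volcano plot of copy-number divergence calls
#'
#' @param object A `cnd_calls` tibble.
#' @param up,down,alpha Thresholds drawn as reference lines.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.cnd_calls <- function(object, up = 1, down = -1, alpha = 0.1, ...) {
  x <- filter(as_tibble(object), !is.na(p_adj))
  ggplot(x, aes(x = log2_fc, y = -log10(pmax(p_adj, 1e-300)),
                colour = cnd_class)) +
    geom_point(alpha = 0.6, size = 0.8) +
    geom_vline(xintercept = c(down, up), linetype = 2, colour = "grey40") +
    geom_hline(yintercept = -log10(alpha), linetype = 2, colour = "grey40") +
    scale_colour_manual(values = c(CNE = "firebrick", CNR = "steelblue",
                                   neutral = "grey60"), name = NULL) +
    labs(x = expression(log[2] ~ "ratio (heterologous / reference)"),
         y = expression(-log[10] ~ "BH-adjusted p"),
         title = "Copy-number divergence calls") +
    theme_bw()
}
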