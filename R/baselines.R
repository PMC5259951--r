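# Unified nearest-neighbour free-energy parameters (duplex DNA, 37 C,
# 1 M NaCl), delta-G in kcal/mol. Keyed by the top-strand dinucleotide;
# a dinucleotide and its reverse complement share one stack value.
NN_DG37 <- c(
  AA = -1.00, TT = -1.00,
  AT = -0.88, TA = -0.58,
  CA = -1.45, TG = -1.45,
  GT = -1.44, AC = -1.44,
  CT = -1.28, AG = -1.28,
  GA = -1.30, TC = -1.30,
  CG = -2.17, GC = -2.24,
  GG = -1.84, CC = -1.84
)
# duplex initiation penalty per terminal base pair
NN_INIT <- c(A = 1.03, T = 1.03, G = 0.98, C = 0.98)

#' Nearest-neighbour duplex free energy at 37 degrees C
#'
#' Sums the 16 published dinucleotide stacking parameters of the unified
#' nearest-neighbour model plus the two terminal initiation penalties
#' (G/C terminus +0.98, A/T terminus +1.03 kcal/mol). Salt correction and
#' the self-complementarity symmetry term are omitted, matching the use
#' of a stock oligo-property calculator. The stack table is symmetric
#' under reverse complementation, so a sequence and its reverse
#' complement have identical free energy.
#'
#' @param seq Character vector of DNA sequences (length >= 2, A/C/G/T
#'   only).
#' @return Numeric vector of free energies in kcal/mol (negative =
#'   more stable duplex).
#' @export
delta_g37 <- function(seq) {
  seq <- str_to_upper(seq)
  if (any(nchar(seq) < 2)) abort("sequences must have length >= 2")
  if (any(!grepl("^[ACGT]+$", seq))) {
    abort("sequences must contain only A/C/G/T (no ambiguity codes)")
  }
  vapply(seq, function(s) {
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    stacks <- paste0(b[-length(b)], b[-1])
    sum(NN_DG37[stacks]) + NN_INIT[[b[1]]] + NN_INIT[[b[length(b)]]]
  }, numeric(1), USE.NAMES = FALSE)
}

#' Average-difference summarisation with outlier trimming
#'
#' The classic average-difference probeset summary: probe values lying
#' within `n_sd` standard deviations of the probeset centre are averaged.
#' As in the original algorithm, the centre and spread are computed after
#' discarding the single highest and lowest value, so that an extreme
#' outlier cannot mask itself by inflating the standard deviation (with
#' few probes, an outlier is never more than `(n-1)/sqrt(n)` SDs from a
#' mean that includes it). The trim is applied once (no iteration).
#'
#' @param x Numeric vector of probe-level values.
#' @param n_sd Trim width in standard deviations (default 3).
#' @return The trimmed mean.
#' @export
avdiff <- function(x, n_sd = 3) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  if (length(x) <= 2) return(mean(x))
  st <- sort(x)[-c(1, length(x))]
  m <- mean(st)
  s <- sd(st)
  if (!is.finite(s)) return(mean(x))
  keep <- abs(x - m) <= n_sd * s | abs(x - m) < sqrt(.Machine$double.eps)
  mean(x[keep])
}

#' Baseline caller: loess normalisation on conserved genes
#'
#' Re-implementation of a cross-species array-CGH workflow built around
#' loess normalisation on a conserved-gene subset: probe-level
#' (mean-intensity, log-ratio) clouds are normalised by a loess curve
#' fitted on probes of up to `n_select` conserved single-copy genes (local
#' linear regression, tricube weights, span 0.5), probeset log-ratios are
#' summarised by the average-difference rule ([avdiff()]), p-values come
#' from the moderated probe-level test, and genes with log2 ratio above 0
#' (below 0) and BH-adjusted p <= `alpha` are called expanded (reduced).
#'
#' @param home,het Background-corrected intensity tibbles (raw linear
#'   scale).
#' @param conserved Character vector of conserved single-copy probeset
#'   ids.
#' @param n_select Number of conserved probesets used for the fit
#'   (default 1000); if fewer are supplied, all are used with a warning.
#' @param span Loess span (default 0.5).
#' @param alpha BH-adjusted p cut-off (default 0.1).
#' @param value_col Intensity column (default `"intensity"`).
#' @return A `cnd_calls` tibble.
#' @export
baseline_conserved_loess <- function(home, het, conserved, n_select = 1000L,
                                     span = 0.5, alpha = 0.1,
                                     value_col = "intensity") {
  if (length(conserved) < n_select) {
    warn(sprintf("only %d conserved probesets supplied (< %d); using all",
                 length(conserved), n_select))
    sel <- conserved
  } else {
    sel <- sample(conserved, n_select)
  }
  pick <- function(x) x |>
    filter(!masked) |>
    select(probeset_id, probe_index, replicate, value = all_of(value_col))
  x <- inner_join(pick(home), pick(het),
                  by = c("probeset_id", "probe_index", "replicate"),
                  suffix = c("_home", "_het")) |>
    mutate(A = 0.5 * (log2(value_home) + log2(value_het)),
           M = log2(value_het) - log2(value_home))
  corrected <- x |>
    group_by(replicate) |>
    group_map(function(w, key) {
      fit_data <- filter(w, probeset_id %in% sel)
      fit <- loess(M ~ A, data = fit_data, span = span, degree = 1,
                   family = "gaussian",
                   control = stats::loess.control(surface = "direct"))
      a_clamped <- pmin(pmax(w$A, min(fit_data$A)), max(fit_data$A))
      mutate(w, replicate = key$replicate,
             log2_ratio = M - predict(fit, newdata = tibble(A = a_clamped)))
    }) |>
    bind_rows()
  ratios <- corrected |>
    select(probeset_id, probe_index, replicate, log2_ratio)
  fit <- test_probesets(ratios)
  fc <- ratios |>
    group_by(probeset_id, replicate) |>
    summarise(m = avdiff(log2_ratio), .groups = "drop") |>
    group_by(probeset_id) |>
    summarise(log2_fc = mean(m), .groups = "drop")
  tab <- fit$probesets |>
    select(probeset_id, p_raw) |>
    inner_join(fc, by = "probeset_id")
  call_cnd(tab, up = .Machine$double.eps, down = -.Machine$double.eps,
           alpha = alpha)
}

#' Baseline caller: probe-affinity adjustment and control-probe scaling
#'
#' Re-implementation of a tiling-array workflow that normalises probe
#' signal by thermodynamic binding affinity and scales species by control
#' probes: per sample, log2 intensity is regressed on the probe's
#' nearest-neighbour free energy ([delta_g37()]) over the control probes,
#' the fitted affinity component is removed from all probes, signals are
#' scaled by the control-probe median, probe log2 ratios are summarised to
#' probeset means, and genes are classified by a log2-ratio threshold of
#' +/- 0.25 (no significance test; the thresholds carry the call).
#'
#' @param home,het Background-corrected intensity tibbles.
#' @param probes Probe annotation (for the 25-mer sequences).
#' @param control_probes Character vector of control probeset ids.
#' @param threshold Absolute log2-ratio threshold (default 0.25).
#' @param value_col Intensity column (default `"intensity"`).
#' @return A `cnd_calls` tibble (`p_raw`/`p_adj` are `NA`).
#' @export
baseline_affinity_scaled <- function(home, het, probes, control_probes,
                                     threshold = 0.25,
                                     value_col = "intensity") {
  if (length(control_probes) == 0) abort("empty control-probe set")
  dg <- probes |>
    mutate(dg37 = delta_g37(sequence)) |>
    select(probeset_id, probe_index, dg37)
  adjust <- function(x) {
    x |>
      filter(!masked) |>
      inner_join(dg, by = c("probeset_id", "probe_index")) |>
      group_by(sample_id) |>
      group_map(function(w, key) {
        ctrl <- filter(w, probeset_id %in% control_probes)
        if (nrow(ctrl) == 0) abort("no control probes present in a sample")
        fit <- lm(log2(value) ~ dg37, data = mutate(ctrl, value = .data[[value_col]]))
        adj <- log2(w[[value_col]]) -
          (coef(fit)[1] + coef(fit)[2] * w$dg37)
        adj <- adj - median(adj[w$probeset_id %in% control_probes])
        mutate(w, sample_id = key$sample_id, adj = adj)
      }) |>
      bind_rows()
  }
  h <- adjust(home)
  i <- adjust(het)
  x <- inner_join(
    select(h, probeset_id, probe_index, replicate, adj),
    select(i, probeset_id, probe_index, replicate, adj),
    by = c("probeset_id", "probe_index", "replicate"),
    suffix = c("_home", "_het"))
  out <- x |>
    group_by(probeset_id) |>
    summarise(log2_fc = mean(adj_het - adj_home), .groups = "drop") |>
    mutate(p_raw = NA_real_, p_adj = NA_real_,
           cnd_class = ifelse(log2_fc >= threshold, "CNE",
                       ifelse(log2_fc <= -threshold, "CNR", "neutral"))) |>
    select(probeset_id, log2_fc, p_raw, p_adj, cnd_class)
  class(out) <- c("cnd_calls", class(out))
  out
}
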