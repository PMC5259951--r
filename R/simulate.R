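#' Default mismatch attenuation profile
#'
#' Multiplicative signal attenuation per mismatch count: no attenuation
#' for a fully conserved probe, a large first-mismatch drop (default to
#' 0.63 of the conserved signal, i.e. a 37% loss, the midpoint of the 34
#' and 40% single-mismatch losses measured in the two heterologous
#' species), then small geometric decrements per additional mismatch
#' (default 0.928 per step, so four mismatches sit a further ~20% below
#' one mismatch).
#'
#' @param n Probe length (profile covers k = 0..n).
#' @param first First-mismatch multiplier (default 0.63).
#' @param step Per-additional-mismatch multiplier (default 0.928).
#' @return Numeric vector of length `n + 1`, element `k + 1` giving the
#'   multiplier for `k` mismatches; non-increasing in `k`.
#' @export
attenuation_profile <- function(n = 25L, first = 0.63, step = 0.928) {
  if (first <= 0 || first > 1 || step <= 0 || step > 1) {
    abort("attenuation multipliers must lie in (0, 1]")
  }
  c(1, first * step^(0:(n - 1)))
}

#' Simulation configuration for synthetic cross-species array-CGH data
#'
#' Defines the study conditions emulated by the generator: 25-mer probes
#' drawn uniformly; heterologous targets derived by per-base substitution
#' with probability `p_divergence` (0.06, matching 94% average nucleotide
#' identity); per-mismatch multiplicative signal attenuation
#' ([attenuation_profile()]); log-normal baseline intensities with
#' per-probe affinity effects; independent replicate noise on the log2
#' scale; and planted copy-number states (a fraction of genes duplicated
#' to `cne_copy` = 2x and a fraction halved to `cnr_copy` = 0.5x). A
#' category map with one planted enriched category and a deterministic
#' genome layout (genes laid end to end across chromosomes, optionally
#' with clustered divergent blocks) complete the truth bundle.
#'
#' @param n_genes Number of genes/probesets (default 2000).
#' @param probes_per_gene Probes per probeset (default 11).
#' @param replicates Replicate hybridisations per species (default 2).
#' @param p_divergence Per-base substitution probability (default 0.06).
#' @param attenuation Numeric vector over k = 0..25 of signal multipliers
#'   (default [attenuation_profile()]); must be non-increasing.
#' @param cne_fraction,cnr_fraction Fractions of genes planted as
#'   copy-number expanded / reduced (defaults 0.05 each).
#' @param cne_copy,cnr_copy Copy ratios of planted genes (defaults 2 and
#'   0.5).
#' @param noise_sd Replicate noise SD on the log2 scale (default 0.25).
#' @param gene_mean_log2,gene_sd_log2 Log2-normal distribution of
#'   gene-level baseline intensity (defaults 9 and 1).
#' @param probe_sd SD of per-probe affinity effects on the log2 scale
#'   (default 0.5).
#' @param n_categories Number of functional categories (default 20).
#' @param category_prob Per-gene membership probability of each
#'   background category (default 0.08).
#' @param planted_category_prob Baseline membership probability of the
#'   planted category (default 0.25, emulating one of the largest
#'   top-level functional classes; a 2-fold enrichment is only reliably
#'   detectable in a list of ~100 genes when the category is large, so
#'   the planted signal lives in a large category — see the methods
#'   vignette for the power analysis).
#' @param enriched_factor Membership-probability multiplier of the
#'   planted category among planted CNE genes (default 2).
#' @param n_chrom Number of chromosomes (default 2).
#' @param gene_length,gene_gap Gene body length and intergenic gap in
#'   bases (defaults 2000 and 3000, i.e. one gene per 5 kb).
#' @param cluster_cnds Place planted divergent genes in contiguous blocks
#'   (default `FALSE`), exercising the segment scanner.
#' @param block_size Genes per clustered block (default 8).
#' @param home_species,het_species Species labels.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L, probes_per_gene = 11L,
                       replicates = 2L, p_divergence = 0.06,
                       attenuation = attenuation_profile(),
                       cne_fraction = 0.05, cnr_fraction = 0.05,
                       cne_copy = 2, cnr_copy = 0.5,
                       noise_sd = 0.25,
                       gene_mean_log2 = 9, gene_sd_log2 = 1,
                       probe_sd = 0.5,
                       n_categories = 20L, category_prob = 0.08,
                       planted_category_prob = 0.25,
                       enriched_factor = 2,
                       n_chrom = 2L, gene_length = 2000L,
                       gene_gap = 3000L,
                       cluster_cnds = FALSE, block_size = 8L,
                       home_species = "home", het_species = "het") {
  stopifnot(p_divergence >= 0, p_divergence <= 1,
            cne_fraction >= 0, cnr_fraction >= 0,
            cne_fraction + cnr_fraction <= 1,
            noise_sd >= 0, replicates >= 1)
  if (any(attenuation <= 0 | attenuation > 1)) {
    abort("attenuation multipliers must lie in (0, 1]")
  }
  if (any(diff(attenuation) > 1e-12)) {
    abort("attenuation must be non-increasing in k")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a synthetic cross-species array-CGH dataset
#'
#' Generates every input of the analysis pipeline together with the
#' ground truth: probe annotation with gene coordinates, heterologous
#' target sequences (and thus exact per-probe mismatch counts), raw
#' intensity tables for the homologous and heterologous species, the
#' truth set of planted copy states, and a functional category map with
#' one planted enriched category. The heterologous intensity of a probe
#' with `k` mismatches is `home_true * copy_ratio * attenuation[k]` times
#' log-normal replicate noise. Fully reproducible: the same seed yields
#' identical output.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed (mandatory).
#' @return A list of class `sim_dataset` with elements `probes`,
#'   `targets`, `intensities` (both species, long layout, raw scale),
#'   `mismatch` (per-probe true mismatch counts), `truth`, `categories`,
#'   `coords`, `chrom_lengths`, `config`, `seed`.
#' @export
simulate_dataset <- function(cfg = sim_config(), seed) {
  stopifnot(inherits(cfg, "sim_config"))
  if (missing(seed) || is.null(seed)) abort("a seed is mandatory")
  withr::local_seed(as.integer(seed))
  ng <- cfg$n_genes; np <- cfg$probes_per_gene; nr <- cfg$replicates
  gene_id <- sprintf("g%05d", seq_len(ng))
  probeset_id <- paste0(gene_id, "_at")

  # planted copy states; optionally clustered into contiguous blocks
  n_cne <- round(cfg$cne_fraction * ng)
  n_cnr <- round(cfg$cnr_fraction * ng)
  status <- rep("single_copy", ng)
  if (cfg$cluster_cnds) {
    place_blocks <- function(status, n_plant, label, block) {
      planted <- 0
      while (planted < n_plant) {
        len <- min(block, n_plant - planted)
        free <- which(status == "single_copy")
        starts <- free[free <= ng - len + 1]
        starts <- starts[vapply(starts, function(s)
          all(status[s:(s + len - 1)] == "single_copy"), logical(1))]
        if (length(starts) == 0) abort("cannot place clustered blocks; genome too full")
        s <- sample(starts, 1)
        status[s:(s + len - 1)] <- label
        planted <- planted + len
      }
      status
    }
    status <- place_blocks(status, n_cne, "expanded", cfg$block_size)
    status <- place_blocks(status, n_cnr, "reduced", cfg$block_size)
  } else {
    idx <- sample.int(ng, n_cne + n_cnr)
    status[idx[seq_len(n_cne)]] <- "expanded"
    status[idx[n_cne + seq_len(n_cnr)]] <- "reduced"
  }
  copy_ratio <- ifelse(status == "expanded", cfg$cne_copy,
                ifelse(status == "reduced", cfg$cnr_copy, 1))
  truth <- tibble(gene_id = gene_id, status = status)

  # genome layout: genes laid end to end, split evenly across chromosomes
  per_chrom <- ceiling(ng / cfg$n_chrom)
  chrom_of <- paste0("chr", ((seq_len(ng) - 1) %/% per_chrom) + 1)
  pos_in_chrom <- ((seq_len(ng) - 1) %% per_chrom)
  gstart <- pos_in_chrom * (cfg$gene_length + cfg$gene_gap)
  coords <- tibble(gene_id = gene_id, chrom = chrom_of,
                   start = as.integer(gstart),
                   end = as.integer(gstart + cfg$gene_length),
                   strand = "+")
  chrom_lengths <- coords |>
    group_by(chrom) |>
    summarise(length = max(end) + cfg$gene_gap, .groups = "drop")

  # probe and target sequences; per-base substitution gives exact k
  bases <- c("A", "C", "G", "T")
  n_probes <- ng * np
  probe_seq_mat <- matrix(sample(bases, n_probes * 25, replace = TRUE),
                          nrow = n_probes)
  sub_mask <- matrix(runif(n_probes * 25) < cfg$p_divergence, nrow = n_probes)
  target_mat <- probe_seq_mat
  if (any(sub_mask)) {
    idx <- which(sub_mask)
    cur <- target_mat[idx]
    # substitute with one of the three other bases, uniformly
    repl <- vapply(cur, function(b) sample(setdiff(bases, b), 1), character(1))
    target_mat[idx] <- repl
  }
  k <- as.integer(rowSums(sub_mask))
  probes <- tibble(
    probeset_id = rep(probeset_id, each = np),
    probe_index = rep(seq_len(np), times = ng),
    sequence = apply(probe_seq_mat, 1, paste, collapse = ""),
    gene_id = rep(gene_id, each = np)
  ) |>
    left_join(coords, by = "gene_id")
  targets <- tibble(probeset_id = probes$probeset_id,
                    probe_index = probes$probe_index,
                    target = apply(target_mat, 1, paste, collapse = ""))
  mismatch <- tibble(probeset_id = probes$probeset_id,
                     probe_index = probes$probe_index,
                     k = k, species = cfg$het_species)

  # intensities: gene baseline + probe affinity, then copy ratio and
  # mismatch attenuation for the heterologous species, replicate noise
  base_log2 <- rnorm(ng, cfg$gene_mean_log2, cfg$gene_sd_log2)
  probe_log2 <- rep(base_log2, each = np) + rnorm(n_probes, 0, cfg$probe_sd)
  het_log2 <- probe_log2 + log2(rep(copy_ratio, each = np)) +
    log2(cfg$attenuation[k + 1])
  one_species <- function(true_log2, species) {
    map(seq_len(nr), function(r) {
      tibble(probeset_id = probes$probeset_id,
             probe_index = probes$probe_index,
             sample_id = sprintf("%s_r%d", species, r),
             species = species, replicate = r,
             intensity = 2^(true_log2 + rnorm(n_probes, 0, cfg$noise_sd)))
    }) |> bind_rows()
  }
  intensities <- bind_rows(one_species(probe_log2, cfg$home_species),
                           one_species(het_log2, cfg$het_species))
  intensities$masked <- FALSE

  # category map with one planted enriched category among CNE genes
  cat_ids <- sprintf("B%02d", seq_len(cfg$n_categories))
  planted_cat <- cat_ids[1]
  member <- map(seq_len(cfg$n_categories), function(ci) {
    base_pr <- if (cat_ids[ci] == planted_cat) cfg$planted_category_prob else cfg$category_prob
    pr <- rep(base_pr, ng)
    if (cat_ids[ci] == planted_cat) {
      pr[status == "expanded"] <- pmin(1, base_pr * cfg$enriched_factor)
    }
    hit <- runif(ng) < pr
    tibble(probeset_id = probeset_id[hit], category = cat_ids[ci])
  }) |> bind_rows()

  structure(list(probes = probes, targets = targets,
                 intensities = intensities, mismatch = mismatch,
                 truth = truth, categories = member, coords = coords,
                 chrom_lengths = chrom_lengths,
                 planted_category = planted_cat,
                 config = cfg, seed = as.integer(seed)),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d genes x %d probes x %d replicates (seed %d)\n",
              x$config$n_genes, x$config$probes_per_gene,
              x$config$replicates, x$seed))
  cat(sprintf("planted: %d expanded, %d reduced\n",
              sum(x$truth$status == "expanded"),
              sum(x$truth$status == "reduced")))
  invisible(x)
}

#' Draw a reference subset for scaling estimation
#'
#' Mirrors the construction of a curated reference dataset: a random
#' subset of single-copy genes — planted expanded or reduced genes are
#' excluded, as known copy-number divergent genes were removed from the
#' curated reference set — whose sequences and mismatch counts drive the
#' estimation of the incremental correction factors.
#'
#' @param dataset A `sim_dataset`.
#' @param n_genes Subset size (default 40).
#' @param seed Optional seed for the draw.
#' @return List with `probes`, `targets` and `mismatch` restricted to the
#'   subset, plus `gene_ids`.
#' @export
make_reference_subset <- function(dataset, n_genes = 40L, seed = NULL) {
  single <- dataset$truth$gene_id[dataset$truth$status == "single_copy"]
  if (length(single) < n_genes) {
    abort(sprintf("only %d single-copy genes available (< %d)",
                  length(single), n_genes))
  }
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  sel <- sample(single, n_genes)
  sel_ps <- dataset$probes$probeset_id[dataset$probes$gene_id %in% sel]
  list(
    gene_ids = sort(sel),
    probes = filter(dataset$probes, gene_id %in% sel),
    targets = filter(dataset$targets, probeset_id %in% sel_ps),
    mismatch = filter(dataset$mismatch, probeset_id %in% sel_ps)
  )
}

#' Simulate reference probes with balanced mismatch strata
#'
#' Builds a reference-style dataset with a fixed number of probes per
#' mismatch count — the design used to characterise scaling-factor
#' recovery, where every stratum k = 0..kmax is equally populated rather
#' than binomially thinned.
#'
#' @param n_per_k Probes per mismatch stratum (default 200).
#' @param kmax Largest stratum (default 4).
#' @param attenuation Attenuation profile (default
#'   [attenuation_profile()]).
#' @param noise_sd Replicate noise SD on the log2 scale (default 0.25).
#' @param replicates Replicates per species (default 2).
#' @param mean_log2,sd_log2 Baseline intensity distribution.
#' @param seed Integer seed (mandatory).
#' @return List with `mismatch` (probe-to-k table) and `home`, `het`
#'   intensity tibbles (raw scale, one probeset per probe).
#' @export
simulate_reference_probes <- function(n_per_k = 200L, kmax = 4L,
                                      attenuation = attenuation_profile(),
                                      noise_sd = 0.25, replicates = 2L,
                                      mean_log2 = 9, sd_log2 = 1, seed) {
  if (missing(seed) || is.null(seed)) abort("a seed is mandatory")
  withr::local_seed(as.integer(seed))
  n <- n_per_k * (kmax + 1)
  k <- rep(0:kmax, each = n_per_k)
  probeset_id <- sprintf("ref%05d_at", seq_len(n))
  base <- rnorm(n, mean_log2, sd_log2)
  het_true <- base + log2(attenuation[k + 1])
  mk <- function(true_log2, species) {
    map(seq_len(replicates), function(r) {
      tibble(probeset_id = probeset_id, probe_index = 1L,
             sample_id = sprintf("%s_r%d", species, r),
             species = species, replicate = r,
             intensity = 2^(true_log2 + rnorm(n, 0, noise_sd)),
             masked = FALSE)
    }) |> bind_rows()
  }
  list(
    mismatch = tibble(probeset_id = probeset_id, probe_index = 1L,
                      k = k, species = "het"),
    home = mk(base, "home"),
    het = mk(het_true, "het")
  )
}
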