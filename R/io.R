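#' Read a probe annotation table
#'
#' Reads the tab-separated probe annotation that links every 25-mer probe on
#' the array to its probeset (gene). Required columns are `probeset_id`,
#' `probe_index` and `sequence`; optional columns `gene_id`, `chrom`,
#' `start`, `end`, `strand` carry the gene link and genomic coordinates
#' (0-based, half-open).
#'
#' @param path Path to a TSV file.
#' @return A tibble with one row per probe, validated: all sequences are
#'   25-mers over A/C/G/T and `(probeset_id, probe_index)` is unique.
#' @export
read_probe_annotation <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_probes(x, source = path)
}

validate_probes <- function(x, source = "probe annotation") {
  need <- c("probeset_id", "probe_index", "sequence")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s: missing required column(s): %s",
                  source, paste(missing_cols, collapse = ", ")))
  }
  x <- as_tibble(x)
  x$probeset_id <- as.character(x$probeset_id)
  x$probe_index <- as.integer(x$probe_index)
  x$sequence <- str_to_upper(as.character(x$sequence))
  bad <- which(nchar(x$sequence) != 25L | !grepl("^[ACGT]+$", x$sequence))
  if (length(bad) > 0) {
    abort(sprintf(
      "%s: invalid probe sequence (must be a 25-mer over A/C/G/T) at row(s): %s",
      source, paste(head(bad, 5), collapse = ", ")))
  }
  dup <- duplicated(x[, c("probeset_id", "probe_index")])
  if (any(dup)) {
    abort(sprintf("%s: duplicated (probeset_id, probe_index) at row(s): %s",
                  source, paste(head(which(dup), 5), collapse = ", ")))
  }
  if (all(c("start", "end") %in% names(x))) {
    has <- !is.na(x$start) & !is.na(x$end)
    if (any(has & x$end <= x$start)) {
      abort(sprintf("%s: gene coordinates must satisfy end > start", source))
    }
  }
  if (!"gene_id" %in% names(x)) x$gene_id <- x$probeset_id
  x
}

#' Write a probe annotation table
#'
#' @param probes Tibble as returned by [read_probe_annotation()].
#' @param path Output TSV path.
#' @return `probes`, invisibly.
#' @export
write_probe_annotation <- function(probes, path) {
  readr::write_tsv(probes, path, progress = FALSE)
  invisible(probes)
}

#' Read a probe-intensity table
#'
#' Accepts either a long table with columns `probeset_id`, `probe_index`,
#' `sample_id`, `species`, `replicate`, `intensity`, or a wide table with one
#' column per sample (then `samples` must supply the sample metadata).
#'
#' @param path Path to a TSV/CSV file (delimiter inferred from extension).
#' @param samples Optional tibble `(sample_id, species, replicate)`; required
#'   for the wide layout. Sample order is taken from this table and is never
#'   silently reordered.
#' @param probes Optional probe annotation; probes in the intensity file that
#'   are absent from the annotation are reported with a warning (not
#'   dropped).
#' @return A long intensity tibble with a logical `masked` column
#'   (initially all `FALSE`).
#' @export
read_intensities <- function(path, samples = NULL, probes = NULL) {
  reader <- if (grepl("\\.csv$", path)) readr::read_csv else readr::read_tsv
  x <- reader(path, show_col_types = FALSE, progress = FALSE)
  long_cols <- c("probeset_id", "probe_index", "sample_id", "intensity")
  if (all(long_cols %in% names(x))) {
    if (!all(c("species", "replicate") %in% names(x))) {
      if (is.null(samples)) {
        abort("long intensity table lacks species/replicate; supply `samples`")
      }
      x <- left_join(x, samples, by = "sample_id")
    }
  } else {
    if (is.null(samples)) {
      abort("wide intensity table requires a `samples` metadata tibble")
    }
    id_cols <- intersect(c("probeset_id", "probe_index"), names(x))
    miss <- setdiff(samples$sample_id, names(x))
    if (length(miss) > 0) {
      abort(sprintf("sample column(s) missing from intensity file: %s",
                    paste(miss, collapse = ", ")))
    }
    x <- pivot_longer(x[, c(id_cols, samples$sample_id)],
                      cols = all_of(samples$sample_id),
                      names_to = "sample_id", values_to = "intensity")
    x <- left_join(x, samples, by = "sample_id")
    # restore metadata sample order
    x$sample_id <- factor(x$sample_id, levels = samples$sample_id)
    x <- arrange(x, sample_id, probeset_id, probe_index)
    x$sample_id <- as.character(x$sample_id)
  }
  as_intensities(x, source = path)
}

as_intensities <- function(x, source = "intensity table") {
  x <- as_tibble(x)
  if (any(is.na(x$species) | !nzchar(as.character(x$species)))) {
    abort(sprintf("%s: sample(s) with missing species label", source))
  }
  if (any(is.na(x$intensity))) {
    abort(sprintf("%s: missing intensity values", source))
  }
  if (any(x$intensity < 0)) {
    abort(sprintf("%s: negative intensity values are not allowed", source))
  }
  sp_per_sample <- tapply(x$species, x$sample_id,
                          function(s) length(unique(s)))
  if (any(sp_per_sample > 1)) {
    abort(sprintf("%s: a sample maps to more than one species", source))
  }
  x$probeset_id <- as.character(x$probeset_id)
  x$probe_index <- as.integer(x$probe_index)
  x$replicate <- as.integer(x$replicate)
  if (!"masked" %in% names(x)) x$masked <- FALSE
  x
}

check_against_annotation <- function(x, probes) {
  known <- paste(probes$probeset_id, probes$probe_index)
  seen <- unique(paste(x$probeset_id, x$probe_index))
  unknown <- setdiff(seen, known)
  if (length(unknown) > 0) {
    warn(sprintf("%d probe(s) in the intensity table are absent from the annotation (kept): %s%s",
                 length(unknown), paste(head(unknown, 3), collapse = ", "),
                 if (length(unknown) > 3) ", ..." else ""))
  }
  invisible(unknown)
}

#' Write a long intensity table
#'
#' @param x Long intensity tibble.
#' @param path Output TSV path.
#' @return `x`, invisibly.
#' @export
write_intensities <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(x)
}

#' Read a copy-number truth set
#'
#' A two-column TSV `(gene_id, status)` with statuses `expanded`,
#' `single_copy` or `reduced` — the format of a curated set of genes with
#' known copy number used for validation.
#'
#' @param path Path to a TSV file.
#' @return Tibble `(gene_id, status)`.
#' @export
read_truth_set <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("gene_id", "status") %in% names(x))) {
    abort("truth set needs columns gene_id, status")
  }
  ok <- c("expanded", "single_copy", "reduced")
  if (!all(x$status %in% ok)) {
    abort(sprintf("truth statuses must be one of: %s", paste(ok, collapse = ", ")))
  }
  if (anyDuplicated(x$gene_id)) {
    abort("truth set assigns more than one status to a gene")
  }
  as_tibble(x)
}

#' Read a gene-to-category map
#'
#' Two-column TSV `(probeset_id, category)`, MapMan-BIN style: a gene may
#' appear on several rows (multi-assignment), and `category` may be a
#' hierarchical path such as `"13.2:protein degradation"` whose top level is
#' the part of the code before the first dot.
#'
#' @param path Path to a TSV file.
#' @return Tibble `(probeset_id, category)`.
#' @export
read_category_map <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("probeset_id", "category") %in% names(x))) {
    abort("category map needs columns probeset_id, category")
  }
  distinct(as_tibble(x[, c("probeset_id", "category")]))
}

#' Read gene coordinates from BED or GFF
#'
#' BED input is taken as 0-based half-open; GFF (1-based, closed) is
#' converted to the internal 0-based half-open convention on read.
#'
#' @param path Path to a `.bed`, `.gff`/`.gff3` file.
#' @param format `"auto"` (by extension), `"bed"` or `"gff"`.
#' @return Tibble `(gene_id, chrom, start, end, strand)`.
#' @export
read_gene_coords <- function(path, format = c("auto", "bed", "gff")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path)) "gff" else "bed"
  }
  if (format == "bed") {
    x <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         show_col_types = FALSE, progress = FALSE)
    nm <- c("chrom", "start", "end", "gene_id", "score", "strand")
    names(x)[seq_len(min(ncol(x), 6))] <- nm[seq_len(min(ncol(x), 6))]
    if (!"gene_id" %in% names(x)) x$gene_id <- paste0("feature_", seq_len(nrow(x)))
    if (!"strand" %in% names(x)) x$strand <- "+"
    tibble(gene_id = as.character(x$gene_id), chrom = as.character(x$chrom),
           start = as.integer(x$start), end = as.integer(x$end),
           strand = as.character(x$strand))
  } else {
    x <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         show_col_types = FALSE, progress = FALSE)
    if (ncol(x) < 9) abort("GFF file must have 9 columns")
    attr_id <- sub(".*(?:ID|Name)=([^;]+).*", "\\1", x[[9]])
    tibble(gene_id = attr_id, chrom = as.character(x[[1]]),
           start = as.integer(x[[4]]) - 1L, end = as.integer(x[[5]]),
           strand = as.character(x[[7]]))
  }
}

#' Default analysis configuration
#'
#' Thresholds and model parameters used across the pipeline: calling
#' thresholds (`up = +1`, `down = -1` on the log2 scale, `alpha = 0.1` BH
#' FDR), mismatch model (`n = 25`, `p = 0.06`, `kmax = 4`), background
#' quantile (`q = 0.02`) and the ORA FDR cut-off (`ora_alpha = 0.05`).
#'
#' @return A named list.
#' @export
default_config <- function() {
  list(
    thresholds = list(up = 1, down = -1, alpha = 0.1),
    model = list(n = 25L, p = 0.06, kmax = 4L),
    background = list(method = "quantile_floor", q = 0.02, floor = 1.0,
                      rel_floor = 0.05),
    scaling = list(min_probes = 2L, renormalize = FALSE),
    ora = list(alpha = 0.05, alternative = "greater"),
    segments = list(window = 20000L, step = 10000L, min_cov = 5000L,
                    min_consecutive = 3L)
  )
}

#' Read a YAML configuration file
#'
#' Values present in the file override the defaults from
#' [default_config()]; everything else keeps its default.
#'
#' @param path Path to a YAML file (or `NULL` for pure defaults).
#' @return A named list with the structure of [default_config()].
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_lists <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        base[[nm]] <- merge_lists(base[[nm]], over[[nm]])
      } else {
        base[[nm]] <- over[[nm]]
      }
    }
    base
  }
  merge_lists(cfg, user)
}
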