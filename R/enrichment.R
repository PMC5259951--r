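#' Over-representation analysis of functional categories
#'
#' Tests each functional category (MapMan-BIN style) for over-representation
#' in a gene list relative to the array background with a one-sided
#' Fisher's exact test on the 2x2 table (in-list & in-category, in-list &
#' out, out-of-list & in-category, out & out), followed by
#' Benjamini-Hochberg adjustment across categories. Genes assigned to
#' several categories count once per category. By default hierarchical
#' category codes are collapsed to their top level (the code before the
#' first dot), mirroring top-BIN-only testing; set `top_level = FALSE` to
#' test categories exactly as given.
#'
#' @param gene_list Character vector of probeset ids (must be a subset of
#'   `background`).
#' @param categories Category map tibble (`probeset_id`, `category`).
#' @param background Character vector of probeset ids: all unmasked nuclear
#'   probesets on the array.
#' @param alpha BH-adjusted significance cut-off (default 0.05).
#' @param alternative `"greater"` (enrichment; default) or `"two.sided"`.
#' @param top_level Collapse category codes to their top level.
#' @return Tibble, one row per category: `category`, `in_list`,
#'   `in_background`, `pct_list`, `pct_background`, `fold`, `p_raw`,
#'   `p_adj`, `significant`; sorted by `p_raw`.
#' @export
ora <- function(gene_list, categories, background, alpha = 0.05,
                alternative = c("greater", "two.sided"),
                top_level = TRUE) {
  alternative <- match.arg(alternative)
  gene_list <- unique(as.character(gene_list))
  background <- unique(as.character(background))
  if (length(gene_list) == 0) abort("empty gene list")
  if (length(background) == 0) abort("empty background")
  stray <- setdiff(gene_list, background)
  if (length(stray) > 0) {
    abort(sprintf("%d gene(s) in the list are not in the background (e.g. %s)",
                  length(stray), stray[1]))
  }
  cats <- categories |>
    filter(probeset_id %in% background) |>
    mutate(category = if (top_level) top_bin(category) else category) |>
    distinct(probeset_id, category)
  n_list <- length(gene_list)
  n_bg <- length(background)
  out <- cats |>
    group_by(category) |>
    summarise(
      in_list = sum(probeset_id %in% gene_list),
      in_background = n(),
      .groups = "drop"
    ) |>
    mutate(
      pct_list = 100 * in_list / n_list,
      pct_background = 100 * in_background / n_bg,
      fold = pct_list / pct_background,
      p_raw = map_dbl(seq_len(n()), function(i) {
        a <- in_list[i]
        b <- n_list - a
        cc <- in_background[i] - a
        d <- n_bg - n_list - cc
        fisher.test(matrix(c(a, b, cc, d), nrow = 2, byrow = TRUE),
                    alternative = alternative)$p.value
      })
    ) |>
    mutate(p_adj = p.adjust(p_raw, method = "BH"),
           significant = p_adj <= alpha) |>
    arrange(p_raw)
  class(out) <- c("ora_result", class(out))
  out
}

#' Top-level BIN code of a hierarchical category label
#'
#' `"13.2:protein degradation"` has code `"13.2"` and top level `"13"`.
#'
#' @param x Character vector of category labels, optionally of the form
#'   `"code:name"` with a dot-separated hierarchical code.
#' @return Character vector of top-level codes.
#' @export
top_bin <- function(x) {
  code <- sub(":.*$", "", x)
  sub("\\..*$", "", code)
}

#' Bar plot of category enrichment
#'
#' @param object An `ora_result` tibble.
#' @param max_categories Show at most this many categories (by p-value).
#' @param ... Unused.
#' @return A ggplot of fold enrichment, significant categories filled.
#' @exportS3Method ggplot2::autoplot
autoplot.ora_result <- function(object, max_categories = 20, ...) {
  x <- head(as_tibble(object), max_categories)
  x$category <- factor(x$category, levels = rev(x$category))
  ggplot(x, aes(x = fold, y = category, fill = significant)) +
    geom_col() +
    geom_vline(xintercept = 1, linetype = 2) +
    scale_colour_manual(values = NULL) +
    labs(x = "fold enrichment (% list / % background)", y = NULL,
         title = "Category over-representation") +
    theme_bw()
}
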