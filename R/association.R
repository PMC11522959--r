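#' Fisher exact test for one 2x2 table
#'
#' Cells follow the gene-association layout: `a` present and in-class, `b`
#' absent and in-class, `c` present and out-of-class, `d` absent and
#' out-of-class. The odds ratio is the unconditional cross-product
#' `(a*d)/(b*c)` — the quantity usually quoted alongside raw presence
#' percentages — reported as `Inf` or `0` when a single off-diagonal cell is
#' zero and `NaN` when the table is degenerate. The two-sided p-value sums
#' the hypergeometric probabilities of all tables (at fixed margins) no more
#' probable than the observed one.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return List with `odds_ratio`, `p_value`, and `degenerate` (flag for a
#'   zero cross-product cell).
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers")
  }
  if (sum(cells) == 0) stop("at least one margin must be positive")
  num <- a * d
  den <- b * c
  or <- if (den > 0) num / den else if (num > 0) Inf else NaN
  p <- stats::fisher.test(matrix(c(a, b, c, d), nrow = 2))$p.value
  list(odds_ratio = or, p_value = min(p, 1), degenerate = (den == 0 || num == 0))
}

#' Per-KO association table against a binary classification
#'
#' For each KO, cross-tabulates presence/absence against the class labels
#' and reports presence percentages, the cross-product odds ratio and the
#' raw (uncorrected) two-sided Fisher p-value, the report used to re-analyze
#' consensus-selected KOs.
#'
#' @param mat A [ko_matrix()] (all strains).
#' @param labels Binary labels aligned to the matrix rows.
#' @param ko_ids KOs to test; default all columns. Unknown ids error.
#' @param importance Optional named vector of median consensus importances
#'   used to order the table; otherwise rows sort by raw p.
#' @return An `association_table` tibble: `ko_id`, `a`, `b`, `c`, `d`,
#'   `pct_in_class`, `pct_out_class`, `odds_ratio`, `p_value`,
#'   `median_importance`.
#' @export
ko_association_table <- function(mat, labels, ko_ids = NULL,
                                 importance = NULL) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(mat))
  if (is.null(ko_ids)) ko_ids <- colnames(mat)
  if (length(ko_ids) == 0) {
    out <- tibble::tibble(
      ko_id = character(), a = integer(), b = integer(), c = integer(),
      d = integer(), pct_in_class = double(), pct_out_class = double(),
      odds_ratio = double(), p_value = double(),
      median_importance = double())
    return(structure(out, class = c("association_table", class(out))))
  }
  missing <- setdiff(ko_ids, colnames(mat))
  if (length(missing) > 0) {
    stop("KO(s) not in matrix: ", paste(missing, collapse = ", "))
  }
  n_in <- sum(labels == 1L)
  n_out <- sum(labels == 0L)
  rows <- lapply(ko_ids, function(ko) {
    present <- mat[, ko]
    a <- sum(present == 1L & labels == 1L)
    cc <- sum(present == 1L & labels == 0L)
    ft <- fisher_exact_2x2(a, n_in - a, cc, n_out - cc)
    tibble::tibble(
      ko_id = ko, a = a, b = n_in - a, c = cc, d = n_out - cc,
      pct_in_class = 100 * a / n_in,
      pct_out_class = 100 * cc / n_out,
      odds_ratio = ft$odds_ratio, p_value = ft$p_value)
  })
  out <- dplyr::bind_rows(rows)
  out$median_importance <- if (!is.null(importance)) {
    as.numeric(importance[out$ko_id])
  } else {
    NA_real_
  }
  out <- if (!is.null(importance)) {
    out[order(-out$median_importance, out$ko_id), ]
  } else {
    out[order(out$p_value, out$ko_id), ]
  }
  structure(out, class = c("association_table", class(out)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction; input order is preserved.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Drop yeast-restricted KEGG pathways from a pathway map
#'
#' KEGG labels some pathways with a " - yeast" suffix; these are narrowly
#' defined for Saccharomycetales and under-annotated elsewhere, so they are
#' excluded before enrichment. Matching normalizes hyphen/en-dash/em-dash
#' and surrounding whitespace.
#'
#' @param pathway_map Tibble with columns `ko_id`, `pathway_id`,
#'   `pathway_label`.
#' @return The map without the matching pathways; a message reports how many
#'   pathways were removed.
#' @export
filter_yeast_pathways <- function(pathway_map) {
  norm <- stringr::str_replace_all(pathway_map$pathway_label,
                                   "[–—]", "-")
  hit <- stringr::str_detect(norm, stringr::regex("-\\s*yeast\\s*$",
                                                  ignore_case = TRUE))
  removed <- unique(pathway_map$pathway_id[hit])
  if (length(removed) > 0) {
    message("removed ", length(removed),
            " yeast-restricted pathway(s): ",
            paste(unique(pathway_map$pathway_label[hit]), collapse = ", "))
  }
  pathway_map[!pathway_map$pathway_id %in% removed, ]
}

#' Pathway over-representation of a selected KO set
#'
#' One-sided hypergeometric test per pathway: with `N` universe KOs of which
#' `K` lie in the pathway and `n` selected KOs of which `k` lie in the
#' pathway, the p-value is the upper tail `P(X >= k)`. The universe should
#' be all KOs annotated in the input genomes (here: the columns of the
#' analyzed matrix). P-values are BH-adjusted across tested pathways.
#'
#' @param selected_kos Character vector, the consensus-selected KOs
#'   (must be a subset of the universe).
#' @param universe_kos Character vector, the background KO set.
#' @param pathway_map Tibble (`ko_id`, `pathway_id`, `pathway_label`),
#'   already stripped of yeast-restricted pathways where desired.
#' @param min_size Minimum pathway size (in-universe KOs) to test.
#' @return An `enrichment_table` tibble: `pathway_id`, `pathway_label`, `k`,
#'   `n`, `K`, `N`, `p_value`, `p_adjusted`, sorted by increasing p.
#' @export
pathway_enrichment <- function(selected_kos, universe_kos, pathway_map,
                               min_size = 3) {
  offenders <- setdiff(selected_kos, universe_kos)
  if (length(offenders) > 0) {
    stop("selected KOs outside the universe: ",
         paste(utils::head(offenders, 10), collapse = ", "))
  }
  pm <- pathway_map[pathway_map$ko_id %in% universe_kos, ]
  N <- length(unique(universe_kos))
  n <- length(unique(selected_kos))
  paths <- unique(pm[, c("pathway_id", "pathway_label")])
  rows <- lapply(seq_len(nrow(paths)), function(i) {
    kos <- unique(pm$ko_id[pm$pathway_id == paths$pathway_id[i]])
    K <- length(kos)
    if (K < max(1, min_size)) return(NULL)
    k <- length(intersect(kos, selected_kos))
    tibble::tibble(
      pathway_id = paths$pathway_id[i],
      pathway_label = paths$pathway_label[i],
      k = k, n = n, K = K, N = N,
      p_value = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(pathway_id = character(),
                          pathway_label = character(),
                          k = integer(), n = integer(), K = integer(),
                          N = integer(), p_value = double(),
                          p_adjusted = double())
    return(structure(out, class = c("enrichment_table", class(out))))
  }
  out$p_adjusted <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, -out$k, out$pathway_id), ]
  structure(out, class = c("enrichment_table", class(out)))
}
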