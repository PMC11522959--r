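#' Construct a strain-by-KO presence/absence matrix
#'
#' @param mat Integer or logical matrix with strain ids as rownames and
#'   KEGG-ortholog (KO) ids as colnames; values strictly 0/1.
#' @return A `ko_matrix` object (the validated integer matrix).
#' @export
ko_matrix <- function(mat) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("ko_matrix needs strain rownames and KO colnames")
  }
  if (anyDuplicated(rownames(mat)) > 0) {
    stop("duplicate strain id(s): ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]),
               collapse = ", "))
  }
  if (anyDuplicated(colnames(mat)) > 0) stop("duplicate KO id(s)")
  bad <- which(!(mat %in% c(0L, 1L)) | is.na(mat))
  if (length(bad) > 0) {
    i <- ((bad[1] - 1) %% nrow(mat)) + 1
    j <- ((bad[1] - 1) %/% nrow(mat)) + 1
    stop("non-binary value at strain '", rownames(mat)[i], "', KO '",
         colnames(mat)[j], "': ", mat[bad[1]])
  }
  storage.mode(mat) <- "integer"
  structure(mat, class = c("ko_matrix", "matrix", "array"))
}

#' @export
print.ko_matrix <- function(x, ...) {
  cat("<ko_matrix> ", nrow(x), " strains x ", ncol(x), " KOs; overall presence ",
      sprintf("%.1f%%", 100 * mean(x)), "\n", sep = "")
  invisible(x)
}

#' Read a strain-by-KO table from TSV
#'
#' First column holds strain ids; the remaining columns are KO ids with
#' strictly binary cells.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A [ko_matrix()].
#' @export
load_ko_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()))
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  ko_matrix(mat)
}

#' Write a KO matrix as TSV
#'
#' @param mat A [ko_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ko_table <- function(mat, path) {
  df <- tibble::as_tibble(unclass(mat), rownames = "strain_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a KO-to-pathway map from TSV
#'
#' Columns: `ko_id`, `pathway_id`, `pathway_label` (one row per KO-pathway
#' pair; a KO may belong to several pathways).
#'
#' @param path Path to a tab-separated file.
#' @return A tibble.
#' @export
load_pathway_map <- function(path) {
  pm <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()))
  need <- c("ko_id", "pathway_id", "pathway_label")
  miss <- setdiff(need, names(pm))
  if (length(miss) > 0) {
    stop("pathway map is missing column(s): ", paste(miss, collapse = ", "))
  }
  pm[, need]
}

#' Drop KOs with low prevalence
#'
#' Removes every KO whose presence fraction across strains is strictly below
#' the threshold; the default removes KOs present in fewer than 20% of
#' strains. Column order of the survivors is preserved.
#'
#' @param mat A [ko_matrix()].
#' @param threshold Minimum presence fraction in `[0, 1]`.
#' @return A [ko_matrix()] with the surviving KO columns.
#' @export
filter_low_prevalence <- function(mat, threshold = 0.20) {
  stopifnot(threshold >= 0, threshold <= 1)
  keep <- colMeans(mat) >= threshold
  if (!any(keep)) warning("no KO survives the prevalence filter")
  out <- unclass(mat)[, keep, drop = FALSE]
  structure(out, class = c("ko_matrix", "matrix", "array"))
}

#' Evaluate code with a temporary RNG seed
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Balance a binary label vector by downsampling the majority class
#'
#' The minority class is fully retained; the majority class is sampled
#' without replacement to the same size. Deterministic given `seed`.
#'
#' @param labels Binary (0/1) vector.
#' @param seed Integer seed.
#' @return Sorted integer indices into `labels` with equal class counts.
#' @export
balance_downsample <- function(labels, seed) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stop("both classes must be non-empty")
  k <- min(n0, n1)
  idx1 <- which(labels == 1L)
  idx0 <- which(labels == 0L)
  with_seed(seed, {
    if (n1 > k) idx1 <- sort(sample(idx1, k))
    if (n0 > k) idx0 <- sort(sample(idx0, k))
  })
  sort(c(idx0, idx1))
}

#' Stratified train/test split
#'
#' Withholds `test_fraction` of the supplied indices for testing (default
#' 20%, the remaining 80% train), stratified by label so both classes appear
#' in the test set. The total test size is `round(test_fraction * n)`,
#' allocated across classes by largest remainder.
#'
#' @param indices Integer indices (e.g. a balanced set).
#' @param labels Binary label vector the indices point into.
#' @param test_fraction Fraction withheld for testing.
#' @param seed Integer seed.
#' @return A `split_plan`: list with `balanced`, `train`, `test`,
#'   `test_fraction`, `seed`.
#' @export
make_split <- function(indices, labels, test_fraction = 0.20, seed) {
  if (length(indices) < 10) stop("need at least 10 indices to split")
  stopifnot(test_fraction > 0, test_fraction < 1)
  lab <- as.integer(labels)[indices]
  total_test <- round(test_fraction * length(indices))
  by_class <- split(indices, lab)
  if (length(by_class) < 2) stop("both classes needed to stratify")
  raw <- vapply(by_class, length, integer(1)) * test_fraction
  base <- floor(raw)
  rem <- total_test - sum(base)
  # largest remainder, ties broken by class name for determinism
  ord <- order(-(raw - base), names(by_class))
  take <- base
  if (rem > 0) take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1
  if (rem < 0) {
    drop <- rev(ord)[seq_len(-rem)]
    take[drop] <- take[drop] - 1
  }
  if (any(take == 0) || any(take >= lengths(by_class))) {
    stop("too few samples in a class to stratify the test set")
  }
  test <- with_seed(seed, {
    unlist(lapply(names(by_class), function(cl) {
      sort(sample(by_class[[cl]], take[[cl]]))
    }), use.names = FALSE)
  })
  test <- sort(test)
  structure(
    list(balanced = sort(indices),
         train = setdiff(sort(indices), test),
         test = test,
         test_fraction = test_fraction,
         seed = seed),
    class = "split_plan"
  )
}

#' @export
print.split_plan <- function(x, ...) {
  cat("<split_plan> ", length(x$balanced), " samples: ",
      length(x$train), " train / ", length(x$test), " test (",
      sprintf("%.0f%%", 100 * x$test_fraction), " withheld), seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}
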