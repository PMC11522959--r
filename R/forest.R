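#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) form: the probability that a uniformly chosen positive
#' receives a higher score than a uniformly chosen negative, with ties
#' counting one half.
#'
#' @param y_true Binary (0/1) truth vector.
#' @param scores Numeric scores, higher meaning more positive.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(y_true, scores) {
  y <- as.integer(y_true)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes in y_true")
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Tuning configuration for the forest protocol
#'
#' The first-stage grid brackets standard forest defaults; the second stage
#' refines the stage-1 winner by the multipliers (default 0.75 and 1.25),
#' rounded to valid integers, deduplicated, and clamped to at least 1.
#'
#' @param mtry_grid Stage-1 candidate values for `mtry` (variables tried per
#'   split); `NULL` defaults to `round(c(sqrt(p), p/10, p/3))` at fit time.
#' @param min_n_grid Stage-1 candidates for `min_n` (minimum node size).
#' @param multipliers Refinement multipliers applied to the stage-1 winner.
#' @param num_trees Trees per forest.
#' @return A `tune_config` list.
#' @export
tune_config <- function(mtry_grid = NULL, min_n_grid = c(2, 5, 10),
                        multipliers = c(0.75, 1.25), num_trees = 500) {
  stopifnot(all(multipliers > 0), length(min_n_grid) > 0, num_trees >= 1)
  structure(list(mtry_grid = mtry_grid, min_n_grid = min_n_grid,
                 multipliers = multipliers, num_trees = num_trees),
            class = "tune_config")
}

default_mtry_grid <- function(p) {
  sort(unique(pmax(1L, pmin(p, round(c(sqrt(p), p / 10, p / 3))))))
}

refine_grid <- function(best, multipliers, upper = Inf) {
  vals <- round(best * sort(c(multipliers, 1)))
  sort(unique(pmax(1, pmin(upper, vals))))
}

fit_ranger <- function(X, y, mtry, min_n, num_trees, seed,
                       importance = "none") {
  ranger::ranger(
    x = X, y = factor(y, levels = c(0, 1)),
    num.trees = num_trees,
    mtry = min(mtry, ncol(X)),
    min.node.size = min_n,
    probability = TRUE,
    importance = importance,
    respect.unordered.factors = FALSE,
    num.threads = 1,
    seed = seed
  )
}

predict_scores <- function(model, X) {
  as.numeric(stats::predict(model, data = X, num.threads = 1)$
               predictions[, "1"])
}

#' Two-stage grid search for forest hyperparameters
#'
#' Evaluates a coarse grid over `mtry` and `min_n` on an internal 20%
#' validation split of the (balanced) training data, then a refinement grid
#' at 0.75x / 1x / 1.25x the stage-1 winner, selecting the pair with maximum
#' validation AUC over both stages (ties broken toward the earlier, smaller
#' configuration).
#'
#' @param X Feature matrix (strains x KOs).
#' @param y Binary labels aligned to `X` rows.
#' @param config A [tune_config()].
#' @param seed Integer seed controlling the validation split and forests.
#' @return A `tuning_result` with the evaluated grid and the selected pair.
#' @export
tune_forest <- function(X, y, config = tune_config(), seed = 1) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("y must contain both classes")
  p <- ncol(X)
  mtry_grid <- config$mtry_grid %||% default_mtry_grid(p)
  split <- make_split(seq_along(y), y, test_fraction = 0.20, seed = seed)
  eval_grid <- function(mtrys, min_ns, stage) {
    grid <- expand.grid(mtry = mtrys, min_n = min_ns)
    grid$stage <- stage
    grid$auc <- vapply(seq_len(nrow(grid)), function(i) {
      m <- fit_ranger(X[split$train, , drop = FALSE], y[split$train],
                      grid$mtry[i], grid$min_n[i], config$num_trees,
                      seed = seed + i)
      auc(y[split$test],
          predict_scores(m, X[split$test, , drop = FALSE]))
    }, numeric(1))
    grid
  }
  s1 <- eval_grid(mtry_grid, config$min_n_grid, 1L)
  best1 <- s1[order(-s1$auc, s1$mtry, s1$min_n), ][1, ]
  s2 <- eval_grid(refine_grid(best1$mtry, config$multipliers, upper = p),
                  refine_grid(best1$min_n, config$multipliers), 2L)
  all_eval <- rbind(s1, s2)
  best <- all_eval[order(-all_eval$auc, all_eval$stage,
                         all_eval$mtry, all_eval$min_n), ][1, ]
  structure(
    list(evaluated = tibble::as_tibble(
           all_eval[, c("stage", "mtry", "min_n", "auc")]),
         mtry = best$mtry, min_n = best$min_n, auc = best$auc,
         seed = seed),
    class = "tuning_result"
  )
}

#' @export
print.tuning_result <- function(x, ...) {
  cat("<tuning_result> selected mtry = ", x$mtry, ", min_n = ", x$min_n,
      " (validation AUC ", sprintf("%.3f", x$auc), ", ",
      nrow(x$evaluated), " configurations)\n", sep = "")
  invisible(x)
}

#' @export
tidy.tuning_result <- function(x, ...) x$evaluated

#' @export
glance.tuning_result <- function(x, ...) {
  tibble::tibble(mtry = x$mtry, min_n = x$min_n, auc = x$auc,
                 n_evaluated = nrow(x$evaluated))
}

#' Test-fold permutation importance
#'
#' For each feature, shuffles its test-fold column and reports the mean AUC
#' drop relative to the unpermuted baseline over `n_repeats` shuffles. A
#' feature the model does not use scores (close to) zero.
#'
#' @param model A fitted `ranger` probability forest.
#' @param X_test,y_test Held-out features and binary labels.
#' @param n_repeats Shuffles per feature (>= 1).
#' @param seed Integer seed.
#' @return Named numeric vector of importances (one per column of `X_test`).
#' @export
permutation_importance <- function(model, X_test, y_test, n_repeats = 5,
                                   seed = 1) {
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  baseline <- auc(y_test, predict_scores(model, X_test))
  n <- nrow(X_test)
  imp <- with_seed(seed, {
    vapply(seq_len(ncol(X_test)), function(j) {
      drops <- vapply(seq_len(n_repeats), function(r) {
        Xp <- X_test
        Xp[, j] <- Xp[sample.int(n), j]
        baseline - auc(y_test, predict_scores(model, Xp))
      }, numeric(1))
      mean(drops)
    }, numeric(1))
  })
  stats::setNames(imp, colnames(X_test))
}

#' Fit one resampled forest iteration
#'
#' Trains on the split's training indices only, evaluates AUC and the
#' true-positive rate (score threshold 0.5) on the held-out test indices,
#' and records a permutation importance per KO. The default importance mode
#' is ranger's out-of-bag permutation importance; `"test"` instead applies
#' [permutation_importance()] on the held-out fold.
#'
#' @param X Full feature matrix.
#' @param y Full binary label vector.
#' @param params List with `mtry`, `min_n` and optionally `num_trees`
#'   (default 500); e.g. a [tune_forest()] result.
#' @param split A [make_split()] plan.
#' @param seed Integer seed.
#' @param importance_mode `"oob"` or `"test"`.
#' @param iteration Iteration index stored in the result.
#' @return An `iteration_result`: AUC, TPR, per-strain test predictions, and
#'   the importance vector.
#' @export
fit_iteration <- function(X, y, params, split, seed,
                          importance_mode = c("oob", "test"),
                          iteration = 1L) {
  importance_mode <- match.arg(importance_mode)
  y <- as.integer(y)
  tr <- split$train
  te <- split$test
  if (length(unique(y[tr])) < 2) stop("training fold has a single class")
  model <- fit_ranger(
    X[tr, , drop = FALSE], y[tr], params$mtry, params$min_n,
    params$num_trees %||% 500, seed = seed,
    importance = if (importance_mode == "oob") "permutation" else "none")
  scores <- predict_scores(model, X[te, , drop = FALSE])
  truth <- y[te]
  pred <- as.integer(scores >= 0.5)
  tp <- sum(pred == 1L & truth == 1L)
  fn <- sum(pred == 0L & truth == 1L)
  imp <- if (importance_mode == "oob") {
    model$variable.importance[colnames(X)]
  } else {
    permutation_importance(model, X[te, , drop = FALSE], truth,
                           n_repeats = 1, seed = seed)
  }
  structure(
    list(iteration = iteration, seed = seed, split = split,
         auc = auc(truth, scores),
         tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         predictions = tibble::tibble(
           strain = rownames(X)[te] %||% as.character(te),
           truth = truth, score = scores, predicted = pred),
         importance = stats::setNames(as.numeric(imp), colnames(X))),
    class = "iteration_result"
  )
}

#' Run the repeated resampled-forest protocol
#'
#' Repeats, `n_iterations` times (the study protocol uses 100): draw a fresh
#' balanced set by downsampling the majority class, withhold a stratified
#' test fraction (default 20%), fit the forest with the supplied parameters,
#' and store AUC, TPR, test predictions and the per-KO permutation
#' importance. Iteration `i` uses seed `base_seed + i`, so the whole run is
#' reproducible from `base_seed`.
#'
#' @param X Feature matrix (all strains).
#' @param y Binary label vector aligned to `X`.
#' @param params List with `mtry`, `min_n`, optionally `num_trees`.
#' @param n_iterations Number of iterations.
#' @param test_fraction Fraction withheld per iteration.
#' @param base_seed Integer master seed.
#' @param rebalance_each Draw a fresh balanced set each iteration (default);
#'   if `FALSE`, one balanced set from `base_seed` is reused and only the
#'   splits vary.
#' @param importance_mode Passed to [fit_iteration()].
#' @return A `forest_run`: list of `iteration_result`s plus run metadata.
#' @export
run_iterations <- function(X, y, params, n_iterations = 100,
                           test_fraction = 0.20, base_seed = 1,
                           rebalance_each = TRUE,
                           importance_mode = c("oob", "test")) {
  importance_mode <- match.arg(importance_mode)
  y <- as.integer(y)
  fixed_idx <- if (!rebalance_each) balance_downsample(y, base_seed)
  results <- lapply(seq_len(n_iterations), function(i) {
    seed_i <- base_seed + i
    idx <- if (rebalance_each) balance_downsample(y, seed_i) else fixed_idx
    split <- make_split(idx, y, test_fraction, seed = seed_i)
    fit_iteration(X, y, params, split, seed = seed_i,
                  importance_mode = importance_mode, iteration = i)
  })
  structure(
    list(iterations = results,
         params = params, n_iterations = n_iterations,
         test_fraction = test_fraction, base_seed = base_seed,
         rebalance_each = rebalance_each,
         importance_mode = importance_mode,
         ko_ids = colnames(X)),
    class = "forest_run"
  )
}

#' @export
print.forest_run <- function(x, ...) {
  aucs <- vapply(x$iterations, `[[`, numeric(1), "auc")
  cat("<forest_run> ", x$n_iterations, " iterations, mean AUC ",
      sprintf("%.3f", mean(aucs)), " (seed ", x$base_seed, ")\n", sep = "")
  invisible(x)
}

#' Per-iteration metrics of a forest run
#'
#' @param x A `forest_run`.
#' @param ... Unused.
#' @return Tibble with `iteration`, `seed`, `auc`, `tpr`.
#' @export
tidy.forest_run <- function(x, ...) {
  tibble::tibble(
    iteration = vapply(x$iterations, `[[`, integer(1), "iteration"),
    seed = vapply(x$iterations, `[[`, numeric(1), "seed"),
    auc = vapply(x$iterations, `[[`, numeric(1), "auc"),
    tpr = vapply(x$iterations, `[[`, numeric(1), "tpr")
  )
}

#' @export
glance.forest_run <- function(x, ...) {
  m <- tidy(x)
  tibble::tibble(n_iterations = nrow(m), mean_auc = mean(m$auc),
                 sd_auc = stats::sd(m$auc), mean_tpr = mean(m$tpr,
                                                            na.rm = TRUE))
}

#' KO-by-iteration importance matrix of a run
#'
#' @param run A `forest_run`.
#' @return Numeric matrix, KOs in rows, iterations in columns.
#' @export
importance_matrix <- function(run) {
  do.call(cbind, lapply(run$iterations, `[[`, "importance"))
}

#' Consensus of important KOs across model iterations
#'
#' For every iteration, the KOs are ranked by permutation importance
#' (descending, ties broken by KO id) and the top `top_k` are marked. A KO is
#' consensus-flagged when it appears in the top set in at least
#' `ceil(min_frac * n_iterations)` iterations — the study rule is the top
#' 1000 KOs in 80% of 100 models.
#'
#' @param run A `forest_run` (or list of `iteration_result`s).
#' @param top_k Size of the per-iteration top set.
#' @param min_frac Minimum fraction of iterations for the consensus flag.
#' @return A `consensus_report` tibble: `ko_id`, `n_top`, `n_iterations`,
#'   `median_importance`, `consensus`, ordered by decreasing `n_top` then
#'   decreasing median importance.
#' @export
consensus_importance <- function(run, top_k = 1000, min_frac = 0.80) {
  if (top_k < 1) stop("top_k must be >= 1")
  imp <- if (inherits(run, "forest_run")) importance_matrix(run)
         else do.call(cbind, lapply(run, `[[`, "importance"))
  n_iter <- ncol(imp)
  ko_ids <- rownames(imp)
  k <- min(top_k, nrow(imp))
  in_top <- matrix(FALSE, nrow(imp), n_iter)
  for (j in seq_len(n_iter)) {
    ord <- order(-imp[, j], ko_ids)
    in_top[ord[seq_len(k)], j] <- TRUE
  }
  n_top <- rowSums(in_top)
  need <- ceiling(min_frac * n_iter)
  out <- tibble::tibble(
    ko_id = ko_ids,
    n_top = as.integer(n_top),
    n_iterations = n_iter,
    median_importance = apply(imp, 1, stats::median),
    consensus = n_top >= need
  )
  out <- out[order(-out$n_top, -out$median_importance, out$ko_id), ]
  structure(out, class = c("consensus_report", class(out)),
            top_k = top_k, min_frac = min_frac)
}

#' Consistently misclassified strains across iterations
#'
#' A strain is consistently misclassified when it was predicted wrongly in
#' every iteration in which it appeared in a test set. Consistent false
#' positives are truth-0 strains always predicted 1; consistent false
#' negatives the reverse.
#'
#' @param run A `forest_run`.
#' @return List with `per_strain` (tibble: `strain`, `truth`, `n_test`,
#'   `n_wrong`, `error_rate`), `consistent_false_pos` and
#'   `consistent_false_neg` (character vectors of strain ids).
#' @export
misclassification_audit <- function(run) {
  preds <- dplyr::bind_rows(lapply(run$iterations, `[[`, "predictions"))
  per <- preds |>
    dplyr::group_by(.data$strain, .data$truth) |>
    dplyr::summarise(
      n_test = dplyr::n(),
      n_wrong = sum(.data$predicted != .data$truth),
      .groups = "drop") |>
    dplyr::mutate(error_rate = .data$n_wrong / .data$n_test) |>
    dplyr::arrange(dplyr::desc(.data$error_rate), .data$strain)
  consistent <- per[per$n_wrong == per$n_test & per$n_test > 0, ]
  list(
    per_strain = per,
    consistent_false_pos = consistent$strain[consistent$truth == 0L],
    consistent_false_neg = consistent$strain[consistent$truth == 1L]
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
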