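sep_data <- function(n = 60, p = 10, seed = 1) {
  # one feature equal to the label, the rest noise
  set.seed(seed)
  y <- rep(c(0L, 1L), n / 2)
  X <- matrix(rbinom(n * p, 1, 0.5), n, p,
              dimnames = list(sprintf("s%03d", 1:n),
                              sprintf("K%05d", 1:p)))
  X[, 1] <- y
  X[, 2] <- 1L  # constant column
  list(X = X, y = y)
}

test_that("auc handles perfect, inverted and tied rankings", {
  y <- c(0, 0, 1, 1)
  expect_identical(auc(y, c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_identical(auc(y, c(0.9, 0.8, 0.2, 0.1)), 0)
  expect_identical(auc(y, rep(0.5, 4)), 0.5)
  expect_error(auc(c(1, 1), c(0.5, 0.6)), "both classes")
})

test_that("auc equals the pairwise-enumeration oracle", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(10:60, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- sample(c(runif(n), round(runif(n), 1)), n)  # some ties
    expect_equal(auc(y, s), auc_oracle(y, s), tolerance = 1e-12)
    if (seed <= 5 && requireNamespace("pROC", quietly = TRUE)) {
      expect_equal(auc(y, s),
                   as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                  direction = "<"))),
                   tolerance = 1e-9)
    }
  }
})

test_that("the refinement grid applies the 0.75/1.25 multipliers", {
  expect_identical(yeastenv:::refine_grid(40, c(0.75, 1.25)),
                   c(30, 40, 50))
  expect_identical(yeastenv:::refine_grid(8, c(0.75, 1.25)),
                   c(6, 8, 10))
  # rounding (R's round-half-to-even), clamping at 1, and deduplication
  expect_identical(yeastenv:::refine_grid(1, c(0.75, 1.25)), 1)
  expect_identical(yeastenv:::refine_grid(3, c(0.75, 1.25)), c(2, 3, 4))
  expect_identical(yeastenv:::refine_grid(40, c(0.75, 1.25), upper = 45),
                   c(30, 40, 45))
})

test_that("tuning selects the maximum-AUC configuration", {
  d <- sep_data(n = 80, p = 12, seed = 2)
  tr <- tune_forest(d$X, d$y, tune_config(num_trees = 100), seed = 5)
  expect_identical(tr$auc, max(tr$evaluated$auc))
  expect_identical(tr$auc, 1)  # perfectly separable
  expect_true(all(c(1L, 2L) %in% tr$evaluated$stage))
  # selected params reproduce their recorded AUC under the same seed
  tr2 <- tune_forest(d$X, d$y, tune_config(num_trees = 100), seed = 5)
  expect_identical(tr$mtry, tr2$mtry)
  expect_identical(tr$auc, tr2$auc)
  expect_error(tune_forest(d$X, rep(1L, nrow(d$X))), "both classes")
})

test_that("a deterministic feature yields AUC 1 and top importance", {
  d <- sep_data(n = 80, p = 12, seed = 3)
  sp <- make_split(seq_along(d$y), d$y, 0.2, seed = 1)
  it <- fit_iteration(d$X, d$y, list(mtry = 4, min_n = 2, num_trees = 200),
                      sp, seed = 9)
  expect_identical(it$auc, 1)
  expect_identical(it$tpr, 1)
  expect_identical(names(which.max(it$importance)), "K00001")
  # constant feature carries (near) zero importance
  expect_lt(abs(it$importance[["K00002"]]), 1e-8)
  expect_error(fit_iteration(d$X, rep(c(0L, 1L), c(79, 1)),
                             list(mtry = 4, min_n = 2),
                             make_split(1:80, rep(c(0L, 1L), c(70, 10)),
                                        0.2, 1),
                             seed = 1),
               "single class")
})

test_that("label-shuffled data scores near chance", {
  set.seed(11)
  aucs <- vapply(1:12, function(s) {
    set.seed(s)
    n <- 80
    X <- matrix(rbinom(n * 20, 1, 0.5), n, 20,
                dimnames = list(NULL, sprintf("K%05d", 1:20)))
    y <- sample(rep(c(0L, 1L), n / 2))
    sp <- make_split(seq_len(n), y, 0.2, seed = s)
    fit_iteration(X, y, list(mtry = 4, min_n = 5, num_trees = 100), sp,
                  seed = s)$auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("test-fold permutation importance isolates informative columns", {
  d <- sep_data(n = 100, p = 8, seed = 4)
  sp <- make_split(seq_along(d$y), d$y, 0.3, seed = 2)
  model <- yeastenv:::fit_ranger(d$X[sp$train, ], d$y[sp$train],
                                 mtry = 3, min_n = 2, num_trees = 200,
                                 seed = 7)
  imp <- permutation_importance(model, d$X[sp$test, ], d$y[sp$test],
                                n_repeats = 3, seed = 1)
  expect_length(imp, ncol(d$X))
  expect_identical(names(which.max(imp)), "K00001")
  expect_identical(imp[["K00002"]], 0)  # constant column
  expect_identical(imp,
                   permutation_importance(model, d$X[sp$test, ],
                                          d$y[sp$test], 3, seed = 1))
  expect_error(permutation_importance(model, d$X, d$y, 0, 1), "n_repeats")
})

test_that("duplicated informative columns still outrank noise", {
  set.seed(21)
  n <- 120
  y <- rep(c(0L, 1L), n / 2)
  X <- matrix(rbinom(n * 10, 1, 0.5), n, 10,
              dimnames = list(NULL, sprintf("K%05d", 1:10)))
  signal <- ifelse(y == 1, rbinom(n, 1, 0.9), rbinom(n, 1, 0.2))
  X[, 1] <- signal
  X[, 2] <- signal
  sp <- make_split(seq_len(n), y, 0.25, seed = 3)
  it <- fit_iteration(X, y, list(mtry = 3, min_n = 2, num_trees = 300), sp,
                      seed = 5)
  ranks <- rank(-it$importance)
  expect_true(all(ranks[c("K00001", "K00002")] <= 4))
})

test_that("repeated iterations are reproducible and vary by seed", {
  d <- sep_data(n = 60, p = 10, seed = 6)
  params <- list(mtry = 3, min_n = 2, num_trees = 100)
  r1 <- run_iterations(d$X, d$y, params, n_iterations = 6, base_seed = 42)
  r2 <- run_iterations(d$X, d$y, params, n_iterations = 6, base_seed = 42)
  expect_identical(tidy(r1)$auc, tidy(r2)$auc)
  expect_identical(length(r1$iterations), 6L)
  splits <- lapply(r1$iterations, function(it) it$split$test)
  expect_gt(length(unique(splits)), 1)
  # fixed balanced set mode reuses one index set
  r3 <- run_iterations(d$X, d$y, params, n_iterations = 3, base_seed = 1,
                       rebalance_each = FALSE)
  bals <- unique(lapply(r3$iterations, function(it) it$split$balanced))
  expect_length(bals, 1)
})

test_that("consensus counting matches a brute-force recount", {
  d <- sep_data(n = 60, p = 15, seed = 8)
  params <- list(mtry = 4, min_n = 2, num_trees = 100)
  run <- run_iterations(d$X, d$y, params, n_iterations = 8, base_seed = 3)
  top_k <- 5
  rep_ <- consensus_importance(run, top_k = top_k, min_frac = 0.8)
  imp <- importance_matrix(run)
  recount <- sapply(rownames(imp), function(ko) {
    sum(vapply(seq_len(ncol(imp)), function(j) {
      ord <- order(-imp[, j], rownames(imp))
      ko %in% rownames(imp)[ord[seq_len(top_k)]]
    }, logical(1)))
  })
  expect_identical(stats::setNames(rep_$n_top, rep_$ko_id)[names(recount)],
                   recount)
  expect_identical(rep_$consensus, rep_$n_top >= ceiling(0.8 * 8))
  # the deterministic separating feature is in the top set every time
  expect_identical(rep_$n_top[rep_$ko_id == "K00001"], 8L)
  # a KO never in the top set is unflagged with count 0
  never <- rep_[rep_$n_top == 0, ]
  if (nrow(never) > 0) expect_false(any(never$consensus))
  # invariance to iteration order
  run_rev <- run
  run_rev$iterations <- rev(run$iterations)
  rep_rev <- consensus_importance(run_rev, top_k = top_k, min_frac = 0.8)
  expect_identical(rep_[order(rep_$ko_id), ],
                   rep_rev[order(rep_rev$ko_id), ])
})

test_that("misclassification audit finds consistently wrong strains", {
  # hand-built run: strain s1 always wrong, s2 sometimes, s3 never
  fake_it <- function(i, preds) {
    structure(list(iteration = i, seed = i, split = NULL, auc = 0.5,
                   tpr = 0.5, predictions = preds,
                   importance = c(K1 = 0)),
              class = "iteration_result")
  }
  run <- structure(list(iterations = list(
    fake_it(1, tibble::tibble(strain = c("s1", "s2", "s3"),
                              truth = c(1L, 0L, 0L),
                              score = c(0.2, 0.9, 0.1),
                              predicted = c(0L, 1L, 0L))),
    fake_it(2, tibble::tibble(strain = c("s1", "s2"),
                              truth = c(1L, 0L),
                              score = c(0.1, 0.2),
                              predicted = c(0L, 0L)))
  )), class = "forest_run")
  aud <- misclassification_audit(run)
  expect_identical(aud$consistent_false_neg, "s1")
  expect_length(aud$consistent_false_pos, 0)
  s2 <- aud$per_strain[aud$per_strain$strain == "s2", ]
  expect_identical(s2$n_test, 2L)
  expect_identical(s2$n_wrong, 1L)
  expect_identical(s2$error_rate, 0.5)
})

test_that("a perfect classifier leaves the audit sets empty", {
  d <- sep_data(n = 60, p = 8, seed = 10)
  run <- run_iterations(d$X, d$y, list(mtry = 4, min_n = 2,
                                       num_trees = 200),
                        n_iterations = 4, base_seed = 6)
  aud <- misclassification_audit(run)
  expect_length(aud$consistent_false_pos, 0)
  expect_length(aud$consistent_false_neg, 0)
})
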