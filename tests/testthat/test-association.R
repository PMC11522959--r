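test_that("fisher test reports the cross-product odds ratio", {
  res <- fisher_exact_2x2(295, 44, 495, 252)
  expect_equal(res$odds_ratio, (295 * 252) / (44 * 495), tolerance = 1e-12)
  expect_equal(round(res$odds_ratio, 2), 3.41)
  expect_equal(res$p_value, fisher_p_oracle(295, 44, 495, 252),
               tolerance = 1e-9)
  sym <- fisher_exact_2x2(10, 10, 10, 10)
  expect_identical(sym$odds_ratio, 1)
  expect_equal(sym$p_value, 1, tolerance = 1e-12)
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "margin")
})

test_that("zero cells follow the documented odds-ratio convention", {
  expect_identical(fisher_exact_2x2(5, 0, 3, 4)$odds_ratio, Inf)
  expect_true(fisher_exact_2x2(5, 0, 3, 4)$degenerate)
  expect_identical(fisher_exact_2x2(0, 5, 3, 4)$odds_ratio, 0)
  expect_true(is.nan(fisher_exact_2x2(0, 5, 0, 4)$odds_ratio))
})

test_that("fisher p matches enumeration on random small tables", {
  set.seed(99)
  for (i in 1:200) {
    t <- rmultinom(1, sample(4:30, 1), runif(4, 0.05, 1))
    res <- fisher_exact_2x2(t[1], t[2], t[3], t[4])
    expect_equal(res$p_value, fisher_p_oracle(t[1], t[2], t[3], t[4]),
                 tolerance = 1e-9)
  }
})

test_that("fisher p is invariant under simultaneous row/column swap", {
  set.seed(5)
  for (i in 1:30) {
    t <- rmultinom(1, 40, runif(4, 0.1, 1))
    p1 <- fisher_exact_2x2(t[1], t[2], t[3], t[4])$p_value
    p2 <- fisher_exact_2x2(t[4], t[3], t[2], t[1])$p_value
    expect_equal(p1, p2, tolerance = 1e-12)
  }
})

test_that("odds ratio exceeds 1 exactly when in-class presence is higher", {
  set.seed(6)
  for (i in 1:40) {
    t <- rmultinom(1, 60, runif(4, 0.2, 1)) + 1  # all cells > 0
    res <- fisher_exact_2x2(t[1], t[2], t[3], t[4])
    frac_in <- t[1] / (t[1] + t[2])
    frac_out <- t[3] / (t[3] + t[4])
    if (frac_in != frac_out) {
      expect_identical(res$odds_ratio > 1, frac_in > frac_out)
    }
  }
})

test_that("association table reproduces printed class percentages", {
  # 339 in-class strains with 295 carriers; 747 out-of-class with 495
  mat <- matrix(0L, 1086, 1,
                dimnames = list(sprintf("s%04d", 1:1086), "K00661"))
  mat[1:295, 1] <- 1L
  mat[340 + seq_len(495), 1] <- 1L
  labels <- rep(c(1L, 0L), c(339, 747))
  tab <- ko_association_table(ko_matrix(mat), labels)
  expect_identical(c(tab$a, tab$b, tab$c, tab$d),
                   c(295L, 44L, 495L, 252L))
  expect_identical(round(tab$pct_in_class), 87)
  expect_identical(round(tab$pct_out_class), 66)
  expect_equal(round(tab$odds_ratio, 2), 3.41)
  # ordering by importance when provided
  expect_identical(nrow(ko_association_table(ko_matrix(mat), labels,
                                             ko_ids = character())), 0L)
  expect_error(ko_association_table(ko_matrix(mat), labels, "K99999"),
               "not in matrix")
})

test_that("BH adjustment matches the step-up oracle", {
  expect_identical(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4),
               tolerance = 1e-12)
  set.seed(12)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj >= 0 & adj <= 1))
    # monotone: sorted by raw p, adjusted values never decrease
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("yeast-restricted pathway labels are filtered out", {
  pm <- tibble::tibble(
    ko_id = paste0("K", 1:5),
    pathway_id = paste0("pw", 1:5),
    pathway_label = c("Meiosis – yeast", "Cell cycle - yeast",
                      "Lysosome", "Spliceosome", "Yeast surface display"))
  expect_message(out <- filter_yeast_pathways(pm), "removed 2")
  expect_setequal(out$pathway_label,
                  c("Lysosome", "Spliceosome", "Yeast surface display"))
  clean <- pm[3:5, ]
  expect_identical(filter_yeast_pathways(clean), clean)
})

test_that("pathway enrichment recovers a planted pathway", {
  set.seed(33)
  universe <- sprintf("K%05d", 1:2000)
  pm <- tibble::tibble(
    ko_id = universe,
    pathway_id = sprintf("pw%03d", sample(1:60, 2000, replace = TRUE)))
  pm$pathway_label <- paste("Pathway", pm$pathway_id)
  planted_kos <- sprintf("K%05d", 1901:1912)
  pm <- rbind(pm[!pm$ko_id %in% planted_kos, ],
              tibble::tibble(ko_id = planted_kos, pathway_id = "pw_planted",
                             pathway_label = "Planted pathway"))
  selected <- c(planted_kos[1:10], sample(setdiff(universe, planted_kos),
                                          199))
  enr <- pathway_enrichment(selected, universe, pm)
  expect_identical(enr$pathway_id[1], "pw_planted")
  expect_lt(enr$p_adjusted[1], 0.01)
  row1 <- enr[1, ]
  expect_identical(c(row1$k, row1$K, row1$n, row1$N),
                   c(10L, 12L, 209L, 2000L))
  expect_equal(row1$p_value,
               hyper_tail_oracle(row1$k, row1$K, row1$N, row1$n),
               tolerance = 1e-9)
})

test_that("enrichment degenerate cases behave", {
  pm <- tibble::tibble(ko_id = paste0("K", 1:10),
                       pathway_id = rep(c("a", "b"), each = 5),
                       pathway_label = c(rep("A", 5), rep("B", 5)))
  universe <- paste0("K", 1:10)
  enr <- pathway_enrichment(universe, universe, pm)
  expect_true(all(enr$p_value == 1))
  expect_error(pathway_enrichment(c("K1", "KX"), universe, pm),
               "outside the universe")
  # pathways below the minimum size are skipped
  enr2 <- pathway_enrichment("K1", universe, pm, min_size = 6)
  expect_identical(nrow(enr2), 0L)
})

test_that("enrichment p is monotone non-increasing in k at fixed n, K, N", {
  universe <- paste0("K", 1:100)
  in_path <- universe[1:10]
  pm <- tibble::tibble(ko_id = universe,
                       pathway_id = ifelse(universe %in% in_path,
                                           "pw", "bg"),
                       pathway_label = ifelse(universe %in% in_path,
                                              "Pathway", "Background"))
  ps <- vapply(0:8, function(k) {
    selected <- c(in_path[seq_len(k)],
                  setdiff(universe, in_path)[seq_len(8 - k)])
    enr <- pathway_enrichment(selected, universe, pm)
    enr$p_value[enr$pathway_id == "pw"]
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-15))
})
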