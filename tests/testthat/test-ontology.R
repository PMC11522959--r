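test_that("construction enforces the structural invariants", {
  expect_error(
    eco_ontology(data.frame(id = c("a", "a"), parent_id = c(NA, NA))),
    "duplicate class")
  expect_error(
    eco_ontology(data.frame(id = "a", parent_id = "ghost")),
    "not declared")
  expect_error(
    eco_ontology(data.frame(id = c("a", "b"), parent_id = c("b", "a"))),
    "cycle")
  ont <- toy_ontology()
  expect_error(
    eco_ontology(ont$classes, ont$properties,
                 tibble::tibble(id = "x", direct = list(character()))),
    "no direct class")
  expect_error(
    eco_ontology(ont$classes, ont$properties,
                 tibble::tibble(id = "x", direct = list("nonexistent"))),
    "unknown class")
  expect_error(
    eco_ontology(data.frame(id = "a", parent_id = NA),
                 data.frame(id = "p", label = "p", kind = "causal")),
    "relational.*modifier")
})

test_that("ancestors walks the subclass chain root first", {
  ont <- toy_ontology()
  expect_identical(ancestors(ont, "pollen"),
                   c("plant", "plant_parts", "flower"))
  expect_identical(ancestors(ont, "plant"), character())
  expect_error(ancestors(ont, "nope"), "unknown class")
})

test_that("membership uses transitive closure and is non-exclusive", {
  ont <- toy_ontology()
  # a strain placed on a leaf is counted in the leaf and every ancestor
  expect_true("s_pollen" %in% members(ont, "pollen"))
  expect_true("s_pollen" %in% members(ont, "flower"))
  expect_true("s_pollen" %in% members(ont, "plant"))
  expect_false("s_pollen" %in% members(ont, "animal"))
  # leaf with no instances
  expect_identical(members(ont, "arthropoda"), "s_beetle_on_flower")
  expect_length(members(ont, "pollen"), 1)
})

test_that("relational membership closes over the target class", {
  ont <- toy_ontology()
  # relation targets "flower", so the strain appears under "plant" too
  expect_true("s_beetle_on_flower" %in% relational_members(ont, "plant"))
  expect_true("s_beetle_on_flower" %in%
                relational_members(ont, "flower",
                                   "is_from_animal_on_plant"))
  expect_false("s_beetle_on_flower" %in%
                 relational_members(ont, "plant", "has_decay_association"))
  expect_error(relational_members(ont, "plant", "no_such_prop"),
               "unknown property")
})

test_that("closure queries agree with brute-force traversal", {
  for (seed in 1:20) {
    ont <- random_ontology(seed)
    for (cid in sample(ont$classes$id, min(15, nrow(ont$classes)))) {
      expect_identical(ancestors(ont, cid), ancestors_oracle(ont, cid))
      expect_setequal(members(ont, cid), members_oracle(ont, cid))
      expect_setequal(relational_members(ont, cid),
                      relational_members_oracle(ont, cid))
    }
  }
})

test_that("membership is monotone up the hierarchy", {
  for (seed in 21:30) {
    ont <- random_ontology(seed)
    non_roots <- ont$classes[!is.na(ont$classes$parent_id), ]
    idx <- sample(nrow(non_roots), min(20, nrow(non_roots)))
    for (i in idx) {
      expect_true(all(members(ont, non_roots$id[i]) %in%
                        members(ont, non_roots$parent_id[i])))
    }
  }
})

test_that("class size queries count closure members inclusively", {
  classes <- data.frame(
    id = c("fungal", "mushroom_fruiting_bodies"),
    parent_id = c(NA, "fungal"))
  strains <- tibble::tibble(
    id = paste0("s", 1:5),
    species = c("Candida inulinophila", "Candida morakotiae",
                "Candida smagusa", "Kodamaea fukazawae",
                "Kodamaea fungicola"),
    order = "Serinales",
    direct = replicate(5, "mushroom_fruiting_bodies", simplify = FALSE),
    relations = replicate(5, tibble::tibble(property_id = character(),
                                            target_class_id = character()),
                          simplify = FALSE),
    isolation = "mushroom fruiting body")
  ont <- eco_ontology(classes, strains = strains)
  res <- class_size_query(ont, 5, 10)
  expect_setequal(res$class_id, c("fungal", "mushroom_fruiting_bodies"))
  expect_true(all(res$n_members == 5))
  expect_identical(nrow(class_size_query(ont, 6, 10)), 0L)
  expect_error(class_size_query(ont, 10, 5), "min_count")
})

test_that("order distribution partitions strains in exclusive mode", {
  ont <- random_ontology(31, n_strains = 60)
  res <- order_distribution(ont, ont$roots, exclusive = TRUE)
  # every strain has exactly one root, so numerators sum to the order sizes
  tot <- tapply(res$numerator, res$order, sum)
  den <- tapply(res$denominator, res$order, unique)
  expect_identical(as.integer(tot), as.integer(den))
  expect_true(all(res$fraction >= 0 & res$fraction <= 1))
  # single strain, single order, one category
  one <- toy_ontology()
  res1 <- order_distribution(one, "animal", exclusive = TRUE)
  expect_identical(res1$numerator, 1L)
  expect_identical(res1$fraction, 1)
})

test_that("non-exclusive distribution can count relational connections", {
  ont <- toy_ontology()
  plain <- order_distribution(ont, "plant", exclusive = FALSE,
                              use_modifiers = FALSE)
  with_mod <- order_distribution(ont, "plant", exclusive = FALSE,
                                 use_modifiers = TRUE)
  ser_plain <- plain$numerator[plain$order == "Serinales"]
  ser_mod <- with_mod$numerator[with_mod$order == "Serinales"]
  # the beetle strain joins the plant category only through its relation
  expect_identical(ser_plain, 1L)
  expect_identical(ser_mod, 2L)
})

test_that("task labels honour relational inclusion and exclusion", {
  ont <- toy_ontology()
  plain <- class_task("plant", include_classes = "plant")
  lab <- build_labels(ont, plain)
  # insect-borne strain is not a plant member under the plain task
  expect_identical(unname(lab[c("s_pollen", "s_beetle_on_flower",
                                "s_decayed_wood")]),
                   c(1L, 0L, 1L))
  widened <- class_task("plant_or_from_plant",
                        include_classes = "plant",
                        include_relational = "is_from_animal_on_plant->plant")
  lab2 <- build_labels(ont, widened)
  expect_identical(unname(lab2["s_beetle_on_flower"]), 1L)
  revised <- class_task("plant_no_decay",
                        include_classes = "plant",
                        include_relational = "plant",
                        exclude_relational = "has_decay_association->plant")
  lab3 <- build_labels(ont, revised)
  expect_identical(unname(lab3[c("s_beetle_on_flower", "s_decayed_wood")]),
                   c(1L, 0L))
})

test_that("a task on a root containing all strains labels everything 1", {
  classes <- data.frame(id = c("r", "c1"), parent_id = c(NA, "r"))
  strains <- tibble::tibble(
    id = c("a", "b"), species = NA, order = NA,
    direct = list("c1", "r"),
    relations = replicate(2, tibble::tibble(property_id = character(),
                                            target_class_id = character()),
                          simplify = FALSE),
    isolation = NA)
  ont <- eco_ontology(classes, strains = strains)
  lab <- build_labels(ont, class_task("all", include_classes = "r"))
  expect_identical(unname(lab), c(1L, 1L))
})

test_that("labels are deterministic and order-equivariant", {
  ont <- random_ontology(44, n_strains = 40)
  task <- class_task("t", include_classes = ont$roots[1],
                     include_relational = ont$roots[1])
  lab1 <- build_labels(ont, task)
  lab2 <- build_labels(ont, task)
  expect_identical(lab1, lab2)
  perm <- sample(names(lab1))
  lab3 <- build_labels(ont, task, strain_order = perm)
  expect_identical(lab3, lab1[perm])
  expect_error(build_labels(ont, task, strain_order = perm[-1]),
               "exactly once")
})
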