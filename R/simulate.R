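DEFAULT_ROOTS <- c("animal", "plant", "environmental", "fungal",
                   "industrial_products", "victuals")

DEFAULT_ORDERS <- c("Serinales", "Saccharomycetales", "Pichiales",
                    "Phaffomycetales", "Lipomycetales", "Dipodascales")

#' Simulation configuration
#'
#' Bundles the knobs of the synthetic-study generator. Defaults emulate the
#' real study's shape: ~1000 strain instances over a ~1500-class
#' single-parent hierarchy with six exclusive roots, cross-root relational
#' assertions on a fifth of the strains, baseline KO prevalences uniform on
#' `[0.25, 0.95]` (so most KOs survive the 20% prevalence filter), and a
#' single planted KO whose carrier rate is 87% in the positive class versus
#' 66% outside it — the effect size of the study's strongest
#' animal-associated gene.
#'
#' @param n_strains Number of strain instances (>= 20).
#' @param n_kos Number of KO columns.
#' @param n_roots,depth,branching Hierarchy shape: number of root classes,
#'   levels below each root, and the per-node child-count range.
#' @param class_mixture Named numeric over roots: sampling probabilities
#'   (summing to 1) or exact per-root strain counts (summing to
#'   `n_strains`). `NULL` gives the default mixture (0.31 on the first
#'   root, 0.34 on the second, remainder split evenly).
#' @param relation_rate Probability a strain carries one cross-root
#'   relational assertion.
#' @param relational_positive_frac Fraction of strains outside the first
#'   root that are additionally given a relational assertion into it, so
#'   their positive signal is carried only relationally (exercising task
#'   redefinition).
#' @param baseline_range Range of per-KO baseline carrier prevalences.
#' @param planted Data frame (`ko_index`, `prev_pos`, `prev_neg`): KOs whose
#'   prevalence is class-conditional. Default: one KO at (0.87, 0.66).
#' @param n_pathways Number of background pathways.
#' @param planted_pathway_size Size of the pathway holding the planted KOs.
#' @param planted_in_pathway_frac Fraction of planted KOs placed in the
#'   planted pathway.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_strains = 1000, n_kos = 2000,
                       n_roots = 6, depth = 4, branching = c(3, 4),
                       class_mixture = NULL,
                       relation_rate = 0.20,
                       relational_positive_frac = 0.10,
                       baseline_range = c(0.25, 0.95),
                       planted = data.frame(ko_index = 1, prev_pos = 0.87,
                                            prev_neg = 0.66),
                       n_pathways = 40,
                       planted_pathway_size = 12,
                       planted_in_pathway_frac = 1.0) {
  stopifnot(n_strains >= 20, n_kos >= 1, n_roots >= 1, depth >= 1)
  if (nrow(planted) > 0) {
    stopifnot(all(planted$prev_pos >= 0 & planted$prev_pos <= 1),
              all(planted$prev_neg >= 0 & planted$prev_neg <= 1),
              anyDuplicated(planted$ko_index) == 0,
              nrow(planted) <= n_kos)
  }
  structure(
    list(n_strains = n_strains, n_kos = n_kos, n_roots = n_roots,
         depth = depth, branching = branching,
         class_mixture = class_mixture, relation_rate = relation_rate,
         relational_positive_frac = relational_positive_frac,
         baseline_range = baseline_range, planted = planted,
         n_pathways = n_pathways,
         planted_pathway_size = planted_pathway_size,
         planted_in_pathway_frac = planted_in_pathway_frac),
    class = "sim_config"
  )
}

#' Generate a random environment-class hierarchy
#'
#' Builds a strict forest with the configured number of roots (named after
#' the six exclusive top categories when `n_roots <= 6`), a fixed depth, and
#' a random child count per internal node. Relational properties of the
#' form `is_from_<root>_on_<root>` are declared for every ordered pair of
#' roots, plus a few modifier properties (microbe/decay/fermentation
#' associations).
#'
#' @param n_roots,depth,branching As in [sim_config()].
#' @param seed Integer seed.
#' @return An [eco_ontology()] without instances.
#' @export
generate_ontology <- function(n_roots = 6, depth = 4, branching = c(3, 4),
                              seed = 1) {
  stopifnot(n_roots >= 1, depth >= 1, all(branching >= 1))
  roots <- if (n_roots <= length(DEFAULT_ROOTS)) {
    DEFAULT_ROOTS[seq_len(n_roots)]
  } else {
    c(DEFAULT_ROOTS, paste0("root_", seq_len(n_roots - length(DEFAULT_ROOTS))))
  }
  kinds <- c("type", "part", "product")
  with_seed(seed, {
    ids <- roots
    labels <- roots
    parents <- rep(NA_character_, n_roots)
    frontier <- roots
    for (lev in seq_len(depth)) {
      nxt <- character()
      for (node in frontier) {
        n_kids <- if (length(branching) > 1) {
          sample(seq(branching[1], branching[2]), 1)
        } else {
          branching
        }
        kids <- paste0(node, "_", seq_len(n_kids))
        kid_labels <- paste0(gsub("_", " ", kids), " (",
                             sample(kinds, n_kids, replace = TRUE), ")")
        ids <- c(ids, kids)
        labels <- c(labels, kid_labels)
        parents <- c(parents, rep(node, n_kids))
        nxt <- c(nxt, kids)
      }
      frontier <- nxt
    }
    rel <- expand.grid(from = roots, to = roots, stringsAsFactors = FALSE)
    rel <- rel[rel$from != rel$to, ]
    props <- tibble::tibble(
      id = c(paste0("is_from_", rel$from, "_on_", rel$to),
             "has_microbe_association", "has_decay_association",
             "is_fermented"),
      label = c(paste("is from", rel$from, "on", rel$to),
                "has microbe association", "has decay association",
                "is fermented"),
      kind = c(rep("relational", nrow(rel)), rep("modifier", 3))
    )
    eco_ontology(
      tibble::tibble(id = ids, label = labels, parent_id = parents,
                     description = NA_character_),
      properties = props
    )
  })
}

leaf_classes <- function(ont) {
  setdiff(ont$classes$id, stats::na.omit(ont$classes$parent_id))
}

default_mixture <- function(roots) {
  n <- length(roots)
  m <- if (n >= 3) {
    c(0.31, 0.34, rep(0.35 / (n - 2), n - 2))
  } else {
    rep(1 / n, n)
  }
  stats::setNames(m / sum(m), roots)
}

#' Populate an ontology with random strain instances
#'
#' Each strain gets one leaf class sampled under a root drawn from the
#' mixture (or exactly the given per-root counts), a taxonomic order drawn
#' from six order names, and — at the configured rate — one relational
#' assertion targeting a class under a different root, using the matching
#' `is_from_<root>_on_<root>` property.
#'
#' @param ont An [eco_ontology()] without (or with) instances.
#' @param n Number of strains to add.
#' @param class_mixture Named numeric over the roots: probabilities
#'   (sum 1) or exact counts (sum `n`); `NULL` for the default mixture.
#' @param relation_rate Probability of one cross-root relational assertion.
#' @param seed Integer seed.
#' @return The ontology with `n` instances added.
#' @export
generate_strains <- function(ont, n, class_mixture = NULL,
                             relation_rate = 0.20, seed = 1) {
  roots <- ont$roots
  mix <- class_mixture %||% default_mixture(roots)
  stopifnot(setequal(names(mix), roots))
  mix <- mix[roots]
  leaves <- leaf_classes(ont)
  leaves_by_root <- lapply(roots, function(r) {
    lv <- intersect(leaves, c(r, descendants(ont, r)))
    if (length(lv) == 0) stop("root '", r, "' has no leaf classes")
    lv
  })
  names(leaves_by_root) <- roots
  with_seed(seed, {
    strain_roots <- if (sum(mix) > 1.5) {
      stopifnot(sum(mix) == n)
      sample(rep(roots, times = mix))
    } else {
      sample(roots, n, replace = TRUE, prob = mix)
    }
    direct <- vapply(strain_roots, function(r) {
      lv <- leaves_by_root[[r]]
      lv[sample.int(length(lv), 1)]
    }, character(1))
    has_rel <- stats::rbinom(n, 1, relation_rate) == 1
    relations <- lapply(seq_len(n), function(i) {
      if (!has_rel[i] || length(roots) < 2) return(empty_relations())
      other <- sample(setdiff(roots, strain_roots[i]), 1)
      targets <- c(other, descendants(ont, other))
      pid <- paste0("is_from_", strain_roots[i], "_on_", other)
      if (!pid %in% ont$properties$id) {
        pid <- ont$properties$id[ont$properties$kind == "relational"][1]
      }
      tibble::tibble(property_id = pid,
                     target_class_id = targets[sample.int(length(targets), 1)])
    })
    strains <- tibble::tibble(
      id = sprintf("strain_%04d", nrow(ont$strains) + seq_len(n)),
      species = sprintf("Synthetica species%04d", seq_len(n)),
      order = sample(DEFAULT_ORDERS, n, replace = TRUE),
      direct = lapply(direct, identity),
      relations = relations,
      isolation = paste("synthetic isolation record under", direct)
    )
    eco_ontology(ont$classes, ont$properties,
                 dplyr::bind_rows(ont$strains, strains))
  })
}

#' Generate a class-conditional KO presence/absence matrix
#'
#' Non-planted KOs carry one baseline prevalence each (drawn once per KO,
#' mirroring presence/absence as a species-level trait) applied to every
#' strain. Planted KOs use `prev_pos` for label-1 strains and `prev_neg`
#' for label-0 strains. Every KO is assigned to at least one pathway;
#' planted KOs are concentrated in a dedicated planted pathway padded with
#' random filler KOs to the configured size.
#'
#' @param labels Named binary vector (names become strain row ids).
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List with `matrix` (a [ko_matrix()]), `pathway_map` (tibble) and
#'   `ground_truth` (labels, planted KO table with true prevalences, planted
#'   pathway id).
#' @export
generate_ko_matrix <- function(labels, config = sim_config(), seed = 1) {
  labels <- as.integer(labels) |> stats::setNames(names(labels))
  n <- length(labels)
  if (is.null(names(labels))) {
    names(labels) <- sprintf("strain_%04d", seq_len(n))
  }
  p <- config$n_kos
  ko_ids <- sprintf("K%05d", seq_len(p))
  planted <- config$planted
  with_seed(seed, {
    base_prev <- stats::runif(p, config$baseline_range[1],
                              config$baseline_range[2])
    prob <- matrix(rep(base_prev, each = n), nrow = n)
    if (nrow(planted) > 0) {
      for (i in seq_len(nrow(planted))) {
        j <- planted$ko_index[i]
        prob[, j] <- ifelse(labels == 1L, planted$prev_pos[i],
                            planted$prev_neg[i])
      }
    }
    mat <- matrix(stats::rbinom(n * p, 1, prob), nrow = n,
                  dimnames = list(names(labels), ko_ids))
    # background pathways: one per KO, uniform
    pw_ids <- sprintf("pw%03d", seq_len(config$n_pathways))
    assign <- sample(pw_ids, p, replace = TRUE)
    pm <- tibble::tibble(
      ko_id = ko_ids, pathway_id = assign,
      pathway_label = paste("Pathway", sub("pw", "", assign)))
    planted_tbl <- tibble::tibble(
      ko_id = character(), prev_pos = double(), prev_neg = double())
    planted_pw <- NA_character_
    if (nrow(planted) > 0) {
      planted_ids <- ko_ids[planted$ko_index]
      planted_tbl <- tibble::tibble(ko_id = planted_ids,
                                    prev_pos = planted$prev_pos,
                                    prev_neg = planted$prev_neg)
      n_in <- max(1, round(config$planted_in_pathway_frac *
                             length(planted_ids)))
      in_pw <- planted_ids[seq_len(n_in)]
      planted_pw <- "pw_planted"
      # planted KOs live only in the planted pathway; pad with filler KOs
      # that keep their background membership too
      pm <- pm[!pm$ko_id %in% in_pw, ]
      n_fill <- max(0, config$planted_pathway_size - n_in)
      filler <- sample(setdiff(ko_ids, planted_ids),
                       min(n_fill, p - length(planted_ids)))
      pm <- dplyr::bind_rows(pm, tibble::tibble(
        ko_id = c(in_pw, filler),
        pathway_id = planted_pw,
        pathway_label = "Planted pathway"))
    }
    list(
      matrix = ko_matrix(mat),
      pathway_map = pm[order(pm$pathway_id, pm$ko_id), ],
      ground_truth = list(labels = labels, planted = planted_tbl,
                          planted_pathway_id = planted_pw)
    )
  })
}

#' Simulate a complete synthetic study
#'
#' Chains the generators: hierarchy, strain instances, ontology-derived
#' labels, and a class-conditional KO matrix with pathway map. The positive
#' class is membership (by transitive closure) in the first root — including
#' strains connected to it only relationally, a configurable fraction of
#' which is forced so that task redefinition has something to recover. The
#' labels are computed through [build_labels()], exercising the same query
#' machinery the real pipeline uses.
#'
#' @param config A [sim_config()].
#' @param seed Integer master seed.
#' @return List with `ontology`, `task` (the labelling [class_task()]),
#'   `labels`, `matrix`, `pathway_map`, `ground_truth`.
#' @export
simulate_study <- function(config = sim_config(), seed = 1) {
  ont <- generate_ontology(config$n_roots, config$depth, config$branching,
                           seed = seed)
  ont <- generate_strains(ont, config$n_strains, config$class_mixture,
                          config$relation_rate, seed = seed + 1)
  target_root <- ont$roots[1]
  # force relational-only positives: strains outside the target root that
  # carry a relation into it
  if (config$relational_positive_frac > 0) {
    direct_pos <- members(ont, target_root)
    outsiders <- setdiff(ont$strains$id, direct_pos)
    n_force <- round(config$relational_positive_frac * length(outsiders))
    if (n_force > 0) {
      forced <- with_seed(seed + 2, sample(outsiders, n_force))
      tgt_pool <- c(target_root, descendants(ont, target_root))
      st <- ont$strains
      for (sid in forced) {
        i <- which(st$id == sid)
        root_i <- root_of(ont, st$direct[[i]][1])
        pid <- paste0("is_from_", root_i, "_on_", target_root)
        if (!pid %in% ont$properties$id) {
          pid <- ont$properties$id[ont$properties$kind == "relational"][1]
        }
        tgt <- with_seed(seed + 2 + i,
                         tgt_pool[sample.int(length(tgt_pool), 1)])
        st$relations[[i]] <- dplyr::bind_rows(
          st$relations[[i]],
          tibble::tibble(property_id = pid, target_class_id = tgt))
      }
      ont <- eco_ontology(ont$classes, ont$properties, st)
    }
  }
  task <- class_task(paste0(target_root, "_associated"),
                     include_classes = target_root,
                     include_relational = target_root)
  labels <- build_labels(ont, task)
  km <- generate_ko_matrix(labels, config, seed = seed + 3)
  list(ontology = ont, task = task, labels = labels,
       matrix = km$matrix, pathway_map = km$pathway_map,
       ground_truth = km$ground_truth)
}

#' Write a simulated study bundle to disk
#'
#' Emits the OWL file, the TSV assignment dialect (strains, classes,
#' properties), the KO matrix TSV, the pathway map TSV, and a ground-truth
#' JSON.
#'
#' @param bundle A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_owl(bundle$ontology, file.path(dir, "ontology.owl"))
  write_assignments_tsv(bundle$ontology,
                        file.path(dir, "strains.tsv"),
                        file.path(dir, "classes.tsv"),
                        file.path(dir, "properties.tsv"))
  write_ko_table(bundle$matrix, file.path(dir, "ko_matrix.tsv"))
  readr::write_tsv(bundle$pathway_map, file.path(dir, "pathway_map.tsv"))
  gt <- bundle$ground_truth
  jsonlite::write_json(
    list(labels = as.list(gt$labels),
         planted = gt$planted,
         planted_pathway_id = gt$planted_pathway_id),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
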