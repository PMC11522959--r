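#' Pipeline configuration
#'
#' Houses the fixed constants of the genotype-to-ecology protocol: the 20%
#' prevalence filter, the 20% test withholding, 100 model iterations, the
#' top-1000-in-80%-of-models consensus rule, and the BH significance level.
#' Scale-sensitive values (iterations, `top_k`) can be reduced for smaller
#' simulated studies.
#'
#' @param prevalence_threshold Minimum KO presence fraction.
#' @param test_fraction Withheld test fraction per iteration.
#' @param n_iterations Forest iterations.
#' @param top_k Per-iteration top-importance set size.
#' @param consensus_frac Minimum fraction of iterations for consensus.
#' @param bh_alpha Significance level on BH-adjusted enrichment p-values.
#' @param num_trees Trees per forest.
#' @param min_pathway_size Minimum in-universe pathway size to test.
#' @param tune Run the two-stage grid search before iterating; if `FALSE`,
#'   `mtry`/`min_n` defaults (`round(sqrt(p))`, 5) are used.
#' @param importance_mode `"oob"` or `"test"` (see [fit_iteration()]).
#' @param rebalance_each Fresh balanced set per iteration.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(prevalence_threshold = 0.20,
                            test_fraction = 0.20,
                            n_iterations = 100,
                            top_k = 1000,
                            consensus_frac = 0.80,
                            bh_alpha = 0.05,
                            num_trees = 500,
                            min_pathway_size = 3,
                            tune = TRUE,
                            importance_mode = "oob",
                            rebalance_each = TRUE,
                            seed = 1) {
  stopifnot(prevalence_threshold >= 0, prevalence_threshold <= 1,
            test_fraction > 0, test_fraction < 1,
            n_iterations >= 1, top_k >= 1,
            consensus_frac > 0, consensus_frac <= 1,
            bh_alpha > 0, bh_alpha <= 1)
  structure(
    list(prevalence_threshold = prevalence_threshold,
         test_fraction = test_fraction, n_iterations = n_iterations,
         top_k = top_k, consensus_frac = consensus_frac,
         bh_alpha = bh_alpha, num_trees = num_trees,
         min_pathway_size = min_pathway_size, tune = tune,
         importance_mode = importance_mode,
         rebalance_each = rebalance_each, seed = seed),
    class = "pipeline_config"
  )
}

#' Read / write a pipeline configuration as YAML
#'
#' The round trip is lossless: `read_pipeline_config(write_pipeline_config(
#' cfg, f))` equals `cfg`.
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return The configuration (read) or `path` invisibly (write).
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

check_id_alignment <- function(ont, mat) {
  missing <- setdiff(ont$strains$id, rownames(mat))
  if (length(missing) > 0) {
    stop("ontology instance(s) absent from the KO matrix: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) sprintf(" (and %d more)",
                                           length(missing) - 10))
  }
  invisible(TRUE)
}

#' Run one classification task end to end
#'
#' Labels the strains with [build_labels()], filters low-prevalence KOs,
#' optionally tunes the forest, runs the repeated balanced-forest protocol,
#' derives the consensus KO set, re-analyzes the consensus KOs with Fisher
#' exact tests, performs pathway over-representation (after dropping
#' yeast-restricted pathways), and audits consistently misclassified
#' strains. When `out_dir` is given, all tables are written as TSV together
#' with a JSON run manifest.
#'
#' @param ont An [eco_ontology()] with instances.
#' @param mat A [ko_matrix()] covering all instances.
#' @param task A [class_task()].
#' @param config A [pipeline_config()].
#' @param pathway_map Optional pathway map tibble for enrichment.
#' @param out_dir Optional output directory.
#' @return A `task_result` list: `task`, `labels`, `tuning`, `run`,
#'   `consensus`, `association`, `enrichment`, `audit`, `config`.
#' @export
run_task <- function(ont, mat, task, config = pipeline_config(),
                     pathway_map = NULL, out_dir = NULL) {
  check_id_alignment(ont, mat)
  labels <- build_labels(ont, task)
  X <- unclass(mat)[names(labels), , drop = FALSE]
  Xf <- filter_low_prevalence(ko_matrix(X), config$prevalence_threshold)
  p <- ncol(Xf)
  tuning <- NULL
  if (isTRUE(config$tune)) {
    bal <- balance_downsample(labels, config$seed)
    tuning <- tune_forest(unclass(Xf)[bal, , drop = FALSE], labels[bal],
                          tune_config(num_trees = config$num_trees),
                          seed = config$seed)
    params <- list(mtry = tuning$mtry, min_n = tuning$min_n,
                   num_trees = config$num_trees)
  } else {
    params <- list(mtry = max(1, round(sqrt(p))), min_n = 5,
                   num_trees = config$num_trees)
  }
  run <- run_iterations(unclass(Xf), labels, params,
                        n_iterations = config$n_iterations,
                        test_fraction = config$test_fraction,
                        base_seed = config$seed,
                        rebalance_each = config$rebalance_each,
                        importance_mode = config$importance_mode)
  consensus <- consensus_importance(run, top_k = config$top_k,
                                    min_frac = config$consensus_frac)
  sel <- consensus$ko_id[consensus$consensus]
  assoc <- ko_association_table(
    Xf, labels, ko_ids = sel,
    importance = stats::setNames(consensus$median_importance,
                                 consensus$ko_id))
  enrich <- NULL
  if (!is.null(pathway_map) && length(sel) > 0) {
    pm <- filter_yeast_pathways(pathway_map)
    enrich <- pathway_enrichment(sel, colnames(Xf), pm,
                                 min_size = config$min_pathway_size)
  }
  audit <- misclassification_audit(run)
  result <- structure(
    list(task = task, labels = labels, tuning = tuning, run = run,
         consensus = consensus, association = assoc, enrichment = enrich,
         audit = audit, config = config),
    class = "task_result"
  )
  if (!is.null(out_dir)) write_task_result(result, out_dir)
  result
}

#' @export
print.task_result <- function(x, ...) {
  g <- glance(x$run)
  cat("<task_result> '", x$task$name, "': ",
      sum(x$labels == 1), " positive / ", sum(x$labels == 0),
      " negative strains\n", sep = "")
  cat("  mean AUC ", sprintf("%.3f", g$mean_auc), " over ",
      g$n_iterations, " iterations; ",
      sum(x$consensus$consensus), " consensus KO(s)\n", sep = "")
  invisible(x)
}

fmt_num <- function(x) {
  ifelse(is.na(x), NA_character_, formatC(x, digits = 6, format = "g"))
}

#' Write all tables of a task result
#'
#' Emits per-iteration metrics, the strain-by-iteration prediction table,
#' the KO-by-iteration importance table, the consensus report, the
#' Fisher-association report (percent presences rounded to integers, as in
#' the study's figure), the enrichment table, the misclassification audit,
#' and a JSON manifest with seeds and configuration.
#'
#' @param result A `task_result`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_task_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(out_dir, f)
  readr::write_tsv(tidy(result$run), out("iteration_metrics.tsv"))
  preds <- dplyr::bind_rows(lapply(result$run$iterations, function(it) {
    dplyr::mutate(it$predictions, iteration = it$iteration)
  }))
  readr::write_tsv(preds, out("predictions.tsv"))
  imp <- importance_matrix(result$run)
  imp_df <- tibble::as_tibble(imp, rownames = "ko_id",
                              .name_repair = ~ c(sprintf(
                                "iter_%03d", seq_along(.x))))
  names(imp_df)[1] <- "ko_id"
  readr::write_tsv(imp_df, out("importance.tsv"))
  readr::write_tsv(tibble::as_tibble(result$consensus), out("consensus.tsv"))
  assoc <- tibble::as_tibble(result$association)
  assoc$pct_in_class <- round(assoc$pct_in_class)
  assoc$pct_out_class <- round(assoc$pct_out_class)
  readr::write_tsv(assoc, out("association.tsv"))
  if (!is.null(result$enrichment)) {
    readr::write_tsv(tibble::as_tibble(result$enrichment),
                     out("enrichment.tsv"))
  }
  readr::write_tsv(result$audit$per_strain, out("audit.tsv"))
  cfg <- unclass(result$config)
  manifest <- list(
    task = result$task$name,
    config = cfg,
    n_positive = sum(result$labels == 1),
    n_negative = sum(result$labels == 0),
    params = result$run$params,
    iteration_seeds = vapply(result$run$iterations, `[[`, numeric(1),
                             "seed"),
    config_hash = rlang::hash(cfg)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}

#' Compare a task against a redefined variant
#'
#' Runs both tasks and reports which strains flipped label — widened in by a
#' relational inclusion, or dropped by an exclusion term — together with the
#' paired change in mean test AUC. This is the redefinition workflow that
#' turned "member of the plant class" into "plant member or 'from plant'
#' relational value, minus decay-associated strains".
#'
#' @param ont,mat,config,pathway_map,out_dir As in [run_task()].
#' @param base_task,revised_task Two [class_task()]s.
#' @return A `redefinition_result`: both `task_result`s, the flip table, and
#'   the mean-AUC change.
#' @export
run_redefinition <- function(ont, mat, base_task, revised_task,
                             config = pipeline_config(),
                             pathway_map = NULL, out_dir = NULL) {
  base_labels <- build_labels(ont, base_task)
  revised_labels <- build_labels(ont, revised_task)
  if (identical(unname(base_labels), unname(revised_labels))) {
    warning("the two tasks label every strain identically")
  }
  base <- run_task(ont, mat, base_task, config, pathway_map)
  revised <- run_task(ont, mat, revised_task, config, pathway_map)
  flips <- tibble::tibble(
    strain = names(base_labels),
    base_label = as.integer(base_labels),
    revised_label = as.integer(revised_labels)
  )
  flips <- flips[flips$base_label != flips$revised_label, ]
  flips$reason <- ifelse(flips$revised_label == 1,
                         "included by revised task",
                         "excluded by revised task")
  delta <- glance(revised$run)$mean_auc - glance(base$run)$mean_auc
  result <- structure(
    list(base = base, revised = revised, flips = flips,
         mean_auc_base = glance(base$run)$mean_auc,
         mean_auc_revised = glance(revised$run)$mean_auc,
         mean_auc_change = delta),
    class = "redefinition_result"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_task_result(base, file.path(out_dir, "base"))
    write_task_result(revised, file.path(out_dir, "revised"))
    readr::write_tsv(flips, file.path(out_dir, "label_flips.tsv"))
  }
  result
}

#' @export
print.redefinition_result <- function(x, ...) {
  cat("<redefinition_result> ", nrow(x$flips), " label flip(s); mean AUC ",
      sprintf("%.3f", x$mean_auc_base), " -> ",
      sprintf("%.3f", x$mean_auc_revised), "\n", sep = "")
  invisible(x)
}

#' Tabular ontology queries
#'
#' One entry point for the interrogation queries: closure members of a
#' class, relational members, classes within a membership-size range, and
#' order-by-category distributions. Always returns a tibble with a stable
#' column order, suitable for printing or TSV export.
#'
#' @param ont An [eco_ontology()].
#' @param type One of `"members"`, `"relational_members"`, `"class_size"`,
#'   `"order_distribution"`.
#' @param class_id Class id for the membership queries.
#' @param property_id Optional property filter for relational membership.
#' @param min_count,max_count Bounds for the class-size query.
#' @param categories,exclusive,use_modifiers For the distribution query
#'   (see [order_distribution()]).
#' @return A tibble.
#' @export
query_ontology <- function(ont,
                           type = c("members", "relational_members",
                                    "class_size", "order_distribution"),
                           class_id = NULL, property_id = NULL,
                           min_count = NULL, max_count = NULL,
                           categories = NULL, exclusive = TRUE,
                           use_modifiers = FALSE) {
  type <- match.arg(type)
  suggest <- function(cid) {
    if (!is.null(cid) && !cid %in% ont$classes$id) {
      near <- utils::head(ont$classes$id[
        order(utils::adist(cid, ont$classes$id))], 3)
      stop("unknown class '", cid, "'; nearest ids: ",
           paste(near, collapse = ", "))
    }
  }
  switch(type,
    members = {
      suggest(class_id)
      ids <- members(ont, class_id)
      st <- ont$strains[ont$strains$id %in% ids, ]
      tibble::tibble(strain_id = st$id, species = st$species,
                     order = st$order, class_id = class_id)
    },
    relational_members = {
      suggest(class_id)
      ids <- relational_members(ont, class_id, property_id)
      st <- ont$strains[ont$strains$id %in% ids, ]
      tibble::tibble(strain_id = st$id, species = st$species,
                     order = st$order, target_class_id = class_id)
    },
    class_size = class_size_query(ont, min_count, max_count),
    order_distribution = {
      for (cid in categories) suggest(cid)
      order_distribution(ont, categories, exclusive = exclusive,
                         use_modifiers = use_modifiers)
    })
}
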