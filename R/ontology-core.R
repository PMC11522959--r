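#' Construct an isolation-environment ontology
#'
#' An `eco_ontology` bundles three tables: a class hierarchy (a strict forest:
#' every non-root class has exactly one parent), a set of property definitions
#' (relational properties link a strain's primary environment to a secondary
#' one, e.g. "is from animal on plant"; modifier properties annotate an
#' environment, e.g. "has microbe association"), and strain instances. Each
#' strain carries a non-empty set of *direct* classes — the most specific
#' class(es) describing the immediate isolation environment — plus optional
#' relational assertions. Memberships in ancestor classes are always derived
#' by transitive closure, never stored.
#'
#' @param classes Data frame with columns `id`, `label`, `parent_id`
#'   (`NA` for root classes) and optionally `description`.
#' @param properties Data frame with columns `id`, `label`, `kind`
#'   (`"relational"` or `"modifier"`). May be empty.
#' @param strains Data frame with columns `id`, `species`, `order`,
#'   `direct` (list column of character vectors of class ids),
#'   `relations` (list column of data frames with columns `property_id`,
#'   `target_class_id`) and `isolation` (free text). May be empty.
#' @param roots Optional character vector fixing the display order of root
#'   classes; defaults to the roots in `classes` order.
#'
#' @return An object of class `eco_ontology`.
#' @examples
#' ont <- eco_ontology(
#'   classes = data.frame(
#'     id = c("plant", "flower", "pollen"),
#'     label = c("Plant", "Flower", "Pollen"),
#'     parent_id = c(NA, "plant", "flower")
#'   )
#' )
#' ancestors(ont, "pollen")
#' @export
eco_ontology <- function(classes,
                         properties = empty_properties(),
                         strains = empty_strains(),
                         roots = NULL) {
  classes <- as_class_table(classes)
  properties <- as_property_table(properties)
  strains <- as_strain_table(strains)
  if (is.null(roots)) {
    roots <- classes$id[is.na(classes$parent_id)]
  }
  ont <- structure(
    list(classes = classes, properties = properties,
         strains = strains, roots = roots),
    class = "eco_ontology"
  )
  validate_ontology(ont)
}

empty_properties <- function() {
  tibble::tibble(id = character(), label = character(), kind = character())
}

empty_strains <- function() {
  tibble::tibble(
    id = character(), species = character(), order = character(),
    direct = list(), relations = list(), isolation = character()
  )
}

empty_relations <- function() {
  tibble::tibble(property_id = character(), target_class_id = character())
}

as_class_table <- function(x) {
  x <- tibble::as_tibble(x)
  stopifnot(all(c("id", "parent_id") %in% names(x)))
  if (!"label" %in% names(x)) x$label <- x$id
  if (!"description" %in% names(x)) x$description <- NA_character_
  x$id <- trimws(as.character(x$id))
  x$label <- as.character(x$label)
  x$parent_id <- trimws(as.character(x$parent_id))
  x$parent_id[x$parent_id %in% c("", "NA")] <- NA_character_
  x$description <- as.character(x$description)
  x[, c("id", "label", "parent_id", "description")]
}

as_property_table <- function(x) {
  x <- tibble::as_tibble(x)
  if (nrow(x) == 0 && !all(c("id", "label", "kind") %in% names(x))) {
    return(empty_properties())
  }
  stopifnot(all(c("id", "kind") %in% names(x)))
  if (!"label" %in% names(x)) x$label <- x$id
  x$id <- trimws(as.character(x$id))
  x[, c("id", "label", "kind")]
}

as_strain_table <- function(x) {
  x <- tibble::as_tibble(x)
  if (nrow(x) == 0) return(empty_strains())
  stopifnot(all(c("id", "direct") %in% names(x)))
  for (col in c("species", "order", "isolation")) {
    if (!col %in% names(x)) x[[col]] <- NA_character_
  }
  if (!"relations" %in% names(x)) {
    x$relations <- replicate(nrow(x), empty_relations(), simplify = FALSE)
  }
  x$id <- trimws(as.character(x$id))
  x$direct <- lapply(x$direct, function(d) trimws(as.character(d)))
  x$relations <- lapply(x$relations, function(r) {
    r <- tibble::as_tibble(r)
    if (nrow(r) == 0) return(empty_relations())
    r$property_id <- trimws(as.character(r$property_id))
    r$target_class_id <- trimws(as.character(r$target_class_id))
    r[, c("property_id", "target_class_id")]
  })
  x[, c("id", "species", "order", "direct", "relations", "isolation")]
}

#' Validate an ontology's structural invariants
#'
#' Checks id uniqueness, parent resolution, acyclicity of the class forest,
#' property kinds, and that every strain has at least one direct class with
#' all referenced class/property ids resolving. Called by [eco_ontology()];
#' exported so that externally built or deserialized objects can be re-checked.
#'
#' @param ont An `eco_ontology`.
#' @return `ont`, invisibly unchanged, or an error describing the violation.
#' @export
validate_ontology <- function(ont) {
  cls <- ont$classes
  dup <- cls$id[duplicated(cls$id)]
  if (length(dup) > 0) {
    stop("duplicate class id(s): ", paste(unique(dup), collapse = ", "))
  }
  bad_parent <- setdiff(stats::na.omit(cls$parent_id), cls$id)
  if (length(bad_parent) > 0) {
    stop("parent id(s) not declared as classes: ",
         paste(bad_parent, collapse = ", "))
  }
  # acyclicity: follow parent links; a cycle never reaches a root
  parent <- stats::setNames(cls$parent_id, cls$id)
  for (id in cls$id) {
    seen <- character()
    cur <- id
    while (!is.na(parent[[cur]])) {
      if (cur %in% seen) stop("cycle in class hierarchy at: ", cur)
      seen <- c(seen, cur)
      cur <- parent[[cur]]
    }
  }
  if (length(ont$roots) > 0) {
    if (!setequal(ont$roots, cls$id[is.na(cls$parent_id)])) {
      stop("declared roots do not match parentless classes")
    }
  }
  props <- ont$properties
  if (any(duplicated(props$id))) {
    stop("duplicate property id(s): ",
         paste(unique(props$id[duplicated(props$id)]), collapse = ", "))
  }
  bad_kind <- setdiff(props$kind, c("relational", "modifier"))
  if (length(bad_kind) > 0) {
    stop("property kind must be 'relational' or 'modifier', got: ",
         paste(bad_kind, collapse = ", "))
  }
  st <- ont$strains
  if (any(duplicated(st$id))) {
    stop("duplicate strain id(s): ",
         paste(unique(st$id[duplicated(st$id)]), collapse = ", "))
  }
  for (i in seq_len(nrow(st))) {
    d <- st$direct[[i]]
    if (length(d) == 0) {
      stop("strain '", st$id[i], "' has no direct class")
    }
    missing <- setdiff(d, cls$id)
    if (length(missing) > 0) {
      stop("strain '", st$id[i], "' references unknown class(es): ",
           paste(missing, collapse = ", "))
    }
    r <- st$relations[[i]]
    if (nrow(r) > 0) {
      mp <- setdiff(r$property_id, props$id)
      if (length(mp) > 0) {
        stop("strain '", st$id[i], "' uses unknown property: ",
             paste(mp, collapse = ", "))
      }
      mt <- setdiff(r$target_class_id, cls$id)
      if (length(mt) > 0) {
        stop("strain '", st$id[i], "' relation targets unknown class: ",
             paste(mt, collapse = ", "))
      }
    }
  }
  invisible(ont)
}

#' @export
print.eco_ontology <- function(x, ...) {
  cat("<eco_ontology>\n")
  cat("  classes:    ", nrow(x$classes),
      " (", length(x$roots), " roots)\n", sep = "")
  cat("  properties: ", nrow(x$properties), "\n", sep = "")
  cat("  instances:  ", nrow(x$strains), "\n", sep = "")
  invisible(x)
}

#' Summary census of an ontology
#'
#' @param object An `eco_ontology`.
#' @param ... Unused.
#' @return A one-row tibble with the numbers of classes, root classes, object
#'   properties (by kind) and strain instances.
#' @export
glance.eco_ontology <- function(object, ...) {
  tibble::tibble(
    n_classes = nrow(object$classes),
    n_roots = length(object$roots),
    n_properties = nrow(object$properties),
    n_relational = sum(object$properties$kind == "relational"),
    n_modifier = sum(object$properties$kind == "modifier"),
    n_instances = nrow(object$strains)
  )
}

parent_lookup <- function(ont) {
  stats::setNames(ont$classes$parent_id, ont$classes$id)
}

check_class <- function(ont, class_id) {
  if (!class_id %in% ont$classes$id) {
    stop("unknown class id: '", class_id, "'")
  }
  invisible(class_id)
}

#' Ancestors of a class, root first
#'
#' Follows the single-parent subclass chain upward, e.g. pollen is a subclass
#' of flower, itself a subclass of plant parts, under the plant root.
#'
#' @param ont An `eco_ontology`.
#' @param class_id A class id present in the ontology.
#' @return Character vector of ancestor ids ordered root first; excludes
#'   `class_id` itself; empty for a root.
#' @export
ancestors <- function(ont, class_id) {
  check_class(ont, class_id)
  parent <- parent_lookup(ont)
  out <- character()
  cur <- parent[[class_id]]
  while (!is.na(cur)) {
    out <- c(cur, out)
    cur <- parent[[cur]]
  }
  out
}

#' All descendants of a class (excluding the class itself)
#' @noRd
descendants <- function(ont, class_id) {
  kids <- split(ont$classes$id, ont$classes$parent_id)
  out <- character()
  frontier <- kids[[class_id]]
  while (length(frontier) > 0) {
    out <- c(out, frontier)
    frontier <- unlist(kids[frontier], use.names = FALSE)
  }
  out
}

#' Strains belonging to a class under closure semantics
#'
#' A strain is a member of a class if one of its direct classes is that class
#' or any of its subclasses, so membership is monotone up the hierarchy and a
#' strain placed on "Angiosperm" is counted in both "Angiosperm" and "Plant".
#'
#' @param ont An `eco_ontology`.
#' @param class_id A class id.
#' @return Character vector of member strain ids (ontology order).
#' @export
members <- function(ont, class_id) {
  check_class(ont, class_id)
  closure <- c(class_id, descendants(ont, class_id))
  keep <- vapply(ont$strains$direct,
                 function(d) any(d %in% closure), logical(1))
  ont$strains$id[keep]
}

#' Strains connected to a class by a relational assertion
#'
#' Closure applies to the *target* of the relation: a strain related to
#' "beetle" counts as relationally connected to "animal". Optionally restrict
#' to a single property.
#'
#' @param ont An `eco_ontology`.
#' @param target_class_id Class id the relation should point into.
#' @param property_id Optional property id filter; `NULL` (default) accepts
#'   any property.
#' @return Character vector of strain ids.
#' @export
relational_members <- function(ont, target_class_id, property_id = NULL) {
  check_class(ont, target_class_id)
  if (!is.null(property_id) && !property_id %in% ont$properties$id) {
    stop("unknown property id: '", property_id, "'")
  }
  closure <- c(target_class_id, descendants(ont, target_class_id))
  keep <- vapply(ont$strains$relations, function(r) {
    if (nrow(r) == 0) return(FALSE)
    if (!is.null(property_id)) r <- r[r$property_id == property_id, ]
    any(r$target_class_id %in% closure)
  }, logical(1))
  ont$strains$id[keep]
}

#' Classes whose closure membership count lies in a range
#'
#' @param ont An `eco_ontology`.
#' @param min_count,max_count Inclusive bounds on the number of member
#'   strains (closure semantics).
#' @return Tibble with columns `class_id`, `label`, `n_members`, sorted by
#'   decreasing size then id.
#' @export
class_size_query <- function(ont, min_count, max_count) {
  if (min_count > max_count) stop("min_count must be <= max_count")
  n <- vapply(ont$classes$id, function(cid) length(members(ont, cid)),
              integer(1))
  keep <- n >= min_count & n <= max_count
  out <- tibble::tibble(
    class_id = ont$classes$id[keep],
    label = ont$classes$label[keep],
    n_members = unname(n[keep])
  )
  out[order(-out$n_members, out$class_id), ]
}

root_of <- function(ont, class_id) {
  a <- ancestors(ont, class_id)
  if (length(a) == 0) class_id else a[[1]]
}

#' Distribution of taxonomic orders across environment categories
#'
#' Cross-tabulates strain taxonomic orders against a chosen set of ontology
#' categories. Two counting modes are offered. In exclusive mode each strain
#' is counted at most once, through the category (if any) containing its
#' direct classes; the denominator is the number of strains of the order that
#' fall in any of the given categories. In non-exclusive mode a strain counts
#' for every category it belongs to by closure — and, when
#' `use_modifiers = TRUE`, also by relational assertion — and the denominator
#' is the full order size.
#'
#' @param ont An `eco_ontology`.
#' @param category_class_ids Character vector of category class ids.
#' @param exclusive Count each strain in at most one category (default
#'   `TRUE`).
#' @param use_modifiers In non-exclusive mode, also count relational
#'   connections into each category.
#' @return Tibble with columns `order`, `category`, `numerator`,
#'   `denominator`, `fraction`.
#' @export
order_distribution <- function(ont, category_class_ids,
                               exclusive = TRUE, use_modifiers = FALSE) {
  for (cid in category_class_ids) check_class(ont, cid)
  st <- ont$strains
  if (nrow(st) == 0) {
    return(tibble::tibble(order = character(), category = character(),
                          numerator = integer(), denominator = integer(),
                          fraction = double()))
  }
  member_sets <- lapply(category_class_ids, function(cid) members(ont, cid))
  names(member_sets) <- category_class_ids
  if (exclusive) {
    # assign each strain to the first category containing it (categories are
    # expected to be disjoint subtrees, e.g. the six roots)
    assigned <- rep(NA_character_, nrow(st))
    for (cid in category_class_ids) {
      hit <- st$id %in% member_sets[[cid]] & is.na(assigned)
      assigned[hit] <- cid
    }
    df <- tibble::tibble(order = st$order, category = assigned)
    df <- df[!is.na(df$category), ]
    denom <- table(df$order)
    counts <- as.data.frame(table(df$order, df$category),
                            stringsAsFactors = FALSE)
    names(counts) <- c("order", "category", "numerator")
    counts$denominator <- as.integer(denom[counts$order])
  } else {
    if (use_modifiers) {
      rel_sets <- lapply(category_class_ids,
                         function(cid) relational_members(ont, cid))
      names(rel_sets) <- category_class_ids
      member_sets <- lapply(category_class_ids, function(cid) {
        union(member_sets[[cid]], rel_sets[[cid]])
      })
      names(member_sets) <- category_class_ids
    }
    denom <- table(st$order)
    grid <- expand.grid(order = names(denom), category = category_class_ids,
                        stringsAsFactors = FALSE)
    grid$numerator <- mapply(function(o, cid) {
      sum(st$order == o & st$id %in% member_sets[[cid]])
    }, grid$order, grid$category)
    grid$denominator <- as.integer(denom[grid$order])
    counts <- grid
  }
  counts$numerator <- as.integer(counts$numerator)
  counts$fraction <- counts$numerator / counts$denominator
  out <- tibble::as_tibble(counts)
  out[order(out$order, out$category), ]
}

#' Define a classification task over the ontology
#'
#' A task names the strains to label positive: members (closure semantics) of
#' any include class, plus relational members of any include relation, minus
#' members/relational members of the exclude terms. This is how, for
#' instance, "plant-associated" can be widened to strains carrying a
#' "from plant" relational value while dropping decayed-substrate strains.
#'
#' @param name Task name.
#' @param include_classes Character vector of class ids (non-empty together
#'   with `include_relational`).
#' @param include_relational,exclude_relational Relation terms: character
#'   vector, each element either `"property_id->target_class_id"` or a bare
#'   target class id (any property).
#' @param exclude_classes Character vector of class ids.
#' @return A `class_task` object.
#' @export
class_task <- function(name, include_classes = character(),
                       include_relational = character(),
                       exclude_classes = character(),
                       exclude_relational = character()) {
  if (length(include_classes) == 0 && length(include_relational) == 0) {
    stop("a task needs at least one include term")
  }
  structure(
    list(name = name,
         include_classes = include_classes,
         include_relational = parse_rel_terms(include_relational),
         exclude_classes = exclude_classes,
         exclude_relational = parse_rel_terms(exclude_relational)),
    class = "class_task"
  )
}

parse_rel_terms <- function(x) {
  if (length(x) == 0) return(empty_relations())
  parts <- strsplit(x, "->", fixed = TRUE)
  tibble::tibble(
    property_id = vapply(parts, function(p) {
      if (length(p) == 2) p[[1]] else NA_character_
    }, character(1)),
    target_class_id = vapply(parts, function(p) p[[length(p)]], character(1))
  )
}

task_member_set <- function(ont, classes, rel) {
  ids <- character()
  for (cid in classes) ids <- union(ids, members(ont, cid))
  if (nrow(rel) > 0) {
    for (i in seq_len(nrow(rel))) {
      pid <- rel$property_id[i]
      ids <- union(ids, relational_members(
        ont, rel$target_class_id[i],
        property_id = if (is.na(pid)) NULL else pid))
    }
  }
  ids
}

#' Binary labels for a classification task
#'
#' @param ont An `eco_ontology`.
#' @param task A [class_task()].
#' @param strain_order Character vector of strain ids defining the output
#'   order; defaults to the ontology's instance order and must cover every
#'   instance exactly once.
#' @return Named integer vector of 0/1 labels in `strain_order`.
#' @export
build_labels <- function(ont, task, strain_order = NULL) {
  stopifnot(inherits(task, "class_task"))
  if (is.null(strain_order)) strain_order <- ont$strains$id
  if (!setequal(strain_order, ont$strains$id) ||
      anyDuplicated(strain_order) > 0) {
    stop("strain_order must cover every ontology instance exactly once")
  }
  for (cid in c(task$include_classes, task$exclude_classes)) {
    check_class(ont, cid)
  }
  inc <- task_member_set(ont, task$include_classes, task$include_relational)
  exc <- task_member_set(ont, task$exclude_classes, task$exclude_relational)
  lab <- as.integer(strain_order %in% setdiff(inc, exc))
  stats::setNames(lab, strain_order)
}
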