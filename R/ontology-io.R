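IRI_BASE <- "http://yeastenv.org/ontology#"
NS_RDF <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
NS_RDFS <- "http://www.w3.org/2000/01/rdf-schema#"
NS_OWL <- "http://www.w3.org/2002/07/owl#"
NS_YE <- "http://yeastenv.org/terms#"

iri_local <- function(iri) {
  # fragment after '#', else after the last '/'
  sub(".*[#/]", "", iri)
}

xattr <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  v
}

#' Read an ontology from an OWL (RDF/XML) file
#'
#' Supports the OWL subset used for isolation-environment ontologies: named
#' classes with a single `rdfs:subClassOf` axiom each, object properties, and
#' named individuals (strains) typed by their direct classes and linked to
#' secondary environments through object-property assertions. Unknown
#' constructs (anonymous restriction axioms, equivalence axioms) are reported
#' with a warning rather than silently dropped; a class with more than one
#' named parent is an error, since the hierarchy is a strict forest.
#'
#' @param path Path to an RDF/XML file.
#' @return A validated [eco_ontology()].
#' @export
parse_owl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("OWL parse failure: ",
                                           conditionMessage(e)))
  ns <- c(rdf = NS_RDF, rdfs = NS_RDFS, owl = NS_OWL, ye = NS_YE)

  unknown <- character()

  cls_nodes <- xml2::xml_find_all(doc, ".//owl:Class[@rdf:about]", ns)
  classes <- purrr::map_dfr(cls_nodes, function(node) {
    id <- iri_local(xattr(node, "about"))
    sub_nodes <- xml2::xml_find_all(node, "./rdfs:subClassOf", ns)
    parents <- character()
    for (sn in sub_nodes) {
      res <- xattr(sn, "resource")
      if (is.na(res)) {
        unknown <<- c(unknown,
                      paste0("anonymous subClassOf axiom on class '", id, "'"))
      } else {
        parents <- c(parents, iri_local(res))
      }
    }
    parents <- unique(parents)
    if (length(parents) > 1) {
      stop("class '", id, "' has multiple parents (",
           paste(parents, collapse = ", "),
           "): the hierarchy must be a strict forest")
    }
    lab <- xml2::xml_text(xml2::xml_find_first(node, "./rdfs:label", ns))
    desc <- xml2::xml_text(xml2::xml_find_first(node, "./rdfs:comment", ns))
    other <- xml2::xml_find_all(
      node, "./*[not(self::rdfs:subClassOf or self::rdfs:label or self::rdfs:comment)]", ns)
    if (length(other) > 0) {
      unknown <<- c(unknown, paste0("construct(s) on class '", id, "': ",
                                    paste(unique(xml2::xml_name(other)),
                                          collapse = ", ")))
    }
    tibble::tibble(
      id = id,
      label = ifelse(is.na(lab), id, lab),
      parent_id = if (length(parents) == 1) parents else NA_character_,
      description = desc
    )
  })

  prop_nodes <- xml2::xml_find_all(doc, ".//owl:ObjectProperty[@rdf:about]", ns)
  properties <- purrr::map_dfr(prop_nodes, function(node) {
    id <- iri_local(xattr(node, "about"))
    lab <- xml2::xml_text(xml2::xml_find_first(node, "./rdfs:label", ns))
    kind <- xml2::xml_text(xml2::xml_find_first(node, "./ye:propertyKind", ns))
    tibble::tibble(
      id = id,
      label = ifelse(is.na(lab), id, lab),
      kind = ifelse(is.na(kind), "relational", kind)
    )
  })
  if (nrow(properties) == 0) properties <- empty_properties()

  ind_nodes <- xml2::xml_find_all(doc, ".//owl:NamedIndividual[@rdf:about]", ns)
  strains <- purrr::map_dfr(ind_nodes, function(node) {
    id <- iri_local(xattr(node, "about"))
    types <- xml2::xml_find_all(node, "./rdf:type[@rdf:resource]", ns)
    direct <- setdiff(iri_local(xml2::xml_attr(types, "resource")),
                      "NamedIndividual")
    species <- xml2::xml_text(
      xml2::xml_find_first(node, "./ye:speciesName", ns))
    ord <- xml2::xml_text(xml2::xml_find_first(node, "./ye:taxonOrder", ns))
    iso <- xml2::xml_text(
      xml2::xml_find_first(node, "./ye:isolationText", ns))
    rel_nodes <- xml2::xml_find_all(
      node,
      paste0("./*[@rdf:resource and not(self::rdf:type)",
             " and not(self::ye:speciesName) and not(self::ye:taxonOrder)",
             " and not(self::ye:isolationText)]"),
      ns)
    rel <- if (length(rel_nodes) > 0) {
      tibble::tibble(
        property_id = xml2::xml_name(rel_nodes),
        target_class_id = iri_local(xml2::xml_attr(rel_nodes, "resource"))
      )
    } else {
      empty_relations()
    }
    tibble::tibble(
      id = id, species = species, order = ord,
      direct = list(direct), relations = list(rel), isolation = iso
    )
  })
  if (nrow(strains) == 0) strains <- empty_strains()

  if (length(unknown) > 0) {
    warning("unsupported OWL construct(s) ignored: ",
            paste(unique(unknown), collapse = "; "))
  }
  eco_ontology(classes, properties, strains)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

#' Write an ontology to an OWL (RDF/XML) file
#'
#' The serialization round-trips: `parse_owl(write_owl(ont, f))` reconstructs
#' an equal ontology, and writing the same ontology twice produces identical
#' bytes.
#'
#' @param ont An `eco_ontology`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_owl <- function(ont, path) {
  validate_ontology(ont)
  iri <- function(id) paste0(IRI_BASE, id)
  L <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<rdf:RDF xmlns:rdf=\"", NS_RDF, "\""),
    paste0("         xmlns:rdfs=\"", NS_RDFS, "\""),
    paste0("         xmlns:owl=\"", NS_OWL, "\""),
    paste0("         xmlns:ye=\"", NS_YE, "\">"),
    paste0("  <owl:Ontology rdf:about=\"", IRI_BASE, "ontology\"/>")
  )
  for (i in seq_len(nrow(ont$classes))) {
    cl <- ont$classes[i, ]
    L <- c(L, paste0("  <owl:Class rdf:about=\"", iri(cl$id), "\">"),
           paste0("    <rdfs:label>", xml_escape(cl$label), "</rdfs:label>"))
    if (!is.na(cl$description)) {
      L <- c(L, paste0("    <rdfs:comment>", xml_escape(cl$description),
                       "</rdfs:comment>"))
    }
    if (!is.na(cl$parent_id)) {
      L <- c(L, paste0("    <rdfs:subClassOf rdf:resource=\"",
                       iri(cl$parent_id), "\"/>"))
    }
    L <- c(L, "  </owl:Class>")
  }
  for (i in seq_len(nrow(ont$properties))) {
    pr <- ont$properties[i, ]
    L <- c(L,
           paste0("  <owl:ObjectProperty rdf:about=\"", iri(pr$id), "\">"),
           paste0("    <rdfs:label>", xml_escape(pr$label), "</rdfs:label>"),
           paste0("    <ye:propertyKind>", pr$kind, "</ye:propertyKind>"),
           "  </owl:ObjectProperty>")
  }
  for (i in seq_len(nrow(ont$strains))) {
    st <- ont$strains[i, ]
    L <- c(L, paste0("  <owl:NamedIndividual rdf:about=\"", iri(st$id), "\">"))
    for (d in st$direct[[1]]) {
      L <- c(L, paste0("    <rdf:type rdf:resource=\"", iri(d), "\"/>"))
    }
    if (!is.na(st$species)) {
      L <- c(L, paste0("    <ye:speciesName>", xml_escape(st$species),
                       "</ye:speciesName>"))
    }
    if (!is.na(st$order)) {
      L <- c(L, paste0("    <ye:taxonOrder>", xml_escape(st$order),
                       "</ye:taxonOrder>"))
    }
    if (!is.na(st$isolation)) {
      L <- c(L, paste0("    <ye:isolationText>", xml_escape(st$isolation),
                       "</ye:isolationText>"))
    }
    rel <- st$relations[[1]]
    for (j in seq_len(nrow(rel))) {
      L <- c(L, paste0("    <ye:", rel$property_id[j], " rdf:resource=\"",
                       iri(rel$target_class_id[j]), "\"/>"))
    }
    L <- c(L, "  </owl:NamedIndividual>")
  }
  L <- c(L, "</rdf:RDF>")
  writeLines(L, path, useBytes = TRUE)
  invisible(path)
}

split_multi <- function(x) {
  if (is.na(x) || x == "") character() else strsplit(x, "|", fixed = TRUE)[[1]]
}

#' Read strain assignments from the TSV dialect
#'
#' A hand-editable flat representation of the same information as the OWL
#' file, spread over up to three files. The class table has columns
#' `id`, `label`, `parent_id` (empty for roots), `description`; the optional
#' property table has `id`, `label`, `kind`; the strain table has columns
#' `id`, `species`, `order`, `direct_classes` (`|`-separated class ids),
#' `relations` (`|`-separated `property_id->target_class_id` triples) and
#' `isolation_text`. All files are UTF-8, tab-separated, with headers.
#'
#' @param strains_path,classes_path,properties_path File paths;
#'   `properties_path` may be `NULL` when no properties are used.
#' @return A validated [eco_ontology()].
#' @export
read_assignments_tsv <- function(strains_path, classes_path,
                                 properties_path = NULL) {
  classes <- readr::read_tsv(classes_path, col_types = readr::cols(
    .default = readr::col_character()), na = "")
  properties <- if (!is.null(properties_path)) {
    readr::read_tsv(properties_path, col_types = readr::cols(
      .default = readr::col_character()), na = "")
  } else {
    empty_properties()
  }
  raw <- readr::read_tsv(strains_path, col_types = readr::cols(
    .default = readr::col_character()), na = "")
  need <- c("id", "species", "order", "direct_classes", "relations",
            "isolation_text")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop("strain table is missing column(s): ", paste(miss, collapse = ", "))
  }
  relations <- lapply(seq_len(nrow(raw)), function(i) {
    terms <- split_multi(raw$relations[i])
    if (length(terms) == 0) return(empty_relations())
    parts <- strsplit(terms, "->", fixed = TRUE)
    bad <- lengths(parts) != 2
    if (any(bad)) {
      stop("malformed relation triple in strain row ", i, " ('", raw$id[i],
           "'): ", paste(terms[bad], collapse = ", "))
    }
    tibble::tibble(
      property_id = vapply(parts, `[[`, character(1), 1),
      target_class_id = vapply(parts, `[[`, character(1), 2)
    )
  })
  strains <- tibble::tibble(
    id = raw$id, species = raw$species, order = raw$order,
    direct = lapply(raw$direct_classes, split_multi),
    relations = relations, isolation = raw$isolation_text
  )
  eco_ontology(classes, properties, strains)
}

join_multi <- function(x) {
  if (length(x) == 0) NA_character_ else paste(x, collapse = "|")
}

#' Write strain assignments in the TSV dialect
#'
#' Counterpart of [read_assignments_tsv()]; the round trip is lossless
#' against the OWL representation.
#'
#' @param ont An `eco_ontology`.
#' @param strains_path,classes_path,properties_path Output paths;
#'   `properties_path` may be `NULL` to skip the property table.
#' @return `strains_path`, invisibly.
#' @export
write_assignments_tsv <- function(ont, strains_path, classes_path,
                                  properties_path = NULL) {
  validate_ontology(ont)
  readr::write_tsv(ont$classes, classes_path, na = "")
  if (!is.null(properties_path)) {
    readr::write_tsv(ont$properties, properties_path, na = "")
  }
  st <- ont$strains
  flat <- tibble::tibble(
    id = st$id, species = st$species, order = st$order,
    direct_classes = vapply(st$direct, join_multi, character(1)),
    relations = vapply(st$relations, function(r) {
      if (nrow(r) == 0) return(NA_character_)
      join_multi(paste0(r$property_id, "->", r$target_class_id))
    }, character(1)),
    isolation_text = st$isolation
  )
  readr::write_tsv(flat, strains_path, na = "")
  invisible(strains_path)
}

#' Test two ontologies for semantic equality
#'
#' Compares class, property and strain content irrespective of row order and
#' of the order of direct classes / relation assertions within a strain.
#'
#' @param a,b `eco_ontology` objects.
#' @return `TRUE` or `FALSE`.
#' @export
ontology_equal <- function(a, b) {
  norm_cls <- function(o) {
    x <- o$classes[order(o$classes$id), ]
    rownames(x) <- NULL
    x
  }
  norm_props <- function(o) {
    x <- o$properties[order(o$properties$id), ]
    rownames(x) <- NULL
    x
  }
  norm_strains <- function(o) {
    x <- o$strains[order(o$strains$id), ]
    x$direct <- lapply(x$direct, sort)
    x$relations <- lapply(x$relations, function(r) {
      r <- r[order(r$property_id, r$target_class_id), ]
      rownames(r) <- NULL
      r
    })
    rownames(x) <- NULL
    x
  }
  isTRUE(all.equal(norm_cls(a), norm_cls(b), check.attributes = FALSE)) &&
    isTRUE(all.equal(norm_props(a), norm_props(b),
                     check.attributes = FALSE)) &&
    isTRUE(all.equal(norm_strains(a), norm_strains(b),
                     check.attributes = FALSE))
}
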