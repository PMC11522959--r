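# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately avoid the code paths they verify.

# ancestors by repeated scan of the class table (no lookup structures)
ancestors_oracle <- function(ont, class_id) {
  out <- character()
  cur <- class_id
  repeat {
    row <- which(ont$classes$id == cur)
    p <- ont$classes$parent_id[row]
    if (is.na(p)) break
    out <- c(p, out)
    cur <- p
  }
  out
}

# closure membership by walking every strain's direct classes upward
members_oracle <- function(ont, class_id) {
  hit <- vapply(seq_len(nrow(ont$strains)), function(i) {
    any(vapply(ont$strains$direct[[i]], function(d) {
      d == class_id || class_id %in% ancestors_oracle(ont, d)
    }, logical(1)))
  }, logical(1))
  ont$strains$id[hit]
}

relational_members_oracle <- function(ont, target_class_id,
                                      property_id = NULL) {
  hit <- vapply(seq_len(nrow(ont$strains)), function(i) {
    r <- ont$strains$relations[[i]]
    if (nrow(r) == 0) return(FALSE)
    if (!is.null(property_id)) r <- r[r$property_id == property_id, ]
    any(vapply(r$target_class_id, function(tc) {
      tc == target_class_id ||
        target_class_id %in% ancestors_oracle(ont, tc)
    }, logical(1)))
  }, logical(1))
  ont$strains$id[hit]
}

# two-sided Fisher p by full enumeration over tables with fixed margins
fisher_p_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  xs <- max(0, c1 - r2):min(c1, r1)
  probs <- vapply(xs, function(x) {
    exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1))
  }, numeric(1))
  obs <- probs[xs == a]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# BH step-up formula: p_(i) * n / i with a cumulative minimum from the top
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj_sorted <- pmin(1, rev(cummin(rev(p[o] * n / seq_len(n)))))
  out <- numeric(n)
  out[o] <- adj_sorted
  out
}

# AUC by exhaustive pairwise comparison
auc_oracle <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  total <- 0
  for (sp in pos) total <- total + sum(sp > neg) + 0.5 * sum(sp == neg)
  total / (length(pos) * length(neg))
}

# hypergeometric upper tail by direct summation
hyper_tail_oracle <- function(k, K, N, n) {
  xs <- k:min(K, n)
  sum(vapply(xs, function(x) {
    exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n))
  }, numeric(1)))
}

# small fixed ontology: two roots, a plant chain down to pollen, and a
# decayed-wood leaf, with strains covering direct, relational and modifier
# annotation patterns
toy_ontology <- function() {
  classes <- data.frame(
    id = c("plant", "plant_parts", "flower", "pollen", "decayed_wood",
           "animal", "arthropoda", "beetle"),
    label = c("Plant", "Plant parts", "Flower", "Pollen", "Decayed wood",
              "Animal", "Arthropoda", "Beetle"),
    parent_id = c(NA, "plant", "plant_parts", "flower", "plant",
                  NA, "animal", "arthropoda")
  )
  properties <- data.frame(
    id = c("is_from_animal_on_plant", "has_decay_association"),
    label = c("is from animal on plant", "has decay association"),
    kind = c("relational", "modifier")
  )
  strains <- tibble::tibble(
    id = c("s_pollen", "s_beetle_on_flower", "s_decayed_wood"),
    species = c("Metschnikowia mauinuiana", "Metschnikowia shivogae",
                "Sugiyamaella lignohabitans"),
    order = c("Serinales", "Serinales", "Dipodascales"),
    direct = list("pollen", "beetle", "decayed_wood"),
    relations = list(
      tibble::tibble(property_id = character(),
                     target_class_id = character()),
      tibble::tibble(property_id = "is_from_animal_on_plant",
                     target_class_id = "flower"),
      tibble::tibble(property_id = "has_decay_association",
                     target_class_id = "decayed_wood")
    ),
    isolation = c("pollen of ohia flower", "insects of morning glories",
                  "decayed wood")
  )
  eco_ontology(classes, properties, strains)
}

# small random ontology with strains, for property tests
random_ontology <- function(seed, n_strains = 25) {
  set.seed(seed)
  ont <- generate_ontology(n_roots = sample(2:6, 1), depth = sample(2:3, 1),
                           branching = c(2, 3), seed = seed)
  generate_strains(ont, n_strains, relation_rate = 0.4, seed = seed + 1000)
}
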