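# Independent oracles (plain recursive / powerset enumeration) and random
# instance generators used across the test files.

# -- brute-force hierarchy queries (recursion over the raw parent map) -------

bf_ancestors <- function(O, code) {
  ps <- O$parents[[code]]
  unique(c(code, unlist(lapply(ps, function(p) bf_ancestors(O, p)))))
}

bf_most_specific <- function(codes, O) {
  codes <- unique(codes)
  codes[vapply(codes, function(s)
    !any(vapply(setdiff(codes, s), function(t) s %in% bf_ancestors(O, t),
                TRUE)), TRUE)]
}

bf_lca <- function(x, y, O) {
  bf_most_specific(intersect(bf_ancestors(O, x), bf_ancestors(O, y)), O)
}

# -- random ontologies and antichains ----------------------------------------

random_tree_ontology <- function(n = 10, prefix = "C") {
  codes <- paste0(prefix, seq_len(n))
  parent <- vapply(seq_len(n), function(i) {
    if (i == 1L) ontology_root() else
      sample(c(ontology_root(), codes[seq_len(i - 1L)]), 1L)
  }, "")
  load_edge_list(data.frame(parent = parent, child = codes))
}

random_dag_ontology <- function(n = 10, prefix = "D") {
  codes <- paste0(prefix, seq_len(n))
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    pool <- c(ontology_root(), codes[seq_len(i - 1L)])
    ps <- sample(pool, min(length(pool), sample(1:2, 1L)))
    data.frame(parent = ps, child = codes[i])
  }))
  load_edge_list(edges)
}

random_antichain <- function(O, max_size = 3) {
  pool <- ontology_classes(O)
  cand <- sample(pool, min(length(pool), sample(seq_len(max_size), 1L)))
  bf_most_specific(cand, O)
}

# -- random descriptions per dialect -----------------------------------------

random_prescription_set <- function(drugs, max_presc = 3) {
  n <- sample(0:max_presc, 1L)
  ps <- lapply(seq_len(n), function(i)
    sample(drugs, sample(seq_len(min(3, length(drugs))), 1L)))
  max_antichain(ps, function(a, b) all(a %in% b))
}

random_chapter_vector_d1 <- function(chapters, drugs) {
  comp <- lapply(chapters, function(ch) random_prescription_set(drugs))
  chapter_vector(stats::setNames(comp, chapters), chapters, dialect = 1L)
}

random_class_set <- function(O, max_size = 2) random_antichain(O, max_size)

random_chapter_vector_d2 <- function(chapters, drug_O) {
  comp <- lapply(chapters, function(ch) {
    n <- sample(0:2, 1L)
    ps <- lapply(seq_len(n), function(i) random_class_set(drug_O))
    max_antichain(ps, function(a, b) leq_class_sets(a, b, drug_O))
  })
  chapter_vector(stats::setNames(comp, chapters), chapters, dialect = 2L)
}

random_ade_vector <- function(drug_O, phen_O) {
  ade_vector(random_antichain(drug_O, 2), random_antichain(phen_O, 2))
}

random_ade_set <- function(drug_O, phen_O, max_size = 3) {
  n <- sample(seq_len(max_size), 1L)
  vs <- lapply(seq_len(n), function(i) random_ade_vector(drug_O, phen_O))
  ade_set(max_antichain(vs, function(a, b) leq_ade(a, b, drug_O, phen_O)))
}

# -- brute-force pattern-concept enumeration ---------------------------------

# All pattern concepts of a context by powerset enumeration: close every
# non-empty subset of patients through an explicit meet fold and membership
# scan, keep the distinct extents.
bf_concepts <- function(delta, space) {
  G <- sort(names(delta))
  n <- length(G)
  seen <- character()
  out <- list()
  for (mask in seq_len(2^n - 1L)) {
    A <- G[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0]
    d <- Reduce(function(x, y) ps_meet(space, x, y), delta[A])
    ext <- G[vapply(G, function(g) ps_leq(space, d, delta[[g]]), TRUE)]
    key <- paste(ext, collapse = ",")
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- list(extent = ext, intent = d)
    }
  }
  out
}

extent_key_set <- function(concepts) {
  sort(vapply(concepts, function(cc) paste(sort(cc$extent), collapse = ","), ""))
}

# -- brute-force closed-itemset rules on a binary context --------------------

# membership: named list patient -> attribute character vector.
bf_binary_closure <- function(S, membership) {
  objs <- names(membership)[vapply(membership, function(at) all(S %in% at), TRUE)]
  if (!length(objs)) return(NULL)
  Reduce(intersect, membership[objs])
}

bf_binary_rules <- function(membership, min_support, min_confidence) {
  attrs <- sort(unique(unlist(membership)))
  n <- length(attrs)
  closed <- list()
  seen <- character()
  for (mask in 0:(2^n - 1L)) {
    S <- attrs[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0]
    cl <- bf_binary_closure(S, membership)
    if (is.null(cl)) next
    key <- paste(sort(cl), collapse = ",")
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      supp <- names(membership)[vapply(membership, function(at)
        all(cl %in% at), TRUE)]
      closed[[length(closed) + 1L]] <- list(items = sort(cl), objs = supp)
    }
  }
  rules <- list()
  for (l in closed) for (r in closed) {
    if (length(r$objs) >= length(l$objs)) next
    if (!all(r$objs %in% l$objs)) next
    if (length(r$objs) < min_support) next
    conf <- length(r$objs) / length(l$objs)
    if (conf < min_confidence) next
    R <- setdiff(r$items, l$items)
    if (!length(R)) next
    key <- paste(paste(l$items, collapse = ","), paste(R, collapse = ","),
                 sep = "=>")
    prev <- rules[[key]]
    if (is.null(prev) || prev$support < length(r$objs)) {
      rules[[key]] <- list(L = l$items, R = R, support = length(r$objs),
                           confidence = conf)
    }
  }
  rules
}

# Translate dialect-3 rules mined on binary_ade_context() back to itemsets.
mined_binary_rule_keys <- function(rules) {
  side_items <- function(d) sort(vapply(unclass(d), function(v)
    sub("^d\\.", "", v$D), ""))
  vapply(rules$rules, function(r)
    paste(paste(side_items(r$L), collapse = ","),
          paste(side_items(r$R), collapse = ","), sep = "=>"), "")
}

# -- misc --------------------------------------------------------------------

table4_membership <- function() {
  list(P1 = c("ADE1", "ADE3"), P2 = c("ADE1", "ADE2"),
       P3 = c("ADE1", "ADE3", "ADE4"))
}

random_membership <- function(n_patients, n_attrs) {
  attrs <- paste0("A", seq_len(n_attrs))
  m <- lapply(seq_len(n_patients), function(i)
    sort(sample(attrs, sample(seq_len(n_attrs), 1L))))
  stats::setNames(m, paste0("P", seq_len(n_patients)))
}
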