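test_that("ATC hierarchy is inferred from code prefixes", {
  O <- build_atc_from_codes(c("H02AA03", "H02AB07", "N02BE01"))
  expect_true(all(c("H02A", "H02AA", "H02AB", "N02B", "N02BE") %in%
                    ontology_classes(O)))
  expect_true(is_ancestor(O, "H02A", "H02AA03"))
  expect_true(is_ancestor(O, "H02A", "H02AB07"))
  expect_identical(lca("H02AA03", "N02BE01", O), ontology_root())
  # retained top-level classes sit directly under the root
  expect_identical(O$parents[["H02A"]], ontology_root())
  expect_identical(O$parents[["N02B"]], ontology_root())
})

test_that("ATC builder rejects malformed codes, drops over-general levels", {
  expect_error(build_atc_from_codes(c("H02AB07", "h02")), "h02")
  expect_warning(O <- build_atc_from_codes(c("H02", "H02AB07")), "H02")
  expect_false(has_class(O, "H02"))
  empty <- build_atc_from_codes(character())
  expect_identical(ontology_classes(empty), character())
})

test_that("every toy ATC class reaches the root through parent links", {
  O <- toy_ontologies()$drug
  for (code in ontology_classes(O)) {
    expect_true(ontology_root() %in% bf_ancestors(O, code))
  }
})

test_that("ICD-9-CM codes attach to three-digit codes, chapters, root", {
  O <- build_icd9_from_codes(c("599.8", "599.9", "719.4"),
                             chapters = c("580-629", "710-739"))
  expect_identical(O$parents[["599.8"]], "599")
  expect_identical(O$parents[["599.9"]], "599")
  expect_identical(O$parents[["599"]], "580-629")
  expect_identical(O$parents[["719.4"]], "719")
  expect_identical(O$parents[["719"]], "710-739")
  expect_identical(lca("599.8", "599.9", O), "599")

  O2 <- build_icd9_from_codes("586", chapters = "580-629")
  expect_identical(O2$parents[["586"]], "580-629")

  O3 <- build_icd9_from_codes(character(), chapters = "280-289")
  expect_identical(ontology_classes(O3), "280-289")

  expect_warning(O4 <- build_icd9_from_codes("042", chapters = "580-629"),
                 "no chapter")
  expect_identical(O4$parents[["042"]], ontology_root())
})

test_that("edge-list loader handles roots, diamonds and rejects cycles", {
  O <- load_edge_list(data.frame(parent = c("A", "A"), child = c("B", "C")))
  expect_identical(O$parents[["A"]], ontology_root())
  expect_identical(O$parents[["B"]], "A")

  dia <- load_edge_list(data.frame(parent = c("A", "A", "B", "C"),
                                   child = c("B", "C", "x", "x")))
  expect_setequal(dia$parents[["x"]], c("B", "C"))
  expect_setequal(lca("x", "x", dia), "x")

  expect_error(load_edge_list(data.frame(parent = c("A", "B"),
                                         child = c("B", "A"))), "cycle")
})

test_that("lca matches the worked corticosteroid examples and is reflexive", {
  O <- toy_ontologies()$drug
  expect_identical(lca("H02AB07", "H02AA03", O), "H02A")
  expect_identical(lca("N02BE01", "H02AA03", O), ontology_root())
  expect_identical(lca("H02AB07", "H02AB07", O), "H02AB07")
})

test_that("lca returns all minimal common ancestors on a diamond DAG", {
  dia <- load_edge_list(data.frame(
    parent = c("A", "A", "B", "C", "B", "C"),
    child = c("B", "C", "x", "x", "y", "y")))
  expect_setequal(lca("x", "y", dia), c("B", "C"))
  expect_setequal(lca("x", "y", dia), bf_lca("x", "y", dia))
})

test_that("lca agrees with the brute-force oracle on random DAGs", {
  set.seed(41)
  for (i in 1:20) {
    O <- random_dag_ontology(n = 8)
    cls <- ontology_classes(O)
    pair <- sample(cls, 2)
    expect_setequal(lca(pair[1], pair[2], O), bf_lca(pair[1], pair[2], O))
  }
})

test_that("on a tree ontology every class pair has a single lca", {
  set.seed(42)
  O <- random_tree_ontology(n = 12)
  cls <- ontology_classes(O)
  for (x in cls) for (y in cls) expect_length(lca(x, y, O), 1L)
})

test_that("ontology meet reproduces the worked antichain examples", {
  O <- toy_ontologies()$drug
  expect_identical(meet_class_sets("H02AB07", "H02AA03", O), "H02A")
  expect_identical(meet_class_sets("N02BE01", "H02AA03", O), ontology_root())
  # the root-valued pairwise lca is pruned by the max reduction
  expect_identical(meet_class_sets(c("H02AB07", "N02BE01"), "H02AA03", O),
                   "H02A")
  x <- c("C03C", "H02AB")
  expect_setequal(meet_class_sets(x, x, O), x)
})

test_that("class-antichain order matches the meet-based definition", {
  O <- toy_ontologies()$drug
  expect_true(leq_class_sets(ontology_root(), "H02A", O))
  expect_true(leq_class_sets("H02A", "H02AB07", O))
  expect_false(leq_class_sets("H02AB07", "N02BE01", O))
})

test_that("max_antichain keeps exactly the maximal elements", {
  subset_leq <- function(a, b) all(a %in% b)
  expect_identical(max_antichain(list(c("d1", "d2"), "d2"), subset_leq),
                   list(c("d1", "d2")))
  O <- toy_ontologies()$drug
  res <- max_antichain(list("H02A", ontology_root()),
                       function(a, b) leq_class_sets(a, b, O))
  expect_identical(res, list("H02A"))
  expect_identical(max_antichain(list(), subset_leq), list())
})

test_that("max_antichain equals brute-force filtering on small set systems", {
  set.seed(7)
  subset_leq <- function(a, b) all(a %in% b)
  for (i in 1:50) {
    S <- lapply(seq_len(sample(1:8, 1)), function(j)
      sort(sample(letters[1:4], sample(1:3, 1))))
    got <- max_antichain(S, subset_leq)
    keys <- vapply(S, paste, "", collapse = ",")
    bf <- S[vapply(seq_along(S), function(a) !any(vapply(seq_along(S),
      function(b) a != b && subset_leq(S[[a]], S[[b]]) &&
        !subset_leq(S[[b]], S[[a]]), TRUE)), TRUE)]
    bf_keys <- unique(vapply(bf, paste, "", collapse = ","))
    expect_setequal(vapply(got, paste, "", collapse = ","), bf_keys)
  }
})

test_that("ontology meet is idempotent, commutative, associative, and lower", {
  set.seed(11)
  O <- random_tree_ontology(n = 12)
  key <- function(x) paste(sort(x), collapse = ",")
  for (i in 1:60) {
    x <- random_antichain(O); y <- random_antichain(O); z <- random_antichain(O)
    expect_identical(key(meet_class_sets(x, x, O)), key(x))
    expect_identical(key(meet_class_sets(x, y, O)),
                     key(meet_class_sets(y, x, O)))
    expect_identical(
      key(meet_class_sets(meet_class_sets(x, y, O), z, O)),
      key(meet_class_sets(x, meet_class_sets(y, z, O), O)))
    m <- meet_class_sets(x, y, O)
    expect_true(leq_class_sets(m, x, O))
    expect_true(leq_class_sets(m, y, O))
  }
})

test_that("class-antichain order is reflexive, antisymmetric, transitive", {
  set.seed(13)
  O <- random_tree_ontology(n = 10)
  for (i in 1:40) {
    x <- random_antichain(O); y <- random_antichain(O); z <- random_antichain(O)
    expect_true(leq_class_sets(x, x, O))
    if (leq_class_sets(x, y, O) && leq_class_sets(y, x, O)) {
      expect_setequal(x, y)
    }
    if (leq_class_sets(x, y, O) && leq_class_sets(y, z, O)) {
      expect_true(leq_class_sets(x, z, O))
    }
  }
})

test_that("pruning general levels re-parents children to the root", {
  O <- toy_ontologies()$phenotype
  P <- prune_general_levels(O)
  expect_false(has_class(P, "580-629"))
  expect_identical(P$parents[["599"]], ontology_root())
  expect_identical(lca("599.8", "599.9", P), "599")
  expect_identical(lca("599.8", "719.4", P), ontology_root())
})

test_that("chapters_of finds the enclosing chapter ranges", {
  O <- toy_ontologies()$phenotype
  expect_identical(chapters_of(O, "599.8"), "580-629")
  expect_identical(chapters_of(O, "719.4"), "710-739")
  expect_identical(chapters_of(O, "428"), "390-459")
})

test_that("edge-list TSV round-trips through the reader", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("B\tA", "C\tA", "x\tB"), tsv)
  O <- read_edge_list_tsv(tsv)
  expect_identical(O$parents[["x"]], "B")
  expect_identical(O$parents[["A"]], ontology_root())
})
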