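two_ch <- c("580-629", "710-739")

test_that("dialect-1 patient descriptions reproduce the running example", {
  sp <- example_space(1)
  coh <- example_cohort()
  d <- lapply(coh$patients, describe_patient, space = sp)
  expect_identical(
    desc_key(d$P1),
    desc_key(chapter_vector(list(
      `580-629` = list("prednisone", "acetaminophen")), two_ch, 1L)))
  expect_identical(
    desc_key(d$P2),
    desc_key(chapter_vector(list(`580-629` = list("prednisone"),
                                 `710-739` = list("prednisone")),
                            two_ch, 1L)))
  expect_identical(
    desc_key(d$P3),
    desc_key(chapter_vector(list(
      `580-629` = list(c("acetaminophen", "prednisone")),
      `710-739` = list("acetaminophen")), two_ch, 1L)))
})

test_that("dialect-2 patient descriptions substitute ATC classes", {
  sp <- example_space(2)
  coh <- example_cohort(include_p4 = TRUE)
  d <- lapply(coh$patients, describe_patient, space = sp,
              drug_map = toy_drug_map())
  expect_identical(
    desc_key(d$P3),
    desc_key(chapter_vector(list(
      `580-629` = list(c("H02AB07", "N02BE01")),
      `710-739` = list("N02BE01")), two_ch, 2L)))
  expect_identical(
    desc_key(d$P4),
    desc_key(chapter_vector(list(`580-629` = list("H02AA03")), two_ch, 2L)))
})

test_that("dialect-3 patient descriptions are sets of ADE vectors", {
  sp <- example_space(3)
  coh <- example_cohort()
  d <- lapply(coh$patients, describe_patient, space = sp,
              drug_map = toy_drug_map())
  expect_identical(
    desc_key(d$P1),
    desc_key(ade_set(list(ade_vector("H02AB07", "599.8"),
                          ade_vector("N02BE01", "599.9")))))
  expect_identical(
    desc_key(d$P2),
    desc_key(ade_set(list(ade_vector("H02AB07", "599.8"),
                          ade_vector("H02AB07", "719.4")))))
  expect_identical(
    desc_key(d$P3),
    desc_key(ade_set(list(ade_vector(c("H02AB07", "N02BE01"), "599.9"),
                          ade_vector("N02BE01", "719.4")))))
})

test_that("set-of-prescriptions meet keeps only maximal intersections", {
  m1 <- function(X, Y) generic_set_meet(
    X, Y, function(x, y) sort(intersect(x, y)), function(x, y) all(x %in% y))
  got <- m1(list(c("d1", "d2", "d3")), list(c("d1", "d2"), c("d2", "d4")))
  expect_identical(got, list(c("d1", "d2")))
  X <- list(c("a", "b"), "c")
  expect_setequal(vapply(m1(X, X), paste, "", collapse = ","),
                  vapply(X, paste, "", collapse = ","))
  # disjoint prescriptions leave the empty prescription as sole survivor
  expect_identical(m1(list("a"), list("b")), list(character()))
})

test_that("chapter-vector meet matches the corticosteroid generalization", {
  sp2 <- example_space(2)
  coh <- example_cohort(include_p4 = TRUE)
  d <- lapply(coh$patients, describe_patient, space = sp2,
              drug_map = toy_drug_map())
  m <- meet_chapter_vectors(d$P1, d$P4, sp2)
  expect_identical(
    desc_key(m),
    desc_key(chapter_vector(list(`580-629` = list("H02A")), two_ch, 2L)))
  expect_identical(desc_key(meet_chapter_vectors(d$P2, d$P2, sp2)),
                   desc_key(d$P2))

  sp1 <- example_space(1)
  d1 <- lapply(example_cohort()$patients, describe_patient, space = sp1)
  m12 <- meet_chapter_vectors(d1$P1, d1$P2, sp1)
  expect_identical(
    desc_key(m12),
    desc_key(chapter_vector(list(`580-629` = list("prednisone")), two_ch, 1L)))
  expect_error(meet_chapter_vectors(
    d1$P1, chapter_vector(list(), "580-629", 1L), sp1), "chapter")
})

test_that("ADE meet generalizes both dimensions or collapses to null", {
  onto <- toy_ontologies()
  phen <- prune_general_levels(onto$phenotype)
  # drugs share only the root: null vector
  m <- meet_ade(ade_vector("H02AB07", "599.8"), ade_vector("N02BE01", "599.9"),
                onto$drug, phen)
  expect_true(length(m$D) == 0 && length(m$P) == 0)
  # max keeps the specific drug, phenotypes equal
  m2 <- meet_ade(ade_vector("H02AB07", "599.9"),
                 ade_vector(c("H02AB07", "N02BE01"), "599.9"),
                 onto$drug, phen)
  expect_identical(desc_key(m2), desc_key(ade_vector("H02AB07", "599.9")))
  v <- ade_vector(c("H02AB07", "N02BE01"), c("599.8", "719.4"))
  expect_identical(desc_key(meet_ade(v, v, onto$drug, phen)), desc_key(v))
})

test_that("ADE-set meet equals the brute-force pairwise enumeration", {
  sp <- example_space(3)
  coh <- example_cohort()
  d <- lapply(coh$patients, describe_patient, space = sp,
              drug_map = toy_drug_map())
  got <- meet_ade_sets(d$P1, d$P3, sp$drug_ontology, sp$phen_ontology)
  # oracle: enumerate the four pairwise ADE meets by hand
  pairs <- list()
  for (vx in unclass(d$P1)) for (vy in unclass(d$P3)) {
    pairs[[length(pairs) + 1L]] <-
      meet_ade(vx, vy, sp$drug_ontology, sp$phen_ontology)
  }
  pairs <- Filter(function(v) length(v$D) > 0, pairs)
  keep <- pairs[vapply(seq_along(pairs), function(i)
    !any(vapply(seq_along(pairs), function(j)
      i != j && leq_ade(pairs[[i]], pairs[[j]], sp$drug_ontology,
                        sp$phen_ontology) &&
        !leq_ade(pairs[[j]], pairs[[i]], sp$drug_ontology,
                 sp$phen_ontology), TRUE)), TRUE)]
  expect_setequal(vapply(unclass(got), function(v) attr(v, "key"), ""),
                  unique(vapply(keep, function(v) attr(v, "key"), "")))
  # prednisone ADEs generalize to the shared 599 class; the acetaminophen
  # ADE is common to both patients at the exact 599.9 phenotype
  got_keys <- vapply(unclass(got), function(v) attr(v, "key"), "")
  expect_true(desc_key(ade_vector("H02AB07", "599")) %in% got_keys)
  expect_true(desc_key(ade_vector("N02BE01", "599.9")) %in% got_keys)
  expect_identical(
    desc_key(meet_ade_sets(d$P2, d$P2, sp$drug_ontology, sp$phen_ontology)),
    desc_key(d$P2))
})

test_that("ADE sets with no shared non-root class meet to the empty set", {
  onto <- toy_ontologies()
  phen <- prune_general_levels(onto$phenotype)
  got <- meet_ade_sets(ade_set(list(ade_vector("C03C", "280"))),
                       ade_set(list(ade_vector("N05B", "580"))),
                       onto$drug, phen)
  expect_length(got, 0L)
})

test_that("description order follows the meet-based definition", {
  sp2 <- example_space(2)
  coh <- example_cohort(include_p4 = TRUE)
  d <- lapply(coh$patients, describe_patient, space = sp2,
              drug_map = toy_drug_map())
  gen <- chapter_vector(list(`580-629` = list("H02A")), two_ch, 2L)
  expect_true(leq_descriptions(gen, d$P1, sp2))
  expect_true(leq_descriptions(d$P1, d$P1, sp2))
  expect_false(leq_descriptions(d$P1, gen, sp2))
})

test_that("all three dialect meets satisfy the semilattice laws", {
  set.seed(21)
  drug_O <- random_tree_ontology(n = 8, prefix = "G")
  phen_O <- random_tree_ontology(n = 8, prefix = "F")
  chapters <- c("chA", "chB")
  drugs <- letters[1:5]
  gens <- list(
    function() random_chapter_vector_d1(chapters, drugs),
    function() random_chapter_vector_d2(chapters, drug_O),
    function() random_ade_set(drug_O, phen_O))
  spaces <- list(
    pattern_space(1L, chapters = chapters),
    pattern_space(2L, drug_ontology = drug_O, chapters = chapters),
    pattern_space(3L, drug_ontology = drug_O, phen_ontology = phen_O))
  for (k in 1:3) {
    sp <- spaces[[k]]
    for (i in 1:40) {
      X <- gens[[k]](); Y <- gens[[k]](); Z <- gens[[k]]()
      expect_identical(desc_key(ps_meet(sp, X, X)), desc_key(X))
      expect_identical(desc_key(ps_meet(sp, X, Y)),
                       desc_key(ps_meet(sp, Y, X)))
      expect_identical(desc_key(ps_meet(sp, ps_meet(sp, X, Y), Z)),
                       desc_key(ps_meet(sp, X, ps_meet(sp, Y, Z))))
      m <- ps_meet(sp, X, Y)
      expect_true(ps_leq(sp, m, X))
      expect_true(ps_leq(sp, m, Y))
    }
  }
})

test_that("meets preserve the antichain invariants of their outputs", {
  set.seed(22)
  drug_O <- random_tree_ontology(n = 8, prefix = "G")
  phen_O <- random_tree_ontology(n = 8, prefix = "F")
  sp <- pattern_space(3L, drug_ontology = drug_O, phen_ontology = phen_O)
  for (i in 1:30) {
    m <- ps_meet(sp, random_ade_set(drug_O, phen_O),
                 random_ade_set(drug_O, phen_O))
    vs <- unclass(m)
    expect_false(any(vapply(vs, function(v) length(v$D) == 0, TRUE)))
    for (a in seq_along(vs)) for (b in seq_along(vs)) {
      if (a != b) {
        expect_false(leq_ade(vs[[a]], vs[[b]], drug_O, phen_O) &&
                       leq_ade(vs[[b]], vs[[a]], drug_O, phen_O))
      }
    }
  }
})

test_that("flat-ontology dialect 3 coincides with binary-context FCA", {
  ctx <- binary_ade_context(table4_membership())
  # patient descriptions are antichains of incomparable singleton ADEs,
  # and the meet is exactly attribute-set intersection
  d1 <- ctx$delta$P1; d3 <- ctx$delta$P3
  m <- ps_meet(ctx$space, d1, d3)
  items <- sort(vapply(unclass(m), function(v) sub("^d\\.", "", v$D), ""))
  expect_identical(items, intersect(table4_membership()$P1,
                                    table4_membership()$P3))
})

test_that("unmapped drug codes become pseudo-classes compared to themselves", {
  onto <- toy_ontologies()
  sp <- pattern_space(3L, drug_ontology = onto$drug,
                      phen_ontology = prune_general_levels(onto$phenotype))
  # the raw code is kept: it can only ever meet itself above the root
  d <- describe_patient(list(new_candidate("g", "mystery_drug", "599.8")),
                        sp, drug_map = list())
  expect_identical(unclass(d)[[1]]$D, "mystery_drug")
})
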