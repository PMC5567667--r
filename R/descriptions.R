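# Pattern-structure descriptions of a patient's adverse drug events, in
# three dialects of increasing semantic depth:
#
#   dialect 1 - a vector of sub-descriptions indexed by first-level phenotype
#               classes (ICD-9-CM chapters); each sub-description is a set of
#               prescriptions, i.e. a set of sets of raw drug codes, compared
#               with plain set intersection;
#   dialect 2 - the same vector, with drugs replaced by their ATC classes and
#               intersection replaced by the ontology meet;
#   dialect 3 - a set of ADE vectors <D, P>, each pairing a drug-class
#               antichain with a phenotype-class antichain, compared with an
#               ADE-level meet over both ontologies.
#
# Every meet returns the most specific common generalization of its operands
# and induces the order X <= Y  <=>  X meet Y = X ("Y refines X").

## ---- canonical constructors ------------------------------------------------

canon_prescription <- function(codes) sort(unique(as.character(codes)))

presc_key <- function(p) paste(p, collapse = ",")

canon_subdescription <- function(prescriptions) {
  prescriptions <- lapply(prescriptions, canon_prescription)
  keys <- vapply(prescriptions, presc_key, "")
  prescriptions[order(keys)][!duplicated(sort(keys))]
}

#' Construct a chapter-indexed description (dialects 1 and 2)
#'
#' @param components Named list mapping each chapter key to a list of
#'   prescriptions (character vectors of drug codes for dialect 1, of ATC
#'   classes for dialect 2).  Missing chapters become empty components.
#' @param chapters Character vector fixing the full chapter key set.
#' @param dialect 1 or 2.
#' @return A `chapter_vector` description.
#' @export
chapter_vector <- function(components, chapters, dialect = 1L) {
  chapters <- sort(chapters)
  comp <- stats::setNames(vector("list", length(chapters)), chapters)
  for (ch in chapters) {
    comp[[ch]] <- canon_subdescription(
      if (ch %in% names(components)) components[[ch]] else list())
  }
  d <- structure(comp, class = "chapter_vector", dialect = as.integer(dialect))
  attr(d, "key") <- chapter_vector_key(d)
  d
}

chapter_vector_key <- function(d) {
  paste(vapply(names(d), function(ch) {
    paste0(ch, ":{", paste(vapply(d[[ch]], presc_key, ""), collapse = ";"), "}")
  }, ""), collapse = "|")
}

#' Construct an ADE vector or a set of ADE vectors (dialect 3)
#'
#' An ADE vector pairs an antichain of drug classes with an antichain of
#' phenotype classes.  The null vector (both dimensions empty) stands for
#' "no common ADE" and is produced when a meet generalizes both operands
#' away to the ontology roots.
#'
#' @param D,P Character vectors of drug / phenotype class codes.
#' @return `ade_vector()`: an `ade` object; `ade_set()`: an `ade_set`.
#' @export
ade_vector <- function(D = character(), P = character()) {
  v <- structure(list(D = sort(unique(as.character(D))),
                      P = sort(unique(as.character(P)))), class = "ade")
  attr(v, "key") <- paste0(paste(v$D, collapse = ","), ">",
                           paste(v$P, collapse = ","))
  v
}

#' @rdname ade_vector
#' @param ades A list of `ade` vectors.
#' @export
ade_set <- function(ades = list()) {
  ades <- lapply(ades, function(v) {
    if (inherits(v, "ade")) v else ade_vector(v$D, v$P)
  })
  keys <- vapply(ades, function(v) attr(v, "key"), "")
  ades <- ades[order(keys)][!duplicated(sort(keys))]
  d <- structure(ades, class = "ade_set")
  attr(d, "key") <- if (!length(d)) "{empty}" else
    paste(vapply(d, function(v) attr(v, "key"), ""), collapse = " ; ")
  d
}

is_null_ade <- function(v) !length(v$D) && !length(v$P)

#' Canonical serialization key of a description
#'
#' Two descriptions are equal exactly when their keys are equal; keys drive
#' hashing and memoization throughout lattice construction.
#'
#' @param d A description (`chapter_vector` or `ade_set`).
#' @return A character string.
#' @export
desc_key <- function(d) attr(d, "key")

#' @export
print.chapter_vector <- function(x, ...) {
  cat(sprintf("<chapter_vector dialect %d>\n", attr(x, "dialect")))
  for (ch in names(x)) {
    body <- if (!length(x[[ch]])) "{}" else
      paste0("{", paste(vapply(x[[ch]], function(p)
        paste0("{", paste(p, collapse = ","), "}"), ""), collapse = ", "), "}")
    cat(" ", ch, ":", body, "\n")
  }
  invisible(x)
}

#' @export
print.ade_set <- function(x, ...) {
  cat("<ade_set>", if (!length(x)) "(empty)" else "", "\n")
  for (v in x) {
    cat(sprintf("  <{%s}, {%s}>\n", paste(v$D, collapse = ","),
                paste(v$P, collapse = ",")))
  }
  invisible(x)
}

## ---- generic antichain-of-elements meet ------------------------------------

#' Meet of two antichains of elements
#'
#' The backbone shared by all three dialects: all pairwise element meets,
#' reduced to the maximal (most specific) elements under the element order.
#' Used with (set intersection, subset) for dialect 1, with the ontology
#' meet and order for dialect 2, and with the ADE meet and order for
#' dialect 3.
#'
#' @param X,Y Lists of elements, each an antichain under `element_leq`.
#' @param element_meet `function(x, y)` returning the meet of two elements.
#' @param element_leq `function(x, y)` returning `TRUE` when `x <= y`.
#' @param drop Optional predicate; elements for which it returns `TRUE`
#'   (e.g. null ADE vectors) are removed before the max reduction.
#' @return A list of elements (an antichain).
#' @export
generic_set_meet <- function(X, Y, element_meet, element_leq, drop = NULL) {
  if (!length(X) || !length(Y)) return(list())
  prod <- vector("list", length(X) * length(Y))
  k <- 0L
  for (x in X) for (y in Y) {
    k <- k + 1L
    prod[[k]] <- element_meet(x, y)
  }
  if (!is.null(drop)) prod <- prod[!vapply(prod, drop, TRUE)]
  max_antichain(prod, element_leq)
}

## ---- pattern spaces --------------------------------------------------------

#' Define the description space of a pattern structure
#'
#' Bundles a dialect with the ontologies and chapter keys its meet operator
#' needs, exposing `ps_meet()`, `ps_leq()` and friends uniformly.
#'
#' @param dialect 1, 2 or 3.
#' @param drug_ontology ATC-style ontology (dialects 2 and 3).
#' @param phen_ontology Phenotype ontology.  Dialects 1 and 2 take their
#'   chapter keys from it; dialect 3 uses its full hierarchy (usually with
#'   the most general levels pruned, see [prune_general_levels()]).
#' @param chapters Chapter key set for dialects 1/2 (default: the chapters
#'   of `phen_ontology`).
#' @return A `pattern_space` object.
#' @export
pattern_space <- function(dialect, drug_ontology = NULL, phen_ontology = NULL,
                          chapters = NULL) {
  dialect <- as.integer(dialect)
  stopifnot(dialect %in% 1:3)
  if (dialect >= 2L && is.null(drug_ontology)) {
    stop("dialects 2 and 3 require a drug ontology")
  }
  if (dialect == 3L && is.null(phen_ontology)) {
    stop("dialect 3 requires a phenotype ontology")
  }
  if (dialect <= 2L && is.null(chapters)) {
    if (is.null(phen_ontology) || !length(phen_ontology$chapters)) {
      stop("dialects 1 and 2 need chapter keys (or a phenotype ontology ",
           "with chapters)")
    }
    chapters <- phen_ontology$chapters
  }
  structure(list(dialect = dialect, drug_ontology = drug_ontology,
                 phen_ontology = phen_ontology,
                 chapters = if (dialect <= 2L) sort(chapters) else NULL),
            class = "pattern_space")
}

#' @export
print.pattern_space <- function(x, ...) {
  cat(sprintf("<pattern_space dialect %d>\n", x$dialect))
  invisible(x)
}

space_element_ops <- function(space) {
  if (space$dialect == 1L) {
    list(meet = function(x, y) canon_prescription(intersect(x, y)),
         leq = function(x, y) all(x %in% y))
  } else {
    O <- space$drug_ontology
    list(meet = function(x, y) meet_class_sets(x, y, O),
         leq = function(x, y) leq_class_sets(x, y, O))
  }
}

#' Meet of two chapter-indexed descriptions (dialects 1 and 2)
#'
#' Componentwise [generic_set_meet()] over the shared chapter keys; an empty
#' component on either side yields an empty component.
#'
#' @param X,Y `chapter_vector` descriptions over identical chapter keys.
#' @param space The `pattern_space` (supplies dialect and drug ontology).
#' @return A `chapter_vector`.
#' @export
meet_chapter_vectors <- function(X, Y, space) {
  if (!identical(names(X), names(Y))) {
    stop("chapter key sets differ between descriptions")
  }
  ops <- space_element_ops(space)
  comp <- lapply(names(X), function(ch)
    generic_set_meet(X[[ch]], Y[[ch]], ops$meet, ops$leq))
  chapter_vector(stats::setNames(comp, names(X)), chapters = names(X),
                 dialect = space$dialect)
}

#' Meet of two ADE vectors
#'
#' Applies the ontology meet on both dimensions.  When either resulting
#' dimension holds nothing more specific than the ontology root, the whole
#' result collapses to the null vector, so that uninformative
#' generalizations are ignored downstream.
#'
#' @param vx,vy `ade` vectors.
#' @param drug_O,phen_O Drug and phenotype ontologies.
#' @return An `ade` vector (possibly the null vector).
#' @export
meet_ade <- function(vx, vy, drug_O, phen_O) {
  D <- meet_class_sets(vx$D, vy$D, drug_O)
  P <- meet_class_sets(vx$P, vy$P, phen_O)
  if (length(setdiff(D, drug_O$root)) && length(setdiff(P, phen_O$root))) {
    ade_vector(D, P)
  } else {
    ade_vector()
  }
}

#' @rdname meet_ade
#' @export
leq_ade <- function(vx, vy, drug_O, phen_O) {
  identical(attr(meet_ade(vx, vy, drug_O, phen_O), "key"), attr(vx, "key"))
}

#' Meet of two ADE-set descriptions (dialect 3)
#'
#' All pairwise ADE meets, null vectors removed, reduced to the most
#' specific antichain.
#'
#' @param X,Y `ade_set` descriptions.
#' @param drug_O,phen_O Drug and phenotype ontologies.
#' @return An `ade_set`.
#' @export
meet_ade_sets <- function(X, Y, drug_O, phen_O) {
  res <- generic_set_meet(
    X, Y,
    element_meet = function(a, b) meet_ade(a, b, drug_O, phen_O),
    element_leq = function(a, b) leq_ade(a, b, drug_O, phen_O),
    drop = is_null_ade)
  ade_set(res)
}

#' Dialect-dispatching meet, order and equality on descriptions
#'
#' @param space A `pattern_space`.
#' @param X,Y Descriptions of that space's dialect.
#' @return `ps_meet()`: a description; `ps_leq()`, `ps_equal()`: logical.
#' @export
ps_meet <- function(space, X, Y) {
  if (space$dialect == 3L) {
    meet_ade_sets(X, Y, space$drug_ontology, space$phen_ontology)
  } else {
    meet_chapter_vectors(X, Y, space)
  }
}

#' @rdname ps_meet
#' @export
ps_leq <- function(space, X, Y) {
  identical(desc_key(ps_meet(space, X, Y)), desc_key(X))
}

#' @rdname ps_meet
#' @export
ps_equal <- function(space, X, Y) identical(desc_key(X), desc_key(Y))

#' @rdname ps_meet
#' @export
leq_descriptions <- function(X, Y, space) ps_leq(space, X, Y)

#' Most general description of a space (the empty description)
#'
#' Refined by every description: all-empty chapter components (dialects 1/2)
#' or the empty ADE set (dialect 3).
#'
#' @param space A `pattern_space`.
#' @return A description.
#' @export
ps_top <- function(space) {
  if (space$dialect == 3L) ade_set() else
    chapter_vector(list(), chapters = space$chapters, dialect = space$dialect)
}

## ---- difference and combination (for rule sides) ---------------------------

# Description difference: elements of `specific` absent from `general`,
# by structural equality.  Used to form the right-hand side of a rule.
desc_diff <- function(space, general, specific) {
  if (space$dialect == 3L) {
    gk <- vapply(general, function(v) attr(v, "key"), "")
    ade_set(specific[!vapply(specific, function(v) attr(v, "key") %in% gk, TRUE)])
  } else {
    comp <- lapply(names(specific), function(ch) {
      gk <- vapply(general[[ch]], presc_key, "")
      specific[[ch]][!vapply(specific[[ch]], function(p) presc_key(p) %in% gk, TRUE)]
    })
    chapter_vector(stats::setNames(comp, names(specific)),
                   chapters = names(specific), dialect = space$dialect)
  }
}

# Union of two descriptions, antichain-reduced towards the most specific
# elements (the description demanding everything both operands demand).
desc_combine <- function(space, X, Y) {
  if (space$dialect == 3L) {
    pool <- c(unclass(X), unclass(Y))
    pool <- pool[!vapply(pool, is_null_ade, TRUE)]
    keep <- max_antichain(pool, function(a, b)
      leq_ade(a, b, space$drug_ontology, space$phen_ontology))
    ade_set(keep)
  } else {
    ops <- space_element_ops(space)
    comp <- lapply(names(X), function(ch)
      max_antichain(c(X[[ch]], Y[[ch]]), ops$leq))
    chapter_vector(stats::setNames(comp, names(X)), chapters = names(X),
                   dialect = space$dialect)
  }
}

desc_is_empty <- function(d) {
  if (inherits(d, "ade_set")) length(d) == 0L else all(lengths(d) == 0L)
}

## ---- patient descriptions --------------------------------------------------

map_drug_classes <- function(drugs, drug_map, drug_O) {
  classes <- unlist(lapply(drugs, function(d) {
    cl <- drug_map[[d]]
    if (is.null(cl)) d else cl
  }), use.names = FALSE)
  max_specific(unique(classes), drug_O)
}

#' Describe a patient's ADE candidates in a pattern-space dialect
#'
#' Turns a patient's list of ADE candidates (pairs of a drug set and a
#' phenotype set) into a description:
#'
#' * dialect 1: each candidate contributes its raw drug set to the component
#'   of every chapter containing one of its phenotypes;
#' * dialect 2: likewise, with each drug replaced by its ATC class(es);
#' * dialect 3: each candidate becomes an ADE vector `<classes(D), classes(P)>`.
#'
#' All containers are antichain-reduced towards their most specific elements.
#'
#' @param cands List of candidates, each with fields `drugs` and `phenotypes`
#'   (see [extract_ehr_candidates()]).
#' @param space A `pattern_space`.
#' @param drug_map Named list mapping a raw drug code to its ATC class(es);
#'   required for dialects 2 and 3.  Codes without an entry are taken to be
#'   ontology classes already (or pseudo-classes directly under the root).
#' @return A description of the space's dialect.
#' @export
describe_patient <- function(cands, space, drug_map = NULL) {
  if (space$dialect >= 2L && is.null(drug_map)) {
    stop("dialects 2 and 3 require a drug_map")
  }
  if (space$dialect == 3L) {
    phen_O <- space$phen_ontology
    ades <- lapply(cands, function(cc) {
      D <- map_drug_classes(cc$drugs, drug_map, space$drug_ontology)
      P <- max_specific(intersect(cc$phenotypes, ontology_classes(phen_O)),
                        phen_O)
      if (length(setdiff(D, space$drug_ontology$root)) &&
          length(setdiff(P, phen_O$root))) ade_vector(D, P) else ade_vector()
    })
    ades <- ades[!vapply(ades, is_null_ade, TRUE)]
    ade_set(max_antichain(ades, function(a, b)
      leq_ade(a, b, space$drug_ontology, phen_O)))
  } else {
    phen_O <- space$phen_ontology
    comp <- stats::setNames(
      lapply(space$chapters, function(ch) list()), space$chapters)
    for (cc in cands) {
      presc <- if (space$dialect == 1L) canon_prescription(cc$drugs) else
        map_drug_classes(cc$drugs, drug_map, space$drug_ontology)
      chs <- unique(unlist(lapply(cc$phenotypes, function(p) {
        if (!is.null(phen_O) && has_class(phen_O, p)) chapters_of(phen_O, p)
        else intersect(p, space$chapters)
      }), use.names = FALSE))
      for (ch in chs) comp[[ch]] <- c(comp[[ch]], list(presc))
    }
    ops <- space_element_ops(space)
    comp <- lapply(comp, function(sd) max_antichain(sd, ops$leq))
    chapter_vector(comp, chapters = space$chapters, dialect = space$dialect)
  }
}
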