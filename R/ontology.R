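# Class hierarchies (ATC, ICD-9-CM, generic DAGs) with ancestor and
# least-common-ancestor queries, and the ontology meet on antichains of
# classes.  All ontologies are rooted at a synthetic top class whose code is
# returned by ontology_root().

#' Code of the synthetic root class
#'
#' Every ontology built by this package is rooted at a synthetic top class
#' (the most general class, an ancestor of everything).  Its code is the
#' string returned here.
#'
#' @return A length-one character string.
#' @export
ontology_root <- function() "TOP"

new_ontology <- function(parents, labels = character(), kind = "generic",
                         chapters = character(), general = character()) {
  root <- ontology_root()
  parents[[root]] <- character()
  # parent references must resolve
  for (code in names(parents)) {
    bad <- setdiff(parents[[code]], names(parents))
    if (length(bad)) {
      stop("unresolved parent reference(s) for class ", code, ": ",
           paste(bad, collapse = ", "))
    }
  }
  O <- structure(
    list(parents = parents, labels = labels, root = root, kind = kind,
         chapters = chapters, general = general, cache = new.env(parent = emptyenv())),
    class = "ontology"
  )
  cyc <- find_cycle(parents)
  if (!is.null(cyc)) {
    stop("cycle among parent links: ", paste(cyc, collapse = " -> "))
  }
  O
}

# Returns one cycle (as a code path) or NULL when the parent links are acyclic.
find_cycle <- function(parents) {
  state <- new.env(parent = emptyenv()) # 1 = in progress, 2 = done
  path <- character()
  cyc <- NULL
  visit <- function(code) {
    st <- get0(code, envir = state, ifnotfound = 0L)
    if (st == 2L) return(FALSE)
    if (st == 1L) {
      i <- match(code, path)
      cyc <<- c(path[i:length(path)], code)
      return(TRUE)
    }
    assign(code, 1L, envir = state)
    path <<- c(path, code)
    for (p in parents[[code]]) if (visit(p)) return(TRUE)
    path <<- path[-length(path)]
    assign(code, 2L, envir = state)
    FALSE
  }
  for (code in names(parents)) if (visit(code)) return(cyc)
  NULL
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology> %s: %d classes (root '%s')\n",
              x$kind, length(x$parents) - 1L, x$root))
  if (length(x$chapters)) {
    cat("  chapters:", paste(x$chapters, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Class codes of an ontology
#'
#' @param O An ontology.
#' @param include_root Keep the synthetic root in the result?
#' @return Character vector of class codes.
#' @export
ontology_classes <- function(O, include_root = FALSE) {
  codes <- names(O$parents)
  if (!include_root) codes <- setdiff(codes, O$root)
  codes
}

#' @rdname ontology_classes
#' @param code A class code.
#' @export
has_class <- function(O, code) code %in% names(O$parents)

check_class <- function(O, code) {
  missing <- setdiff(code, names(O$parents))
  if (length(missing)) {
    stop("unknown ontology class code(s): ", paste(missing, collapse = ", "))
  }
  invisible(code)
}

#' Ancestors of a class
#'
#' Reflexive-transitive closure of the parent links: a class is an ancestor
#' of itself.  Results are memoized inside the ontology object.
#'
#' @param O An ontology.
#' @param code A class code.
#' @return Character vector of ancestor codes (including `code` and the root).
#' @export
class_ancestors <- function(O, code) {
  check_class(O, code)
  memo_ancestors(O, code)
}

memo_ancestors <- function(O, code) {
  hit <- get0(code, envir = O$cache, ifnotfound = NULL)
  if (!is.null(hit)) return(hit)
  anc <- code
  frontier <- O$parents[[code]]
  while (length(frontier)) {
    anc <- c(anc, frontier)
    frontier <- setdiff(unique(unlist(O$parents[frontier], use.names = FALSE)), anc)
  }
  anc <- unique(anc)
  assign(code, anc, envir = O$cache)
  anc
}

#' Subclass order between two classes
#'
#' `is_ancestor(O, a, b)` is `TRUE` when `a` is an ancestor of `b` (or equal
#' to it), i.e. `a` is at least as general as `b` in the class hierarchy.
#'
#' @param O An ontology.
#' @param a,b Class codes.
#' @return Logical.
#' @export
is_ancestor <- function(O, a, b) {
  a %in% memo_ancestors(O, check_class(O, b))
}

#' Least common ancestors of two classes
#'
#' The set of most specific common ancestors of `x` and `y`.  On a tree this
#' is a single class; on a DAG (multiple parents) several incomparable
#' classes can qualify and all of them are returned.
#'
#' @param O An ontology.
#' @param x,y Class codes.
#' @return Character vector of class codes (an antichain).
#' @export
lca <- function(x, y, O) {
  check_class(O, c(x, y))
  key <- if (x <= y) paste0("lca\r", x, "\r", y) else paste0("lca\r", y, "\r", x)
  hit <- get0(key, envir = O$cache, ifnotfound = NULL)
  if (!is.null(hit)) return(hit)
  common <- intersect(memo_ancestors(O, x), memo_ancestors(O, y))
  res <- max_specific(common, O)
  assign(key, res, envir = O$cache)
  res
}

#' Most specific subset of a set of classes
#'
#' `max_specific(codes, O)` keeps the classes that have no descendant in the
#' set: the "max" reduction of the subclass order, producing an antichain.
#'
#' @param codes Character vector of class codes.
#' @param O An ontology.
#' @return Character vector (an antichain of classes).
#' @export
max_specific <- function(codes, O) {
  codes <- unique(codes)
  if (length(codes) <= 1L) return(codes)
  check_class(O, codes)
  # drop a code when it is a strict ancestor of another member
  anc_all <- unlist(lapply(codes, function(cc)
    setdiff(memo_ancestors(O, cc), cc)), use.names = FALSE)
  codes[!(codes %in% anc_all)]
}

#' Ontology meet of two class antichains
#'
#' The similarity of two sets of classes: the union of pairwise least common
#' ancestors, reduced to its most specific subset.  The root appears only
#' when it is the sole common ancestor.
#'
#' @param x,y Character vectors of class codes (antichains).
#' @param O An ontology.
#' @return Character vector (an antichain of classes).
#' @export
meet_class_sets <- function(x, y, O) {
  if (!length(x) || !length(y)) return(character())
  pairs <- unique(unlist(
    lapply(x, function(cx) lapply(y, function(cy) lca(cx, cy, O))),
    use.names = FALSE))
  max_specific(pairs, O)
}

#' Partial order on class antichains
#'
#' `leq_class_sets(x, y, O)` is `TRUE` when `y` is at least as specific as
#' `x`, i.e. the ontology meet of `x` and `y` equals `x`.
#'
#' @inheritParams meet_class_sets
#' @return Logical.
#' @export
leq_class_sets <- function(x, y, O) {
  setequal(meet_class_sets(x, y, O), x)
}

#' Maximal elements of a set under a partial order
#'
#' Generic "max" reduction: keeps the elements with no strict successor in
#' `S`; elements equal under the order are collapsed to one representative.
#'
#' @param S A list of elements.
#' @param leq A predicate `function(a, b)` that is `TRUE` when `a <= b`.
#' @return A list: the maximal elements of `S`.
#' @export
max_antichain <- function(S, leq) {
  n <- length(S)
  if (n <= 1L) return(S)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    for (j in seq_len(n)) {
      if (i == j || !keep[j]) next
      if (leq(S[[i]], S[[j]])) {
        if (leq(S[[j]], S[[i]])) {
          if (j < i) { keep[i] <- FALSE; break } # duplicate, keep first
        } else {
          keep[i] <- FALSE; break                # strict successor exists
        }
      }
    }
  }
  S[keep]
}

## ---- builders --------------------------------------------------------------

atc_level_lengths <- c(1L, 3L, 4L, 5L, 7L)

atc_is_valid <- function(code) {
  grepl("^[A-Z]$", code) | grepl("^[A-Z][0-9]{2}$", code) |
    grepl("^[A-Z][0-9]{2}[A-Z]$", code) |
    grepl("^[A-Z][0-9]{2}[A-Z]{2}$", code) |
    grepl("^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$", code)
}

#' Build an ATC-style drug ontology from bare codes
#'
#' The hierarchy is inferred from code prefixes.  Only the three most
#' specific ATC levels are kept: pharmacological subgroups (e.g. `H02A`),
#' chemical subgroups (`H02AB`) and chemical substances (`H02AB07`).
#' Prefix-implied intermediate classes are materialized, and the retained
#' top-level classes become direct children of the root.  Codes at the two
#' most general ATC levels (anatomical groups such as `H` and therapeutic
#' subgroups such as `H02`) are dropped with a warning.
#'
#' @param codes Character vector of ATC codes.
#' @param labels Optional named character vector of class labels.
#' @return An ontology.
#' @export
#' @examples
#' O <- build_atc_from_codes(c("H02AA03", "H02AB07", "N02BE01"))
#' lca("H02AB07", "H02AA03", O)  # "H02A"
build_atc_from_codes <- function(codes, labels = character()) {
  codes <- unique(as.character(codes))
  bad <- codes[!atc_is_valid(codes)]
  if (length(bad)) {
    stop("malformed ATC code(s): ", paste(bad, collapse = ", "))
  }
  general <- codes[nchar(codes) < 4L]
  if (length(general)) {
    warning("dropping ATC code(s) above the three retained levels: ",
            paste(general, collapse = ", "))
    codes <- setdiff(codes, general)
  }
  parents <- list()
  root <- ontology_root()
  for (code in codes) {
    n <- nchar(code)
    chain <- unique(c(substr(code, 1L, 4L),
                      if (n >= 5L) substr(code, 1L, 5L),
                      if (n == 7L) code))
    for (i in seq_along(chain)) {
      parents[[chain[i]]] <- if (i == 1L) root else chain[i - 1L]
    }
  }
  new_ontology(parents, labels = labels, kind = "atc")
}

icd9_parse_chapter <- function(chapter) {
  if (!grepl("^[0-9]{3}-[0-9]{3}$", chapter)) {
    stop("malformed ICD-9-CM chapter range: ", chapter)
  }
  as.integer(strsplit(chapter, "-", fixed = TRUE)[[1]])
}

#' Build an ICD-9-CM-style phenotype ontology from codes and chapter ranges
#'
#' Decimal codes (`599.8`) parent to their three-digit code (`599`), which
#' parents to the enclosing chapter range (`580-629`), which parents to the
#' root.  Chapter ranges are recorded as the most general level so that they
#' can later be excluded for deep semantic comparisons (see
#' [prune_general_levels()]).  A three-digit code covered by no chapter is
#' attached directly to the root with a warning.
#'
#' @param codes Character vector of three-digit or decimal ICD-9-CM codes.
#' @param chapters Character vector of chapter range labels like `"580-629"`.
#' @param labels Optional named character vector of class labels.
#' @return An ontology; chapter codes are available as `$chapters`.
#' @export
#' @examples
#' O <- build_icd9_from_codes(c("599.8", "599.9", "719.4"),
#'                            chapters = c("580-629", "710-739"))
#' lca("599.8", "599.9", O)  # "599"
build_icd9_from_codes <- function(codes, chapters, labels = character()) {
  codes <- unique(as.character(codes))
  chapters <- unique(as.character(chapters))
  ranges <- vapply(chapters, icd9_parse_chapter, integer(2))
  ok <- grepl("^[0-9]{3}$", codes) | grepl("^[0-9]{3}\\.[0-9]{1,2}$", codes)
  if (any(!ok)) {
    stop("malformed ICD-9-CM code(s): ", paste(codes[!ok], collapse = ", "))
  }
  root <- ontology_root()
  parents <- list()
  for (ch in chapters) parents[[ch]] <- root
  chapter_of <- function(code3) {
    v <- as.integer(code3)
    hit <- chapters[ranges[1, ] <= v & v <= ranges[2, ]]
    if (!length(hit)) {
      warning("ICD-9-CM code ", code3,
              " is covered by no chapter; attaching it to the root")
      return(root)
    }
    hit[1]
  }
  for (code in codes) {
    code3 <- substr(code, 1L, 3L)
    if (is.null(parents[[code3]])) parents[[code3]] <- chapter_of(code3)
    if (nchar(code) > 3L) parents[[code]] <- code3
  }
  new_ontology(parents, labels = labels, kind = "icd9",
               chapters = chapters, general = chapters)
}

#' Load a generic rooted DAG ontology from a parent-child edge list
#'
#' Classes may have multiple parents (SNOMED-CT-like).  Parentless classes
#' become direct children of the root.  A directed cycle is a hard failure.
#'
#' @param edges A data frame (or two-column matrix) with columns `parent`
#'   and `child`.
#' @param labels Optional named character vector of class labels.
#' @return An ontology.
#' @export
load_edge_list <- function(edges, labels = character()) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("parent", "child") %in% names(edges))) {
    names(edges)[1:2] <- c("parent", "child")
  }
  root <- ontology_root()
  nodes <- unique(c(edges$parent, edges$child))
  parents <- stats::setNames(
    lapply(nodes, function(v) unique(edges$parent[edges$child == v])), nodes)
  orphan <- nodes[lengths(parents[nodes]) == 0L]
  for (v in orphan) parents[[v]] <- root
  new_ontology(parents, labels = labels, kind = "generic")
}

#' Read an ontology from a child-parent TSV edge list
#'
#' @param path Path to a two-column TSV (`child`, `parent`), no header
#'   required; a header line `child<TAB>parent` is recognised and skipped.
#' @param labels_path Optional path to a two-column TSV (`code`, `label`).
#' @return An ontology.
#' @export
read_edge_list_tsv <- function(path, labels_path = NULL) {
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (nrow(tab) && identical(tolower(unlist(tab[1, ])), c("child", "parent"))) {
    tab <- tab[-1, , drop = FALSE]
  }
  labels <- character()
  if (!is.null(labels_path)) {
    lt <- utils::read.delim(labels_path, header = FALSE, colClasses = "character")
    labels <- stats::setNames(lt[[2]], lt[[1]])
  }
  load_edge_list(data.frame(parent = tab[[2]], child = tab[[1]],
                            stringsAsFactors = FALSE), labels = labels)
}

#' Remove the most general levels of an ontology
#'
#' Deletes the given classes from the hierarchy and re-parents their
#' children directly to the root, so that exclusion of over-general levels
#' becomes a structural property of the graph rather than a query-time
#' check.  With no `codes` argument, the classes the builder recorded as
#' most general (the ICD-9-CM chapter ranges) are removed.
#'
#' @param O An ontology.
#' @param codes Class codes to delete (default: `O$general`).
#' @return A new ontology.
#' @export
prune_general_levels <- function(O, codes = NULL) {
  if (is.null(codes)) codes <- O$general
  codes <- setdiff(codes, O$root)
  if (!length(codes)) return(O)
  check_class(O, codes)
  parents <- O$parents[setdiff(names(O$parents), codes)]
  for (v in names(parents)) {
    p <- setdiff(parents[[v]], codes)
    if (!length(p) && v != O$root) p <- O$root
    parents[[v]] <- p
  }
  new_ontology(parents, labels = O$labels, kind = O$kind,
               chapters = setdiff(O$chapters, codes),
               general = setdiff(O$general, codes))
}

#' Chapters (first-level classes) containing a phenotype class
#'
#' @param O An ontology with chapter metadata (see [build_icd9_from_codes()]).
#' @param code A phenotype class code.
#' @return Character vector of chapter codes containing `code` (possibly
#'   several on a DAG, empty when the code sits outside every chapter).
#' @export
chapters_of <- function(O, code) {
  intersect(memo_ancestors(O, check_class(O, code)), O$chapters)
}
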