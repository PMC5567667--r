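# Association rules between ADE descriptions, read off the pattern-concept
# lattice.  A rule comes from any comparable pair of concepts (l, r) with
# extent(r) strictly included in extent(l): the left-hand side is delta(l),
# the right-hand side is the description difference delta(r) - delta(l),
# the support is |extent(r)| and the confidence |extent(r)| / |extent(l)|.

new_rule <- function(L, R, combined, support, confidence, extent, source) {
  structure(list(L = L, R = R, combined = combined, support = support,
                 confidence = confidence, extent = extent, source = source),
            class = "ade_rule")
}

#' @export
print.ade_rule <- function(x, ...) {
  cat(sprintf("<ade_rule> support %d, confidence %.3f\n  L: %s\n  R: %s\n",
              x$support, x$confidence, format_description(x$L),
              format_description(x$R)))
  invisible(x)
}

#' Compact textual form of a description
#'
#' @param d A description.
#' @return A character string.
#' @export
format_description <- function(d) {
  if (inherits(d, "ade_set")) {
    if (!length(d)) return("{}")
    paste0("{", paste(vapply(unclass(d), function(v)
      sprintf("<{%s},{%s}>", paste(v$D, collapse = ","),
              paste(v$P, collapse = ",")), ""), collapse = ", "), "}")
  } else {
    parts <- vapply(names(d), function(ch) {
      if (!length(d[[ch]])) return(NA_character_)
      sprintf("%s:{%s}", ch, paste(vapply(d[[ch]], function(p)
        paste0("{", paste(p, collapse = ","), "}"), ""), collapse = ","))
    }, "")
    parts <- parts[!is.na(parts)]
    if (!length(parts)) "{}" else paste(parts, collapse = " | ")
  }
}

#' Extract association rules from a pattern-concept lattice
#'
#' Considers every ordered pair of comparable concepts (not only lattice
#' neighbours), scores it, keeps rules meeting the support and confidence
#' thresholds, and collapses rules sharing the same (L, R) sides to the
#' instance with the largest support.
#'
#' @param lat A `pattern_lattice` built with `min_extent <= min_support`.
#' @param min_support Minimum number of supporting patients (default 5).
#' @param min_confidence Minimum confidence (default 0.75).
#' @return An `ade_rules` collection.  `attr(, "n_collapsed")` counts the
#'   duplicate (L, R) instances removed.
#' @export
extract_rules <- function(lat, min_support = 5, min_confidence = 0.75) {
  if (lat$min_extent > min_support) {
    stop("lattice was pruned at min_extent = ", lat$min_extent,
         " > min_support = ", min_support)
  }
  space <- lat$ctx$space
  cs <- lat$concepts
  sizes <- lengths(lapply(cs, `[[`, "extent_idx"))
  idx <- which(sizes >= min_support)
  rules <- list()
  for (i in idx) { # candidate general concept l
    for (j in idx) { # candidate specific concept r
      if (i == j) next
      ei <- cs[[i]]$extent_idx; ej <- cs[[j]]$extent_idx
      if (length(ej) >= length(ei) || !all(ej %in% ei)) next
      conf <- length(ej) / length(ei)
      if (conf < min_confidence) next
      R <- desc_diff(space, cs[[i]]$intent, cs[[j]]$intent)
      if (desc_is_empty(R)) next
      rules[[length(rules) + 1L]] <- new_rule(
        L = cs[[i]]$intent, R = R, combined = cs[[j]]$intent,
        support = length(ej), confidence = conf,
        extent = cs[[j]]$extent, source = c(l = i, r = j))
    }
  }
  keys <- vapply(rules, function(r)
    paste(desc_key(r$L), desc_key(r$R), sep = " => "), "")
  keep <- integer()
  for (k in unique(keys)) {
    grp <- which(keys == k)
    grp <- grp[order(-vapply(rules[grp], `[[`, 0L, "support"),
                     -vapply(rules[grp], `[[`, 0, "confidence"))]
    keep <- c(keep, grp[1L])
  }
  out <- structure(list(rules = rules[sort(keep)], space = space,
                        min_support = min_support,
                        min_confidence = min_confidence),
                   class = "ade_rules")
  attr(out, "n_collapsed") <- length(rules) - length(keep)
  out
}

#' @export
print.ade_rules <- function(x, ...) {
  cat(sprintf("<ade_rules> %d rules (min support %d, min confidence %.2f)\n",
              length(x$rules), x$min_support, x$min_confidence))
  invisible(x)
}

#' @export
length.ade_rules <- function(x) length(x$rules)

## ---- rule filters ----------------------------------------------------------

classes_comparable <- function(x, y, O) {
  leq_class_sets(x, y, O) || leq_class_sets(y, x, O)
}

# (drug classes, phenotype classes) pairs of a rule side, in a uniform shape
# across dialects: for dialects 1/2 the chapter key is the phenotype handle.
side_ade_pairs <- function(d, dialect) {
  if (inherits(d, "ade_set")) {
    lapply(unclass(d), function(v) list(D = v$D, P = v$P))
  } else {
    out <- list()
    for (ch in names(d)) {
      for (p in d[[ch]]) out[[length(out) + 1L]] <- list(D = p, P = ch)
    }
    out
  }
}

#' Right-hand-side novelty filter
#'
#' Keeps a rule only when its right-hand side contains at least one ADE
#' whose drugs and phenotypes are both unrelated (not comparable in the
#' ontology, in either direction) to those of every ADE of the left-hand
#' side — i.e. the rule genuinely introduces a new ADE rather than a
#' refinement of the left-hand side.  For dialect-1/2 rules the chapter keys
#' act as the phenotype granularity and drug sets are compared with the
#' dialect's own element order.
#'
#' @param rule An `ade_rule`.
#' @param space The `pattern_space` the rule was mined in.
#' @return `TRUE` to keep the rule, `FALSE` to drop it.
#' @export
rhs_novelty_filter <- function(rule, space) {
  Ls <- side_ade_pairs(rule$L, space$dialect)
  Rs <- side_ade_pairs(rule$R, space$dialect)
  if (!length(Rs)) return(FALSE)
  drug_cmp <- if (space$dialect == 1L) {
    function(x, y) all(x %in% y) || all(y %in% x)
  } else {
    function(x, y) classes_comparable(x, y, space$drug_ontology)
  }
  phen_cmp <- if (space$dialect == 3L) {
    function(x, y) classes_comparable(x, y, space$phen_ontology)
  } else {
    function(x, y) identical(x, y) # chapter keys
  }
  any(vapply(Rs, function(r) {
    !any(vapply(Ls, function(l)
      drug_cmp(r$D, l$D) || phen_cmp(r$P, l$P), TRUE))
  }, TRUE))
}

#' Phenotype exclusion filter
#'
#' Drops rules mentioning, on either side, a phenotype class equal to or a
#' descendant of any excluded class (e.g. the disease the cohort was
#' selected on, so that disease-related phenotypes do not masquerade as
#' ADEs).
#'
#' @param rule An `ade_rule`.
#' @param space The `pattern_space` the rule was mined in.
#' @param excluded Character vector of excluded phenotype class codes.
#' @return `TRUE` to keep the rule, `FALSE` to drop it.
#' @export
phenotype_exclusion_filter <- function(rule, space, excluded = "710") {
  O <- space$phen_ontology
  if (is.null(O)) stop("phenotype exclusion requires a phenotype ontology")
  check_class(O, excluded)
  phen <- unique(unlist(lapply(c(side_ade_pairs(rule$L, space$dialect),
                                 side_ade_pairs(rule$R, space$dialect)),
                               `[[`, "P"), use.names = FALSE))
  phen <- intersect(phen, ontology_classes(O))
  !any(vapply(phen, function(p)
    any(vapply(excluded, function(ex) is_ancestor(O, ex, p), TRUE)), TRUE))
}

#' Apply the standard rule filters to a rule collection
#'
#' @param rules An `ade_rules` collection.
#' @param excluded Excluded phenotype classes (`NULL` disables the
#'   exclusion filter).
#' @param novelty Apply [rhs_novelty_filter()]?
#' @return The filtered `ade_rules`; `attr(, "drop_reasons")` logs one
#'   reason per dropped rule.
#' @export
filter_rules <- function(rules, excluded = "710", novelty = TRUE) {
  space <- rules$space
  keep <- rep(TRUE, length(rules$rules))
  reasons <- character()
  for (i in seq_along(rules$rules)) {
    r <- rules$rules[[i]]
    if (novelty && !rhs_novelty_filter(r, space)) {
      keep[i] <- FALSE
      reasons <- c(reasons, sprintf("rule %d: right-hand side not novel", i))
    } else if (!is.null(excluded) &&
               !phenotype_exclusion_filter(r, space, excluded)) {
      keep[i] <- FALSE
      reasons <- c(reasons, sprintf("rule %d: excluded phenotype class", i))
    }
  }
  out <- rules
  out$rules <- rules$rules[keep]
  attr(out, "drop_reasons") <- reasons
  out
}

#' Support of a rule in another cohort
#'
#' Re-evaluates a mined rule against a second patient population (same
#' dialect and ontologies): the number of patients whose description
#' refines the rule's combined description (left- and right-hand sides
#' together).  Replaces, at desk scale, the re-evaluation of rules as
#' database queries over a full clinical warehouse.
#'
#' @param rule An `ade_rule`.
#' @param ctx2 A `pattern_context` over the second cohort.
#' @return Integer support.
#' @export
evaluate_rule_on_cohort <- function(rule, ctx2) {
  if (inherits(rule$combined, "ade_set") != (ctx2$space$dialect == 3L)) {
    stop("rule dialect does not match the evaluation context")
  }
  if (!inherits(rule$combined, "ade_set") &&
      !identical(names(rule$combined), ctx2$space$chapters)) {
    stop("chapter keys of the rule and the evaluation context differ")
  }
  length(derive_extent(rule$combined, ctx2))
}

## ---- serialization ---------------------------------------------------------

#' Write rules as TSV and JSON lines
#'
#' The TSV carries the human-readable sides plus support, confidence and
#' provenance; the JSON lines carry the full structural serialization.
#' Both are emitted in a stable, sorted order.
#'
#' @param rules An `ade_rules` collection.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
rules_to_tsv <- function(rules, path) {
  rs <- rules$rules
  tab <- data.frame(
    L = vapply(rs, function(r) format_description(r$L), ""),
    R = vapply(rs, function(r) format_description(r$R), ""),
    support = vapply(rs, `[[`, 0L, "support"),
    confidence = vapply(rs, `[[`, 0, "confidence"),
    concept_l = vapply(rs, function(r) r$source[["l"]], 0L),
    concept_r = vapply(rs, function(r) r$source[["r"]], 0L),
    patients = vapply(rs, function(r) paste(r$extent, collapse = ";"), ""))
  tab <- tab[order(-tab$support, tab$L, tab$R), , drop = FALSE]
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname rules_to_tsv
#' @export
rules_to_jsonl <- function(rules, path) {
  con <- file(path, "w")
  on.exit(close(con))
  rs <- rules$rules
  ord <- order(-vapply(rs, `[[`, 0L, "support"),
               vapply(rs, function(r) desc_key(r$L), ""))
  for (r in rs[ord]) {
    writeLines(jsonlite::toJSON(list(
      L = desc_to_list(r$L), R = desc_to_list(r$R),
      support = r$support, confidence = r$confidence,
      extent = r$extent, source = as.list(r$source)),
      auto_unbox = TRUE), con)
  }
  invisible(path)
}
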