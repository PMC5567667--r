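# Aggregation of mined rules into drug-class co-association ratios and a
# Z-test of their deviation from the ratio expected if right-hand-side
# classes were distributed proportionally across rules.

#' Combined support of a set of rules
#'
#' The number of distinct patients matched by at least one of the rules
#' (a patient can verify several rules, so supports are united, not summed).
#'
#' @param rules A list of `ade_rule` objects or an `ade_rules` collection.
#' @return Integer.
#' @export
combined_support <- function(rules) {
  if (inherits(rules, "ade_rules")) rules <- rules$rules
  length(unique(unlist(lapply(rules, `[[`, "extent"), use.names = FALSE)))
}

# Does a class (or one of its subclasses) appear among the drug classes of a
# rule side?
side_mentions_class <- function(d, cls, drug_O, dialect) {
  codes <- unique(unlist(lapply(side_ade_pairs(d, dialect), `[[`, "D"),
                         use.names = FALSE))
  codes <- intersect(codes, ontology_classes(drug_O))
  any(vapply(codes, function(cc) is_ancestor(drug_O, cls, cc), TRUE))
}

rules_with_class <- function(rules, cls, side = c("L", "R")) {
  side <- match.arg(side)
  drug_O <- rules$space$drug_ontology
  sel <- vapply(rules$rules, function(r)
    side_mentions_class(r[[side]], cls, drug_O, rules$space$dialect), TRUE)
  rules$rules[sel]
}

#' Expected right-hand-side ratio of a drug class
#'
#' The combined support of rules with `r_class` (or a subclass) in their
#' right-hand side, divided by the combined support of all rules: the ratio
#' one would see for any left-hand class if right-hand classes were
#' distributed proportionally.
#'
#' @param r_class An ATC class code.
#' @param rules An `ade_rules` collection (dialect with a drug ontology).
#' @return A fraction in `[0, 1]`.
#' @export
expected_ratio <- function(r_class, rules) {
  if (!length(rules$rules)) stop("empty rule set")
  combined_support(rules_with_class(rules, r_class, "R")) /
    combined_support(rules)
}

#' Drug-class pair association ratios with significance tests
#'
#' For every ordered pair (l, r) of the given ATC classes: `n_l` is the
#' combined support of rules where `l` or a subclass appears in the
#' left-hand side; `n_pair` the combined support of the subset of those
#' rules where `r` or a subclass appears in the right-hand side; `ratio =
#' n_pair / n_l` measures how often rules about `l`-ADEs also point to an
#' `r`-ADE.  Each ratio is compared to the class's [expected_ratio()] with a
#' one-proportion Z-test (two-sided normal approximation)
#' `z = (ratio - expected) / sqrt(expected (1 - expected) / n_l)`.
#'
#' @param rules An `ade_rules` collection.
#' @param classes Character vector of ATC class codes to cross (rows and
#'   columns); mixed hierarchy levels are allowed.
#' @param alpha Significance level (default 0.001).
#' @return Data frame with one row per (l, r) pair: `l_class`, `r_class`,
#'   `n_l`, `n_r`, `n_pair`, `ratio`, `expected`, `z`, `p`, `significant`.
#'   Cells with `n_l = 0` or a degenerate expected ratio (0 or 1) are
#'   marked untestable (`NA` z and p).
#' @export
pair_ratio_matrix <- function(rules, classes, alpha = 0.001) {
  drug_O <- rules$space$drug_ontology
  check_class(drug_O, classes)
  rows <- list()
  for (l in classes) {
    l_rules <- rules_with_class(rules, l, "L")
    n_l <- combined_support(l_rules)
    for (r in classes) {
      n_r <- combined_support(rules_with_class(rules, r, "R"))
      sub <- structure(list(rules = l_rules, space = rules$space),
                       class = "ade_rules")
      pair_rules <- rules_with_class(sub, r, "R")
      n_pair <- combined_support(pair_rules)
      ratio <- if (n_l > 0) n_pair / n_l else NA_real_
      expected <- expected_ratio(r, rules)
      cell <- z_test_cell(list(l_class = l, r_class = r, n_l = n_l,
                               n_r = n_r, n_pair = n_pair, ratio = ratio,
                               expected = expected), alpha = alpha)
      rows[[length(rows) + 1L]] <- as.data.frame(cell)
    }
  }
  do.call(rbind, rows)
}

#' Z-test of an observed pair ratio against its expected value
#'
#' @param cell A list with at least `ratio`, `expected` and `n_l`.
#' @param alpha Significance level (default 0.001).
#' @return The cell completed with `z`, two-sided `p` and `significant`;
#'   untestable cells (`n_l = 0`, or expected ratio of exactly 0 or 1)
#'   carry `NA`s.
#' @export
z_test_cell <- function(cell, alpha = 0.001) {
  testable <- !is.na(cell$ratio) && cell$n_l > 0 &&
    cell$expected > 0 && cell$expected < 1
  if (testable) {
    cell$z <- (cell$ratio - cell$expected) /
      sqrt(cell$expected * (1 - cell$expected) / cell$n_l)
    cell$p <- 2 * stats::pnorm(-abs(cell$z))
    cell$significant <- cell$p < alpha
  } else {
    cell$z <- NA_real_
    cell$p <- NA_real_
    cell$significant <- NA
  }
  cell
}

#' Write a pair-ratio table as TSV
#'
#' @param tab Output of [pair_ratio_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
pair_ratios_to_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
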