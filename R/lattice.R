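# Pattern-concept lattices.  A pattern structure is a triple (G, (D, meet),
# delta): patients, a description semilattice, and the map from patients to
# descriptions.  The derivation operators
#
#   intent(A) = meet of delta(g) over g in A
#   extent(d) = { g in G | d <= delta(g) }
#
# form a Galois connection; their fixed pairs (A, d) are the pattern
# concepts, enumerated here with a CloseByOne-style canonical closure search
# over extents.

#' Build a pattern-structure context from a cohort
#'
#' Describes every patient of the cohort in the given pattern space and
#' packages patients, descriptions and the dialect meet together with a
#' memoization pool (meets and order checks are cached by canonical
#' description keys, which dominates lattice-building cost).
#'
#' @param cohort An `ade_cohort` (see [select_multi_ade_patients()]), or a
#'   named list of pre-computed descriptions via `delta`.
#' @param space A `pattern_space`.
#' @param drug_map Drug-to-ATC-class map for dialects 2 and 3.
#' @param delta Optionally, a named list patient id -> description, bypassing
#'   [describe_patient()].
#' @return A `pattern_context`.
#' @export
pattern_context <- function(cohort = NULL, space, drug_map = NULL,
                            delta = NULL) {
  if (is.null(delta)) {
    stopifnot(inherits(cohort, "ade_cohort"))
    delta <- lapply(cohort$patients, describe_patient, space = space,
                    drug_map = drug_map)
  }
  if (is.null(names(delta)) || anyNA(names(delta)) || any(!nzchar(names(delta)))) {
    stop("every patient needs an id (names of delta)")
  }
  delta <- delta[sort(names(delta))]
  memo <- new.env(parent = emptyenv())
  memo$pool <- new.env(parent = emptyenv())
  memo$meets <- new.env(parent = emptyenv())
  memo$extents <- new.env(parent = emptyenv())
  ctx <- structure(list(G = names(delta), delta = delta, space = space,
                        memo = memo), class = "pattern_context")
  for (d in delta) assign(desc_key(d), d, envir = memo$pool)
  ctx
}

#' @export
print.pattern_context <- function(x, ...) {
  cat(sprintf("<pattern_context> %d patients, dialect %d\n",
              length(x$G), x$space$dialect))
  invisible(x)
}

ctx_meet <- function(ctx, X, Y) {
  kx <- desc_key(X); ky <- desc_key(Y)
  if (identical(kx, ky)) return(X)
  key <- if (kx < ky) paste0(kx, "\r&\r", ky) else paste0(ky, "\r&\r", kx)
  rk <- get0(key, envir = ctx$memo$meets, ifnotfound = NULL)
  if (!is.null(rk)) return(get(rk, envir = ctx$memo$pool))
  res <- ps_meet(ctx$space, X, Y)
  rk <- desc_key(res)
  if (is.null(get0(rk, envir = ctx$memo$pool, ifnotfound = NULL))) {
    assign(rk, res, envir = ctx$memo$pool)
  }
  assign(key, rk, envir = ctx$memo$meets)
  get(rk, envir = ctx$memo$pool)
}

ctx_leq <- function(ctx, X, Y) {
  identical(desc_key(ctx_meet(ctx, X, Y)), desc_key(X))
}

#' Galois derivation operators
#'
#' `derive_intent(A, ctx)` folds the dialect meet over the descriptions of
#' the patients in `A` (order-independent by associativity); it is the most
#' specific description shared by all of them.  `derive_extent(d, ctx)` is
#' the set of patients whose description refines `d`.
#'
#' @param A Character vector of patient ids (non-empty).
#' @param d A description of the context's dialect.
#' @param ctx A `pattern_context`.
#' @return `derive_intent()`: a description; `derive_extent()`: a character
#'   vector of patient ids.
#' @export
derive_intent <- function(A, ctx) {
  A <- as.character(A)
  if (!length(A)) stop("the intent of an empty patient set is undefined")
  missing <- setdiff(A, ctx$G)
  if (length(missing)) stop("unknown patient id(s): ",
                            paste(missing, collapse = ", "))
  Reduce(function(X, Y) ctx_meet(ctx, X, Y), ctx$delta[A])
}

#' @rdname derive_intent
#' @export
derive_extent <- function(d, ctx) {
  ctx$G[vapply(ctx$G, function(g) ctx_leq(ctx, d, ctx$delta[[g]]), TRUE)]
}

extent_indices <- function(d, ctx) {
  key <- desc_key(d)
  hit <- get0(key, envir = ctx$memo$extents, ifnotfound = NULL)
  if (!is.null(hit)) return(hit)
  res <- which(vapply(ctx$G, function(g) ctx_leq(ctx, d, ctx$delta[[g]]), TRUE,
                      USE.NAMES = FALSE))
  assign(key, res, envir = ctx$memo$extents)
  res
}

#' Enumerate the pattern-concept lattice of a context
#'
#' CloseByOne enumeration over extents with a lectic canonicity test:
#' extents are extended one patient at a time in a fixed (sorted-id) order
#' and closed through the derivation operators, so each concept is produced
#' exactly once and runs are bit-reproducible.  Only concepts with a
#' non-empty extent are emitted; `min_extent` then filters the result to the
#' support-pruned ("iceberg") sub-lattice.
#'
#' @param ctx A `pattern_context`.
#' @param min_extent Minimum extent size of reported concepts (default 1).
#' @param max_concepts Resource guard: enumeration aborts (with the partial
#'   count in the error) once this many concepts have been generated.
#' @return A `pattern_lattice`: concepts (extent, intent) ordered by
#'   decreasing extent size, plus the transitive reduction of the
#'   extent-inclusion order (`$parents[[i]]` lists the immediate
#'   generalizations of concept `i`).
#' @export
build_lattice <- function(ctx, min_extent = 1, max_concepts = 2e5) {
  n <- length(ctx$G)
  if (!n) stop("empty cohort: no concepts to build")
  acc <- new.env(parent = emptyenv())
  acc$extents <- list()
  acc$intents <- list()
  acc$count <- 0L

  cbo <- function(extent, intent, minj) {
    acc$count <- acc$count + 1L
    if (acc$count > max_concepts) {
      stop("concept cap exceeded (", max_concepts, " concepts generated; ",
           "partial result discarded) - raise max_concepts or min_extent")
    }
    acc$extents[[acc$count]] <- extent
    acc$intents[[acc$count]] <- intent
    js <- setdiff(seq_len(n), extent)
    js <- js[js > minj]
    for (j in js) {
      ni <- ctx_meet(ctx, intent, ctx$delta[[j]])
      ne <- extent_indices(ni, ctx)
      if (identical(ne[ne < j], extent[extent < j])) cbo(ne, ni, j)
    }
  }
  for (j in seq_len(n)) {
    d <- ctx$delta[[j]]
    e <- extent_indices(d, ctx)
    if (!any(e < j)) cbo(e, d, j)
  }

  keep <- which(lengths(acc$extents) >= min_extent)
  ord <- keep[order(-lengths(acc$extents)[keep])]
  concepts <- lapply(ord, function(i) list(
    extent = ctx$G[acc$extents[[i]]],
    extent_idx = acc$extents[[i]],
    intent = acc$intents[[i]]))
  lat <- structure(list(concepts = concepts, ctx = ctx,
                        min_extent = min_extent,
                        n_concepts_total = length(acc$extents)),
                   class = "pattern_lattice")
  lat$parents <- lattice_parents(lat)
  lat
}

# Immediate generalizations: transitive reduction of strict extent inclusion.
# Concepts are sorted by decreasing extent size, so parents precede children.
lattice_parents <- function(lat) {
  k <- length(lat$concepts)
  ext <- lapply(lat$concepts, `[[`, "extent_idx")
  supersets <- lapply(seq_len(k), function(i) {
    if (i == 1L) return(integer())
    cand <- seq_len(i - 1L)
    cand[vapply(cand, function(j)
      length(ext[[j]]) > length(ext[[i]]) && all(ext[[i]] %in% ext[[j]]),
      TRUE)]
  })
  lapply(seq_len(k), function(i) {
    ss <- supersets[[i]]
    # j is an immediate parent unless some other superset of i lies below it
    ss[!vapply(ss, function(j)
      any(vapply(setdiff(ss, j), function(m) j %in% supersets[[m]], TRUE)),
      TRUE)]
  })
}

#' @export
print.pattern_lattice <- function(x, ...) {
  cat(sprintf(
    "<pattern_lattice> %d concepts (of %d enumerated), min_extent = %d\n",
    length(x$concepts), x$n_concepts_total, x$min_extent))
  invisible(x)
}

#' Number of concepts in a lattice
#' @param lat A `pattern_lattice`.
#' @return Integer.
#' @export
lattice_size <- function(lat) length(lat$concepts)

## ---- serialization ---------------------------------------------------------

desc_to_list <- function(d) {
  if (inherits(d, "ade_set")) {
    list(dialect = 3L,
         ades = lapply(unclass(d), function(v) list(D = v$D, P = v$P)))
  } else {
    list(dialect = attr(d, "dialect"),
         chapters = lapply(unclass(d), function(sd) lapply(sd, identity)))
  }
}

#' Dump a lattice as JSON lines
#'
#' One concept per line: extent (patient ids), intent (serialized
#' description) and parent concept indices (1-based, in file order).
#'
#' @param lat A `pattern_lattice`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
lattice_to_jsonl <- function(lat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(lat$concepts)) {
    cpt <- lat$concepts[[i]]
    writeLines(jsonlite::toJSON(list(
      id = i, extent = cpt$extent, parents = lat$parents[[i]],
      intent = desc_to_list(cpt$intent)), auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Export a small lattice as a DOT diagram
#'
#' @param lat A `pattern_lattice`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
lattice_to_dot <- function(lat, path) {
  lines <- c("digraph lattice {", "  rankdir=BT;")
  for (i in seq_along(lat$concepts)) {
    cpt <- lat$concepts[[i]]
    lines <- c(lines, sprintf(
      '  n%d [label="{%s}", shape=box];', i,
      paste(cpt$extent, collapse = ",")))
  }
  for (i in seq_along(lat$concepts)) {
    for (p in lat$parents[[i]]) {
      lines <- c(lines, sprintf("  n%d -> n%d;", i, p))
    }
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}
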