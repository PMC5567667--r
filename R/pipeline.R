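# End-to-end orchestration: extract -> describe -> lattice -> rules ->
# stats, with a structured config, stage-count logging and reproducible
# artifacts.

#' Assemble a pipeline configuration
#'
#' @param visits Path to a visit TSV, or a visit data frame.
#' @param faers Path to a FAERS-like report TSV, or a data frame (used when
#'   `visits` is absent).
#' @param side_effects Path to a side-effect TSV, or a data frame (required
#'   for the EHR path).
#' @param simulate Optional list of arguments for [generate_cohort()]; when
#'   given, inputs are simulated and the file inputs are ignored.
#' @param dialect Description dialect (1, 2 or 3; default 3).
#' @param max_interval_days Extraction window in days (default 14).
#' @param min_support,min_confidence Rule thresholds (defaults 5 and 0.75).
#' @param min_ades Minimum ADEs per retained patient (default 2).
#' @param alpha Significance level for the pair-ratio Z-tests (default 0.001).
#' @param excluded_phenotypes Phenotype classes whose rules are dropped
#'   (default `"710"`; `NULL` disables).
#' @param novelty_filter Apply the right-hand-side novelty filter (default
#'   `TRUE`).
#' @param ontologies List with `drug` and `phenotype` ontologies (default:
#'   [toy_ontologies()]).
#' @param drug_map Raw-drug-code to ATC-class map (dialects 2 and 3).
#' @param stat_classes ATC classes to cross in the pair-ratio table
#'   (default: every drug class mentioned by a retained rule).
#' @param seed Integer seed for simulation (default 1).
#' @param out_dir Output directory for artifacts (`NULL`: nothing written).
#' @param max_concepts Lattice resource guard (default 2e5).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(visits = NULL, faers = NULL, side_effects = NULL,
                            simulate = NULL, dialect = 3,
                            max_interval_days = 14, min_support = 5,
                            min_confidence = 0.75, min_ades = 2,
                            alpha = 0.001, excluded_phenotypes = "710",
                            novelty_filter = TRUE, ontologies = NULL,
                            drug_map = NULL, stat_classes = NULL, seed = 1,
                            out_dir = NULL, max_concepts = 2e5) {
  cfg <- list(visits = visits, faers = faers, side_effects = side_effects,
              simulate = simulate, dialect = as.integer(dialect),
              max_interval_days = max_interval_days,
              min_support = min_support, min_confidence = min_confidence,
              min_ades = min_ades, alpha = alpha,
              excluded_phenotypes = excluded_phenotypes,
              novelty_filter = novelty_filter, ontologies = ontologies,
              drug_map = drug_map, stat_classes = stat_classes, seed = seed,
              out_dir = out_dir, max_concepts = max_concepts)
  stopifnot(cfg$dialect %in% 1:3, cfg$max_interval_days > 0,
            cfg$min_support > 0, cfg$min_confidence > 0,
            cfg$min_confidence <= 1, cfg$min_ades > 0)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path Path to a YAML file whose keys are [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

stage <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(fmt, ...))
}

#' Run the full ADE association-mining pipeline
#'
#' Executes extract, describe, lattice, rules and stats in
#' order, logging counts at each stage, and (when `out_dir` is set) writes
#' the candidate TSV, the lattice JSONL, the rules JSONL/TSV, the
#' pair-ratio TSV and a JSON run manifest echoing the configuration and the
#' stage counts.
#'
#' @param config A `pipeline_config` (or a list of its arguments).
#' @param quiet Suppress stage messages?
#' @return A list with `cohort`, `space`, `ctx`, `lattice`, `rules`
#'   (unfiltered), `retained` (filtered rules), `stats` and `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) {
    config <- do.call(pipeline_config, config)
  }
  cfg <- config
  sim <- NULL
  if (!is.null(cfg$simulate)) {
    sim <- do.call(generate_cohort,
                   c(cfg$simulate, if (is.null(cfg$simulate$seed))
                     list(seed = cfg$seed)))
    cfg$visits <- sim$visits
    cfg$side_effects <- sim$side_effects
    cfg$drug_map <- sim$drug_map
    if (is.null(cfg$ontologies)) cfg$ontologies <- sim$ontologies
  }
  if (is.null(cfg$ontologies)) cfg$ontologies <- toy_ontologies()
  if (is.character(cfg$drug_map)) cfg$drug_map <- read_drug_map_tsv(cfg$drug_map)
  as_table <- function(x, reader) if (is.character(x)) reader(x) else x

  # -- extract ---------------------------------------------------------------
  if (!is.null(cfg$visits)) {
    visits <- as_table(cfg$visits, read_visits_tsv)
    se <- as_table(cfg$side_effects, read_side_effects_tsv)
    if (is.null(se)) stop("stage extract failed: the EHR path needs a ",
                          "side-effect table")
    cohort <- extract_ehr_cohort(visits, se,
                                 max_interval_days = cfg$max_interval_days,
                                 k = cfg$min_ades)
  } else if (!is.null(cfg$faers)) {
    cohort <- extract_faers_cases(as_table(cfg$faers, read_faers_tsv),
                                  k = cfg$min_ades)
  } else {
    stop("stage extract failed: no input (visits, faers or simulate)")
  }
  stage(quiet, "extract: %d patients, %d ADEs", length(cohort$patients),
        cohort_n_ades(cohort))

  manifest <- list(
    config = list(dialect = cfg$dialect,
                  max_interval_days = cfg$max_interval_days,
                  min_support = cfg$min_support,
                  min_confidence = cfg$min_confidence,
                  min_ades = cfg$min_ades, alpha = cfg$alpha,
                  excluded_phenotypes = cfg$excluded_phenotypes,
                  seed = cfg$seed),
    counts = list(patients = length(cohort$patients),
                  ades = cohort_n_ades(cohort)))

  empty_result <- function() {
    manifest$counts <- c(manifest$counts, list(
      concepts = 0L, rules_extracted = 0L, rules_retained = 0L,
      max_support = 0L))
    list(cohort = cohort, space = NULL, ctx = NULL, lattice = NULL,
         rules = NULL, retained = NULL, stats = NULL, manifest = manifest)
  }

  # -- describe --------------------------------------------------------------
  space <- if (cfg$dialect == 3L) {
    pattern_space(3L, drug_ontology = cfg$ontologies$drug,
                  phen_ontology = prune_general_levels(cfg$ontologies$phenotype))
  } else {
    pattern_space(cfg$dialect, drug_ontology = cfg$ontologies$drug,
                  phen_ontology = cfg$ontologies$phenotype)
  }
  if (!length(cohort$patients)) {
    res <- empty_result()
    if (!is.null(cfg$out_dir)) write_artifacts(res, cfg, quiet)
    return(res)
  }
  ctx <- pattern_context(cohort, space, drug_map = cfg$drug_map)
  stage(quiet, "describe: dialect %d, %d descriptions", cfg$dialect,
        length(ctx$G))

  # -- lattice ---------------------------------------------------------------
  lat <- build_lattice(ctx, min_extent = cfg$min_support,
                       max_concepts = cfg$max_concepts)
  stage(quiet, "lattice: %d concepts kept of %d enumerated",
        lattice_size(lat), lat$n_concepts_total)

  # -- rules -----------------------------------------------------------------
  rules <- extract_rules(lat, min_support = cfg$min_support,
                         min_confidence = cfg$min_confidence)
  retained <- filter_rules(rules, excluded = cfg$excluded_phenotypes,
                           novelty = cfg$novelty_filter)
  max_support <- if (length(retained$rules))
    max(vapply(retained$rules, `[[`, 0L, "support")) else 0L
  stage(quiet, "rules: %d extracted, %d retained, max support %d",
        length(rules$rules), length(retained$rules), max_support)

  # -- stats -----------------------------------------------------------------
  stats_tab <- NULL
  if (cfg$dialect >= 2L && length(retained$rules)) {
    classes <- cfg$stat_classes
    if (is.null(classes)) {
      classes <- sort(unique(unlist(lapply(retained$rules, function(r)
        c(unlist(lapply(side_ade_pairs(r$L, cfg$dialect), `[[`, "D")),
          unlist(lapply(side_ade_pairs(r$R, cfg$dialect), `[[`, "D")))),
        use.names = FALSE)))
      classes <- intersect(classes, ontology_classes(space$drug_ontology))
    }
    if (length(classes)) {
      stats_tab <- pair_ratio_matrix(retained, classes, alpha = cfg$alpha)
    }
  }

  manifest$counts <- c(manifest$counts, list(
    concepts = lattice_size(lat),
    concepts_enumerated = lat$n_concepts_total,
    rules_extracted = length(rules$rules),
    rules_retained = length(retained$rules),
    max_support = max_support))

  res <- list(cohort = cohort, space = space, ctx = ctx, lattice = lat,
              rules = rules, retained = retained, stats = stats_tab,
              manifest = manifest, truth = if (!is.null(sim)) sim$truth)
  if (!is.null(cfg$out_dir)) write_artifacts(res, cfg, quiet)
  res
}

write_artifacts <- function(res, cfg, quiet = FALSE) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(cfg$out_dir, f)
  write_candidates_tsv(res$cohort, path("candidates.tsv"))
  if (!is.null(res$lattice)) lattice_to_jsonl(res$lattice, path("lattice.jsonl"))
  if (!is.null(res$retained)) {
    rules_to_tsv(res$retained, path("rules.tsv"))
    rules_to_jsonl(res$retained, path("rules.jsonl"))
  } else {
    writeLines("L\tR\tsupport\tconfidence\tconcept_l\tconcept_r\tpatients",
               path("rules.tsv"))
    file.create(path("rules.jsonl"))
  }
  if (!is.null(res$stats)) pair_ratios_to_tsv(res$stats, path("stats.tsv"))
  jsonlite::write_json(res$manifest, path("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  stage(quiet, "artifacts written to %s", cfg$out_dir)
  invisible(cfg$out_dir)
}
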