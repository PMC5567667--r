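# Synthetic inputs: toy drug and phenotype ontologies, a small worked
# example cohort, and a visit-level cohort generator with planted ADE
# associations and a matching side-effect table, so that the whole pipeline
# is testable without access to any clinical database.

toy_atc_codes <- c(
  "A02B", "A02BC", "A04A", "A06A", "A07A", "B01A", "B03X", "B05X",
  "C01BB03", "C03C", "C05B", "C07A", "C08D", "C08DB", "C09A", "C10A",
  "G04BE", "G04BE04", "H02A", "H02AA03", "H02AB", "H02AB07", "N02A",
  "N02B", "N02BE01", "N05B", "N05C", "N06BC", "N06BC01", "R05D", "R06A",
  "R06AA", "R06AA09", "S01A", "S01AX")

toy_atc_labels <- c(
  A02B = "Drugs for peptic ulcer and gastro-oesophageal reflux disease",
  A02BC = "Proton pump inhibitors", A04A = "Antiemetics and antinauseants",
  A06A = "Drugs for constipation", A07A = "Intestinal antiinfectives",
  B01A = "Antithrombotic agents", B03X = "Other antianemic preparations",
  B05X = "I.V. solution additives", C01BB03 = "Tocainide",
  C03C = "High-ceiling diuretics", C05B = "Antivaricose therapy",
  C07A = "Beta blocking agents",
  C08D = "Selective calcium channel blockers with direct cardiac effects",
  C08DB = "Benzothiazepine derivatives", C09A = "Ace inhibitors, plain",
  C10A = "Lipid modifying agents, plain",
  G04BE = "Drugs used in erectile dysfunction", G04BE04 = "Yohimbin",
  H02A = "Corticosteroids for systemic use, plain",
  H02AA03 = "Desoxycortone", H02AB = "Glucocorticoids",
  H02AB07 = "Prednisone", N02A = "Opioids",
  N02B = "Other analgesics and antipyretics", N02BE01 = "Acetaminophen",
  N05B = "Anxiolytics", N05C = "Hypnotics and sedatives",
  N06BC = "Xanthine derivatives", N06BC01 = "Caffeine",
  R05D = "Cough suppressants", R06A = "Antihistamines for systemic use",
  R06AA = "Aminoalkyl ethers", R06AA09 = "Doxylamine",
  S01A = "Antiinfectives", S01AX = "Other antiinfectives")

toy_icd_codes <- c("280", "285.9", "287.5", "427.31", "428", "428.0",
                   "428.9", "580", "586", "599.8", "599.9", "710", "719.4")

toy_icd_labels <- c(
  "280-289" = "Diseases of the blood and blood-forming organs",
  "280" = "Iron deficiency anemias", "285.9" = "Anemia, unspecified",
  "287.5" = "Thrombocytopenia, unspecified",
  "390-459" = "Diseases of the circulatory system",
  "427.31" = "Atrial fibrillation", "428" = "Heart failure",
  "428.0" = "Congestive heart failure, unspecified",
  "428.9" = "Heart failure, unspecified",
  "580-629" = "Diseases of the genitourinary system",
  "580" = "Acute glomerulonephritis", "586" = "Renal failure, unspecified",
  "599.8" = "Other specified disorders of urethra and urinary tract",
  "599.9" = "Unspecified disorder of urethra and urinary tract",
  "710-739" = "Diseases of the musculoskeletal system and connective tissue",
  "710" = "Diffuse diseases of connective tissue", "719.4" = "Pain in joint")

# The standard ICD-9-CM chapter ranges, so every toy code finds a chapter.
icd9_standard_chapters <- c(
  "001-139", "140-239", "240-279", "280-289", "290-319", "320-389",
  "390-459", "460-519", "520-579", "580-629", "630-679", "680-709",
  "710-739", "740-759", "760-779", "780-799", "800-999")

#' Toy drug and phenotype ontologies
#'
#' Small, fixed ATC and ICD-9-CM fragments covering the codes used in the
#' package's worked examples: corticosteroids (`H02A` and descendants),
#' analgesics, antithrombotics, urinary-tract and musculoskeletal phenotype
#' classes, etc.
#'
#' @return A list with elements `drug` (ATC-style ontology) and `phenotype`
#'   (ICD-9-CM-style ontology with standard chapter ranges).
#' @export
toy_ontologies <- function() {
  list(drug = build_atc_from_codes(toy_atc_codes, labels = toy_atc_labels),
       phenotype = build_icd9_from_codes(toy_icd_codes,
                                         chapters = icd9_standard_chapters,
                                         labels = toy_icd_labels))
}

#' Drug-name to ATC-class map for the worked examples
#'
#' @return Named list mapping drug names to ATC class codes.
#' @export
toy_drug_map <- function() {
  list(prednisone = "H02AB07", acetaminophen = "N02BE01",
       desoxycortone = "H02AA03", yohimbine = "G04BE04",
       caffeine = "N06BC01", doxylamine = "R06AA09", tocainide = "C01BB03")
}

#' The running-example cohort of three (or four) patients
#'
#' Three patients with two ADEs each over prednisone/acetaminophen and
#' urinary-tract or joint phenotypes; the optional fourth patient carries a
#' single desoxycortone ADE and is used to illustrate generalization to the
#' shared corticosteroid class.  The candidates are taken as given (no
#' extraction filters are applied).
#'
#' @param include_p4 Add the fourth patient?
#' @return An `ade_cohort`.
#' @export
example_cohort <- function(include_p4 = FALSE) {
  p <- list(
    P1 = list(new_candidate("P1", "acetaminophen", "599.9"),
              new_candidate("P1", "prednisone", "599.8")),
    P2 = list(new_candidate("P2", "prednisone", "599.8"),
              new_candidate("P2", "prednisone", "719.4")),
    P3 = list(new_candidate("P3", "acetaminophen", "719.4"),
              new_candidate("P3", c("acetaminophen", "prednisone"), "599.9")))
  if (include_p4) {
    p$P4 <- list(new_candidate("P4", "desoxycortone", "599.8"))
  }
  structure(list(patients = p), class = "ade_cohort")
}

#' Pattern space matching the worked examples
#'
#' Dialects 1 and 2 use the two chapters of the running example
#' (genitourinary 580-629 and musculoskeletal 710-739); dialect 3 uses the
#' toy ontologies with the ICD chapter level pruned away.
#'
#' @param dialect 1, 2 or 3.
#' @return A `pattern_space`.
#' @export
example_space <- function(dialect) {
  onto <- toy_ontologies()
  if (dialect == 3L) {
    pattern_space(3L, drug_ontology = onto$drug,
                  phen_ontology = prune_general_levels(onto$phenotype))
  } else {
    pattern_space(dialect, drug_ontology = onto$drug,
                  phen_ontology = onto$phenotype,
                  chapters = c("580-629", "710-739"))
  }
}

#' Flat ontology: every code a direct child of the root
#'
#' With a flat ontology the ontology meet degenerates to equality testing,
#' which reduces the dialect-3 pattern structure to classical formal concept
#' analysis on binary attributes.
#'
#' @param codes Character vector of class codes.
#' @return An ontology.
#' @export
flat_ontology <- function(codes) {
  root <- ontology_root()
  parents <- stats::setNames(as.list(rep(root, length(codes))), codes)
  new_ontology(parents, kind = "flat")
}

#' Encode a binary patient-by-attribute context as a dialect-3 structure
#'
#' Each binary attribute `a` becomes a distinct ADE vector `<{d.a}, {p.a}>`
#' over flat ontologies, so that dialect-3 mining on the resulting context
#' is exactly classical FCA on the original binary table.
#'
#' @param membership Named list: patient id -> character vector of attribute
#'   names.
#' @return A `pattern_context`.
#' @export
binary_ade_context <- function(membership) {
  attrs <- sort(unique(unlist(membership, use.names = FALSE)))
  drug_O <- flat_ontology(paste0("d.", attrs))
  phen_O <- flat_ontology(paste0("p.", attrs))
  space <- pattern_space(3L, drug_ontology = drug_O, phen_ontology = phen_O)
  delta <- lapply(membership, function(as)
    ade_set(lapply(as, function(a)
      ade_vector(paste0("d.", a), paste0("p.", a)))))
  pattern_context(space = space, delta = delta)
}

## ---- cohort generator ------------------------------------------------------

#' Declare a planted ADE association
#'
#' A pair of ADE templates given to [generate_cohort()]: `carrier_count`
#' patients experience both ADEs, `exclusive_count` additional patients
#' experience only `ade_a` (so that the association is a proper rule with
#' confidence below 1 rather than an indistinguishable co-occurrence).
#'
#' @param ade_a,ade_b Lists with fields `drugs` (ATC leaf classes) and
#'   `phenotypes` (phenotype leaf classes).
#' @param carrier_count Number of patients given both ADEs (default 10).
#' @param exclusive_count Number of patients given only `ade_a` (default
#'   `carrier_count %/% 4`, keeping the planted confidence at about 0.8).
#' @return A `planted_association`.
#' @export
planted_association <- function(
    ade_a = list(drugs = "H02AB07", phenotypes = "599.8"),
    ade_b = list(drugs = "N02BE01", phenotypes = "285.9"),
    carrier_count = 10, exclusive_count = max(2L, carrier_count %/% 4L)) {
  structure(list(ade_a = ade_a, ade_b = ade_b,
                 carrier_count = as.integer(carrier_count),
                 exclusive_count = as.integer(exclusive_count)),
            class = "planted_association")
}

#' Leaf classes of an ontology
#' @param O An ontology.
#' @return Character vector of codes with no children.
#' @export
ontology_leaves <- function(O) {
  all_parents <- unique(unlist(O$parents, use.names = FALSE))
  setdiff(ontology_classes(O), all_parents)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic visit-level cohort with planted ADE associations
#'
#' Emulates the structure of a longitudinal EHR extract: each ADE of a
#' patient is realized as a pair of visits seven days apart — drugs
#' prescribed at the first, phenotypes diagnosed at the second — with
#' successive pairs spaced well beyond the extraction window.  Carrier
#' patients of each planted association receive both template ADEs,
#' exclusive patients only the first; every other patient receives two
#' distinct background ADEs drawn from the toy ontology leaves that are
#' hierarchy-incomparable with all planted classes, and with probability
#' `noise_rate` any patient gains one extra background ADE.  The
#' side-effect table covers every emitted (drug, phenotype) pair plus a few
#' decoy pairs.
#'
#' @param n_patients Cohort size (default 100).
#' @param plants List of [planted_association()] objects.
#' @param noise_rate Per-patient probability of one extra random ADE
#'   (default 0).
#' @param n_decoys Decoy pairs added to the side-effect table (default 5).
#' @param seed Integer seed; generation is a single pseudo-random stream,
#'   so equal seeds give byte-identical outputs.
#' @return A list: `visits` (data frame), `side_effects` (data frame),
#'   `drug_map` (raw drug code -> ATC class), `truth` (per plant: carrier
#'   and exclusive patient ids plus class-level templates), `ontologies`.
#' @export
generate_cohort <- function(n_patients = 100,
                            plants = list(planted_association()),
                            noise_rate = 0, n_decoys = 5, seed = 1) {
  onto <- toy_ontologies()
  planted_drugs <- unique(unlist(lapply(plants, function(pl)
    c(pl$ade_a$drugs, pl$ade_b$drugs)), use.names = FALSE))
  planted_phen <- unique(unlist(lapply(plants, function(pl)
    c(pl$ade_a$phenotypes, pl$ade_b$phenotypes)), use.names = FALSE))
  check_class(onto$drug, planted_drugs)
  check_class(onto$phenotype, planted_phen)
  incomparable <- function(leaves, planted, O) {
    leaves[!vapply(leaves, function(cc) any(vapply(planted, function(pp)
      is_ancestor(O, cc, pp) || is_ancestor(O, pp, cc), TRUE)), TRUE)]
  }
  drug_pool <- incomparable(ontology_leaves(onto$drug), planted_drugs,
                            onto$drug)
  phen_pool <- incomparable(
    setdiff(ontology_leaves(onto$phenotype), onto$phenotype$general),
    planted_phen, onto$phenotype)
  need <- sum(vapply(plants, function(pl)
    pl$carrier_count + pl$exclusive_count, 0L))
  if (need > n_patients) {
    stop("planted associations need ", need, " patients but n_patients = ",
         n_patients)
  }
  ids <- sprintf("P%03d", seq_len(n_patients))

  with_seed(seed, {
    avail <- sample(ids) # randomized assignment order
    truth <- list()
    ades <- stats::setNames(vector("list", n_patients), ids)
    for (k in seq_along(plants)) {
      pl <- plants[[k]]
      carriers <- sort(avail[seq_len(pl$carrier_count)])
      avail <- avail[-seq_len(pl$carrier_count)]
      exclusives <- sort(avail[seq_len(pl$exclusive_count)])
      avail <- avail[-seq_len(pl$exclusive_count)]
      for (g in carriers) ades[[g]] <- list(pl$ade_a, pl$ade_b)
      for (g in exclusives) ades[[g]] <- list(pl$ade_a)
      truth[[k]] <- list(plant = unclass(pl), carriers = carriers,
                         exclusives = exclusives)
    }
    background_ade <- function(exclude_drugs) {
      pool <- setdiff(drug_pool, exclude_drugs)
      list(drugs = sample(pool, 1L), phenotypes = sample(phen_pool, 1L))
    }
    for (g in ids) {
      want <- max(0L, 2L - length(ades[[g]]))
      for (i in seq_len(want)) {
        used <- unlist(lapply(ades[[g]], `[[`, "drugs"), use.names = FALSE)
        ades[[g]] <- c(ades[[g]], list(background_ade(used)))
      }
      if (noise_rate > 0 && stats::runif(1) < noise_rate) {
        used <- unlist(lapply(ades[[g]], `[[`, "drugs"), use.names = FALSE)
        ades[[g]] <- c(ades[[g]], list(background_ade(used)))
      }
    }
    rows <- list()
    se_pairs <- character()
    for (g in ids) {
      for (i in seq_along(ades[[g]])) {
        base <- 40L * (i - 1L) + sample(0:10, 1L)
        a <- ades[[g]][[i]]
        raw <- paste0("d_", a$drugs)
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = g, date = as.character(as.Date("2013-01-01") + base),
          drug_codes = paste(raw, collapse = ";"), dx_codes = "")
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = g,
          date = as.character(as.Date("2013-01-01") + base + 7L),
          drug_codes = "", dx_codes = paste(a$phenotypes, collapse = ";"))
        se_pairs <- c(se_pairs, as.vector(outer(raw, a$phenotypes,
                                                paste, sep = "\r")))
      }
    }
    se_pairs <- unique(se_pairs)
    for (i in seq_len(n_decoys)) {
      se_pairs <- c(se_pairs, paste(paste0("d_", sample(drug_pool, 1L)),
                                    sample(phen_pool, 1L), sep = "\r"))
    }
    se_pairs <- unique(se_pairs)
    visits <- do.call(rbind, rows)
    visits <- visits[order(visits$patient_id, visits$date), , drop = FALSE]
    rownames(visits) <- NULL
    se_split <- strsplit(se_pairs, "\r", fixed = TRUE)
    side_effects <- data.frame(
      drug_code = vapply(se_split, `[[`, "", 1L),
      phenotype_code = vapply(se_split, `[[`, "", 2L))
    side_effects <- side_effects[order(side_effects$drug_code,
                                       side_effects$phenotype_code), ,
                                 drop = FALSE]
    rownames(side_effects) <- NULL
    all_classes <- unique(c(drug_pool, planted_drugs))
    drug_map <- stats::setNames(as.list(all_classes),
                                paste0("d_", all_classes))
    list(visits = visits, side_effects = side_effects, drug_map = drug_map,
         truth = truth, ontologies = onto, seed = seed,
         n_patients = n_patients, noise_rate = noise_rate)
  })
}

#' Convert a visit-level cohort to a FAERS-like case/report table
#'
#' Each qualifying visit pair (the same extraction rule as
#' [extract_ehr_candidates()]) becomes one report; a patient's reports are
#' grouped into one case.
#'
#' @param visits Visit table from [generate_cohort()].
#' @param max_interval_days Extraction window (default 14).
#' @return Data frame with columns `case_id`, `report_id`, `drug_codes`,
#'   `phenotype_codes`.
#' @export
degrade_to_faers <- function(visits, max_interval_days = 14) {
  cands <- extract_ehr_candidates(visits, max_interval_days)
  if (!length(cands)) {
    return(data.frame(case_id = character(), report_id = character(),
                      drug_codes = character(), phenotype_codes = character()))
  }
  pid <- vapply(cands, `[[`, "", "patient_id")
  rep_no <- stats::ave(seq_along(pid), pid, FUN = seq_along)
  data.frame(
    case_id = pid,
    report_id = sprintf("%s_r%d", pid, rep_no),
    drug_codes = join_codes(lapply(cands, `[[`, "drugs")),
    phenotype_codes = join_codes(lapply(cands, `[[`, "phenotypes")))
}

#' Dialect-3 description of a planted association
#'
#' @param plant A `planted_association`.
#' @param space The dialect-3 `pattern_space` used for mining.
#' @return An `ade_set` with the two template vectors.
#' @export
plant_description <- function(plant, space) {
  ade_set(list(ade_vector(plant$ade_a$drugs, plant$ade_a$phenotypes),
               ade_vector(plant$ade_b$drugs, plant$ade_b$phenotypes)))
}

#' Rules matching a planted association
#'
#' A rule matches when its combined description (left and right sides
#' together) refines the plant's two-ADE description, i.e. every patient
#' verifying the rule carries both planted ADEs (possibly specialized).
#'
#' @param rules An `ade_rules` collection (dialect 3).
#' @param plant A `planted_association`.
#' @return The matching `ade_rule` objects (possibly an empty list).
#' @export
planted_rule_matches <- function(rules, plant) {
  space <- rules$space
  target <- plant_description(plant, space)
  Filter(function(r) ps_leq(space, target, r$combined), rules$rules)
}
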