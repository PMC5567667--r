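# Building filtered ADE candidate sets from longitudinal visit tables
# (EHR-like) and from case-grouped report tables (FAERS-like).
#
# An ADE candidate is a pair (D, P): the drugs prescribed at one visit and
# the diagnoses reported at the next visit within a short window, filtered
# down to phenotypes known as side effects of at least one of the drugs.

split_codes <- function(x) {
  if (is.list(x)) return(lapply(x, function(v) sort(unique(as.character(v)))))
  x <- as.character(x)
  x[is.na(x)] <- ""
  lapply(strsplit(x, ";", fixed = TRUE),
         function(v) sort(unique(v[nzchar(v)])))
}

join_codes <- function(sets) {
  vapply(sets, function(v) paste(v, collapse = ";"), "")
}

new_candidate <- function(patient_id, drugs, phenotypes, source = "") {
  list(patient_id = patient_id, drugs = sort(unique(drugs)),
       phenotypes = sort(unique(phenotypes)), source = source)
}

#' Extract ADE candidates from a visit-level EHR table
#'
#' For each patient, visits are merged by calendar day (union of drugs and
#' diagnoses), sorted, and each pair of chronologically consecutive visits
#' (v1, v2) with `0 < date(v2) - date(v1) <= max_interval_days`, a non-empty
#' drug set at v1 and a non-empty diagnosis set at v2 yields the candidate
#' `(drugs(v1), diagnoses(v2))`.  Exact duplicate (D, P) pairs of one
#' patient are collapsed.
#'
#' @param visits Data frame with columns `patient_id`, `date` (ISO-8601 or
#'   `Date`), `drug_codes` and `dx_codes` (semicolon-separated strings, or
#'   list columns named `drugs` / `diagnoses`).
#' @param max_interval_days Window bound in days (default 14).
#' @return List of ADE candidates, each a list with fields `patient_id`,
#'   `drugs`, `phenotypes`, `source`.
#' @export
extract_ehr_candidates <- function(visits, max_interval_days = 14) {
  stopifnot(max_interval_days > 0)
  visits <- as.data.frame(visits)
  drugs <- split_codes(if ("drugs" %in% names(visits)) visits$drugs
                       else visits$drug_codes)
  dx <- split_codes(if ("diagnoses" %in% names(visits)) visits$diagnoses
                    else visits$dx_codes)
  dates <- suppressWarnings(as.Date(as.character(visits$date)))
  bad <- is.na(dates)
  if (any(bad)) {
    warning(sum(bad), " visit row(s) with unparseable dates rejected")
    visits <- visits[!bad, , drop = FALSE]
    drugs <- drugs[!bad]; dx <- dx[!bad]; dates <- dates[!bad]
  }
  out <- list()
  for (pid in sort(unique(as.character(visits$patient_id)))) {
    idx <- which(visits$patient_id == pid)
    days <- sort(unique(dates[idx]))
    vd <- lapply(days, function(d) {
      at <- idx[dates[idx] == d]
      list(drugs = sort(unique(unlist(drugs[at]))),
           dx = sort(unique(unlist(dx[at]))))
    })
    if (length(days) < 2L) next
    seen <- character()
    for (i in seq_len(length(days) - 1L)) {
      gap <- as.numeric(days[i + 1L] - days[i])
      if (gap <= 0 || gap > max_interval_days) next
      D <- vd[[i]]$drugs; P <- vd[[i + 1L]]$dx
      if (!length(D) || !length(P)) next
      key <- paste(paste(D, collapse = ","), paste(P, collapse = ","), sep = "|")
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- new_candidate(
        pid, D, P, source = paste(days[i], days[i + 1L], sep = ".."))
    }
  }
  out
}

#' Keep only phenotypes known as side effects of the candidate's drugs
#'
#' Each candidate's phenotype set is reduced to the phenotypes reported as a
#' side effect of at least one drug of its drug set; candidates left with no
#' phenotype are removed.
#'
#' @param cands List of ADE candidates.
#' @param se Side-effect table: data frame with columns `drug_code` and
#'   `phenotype_code`.
#' @return Filtered list of candidates.
#' @export
filter_by_side_effects <- function(cands, se) {
  se_key <- paste(se$drug_code, se$phenotype_code, sep = "\r")
  out <- lapply(cands, function(cc) {
    keep <- vapply(cc$phenotypes, function(p)
      any(paste(cc$drugs, p, sep = "\r") %in% se_key), TRUE)
    cc$phenotypes <- cc$phenotypes[keep]
    cc
  })
  out[vapply(out, function(cc) length(cc$phenotypes) > 0L, TRUE)]
}

#' Retain only maximally specialized drug sets per patient
#'
#' Within one patient, a candidate whose drug set is a strict subset of
#' another candidate's drug set is removed (reiterated prescription of the
#' smaller set suggests those drugs are tolerated); candidates with
#' identical drug sets are merged into one, with the union of their
#' phenotype sets.  The operation is idempotent.
#'
#' @param cands List of ADE candidates.
#' @return Filtered list of candidates.
#' @export
filter_maximal_drugsets <- function(cands) {
  out <- list()
  for (pid in sort(unique(vapply(cands, `[[`, "", "patient_id")))) {
    mine <- Filter(function(cc) cc$patient_id == pid, cands)
    # merge identical drug sets
    keys <- vapply(mine, function(cc) paste(cc$drugs, collapse = ","), "")
    merged <- lapply(unique(keys), function(k) {
      grp <- mine[keys == k]
      new_candidate(pid, grp[[1]]$drugs,
                    unlist(lapply(grp, `[[`, "phenotypes")),
                    source = paste(unique(vapply(grp, `[[`, "", "source")),
                                   collapse = "+"))
    })
    # drop strict subsets
    keep <- vapply(seq_along(merged), function(i) {
      !any(vapply(seq_along(merged), function(j) {
        i != j && all(merged[[i]]$drugs %in% merged[[j]]$drugs) &&
          length(merged[[i]]$drugs) < length(merged[[j]]$drugs)
      }, TRUE))
    }, TRUE)
    out <- c(out, merged[keep])
  }
  out
}

#' Keep only patients with at least k surviving ADE candidates
#'
#' @param cands List of ADE candidates.
#' @param k Minimum number of ADEs per patient (default 2).
#' @return An `ade_cohort`: named list mapping each retained patient id to
#'   its list of candidates.
#' @export
select_multi_ade_patients <- function(cands, k = 2) {
  pids <- vapply(cands, `[[`, "", "patient_id")
  keep <- names(which(table(pids) >= k))
  cohort <- stats::setNames(
    lapply(sort(keep), function(pid) cands[pids == pid]), sort(keep))
  structure(list(patients = cohort), class = "ade_cohort")
}

#' @export
print.ade_cohort <- function(x, ...) {
  cat(sprintf("<ade_cohort> %d patients, %d ADEs\n",
              length(x$patients), sum(lengths(x$patients))))
  invisible(x)
}

#' Number of ADE candidates in a cohort
#' @param cohort An `ade_cohort`.
#' @return Integer.
#' @export
cohort_n_ades <- function(cohort) sum(lengths(cohort$patients))

#' Build a cohort from a FAERS-like case/report table
#'
#' Each report becomes an ADE candidate of its case; within a case, the same
#' drug-set-inclusion exclusion as [filter_maximal_drugsets()] is applied
#' (identical drug sets merged, strict subsets dropped), and only cases with
#' at least `k` distinct surviving ADEs are retained.
#'
#' @param reports Data frame with columns `case_id`, `report_id`,
#'   `drug_codes`, `phenotype_codes` (semicolon-separated strings or list
#'   columns `drugs` / `phenotypes`).
#' @param k Minimum number of distinct ADEs per case (default 2).
#' @return An `ade_cohort` keyed by case id.
#' @export
extract_faers_cases <- function(reports, k = 2) {
  reports <- as.data.frame(reports)
  drugs <- split_codes(if ("drugs" %in% names(reports)) reports$drugs
                       else reports$drug_codes)
  phen <- split_codes(if ("phenotypes" %in% names(reports)) reports$phenotypes
                      else reports$phenotype_codes)
  cands <- lapply(seq_len(nrow(reports)), function(i)
    new_candidate(as.character(reports$case_id[i]), drugs[[i]], phen[[i]],
                  source = as.character(reports$report_id[i])))
  cands <- cands[vapply(cands, function(cc)
    length(cc$drugs) > 0L && length(cc$phenotypes) > 0L, TRUE)]
  select_multi_ade_patients(filter_maximal_drugsets(cands), k = k)
}

#' Full EHR extraction pipeline
#'
#' Chains [extract_ehr_candidates()], [filter_by_side_effects()],
#' [filter_maximal_drugsets()] and [select_multi_ade_patients()].
#'
#' @inheritParams extract_ehr_candidates
#' @inheritParams filter_by_side_effects
#' @inheritParams select_multi_ade_patients
#' @return An `ade_cohort`.
#' @export
extract_ehr_cohort <- function(visits, se, max_interval_days = 14, k = 2) {
  cands <- extract_ehr_candidates(visits, max_interval_days)
  cands <- filter_by_side_effects(cands, se)
  cands <- filter_maximal_drugsets(cands)
  select_multi_ade_patients(cands, k = k)
}

#' Cohort size for a sweep of window bounds
#'
#' Reports, for each candidate window bound, the number of retained patients
#' and their total number of ADEs after the full extraction pipeline —
#' the usual sensitivity table for choosing the inter-visit interval.
#'
#' @inheritParams extract_ehr_cohort
#' @param intervals Integer vector of window bounds in days.
#' @return Data frame with columns `interval`, `patients`, `ades`.
#' @export
ade_interval_counts <- function(visits, se, intervals = c(1, 2, 6, 10, 14, 18),
                                k = 2) {
  rows <- lapply(intervals, function(w) {
    cohort <- extract_ehr_cohort(visits, se, max_interval_days = w, k = k)
    data.frame(interval = w, patients = length(cohort$patients),
               ades = cohort_n_ades(cohort))
  })
  do.call(rbind, rows)
}

## ---- tabular I/O -----------------------------------------------------------

#' Read and write the package's TSV dialects
#'
#' Visit tables carry `patient_id`, `date`, `drug_codes`, `dx_codes`;
#' FAERS-like tables carry `case_id`, `report_id`, `drug_codes`,
#' `phenotype_codes`; side-effect tables carry `drug_code`,
#' `phenotype_code`.  Code sets are semicolon-separated.
#'
#' @param path File path.
#' @return A data frame.
#' @export
read_visits_tsv <- function(path) {
  utils::read.delim(path, colClasses = "character")
}

#' @rdname read_visits_tsv
#' @export
read_faers_tsv <- function(path) {
  utils::read.delim(path, colClasses = "character")
}

#' @rdname read_visits_tsv
#' @export
read_side_effects_tsv <- function(path) {
  utils::read.delim(path, colClasses = "character")
}

#' @rdname read_visits_tsv
#' @export
read_drug_map_tsv <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character")
  stats::setNames(split_codes(tab[[2]]), tab[[1]])
}

#' @rdname read_visits_tsv
#' @param drug_map Named list mapping drug codes to ATC class vectors.
#' @export
write_drug_map_tsv <- function(drug_map, path) {
  tab <- data.frame(drug_code = names(drug_map),
                    atc_codes = join_codes(drug_map))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_visits_tsv
#' @param cands List of ADE candidates or an `ade_cohort`.
#' @export
write_candidates_tsv <- function(cands, path) {
  if (inherits(cands, "ade_cohort")) cands <- unlist(cands$patients,
                                                     recursive = FALSE)
  tab <- data.frame(
    patient_id = vapply(cands, `[[`, "", "patient_id"),
    drug_codes = join_codes(lapply(cands, `[[`, "drugs")),
    phenotype_codes = join_codes(lapply(cands, `[[`, "phenotypes")),
    source = vapply(cands, `[[`, "", "source"))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
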