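# Panel selection: classification bands, abundance ranking, deduplication,
# adaptive affinity relaxation, and the shared inert panel.

#' Selection criteria for peptide panels
#'
#' Defaults encode the study's selection bands: stimulatory and tolerogenic
#' peptides require best-DR normalized affinity below `-1.5` and liberal
#' cathepsin release, and are split by TCEM frequency class (rare, FC >= 17,
#' stimulatory; frequent, FC <= 7, tolerogenic). Inert peptides require
#' normalized affinity above `+1` for every patient's DR, DQ and DP alleles
#' and strict no-cleavage. Panel sizes: 10 stimulatory and 5 tolerogenic per
#' patient, 7 shared inert. When a patient has too few qualifying
#' candidates the affinity limit is relaxed in steps of `relaxation_step`
#' up to `relaxation_limit` (affinity only; FC and cleavage bands are never
#' relaxed).
#'
#' @param affinity_threshold_stim_tol,affinity_threshold_inert,fc_min_stimulatory,fc_max_tolerogenic,n_stimulatory,n_tolerogenic,n_inert,relaxation_step,relaxation_limit
#'   see description.
#' @return List of class `selection_criteria`.
#' @export
selection_criteria <- function(affinity_threshold_stim_tol = -1.5,
                               affinity_threshold_inert = 1.0,
                               fc_min_stimulatory = 17L,
                               fc_max_tolerogenic = 7L,
                               n_stimulatory = 10L,
                               n_tolerogenic = 5L,
                               n_inert = 7L,
                               relaxation_step = 0.1,
                               relaxation_limit = -0.5) {
  stopifnot(fc_min_stimulatory > fc_max_tolerogenic,
            n_stimulatory >= 0, n_tolerogenic >= 0, n_inert >= 0,
            relaxation_step > 0)
  structure(list(affinity_threshold_stim_tol = affinity_threshold_stim_tol,
                 affinity_threshold_inert = affinity_threshold_inert,
                 fc_min_stimulatory = as.integer(fc_min_stimulatory),
                 fc_max_tolerogenic = as.integer(fc_max_tolerogenic),
                 n_stimulatory = as.integer(n_stimulatory),
                 n_tolerogenic = as.integer(n_tolerogenic),
                 n_inert = as.integer(n_inert),
                 relaxation_step = relaxation_step,
                 relaxation_limit = relaxation_limit),
            class = "selection_criteria")
}

#' Classify scored candidates into antigenic-property categories
#'
#' `stimulatory`: best-DR normalized affinity below the stimulatory/
#' tolerogenic threshold AND liberal cathepsin release AND FC at or above
#' the rare band. `tolerogenic`: same affinity/release conditions with FC
#' at or below the frequent band. `inert`: normalized affinity above the
#' inert threshold for all patients' class II alleles AND strict
#' no-cleavage. Anything else: `none` (including the FC band gap).
#'
#' @param scored data.frame from [score_candidates()].
#' @param criteria a [selection_criteria()].
#' @param affinity_threshold override for the stimulatory/tolerogenic
#'   affinity threshold (used internally during relaxation).
#' @return Character vector of categories.
#' @export
classify_candidates <- function(scored, criteria = selection_criteria(),
                                affinity_threshold = NULL) {
  needed <- c("best_dr_norm", "min_all_norm", "liberal_released",
              "strict_eligible", "fc")
  missing <- needed[!needed %in% names(scored)]
  if (length(missing) > 0) {
    stop_idioscope("candidates lack score component(s): %s",
                   paste(missing, collapse = ", "))
  }
  thr <- affinity_threshold %||% criteria$affinity_threshold_stim_tol
  antigenic <- !is.na(scored$best_dr_norm) & scored$best_dr_norm < thr &
    scored$liberal_released & !is.na(scored$fc)
  out <- rep("none", nrow(scored))
  out[antigenic & scored$fc >= criteria$fc_min_stimulatory] <- "stimulatory"
  out[antigenic & scored$fc <= criteria$fc_max_tolerogenic] <- "tolerogenic"
  inert <- !is.na(scored$min_all_norm) &
    scored$min_all_norm > criteria$affinity_threshold_inert &
    scored$strict_eligible & !is.na(scored$fc)
  out[inert & out == "none"] <- "inert"
  out
}

# Deterministic candidate ordering: transcript abundance (descending), then
# best-DR normalized affinity (ascending: stronger binder first), then
# peptide string.
rank_candidates <- function(df) {
  df[order(-df$transcript_count, df$best_dr_norm, df$peptide), , drop = FALSE]
}

# Deduplicate by peptide string, keeping the first (best-ranked) instance.
dedup_candidates <- function(df) {
  df[!duplicated(df$peptide), , drop = FALSE]
}

new_panel <- function(peptides, patient_id, category, relaxed = NA_real_) {
  rownames(peptides) <- NULL
  structure(peptides,
            patient_id = patient_id, category = category,
            relaxed_threshold_used = relaxed,
            class = c("peptide_panel", class(peptides)))
}

#' @export
print.peptide_panel <- function(x, ...) {
  cat(sprintf("<%s panel, %s: %d peptide(s)%s>\n",
              attr(x, "category"), attr(x, "patient_id"), nrow(x),
              if (!is.na(attr(x, "relaxed_threshold_used"))) {
                sprintf(", affinity threshold relaxed to %.2f",
                        attr(x, "relaxed_threshold_used"))
              } else ""))
  print(as.data.frame(x)[, c("peptide", "record_id", "transcript_count",
                             "best_dr_norm", "fc")])
  invisible(x)
}

#' Build the stimulatory and tolerogenic panels of one patient
#'
#' Candidates must be restricted to the patient's own repertoire. Within
#' each category, candidates are ranked by transcript abundance (ties by
#' normalized affinity, then peptide string), duplicate peptide strings
#' removed, and the top n taken. If fewer than n qualify, the affinity
#' threshold is raised by `relaxation_step` repeatedly (FC and cleavage
#' conditions unchanged) until n are found or `relaxation_limit` is
#' reached; the relaxed threshold is recorded. A panel still short at the
#' limit is returned under-filled with a warning. Tolerogenic selection
#' additionally excludes peptide strings already in the stimulatory panel.
#'
#' @param scored scored candidates of a single patient.
#' @param criteria a [selection_criteria()].
#' @return Named list `stimulatory`, `tolerogenic` of `peptide_panel`
#'   objects.
#' @export
build_patient_panels <- function(scored, criteria = selection_criteria()) {
  pid <- unique(scored$patient_id)
  if (length(pid) != 1) {
    stop_idioscope("candidates must come from a single patient (got %d)",
                   length(pid))
  }
  pick <- function(category, n, exclude = character(0)) {
    thr <- criteria$affinity_threshold_stim_tol
    relaxed <- NA_real_
    repeat {
      cls <- classify_candidates(scored, criteria, affinity_threshold = thr)
      sel <- scored[cls == category & !scored$peptide %in% exclude, ,
                    drop = FALSE]
      sel <- dedup_candidates(rank_candidates(sel))
      if (nrow(sel) >= n || thr + criteria$relaxation_step >
          criteria$relaxation_limit + 1e-9) {
        break
      }
      thr <- thr + criteria$relaxation_step
      relaxed <- thr
    }
    if (nrow(sel) < n) {
      warning(sprintf("%s panel for %s under-filled: %d of %d",
                      category, pid, nrow(sel), n))
    }
    new_panel(utils::head(sel, n), pid, category, relaxed)
  }
  stim <- pick("stimulatory", criteria$n_stimulatory)
  tol <- pick("tolerogenic", criteria$n_tolerogenic,
              exclude = stim$peptide)
  list(stimulatory = stim, tolerogenic = tol)
}

#' Build the shared inert panel
#'
#' Selected from the pooled candidates of all patients: each member must be
#' inert-eligible against every patient's full class II allele set (already
#' encoded in `min_all_norm`) and strictly non-cleavable. The panel mixes
#' TCEM frequencies: when available, at least one member with FC in the
#' rare band and one in the frequent band are included (swapped in for the
#' lowest-ranked members if the abundance-ranked top n lacks them).
#'
#' @param scored scored candidates pooled over the full repertoire.
#' @param criteria a [selection_criteria()].
#' @return A `peptide_panel` with `patient_id = "shared"`.
#' @export
build_inert_panel <- function(scored, criteria = selection_criteria()) {
  cls <- classify_candidates(scored, criteria)
  sel <- dedup_candidates(rank_candidates(scored[cls == "inert", ,
                                                 drop = FALSE]))
  n <- criteria$n_inert
  panel <- utils::head(sel, n)
  is_high <- function(df) df$fc >= criteria$fc_min_stimulatory
  is_low <- function(df) df$fc <= criteria$fc_max_tolerogenic
  if (nrow(panel) == n && nrow(sel) > n) {
    rest <- sel[-seq_len(n), , drop = FALSE]
    for (want in list(is_high, is_low)) {
      if (!any(want(panel)) && any(want(rest))) {
        add <- rest[which(want(rest))[1], , drop = FALSE]
        drop_i <- rev(which(!is_high(panel) & !is_low(panel)))[1]
        if (is.na(drop_i)) drop_i <- nrow(panel)
        panel <- rank_candidates(rbind(panel[-drop_i, , drop = FALSE], add))
        rest <- rest[rest$peptide != add$peptide, , drop = FALSE]
      }
    }
  }
  if (nrow(panel) < n) {
    warning(sprintf("inert panel under-filled: %d of %d", nrow(panel), n))
  }
  new_panel(panel, "shared", "inert")
}

#' Build all panels of a study
#'
#' Per-patient stimulatory and tolerogenic panels plus the shared inert
#' panel, combined into one tidy table.
#'
#' @param scored scored candidates over the full repertoire (all patients).
#' @param criteria a [selection_criteria()].
#' @return List with `panels` (named list per patient plus `inert`) and
#'   `table` (one row per selected peptide: `patient_id`, `category`,
#'   `rank`, candidate columns, `relaxed_threshold_used`).
#' @export
build_all_panels <- function(scored, criteria = selection_criteria()) {
  patients <- sort(unique(scored$patient_id))
  panels <- lapply(setNames(nm = patients), function(p) {
    build_patient_panels(scored[scored$patient_id == p, , drop = FALSE],
                         criteria)
  })
  inert <- build_inert_panel(scored, criteria)
  rows <- list()
  for (p in patients) {
    for (cat in c("stimulatory", "tolerogenic")) {
      pan <- panels[[p]][[cat]]
      if (nrow(pan) == 0) next
      df <- as.data.frame(pan)
      df$panel_patient <- p
      df$category <- cat
      df$rank <- seq_len(nrow(df))
      df$relaxed_threshold_used <- attr(pan, "relaxed_threshold_used")
      rows[[length(rows) + 1]] <- df
    }
  }
  if (nrow(inert) > 0) {
    df <- as.data.frame(inert)
    df$panel_patient <- "shared"
    df$category <- "inert"
    df$rank <- seq_len(nrow(df))
    df$relaxed_threshold_used <- NA_real_
    rows[[length(rows) + 1]] <- df
  }
  list(panels = c(panels, list(inert = inert)),
       table = do.call(rbind, rows))
}
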