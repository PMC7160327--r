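# End-to-end orchestration: enumerate -> score -> select -> (delta) ->
# (respond), with a manifest for provenance. Stages are the exported module
# functions; this wrapper only sequences them and writes their outputs.

#' Default pipeline configuration
#'
#' Every threshold of the pipeline has a home here; override any element
#' via `run_pipeline(config = modifyList(default_config(), list(...)))`.
#'
#' @return Named list of configuration blocks.
#' @export
default_config <- function() {
  list(
    pad_len = 3L,
    include_padding = FALSE,
    region_rule = "first_aa",
    tcem = list(core_start = 3L, fc_cap = 24L, masks = tcem_masks()),
    release = list(flank_window = 3L, cut_liberal = 0.5, cut_strict = 0.3),
    criteria = selection_criteria(),
    delta = list(flank = 3L, threshold = 0.1,
                 delta_cathepsins = c("S", "B")),
    fold_threshold = 3
  )
}

#' Run the idiotope-prioritization pipeline
#'
#' Executes enumerate -> score -> select, optionally followed by the
#' germline-delta imputation and the response-assay analysis, writing each
#' stage's table plus a JSON manifest (per-stage row counts, configuration)
#' under `out_dir`. Re-running with the same inputs and configuration
#' reproduces identical outputs.
#'
#' @param repertoire an [ighv_repertoire()] (padded records are stripped
#'   with `config$pad_len`).
#' @param hla a [hla_table()].
#' @param reference_repertoires named list of repertoires for the TCEM
#'   index.
#' @param affinity,cleavage model objects (defaults: shipped surrogates).
#' @param flow optional flow-count table; when given, activation results
#'   and the group comparison are computed.
#' @param config configuration list, see [default_config()].
#' @param out_dir output directory (created); `NULL` skips writing.
#' @param compute_deltas impute germline deltas for selected panels?
#' @return List with `candidates`, `scored`, `panels`, `panel_table`,
#'   `deltas`, `responses`, `comparison`, `manifest`.
#' @export
run_pipeline <- function(repertoire, hla, reference_repertoires,
                         affinity = surrogate_affinity_model(),
                         cleavage = surrogate_cleavage_model(),
                         flow = NULL, config = default_config(),
                         out_dir = NULL, compute_deltas = TRUE) {
  if (nrow(repertoire) == 0) stop_idioscope("enumerate stage: empty repertoire")
  if (any(repertoire$padded)) {
    repertoire <- strip_padding(repertoire, config$pad_len)
  }
  candidates <- enumerate_15mers(repertoire,
                                 include_padding = config$include_padding,
                                 pad_len = config$pad_len,
                                 region_rule = config$region_rule)
  tcem <- build_frequency_index(reference_repertoires,
                                core_start = config$tcem$core_start,
                                masks = config$tcem$masks,
                                fc_cap = config$tcem$fc_cap)
  scored <- score_candidates(candidates, repertoire, hla, affinity, cleavage,
                             tcem,
                             flank_window = config$release$flank_window,
                             cut_liberal = config$release$cut_liberal,
                             cut_strict = config$release$cut_strict)
  sel <- build_all_panels(scored, config$criteria)
  deltas <- NULL
  if (compute_deltas) {
    own <- sel$table[sel$table$category != "inert", , drop = FALSE]
    deltas <- germline_deltas(own, repertoire, hla, affinity, cleavage, tcem,
                              flank = config$delta$flank,
                              threshold = config$delta$threshold,
                              delta_cathepsins = config$delta$delta_cathepsins)
  }
  responses <- NULL; comparison <- NULL
  if (!is.null(flow)) {
    responses <- activation_results(flow,
                                    fold_threshold = config$fold_threshold)
    peptide_rows <- responses[responses$category != "control", , drop = FALSE]
    comparison <- compare_groups(peptide_rows)
  }
  manifest <- list(
    n_patients = length(unique(repertoire$patient_id)),
    n_sequences = nrow(repertoire),
    n_candidates = nrow(candidates),
    n_scored = nrow(scored),
    n_selected = nrow(sel$table),
    stimuli_per_patient = with(sel$table, length(unique(
      peptide[category == "inert"])) +
        if (any(category != "inert")) {
          max(table(panel_patient[category != "inert"]))
        } else 0L),
    config = config[setdiff(names(config), "criteria")],
    criteria = unclass(config$criteria)
  )
  out <- list(candidates = candidates, scored = scored, panels = sel$panels,
              panel_table = sel$table, deltas = deltas,
              responses = responses, comparison = comparison,
              manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(sel$table, file.path(out_dir, "panels.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(deltas)) {
      write.table(deltas, file.path(out_dir, "germline_deltas.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(responses)) {
      write.table(responses, file.path(out_dir, "responses.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}
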