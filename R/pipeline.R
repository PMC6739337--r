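# End-to-end orchestration: load or generate inputs, build the consensus
# table, compute observed rank distributions, both randomized controls,
# significance tests, and the association network, and collect everything
# into one machine-readable run summary.

#' The two-indication worked example
#'
#' The didactic fixture used throughout: a psychoactive (ergoline) with
#' consensus count 7 for Pica (a mental-health eating disorder) and 3 for
#' Stomach pain, and a non-psychoactive (aspirin) with counts 4 and 6. On
#' this table the normalized compound ranks are 70% (ergoline) and 40%
#' (aspirin) and the normalized indication ranks are 63.64% (Pica, 64% at
#' integer precision) and 33.33% (Stomach pain).
#'
#' @return list with `table` (a [consensus_table()] at Top10), `compounds`
#'   and `indications` metadata tables.
#' @export
worked_example <- function() {
  compounds <- compound_table(
    compound_id = c("ergoline", "aspirin"),
    name = c("ergoline", "aspirin"),
    is_psychoactive = c(TRUE, FALSE),
    chem_class = c("other", "none")
  )
  indications <- indication_table(
    mesh_id = c("pica", "stomach-pain"),
    name = c("Pica", "Stomach pain"),
    is_mental_health = c(TRUE, FALSE)
  )
  table <- consensus_table(data.frame(
    indication_id = c("pica", "pica", "stomach-pain", "stomach-pain"),
    compound_id = c("ergoline", "aspirin", "ergoline", "aspirin"),
    topx = 10L,
    consensus_count = c(7L, 4L, 3L, 6L) # ergoline 7/3, aspirin 4/6
  ))
  list(table = table, compounds = compounds, indications = indications)
}

#' Run the full analysis pipeline
#'
#' Stages: load/generate inputs, consensus prediction at every configured
#' TopX, observed indication- and compound-rank distributions, the two
#' randomized controls, one-tailed KS and paired t tests (observed vs
#' compound-shuffle null; compound-shuffle vs indication-shuffle null),
#' and the thresholded association network. All randomness flows from
#' `config$seed`; identical config and inputs give identical summaries.
#'
#' @param config an [analysis_config()].
#' @param inputs either a [synthetic_spec()], a `synthetic_cohort`, a list
#'   with elements `matrix`, `compounds`, `indications` (in-memory), or a
#'   list of file paths `matrix_path`, `compounds_path`,
#'   `indications_path`.
#' @param out_dir optional directory: stage TSVs and `summary.json` are
#'   written there.
#' @param quiet suppress stage progress messages.
#' @return list of class `run_summary`: config snapshot, per-TopX blocks
#'   (observed mean ranks, null means, test results, association edge
#'   count), and stage tables (`consensus`, `associations`).
#' @export
run_pipeline <- function(config = analysis_config(), inputs, out_dir = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  if (inherits(inputs, "synthetic_spec")) {
    say("stage load: generating synthetic cohort (seed ", inputs$seed, ")")
    inputs <- generate_cohort(inputs)
  }
  if (inherits(inputs, "synthetic_cohort")) {
    mat <- inputs$matrix; compounds <- inputs$compounds
    indications <- inputs$indications
  } else if (!is.null(inputs$matrix_path)) {
    say("stage load: reading ", inputs$matrix_path)
    mat <- load_matrix(inputs$matrix_path)
    meta <- load_metadata(inputs$compounds_path, inputs$indications_path, mat)
    compounds <- meta$compounds; indications <- meta$indications
  } else {
    mat <- inputs$matrix; compounds <- inputs$compounds
    indications <- inputs$indications
  }
  say(sprintf("stage load: %d compounds (%d psychoactive), %d indications (%d mental-health, %d usable)",
              nrow(compounds), sum(compounds$is_psychoactive),
              nrow(indications), sum(indications$is_mental_health),
              sum(indications$usable)))

  say("stage predict: building consensus table")
  table <- withCallingHandlers(
    build_consensus_table(indications, mat, config),
    warning = function(w) { say("  ", conditionMessage(w))
                            invokeRestart("muffleWarning") })

  blocks <- list()
  for (x in sort(config$topx_values)) {
    say("stage rank/null/test: Top", x)
    ir <- suppressWarnings(indication_rank(table, compounds, x))
    cr <- compound_rank(table, indications, x)
    mh_ids <- indications$mesh_id[indications$is_mental_health]
    ir_mh <- ir[ir$indication_id %in% mh_ids, , drop = FALSE]
    psy_ids <- compounds$compound_id[compounds$is_psychoactive]
    cr_psy <- cr[cr$compound_id %in% psy_ids, , drop = FALSE]

    null_cmp_ir <- shuffle_compounds(table, compounds, x,
                                     n_reps = config$n_randomizations,
                                     seed = config$seed, kind = "indication_rank")
    null_cmp_cr <- shuffle_compounds(table, compounds, x,
                                     n_reps = config$n_randomizations,
                                     seed = config$seed + 1L,
                                     kind = "compound_rank",
                                     indications = indications)
    null_ind <- tryCatch(
      shuffle_indications(indications, table, x,
                          n_reps = config$n_randomizations,
                          seed = config$seed + 2L),
      error = function(e) { say("  indication shuffle skipped: ",
                                conditionMessage(e)); NULL })

    obs_ir <- stats::setNames(ir_mh$value, ir_mh$indication_id)
    obs_cr <- stats::setNames(cr_psy$value, cr_psy$compound_id)
    nm_ir <- null_values(null_cmp_ir)
    nm_ir <- nm_ir[names(nm_ir) %in% mh_ids]
    ks_ir <- if (length(obs_ir)) ks_one_tailed(obs_ir, nm_ir) else NULL
    psy_null_cr <- null_values(null_cmp_cr)
    psy_null_cr <- psy_null_cr[names(psy_null_cr) %in% psy_ids]
    ks_cr <- if (length(obs_cr) && length(psy_null_cr)) {
      ks_one_tailed(obs_cr, psy_null_cr)
    } else NULL
    t_nulls <- if (!is.null(null_ind)) {
      tryCatch(paired_t_one_tailed(null_values(null_cmp_cr),
                                   null_values(null_ind)),
               error = function(e) NULL)
    } else NULL

    assoc <- if (as.character(x) %in% names(config$association_thresholds)) {
      build_associations(table, compounds, x, config, indications)
    } else NULL

    blocks[[as.character(x)]] <- list(
      topx = x,
      observed_mean_indication_rank_mh =
        if (length(obs_ir)) mean(obs_ir) else NA_real_,
      observed_mean_compound_rank_psy =
        if (length(obs_cr)) mean(obs_cr) else NA_real_,
      null_mean_indication_rank_compound_shuffle =
        if (length(nm_ir)) mean(nm_ir) else NA_real_,
      null_mean_compound_rank_compound_shuffle =
        if (length(psy_null_cr)) mean(psy_null_cr) else NA_real_,
      null_mean_compound_rank_indication_shuffle =
        if (!is.null(null_ind)) mean(null_values(null_ind)) else NA_real_,
      ks_indication_rank = ks_ir,
      ks_compound_rank = ks_cr,
      paired_t_nulls = t_nulls,
      n_association_edges = if (is.null(assoc)) NA_integer_ else nrow(assoc),
      associations = assoc,
      indication_rank = ir,
      compound_rank = cr
    )
  }

  summary <- structure(
    list(config = unclass(config),
         seed = config$seed,
         version = as.character(utils::packageVersion("repsig")),
         topx = blocks,
         consensus = table),
    class = "run_summary"
  )
  if (!is.null(out_dir)) write_summary(summary, out_dir)
  summary
}

#' @export
print.run_summary <- function(x, ...) {
  cat("run_summary (seed ", x$seed, ")\n", sep = "")
  for (b in x$topx) {
    cat(sprintf("  Top%-4d obs MH ind rank %6.2f%% (null %6.2f%%)  obs psy cmp rank %6.2f%% (null %6.2f%% / %6.2f%%)  edges %s\n",
                b$topx, b$observed_mean_indication_rank_mh,
                b$null_mean_indication_rank_compound_shuffle,
                b$observed_mean_compound_rank_psy,
                b$null_mean_compound_rank_compound_shuffle,
                b$null_mean_compound_rank_indication_shuffle,
                b$n_association_edges))
  }
  invisible(x)
}

# Persist stage TSVs plus a JSON summary into out_dir.
write_summary <- function(summary, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(as.data.frame(summary$consensus),
                     file.path(out_dir, "consensus.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (b in summary$topx) {
    if (!is.null(b$associations)) {
      utils::write.table(b$associations,
                         file.path(out_dir, sprintf("associations_top%d.tsv", b$topx)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(as.data.frame(b$indication_rank),
                       file.path(out_dir, sprintf("indication_rank_top%d.tsv", b$topx)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(b$compound_rank),
                       file.path(out_dir, sprintf("compound_rank_top%d.tsv", b$topx)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  strip <- function(b) {
    b$associations <- NULL; b$indication_rank <- NULL; b$compound_rank <- NULL
    b$ks_indication_rank <- unclass(b$ks_indication_rank)
    b$ks_compound_rank <- unclass(b$ks_compound_rank)
    b$paired_t_nulls <- unclass(b$paired_t_nulls)
    b
  }
  jsonlite::write_json(
    list(config = summary$config, seed = summary$seed,
         version = summary$version, topx = lapply(summary$topx, strip)),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(out_dir)
}
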