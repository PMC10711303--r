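#' Default end-to-end run configuration
#'
#' The pipeline runs on the synthetic fixture bundle by default: every
#' stage's inputs are generated by the seeded [sim_config()] generators, so
#' an end-to-end run is fully reproducible and carries ground truth.
#' Individual stages can be pointed at real inputs by overriding the
#' corresponding paths in the configuration (YAML or list); the `paper`
#' preset block fixes the decontamination thresholds (rounds 1 and 2), the
#' consensus rule `k = 1` and three-tool selection.
#'
#' @param outdir output directory.
#' @param seed master seed.
#' @param stages stages to run, in the fixed DAG order.
#' @return a named list (class `run_config`).
#' @export
default_run_config <- function(outdir = "mrolens_run", seed = 1L,
                               stages = c("simulate", "decontam", "bench",
                                          "call", "matrix", "ancestry",
                                          "ogscreen")) {
  structure(list(outdir = outdir, seed = as.integer(seed), stages = stages,
                 preset = "paper",
                 target_clade = "Amoebozoa",
                 k = 1L, select_k = 3L, min_specificity = 50,
                 coding = "MRO_PLUS_CLADE",
                 ancestry_mode = "dollo",
                 sim = list()),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param file YAML file with any subset of the [default_run_config()]
#'   fields; unspecified fields keep their defaults.
#' @return a `run_config`.
#' @export
read_run_config <- function(file) {
  if (!file.exists(file)) stopf("run config file not found: %s", file)
  user <- yaml::read_yaml(file)
  cfg <- default_run_config()
  cfg[names(user)] <- user
  cfg
}

stage_order <- c("simulate", "decontam", "bench", "call", "matrix",
                 "ancestry", "ogscreen")

log_line <- function(log_path, msg) {
  cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), msg),
      file = log_path, append = TRUE)
}

#' Run the full pipeline on the synthetic fixture bundle
#'
#' Executes decontamination, predictor benchmarking, consensus MRO calling,
#' character-matrix assembly, Dollo gain/loss reconstruction (under both
#' published topologies) and orthogroup enrichment, writing per-stage TSV
#' outputs, a timestamped plain-text log, a JSON run report and a
#' `manifest.json` listing every output file with its MD5 checksum plus all
#' decision parameters.  The manifest deliberately contains no timestamps:
#' two runs on identical inputs are byte-identical.
#'
#' @param config a `run_config` (list), or path to a YAML file.
#' @return the run report (named list), invisibly; its `manifest` element
#'   mirrors `manifest.json`.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run.log")
  unlink(log_path)
  unknown <- setdiff(config$stages, stage_order)
  if (length(unknown))
    stopf("unknown stage(s): %s", paste(unknown, collapse = ", "))
  stages <- stage_order[stage_order %in% config$stages]
  sim_cfg <- do.call(sim_config, c(list(seed = config$seed), config$sim))
  report <- list(package = "mrolens",
                 version = as.character(utils::packageVersion("mrolens")),
                 seed = config$seed,
                 parameters = list(
                   preset = config$preset, target_clade = config$target_clade,
                   round1 = list(evalue = 1e-2, best_hits = 5L,
                                 identity = 75, coverage = 50),
                   round2 = list(evalue = 1e-5, best_hits = 1L,
                                 identity = 70, coverage = NULL),
                   k = config$k, select_k = config$select_k,
                   min_specificity = config$min_specificity,
                   coding = config$coding,
                   ancestry_mode = config$ancestry_mode),
                 stages = list())
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    log_line(log_path, sprintf("stage %s: start", name))
    res <- tryCatch(fun(), error = function(e)
      stopf("stage %s failed: %s", name, conditionMessage(e)))
    log_line(log_path, sprintf("stage %s: ok", name))
    report$stages[[name]] <<- c(list(status = "ok"), res)
  }

  for (name in stages) {
    switch(name,
      simulate = run_stage("simulate", function() {
        state$decontam_in <- sim_decontam_inputs(sim_cfg, dir = outdir)
        state$bench_in <- sim_predictor_calls(sim_cfg)
        state$chars <- sim_character_matrix(sim_cfg)
        state$ogs <- sim_orthogroups(sim_cfg)
        write_calls(state$bench_in$calls, file.path(outdir, "calls.tsv"))
        write_labels(state$bench_in$labels, file.path(outdir, "labels.tsv"))
        write_orthogroups(state$ogs$ogs, file.path(outdir, "orthogroups.txt"))
        ape::write.tree(sim_cfg$tree, file.path(outdir, "species_tree.nwk"))
        list(n_transcripts = length(state$decontam_in$transcript_ids),
             n_reference = nrow(state$bench_in$labels),
             n_characters = ncol(state$chars$matrix),
             n_orthogroups = length(unique(state$ogs$ogs$og_id)))
      }),
      decontam = run_stage("decontam", function() {
        din <- state$decontam_in %||%
          stopf("missing decontamination inputs (run the simulate stage)")
        rep2 <- two_round_filter(din$transcript_ids, din$nt_hits,
                                 din$protein_ids, din$aa_hits,
                                 target_clade = config$target_clade)
        state$decontam <- rep2
        write_filter_report(rep2, file.path(outdir, "decontam_decisions.tsv"))
        list(removed_transcripts = length(rep2$removed_transcripts),
             removed_proteins = length(rep2$removed_proteins))
      }),
      bench = run_stage("bench", function() {
        bin <- state$bench_in %||% stopf("missing benchmark inputs")
        tools_all <- unique(bin$calls$tool_name)
        sums <- lapply(tools_all, function(t)
          confusion(bin$calls, bin$labels, t))
        state$summaries <- summaries_frame(sums)
        write_tsv(state$summaries, file.path(outdir, "confusion.tsv"))
        state$selected <- suppressWarnings(
          rank_and_select(sums, k = config$select_k,
                          min_specificity = config$min_specificity))
        if (length(state$selected) == 3L) {
          vp <- venn_partition(bin$calls, bin$labels, state$selected,
                               truth = "MRO", polarity = "POSITIVES")
          write_tsv(data.frame(cell = names(vp$cell_counts),
                               count = as.integer(vp$cell_counts),
                               stringsAsFactors = FALSE),
                    file.path(outdir, "venn_true_positives.tsv"))
        }
        list(tools = tools_all, selected = state$selected)
      }),
      call = run_stage("call", function() {
        bin <- state$bench_in %||% stopf("missing benchmark inputs")
        sel <- state$selected %||% stopf("missing tool selection")
        calls <- bin$calls[bin$calls$tool_name %in% sel, , drop = FALSE]
        votes <- vapply(sel, function(t) {
          tc <- calls[calls$tool_name == t, , drop = FALSE]
          idx <- match(bin$labels$protein_id, tc$protein_id)
          !is.na(idx) & is_positive_call(tc$normalized_class[idx])
        }, logical(nrow(bin$labels)))
        colnames(votes) <- sel
        ev <- evidence_table(bin$labels$protein_id,
                             species = "synthetic",
                             votes = votes,
                             homology_affinity = FALSE,
                             selected_tools = sel, k = config$k)
        state$evidence <- ev
        write_evidence(ev, file.path(outdir, "evidence.tsv"))
        list(n_mro_called = sum(ev$final_call == "MRO"))
      }),
      matrix = run_stage("matrix", function() {
        chars <- state$chars %||% stopf("missing simulated characters")
        cm <- chars$matrix
        write_tsv(data.frame(species = rownames(cm), cm, check.names = FALSE,
                             stringsAsFactors = FALSE),
                  file.path(outdir, "character_matrix.tsv"))
        state$matrix <- cm
        list(n_species = nrow(cm), n_characters = ncol(cm))
      }),
      ancestry = run_stage("ancestry", function() {
        cm <- state$matrix %||% stopf("missing character matrix")
        sc <- dollo_reconstruct(sim_cfg$tree, cm,
                                mode = config$ancestry_mode)
        write_scenario(sc, file.path(outdir, "gain_loss_events.tsv"),
                       file.path(outdir, "ancestral_states.tsv"))
        cmp <- if (length(sim_cfg$tree$tip.label) ==
                     length(alt_species_tree()$tip.label) &&
                   setequal(sim_cfg$tree$tip.label,
                            alt_species_tree()$tip.label)) {
          tc <- compare_topologies(cm, sim_cfg$tree, alt_species_tree())
          write_tsv(tc$table, file.path(outdir, "topology_comparison.tsv"))
          sum(tc$table$changed)
        } else NA_integer_
        list(total_losses = sum(sc$events$n_losses),
             characters_changed_by_topology = cmp)
      }),
      ogscreen = run_stage("ogscreen", function() {
        ogs <- state$ogs %||% stopf("missing orthogroups")
        enr <- og_enrichment(ogs$ogs, ogs$mro_ids, universe = ogs$universe)
        write_tsv(as.data.frame(enr), file.path(outdir, "og_enrichment.tsv"))
        list(n_q_below_0.05 = sum(enr$q_value < 0.05))
      }))
  }

  jsonlite::write_json(report, file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  files <- sort(setdiff(list.files(outdir, recursive = TRUE),
                        c("run.log", "manifest.json")))
  manifest <- list(parameters = report$parameters, seed = config$seed,
                   files = lapply(files, function(f)
                     list(path = f,
                          md5 = unname(tools::md5sum(file.path(outdir, f))))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  report$manifest <- manifest
  log_line(log_path, "run complete")
  invisible(report)
}
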