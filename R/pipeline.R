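#' Build a pipeline run configuration
#'
#' Collects stage selections, dose ladders, thresholds and seeds for
#' [run_pipeline()]. Any field can be overridden; the defaults are the
#' package's standard study conditions.
#'
#' @param stages character vector of stages to run, in dependency order
#'   from `c("capture", "compete", "discover", "afscore", "marks",
#'   "growth")`.
#' @param seed master RNG seed, recorded in the manifest.
#' @param capture_doses,histone_doses,growth_doses dose ladders (uM).
#' @param n_replicates replicates for capture and histone stages.
#' @param noise_cv generator noise level.
#' @param fc_threshold,p_threshold enrichment cutoffs.
#' @param k,tsne_seed,kmeans_seed clustering parameters.
#' @param min_drop sensitive-cluster total-drop cutoff (log2 units).
#' @param min_stoich reproducibility-filter mean cutoff (percent).
#' @param mark_fc_threshold responsiveness fold-change cutoff.
#' @param low_dose,high_dose doses compared by the responsiveness filter.
#' @param pae_cutoff,distance_cutoff interface-scoring cutoffs (Angstrom).
#' @param ... further overrides stored verbatim.
#' @return A `run_config` list.
#' @export
run_config <- function(stages = c("capture", "compete", "discover",
                                  "afscore", "marks", "growth"),
                       seed = 0,
                       capture_doses = c(0, 0.1, 1, 10),
                       histone_doses = c(0, 0.1, 1, 10, 30),
                       growth_doses = c(0.01, 0.1, 1, 10, 100),
                       n_replicates = 3,
                       noise_cv = 0.1,
                       fc_threshold = 0.6, p_threshold = 0.05,
                       k = 5, tsne_seed = 0, kmeans_seed = 0,
                       min_drop = 1,
                       min_stoich = 1, mark_fc_threshold = 2,
                       low_dose = 0.1, high_dose = 30,
                       pae_cutoff = 12, distance_cutoff = 8, ...) {
  cfg <- c(as.list(environment()), list(...))
  thresholds <- c("fc_threshold", "p_threshold", "min_drop", "min_stoich",
                  "mark_fc_threshold", "pae_cutoff", "distance_cutoff", "k")
  bad <- vapply(thresholds, function(f) cfg[[f]] <= 0, logical(1))
  if (any(bad))
    stop("thresholds must be positive: ",
         paste(thresholds[bad], collapse = ", "), call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#' @param file YAML file of `run_config` fields.
#' @return A [run_config()].
#' @export
read_run_config <- function(file) {
  do.call(run_config, yaml::read_yaml(file))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic-to-report pipeline
#'
#' Generates the synthetic inputs from `truth`, then executes the selected
#' stages in dependency order, writing every tabular output as TSV plus a
#' JSON manifest with the configuration, seed, an MD5 per output file, and
#' one log record per stage with its input/output row counts. A stage
#' failure aborts downstream stages and leaves a partial manifest.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param truth a [synthetic_truth()]; defaults to the standard study
#'   conditions.
#' @return the manifest, invisibly (also written to
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(config = run_config(), out_dir, truth = synthetic_truth()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  files <- character(0)
  log <- list()
  note <- function(stage, ...) {
    log[[stage]] <<- list(stage = stage, ...)
  }
  state <- new.env(parent = emptyenv())

  steps <- list(
    capture = function() {
      state$capture <- generate_capture_dataset(
        truth, doses = config$capture_doses,
        n_replicates = config$n_replicates, noise_cv = config$noise_cv)
      files <<- c(files, write_capture_dataset(
        state$capture, file.path(out_dir, "capture_quant.tsv"),
        file.path(out_dir, "capture_samples.tsv")))
      files <<- c(files, write_tsv(truth_annotation(truth),
                                   file.path(out_dir, "complex_annotation.tsv")))
      note("capture", n_proteins = nrow(state$capture$abundance),
           n_samples = ncol(state$capture$abundance))
    },
    compete = function() {
      enr <- test_enrichment(state$capture, config$fc_threshold,
                             config$p_threshold)
      state$profiles <- compute_competition_profiles(state$capture,
                                                     enrichment = enr)
      files <<- c(files, write_tsv(enr, file.path(out_dir, "enrichment.tsv")),
                  write_competition_profiles(
                    state$profiles, file.path(out_dir, "competition_profiles.tsv")),
                  write_tsv(as.data.frame(occupancy_matrix(state$profiles)),
                            file.path(out_dir, "occupancy_matrix.tsv")))
      note("compete", n_tested = nrow(enr), n_specific = sum(enr$specific),
           n_profiled = length(state$profiles$proteins))
    },
    discover = function() {
      if (length(state$profiles$proteins) < 5) {
        # too few specific proteins to embed; emit empty-but-valid tables
        empty_emb <- data.frame(protein = character(), tsne1 = numeric(),
                                tsne2 = numeric(), cluster = integer(),
                                sensitive = logical())
        empty_cand <- data.frame(protein = character(), cluster = integer(),
                                 signature = character(),
                                 co_annotated = character())
        state$candidates <- empty_cand
        files <<- c(files,
                    write_tsv(empty_emb, file.path(out_dir, "embedding.tsv")),
                    write_tsv(empty_cand, file.path(out_dir, "candidates.tsv")))
        note("discover", n_clustered = 0L, sensitive_clusters = "",
             n_sensitive_proteins = 0L, n_candidates = 0L,
             skipped = "fewer than 5 specific proteins")
        return(invisible(NULL))
      }
      feats <- build_feature_matrix(state$profiles)
      coords <- embed_2d(feats, seed = config$tsne_seed)
      cl <- cluster_kmeans(coords, feats, k = config$k,
                           seed = config$kmeans_seed)
      sens <- classify_sensitive_clusters(cl, min_drop = config$min_drop)
      annot <- complex_annotation(truth_annotation(truth))
      cand <- flag_candidate_interactors(cl, annot, sens)
      state$candidates <- cand
      state$cluster <- cl
      emb <- data.frame(protein = rownames(coords), coords,
                        cluster = cl$labels,
                        sensitive = cl$labels %in% sens)
      files <<- c(files, write_tsv(emb, file.path(out_dir, "embedding.tsv")),
                  write_tsv(cand, file.path(out_dir, "candidates.tsv")))
      note("discover", n_clustered = nrow(emb),
           sensitive_clusters = paste(sens, collapse = ","),
           n_sensitive_proteins = sum(emb$sensitive),
           n_candidates = nrow(cand))
    },
    afscore = function() {
      bundles <- generate_af_candidates(truth)
      records <- do.call(rbind, lapply(bundles, af_metrics,
                                       pae_cutoff = config$pae_cutoff,
                                       distance_cutoff = config$distance_cutoff))
      ranked <- composite_rank(records)
      state$af_ranked <- ranked
      files <<- c(files, write_tsv(ranked, file.path(out_dir, "af_ranking.tsv")))
      note("afscore", n_pairs = nrow(ranked),
           top_pair = ranked$pair_id[1])
    },
    marks = function() {
      tab <- generate_histone_dataset(truth, doses = config$histone_doses,
                                      n_replicates = config$n_replicates,
                                      noise_cv = config$noise_cv)
      stoich <- compute_stoichiometries(tab)
      kept <- apply_reproducibility_filter(stoich, min_mean = config$min_stoich)
      kept_stoich <- merge(stoich, kept[, c("peptide_id", "modform")],
                           by = c("peptide_id", "modform"))
      resp <- call_responsive_marks(kept_stoich, config$low_dose,
                                    config$high_dose,
                                    config$mark_fc_threshold)
      panel <- biomarker_panel_report(kept_stoich)
      state$marks <- list(kept = kept, responsive = resp, panel = panel)
      files <<- c(files,
                  write_tsv(stoich, file.path(out_dir, "stoichiometry.tsv")),
                  write_tsv(kept, file.path(out_dir, "reproducible_marks.tsv")),
                  write_tsv(resp, file.path(out_dir, "responsive_marks.tsv")),
                  write_tsv(panel, file.path(out_dir, "biomarker_panel.tsv")))
      note("marks", n_forms = length(unique(paste(stoich$peptide_id,
                                                  stoich$modform))),
           n_reproducible = nrow(kept), n_responsive = sum(resp$responsive))
    },
    growth = function() {
      viab <- generate_viability_dataset(truth, doses = config$growth_doses)
      g <- growth_curves(viab)
      state$growth <- g
      files <<- c(files, write_tsv(viab, file.path(out_dir, "viability.tsv")),
                  write_tsv(g, file.path(out_dir, "gi50.tsv")),
                  write_tsv(attr(g, "curves"),
                            file.path(out_dir, "growth_curves.tsv")))
      note("growth", n_lines = nrow(g), gi50 = g$gi50[1])
    })

  status <- "complete"
  for (stage in config$stages) {
    ok <- tryCatch({ steps[[stage]](); TRUE },
                   error = function(e) {
                     note(stage, error = conditionMessage(e))
                     FALSE
                   })
    if (!ok) { status <- paste0("failed at ", stage); break }
  }

  cfg_path <- file.path(out_dir, "run_config.yaml")
  yaml::write_yaml(lapply(unclass(config), function(x) x), cfg_path)
  manifest <- list(status = status, seed = config$seed,
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   files = as.list(setNames(tools::md5sum(files),
                                            basename(files))),
                   log = unname(log))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
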