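#' Pipeline configuration
#'
#' Bundles every tunable parameter of the end-to-end analysis with the
#' field-standard defaults: 2.5 Hz frequency-mode bins, 5 ms
#' autocorrelogram bins up to 1 s lag, 20 ms doublet window, pauses at
#' 5 times the mean ISI, 75 s minimum recording duration. The
#' configuration round-trips to JSON via [write_pipeline_config()] /
#' [read_pipeline_config()].
#'
#' @param input_dir Directory of `<cell>.events.tsv` / `<cell>.meta.dcf`
#'   pairs to analyze (ignored when `simulate` is given).
#' @param output_dir Directory for all outputs (created if needed).
#' @param simulate `NULL`, or a list of cohort requests, each a list with
#'   `preset`, `n_cells`, and optionally `group_label` and `duration_s`.
#' @param seed Master seed: drives simulation and the tSNE embedding.
#' @param classifier [classifier_params()] values as a list.
#' @param min_duration_s Recording-duration inclusion threshold (75 s).
#' @param min_simple_spikes Minimum simple spikes per cell (10).
#' @param frequency_mode_bin_hz,pause_threshold_multiple,acg_bin_width_s,acg_max_lag_s,ri_rule
#'   Feature parameters; see [extract_features()].
#' @param linkage_method,tsne_perplexity Population parameters.
#' @param write_acg Also write per-cell autocorrelogram tables.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, output_dir = "purkinjetrain-out",
                            simulate = NULL, seed = 1L,
                            classifier = list(doublet_window_s = 0.020,
                                              doublet_ratio = 0.9,
                                              cs_min_spikelets = 3,
                                              cs_train_max_gap_s = 0.100),
                            min_duration_s = 75,
                            min_simple_spikes = 10L,
                            frequency_mode_bin_hz = 2.5,
                            pause_threshold_multiple = 5,
                            acg_bin_width_s = 0.005,
                            acg_max_lag_s = 1.0,
                            ri_rule = "deviation",
                            linkage_method = "average",
                            tsne_perplexity = 30,
                            write_acg = FALSE) {
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 simulate = simulate, seed = as.integer(seed),
                 classifier = classifier, min_duration_s = min_duration_s,
                 min_simple_spikes = min_simple_spikes,
                 frequency_mode_bin_hz = frequency_mode_bin_hz,
                 pause_threshold_multiple = pause_threshold_multiple,
                 acg_bin_width_s = acg_bin_width_s,
                 acg_max_lag_s = acg_max_lag_s, ri_rule = ri_rule,
                 linkage_method = linkage_method,
                 tsne_perplexity = tsne_perplexity,
                 write_acg = write_acg),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#' @param config A [pipeline_config()].
#' @param path JSON file path.
#' @return `path` (write) or a `pipeline_config` (read).
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  do.call(pipeline_config, x)
}

#' Run the full analysis pipeline
#'
#' Executes simulate-or-ingest, duration filtering, spike-type
#' classification, per-cell feature extraction, and the population stage
#' (clusterogram, tSNE pseudo-timeline, group-mean linkage, per-feature
#' ANOVA + Tukey-Kramer), writing all outputs plus an exclusion log and a
#' provenance document under `config$output_dir`. Per-cell failures
#' (short recordings, too few simple spikes) are logged and tabulated,
#' never fatal.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the feature table, exclusion log,
#'   population objects and output paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)

  cparams <- do.call(classifier_params, config$classifier)
  series_list <- list()
  if (!is.null(config$simulate)) {
    say("simulating cohorts")
    ev_dir <- file.path(out, "events")
    dir.create(ev_dir, showWarnings = FALSE)
    with_seed(config$seed, {
      cohort_seeds <- sample.int(2^31 - 2, length(config$simulate))
    })
    for (i in seq_along(config$simulate)) {
      cs <- config$simulate[[i]]
      cohort <- generate_cohort(cs$preset, cs$n_cells,
                                seed = cohort_seeds[i],
                                duration_s = cs$duration_s %||% 186,
                                group_label = cs$group_label %||% cs$preset)
      for (s in cohort) {
        write_event_series(s, file.path(ev_dir, paste0(s$cell_id, ".events.tsv")),
                           file.path(ev_dir, paste0(s$cell_id, ".meta.dcf")))
        truth <- data.frame(time_s = sprintf("%.9f", s$times),
                            true_label = s$true_labels)
        write.table(truth, file.path(ev_dir, paste0(s$cell_id, ".truth.tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
      series_list <- c(series_list, cohort)
    }
  } else {
    if (is.null(config$input_dir) || !dir.exists(config$input_dir))
      stop_validation("input_dir does not exist and no simulation was requested")
    ev_files <- sort(list.files(config$input_dir, pattern = "\\.events\\.tsv$",
                                full.names = TRUE))
    if (!length(ev_files)) stop_validation("no *.events.tsv files in input_dir")
    series_list <- lapply(ev_files, function(f) {
      load_event_series(f, sub("\\.events\\.tsv$", ".meta.dcf", f))
    })
  }

  say("classifying and extracting features for ", length(series_list), " cells")
  feats <- list()
  exclusions <- data.frame(cell_id = character(0), reason = character(0))
  for (s in series_list) {
    dec <- filter_by_duration(s, config$min_duration_s)
    if (!dec) {
      exclusions <- rbind(exclusions, data.frame(cell_id = s$cell_id,
                                                 reason = attr(dec, "reason")))
      next
    }
    cl <- classify_events(s, cparams)
    fv <- tryCatch(
      extract_features(s, cl,
                       min_simple_spikes = config$min_simple_spikes,
                       frequency_mode_bin_hz = config$frequency_mode_bin_hz,
                       pause_threshold_multiple = config$pause_threshold_multiple,
                       acg_bin_width_s = config$acg_bin_width_s,
                       acg_max_lag_s = config$acg_max_lag_s,
                       ri_rule = config$ri_rule),
      purkinjetrain_insufficient_data = function(e) {
        exclusions <<- rbind(exclusions,
                             data.frame(cell_id = s$cell_id,
                                        reason = conditionMessage(e)))
        NULL
      })
    if (is.null(fv)) next
    if (isTRUE(config$write_acg)) {
      st <- s$times[cl$labels == "simple"]
      acg <- compute_autocorrelogram(st, config$acg_bin_width_s,
                                     config$acg_max_lag_s,
                                     s$recording_duration_s)
      dir.create(file.path(out, "acg"), showWarnings = FALSE)
      write.table(data.frame(lag_s = acg$lag_centers_s, count = acg$counts),
                  file.path(out, "acg", paste0(s$cell_id, ".acg.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    feats[[length(feats) + 1L]] <- fv
  }
  if (!length(feats)) stop_validation("no cells survived filtering")
  feature_table <- do.call(rbind, feats)
  ft_path <- file.path(out, "features.tsv")
  write_feature_table(feature_table, ft_path)
  write.table(exclusions, file.path(out, "exclusions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  say(nrow(feature_table), " cells in feature table; ",
      nrow(exclusions), " excluded")

  pop <- NULL; emb <- NULL; cg <- NULL; gl <- NULL; stats_tables <- NULL
  if (nrow(feature_table) >= 3L) {
    pop <- assemble_population(feature_table)
    cg <- clusterogram(pop, linkage_method = config$linkage_method)
    write_dendrogram_newick(cg, file.path(out, "cells_dendrogram.nwk"))
    perp <- min(config$tsne_perplexity, floor((nrow(feature_table) - 1) / 3))
    emb <- tsne_pseudotimeline(pop, perplexity = perp, seed = config$seed)
    write.table(data.frame(cell_id = pop$cell_ids,
                           group_label = pop$group_labels,
                           tSNE1 = sprintf("%.10g", emb$coordinates[, 1]),
                           tSNE2 = sprintf("%.10g", emb$coordinates[, 2])),
                file.path(out, "tsne_coordinates.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (length(unique(pop$group_labels)) >= 3L) {
      gl <- group_linkage(pop, linkage_method = config$linkage_method)
      write_dendrogram_newick(gl, file.path(out, "groups_dendrogram.nwk"))
    } else say("fewer than 3 groups: skipping group linkage")
    if (length(unique(pop$group_labels)) >= 2L) {
      stats_tables <- lapply(CLUSTER_FEATURES, function(fn) {
        cmp <- compare_groups(feature_table, fn)
        cbind(feature = fn, f = cmp$f, p = cmp$p, cmp$tukey)
      })
      stats_df <- do.call(rbind, stats_tables)
      write.table(stats_df, file.path(out, "anova_tukey.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  } else say("fewer than 3 cells: skipping population stage")

  input_files <- if (!is.null(config$simulate))
    list.files(file.path(out, "events"), full.names = TRUE)
  else list.files(config$input_dir, full.names = TRUE)
  provenance <- list(
    package = "purkinjetrain",
    version = as.character(utils::packageVersion("purkinjetrain")),
    r_version = R.version.string,
    timestamp_omitted_for_determinism = TRUE,
    config = unclass(config),
    tsne = if (!is.null(emb)) list(seed = emb$seed, perplexity = emb$perplexity),
    input_checksums = as.list(tools::md5sum(sort(input_files))))
  jsonlite::write_json(provenance, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(list(feature_table = feature_table, exclusions = exclusions,
                 population = pop, clusterogram = cg, embedding = emb,
                 group_linkage = gl,
                 paths = list(features = ft_path, output_dir = out)))
}
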