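#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with defaults equal to
#' the study design: 500 Hz acquisition downsampled to 250 Hz, 1-30 Hz
#' zero-phase Butterworth of design order 4, average reference, 30 s epochs,
#' PE with n = 3, stratified 100-epoch group sampling, five-class cut-off,
#' random forest with tau = 3 features. The full configuration (plus seed)
#' is serialized into every report for provenance.
#'
#' @param out_dir output directory for all report files.
#' @param seed master seed for every stochastic step.
#' @param n_healthy,n_mcs,n_uws synthetic cohort sizes.
#' @param healthy_duration_s,doc_duration_s per-subject durations (s).
#' @param sampling_rate acquisition rate (Hz).
#' @param target_rate analysis rate after downsampling (Hz).
#' @param low,high,filter_order band-pass parameters.
#' @param epoch_s epoch length (s).
#' @param pe_n,pe_tau permutation entropy parameters (tau in samples at the
#'   analysis rate).
#' @param k healthy-anchored flat cluster count.
#' @param classifier "random_forest" or "feedforward_net".
#' @param ntree forest size.
#' @param grid hyperparameter grid (NULL for the default).
#' @param run_loso also run leave-one-subject-out validation on the healthy
#'   cohort (slower; default FALSE).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("docsleep-"), seed = 1L,
                            n_healthy = 3, n_mcs = 1, n_uws = 1,
                            healthy_duration_s = 3600, doc_duration_s = 3600,
                            sampling_rate = 500, target_rate = 250,
                            low = 1, high = 30, filter_order = 4,
                            epoch_s = 30, pe_n = 3, pe_tau = 3, k = 5,
                            classifier = "random_forest", ntree = 500,
                            grid = NULL, run_loso = FALSE) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_healthy = n_healthy, n_mcs = n_mcs, n_uws = n_uws,
                 healthy_duration_s = healthy_duration_s,
                 doc_duration_s = doc_duration_s,
                 sampling_rate = sampling_rate, target_rate = target_rate,
                 low = low, high = high, filter_order = filter_order,
                 epoch_s = epoch_s, pe_n = pe_n, pe_tau = pe_tau, k = k,
                 classifier = classifier, ntree = ntree, grid = grid,
                 run_loso = isTRUE(run_loso)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param config a `pipeline_config`.
#' @param file YAML path.
#' @return `file` (writer) or a `pipeline_config` (reader).
#' @export
write_config_yaml <- function(config, file) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(file) {
  cfg <- yaml::read_yaml(file)
  do.call(pipeline_config, cfg)
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  v <- utf8ToInt(as.character(s))
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 2147483647)
}

preprocess_and_features <- function(rec, config) {
  rec <- preprocess_recording(rec, target_rate = config$target_rate,
                              low = config$low, high = config$high,
                              order = config$filter_order)
  grid <- segment_epochs(rec, config$epoch_s)
  feats <- epoch_features(rec, grid, pe_params(config$pe_n, config$pe_tau))
  list(recording = rec, grid = grid, features = feats)
}

#' Run the full pipeline: simulate, preprocess, extract complexity, cluster,
#' train, predict, validate
#'
#' Executes the processing chain on a synthetic cohort: complexity
#' estimation per subject, group-level cluster analysis with the
#' healthy-anchored cut-off transferred unchanged to MCS and UWS, classifier
#' training on the labeled healthy epochs, epoch-by-epoch DOC prediction and
#' binary sleep-vs-eyes-closed validation. All artifacts are written to
#' `config$out_dir` with the configuration, seed and a config hash embedded;
#' a rerun with the same configuration yields byte-identical JSON reports.
#'
#' @param config a `pipeline_config`.
#' @return The report bundle (list), invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- list(config = unclass(config), config_hash = config_hash(config))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_docsleep("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }

  cohort <- stage("simulate", simulate_cohort(
    n_healthy = config$n_healthy, n_mcs = config$n_mcs, n_uws = config$n_uws,
    healthy_duration_s = config$healthy_duration_s,
    doc_duration_s = config$doc_duration_s,
    sampling_rate = config$sampling_rate, seed = config$seed))

  healthy <- stage("complexity-healthy", lapply(cohort$healthy, function(s) {
    pf <- preprocess_and_features(s$recording, config)
    c(s, pf[c("grid", "features")])
  }))
  doc <- stage("complexity-doc", lapply(cohort$doc, function(s) {
    pf <- preprocess_and_features(s$recording, config)
    s$grid <- pf$grid
    s$features <- pf$features
    s$day_night <- split_day_night(pf$grid, s$intervals)
    s$eyes_epoch <- align_eye_states(pf$grid, s$eye_states)
    s
  }))

  clust <- stage("clustering", {
    hs <- lapply(seq_along(healthy), function(i)
      suppressWarnings(sample_epochs(healthy[[i]]$features,
                                     healthy[[i]]$stages[healthy[[i]]$grid$epoch + 1L],
                                     sampling_scheme("healthy"),
                                     seed = derive_seed(config$seed, 300L + i))))
    gh <- group_average(hs, "healthy")
    th <- hcluster(gh)
    cutoff <- select_cutoff(th, config$k)
    groups <- list(healthy = list(tree = th, mat = gh))
    for (grp in c("MCS", "UWS")) {
      subj <- Filter(function(s) s$spec$group == grp, doc)
      if (length(subj) == 0) next
      ds <- lapply(seq_along(subj), function(i)
        suppressWarnings(sample_epochs(subj[[i]]$features, subj[[i]]$day_night,
                                       sampling_scheme("doc"),
                                       seed = derive_seed(config$seed, 400L + i))))
      gm <- group_average(ds, grp)
      groups[[grp]] <- list(tree = hcluster(gm), mat = gm)
    }
    summaries <- lapply(names(groups), function(g) {
      tr <- groups[[g]]$tree
      asg <- cut_tree(tr, cutoff)
      sm <- summarize_clusters(asg, groups[[g]]$mat, root_height = max(tr$heights))
      write_merge_table(tr, file.path(config$out_dir, paste0("merge_", g, ".csv")))
      tree_to_newick(tr, file.path(config$out_dir, paste0("tree_", g, ".nwk")))
      list(group = g, cutoff = cutoff, n_clusters = sm$n_clusters,
           root_height = sm$root_height,
           clusters = lapply(sm$clusters, function(cl)
             cl[c("cluster", "size", "mean_pe", "sd_pooled", "sd_epoch_means")]))
    })
    names(summaries) <- names(groups)
    list(cutoff = cutoff, summaries = summaries)
  })
  jsonlite::write_json(c(prov, clust["cutoff"], list(groups = clust$summaries)),
                       file.path(config$out_dir, "clustering.json"),
                       auto_unbox = TRUE, digits = NA)

  clf <- stage("train", {
    lfs <- labeled_feature_set(
      lapply(healthy, function(s) unclass(s$features)),
      lapply(healthy, function(s) s$stages[s$grid$epoch + 1L]),
      vapply(healthy, function(s) s$spec$subject_id, character(1)))
    train_stage_classifier(lfs, config$classifier, grid = config$grid,
                           seed = derive_seed(config$seed, 500L),
                           ntree = config$ntree)
  })
  jsonlite::write_json(c(prov, list(kind = clf$kind,
                                    hyperparameters = clf$hyperparameters,
                                    importance = if (clf$kind == "random_forest")
                                      as.list(feature_importance(clf)) else NULL)),
                       file.path(config$out_dir, "classifier.json"),
                       auto_unbox = TRUE, digits = NA)

  loso <- NULL
  if (config$run_loso) {
    loso <- stage("loso", loso_evaluate(
      labeled_feature_set(lapply(healthy, function(s) unclass(s$features)),
                          lapply(healthy, function(s) s$stages[s$grid$epoch + 1L]),
                          vapply(healthy, function(s) s$spec$subject_id, character(1))),
      config$classifier, grid = config$grid,
      seed = derive_seed(config$seed, 600L), ntree = config$ntree))
    write_cv_result(loso, file.path(config$out_dir, "loso.json"))
  }

  validation <- stage("validate", {
    per <- lapply(doc, function(s) {
      pred <- predict_hypnogram(clf, unclass(s$features))
      bf <- binary_f1(collapse_to_binary(pred), s$eyes_epoch$eye_state)
      export_hypnogram(pred, s$eyes_epoch$eye_state, s$day_night,
                       file.path(config$out_dir,
                                 paste0("hypnogram_", s$spec$subject_id, ".csv")))
      list(subject = s$spec$subject_id, group = s$spec$group, f1 = bf$f1,
           precision = bf$precision, recall = bf$recall,
           n_included = bf$n_included, n_excluded_na = bf$n_excluded_na,
           n_oc = bf$n_oc, note = bf$note)
    })
    rep <- cohort_report(vapply(per, `[[`, numeric(1), "f1"),
                         vapply(per, `[[`, character(1), "subject"),
                         vapply(per, `[[`, character(1), "group"))
    list(per_subject = per, overall = rep$overall, per_group = rep$per_group,
         high_performers = rep$high_performers,
         low_performers = rep$low_performers)
  })
  jsonlite::write_json(c(prov, validation),
                       file.path(config$out_dir, "validation.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(config = config, clustering = clust, classifier = clf,
                 loso = loso, validation = validation,
                 healthy = healthy, doc = doc))
}
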