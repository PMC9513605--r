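run_config_schema <- function() {
  list(
    seed = 1L,
    data = list(
      synthetic = list(
        n_mirna = 60L, n_disease = 40L, n_positive = 150L,
        ontology_depth = 4L, ontology_branching = 3L,
        contamination_rate = 0.05, seed = NULL
      ),
      associations = NULL, ontology = NULL,
      ontology_dialect = "edge_list", functional_sim = NULL
    ),
    similarity = list(delta = 0.5, log_base = NULL, gamma_prime = 1),
    sampling = list(
      k = 2L, n_select = 1L, n_repeats = 10L, batch_size = 1024L,
      max_iter = 100L
    ),
    ensemble = list(
      m = 10L, learner = "xgb", feature_fraction = 0.75,
      fs_num_trees = 100L, params = list()
    ),
    evaluation = list(
      folds = 5L, repeats = 10L, ranking_mode = "balanced_fold",
      strict_cv = FALSE
    )
  )
}

merge_config <- function(schema, user, path = character()) {
  if (is.null(user)) return(schema)
  unknown <- setdiff(names(user), names(schema))
  if (length(unknown) > 0L) {
    rlang::abort(sprintf(
      "unknown config key(s): %s",
      paste(paste(c(path, unknown[1]), collapse = "."), collapse = ", ")
    ))
  }
  for (key in names(user)) {
    if (is.list(schema[[key]]) && !identical(key, "params")) {
      schema[[key]] <- merge_config(schema[[key]], user[[key]], c(path, key))
    } else {
      schema[[key]] <- user[[key]]
    }
  }
  schema
}

#' Build and validate a run configuration
#'
#' A single document collecting every tunable of the pipeline. Unknown
#' keys are rejected; cross-field constraints (e.g. `n_select < k`) are
#' checked here, before any compute. One master `seed` fans out to the
#' stage seeds by fixed offsets.
#'
#' @param config named list of overrides (possibly nested), or the result
#'   of `yaml::read_yaml()` on a config file.
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  cfg <- merge_config(run_config_schema(), config)
  if (is.null(cfg$data$synthetic$seed)) cfg$data$synthetic$seed <- cfg$seed
  if (cfg$sampling$n_select >= cfg$sampling$k) {
    rlang::abort("`sampling.n_select` must be smaller than `sampling.k`")
  }
  if (!cfg$ensemble$learner %in% c("xgb", "rf", "adaboost", "extratrees")) {
    rlang::abort("`ensemble.learner` must be one of xgb, rf, adaboost, extratrees")
  }
  if (!cfg$evaluation$ranking_mode %in% c("balanced_fold", "fold_plus_unlabeled")) {
    rlang::abort("`evaluation.ranking_mode` must be balanced_fold or fold_plus_unlabeled")
  }
  if (cfg$evaluation$folds < 2L) rlang::abort("`evaluation.folds` must be >= 2")
  assert_prob(cfg$ensemble$feature_fraction, "ensemble.feature_fraction",
    open_left = TRUE
  )
  structure(cfg, class = c("run_config", "list"))
}

#' Read a YAML run configuration
#'
#' @param path YAML file.
#' @return a validated [run_config()].
#' @export
read_run_config <- function(path) {
  run_config(yaml::read_yaml(path))
}

#' Run the full pipeline
#'
#' Executes the stages data -> similarity -> sample -> train -> evaluate
#' in order, writing each stage's artifacts under `out_dir` together with
#' a manifest (config hash, seeds, package version, completed stages).
#' When rerun with an identical configuration, completed stages are
#' skipped and their artifacts reloaded; a stage failure aborts with the
#' stage name while earlier artifacts remain on disk.
#'
#' @param config a [run_config()] (or a list coerced through it).
#' @param out_dir output directory.
#' @return (invisibly) a list with the bundle, partition, model and
#'   cross-validation report.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- rlang::hash(unclass(cfg))
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else NULL
  if (is.null(manifest) || !identical(manifest$config_hash, cfg_hash)) {
    manifest <- list(
      config_hash = cfg_hash, seed = cfg$seed,
      package_version = as.character(utils::packageVersion("pumda")),
      stages = character(0)
    )
  }
  done <- function(stage, files) {
    stage %in% manifest$stages && all(file.exists(file.path(out_dir, files)))
  }
  mark <- function(stage) {
    manifest$stages <<- union(manifest$stages, stage)
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
    })
  }

  # ---- data ----
  data_files <- c("associations.tsv", "ontology.tsv", "functional_similarity.csv")
  if (!done("data", data_files)) {
    run_stage("data", {
      if (!is.null(cfg$data$associations)) {
        assoc <- read_association_table(cfg$data$associations)
        ont <- if (!is.null(cfg$data$ontology)) {
          read_ontology(cfg$data$ontology, cfg$data$ontology_dialect)
        } else disease_ontology(tibble::tibble(parent = character(), child = character()))
        fs <- if (!is.null(cfg$data$functional_sim)) {
          read_similarity_matrix(cfg$data$functional_sim)
        } else matrix(0, 0, 0)
      } else {
        ds <- generate_synthetic_dataset(do.call(synthetic_spec, cfg$data$synthetic))
        assoc <- ds$associations
        ont <- ds$ontology
        fs <- ds$functional_similarity
        readr::write_tsv(ds$hidden_positives, file.path(out_dir, "hidden_positives.tsv"))
      }
      write_association_table(assoc, file.path(out_dir, "associations.tsv"))
      write_ontology(ont, file.path(out_dir, "ontology.tsv"))
      write_similarity_matrix(fs, file.path(out_dir, "functional_similarity.csv"))
    })
    mark("data")
  }
  assoc <- read_association_table(file.path(out_dir, "associations.tsv"))
  ont <- read_ontology(file.path(out_dir, "ontology.tsv"), "edge_list")
  fs <- read_similarity_matrix(file.path(out_dir, "functional_similarity.csv"))

  # ---- similarity ----
  log_base <- if (is.null(cfg$similarity$log_base)) exp(1) else cfg$similarity$log_base
  bundle <- run_stage("similarity", {
    b <- similarity_bundle(
      assoc, ont,
      functional_sim = if (nrow(fs) > 0) fs else NULL,
      delta = cfg$similarity$delta, log_base = log_base,
      gamma_prime = cfg$similarity$gamma_prime
    )
    if (!done("similarity", "IDS.csv")) {
      for (nm in c("SS", "GD", "GM", "IDS", "IMS")) {
        write_similarity_matrix(b[[nm]], file.path(out_dir, paste0(nm, ".csv")))
      }
      mark("similarity")
    }
    b
  })

  # ---- sample ----
  partition <- if (done("sample", "negatives.tsv")) {
    neg <- readr::read_tsv(file.path(out_dir, "negatives.tsv"),
      col_types = "cc", progress = FALSE
    )
    reload_partition(bundle, neg, cfg)
  } else {
    run_stage("sample", {
      p <- sample_negatives(
        bundle,
        k = cfg$sampling$k, n_select = cfg$sampling$n_select,
        n_repeats = cfg$sampling$n_repeats, batch_size = cfg$sampling$batch_size,
        max_iter = cfg$sampling$max_iter, seed = derive_seed(cfg$seed, 11L)
      )
      write_negatives(p, file.path(out_dir, "negatives.tsv"))
      mark("sample")
      p
    })
  }

  # ---- train ----
  model_path <- file.path(out_dir, "model.rds")
  model <- if (done("train", "model.rds")) {
    readRDS(model_path)
  } else {
    run_stage("train", {
      subsets <- make_training_subsets(
        positives(partition), negatives(partition),
        m = cfg$ensemble$m, seed = derive_seed(cfg$seed, 23L)
      )
      mdl <- train_ensemble(
        bundle, subsets,
        learner = cfg$ensemble$learner,
        feature_fraction = cfg$ensemble$feature_fraction,
        fs_num_trees = cfg$ensemble$fs_num_trees,
        params = cfg$ensemble$params, seed = derive_seed(cfg$seed, 29L)
      )
      saveRDS(mdl, model_path)
      jsonlite::write_json(
        lapply(mdl$members, function(m) m$selected_features),
        file.path(out_dir, "selected_features.json")
      )
      mark("train")
      mdl
    })
  }

  # ---- evaluate ----
  report_path <- file.path(out_dir, "report.json")
  cv <- if (done("evaluate", "report.json")) {
    jsonlite::read_json(report_path, simplifyVector = TRUE)
  } else {
    run_stage("evaluate", {
      res <- cross_validate(
        bundle, partition,
        folds = cfg$evaluation$folds, repeats = cfg$evaluation$repeats,
        m = cfg$ensemble$m, learner = cfg$ensemble$learner,
        feature_fraction = cfg$ensemble$feature_fraction,
        fs_num_trees = cfg$ensemble$fs_num_trees, params = cfg$ensemble$params,
        ranking_mode = cfg$evaluation$ranking_mode,
        strict_cv = cfg$evaluation$strict_cv,
        seed = derive_seed(cfg$seed, 37L)
      )
      jsonlite::write_json(
        list(summary = glance(res), per_fold = tidy(res)),
        report_path,
        auto_unbox = TRUE, digits = NA, dataframe = "rows"
      )
      mark("evaluate")
      res
    })
  }

  invisible(list(bundle = bundle, partition = partition, model = model, cv = cv))
}

# Rebuild a sample_partition from a written negative set.
reload_partition <- function(bundle, negative_pairs, cfg) {
  pairs <- pair_grid(bundle$mirna_index, bundle$disease_index)
  keys <- pair_key(pairs$mirna, pairs$disease)
  md_vec <- bundle$MD[cbind(
    match(pairs$mirna, bundle$mirna_index),
    match(pairs$disease, bundle$disease_index)
  )]
  structure(
    list(
      pairs = pairs,
      positive_idx = which(md_vec == 1L),
      negative_idx = sort(match(pair_key(negative_pairs$mirna, negative_pairs$disease), keys)),
      labels = NULL, p = NULL, selected_clusters = NULL,
      k = cfg$sampling$k, n_select = cfg$sampling$n_select,
      seed = derive_seed(cfg$seed, 11L)
    ),
    class = "sample_partition"
  )
}
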