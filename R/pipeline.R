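#' Default pipeline configuration
#'
#' All analysis settings at their canonical defaults: six bands, 10%
#' proportional threshold, NBS at primary threshold 3.45 with 5000
#' permutations and alpha 0.05, and 10-fold cross-validation repeated 100
#' times.
#'
#' @return A nested list of class `hemilat_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1,
    outdir = "hemilat_run",
    stages = list(simulate = TRUE, connect = TRUE, graph = TRUE,
                  stats = TRUE, nbs = TRUE, classify = TRUE),
    cohort = list(groups = c(HC = 22, LP = 25, RP = 16),
                  effect_delta = 0.1, between_subject_sd = 0.05,
                  mode = "adjacency", bands = band_names(), n_rois = 246),
    graph = list(density = 0.10),
    nbs = list(primary_threshold = 3.45, n_permutations = 5000,
               alpha = 0.05, direction = "both"),
    classify = list(n_folds = 10, n_repeats = 100, fdr_alpha = 0.05)
  ), class = "hemilat_config")
}

#' @keywords internal
merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (path == "") key else paste(path, key, sep = ".")
    if (!key %in% names(defaults)) {
      stop("unknown configuration key: ", full, call. = FALSE)
    }
    if (is.list(defaults[[key]]) && !is.list(user[[key]])) {
      stop("configuration key ", full, " must be a mapping", call. = FALSE)
    }
    if (is.list(defaults[[key]])) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      val <- user[[key]]
      if (is.numeric(defaults[[key]]) && !is.numeric(val) &&
          !is.null(names(defaults[[key]]))) {
        stop("configuration key ", full, " has the wrong type",
             call. = FALSE)
      }
      if (!is.null(names(defaults[[key]]))) val <- unlist(val)
      defaults[[key]] <- val
    }
  }
  defaults
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML (or JSON) configuration file, applies defaults for any key
#' not given, rejects unknown keys with their full key path, and checks the
#' module invariants (NBS permutation minimum, threshold positivity,
#' density range).
#'
#' @param path Path to a config file; `NULL` or an empty file yields the
#'   defaults.
#' @return A fully resolved `hemilat_config`.
#' @export
validate_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- if (grepl("\\.json$", path)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    if (!is.null(user)) cfg <- merge_config(cfg, user)
  }
  # invariant checks via the constructors
  nbs_config(cfg$nbs$primary_threshold, cfg$nbs$n_permutations,
             cfg$nbs$alpha, cfg$nbs$direction)
  if (cfg$graph$density <= 0 || cfg$graph$density > 1) {
    stop("graph.density must lie in (0, 1]", call. = FALSE)
  }
  if (any(cfg$cohort$groups < 2)) {
    stop("cohort.groups must all be >= 2", call. = FALSE)
  }
  class(cfg) <- "hemilat_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order (simulate, connect, graph, stats,
#' nbs, classify) on a synthetic cohort and writes every product under
#' `config$outdir`, recording each output file with its MD5 hash in a run
#' manifest. Disabled stages read their inputs from a previous run's
#' outputs in the same directory; a missing input is reported as a
#' dependency error naming the absent artifact. Re-running an identical
#' configuration reproduces identical outputs.
#'
#' @param config A `hemilat_config` (see [validate_config()]).
#' @param atlas Atlas table (default [default_atlas()]).
#' @return The run manifest (list), invisibly written to
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = default_config(),
                         atlas = default_atlas()) {
  stopifnot(inherits(config, "hemilat_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  st <- config$stages

  cohort_dir <- file.path(outdir, "cohort")
  if (isTRUE(st$simulate)) {
    spec <- cohort_spec(groups = config$cohort$groups,
                        effect_delta = config$cohort$effect_delta,
                        between_subject_sd = config$cohort$between_subject_sd,
                        mode = config$cohort$mode,
                        bands = config$cohort$bands,
                        n_rois = config$cohort$n_rois,
                        atlas = atlas,
                        seed = derive_seed(config$seed, 1L))
    cohort <- generate_cohort(spec)
    if (spec$mode == "sensor" && isTRUE(st$connect)) {
      # beamform each subject back to source space, then dwPLI connectomes
      cohort$subjects <- lapply(cohort$subjects, function(s) {
        ve <- beamform_rois(s$sensors, cohort$leadfields$leadfields)
        s$matrices <- connectivity_matrices(ve, config$cohort$bands)
        s
      })
    }
    write_cohort(cohort, cohort_dir)
    files <- c(files, list.files(cohort_dir, recursive = TRUE,
                                 full.names = TRUE))
  } else {
    if (!file.exists(file.path(cohort_dir, "manifest.json"))) {
      stop("stage dependency missing: no cohort at ", cohort_dir,
           call. = FALSE)
    }
    cohort <- read_cohort(cohort_dir)
  }

  features_path <- file.path(outdir, "features.tsv")
  if (isTRUE(st$graph)) {
    features <- cohort_feature_table(cohort, atlas,
                                     density = config$graph$density)
    utils::write.table(features, features_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, features_path)
  } else if (isTRUE(st$stats) || isTRUE(st$classify)) {
    if (!file.exists(features_path)) {
      stop("stage dependency missing: ", features_path, call. = FALSE)
    }
    features <- utils::read.delim(features_path, stringsAsFactors = FALSE)
  }

  tests_path <- file.path(outdir, "feature_tests.tsv")
  if (isTRUE(st$stats)) {
    tests <- feature_group_tests(features, "RP", "LP")
    utils::write.table(tests, tests_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, tests_path)
  }

  if (isTRUE(st$nbs)) {
    res <- nbs_test(cohort_matrices(cohort, "theta", "RP"),
                    cohort_matrices(cohort, "theta", "LP"),
                    nbs_config(config$nbs$primary_threshold,
                               config$nbs$n_permutations,
                               config$nbs$alpha, config$nbs$direction,
                               seed = derive_seed(config$seed, 2L)))
    write_nbs_result(res, file.path(outdir, "nbs"))
    files <- c(files, list.files(file.path(outdir, "nbs"),
                                 full.names = TRUE))
  }

  if (isTRUE(st$classify)) {
    if (!file.exists(tests_path)) {
      stop("stage dependency missing: ", tests_path, call. = FALSE)
    }
    tests <- utils::read.delim(tests_path, stringsAsFactors = FALSE)
    selected <- tests$feature[tests$p_fdr < config$classify$fdr_alpha]
    if (length(selected) == 0) {
      stop("no feature passed FDR selection; nothing to classify",
           call. = FALSE)
    }
    pat <- features$label %in% c("LP", "RP")
    report <- nb_crossvalidate(features[pat, selected, drop = FALSE],
                               features$label[pat],
                               n_folds = config$classify$n_folds,
                               n_repeats = config$classify$n_repeats,
                               seed = derive_seed(config$seed, 3L))
    cls_path <- file.path(outdir, "classifier.json")
    jsonlite::write_json(list(
      selected_features = selected,
      accuracy = as.list(report$accuracy),
      per_class = report$per_class,
      weighted_average = as.list(report$weighted_average)
    ), cls_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    files <- c(files, cls_path)
  }

  files <- sort(unique(files))
  manifest <- list(
    seed = config$seed,
    stages = st,
    outputs = data.frame(file = files,
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
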