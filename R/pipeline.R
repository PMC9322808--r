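# End-to-end pipeline: ingest -> homology -> ERCP training -> screen ->
# funnel, driven by a strictly validated config with a JSON run manifest.

default_run_config <- function() {
  list(seed = 1L,
       focal_target = NULL,
       fingerprint = list(radius = 2L, n_bits = 2048L),
       homology = list(source = "identity_table", threshold = 0.4,
                       identity_table = NULL, targets_fasta = NULL,
                       transitive = FALSE),
       inputs = list(activities = NULL, compounds = NULL,
                     references = NULL, library = NULL),
       training = list(negative_ratio = 1, n_ensemble = 10L,
                       learner = "glmnet", alpha = 0, lambda = 0.01,
                       test_fraction = 0.25),
       funnel = list(stages = list()),
       output = list(dir = NULL, format = "tsv"))
}

# strict validation: any key not present in the default schema is a hard
# error -- silent typo tolerance ("negativ_ratio") is how screens become
# irreproducible
check_unknown_keys <- function(config, schema, path = "") {
  if (!is.list(config)) return(invisible(NULL))
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown))
    stop("unknown config key", if (length(unknown) > 1) "s" else "", ": ",
         paste0(path, unknown, collapse = ", "), call. = FALSE)
  for (k in names(config)) {
    if (k == "funnel") {
      extra <- setdiff(names(config$funnel), "stages")
      if (length(extra))
        stop("unknown config key: ", paste0(path, "funnel.", extra, collapse = ", "),
             call. = FALSE)
      for (i in seq_along(config$funnel$stages)) {
        st <- config$funnel$stages[[i]]
        extra <- setdiff(names(st), c("type", "cutoff", "k", "ids", "ids_file"))
        if (length(extra))
          stop("unknown config key in funnel stage ", i, ": ",
               paste(extra, collapse = ", "), call. = FALSE)
      }
    } else if (is.list(schema[[k]])) {
      check_unknown_keys(config[[k]], schema[[k]], paste0(path, k, "."))
    }
  }
  invisible(NULL)
}

merge_config <- function(defaults, config) {
  for (k in names(config)) {
    if (is.list(defaults[[k]]) && is.list(config[[k]]) && k != "funnel")
      defaults[[k]] <- merge_config(defaults[[k]], config[[k]])
    else defaults[[k]] <- config[[k]]
  }
  defaults
}

#' Validate and complete a pipeline configuration
#'
#' Unknown keys anywhere in the config are a hard error (fail-fast; no
#' silent typo tolerance). Known keys are merged over the defaults.
#'
#' @param config Nested list (parsed JSON/YAML); see the README for the
#'   schema.
#' @return The completed config.
#' @export
validate_config <- function(config) {
  schema <- default_run_config()
  check_unknown_keys(config, schema)
  cfg <- merge_config(schema, config)
  if (is.null(cfg$focal_target)) stop("config is missing 'focal_target'")
  for (f in c("activities", "references", "library"))
    if (is.null(cfg$inputs[[f]])) stop("config is missing 'inputs.", f, "'")
  if (is.null(cfg$output$dir)) stop("config is missing 'output.dir'")
  cfg$homology$source <- match.arg(cfg$homology$source,
                                   c("identity_table", "pairwise_alignment",
                                     "family_label"))
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Read a pipeline configuration file (JSON or YAML)
#'
#' @param path Config file; format chosen by extension (`.json` vs
#'   `.yml`/`.yaml`).
#' @return Parsed nested list (unvalidated; see [validate_config()]).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML configs; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  }
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

stages_from_config <- function(stage_list) {
  lapply(seq_along(stage_list), function(i) {
    st <- stage_list[[i]]
    if (is.null(st$type)) stop("funnel stage ", i, " has no 'type'")
    switch(st$type,
      score_cutoff = stage_score_cutoff(st$cutoff),
      top_k = stage_top_k(st$k),
      keep_list = {
        ids <- st$ids
        if (!is.null(st$ids_file)) ids <- c(ids, readLines(st$ids_file))
        stage_keep_list(ids)
      },
      stop("unknown funnel stage type: ", st$type))
  })
}

file_md5 <- function(paths) {
  paths <- paths[!vapply(paths, is.null, logical(1))]
  paths <- unlist(paths)
  if (!length(paths)) return(stats::setNames(list(), character(0)))
  ok <- file.exists(paths)
  out <- as.list(ifelse(ok, unname(tools::md5sum(paths)), NA_character_))
  names(out) <- paths
  out
}

write_manifest <- function(path, command, config, seed, inputs, outputs,
                           status = "ok", failed_stage = NULL, message = NULL,
                           extra = NULL) {
  manifest <- list(command = command, status = status, seed = seed,
                   config = config, config_hash = config_hash(config),
                   inputs = file_md5(inputs), outputs = outputs,
                   failed_stage = failed_stage, message = message,
                   versions = list(
                     ecbscreen = as.character(utils::packageVersion("ecbscreen")),
                     R = paste(R.version$major, R.version$minor, sep = ".")))
  if (!is.null(extra)) manifest <- c(manifest, extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Run the full screening pipeline
#'
#' Executes train -> score -> funnel from one validated config: reads
#' compounds, activities and homology inputs; enumerates ERCPs for the
#' focal target; trains the target-specific ensemble; screens the library
#' against the references with max aggregation; applies the funnel stages;
#' and writes `model.rds`, `results.<fmt>`, `hits.<fmt>` and
#' `manifest.json` into the output directory. The manifest (seed, config +
#' hash, input checksums, stage counts) is written even when a stage
#' fails, with the failing stage named.
#'
#' @param config Nested list or path to a JSON/YAML config file.
#' @param out_dir Optional override of `config$output$dir`.
#' @return Invisibly, a list of output paths plus the funnel stage
#'   summary. Errors in any stage re-raise after the failure manifest is
#'   written.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- validate_config(config)
  if (!is.null(out_dir)) cfg$output$dir <- out_dir
  dir.create(cfg$output$dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- match.arg(cfg$output$format, c("tsv", "csv"))
  paths <- list(model = file.path(cfg$output$dir, "model.rds"),
                results = file.path(cfg$output$dir, paste0("results.", fmt)),
                hits = file.path(cfg$output$dir, paste0("hits.", fmt)),
                manifest = file.path(cfg$output$dir, "manifest.json"))
  inputs <- c(cfg$inputs[c("activities", "compounds", "references", "library")],
              cfg$homology[c("identity_table", "targets_fasta")])
  stage <- "ingest"
  res <- tryCatch({
    fpc <- fingerprint_config(cfg$fingerprint$radius, cfg$fingerprint$n_bits)
    references <- read_compounds(cfg$inputs$references, "smi", fpc,
                                 source = "reference", on_invalid = "error")
    library_set <- read_compounds(cfg$inputs$library, "smi", fpc,
                                  source = "library")
    compounds <- if (!is.null(cfg$inputs$compounds))
      read_compounds(cfg$inputs$compounds, "smi", fpc, source = "library",
                     on_invalid = "error")
    else {
      extra <- setdiff(library_set$compound_id, references$compound_id)
      combine_compounds(references, library_set[extra])
    }
    activities <- read_activity_table(cfg$inputs$activities)

    stage <- "homology"
    graph <- if (cfg$homology$source == "pairwise_alignment") {
      targets <- read_targets_fasta(cfg$homology$targets_fasta)
      build_homology_graph(targets, "pairwise_alignment",
                           threshold = cfg$homology$threshold,
                           transitive = isTRUE(cfg$homology$transitive))
    } else if (cfg$homology$source == "identity_table") {
      tab <- read_identity_table(cfg$homology$identity_table)
      targets <- target_set(sort(unique(c(tab$target_a, tab$target_b,
                                          activities$target_id))))
      build_homology_graph(targets, "identity_table",
                           threshold = cfg$homology$threshold,
                           identity_table = tab,
                           transitive = isTRUE(cfg$homology$transitive))
    } else stop("homology source 'family_label' is API-only; ",
                "supply an identity table or FASTA to the pipeline")

    stage <- "train"
    pairs <- enumerate_ercps(activities, graph, cfg$focal_target,
                             negative_ratio = cfg$training$negative_ratio,
                             seed = cfg$seed, compounds = compounds)
    tcfg <- ecbs_training_config(n_ensemble = cfg$training$n_ensemble,
                                 learner = cfg$training$learner,
                                 alpha = cfg$training$alpha,
                                 lambda = cfg$training$lambda,
                                 test_fraction = cfg$training$test_fraction,
                                 seed = cfg$seed)
    model <- train_ecbs_model(pairs, compounds, tcfg)
    save_ecbs_model(model, paths$model)

    stage <- "screen"
    results <- screen_library(model, references, library_set)
    write_results(results, paths$results, fmt)

    stage <- "funnel"
    stages <- stages_from_config(cfg$funnel$stages)
    hits <- apply_funnel(results, stages)
    write_results(hits, paths$hits, fmt)
    list(results = results, hits = hits,
         stage_summary = attr(hits, "stage_summary"),
         cv_auroc = model$cv_auroc)
  }, error = function(e) {
    # remove partial outputs so a failed run can't be mistaken for a result
    unlink(unlist(paths[c("model", "results", "hits")]))
    write_manifest(paths$manifest, "pipeline", cfg, cfg$seed, inputs,
                   outputs = list(), status = "failed", failed_stage = stage,
                   message = conditionMessage(e))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  write_manifest(paths$manifest, "pipeline", cfg, cfg$seed, inputs,
                 outputs = paths[c("model", "results", "hits")],
                 extra = list(stage_summary = res$stage_summary,
                              n_results = nrow(res$results),
                              n_hits = nrow(res$hits),
                              cv_auroc = res$cv_auroc))
  invisible(c(paths, res["stage_summary"]))
}
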