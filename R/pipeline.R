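#' Build a pipeline run configuration
#'
#' A single structured configuration drives every pipeline stage. It can be
#' built in code or read from a YAML file with [read_run_config()]; unset
#' fields take the defaults below.
#'
#' @param out_dir Output directory of the run.
#' @param seed Integer seed recorded in every output.
#' @param simulate List of [cohort_config()] arguments (e.g. `n_subjects`,
#'   `events_per_sample`, `sessions`).
#' @param lps `TRUE` to also simulate a post-endotoxin sample and include it
#'   in the second response-model analysis.
#' @param gates Either `"derive"` (derive thresholds from the pooled control
#'   samples) or a named list of [subset_gates()] arguments.
#' @param stats List: `conf_level`, `adjust`.
#' @param flood List: `k_c`, `k_r`, `control_var`, `coverage`,
#'   `max_cells_per_sample`.
#' @param format Event-file format for [pipeline_simulate()].
#' @param input Optional path of an existing cohort `metadata.tsv` to use
#'   instead of simulating.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir = "flood_run", seed = 1L,
                       simulate = list(), lps = FALSE,
                       gates = "derive",
                       stats = list(conf_level = 0.95, adjust = "tukey"),
                       flood = list(k_c = NULL, k_r = 2L,
                                    control_var = 0.90, coverage = 0.80,
                                    max_cells_per_sample = NULL),
                       format = "delimited",
                       input = NULL) {
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), simulate = simulate,
         lps = isTRUE(lps), gates = gates, stats = stats, flood = flood,
         format = format, input = input),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the arguments of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw[intersect(names(raw), names(formals(run_config)))])
}

# manifest: config echo + seed + versions + md5 of every written file
write_manifest <- function(config, dir, step) {
  files <- setdiff(list.files(dir, recursive = TRUE),
                   sprintf("manifest_%s.json", step))
  hashes <- tools::md5sum(file.path(dir, files))
  manifest <- list(
    step = step,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("floodr")),
    r_version = as.character(getRversion()),
    config = unclass(config),
    files = as.list(stats::setNames(unname(hashes), files))
  )
  jsonlite::write_json(manifest,
                       file.path(dir, sprintf("manifest_%s.json", step)),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(manifest)
}

resolve_cohort <- function(config) {
  meta <- if (!is.null(config$input)) config$input else
    file.path(config$out_dir, "cohort", "metadata.tsv")
  if (!file.exists(meta)) {
    stop("cohort metadata not found at ", meta,
         "; run pipeline_simulate first or set input", call. = FALSE)
  }
  read_cohort(meta)
}

resolve_gates <- function(config, cohort) {
  if (identical(config$gates, "derive")) {
    control <- cohort[cohort$group == "control", , drop = FALSE]
    derive_gates(dplyr::bind_rows(control$events))
  } else {
    do.call(subset_gates, config$gates)
  }
}

#' Pipeline stage: simulate and write a synthetic cohort
#'
#' @param config A [run_config()].
#' @return Path of the written cohort metadata table, invisibly.
#' @export
pipeline_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- do.call(cohort_config, config$simulate)
  cohort <- simulate_cohort(cfg, seed = config$seed)
  dir <- file.path(config$out_dir, "cohort")
  meta <- write_cohort(cohort, dir, format = config$format)
  if (config$lps) {
    lps <- simulate_lps_sample(lps_config(), seed = config$seed + 1L)
    write_events(lps$events[[1]], file.path(dir, "lps_sample.tsv"))
    utils::write.table(dplyr::select(lps, -"events"),
                       file.path(dir, "lps_metadata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_manifest(config, dir, "simulate")
  invisible(meta)
}

#' Pipeline stage: gate every sample and write the cohort table
#'
#' @param config A [run_config()].
#' @return The cohort table, invisibly; written as `cohort_table.tsv`.
#' @export
pipeline_gate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohort <- resolve_cohort(config)
  gates <- resolve_gates(config, cohort)
  table <- gate_cohort(cohort, gates)
  dir <- file.path(config$out_dir, "gating")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(table, file.path(dir, "cohort_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  yaml::write_yaml(
    list(scatter = gates$scatter, cd66b_min = gates$cd66b_min,
         cd16_positive = gates$cd16_positive,
         cd16_bright = gates$cd16_bright,
         cd62l_bright = gates$cd62l_bright),
    file.path(dir, "gates.yaml")
  )
  write_manifest(config, dir, "gate")
  invisible(table)
}

#' Pipeline stage: cohort statistics (contrast report)
#'
#' Morning samples are analysed across days 1/5/8 and evening samples across
#' days 0/4/7, per measure (total and subset concentrations, marker MFIs).
#'
#' @param config A [run_config()].
#' @return Tibble of contrasts, invisibly; written as `contrasts.tsv`.
#' @export
pipeline_stats <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir <- file.path(config$out_dir, "gating")
  path <- file.path(dir, "cohort_table.tsv")
  if (!file.exists(path)) {
    stop("cohort table not found; run pipeline_gate first", call. = FALSE)
  }
  table <- tibble::as_tibble(utils::read.table(path, header = TRUE,
                                               sep = "\t",
                                               check.names = FALSE))
  out <- purrr::map_dfr(intersect(c("morning", "evening"),
                                  unique(table$session)), function(s) {
    sub <- table[table$session == s, , drop = FALSE]
    res <- cohort_contrasts(sub,
                            conf_level = config$stats$conf_level %||% 0.95,
                            adjust = config$stats$adjust %||% "tukey")
    res$session <- s
    res
  })
  sdir <- file.path(config$out_dir, "stats")
  dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(out, file.path(sdir, "contrasts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(out, file.path(sdir, "contrasts.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(config, sdir, "stats")
  invisible(out)
}

#' Pipeline stage: control-anchored response model(s)
#'
#' Runs the tour-only analysis (control = morning day 1, response = the five
#' other occasions) and, when `lps` is enabled, a second analysis whose
#' response pool additionally contains the post-endotoxin sample. Model
#' summaries, loadings, overlaps and biplots are written per analysis.
#'
#' @param config A [run_config()].
#' @return Named list of `flood_analysis` objects, invisibly.
#' @export
pipeline_flood <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohort <- resolve_cohort(config)
  gates <- resolve_gates(config, cohort)
  analyses <- list(tfl = cohort)
  lps_meta <- file.path(config$out_dir, "cohort", "lps_metadata.tsv")
  if (config$lps && file.exists(lps_meta)) {
    lps <- tibble::as_tibble(utils::read.table(lps_meta, header = TRUE,
                                               sep = "\t",
                                               check.names = FALSE))
    lps$events <- list(read_events(file.path(config$out_dir, "cohort",
                                             "lps_sample.tsv")))
    analyses$tfl_lps <- dplyr::bind_rows(cohort, lps)
  }
  fl <- config$flood
  out <- purrr::imap(analyses, function(cohort_i, nm) {
    an <- flood_analysis(
      cohort_i, gates,
      k_c = fl$k_c, k_r = fl$k_r %||% 2L,
      control_var = fl$control_var %||% 0.90,
      coverage = fl$coverage %||% 0.80,
      max_cells_per_sample = fl$max_cells_per_sample
    )
    dir <- file.path(config$out_dir, "flood", nm)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    serialize_flood_model(an$model, file.path(dir, "model.yaml"))
    first <- an$sample_scores[seq_len(min(3L, length(an$sample_scores)))]
    export_biplot(an$model, first, dir)
    utils::write.table(
      dplyr::mutate(an$sample_meta, sample = names(an$sample_scores),
                    inside_control = unname(an$overlap)),
      file.path(dir, "overlap_report.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    write_manifest(config, dir, paste0("flood_", nm))
    an
  })
  invisible(out)
}

#' Serialize a fitted response model to structured text
#'
#' @param model A `flood_model`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
serialize_flood_model <- function(model, path) {
  stopifnot(inherits(model, "flood_model"))
  yaml::write_yaml(
    list(
      markers = model$markers, k_c = model$k_c, k_r = model$k_r,
      control_loadings = apply(model$control_loadings, 2, as.numeric,
                               simplify = FALSE),
      response_loadings = apply(model$response_loadings, 2, as.numeric,
                                simplify = FALSE),
      eigenvalues = model$eigenvalues,
      explained = model$explained,
      benchmark = list(center = as.numeric(model$benchmark$center),
                       shape = as.numeric(model$benchmark$shape),
                       threshold = model$benchmark$threshold,
                       coverage = model$benchmark$coverage,
                       n = model$benchmark$n)
    ),
    path
  )
  invisible(path)
}

#' Run the full pipeline: simulate, gate, stats, response model
#'
#' @param config A [run_config()].
#' @return Named list with the outputs of each stage, invisibly.
#' @export
pipeline_all <- function(config) {
  pipeline_simulate(config)
  gating <- pipeline_gate(config)
  stats <- pipeline_stats(config)
  flood <- pipeline_flood(config)
  invisible(list(gating = gating, stats = stats, flood = flood))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
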