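# Orchestration of full experiments: manifest bookkeeping, directory layout
# outputs/<model>/<mu>_<s>/run_<i>/, and the four pipeline commands. A thin
# command-line wrapper around these functions ships in inst/cli/matemarket.R.

.config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2)[-(1:14)])
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.log_line <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, paste0(...)))
}

#' Enumerate the run grid of an experiment
#'
#' One row per (model, mutation sd, selection strength, replicate) with its
#' substream seed and artifact directory: the bookkeeping behind a sweep. The
#' canonical full-scale experiment (8 models x 9 settings x 50 runs) has
#' 3,600 rows, 450 per model.
#'
#' @param models character vector of model names (see [model_configs()]).
#' @param mutation_sds,selection_strengths parameter grids.
#' @param runs replicates per setting.
#' @param seed root seed.
#' @return data frame with columns `model`, `mutation_sd`,
#'   `selection_strength`, `run`, `seed`, `dir`.
#' @export
experiment_manifest <- function(models = names(model_configs()),
                                mutation_sds = c(0.06, 0.15, 0.30),
                                selection_strengths = c(0.10, 0.15, 0.20),
                                runs = 50L, seed = 1L) {
  grid <- expand.grid(run = seq_len(runs),
                      selection_strength = selection_strengths,
                      mutation_sd = mutation_sds,
                      model = models, stringsAsFactors = FALSE)
  grid <- grid[c("model", "mutation_sd", "selection_strength", "run")]
  cfgs <- model_configs()
  tag <- vapply(grid$model, function(m)
    paste(cfgs[[m]]$rule, cfgs[[m]]$pairing, sep = "."), character(1))
  grid$seed <- mapply(function(m, mu, s, r) {
    mi <- match(mu, mutation_sds); si <- match(s, selection_strengths)
    substream_seed(seed, sum(utf8ToInt(m)), mi, si, r)
  }, tag, grid$mutation_sd, grid$selection_strength, grid$run)
  grid$dir <- sprintf("%s/%g_%g/run_%d", tag, grid$mutation_sd,
                      grid$selection_strength, grid$run)
  if (anyDuplicated(grid[c("model", "mutation_sd", "selection_strength",
                           "run")]))
    stop("experiment grid contains duplicate run triples")
  rownames(grid) <- NULL
  grid
}

.read_config_file <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Run the simulation stage of an experiment
#'
#' Reads a config file (JSON or YAML) with fields `models`, `mutation_sds`,
#' `selection_strengths`, `runs`, `seed` and optionally `n_agents`,
#' `n_traits`, `generations`, `search_k`; executes the sweep; writes per-run
#' artifacts (final population CSV + sidecar, per-generation summary CSV)
#' under `outdir` and a `manifest.json` stamped with the config hash.
#' Re-invocation skips completed runs; a manifest that no longer parses
#' aborts rather than silently overwriting.
#'
#' @param config_path path to the config file.
#' @param outdir output directory.
#' @return the manifest data frame, invisibly.
#' @export
cmd_simulate <- function(config_path, outdir) {
  cfg <- .read_config_file(config_path)
  models <- cfg$models %||% names(model_configs())
  mus <- cfg$mutation_sds %||% c(0.06, 0.15, 0.30)
  ss <- cfg$selection_strengths %||% c(0.10, 0.15, 0.20)
  runs <- cfg$runs %||% 50L
  seed <- cfg$seed %||% 1L

  manifest_path <- file.path(outdir, "manifest.json")
  if (file.exists(manifest_path)) {
    ok <- tryCatch({jsonlite::read_json(manifest_path); TRUE},
                   error = function(e) FALSE)
    if (!ok) stop("corrupted manifest at ", manifest_path,
                  "; refusing to overwrite")
  }
  manifest <- experiment_manifest(models, mus, ss, runs, seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  for (m in models) {
    base <- sim_config(rule = m,
                       n_agents = cfg$n_agents %||% 200L,
                       n_traits = cfg$n_traits %||% 20L,
                       generations = cfg$generations %||% 200L,
                       runs = runs, search_k = cfg$search_k, seed = seed)
    done_before <- list.files(outdir, pattern = "^population\\.csv$",
                              recursive = TRUE)
    t0 <- Sys.time()
    run_sweep(base, mus, ss, runs, outdir = outdir)
    done_after <- list.files(outdir, pattern = "^population\\.csv$",
                             recursive = TRUE)
    skipped <- sum(startsWith(done_before,
                              paste(base$rule, base$pairing, sep = ".")))
    .log_line("simulate", sprintf(
      "model=%s runs=%d new=%d skipped=%d seed=%d elapsed=%.1fs", m,
      sum(manifest$model == m), length(done_after) - length(done_before),
      skipped, seed, as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  manifest$completed <- file.exists(file.path(outdir, manifest$dir,
                                              "population.csv"))
  jsonlite::write_json(list(config_hash = .config_hash(cfg), seed = seed,
                            runs = manifest),
                       manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compute mate-value records for every run in a directory
#'
#' Applies [mate_value_suite()] to each `population.csv` under
#' `populations_dir` and writes a `records.csv` beside it.
#'
#' @param populations_dir directory produced by [cmd_simulate()].
#' @return character vector of written record files, invisibly.
#' @export
cmd_metrics <- function(populations_dir) {
  pops <- list.files(populations_dir, pattern = "^population\\.csv$",
                     recursive = TRUE, full.names = TRUE)
  if (!length(pops)) stop("no population.csv files under ", populations_dir)
  out <- character(0)
  for (p in pops) {
    pop <- read_population(p)
    rec <- mate_value_suite(pop)
    rec$group <- dirname(sub(paste0(populations_dir, "/?"), "", p))
    f <- file.path(dirname(p), "records.csv")
    utils::write.csv(rec, f, row.names = FALSE)
    out <- c(out, f)
  }
  .log_line("metrics", sprintf("records written for %d runs", length(out)))
  invisible(out)
}

#' Compare recorded runs against a cohort file
#'
#' Reads every `records.csv` under `records_dir` (grouping runs by their
#' model directory), validates the cohort table, and writes the leaderboard
#' as CSV and JSON.
#'
#' @param records_dir directory holding per-run `records.csv` files.
#' @param cohort_path CSV cohort table (see [cmd_synth()]).
#' @param out_prefix path prefix for `"<prefix>.csv"` / `"<prefix>.json"`.
#' @return the `mm_fitreport`, invisibly.
#' @export
cmd_compare <- function(records_dir, cohort_path,
                        out_prefix = file.path(records_dir, "leaderboard")) {
  files <- list.files(records_dir, pattern = "^records\\.csv$",
                      recursive = TRUE, full.names = TRUE)
  if (!length(files)) stop("no records.csv files under ", records_dir)
  cohort <- utils::read.csv(cohort_path, stringsAsFactors = FALSE)
  viol <- validate_cohort(cohort)
  if (nrow(viol) > 0) {
    print(utils::head(viol, 20))
    stop("cohort file failed validation with ", nrow(viol), " violation(s)")
  }
  rel <- sub(paste0(records_dir, "/?"), "", files)
  model <- vapply(strsplit(rel, "/"), `[[`, character(1), 1L)
  runs_by_model <- lapply(split(files, model), function(fs)
    lapply(fs, utils::read.csv, stringsAsFactors = FALSE))
  report <- compare_models(runs_by_model, mate_value_suite(cohort))
  utils::write.csv(report, paste0(out_prefix, ".csv"), row.names = FALSE)
  jsonlite::write_json(report, paste0(out_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  .log_line("compare", sprintf("%d models scored, leaderboard at %s.csv",
                               nrow(report), out_prefix))
  invisible(report)
}

#' Generate, validate and write a synthetic cohort
#'
#' @param spec_path optional JSON/YAML file of [cohort_spec()] fields;
#'   omitted fields take their defaults.
#' @param output_path CSV destination.
#' @return the cohort table, invisibly.
#' @export
cmd_synth <- function(spec_path = NULL, output_path) {
  fields <- if (is.null(spec_path)) list() else .read_config_file(spec_path)
  spec <- do.call(cohort_spec, fields)
  cohort <- generate_cohort(spec)
  viol <- validate_cohort(cohort)
  if (nrow(viol) > 0)
    stop("generated cohort failed validation with ", nrow(viol),
         " violation(s)")
  dir.create(dirname(output_path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort, output_path, row.names = FALSE)
  .log_line("synth", sprintf("cohort of %d respondents in %d countries -> %s",
                             nrow(cohort), length(unique(cohort$country)),
                             output_path))
  invisible(cohort)
}
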