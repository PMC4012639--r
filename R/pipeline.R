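# Pipeline orchestration: config-driven execution of the analysis stages
# with provenance, per-stage seeds, simple caching and CSV/JSON export.

PIPELINE_STAGES <- c("sweep", "impacts", "stack", "transduce", "synth",
                     "analyze")

#' Pipeline configuration
#'
#' Defaults reproduce the reference analysis settings: temperatures 18 and
#' 28 C, 4 grid steps per Q10 parameter, the standard 12-amplitude step
#' protocol, dt = 0.01 ms. A single global seed fans out to per-stage
#' child seeds derived by hashing the stage name.
#'
#' @param stages Character vector of stages to run, in any order;
#'   dependencies are resolved (`impacts`, `stack` and `transduce` need
#'   `sweep`; `analyze` needs `synth`).
#' @param steps Grid steps per Q10 parameter (4 full, 2 or 3 smoke).
#' @param T_cold,T_hot Temperatures (degrees C).
#' @param dt Integration step (ms).
#' @param seed Global RNG seed.
#' @param out_dir Output directory.
#' @param observable Observable for `impacts`/`stack` (default "rmsd").
#' @param synth_spec A [generator_spec()] for the `synth` stage.
#' @param verbose Log to stderr.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(stages = PIPELINE_STAGES, steps = 4,
                            T_cold = 18, T_hot = 28, dt = 0.01, seed = 1,
                            out_dir = tempfile("thermospike_run_"),
                            observable = "rmsd",
                            synth_spec = generator_spec(),
                            verbose = TRUE) {
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "),
         "; valid: ", paste(PIPELINE_STAGES, collapse = ", "))
  structure(list(stages = stages, steps = steps, T_cold = T_cold,
                 T_hot = T_hot, dt = dt, seed = seed, out_dir = out_dir,
                 observable = observable, synth_spec = synth_spec,
                 verbose = verbose),
            class = "pipeline_config")
}

config_hash <- function(config) {
  c2 <- unclass(config)
  c2$out_dir <- NULL
  c2$verbose <- NULL
  rlang::hash(c2)
}

#' Deterministic per-stage child seed
#' @param seed Global seed.
#' @param stage Stage name.
#' @return An integer seed < 2^31 derived by hashing `seed` and the stage
#'   name.
#' @export
stage_seed <- function(seed, stage) {
  h <- rlang::hash(list(seed = seed, stage = stage))
  as.integer(strtoi(substr(h, 1, 7), base = 16L) %% .Machine$integer.max)
}

#' Run the analysis pipeline
#'
#' Executes the selected stages in dependency order
#' (sweep -> impacts/stack/transduce; synth -> analyze), writing one CSV
#' (or JSON) per stage into `out_dir` together with `config.json`
#' carrying the configuration and its hash. A stage whose outputs already
#' exist under the same config hash is skipped (cache hit). Per-stage
#' failures abort with an informative error; upstream outputs missing for
#' a requested downstream stage raise a dependency error.
#'
#' @param config A [pipeline_config()].
#' @return The output directory, invisibly; the run summary (per-stage
#'   timing, record counts, cache hits) is returned as attribute
#'   `summary`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  log_msg <- function(...) if (config$verbose) message("[pipeline] ", ...)
  hash_file <- file.path(config$out_dir, "config.json")
  cached_hash <- if (file.exists(hash_file))
    tryCatch(jsonlite::read_json(hash_file)$hash, error = function(e) NULL)
  cache_valid <- identical(cached_hash, hash)
  cfg_json <- unclass(config)
  cfg_json$synth_spec <- unclass(cfg_json$synth_spec)
  jsonlite::write_json(list(hash = hash, config = cfg_json), hash_file,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)

  ordered <- intersect(PIPELINE_STAGES, config$stages)
  need_sweep <- any(c("impacts", "stack", "transduce") %in% ordered)
  if (need_sweep && !"sweep" %in% ordered && !cache_valid)
    stop("dependency error: impacts/stack/transduce need the sweep stage ",
         "(or a cached sweep under the same config)")
  if ("analyze" %in% ordered && !"synth" %in% ordered && !cache_valid)
    stop("dependency error: analyze needs the synth stage")

  summary <- list()
  sweep <- NULL
  impacts <- NULL
  rec <- NULL
  out <- function(f) file.path(config$out_dir, f)

  run_stage <- function(stage, files, fun) {
    if (cache_valid && all(file.exists(out(files)))) {
      log_msg(stage, ": cache hit")
      summary[[stage]] <<- list(cached = TRUE)
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    n <- fun()
    dt_s <- proc.time()[["elapsed"]] - t0
    log_msg(sprintf("%s: %s records in %.1f s", stage,
                    if (is.null(n)) "?" else n, dt_s))
    summary[[stage]] <<- list(cached = FALSE, seconds = dt_s, records = n)
  }

  if ("sweep" %in% ordered) {
    run_stage("sweep", "sweep.csv", function() {
      grid <- q10_grid(config$steps)
      sweep <<- run_sweep(grid, T_cold = config$T_cold,
                          T_hot = config$T_hot, dt = config$dt,
                          progress = config$verbose)
      write_sweep(sweep, config$out_dir)
      nrow(sweep)
    })
  }
  load_sweep <- function() {
    if (!is.null(sweep)) return(sweep)
    if (!file.exists(out("sweep.csv")))
      stop("dependency error: no sweep output in ", config$out_dir)
    tab <- read.csv(out("sweep.csv"))
    structure(tab, class = c("sweep_table", "data.frame"),
              grid = q10_grid(config$steps))
  }
  if ("impacts" %in% ordered) {
    run_stage("impacts", "impacts.csv", function() {
      impacts <<- impact_scores(load_sweep(), config$observable)
      write_impacts_csv(impacts, out("impacts.csv"))
      nrow(impacts)
    })
  }
  if ("stack" %in% ordered) {
    run_stage("stack", "stack.csv", function() {
      if (is.null(impacts) && file.exists(out("impacts.csv")))
        impacts <- structure(read.csv(out("impacts.csv")),
                             class = c("impact_table", "data.frame"))
      st <- dimensional_stack(load_sweep(), config$observable,
                              impacts = impacts)
      write.csv(st$image, out("stack.csv"), row.names = FALSE)
      jsonlite::write_json(
        list(x_params = st$x_params, y_params = st$y_params,
             order = st$order),
        out("stack_axes.json"), auto_unbox = TRUE)
      length(st$image)
    })
  }
  if ("transduce" %in% ordered) {
    run_stage("transduce", "transduction.csv", function() {
      sw <- load_sweep()
      ok <- is.finite(sw$A_cold) & is.finite(sw$A_hot)
      td <- transduction_q10_distribution(
        data.frame(A = sw$A_cold[ok], I0 = sw$I0_cold[ok]),
        data.frame(A = sw$A_hot[ok], I0 = sw$I0_hot[ok]),
        T_cold = config$T_cold, T_hot = config$T_hot)
      write.csv(cbind(index = sw$index[ok], td$q10),
                out("transduction.csv"), row.names = FALSE)
      nrow(td$q10)
    })
  }
  if ("synth" %in% ordered) {
    run_stage("synth", "synthetic/spec.json", function() {
      spec <- config$synth_spec
      spec$seed <- stage_seed(config$seed, "synth")
      rec <<- generate_recordings(spec)
      write_recordings(rec, out("synthetic"))
      nrow(rec$spikes)
    })
  }
  if ("analyze" %in% ordered) {
    run_stage("analyze", "analysis_q10.csv", function() {
      if (is.null(rec)) {
        if (!dir.exists(out("synthetic")))
          stop("dependency error: no synthetic data in ", config$out_dir)
        spec <- config$synth_spec
        spec$seed <- stage_seed(config$seed, "synth")
        rec <- generate_recordings(spec)
      }
      an <- analyze_recordings(rec)
      write.csv(an$q10, out("analysis_q10.csv"), row.names = FALSE)
      st <- q10_statistics(an)
      write.csv(st$stats, out("analysis_stats.csv"), row.names = FALSE)
      nrow(an$q10)
    })
  }
  structure(invisible(config$out_dir), summary = summary)
}
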