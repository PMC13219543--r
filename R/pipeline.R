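#' Build a pipeline configuration
#'
#' Assembles (and validates) the single configuration object driving
#' [run_pipeline()]. Any subset of the four stages can be requested;
#' analysis stages read either the files produced by the `simulate` stage
#' in `out_dir` or explicit input paths given under `inputs`.
#'
#' @param out_dir Output directory (created if absent).
#' @param stages Stages to run, in pipeline order, among `"simulate"`,
#'   `"calcium"`, `"coreg"`, `"te"`.
#' @param seed Master seed; stage generators derive their seeds from it.
#' @param calibration Named list overriding [calibration_params()] fields.
#' @param calcium List: `mode` (`"aggregate"`/`"pointwise"`),
#'   `resting_window` (s).
#' @param coreg List: `fc_cutoff`, `p_cutoff`, `strict_transcripts`.
#' @param te List: `fc_cutoff`, `vip_threshold`, `n_components`, `source`.
#' @param simulate List: `n_traces` plus optional `trace`, `omics`,
#'   `counts` lists overriding the corresponding spec defaults.
#' @param inputs Optional explicit input paths: `traces_dir`, `traces_meta`,
#'   `transcripts`, `proteins`, `counts`, `samples`.
#' @return An object of class `pipeline_config` (a validated nested list).
#' @export
pipeline_config <- function(out_dir, stages = c("simulate", "calcium", "coreg", "te"),
                            seed = 1,
                            calibration = list(), calcium = list(),
                            coreg = list(), te = list(),
                            simulate = list(), inputs = list()) {
  stages <- match.arg(stages, c("simulate", "calcium", "coreg", "te"),
                      several.ok = TRUE)
  cfg <- list(
    out_dir = out_dir, stages = stages, seed = seed,
    calibration = utils::modifyList(
      list(slope = 0.332588, intercept = 5.5593, log_base = 10), calibration),
    calcium = utils::modifyList(
      list(mode = "aggregate", resting_window = 60), calcium),
    coreg = utils::modifyList(
      list(fc_cutoff = 1.5, p_cutoff = 0.05, strict_transcripts = FALSE), coreg),
    te = utils::modifyList(
      list(fc_cutoff = 1.25, vip_threshold = 1.0, n_components = 2,
           source = "ratio"), te),
    simulate = utils::modifyList(
      list(n_traces = 5, trace = list(), omics = list(), counts = list()),
      simulate),
    inputs = inputs)
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  stopifnot(is.list(cfg), !is.null(cfg$out_dir), length(cfg$stages) >= 1L)
  with(cfg$te, stopifnot(fc_cutoff >= 1, vip_threshold >= 0,
                         n_components >= 1,
                         source %in% c("ratio", "monosome", "polysome")))
  with(cfg$coreg, stopifnot(fc_cutoff > 1, p_cutoff > 0, p_cutoff < 1))
  stopifnot(cfg$calcium$mode %in% c("aggregate", "pointwise"),
            cfg$calcium$resting_window > 0)
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' The YAML round trip (`read_pipeline_config(write_pipeline_config(cfg))`)
#' is an identity on the validated configuration.
#'
#' @param path YAML file path.
#' @return For `read_pipeline_config`, a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw[intersect(names(raw), names(formals(pipeline_config)))])
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @return For `write_pipeline_config`, `path` invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

derive_seed <- function(seed, offset)  # doubles avoid 32-bit overflow
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483647)

#' Run the analysis pipeline
#'
#' Executes the requested stages in fixed order (simulate, calcium, coreg,
#' te), writing every table under `config$out_dir` together with a JSON run
#' manifest recording the package version, a hash of the configuration,
#' the seed and per-stage output files with their row counts. With
#' identical configuration and inputs the run is deterministic: all
#' non-timestamp output bytes reproduce exactly.
#'
#' @param config A [pipeline_config()] (or a path to a YAML file for
#'   [read_pipeline_config()]).
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out, "config.yaml")
  write_pipeline_config(config, cfg_path)
  manifest <- list(package = "mitoprostat",
                   version = as.character(utils::packageVersion("mitoprostat")),
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   seed = config$seed,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   stages = list())
  register <- function(stage, files, rows) {
    for (f in files) if (!file.exists(f) || file.size(f) == 0)
      stop(sprintf("[%s] expected output missing or empty: %s", stage, f))
    manifest$stages[[stage]] <<- list(outputs = as.list(basename(files)),
                                      rows = as.list(rows))
  }
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      manifest$stages[[stage]] <<- list(failed = TRUE, error = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
    })
  }

  params <- do.call(calibration_params, config$calibration)
  inp <- config$inputs

  if ("simulate" %in% config$stages) run_stage("simulate", function() {
    sim <- config$simulate
    tdir <- file.path(out, "traces")
    dir.create(tdir, showWarnings = FALSE)
    meta <- NULL
    for (i in seq_len(sim$n_traces)) {
      sp <- do.call(trace_spec, utils::modifyList(
        sim$trace, list(seed = derive_seed(config$seed, i))))
      g <- gen_luminescence_trace(sp, params)
      row <- write_trace(g$trace, file.path(tdir, sprintf("trace_%02d.tsv", i)))
      row <- cbind(data.frame(trace_id = sprintf("trace_%02d", i)), row)
      meta <- rbind(meta, row)
    }
    write_tsv(meta, file.path(out, "traces_meta.tsv"))
    om <- gen_coreg_table(do.call(omics_spec, utils::modifyList(
      sim$omics, list(seed = derive_seed(config$seed, 101L)))))
    write_tsv(om$transcripts, file.path(out, "transcripts.tsv"))
    write_tsv(om$proteins, file.path(out, "proteins.tsv"))
    write_tsv(om$truth, file.path(out, "coreg_truth.tsv"))
    cs <- gen_polysome_counts(do.call(count_spec, utils::modifyList(
      sim$counts, list(seed = derive_seed(config$seed, 202L)))))
    write_counts(cs$experiment$counts, file.path(out, "counts.tsv"))
    write_tsv(cs$experiment$samples, file.path(out, "samples.tsv"))
    write_tsv(cs$truth, file.path(out, "te_truth.tsv"))
    register("simulate",
             file.path(out, c("traces_meta.tsv", "transcripts.tsv",
                              "proteins.tsv", "counts.tsv", "samples.tsv")),
             c(sim$n_traces, nrow(om$transcripts), nrow(om$proteins),
               nrow(cs$experiment$counts), nrow(cs$experiment$samples)))
  })

  if ("calcium" %in% config$stages) run_stage("calcium", function() {
    tdir <- if (!is.null(inp$traces_dir)) inp$traces_dir else file.path(out, "traces")
    mpath <- if (!is.null(inp$traces_meta)) inp$traces_meta
             else file.path(out, "traces_meta.tsv")
    meta <- read_tsv(mpath)
    sigs <- lapply(seq_len(nrow(meta)), function(i) {
      tr <- read_trace(file.path(tdir, paste0(meta$trace_id[i], ".tsv")),
                       meta[i, ])
      ca <- calibrate_trace(tr, params, mode = config$calcium$mode,
                            resting_window = config$calcium$resting_window)
      extract_signature(ca)
    })
    tab <- data.frame(trace_id = meta$trace_id,
                      amplitude_M = vapply(sigs, `[[`, numeric(1), "amplitude"),
                      curve_area_Ms = vapply(sigs, `[[`, numeric(1), "curve_area"),
                      peak_time_s = vapply(sigs, `[[`, numeric(1), "peak_time"),
                      resting_M = vapply(sigs, `[[`, numeric(1), "resting_level"))
    write_tsv(tab, file.path(out, "signatures.tsv"),
              comments = c(mode = config$calcium$mode,
                           curve_area_scale = "concentration",
                           resting_window_s = config$calcium$resting_window))
    write_tsv(summarize_group(sigs), file.path(out, "signature_summary.tsv"))
    register("calcium",
             file.path(out, c("signatures.tsv", "signature_summary.tsv")),
             c(nrow(tab), 4L))
  })

  if ("coreg" %in% config$stages) run_stage("coreg", function() {
    tr <- read_tsv(if (!is.null(inp$transcripts)) inp$transcripts
                   else file.path(out, "transcripts.tsv"))
    pr <- read_tsv(if (!is.null(inp$proteins)) inp$proteins
                   else file.path(out, "proteins.tsv"))
    rec <- suppressMessages(merge_coreg_tables(tr, pr))
    qr <- classify_quadrants(rec, fc_cutoff = config$coreg$fc_cutoff,
                             p_cutoff = config$coreg$p_cutoff,
                             strict_transcripts = config$coreg$strict_transcripts)
    write_tsv(qr$assignments, file.path(out, "quadrant_assignments.tsv"),
              comments = c(fc_cutoff = qr$fc_cutoff, p_cutoff = qr$p_cutoff))
    write_tsv(quadrant_summary(qr)$summary, file.path(out, "quadrant_summary.tsv"))
    register("coreg",
             file.path(out, c("quadrant_assignments.tsv", "quadrant_summary.tsv")),
             c(nrow(qr$assignments), 4L))
  })

  if ("te" %in% config$stages) run_stage("te", function() {
    counts <- read_counts(if (!is.null(inp$counts)) inp$counts
                          else file.path(out, "counts.tsv"))
    samples <- read_tsv(if (!is.null(inp$samples)) inp$samples
                        else file.path(out, "samples.tsv"))
    exp <- polysome_experiment(counts, samples)
    te <- compute_te(exp)
    model <- fit_te_plsda(exp, source = config$te$source,
                          n_components = config$te$n_components)
    vip <- vip_scores(model)
    res <- select_sate(te, vip, fc_cutoff = config$te$fc_cutoff,
                       vip_threshold = config$te$vip_threshold)
    write_tsv(res, file.path(out, "te_results.tsv"),
              comments = c(vip_source = attr(model, "source"),
                           fc_cutoff = config$te$fc_cutoff,
                           vip_threshold = config$te$vip_threshold))
    write_tsv(data.frame(component = seq_len(model$n_components),
                         var_explained_y = model$var_explained_y),
              file.path(out, "plsda_summary.tsv"))
    write_tsv(data.frame(sample = rownames(model$scores),
                         as.data.frame(model$scores)),
              file.path(out, "plsda_scores.tsv"))
    write_tsv(polysome_monosome_ratio(exp), file.path(out, "rnap_rnam_ratio.tsv"))
    register("te",
             file.path(out, c("te_results.tsv", "plsda_summary.tsv",
                              "plsda_scores.tsv", "rnap_rnam_ratio.tsv")),
             c(nrow(res), model$n_components, nrow(model$scores), 2L))
  })

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
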