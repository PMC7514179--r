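## End-to-end orchestration: a single config drives synthetic generation or
## file reading, preprocessing, the posture-space PCA, the measure table and
## the statistics layer, writing all artifacts plus a provenance record.

#' Build a run configuration
#'
#' @param mode "synthetic" (generate a cohort from \code{spec}) or "files"
#'   (read wide-CSV trials listed in \code{paths}).
#' @param spec a [cohortSpec()] (synthetic mode).
#' @param paths character vector of trial CSV paths (files mode); JSON
#'   sidecars are found by extension swap.
#' @param cut_s seconds trimmed from each trial end.
#' @param target_rate decimation target (Hz).
#' @param keep marker keep-list.
#' @param masses segment-mass table.
#' @param entropy an [entropyParams()].
#' @param cutoff,filter_order low-pass settings.
#' @param detrend_window detrend window (samples, odd).
#' @param threshold "columns" (1/n columns) or a numeric fraction.
#' @param alpha significance level for the statistics layer.
#' @param out_dir output directory (NULL = no files written).
#' @param seed integer seed (synthetic mode).
#' @return list of class \code{RunConfig}.
#' @export
runConfig <- function(mode = c("synthetic", "files"), spec = NULL,
                      paths = NULL, cut_s = 10, target_rate = 120,
                      keep = defaultMarkerSet(), masses = defaultMassTable(),
                      entropy = NULL, cutoff = 7, filter_order = 6L,
                      detrend_window = 501L, threshold = "columns",
                      alpha = 0.05, out_dir = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "synthetic" && is.null(spec))
    spec <- cohortSpec(seed = seed)
  if (mode == "files") {
    if (is.null(paths) || !length(paths)) stop("files mode requires paths")
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("missing trial file(s): ", paste(missing, collapse = ", "))
  }
  if (is.null(entropy)) entropy <- entropyParams(rate = target_rate)
  structure(list(mode = mode, spec = spec, paths = paths, cut_s = cut_s,
                 target_rate = target_rate, keep = keep, masses = masses,
                 entropy = entropy, cutoff = cutoff,
                 filter_order = as.integer(filter_order),
                 detrend_window = as.integer(detrend_window),
                 threshold = threshold, alpha = alpha, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "RunConfig")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the [runConfig()] arguments; \code{spec} holds
#' [cohortSpec()] arguments, \code{entropy} holds [entropyParams()]
#' arguments.
#'
#' @param path YAML file.
#' @return a \code{RunConfig}.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  spec <- if (!is.null(y$spec)) do.call(cohortSpec, y$spec) else NULL
  entropy <- if (!is.null(y$entropy)) do.call(entropyParams, y$entropy) else NULL
  args <- y[setdiff(names(y), c("spec", "entropy"))]
  do.call(runConfig, c(args, list(spec = spec, entropy = entropy)))
}

#' Run the full analysis pipeline
#'
#' Generates or reads trials, preprocesses them in the fixed stage order,
#' fits the posture-space PCA, selects PMs by the information threshold,
#' computes the per-PM measures, and runs the split-plot ANOVA layer with
#' post-hocs. Deterministic given the seed. When \code{out_dir} is set,
#' writes \code{basis.json}, \code{measures.csv}, \code{anova.csv},
#' \code{posthoc.csv} (if any), and \code{provenance.json}.
#'
#' @param config a [runConfig()] (or YAML path).
#' @return list: \code{basis}, \code{retained}, \code{loo}, \code{scores}
#'   (list of [PMScores-class]), \code{measures} (long table),
#'   \code{stats} (list with anova/posthoc), \code{ledger} (synthetic mode),
#'   \code{provenance}.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  stopifnot(inherits(config, "RunConfig"))
  ledger <- NULL
  if (config$mode == "synthetic") {
    cohort <- generateCohort(config$spec)
    trials <- cohort$trials
    ledger <- cohort$ledger
  } else {
    trials <- lapply(config$paths, readTrial)
  }
  blocks <- lapply(trials, preprocessTrial, cut_s = config$cut_s,
                   target_rate = config$target_rate, keep = config$keep,
                   masses = config$masses)
  X <- buildInputMatrix(blocks)
  basis <- fitPMA(X)
  thr_n <- if (identical(config$threshold, "columns")) ncol(postureData(X))
           else round(1 / as.numeric(config$threshold))
  retained <- selectPMs(relEV(basis), thr_n)
  loo <- tryCatch(
    looCrossValidate(X, basis, k = max(retained)),
    error = function(e) NULL)
  scores <- lapply(blocks, function(b)
    pmScores(b$block, basis, rate = b$rate, meta = b$meta,
             k = max(retained)))
  measures <- computeMeasures(scores, retained, params = config$entropy,
                              cutoff = config$cutoff,
                              order = config$filter_order,
                              detrend_window = config$detrend_window)
  stats_out <- analyzeMeasures(measures, alpha = config$alpha)
  provenance <- list(
    mode = config$mode,
    n_trials = length(trials),
    n_rows = nrow(postureData(X)),
    n_columns = ncol(postureData(X)),
    rate_hz = sampleRate(X),
    cut_s = config$cut_s,
    threshold = 1 / thr_n,
    retained_pms = retained,
    entropy = unclass(config$entropy),
    cutoff_hz = config$cutoff,
    filter_order = config$filter_order,
    detrend_window = config$detrend_window,
    alpha = config$alpha,
    seed = config$seed)
  out <- list(basis = basis, retained = retained, loo = loo, scores = scores,
              measures = measures, stats = stats_out, ledger = ledger,
              provenance = provenance)
  if (!is.null(config$out_dir)) .writeArtifacts(out, config$out_dir)
  out
}

.writeArtifacts <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeBasis(out$basis, file.path(dir, "basis.json"))
  utils::write.csv(out$measures, file.path(dir, "measures.csv"),
                   row.names = FALSE)
  if (!is.null(out$stats$anova))
    utils::write.csv(out$stats$anova, file.path(dir, "anova.csv"),
                     row.names = FALSE)
  if (!is.null(out$stats$posthoc))
    utils::write.csv(out$stats$posthoc, file.path(dir, "posthoc.csv"),
                     row.names = FALSE)
  if (!is.null(out$loo))
    utils::write.csv(out$loo, file.path(dir, "loo.csv"), row.names = FALSE)
  jsonlite::write_json(out$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
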