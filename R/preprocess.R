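## Preprocessing: raw marker trials -> normalized, weighted, concatenated
## posture matrix. Fixed stage order: fill gaps -> trim -> downsample ->
## mirror -> select markers -> center + height-normalize -> mass-weight ->
## concatenate. Every stage preserves the frame count except trim and
## downsample, whose counts are exactly predictable.

#' Write a trial as wide CSV + JSON sidecar
#'
#' Columns \code{time, <MARKER>_X/_Y/_Z}; missing marker-frames are empty
#' cells. Coordinates are written with 17 significant digits so reading the
#' file back reproduces the doubles bit-exactly. The sidecar holds
#' \code{subject_id, group, condition, height_m, rate_hz, front_foot}.
#'
#' @param trial a [MarkerTrial-class].
#' @param path CSV output path.
#' @param sidecar JSON output path (default: \code{path} with
#'   \code{.json} extension).
#' @return invisibly, the CSV path.
#' @export
writeTrial <- function(trial, path, sidecar = NULL) {
  if (is.null(sidecar)) sidecar <- sub("\\.csv$", ".json", path)
  X <- coords(trial)
  n <- nrow(X)
  tt <- (seq_len(n) - 1L) / sampleRate(trial)
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  body <- cbind(sprintf("%.17g", tt),
                matrix(fmt(X), n, ncol(X)))
  lines <- c(paste(c("time", .coordColumns(markerLabels(trial))), collapse = ","),
             apply(body, 1L, paste, collapse = ","))
  writeLines(lines, path)
  m <- trialMeta(trial)
  jsonlite::write_json(
    list(subject_id = m$subject_id, group = m$group, condition = m$condition,
         height_m = m$height, rate_hz = sampleRate(trial),
         front_foot = m$front_foot),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trial from wide CSV + JSON sidecar
#'
#' @param path CSV file with columns \code{time, <MARKER>_X/_Y/_Z} (meters);
#'   empty cells mark missing marker-frames.
#' @param sidecar JSON sidecar path (default: \code{path} with \code{.json}
#'   extension) with fields \code{subject_id, group, condition, height_m,
#'   rate_hz, front_foot}.
#' @return a [MarkerTrial-class].
#' @export
readTrial <- function(path, sidecar = NULL) {
  if (grepl("\\.c3d$", path, ignore.case = TRUE))
    stop("C3D input is not supported by this build; export to wide CSV + ",
         "JSON sidecar (see writeTrial)")
  if (!file.exists(path)) stop("no such trial file: ", path)
  if (is.null(sidecar)) sidecar <- sub("\\.csv$", ".json", path)
  if (!file.exists(sidecar)) stop("missing JSON sidecar: ", sidecar)
  meta_raw <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  need <- c("subject_id", "group", "condition", "height_m", "rate_hz",
            "front_foot")
  miss <- setdiff(need, names(meta_raw))
  if (length(miss))
    stop("sidecar lacks required metadata: ", paste(miss, collapse = ", "))
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "numeric")
  if (names(df)[1L] != "time") stop("first CSV column must be 'time'")
  cn <- names(df)[-1L]
  if (length(cn) %% 3L != 0L || !all(grepl("_(X|Y|Z)$", cn)))
    stop("coordinate columns must be <MARKER>_X/_Y/_Z triplets")
  markers <- unique(sub("_(X|Y|Z)$", "", cn))
  if (!identical(cn, .coordColumns(markers)))
    stop("coordinate columns must be grouped per marker in X,Y,Z order")
  X <- as.matrix(df[, -1L, drop = FALSE])
  new("MarkerTrial", coords = X, markers = markers,
      rate = as.numeric(meta_raw$rate_hz),
      meta = list(subject_id = as.character(meta_raw$subject_id),
                  group = as.character(meta_raw$group),
                  condition = as.character(meta_raw$condition),
                  height = as.numeric(meta_raw$height_m),
                  front_foot = as.character(meta_raw$front_foot)))
}

#' Fill marker occlusion gaps by iterative low-rank reconstruction
#'
#' Missing entries are initialized by linear interpolation per column, then
#' refined by alternating a rank-\code{n_components} PCA reconstruction of
#' the centered matrix with re-imposition of the observed entries, until the
#' imputed values change by less than \code{tol} (RMS) or \code{max_iter}
#' is reached. Observed entries are never altered.
#'
#' @param trial a [MarkerTrial-class] with \code{NA} gaps.
#' @param n_components PCA rank used for reconstruction.
#' @param tol RMS convergence tolerance on successive imputations.
#' @param max_iter iteration cap.
#' @return the trial with all gaps imputed.
#' @export
fillGapsPCA <- function(trial, n_components = 5L, tol = 1e-8, max_iter = 100L) {
  X <- coords(trial)
  miss <- is.na(X)
  if (!any(miss)) return(trial)
  colMiss <- colSums(miss)
  if (any(colMiss == nrow(X))) {
    bad <- unique(sub("_(X|Y|Z)$", "",
                      colnames(X)[colMiss == nrow(X)]))
    stop("marker(s) missing for the entire trial: ",
         paste(bad, collapse = ", "))
  }
  if (mean(miss) >= 0.5)
    stop(sprintf("gap fraction %.1f%% exceeds the 50%% limit", 100 * mean(miss)))
  # init: linear interpolation in time, extending ends
  for (j in which(colMiss > 0L))
    X[, j] <- zoo::na.approx(X[, j], na.rm = FALSE, rule = 2)
  r <- min(n_components, ncol(X), nrow(X) - 1L)
  for (it in seq_len(max_iter)) {
    mu <- colMeans(X)
    Xc <- sweep(X, 2L, mu)
    sv <- svd(Xc, nu = r, nv = r)
    Xhat <- sv$u %*% (sv$d[seq_len(r)] * t(sv$v))
    Xhat <- sweep(Xhat, 2L, mu, `+`)
    delta <- sqrt(mean((Xhat[miss] - X[miss])^2))
    X[miss] <- Xhat[miss]
    if (delta < tol) break
  }
  methods::initialize(trial, coords = X)
}

#' Trim trial start and end
#'
#' Removes the first and last \code{cut_s} seconds (settling-in and
#' end-anticipation effects).
#'
#' @param trial a [MarkerTrial-class].
#' @param cut_s seconds to cut from each end (default 10).
#' @return the shortened trial.
#' @export
trimTrial <- function(trial, cut_s = 10) {
  if (cut_s == 0) return(trial)
  n <- nrow(coords(trial))
  ncut <- round(cut_s * sampleRate(trial))
  if (n <= 2L * ncut)
    stop(sprintf("trial too short to trim %g s from both ends (%d frames)",
                 cut_s, n))
  keep <- (ncut + 1L):(n - ncut)
  methods::initialize(trial, coords = coords(trial)[keep, , drop = FALSE])
}

#' Downsample a trial by decimation
#'
#' Keeps every (rate/target_rate)-th frame starting at the first frame. No
#' anti-alias prefilter is applied; the downstream 7 Hz low-pass bounds the
#' effect of any aliased high-frequency noise on the measures.
#'
#' @param trial a [MarkerTrial-class].
#' @param target_rate new rate (Hz); must divide the current rate.
#' @return the decimated trial with updated rate.
#' @export
downsampleTrial <- function(trial, target_rate = 120) {
  r <- sampleRate(trial)
  if (r == target_rate) return(trial)
  step <- r / target_rate
  if (abs(step - round(step)) > 1e-9 || step < 1)
    stop(sprintf("rate %g Hz is not an integer multiple of target %g Hz",
                 r, target_rate))
  keep <- seq(1L, nrow(coords(trial)), by = as.integer(round(step)))
  methods::initialize(trial, coords = coords(trial)[keep, , drop = FALSE],
                      rate = target_rate)
}

#' Mirror a left-foot-in-front trial about the sagittal plane
#'
#' Trials performed with the left foot in front are reflected so every trial
#' describes a right-foot-in-front stance: the mediolateral axis (X by
#' convention) is negated for all markers and bilateral L/R marker labels
#' are swapped (midline markers map to themselves). Right-front trials are
#' returned unchanged unless \code{force = TRUE}. Applying the reflection
#' twice restores the original coordinates.
#'
#' @param trial a [MarkerTrial-class].
#' @param force apply the reflection regardless of \code{front_foot}.
#' @return the mirrored trial with \code{front_foot} updated.
#' @export
mirrorTrial <- function(trial, force = FALSE) {
  m <- trialMeta(trial)
  if (!force && m$front_foot == "right") return(trial)
  labs <- markerLabels(trial)
  partner <- .mirrorLabel(labs)
  missing_partner <- setdiff(partner, labs)
  if (length(missing_partner))
    stop("unpaired bilateral marker(s): mirror partners absent for ",
         paste(labs[!partner %in% labs], collapse = ", "))
  X <- coords(trial)
  perm <- match(partner, labs)
  colIdx <- function(i) (3L * (i - 1L) + 1L):(3L * i)
  Xnew <- X
  for (i in seq_along(labs)) {
    src <- colIdx(perm[i])
    Xnew[, colIdx(i)] <- X[, src]
    Xnew[, colIdx(i)[1L]] <- -X[, src[1L]]  # negate mediolateral (X)
  }
  colnames(Xnew) <- .coordColumns(labs)
  m$front_foot <- if (m$front_foot == "left") "right" else "left"
  methods::initialize(trial, coords = Xnew, meta = m)
}

#' Restrict a trial to a symmetric marker subset
#'
#' @param trial a [MarkerTrial-class].
#' @param keep labels to retain, in the desired stable order (default the
#'   28-marker symmetric set).
#' @return the trial with exactly the \code{keep} markers.
#' @export
selectMarkers <- function(trial, keep = defaultMarkerSet()) {
  labs <- markerLabels(trial)
  miss <- setdiff(keep, labs)
  if (length(miss))
    stop("trial lacks marker(s): ", paste(miss, collapse = ", "))
  idx <- match(keep, labs)
  cols <- as.vector(vapply(idx, function(i) (3L * (i - 1L) + 1L):(3L * i),
                           integer(3L)))
  X <- coords(trial)[, cols, drop = FALSE]
  colnames(X) <- .coordColumns(keep)
  methods::initialize(trial, coords = X, markers = keep)
}

#' Center and height-normalize a trial
#'
#' Subtracts the trial's mean posture (per-column temporal mean) and divides
#' by the participant's height, yielding dimensionless posture deviations.
#' Invariant to rigid translation of the lab origin.
#'
#' @param trial a complete (gap-free) [MarkerTrial-class].
#' @return numeric matrix frames x columns, column means 0.
#' @export
centerNormalize <- function(trial) {
  h <- trialMeta(trial)$height
  if (is.null(h) || !is.finite(h) || h <= 0)
    stop("trial height must be positive")
  X <- coords(trial)
  if (any(is.na(X)))
    stop("trial still has gaps; run fillGapsPCA first")
  sweep(X, 2L, colMeans(X)) / h
}

#' Apply relative segment-mass weights to a normalized block
#'
#' Multiplies all three axis columns of each marker by that marker's
#' relative segment mass (weights renormalized to sum to 1 over the
#' retained set).
#'
#' @param block frames x (3 n markers) numeric matrix from
#'   [centerNormalize()], with \code{<MARKER>_X/_Y/_Z} column names.
#' @param masses named numeric relative masses (default
#'   [defaultMassTable()]).
#' @return the weighted block.
#' @export
weightMarkers <- function(block, masses = defaultMassTable()) {
  markers <- unique(sub("_(X|Y|Z)$", "", colnames(block)))
  w <- normalizeMasses(masses, markers)
  sweep(block, 2L, rep(w, each = 3L), `*`)
}

#' Preprocess one trial end to end
#'
#' Runs the fixed stage order fill gaps -> trim -> downsample -> mirror ->
#' select -> center + normalize -> weight and returns the finished block
#' with its metadata.
#'
#' @param trial a [MarkerTrial-class].
#' @param cut_s seconds trimmed from each end (default 10).
#' @param target_rate decimation target (Hz, default 120).
#' @param keep marker keep-list (default [defaultMarkerSet()]).
#' @param masses segment-mass table (default [defaultMassTable()]).
#' @param gap_components,gap_tol,gap_max_iter gap-filling settings, see
#'   [fillGapsPCA()].
#' @return list with \code{block} (weighted matrix), \code{meta}, \code{rate}.
#' @export
preprocessTrial <- function(trial, cut_s = 10, target_rate = 120,
                            keep = defaultMarkerSet(),
                            masses = defaultMassTable(),
                            gap_components = 5L, gap_tol = 1e-8,
                            gap_max_iter = 100L) {
  t1 <- fillGapsPCA(trial, n_components = gap_components, tol = gap_tol,
                    max_iter = gap_max_iter)
  t2 <- trimTrial(t1, cut_s = cut_s)
  t3 <- downsampleTrial(t2, target_rate = target_rate)
  t4 <- mirrorTrial(t3)
  t5 <- selectMarkers(t4, keep = keep)
  block <- weightMarkers(centerNormalize(t5), masses = masses)
  list(block = block, meta = trialMeta(t5), rate = sampleRate(t5))
}

#' Concatenate preprocessed trial blocks into the PCA input matrix
#'
#' @param blocks list as returned by [preprocessTrial()] (each with
#'   \code{block}, \code{meta}, \code{rate}).
#' @return a [PostureMatrix-class] with complete row/column ledgers.
#' @export
buildInputMatrix <- function(blocks) {
  if (!length(blocks)) stop("no trial blocks supplied")
  cn <- colnames(blocks[[1L]]$block)
  rates <- vapply(blocks, `[[`, numeric(1), "rate")
  if (length(unique(rates)) != 1L)
    stop("trials have inconsistent sampling rates")
  for (b in blocks)
    if (!identical(colnames(b$block), cn))
      stop("trials have inconsistent marker sets or column order")
  data <- do.call(rbind, lapply(blocks, `[[`, "block"))
  nrows <- vapply(blocks, function(b) nrow(b$block), integer(1))
  ends <- cumsum(nrows)
  rowLedger <- data.frame(
    subject_id = vapply(blocks, function(b) b$meta$subject_id, character(1)),
    group      = vapply(blocks, function(b) b$meta$group, character(1)),
    condition  = vapply(blocks, function(b) b$meta$condition, character(1)),
    height     = vapply(blocks, function(b) b$meta$height, numeric(1)),
    row_start  = c(1L, head(ends, -1L) + 1L),
    row_end    = ends,
    stringsAsFactors = FALSE)
  markers <- sub("_(X|Y|Z)$", "", cn)
  axes <- sub("^.*_", "", cn)
  colLedger <- data.frame(column = seq_along(cn), marker = markers,
                          axis = axes, stringsAsFactors = FALSE)
  new("PostureMatrix", data = data, rowLedger = rowLedger,
      colLedger = colLedger, rate = rates[1L])
}
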