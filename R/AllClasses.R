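#' @import methods
#' @importFrom stats var sd quantile rnorm runif rgeom fft qf pf pchisq
#'   pt shapiro.test aggregate complete.cases setNames
#' @importFrom utils read.csv head tail
#' @useDynLib posturePMA, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' MarkerTrial: one trial's marker kinematics
#'
#' Container for a single quiet-stance trial: 3-D marker coordinates over
#' time in lab coordinates (meters), plus the metadata needed downstream
#' (subject, age group, dual-task condition, body height, front foot).
#' Missing marker-frames (occlusions) are encoded as \code{NA} in
#' \code{coords}; all three axes of a marker are missing together.
#'
#' @slot coords numeric matrix, frames x (3 * n markers); columns ordered
#'   \code{<MARKER>_X, <MARKER>_Y, <MARKER>_Z} per marker. Units: m.
#'   Convention: X = mediolateral, Y = anteroposterior, Z = vertical.
#' @slot markers character vector of marker labels (one per marker).
#' @slot rate sampling rate in Hz.
#' @slot meta named list with \code{subject_id}, \code{group} ("young" or
#'   "old"), \code{condition} ("ST", "DT1".."DT4"), \code{height} (m),
#'   \code{front_foot} ("left" or "right").
#'
#' @seealso [readTrial()], [generateCohort()]
#' @export
setClass("MarkerTrial",
  representation(
    coords  = "matrix",
    markers = "character",
    rate    = "numeric",
    meta    = "list"
  )
)

setValidity("MarkerTrial", function(object) {
  msg <- character()
  if (ncol(object@coords) != 3L * length(object@markers))
    msg <- c(msg, sprintf("coords has %d columns but %d markers imply %d",
                          ncol(object@coords), length(object@markers),
                          3L * length(object@markers)))
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
    msg <- c(msg, "rate must be a single positive number")
  need <- c("subject_id", "group", "condition", "height", "front_foot")
  miss <- setdiff(need, names(object@meta))
  if (length(miss))
    msg <- c(msg, paste("meta lacks:", paste(miss, collapse = ", ")))
  h <- object@meta$height
  if (!is.null(h) && (!is.finite(h) || h <= 0))
    msg <- c(msg, "meta$height must be positive")
  ff <- object@meta$front_foot
  if (!is.null(ff) && !ff %in% c("left", "right"))
    msg <- c(msg, "meta$front_foot must be 'left' or 'right'")
  if (any(is.infinite(object@coords)))
    msg <- c(msg, "coords must be finite or NA")
  if (length(msg)) msg else TRUE
})

#' PostureMatrix: concatenated normalized posture vectors
#'
#' The input matrix of the posture-space PCA: every row is one time sample's
#' centered, height-normalized, mass-weighted posture vector; all trials of
#' all subjects are stacked. Row and column ledgers keep the provenance of
#' every entry.
#'
#' @slot data numeric matrix, rows = time samples, columns = marker-axis
#'   coordinates (dimensionless).
#' @slot rowLedger data.frame with one row per trial block: \code{subject_id},
#'   \code{group}, \code{condition}, \code{row_start}, \code{row_end}.
#' @slot colLedger data.frame mapping column index to \code{marker} and
#'   \code{axis} ("X","Y","Z").
#' @slot rate common sampling rate (Hz) of the concatenated trials.
#' @export
setClass("PostureMatrix",
  representation(
    data      = "matrix",
    rowLedger = "data.frame",
    colLedger = "data.frame",
    rate      = "numeric"
  )
)

setValidity("PostureMatrix", function(object) {
  msg <- character()
  if (nrow(object@colLedger) != ncol(object@data))
    msg <- c(msg, "colLedger rows must equal data columns")
  if (nrow(object@rowLedger)) {
    if (max(object@rowLedger$row_end) != nrow(object@data))
      msg <- c(msg, "rowLedger does not cover data rows")
  }
  if (any(!is.finite(object@data)))
    msg <- c(msg, "posture matrix must be finite (fill gaps first)")
  if (length(msg)) msg else TRUE
})

#' PMBasis: fitted posture-space model
#'
#' Mean posture plus orthonormal principal-component vectors spanning the
#' posture space, with eigenvalues and relative explained variance (EV) per
#' principal movement (PM).
#'
#' @slot meanPosture numeric vector (length = n columns of the input matrix).
#' @slot vectors numeric matrix, k x n: row k is the unit-norm PC vector of
#'   the k-th PM.
#' @slot eigenvalues numeric, non-increasing variances along each PC.
#' @slot relEV numeric fractions, eigenvalue / total variance.
#' @slot nColumns integer, number of posture-space coordinates (84 for the
#'   28-marker set) — defines the PM selection threshold 1/nColumns.
#' @slot colLedger data.frame carried over from the [PostureMatrix-class].
#' @export
setClass("PMBasis",
  representation(
    meanPosture = "numeric",
    vectors     = "matrix",
    eigenvalues = "numeric",
    relEV       = "numeric",
    nColumns    = "integer",
    colLedger   = "data.frame"
  )
)

setValidity("PMBasis", function(object) {
  msg <- character()
  k <- nrow(object@vectors)
  if (ncol(object@vectors) != length(object@meanPosture))
    msg <- c(msg, "vectors columns must match meanPosture length")
  if (length(object@eigenvalues) != k || length(object@relEV) != k)
    msg <- c(msg, "eigenvalues/relEV length must equal number of PC vectors")
  if (k) {
    G <- tcrossprod(object@vectors)
    if (max(abs(G - diag(k))) > 1e-8)
      msg <- c(msg, "PC vectors are not orthonormal (tol 1e-8)")
    if (any(diff(object@eigenvalues) > 1e-10))
      msg <- c(msg, "eigenvalues must be non-increasing")
    if (any(object@eigenvalues < -1e-12))
      msg <- c(msg, "eigenvalues must be non-negative")
    if (sum(object@relEV) > 1 + 1e-8)
      msg <- c(msg, "relative EVs must sum to at most 1")
  }
  if (length(msg)) msg else TRUE
})

#' PMScores: principal position / velocity / acceleration series of one trial
#'
#' Time series of one trial's scores along each retained principal movement
#' (principal positions PP), and their first and second time derivatives
#' (principal velocities PV, principal accelerations PA).
#'
#' @slot pp numeric matrix frames x k, dimensionless normalized-posture units.
#' @slot pv numeric matrix frames x k, per second.
#' @slot pa numeric matrix frames x k, per second squared.
#' @slot rate sampling rate (Hz).
#' @slot meta trial metadata list (as in [MarkerTrial-class]).
#' @export
setClass("PMScores",
  representation(
    pp   = "matrix",
    pv   = "matrix",
    pa   = "matrix",
    rate = "numeric",
    meta = "list"
  )
)

setValidity("PMScores", function(object) {
  msg <- character()
  if (!identical(dim(object@pp), dim(object@pv)) ||
      !identical(dim(object@pp), dim(object@pa)))
    msg <- c(msg, "pp, pv, pa must share dimensions")
  if (any(!is.finite(object@pp)))
    msg <- c(msg, "pp must be finite")
  if (length(msg)) msg else TRUE
})

## ---- show methods -----------------------------------------------------

setMethod("show", "MarkerTrial", function(object) {
  m <- object@meta
  cat(sprintf("MarkerTrial: %d frames x %d markers @ %g Hz (%.1f s)\n",
              nrow(object@coords), length(object@markers), object@rate,
              nrow(object@coords) / object@rate))
  cat(sprintf("  subject %s | group %s | condition %s | height %.2f m | front foot %s\n",
              m$subject_id, m$group, m$condition, m$height, m$front_foot))
  nmiss <- sum(is.na(object@coords))
  if (nmiss)
    cat(sprintf("  missing marker-frame coordinates: %d (%.2f%%)\n",
                nmiss, 100 * nmiss / length(object@coords)))
})

setMethod("show", "PostureMatrix", function(object) {
  cat(sprintf("PostureMatrix: %d rows x %d columns @ %g Hz, %d trial blocks\n",
              nrow(object@data), ncol(object@data), object@rate,
              nrow(object@rowLedger)))
})

setMethod("show", "PMBasis", function(object) {
  cat(sprintf("PMBasis: %d principal movements over %d posture coordinates\n",
              nrow(object@vectors), object@nColumns))
  k <- min(8L, length(object@relEV))
  cat("  relative EV (%):",
      paste(sprintf("%.1f", 100 * object@relEV[seq_len(k)]), collapse = " "),
      if (length(object@relEV) > k) "..." else "", "\n")
})

setMethod("show", "PMScores", function(object) {
  cat(sprintf("PMScores: %d frames x %d PMs @ %g Hz (subject %s, %s)\n",
              nrow(object@pp), ncol(object@pp), object@rate,
              object@meta$subject_id, object@meta$condition))
})
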