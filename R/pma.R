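## Posture-space PCA: principal movements (PM), their score series (PP) and
## derivatives (PV, PA), the 1/n-columns selection rule, and leave-one-out
## robustness validation of the PC-vector orientations.

#' Fit the posture-space principal component analysis
#'
#' Eigendecomposition of the covariance (not correlation) of the
#' concatenated posture matrix. The matrix enters already centered per
#' trial, height-normalized and mass-weighted; no per-column
#' re-standardization is applied. Signs follow the convention that each
#' vector's largest-magnitude loading is positive.
#'
#' @param X a [PostureMatrix-class] (or plain numeric matrix).
#' @param k number of components to keep (default: all).
#' @return a [PMBasis-class].
#' @export
fitPMA <- function(X, k = NULL) {
  if (is(X, "PostureMatrix")) {
    M <- postureData(X)
    cl <- colLedger(X)
  } else {
    M <- X
    cl <- data.frame(column = seq_len(ncol(X)))
  }
  if (!all(is.finite(M))) stop("posture matrix must be finite")
  if (nrow(M) <= ncol(M))
    stop("need more time samples than posture coordinates")
  mu <- colMeans(M)
  Mc <- sweep(M, 2L, mu)
  S <- crossprod(Mc) / (nrow(Mc) - 1L)
  e <- eigen(S, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  V <- .fixSigns(t(e$vectors))
  if (!is.null(k)) {
    k <- min(k, nrow(V))
    V <- V[seq_len(k), , drop = FALSE]
    lam_k <- lam[seq_len(k)]
  } else lam_k <- lam
  new("PMBasis", meanPosture = mu, vectors = V, eigenvalues = lam_k,
      relEV = lam_k / sum(lam), nColumns = ncol(M), colLedger = cl)
}

#' Project a trial block onto the principal movements
#'
#' @param block frames x n numeric matrix of normalized, weighted posture
#'   vectors (same column order as the training matrix).
#' @param basis a [PMBasis-class].
#' @return frames x k matrix of principal-position scores PP.
#' @export
projectTrial <- function(block, basis) {
  if (ncol(block) != length(meanPosture(basis)))
    stop(sprintf("block has %d columns, basis expects %d",
                 ncol(block), length(meanPosture(basis))))
  sweep(block, 2L, meanPosture(basis)) %*% t(pcVectors(basis))
}

#' Reconstruct posture vectors from PM scores
#'
#' Inverse of [projectTrial()]; exact when the basis spans the full rank.
#'
#' @param pp frames x k score matrix.
#' @param basis a [PMBasis-class].
#' @return frames x n posture matrix.
#' @export
reconstructTrial <- function(pp, basis) {
  sweep(pp %*% pcVectors(basis), 2L, meanPosture(basis), `+`)
}

#' Differentiate principal positions
#'
#' Central differences (zero phase error): \code{pv_t = (pp[t+1] -
#' pp[t-1]) * rate / 2}, \code{pa_t = (pp[t+1] - 2 pp[t] + pp[t-1]) *
#' rate^2}; the first and last frame use the adjacent interior stencil
#' (one-sided), keeping the series length unchanged.
#'
#' @param pp numeric vector or frames x k matrix of PP scores.
#' @param rate sampling rate (Hz).
#' @return list with \code{pv} and \code{pa} matching \code{pp}'s shape.
#' @export
differentiate <- function(pp, rate) {
  vec <- is.null(dim(pp))
  P <- if (vec) matrix(pp, ncol = 1L) else pp
  n <- nrow(P)
  if (n < 5L) stop("need at least 5 frames to differentiate")
  i <- 2L:(n - 1L)
  pv <- P; pa <- P
  pv[i, ] <- (P[i + 1L, , drop = FALSE] - P[i - 1L, , drop = FALSE]) * rate / 2
  pa[i, ] <- (P[i + 1L, , drop = FALSE] - 2 * P[i, , drop = FALSE] +
                P[i - 1L, , drop = FALSE]) * rate^2
  pv[1L, ] <- (P[2L, ] - P[1L, ]) * rate
  pv[n, ] <- (P[n, ] - P[n - 1L, ]) * rate
  pa[1L, ] <- pa[2L, ]
  pa[n, ] <- pa[n - 1L, ]
  if (vec) list(pv = pv[, 1L], pa = pa[, 1L]) else list(pv = pv, pa = pa)
}

#' Compute PM score series for one trial
#'
#' Projects a preprocessed block onto the basis and differentiates.
#'
#' @param block preprocessed trial block (frames x n).
#' @param basis a [PMBasis-class].
#' @param rate sampling rate (Hz).
#' @param meta trial metadata list.
#' @param k number of leading PMs to keep (default: all in the basis).
#' @return a [PMScores-class].
#' @export
pmScores <- function(block, basis, rate, meta = list(), k = NULL) {
  pp <- projectTrial(block, basis)
  if (!is.null(k)) pp <- pp[, seq_len(k), drop = FALSE]
  d <- differentiate(pp, rate)
  colnames(pp) <- paste0("PM", seq_len(ncol(pp)))
  new("PMScores", pp = pp, pv = d$pv, pa = d$pa, rate = rate, meta = meta)
}

#' Select principal movements above the information threshold
#'
#' On average each of the n input columns contributes 1/n of the overall
#' information; only PMs whose relative EV strictly exceeds 1/n are
#' retained (with 84 columns: 1/84 = 1.2 %).
#'
#' @param rel_ev relative EV fractions (or a [PMBasis-class]).
#' @param n_columns number of input-matrix columns defining the threshold.
#' @return integer indices of retained PMs.
#' @export
selectPMs <- function(rel_ev, n_columns = NULL) {
  if (is(rel_ev, "PMBasis")) {
    if (is.null(n_columns)) n_columns <- rel_ev@nColumns
    rel_ev <- relEV(rel_ev)
  }
  if (is.null(n_columns)) stop("n_columns required when rel_ev is numeric")
  which(rel_ev > 1 / n_columns)
}

#' The PM selection threshold
#'
#' @param n_columns number of posture-space columns.
#' @return the threshold as a fraction (1/n_columns).
#' @export
pmThreshold <- function(n_columns) 1 / n_columns

#' Leave-one-out robustness of the PC-vector orientations
#'
#' Refits the PCA with each subject's rows removed and measures the angle
#' between each full-data PC vector and its leave-one-out counterpart
#' (matched by eigenvalue rank, signs aligned by dot-product sign;
#' optionally by greedy maximum-|dot| matching for near-degenerate
#' spectra). A PM is robust when its worst-case angle stays below
#' \code{angle_limit}.
#'
#' @param X a [PostureMatrix-class] (rowLedger identifies subjects).
#' @param basis the full-data [PMBasis-class].
#' @param k number of leading PMs to validate.
#' @param angle_limit degrees (default 15).
#' @param match "rank" (eigenvalue order) or "greedy" (max |dot|).
#' @return data.frame per PM: \code{pm}, \code{max_angle_deg},
#'   \code{robust}.
#' @export
looCrossValidate <- function(X, basis, k, angle_limit = 15,
                             match = c("rank", "greedy")) {
  match <- match.arg(match)
  rl <- rowLedger(X)
  subjects <- unique(rl$subject_id)
  if (length(subjects) < 3L) stop("need at least 3 subjects for leave-one-out")
  M <- postureData(X)
  Vfull <- pcVectors(basis)[seq_len(k), , drop = FALSE]
  worst <- rep(0, k)
  for (s in subjects) {
    drop_rows <- unlist(lapply(which(rl$subject_id == s),
                               function(i) rl$row_start[i]:rl$row_end[i]))
    sub <- fitPMA(M[-drop_rows, , drop = FALSE], k = if (match == "rank") k else NULL)
    Vloo <- pcVectors(sub)
    D <- abs(Vfull %*% t(Vloo))  # k x k' matrix of |cosines|
    if (match == "rank") {
      cosines <- diag(D[, seq_len(k), drop = FALSE])
    } else {
      cosines <- numeric(k)
      avail <- rep(TRUE, ncol(D))
      for (i in seq_len(k)) {
        j <- which.max(ifelse(avail, D[i, ], -Inf))
        cosines[i] <- D[i, j]
        avail[j] <- FALSE
      }
    }
    ang <- acos(pmin(1, cosines)) * 180 / pi
    worst <- pmax(worst, ang)
  }
  data.frame(pm = seq_len(k), max_angle_deg = worst,
             robust = worst < angle_limit)
}

#' Extreme postures of one principal movement
#'
#' The postures at the minimal and maximal observed deviation along PM k,
#' amplified for visualization: \code{mean_posture + amp_factor *
#' extreme(pp_k) * PC_k}, optionally de-normalized by height (meters).
#'
#' @param basis a [PMBasis-class].
#' @param pp PP score matrix (frames x >= k).
#' @param k PM index.
#' @param amp_factor amplification factor (0 returns the mean posture
#'   twice).
#' @param height if given, multiply by height to return meters.
#' @return 2 x n matrix, rows \code{min} and \code{max}.
#' @export
pmExtremePostures <- function(basis, pp, k, amp_factor = 1, height = NULL) {
  v <- pcVectors(basis)[k, ]
  lo <- min(pp[, k]); hi <- max(pp[, k])
  out <- rbind(min = meanPosture(basis) + amp_factor * lo * v,
               max = meanPosture(basis) + amp_factor * hi * v)
  if (!is.null(height)) out <- out * height
  out
}

#' Serialize a basis to JSON
#'
#' @param basis a [PMBasis-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeBasis <- function(basis, path) {
  jsonlite::write_json(
    list(mean_posture = meanPosture(basis),
         pc_vectors = pcVectors(basis),
         eigenvalues = eigenValues(basis),
         rel_ev = relEV(basis),
         n_columns = basis@nColumns),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}
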