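## Synthetic marker-trajectory cohorts with known ground truth.
##
## The generator inverts the analysis: principal-position score series with a
## prescribed variance spectrum and controllable irregularity are synthesized
## in the (centered, height-normalized, mass-weighted) posture space, then
## mapped back to lab-frame marker coordinates. Running the preprocessing +
## PCA pipeline on the result must recover the planted spectrum, which gives
## every downstream stage a parameter-recovery test surface.

#' Specification of a synthetic cohort
#'
#' Defaults reproduce the tandem-stance study design: two age groups (23
#' young at 1.7 m, 18 old at 1.6 m), five conditions (single task ST and
#' auditory n-back dual tasks DT1..DT4), 28 markers recorded at 240 Hz for
#' 80 s, and a dominant low-frequency eigenspectrum whose leading six
#' components carry 51.1, 26.5, 9.7, 3.9, 2.6 and 1.9 % of the variance
#' (the residual 4.3 % decays geometrically over trailing components).
#'
#' Each principal-position series is a sum of 2-3 sinusoids (0.2-2 Hz,
#' random phases) mixed with 1/f-filtered Gaussian noise; the mixing weight
#' in [0,1] (share of noise variance) is the regularity knob: higher weight
#' means a more irregular signal, hence higher sample entropy. Condition
#' effects modulate that weight multiplicatively following an effect-shape
#' template ("n": peak at the middle condition; "monotone"; "flat"); group
#' effects add a scalar offset for the old group.
#'
#' @param n_subjects_per_group integer length-2, subjects in (young, old).
#' @param n_conditions number of within-subject conditions (labeled ST,
#'   DT1..).
#' @param n_markers number of markers (3 coordinates each).
#' @param sampling_rate Hz.
#' @param duration trial length in seconds.
#' @param ev_profile fractions of total variance per planted PM, positive,
#'   non-increasing, summing to <= 1; any remainder is spread geometrically
#'   over the remaining posture-space directions.
#' @param base_regularity baseline noise-mixing weight per PM (recycled);
#'   in [0,1].
#' @param effect_shape "n", "monotone" or "flat": per-condition template
#'   applied to the mixing weight.
#' @param effect_amplitude peak fractional modulation of the mixing weight
#'   (e.g. 0.3 means the weight rises by up to 30 % across conditions).
#' @param group_offset additive mixing-weight offset for the old group.
#' @param heights numeric length-2, body height (m) per group.
#' @param signal_var total posture-space variance of the planted PP signals
#'   (dimensionless normalized units).
#' @param noise_sd SD of isotropic measurement noise added in posture-space
#'   units (0 = noiseless).
#' @param gap_rate expected fraction of marker-frames missing per marker,
#'   in [0, 0.2); gaps occur in contiguous runs (geometric run lengths,
#'   mean 0.25 s) as in real occlusions.
#' @param seed integer master seed; identical seeds give identical cohorts.
#' @return object of class \code{SyntheticCohortSpec} (a validated list).
#' @export
cohortSpec <- function(n_subjects_per_group = c(23L, 18L),
                       n_conditions = 5L,
                       n_markers = 28L,
                       sampling_rate = 240,
                       duration = 80,
                       ev_profile = c(0.511, 0.265, 0.097, 0.039, 0.026, 0.019),
                       base_regularity = 0.5,
                       effect_shape = c("n", "monotone", "flat"),
                       effect_amplitude = 0.3,
                       group_offset = 0,
                       heights = c(1.7, 1.6),
                       signal_var = 2.5e-5,
                       noise_sd = 0,
                       gap_rate = 0,
                       seed = 1L) {
  effect_shape <- match.arg(effect_shape)
  stopifnot(length(n_subjects_per_group) == 2L,
            all(n_subjects_per_group >= 1L),
            n_conditions >= 1L, n_markers >= 2L,
            sampling_rate > 0, duration > 0)
  if (any(ev_profile <= 0) || sum(ev_profile) > 1 + 1e-12)
    stop("ev_profile entries must be positive and sum to at most 1")
  if (any(diff(ev_profile) > 1e-12))
    stop("ev_profile must be non-increasing")
  if (length(ev_profile) > 3L * n_markers)
    stop("more planted components than posture-space dimensions")
  if (gap_rate < 0 || gap_rate >= 0.2)
    stop("gap_rate must be in [0, 0.2)")
  if (any(base_regularity < 0) || any(base_regularity > 1))
    stop("base_regularity must lie in [0, 1]")
  k <- length(ev_profile)
  conds <- .conditionLabels(n_conditions)
  base <- rep_len(base_regularity, k)
  template <- .effectTemplate(effect_shape, n_conditions)
  reg <- outer(base, 1 + effect_amplitude * template)  # k x conditions
  reg <- pmin(pmax(reg, 0), 1)
  dimnames(reg) <- list(paste0("PM", seq_len(k)), conds)
  structure(list(
    n_subjects_per_group = as.integer(n_subjects_per_group),
    n_conditions = as.integer(n_conditions),
    conditions = conds,
    n_markers = as.integer(n_markers),
    sampling_rate = sampling_rate,
    duration = duration,
    ev_profile = ev_profile,
    regularity_profile = reg,
    effect_shape = effect_shape,
    effect_amplitude = effect_amplitude,
    group_offset = group_offset,
    heights = heights,
    signal_var = signal_var,
    noise_sd = noise_sd,
    gap_rate = gap_rate,
    seed = as.integer(seed)
  ), class = "SyntheticCohortSpec")
}

.conditionLabels <- function(n) {
  if (n == 1L) "ST" else c("ST", paste0("DT", seq_len(n - 1L)))
}

## Condition-effect template, scaled to [0, 1] with the stated shape.
.effectTemplate <- function(shape, n) {
  if (n == 1L) return(0)
  x <- seq(0, 1, length.out = n)
  switch(shape,
    n        = 1 - (2 * x - 1)^2,   # peak at the middle condition
    monotone = x,
    flat     = rep(0, n))
}

#' Random orthonormal posture basis
#'
#' Draws k orthonormal direction vectors in an n_dof-dimensional posture
#' space (QR of a Gaussian matrix, signs fixed so the largest-magnitude
#' loading of each vector is positive) plus a mean-posture vector.
#'
#' @param n_dof posture-space dimension.
#' @param k number of basis vectors, k <= n_dof.
#' @param seed integer seed.
#' @return list with \code{basis} (k x n_dof, orthonormal rows) and
#'   \code{mean_posture} (length n_dof).
#' @export
makePostureBasis <- function(n_dof, k, seed = 1L) {
  if (k > n_dof) stop("k must not exceed n_dof")
  rs <- .seedState(seed)
  A <- matrix(rs$norm(n_dof * k), n_dof, k)
  Q <- qr.Q(qr(A))[, seq_len(k), drop = FALSE]
  V <- t(Q)
  V <- .fixSigns(V)
  list(basis = V, mean_posture = rs$norm(n_dof) * 0.1)
}

## Local RNG stream that never touches the global .Random.seed.
.seedState <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed %% .Machine$integer.max)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  withState <- function(f) function(...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- f(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    out
  }
  list(norm = withState(stats::rnorm),
       unif = withState(stats::runif),
       geom = withState(stats::rgeom),
       int  = withState(function(n, max) sample.int(max, n, replace = TRUE)))
}

## Sign convention shared with fitPMA: largest |loading| positive.
.fixSigns <- function(V) {
  for (i in seq_len(nrow(V))) {
    j <- which.max(abs(V[i, ]))
    if (V[i, j] < 0) V[i, ] <- -V[i, ]
  }
  V
}

## 1/f-amplitude ("pink") Gaussian noise of length n, unit variance.
.pinkNoise <- function(n, rnorm_fun) {
  w <- rnorm_fun(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))            # avoid division by zero at DC
  f <- pmin(f, n - f + 1)              # symmetric frequency index
  W <- W / sqrt(f)
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  x <- x - mean(x)
  x / stats::sd(x)
}

#' Simulate one principal-position score series
#'
#' Produces the PP series for one PM of one trial: sinusoids (0.2-2 Hz) plus
#' 1/f noise, mixed by the regularity weight for that PM and condition, and
#' scaled so the series variance equals the PM's target share of
#' \code{signal_var} exactly.
#'
#' @param pm_index which planted PM (1-based, <= length of
#'   \code{spec$ev_profile}).
#' @param condition condition label, one of \code{spec$conditions}.
#' @param spec a [cohortSpec()].
#' @param subject_seed integer seed for this subject x condition draw.
#' @param group_offset additive offset on the mixing weight (group effect).
#' @param n_frames optional override of the series length (defaults to
#'   duration x rate).
#' @return numeric PP series, zero mean, variance =
#'   \code{signal_var * ev_profile[pm_index]}.
#' @export
simulatePP <- function(pm_index, condition, spec, subject_seed,
                       group_offset = 0, n_frames = NULL) {
  if (!condition %in% spec$conditions)
    stop("unknown condition label: ", condition)
  if (pm_index < 1L || pm_index > length(spec$ev_profile))
    stop("pm_index out of range")
  n <- if (is.null(n_frames)) round(spec$duration * spec$sampling_rate) else n_frames
  target_var <- spec$signal_var * spec$ev_profile[pm_index]
  if (target_var == 0) return(numeric(n))
  w <- spec$regularity_profile[pm_index, condition] + group_offset
  w <- min(max(w, 0), 1)
  rs <- .seedState(subject_seed + 7919L * pm_index)
  tt <- seq_len(n) / spec$sampling_rate
  n_sin <- 2L + (rs$int(1, 2L) - 1L)               # 2 or 3 sinusoids
  freqs <- 0.2 + rs$unif(n_sin) * 1.8
  phases <- rs$unif(n_sin) * 2 * pi
  amps <- 1 / seq_len(n_sin)
  s <- rowSums(vapply(seq_len(n_sin),
                      function(i) amps[i] * sin(2 * pi * freqs[i] * tt + phases[i]),
                      numeric(n)))
  s <- (s - mean(s)) / stats::sd(s)
  z <- .pinkNoise(n, rs$norm)
  x <- sqrt(1 - w) * s + sqrt(w) * z
  x <- x - mean(x)
  x * sqrt(target_var / stats::var(x))
}

#' Assemble a lab-frame trial from planted posture-space scores
#'
#' Inverts the pipeline's normalization: marker coordinates are
#' \code{height * (scores \%*\% basis + noise) / w + mean_posture} per
#' column, where \code{w} is the column's segment-mass weight. Running
#' center/normalize/weight/PCA on the result recovers the planted scores.
#'
#' @param basis k x (3 n_markers) orthonormal matrix (rows = PC vectors).
#' @param mean_posture lab-frame mean posture vector (m), length 3 n_markers.
#' @param pp_matrix frames x k matrix of PP score series.
#' @param height subject height (m).
#' @param masses named numeric relative segment masses over the marker set.
#' @param markers marker labels (length = columns / 3).
#' @param rate sampling rate (Hz).
#' @param meta trial metadata list (subject_id, group, condition, height,
#'   front_foot); height is filled in from \code{height}.
#' @param noise_sd posture-space measurement-noise SD.
#' @param gap_rate expected missing fraction per marker, in [0, 0.2).
#' @param seed integer seed for noise and gaps.
#' @return a [MarkerTrial-class].
#' @export
assembleTrial <- function(basis, mean_posture, pp_matrix, height,
                          masses = defaultMassTable(),
                          markers = defaultMarkerSet(),
                          rate = 240, meta = list(),
                          noise_sd = 0, gap_rate = 0, seed = 1L) {
  if (!all(is.finite(basis)) || !all(is.finite(pp_matrix)) ||
      !all(is.finite(mean_posture)) || !is.finite(height) || height <= 0)
    stop("assembleTrial: inputs must be finite and height positive")
  if (ncol(pp_matrix) != nrow(basis))
    stop("pp_matrix columns must match basis vectors")
  if (ncol(basis) != 3L * length(markers))
    stop("basis width must equal 3 x number of markers")
  w <- normalizeMasses(masses, markers)
  wcol <- rep(w, each = 3L)
  X <- pp_matrix %*% basis
  rs <- .seedState(seed)
  if (noise_sd > 0)
    X <- X + matrix(rs$norm(length(X), sd = noise_sd), nrow(X), ncol(X))
  coords <- sweep(X, 2L, wcol, `/`) * height
  coords <- sweep(coords, 2L, mean_posture, `+`)
  colnames(coords) <- .coordColumns(markers)
  if (gap_rate > 0)
    coords <- .plantGaps(coords, length(markers), gap_rate, rate, rs)
  meta$height <- height
  meta <- utils::modifyList(
    list(subject_id = "S1", group = "young", condition = "ST",
         front_foot = "right"), meta)
  new("MarkerTrial", coords = coords, markers = markers, rate = rate,
      meta = meta)
}

## Contiguous occlusion runs: geometric run lengths with mean 0.25 s, run
## starts drawn until the expected per-marker missing fraction is reached.
.plantGaps <- function(coords, n_markers, gap_rate, rate, rs) {
  n <- nrow(coords)
  mean_run <- max(1, round(0.25 * rate))
  for (m in seq_len(n_markers)) {
    miss <- logical(n)
    while (sum(miss) < gap_rate * n) {
      start <- rs$int(1, n)
      len <- 1L + rs$geom(1, 1 / mean_run)
      idx <- start:min(n, start + len - 1L)
      miss[idx] <- TRUE
    }
    cols <- (3L * (m - 1L) + 1L):(3L * m)
    coords[miss, cols] <- NA_real_
  }
  coords
}

#' Generate a full synthetic cohort with ground-truth ledger
#'
#' Draws one shared posture basis, then per subject x condition simulates PP
#' series for every planted PM (plus geometrically decaying residual
#' components filling the unplanted variance), assembles lab-frame trials,
#' and returns them with a ledger of all planted quantities.
#'
#' @param spec a [cohortSpec()].
#' @param markers marker labels (default [defaultMarkerSet()] truncated /
#'   extended to \code{spec$n_markers}).
#' @return list with \code{trials} (list of [MarkerTrial-class]) and
#'   \code{ledger}: true EV profile (including residual components), the
#'   regularity matrix per group, effect shape/amplitude, heights, seeds.
#' @export
generateCohort <- function(spec, markers = NULL) {
  stopifnot(inherits(spec, "SyntheticCohortSpec"))
  if (is.null(markers)) {
    base <- defaultMarkerSet()
    if (spec$n_markers <= length(base)) markers <- base[seq_len(spec$n_markers)]
    else stop("n_markers exceeds the default marker set; supply labels")
  }
  n_dof <- 3L * spec$n_markers
  k_planted <- length(spec$ev_profile)
  resid <- 1 - sum(spec$ev_profile)
  ev_full <- spec$ev_profile
  if (resid > 1e-9) {
    # geometric decay over trailing components, first term kept below the
    # smallest planted EV so the full spectrum stays non-increasing
    a <- min(min(spec$ev_profile), resid) * 0.95
    if (a >= resid * 0.99) {
      extra <- resid
    } else {
      r <- 1 - a / resid
      n_extra <- min(n_dof - k_planted,
                     max(2L, as.integer(ceiling(log(0.01) / log(r)))))
      extra <- a * r^(0:(n_extra - 1L))
      extra <- extra * (resid / sum(extra))
    }
    if (extra[1L] > min(spec$ev_profile) + 1e-12)
      stop("residual variance cannot be spread without exceeding planted EVs")
    ev_full <- c(spec$ev_profile, extra)
  }
  k <- length(ev_full)
  bas <- makePostureBasis(n_dof, k, seed = spec$seed)
  spec_full <- spec
  spec_full$ev_profile <- ev_full
  reg_full <- matrix(0.5, k, spec$n_conditions,
                     dimnames = list(paste0("PM", seq_len(k)), spec$conditions))
  reg_full[seq_len(k_planted), ] <- spec$regularity_profile
  spec_full$regularity_profile <- reg_full

  groups <- c("young", "old")
  trials <- list()
  subject_seeds <- integer(0)
  idx <- 0L
  for (g in 1:2) {
    for (s in seq_len(spec$n_subjects_per_group[g])) {
      idx <- idx + 1L
      sid <- sprintf("%s%02d", c("Y", "O")[g], s)
      goff <- if (g == 2L) spec$group_offset else 0
      for (ci in seq_len(spec$n_conditions)) {
        cond <- spec$conditions[ci]
        sseed <- (spec$seed + 100003L * idx + 1009L * ci) %% 2147483647L
        subject_seeds <- c(subject_seeds, sseed)
        n <- round(spec$duration * spec$sampling_rate)
        pp <- vapply(seq_len(k), function(pm)
          simulatePP(pm, cond, spec_full, sseed, group_offset = goff,
                     n_frames = n), numeric(n))
        trial <- assembleTrial(
          bas$basis, bas$mean_posture, pp, spec$heights[g],
          markers = markers, rate = spec$sampling_rate,
          meta = list(subject_id = sid, group = groups[g], condition = cond,
                      front_foot = "right"),
          noise_sd = spec$noise_sd, gap_rate = spec$gap_rate,
          seed = sseed + 17L)
        trials[[length(trials) + 1L]] <- trial
      }
    }
  }
  ledger <- list(
    ev_profile = ev_full,
    n_planted = k_planted,
    regularity_young = spec$regularity_profile,
    regularity_old = pmin(pmax(spec$regularity_profile + spec$group_offset, 0), 1),
    effect_shape = spec$effect_shape,
    effect_amplitude = spec$effect_amplitude,
    group_offset = spec$group_offset,
    heights = spec$heights,
    signal_var = spec$signal_var,
    noise_sd = spec$noise_sd,
    gap_rate = spec$gap_rate,
    seed = spec$seed,
    subject_seeds = subject_seeds
  )
  list(trials = trials, ledger = ledger)
}
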