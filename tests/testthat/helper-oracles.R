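# Independent oracles and small fixture builders shared across the suite.
# Oracles deliberately use naive, readable algorithms (vectorized pairwise
# enumeration, base aov/car fits) so they never share code with the
# implementation they check.

# Exhaustive-pair sample entropy: lag-tau embedding at dimensions m and m+1
# over the common template range, Chebyshev distance, self-matches excluded.
sampenOracle <- function(x, m = 2L, tau = 1L, r_coeff = 0.2) {
  n <- length(x)
  r <- r_coeff * sd(x)
  nt <- n - m * tau
  # full pairwise Chebyshev distances of the lag-tau embeddings, built by
  # element-wise maxima of per-coordinate |outer| differences
  chebMatch <- function(d) {
    D <- matrix(0, nt, nt)
    for (j in 0:(d - 1L)) {
      xs <- x[(1:nt) + j * tau]
      D <- pmax(D, abs(outer(xs, xs, "-")))
    }
    sum(D[upper.tri(D)] <= r)
  }
  B <- chebMatch(m)
  A <- chebMatch(m + 1L)
  c(A = A, B = B, saen = -log(A / B))
}

# Zero-crossing oracle: walk the series keeping the last nonzero sign.
zeroCrossOracle <- function(x) {
  last <- 0
  cnt <- 0L
  for (v in x) {
    s <- sign(v)
    if (s != 0) {
      if (last != 0 && s != last) cnt <- cnt + 1L
      last <- s
    }
  }
  cnt
}

# Tiny marker trial with mirror-able labels; coords filled from a function
# of (frame, column) or a given matrix.
toyTrial <- function(coords, markers = c("LASI", "RASI", "C7"),
                     rate = 120, height = 1.7, front_foot = "right",
                     subject_id = "S1", group = "young", condition = "ST") {
  if (is.function(coords)) {
    n <- 24L
    coords <- outer(seq_len(n), seq_len(3L * length(markers)), coords)
  }
  colnames(coords) <- posturePMA:::.coordColumns(markers)
  new("MarkerTrial", coords = coords, markers = markers, rate = rate,
      meta = list(subject_id = subject_id, group = group,
                  condition = condition, height = height,
                  front_foot = front_foot))
}

# Small synthetic cohort spec for fast end-to-end tests.
tinySpec <- function(n_per_group = c(3L, 3L), duration = 15, rate = 120,
                     n_markers = 28L, seed = 11L, ...) {
  cohortSpec(n_subjects_per_group = n_per_group, sampling_rate = rate,
             duration = duration, n_markers = n_markers, seed = seed, ...)
}

# Long-format null measure table: one measure column `y`, iid values unless
# cond_effects / group_effects are supplied (per condition / per group).
makeMeasureTable <- function(n_per_group = c(20L, 20L), n_cond = 5L,
                             cond_effects = rep(0, n_cond),
                             group_effects = c(0, 0),
                             subj_sd = 1, noise_sd = 1, pm = 1L) {
  conds <- if (n_cond == 1L) "ST" else c("ST", paste0("DT", seq_len(n_cond - 1L)))
  rows <- list()
  idx <- 0L
  for (g in 1:2) for (s in seq_len(n_per_group[g])) {
    idx <- idx + 1L
    sid <- sprintf("s%03d", idx)
    subj <- rnorm(1, sd = subj_sd)
    for (ci in seq_len(n_cond)) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, group = c("young", "old")[g], condition = conds[ci],
        pm = pm,
        y = subj + group_effects[g] + cond_effects[ci] + rnorm(1, sd = noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Split-plot F statistics via base aov with an explicit error stratum
# (valid oracle for balanced designs, where Type I = Type III).
aovOracle <- function(table, value_col = "y") {
  d <- table
  d$subject_id <- factor(d$subject_id)
  d$group <- factor(d$group)
  d$condition <- factor(d$condition)
  d$y <- d[[value_col]]
  fit <- summary(aov(y ~ group * condition + Error(subject_id / condition),
                     data = d))
  btw <- fit[["Error: subject_id"]][[1]]
  wth <- fit[["Error: subject_id:condition"]][[1]]
  list(F_group = btw["group", "F value"],
       df_group = c(btw["group", "Df"], btw["Residuals", "Df"]),
       F_cond = wth["condition", "F value"],
       F_int = wth["group:condition", "F value"],
       df_within = c(wth["condition", "Df"], wth["Residuals", "Df"]))
}
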