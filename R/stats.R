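## Split-plot (mixed-design) repeated-measures ANOVA layer: one
## between-subjects factor (age group) and one within-subjects factor
## (dual-task condition), two error strata. Sphericity is tested with
## Mauchly's W; when violated, degrees of freedom are scaled by the
## Greenhouse-Geisser epsilon (if eps_GG < 0.75) or the Huynh-Feldt epsilon
## (otherwise). Effects are reported with partial eta squared and observed
## power (noncentral F, lambda = F * df1, the SPSS convention). With
## unequal group sizes the within-effect sums of squares are Type III
## (unweighted marginal means), matching the SPSS output the field reports.

## Reshape a long measure table slice into subjects x conditions, dropping
## (listwise) subjects with any missing cell.
.wideSlice <- function(table, variable, pm) {
  sl <- table[table$pm == pm, c("subject_id", "group", "condition", variable)]
  names(sl)[4L] <- "y"
  sl$y[!is.finite(sl$y)] <- NA_real_
  conds <- unique(sl$condition)
  subjects <- unique(sl$subject_id)
  Y <- matrix(NA_real_, length(subjects), length(conds),
              dimnames = list(subjects, conds))
  for (i in seq_len(nrow(sl)))
    Y[sl$subject_id[i], sl$condition[i]] <- sl$y[i]
  grp <- sl$group[match(subjects, sl$subject_id)]
  keep <- stats::complete.cases(Y)
  n_dropped <- sum(!keep)
  if (n_dropped)
    message(sprintf("listwise removal of %d subject(s) with undefined %s (PM %d)",
                    n_dropped, variable, pm))
  list(Y = Y[keep, , drop = FALSE], group = factor(grp[keep]),
       conditions = conds, n_dropped = n_dropped)
}

## Orthonormal within-subject contrast matrix ((c-1) x c), rows orthogonal
## to the unit vector.
.orthContrasts <- function(c_levels) {
  H <- stats::contr.helmert(c_levels)       # c x (c-1)
  H <- sweep(H, 2L, sqrt(colSums(H^2)), `/`)
  t(H)
}

#' Mauchly's test and sphericity epsilons
#'
#' Mauchly's W on the pooled within-group covariance of the
#' orthonormalized within-subject contrasts, with the chi-square
#' approximation; Greenhouse-Geisser epsilon from the eigenvalues of the
#' contrast covariance and the Huynh-Feldt small-sample adjustment (capped
#' at 1).
#'
#' @param Y subjects x conditions numeric matrix (complete).
#' @param group factor of between-subject group per row (a single-level
#'   factor is allowed).
#' @return list: \code{mauchly_w}, \code{mauchly_p}, \code{epsilon_gg},
#'   \code{epsilon_hf}, \code{epsilon_lb} (lower bound 1/(c-1)).
#' @export
mauchlyEpsilon <- function(Y, group = NULL) {
  c_levels <- ncol(Y)
  if (c_levels < 3L) stop("need at least 3 within-subject levels")
  N <- nrow(Y)
  if (is.null(group)) group <- factor(rep("all", N))
  g <- nlevels(droplevels(group))
  M <- .orthContrasts(c_levels)
  Z <- Y %*% t(M)                                   # N x (c-1)
  R <- Z - rowsum(Z, group)[group, , drop = FALSE] / c(table(group)[group])
  n_e <- N - g                                      # error df
  S <- crossprod(R) / n_e
  p <- c_levels - 1L
  lam <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  gg <- sum(lam)^2 / (p * sum(lam^2))
  gg <- max(gg, 1 / p)
  hf <- ((n_e + 1) * p * gg - 2) / (p * (n_e - p * gg))
  hf <- min(max(hf, gg), 1)
  if (min(lam) < .Machine$double.eps * max(lam) * 1e3) {
    warning("singular contrast covariance: epsilon at lower bound, Mauchly p -> 0")
    return(list(mauchly_w = 0, mauchly_p = 0, epsilon_gg = 1 / p,
                epsilon_hf = min(hf, 1), epsilon_lb = 1 / p))
  }
  W <- prod(lam) / (sum(lam) / p)^p
  # chi-square approximation with the second-order refinement used by
  # SPSS/SAS (and car), so printed Mauchly p-values are reproduced
  rho <- 1 - (2 * p^2 + p + 2) / (6 * p * n_e)
  chi2 <- -n_e * rho * log(W)
  df <- p * (p + 1) / 2 - 1
  w2 <- (p + 2) * (p - 1) * (p - 2) * (2 * p^3 + 6 * p^2 + 3 * c_levels + 2) /
    (288 * (n_e * p * rho)^2)
  pr1 <- stats::pchisq(chi2, df, lower.tail = FALSE)
  pr2 <- stats::pchisq(chi2, df + 4, lower.tail = FALSE)
  pval <- pr1 + w2 * (pr2 - pr1)
  list(mauchly_w = W, mauchly_p = pval, epsilon_gg = gg, epsilon_hf = hf,
       epsilon_lb = 1 / p)
}

#' Partial eta squared from an F statistic
#'
#' eta_p^2 = F df1 / (F df1 + df2).
#'
#' @param F_value F statistic (>= 0).
#' @param df1,df2 effect and error degrees of freedom.
#' @return fraction in [0, 1].
#' @export
partialEtaSq <- function(F_value, df1, df2) {
  (F_value * df1) / (F_value * df1 + df2)
}

#' Observed power of an F test
#'
#' Noncentral-F tail probability beyond the alpha critical value with
#' noncentrality lambda = F df1 (the convention of standard statistics
#' packages); corrected degrees of freedom are used when a sphericity
#' correction was applied.
#'
#' @param F_value observed F (>= 0).
#' @param df1,df2 degrees of freedom (possibly epsilon-corrected).
#' @param alpha test level (default 0.05).
#' @return power in [0, 1].
#' @export
observedPower <- function(F_value, df1, df2, alpha = 0.05) {
  crit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(crit, df1, df2, ncp = F_value * df1, lower.tail = FALSE)
}

#' Split-plot repeated-measures ANOVA
#'
#' Two-stratum decomposition for one between-subjects factor (group) and
#' one within-subjects factor (condition): the between stratum tests group
#' against subjects-within-group; the within stratum tests condition and
#' condition x group against condition x subjects-within-group. With
#' unequal group sizes the condition effect uses Type III (unweighted
#' marginal means). Sphericity corrections follow the
#' Mauchly-then-epsilon rule (see [applyCorrection()]).
#'
#' @param table long measure table (columns \code{subject_id, group,
#'   condition, pm} plus measure columns).
#' @param variable measure column name ("saen_pp", "saen_pa", "n",
#'   "sigma").
#' @param pm PM index to analyze.
#' @param alpha level used for the Mauchly decision and power (default
#'   0.05).
#' @param correct "auto" (correct only when Mauchly p < alpha), "always",
#'   or "never".
#' @return data.frame with one row per effect (condition, group,
#'   condition:group): F, dfs (uncorrected and corrected), epsilons,
#'   correction used, p, partial eta squared, observed power, SS columns.
#' @export
splitPlotAnova <- function(table, variable, pm, alpha = 0.05,
                           correct = c("auto", "always", "never")) {
  correct <- match.arg(correct)
  ws <- .wideSlice(table, variable, pm)
  Y <- ws$Y
  group <- droplevels(ws$group)
  N <- nrow(Y); c_levels <- ncol(Y); g <- nlevels(group)
  if (N < 4L) stop("too few complete subjects for the ANOVA")
  if (any(table(group) < 2L) && g > 1L)
    stop("need at least 2 subjects per group")

  subj_mean <- rowMeans(Y)
  grand <- mean(Y)
  ## ---- between-subjects stratum (on subject means, x c) ----
  if (g > 1L) {
    grp_mean <- tapply(subj_mean, group, mean)
    ng <- as.vector(table(group))
    ss_group <- c_levels * sum(ng * (grp_mean - sum(ng * grp_mean) / N)^2)
    df_group <- g - 1
  } else {
    ss_group <- NA_real_; df_group <- NA_real_
  }
  ss_subj <- c_levels * sum((subj_mean - stats::ave(subj_mean, group))^2)
  df_subj <- N - g

  ## ---- within stratum via orthonormal contrasts ----
  M <- .orthContrasts(c_levels)
  Z <- Y %*% t(M)                                  # N x (c-1)
  Zg <- rowsum(Z, group) / as.vector(table(group)) # group means of contrasts
  E <- Z - Zg[group, , drop = FALSE]
  ss_err_w <- sum(E^2)
  df_err_w <- (N - g) * (c_levels - 1)
  ## condition: Type III — unweighted average of group means
  zbar_unw <- colMeans(Zg)
  n_h <- g^2 / sum(1 / table(group))               # effective N for unweighted mean
  ss_cond <- n_h * sum(zbar_unw^2)
  df_cond <- c_levels - 1
  ## interaction: dispersion of group contrast means
  if (g > 1L) {
    zbar_w <- colSums(Z) / N
    ss_int <- sum(as.vector(table(group)) * rowSums(
      (Zg - matrix(zbar_w, g, ncol(Z), byrow = TRUE))^2))
    df_int <- (g - 1) * (c_levels - 1)
  } else {
    ss_int <- NA_real_; df_int <- NA_real_
  }

  sph <- if (c_levels >= 3L) mauchlyEpsilon(Y, group)
         else list(mauchly_p = NA_real_, epsilon_gg = 1, epsilon_hf = 1)
  mk <- function(effect, ss, df, ss_err, df_err, within) {
    F_value <- (ss / df) / (ss_err / df_err)
    data.frame(effect = effect, ss = ss, df1 = df, df2 = df_err,
               F = F_value,
               mauchly_p = if (within) sph$mauchly_p else NA_real_,
               epsilon_gg = if (within) sph$epsilon_gg else NA_real_,
               epsilon_hf = if (within) sph$epsilon_hf else NA_real_,
               stringsAsFactors = FALSE)
  }
  res <- rbind(
    if (g > 1L) mk("group", ss_group, df_group, ss_subj, df_subj, FALSE),
    mk("condition", ss_cond, df_cond, ss_err_w, df_err_w, TRUE),
    if (g > 1L) mk("condition:group", ss_int, df_int, ss_err_w, df_err_w, TRUE))
  res <- applyCorrection(res, alpha = alpha, mode = correct)
  res$eta_p2 <- partialEtaSq(res$F, res$df1, res$df2)
  res$power <- observedPower(res$F, res$df1_corr, res$df2_corr, alpha = alpha)
  res$variable <- variable
  res$pm <- pm
  res$n_subjects <- N
  res$n_dropped <- ws$n_dropped
  rownames(res) <- NULL
  res
}

#' Apply the sphericity-correction rule
#'
#' For within-subject effects with a significant Mauchly test, scales both
#' degrees of freedom by the Greenhouse-Geisser epsilon when eps_GG <
#' \code{rule_threshold}, otherwise by the Huynh-Feldt epsilon; the F value
#' is unchanged and p is recomputed on the scaled dfs.
#'
#' @param res effect table from [splitPlotAnova()] (columns F, df1, df2,
#'   mauchly_p, epsilon_gg, epsilon_hf).
#' @param rule_threshold epsilon threshold for GG vs HF (default 0.75).
#' @param alpha Mauchly significance level (default 0.05).
#' @param mode "auto" (only when Mauchly rejects), "always", "never".
#' @return the table with \code{correction}, \code{df1_corr},
#'   \code{df2_corr}, \code{p} columns.
#' @export
applyCorrection <- function(res, rule_threshold = 0.75, alpha = 0.05,
                            mode = c("auto", "always", "never")) {
  mode <- match.arg(mode)
  res$correction <- "none"
  res$df1_corr <- res$df1
  res$df2_corr <- res$df2
  within <- !is.na(res$mauchly_p)
  doit <- within & switch(mode,
    auto = res$mauchly_p < alpha,
    always = TRUE,
    never = FALSE)
  use_gg <- doit & res$epsilon_gg < rule_threshold
  use_hf <- doit & !use_gg
  eps <- ifelse(use_gg, res$epsilon_gg, ifelse(use_hf, res$epsilon_hf, 1))
  res$correction[use_gg] <- "GG"
  res$correction[use_hf] <- "HF"
  res$df1_corr <- res$df1 * eps
  res$df2_corr <- res$df2 * eps
  res$p <- stats::pf(res$F, res$df1_corr, res$df2_corr, lower.tail = FALSE)
  res
}

#' Sidak-corrected pairwise condition contrasts
#'
#' Paired t tests on subject means for every condition pair (the full
#' family of choose(c, 2) contrasts; 10 for five conditions), with Sidak
#' adjustment p_sidak = 1 - (1 - p)^family and percent change between
#' condition means.
#'
#' @param table long measure table.
#' @param variable measure column name.
#' @param pm PM index.
#' @param alpha significance level for the \code{significant} flag.
#' @return data.frame per pair: condition_a, condition_b, mean_diff,
#'   percent_change, p_raw, p_sidak, significant.
#' @export
sidakPosthoc <- function(table, variable, pm, alpha = 0.05) {
  ws <- .wideSlice(table, variable, pm)
  Y <- ws$Y
  conds <- colnames(Y)
  pairs <- utils::combn(length(conds), 2L)
  fam <- ncol(pairs)
  out <- lapply(seq_len(fam), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    d <- Y[, b] - Y[, a]
    if (stats::sd(d) == 0) {
      # degenerate paired test: identical conditions are a clear null,
      # an exactly constant nonzero shift a clear rejection
      p_raw <- if (mean(d) == 0) 1 else 0
    } else {
      tstat <- mean(d) / (stats::sd(d) / sqrt(length(d)))
      p_raw <- 2 * stats::pt(abs(tstat), length(d) - 1L, lower.tail = FALSE)
    }
    ma <- mean(Y[, a]); mb <- mean(Y[, b])
    pc <- if (abs(ma) < .Machine$double.eps) NA_real_ else (mb - ma) / ma * 100
    data.frame(condition_a = conds[a], condition_b = conds[b],
               mean_diff = mb - ma, percent_change = pc, p_raw = p_raw,
               p_sidak = 1 - (1 - p_raw)^fam, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$significant <- out$p_sidak < alpha
  attr(out, "family_size") <- fam
  out
}

#' Normality and variance-homogeneity checks
#'
#' Advisory per-cell normality tests (Lilliefors-corrected
#' Kolmogorov-Smirnov against a fitted normal, and Shapiro-Wilk) and
#' Levene's test (center = mean) of variance equality across groups per
#' condition. The pipeline proceeds regardless; this report is diagnostic.
#'
#' @param table long measure table.
#' @param variable measure column name.
#' @param pm PM index.
#' @return list with \code{normality} (per group x condition: n, ks_p,
#'   sw_p) and \code{levene} (per condition: F, p), cells with fewer than 3
#'   observations skipped with NA.
#' @export
assumptionChecks <- function(table, variable, pm) {
  sl <- table[table$pm == pm, ]
  y <- sl[[variable]]
  cells <- split(y, list(sl$group, sl$condition), drop = TRUE)
  normality <- do.call(rbind, lapply(names(cells), function(nm) {
    v <- cells[[nm]]; v <- v[is.finite(v)]
    ks <- if (length(v) >= 5L) tryCatch(nortest::lillie.test(v)$p.value,
                                        error = function(e) NA_real_)
          else NA_real_
    sw <- if (length(v) >= 3L) tryCatch(stats::shapiro.test(v)$p.value,
                                        error = function(e) NA_real_)
          else NA_real_
    data.frame(cell = nm, n = length(v), ks_p = ks, sw_p = sw,
               stringsAsFactors = FALSE)
  }))
  lev <- do.call(rbind, lapply(unique(sl$condition), function(cc) {
    sub <- sl[sl$condition == cc & is.finite(sl[[variable]]), ]
    if (length(unique(sub$group)) < 2L || nrow(sub) < 4L)
      return(data.frame(condition = cc, F = NA_real_, p = NA_real_))
    lt <- car::leveneTest(sub[[variable]], factor(sub$group), center = mean)
    data.frame(condition = cc, F = lt$`F value`[1L], p = lt$`Pr(>F)`[1L])
  }))
  list(normality = normality, levene = lev)
}

#' Run the ANOVA layer over all variables and PMs
#'
#' @param table long measure table from [computeMeasures()].
#' @param variables measure columns to analyze.
#' @param alpha level for corrections/power and the post-hoc trigger.
#' @param posthoc run [sidakPosthoc()] for significant condition effects.
#' @return list with \code{anova} (stacked effect rows) and \code{posthoc}
#'   (stacked pairwise rows, possibly empty).
#' @export
analyzeMeasures <- function(table, variables = c("saen_pp", "saen_pa", "n",
                                                 "sigma"),
                            alpha = 0.05, posthoc = TRUE) {
  pms <- sort(unique(table$pm))
  an <- list(); ph <- list()
  for (v in variables) for (k in pms) {
    res <- tryCatch(splitPlotAnova(table, v, k, alpha = alpha),
                    error = function(e) NULL)
    if (is.null(res)) next
    an[[length(an) + 1L]] <- res
    cond_p <- res$p[res$effect == "condition"]
    if (posthoc && length(cond_p) && is.finite(cond_p) && cond_p < alpha) {
      pr <- sidakPosthoc(table, v, k, alpha = alpha)
      pr$variable <- v; pr$pm <- k
      ph[[length(ph) + 1L]] <- pr
    }
  }
  list(anova = do.call(rbind, an),
       posthoc = if (length(ph)) do.call(rbind, ph) else NULL)
}
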