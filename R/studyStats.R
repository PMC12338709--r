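#' Shapiro-Wilk normality screen with Bonferroni correction
#'
#' Runs a Shapiro-Wilk test within every group of the table (by default
#' metabolite x method x session) and flags which groups stay consistent
#' with normality at the Bonferroni-corrected threshold alpha / m, with m
#' the number of groups tested (configurable).
#'
#' @param study data.frame holding the value column and grouping columns.
#' @param value name of the value column.
#' @param groups character vector of grouping columns present in `study`.
#' @param alpha familywise significance level (default 0.05).
#' @param m Bonferroni divisor; defaults to the number of groups.
#' @return data.frame with columns group, n, W, p_raw,
#'   pass_after_correction. Constant-valued groups get NA statistics and an
#'   NA pass flag (the test is undefined there).
#' @export
shapiroNormalityScreen <- function(study, value = "conc_mM",
                                   groups = c("metabolite", "method", "session"),
                                   alpha = 0.05, m = NULL) {
  groups <- intersect(groups, names(study))
  if (!length(groups)) stop("no grouping columns found", call. = FALSE)
  key <- interaction(study[groups], drop = TRUE, sep = ":")
  splits <- split(study[[value]], key)
  if (is.null(m)) m <- length(splits)
  rows <- lapply(names(splits), function(g) {
    x <- splits[[g]]
    if (length(x) < 3L) {
      stop("group too small for a Shapiro-Wilk test (n < 3): ", g,
           call. = FALSE)
    }
    if (stats::sd(x) == 0) {
      return(data.frame(group = g, n = length(x), W = NA_real_,
                        p_raw = NA_real_, pass_after_correction = NA,
                        stringsAsFactors = FALSE))
    }
    sw <- stats::shapiro.test(x)
    data.frame(group = g, n = length(x), W = unname(sw$statistic),
               p_raw = sw$p.value,
               pass_after_correction = sw$p.value >= alpha / m,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Paired t-test between sessions with Bonferroni correction
#'
#' Classical paired t-test on the session-2 minus session-1 differences of
#' one metric, with the p-value multiplied by the number of metrics in the
#' family (three quality metrics by default) and capped at 1.
#'
#' @param x1,x2 paired values for session 1 and session 2 (same order and
#'   length).
#' @param mBonferroni Bonferroni multiplier (default 3).
#' @return list with t, df, p_raw, p_adjusted.
#' @export
pairedSessionTest <- function(x1, x2, mBonferroni = 3) {
  if (length(x1) != length(x2)) {
    stop("unpaired data: sessions differ in length", call. = FALSE)
  }
  if (length(x1) < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- x2 - x1
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(list(t = 0, df = length(d) - 1L, p_raw = 1, p_adjusted = 1))
    }
    stop("zero-variance differences: paired t statistic undefined",
         call. = FALSE)
  }
  tt <- stats::t.test(x2, x1, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_raw = tt$p.value, p_adjusted = min(1, tt$p.value * mBonferroni))
}

# Assert a complete balanced participant x method x session design and
# return the table with factors in a canonical order.
checkBalancedDesign <- function(study, response) {
  for (col in c("participant", "method", "session", response)) {
    if (!col %in% names(study)) {
      stop("study table is missing column: ", col, call. = FALSE)
    }
  }
  tab <- table(study$participant, study$method, study$session)
  if (any(tab != 1L)) {
    stop("unbalanced design: every participant x method x session cell ",
         "must be present exactly once", call. = FALSE)
  }
  if (length(unique(study$method)) < 2L) {
    stop("need at least 2 methods", call. = FALSE)
  }
  if (length(unique(study$session)) < 2L) {
    stop("need at least 2 sessions", call. = FALSE)
  }
  study
}

#' Method x Session repeated-measures model with participant intercepts
#'
#' Fits the model response ~ Method * Session with a participant random
#' intercept to a complete balanced test-retest table. For this design the
#' mixed model is exactly the balanced repeated-measures ANOVA, so the fit
#' is computed in closed form from the sums-of-squares decomposition:
#' all fixed effects are tested against the pooled within-participant
#' error stratum, whose degrees of freedom are
#' (n_participants - 1) * (n_cells - 1) — e.g. F(2, 60) for 13 participants
#' with 3 methods and 2 sessions. Estimated marginal means are cell means
#' averaged over the other factor; their standard errors combine the
#' participant and residual variance components
#' (sigma_p^2 / n + sigma_e^2 / (n * levels_other)) and their 95% CIs use
#' the participant stratum df (n - 1, containment). Incomplete or
#' unbalanced tables are rejected rather than approximated.
#'
#' @param study long-format data.frame with columns `participant`,
#'   `method`, `session` and the response.
#' @param response name of the response column (e.g. "conc_mM" or "f_gm").
#' @return a [MethodSessionFit-class] object.
#' @export
methodSessionModel <- function(study, response) {
  study <- checkBalancedDesign(study, response)
  y <- study[[response]]
  p <- factor(study$participant)
  m <- factor(study$method)
  s <- factor(study$session)
  n <- nlevels(p); nm <- nlevels(m); ns <- nlevels(s)
  cells <- nm * ns
  grand <- mean(y)

  pm <- tapply(y, p, mean)
  mm <- tapply(y, m, mean)
  sm <- tapply(y, s, mean)
  cm <- tapply(y, list(m, s), mean)

  ssP <- cells * sum((pm - grand)^2)
  ssM <- n * ns * sum((mm - grand)^2)
  ssS <- n * nm * sum((sm - grand)^2)
  ssCells <- n * sum((cm - grand)^2)
  ssInt <- ssCells - ssM - ssS
  ssTot <- sum((y - grand)^2)
  ssE <- ssTot - ssP - ssCells

  dfP <- n - 1L
  dfM <- nm - 1L
  dfS <- ns - 1L
  dfInt <- dfM * dfS
  dfE <- (n - 1L) * (cells - 1L)
  msE <- ssE / dfE
  msP <- ssP / dfP
  if (msE <= 0) {
    stop("zero residual variance: F statistics undefined", call. = FALSE)
  }

  Fs <- c(Method = (ssM / dfM) / msE,
          Session = (ssS / dfS) / msE,
          `Method:Session` = (ssInt / dfInt) / msE)
  anova <- data.frame(
    term = names(Fs),
    df_num = c(dfM, dfS, dfInt),
    df_den = dfE,
    F = pmax(unname(Fs), 0),
    p = stats::pf(pmax(unname(Fs), 0), c(dfM, dfS, dfInt), dfE,
                  lower.tail = FALSE),
    stringsAsFactors = FALSE)

  sig2e <- msE
  sig2p <- max(0, (msP - msE) / cells)
  emm <- function(levMeans, nOther) {
    se <- sqrt(sig2p / n + sig2e / (n * nOther))
    tq <- stats::qt(0.975, dfP)
    data.frame(level = names(levMeans), mean = unname(levMeans), se = se,
               df = dfP, ci_low = unname(levMeans) - tq * se,
               ci_high = unname(levMeans) + tq * se,
               stringsAsFactors = FALSE)
  }
  means <- rbind(
    cbind(factor = "method", emm(mm, ns)),
    cbind(factor = "session", emm(sm, nm)))

  new("MethodSessionFit",
      anova = anova,
      means = means,
      varcomp = c(sigma2_participant = sig2p, sigma2_error = sig2e),
      design = list(n = n, methods = levels(m), sessions = levels(s),
                    response = response, df_error = dfE, ms_error = msE,
                    grand_mean = grand))
}

#' Tukey HSD pairwise comparisons of method marginal means
#'
#' All-pairs contrasts of the method marginal means from a fitted
#' [methodSessionModel()]. Each estimate is a within-participant contrast,
#' so its standard error uses only the residual stratum,
#' sqrt(2 sigma_e^2 / (n * n_sessions)), with the model's error df.
#' P-values are adjusted over the family via the studentized-range
#' distribution.
#'
#' @param fit a [MethodSessionFit-class] object.
#' @return data.frame with columns pair, estimate, se, df, t_ratio,
#'   p_adjusted, in canonical (alphabetical) pair order.
#' @export
tukeyPairwise <- function(fit) {
  stopifnot(is(fit, "MethodSessionFit"))
  mm <- marginalMeans(fit, "method")
  if (nrow(mm) < 2L) stop("need at least 2 method levels", call. = FALSE)
  means <- stats::setNames(mm$mean, mm$level)
  k <- length(means)
  n <- fit@design$n
  ns <- length(fit@design$sessions)
  dfE <- fit@design$df_error
  se <- sqrt(2 * fit@design$ms_error / (n * ns))
  deltas <- pairwiseMethodDeltas(means)
  t <- deltas$estimate / se
  data.frame(
    pair = deltas$pair,
    estimate = deltas$estimate,
    se = se,
    df = dfE,
    t_ratio = t,
    p_adjusted = stats::ptukey(sqrt(2) * abs(t), k, dfE, lower.tail = FALSE),
    stringsAsFactors = FALSE)
}

#' Normalized gray-matter fraction
#'
#' fGM / (fGM + fWM): a CSF-independent measure of gray-matter content,
#' used for age associations.
#'
#' @param f a [TissueFractions-class] object, numeric(3) (gm, wm, csf), or
#'   a data.frame/matrix with columns f_gm/f_wm (vectorized).
#' @return normalized GM fraction(s) in \[0, 1\].
#' @export
normalizedGM <- function(f) {
  if (is(f, "TissueFractions")) {
    g <- f@fGM; w <- f@fWM
  } else if (is.data.frame(f) || is.matrix(f)) {
    f <- as.data.frame(f)
    g <- f$f_gm; w <- f$f_wm
    if (is.null(g) || is.null(w)) {
      stop("need columns f_gm and f_wm", call. = FALSE)
    }
  } else {
    g <- f[1]; w <- f[2]
  }
  if (any(g + w <= 0)) {
    stop("fGM + fWM must be positive", call. = FALSE)
  }
  g / (g + w)
}

#' Pearson correlation with r^2 and two-sided p
#'
#' @param x,y numeric vectors (n >= 3, finite, nonzero variance).
#' @return data.frame with columns r, r_squared, p, n.
#' @export
pearsonAssociation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  data.frame(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
             p = ct$p.value, n = length(x))
}

#' Steiger's Z for two dependent correlations sharing a variable
#'
#' Compares r_xy with r_xz when both correlations come from the same
#' sample and share the variable x (e.g. age correlated with the same
#' measure derived from two segmentation methods). The Fisher-z
#' difference is scaled by the asymptotic standard error that accounts for
#' the correlation r_yz between the non-shared variables, using the pooled
#' correlation (r_xy + r_xz)/2 in the covariance term (Steiger 1980,
#' overlapping case). Z is antisymmetric in the two compared correlations;
#' the p-value is two-sided normal.
#'
#' @param rXY,rXZ the two correlations being compared, each in (-1, 1).
#' @param rYZ correlation between the non-shared variables, in (-1, 1).
#' @param n sample size (>= 4).
#' @return list with z and p.
#' @export
steigerDependentZ <- function(rXY, rXZ, rYZ, n) {
  r <- c(rXY, rXZ, rYZ)
  if (any(abs(r) >= 1)) {
    stop("correlations must lie strictly in (-1, 1)", call. = FALSE)
  }
  if (n < 4L) stop("need n >= 4", call. = FALSE)
  z1 <- atanh(rXY)
  z2 <- atanh(rXZ)
  rb <- (rXY + rXZ) / 2
  psi <- rYZ * (1 - 2 * rb^2) - 0.5 * rb^2 * (1 - 2 * rb^2 - rYZ^2)
  s <- psi / (1 - rb^2)^2
  z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * s))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}
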