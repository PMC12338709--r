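# Brute-force oracles for the balanced repeated-measures model, computed
# through an independent path (aov Error-stratum projections / OLS with
# dummy variables) rather than the package's closed-form decomposition.

oracleAnova <- function(d, response) {
  d$y <- d[[response]]
  d$participant <- factor(d$participant)
  d$method <- factor(d$method)
  d$session <- factor(d$session)
  fit <- stats::aov(y ~ method * session + Error(participant), data = d)
  within <- summary(fit)[["Error: Within"]][[1]]
  rn <- trimws(rownames(within))
  terms <- c("method", "session", "method:session")
  data.frame(
    term = c("Method", "Session", "Method:Session"),
    df_num = within[match(terms, rn), "Df"],
    df_den = within[rn == "Residuals", "Df"],
    F = within[match(terms, rn), "F value"],
    p = within[match(terms, rn), "Pr(>F)"],
    stringsAsFactors = FALSE)
}

# Stratum mean squares via aov projections (not via the package's sums).
oracleStrata <- function(d, response) {
  d$y <- d[[response]]
  d$participant <- factor(d$participant)
  fit <- stats::aov(y ~ method * session + Error(participant), data = d)
  s <- summary(fit)
  pTab <- s[["Error: participant"]][[1]]
  wTab <- s[["Error: Within"]][[1]]
  list(msP = pTab[trimws(rownames(pTab)) == "Residuals", "Mean Sq"],
       dfP = pTab[trimws(rownames(pTab)) == "Residuals", "Df"],
       msE = wTab[trimws(rownames(wTab)) == "Residuals", "Mean Sq"],
       dfE = wTab[trimws(rownames(wTab)) == "Residuals", "Df"])
}

# Marginal means with variance-component CIs assembled from the aov strata.
oracleMethodMeans <- function(d, response) {
  st <- oracleStrata(d, response)
  n <- length(unique(d$participant))
  ns <- length(unique(d$session))
  nm <- length(unique(d$method))
  sig2p <- max(0, (st$msP - st$msE) / (nm * ns))
  se <- sqrt(sig2p / n + st$msE / (n * ns))
  mm <- tapply(d[[response]], d$method, mean)
  tq <- stats::qt(0.975, st$dfP)
  data.frame(level = names(mm), mean = unname(mm), se = se, df = st$dfP,
             ci_low = unname(mm) - tq * se, ci_high = unname(mm) + tq * se,
             stringsAsFactors = FALSE)
}

# Tukey contrasts through OLS with participant dummies (QR path) and the
# studentized-range distribution applied to every ordered pair by hand.
oracleTukey <- function(d, response) {
  d$y <- d[[response]]
  d$participant <- factor(d$participant)
  d$method <- factor(d$method)
  d$session <- factor(d$session)
  fit <- stats::lm(y ~ participant + method * session, data = d)
  k <- nlevels(d$method)
  levs <- levels(d$method)
  # contrast of method marginal means averaged over sessions
  grid <- expand.grid(method = levs, session = levels(d$session),
                      participant = levels(d$participant))
  X <- stats::model.matrix(stats::delete.response(stats::terms(fit)), grid)
  L <- sapply(levs, function(m) colMeans(X[grid$method == m, , drop = FALSE]))
  pairs <- utils::combn(sort(levs), 2)
  est <- se <- tr <- numeric(ncol(pairs))
  V <- stats::vcov(fit)
  beta <- stats::coef(fit)
  for (j in seq_len(ncol(pairs))) {
    l <- L[, pairs[1, j]] - L[, pairs[2, j]]
    est[j] <- sum(l * beta)
    se[j] <- sqrt(drop(t(l) %*% V %*% l))
    tr[j] <- est[j] / se[j]
  }
  dfE <- fit$df.residual
  data.frame(pair = apply(pairs, 2, paste, collapse = " - "),
             estimate = est, se = se, df = dfE, t_ratio = tr,
             p_adjusted = stats::ptukey(sqrt(2) * abs(tr), k, dfE,
                                        lower.tail = FALSE),
             stringsAsFactors = FALSE)
}
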