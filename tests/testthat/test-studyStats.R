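test_that("Shapiro screen flags heavy tails and passes normal data", {
  set.seed(21)
  norm <- data.frame(
    metabolite = "tCr",
    method = rep(sprintf("M%02d", 1:20), each = 250),
    session = 1,
    conc_mM = stats::rnorm(5000, 7, 0.5))
  scr <- shapiroNormalityScreen(norm)
  expect_equal(nrow(scr), 20)
  expect_gte(mean(scr$pass_after_correction), 0.95)

  heavy <- data.frame(metabolite = "tCr",
                      method = rep(sprintf("M%02d", 1:20), each = 50),
                      session = 1,
                      conc_mM = stats::rcauchy(1000))
  scrH <- shapiroNormalityScreen(heavy)
  expect_gte(mean(!scrH$pass_after_correction), 0.7)

  const <- data.frame(metabolite = "tCr", method = "A", session = 1,
                      conc_mM = rep(5, 10))
  scrC <- shapiroNormalityScreen(const)
  expect_true(is.na(scrC$W) && is.na(scrC$pass_after_correction))

  tiny <- data.frame(metabolite = "tCr", method = "A", session = 1,
                     conc_mM = c(1, 2))
  expect_error(shapiroNormalityScreen(tiny), "too small")
})

test_that("paired session test matches the noncentral-t power oracle", {
  expect_equal(pairedSessionTest(c(1, 2, 3), c(1, 2, 3)),
               list(t = 0, df = 2L, p_raw = 1, p_adjusted = 1))
  expect_error(pairedSessionTest(c(1, 2, 3), c(2, 3, 4)), "zero-variance")
  expect_error(pairedSessionTest(1:3, 1:4), "unpaired")

  # Bonferroni factor and cap
  set.seed(5)
  x1 <- stats::rnorm(10); x2 <- x1 + stats::rnorm(10, 0.1, 1)
  r <- pairedSessionTest(x1, x2, mBonferroni = 3)
  expect_equal(r$p_adjusted, min(1, 3 * r$p_raw))

  # empirical rejection rate at a 1-SD shift vs closed-form power
  set.seed(31)
  n <- 13; reps <- 1000
  rej <- mean(replicate(reps, {
    d <- stats::rnorm(n, 1, 1)
    pairedSessionTest(rep(0, n), d, mBonferroni = 1)$p_adjusted < 0.05
  }))
  ncp <- sqrt(n)
  tc <- stats::qt(0.975, n - 1)
  power <- 1 - stats::pt(tc, n - 1, ncp) + stats::pt(-tc, n - 1, ncp)
  expect_lt(abs(rej - power), 0.05)
})

test_that("balanced model matches the aov/OLS oracle on random fixtures", {
  set.seed(7)
  for (i in 1:5) {
    n <- sample(3:10, 1)
    d <- randomBalancedStudy(n, methodEffects = stats::rnorm(3, 0, 0.5),
                             sessionEffect = stats::rnorm(1, 0, 0.2))
    fit <- methodSessionModel(d, "y")
    expect_equal(anovaTable(fit), oracleAnova(d, "y"), tolerance = 1e-10)
    mm <- marginalMeans(fit, "method")
    om <- oracleMethodMeans(d, "y")
    expect_equal(mm$mean, om$mean, tolerance = 1e-10)
    expect_equal(mm$se, om$se, tolerance = 1e-10)
    expect_equal(mm$ci_low, om$ci_low, tolerance = 1e-10)
    tk <- tukeyPairwise(fit)
    ot <- oracleTukey(d, "y")
    expect_equal(tk$estimate, ot$estimate, tolerance = 1e-10)
    expect_equal(tk$se, ot$se, tolerance = 1e-10)
    expect_equal(tk$p_adjusted, ot$p_adjusted, tolerance = 1e-10)
  }
})

test_that("balanced model agrees with nlme::lme + emmeans", {
  set.seed(13)
  d <- randomBalancedStudy(8, methodEffects = c(0, 0.4, -0.2))
  fit <- methodSessionModel(d, "y")
  lmeFit <- nlme::lme(y ~ method * session,
                      random = ~ 1 | participant,
                      data = transform(d, method = factor(method),
                                       session = factor(session)))
  av <- stats::anova(lmeFit)
  expect_equal(anovaTable(fit)$F, av[c("method", "session", "method:session"),
                                     "F-value"], tolerance = 1e-6)
  expect_equal(anovaTable(fit)$df_den, rep(av["method", "denDF"], 3))
  em <- as.data.frame(emmeans::emmeans(lmeFit, "method"))
  mm <- marginalMeans(fit, "method")
  expect_equal(mm$mean, em$emmean, tolerance = 1e-6)
  expect_equal(mm$se, em$SE, tolerance = 1e-5)
  expect_equal(mm$df, em$df)
  expect_equal(mm$ci_low, em$lower.CL, tolerance = 1e-5)
})

test_that("model degrees of freedom come from the design", {
  set.seed(3)
  d <- randomBalancedStudy(13)
  fit <- methodSessionModel(d, "y")
  expect_equal(anovaTable(fit)$df_den, rep(60, 3))  # (13-1) * (6-1)
  expect_equal(tukeyPairwise(fit)$df, rep(60, 3))
  d5 <- randomBalancedStudy(5)
  expect_equal(anovaTable(methodSessionModel(d5, "y"))$df_den, rep(20, 3))
})

test_that("model handles nulls, conservation, and rejects bad designs", {
  set.seed(17)
  # participant offsets, session-level noise shared across methods, but no
  # variation between methods: F(Method) = 0 exactly, means equal
  d <- randomBalancedStudy(6, residSD = 0, participantSD = 1)
  ps <- interaction(d$participant, d$session)
  d$y <- d$y + stats::rnorm(nlevels(ps))[as.integer(ps)]
  fit <- methodSessionModel(d, "y")
  expect_lt(anovaTable(fit)$F[1], 1e-12)
  mm <- marginalMeans(fit, "method")
  expect_lt(diff(range(mm$mean)), 1e-10)

  # conservation: marginal means average to the grand mean
  d2 <- randomBalancedStudy(7, methodEffects = c(1, -0.5, 0.2),
                            sessionEffect = 0.3)
  fit2 <- methodSessionModel(d2, "y")
  expect_equal(mean(marginalMeans(fit2, "method")$mean), mean(d2$y),
               tolerance = 1e-10)
  expect_equal(mean(marginalMeans(fit2, "session")$mean), mean(d2$y),
               tolerance = 1e-10)
  # CI sanity
  mm2 <- marginalMeans(fit2, "method")
  expect_true(all(mm2$ci_low <= mm2$mean & mm2$mean <= mm2$ci_high))

  dBad <- d2[-1, ]
  expect_error(methodSessionModel(dBad, "y"), "unbalanced design")
  dOne <- d2[d2$method == "A", ]
  expect_error(methodSessionModel(dOne, "y"), "at least 2 methods")
})

test_that("Tukey adjustment dominates the unadjusted pairwise p-values", {
  set.seed(19)
  d <- randomBalancedStudy(9, methodEffects = c(0, 0.3, 0.5))
  tk <- tukeyPairwise(methodSessionModel(d, "y"))
  pRaw <- 2 * stats::pt(-abs(tk$t_ratio), tk$df)
  expect_true(all(tk$p_adjusted >= pRaw - 1e-12))
  # equal means: all adjusted p near 1
  dEq <- randomBalancedStudy(30, residSD = 1e-6, participantSD = 1)
  tkEq <- tukeyPairwise(methodSessionModel(dEq, "y"))
  expect_true(all(tkEq$p_adjusted > 0.2))
})

test_that("normalized GM is the CSF-independent ratio", {
  expect_equal(normalizedGM(c(0.5, 0.5, 0)), 0.5)
  expect_equal(normalizedGM(tissueFractions(0.56, 0.27, 0.17)), 0.56 / 0.83,
               tolerance = 1e-12)
  expect_equal(normalizedGM(data.frame(f_gm = c(0.4, 0.2),
                                       f_wm = c(0.4, 0.6))), c(0.5, 0.25))
  expect_error(normalizedGM(c(0, 0, 1)), "must be positive")
})

test_that("Pearson association matches the manual t-transform oracle", {
  r1 <- pearsonAssociation(1:10, -(1:10))
  expect_equal(r1$r, -1)
  expect_equal(r1$r_squared, 1)

  x <- c(1, 2, 3); y <- c(1, 2, 4)
  got <- pearsonAssociation(x, y)
  rHand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tHand <- rHand * sqrt((3 - 2) / (1 - rHand^2))
  expect_equal(got$r, rHand, tolerance = 1e-12)
  expect_equal(got$r_squared, rHand^2, tolerance = 1e-12)
  expect_equal(got$p, 2 * stats::pt(-abs(tHand), 1), tolerance = 1e-12)

  set.seed(23)
  ind <- pearsonAssociation(stats::rnorm(1e4), stats::rnorm(1e4))
  expect_lt(abs(ind$r), 0.05)
  expect_error(pearsonAssociation(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("Steiger's Z matches its frozen oracle and is calibrated", {
  # equal correlations: Z = 0, p = 1
  z0 <- steigerDependentZ(0.5, 0.5, 0.3, 30)
  expect_equal(z0$z, 0)
  expect_equal(z0$p, 1)
  # antisymmetry
  za <- steigerDependentZ(0.5, 0.3, 0.4, 50)
  zb <- steigerDependentZ(0.3, 0.5, 0.4, 50)
  expect_equal(za$z, -zb$z, tolerance = 1e-12)
  # frozen independently computed value for (0.5, 0.3, 0.4, n = 50)
  expect_equal(za$z, 1.4164452831948784, tolerance = 1e-10)
  expect_equal(za$p, 2 * stats::pnorm(-1.4164452831948784), tolerance = 1e-10)

  # Monte-Carlo calibration under H0 (equal true correlations)
  set.seed(29)
  C <- rbind(c(1, 0.4, 0.4), c(0.4, 1, 0.5), c(0.4, 0.5, 1))
  L <- t(chol(C))
  rej <- mean(replicate(2000, {
    X <- matrix(stats::rnorm(50 * 3), 50) %*% t(L)
    r <- stats::cor(X)
    abs(steigerDependentZ(r[1, 2], r[1, 3], r[2, 3], 50)$z) > 1.96
  }))
  expect_lt(abs(rej - 0.05), 0.03)

  expect_error(steigerDependentZ(1, 0.3, 0.4, 50), "strictly")
  expect_error(steigerDependentZ(0.5, 0.3, 0.4, 3), "n >= 4")
})
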