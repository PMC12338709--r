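#' Symmetric percent difference of two positive values
#'
#' 100 * |a - b| / ((a + b) / 2). Using the pair mean as denominator makes
#' the measure symmetric in its arguments. Set `signed = TRUE` to keep the
#' sign of a - b.
#'
#' @param a,b numeric vectors.
#' @param signed keep the sign of `a - b` (default FALSE, magnitudes).
#' @return percent difference(s).
#' @export
percentDifference <- function(a, b, signed = FALSE) {
  denom <- (a + b) / 2
  if (any(!is.finite(denom)) || any(denom <= 0)) {
    stop("pair mean must be positive for a percent difference", call. = FALSE)
  }
  d <- 100 * (a - b) / denom
  if (signed) d else abs(d)
}

#' Within-method percent change between sessions
#'
#' Per participant, the percent change in concentration between the two
#' scan sessions under one segmentation method, summarized across
#' participants as mean and SD. Magnitudes are reported by default (set
#' `signed = TRUE` for directional changes).
#'
#' @param study long-format study table with columns `participant`,
#'   `session`, `method`, `metabolite` and the value column.
#' @param method segmentation method to summarize.
#' @param value name of the value column (default "conc_mM").
#' @param metabolite optional metabolite filter (required when the table
#'   has several).
#' @param signed see [percentDifference()].
#' @return one-row data.frame: scope, labels, metabolite, mean_pct, sd_pct,
#'   n; attribute `per_participant` holds the per-participant values.
#' @export
sessionPercentChange <- function(study, method, value = "conc_mM",
                                 metabolite = NULL, signed = FALSE) {
  d <- study[study$method == method, , drop = FALSE]
  if (!is.null(metabolite)) d <- d[d$metabolite == metabolite, , drop = FALSE]
  if (length(unique(d$metabolite)) > 1L) {
    stop("several metabolites present; pass `metabolite`", call. = FALSE)
  }
  if (!nrow(d)) stop("no rows for method: ", method, call. = FALSE)
  s1 <- d[d$session == sort(unique(d$session))[1], ]
  s2 <- d[d$session == sort(unique(d$session))[2], ]
  ids <- sort(unique(d$participant))
  if (!setequal(s1$participant, ids) || !setequal(s2$participant, ids)) {
    stop("unpaired participant: every participant needs both sessions",
         call. = FALSE)
  }
  c1 <- s1[[value]][match(ids, s1$participant)]
  c2 <- s2[[value]][match(ids, s2$participant)]
  pct <- percentDifference(c2, c1, signed = signed)
  out <- data.frame(scope = "within_method_between_sessions",
                    labels = method,
                    metabolite = unique(d$metabolite)[1],
                    mean_pct = mean(pct),
                    sd_pct = stats::sd(pct),
                    n = length(ids),
                    stringsAsFactors = FALSE)
  attr(out, "per_participant") <- stats::setNames(pct, ids)
  out
}

#' Between-method percent difference of session-averaged concentrations
#'
#' For each participant, concentrations are first averaged over sessions
#' within each method; the percent difference between the two methods is
#' then computed per participant (pair-mean denominator) and summarized as
#' mean and SD. A group-level variant — the percent difference of the two
#' method means — is reported alongside, since summaries in the field use
#' either order of averaging.
#'
#' @param study long-format study table (see [sessionPercentChange()]).
#' @param methodA,methodB the two segmentation methods to compare.
#' @inheritParams sessionPercentChange
#' @return one-row data.frame: scope, labels, metabolite, mean_pct, sd_pct,
#'   group_pct, n; attribute `per_participant` as above.
#' @export
betweenMethodPercentDifference <- function(study, methodA, methodB,
                                           value = "conc_mM",
                                           metabolite = NULL,
                                           signed = FALSE) {
  if (identical(methodA, methodB)) {
    stop("methods to compare must be distinct", call. = FALSE)
  }
  d <- study[study$method %in% c(methodA, methodB), , drop = FALSE]
  if (!is.null(metabolite)) d <- d[d$metabolite == metabolite, , drop = FALSE]
  if (length(unique(d$metabolite)) > 1L) {
    stop("several metabolites present; pass `metabolite`", call. = FALSE)
  }
  sessionAvg <- function(mth) {
    dm <- d[d$method == mth, , drop = FALSE]
    if (!nrow(dm)) stop("missing method: ", mth, call. = FALSE)
    tapply(dm[[value]], dm$participant, mean)
  }
  a <- sessionAvg(methodA)
  b <- sessionAvg(methodB)
  ids <- sort(intersect(names(a), names(b)))
  if (!setequal(names(a), names(b))) {
    stop("missing method: both methods required for every participant",
         call. = FALSE)
  }
  a <- a[ids]; b <- b[ids]
  pct <- percentDifference(a, b, signed = signed)
  out <- data.frame(scope = "between_methods",
                    labels = paste(methodA, methodB, sep = " - "),
                    metabolite = unique(d$metabolite)[1],
                    mean_pct = mean(pct),
                    sd_pct = stats::sd(pct),
                    group_pct = percentDifference(mean(a), mean(b),
                                                  signed = signed),
                    n = length(ids),
                    stringsAsFactors = FALSE)
  attr(out, "per_participant") <- stats::setNames(pct, ids)
  out
}

#' Pairwise differences of method marginal means
#'
#' Simple differences mean_A - mean_B for every method pair in canonical
#' (alphabetical) order — the estimates of a Tukey-style pairwise table.
#'
#' @param means named numeric vector of method marginal means.
#' @return data.frame with columns `pair` ("A - B") and `estimate`.
#' @export
pairwiseMethodDeltas <- function(means) {
  if (is.null(names(means)) || length(means) < 2L) {
    stop("need >= 2 named method means", call. = FALSE)
  }
  nm <- sort(names(means))
  pairs <- utils::combn(nm, 2)
  data.frame(
    pair = apply(pairs, 2, paste, collapse = " - "),
    estimate = means[pairs[1, ]] - means[pairs[2, ]],
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Sensitivity of the molar concentration to the CSF fraction
#'
#' d\[M\]/dfCSF at fixed signals, holding the GM:WM ratio fixed while fCSF
#' varies (the perturbation stays on the simplex). CSF enters the
#' correction both through the water-signal composition and through the
#' (1 - fCSF) metabolite-volume denominator, so misestimated CSF fractions
#' bias concentrations disproportionately. Writing the GM+WM split as
#' gamma = fGM/(fGM+fWM), the closed form is
#' d\[M\]/dc = K * dCSF * R_CSF / (1 - c)^2 with
#' K = (S_M/S_H2O) \[H2O\] / R_M — available as `method = "analytic"` —
#' and the default is a central finite difference of
#' [molarConcentration()] with step `delta`.
#'
#' @param f tissue fractions ([TissueFractions-class] or numeric(3)).
#' @param att an [AttenuationFactors-class] object.
#' @param config a [QuantConfig-class] object.
#' @param sMet,sH2O signal amplitudes held fixed (default 1, 1).
#' @param delta finite-difference step on fCSF (default 1e-5).
#' @param method "fd" (central finite difference) or "analytic".
#' @return derivative in mM per unit CSF fraction.
#' @export
csfSensitivity <- function(f, att, config = defaultQuantConfig(),
                           sMet = 1, sH2O = 1, delta = 1e-5,
                           method = c("fd", "analytic")) {
  method <- match.arg(method)
  fv <- drop(fractionMatrix(f))
  csf <- fv["csf"]
  gw <- fv["gm"] + fv["wm"]
  if (gw <= 0) stop("no metabolite-bearing tissue: fCSF >= 1", call. = FALSE)
  gamma <- fv["gm"] / gw
  onSimplex <- function(c) {
    if (c < 0 || c >= 1) {
      stop("perturbation leaves the simplex (fCSF + delta must stay in [0, 1))",
           call. = FALSE)
    }
    c((1 - c) * gamma, (1 - c) * (1 - gamma), c)
  }
  if (method == "analytic") {
    K <- (sMet / sH2O) * 1000 * config@h2oMolar / att@rMet
    return(unname(K * config@densities["csf"] * att@rH2O["csf"] / (1 - csf)^2))
  }
  fLo <- onSimplex(csf - delta)
  fHi <- onSimplex(csf + delta)
  mLo <- molarConcentration(sMet, sH2O, fLo, att, config)
  mHi <- molarConcentration(sMet, sH2O, fHi, att, config)
  (mHi - mLo) / (2 * delta)
}
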