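#' Default quantification configuration
#'
#' Acquisition TE/TR of 35/2000 ms, relative water densities of
#' dGM = 0.78, dWM = 0.65, dCSF = 0.97, pure-water molarity 55.51 mol/L,
#' and 3 T literature water and metabolite relaxation times. The relaxation
#' defaults (seconds) are GM T1/T2 = 1.331/0.110, WM 0.832/0.0799,
#' CSF 4.163/0.503 for water, and 1.35/0.166 for total creatine; they are
#' representative literature substitutes and should be replaced with
#' study-specific values via [quantConfig()] or a config file when
#' available.
#'
#' @return a [QuantConfig-class] object.
#' @export
defaultQuantConfig <- function() {
  quantConfig()
}

#' Construct a quantification configuration
#'
#' @param teMS,trMS echo / repetition time in milliseconds (35 / 2000 by
#'   default). Provide `teS`/`trS` instead for values in seconds; the two
#'   unit forms are mutually exclusive.
#' @param teS,trS echo / repetition time in seconds.
#' @param densities named numeric(3) (gm, wm, csf) relative water densities.
#' @param waterT1,waterT2 named numeric(3) (gm, wm, csf), seconds.
#' @param metabT1,metabT2 named numerics, one entry per metabolite, seconds.
#' @param h2oMolar molarity of pure water, mol/L.
#' @return a [QuantConfig-class] object.
#' @export
quantConfig <- function(teMS = NULL, trMS = NULL, teS = NULL, trS = NULL,
                        densities = c(gm = 0.78, wm = 0.65, csf = 0.97),
                        waterT1 = c(gm = 1.331, wm = 0.832, csf = 4.163),
                        waterT2 = c(gm = 0.110, wm = 0.0799, csf = 0.503),
                        metabT1 = c(tCr = 1.35),
                        metabT2 = c(tCr = 0.166),
                        h2oMolar = 55.51) {
  if (!is.null(teMS) && !is.null(teS)) {
    stop("give TE either in ms (teMS) or in seconds (teS), not both",
         call. = FALSE)
  }
  if (!is.null(trMS) && !is.null(trS)) {
    stop("give TR either in ms (trMS) or in seconds (trS), not both",
         call. = FALSE)
  }
  if (is.null(teS)) teS <- (if (is.null(teMS)) 35 else teMS) / 1000
  if (is.null(trS)) trS <- (if (is.null(trMS)) 2000 else trMS) / 1000
  new("QuantConfig", teS = teS, trS = trS,
      densities = densities[c("gm", "wm", "csf")],
      waterT1 = waterT1[c("gm", "wm", "csf")],
      waterT2 = waterT2[c("gm", "wm", "csf")],
      metabT1 = metabT1, metabT2 = metabT2, h2oMolar = h2oMolar)
}

# Parse a JSON or YAML config file into a list (extension decides the parser).
readConfigFile <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be .json, .yaml or .yml: ", path, call. = FALSE)
  }
}

#' Read a quantification configuration from JSON or YAML
#'
#' Expected keys: `acquisition` (te_ms/tr_ms or te_s/tr_s),
#' `water_relaxation` (gm/wm/csf, each with t1_s and t2_s),
#' `metabolite_relaxation` (per metabolite, t1_s and t2_s), `densities`
#' (gm/wm/csf) and `h2o_molar`. Missing blocks fall back to the defaults of
#' [quantConfig()].
#'
#' @param path path to the config file.
#' @return a [QuantConfig-class] object.
#' @export
readQuantConfig <- function(path) {
  cfg <- readConfigFile(path)
  args <- list()
  acq <- cfg$acquisition
  if (!is.null(acq)) {
    if (!is.null(acq$te_ms)) args$teMS <- acq$te_ms
    if (!is.null(acq$te_s)) args$teS <- acq$te_s
    if (!is.null(acq$tr_ms)) args$trMS <- acq$tr_ms
    if (!is.null(acq$tr_s)) args$trS <- acq$tr_s
  }
  wr <- cfg$water_relaxation
  if (!is.null(wr)) {
    args$waterT1 <- vapply(wr[c("gm", "wm", "csf")], function(x) x$t1_s, 0)
    args$waterT2 <- vapply(wr[c("gm", "wm", "csf")], function(x) x$t2_s, 0)
  }
  mr <- cfg$metabolite_relaxation
  if (!is.null(mr)) {
    args$metabT1 <- vapply(mr, function(x) x$t1_s, 0)
    args$metabT2 <- vapply(mr, function(x) x$t2_s, 0)
  }
  if (!is.null(cfg$densities)) {
    args$densities <- unlist(cfg$densities)[c("gm", "wm", "csf")]
  }
  if (!is.null(cfg$h2o_molar)) args$h2oMolar <- cfg$h2o_molar
  do.call(quantConfig, args)
}

#' Write a quantification configuration to JSON
#'
#' @param config a [QuantConfig-class] object.
#' @param path output path (.json).
#' @return `path`, invisibly.
#' @export
writeQuantConfig <- function(config, path) {
  stopifnot(is(config, "QuantConfig"))
  relax <- function(t1, t2) {
    stats::setNames(
      lapply(seq_along(t1), function(i) list(t1_s = unname(t1[i]),
                                             t2_s = unname(t2[i]))),
      names(t1))
  }
  obj <- list(
    acquisition = list(te_ms = 1000 * config@teS, tr_ms = 1000 * config@trS),
    water_relaxation = relax(config@waterT1, config@waterT2),
    metabolite_relaxation = relax(config@metabT1, config@metabT2),
    densities = as.list(config@densities),
    h2o_molar = config@h2oMolar
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Exponential relaxation attenuation factor
#'
#' Standard exponential model of signal attenuation from T2 decay during
#' the echo time and incomplete T1 recovery over the repetition time:
#' R = exp(-TE/T2) * (1 - exp(-TR/T1)). The factor is strictly between 0
#' and 1 for positive TE and finite TR, decreasing in TE and increasing
#' in TR.
#'
#' @param t1S,t2S longitudinal / transverse relaxation time (s); vectorized.
#' @param teS,trS echo / repetition time (s).
#' @return attenuation factor(s) in (0, 1).
#' @export
attenuationFactor <- function(t1S, t2S, teS, trS) {
  if (any(t1S <= 0) || any(t2S <= 0)) {
    stop("relaxation times must be strictly positive", call. = FALSE)
  }
  if (teS < 0 || trS <= teS) {
    stop("require 0 <= TE < TR", call. = FALSE)
  }
  exp(-teS / t2S) * (1 - exp(-trS / t1S))
}

#' Attenuation factors for all water compartments and one metabolite
#'
#' @param config a [QuantConfig-class] object.
#' @param metabolite name of the metabolite whose relaxation values to use
#'   (must be present in the config; default "tCr").
#' @return an [AttenuationFactors-class] object.
#' @export
attenuationFactors <- function(config, metabolite = "tCr") {
  stopifnot(is(config, "QuantConfig"))
  if (!(metabolite %in% names(config@metabT1))) {
    stop("no relaxation values configured for metabolite: ", metabolite,
         call. = FALSE)
  }
  rH2O <- attenuationFactor(config@waterT1, config@waterT2,
                            config@teS, config@trS)
  rMet <- attenuationFactor(config@metabT1[[metabolite]],
                            config@metabT2[[metabolite]],
                            config@teS, config@trS)
  new("AttenuationFactors", rH2O = rH2O, rMet = unname(rMet))
}

# Accept TissueFractions, a numeric(3), or a 3-column matrix/data.frame;
# returns an n x 3 matrix with columns gm, wm, csf. Rows must sum to 1
# within 0.02 — compositions printed to two decimals are accepted as
# given, without rescaling — and are used exactly as supplied.
fractionMatrix <- function(f) {
  if (is(f, "TissueFractions")) {
    m <- matrix(c(f@fGM, f@fWM, f@fCSF), 1)
  } else if (is.matrix(f) || is.data.frame(f)) {
    m <- as.matrix(f)
    cn <- colnames(m)
    if (!is.null(cn) && all(c("f_gm", "f_wm", "f_csf") %in% cn)) {
      m <- m[, c("f_gm", "f_wm", "f_csf"), drop = FALSE]
    }
    if (ncol(m) != 3L) stop("fractions must have 3 columns", call. = FALSE)
  } else {
    if (length(f) != 3L) stop("fractions must have 3 components", call. = FALSE)
    m <- matrix(as.numeric(f), 1)
  }
  if (any(abs(rowSums(m) - 1) > 0.02)) {
    stop("fractions must be normalized (rows summing to 1)", call. = FALSE)
  }
  colnames(m) <- c("gm", "wm", "csf")
  m
}

#' Water-side tissue-and-relaxation correction factor
#'
#' The composition-dependent part of the water-referenced quantification:
#' (fGM dGM R_GM + fWM dWM R_WM + fCSF dCSF R_CSF) / (1 - fCSF),
#' where d are the compartment water densities and R the water attenuation
#' factors. The (1 - fCSF) denominator excludes CSF from the
#' metabolite-bearing volume. Molar concentration equals
#' (S_M / S_H2O) * correctionFactor / R_M * \[H2O\].
#'
#' @param f tissue fractions: a [TissueFractions-class] object, numeric(3)
#'   (gm, wm, csf), or a matrix/data.frame with columns f_gm/f_wm/f_csf.
#' @param att an [AttenuationFactors-class] object.
#' @param config a [QuantConfig-class] object (supplies densities).
#' @return numeric vector of correction factors (one per fraction row).
#' @export
correctionFactor <- function(f, att, config = defaultQuantConfig()) {
  stopifnot(is(att, "AttenuationFactors"), is(config, "QuantConfig"))
  m <- fractionMatrix(f)
  if (any(m[, "csf"] >= 1 - 1e-9)) {
    stop("no metabolite-bearing tissue: fCSF >= 1", call. = FALSE)
  }
  d <- config@densities
  r <- att@rH2O
  num <- m[, "gm"] * d["gm"] * r["gm"] +
         m[, "wm"] * d["wm"] * r["wm"] +
         m[, "csf"] * d["csf"] * r["csf"]
  unname(num / (1 - m[, "csf"]))
}

#' Water-referenced molar metabolite concentration
#'
#' Converts an observed metabolite/water signal pair into a molar
#' concentration with partial-volume and relaxation correction:
#'
#' \[M\] = (S_M / S_H2O) *
#'   (fGM dGM R_GM + fWM dWM R_WM + fCSF dCSF R_CSF) /
#'   ((1 - fCSF) R_M) * \[H2O\]
#'
#' The number of protons contributing to the metabolite signal is assumed
#' to be absorbed into `sMet` (it is encoded in the fitting basis set), so
#' no proton-count division is applied here.
#'
#' @param sMet,sH2O observed metabolite and water signal amplitudes (same
#'   arbitrary units); vectorized. `sH2O` must be positive.
#' @param f tissue fractions (see [correctionFactor()]).
#' @param att an [AttenuationFactors-class] object.
#' @param config a [QuantConfig-class] object.
#' @return concentration(s) in mM.
#' @export
molarConcentration <- function(sMet, sH2O, f, att,
                               config = defaultQuantConfig()) {
  if (any(sH2O <= 0)) stop("water signal must be positive", call. = FALSE)
  if (any(sMet < 0)) stop("metabolite signal must be nonnegative", call. = FALSE)
  cf <- correctionFactor(f, att, config)
  1000 * (sMet / sH2O) * cf / att@rMet * config@h2oMolar
}

#' Forward signal model (inverse of the quantification equation)
#'
#' Given a true molar concentration and a water amplitude, returns the
#' metabolite amplitude that the quantification equation would map back to
#' that concentration — the generative model used by the synthetic study.
#'
#' @param trueMM true concentration in mM (nonnegative; vectorized).
#' @param f tissue fractions (see [correctionFactor()]).
#' @param att an [AttenuationFactors-class] object.
#' @param config a [QuantConfig-class] object.
#' @param sH2O water amplitude(s), positive.
#' @return metabolite amplitude(s) `sMet` such that
#'   `molarConcentration(sMet, sH2O, f, att, config) == trueMM` to relative
#'   1e-10.
#' @export
forwardSignal <- function(trueMM, f, att, config = defaultQuantConfig(),
                          sH2O = 1) {
  if (any(trueMM < 0)) stop("concentration must be nonnegative", call. = FALSE)
  if (any(sH2O <= 0)) stop("water signal must be positive", call. = FALSE)
  cf <- correctionFactor(f, att, config)
  (trueMM / 1000) * sH2O * att@rMet / (cf * config@h2oMolar)
}

#' Quantify every row of a study table
#'
#' Applies [molarConcentration()] row-wise to a long-format study table
#' with columns `metabolite`, `s_met`, `s_h2o`, `f_gm`, `f_wm`, `f_csf`,
#' using the metabolite column to select relaxation values.
#'
#' @param study a data.frame in the study-table schema.
#' @param config a [QuantConfig-class] object.
#' @return `study` with a `conc_mM` column added (or replaced).
#' @export
quantifyStudy <- function(study, config = defaultQuantConfig()) {
  required <- c("metabolite", "s_met", "s_h2o", "f_gm", "f_wm", "f_csf")
  miss <- setdiff(required, names(study))
  if (length(miss)) {
    stop("study table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  study$conc_mM <- NA_real_
  for (met in unique(study$metabolite)) {
    att <- attenuationFactors(config, met)
    sel <- study$metabolite == met
    study$conc_mM[sel] <- molarConcentration(
      study$s_met[sel], study$s_h2o[sel],
      study[sel, c("f_gm", "f_wm", "f_csf")], att, config)
  }
  study
}
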