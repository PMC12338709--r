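#' @import methods
NULL

#' Tissue-probability maps for GM, WM and CSF on a shared grid
#'
#' Container for the three tissue-probability volumes produced by an
#' anatomical segmentation (gray matter, white matter, CSF), together with
#' the voxel-index-to-world affine of the grid they live on. All three
#' volumes must share shape and affine, and every stored value must be a
#' probability in \[0, 1\].
#'
#' @slot probGM,probWM,probCSF 3-D numeric arrays of tissue probabilities.
#' @slot affine 4x4 matrix mapping 0-based voxel indices to world mm (RAS).
#'
#' @seealso [loadProbabilityMaps()], [extractFractions()]
#' @export
setClass("SegmentationMaps",
  representation(
    probGM = "array",
    probWM = "array",
    probCSF = "array",
    affine = "matrix"
  )
)

setValidity("SegmentationMaps", function(object) {
  msgs <- character()
  dims <- dim(object@probGM)
  if (length(dims) != 3L) {
    msgs <- c(msgs, "probability maps must be 3-D")
  }
  if (!identical(dims, dim(object@probWM)) ||
      !identical(dims, dim(object@probCSF))) {
    msgs <- c(msgs, "grid mismatch: maps do not share a common shape")
  }
  if (!identical(dim(object@affine), c(4L, 4L))) {
    msgs <- c(msgs, "affine must be a 4x4 matrix")
  }
  rng <- range(object@probGM, object@probWM, object@probCSF)
  if (rng[1] < 0 || rng[2] > 1) {
    msgs <- c(msgs, "probabilities must lie in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Geometry of the MRS acquisition voxel
#'
#' The cm-scale MRS box (distinct from the mm-scale image voxels): its
#' center in world mm, its three edge lengths, and a 3x3 rotation whose
#' rows are the unit edge directions. An identity orientation describes an
#' axis-aligned box.
#'
#' @slot centerMM numeric(3), world coordinates of the box center (mm).
#' @slot edgeMM numeric(3), edge lengths (mm), all positive.
#' @slot orientation 3x3 orthonormal matrix, rows = edge directions.
#'
#' @export
setClass("VoxelGeometry",
  representation(
    centerMM = "numeric",
    edgeMM = "numeric",
    orientation = "matrix"
  )
)

setValidity("VoxelGeometry", function(object) {
  msgs <- character()
  if (length(object@centerMM) != 3L) msgs <- c(msgs, "centerMM must have length 3")
  if (length(object@edgeMM) != 3L || any(object@edgeMM <= 0)) {
    msgs <- c(msgs, "edgeMM must be three positive lengths")
  }
  R <- object@orientation
  if (!identical(dim(R), c(3L, 3L))) {
    msgs <- c(msgs, "orientation must be 3x3")
  } else if (max(abs(crossprod(R) - diag(3))) >= 1e-8) {
    msgs <- c(msgs, "orientation must be orthonormal (||R'R - I|| < 1e-8)")
  }
  if (length(msgs)) msgs else TRUE
})

#' Normalized tissue fractions within an MRS voxel
#'
#' Fractional volumes of gray matter, white matter and CSF occupying the
#' MRS voxel. Fractions are unitless, each in \[0, 1\], and sum to 1 within
#' 1e-9 (they are normalized at construction).
#'
#' @slot fGM,fWM,fCSF numeric(1) fractional volumes.
#'
#' @seealso [tissueFractions()], [normalizeFractions()]
#' @export
setClass("TissueFractions",
  representation(fGM = "numeric", fWM = "numeric", fCSF = "numeric")
)

setValidity("TissueFractions", function(object) {
  f <- c(object@fGM, object@fWM, object@fCSF)
  msgs <- character()
  if (length(f) != 3L || any(!is.finite(f))) {
    msgs <- c(msgs, "fractions must be three finite numbers")
  } else {
    if (any(f < -1e-12) || any(f > 1 + 1e-12)) {
      msgs <- c(msgs, "each fraction must lie in [0, 1]")
    }
    if (abs(sum(f) - 1) > 1e-9) {
      msgs <- c(msgs, "fractions must sum to 1 within 1e-9")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Acquisition, relaxation and water-density configuration
#'
#' All quantities needed by the water-referenced tissue-and-relaxation
#' correction: echo and repetition time, compartment-specific water T1/T2,
#' metabolite T1/T2 (averaged over GM and WM), relative water densities of
#' the three compartments, and the molar concentration of pure water.
#' Times are stored in seconds; water molarity in mol/L.
#'
#' @slot teS,trS echo / repetition time in seconds, 0 < TE < TR.
#' @slot densities named numeric(3) (gm, wm, csf), relative water densities.
#' @slot waterT1,waterT2 named numeric(3) (gm, wm, csf), seconds.
#' @slot metabT1,metabT2 named numerics (one entry per metabolite), seconds.
#' @slot h2oMolar molar concentration of pure water, mol/L.
#'
#' @seealso [quantConfig()], [defaultQuantConfig()], [attenuationFactors()]
#' @export
setClass("QuantConfig",
  representation(
    teS = "numeric",
    trS = "numeric",
    densities = "numeric",
    waterT1 = "numeric",
    waterT2 = "numeric",
    metabT1 = "numeric",
    metabT2 = "numeric",
    h2oMolar = "numeric"
  )
)

setValidity("QuantConfig", function(object) {
  msgs <- character()
  if (!(object@teS > 0 && object@teS < object@trS)) {
    msgs <- c(msgs, "require 0 < TE < TR (seconds)")
  }
  cps <- c("gm", "wm", "csf")
  for (sl in c("densities", "waterT1", "waterT2")) {
    v <- slot(object, sl)
    if (!all(cps %in% names(v))) {
      msgs <- c(msgs, sprintf("%s must be named with gm, wm, csf", sl))
    }
  }
  if (any(object@densities <= 0) || any(object@densities > 1)) {
    msgs <- c(msgs, "water densities must lie in (0, 1]")
  }
  if (any(c(object@waterT1, object@waterT2, object@metabT1, object@metabT2) <= 0)) {
    msgs <- c(msgs, "relaxation times must be strictly positive")
  }
  if (any(object@waterT2[cps] > object@waterT1[cps])) {
    msgs <- c(msgs, "water T2 must not exceed T1")
  }
  common <- intersect(names(object@metabT1), names(object@metabT2))
  if (any(object@metabT2[common] > object@metabT1[common])) {
    msgs <- c(msgs, "metabolite T2 must not exceed T1")
  }
  if (object@h2oMolar <= 0) msgs <- c(msgs, "h2oMolar must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Relaxation attenuation factors
#'
#' Unitless signal-attenuation factors from T1 saturation and T2 decay at
#' the acquisition TE/TR: one per water compartment (GM, WM, CSF) and one
#' for the metabolite of interest. All lie in (0, 1], with 1 the
#' fully-relaxed limit (TE = 0, TR much longer than T1).
#'
#' @slot rH2O named numeric(3) (gm, wm, csf).
#' @slot rMet numeric(1).
#'
#' @seealso [attenuationFactors()], [attenuationFactor()]
#' @export
setClass("AttenuationFactors",
  representation(rH2O = "numeric", rMet = "numeric")
)

setValidity("AttenuationFactors", function(object) {
  msgs <- character()
  if (!all(c("gm", "wm", "csf") %in% names(object@rH2O))) {
    msgs <- c(msgs, "rH2O must be named with gm, wm, csf")
  }
  if (any(object@rH2O <= 0) || any(object@rH2O > 1) ||
      object@rMet <= 0 || object@rMet > 1) {
    msgs <- c(msgs, "attenuation factors must lie in (0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Fitted Method-by-Session repeated-measures model
#'
#' Result of fitting the balanced Method x Session model with a participant
#' random intercept to one response: ANOVA-style fixed-effect tests,
#' estimated marginal means with 95% CIs, and the variance components of
#' the participant and residual strata.
#'
#' @slot anova data.frame with columns term, df_num, df_den, F, p.
#' @slot means data.frame of marginal means (factor, level, mean, se, df,
#'   ci_low, ci_high).
#' @slot varcomp named numeric(2): sigma2_participant, sigma2_error.
#' @slot design list describing the design (n participants, method and
#'   session levels, response name, error df).
#'
#' @seealso [methodSessionModel()], [tukeyPairwise()]
#' @export
setClass("MethodSessionFit",
  representation(
    anova = "data.frame",
    means = "data.frame",
    varcomp = "numeric",
    design = "list"
  )
)
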