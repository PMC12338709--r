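#' Configuration of the synthetic test-retest study generator
#'
#' Defines the conditions the generator emulates: a cohort scanned twice,
#' with tissue fractions extracted by three segmentation methods whose
#' method-level mean compositions differ, participant-level anatomical
#' variation shared across methods, an age-linked decline in normalized
#' gray matter, and no systematic session effect. Method mean fractions
#' default to the marginal compositions of the three common tools on a
#' medial parietal voxel (ANTs 0.45/0.33/0.22, FSL 0.43/0.30/0.26,
#' SPM 0.56/0.27/0.17). Between-participant and between-session fraction
#' SDs are not published for this design; the defaults (0.03 and 0.01) are
#' back-derived from the reported 95% CIs of the method means at n = 13.
#'
#' @slot nParticipants cohort size (default 13).
#' @slot methods method names.
#' @slot methodMeans matrix (methods x gm/wm/csf) of mean fractions.
#' @slot participantSD SD of participant-level fraction deviations (simplex
#'   axes; shared across methods and sessions).
#' @slot sessionSD SD of per-row fraction noise.
#' @slot ageRange numeric(2), years (default 19-66).
#' @slot ageGMCorrelation target correlation between age and normalized GM
#'   (default -0.7).
#' @slot metabolite metabolite name (default "tCr").
#' @slot trueConcMM true concentration in mM (default 7.2).
#' @slot concAgeSlope true concentration slope in mM per year (default 0).
#' @slot signalNoiseSD SD of multiplicative (log-scale) signal noise.
#' @slot waterAmplitude water reference amplitude (arbitrary units).
#' @slot sessionOffset optional systematic session-2 shift on the GM/WM
#'   axis (default 0: the session null is exact by construction).
#'
#' @seealso [generatorConfig()], [simulateStudy()]
#' @export
setClass("GeneratorConfig",
  representation(
    nParticipants = "numeric",
    methods = "character",
    methodMeans = "matrix",
    participantSD = "numeric",
    sessionSD = "numeric",
    ageRange = "numeric",
    ageGMCorrelation = "numeric",
    metabolite = "character",
    trueConcMM = "numeric",
    concAgeSlope = "numeric",
    signalNoiseSD = "numeric",
    waterAmplitude = "numeric",
    sessionOffset = "numeric"
  )
)

setValidity("GeneratorConfig", function(object) {
  msgs <- character()
  if (object@nParticipants < 2) msgs <- c(msgs, "need >= 2 participants")
  mm <- object@methodMeans
  if (nrow(mm) != length(object@methods) || ncol(mm) != 3L) {
    msgs <- c(msgs, "methodMeans must be (methods x 3)")
  } else if (any(mm < 0) || any(abs(rowSums(mm) - 1) > 1e-6)) {
    msgs <- c(msgs, "method mean fractions must lie on the unit simplex")
  }
  if (object@participantSD < 0 || object@sessionSD < 0 ||
      object@signalNoiseSD < 0) {
    msgs <- c(msgs, "SDs must be nonnegative")
  }
  if (diff(object@ageRange) < 0) msgs <- c(msgs, "ageRange must be increasing")
  if (abs(object@ageGMCorrelation) > 1) {
    msgs <- c(msgs, "ageGMCorrelation must lie in [-1, 1]")
  }
  if (object@trueConcMM < 0) msgs <- c(msgs, "trueConcMM must be nonnegative")
  if (object@waterAmplitude <= 0) msgs <- c(msgs, "waterAmplitude must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Construct a generator configuration
#'
#' @param nParticipants,methods,methodMeans,participantSD,sessionSD see
#'   [GeneratorConfig-class].
#' @param ageRange,ageGMCorrelation,metabolite,trueConcMM,concAgeSlope see
#'   [GeneratorConfig-class].
#' @param signalNoiseSD,waterAmplitude,sessionOffset see
#'   [GeneratorConfig-class].
#' @return a [GeneratorConfig-class] object.
#' @export
generatorConfig <- function(nParticipants = 13,
                            methods = c("ANTs", "FSL", "SPM"),
                            methodMeans = rbind(
                              ANTs = c(0.45, 0.33, 0.22),
                              FSL = c(0.43, 0.30, 0.26),
                              SPM = c(0.56, 0.27, 0.17)),
                            participantSD = 0.03,
                            sessionSD = 0.01,
                            ageRange = c(19, 66),
                            ageGMCorrelation = -0.7,
                            metabolite = "tCr",
                            trueConcMM = 7.2,
                            concAgeSlope = 0,
                            signalNoiseSD = 0.02,
                            waterAmplitude = 1000,
                            sessionOffset = 0) {
  methodMeans <- as.matrix(methodMeans)
  if (any(abs(rowSums(methodMeans) - 1) > 0.02)) {
    stop("method mean fractions must lie near the unit simplex", call. = FALSE)
  }
  methodMeans <- methodMeans / rowSums(methodMeans)
  rownames(methodMeans) <- methods
  colnames(methodMeans) <- c("gm", "wm", "csf")
  new("GeneratorConfig",
      nParticipants = nParticipants, methods = methods,
      methodMeans = methodMeans, participantSD = participantSD,
      sessionSD = sessionSD, ageRange = as.numeric(ageRange),
      ageGMCorrelation = ageGMCorrelation, metabolite = metabolite,
      trueConcMM = trueConcMM, concAgeSlope = concAgeSlope,
      signalNoiseSD = signalNoiseSD, waterAmplitude = waterAmplitude,
      sessionOffset = sessionOffset)
}

#' Read a generator configuration from JSON or YAML
#'
#' Keys mirror the arguments of [generatorConfig()] in snake_case
#' (`n_participants`, `methods`, `method_means` as a list of 3-vectors per
#' method, `participant_sd`, `session_sd`, `age_range`,
#' `age_gm_correlation`, `metabolite`, `true_conc_mm`, `conc_age_slope`,
#' `signal_noise_sd`, `water_amplitude`, `session_offset`).
#'
#' @param path path to the config file.
#' @return a [GeneratorConfig-class] object.
#' @export
readGeneratorConfig <- function(path) {
  cfg <- readConfigFile(path)
  args <- list()
  grab <- function(key, name) {
    if (!is.null(cfg[[key]])) args[[name]] <<- cfg[[key]]
  }
  grab("n_participants", "nParticipants")
  grab("participant_sd", "participantSD")
  grab("session_sd", "sessionSD")
  grab("age_range", "ageRange")
  grab("age_gm_correlation", "ageGMCorrelation")
  grab("metabolite", "metabolite")
  grab("true_conc_mm", "trueConcMM")
  grab("conc_age_slope", "concAgeSlope")
  grab("signal_noise_sd", "signalNoiseSD")
  grab("water_amplitude", "waterAmplitude")
  grab("session_offset", "sessionOffset")
  if (!is.null(cfg$method_means)) {
    mm <- do.call(rbind, lapply(cfg$method_means, as.numeric))
    args$methods <- names(cfg$method_means)
    args$methodMeans <- mm
  }
  do.call(generatorConfig, args)
}

# Renormalize fraction rows to the simplex, erroring if too many rows
# left it pre-normalization (a sign the configured SDs are unrealistic).
renormalizeRows <- function(m, what) {
  bad <- rowSums(m < 0 | m > 1) > 0
  if (mean(bad) > 0.01) {
    stop("more than 1% of ", what, " draws left the simplex before ",
         "normalization; reduce participantSD/sessionSD", call. = FALSE)
  }
  m[m < 0] <- 0
  m / rowSums(m)
}

#' Generate the tissue-fraction rows of a synthetic study table
#'
#' Each participant receives a latent anatomical deviation shared across
#' methods and sessions, built from two zero-sum simplex axes: a GM/WM
#' axis tied to age (so normalized GM declines with age at the configured
#' target correlation) and an independent CSF-versus-parenchyma axis. Each
#' row (participant x session x method) is the method mean composition
#' plus that deviation plus small per-row session noise, renormalized to
#' the simplex. Session has no systematic effect unless `sessionOffset` is
#' set. Reference (method-independent) compositions for the shared signal
#' model are generated alongside.
#'
#' @param cfg a [GeneratorConfig-class] object.
#' @param seed optional integer seed (fixed seed implies identical output).
#' @return data.frame with columns participant, age, session, method,
#'   f_gm, f_wm, f_csf, ref_gm, ref_wm, ref_csf.
#' @export
generateFractions <- function(cfg, seed = NULL) {
  stopifnot(is(cfg, "GeneratorConfig"))
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(cfg@nParticipants)
  methods <- cfg@methods
  nm <- length(methods)

  age <- stats::runif(n, cfg@ageRange[1], cfg@ageRange[2])
  za <- if (stats::sd(age) > 0) (age - mean(age)) / stats::sd(age) else age * 0
  rho <- cfg@ageGMCorrelation
  u1 <- rho * za + sqrt(1 - rho^2) * stats::rnorm(n)
  u2 <- stats::rnorm(n)
  # zero-sum deviation axes: GM/WM exchange and CSF vs parenchyma
  dev <- cfg@participantSD *
    (outer(u1, c(1, -1, 0)) + outer(u2, c(-0.5, -0.5, 1)))

  grid <- expand.grid(participant = sprintf("P%02d", seq_len(n)),
                      session = 1:2, method = methods,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$participant, grid$session, grid$method), ]
  rownames(grid) <- NULL
  pIdx <- match(grid$participant, sprintf("P%02d", seq_len(n)))

  base <- cfg@methodMeans[grid$method, , drop = FALSE] + dev[pIdx, ]
  base[, 1] <- base[, 1] + cfg@sessionOffset * (grid$session == 2)
  base[, 2] <- base[, 2] - cfg@sessionOffset * (grid$session == 2)
  noise <- matrix(stats::rnorm(nrow(grid) * 3, 0, cfg@sessionSD), ncol = 3)
  f <- renormalizeRows(base + noise, "fraction")

  # reference composition (method-independent) per participant x session
  ps <- unique(grid[c("participant", "session")])
  psIdx <- match(ps$participant, sprintf("P%02d", seq_len(n)))
  refMean <- colMeans(cfg@methodMeans)
  refNoise <- matrix(stats::rnorm(nrow(ps) * 3, 0, cfg@sessionSD), ncol = 3)
  ref <- renormalizeRows(
    matrix(refMean, nrow(ps), 3, byrow = TRUE) + dev[psIdx, ] + refNoise,
    "reference fraction")
  key <- paste(grid$participant, grid$session)
  refRow <- match(key, paste(ps$participant, ps$session))

  data.frame(participant = grid$participant,
             age = age[pIdx],
             session = grid$session,
             method = grid$method,
             f_gm = f[, 1], f_wm = f[, 2], f_csf = f[, 3],
             ref_gm = ref[refRow, 1], ref_wm = ref[refRow, 2],
             ref_csf = ref[refRow, 3],
             stringsAsFactors = FALSE)
}

#' Generate signal amplitudes for a synthetic study table
#'
#' Completes a fraction table with water and metabolite amplitudes via the
#' forward (inverse-quantification) model and multiplicative log-normal
#' noise. With the default `signalBasis = "shared"` one signal pair is
#' generated per participant x session from the participant's reference
#' composition and shared across methods — the acquisition is one physical
#' measurement, and methods differ only in the correction they apply, so
#' between-method concentration differences arise purely from segmentation
#' differences. With `signalBasis = "per_row"` each row's own fractions
#' generate its signal, making quantification recover the true
#' concentration exactly at zero noise (the round-trip identity).
#'
#' @param fractions output of [generateFractions()] (or any table with the
#'   same columns).
#' @param cfg a [GeneratorConfig-class] object.
#' @param config a [QuantConfig-class] object.
#' @param signalBasis "shared" (default) or "per_row".
#' @param seed optional integer seed.
#' @return the table with columns metabolite, s_met, s_h2o, true_conc_mM
#'   added.
#' @export
generateSignals <- function(fractions, cfg, config = defaultQuantConfig(),
                            signalBasis = c("shared", "per_row"),
                            seed = NULL) {
  stopifnot(is(cfg, "GeneratorConfig"), is(config, "QuantConfig"))
  signalBasis <- match.arg(signalBasis)
  if (!is.null(seed)) set.seed(seed)
  att <- attenuationFactors(config, cfg@metabolite)
  ageMid <- mean(cfg@ageRange)
  trueConc <- cfg@trueConcMM + cfg@concAgeSlope * (fractions$age - ageMid)
  if (any(trueConc < 0)) {
    stop("concAgeSlope drives true concentrations negative", call. = FALSE)
  }
  sH2O <- rep(cfg@waterAmplitude, nrow(fractions))

  if (signalBasis == "per_row") {
    basis <- fractions[c("f_gm", "f_wm", "f_csf")]
    eps <- stats::rnorm(nrow(fractions), 0, cfg@signalNoiseSD)
  } else {
    basis <- fractions[c("ref_gm", "ref_wm", "ref_csf")]
    names(basis) <- c("f_gm", "f_wm", "f_csf")
    # one noise draw per participant x session, shared across methods
    key <- paste(fractions$participant, fractions$session)
    uk <- unique(key)
    eps <- stats::rnorm(length(uk), 0, cfg@signalNoiseSD)[match(key, uk)]
  }
  sMet <- forwardSignal(trueConc, basis, att, config, sH2O) * exp(eps)

  fractions$metabolite <- cfg@metabolite
  fractions$s_met <- sMet
  fractions$s_h2o <- sH2O
  fractions$true_conc_mM <- trueConc
  fractions
}

#' Simulate a complete synthetic test-retest study
#'
#' [generateFractions()] followed by [generateSignals()], producing a
#' complete balanced long-format study table ready for [quantifyStudy()].
#'
#' @inheritParams generateSignals
#' @param seed integer seed (fixed seed implies a byte-identical table).
#' @return a study table data.frame.
#' @export
simulateStudy <- function(cfg = generatorConfig(),
                          config = defaultQuantConfig(),
                          seed = NULL,
                          signalBasis = c("shared", "per_row")) {
  if (!is.null(seed)) set.seed(seed)
  frac <- generateFractions(cfg)
  generateSignals(frac, cfg, config, signalBasis = signalBasis)
}

#' Generate 3-D probability-map phantoms with known fractions
#'
#' Builds GM/WM/CSF probability maps on a world-centered isotropic grid
#' with a planar GM/WM interface (optionally smoothed with a Gaussian
#' profile) and an optional sharp CSF slab, together with a function
#' returning the exact analytic tissue fractions of an MRS box — the
#' oracle that voxel-mask extraction is tested against.
#'
#' The analytic fractions are available for (a) axis-aligned boxes and (b)
#' boxes of any orientation whose center lies exactly on the GM/WM plane
#' (where the split is 1/2 by symmetry); other oblique cases have no
#' closed form here and raise an error.
#'
#' @param gridDim grid size per axis (scalar or length 3, >= 8).
#' @param voxelSizeMM isotropic image voxel size in mm.
#' @param planeAxis world axis (1-3) perpendicular to the GM/WM interface.
#' @param planeOffsetMM position of the interface along that axis (mm).
#' @param smoothFWHM FWHM (mm) of the Gaussian interface profile (0 = sharp).
#' @param csfAxis,csfStartMM optional sharp CSF slab: all tissue at
#'   coordinates >= `csfStartMM` along `csfAxis` is CSF. Must differ from
#'   `planeAxis`.
#' @return list with elements `maps` (a [SegmentationMaps-class]) and
#'   `analyticFractions`, a function of a [VoxelGeometry-class] returning
#'   numeric(3) (gm, wm, csf).
#' @export
generatePhantomMaps <- function(gridDim = 32, voxelSizeMM = 2,
                                planeAxis = 1, planeOffsetMM = 0,
                                smoothFWHM = 0,
                                csfAxis = 3, csfStartMM = NULL) {
  if (length(gridDim) == 1L) gridDim <- rep(gridDim, 3L)
  gridDim <- as.integer(gridDim)
  if (any(gridDim < 8L)) stop("grid must be at least 8 per axis", call. = FALSE)
  if (!is.null(csfStartMM) && csfAxis == planeAxis) {
    stop("CSF slab axis must differ from the GM/WM plane axis", call. = FALSE)
  }
  affine <- diag(c(rep(voxelSizeMM, 3), 1))
  affine[1:3, 4] <- -voxelSizeMM * (gridDim - 1) / 2
  coord1 <- function(axis) {
    voxelSizeMM * (seq_len(gridDim[axis]) - 1) + affine[axis, 4]
  }
  ax <- coord1(planeAxis)
  if (smoothFWHM > 0) {
    sigma <- smoothFWHM / (2 * sqrt(2 * log(2)))
    pBelow1 <- stats::pnorm((planeOffsetMM - ax) / sigma)
  } else {
    pBelow1 <- as.numeric(ax < planeOffsetMM)
  }
  expandAlong <- function(v, axis) {
    perm <- c(axis, setdiff(1:3, axis))
    aperm(array(v, gridDim[perm]), order(perm))
  }
  pBelow <- expandAlong(pBelow1, planeAxis)
  pGM <- pBelow
  pWM <- 1 - pBelow
  pCSF <- array(0, gridDim)
  if (!is.null(csfStartMM)) {
    inSlab <- expandAlong(as.numeric(coord1(csfAxis) >= csfStartMM), csfAxis)
    pGM <- pGM * (1 - inSlab)
    pWM <- pWM * (1 - inSlab)
    pCSF <- inSlab
  }
  maps <- segmentationMaps(pGM, pWM, pCSF, affine)

  analyticFractions <- function(geom) {
    stopifnot(is(geom, "VoxelGeometry"))
    R <- geom@orientation
    axisAligned <- max(abs(abs(R) - diag(3))) < 1e-12
    # world-axis half-extent of the (possibly rotated) box
    halfExtent <- function(axis) {
      sum(geom@edgeMM / 2 * abs(R[, axis]))
    }
    # CSF slab coverage
    alpha <- 0
    if (!is.null(csfStartMM)) {
      c0 <- geom@centerMM[csfAxis]
      h <- halfExtent(csfAxis)
      if (csfStartMM >= c0 + h) {
        alpha <- 0
      } else if (csfStartMM <= c0 - h) {
        alpha <- 1
      } else if (axisAligned) {
        alpha <- ((c0 + h) - csfStartMM) / (2 * h)
      } else {
        stop("no closed-form CSF fraction for an oblique box cut by the slab",
             call. = FALSE)
      }
    }
    # GM share of the non-CSF part
    cP <- geom@centerMM[planeAxis]
    hP <- halfExtent(planeAxis)
    if (abs(cP - planeOffsetMM) < 1e-12) {
      beta <- 0.5  # symmetry: any orientation, symmetric smoothing
    } else if (axisAligned && smoothFWHM == 0) {
      beta <- min(1, max(0, (planeOffsetMM - (cP - hP)) / (2 * hP)))
    } else {
      stop("no closed-form GM fraction for this geometry", call. = FALSE)
    }
    c(gm = (1 - alpha) * beta, wm = (1 - alpha) * (1 - beta), csf = alpha)
  }
  list(maps = maps, analyticFractions = analyticFractions)
}

#' Write segmentation maps to NIfTI-1 files
#'
#' @param maps a [SegmentationMaps-class] object.
#' @param prefix output path prefix; files `<prefix>_gm.nii.gz`,
#'   `<prefix>_wm.nii.gz`, `<prefix>_csf.nii.gz` are written with the
#'   maps' affine as sform/qform.
#' @return named character(3) of file paths, invisibly.
#' @export
writeSegmentationMaps <- function(maps, prefix) {
  stopifnot(is(maps, "SegmentationMaps"))
  paths <- c(gm = paste0(prefix, "_gm.nii.gz"),
             wm = paste0(prefix, "_wm.nii.gz"),
             csf = paste0(prefix, "_csf.nii.gz"))
  vols <- list(maps@probGM, maps@probWM, maps@probCSF)
  for (i in 1:3) {
    img <- RNifti::asNifti(vols[[i]])
    RNifti::sform(img) <- structure(maps@affine, code = 2L)
    RNifti::writeNifti(img, paths[i])
  }
  invisible(paths)
}
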