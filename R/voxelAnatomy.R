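#' Construct segmentation maps from arrays
#'
#' @param probGM,probWM,probCSF 3-D arrays of tissue probabilities sharing
#'   one grid. Values outside \[0, 1\] by more than `clampTol` are an error;
#'   smaller excursions (floating-point spill from interpolation or
#'   compression) are clamped.
#' @param affine 4x4 voxel-index (0-based) to world-mm transform.
#' @param clampTol tolerance for out-of-range probabilities (default 1e-3).
#' @return a [SegmentationMaps-class] object.
#' @export
segmentationMaps <- function(probGM, probWM, probCSF, affine = diag(4),
                             clampTol = 1e-3) {
  vols <- list(probGM = probGM, probWM = probWM, probCSF = probCSF)
  vols <- lapply(vols, function(v) {
    v <- array(as.numeric(v), dim = dim(v))  # strip niftiImage attributes
    if (length(dim(v)) != 3L) {
      stop("probability maps must be 3-D volumes", call. = FALSE)
    }
    rng <- range(v)
    if (rng[1] < -clampTol || rng[2] > 1 + clampTol) {
      stop(sprintf(
        "probability values outside [0, 1] beyond tolerance (range %.4g..%.4g)",
        rng[1], rng[2]), call. = FALSE)
    }
    storage.mode(v) <- "double"
    pmin(pmax(v, 0), 1)
  })
  if (!identical(dim(vols$probGM), dim(vols$probWM)) ||
      !identical(dim(vols$probGM), dim(vols$probCSF))) {
    stop("grid mismatch: probability maps do not share a common shape",
         call. = FALSE)
  }
  new("SegmentationMaps",
      probGM = vols$probGM, probWM = vols$probWM, probCSF = vols$probCSF,
      affine = unname(as.matrix(affine)))
}

#' Load GM/WM/CSF probability maps from NIfTI-1 files
#'
#' Reads three tissue-probability volumes (as written by any segmentation
#' tool), verifies that they are 3-D and share one grid and affine, and
#' clamps small floating-point excursions outside \[0, 1\].
#'
#' @param gm,wm,csf paths to NIfTI-1 files (.nii or .nii.gz).
#' @param clampTol see [segmentationMaps()].
#' @return a [SegmentationMaps-class] object with the affine taken verbatim
#'   from the NIfTI header (RAS world mm, 0-based indices).
#' @export
loadProbabilityMaps <- function(gm, wm, csf, clampTol = 1e-3) {
  paths <- c(gm = gm, wm = wm, csf = csf)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("cannot read probability map(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  imgs <- lapply(paths, RNifti::readNifti)
  affines <- lapply(imgs, function(im) unclass(RNifti::xform(im))[1:4, 1:4])
  for (k in 2:3) {
    if (!identical(dim(imgs[[1]]), dim(imgs[[k]]))) {
      stop("grid mismatch: probability maps differ in shape", call. = FALSE)
    }
    if (max(abs(affines[[1]] - affines[[k]])) > 1e-4) {
      stop("grid mismatch: probability maps differ in affine", call. = FALSE)
    }
  }
  segmentationMaps(as.array(imgs$gm), as.array(imgs$wm), as.array(imgs$csf),
                   affine = affines[[1]], clampTol = clampTol)
}

#' Construct an MRS voxel geometry
#'
#' @param centerMM numeric(3), world coordinates of the box center (mm).
#' @param edgeMM edge lengths in mm; a scalar is recycled to an isotropic
#'   box (the common 30 mm case).
#' @param orientation 3x3 orthonormal matrix whose rows are the unit edge
#'   directions; identity (default) for an axis-aligned box.
#' @return a [VoxelGeometry-class] object.
#' @export
voxelGeometry <- function(centerMM, edgeMM = 30, orientation = diag(3)) {
  if (length(edgeMM) == 1L) edgeMM <- rep(edgeMM, 3L)
  new("VoxelGeometry",
      centerMM = as.numeric(centerMM), edgeMM = as.numeric(edgeMM),
      orientation = unname(as.matrix(orientation)))
}

#' Read a voxel geometry from a JSON or YAML config file
#'
#' The file must provide `center_mm` and `edge_mm`; `orientation` (9 numbers,
#' row-major) is optional and defaults to axis-aligned.
#'
#' @param path path to a .json/.yaml/.yml file.
#' @return a [VoxelGeometry-class] object.
#' @export
readVoxelGeometry <- function(path) {
  cfg <- readConfigFile(path)
  if (is.null(cfg$center_mm) || is.null(cfg$edge_mm)) {
    stop("geometry config must define center_mm and edge_mm", call. = FALSE)
  }
  orient <- diag(3)
  if (!is.null(cfg$orientation)) {
    orient <- matrix(as.numeric(unlist(cfg$orientation)), 3, 3, byrow = TRUE)
  }
  voxelGeometry(as.numeric(unlist(cfg$center_mm)),
                as.numeric(unlist(cfg$edge_mm)), orient)
}

#' Build the MRS voxel mask on the image grid
#'
#' Computes, for every image voxel, the fraction of its volume lying inside
#' the (possibly oblique) MRS box. Partial-volume coverage at the box
#' boundary is estimated by placing `supersample^3` regularly spaced
#' subsample points inside each image voxel, so the discretization error of
#' any downstream fraction is bounded by roughly 1/supersample of the
#' boundary voxel layer. The probability maps are never resampled: all
#' work happens on their native grid.
#'
#' @param maps a [SegmentationMaps-class] object (supplies grid and affine).
#' @param geom a [VoxelGeometry-class] object.
#' @param supersample positive integer, subsample points per voxel edge
#'   (default 3).
#' @return a 3-D weight array matching the map grid, values in \[0, 1\].
#'   Attribute `volumeMM3` holds sum(weights) x voxel volume.
#' @export
buildVoxelMask <- function(maps, geom, supersample = 3L) {
  stopifnot(is(maps, "SegmentationMaps"), is(geom, "VoxelGeometry"))
  supersample <- as.integer(supersample)
  if (is.na(supersample) || supersample < 1L) {
    stop("supersample must be a positive integer", call. = FALSE)
  }
  dims <- dim(maps@probGM)
  A <- maps@affine
  Ainv <- solve(A)
  R <- geom@orientation
  half <- geom@edgeMM / 2

  # box corners in world then index space -> bounding box of candidate voxels
  signs <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  cornersW <- t(apply(signs, 1, function(s) geom@centerMM + drop(t(R) %*% (s * half))))
  cornersI <- t(Ainv %*% rbind(t(cornersW), 1))[, 1:3, drop = FALSE]
  lo <- pmax(floor(apply(cornersI, 2, min)) - 1, 0)
  hi <- pmin(ceiling(apply(cornersI, 2, max)) + 1, dims - 1)
  if (any(lo > hi)) {
    stop("voxel outside image: MRS box does not intersect the field of view",
         call. = FALSE)
  }

  idx <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]))
  # subsample offsets: centers of a supersample^3 partition of each voxel
  off1 <- (seq_len(supersample) - 0.5) / supersample - 0.5
  offs <- as.matrix(expand.grid(off1, off1, off1))

  inside <- numeric(nrow(idx))
  for (q in seq_len(nrow(offs))) {
    pts <- sweep(idx, 2, offs[q, ], "+")                 # index space, 0-based
    w <- A %*% rbind(t(pts), 1)                          # world mm
    u <- R %*% (w[1:3, , drop = FALSE] - geom@centerMM)  # box coordinates
    ok <- abs(u[1, ]) <= half[1] + 1e-12 &
          abs(u[2, ]) <= half[2] + 1e-12 &
          abs(u[3, ]) <= half[3] + 1e-12
    inside <- inside + ok
  }
  wts <- inside / nrow(offs)
  if (sum(wts) == 0) {
    stop("voxel outside image: MRS box does not intersect the field of view",
         call. = FALSE)
  }
  mask <- array(0, dims)
  mask[idx + 1L] <- wts
  voxVol <- abs(det(A[1:3, 1:3]))
  attr(mask, "volumeMM3") <- sum(wts) * voxVol
  mask
}

#' Extract normalized tissue fractions within a voxel mask
#'
#' Weighted mean probability of each tissue class inside the mask, followed
#' by sum-to-one normalization:
#' f_x = sum(w * p_x) / sum(w * (p_gm + p_wm + p_csf)).
#'
#' @param maps a [SegmentationMaps-class] object.
#' @param mask weight volume from [buildVoxelMask()] (same grid).
#' @return a [TissueFractions-class] object. Attribute `qc` holds the
#'   pre-normalization mean probability sum and the mask volume in mm^3.
#' @export
extractFractions <- function(maps, mask) {
  stopifnot(is(maps, "SegmentationMaps"))
  if (!identical(dim(maps@probGM), dim(mask))) {
    stop("grid mismatch: mask does not match the probability maps", call. = FALSE)
  }
  wSum <- sum(mask)
  if (wSum <= 0) stop("mask has zero total weight", call. = FALSE)
  raw <- c(gm = sum(mask * maps@probGM),
           wm = sum(mask * maps@probWM),
           csf = sum(mask * maps@probCSF)) / wSum
  if (sum(raw) < 0.5) {
    stop("insufficient brain coverage: probabilities inside the voxel sum to ",
         sprintf("%.3f", sum(raw)), call. = FALSE)
  }
  f <- normalizeFractions(raw)
  attr(f, "qc") <- list(preNormalizationSum = unname(sum(raw)),
                        maskVolumeMM3 = attr(mask, "volumeMM3"))
  f
}

#' Normalize raw tissue fractions to sum to one
#'
#' Divides three nonnegative components by their sum so the result lies on
#' the unit simplex. A pre-normalization sum below 0.5 means the voxel is
#' mostly non-brain, where rescaling would silently amplify noise, so it is
#' rejected instead.
#'
#' @param raw numeric(3) of nonnegative values (gm, wm, csf order), or a
#'   [TissueFractions-class] object (returned unchanged).
#' @return a [TissueFractions-class] object.
#' @export
normalizeFractions <- function(raw) {
  if (is(raw, "TissueFractions")) return(raw)
  raw <- as.numeric(raw)
  if (length(raw) != 3L || any(!is.finite(raw)) || any(raw < 0)) {
    stop("raw fractions must be three finite nonnegative numbers", call. = FALSE)
  }
  s <- sum(raw)
  if (s < 0.5) {
    stop(sprintf("degenerate fractions: pre-normalization sum %.3f < 0.5", s),
         call. = FALSE)
  }
  f <- raw / s
  new("TissueFractions", fGM = f[1], fWM = f[2], fCSF = f[3])
}

#' Construct tissue fractions directly
#'
#' @param fGM,fWM,fCSF nonnegative fractions; normalized to sum to one.
#' @return a [TissueFractions-class] object.
#' @export
tissueFractions <- function(fGM, fWM, fCSF) {
  normalizeFractions(c(fGM, fWM, fCSF))
}
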