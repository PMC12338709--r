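#' @rdname SegmentationMaps-class
#' @param object,x an object.
#' @export
setGeneric("affineMatrix", function(x) standardGeneric("affineMatrix"))

#' @rdname TissueFractions-class
#' @export
setGeneric("fGM", function(x) standardGeneric("fGM"))

#' @rdname TissueFractions-class
#' @export
setGeneric("fWM", function(x) standardGeneric("fWM"))

#' @rdname TissueFractions-class
#' @export
setGeneric("fCSF", function(x) standardGeneric("fCSF"))

#' @rdname MethodSessionFit-class
#' @export
setGeneric("anovaTable", function(x) standardGeneric("anovaTable"))

#' @rdname MethodSessionFit-class
#' @export
setGeneric("marginalMeans", function(x, factor = "method") {
  standardGeneric("marginalMeans")
})

#' @export
#' @rdname SegmentationMaps-class
setMethod("affineMatrix", "SegmentationMaps", function(x) x@affine)

#' @export
#' @rdname TissueFractions-class
setMethod("fGM", "TissueFractions", function(x) x@fGM)

#' @export
#' @rdname TissueFractions-class
setMethod("fWM", "TissueFractions", function(x) x@fWM)

#' @export
#' @rdname TissueFractions-class
setMethod("fCSF", "TissueFractions", function(x) x@fCSF)

#' @export
#' @rdname MethodSessionFit-class
setMethod("anovaTable", "MethodSessionFit", function(x) x@anova)

#' @export
#' @rdname MethodSessionFit-class
setMethod("marginalMeans", "MethodSessionFit", function(x, factor = "method") {
  factor <- match.arg(factor, c("method", "session"))
  x@means[x@means$factor == factor, , drop = FALSE]
})

setMethod("show", "SegmentationMaps", function(object) {
  d <- dim(object@probGM)
  cat(sprintf("SegmentationMaps: %d x %d x %d grid (GM/WM/CSF probabilities)\n",
              d[1], d[2], d[3]))
  sp <- sqrt(colSums(object@affine[1:3, 1:3]^2))
  cat(sprintf("  voxel spacing (mm): %.3g x %.3g x %.3g\n", sp[1], sp[2], sp[3]))
})

setMethod("show", "VoxelGeometry", function(object) {
  cat(sprintf("VoxelGeometry: %g x %g x %g mm box at (%.1f, %.1f, %.1f) mm\n",
              object@edgeMM[1], object@edgeMM[2], object@edgeMM[3],
              object@centerMM[1], object@centerMM[2], object@centerMM[3]))
  if (max(abs(object@orientation - diag(3))) < 1e-12) {
    cat("  axis-aligned\n")
  } else {
    cat("  oblique orientation\n")
  }
})

setMethod("show", "TissueFractions", function(object) {
  cat(sprintf("TissueFractions: fGM = %.4f, fWM = %.4f, fCSF = %.4f\n",
              object@fGM, object@fWM, object@fCSF))
})

setMethod("show", "QuantConfig", function(object) {
  cat(sprintf("QuantConfig: TE = %g ms, TR = %g ms, [H2O] = %.2f mol/L\n",
              1000 * object@teS, 1000 * object@trS, object@h2oMolar))
  cat(sprintf("  water densities (GM/WM/CSF): %.2f / %.2f / %.2f\n",
              object@densities["gm"], object@densities["wm"],
              object@densities["csf"]))
  cat(sprintf("  metabolites with relaxation values: %s\n",
              paste(names(object@metabT1), collapse = ", ")))
})

setMethod("show", "AttenuationFactors", function(object) {
  cat(sprintf(
    "AttenuationFactors: R_H2O (GM/WM/CSF) = %.3f / %.3f / %.3f; R_M = %.3f\n",
    object@rH2O["gm"], object@rH2O["wm"], object@rH2O["csf"], object@rMet))
})

setMethod("show", "MethodSessionFit", function(object) {
  cat(sprintf("MethodSessionFit for '%s': %d participants x %d methods x %d sessions\n",
              object@design$response, object@design$n,
              length(object@design$methods), length(object@design$sessions)))
  print(object@anova, row.names = FALSE, digits = 4)
})

#' Coerce tissue fractions to a named numeric vector
#'
#' @param x a [TissueFractions-class] object.
#' @param ... ignored.
#' @return named numeric(3) with elements gm, wm, csf.
#' @export
setMethod("as.numeric", "TissueFractions", function(x, ...) {
  c(gm = x@fGM, wm = x@fWM, csf = x@fCSF)
})
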