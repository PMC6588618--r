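#' @useDynLib dualmark, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats coef cor cor.test dnorm filter lm na.omit p.adjust pnorm
#'   pt qnorm quantile rnorm runif sd setNames t.test var
NULL

#' Spatial network template
#'
#' A set of K Z-valued 3-D spatial maps on a common voxel grid, used as the
#' spatial design of dual regression. The canonical example in the field is a
#' 10-network resting-state template; the synthetic generator
#' \code{\link{makeTemplate}} builds a desk-scale surrogate with known blob
#' locations.
#'
#' @slot maps 4-D numeric array, X x Y x Z x K, Z-valued spatial maps.
#' @slot voxelSizeMm numeric(3), voxel edge lengths in mm.
#' @slot blobCenters list of K integer(3) voxel coordinates (peak locations;
#'   may be empty for templates loaded from file).
#' @slot templateId character scalar identifier.
#' @export
setClass("NetworkTemplate",
  representation(maps = "array", voxelSizeMm = "numeric",
                 blobCenters = "list", templateId = "character"),
  prototype(voxelSizeMm = c(2, 2, 2), blobCenters = list(),
            templateId = "template"))

setValidity("NetworkTemplate", function(object) {
  d <- dim(object@maps)
  if (length(d) != 4L) return("maps must be a 4-D array (X, Y, Z, K)")
  if (length(object@voxelSizeMm) != 3L || any(object@voxelSizeMm <= 0))
    return("voxelSizeMm must be 3 positive reals")
  if (any(!is.finite(object@maps))) return("maps contain non-finite values")
  TRUE
})

#' Ground truth of a synthetic cohort
#'
#' Records where and how strongly the two groups differ, the temporal noise
#' model, and the phenotype-score generating loadings, so that every
#' downstream recovery claim can be checked against a known answer.
#'
#' @slot effectRegions named list; each element (named by component index)
#'   is a list with integer vectors \code{pos} and \code{neg} of linear voxel
#'   indices where the ASD group's component amplitude is raised / lowered.
#' @slot effectSize group amplitude difference within an effect region, in
#'   units of the temporal noise SD.
#' @slot noiseSd marginal SD of the AR(1) voxel noise.
#' @slot ar1Coef AR(1) coefficient in [0, 1).
#' @slot subjectAmpSd between-subject SD of the per-subject amplitude factor,
#'   same units as \code{effectSize}.
#' @slot signalScale BOLD amplitude per unit template Z (default 0.15, i.e.
#'   a Z = 6.7 template voxel carries signal of about one noise SD).
#' @slot phenotypeLoadings data.frame with columns \code{score},
#'   \code{component}, \code{r}: target population correlation between a
#'   questionnaire score and the true biomarker of a component.
#' @slot timecourses list of per-subject T x K matrices (filled by
#'   \code{\link{simulateCohort}}).
#' @slot trueBiomarkers numeric matrix subjects x K of true per-subject
#'   amplitude offsets (filled by \code{\link{simulateCohort}}).
#' @export
setClass("GroundTruth",
  representation(effectRegions = "list", effectSize = "numeric",
                 noiseSd = "numeric", ar1Coef = "numeric",
                 subjectAmpSd = "numeric", signalScale = "numeric",
                 phenotypeLoadings = "data.frame",
                 timecourses = "list", trueBiomarkers = "matrix"),
  prototype(effectRegions = list(), effectSize = 1.5, noiseSd = 1,
            ar1Coef = 0.3, subjectAmpSd = 0.5, signalScale = 0.15,
            phenotypeLoadings = data.frame(score = character(),
                                           component = integer(),
                                           r = numeric()),
            timecourses = list(), trueBiomarkers = matrix(0, 0, 0)))

setValidity("GroundTruth", function(object) {
  if (object@ar1Coef < 0 || object@ar1Coef >= 1)
    return("ar1Coef must lie in [0, 1)")
  if (object@noiseSd <= 0) return("noiseSd must be positive")
  for (er in object@effectRegions) {
    if (length(intersect(er$pos, er$neg)) > 0)
      return("positive and negative effect regions must be disjoint")
  }
  if (nrow(object@phenotypeLoadings) &&
      any(abs(object@phenotypeLoadings$r) > 1))
    return("phenotype loadings must be correlations in [-1, 1]")
  TRUE
})

#' One synthetic subject
#'
#' @slot subjectId character scalar.
#' @slot group \code{"ASD"} or \code{"TD"}.
#' @slot bold 4-D numeric array X x Y x Z x T.
#' @slot motion6 T x 6 matrix (3 rotations then 3 translations).
#' @slot wmMask,csfMask 3-D logical arrays, mutually disjoint.
#' @slot scores named numeric(9) of questionnaire scores.
#' @export
setClass("SyntheticSubject",
  representation(subjectId = "character", group = "character",
                 bold = "array", motion6 = "matrix",
                 wmMask = "array", csfMask = "array", scores = "numeric"))

setValidity("SyntheticSubject", function(object) {
  d <- dim(object@bold)
  if (length(d) != 4L) return("bold must be 4-D (X, Y, Z, T)")
  if (d[4] < 30L) return("bold must have at least 30 time points")
  if (!all(is.finite(range(object@bold))))
    return("bold contains non-finite values")
  if (!object@group %in% c("ASD", "TD")) return("group must be ASD or TD")
  if (nrow(object@motion6) != d[4] || ncol(object@motion6) != 6L)
    return("motion6 must be T x 6")
  if (any(object@wmMask & object@csfMask))
    return("wmMask and csfMask must be disjoint")
  TRUE
})

#' Confound-cleaned 4-D time series
#'
#' @slot data 4-D numeric array X x Y x Z x T after cleaning.
#' @slot trSec repetition time in seconds.
#' @slot bandHz numeric(2), band-pass edges in Hz.
#' @slot fwhmMm smoothing kernel FWHM in mm (0 = none).
#' @slot provenance character vector of applied steps, in order.
#' @slot voxelSizeMm numeric(3).
#' @export
setClass("CleanedBold",
  representation(data = "array", trSec = "numeric", bandHz = "numeric",
                 fwhmMm = "numeric", provenance = "character",
                 voxelSizeMm = "numeric"),
  prototype(bandHz = c(0.01, 0.08), fwhmMm = 6, provenance = character(),
            voxelSizeMm = c(2, 2, 2)))

setValidity("CleanedBold", function(object) {
  if (length(dim(object@data)) != 4L) return("data must be 4-D")
  if (object@trSec <= 0) return("trSec must be positive")
  TRUE
})

#' Per-subject dual-regression output
#'
#' K per-subject functional-connectivity Z-maps (stage 2) and the stage-1
#' network time-courses they were computed from.
#'
#' @slot subjectId character scalar.
#' @slot zmaps 4-D numeric array X x Y x Z x K of beta/SE values.
#' @slot timecourses T x K matrix of stage-1 time-courses.
#' @slot templateId template identifier.
#' @slot dof residual degrees of freedom (T - K - 1).
#' @export
setClass("SubjectNetworkMaps",
  representation(subjectId = "character", zmaps = "array",
                 timecourses = "matrix", templateId = "character",
                 dof = "numeric"))

setValidity("SubjectNetworkMaps", function(object) {
  if (length(dim(object@zmaps)) != 4L) return("zmaps must be 4-D")
  if (dim(object@zmaps)[4] != ncol(object@timecourses))
    return("component count mismatch between zmaps and timecourses")
  if (object@dof <= 0) return("dof must be positive (need T > K + 1)")
  TRUE
})

#' TFCE parameters
#'
#' @slot E extent exponent (default 0.5).
#' @slot H height exponent (default 2).
#' @slot nSteps number of threshold integration steps (default 100).
#' @slot connectivity 6, 18 or 26 (default 26).
#' @export
setClass("TfceParams",
  representation(E = "numeric", H = "numeric", nSteps = "integer",
                 connectivity = "integer"),
  prototype(E = 0.5, H = 2, nSteps = 100L, connectivity = 26L))

setValidity("TfceParams", function(object) {
  if (object@E < 0 || object@H < 0) return("E and H must be >= 0")
  if (object@nSteps < 10L) return("nSteps must be >= 10")
  if (!object@connectivity %in% c(6L, 18L, 26L))
    return("connectivity must be 6, 18 or 26")
  TRUE
})

#' TfceParams constructor
#' @param E,H TFCE extent and height exponents.
#' @param nSteps integration steps.
#' @param connectivity 6, 18 or 26.
#' @return A \linkS4class{TfceParams} object.
#' @export
TfceParams <- function(E = 0.5, H = 2, nSteps = 100L, connectivity = 26L) {
  new("TfceParams", E = E, H = H, nSteps = as.integer(nSteps),
      connectivity = as.integer(connectivity))
}

#' Group inference result for one component
#'
#' @slot tmap 3-D pooled-variance two-sample t map (group A minus group B).
#' @slot tfcePos,tfceNeg 3-D TFCE-enhanced maps for each direction.
#' @slot pfwePos,pfweNeg 3-D FWE-corrected p maps in (0, 1].
#' @slot nPerm number of relabelings used (observed labeling included).
#' @slot seed RNG seed used for Monte-Carlo relabelings.
#' @slot exhaustive TRUE if all distinct relabelings were enumerated.
#' @export
setClass("InferenceResult",
  representation(tmap = "array", tfcePos = "array", tfceNeg = "array",
                 pfwePos = "array", pfweNeg = "array", nPerm = "integer",
                 seed = "integer", exhaustive = "logical"))

setValidity("InferenceResult", function(object) {
  if (any(object@pfwePos < 1 / object@nPerm - 1e-12) ||
      any(object@pfweNeg < 1 / object@nPerm - 1e-12))
    return("corrected p-values cannot fall below 1/nPerm")
  if (any(object@pfwePos > 1) || any(object@pfweNeg > 1))
    return("corrected p-values cannot exceed 1")
  TRUE
})

#' Labeled binary mask set
#'
#' Holds the template-threshold masks (R1..RK) and group-difference masks
#' (A1..A2K; first K = group A greater, last K = group A smaller), with the
#' component and direction bookkeeping needed to extract biomarkers.
#'
#' @slot masks named list of 3-D logical arrays.
#' @slot networkOf named integer vector: mask name -> component index.
#' @slot directionOf named character vector: \code{"ASD>TD"}, \code{"ASD<TD"}
#'   or \code{NA} for R-masks.
#' @slot volumesMm3 named numeric vector of mask volumes.
#' @slot voxelSizeMm numeric(3).
#' @export
setClass("MaskSet",
  representation(masks = "list", networkOf = "integer",
                 directionOf = "character", volumesMm3 = "numeric",
                 voxelSizeMm = "numeric"))

setValidity("MaskSet", function(object) {
  nm <- names(object@masks)
  if (is.null(nm) || anyDuplicated(nm)) return("masks must be uniquely named")
  if (!identical(nm, names(object@networkOf)) ||
      !identical(nm, names(object@volumesMm3)))
    return("networkOf / volumesMm3 names must match mask names")
  # every A-mask must be nested in its R counterpart
  for (n in nm[startsWith(nm, "A")]) {
    k <- object@networkOf[[n]]
    rn <- paste0("R", k)
    if (rn %in% nm && any(object@masks[[n]] & !object@masks[[rn]]))
      return(sprintf("%s is not a subset of %s", n, rn))
  }
  TRUE
})

#' Biomarker matrix container
#'
#' A \linkS4class{SummarizedExperiment} subclass with one assay
#' (\code{"biomarkers"}, masks x subjects), group labels and questionnaire
#' scores in \code{colData}, and mask bookkeeping in \code{rowData}.
#'
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @export
setClass("BiomarkerMatrix", contains = "SummarizedExperiment")

## ---- accessors and show methods ----

#' @describeIn NetworkTemplate number of template components
#' @param object a NetworkTemplate.
#' @export
setMethod("length", "NetworkTemplate", function(x) dim(x@maps)[4])

#' Template maps accessor
#' @param x a \linkS4class{NetworkTemplate}.
#' @return the 4-D map array.
#' @export
templateMaps <- function(x) x@maps

#' Voxel size accessor
#' @param x an object with a voxel size slot.
#' @return numeric(3) voxel edge lengths in mm.
#' @export
voxelSize <- function(x) x@voxelSizeMm

#' Mask list accessor
#' @param x a \linkS4class{MaskSet}.
#' @return named list of logical 3-D arrays.
#' @export
maskList <- function(x) x@masks

#' Mask volumes accessor
#' @param x a \linkS4class{MaskSet}.
#' @return named numeric vector of volumes in mm^3.
#' @export
maskVolumes <- function(x) x@volumesMm3

#' Biomarker values accessor
#' @param x a \linkS4class{BiomarkerMatrix}.
#' @return subjects x masks numeric matrix (transposed assay).
#' @export
biomarkerValues <- function(x)
  t(SummarizedExperiment::assay(x, "biomarkers"))

#' Subject group labels accessor
#' @param x a \linkS4class{BiomarkerMatrix}.
#' @return character vector of group labels.
#' @export
groupLabels <- function(x) as.character(SummarizedExperiment::colData(x)$group)

setMethod("show", "NetworkTemplate", function(object) {
  d <- dim(object@maps)
  cat(sprintf("NetworkTemplate '%s': %d components on a %dx%dx%d grid (%s mm)\n",
              object@templateId, d[4], d[1], d[2], d[3],
              paste(object@voxelSizeMm, collapse = "x")))
})

setMethod("show", "SyntheticSubject", function(object) {
  d <- dim(object@bold)
  cat(sprintf("SyntheticSubject %s [%s]: %dx%dx%d x %d time points\n",
              object@subjectId, object@group, d[1], d[2], d[3], d[4]))
})

setMethod("show", "CleanedBold", function(object) {
  d <- dim(object@data)
  cat(sprintf("CleanedBold: %dx%dx%d x %d, TR %.2g s, band %.3g-%.3g Hz\n",
              d[1], d[2], d[3], d[4], object@trSec,
              object@bandHz[1], object@bandHz[2]))
  cat("  provenance:", paste(object@provenance, collapse = " -> "), "\n")
})

setMethod("show", "SubjectNetworkMaps", function(object) {
  d <- dim(object@zmaps)
  cat(sprintf("SubjectNetworkMaps %s: %d maps on %dx%dx%d (dof %d)\n",
              object@subjectId, d[4], d[1], d[2], d[3], object@dof))
})

setMethod("show", "InferenceResult", function(object) {
  cat(sprintf("InferenceResult: %d permutations%s, min pFWE (pos) %.4g, (neg) %.4g\n",
              object@nPerm, if (object@exhaustive) " (exhaustive)" else "",
              min(object@pfwePos), min(object@pfweNeg)))
})

setMethod("show", "MaskSet", function(object) {
  nz <- sum(vapply(object@masks, any, logical(1)))
  cat(sprintf("MaskSet: %d masks (%d non-empty), total volume %.0f mm^3\n",
              length(object@masks), nz, sum(object@volumesMm3)))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: effect size %.2g (noise SD %.2g, AR1 %.2g) in component(s) %s\n",
              object@effectSize, object@noiseSd, object@ar1Coef,
              paste(names(object@effectRegions), collapse = ", ")))
})
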