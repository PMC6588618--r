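## R-mask / A-mask construction and mask-averaged biomarker extraction.

#' Build template-threshold R-masks
#'
#' R-mask k is the set of voxels with template Z value strictly above the
#' threshold (default 4). Empty masks are allowed and recorded with volume 0.
#'
#' @param template a \linkS4class{NetworkTemplate}.
#' @param zThreshold strict lower Z cutoff (default 4).
#' @return named list of 3-D logical arrays \code{R1..RK} with attribute
#'   \code{volumesMm3}.
#' @export
buildRMasks <- function(template, zThreshold = 4) {
  if (zThreshold <= 0) stop("zThreshold must be positive")
  maps <- templateMaps(template)
  k <- dim(maps)[4]
  voxVol <- prod(voxelSize(template))
  masks <- lapply(seq_len(k), function(j) maps[, , , j] > zThreshold)
  names(masks) <- paste0("R", seq_len(k))
  attr(masks, "volumesMm3") <-
    setNames(vapply(masks, sum, numeric(1)) * voxVol, names(masks))
  masks
}

#' Build group-difference A-masks
#'
#' A-mask k (direction group A > group B) is the set of voxels significant
#' in the positive contrast (FWE-corrected p strictly below \code{alpha})
#' intersected with R-mask k; A-mask k+K uses the negative contrast. Empty
#' masks are recorded with volume 0.
#'
#' @param results list of K \linkS4class{InferenceResult} objects, one per
#'   component, on the same grid as the R-masks.
#' @param rMasks output of \code{\link{buildRMasks}}.
#' @param alpha FWE significance level (default 0.05, strict).
#' @param voxelSizeMm numeric(3) for volume bookkeeping.
#' @return named list of 3-D logical arrays \code{A1..A2K} with attribute
#'   \code{volumesMm3}.
#' @export
buildAMasks <- function(results, rMasks, alpha = 0.05,
                        voxelSizeMm = c(2, 2, 2)) {
  k <- length(rMasks)
  if (length(results) != k)
    stop(sprintf("component count mismatch: %d inference results for %d R-masks",
                 length(results), k))
  voxVol <- prod(voxelSizeMm)
  masks <- vector("list", 2 * k)
  for (j in seq_len(k)) {
    res <- results[[j]]
    if (!identical(dim(res@pfwePos), dim(rMasks[[j]])))
      stop("inference result grid does not match mask grid for component ", j)
    masks[[j]] <- (res@pfwePos < alpha) & rMasks[[j]]
    masks[[j + k]] <- (res@pfweNeg < alpha) & rMasks[[j]]
  }
  names(masks) <- c(paste0("A", seq_len(k)), paste0("A", k + seq_len(k)))
  attr(masks, "volumesMm3") <-
    setNames(vapply(masks, sum, numeric(1)) * voxVol, names(masks))
  masks
}

#' Assemble a full mask set
#'
#' Combines R- and A-masks into a \linkS4class{MaskSet} with the fixed
#' ordering R1..RK, A1..A2K and the component/direction bookkeeping
#' (A_k and A_{k+K} both map to component k; the first K A-masks are the
#' \code{ASD>TD} direction, the rest \code{ASD<TD}).
#'
#' @param rMasks output of \code{\link{buildRMasks}}.
#' @param aMasks output of \code{\link{buildAMasks}}.
#' @param voxelSizeMm numeric(3).
#' @return a \linkS4class{MaskSet}.
#' @export
makeMaskSet <- function(rMasks, aMasks, voxelSizeMm = c(2, 2, 2)) {
  k <- length(rMasks)
  if (length(aMasks) != 2 * k)
    stop("need exactly 2 A-masks per R-mask")
  masks <- c(rMasks, aMasks)
  attributes(masks) <- list(names = c(names(rMasks), names(aMasks)))
  networkOf <- setNames(c(seq_len(k), seq_len(k), seq_len(k)), names(masks))
  directionOf <- setNames(c(rep(NA_character_, k), rep("ASD>TD", k),
                            rep("ASD<TD", k)), names(masks))
  voxVol <- prod(voxelSizeMm)
  volumes <- setNames(vapply(masks, sum, numeric(1)) * voxVol, names(masks))
  new("MaskSet", masks = masks, networkOf = networkOf,
      directionOf = directionOf, volumesMm3 = volumes,
      voxelSizeMm = voxelSizeMm)
}

#' Extract mask-averaged biomarkers for one subject
#'
#' The biomarker for mask m is the unweighted arithmetic mean of the
#' subject's component-c(m) FC Z-map over the voxels of m; NA where the mask
#' is empty.
#'
#' @param subjectMaps a \linkS4class{SubjectNetworkMaps}.
#' @param maskSet a \linkS4class{MaskSet}.
#' @return named numeric vector, one value per mask.
#' @export
extractBiomarkers <- function(subjectMaps, maskSet) {
  zm <- subjectMaps@zmaps
  if (!identical(dim(zm)[1:3], dim(maskSet@masks[[1]])))
    stop("subject map grid does not match mask grid")
  out <- setNames(rep(NA_real_, length(maskSet@masks)),
                  names(maskSet@masks))
  for (nm in names(maskSet@masks)) {
    m <- maskSet@masks[[nm]]
    if (!any(m)) next
    cmp <- maskSet@networkOf[[nm]]
    out[nm] <- mean(zm[, , , cmp][m])
  }
  out
}

#' Assemble the biomarker matrix
#'
#' Joins per-subject biomarker vectors with the phenotype table into a
#' \linkS4class{BiomarkerMatrix} (a \code{SummarizedExperiment}: assay =
#' masks x subjects, colData = group + questionnaire scores, rowData = mask
#' bookkeeping). Subjects are ordered by id; missing values from empty
#' masks propagate.
#'
#' @param biomarkerList named list (by subject id) of vectors from
#'   \code{\link{extractBiomarkers}}.
#' @param phenotypes data.frame with columns \code{subject_id},
#'   \code{group}, and score columns.
#' @param maskSet the \linkS4class{MaskSet} used (for rowData).
#' @param cohort cohort tag stored in metadata (e.g. \code{"validation"}).
#' @return a \linkS4class{BiomarkerMatrix}.
#' @export
assembleBiomarkerMatrix <- function(biomarkerList, phenotypes, maskSet,
                                    cohort = "cohort") {
  ids <- names(biomarkerList)
  if (is.null(ids)) stop("biomarkerList must be named by subject id")
  orphanB <- setdiff(ids, phenotypes$subject_id)
  orphanP <- setdiff(phenotypes$subject_id, ids)
  if (length(orphanB) || length(orphanP))
    stop("subject/phenotype mismatch; biomarkers without phenotype: [",
         paste(orphanB, collapse = ", "), "], phenotype without biomarkers: [",
         paste(orphanP, collapse = ", "), "]")
  ids <- sort(ids)
  mat <- do.call(cbind, biomarkerList[ids])
  ph <- phenotypes[match(ids, phenotypes$subject_id), , drop = FALSE]
  rownames(ph) <- ids
  rd <- S4Vectors::DataFrame(
    mask = names(maskSet@masks),
    component = unname(maskSet@networkOf),
    direction = unname(maskSet@directionOf),
    volume_mm3 = unname(maskSet@volumesMm3))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(biomarkers = mat),
    colData = S4Vectors::DataFrame(ph[, setdiff(colnames(ph), "subject_id"),
                                      drop = FALSE]),
    rowData = rd,
    metadata = list(cohort = cohort))
  new("BiomarkerMatrix", se)
}

#' Dice overlap coefficient
#'
#' 2|A n B| / (|A| + |B|); 1 when both masks are empty (identical).
#'
#' @param a,b logical arrays of equal shape.
#' @return numeric in [0, 1].
#' @export
diceCoefficient <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}
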