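## Pipeline orchestration: the derivation arm (template cohort -> 30 masks)
## and the validation arm (masks + new cohort -> biomarker matrix + battery),
## plus a two-cohort demo and a YAML run configuration.

cleanCohort <- function(subjects, template, trSec, config = list()) {
  lapply(subjects, function(s) {
    cleanBold(s@bold, trSec = trSec, motion6 = s@motion6,
              wmMask = s@wmMask, csfMask = s@csfMask,
              bandHz = config$bandHz %||% c(0.01, 0.08),
              fwhmMm = config$fwhmMm %||% 6,
              nCompCor = config$nCompCor %||% 5L,
              voxelSizeMm = voxelSize(template))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

phenotypeFrame <- function(subjects) {
  data.frame(
    subject_id = vapply(subjects, function(s) s@subjectId, ""),
    group = vapply(subjects, function(s) s@group, ""),
    do.call(rbind, lapply(subjects,
                          function(s) as.data.frame(as.list(s@scores)))),
    stringsAsFactors = FALSE)
}

#' Run the biomarker derivation arm
#'
#' Cleans every subject, runs dual regression against the template, performs
#' per-component TFCE permutation inference (ASD vs TD), and builds the
#' R-masks (template Z > \code{zThreshold}) and A-masks (FWE-significant
#' voxels inside the matching R-mask, split by contrast direction).
#'
#' @param subjects list of \linkS4class{SyntheticSubject} (or equivalent)
#'   objects with both groups present.
#' @param template a \linkS4class{NetworkTemplate}.
#' @param trSec repetition time in seconds.
#' @param nPerm permutations per component (default 500 at desk scale; the
#'   reference analysis choice is 5000).
#' @param alpha FWE level for A-masks (default 0.05).
#' @param zThreshold template threshold for R-masks (default 4).
#' @param tfceParams a \linkS4class{TfceParams}.
#' @param seed RNG seed (per-component seeds are derived from it).
#' @param config list of cleaning overrides (\code{bandHz}, \code{fwhmMm},
#'   \code{nCompCor}).
#' @param outDir if given, masks, p-maps and a JSON sidecar are written.
#' @return list: \code{maskSet}, \code{inference} (per component),
#'   \code{networkMaps}, \code{analysisMask}.
#' @export
runDerivation <- function(subjects, template, trSec = 2, nPerm = 500L,
                          alpha = 0.05, zThreshold = 4,
                          tfceParams = TfceParams(), seed = 1L,
                          config = list(), outDir = NULL) {
  groups <- vapply(subjects, function(s) s@group, "")
  if (length(unique(groups)) != 2L)
    stop("derivation cohort must contain both groups")
  k <- length(template)
  cleaned <- cleanCohort(subjects, template, trSec, config)
  amask <- analysisMask(cleaned)
  nmaps <- lapply(seq_along(cleaned), function(i)
    runDualRegression(cleaned[[i]], template, amask,
                      subjectId = subjects[[i]]@subjectId))
  d <- dim(templateMaps(template))[1:3]
  inference <- vector("list", k)
  for (cmp in seq_len(k)) {
    stack <- array(0, dim = c(d, length(nmaps)))
    for (i in seq_along(nmaps))
      stack[, , , i] <- nmaps[[i]]@zmaps[, , , cmp]
    inference[[cmp]] <- permutationFWE(stack, groups, params = tfceParams,
                                       nPerm = nPerm,
                                       seed = as.integer(seed + cmp))
  }
  rMasks <- buildRMasks(template, zThreshold)
  aMasks <- buildAMasks(inference, rMasks, alpha,
                        voxelSizeMm = voxelSize(template))
  maskSet <- makeMaskSet(rMasks, aMasks, voxelSizeMm = voxelSize(template))

  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    for (nm in names(maskList(maskSet)))
      RNifti::writeNifti(RNifti::asNifti(maskList(maskSet)[[nm]] + 0L),
                         file.path(outDir, paste0(nm, ".nii.gz")))
    manifest <- data.frame(mask = names(maskList(maskSet)),
                           component = unname(maskSet@networkOf),
                           direction = unname(maskSet@directionOf),
                           volume_mm3 = unname(maskVolumes(maskSet)))
    utils::write.csv(manifest, file.path(outDir, "mask_manifest.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = seed, n_perm = nPerm, alpha = alpha,
           z_threshold = zThreshold,
           tfce = list(E = tfceParams@E, H = tfceParams@H,
                       n_steps = tfceParams@nSteps,
                       connectivity = tfceParams@connectivity),
           exhaustive = vapply(inference, function(r) r@exhaustive,
                               logical(1)),
           n_subjects = length(subjects)),
      file.path(outDir, "derivation_sidecar.json"),
      auto_unbox = TRUE, digits = NA)
  }
  list(maskSet = maskSet, inference = inference, networkMaps = nmaps,
       analysisMask = amask)
}

#' Run the biomarker validation arm
#'
#' Cleans every subject of a validation cohort, runs dual regression,
#' extracts the mask-averaged biomarkers, and runs the validation battery:
#' group t-tests, FDR-corrected Pearson correlations against the
#' questionnaire scores, and per-biomarker ROC/AUC (scores of
#' \code{ASD<TD}-direction masks sign-flipped, so AUC >= 0.5 corresponds to
#' the hypothesized direction). Empty-mask biomarkers propagate as missing
#' and never abort the run.
#'
#' @param subjects list of subject objects carrying \code{scores}.
#' @param template a \linkS4class{NetworkTemplate}.
#' @param maskSet a \linkS4class{MaskSet} from the derivation arm.
#' @param trSec repetition time in seconds.
#' @param config list of cleaning overrides.
#' @param corFamily FDR family for the correlation table.
#' @param outDir if given, reports are written there.
#' @return list: \code{biomarkerMatrix}, \code{ttestTable},
#'   \code{correlations}, \code{rocs}.
#' @export
runValidation <- function(subjects, template, maskSet, trSec = 2,
                          config = list(), corFamily = "global",
                          outDir = NULL) {
  d <- dim(templateMaps(template))[1:3]
  if (!identical(d, dim(maskList(maskSet)[[1]])))
    stop(sprintf("mask grid (%s) does not match cohort grid (%s)",
                 paste(dim(maskList(maskSet)[[1]]), collapse = "x"),
                 paste(d, collapse = "x")))
  cleaned <- cleanCohort(subjects, template, trSec, config)
  amask <- analysisMask(cleaned)
  nmaps <- lapply(seq_along(cleaned), function(i)
    runDualRegression(cleaned[[i]], template, amask,
                      subjectId = subjects[[i]]@subjectId))
  bmList <- lapply(nmaps, extractBiomarkers, maskSet = maskSet)
  names(bmList) <- vapply(subjects, function(s) s@subjectId, "")
  bm <- assembleBiomarkerMatrix(bmList, phenotypeFrame(subjects), maskSet,
                                cohort = "validation")
  tt <- groupTTestTable(bm)
  ct <- pearsonCorrelations(bm, family = corFamily)
  vals <- biomarkerValues(bm)
  grp <- groupLabels(bm)
  rocs <- list()
  for (nm in colnames(vals)) {
    x <- vals[, nm]
    if (sum(is.finite(x) & grp == "ASD") < 1 ||
        sum(is.finite(x) & grp == "TD") < 1 || all(!is.finite(x))) next
    dirTag <- maskSet@directionOf[[nm]]
    dir <- if (!is.na(dirTag) && dirTag == "ASD<TD") "less" else "greater"
    rocs[[nm]] <- rocAuc(x, grp, positive = "ASD", direction = dir)
  }
  if (!is.null(outDir))
    renderReports(tt, ct, rocs, outDir)
  list(biomarkerMatrix = bm, ttestTable = tt, correlations = ct,
       rocs = rocs)
}

#' Two-cohort demonstration run
#'
#' Generates a derivation cohort and a validation cohort (default 21 ASD +
#' 23 TD, echoing a two-site design), runs both arms end to end at desk
#' scale, and prints a summary: recovered mask volumes, Dice overlap of the
#' recovered effect mask against the ground truth, significant biomarkers,
#' and the effect component's AUC and score correlation.
#'
#' @param seed RNG seed driving everything.
#' @param nDeriv integer(2) derivation cohort sizes (default 15 + 15).
#' @param nValid integer(2) validation cohort sizes (default 21 + 23).
#' @param nPerm permutations per component (default 200 at demo scale).
#' @param gridShape template grid (default 16^3).
#' @param tPoints time points per subject (default 150).
#' @param effectComponent component carrying the group effect (default 4).
#' @param effectSize group amplitude difference in noise-SD units
#'   (default 1.5).
#' @param verbose print the summary (default TRUE).
#' @return invisibly, a list with the derivation and validation results,
#'   the ground truths, and the summary statistics.
#' @export
demoPipeline <- function(seed = 1L, nDeriv = c(15, 15), nValid = c(21, 23),
                         nPerm = 200L, gridShape = c(16, 16, 16),
                         tPoints = 150L, effectComponent = 4L,
                         effectSize = 1.5, verbose = TRUE) {
  template <- makeTemplate(gridShape, k = 10L, seed = seed)
  truth <- makeGroundTruth(template, components = effectComponent,
                           effectSize = effectSize)
  deriv <- simulateCohort(template, nDeriv, truth, tPoints = tPoints,
                          seed = seed + 1000L)
  derivRes <- runDerivation(deriv$subjects, template, trSec = deriv$trSec,
                            nPerm = nPerm, seed = seed)

  # ground-truth comparison for the effect component
  cmp <- effectComponent
  er <- truth@effectRegions[[as.character(cmp)]]
  dir <- if (length(er$pos)) "pos" else "neg"
  aName <- if (dir == "pos") paste0("A", cmp) else paste0("A", cmp + 10L)
  d3 <- dim(templateMaps(template))[1:3]
  trueRegion <- array(FALSE, d3)
  trueRegion[c(er$pos, er$neg)] <- TRUE
  rMask <- maskList(derivRes$maskSet)[[paste0("R", cmp)]]
  dice <- diceCoefficient(maskList(derivRes$maskSet)[[aName]],
                          trueRegion & rMask)

  valid <- simulateCohort(template, nValid, truth, tPoints = tPoints,
                          seed = seed + 2000L)
  validRes <- runValidation(valid$subjects, template, derivRes$maskSet,
                            trSec = valid$trSec)

  tt <- validRes$ttestTable
  sigMarkers <- tt$biomarker[!is.na(tt$p) & tt$p < 0.05]
  aucA <- if (!is.null(validRes$rocs[[aName]]))
    validRes$rocs[[aName]]$auc else NA_real_
  rA <- validRes$correlations$r[aName, "srs_total"]

  if (verbose) {
    cat(sprintf("demo (seed %d): derivation %d+%d, validation %d+%d, %d permutations\n",
                seed, nDeriv[1], nDeriv[2], nValid[1], nValid[2], nPerm))
    cat(sprintf("  non-empty masks: %d of %d; %s volume %.0f mm^3\n",
                sum(maskVolumes(derivRes$maskSet) > 0),
                length(maskList(derivRes$maskSet)), aName,
                maskVolumes(derivRes$maskSet)[[aName]]))
    cat(sprintf("  Dice(%s, true effect region within R%d): %.3f\n",
                aName, cmp, dice))
    cat(sprintf("  validation biomarker matrix: %d x %d\n",
                nrow(biomarkerValues(validRes$biomarkerMatrix)),
                ncol(biomarkerValues(validRes$biomarkerMatrix))))
    cat(sprintf("  group-significant biomarkers (p < 0.05): %s\n",
                if (length(sigMarkers)) paste(sigMarkers, collapse = ", ")
                else "none"))
    cat(sprintf("  %s: AUC %.3f, r(%s, srs_total) %.3f\n",
                aName, aucA, aName, rA))
  }
  invisible(list(template = template, truth = truth,
                 derivation = derivRes, validation = validRes,
                 dice = dice, effectMask = aName, auc = aucA,
                 corSrsTotal = rA, sigMarkers = sigMarkers))
}

#' Read a YAML run configuration
#'
#' Loads a hierarchical YAML configuration for the command-line interface,
#' fills defaults, and checks that every referenced path exists.
#'
#' @param path YAML file.
#' @return named list with defaults filled.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(tr_s = 2, band_hz = c(0.01, 0.08), fwhm_mm = 6,
                   n_compcor = 5L, n_perm = 500L, alpha = 0.05,
                   z_threshold = 4, seed = 1L,
                   tfce = list(E = 0.5, H = 2, n_steps = 100L,
                               connectivity = 26L))
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  for (nm in c("manifest", "masks_dir")) {
    if (!is.null(cfg[[nm]]) && !file.exists(cfg[[nm]]) &&
        !dir.exists(cfg[[nm]]))
      stop("configured path does not exist: ", cfg[[nm]])
  }
  cfg
}
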