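toyTemplate <- function() {
  d <- c(5, 5, 5)
  maps <- array(0, c(d, 2))
  maps[1:3, 1, 1, 1] <- c(3, 4, 6)      # only the 6 exceeds Z > 4
  maps[, , , 2] <- 2.9                   # never exceeds the threshold
  new("NetworkTemplate", maps = maps, voxelSizeMm = c(2, 2, 2),
      templateId = "toy")
}

test_that("R-masks use a strict Z threshold and report volumes", {
  rm <- buildRMasks(toyTemplate())
  expect_named(rm, c("R1", "R2"))
  expect_equal(sum(rm$R1), 1)            # Z = 4.0 exactly is excluded
  expect_false(rm$R1[2, 1, 1])
  expect_true(rm$R1[3, 1, 1])
  expect_equal(sum(rm$R2), 0)            # max Z = 2.9: empty, volume 0
  vols <- attr(rm, "volumesMm3")
  expect_equal(unname(vols), c(1 * 8, 0))
  # threshold voxel count equals brute-force enumeration
  tpl2 <- makeTemplate(c(12, 12, 12), k = 2, seed = 3)
  rm2 <- buildRMasks(tpl2)
  expect_equal(sum(rm2$R1),
               sum(as.numeric(templateMaps(tpl2)[, , , 1]) > 4))
})

fakeInference <- function(d, pPos, pNeg) {
  new("InferenceResult", tmap = array(0, d),
      tfcePos = array(0, d), tfceNeg = array(0, d),
      pfwePos = pPos, pfweNeg = pNeg, nPerm = 100L, seed = 1L,
      exhaustive = FALSE)
}

test_that("A-masks are significant voxels nested in their R-mask", {
  tpl <- toyTemplate()
  d <- c(5, 5, 5)
  rm <- buildRMasks(tpl)
  pPos <- array(1, d); pNeg <- array(1, d)
  pPos[3, 1, 1] <- 0.01                  # significant, inside R1
  pPos[5, 5, 5] <- 0.01                  # significant, outside R1
  pNeg[2, 1, 1] <- 0.04                  # significant but not in R1 (Z=4)
  res <- list(fakeInference(d, pPos, pNeg),
              fakeInference(d, array(1, d), array(1, d)))
  am <- buildAMasks(res, rm)
  expect_named(am, c("A1", "A2", "A3", "A4"))
  expect_equal(sum(am$A1), 1)            # only the in-mask voxel survives
  expect_true(am$A1[3, 1, 1])
  expect_equal(sum(am$A3), 0)            # negative direction excluded at Z=4
  expect_equal(sum(am$A2) + sum(am$A4), 0)
  expect_equal(unname(attr(am, "volumesMm3")), c(8, 0, 0, 0))
  expect_error(buildAMasks(res[1], rm), "mismatch")
  # intersection cardinality equals the direct set oracle
  sigSet <- which(pPos < 0.05)
  expect_equal(sum(am$A1), length(intersect(sigSet, which(rm$R1))))
})

test_that("mask sets enforce nesting and keep the fixed ordering", {
  tpl <- toyTemplate()
  rm <- buildRMasks(tpl)
  d <- c(5, 5, 5)
  am <- list(A1 = array(FALSE, d), A2 = array(FALSE, d),
             A3 = array(FALSE, d), A4 = array(FALSE, d))
  am$A1[3, 1, 1] <- TRUE
  ms <- makeMaskSet(rm, am)
  expect_identical(names(maskList(ms)), c("R1", "R2", "A1", "A2", "A3", "A4"))
  expect_equal(unname(ms@networkOf), c(1, 2, 1, 2, 1, 2))
  expect_equal(unname(ms@directionOf[3:6]),
               c("ASD>TD", "ASD>TD", "ASD<TD", "ASD<TD"))
  # violating nesting is rejected by the validity method
  bad <- am; bad$A2[5, 5, 5] <- TRUE     # R2 is empty, so A2 cannot be inside
  expect_error(makeMaskSet(rm, bad), "subset")
})

test_that("biomarkers are unweighted mask means with missing propagation", {
  tpl <- toyTemplate()
  rm <- buildRMasks(tpl)
  d <- c(5, 5, 5)
  am <- list(A1 = array(FALSE, d), A2 = array(FALSE, d),
             A3 = array(FALSE, d), A4 = array(FALSE, d))
  ms <- makeMaskSet(rm, am)
  z <- array(0, c(d, 2))
  z[, , , 1] <- 5
  snm <- new("SubjectNetworkMaps", subjectId = "s", zmaps = z,
             timecourses = matrix(rnorm(40 * 2), 40, 2),
             templateId = "toy", dof = 37)
  b <- extractBiomarkers(snm, ms)
  expect_equal(unname(b[["R1"]]), 5)        # constant map inside the mask
  expect_true(is.na(b[["R2"]]))             # empty mask -> missing
  expect_true(all(is.na(b[c("A1", "A2", "A3", "A4")])))
  # a 7-voxel hand mean
  rm7 <- rm
  rm7$R1 <- array(FALSE, d); rm7$R1[1:7] <- TRUE
  z2 <- z; z2[, , , 1] <- seq_len(prod(d))
  ms7 <- makeMaskSet(rm7, am)
  snm2 <- new("SubjectNetworkMaps", subjectId = "s", zmaps = z2,
              timecourses = matrix(rnorm(40 * 2), 40, 2),
              templateId = "toy", dof = 37)
  expect_equal(unname(extractBiomarkers(snm2, ms7)[["R1"]]), sum(1:7) / 7)
})

test_that("the biomarker matrix assembles with stable ordering", {
  tpl <- toyTemplate()
  rm <- buildRMasks(tpl)
  d <- c(5, 5, 5)
  am <- list(A1 = array(FALSE, d), A2 = array(FALSE, d),
             A3 = array(FALSE, d), A4 = array(FALSE, d))
  ms <- makeMaskSet(rm, am)
  set.seed(20)
  ids <- sprintf("sub-%03d", 1:44)
  vecs <- lapply(ids, function(i)
    setNames(c(rnorm(2), rep(NA, 4)), names(maskList(ms))))
  names(vecs) <- ids
  pheno <- data.frame(subject_id = ids,
                      group = rep(c("ASD", "TD"), c(21, 23)),
                      stringsAsFactors = FALSE)
  for (nm in scoreNames()) pheno[[nm]] <- rnorm(44)
  bm <- assembleBiomarkerMatrix(vecs, pheno, ms, cohort = "validation")
  expect_s4_class(bm, "BiomarkerMatrix")
  expect_equal(dim(biomarkerValues(bm)), c(44, 6))
  expect_equal(S4Vectors::metadata(bm)$cohort, "validation")
  # input order does not matter after the sort
  bm2 <- assembleBiomarkerMatrix(vecs[rev(ids)], pheno, ms)
  expect_equal(biomarkerValues(bm2), biomarkerValues(bm))
  # column means equal per-subject recomputation
  expect_equal(colMeans(biomarkerValues(bm))[["R1"]],
               mean(vapply(vecs, function(v) v[["R1"]], numeric(1))))
  # orphan subjects are named in the failure
  expect_error(assembleBiomarkerMatrix(vecs[-1], pheno, ms), "sub-001")
})

test_that("Dice coefficient handles empty and identical masks", {
  a <- array(FALSE, c(3, 3, 3)); b <- a
  expect_equal(diceCoefficient(a, b), 1)
  a[1:4] <- TRUE; b[3:6] <- TRUE
  expect_equal(diceCoefficient(a, b), 2 * 2 / (4 + 4))
})
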