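test_that("band-pass removes DC and preserves mid-band amplitude", {
  tt <- seq_len(300) * 2                       # TR = 2 s
  # constant series: DC sits below the 0.01 Hz edge
  out <- bandpassFilter(rep(3.7, 300), trSec = 2)
  expect_lt(max(abs(out)), 1e-6)
  # 0.04 Hz sinusoid: mid-band, amplitude preserved within 5%
  x <- sin(2 * pi * 0.04 * tt)
  y <- bandpassFilter(x, trSec = 2)
  fit <- lm(y ~ sin(2 * pi * 0.04 * tt) + cos(2 * pi * 0.04 * tt))
  amp <- sqrt(sum(coef(fit)[2:3]^2))
  expect_gt(amp, 0.95)
  expect_lt(amp, 1.05)
})

test_that("stop-band attenuation matches the filter's own frequency response", {
  tt <- seq_len(300) * 2
  x <- sin(2 * pi * 0.2 * tt)
  y <- bandpassFilter(x, trSec = 2)
  fit <- lm(y ~ sin(2 * pi * 0.2 * tt) + cos(2 * pi * 0.2 * tt))
  measured <- sqrt(sum(coef(fit)[2:3]^2))
  expect_lt(measured, 0.1)                     # >= 90% attenuation at 2.5x high edge
  # oracle: gain at 0.2 Hz from the DFT of the impulse response
  n <- 1000                                    # 0.2 Hz falls on bin 400 exactly
  imp <- c(rep(0, n / 2), 1, rep(0, n / 2 - 1))
  h <- bandpassFilter(imp, trSec = 2)
  gain <- abs(fft(h))[round(0.2 * n * 2) + 1]
  expect_lt(abs(measured - gain), 0.01)
})

test_that("band-pass validates its inputs", {
  expect_error(bandpassFilter(rnorm(300), trSec = 2, highHz = 0.3),
               "Nyquist")
  expect_error(bandpassFilter(rnorm(10), trSec = 2), "30 time points")
  expect_error(bandpassFilter(c(rnorm(299), NA), trSec = 2), "non-finite")
})

test_that("Friston-24 expansion matches hand-computed derivatives and squares", {
  m <- matrix(0, 4, 6)
  m[, 1] <- c(0, 1, 2, 3)
  f <- buildFriston24(m)
  expect_equal(ncol(f), 24)
  expect_false(anyDuplicated(colnames(f)) > 0)
  # backward difference (0,1,1,1) and square (0,1,4,9), demeaned
  expect_equal(unname(f[, "dmot1"]), c(0, 1, 1, 1) - 0.75)
  expect_equal(unname(f[, "mot1_sq"]), c(0, 1, 4, 9) - 3.5)
  expect_equal(unname(f[, "mot1"]), c(0, 1, 2, 3) - 1.5)
  # zero motion: all-zero columns after demeaning
  z <- buildFriston24(matrix(0, 5, 6))
  expect_true(all(z == 0))
  bad <- matrix(rnorm(24), 4, 6); bad[3, 2] <- NA
  expect_error(buildFriston24(bad), "row\\(s\\): 3")
})

test_that("CompCor recovers a rank-1 tissue signal and orders components", {
  set.seed(11)
  tt <- 40; m <- 30
  s <- sin(seq_len(tt) / 3)
  X <- s %*% t(runif(m, 0.5, 2)) + matrix(rnorm(tt * m, sd = 1e-4), tt, m)
  cc <- compCorComponents(X, nComponents = 3)
  expect_gt(abs(cor(cc[, 1], s)), 0.999)
  # orthogonality
  g <- crossprod(cc)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  # explained variance ordering matches a dense eigendecomposition
  Y <- matrix(rnorm(20 * 50), 20, 50)
  Yc <- sweep(Y, 2, colMeans(Y))
  sdv <- sqrt(colMeans(Yc^2)); Yn <- sweep(Yc, 2, sdv, "/")
  ev <- eigen(tcrossprod(Yn), symmetric = TRUE)$values
  cc2 <- compCorComponents(Y, nComponents = 5)
  frac <- attr(cc2, "explainedVariance")
  expect_equal(frac[1:5], (ev / sum(ev[ev > 1e-12]))[1:5], tolerance = 1e-8)
  expect_true(all(diff(frac[1:5]) <= 1e-12))
})

test_that("rank-deficient tissue data yields fewer components with a warning", {
  s <- rnorm(30)
  X <- s %*% t(seq_len(10))                  # exactly rank 1
  expect_warning(cc <- compCorComponents(X, nComponents = 5), "rank")
  expect_lt(ncol(cc), 5)
  expect_false(is.null(attr(cc, "rankWarning")))
})

test_that("confound regression leaves residuals orthogonal to the design", {
  set.seed(5)
  C <- matrix(rnorm(30 * 4), 30, 4)
  # a series equal to a confound column is annihilated
  out <- regressConfounds(cbind(C[, 2]), C)
  expect_lt(max(abs(out)), 1e-10)
  # confounds orthogonal to the series leave the demeaned input unchanged
  y <- rnorm(30)
  Cd <- sweep(C, 2, colMeans(C))
  yOrth <- y - mean(y)
  yOrth <- yOrth - Cd %*% solve(crossprod(Cd), crossprod(Cd, yOrth))
  res <- regressConfounds(cbind(yOrth), C)
  expect_equal(as.numeric(res), as.numeric(yOrth), tolerance = 1e-10)
  # 10x3 toy system matches the normal equations solved by hand-coded
  # Gaussian elimination
  Y10 <- matrix(rnorm(10 * 3), 10, 3)
  C10 <- matrix(rnorm(10 * 2), 10, 2)
  X <- cbind(1, C10)
  B <- apply(Y10, 2, function(yy) oracleGaussSolve(crossprod(X), crossprod(X, yy)))
  expect_equal(regressConfounds(Y10, C10), Y10 - X %*% B, tolerance = 1e-10)
  expect_error(regressConfounds(Y10, matrix(0, 9, 2)), "row mismatch")
})

test_that("Gaussian smoothing has the closed-form kernel and conserves mass", {
  vol <- array(rnorm(10 * 10 * 10), c(10, 10, 10))
  # sub-voxel-width kernel degenerates to the identity
  expect_identical(gaussianSmooth(vol, fwhmMm = 1e-4), vol)
  # unit impulse under periodic boundary keeps frame sum 1
  imp <- array(0, c(10, 10, 10)); imp[5, 5, 5] <- 1
  sm <- gaussianSmooth(imp, fwhmMm = 6, voxelSizeMm = c(2, 2, 2),
                       boundary = "periodic")
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  # impulse response at one voxel offset equals the normalised Gaussian
  sig <- 6 / (2 * sqrt(2 * log(2)) * 2)            # sigma in voxels, 2 mm
  r <- max(1, ceiling(4 * sig))
  w <- exp(-(-r:r)^2 / (2 * sig^2))
  expected <- (exp(-1 / (2 * sig^2)) / sum(w))^1 * (exp(0) / sum(w))^2
  expect_equal(sm[6, 5, 5], expected, tolerance = 1e-10)
  # renormalized truncation preserves the spatial sum away from edges
  imp2 <- array(0, c(16, 16, 16)); imp2[8, 8, 8] <- 1
  sm2 <- gaussianSmooth(imp2, fwhmMm = 6, voxelSizeMm = c(2, 2, 2))
  expect_equal(sum(sm2), 1, tolerance = 1e-3)
})

test_that("cleaning a pure confound signal leaves almost no energy", {
  set.seed(8)
  tt <- 60
  motion <- cbind(matrix(cumsum(rnorm(tt * 3, sd = 1e-3)), tt, 3),
                  matrix(cumsum(rnorm(tt * 3, sd = 1e-2)), tt, 3))
  f24 <- buildFriston24(motion)
  mix <- as.numeric(f24 %*% rnorm(24))
  bold <- aperm(array(rep(mix, 64), c(tt, 4, 4, 4)), c(2, 3, 4, 1))
  cleaned <- cleanBold(bold, trSec = 2, motion6 = motion, fwhmMm = 0)
  ratio <- sum(cleaned@data^2) / sum(bold^2)
  expect_lt(ratio, 1e-6)
})

cbNoSmooth <- function(s)
  cleanBold(s@bold, 2, s@motion6, fwhmMm = 0)

test_that("the cleaning pipeline records provenance and is reproducible", {
  pc <- plumbingCohort(n = c(2, 2), grid = c(12, 12, 12), k = 3,
                       tPoints = 40)
  s <- pc$cohort$subjects[[1]]
  cb1 <- cleanBold(s@bold, 2, s@motion6, s@wmMask, s@csfMask)
  cb2 <- cleanBold(s@bold, 2, s@motion6, s@wmMask, s@csfMask)
  expect_identical(cb1@data, cb2@data)
  expect_identical(cb1@provenance,
                   c("bandpass", "confound_regression", "smoothing"))
  # voxel temporal means are ~0 after cleaning
  tm <- apply(cb1@data, 1:3, mean)
  expect_lt(max(abs(tm)), 1e-8)
  # residuals orthogonal to the band-passed confounds
  f24 <- buildFriston24(s@motion6)
  fbp <- bandpassFilter(f24, 2)
  Y <- t(matrix(cbNoSmooth(s)@data, ncol = 40))
  ip <- crossprod(fbp, Y)
  rel <- max(abs(ip)) / (max(abs(fbp)) * max(abs(Y)) * 40)
  expect_lt(rel, 1e-6)
  # alternative step order is honoured and recorded
  cb3 <- cleanBold(s@bold, 2, s@motion6, fwhmMm = 0,
                   steps = c("confound_regression", "bandpass"))
  expect_identical(cb3@provenance, c("confound_regression", "bandpass"))
})
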