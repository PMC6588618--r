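# Small fixture builders shared across test files. Everything is generated
# in code at test time; nothing is read from disk.

tinyTemplate <- function(grid = c(12, 12, 12), k = 3, seed = 42)
  makeTemplate(grid, k = k, seed = seed)

# template with orthogonal spatial maps and a known mixing, for exact
# dual-regression recovery checks
orthoTemplate <- function(grid = c(6, 6, 6), k = 3, seed = 7) {
  set.seed(seed)
  V <- prod(grid)
  D <- qr.Q(qr(matrix(rnorm(V * k), V, k)))
  new("NetworkTemplate", maps = array(D, c(grid, k)),
      voxelSizeMm = c(2, 2, 2), templateId = "ortho")
}

# noiseless bold = template maps x given time-courses
boldFromTimecourses <- function(template, W) {
  d <- dim(templateMaps(template))
  M <- matrix(templateMaps(template), ncol = d[4])
  array(t(W %*% t(M)), dim = c(d[1:3], nrow(W)))
}

# a minimal cohort for pipeline plumbing tests (values are irrelevant,
# shapes and determinism are what is checked)
plumbingCohort <- function(n = c(2, 2), grid = c(12, 12, 12), k = 10,
                           tPoints = 60, seed = 3) {
  tpl <- makeTemplate(grid, k = k, seed = seed)
  truth <- makeGroundTruth(tpl, components = min(4L, k), effectSize = 0,
                           phenotypeLoadings = data.frame(
                             score = character(), component = integer(),
                             r = numeric()))
  co <- simulateCohort(tpl, n, truth, tPoints = tPoints, seed = seed)
  list(template = tpl, truth = truth, cohort = co)
}
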