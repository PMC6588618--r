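# Independent oracles used to cross-check the package's implementations.
# These deliberately re-derive everything from first principles (plain R,
# different algorithms) and never call the package's own kernels.

# -- 3-D flood-fill connected components (queue-based, plain R) --------------
oracleNeighbours <- function(connectivity) {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  m <- rowSums(abs(offs))
  if (connectivity == 6) offs[m == 1, , drop = FALSE]
  else if (connectivity == 18) offs[m <= 2, , drop = FALSE]
  else offs
}

oracleLabelComponents <- function(binary, connectivity = 26) {
  d <- dim(binary)
  offs <- oracleNeighbours(connectivity)
  labels <- array(0L, d)
  sizes <- integer(0)
  nxt <- 0L
  idx <- which(binary)
  for (start in idx) {
    if (labels[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    labels[start] <- nxt
    sz <- 0L
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      sz <- sz + 1L
      co <- arrayInd(v, d)
      for (r in seq_len(nrow(offs))) {
        p <- co + offs[r, ]
        if (any(p < 1) || any(p > d)) next
        w <- p[1] + d[1] * (p[2] - 1) + d[1] * d[2] * (p[3] - 1)
        if (binary[w] && labels[w] == 0L) {
          labels[w] <- nxt
          queue <- c(queue, w)
        }
      }
    }
    sizes <- c(sizes, sz)
  }
  list(labels = labels, sizes = sizes)
}

# -- brute-force TFCE: threshold, label, sum ---------------------------------
oracleTfce <- function(stat, E = 0.5, H = 2, nsteps = 100, conn = 26) {
  out <- array(0, dim(stat))
  mx <- max(stat)
  if (mx <= 0) return(out)
  dh <- mx / nsteps
  for (s in seq_len(nsteps)) {
    h <- s * dh
    cc <- oracleLabelComponents(stat >= h, conn)
    act <- cc$labels > 0
    out[act] <- out[act] + cc$sizes[cc$labels[act]]^E * h^H * dh
  }
  out
}

# -- hand-coded Gaussian elimination (partial pivoting) ----------------------
oracleGaussSolve <- function(A, b) {
  n <- nrow(A)
  M <- cbind(A, b)
  for (i in seq_len(n)) {
    p <- which.max(abs(M[i:n, i])) + i - 1L
    if (p != i) M[c(i, p), ] <- M[c(p, i), ]
    M[i, ] <- M[i, ] / M[i, i]
    for (j in seq_len(n)[-i]) M[j, ] <- M[j, ] - M[j, i] * M[i, ]
  }
  M[, n + 1]
}

# -- all-pairs AUC by explicit double loop -----------------------------------
oracleAllPairsAuc <- function(pos, neg) {
  tot <- 0
  for (x in pos) for (y in neg)
    tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(pos) * length(neg))
}

# -- DeLong variance of an AUC difference, coded directly from the
#    structural-components definition ----------------------------------------
oracleDelong <- function(s1, s2, isPos) {
  pc <- function(s) {
    X <- s[isPos]; Y <- s[!isPos]
    v10 <- sapply(X, function(x) sum((x > Y) + 0.5 * (x == Y)) / length(Y))
    v01 <- sapply(Y, function(y) sum((X > y) + 0.5 * (X == y)) / length(X))
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  a <- pc(s1); b <- pc(s2)
  n1 <- sum(isPos); n2 <- sum(!isPos)
  cv <- function(x, y) sum((x - mean(x)) * (y - mean(y))) / (length(x) - 1)
  varDiff <- (cv(a$v10, a$v10) + cv(b$v10, b$v10) - 2 * cv(a$v10, b$v10)) / n1 +
             (cv(a$v01, a$v01) + cv(b$v01, b$v01) - 2 * cv(a$v01, b$v01)) / n2
  z <- (a$auc - b$auc) / sqrt(varDiff)
  list(aucDiff = a$auc - b$auc, varDiff = varDiff, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

# Fisher-z 95% interval around a target correlation at sample size n
fisherInterval <- function(r, n) {
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  tanh(c(z - 1.96 * se, z + 1.96 * se))
}
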