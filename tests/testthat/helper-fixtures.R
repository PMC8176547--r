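# Shared fixtures and tiny independent oracles, built in code.

randomRgb <- function(h, w, seed = 1) {
  leafgrid:::withSeed(seed, array(runif(h * w * 3), c(h, w, 3)))
}

# Number of 8-connected foreground components, by BFS (independent of the
# package's labeling).
countComponents8 <- function(mask) {
  todo <- which(mask > 0)
  if (!length(todo)) return(0L)
  H <- nrow(mask)
  seen <- logical(length(mask))
  comps <- 0L
  offsets <- c(-1, 1, -H, H, -H - 1, -H + 1, H - 1, H + 1)
  rowOf <- function(i) ((i - 1) %% H) + 1
  for (start in todo) {
    if (seen[start]) next
    comps <- comps + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (o in offsets) {
        nb <- cur + o
        if (nb < 1 || nb > length(mask)) next
        if (abs(rowOf(nb) - rowOf(cur)) > 1) next  # no row wrap-around
        if (!seen[nb] && mask[nb] > 0) { seen[nb] <- TRUE; queue <- c(queue, nb) }
      }
    }
  }
  comps
}

# Brute-force binary erosion with a Euclidean disk, for small grids.
bruteErodeDisk <- function(mask, radius) {
  H <- nrow(mask); W <- ncol(mask)
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, ]
  out <- matrix(0, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    keep <- TRUE
    for (k in seq_len(nrow(offs))) {
      rr <- r + offs$dr[k]; cc <- c + offs$dc[k]
      if (rr < 1 || rr > H || cc < 1 || cc > W || mask[rr, cc] == 0) {
        keep <- FALSE; break
      }
    }
    if (keep) out[r, c] <- 1
  }
  out
}

# Brute-force Otsu: the threshold among the 256 bin edges k/256 maximizing
# between-class variance of the strict-below split.
bruteOtsu <- function(g) {
  best <- c(T = NA, v = -1)
  for (k in 1:255) {
    T <- k / 256
    lo <- g[g < T]; hi <- g[g >= T]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(g); w1 <- 1 - w0
    v <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (v > best["v"]) best <- c(T = T, v = v)
  }
  best[["T"]]
}

# Direct evaluation of half-pixel-centers bilinear interpolation.
bruteBilinear <- function(m, outH, outW) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, outH, outW)
  for (i in seq_len(outH)) for (j in seq_len(outW)) {
    sy <- min(max((i - 0.5) * H / outH - 0.5, 0), H - 1)
    sx <- min(max((j - 0.5) * W / outW - 0.5, 0), W - 1)
    y0 <- floor(sy); x0 <- floor(sx)
    fy <- sy - y0; fx <- sx - x0
    y1 <- min(y0 + 1, H - 1); x1 <- min(x0 + 1, W - 1)
    out[i, j] <- (1 - fy) * (1 - fx) * m[y0 + 1, x0 + 1] +
      (1 - fy) * fx * m[y0 + 1, x1 + 1] +
      fy * (1 - fx) * m[y1 + 1, x0 + 1] +
      fy * fx * m[y1 + 1, x1 + 1]
  }
  out
}

# Reduced feature blocks with aligned samples, for fusion bookkeeping tests.
dummyReducedBlocks <- function(nBlocks, nSamples, k, seed = 1) {
  leafgrid:::withSeed(seed, lapply(seq_len(nBlocks), function(i)
    featureMatrix(matrix(rnorm(nSamples * k), nSamples, k),
                  sampleIds = sprintf("s%02d", seq_len(nSamples)),
                  backbone = sprintf("bb%d", i), tile = c(1L, 1L),
                  stage = "reduced")))
}
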