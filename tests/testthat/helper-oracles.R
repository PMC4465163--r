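# Independent brute-force oracles. These deliberately re-derive every
# quantity by exhaustive enumeration, sharing no code with the package.

# all 26 neighbor offsets
.offs26 <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
.offs26 <- .offs26[rowSums(abs(.offs26)) > 0, , drop = FALSE]

# 13 canonical directions: first nonzero component positive
.dirs13 <- .offs26[apply(.offs26, 1, function(v) v[which(v != 0)[1]] > 0), ]

inBounds <- function(v, d) all(v >= 1) && all(v <= d)

# merged symmetric GLCM probabilities by triple-loop pair enumeration
naiveGLCM <- function(bins, nBins = 64L) {
  d <- dim(bins)
  cnt <- matrix(0, nBins, nBins)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- bins[x, y, z]
    if (is.na(a)) next
    for (r in seq_len(nrow(.dirs13))) {
      v <- c(x, y, z) + .dirs13[r, ]
      if (!inBounds(v, d)) next
      b <- bins[v[1], v[2], v[3]]
      if (is.na(b)) next
      cnt[a, b] <- cnt[a, b] + 1   # ordered pair along the direction
      cnt[b, a] <- cnt[b, a] + 1   # symmetrization / reverse direction
    }
  }
  if (sum(cnt) == 0) stop("no pairs")
  cnt / sum(cnt)
}

# NGTDM by explicit neighborhood enumeration
naiveNGTDM <- function(bins) {
  d <- dim(bins)
  lev <- integer(0); dev <- numeric(0)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- bins[x, y, z]
    if (is.na(a)) next
    nb <- numeric(0)
    for (r in seq_len(nrow(.offs26))) {
      v <- c(x, y, z) + .offs26[r, ]
      if (!inBounds(v, d)) next
      b <- bins[v[1], v[2], v[3]]
      if (!is.na(b)) nb <- c(nb, b)
    }
    if (length(nb) == 0) next
    lev <- c(lev, a); dev <- c(dev, abs(a - mean(nb)))
  }
  if (length(lev) == 0) stop("no valid voxels")
  levels <- sort(unique(lev))
  list(levels = levels,
       p = vapply(levels, function(l) mean(lev == l), numeric(1)),
       s = vapply(levels, function(l) sum(dev[lev == l]), numeric(1)))
}

# queue-based breadth-first flood fill
bfsComponent <- function(thr, seed, connectivity = 26L) {
  offs <- switch(as.character(connectivity),
                 "6" = .offs26[rowSums(abs(.offs26)) == 1, , drop = FALSE],
                 "18" = .offs26[rowSums(abs(.offs26)) <= 2, , drop = FALSE],
                 "26" = .offs26)
  d <- dim(thr)
  comp <- array(FALSE, d)
  queue <- list(as.integer(seed))
  comp[matrix(as.integer(seed), 1)] <- TRUE
  while (length(queue) > 0) {
    cur <- queue[[1]]; queue <- queue[-1]
    for (r in seq_len(nrow(offs))) {
      v <- cur + offs[r, ]
      if (!inBounds(v, d)) next
      m <- matrix(v, 1)
      if (thr[m] && !comp[m]) {
        comp[m] <- TRUE
        queue <- c(queue, list(as.integer(v)))
      }
    }
  }
  comp
}

# AUC by exhaustive positive-negative pair counting (ties count 1/2)
pairAUC <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# distance-to-corner optimum by scanning every threshold midpoint
bruteCutoffDistance <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- c(-Inf, (u[-1] + u[-length(u)]) / 2, Inf)
  if (length(u) == 1) cand <- c(-Inf, Inf)
  best <- Inf
  for (cut in cand) {
    pred <- scores > cut
    sens <- sum(pred & labels == 1) / sum(labels == 1)
    spec <- sum(!pred & labels == 0) / sum(labels == 0)
    best <- min(best, sqrt((1 - sens)^2 + (1 - spec)^2))
  }
  best
}

# build a PETVolume from a numeric vector/array
vol3d <- function(x, dim = NULL, spacing = c(4.06, 4.06, 5)) {
  a <- if (is.null(dim)) x else array(x, dim)
  PETVolume(a, spacing = spacing)
}

# full-grid VOIMask over a volume
fullMask <- function(vol) {
  d <- dim(suvGrid(vol))
  new("VOIMask", mask = array(TRUE, d), thresholdSUV = 0.1,
      connectivity = 26L, seedVoxel = hottestVoxel(vol))
}

# DiscretizedVolume from a raw bin array (NA outside the VOI)
discFromBins <- function(bins, nBins = 64L) {
  new("DiscretizedVolume", bins = bins, nBins = as.integer(nBins),
      suvMin = 0, suvMax = 1)
}
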