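# Neighborhood offset sets shared by segmentation, GLCM and NGTDM.

# all 26 nonzero offsets in {-1,0,1}^3
offsets26 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

# offsets for a given 3D connectivity (6 = faces, 18 = faces+edges, 26 = all)
connectivityOffsets <- function(connectivity) {
  o <- offsets26()
  switch(as.character(connectivity),
    "6"  = o[rowSums(abs(o)) == 1, , drop = FALSE],
    "18" = o[rowSums(abs(o)) <= 2, , drop = FALSE],
    "26" = o,
    stop("connectivity must be 6, 18 or 26"))
}

# the 13 unique 3D directions: nonzero offsets modulo sign
# (first nonzero component positive)
glcmDirections <- function() {
  o <- offsets26()
  keep <- apply(o, 1L, function(v) v[which(v != 0)[1]] > 0)
  o[keep, , drop = FALSE]
}

# index ranges such that src + offset = dst, both in-bounds
shiftRanges <- function(d, off) {
  src <- vector("list", 3L)
  dst <- vector("list", 3L)
  for (k in 1:3) {
    s <- max(1L, 1L - off[k]):min(d[k], d[k] - off[k])
    if (length(s) == 0L || s[1] > s[length(s)]) return(NULL)
    src[[k]] <- s
    dst[[k]] <- s + off[k]
  }
  list(src = src, dst = dst)
}
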