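# Independent reference implementations used to cross-check the package's
# fast paths, plus small fixture builders.  The oracles are deliberately
# naive (plain-R loops, set arithmetic) and share no code with the package.

# Brute-force voxel-loop Dice coefficient.
oracleDSC <- function(P, M) {
  p <- 0L; m <- 0L; inter <- 0L
  for (i in seq_along(P)) {
    if (P[i]) p <- p + 1L
    if (M[i]) m <- m + 1L
    if (P[i] && M[i]) inter <- inter + 1L
  }
  if (p + m == 0L) return(1)
  2 * inter / (p + m)
}

# Breadth-first flood fill over a logical 3D array; returns component ids
# in raster order of the seed voxel, like the package's extractor.
oracleFloodFill <- function(mask, connectivity = 26L) {
  dims <- dim(mask)
  lab <- array(0L, dims)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  if (connectivity == 18L) offs <- offs[rowSums(abs(offs)) <= 2, , drop = FALSE]
  nxt <- 0L
  stack <- matrix(0L, prod(dims), 3)
  for (x in seq_len(dims[3])) for (y in seq_len(dims[2]))
    for (z in seq_len(dims[1])) {
      if (!mask[z, y, x] || lab[z, y, x] > 0L) next
      nxt <- nxt + 1L
      top <- 1L
      stack[1, ] <- c(z, y, x)
      lab[z, y, x] <- nxt
      while (top > 0L) {
        v <- stack[top, ]; top <- top - 1L
        for (r in seq_len(nrow(offs))) {
          w <- v + offs[r, ]
          if (any(w < 1L) || any(w > dims)) next
          if (mask[w[1], w[2], w[3]] && lab[w[1], w[2], w[3]] == 0L) {
            lab[w[1], w[2], w[3]] <- nxt
            top <- top + 1L
            stack[top, ] <- w
          }
        }
      }
    }
  lab
}

# A small label volume holding the given cuboid blobs:
# blobs = list(list(label=, z=, y=, x=)) with index ranges.
blobVolume <- function(dims, blobs, spacing = c(1, 1, 1)) {
  v <- array(0L, dims)
  for (b in blobs) v[b$z, b$y, b$x] <- as.integer(b$label)
  labelVolume(v, spacing)
}

# Voxel index set of one label in a volume (for set-arithmetic oracles).
voxelSet <- function(vol, label) which(voxelData(vol) == label)

deskPhantom <- function(seed = 1L, ...) {
  generateLabelPhantom(phantomConfig(seed = seed, ...))
}
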