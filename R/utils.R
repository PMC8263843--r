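`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls never disturb user RNG.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

stopIfNot3D <- function(values, what = "volume") {
  if (length(dim(values)) != 3L)
    stop(sprintf("%s must be a 3D (z, y, x) array", what))
}

checkSameGeometry <- function(a, b) {
  if (!identical(dim(a@values), dim(b@values)))
    stop(sprintf("geometry mismatch: %s vs %s voxels",
                 paste(dim(a@values), collapse = "x"),
                 paste(dim(b@values), collapse = "x")))
  if (max(abs(a@spacing - b@spacing)) > 1e-6)
    stop("geometry mismatch: voxel spacings differ")
  invisible(TRUE)
}

# 1-based linear index <-> (z, y, x) 1-based coordinates for dim (Z, Y, X)
linearToZyx <- function(idx, dims) {
  i0 <- idx - 1L
  z <- i0 %% dims[1]
  y <- (i0 %/% dims[1]) %% dims[2]
  x <- i0 %/% (dims[1] * dims[2])
  cbind(z = z + 1L, y = y + 1L, x = x + 1L)
}

zyxToLinear <- function(zyx, dims) {
  (zyx[, 1] - 1L) + dims[1] * (zyx[, 2] - 1L) +
    dims[1] * dims[2] * (zyx[, 3] - 1L) + 1L
}
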