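# Connected-component labelling and hole filling on 3D logical arrays.
# No morphology package is available in the supported toolchain, so these are
# implemented as vectorised breadth-first floods on a zero-padded grid.

neighbour_offsets <- function(dp, connectivity) {
  steps <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  steps <- steps[!(steps$dx == 0 & steps$dy == 0 & steps$dz == 0), ]
  if (connectivity == 6L) {
    steps <- steps[abs(steps$dx) + abs(steps$dy) + abs(steps$dz) == 1L, ]
  } else if (connectivity != 26L) {
    stop("connectivity must be 6 or 26", call. = FALSE)
  }
  as.integer(steps$dx + steps$dy * dp[1] + steps$dz * dp[1] * dp[2])
}

# Label connected components; returns an integer array (0 = background).
label_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  dp <- d + 2L
  arr <- array(FALSE, dp)
  arr[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  offs <- neighbour_offsets(dp, connectivity)
  labels <- integer(prod(dp))
  todo <- arr
  seeds <- which(arr)
  lab <- 0L
  for (s in seeds) {
    if (!todo[s]) next
    lab <- lab + 1L
    frontier <- s
    todo[s] <- FALSE
    labels[s] <- lab
    while (length(frontier)) {
      nb <- rep(frontier, each = length(offs)) + offs
      nb <- nb[todo[nb]]
      if (!length(nb)) break
      nb <- unique(nb)
      labels[nb] <- lab
      todo[nb] <- FALSE
      frontier <- nb
    }
  }
  dim(labels) <- dp
  labels[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)]
}

# Fill cavities: background voxels not 6-connected to the array border.
fill_holes <- function(mask) {
  d <- dim(mask)
  dp <- d + 2L
  arr <- array(FALSE, dp)
  arr[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  bg <- !arr
  offs <- neighbour_offsets(dp, 6L)
  reached <- logical(prod(dp))
  # all padded-border voxels are background and seed the outside flood
  border <- which(bg)
  coords <- arrayInd(border, dp)
  on_border <- coords[, 1] %in% c(1L, dp[1]) | coords[, 2] %in% c(1L, dp[2]) |
    coords[, 3] %in% c(1L, dp[3])
  frontier <- border[on_border]
  reached[frontier] <- TRUE
  bgv <- as.vector(bg)
  while (length(frontier)) {
    nb <- rep(frontier, each = length(offs)) + offs
    nb <- nb[nb >= 1L & nb <= length(reached)]
    nb <- nb[bgv[nb] & !reached[nb]]
    if (!length(nb)) break
    nb <- unique(nb)
    reached[nb] <- TRUE
    frontier <- nb
  }
  holes <- bgv & !reached
  out <- as.vector(arr) | holes
  dim(out) <- dp
  out[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)]
}
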