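# Internal helpers shared across modules: seeded evaluation, moment matching,
# voxel geometry, and 3D binary-mask morphology (no installed R package offers
# 3D label morphology, so the few primitives needed are implemented here).

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random state.
.with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

# Log-normal (meanlog, sdlog) whose mean and sd equal the given moments.
.lnorm_params <- function(mean, sd) {
  if (any(mean <= 0) || any(sd <= 0))
    stop("log-normal moment matching needs mean > 0 and sd > 0")
  s2 <- log1p((sd / mean)^2)
  cbind(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# Voxel-centre coordinates (mm) for linear indices into a 3D grid.
# Voxel indexing is 0-based; the centre of voxel (0,0,0) sits at spacing/2.
.voxel_coords <- function(idx, dim, spacing) {
  ai <- arrayInd(idx, dim)
  sweep(ai - 0.5, 2, spacing, `*`)
}

# ---- 3D binary morphology (6-connectivity) --------------------------------

# Embed a logical mask in a FALSE border of `pad` voxels.
.pad3 <- function(mask, pad = 1L) {
  d <- dim(mask)
  out <- array(FALSE, d + 2L * pad)
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- mask
  out
}

.unpad3 <- function(mask, d, pad = 1L) {
  array(mask[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])], d)
}

.neighbour_offsets <- function(dp) {
  c(-1L, 1L, -dp[1], dp[1], -dp[1] * dp[2], dp[1] * dp[2])
}

# Connected-component labelling of a logical 3D mask by breadth-first
# frontier expansion. Returns an integer array of the same shape (0 =
# background, components numbered in discovery order).
.components3d <- function(mask) {
  d <- dim(mask)
  m <- .pad3(mask)
  dp <- dim(m)
  offs <- .neighbour_offsets(dp)
  lab <- array(0L, dp)
  todo <- which(m)
  comp <- 0L
  while (length(todo)) {
    todo <- todo[lab[todo] == 0L]
    if (!length(todo)) break
    comp <- comp + 1L
    frontier <- todo[1L]
    lab[frontier] <- comp
    while (length(frontier)) {
      nb <- unique(as.vector(outer(frontier, offs, `+`)))
      nb <- nb[m[nb] & lab[nb] == 0L]
      lab[nb] <- comp
      frontier <- nb
    }
  }
  .unpad3(lab, d)
}

# Fill interior cavities: background voxels not reachable from the array
# border become foreground.
.fill_holes3d <- function(mask) {
  d <- dim(mask)
  m <- .pad3(mask)
  dp <- dim(m)
  offs <- .neighbour_offsets(dp)
  bg <- !m
  reach <- array(FALSE, dp)
  frontier <- 1L  # padding corner, always background and outside
  reach[frontier] <- TRUE
  while (length(frontier)) {
    nb <- unique(as.vector(outer(frontier, offs, `+`)))
    nb <- nb[nb >= 1L & nb <= length(m)]
    nb <- nb[bg[nb] & !reach[nb]]
    reach[nb] <- TRUE
    frontier <- nb
  }
  .unpad3(m | (bg & !reach), d)
}

# One 6-neighbour erosion / dilation pass on a padded logical array.
.shift_lin <- function(m, off) {
  n <- length(m)
  s <- array(FALSE, dim(m))
  if (off > 0) s[(off + 1L):n] <- m[1L:(n - off)]
  else s[1L:(n + off)] <- m[(1L - off):n]
  s
}

.erode1 <- function(mp) {
  out <- mp
  for (off in .neighbour_offsets(dim(mp))) out <- out & .shift_lin(mp, off)
  out
}

.dilate1 <- function(mp) {
  out <- mp
  for (off in .neighbour_offsets(dim(mp))) out <- out | .shift_lin(mp, off)
  # linear shifts can leak into the 1-voxel padding; clear it
  d <- dim(mp)
  out[c(1L, d[1]), , ] <- FALSE
  out[, c(1L, d[2]), ] <- FALSE
  out[, , c(1L, d[3])] <- FALSE
  out
}

# Signed step distance to the mask surface, clipped at K shells: +k for the
# k-th inside shell, -k for the k-th outside shell, +/-(K+1) beyond.
.signed_shells <- function(mask, K) {
  d <- dim(mask)
  mp <- .pad3(mask, K + 1L)
  steps <- array(0L, dim(mp))
  cur <- mp
  for (k in seq_len(K)) {
    nxt <- .erode1(cur)
    steps[cur & !nxt] <- k
    cur <- nxt
  }
  steps[cur] <- K + 1L
  cur <- mp
  for (k in seq_len(K)) {
    nxt <- .dilate1(cur)
    steps[nxt & !cur] <- -k
    cur <- nxt
  }
  steps[!cur] <- -(K + 1L)
  .unpad3(steps, d, K + 1L)
}

# Spatially smooth Gaussian noise field rescaled to a target sd (box blur
# along each axis, edge-replicated), used to displace structure boundaries.
.smooth_noise_field <- function(d, sd_target, passes = 2L) {
  n <- array(rnorm(prod(d)), d)
  for (p in seq_len(passes)) {
    n <- (n[c(1L, seq_len(d[1] - 1L)), , , drop = FALSE] + n +
            n[c(seq_len(d[1] - 1L) + 1L, d[1]), , , drop = FALSE]) / 3
    n <- (n[, c(1L, seq_len(d[2] - 1L)), , drop = FALSE] + n +
            n[, c(seq_len(d[2] - 1L) + 1L, d[2]), , drop = FALSE]) / 3
    n <- (n[, , c(1L, seq_len(d[3] - 1L)), drop = FALSE] + n +
            n[, , c(seq_len(d[3] - 1L) + 1L, d[3]), drop = FALSE]) / 3
  }
  n * (sd_target / stats::sd(n))
}
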