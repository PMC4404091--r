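# Independent oracles and small fixture builders used across the suite.
# Everything here is brute force or closed form, deliberately ignorant of the
# package's own algorithms.

# exact one-tailed signed-rank p-value by enumerating all 2^n sign patterns
# (midranks for tied magnitudes, zeros assumed already removed)
enum_signed_rank_p <- function(d, alternative = "greater") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  w_all <- apply(signs, 1, function(s) sum(r[s]))
  if (alternative == "greater") mean(w_all >= w_obs - 1e-12)
  else mean(w_all <= w_obs + 1e-12)
}

# exact one-tailed Mann-Whitney p by enumerating all C(m+n, m) assignments
# of the pooled values to the x sample (tie-free data)
enum_mann_whitney_p <- function(x, y, alternative = "greater") {
  pooled <- c(x, y)
  m <- length(x)
  u_stat <- function(xx, yy) sum(outer(xx, yy, `>`)) + 0.5 * sum(outer(xx, yy, `==`))
  u_obs <- u_stat(x, y)
  combs <- utils::combn(length(pooled), m)
  u_all <- apply(combs, 2, function(ix) u_stat(pooled[ix], pooled[-ix]))
  if (alternative == "greater") mean(u_all >= u_obs - 1e-12)
  else mean(u_all <= u_obs + 1e-12)
}

# icosphere: subdivided icosahedron projected onto a sphere, outward oriented
icosphere <- function(radius = 1, center = c(0, 0, 0), subdivisions = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    edge_mid <- new.env()
    mid <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- edge_mid[[key]]
      if (!is.null(id)) return(id)
      p <- v[a, ] + v[b, ]
      p <- p / sqrt(sum(p^2))
      v <<- rbind(v, p)
      id <- nrow(v)
      edge_mid[[key]] <- id
      id
    }
    f2 <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- mid(a, b); bc <- mid(b, c_); ca <- mid(c_, a)
      f2[(4 * i - 3):(4 * i), ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc), c(ab, bc, ca))
    }
    f <- f2
  }
  surface_mesh(sweep(v * radius, 2, center, `+`), f)
}

# axis-aligned box mesh (12 triangles, outward oriented)
box_mesh <- function(lo = c(0, 0, 0), hi = c(1, 1, 1)) {
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  # vertex order: x fastest; faces wound so normals point outward
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = lo
    c(5, 6, 7), c(6, 8, 7),   # z = hi
    c(1, 2, 5), c(2, 6, 5),   # y = lo
    c(3, 7, 4), c(4, 7, 8),   # y = hi
    c(1, 5, 3), c(3, 5, 7),   # x = lo
    c(2, 4, 6), c(4, 8, 6)    # x = hi
  )
  surface_mesh(v, f)
}

# sphere-only mask on an isotropic grid
sphere_mask <- function(dims, spacing, center, radius) {
  ax <- lapply(1:3, function(a) (seq_len(dims[a]) - 1) * spacing)
  x <- array(rep(ax[[1]], times = dims[2] * dims[3]), dims)
  y <- array(rep(rep(ax[[2]], each = dims[1]), times = dims[3]), dims)
  z <- array(rep(ax[[3]], each = dims[1] * dims[2]), dims)
  binary_mask((x - center[1])^2 + (y - center[2])^2 + (z - center[3])^2 <=
                radius^2, spacing = spacing)
}

# solid torus mask (through-hole along z)
torus_mask <- function(dims, spacing, center, R, r) {
  ax <- lapply(1:3, function(a) (seq_len(dims[a]) - 1) * spacing)
  x <- array(rep(ax[[1]], times = dims[2] * dims[3]), dims)
  y <- array(rep(rep(ax[[2]], each = dims[1]), times = dims[3]), dims)
  z <- array(rep(ax[[3]], each = dims[1] * dims[2]), dims)
  rho <- sqrt((x - center[1])^2 + (y - center[2])^2)
  binary_mask((rho - R)^2 + (z - center[3])^2 <= r^2, spacing = spacing)
}

# straight-tube-plus-sphere "aneurysm on a vessel" image, noiseless option
tube_sphere_volume <- function(dims = c(48, 48, 48), spacing = 0.22,
                               sphere_center = NULL, sphere_r = 2.2,
                               tube_r = 1, noise_sd = 0, seed = 1) {
  ext <- (dims - 1) * spacing
  if (is.null(sphere_center)) sphere_center <- ext / 2
  ax <- lapply(1:3, function(a) (seq_len(dims[a]) - 1) * spacing)
  x <- array(rep(ax[[1]], times = dims[2] * dims[3]), dims)
  y <- array(rep(rep(ax[[2]], each = dims[1]), times = dims[3]), dims)
  z <- array(rep(ax[[3]], each = dims[1] * dims[2]), dims)
  y0 <- max(sphere_center[2] - 0.92 * (sphere_r + tube_r),
            tube_r + 2 * spacing)
  tube <- sqrt((y - y0)^2 + (z - sphere_center[3])^2) <= tube_r
  sph <- (x - sphere_center[1])^2 + (y - sphere_center[2])^2 +
    (z - sphere_center[3])^2 <= sphere_r^2
  set.seed(seed)
  img <- 10 + 90 * (tube | sph) + rnorm(prod(dims), 0, noise_sd)
  dim(img) <- dims
  list(vol = image_volume(img, spacing = spacing),
       truth_sphere = sph, truth_tube = tube,
       sphere_center = sphere_center, sphere_r = sphere_r,
       spacing = spacing)
}

# number of foreground voxels with at least one 6-neighbour background voxel
surface_voxel_count <- function(mask) {
  m <- mask$values
  d <- dim(m)
  pad <- array(FALSE, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  inner <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  sum(inner & !nb)
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
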