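# Independent brute-force oracles used to check the package's fast paths.
# These deliberately share no code with the implementation.

# Random binary mask as a label_mask
random_mask <- function(shape = c(16, 16, 16), p = 0.4, spacing = 1) {
  label_mask(array(as.integer(runif(prod(shape)) < p), dim = shape),
             spacing = voxel_spacing(spacing))
}

# Neighbour offsets for a connectivity
conn_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  m <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6" = m == 1, "18" = m >= 1 & m <= 2, "26" = m >= 1)
  off[keep, , drop = FALSE]
}

# Flood-fill component labelling, plain R depth-first stack over linear
# indices with explicit coordinate arithmetic
oracle_components <- function(arr, connectivity = 26) {
  fg <- arr != 0
  d <- dim(arr); nx <- d[1]; ny <- d[2]; nz <- d[3]
  off <- conn_offsets(connectivity)
  no <- nrow(off)
  lab <- integer(length(fg))
  nextlab <- 0L
  for (start in which(fg)) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    lab[start] <- nextlab
    stack <- start
    while (length(stack)) {
      cur <- stack[length(stack)]; stack <- stack[-length(stack)]
      c0 <- cur - 1L
      cx <- c0 %% nx; cy <- (c0 %/% nx) %% ny; cz <- c0 %/% (nx * ny)
      for (r in seq_len(no)) {
        x <- cx + off[r, 1]; y <- cy + off[r, 2]; z <- cz + off[r, 3]
        if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) next
        nb <- 1L + x + nx * (y + ny * z)
        if (fg[nb] && lab[nb] == 0L) {
          lab[nb] <- nextlab
          stack <- c(stack, nb)
        }
      }
    }
  }
  dim(lab) <- d
  lab
}

# Sorted list of component voxel-index sets from a label array
oracle_component_sets <- function(lab) {
  sets <- split(which(lab != 0L), lab[lab != 0L])
  unname(sets[order(-lengths(sets), vapply(sets, min, numeric(1)))])
}

# Boundary shell by per-voxel 6-neighbour scan (volume edge = boundary)
oracle_shell <- function(arr) {
  fg <- arr != 0
  d <- dim(arr)
  out <- array(FALSE, dim = d)
  for (v in which(fg)) {
    co <- arrayInd(v, d)
    boundary <- FALSE
    for (a in 1:3) for (s in c(-1L, 1L)) {
      nb <- co; nb[a] <- nb[a] + s
      if (any(nb < 1) || any(nb > d) || !fg[nb[1], nb[2], nb[3]]) boundary <- TRUE
    }
    if (boundary) out[v] <- TRUE
  }
  out
}

# Does any voxel of set A lie within 26-adjacency (or equality) of set B?
oracle_adjacent26 <- function(idx_a, idx_b, d) {
  ca <- arrayInd(idx_a, d); cb <- arrayInd(idx_b, d)
  for (i in seq_len(nrow(ca))) {
    dd <- abs(sweep(cb, 2, ca[i, ]))
    if (any(apply(dd, 1, max) <= 1)) return(TRUE)
  }
  FALSE
}

# All-pairs in-plane axis measurement for a set of 3D voxel coordinates
oracle_axes <- function(coords0, spacing) {
  s <- unclass(spacing)
  best <- list(major_mm = -1, minor_mm = 0, slice_index = NA_integer_)
  for (z in sort(unique(coords0[, 3]))) {
    pts <- coords0[coords0[, 3] == z, 1:2, drop = FALSE]
    n <- nrow(pts)
    px <- pts[, 1] * s[1]; py <- pts[, 2] * s[2]
    maj2 <- 0; pair <- c(1L, 1L)
    if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d2 <- (px[j] - px[i])^2 + (py[j] - py[i])^2
      if (d2 > maj2) { maj2 <- d2; pair <- c(i, j) }
    }
    major <- sqrt(maj2)
    minor <- 0
    if (maj2 > 0) {
      u <- c(px[pair[2]] - px[pair[1]], py[pair[2]] - py[pair[1]])
      u <- u / sqrt(sum(u^2))
      proj <- px * (-u[2]) + py * u[1]
      minor <- max(proj) - min(proj)
    }
    if (major > best$major_mm)
      best <- list(major_mm = major, minor_mm = minor, slice_index = z)
  }
  best
}

# Counting-based metric oracles on plain arrays
oracle_dsc <- function(G, S) {
  g <- sum(G != 0); s <- sum(S != 0); i <- sum(G != 0 & S != 0)
  if (g + s == 0) 1 else 2 * i / (g + s)
}
oracle_avd <- function(G, S, v) v * abs(sum(G != 0) - sum(S != 0))
oracle_rvd <- function(G, S) abs(sum(G != 0) - sum(S != 0)) / sum(G != 0)

# Exact two-sided rank-sum p by full enumeration (doubled tail, capped at 1)
oracle_ranksum_p <- function(a, b) {
  m <- length(a); n <- length(b); N <- m + n
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  u_all <- apply(combn(N, m), 2, function(s) sum(r[s]) - m * (m + 1) / 2)
  eps <- 1e-9
  p <- if (u_obs > m * n / 2) 2 * mean(u_all >= u_obs - eps)
       else 2 * mean(u_all <= u_obs + eps)
  min(1, p)
}

# Small phantom spec for fast per-seed loops (48^3 keeps geometry ratios)
small_phantom_spec <- function(seed = 1L, ...) {
  phantom_spec(shape = c(48L, 48L, 48L), spacing_mm = 2,
               lung_centers = rbind(c(13, 24, 24), c(34, 24, 24)),
               lung_semiaxes = rbind(c(8, 13, 17), c(8, 13, 17)),
               lesions = list(
                 list(category = "parenchymal", center = c(13, 24, 30),
                      radius_vox = 3),
                 list(category = "mediastinal", center = c(23.5, 19, 24),
                      radius_vox = c(4, 4, 5)),
                 list(category = "pleural", side = 1L, thickness_vox = 2,
                      y_halfwidth_vox = 5, z_halfheight_vox = 6)),
               seed = seed, ...)
}
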