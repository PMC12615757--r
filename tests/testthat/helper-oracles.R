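# Independent slow oracles used to validate the fast implementations.
# All are written in plain R against first-principles definitions and are
# only ever run on tiny grids.

# breadth-first connected-component labeling
oracle_label <- function(mask, connectivity = 26) {
  d <- dim(mask)
  lab <- array(0L, d)
  nb <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nb <- nb[rowSums(nb != 0) > 0, ]
  if (connectivity == 6) nb <- nb[rowSums(abs(nb)) == 1, ]
  nxt <- 0L
  for (seed in which(mask & lab == 0L)) {
    if (lab[seed] != 0L) next
    nxt <- nxt + 1L
    queue <- seed
    lab[seed] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      ijk <- arrayInd(cur, d)
      for (r in seq_len(nrow(nb))) {
        p <- ijk + nb[r, ]
        if (any(p < 1) || any(p > d)) next
        q <- p[1] + d[1] * ((p[2] - 1) + d[2] * (p[3] - 1))
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- nxt
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

oracle_n_components <- function(mask, connectivity = 26) {
  max(oracle_label(mask, connectivity))
}

# brute-force largest-inscribed-sphere local thickness (voxel units):
# for each phase voxel c, r2(c) = min squared distance to an
# opposite-phase voxel center; thickness(p) = 2*sqrt(max r2 over spheres
# covering p) - 1, the same discrete convention as the implementation
oracle_thickness <- function(mask) {
  d <- dim(mask)
  fg <- which(mask)
  bg <- which(!mask)
  stopifnot(length(fg) > 0, length(bg) > 0)
  co <- function(idx) arrayInd(idx, d)
  F <- co(fg); B <- co(bg)
  r2 <- vapply(seq_len(nrow(F)), function(i) {
    min(colSums((t(B) - F[i, ])^2))
  }, numeric(1))
  th <- numeric(length(fg))
  for (i in seq_len(nrow(F))) {
    cover <- colSums((t(F) - F[i, ])^2) < r2  # spheres centered anywhere
    th[i] <- max(th[i], 0)
    for (j in which(cover)) th[i] <- max(th[i], r2[j])
  }
  out <- array(0, d)
  out[fg] <- 2 * sqrt(th) - 1
  out
}

# direct line walk along an array axis: bone sample count and number of
# void(or outside)-to-bone transitions over all voxel columns
oracle_axis_intercepts <- function(mask, axis = 3) {
  d <- dim(mask)
  perm <- switch(axis, c(2, 3, 1), c(1, 3, 2), c(1, 2, 3))
  m <- aperm(mask, perm)
  dm <- dim(m)
  total_bone <- 0L
  intercepts <- 0L
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) {
    line <- m[i, j, ]
    total_bone <- total_bone + sum(line)
    intercepts <- intercepts + sum(diff(c(FALSE, line)) == 1L)
  }
  list(bone = total_bone, intercepts = intercepts)
}

# exhaustive-search Otsu: maximize between-class variance over all bin
# splits of an n-bin histogram
oracle_otsu <- function(values, n_bins = 128L) {
  rng <- range(values)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- pmin(findInterval(values, edges, rightmost.closed = TRUE), n_bins)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  best <- -Inf; best_t <- NA
  for (t in 1:(n_bins - 1)) {
    lo <- bin <= t
    w0 <- mean(lo); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- mean(centers[bin[lo]]); mu1 <- mean(centers[bin[!lo]])
    bcv <- w0 * w1 * (mu0 - mu1)^2
    if (bcv > best) { best <- bcv; best_t <- t }
  }
  edges[best_t + 1]
}

# dense direct-solve KUBC homogenization (energy route) via sparse
# Cholesky on the assembled system — independent of the PCG path
oracle_homogenize_dense <- function(roi, material = tissue_material()) {
  mask <- roi$mask; d <- dim(mask); h <- roi$spacing_mm
  Ke <- hex8_element_stiffness(material, h)
  nn <- d + 1L; nnode <- prod(nn)
  nid <- function(x, y, z) x + nn[1] * (y + nn[2] * z)  # 0-based
  elems <- which(mask, arr.ind = TRUE) - 1L
  ne <- nrow(elems)
  dof_list <- matrix(0L, ne, 24)
  for (e in seq_len(ne)) {
    nodes <- integer(8); t <- 1
    for (dk in 0:1) for (dj in 0:1) for (di in 0:1) {
      nodes[t] <- nid(elems[e, 1] + di, elems[e, 2] + dj, elems[e, 3] + dk)
      t <- t + 1
    }
    dof_list[e, ] <- as.vector(t(cbind(3 * nodes, 3 * nodes + 1, 3 * nodes + 2))) + 1L
  }
  ii <- matrix(0L, 576, ne); jj <- matrix(0L, 576, ne)
  for (e in seq_len(ne)) {
    ii[, e] <- rep(dof_list[e, ], times = 24)
    jj[, e] <- rep(dof_list[e, ], each = 24)
  }
  K <- Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj),
                            x = rep(as.vector(Ke), ne),
                            dims = c(3 * nnode, 3 * nnode))
  coords <- as.matrix(expand.grid(x = 0:d[1], y = 0:d[2], z = 0:d[3]))
  bnd <- coords[, 1] == 0 | coords[, 2] == 0 | coords[, 3] == 0 |
    coords[, 1] == d[1] | coords[, 2] == d[2] | coords[, 3] == d[3]
  attached <- rep(FALSE, nnode)
  attached[unique(as.vector((dof_list[, seq(1, 24, by = 3)] - 1L) %/% 3L)) + 1L] <- TRUE
  freed <- rep(!bnd & attached, each = 3)
  s2 <- sqrt(0.5)
  Emats <- list(diag(c(1, 0, 0)), diag(c(0, 1, 0)), diag(c(0, 0, 1)),
                matrix(c(0, 0, 0, 0, 0, s2, 0, s2, 0), 3, 3),
                matrix(c(0, 0, s2, 0, 0, 0, s2, 0, 0), 3, 3),
                matrix(c(0, s2, 0, s2, 0, 0, 0, 0, 0), 3, 3))
  X <- coords * h
  U <- matrix(0, 3 * nnode, 6)
  for (a in 1:6) {
    u <- as.vector(t(X %*% t(Emats[[a]])))
    u[freed] <- 0
    rhs <- -(K %*% u)[freed]
    u[freed] <- as.vector(Matrix::solve(K[freed, freed], rhs))
    U[, a] <- u
  }
  V <- prod(d) * h^3
  S <- as.matrix(Matrix::crossprod(U, K %*% U)) / V
  (S + t(S)) / 2
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
oracle_mw_exact <- function(a, b) {
  n <- length(a) + length(b)
  vals <- c(a, b)
  idx <- utils::combn(n, length(a))
  rk <- rank(vals)
  w_obs <- sum(rk[seq_along(a)])
  ws <- apply(idx, 2, function(s) sum(rk[s]))
  mu <- length(a) * (n + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# greedy matching oracle: repeatedly pick the globally closest pair in
# standardized space
oracle_match <- function(A, B) {
  sdp <- apply(rbind(A, B), 2, sd)
  sdp[sdp == 0] <- 1
  A <- sweep(A, 2, sdp, "/"); B <- sweep(B, 2, sdp, "/")
  out <- NULL
  ai <- seq_len(nrow(A)); bi <- seq_len(nrow(B))
  while (length(ai) && length(bi)) {
    D <- outer(ai, bi, Vectorize(function(i, j) sqrt(sum((A[i, ] - B[j, ])^2))))
    w <- arrayInd(which.min(D), dim(D))
    out <- rbind(out, c(ai[w[1]], bi[w[2]], min(D)))
    ai <- ai[-w[1]]; bi <- bi[-w[2]]
  }
  out
}
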