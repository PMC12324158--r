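# Independent brute-force oracles. These deliberately avoid the package's
# spatial index, hull routine and K-S internals so that agreement is a real
# cross-check, not a tautology.

# Exhaustive neighborhood-expansion DBSCAN on the full distance matrix.
oracle_dbscan <- function(x, y, radius, min_count) {
  n <- length(x)
  if (n == 0) return(integer(0))
  D <- as.matrix(dist(cbind(x, y)))
  dimnames(D) <- NULL
  adj <- D <= radius
  core <- rowSums(adj) >= min_count
  lab <- integer(n)
  cid <- 0
  for (i in seq_len(n)) {
    if (!core[i] || lab[i] != 0) next
    cid <- cid + 1
    queue <- i
    lab[i] <- cid
    while (length(queue) > 0) {
      u <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[u, ] & core & lab == 0)
      lab[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  for (i in which(!core)) {
    cn <- which(adj[i, ] & core)
    if (length(cn) > 0) {
      d <- D[i, cn]
      nearest <- cn[d == min(d)]
      lab[i] <- min(lab[nearest])  # ties -> lowest cluster id
    }
  }
  # canonical ids ordered by lowest member row index
  pos <- lab > 0
  ids <- unique(lab[pos])
  map <- integer(max(c(0L, lab)))
  map[ids] <- seq_along(ids)
  out <- integer(n)
  out[pos] <- map[lab[pos]]
  out
}

# Exhaustive O(n*m) nearest-neighbor distances.
oracle_nnd <- function(qx, qy, rx, ry, exclude_self = FALSE) {
  M <- sqrt(outer(qx, rx, "-")^2 + outer(qy, ry, "-")^2)
  if (exclude_self) diag(M) <- Inf
  apply(M, 1, min)
}

# Gift-wrapping (Jarvis march) convex hull area, independent of chull().
oracle_hull_area <- function(coords) {
  pts <- unique(coords)
  n <- nrow(pts)
  if (n < 3) return(0)
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  start <- which.min(pts[, 1] + 1e-12 * pts[, 2])
  hull <- integer(0)
  p <- start
  repeat {
    hull <- c(hull, p)
    q <- if (p == 1) 2 else 1
    for (r in seq_len(n)) {
      if (r == p) next
      cr <- cross(pts[p, ], pts[q, ], pts[r, ])
      if (cr < 0) q <- r
      else if (cr == 0) {
        # collinear: take the farther point
        dq <- sum((pts[q, ] - pts[p, ])^2)
        dr <- sum((pts[r, ] - pts[p, ])^2)
        if (dr > dq) q <- r
      }
    }
    p <- q
    if (p == start) break
    if (length(hull) > n) break  # degenerate safety
  }
  if (length(hull) < 3) return(0)
  xy <- pts[hull, , drop = FALSE]
  i2 <- c(2:nrow(xy), 1)
  abs(sum(xy[, 1] * xy[i2, 2] - xy[i2, 1] * xy[, 2])) / 2
}

# K-S statistic by direct evaluation of both ECDFs at every pooled point.
oracle_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  dmax <- 0
  for (t in pts) {
    d <- abs(mean(x <= t) - mean(y <= t))
    if (d > dmax) dmax <- d
  }
  dmax
}

# Canonical partition signature: list of member-index sets keyed by cluster,
# comparable across label permutations.
partition_signature <- function(labels) {
  unname(lapply(split(which(labels > 0), labels[labels > 0]), sort))
}
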