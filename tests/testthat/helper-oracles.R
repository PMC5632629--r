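# Independent oracles used to cross-check the implementation. These are
# deliberately naive (scan loops, dense eigensolvers, O(n^3) agglomeration)
# and share no code with the package internals.

# Exhaustive dive scan: walk the depth vector sample by sample, collect
# maximal submergence runs, filter by duration and depth thresholds.
brute_detect_dives <- function(depth, surface = 1, min_depth = 10, min_dur = 60) {
  out <- list()
  i <- 1L
  n <- length(depth)
  while (i <= n) {
    if (depth[i] > surface) {
      j <- i
      while (j < n && depth[j + 1] > surface) j <- j + 1L
      len <- j - i + 1L
      md <- max(depth[i:j])
      if (len > min_dur && md > min_depth) {
        out[[length(out) + 1]] <- c(start = i, end = j, max_depth = md)
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), end = integer(), max_depth = numeric()))
  }
  as.data.frame(do.call(rbind, out))
}

# Exhaustive nearest-cell bathymetry lookup.
brute_bathy_lookup <- function(grid, lon, lat) {
  vapply(seq_along(lon), function(k) {
    i <- which.min(abs(grid$lon - lon[k]))
    j <- which.min(abs(grid$lat - lat[k]))
    grid$depth[i, j]
  }, numeric(1))
}

# Closed-form haversine (independent of geosphere), R = 6371 km.
brute_haversine_km <- function(lon1, lat1, lon2, lat2) {
  rl <- pi / 180
  dphi <- (lat2 - lat1) * rl
  dlam <- (lon2 - lon1) * rl
  a <- sin(dphi / 2)^2 + cos(lat1 * rl) * cos(lat2 * rl) * sin(dlam / 2)^2
  2 * 6371 * asin(sqrt(a))
}

# Naive O(n^3) Ward agglomeration (Lance-Williams update on Euclidean
# distances, ward.D2 form). Returns merge heights (sorted) and the labels
# obtained by stopping at k clusters.
naive_ward <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  active <- seq_len(n)
  members <- as.list(seq_len(n))
  sizes <- rep(1, n)
  heights <- numeric(0)
  labels_at_k <- NULL
  while (length(active) > 1) {
    if (length(active) == k) {
      labels_at_k <- integer(n)
      for (ci in seq_along(active)) labels_at_k[members[[active[ci]]]] <- ci
    }
    best <- c(Inf, NA, NA)
    for (a in seq_along(active)) for (b in seq_len(a - 1)) {
      ia <- active[a]; ib <- active[b]
      if (d[ia, ib] < best[1]) best <- c(d[ia, ib], ia, ib)
    }
    ia <- best[2]; ib <- best[3]
    heights <- c(heights, best[1])
    ni <- sizes[ia]; nj <- sizes[ib]
    for (ic in setdiff(active, c(ia, ib))) {
      nk <- sizes[ic]
      nd <- sqrt(((ni + nk) * d[ia, ic]^2 + (nj + nk) * d[ib, ic]^2 -
                    nk * d[ia, ib]^2) / (ni + nj + nk))
      d[ia, ic] <- nd; d[ic, ia] <- nd
    }
    members[[ia]] <- c(members[[ia]], members[[ib]])
    sizes[ia] <- ni + nj
    active <- setdiff(active, ib)
  }
  if (k == 1) labels_at_k <- rep(1L, n)
  list(heights = sort(heights), labels = labels_at_k)
}

# Agreement of two labelings up to permutation of label values.
same_partition <- function(a, b) {
  ta <- table(a, b)
  sum(ta > 0) == length(unique(a)) && length(unique(a)) == length(unique(b))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
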