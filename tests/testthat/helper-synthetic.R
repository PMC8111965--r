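# synthetic structures and brute-force oracles shared across tests

# random-walk bead chain (fixed step length), optionally confined to a
# sphere of radius R around the origin
rw_chain <- function(n_beads, step = 100, chrom_length = n_beads * 5e4,
                     diameter = 100, R = Inf) {
  pos <- matrix(0, n_beads, 3)
  for (i in seq_len(n_beads)[-1]) {
    repeat {
      s <- stats::rnorm(3)
      cand <- pos[i - 1, ] + s / sqrt(sum(s^2)) * step
      if (sum(cand^2) < R^2) break
    }
    pos[i, ] <- cand
  }
  structure(list(chrom = "chrT",
                 bin_edges = seq(0, chrom_length, length.out = n_beads + 1),
                 bead_diameter = diameter, positions = pos,
                 compartment = rep("A", n_beads)),
            class = "bead_chain")
}

uniform_locs <- function(n, side = 1000) {
  tibble::tibble(x_nm = stats::runif(n, 0, side),
                 y_nm = stats::runif(n, 0, side),
                 z_nm = stats::runif(n, 0, side),
                 source = "background")
}

ball_locs <- function(n, radius = 300) {
  m <- matrix(stats::rnorm(3 * n * 3), ncol = 3)
  m <- m[rowSums(m^2) > 0, , drop = FALSE]
  u <- stats::runif(nrow(m))^(1 / 3)
  m <- m / sqrt(rowSums(m^2)) * u * radius
  m <- m[seq_len(n), , drop = FALSE]
  tibble::tibble(x_nm = m[, 1], y_nm = m[, 2], z_nm = m[, 3],
                 source = "structure")
}

# brute-force gyration radius (naive double loop over the pair-distance
# identity Rg^2 = sum_{i<j} d_ij^2 / N^2)
rg_pairwise_oracle <- function(locs) {
  m <- cbind(locs$x_nm, locs$y_nm, locs$z_nm)
  n <- nrow(m)
  acc <- 0
  for (i in seq_len(n - 1)) {
    d <- m[(i + 1):n, , drop = FALSE] - rep(m[i, ], each = n - i)
    acc <- acc + sum(d^2)
  }
  sqrt(acc / n^2)
}

# convex hull volume by brute-force facet enumeration (gift-wrap style):
# every point triple whose plane has all other points on one side is a hull
# facet; the signed tetrahedra against the origin sum to the volume
convex_hull_volume_oracle <- function(locs) {
  m <- cbind(locs$x_nm, locs$y_nm, locs$z_nm)
  n <- nrow(m)
  vol <- 0
  eps <- 1e-9 * max(abs(m))
  for (i in 1:(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      for (k in (j + 1):n) {
        a <- m[i, ]; b <- m[j, ]; c <- m[k, ]
        nrm <- c((b[2] - a[2]) * (c[3] - a[3]) - (b[3] - a[3]) * (c[2] - a[2]),
                 (b[3] - a[3]) * (c[1] - a[1]) - (b[1] - a[1]) * (c[3] - a[3]),
                 (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
        s <- m %*% nrm - sum(nrm * a)
        if (all(s <= eps)) {
          # outward normal: signed volume of tetra (origin, a, b, c)
          vol <- vol + (a[1] * (b[2] * c[3] - b[3] * c[2]) -
                        a[2] * (b[1] * c[3] - b[3] * c[1]) +
                        a[3] * (b[1] * c[2] - b[2] * c[1])) / 6
        } else if (all(s >= -eps)) {
          vol <- vol - (a[1] * (b[2] * c[3] - b[3] * c[2]) -
                        a[2] * (b[1] * c[3] - b[3] * c[1]) +
                        a[3] * (b[1] * c[2] - b[2] * c[1])) / 6
        }
      }
    }
  }
  abs(vol)
}

# breadth-first search over an adjacency list: indices within graph
# distance k of node i (self included)
bfs_ring_oracle <- function(adjacency, i, k) {
  seen <- i
  frontier <- i
  depth <- 0
  while (depth < k && length(frontier) > 0) {
    nxt <- setdiff(unique(unlist(adjacency[frontier])), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
    depth <- depth + 1
  }
  sort(seen)
}

# two-chromosome desk karyotype used by polymer tests
desk_karyotype <- function(len = 20e6) {
  tibble::tibble(chrom = c("chrA", "chrB"), length = c(len, len))
}
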