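# Shared fixtures and independent oracles used across the test files.

# Independent brute-force ITC oracle: re-solves the 1:1 equilibrium from
# scratch after every injection with its own arithmetic (explicit quadratic
# root, no shared code path with itc_heats()).
oracle_itc_heats <- function(n, kd, dh, baseline, protocol) {
  v0 <- protocol$cell_volume
  vols <- c(protocol$first_volume,
            rep(protocol$inj_volume, protocol$n_inj - 1))
  m_tot <- protocol$cell_conc
  l_tot <- 0
  c_prev <- 0
  heats <- numeric(length(vols))
  for (i in seq_along(vols)) {
    v <- vols[i]
    m_tot <- m_tot * (1 - v / v0)
    l_tot <- l_tot * (1 - v / v0) + protocol$syringe_conc * v / v0
    s <- n * m_tot
    # direct quadratic root (textbook form, small-root formula not used)
    b <- s + l_tot + kd
    cc <- (b - sqrt(b^2 - 4 * s * l_tot)) / 2
    dq <- (cc - c_prev) + (v / v0) * (cc + c_prev) / 2
    heats[i] <- dh * v0 * dq * 1e6 + baseline
    c_prev <- cc
  }
  heats
}

# Toy four-atom coordinate set with a known displacement, for the rotation
# grid-search oracle in the superposition tests.
toy_coords <- function() {
  ref <- matrix(c(0, 0, 0,
                  2, 0, 0,
                  0, 2, 0,
                  0, 0, 2), ncol = 3, byrow = TRUE)
  mob <- ref
  mob[4, ] <- mob[4, ] + c(0, 0, 1)  # one atom displaced by 1 A
  list(reference = ref, mobile = mob)
}

# Brute-force oracle: minimum RMSD over a grid of rotations (Euler angles)
# after centroid alignment.
oracle_min_rmsd <- function(mobile, reference, step = 0.01) {
  a <- sweep(mobile, 2, colMeans(mobile))
  b <- sweep(reference, 2, colMeans(reference))
  best <- Inf
  angles <- seq(-0.3, 0.3, by = step)  # small-angle grid around identity
  rot_mat <- function(ax, ay, az) {
    rx <- matrix(c(1, 0, 0, 0, cos(ax), -sin(ax), 0, sin(ax), cos(ax)), 3,
                 byrow = TRUE)
    ry <- matrix(c(cos(ay), 0, sin(ay), 0, 1, 0, -sin(ay), 0, cos(ay)), 3,
                 byrow = TRUE)
    rz <- matrix(c(cos(az), -sin(az), 0, sin(az), cos(az), 0, 0, 0, 1), 3,
                 byrow = TRUE)
    rx %*% ry %*% rz
  }
  for (ax in angles) for (ay in angles) for (az in angles) {
    r <- rot_mat(ax, ay, az)
    d <- sqrt(mean(rowSums((a %*% r - b)^2)))
    if (d < best) best <- d
  }
  best
}

# Schematic two-strand backbone geometry: N, CA, C, O atoms per residue with
# reciprocal inter-chain N...O contacts at hydrogen-bonding distance (2.2 A,
# 135 degree N-O-C angles). Chain B residue numbering runs antiparallel (or
# parallel) to chain A.
toy_sheet <- function(n_res = 5, antiparallel = TRUE) {
  spacing <- 3.5
  rows <- list()
  for (i in seq_len(n_res)) {
    x <- i * spacing
    rows[[length(rows) + 1]] <- structure_tbl(
      chain = "A", resno = i, resid = "GLY",
      elety = c("N", "CA", "C", "O"),
      x = c(x, x + 0.5, x + 1.0, x),
      y = c(0, -0.5, 0, 1.0), z = 0
    )
    # B residue k sits over A residue j = (antiparallel ? n-k+1 : k)
    k <- i
    xb <- (if (antiparallel) n_res - k + 1 else k) * spacing
    rows[[length(rows) + 1]] <- structure_tbl(
      chain = "B", resno = 100 + k, resid = "GLY",
      elety = c("N", "CA", "C", "O"),
      x = c(xb, xb + 0.5, xb + 1.0, xb),
      y = c(3.2, 3.7, 3.2, 2.2), z = 0
    )
  }
  dplyr::bind_rows(rows)
}

# Minimal guanidinium/carboxylate pair for salt-bridge detection, with the
# N-O separation under control.
toy_bridge <- function(no_dist = 3.0) {
  dplyr::bind_rows(
    structure_tbl("A", 24, "ARG", c("N", "CA", "NH1"),
                  x = c(0, 1, 2), y = 0, z = 0),
    structure_tbl("B", 1567, "GLU", c("N", "CA", "OE1"),
                  x = c(5, 4, 2 + no_dist), y = 0.0, z = 0)
  )
}
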