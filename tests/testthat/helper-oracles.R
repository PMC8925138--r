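# Independent reference implementations used as oracles. These deliberately
# use different formulations than the package internals.

# Dihedral via the projection ("praxeolitic") formulation: project the
# outer bonds onto the plane normal to the central bond and take atan2
# there.
oracle_dihedral <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2
  b1 <- p3 - p2
  b2 <- p4 - p3
  b1 <- b1 / sqrt(sum(b1^2))
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  x <- sum(v * w)
  y <- sum(crossprod_vec(b1, v) * w)
  ang <- atan2(y, x) * 180 / pi
  # praxeolitic sign is opposite to the IUPAC convention used here
  ang <- -ang
  if (ang <= -180) ang <- ang + 360
  ang
}

crossprod_vec <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Planar angle via atan2(|cross|, dot) rather than acos.
oracle_angle <- function(p1, p2, p3) {
  u <- p1 - p2
  v <- p3 - p2
  atan2(sqrt(sum(crossprod_vec(u, v)^2)), sum(u * v)) * 180 / pi
}

# Scalar pairwise geometry recomputation from a backbone, one pair at a
# time.
oracle_pair_geometries <- function(bb) {
  L <- bb$L
  d <- om <- th <- ph <- matrix(NA_real_, L, L)
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (i == j) next
      d[i, j] <- sqrt(sum((bb$cb[i, ] - bb$cb[j, ])^2))
      om[i, j] <- oracle_dihedral(bb$ca[i, ], bb$cb[i, ], bb$cb[j, ],
                                  bb$ca[j, ])
      th[i, j] <- oracle_dihedral(bb$n[i, ], bb$ca[i, ], bb$cb[i, ],
                                  bb$cb[j, ])
      ph[i, j] <- oracle_angle(bb$ca[i, ], bb$cb[i, ], bb$cb[j, ])
    }
  }
  list(dist = d, omega = om, theta = th, phi = ph)
}

# Linear scan over bin edges (half-open [lo, hi); top angular edge wraps
# into the last bin; distance >= 20 A is the no-contact class 0).
oracle_bin <- function(x, objective) {
  spec <- geometry_bin_spec()[[objective]]
  edges <- spec$edges
  if (objective == "dist") {
    if (x >= 20) return(0L)
    if (x < 2) return(1L)
  } else {
    if (x == edges[length(edges)]) return(spec$n - 1L)
  }
  for (k in seq_len(length(edges) - 1L)) {
    if (x >= edges[k] && x < edges[k + 1L]) return(k)
  }
  NA_integer_
}

# Brute-force top-k precision by explicit enumeration of eligible pairs.
oracle_top_k <- function(pred, truth, k_fraction, min_sep) {
  L <- nrow(pred)
  recs <- matrix(0, nrow = L * L, ncol = 4L)
  m <- 0L
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (j - i >= min_sep) {
        m <- m + 1L
        recs[m, ] <- c(i, j, pred[i, j], truth[i, j])
      }
    }
  }
  if (m == 0L) return(NA_real_)
  recs <- recs[seq_len(m), , drop = FALSE]
  ord <- order(-recs[, 3], recs[, 1], recs[, 2])
  n <- max(1, floor(L * k_fraction))
  n <- min(n, m)
  sum(recs[ord[seq_len(n)], 4]) / n
}

# Independent greedy subsamplers working directly from hamming_fraction.
oracle_greedy_min <- function(msa, n) {
  n <- min(n, msa$r)
  sel <- 1L
  while (length(sel) < n) {
    cand <- setdiff(seq_len(msa$r), sel)
    means <- vapply(cand, function(k) {
      mean(vapply(sel, function(s) {
        hamming_fraction(msa$sequences[k], msa$sequences[s])
      }, numeric(1)))
    }, numeric(1))
    sel <- c(sel, cand[which.min(means)])
  }
  sel
}

oracle_greedy_max <- function(msa, n) {
  n <- min(n, msa$r)
  sel <- 1L
  while (length(sel) < n) {
    cand <- setdiff(seq_len(msa$r), sel)
    mins <- vapply(cand, function(k) {
      min(vapply(sel, function(s) {
        hamming_fraction(msa$sequences[k], msa$sequences[s])
      }, numeric(1)))
    }, numeric(1))
    sel <- c(sel, cand[which.max(mins)])
  }
  sel
}
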