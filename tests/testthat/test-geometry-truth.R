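test_that("virtual C-beta has ideal geometry and correct chirality", {
  th <- 111.2 * pi / 180
  n <- c(-1.458, 0, 0)
  ca <- c(0, 0, 0)
  cc <- 1.525 * c(cos(pi - th), sin(pi - th), 0)
  cb <- virtual_cbeta(n, ca, cc)
  expect_equal(sqrt(sum((cb - ca)^2)), 1.53, tolerance = 0.03 / 1.53)
  ang <- function(u, v) acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  expect_lt(abs(ang(n - ca, cb - ca) - 110), 4)      # tetrahedral
  expect_lt(abs(ang(cc - ca, cb - ca) - 110), 4)
  # chirality: Cb lies on the L-amino-acid side of the N-CA-C plane
  normal <- crossprod_vec(ca - n, cc - ca)
  expect_lt(sum(normal * (cb - ca)), 0)
})

test_that("virtual C-beta is equivariant under rigid transforms", {
  n <- c(-1.458, 0, 0); ca <- c(0, 0, 0); cc <- c(0.55, 1.42, 0)
  cb <- virtual_cbeta(n, ca, cc)
  shift <- c(5, 5, 5)
  expect_equal(virtual_cbeta(n + shift, ca + shift, cc + shift), cb + shift,
               tolerance = 1e-12)
  set.seed(3)
  th <- runif(1, 0, 2 * pi)
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3L, 3L,
              byrow = TRUE)
  expect_equal(virtual_cbeta(as.vector(R %*% n), as.vector(R %*% ca),
                             as.vector(R %*% cc)),
               as.vector(R %*% cb), tolerance = 1e-12)
  expect_error(virtual_cbeta(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               "collinear")
})

test_that("dihedrals follow the IUPAC convention", {
  dh <- function(a, b, c, d) {
    msageom:::dihedral_deg(matrix(a, 1L), matrix(b, 1L), matrix(c, 1L),
                           matrix(d, 1L))
  }
  # planar trans and cis
  expect_equal(dh(c(-1, 1, 0), c(-1, 0, 0), c(1, 0, 0), c(1, -1, 0)), 180)
  expect_equal(dh(c(-1, 1, 0), c(-1, 0, 0), c(1, 0, 0), c(1, 1, 0)), 0)
  # oracle agreement on random quadruples, including near-boundary cases
  set.seed(11)
  for (k in 1:50) {
    pts <- matrix(rnorm(12), 4L, 3L)
    got <- dh(pts[1L, ], pts[2L, ], pts[3L, ], pts[4L, ])
    want <- oracle_dihedral(pts[1L, ], pts[2L, ], pts[3L, ], pts[4L, ])
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("pairwise geometry maps match the scalar oracle", {
  for (seed in 1:10) {
    bb <- random_backbone(8L, seed)
    g <- pair_geometries(bb)
    o <- oracle_pair_geometries(bb)
    off <- !diag(8L)
    expect_lt(max(abs(g$dist[off] - o$dist[off])), 1e-6)
    expect_lt(max(abs(g$omega[off] - o$omega[off]), na.rm = TRUE), 1e-4)
    expect_lt(max(abs(g$theta[off] - o$theta[off]), na.rm = TRUE), 1e-4)
    expect_lt(max(abs(g$phi[off] - o$phi[off]), na.rm = TRUE), 1e-4)
    # symmetry structure
    expect_equal(g$dist, t(g$dist))
    expect_equal(g$omega, t(g$omega), tolerance = 1e-9)
    expect_false(isTRUE(all.equal(g$theta, t(g$theta))))
  }
})

test_that("two-residue toy distances are exact", {
  bb <- structure(list(
    n = rbind(c(-1, 1, 0), c(2, 5, 0)),
    ca = rbind(c(-1, 0, 0), c(3, 5, 0)),
    c = rbind(c(0, -0.5, 0), c(4, 4.5, 0)),
    cb = rbind(c(0, 0, 0), c(3, 4, 0)),
    sequence = "AA", resno = 1:2, L = 2L), class = "backbone")
  g <- pair_geometries(bb)
  expect_equal(g$dist[1L, 2L], 5)
  expect_equal(diag(g$dist), c(0, 0))
  expect_true(is.na(g$omega[1L, 1L]))
})

test_that("discretization matches a linear scan over bin edges", {
  set.seed(21)
  L <- 40L
  mk_maps <- function(d, om, th, ph) {
    structure(list(dist = d, omega = om, theta = th, phi = ph, L = L,
                   sequence = strrep("A", L)), class = "geometry_maps")
  }
  d <- matrix(runif(L * L, 0, 30), L, L); d <- (d + t(d)) / 2; diag(d) <- 0
  # force boundary cases into known off-diagonal slots
  d[1L, 2L] <- 3.7; d[2L, 1L] <- 3.7
  d[1L, 3L] <- 25; d[3L, 1L] <- 25
  d[1L, 4L] <- 20; d[4L, 1L] <- 20      # exactly at the no-contact edge
  d[1L, 5L] <- 2.0; d[5L, 1L] <- 2.0    # lowest in-range edge
  # keep the pairs carrying planted angle boundary cases in contact
  for (p in list(c(2L, 3L), c(2L, 4L), c(2L, 5L))) {
    d[p[1L], p[2L]] <- 5; d[p[2L], p[1L]] <- 5
  }
  om <- matrix(runif(L * L, -180 + 1e-9, 180), L, L)
  om[2L, 3L] <- 180
  th <- matrix(runif(L * L, -180 + 1e-9, 180), L, L)
  ph <- matrix(runif(L * L, 0, 180), L, L)
  ph[2L, 4L] <- 180; ph[2L, 5L] <- 0
  g <- mk_maps(d, om, th, ph)
  lab <- suppressWarnings(discretize_geometries(g))  # clamp tested separately

  expect_equal(lab$dist[1L, 2L], 4L)
  expect_equal(lab$dist[1L, 3L], 0L)
  expect_equal(lab$omega[1L, 3L], 0L)   # no-contact masks all objectives
  expect_equal(lab$theta[1L, 3L], 0L)
  expect_equal(lab$phi[1L, 3L], 0L)
  expect_equal(lab$dist[1L, 4L], 0L)
  expect_equal(lab$dist[1L, 5L], 1L)
  expect_equal(lab$omega[2L, 3L], 24L)
  expect_equal(lab$phi[2L, 4L], 12L)
  expect_equal(lab$phi[2L, 5L], 1L)
  expect_equal(diag(lab$dist), rep(0L, L))

  contact <- d < 20 & !diag(L)
  for (obj in c("dist", "omega", "theta", "phi")) {
    x <- g[[obj]]
    want <- matrix(0L, L, L)
    for (i in seq_len(L)) {
      for (j in seq_len(L)) {
        if (i != j && contact[i, j]) {
          want[i, j] <- oracle_bin(x[i, j], obj)
        }
      }
    }
    expect_identical(lab[[obj]], want, label = obj)
  }
})

test_that("sub-2A distances clamp into bin 1 with a warning", {
  d <- matrix(c(0, 1.2, 1.2, 0), 2L, 2L)
  g <- structure(list(dist = d, omega = matrix(10, 2L, 2L),
                      theta = matrix(10, 2L, 2L), phi = matrix(10, 2L, 2L),
                      L = 2L, sequence = "AA"), class = "geometry_maps")
  expect_warning(lab <- discretize_geometries(g), "clamped")
  expect_equal(lab$dist[1L, 2L], 1L)
})

test_that("bin centers invert discretization to within half a bin", {
  set.seed(5)
  for (obj in c("dist", "omega", "theta", "phi")) {
    spec <- geometry_bin_spec()[[obj]]
    width <- diff(spec$edges)[1L]
    lo <- spec$edges[1L]
    hi <- spec$edges[length(spec$edges)]
    xs <- runif(200, lo, hi - 1e-9)
    centers <- bin_centers(obj)
    for (x in xs) {
      k <- oracle_bin(x, obj)
      expect_lte(abs(centers[k + 1L] - x), width / 2 + 1e-12)
    }
  }
})

test_that("labels are invariant under rigid-body transforms", {
  for (seed in 1:3) {
    bb <- random_backbone(8L, seed + 30L)
    lab <- suppressWarnings(discretize_geometries(pair_geometries(bb)))
    bb2 <- transform_backbone(bb, seed)
    lab2 <- suppressWarnings(discretize_geometries(pair_geometries(bb2)))
    expect_identical(lab[c("theta", "phi", "omega", "dist")],
                     lab2[c("theta", "phi", "omega", "dist")])
  }
})

test_that("PDB round trip preserves coordinates and rebuilds glycine CB", {
  bb <- synthetic_backbone(12L, "ideal_helix", seed = 41L)
  # force a glycine so its CB is omitted on write and rebuilt on read
  s <- strsplit(bb$sequence, "")[[1]]; s[5L] <- "G"
  bb$sequence <- paste(s, collapse = "")
  path <- tmp_file(".pdb")
  write_backbone_pdb(bb, path)
  got <- read_backbone(path)
  expect_equal(got$L, 12L)
  expect_equal(got$sequence, bb$sequence)
  expect_lt(max(abs(got$ca - bb$ca)), 1e-3)
  expect_lt(max(abs(got$n - bb$n)), 1e-3)
  # virtual CB of glycine is consistent with its backbone
  expect_lt(max(abs(got$cb[5L, ] -
                      virtual_cbeta(got$n[5L, ], got$ca[5L, ], got$c[5L, ]))),
            1e-9)
  expect_lt(max(abs(got$cb[4L, ] - bb$cb[4L, ])), 1e-3)
})

test_that("incomplete residues are dropped with a warning", {
  bb <- synthetic_backbone(10L, "ideal_helix", seed = 42L)
  path <- tmp_file(".pdb")
  write_backbone_pdb(bb, path)
  lines <- readLines(path)
  ca5 <- which(grepl("^ATOM", lines) & substr(lines, 13, 16) == " CA " &
                 as.integer(substr(lines, 23, 26)) == 5L)
  writeLines(lines[-ca5], path)
  expect_warning(got <- read_backbone(path), "missing N/CA/C")
  expect_equal(got$L, 9L)
})

test_that("multi-model files use the first model with a warning", {
  bb <- synthetic_backbone(6L, "ideal_helix", seed = 44L)
  path <- tmp_file(".pdb")
  write_backbone_pdb(bb, path)
  atoms <- grep("^ATOM", readLines(path), value = TRUE)
  writeLines(c("MODEL     1", atoms, "ENDMDL",
               "MODEL     2", atoms, "ENDMDL", "END"), path)
  expect_warning(got <- read_backbone(path), "2 models")
  expect_equal(got$L, 6L)
})

test_that("degenerate structures raise an insufficient-structure error", {
  bb <- synthetic_backbone(2L, "ideal_helix", seed = 43L)
  path <- tmp_file(".pdb")
  write_backbone_pdb(bb, path)
  lines <- readLines(path)
  keep <- !(grepl("^ATOM", lines) &
              as.integer(substr(lines, 23, 26)) == 2L)
  writeLines(lines[keep], path)
  expect_error(suppressWarnings(read_backbone(path)), "insufficient")
  expect_error(read_backbone(tmp_file(".pdb")), "not found")
})
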