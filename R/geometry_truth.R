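# Ground-truth inter-residue geometries from backbone coordinates, and
# their discretization into classification labels.
#
# Geometries (trRosetta-style):
#   d[i,j]     Cb_i - Cb_j distance (Angstrom), symmetric, zero diagonal
#   omega[i,j] dihedral Ca_i - Cb_i - Cb_j - Ca_j (degrees), symmetric
#   theta[i,j] dihedral N_i - Ca_i - Cb_i - Cb_j (degrees), directional
#   phi[i,j]   planar angle Ca_i - Cb_i - Cb_j (degrees in [0, 180])
# Glycine (or any residue without a deposited Cb) gets a virtual Cb built
# from N, Ca, C by ideal tetrahedral geometry.

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

# Fixed virtual-Cb coefficients applied to the unnormalized frame vectors
# b = Ca - N, c = C - Ca, a = b x c (the trRosetta convention).
CB_COEF_A <- -0.58273431
CB_COEF_B <- 0.56802827
CB_COEF_C <- -0.54067466

NO_CONTACT_DIST <- 20.0
DIST_BIN_LO <- 2.0
DIST_BIN_STEP <- 0.5
ANGLE_BIN_STEP <- 15.0

cross3 <- function(u, v) {
  cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
        u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
        u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
}

row_norm <- function(u) sqrt(rowSums(u * u))

# Signed dihedral (degrees, IUPAC: trans = 180) for stacked point rows.
dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  b2n <- b2 / row_norm(b2)
  m1 <- cross3(n1, b2n)
  ang <- atan2(rowSums(m1 * n2), rowSums(n1 * n2)) * 180 / pi
  bad <- !is.finite(ang) | row_norm(n1) < 1e-9 | row_norm(n2) < 1e-9
  ang[bad] <- NA_real_
  wrap <- which(!bad & ang <= -180)            # range (-180, 180]
  ang[wrap] <- ang[wrap] + 360
  ang
}

planar_angle_deg <- function(p1, p2, p3) {
  u <- p1 - p2
  v <- p3 - p2
  cosang <- rowSums(u * v) / (row_norm(u) * row_norm(v))
  out <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  out[row_norm(u) < 1e-9 | row_norm(v) < 1e-9] <- NA_real_
  out
}

#' Construct a virtual C-beta position
#'
#' Builds the ideal tetrahedral C-beta from backbone N, C-alpha and C using
#' fixed coefficients on the unnormalized frame vectors `b = CA - N`,
#' `c = C - CA` and `a = b x c`. Used for glycine and residues with a
#' missing C-beta.
#'
#' @param n,ca,c numeric length-3 coordinates (or matrices with one row per
#'   residue).
#' @return Coordinate(s) of the virtual C-beta, same shape as `ca`.
#' @export
virtual_cbeta <- function(n, ca, c) {
  vec <- is.null(dim(n))
  if (vec) {
    n <- matrix(n, nrow = 1L); ca <- matrix(ca, nrow = 1L)
    c <- matrix(c, nrow = 1L)
  }
  b <- ca - n
  cc <- c - ca
  a <- cross3(b, cc)
  if (any(row_norm(a) < 1e-8)) {
    stop("degenerate backbone geometry: N, CA, C are collinear")
  }
  cb <- ca + CB_COEF_A * a + CB_COEF_B * b + CB_COEF_C * cc
  if (vec) cb[1L, ] else cb
}

#' Read backbone coordinates from a PDB file
#'
#' Parses one chain's N/CA/C/CB ATOM records (first chain, first model;
#' alternate locations resolved by highest occupancy then altloc id).
#' Residues missing any of N/CA/C are dropped with a warning; glycine or a
#' missing CB gets a virtual one via [virtual_cbeta()].
#'
#' @param path path to a PDB file.
#' @param chain chain identifier; default the first chain in the file.
#' @return Object of class `backbone`: list with L x 3 matrices `n`, `ca`,
#'   `c`, `cb`, one-letter `sequence`, `resno`, and length `L`.
#' @export
read_backbone <- function(path, chain = NULL) {
  if (!file.exists(path)) stop(sprintf("PDB file not found: %s", path))
  n_models <- sum(grepl("^MODEL ", readLines(path, warn = FALSE)))
  if (n_models > 1L) {
    warning(sprintf("%s has %d models; using the first", path, n_models))
  }
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, multi = FALSE)),
                  error = function(e) stop(sprintf(
                    "cannot parse PDB '%s': %s", path, conditionMessage(e))))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$resid %in% names(AA3TO1), , drop = FALSE]
  if (nrow(at) == 0L) stop(sprintf("no standard-residue ATOM records in %s", path))
  if (is.null(chain)) chain <- at$chain[1L]
  at <- at[at$chain %in% chain, , drop = FALSE]
  # altloc: keep highest occupancy, then lexicographically first altloc
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  ord <- order(at$resno, at$elety, -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(at[, c("resno", "elety")]), , drop = FALSE]

  resnos <- sort(unique(at$resno))
  rows <- list()
  dropped <- integer(0)
  for (rn in resnos) {
    sub <- at[at$resno == rn, , drop = FALSE]
    get_atom <- function(name) {
      hit <- sub[sub$elety == name, , drop = FALSE]
      if (nrow(hit) == 0L) return(NULL)
      as.numeric(hit[1L, c("x", "y", "z")])
    }
    n <- get_atom("N"); ca <- get_atom("CA"); cc <- get_atom("C")
    if (is.null(n) || is.null(ca) || is.null(cc)) {
      dropped <- c(dropped, rn)
      next
    }
    cb <- get_atom("CB")
    if (is.null(cb)) cb <- virtual_cbeta(n, ca, cc)
    rows[[length(rows) + 1L]] <- list(n = n, ca = ca, c = cc, cb = cb,
                                      aa = AA3TO1[[sub$resid[1L]]], resno = rn)
  }
  if (length(dropped) > 0L) {
    warning(sprintf("dropped %d residue(s) missing N/CA/C: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  if (length(rows) < 2L) {
    stop(sprintf("insufficient structure in %s: %d complete residue(s)",
                 path, length(rows)))
  }
  bb <- structure(list(
    n = do.call(rbind, lapply(rows, `[[`, "n")),
    ca = do.call(rbind, lapply(rows, `[[`, "ca")),
    c = do.call(rbind, lapply(rows, `[[`, "c")),
    cb = do.call(rbind, lapply(rows, `[[`, "cb")),
    sequence = paste(vapply(rows, `[[`, character(1), "aa"), collapse = ""),
    resno = vapply(rows, `[[`, numeric(1), "resno"),
    L = length(rows)), class = "backbone")
  check_ca_trace(bb)
  bb
}

# Loose physical sanity band on consecutive CA-CA distances; warning only.
check_ca_trace <- function(bb) {
  if (bb$L < 2L) return(invisible(bb))
  step <- row_norm(bb$ca[-1L, , drop = FALSE] - bb$ca[-bb$L, , drop = FALSE])
  consec <- diff(bb$resno) == 1
  odd <- consec & (step < 2.0 | step > 4.5)
  if (any(odd)) {
    warning(sprintf("%d consecutive CA-CA distance(s) outside 2.0-4.5 A",
                    sum(odd)))
  }
  invisible(bb)
}

#' @export
print.backbone <- function(x, ...) {
  cat(sprintf("backbone: %d residues (%s...)\n", x$L,
              substr(x$sequence, 1L, 20L)))
  invisible(x)
}

#' Compute pairwise ground-truth geometries
#'
#' @param s a `backbone`.
#' @return Object of class `geometry_maps`: list of L x L matrices `dist`
#'   (A), `omega`, `theta` (degrees, (-180, 180]) and `phi` (degrees,
#'   [0, 180]). Diagonal and degenerate entries are `NA` for the angular
#'   maps; `dist` has a zero diagonal.
#' @export
pair_geometries <- function(s) {
  stopifnot(inherits(s, "backbone"), s$L >= 2L)
  L <- s$L
  ii <- rep(seq_len(L), times = L)
  jj <- rep(seq_len(L), each = L)
  dvec <- row_norm(s$cb[ii, , drop = FALSE] - s$cb[jj, , drop = FALSE])
  om <- dihedral_deg(s$ca[ii, , drop = FALSE], s$cb[ii, , drop = FALSE],
                     s$cb[jj, , drop = FALSE], s$ca[jj, , drop = FALSE])
  th <- dihedral_deg(s$n[ii, , drop = FALSE], s$ca[ii, , drop = FALSE],
                     s$cb[ii, , drop = FALSE], s$cb[jj, , drop = FALSE])
  ph <- planar_angle_deg(s$ca[ii, , drop = FALSE], s$cb[ii, , drop = FALSE],
                         s$cb[jj, , drop = FALSE])
  to_mat <- function(v) matrix(v, nrow = L, ncol = L)
  dist <- to_mat(dvec)
  diag(dist) <- 0
  omega <- to_mat(om); theta <- to_mat(th); phi <- to_mat(ph)
  diag(omega) <- NA_real_; diag(theta) <- NA_real_; diag(phi) <- NA_real_
  structure(list(dist = dist, omega = omega, theta = theta, phi = phi,
                 L = L, sequence = s$sequence),
            class = "geometry_maps")
}

#' Bin specification for the four geometries
#'
#' Bin 1 (index 0) is the no-contact class for every objective, assigned
#' wherever the C-beta distance is >= 20 A. Distance bins 1..36 tile
#' [2, 20) A in 0.5 A steps; omega/theta bins 1..24 tile (-180, 180] in 15
#' degree steps; phi bins 1..12 tile [0, 180] in 15 degree steps.
#'
#' @return Named list with per-objective bin counts and edges.
#' @export
geometry_bin_spec <- function() {
  list(
    dist = list(n = 37L, edges = seq(DIST_BIN_LO, NO_CONTACT_DIST,
                                     by = DIST_BIN_STEP)),
    omega = list(n = 25L, edges = seq(-180, 180, by = ANGLE_BIN_STEP)),
    theta = list(n = 25L, edges = seq(-180, 180, by = ANGLE_BIN_STEP)),
    phi = list(n = 13L, edges = seq(0, 180, by = ANGLE_BIN_STEP))
  )
}

#' Discretize geometry maps into classification labels
#'
#' Half-open binning `[lo, hi)`; the topmost angular edge (180 degrees)
#' wraps into the last bin. Pairs with `d >= 20` A (and the diagonal) get
#' label 0 — the no-contact class — for all four objectives. Distances
#' below 2 A are clamped into bin 1 with a warning.
#'
#' @param g a `geometry_maps`.
#' @return Object of class `geometry_labels`: integer L x L matrices
#'   (`theta`, `phi`, `omega`, `dist`), values in `[0, bins - 1]`.
#' @export
discretize_geometries <- function(g) {
  stopifnot(inherits(g, "geometry_maps"))
  L <- g$L
  d <- g$dist
  contact <- is.finite(d) & d < NO_CONTACT_DIST
  diag(contact) <- FALSE

  if (any(contact & d < DIST_BIN_LO)) {
    warning(sprintf("%d pair(s) closer than %.1f A clamped into bin 1",
                    sum(contact & d < DIST_BIN_LO), DIST_BIN_LO))
  }
  dist_lab <- matrix(0L, L, L)
  idx <- pmax(0L, pmin(35L, floor((d[contact] - DIST_BIN_LO) / DIST_BIN_STEP)))
  dist_lab[contact] <- 1L + as.integer(idx)

  wrap_bin <- function(x, lo, nbins) {
    # map into [lo, lo + nbins*15); the top edge falls into the last bin
    k <- floor((x - lo) / ANGLE_BIN_STEP)
    k[k == nbins] <- nbins - 1L
    as.integer(pmax(0L, pmin(nbins - 1L, k)))
  }
  angle_labels <- function(x, lo, nbins) {
    lab <- matrix(0L, L, L)
    ok <- contact & is.finite(x)
    lab[ok] <- 1L + wrap_bin(x[ok], lo, nbins)
    lab
  }
  omega_lab <- angle_labels(g$omega, -180, 24L)
  theta_lab <- angle_labels(g$theta, -180, 24L)
  phi_lab <- angle_labels(g$phi, 0, 12L)
  # a contact pair whose dihedral is degenerate cannot be labeled: mask all
  degen <- contact & (!is.finite(g$omega) | !is.finite(g$theta) |
                        !is.finite(g$phi))
  if (any(degen)) {
    dist_lab[degen] <- 0L; omega_lab[degen] <- 0L
    theta_lab[degen] <- 0L; phi_lab[degen] <- 0L
  }
  structure(list(theta = theta_lab, phi = phi_lab, omega = omega_lab,
                 dist = dist_lab, L = L),
            class = "geometry_labels")
}

#' Centers of the geometry bins
#'
#' @param objective one of `"dist"`, `"omega"`, `"theta"`, `"phi"`.
#' @return Numeric vector of length `bins`; entry 1 (the no-contact bin) is
#'   `NA`.
#' @export
bin_centers <- function(objective = c("dist", "omega", "theta", "phi")) {
  objective <- match.arg(objective)
  spec <- geometry_bin_spec()[[objective]]
  mids <- (utils::head(spec$edges, -1L) + spec$edges[-1L]) / 2
  c(NA_real_, mids)
}

#' Featurize a PDB file into training labels
#'
#' Convenience composition of [read_backbone()], [pair_geometries()] and
#' [discretize_geometries()].
#'
#' @param path PDB file path.
#' @param chain optional chain id.
#' @return A `geometry_labels` object with the source sequence attached as
#'   attribute `sequence`.
#' @export
featurize_structure <- function(path, chain = NULL) {
  bb <- read_backbone(path, chain)
  lab <- discretize_geometries(pair_geometries(bb))
  attr(lab, "sequence") <- bb$sequence
  lab
}
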