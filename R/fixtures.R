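# Synthetic-data generators: seeded MSAs with controlled divergence and
# ideal-geometry backbones, so every pipeline stage is testable without
# external databases or models.

IDEAL_BOND_N_CA <- 1.458
IDEAL_BOND_CA_C <- 1.525
IDEAL_BOND_C_N <- 1.329
IDEAL_ANGLE_N_CA_C <- 111.2
IDEAL_ANGLE_CA_C_N <- 116.2
IDEAL_ANGLE_C_N_CA <- 121.7
HELIX_PHI <- -57
HELIX_PSI <- -47
OMEGA_TRANS <- 180

# Turn torsions (phi, psi) joining two helices into an antiparallel
# hairpin with inter-helix Cb contacts below 8 A (calibrated once on the
# ideal-geometry builder).
HAIRPIN_TURN <- matrix(c(-86.6, 112.6,
                         120.3, 168.7,
                        -148.8, -85.2,
                          -5.9, 140.0), ncol = 2L, byrow = TRUE,
                       dimnames = list(NULL, c("phi", "psi")))

#' Generate a synthetic MSA
#'
#' The query is a random residue string; each homolog copies the query and
#' then, per column, substitutes a residue drawn uniformly from the 19
#' alternatives with probability `mutation_rate`, and independently places
#' a gap with probability `gap_rate` (a gap overrides a substitution). The
#' expected hamming fraction of a homolog to the query is therefore
#' `gap_rate + (1 - gap_rate) * mutation_rate`.
#'
#' @param c columns (query length).
#' @param r rows including the query.
#' @param mutation_rate per-column substitution probability.
#' @param gap_rate per-column gap probability.
#' @param seed integer seed.
#' @param query optional query sequence (length `c`); random if `NULL`.
#' @return An `msa`.
#' @export
synthetic_msa <- function(c, r, mutation_rate = 0.2, gap_rate = 0.05,
                          seed = 1L, query = NULL) {
  stopifnot(r >= 1L, c >= 1L, mutation_rate >= 0, mutation_rate <= 1,
            gap_rate >= 0, gap_rate <= 1)
  aa <- MSA_ALPHABET[1:20]
  with_seed(seed, {
    q <- if (is.null(query)) {
      sample(aa, c, replace = TRUE)
    } else {
      stopifnot(nchar(query) == c)
      strsplit(query, "")[[1]]
    }
    rows <- character(r)
    rows[1L] <- paste(q, collapse = "")
    for (k in seq_len(r - 1L)) {
      s <- q
      mut <- stats::runif(c) < mutation_rate
      if (any(mut)) {
        s[mut] <- vapply(s[mut], function(orig) {
          sample(setdiff(aa, orig), 1L)
        }, character(1))
      }
      gap <- stats::runif(c) < gap_rate
      s[gap] <- "-"
      rows[k + 1L] <- paste(s, collapse = "")
    }
    new_msa(rows, c("query", sprintf("hom%d", seq_len(r - 1L))))
  })
}

# NeRF atom placement: position d such that |c-d| = bond, angle(b,c,d) =
# theta and dihedral(a,b,c,d) = tau (degrees).
place_atom <- function(a, b, c, bond, theta, tau) {
  th <- theta * pi / 180
  ta <- tau * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- bond * c(-cos(th), sin(th) * cos(ta), sin(th) * sin(ta))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Build N/CA/C coordinates for a torsion profile: phi[i], psi[i] per
# residue (omega fixed trans). First residue seeds the frame.
build_chain <- function(phi, psi) {
  L <- length(phi)
  n <- matrix(0, L, 3L)
  ca <- matrix(0, L, 3L)
  cc <- matrix(0, L, 3L)
  n[1L, ] <- c(0, 0, 0)
  ca[1L, ] <- c(IDEAL_BOND_N_CA, 0, 0)
  th <- IDEAL_ANGLE_N_CA_C * pi / 180
  cc[1L, ] <- ca[1L, ] + IDEAL_BOND_CA_C * c(-cos(th), sin(th), 0)
  for (i in seq_len(L - 1L) + 1L) {
    n[i, ] <- place_atom(n[i - 1L, ], ca[i - 1L, ], cc[i - 1L, ],
                         IDEAL_BOND_C_N, IDEAL_ANGLE_CA_C_N, psi[i - 1L])
    ca[i, ] <- place_atom(ca[i - 1L, ], cc[i - 1L, ], n[i, ],
                          IDEAL_BOND_N_CA, IDEAL_ANGLE_C_N_CA, OMEGA_TRANS)
    cc[i, ] <- place_atom(cc[i - 1L, ], n[i, ], ca[i, ],
                          IDEAL_BOND_CA_C, IDEAL_ANGLE_N_CA_C, phi[i])
  }
  list(n = n, ca = ca, c = cc)
}

#' Generate a synthetic backbone structure
#'
#' Builds an ideal-geometry backbone from torsion profiles:
#' `ideal_helix` (alpha-helical phi/psi of -57/-47 throughout, ~1.5 A rise
#' per residue), `helix_turn_helix` (two helices joined by a calibrated
#' turn, producing long-range Cb-Cb contacts below 8 A), or `random_chain`
#' (seeded uniform torsions). C-beta atoms are placed with
#' [virtual_cbeta()]; the residue sequence is drawn at random.
#'
#' @param L number of residues (>= 2).
#' @param architecture `"ideal_helix"`, `"helix_turn_helix"` or
#'   `"random_chain"`.
#' @param seed integer seed (sequence and, for `random_chain`, torsions).
#' @return A `backbone` object.
#' @export
synthetic_backbone <- function(L, architecture = c("ideal_helix",
                                                   "helix_turn_helix",
                                                   "random_chain"),
                               seed = 1L) {
  architecture <- match.arg(architecture)
  stopifnot(L >= 2L)
  tor <- with_seed(seed, switch(
    architecture,
    ideal_helix = list(phi = rep(HELIX_PHI, L), psi = rep(HELIX_PSI, L)),
    helix_turn_helix = {
      n_turn <- nrow(HAIRPIN_TURN)
      if (L < n_turn + 4L) stop("helix_turn_helix needs at least 8 residues")
      arm <- (L - n_turn) %/% 2L
      phi <- c(rep(HELIX_PHI, arm), HAIRPIN_TURN[, "phi"],
               rep(HELIX_PHI, L - arm - n_turn))
      psi <- c(rep(HELIX_PSI, arm), HAIRPIN_TURN[, "psi"],
               rep(HELIX_PSI, L - arm - n_turn))
      list(phi = phi, psi = psi)
    },
    random_chain = list(phi = stats::runif(L, -180, 180),
                        psi = stats::runif(L, -180, 180))))
  chain <- build_chain(tor$phi, tor$psi)
  seq <- with_seed(seed + 101L,
                   paste(sample(MSA_ALPHABET[1:20], L, replace = TRUE),
                         collapse = ""))
  cb <- virtual_cbeta(chain$n, chain$ca, chain$c)
  structure(list(n = chain$n, ca = chain$ca, c = chain$c, cb = cb,
                 sequence = seq, resno = seq_len(L), L = L),
            class = "backbone")
}

#' Write a backbone as a minimal PDB file
#'
#' Emits N, CA, C and CB ATOM records (CB omitted for glycine, whose
#' C-beta is virtual and is rebuilt on read).
#'
#' @param bb a `backbone`.
#' @param path output file path.
#' @param chain chain identifier.
#' @return `path`, invisibly.
#' @export
write_backbone_pdb <- function(bb, path, chain = "A") {
  stopifnot(inherits(bb, "backbone"))
  aa1 <- strsplit(bb$sequence, "")[[1]]
  aa3 <- names(AA3TO1)[match(aa1, AA3TO1)]
  xyz <- c()
  elety <- c()
  resno <- c()
  resid <- c()
  for (i in seq_len(bb$L)) {
    atoms <- list(N = bb$n[i, ], CA = bb$ca[i, ], C = bb$c[i, ])
    if (aa1[i] != "G") atoms$CB <- bb$cb[i, ]
    for (nm in names(atoms)) {
      xyz <- c(xyz, atoms[[nm]])
      elety <- c(elety, nm)
      resno <- c(resno, bb$resno[i])
      resid <- c(resid, aa3[i])
    }
  }
  bio3d::write.pdb(file = path, xyz = xyz, resno = resno, resid = resid,
                   elety = elety, chain = rep(chain, length(elety)),
                   eleno = seq_along(elety))
  invisible(path)
}

#' Generate a matched synthetic training example
#'
#' A backbone (labels) plus an MSA whose query is the backbone's sequence,
#' as used by the overfit training fixture and end-to-end tests.
#'
#' @param L residues.
#' @param r MSA rows.
#' @param architecture backbone architecture (see [synthetic_backbone()]).
#' @param mutation_rate,gap_rate MSA divergence parameters.
#' @param seed integer seed.
#' @return `list(msa = <msa>, labels = <geometry_labels>, backbone =
#'   <backbone>)`.
#' @export
synthetic_example <- function(L = 32L, r = 16L,
                              architecture = "helix_turn_helix",
                              mutation_rate = 0.2, gap_rate = 0.02,
                              seed = 1L) {
  bb <- synthetic_backbone(L, architecture, seed = seed)
  labels <- discretize_geometries(pair_geometries(bb))
  msa <- synthetic_msa(L, r, mutation_rate, gap_rate, seed = seed + 17L,
                       query = bb$sequence)
  list(msa = msa, labels = labels, backbone = bb)
}
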