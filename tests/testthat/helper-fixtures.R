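# Shared fixture builders for the test suite.

tmp_file <- function(ext) tempfile(fileext = ext)

write_a3m <- function(lines) {
  path <- tmp_file(".a3m")
  writeLines(lines, path)
  path
}

# Small network configuration used wherever the full-size architecture is
# not itself under test: same topology, far fewer parameters.
tiny_net_config <- function(blocks = 2L, seed = 3L) {
  net_config(reduction_channels = c(12L, 10L, 8L), trunk_blocks = blocks,
             trunk_channels = 8L, mlp_sizes = c(16L, 12L, 8L), seed = seed)
}

tiny_dataset <- function(L = 16L, seeds = c(11L, 12L)) {
  lapply(seeds, function(s) {
    ex <- msageom:::synthetic_example(L = L, r = 8L,
                                      architecture = "ideal_helix", seed = s)
    ex[c("msa", "labels")]
  })
}

# Random backbone with ideal bonded geometry (torsions uniform).
random_backbone <- function(L, seed) synthetic_backbone(L, "random_chain", seed)

# Uniformly random (but normalized) posteriors for metric tests.
random_posteriors <- function(L, seed) {
  set.seed(seed)
  bins <- c(theta = 25L, phi = 13L, omega = 25L, dist = 37L)
  post <- lapply(bins, function(nb) {
    a <- array(stats::runif(L * L * nb), dim = c(L, L, nb))
    s <- apply(a, c(1, 2), sum)
    a / array(rep(s, nb), dim = c(L, L, nb))
  })
  structure(post, class = "geometry_posteriors")
}

# Random labels with no-contact structure.
random_labels <- function(L, seed) {
  set.seed(seed)
  bins <- c(theta = 25L, phi = 13L, omega = 25L, dist = 37L)
  contact <- matrix(stats::runif(L * L) < 0.6, L, L)
  diag(contact) <- FALSE
  labs <- lapply(bins, function(nb) {
    m <- matrix(0L, L, L)
    m[contact] <- sample(seq_len(nb - 1L), sum(contact), replace = TRUE)
    m
  })
  structure(c(labs, list(L = L)), class = "geometry_labels")
}

# Rigid-body transform of a backbone (rotation about a random axis +
# translation).
transform_backbone <- function(bb, seed) {
  set.seed(seed)
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  tr <- stats::rnorm(3, sd = 10)
  out <- bb
  for (f in c("n", "ca", "c", "cb")) {
    out[[f]] <- sweep(bb[[f]] %*% t(R), 2L, -tr, "-")
  }
  out
}
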