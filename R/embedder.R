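# Embedding contract: an embedder maps a tokenized MSA (r x c) to
#   msa_features   r x c x 768   (last attention block output)
#   row_attentions 12 x 12 x c x c (layers x heads), rows softmax-normalized
# The deterministic stub below honours the contract without any external
# model; a pretrained-model adapter can be registered under its own name.

EMBED_DIM <- 768L
ATTN_LAYERS <- 12L
ATTN_HEADS <- 12L
EMBED_MAX_COLUMNS <- 1024L

# --- platform-stable hashing --------------------------------------------
# Multiplicative-congruential mixing in double precision. All intermediates
# stay below 2^53, so results are exact and identical on every platform,
# independent of R's RNG state.
HASH_P <- 2147483647

hash_mix <- function(h, k) {
  (h * 48271 + (k %% HASH_P) * 7919 + 104729) %% HASH_P
}

# Combine integer key vectors (recycled to common length) into U(0,1) draws.
hash01 <- function(...) {
  keys <- list(...)
  h <- 0
  for (k in keys) h <- hash_mix(h, k)
  h <- hash_mix(h, 12582917)  # final avalanche round
  (h + 0.5) / HASH_P
}

hash_normal <- function(...) stats::qnorm(hash01(...))

# --- embedder registry ---------------------------------------------------
embedder_registry <- new.env(parent = emptyenv())

#' Register an embedder implementation
#'
#' @param name registry key (e.g. `"stub"`).
#' @param fn function `(tokens, seed)` returning an `embedder_output`.
#' @export
register_embedder <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = embedder_registry)
  invisible(name)
}

#' Look up a registered embedder
#'
#' @param name registry key.
#' @return The embedder function.
#' @export
get_embedder <- function(name) {
  if (!exists(name, envir = embedder_registry, inherits = FALSE)) {
    stop(sprintf("no embedder registered under '%s' (available: %s)",
                 name, paste(ls(embedder_registry), collapse = ", ")))
  }
  get(name, envir = embedder_registry, inherits = FALSE)
}

#' Embed a tokenized MSA
#'
#' Dispatches to a registered embedder and validates its output against the
#' contract (shapes r x c x 768 and 12 x 12 x c x c, row-stochastic
#' attentions, finite values).
#'
#' @param tokens a `tokenized_msa`.
#' @param embedder registry name; default the deterministic stub.
#' @param seed integer seed forwarded to the embedder.
#' @return An `embedder_output`: list with `msa_features` and
#'   `row_attentions`.
#' @export
embed_msa <- function(tokens, embedder = "stub", seed = 1L) {
  stopifnot(inherits(tokens, "tokenized_msa"))
  if (ncol(tokens$tokens) > EMBED_MAX_COLUMNS) {
    stop(sprintf("alignment has %d columns, exceeding the embedder limit %d",
                 ncol(tokens$tokens), EMBED_MAX_COLUMNS))
  }
  out <- get_embedder(embedder)(tokens, seed)
  validate_embedder_output(out, nrow(tokens$tokens), ncol(tokens$tokens))
  out
}

#' Validate an embedder output against the contract
#'
#' @param e candidate `embedder_output`.
#' @param r,c expected MSA dimensions.
#' @return `e`, invisibly; errors describe the violated clause.
#' @export
validate_embedder_output <- function(e, r, c) {
  feat <- e$msa_features
  att <- e$row_attentions
  if (!identical(dim(feat), c(as.integer(r), as.integer(c), EMBED_DIM))) {
    stop(sprintf("msa_features must be %d x %d x %d, got %s",
                 r, c, EMBED_DIM, paste(dim(feat), collapse = " x ")))
  }
  if (!identical(dim(att), c(ATTN_LAYERS, ATTN_HEADS,
                             as.integer(c), as.integer(c)))) {
    stop(sprintf("row_attentions must be %d x %d x %d x %d, got %s",
                 ATTN_LAYERS, ATTN_HEADS, c, c,
                 paste(dim(att), collapse = " x ")))
  }
  if (anyNA(feat) || any(!is.finite(feat))) stop("msa_features contain NaN/Inf")
  if (anyNA(att) || any(!is.finite(att)) || any(att < 0)) {
    stop("row_attentions must be finite and non-negative")
  }
  sums <- apply(att, c(1L, 2L, 3L), sum)
  if (any(abs(sums - 1) > 1e-4)) {
    stop("row_attentions rows must sum to 1 within 1e-4")
  }
  invisible(e)
}

#' Deterministic stub embedder
#'
#' A test double for the embedding contract. Features are a fixed seeded
#' random projection of one-hot tokens (each residue type maps to a fixed
#' 768-vector), so outputs depend on sequence content. Attention scores are
#' hash-derived from the query row's residue pair and the positions, passed
#' through a per-row softmax. All randomness comes from integer hashing, not
#' the platform RNG, so outputs are bitwise reproducible everywhere.
#'
#' @param tokens a `tokenized_msa`.
#' @param seed integer seed.
#' @return An `embedder_output`.
#' @export
stub_embed <- function(tokens, seed = 1L) {
  tok <- tokens$tokens
  r <- nrow(tok)
  c <- ncol(tok)
  v <- length(tokens$vocab)
  # projection table: one row of 768 pseudo-normal values per vocab symbol
  proj <- matrix(hash_normal(seed, 11L,
                             rep(seq_len(v), times = EMBED_DIM),
                             rep(seq_len(EMBED_DIM), each = v)),
                 nrow = v, ncol = EMBED_DIM)
  feat <- array(proj[as.vector(tok), ], dim = c(r, c, EMBED_DIM))

  qtok <- tok[1L, ]
  att <- array(0, dim = c(ATTN_LAYERS, ATTN_HEADS, c, c))
  ii <- rep(seq_len(c), times = c)
  jj <- rep(seq_len(c), each = c)
  for (l in seq_len(ATTN_LAYERS)) {
    for (h in seq_len(ATTN_HEADS)) {
      score <- hash_normal(seed, 22L, l, h, qtok[ii], qtok[jj], ii, jj)
      s <- matrix(score, nrow = c, ncol = c)
      e <- exp(s - apply(s, 1L, max))
      att[l, h, , ] <- e / rowSums(e)
    }
  }
  structure(list(msa_features = feat, row_attentions = att),
            class = "embedder_output")
}

#' Adapter to a pretrained MSA-transformer embedder
#'
#' The pretrained protein language model is an external, frozen network that
#' this package only consumes through the embedding contract. No R
#' implementation of it is bundled; this loader reports the capability gap
#' with instructions, and exists so that a site with the model available can
#' register a conforming function under `"msa-transformer"`. A conforming
#' adapter must strip any model-side begin-of-sequence column so attentions
#' are exactly c x c, and must remap this package's vocabulary to the
#' model's.
#'
#' @param weights_locator path or registry name for the pretrained weights.
#' @return An embed-conforming function (never returns in the absence of the
#'   optional runtime; errors instead).
#' @export
load_pretrained_adapter <- function(weights_locator = "msa-transformer") {
  stop(sprintf(paste0(
    "pretrained embedder '%s' is not available: no protein-language-model ",
    "runtime is installed. Register a conforming function with ",
    "register_embedder(\"msa-transformer\", fn) where fn(tokens, seed) ",
    "returns validated msa_features (r x c x 768) and row_attentions ",
    "(12 x 12 x c x c)."), weights_locator), call. = FALSE)
}

register_embedder("stub", stub_embed)
register_embedder("msa-transformer", function(tokens, seed) {
  load_pretrained_adapter("msa-transformer")
})
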