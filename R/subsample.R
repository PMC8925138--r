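# MSA subsampling: random (training), diversity-minimizing (inference) and
# diversity-maximizing (ablation) strategies. The query row is always kept
# at row 1 of the output.

#' Subsampling configuration
#'
#' @param train_token_budget token budget for training-time subsampling; the
#'   training row count is `min(r, max(train_min_rows,
#'   floor(train_token_budget / c)))`. Default 2^14 = 16384.
#' @param train_min_rows floor on the training row count (default 16).
#' @param inference_rows number of rows retained at inference (default 256).
#' @param strategy one of `"random"`, `"diversity_min"`, `"diversity_max"`.
#' @param seed integer seed for the random strategy.
#' @return A `subsample_config` list.
#' @export
subsample_config <- function(train_token_budget = 2L^14L,
                             train_min_rows = 16L,
                             inference_rows = 256L,
                             strategy = c("diversity_min", "random",
                                          "diversity_max"),
                             seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(train_min_rows >= 1L, inference_rows >= 1L,
            train_token_budget >= train_min_rows)
  structure(list(train_token_budget = as.integer(train_token_budget),
                 train_min_rows = as.integer(train_min_rows),
                 inference_rows = as.integer(inference_rows),
                 strategy = strategy, seed = as.integer(seed)),
            class = "subsample_config")
}

#' Hamming fraction between two aligned sequences
#'
#' Fraction of columns at which the two rows differ. The gap character is an
#' ordinary symbol: aligning a residue against a gap counts as a mismatch.
#'
#' @param a,b aligned sequences of equal length.
#' @return Mismatch fraction in `[0, 1]`.
#' @export
hamming_fraction <- function(a, b) {
  if (nchar(a) != nchar(b) || nchar(a) == 0L) {
    stop("hamming_fraction requires equal, positive lengths")
  }
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  mean(ca != cb)
}

# Pairwise hamming-fraction matrix from a character matrix of rows.
hamming_matrix <- function(msa) {
  chars <- matrix(unlist(strsplit(msa$sequences, "")),
                  nrow = msa$r, byrow = TRUE)
  r <- msa$r
  d <- matrix(0, r, r)
  for (i in seq_len(r - 1L)) {
    di <- colMeans(chars[i, ] != t(chars[(i + 1L):r, , drop = FALSE]))
    d[i, (i + 1L):r] <- di
    d[(i + 1L):r, i] <- di
  }
  d
}

msa_take_rows <- function(msa, idx) {
  new_msa(msa$sequences[idx], msa$labels[idx])
}

#' Training-time random subsampling
#'
#' Keeps `n = min(r, max(train_min_rows, floor(train_token_budget / c)))`
#' rows: the query plus `n - 1` rows drawn uniformly without replacement,
#' using the configured seed. The budget caps the token count r x c fed to
#' the embedder; small alignments are returned whole.
#'
#' @param msa an `msa`.
#' @param cfg a [subsample_config()].
#' @return Subsampled `msa`, query first.
#' @export
subsample_training <- function(msa, cfg = subsample_config()) {
  stopifnot(inherits(msa, "msa"))
  n <- min(msa$r, max(cfg$train_min_rows,
                      floor(cfg$train_token_budget / msa$c)))
  if (n >= msa$r) return(msa_take_rows(msa, seq_len(msa$r)))
  rest <- with_seed(cfg$seed, sample(seq(2L, msa$r), n - 1L))
  msa_take_rows(msa, c(1L, sort(rest)))
}

# Greedy diversity-based selection shared by the min/max strategies.
# Starts from the query; each round adds the unselected row optimizing the
# objective over hamming fractions to the already-selected set:
#   min: lowest mean distance to selected rows;
#   max: largest minimum distance to selected rows (max-min).
# Ties break on the lowest original row index.
greedy_diversity <- function(msa, n, direction) {
  n <- min(n, msa$r)
  if (n == msa$r) return(msa_take_rows(msa, seq_len(msa$r)))
  d <- hamming_matrix(msa)
  selected <- 1L
  remaining <- setdiff(seq_len(msa$r), selected)
  while (length(selected) < n) {
    sub <- d[remaining, selected, drop = FALSE]
    score <- if (direction == "min") rowMeans(sub) else apply(sub, 1L, min)
    best <- if (direction == "min") {
      remaining[which.min(score)]   # which.min/max: first index on ties
    } else {
      remaining[which.max(score)]
    }
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  msa_take_rows(msa, selected)
}

#' Inference-time diversity-minimizing subsampling
#'
#' Greedily accretes, starting from the query, the row with the lowest
#' average hamming fraction to the rows already selected, until
#' `min(inference_rows, r)` rows are kept. This concentrates the subsample
#' on sequences close to the query neighbourhood, the strategy used at
#' prediction time.
#'
#' @inheritParams subsample_training
#' @return Subsampled `msa`, query first, then in selection order.
#' @export
subsample_inference <- function(msa, cfg = subsample_config()) {
  stopifnot(inherits(msa, "msa"))
  greedy_diversity(msa, cfg$inference_rows, "min")
}

#' Diversity-maximizing subsampling
#'
#' Greedy max-min selection: each round adds the row whose minimum hamming
#' fraction to the selected set is largest. Provided for ablation against
#' [subsample_inference()].
#'
#' @param msa an `msa`.
#' @param n number of rows to keep (capped at `r`).
#' @return Subsampled `msa`, query first.
#' @export
subsample_diversity_max <- function(msa, n) {
  stopifnot(inherits(msa, "msa"))
  greedy_diversity(msa, n, "max")
}

#' Dispatch a subsampling strategy by name
#'
#' @param msa an `msa`.
#' @param cfg a [subsample_config()]; `cfg$strategy` picks the method and
#'   `cfg$inference_rows` the target size for the diversity strategies.
#' @return Subsampled `msa`.
#' @export
subsample_msa <- function(msa, cfg = subsample_config()) {
  switch(cfg$strategy,
         random = subsample_training(msa, cfg),
         diversity_min = subsample_inference(msa, cfg),
         diversity_max = subsample_diversity_max(msa, cfg$inference_rows))
}

# Run code under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
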