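# End-to-end inference: MSA -> subsample -> embed -> pair features ->
# network -> posteriors.

#' Predict inter-residue geometry posteriors for an MSA
#'
#' @param msa an `msa` (or path to an A3M file).
#' @param model a trained `msageom_model`.
#' @param subsample a [subsample_config()]; the strategy field picks the
#'   subsampler (default diversity minimization with 256 rows).
#' @param seed seed forwarded to the embedder.
#' @param symmetrize average the dist/omega posteriors with their
#'   transpose.
#' @return A `geometry_posteriors` with attributes `query` (sequence) and
#'   `meta` (run description).
#' @export
predict_geometry <- function(msa, model, subsample = subsample_config(),
                             seed = 1L, symmetrize = TRUE) {
  stopifnot(inherits(model, "msageom_model"))
  if (is.character(msa)) msa <- read_a3m(msa)
  sub <- subsample_msa(msa, subsample)
  e <- embed_msa(tokenize(sub), embedder = model$embedder, seed = seed)
  feats <- build_pair_features(e, model$params$mlp)
  logits <- forward_geometry(feats, model$params, model$net_config)
  post <- logits_to_posteriors(logits, symmetrize = symmetrize)
  attr(post, "query") <- sub$sequences[1L]
  attr(post, "meta") <- list(
    embedder = model$embedder,
    subsample_strategy = subsample$strategy,
    rows_used = sub$r,
    seed = seed,
    package_version = as.character(utils::packageVersion("msageom")))
  post
}

#' @export
predict.msageom_model <- function(object, newdata, ...) {
  predict_geometry(newdata, object, ...)
}
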