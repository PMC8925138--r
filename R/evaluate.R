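# Contact extraction and evaluation metrics: Top L/k long-range precision
# (CASP convention) and per-objective Pearson correlation between
# maximum-probability bin indices and ground truth.

CONTACT_CUTOFF <- 8.0

#' Collapse distance posteriors into contact probabilities
#'
#' P(contact) is the summed probability of the distance bins lying fully
#' below 8 A (bins 2..13, i.e. [2, 8) A; the no-contact bin and all bins at
#' or beyond 8 A contribute nothing). The map is symmetrized by averaging
#' and the diagonal zeroed.
#'
#' @param post a `geometry_posteriors`.
#' @return c x c matrix of probabilities, class `contact_map`.
#' @export
contact_probability <- function(post) {
  dist <- post$dist
  edges <- geometry_bin_spec()$dist$edges
  upper <- edges[-1L]                      # upper edge of bins 1..36
  sel <- 1L + which(upper <= CONTACT_CUTOFF)  # array slices (skip bin 0)
  p <- apply(dist[, , sel, drop = FALSE], c(1L, 2L), sum)
  p <- (p + t(p)) / 2
  diag(p) <- 0
  p[] <- pmin(1, pmax(0, p))   # clamp float noise, keep the matrix shape
  structure(p, class = "contact_map")
}

#' True contact map from geometry maps
#'
#' @param g a `geometry_maps`.
#' @param cutoff contact cutoff in Angstrom (default 8, strict `<`).
#' @return Logical L x L matrix, symmetric, FALSE diagonal.
#' @export
true_contacts <- function(g, cutoff = CONTACT_CUTOFF) {
  m <- is.finite(g$dist) & g$dist < cutoff
  diag(m) <- FALSE
  m
}

#' Top L/k contact precision
#'
#' Ranks pairs `(i, j)` with `j - i >= min_sep` by predicted probability
#' (ties broken lexicographically by `(i, j)`), takes the top
#' `n = max(1, floor(L * k_fraction))`, and reports the fraction that are
#' true contacts. The CASP long-range class uses `min_sep = 24`.
#'
#' @param pred contact probability matrix (L x L).
#' @param truth logical L x L matrix of true contacts.
#' @param k_fraction fraction of L to keep (1, 1/2, or 1/5 conventionally).
#' @param min_sep minimum sequence separation (default 24).
#' @return Precision in `[0, 1]`, or `NA` (with attribute `reason`) when no
#'   pair satisfies the separation constraint.
#' @export
top_k_precision <- function(pred, truth, k_fraction = 1, min_sep = 24L) {
  L <- nrow(pred)
  stopifnot(all(dim(pred) == c(L, L)), all(dim(truth) == c(L, L)))
  ii <- grid_ii(L)
  jj <- grid_jj(L)
  elig <- (jj - ii) >= min_sep
  if (!any(elig)) {
    return(structure(NA_real_,
                     reason = sprintf("no pairs with separation >= %d at L = %d",
                                      min_sep, L)))
  }
  p <- as.vector(pred)[elig]
  tr <- as.vector(truth)[elig]
  io <- ii[elig]
  jo <- jj[elig]
  ord <- order(-p, io, jo)
  n <- max(1L, floor(L * k_fraction))
  n <- min(n, length(ord))
  sum(tr[ord[seq_len(n)]]) / n
}

#' Precision report at Top L, L/2 and L/5
#'
#' @inheritParams top_k_precision
#' @return Named numeric vector `c(top_L, top_L2, top_L5)` plus attribute
#'   `n_pairs` (eligible pair count).
#' @export
precision_report <- function(pred, truth, min_sep = 24L) {
  out <- c(top_L = top_k_precision(pred, truth, 1, min_sep),
           top_L2 = top_k_precision(pred, truth, 1 / 2, min_sep),
           top_L5 = top_k_precision(pred, truth, 1 / 5, min_sep))
  L <- nrow(pred)
  attr(out, "n_pairs") <- sum((grid_jj(L) - grid_ii(L)) >= min_sep)
  out
}

#' Pearson correlation of maximum-probability bins against ground truth
#'
#' For each objective, collects the argmax posterior bin index over
#' off-diagonal pairs whose ground-truth label is not the no-contact class
#' (bin 0 is categorical, not ordinal) and correlates it with the true
#' index.
#'
#' @param post a `geometry_posteriors`.
#' @param labels a `geometry_labels`.
#' @return Named numeric vector of Pearson r per objective; `NA` where
#'   fewer than two pairs qualify or a vector is constant.
#' @export
maxbin_correlation <- function(post, labels) {
  out <- numeric(0)
  for (nm in names(labels)[names(labels) %in% names(post)]) {
    a <- post[[nm]]
    L <- dim(a)[1L]
    pred_idx <- apply(a, c(1L, 2L), which.max) - 1L  # 0-based bins
    truth <- labels[[nm]]
    use <- truth != 0L
    diag(use) <- FALSE
    r <- if (sum(use) < 2L || stats::sd(pred_idx[use]) == 0 ||
             stats::sd(truth[use]) == 0) {
      NA_real_
    } else {
      stats::cor(pred_idx[use], truth[use])
    }
    out[nm] <- r
  }
  out
}

#' Write contacts in CASP RR format
#'
#' Header with the query sequence, then `i j d1 d2 prob` records (1-based,
#' `i < j`), sorted by decreasing probability.
#'
#' @param pred contact probability matrix.
#' @param sequence query sequence (length L).
#' @param path output file.
#' @param min_sep minimum separation of reported pairs (default 1: all).
#' @param max_records cap on the number of records.
#' @return `path`, invisibly.
#' @export
write_rr <- function(pred, sequence, path, min_sep = 1L,
                     max_records = Inf) {
  L <- nrow(pred)
  stopifnot(nchar(sequence) == L)
  ii <- grid_ii(L)
  jj <- grid_jj(L)
  keep <- (jj - ii) >= min_sep
  p <- as.vector(pred)[keep]
  io <- ii[keep]
  jo <- jj[keep]
  ord <- order(-p, io, jo)
  if (is.finite(max_records)) ord <- ord[seq_len(min(length(ord), max_records))]
  lines <- c("PFRMAT RR", sequence,
             sprintf("%d %d 0 8 %.6f", io[ord], jo[ord], p[ord]), "END")
  writeLines(lines, path)
  invisible(path)
}

#' Read a CASP RR contact file
#'
#' @param path RR file written by [write_rr()] (or compatible).
#' @return List with `sequence` and a data frame `contacts`
#'   (`i`, `j`, `d1`, `d2`, `prob`).
#' @export
read_rr <- function(path) {
  if (!file.exists(path)) stop(sprintf("RR file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & lines != "END"]
  lines <- lines[!grepl("^(PFRMAT|TARGET|AUTHOR|METHOD|MODEL|REMARK)", lines)]
  is_rec <- grepl("^\\d+\\s+\\d+\\s", lines)
  sequence <- paste(lines[!is_rec], collapse = "")
  rec <- lines[is_rec]
  if (length(rec) == 0L) {
    return(list(sequence = sequence,
                contacts = data.frame(i = integer(0), j = integer(0),
                                      d1 = numeric(0), d2 = numeric(0),
                                      prob = numeric(0))))
  }
  parts <- do.call(rbind, lapply(strsplit(rec, "\\s+"), as.numeric))
  list(sequence = sequence,
       contacts = data.frame(i = as.integer(parts[, 1L]),
                             j = as.integer(parts[, 2L]),
                             d1 = parts[, 3L], d2 = parts[, 4L],
                             prob = parts[, 5L]))
}
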