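# Fixed token vocabulary: 20 standard residues, X (unknown), '-' (gap).
MSA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "-")
MSA_VOCAB <- stats::setNames(seq_along(MSA_ALPHABET), MSA_ALPHABET)

# Ambiguous / non-standard residue codes folded into X on parse.
NONSTANDARD_TO_X <- c("B", "Z", "J", "U", "O")

#' Construct and validate an MSA object
#'
#' An `msa` holds aligned sequences over the 20 standard amino acids plus
#' `X` (unknown) and `-` (gap). Row 1 is always the query.
#'
#' @param sequences character vector of aligned rows (identical lengths).
#' @param labels optional character vector of per-row labels (FASTA headers).
#' @return An object of class `msa` with fields `sequences`, `labels`,
#'   `r` (rows) and `c` (columns).
#' @export
new_msa <- function(sequences, labels = NULL) {
  if (length(sequences) < 1L) {
    stop("an MSA needs at least one row (the query)")
  }
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop(sprintf("malformed alignment: row %d has %d columns, expected %d",
                 bad, widths[bad], widths[1L]))
  }
  chars <- unique(unlist(strsplit(sequences, "")))
  illegal <- setdiff(chars, MSA_ALPHABET)
  if (length(illegal) > 0L) {
    row <- which(vapply(strsplit(sequences, ""),
                        function(s) any(s %in% illegal), logical(1)))[1L]
    stop(sprintf("illegal alignment symbol '%s' in row %d", illegal[1L], row))
  }
  if (is.null(labels)) labels <- sprintf("seq%d", seq_along(sequences))
  structure(
    list(sequences = sequences, labels = labels,
         r = length(sequences), c = widths[1L], query_index = 1L),
    class = "msa"
  )
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d sequences x %d columns (query: %s)\n",
              x$r, x$c, x$labels[1L]))
  show <- utils::head(x$sequences, 5L)
  for (i in seq_along(show)) {
    s <- if (x$c > 60L) paste0(substr(show[i], 1L, 57L), "...") else show[i]
    cat(sprintf("  [%d] %s\n", i, s))
  }
  if (x$r > 5L) cat(sprintf("  ... %d more rows\n", x$r - 5L))
  invisible(x)
}

# Shared record reader + cleanup for A3M and aligned FASTA. A3M marks
# insertions relative to the query as lowercase letters (or '.'), which are
# deleted to recover the fixed-width column set of the query.
read_msa_records <- function(path) {
  if (!file.exists(path)) stop(sprintf("MSA file not found: %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop(sprintf(
                    "cannot parse '%s' as FASTA/A3M: %s", path, conditionMessage(e))))
  if (length(set) == 0L) stop(sprintf("empty MSA file: %s", path))
  list(sequences = as.character(set), labels = names(set))
}

clean_a3m_row <- function(s) {
  # Drop lowercase insertion states and '.' placeholders; keep '-' and
  # uppercase match states.
  gsub("[a-z.]", "", s)
}

#' Read an A3M alignment
#'
#' Parses an A3M (or aligned FASTA) file into an [new_msa()] object. Lowercase
#' letters and `.` denote insertions relative to the query and are removed,
#' following the usual A3M convention, so every retained row has the query's
#' column count. The first record is taken as the query. Non-standard residue
#' codes (B, Z, J, U, O) are mapped to `X` with a warning.
#'
#' @param path path to an A3M or aligned FASTA file.
#' @return An `msa` object.
#' @export
read_a3m <- function(path) {
  rec <- read_msa_records(path)
  seqs <- toupper_nonstandard(vapply(rec$sequences, clean_a3m_row, character(1),
                                     USE.NAMES = FALSE))
  widths <- nchar(seqs)
  if (any(widths != widths[1L])) {
    bad <- which(widths != widths[1L])[1L]
    stop(sprintf(
      "malformed alignment in '%s': row %d has %d match columns, expected %d",
      path, bad, widths[bad], widths[1L]))
  }
  new_msa(seqs, rec$labels)
}

#' Read an aligned FASTA alignment
#'
#' Like [read_a3m()] but treats the input as already fixed-width: lowercase
#' letters are uppercased rather than removed.
#'
#' @param path path to an aligned FASTA file.
#' @return An `msa` object.
#' @export
read_fasta_msa <- function(path) {
  rec <- read_msa_records(path)
  seqs <- toupper_nonstandard(toupper(rec$sequences))
  new_msa(seqs, rec$labels)
}

toupper_nonstandard <- function(seqs) {
  hit <- vapply(NONSTANDARD_TO_X,
                function(ch) any(grepl(ch, seqs, fixed = TRUE)), logical(1))
  if (any(hit)) {
    warning(sprintf("non-standard residue code(s) %s mapped to X",
                    paste(NONSTANDARD_TO_X[hit], collapse = ", ")))
    for (ch in NONSTANDARD_TO_X[hit]) seqs <- gsub(ch, "X", seqs, fixed = TRUE)
  }
  seqs
}

#' Write an MSA as aligned FASTA
#'
#' @param msa an `msa` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_msa_fasta <- function(msa, path) {
  stopifnot(inherits(msa, "msa"))
  set <- Biostrings::BStringSet(msa$sequences)
  names(set) <- msa$labels
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Tokenize an MSA into an integer matrix
#'
#' Maps each alignment symbol to its index in the package's fixed vocabulary
#' (20 residues, then `X`, then `-`). The mapping is bijective, so
#' [detokenize()] recovers the input exactly.
#'
#' @param msa an `msa` object.
#' @return Object of class `tokenized_msa`: list with `tokens` (integer
#'   matrix r x c), `vocab`, and the row `labels`.
#' @export
tokenize <- function(msa) {
  stopifnot(inherits(msa, "msa"))
  mat <- matrix(MSA_VOCAB[unlist(strsplit(msa$sequences, ""))],
                nrow = msa$r, ncol = msa$c, byrow = TRUE)
  storage.mode(mat) <- "integer"
  structure(list(tokens = mat, vocab = MSA_VOCAB, labels = msa$labels),
            class = "tokenized_msa")
}

#' Reverse tokenization
#'
#' @param tok a `tokenized_msa`.
#' @return The reconstructed `msa` object.
#' @export
detokenize <- function(tok) {
  stopifnot(inherits(tok, "tokenized_msa"))
  syms <- names(tok$vocab)[t(tok$tokens)]
  seqs <- apply(matrix(syms, ncol = nrow(tok$tokens)), 2L, paste, collapse = "")
  new_msa(seqs, tok$labels)
}
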