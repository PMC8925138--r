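# Restraint container: the four geometry posterior arrays plus metadata,
# serialized as a gzip-compressed binary file with float32 payloads. Key
# names (dist/omega/theta/phi) follow the downstream structure-modeling
# convention and are part of the format contract.

RESTRAINT_MAGIC <- "MGRS"
RESTRAINT_MAJOR <- 1L
RESTRAINT_MINOR <- 0L
RESTRAINT_KEYS <- c("dist", "omega", "theta", "phi")

write_string <- function(con, s) {
  raw <- charToRaw(enc2utf8(s))
  writeBin(length(raw), con, size = 4L, endian = "little")
  writeBin(raw, con)
}

read_string <- function(con) {
  n <- readBin(con, "integer", size = 4L, endian = "little")
  rawToChar(readBin(con, "raw", n = n))
}

#' Write geometry posteriors as a restraint file
#'
#' @param post a `geometry_posteriors` (validated before writing).
#' @param path output file path.
#' @param meta named list of metadata (query sequence, embedder name,
#'   subsample strategy, ...); stored as JSON. Defaults to the `meta`
#'   attribute attached by [predict_geometry()].
#' @return `path`, invisibly.
#' @export
write_restraints <- function(post, path, meta = NULL) {
  validate_posteriors(post)
  if (is.null(meta)) meta <- attr(post, "meta") %||% list()
  meta$query <- meta$query %||% attr(post, "query") %||% ""
  meta$package_version <- as.character(utils::packageVersion("msageom"))
  con <- tryCatch(gzfile(path, "wb"),
                  error = function(e) stop(sprintf(
                    "cannot open '%s' for writing: %s", path,
                    conditionMessage(e))))
  on.exit(close(con))
  writeBin(charToRaw(RESTRAINT_MAGIC), con)
  writeBin(c(RESTRAINT_MAJOR, RESTRAINT_MINOR), con, size = 4L,
           endian = "little")
  write_string(con, as.character(jsonlite::toJSON(meta, auto_unbox = TRUE)))
  writeBin(length(RESTRAINT_KEYS), con, size = 4L, endian = "little")
  for (key in RESTRAINT_KEYS) {
    a <- post[[key]]
    write_string(con, key)
    writeBin(length(dim(a)), con, size = 4L, endian = "little")
    writeBin(as.integer(dim(a)), con, size = 4L, endian = "little")
    writeBin(as.numeric(a), con, size = 4L, endian = "little")  # float32
  }
  invisible(path)
}

#' Read a restraint file
#'
#' Validates the magic, the format major version, the presence of all four
#' geometry keys and the per-pair normalization of each array.
#'
#' @param path restraint file written by [write_restraints()].
#' @param tol normalization tolerance on load (float32 storage loosens the
#'   write-side 1e-5 slightly).
#' @return A `geometry_posteriors` with attribute `meta`.
#' @export
read_restraints <- function(path, tol = 1e-4) {
  if (!file.exists(path)) stop(sprintf("restraint file not found: %s", path))
  con <- gzfile(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (magic != RESTRAINT_MAGIC) {
    stop(sprintf("'%s' is not a restraint file (bad magic)", path))
  }
  ver <- readBin(con, "integer", n = 2L, size = 4L, endian = "little")
  if (ver[1L] != RESTRAINT_MAJOR) {
    stop(sprintf("unsupported restraint format major version %d", ver[1L]))
  }
  meta <- jsonlite::fromJSON(read_string(con))
  n_arr <- readBin(con, "integer", size = 4L, endian = "little")
  arrays <- list()
  for (k in seq_len(n_arr)) {
    key <- read_string(con)
    nd <- readBin(con, "integer", size = 4L, endian = "little")
    dims <- readBin(con, "integer", n = nd, size = 4L, endian = "little")
    dat <- readBin(con, "numeric", n = prod(dims), size = 4L,
                   endian = "little")
    arrays[[key]] <- array(dat, dim = dims)
  }
  missing <- setdiff(RESTRAINT_KEYS, names(arrays))
  if (length(missing) > 0L) {
    stop(sprintf("restraint file missing key(s): %s",
                 paste(missing, collapse = ", ")))
  }
  post <- structure(arrays[RESTRAINT_KEYS], class = "geometry_posteriors")
  validate_posteriors(post, tol = tol)
  attr(post, "meta") <- meta
  post
}
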