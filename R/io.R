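#' Read sequencing reads from FASTA/FASTQ
#'
#' Auto-detects FASTA vs FASTQ (gzip transparently handled) and returns a
#' plain data frame. Chunked access via `n`/`skip` allows iterating over
#' large files without holding everything at once.
#'
#' @param path Path to a FASTA or FASTQ file, optionally `.gz`.
#' @param n Maximum number of records to read (default all).
#' @param skip Number of records to skip first.
#' @return Data frame with columns `id`, `seq` and (FASTQ only) `qual`;
#'   quality strings are Phred+33 and length-matched to their sequences.
#' @export
read_sequences <- function(path, n = Inf, skip = 0) {
  if (!file.exists(path)) stop("no such file: ", path)
  check_gzip_integrity(path)
  con <- gzfile(path, "rt")
  first <- tryCatch(readLines(con, n = 1L), finally = close(con))
  if (length(first) == 0) stop("empty sequence file: ", path)
  nrec <- if (is.finite(n)) as.integer(n) else -1L
  if (startsWith(first, ">")) {
    x <- Biostrings::readDNAStringSet(path, format = "fasta", nrec = nrec,
                                      skip = as.integer(skip))
    data.frame(id = sub("\\s.*", "", names(x)), seq = as.character(x))
  } else if (startsWith(first, "@")) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq", nrec = nrec,
                                      skip = as.integer(skip),
                                      with.qualities = TRUE)
    q <- as.character(S4Vectors::mcols(x)$qualities)
    if (any(nchar(q) != nchar(as.character(x))))
      stop("quality length does not match sequence length in: ", path)
    data.frame(id = sub("\\s.*", "", names(x)), seq = as.character(x),
               qual = q)
  } else {
    stop("cannot detect FASTA/FASTQ format (first character '",
         substr(first, 1, 1), "') in: ", path)
  }
}

# a truncated gzip stream otherwise decompresses silently to a short file:
# compare the trailer's ISIZE field with the actual decompressed length
check_gzip_integrity <- function(path) {
  con <- file(path, "rb")
  magic <- readBin(con, "raw", 2L)
  close(con)
  if (length(magic) < 2L || magic[1] != as.raw(0x1f) || magic[2] != as.raw(0x8b))
    return(invisible(TRUE))
  sz <- file.size(path)
  if (sz < 18) stop("truncated gzip file: ", path)
  con <- file(path, "rb")
  seek(con, sz - 4)
  isize <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  close(con)
  isize <- isize %% 2^32
  got <- 0
  con <- gzfile(path, "rb")
  on.exit(close(con))
  repeat {
    b <- suppressWarnings(readBin(con, "raw", 1048576L))
    if (length(b) == 0L) break
    got <- got + length(b)
  }
  if (got %% 2^32 != isize)
    stop("truncated or corrupt gzip file: ", path,
         " (expected ", isize, " bytes, decompressed ", got, ")")
  invisible(TRUE)
}

open_out <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
}

#' Write reads to FASTA/FASTQ
#'
#' @param x Data frame with `id` and `seq` columns (and `qual` for FASTQ),
#'   or a named character vector of sequences.
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  x <- as_read_df(x)
  con <- open_out(path)
  on.exit(close(con))
  writeLines(paste0(">", x$id, "\n", x$seq), con)
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_fastq <- function(x, path) {
  x <- as_read_df(x)
  if (is.null(x$qual)) stop("FASTQ output requires a 'qual' column")
  if (any(nchar(x$qual) != nchar(x$seq)))
    stop("quality strings must match sequence lengths")
  con <- open_out(path)
  on.exit(close(con))
  writeLines(paste0("@", x$id, "\n", x$seq, "\n+\n", x$qual), con)
  invisible(path)
}

as_read_df <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "seq") %in% names(x)))
    return(x)
  }
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("seq", seq_along(x))
    return(data.frame(id = ids, seq = unname(x)))
  }
  stop("expected a data frame or character vector of sequences")
}

MODEL_SCHEMA_VERSION <- 1L

#' Save and load fitted models as JSON
#'
#' The document records the schema version, component families, weights and
#' parameters, and fit metadata (error, generations, optimizer seed), and
#' round-trips losslessly.
#'
#' @param fit A `kmix` fit (or a bare [mixture_model()]).
#' @param path JSON file path.
#' @return `write_model()` returns `path` invisibly. `read_model()` returns
#'   a list with `model` (a [mixture_model()]), `err`, `generations`,
#'   `seed` and `schema_version`.
#' @export
write_model <- function(fit, path) {
  m <- as_mixture(fit)
  doc <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    ploidy = m$p,
    components = lapply(names(m$components), function(nm) {
      cc <- m$components[[nm]]
      list(name = nm, family = cc$family, weight = cc$weight,
           params = as.numeric(cc$params))
    }),
    err = if (inherits(fit, "kmix")) fit$err else NULL,
    generations = if (inherits(fit, "kmix")) fit$generations else NULL,
    seed = if (inherits(fit, "kmix")) fit$de$seed else NULL)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (field in c("schema_version", "components"))
    if (is.null(doc[[field]]))
      stop("model document is missing required field '", field, "'")
  if (doc$schema_version != MODEL_SCHEMA_VERSION)
    stop("unsupported model schema version: ", doc$schema_version)
  comps <- lapply(doc$components, function(cc) {
    for (field in c("family", "weight", "params"))
      if (is.null(cc[[field]]))
        stop("model component is missing required field '", field, "'")
    list(family = cc$family, weight = as.numeric(cc$weight),
         params = as.numeric(unlist(cc$params)))
  })
  w <- vapply(comps, function(cc) cc$weight, 1.0)
  if (abs(sum(w) - 1) > 1e-6)
    stop("invalid model document: component weights sum to ", sum(w))
  list(model = mixture_model(comps),
       err = doc$err, generations = doc$generations, seed = doc$seed,
       schema_version = doc$schema_version)
}
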