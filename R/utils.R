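# Typed conditions so callers and tests can assert failure modes.
abort_typed <- function(type, msg, ...) {
  stop(structure(
    class = c(paste0("epistrat_", type, "_error"), "epistrat_error",
              "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

config_error     <- function(msg, ...) abort_typed("config", msg, ...)
contract_error   <- function(msg, ...) abort_typed("contract", msg, ...)
numerical_error  <- function(msg, ...) abort_typed("numerical", msg, ...)
dependency_error <- function(msg, ...) abort_typed("dependency", msg, ...)

check_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    contract_error("counts must be a numeric matrix (genes x samples)")
  if (any(counts < 0)) contract_error("counts contain negative entries")
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    contract_error("gene identifiers missing or duplicated")
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts)))
    contract_error("sample identifiers missing or duplicated")
  invisible(counts)
}

#' Read and write tab-separated tables
#'
#' Plain-text TSV round-trip helpers used by every pipeline stage. Matrices
#' are written with row names in the first column (header = sample IDs).
#'
#' @param x data.frame or matrix to write.
#' @param path file path.
#' @param row_names write/read row names in a leading column.
#' @return `read_tsv_matrix` returns a numeric matrix; `read_tsv_table` a
#'   data.frame.
#' @export
write_tsv <- function(x, path, row_names = is.matrix(x)) {
  if (is.matrix(x)) {
    df <- data.frame(id = rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = row_names)
  }
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname write_tsv
#' @export
read_tsv_table <- function(path) {
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read and write GMT gene-set files
#'
#' GMT is the tab-delimited gene-set format: one set per line with a name, a
#' description, and the member genes.
#'
#' @param sets named list of character vectors.
#' @param path file path.
#' @param description optional per-set description (recycled).
#' @return `read_gmt` returns a named list of character vectors.
#' @export
write_gmt <- function(sets, path, description = "") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  sets
}

#' Write and read an expression matrix as MatrixMarket triplets
#'
#' Writes `<stem>.mtx` plus `<stem>.genes.txt` / `<stem>.samples.txt` name
#' files, the layout used for sparse expression exchange.
#'
#' @param m numeric matrix with dimnames.
#' @param stem path stem (without extension).
#' @return `read_mtx` returns a dense named matrix.
#' @export
write_mtx <- function(m, stem) {
  Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix"),
                  paste0(stem, ".mtx"))
  writeLines(rownames(m), paste0(stem, ".genes.txt"))
  writeLines(colnames(m), paste0(stem, ".samples.txt"))
  invisible(stem)
}

#' @rdname write_mtx
#' @export
read_mtx <- function(stem) {
  m <- as.matrix(Matrix::readMM(paste0(stem, ".mtx")))
  rownames(m) <- readLines(paste0(stem, ".genes.txt"))
  colnames(m) <- readLines(paste0(stem, ".samples.txt"))
  m
}

# Deterministic per-stage seed derivation from one top-level seed.
# Keeps results < 2^31 so they remain valid R integers.
derive_seed <- function(seed, stage) {
  offsets <- c(simulate = 11L, preprocess = 23L, stratify = 37L,
               survive = 53L, screen = 71L, enrich = 89L,
               validate = 101L, sc_score = 127L)
  if (!stage %in% names(offsets)) config_error(paste("unknown stage:", stage))
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stage]]
}
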