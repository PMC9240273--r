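#' @keywords internal
"_PACKAGE"

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. All randomized operations in the package go
# through this so that results are pure functions of (inputs, seed).
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic seed-splitting rule: child i of a parent seed. Keeps results
# reproducible per study / per repeat while staying inside 32-bit range.
child_seed <- function(seed, i) {
  as.integer((as.double(seed) + 7919 * as.double(i)) %% .Machine$integer.max)
}

# Validate a taxa-by-samples count matrix.
check_count_matrix <- function(counts, integer_counts = FALSE) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix (taxa x samples)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry taxon rownames and sample colnames")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("duplicate taxon or sample identifiers")
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and non-negative")
  if (integer_counts && any(counts != round(counts)))
    stop("counts must be integers")
  invisible(counts)
}

#' Read a taxa-by-samples count matrix from TSV
#'
#' The expected layout is one row per taxon with the taxon identifier in the
#' first column and one column per sample.
#'
#' @param path Path to a tab-separated file.
#' @return A numeric matrix with taxon rownames and sample colnames.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  check_count_matrix(m)
  m
}

#' Write a taxa-by-samples matrix to TSV
#'
#' @param counts Numeric matrix with taxon rownames and sample colnames.
#' @param path Output path.
#' @param id_col Name for the identifier column.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(counts, path, id_col = "taxon_id") {
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
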