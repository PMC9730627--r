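# Pre-trained embedding ingestion: word2vec text format and the resolution
# of catalog drugs to vectors (concept-ID mapping or raw-name matching).

#' Read an embedding table in word2vec text format
#'
#' Parses the gensim-compatible text format: an optional header line
#' `<count> <dim>` followed by one `token v1 ... ve` line per entry,
#' space-separated. Headerless files are accepted; the dimension is then
#' inferred from the (uniform) row length.
#'
#' @param path Path to the embedding file.
#' @return An object of class `embedding_table`: a list with `dim` (the
#'   embedding dimension `e`) and `vectors`, a numeric matrix with one row
#'   per token (tokens as row names).
#' @export
read_word2vec <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("'%s' contains no embedding rows", path))
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  first <- fields[[1]]
  has_header <- length(first) == 2 &&
    !anyNA(suppressWarnings(as.numeric(first))) &&
    all(as.numeric(first) == round(as.numeric(first)))
  if (has_header) {
    dim_e <- as.integer(first[2])
    fields <- fields[-1]
    offset <- 1L
  } else {
    dim_e <- length(first) - 1L
    offset <- 0L
  }
  if (dim_e <= 0) abort(sprintf("'%s': embedding dimension must be positive", path))
  bad <- which(lengths(fields) != dim_e + 1L)
  if (length(bad) > 0) {
    abort(sprintf(
      "line %d of '%s': expected %d values after the token, found %d",
      bad[1] + offset, path, dim_e, lengths(fields)[bad[1]] - 1L
    ))
  }
  tokens <- vapply(fields, `[[`, "", 1L)
  dup <- which(duplicated(tokens))
  if (length(dup) > 0) {
    abort(sprintf("duplicate token '%s' in '%s'", tokens[dup[1]], path))
  }
  vals <- vapply(fields, function(f) as.numeric(f[-1]), numeric(dim_e))
  vectors <- if (dim_e == 1L) matrix(vals, ncol = 1L) else t(vals)
  if (anyNA(vectors)) abort(sprintf("non-numeric embedding value in '%s'", path))
  rownames(vectors) <- tokens
  structure(list(dim = dim_e, vectors = vectors), class = "embedding_table")
}

#' Write an embedding table in word2vec text format
#'
#' Writes a `<count> <dim>` header followed by one token row per entry,
#' values formatted to six decimal places (so a read/write round trip
#' reproduces vectors to that precision).
#'
#' @param table An `embedding_table` (see [read_word2vec()]) or a numeric
#'   matrix with tokens as row names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_word2vec <- function(table, path) {
  if (inherits(table, "embedding_table")) table <- table$vectors
  stopifnot(is.matrix(table), !is.null(rownames(table)))
  rows <- vapply(seq_len(nrow(table)), function(r) {
    paste(c(rownames(table)[r], sprintf("%.6f", table[r, ])), collapse = " ")
  }, "")
  writeLines(c(paste(nrow(table), ncol(table)), rows), path)
  invisible(path)
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> %d tokens x %d dimensions\n",
              nrow(x$vectors), x$dim))
  invisible(x)
}

#' Read a drug-to-token mapping file
#'
#' @param path TSV file with columns `drug_id<TAB>embedding_token`.
#' @return A tibble with columns `drug_id` and `token`.
#' @export
read_drug_mapping <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2)
  if (length(bad) > 0) {
    abort(sprintf("line %d of '%s': expected drug_id<TAB>token",
                  which(keep)[bad[1]], path))
  }
  tibble(
    drug_id = trimws(vapply(fields, `[[`, "", 1L)),
    token = trimws(vapply(fields, `[[`, "", 2L))
  )
}

#' Resolve catalog drugs to embedding vectors
#'
#' Maps every drug in the catalog to a row of the embedding table. With a
#' mapping supplied, a drug is looked up through its mapped token first
#' (concept mode); otherwise -- and as a fallback when the mapped token is
#' absent -- the drug's own identifier is used as the token (word mode).
#' Coverage (the fraction of drugs that matched a token) is reported via a
#' message; unresolved drugs are filled according to `fallback`.
#'
#' @param catalog A character vector of drug IDs or an `interaction_dataset`.
#' @param table An `embedding_table` from [read_word2vec()].
#' @param mapping Optional tibble with columns `drug_id`, `token` (see
#'   [read_drug_mapping()]).
#' @param fallback Policy for drugs that match no token: `"mean"` (default,
#'   the column-wise mean of the resolved vectors -- a neutral prior that
#'   keeps every drug scoreable), `"zero"`, or `"error"`.
#' @return An object of class `drug_vector_map`: a list with `drugs`,
#'   `matrix` (n x e numeric), `resolved` (logical per drug) and `coverage`
#'   (fraction resolved).
#' @export
resolve_drugs <- function(catalog, table, mapping = NULL,
                          fallback = c("mean", "zero", "error")) {
  fallback <- match.arg(fallback)
  if (inherits(catalog, "interaction_dataset")) catalog <- catalog$drugs
  stopifnot(inherits(table, "embedding_table"))
  tokens <- rownames(table$vectors)
  lookup <- catalog
  if (!is.null(mapping)) {
    mapped <- mapping$token[match(catalog, mapping$drug_id)]
    use_map <- !is.na(mapped) & mapped %in% tokens
    lookup[use_map] <- mapped[use_map]
  }
  row <- match(lookup, tokens)
  resolved <- !is.na(row)
  coverage <- mean(resolved)
  if (fallback == "error" && any(!resolved)) {
    abort(sprintf(
      "unresolved drugs with fallback = 'error': %s",
      paste(catalog[!resolved], collapse = ", ")
    ))
  }
  mat <- matrix(0, length(catalog), table$dim,
                dimnames = list(catalog, NULL))
  mat[resolved, ] <- table$vectors[row[resolved], , drop = FALSE]
  if (fallback == "mean" && any(!resolved) && any(resolved)) {
    mat[!resolved, ] <- matrix(colMeans(mat[resolved, , drop = FALSE]),
                               sum(!resolved), table$dim, byrow = TRUE)
  }
  inform(sprintf("resolved %d/%d drugs to embedding vectors (coverage %.1f%%)",
                 sum(resolved), length(catalog), 100 * coverage))
  structure(
    list(drugs = catalog, matrix = mat, resolved = resolved,
         coverage = coverage),
    class = "drug_vector_map"
  )
}

#' @export
print.drug_vector_map <- function(x, ...) {
  cat(sprintf("<drug_vector_map> %d drugs x %d dims, coverage %.1f%%\n",
              length(x$drugs), ncol(x$matrix), 100 * x$coverage))
  invisible(x)
}
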