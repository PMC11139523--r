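#' Canonical SBS-96 channel labels
#'
#' The 96 single-base-substitution channels in substitution-major COSMIC
#' order: the six pyrimidine-centred substitution types (C>A, C>G, C>T, T>A,
#' T>C, T>G), and within each type the 16 trinucleotide contexts ordered by
#' 5' base (A, C, G, T) then 3' base (A, C, G, T). Labels have the form
#' `"A[C>A]A"`.
#'
#' @return Character vector of length 96.
#' @export
#' @examples
#' head(sbs_channels())
sbs_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    as.vector(t(outer(bases, bases, function(p5, p3)
      paste0(p5, "[", s, "]", p3))))
  }))
}

#' SBS-96 mutation catalogue
#'
#' Validates and canonicalizes a samples x 96 matrix of non-negative integer
#' mutation counts. Columns must be the canonical channel labels (any order;
#' they are re-sorted), row names are sample identifiers and must be unique.
#'
#' @param x Numeric matrix or data frame, samples in rows, 96 channels in
#'   columns named with SBS-96 labels.
#' @param round Round non-integer counts to the nearest integer instead of
#'   raising an error. Default `FALSE`: count data are expected to be integral
#'   under the Poisson/multinomial model.
#' @return A matrix of class `"sbs_catalogue"` with columns in canonical
#'   channel order.
#' @export
as_sbs_catalogue <- function(x, round = FALSE) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("catalogue must be a numeric matrix", call. = FALSE)
  chan <- sbs_channels()
  if (is.null(colnames(x)))
    stop("catalogue columns must be named with the 96 SBS channel labels",
         call. = FALSE)
  miss <- setdiff(chan, colnames(x))
  if (length(miss) > 0)
    stop("catalogue is missing channel(s): ", paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) " ..." else "", call. = FALSE)
  dup <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup) > 0)
    stop("duplicated channel label(s): ", paste(dup, collapse = ", "), call. = FALSE)
  extra <- setdiff(colnames(x), chan)
  if (length(extra) > 0)
    stop("unknown channel label(s): ", paste(utils::head(extra, 5), collapse = ", "),
         call. = FALSE)
  x <- x[, chan, drop = FALSE]
  if (is.null(rownames(x))) rownames(x) <- paste0("Sample", seq_len(nrow(x)))
  if (anyDuplicated(rownames(x)))
    stop("sample IDs must be unique", call. = FALSE)
  bad <- which(!is.finite(x) | x < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("negative or non-finite count at sample '%s', channel '%s'",
                 rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]]), call. = FALSE)
  if (round) {
    x <- base::round(x)
  } else {
    nonint <- which(abs(x - base::round(x)) > 1e-8, arr.ind = TRUE)
    if (nrow(nonint) > 0)
      stop(sprintf(paste0("non-integer count %.4f at sample '%s', channel '%s' ",
                          "(use round = TRUE to round)"),
                   x[nonint[1, , drop = FALSE]],
                   rownames(x)[nonint[1, 1]], colnames(x)[nonint[1, 2]]),
           call. = FALSE)
    x <- base::round(x) # remove representation noise
  }
  storage.mode(x) <- "double"
  structure(x, class = c("sbs_catalogue", "matrix", "array"))
}

#' @export
print.sbs_catalogue <- function(x, ...) {
  tot <- rowSums(x)
  cat(sprintf("SBS-96 catalogue: %d samples, %d channels\n", nrow(x), ncol(x)))
  cat(sprintf("total mutations %g (per-sample median %g, range %g-%g)\n",
              sum(tot), stats::median(tot), min(tot), max(tot)))
  invisible(x)
}

#' Signature matrix container
#'
#' Validates a 96 x k matrix of non-negative signature profiles on the
#' canonical channels. The `"normalized"` attribute records whether every
#' column sums to one (a probability profile).
#'
#' @param x Numeric matrix, 96 channels in rows (rownames = channel labels,
#'   any order) and one column per signature.
#' @return Matrix of class `"signature_matrix"`, rows in canonical order.
#' @export
as_signature_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("signatures must be a numeric matrix", call. = FALSE)
  chan <- sbs_channels()
  if (nrow(x) != 96)
    stop("signature matrix must have 96 channel rows, got ", nrow(x), call. = FALSE)
  if (is.null(rownames(x))) rownames(x) <- chan
  miss <- setdiff(chan, rownames(x))
  if (length(miss) > 0)
    stop("signature matrix missing channel(s): ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  x <- x[chan, , drop = FALSE]
  if (any(!is.finite(x)) || any(x < 0))
    stop("signature profiles must be finite and non-negative", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("SBS96", LETTERS[seq_len(ncol(x))])
  attr(x, "normalized") <- all(abs(colSums(x) - 1) < 1e-9)
  structure(x, class = c("signature_matrix", "matrix", "array"))
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf("signature matrix: 96 channels x %d signatures%s\n", ncol(x),
              if (isTRUE(attr(x, "normalized"))) " (column-normalized)" else ""))
  cat("signatures:", paste(colnames(x), collapse = ", "), "\n")
  invisible(x)
}

# Shared reader for the COSMIC-style TSV dialect: first column "MutationType"
# holding the 96 labels, one column per sample/signature; or the transpose.
read_sbs_table <- function(path, orientation = "auto") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected a tab-separated table with >= 2 columns: ", path,
                         call. = FALSE)
  chan <- sbs_channels()
  first <- as.character(df[[1]])
  in_rows <- sum(first %in% chan)
  in_cols <- sum(colnames(df) %in% chan)
  axis <- switch(orientation,
    auto = {
      if (in_rows >= 90 && in_cols >= 90)
        stop("ambiguous orientation: both axes match SBS channel labels", call. = FALSE)
      if (in_rows >= 90) "rows" else if (in_cols >= 90) "cols"
      else stop("no axis of '", path, "' matches the 96 SBS channel labels",
                call. = FALSE)
    },
    samples_as_columns = "rows",
    samples_as_rows = "cols",
    stop("unknown orientation: ", orientation, call. = FALSE))
  if (axis == "rows") {
    labels <- first
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- labels
  } else {
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    m <- t(m)
  }
  dup <- unique(rownames(m)[duplicated(rownames(m))])
  if (length(dup) > 0)
    stop("duplicated channel label(s) in ", path, ": ", paste(dup, collapse = ", "),
         call. = FALSE)
  miss <- setdiff(chan, rownames(m))
  if (length(miss) > 0)
    stop("missing channel label(s) in ", path, ": ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) " ..." else "", call. = FALSE)
  extra <- setdiff(rownames(m), chan)
  if (length(extra) > 0)
    stop("unknown channel label(s) in ", path, ": ",
         paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
  storage.mode(m) <- "double"
  m[chan, , drop = FALSE] # channels x samples
}

#' Read an SBS-96 mutation catalogue from TSV
#'
#' Reads a COSMIC-dialect tab-separated catalogue: a `MutationType` column
#' with the 96 channel labels and one column per sample, or the transposed
#' layout with one row per sample. The channel axis is auto-detected as the
#' axis on which at least 90 of the 96 labels appear; rows are re-sorted to
#' canonical channel order.
#'
#' @param path Path to a tab-separated file.
#' @param orientation `"auto"` (default), `"samples_as_columns"` or
#'   `"samples_as_rows"`.
#' @param round Passed to [as_sbs_catalogue()].
#' @return An [as_sbs_catalogue()] object (samples x 96).
#' @export
read_catalogue <- function(path, orientation = c("auto", "samples_as_columns",
                                                 "samples_as_rows"),
                           round = FALSE) {
  orientation <- match.arg(orientation)
  m <- read_sbs_table(path, orientation)
  as_sbs_catalogue(t(m), round = round)
}

#' Write an SBS-96 catalogue to TSV
#'
#' Writes the COSMIC layout: 96 rows in canonical channel order with a
#' `MutationType` first column and one integer column per sample.
#'
#' @param C An `sbs_catalogue` (or coercible matrix).
#' @param path Output path.
#' @export
write_catalogue <- function(C, path) {
  C <- as_sbs_catalogue(C)
  df <- data.frame(MutationType = sbs_channels(),
                   t(C), check.names = FALSE)
  for (j in seq(2, ncol(df))) df[[j]] <- as.integer(round(df[[j]]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write signature matrices in COSMIC-style TSV
#'
#' Signature files share the catalogue dialect: a `MutationType` column and
#' one real-valued column per signature. On read, the `"normalized"`
#' attribute is set when every column sums to 1 (within 1e-9).
#'
#' @param path File path.
#' @return `read_signatures`: a [as_signature_matrix()] object.
#' @export
read_signatures <- function(path) {
  m <- read_sbs_table(path, "samples_as_columns")
  as_signature_matrix(m)
}

#' @rdname read_signatures
#' @param S 96 x k signature matrix.
#' @export
write_signatures <- function(S, path) {
  S <- as_signature_matrix(S)
  df <- data.frame(MutationType = sbs_channels(), S, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write exposure matrices
#'
#' Exposures are written samples-in-rows: a `Sample` first column, one
#' real-valued column per signature.
#'
#' @param path File path.
#' @return `read_exposures`: samples x k numeric matrix with sample row names.
#' @export
read_exposures <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (any(!is.finite(m)) || any(m < 0))
    stop("exposures must be finite and non-negative", call. = FALSE)
  m
}

#' @rdname read_exposures
#' @param Z Samples x k non-negative matrix.
#' @export
write_exposures <- function(Z, path) {
  Z <- as.matrix(Z)
  if (is.null(rownames(Z))) rownames(Z) <- paste0("Sample", seq_len(nrow(Z)))
  df <- data.frame(Sample = rownames(Z), Z, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
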