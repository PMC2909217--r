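# All on-disk artifacts are UTF-8, tab-delimited text; lines starting with '#'
# are comments. Gene identifiers are opaque, case-sensitive strings.

.read_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines[!grepl("^#", lines)]
}

.split_fields <- function(lines, sep = "\t") {
  strsplit(lines, sep, fixed = TRUE)
}

#' Read a gene expression matrix
#'
#' Reads a tab-delimited table whose header row holds condition identifiers
#' and whose first column holds gene identifiers. Empty cells and the strings
#' `NA`/`nan` are treated as missing values (to be filled by
#' [impute_missing()]).
#'
#' @param path Path to a TSV file.
#' @param sep Field delimiter, default tab.
#' @return A numeric matrix (genes x conditions) with gene identifiers as row
#'   names and condition identifiers as column names; missing entries are `NA`.
#' @export
read_expression <- function(path, sep = "\t") {
  lines <- .read_lines(path)
  if (length(lines) < 1L) stop("expression file is empty: ", path, call. = FALSE)
  # preserve empty trailing cells (missing values in the last column)
  fields <- lapply(strsplit(paste0(lines, sep, "\x01"), sep, fixed = TRUE),
                   function(f) f[-length(f)])
  header <- fields[[1L]]
  # header may or may not carry a stub for the gene-id column
  body <- fields[-1L]
  if (length(body) == 0L) stop("expression file has no data rows: ", path, call. = FALSE)
  ncond <- length(body[[1L]]) - 1L
  if (ncond < 1L) stop("expression rows need a gene id plus at least one value", call. = FALSE)
  cond_ids <- utils::tail(header, ncond)
  if (length(cond_ids) != ncond || anyDuplicated(cond_ids))
    stop("condition identifiers missing or duplicated in header", call. = FALSE)
  widths <- lengths(body)
  if (any(widths != ncond + 1L))
    stop("ragged expression rows (expected ", ncond + 1L, " fields, got ",
         paste(unique(widths[widths != ncond + 1L]), collapse = ","), ")", call. = FALSE)
  gene_ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifier(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "), call. = FALSE)
  vals <- vapply(body, function(f) {
    x <- f[-1L]
    x[x %in% c("", "NA", "nan", "NaN")] <- NA_character_
    as.numeric(x)
  }, numeric(ncond))
  m <- matrix(t(vals), nrow = length(gene_ids), ncol = ncond,
              dimnames = list(gene_ids, cond_ids))
  if (ncond == 1L) m <- matrix(vals, ncol = 1L, dimnames = list(gene_ids, cond_ids))
  m
}

# canonical unordered pair representation: two-column character matrix, each
# row sorted so that from < to, rows unique
.canonical_pairs <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  keep <- !duplicated(paste(a, b, sep = "\r"))
  cbind(from = a[keep], to = b[keep])
}

#' Read an interaction edge list
#'
#' Reads a two-column TSV of gene identifiers. Self-loops are dropped and
#' duplicate edges (including reversed duplicates) are collapsed; the number
#' of dropped records is reported via `message()`.
#'
#' @inheritParams read_expression
#' @return A two-column character matrix of unordered pairs (columns `from`,
#'   `to`, with `from < to` lexicographically).
#' @export
read_edge_list <- function(path, sep = "\t") {
  lines <- .read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(cbind(from = character(0), to = character(0)))
  fields <- .split_fields(lines, sep)
  if (any(lengths(fields) < 2L))
    stop("edge list rows need at least two columns", call. = FALSE)
  a <- vapply(fields, `[[`, character(1), 1L)
  b <- vapply(fields, `[[`, character(1), 2L)
  self <- a == b
  pairs <- .canonical_pairs(a[!self], b[!self])
  dropped <- length(a) - nrow(pairs)
  if (dropped > 0L)
    message("read_edge_list: dropped ", dropped,
            " record(s) (self-loops or duplicates) from ", path)
  pairs
}

#' Read protein complex memberships
#'
#' One complex per line, members tab-separated. Duplicate members within a
#' complex are collapsed; blank lines are skipped with a warning.
#'
#' @inheritParams read_expression
#' @return A list of character vectors, one per complex.
#' @export
read_complexes <- function(path, sep = "\t") {
  lines <- .read_lines(path)
  blank <- !nzchar(trimws(lines))
  if (any(blank)) warning("read_complexes: skipped ", sum(blank), " blank line(s)")
  lines <- lines[!blank]
  lapply(.split_fields(lines, sep), function(f) unique(f[nzchar(f)]))
}

#' Read labelled gene pairs
#'
#' Three-column TSV: geneA, geneB, label (1 = interacting / SGI,
#' 0 = non-interacting). Self-pairs and conflicting duplicate labels are
#' errors; consistent duplicates are collapsed.
#'
#' @inheritParams read_expression
#' @return A data.frame with columns `from`, `to` (unordered, `from < to`)
#'   and integer `label`.
#' @export
read_pair_labels <- function(path, sep = "\t") {
  lines <- .read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(from = character(0), to = character(0), label = integer(0)))
  fields <- .split_fields(lines, sep)
  # tolerate a header line
  if (suppressWarnings(is.na(as.numeric(fields[[1L]][3L])))) {
    fields <- fields[-1L]
  }
  if (any(lengths(fields) < 3L))
    stop("pair-label rows need three columns (geneA, geneB, label)", call. = FALSE)
  a <- vapply(fields, `[[`, character(1), 1L)
  b <- vapply(fields, `[[`, character(1), 2L)
  lab <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  if (anyNA(lab) || !all(lab %in% c(0, 1)))
    stop("labels must be 0 or 1", call. = FALSE)
  pair_labels(a, b, as.integer(lab))
}

#' Construct a validated labelled pair set
#'
#' @param from,to Gene identifiers (character vectors of equal length).
#' @param label Integer labels in \{0, 1\}.
#' @return data.frame with canonical unordered pairs and labels.
#' @export
pair_labels <- function(from, to, label) {
  if (any(from == to)) stop("self-pairs are not allowed", call. = FALSE)
  if (!all(label %in% c(0L, 1L))) stop("labels must be 0 or 1", call. = FALSE)
  a <- as.character(from); b <- as.character(to)
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  key <- paste(a, b, sep = "\r")
  for (k in unique(key[duplicated(key)])) {
    if (length(unique(label[key == k])) > 1L)
      stop("conflicting labels for pair ", sub("\r", "-", k), call. = FALSE)
  }
  keep <- !duplicated(key)
  data.frame(from = a[keep], to = b[keep], label = as.integer(label[keep]),
             stringsAsFactors = FALSE)
}

#' Write a record table as TSV
#'
#' Writes a data.frame with a header row; round-trips through
#' [read_table_tsv()].
#'
#' @param rows A data.frame.
#' @param path Output path.
#' @param sep Field delimiter, default tab.
#' @export
write_table <- function(rows, path, sep = "\t") {
  stopifnot(is.data.frame(rows))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir, call. = FALSE)
  utils::write.table(rows, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(NULL)
}

#' Read a TSV written by [write_table()]
#'
#' @inheritParams read_expression
#' @return A data.frame.
#' @export
read_table_tsv <- function(path, sep = "\t") {
  utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write an expression matrix as TSV
#'
#' @param matrix Numeric matrix with gene row names and condition col names.
#' @param path Output path.
#' @export
write_expression <- function(matrix, path) {
  df <- data.frame(gene = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(NULL)
}
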