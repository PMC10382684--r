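#' Read a delimited expression matrix
#'
#' Reads a tab- or comma-delimited text file into a genes-by-samples numeric
#' matrix. The first column (or row, for `samples_in_rows`) holds
#' identifiers and the header holds the other axis. Duplicate gene rows are
#' collapsed by their mean, matching aggregation of probe-level data to gene
#' level. Parsing uses the C locale dot decimal regardless of the session
#' locale.
#'
#' @param path file path; `.csv` is read as comma-separated, anything else
#'   as tab-separated (override with `sep`).
#' @param orientation `"genes_in_rows"` (default) if rows are genes, or
#'   `"samples_in_rows"` for the transposed layout.
#' @param sep field separator; `NULL` (default) chooses by file extension.
#' @return numeric matrix, genes in rows, with gene/sample dimnames.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeExpressionMatrix(matrix(1:6, 2, 3,
#'   dimnames = list(c("G1", "G2"), c("S1", "S2", "S3"))), f)
#' readExpressionMatrix(f)
#' @export
readExpressionMatrix <- function(path,
                                 orientation = c("genes_in_rows",
                                                 "samples_in_rows"),
                                 sep = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("empty expression file: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop("expression file has no data body: ", path)
  ids <- raw[[1]]
  body <- raw[, -1, drop = FALSE]
  vals <- matrix(NA_real_, nrow(body), ncol(body),
                 dimnames = list(NULL, colnames(body)))
  for (j in seq_len(ncol(body))) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v) & !is.na(body[[j]]) &
                   !body[[j]] %in% c("NA", ""))
    if (length(bad))
      stop(sprintf(
        "non-numeric value %s at row '%s', column '%s' of %s",
        dQuote(body[[j]][bad[1]]), ids[bad[1]], colnames(body)[j], path))
    vals[, j] <- v
  }
  rownames(vals) <- ids
  if (orientation == "samples_in_rows") vals <- t(vals)
  collapseDuplicateGenes(vals)
}

## mean-collapse duplicate gene rows, keeping first-occurrence order
collapseDuplicateGenes <- function(mat) {
  ids <- rownames(mat)
  if (!anyDuplicated(ids)) return(mat)
  keep <- ids[!duplicated(ids)]
  out <- rowsum(mat, group = ids, reorder = FALSE) /
    as.vector(table(factor(ids, levels = unique(ids))))
  out[keep, , drop = FALSE]
}

#' Write an expression matrix as delimited text
#'
#' Inverse of [readExpressionMatrix()]: writes genes in rows with a leading
#' `gene_id` column, at full double precision so a read round-trip
#' reproduces values to better than 1e-12.
#'
#' @param expr numeric genes-by-samples matrix with dimnames.
#' @param path output path; `.csv` writes comma-separated, else tabs.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(expr, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(gene_id = rownames(expr),
                   format(expr, digits = 17, trim = TRUE,
                          scientific = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column response table
#'
#' Reads `(sample_id, label)` or `(sample_id, ic50)` delimited text. With
#' `maxConc` supplied the second column is treated as IC50 values and
#' dichotomised via [dichotomizeIC50()]; otherwise it must already be 0/1.
#'
#' @param path file path (`.csv` comma-separated, else tab).
#' @param maxConc optional maximum screening concentration for IC50 input.
#' @return named integer vector of 0/1 labels (names = sample ids).
#' @export
readResponseTable <- function(path, maxConc = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("response table needs two columns: ", path)
  ids <- as.character(tab[[1]])
  val <- suppressWarnings(as.numeric(tab[[2]]))
  if (anyNA(val))
    stop("non-numeric response values for samples: ",
         paste(ids[is.na(val)], collapse = ", "))
  y <- if (is.null(maxConc)) {
    if (!all(val %in% c(0, 1)))
      stop("labels must be 0/1; pass 'maxConc' for IC50 input")
    as.integer(val)
  } else {
    dichotomizeIC50(val, maxConc)
  }
  stats::setNames(y, ids)
}

#' Dichotomise IC50 drug response
#'
#' A cell line is called sensitive (1) when its IC50 is less than or equal
#' to the drug's maximum screening concentration, resistant (0) otherwise.
#'
#' @param ic50 numeric vector of IC50 values (finite).
#' @param maxConc positive maximum screening concentration, on the same
#'   scale as `ic50`.
#' @return integer 0/1 vector (1 = sensitive).
#' @examples
#' dichotomizeIC50(c(0.5, 2), maxConc = 1)  # 1, 0
#' @export
dichotomizeIC50 <- function(ic50, maxConc) {
  if (!is.numeric(maxConc) || length(maxConc) != 1L || maxConc <= 0)
    stop("'maxConc' must be a single positive number")
  bad <- which(!is.finite(ic50))
  if (length(bad)) {
    nm <- if (!is.null(names(ic50))) names(ic50)[bad] else as.character(bad)
    stop("non-finite IC50 values for samples: ", paste(nm, collapse = ", "))
  }
  out <- as.integer(ic50 <= maxConc)
  names(out) <- names(ic50)
  out
}
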