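#' Read a gene x sample expression matrix from TSV
#'
#' The file must have a header row of sample identifiers, a first column
#' named `gene_id` holding unique gene identifiers, and a numeric body
#' (normalized expression values, unitless). Gene and sample order on disk
#' becomes the in-memory order.
#'
#' @param path Path to a TSV file.
#' @param drop_zero_variance Drop genes whose expression is constant across
#'   samples (their correlation with any other gene is undefined). Default
#'   `TRUE`; the number of dropped genes is reported via a message.
#' @param na_policy Either `"error"` (default: any missing cell is a hard
#'   error) or `"drop-gene"` (genes with any missing cell are removed).
#' @return A numeric matrix (genes x samples) with gene ids as row names and
#'   sample ids as column names. The integer attribute `"dropped"` records
#'   how many genes were removed.
#' @export
read_expression <- function(path, drop_zero_variance = TRUE,
                            na_policy = c("error", "drop-gene")) {
  na_policy <- match.arg(na_policy)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA)
  if (ncol(df) < 2L) stop("expression file needs a gene_id column plus >= 1 sample column")
  gene_ids <- as.character(df[[1L]])
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    stop("duplicate gene id(s): ", paste(utils::head(dup, 5L), collapse = ", "))
  }
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))
      row_name <- if (length(bad)) gene_ids[bad[1L]] else "?"
      stop("non-numeric value in column '", names(body)[j], "', row '", row_name, "'")
    }
  }
  mat <- as.matrix(body)
  rownames(mat) <- gene_ids
  dropped <- 0L
  if (anyNA(mat)) {
    if (na_policy == "error") {
      stop("missing values in expression matrix; use na_policy = \"drop-gene\" to remove affected genes")
    }
    keep <- rowSums(is.na(mat)) == 0L
    dropped <- dropped + sum(!keep)
    mat <- mat[keep, , drop = FALSE]
  }
  if (drop_zero_variance) {
    v <- apply(mat, 1L, stats::var)
    keep <- v > 0
    n_zv <- sum(!keep)
    if (n_zv > 0L) {
      message(n_zv, " zero-variance gene(s) dropped")
      mat <- mat[keep, , drop = FALSE]
      dropped <- dropped + n_zv
    }
  }
  attr(mat, "dropped") <- dropped
  mat
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression()]: first column `gene_id`, one column per
#' sample. Values are written at full double precision.
#'
#' @param expr Numeric matrix, genes x samples, with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample -> tissue label table and one-hot binarize it
#'
#' The TSV must have columns `sample_id` and `tissue`; a sample may appear on
#' several rows (multi-label samples are permitted). The resulting binary
#' design matrix is aligned to the supplied sample order.
#'
#' @param path Path to a TSV file.
#' @param samples Ordered sample identifiers (typically
#'   `colnames(expression)`); every one must appear in the file.
#' @return Binary integer matrix, samples x tissues, with `samples` as row
#'   names and sorted distinct tissue labels as column names.
#' @export
read_traits <- function(path, samples) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "tissue") %in% names(df))) {
    stop("trait file must have columns 'sample_id' and 'tissue'")
  }
  missing <- setdiff(samples, df$sample_id)
  if (length(missing)) {
    stop("sample(s) present in expression but absent from trait file: ",
         paste(utils::head(missing, 10L), collapse = ", "))
  }
  trait_design(df[c("sample_id", "tissue")], samples)
}

#' Build a binary trait design matrix from a sample/tissue data frame
#'
#' @param df Data frame with columns `sample_id` and `tissue`.
#' @param samples Ordered sample identifiers the design is aligned to.
#' @return Binary integer matrix, samples x tissues.
#' @export
trait_design <- function(df, samples) {
  df <- df[df$sample_id %in% samples, , drop = FALSE]
  tissues <- sort(unique(as.character(df$tissue)))
  design <- matrix(0L, nrow = length(samples), ncol = length(tissues),
                   dimnames = list(samples, tissues))
  design[cbind(match(df$sample_id, samples), match(df$tissue, tissues))] <- 1L
  if (any(rowSums(design) < 1L)) {
    bad <- rownames(design)[rowSums(design) < 1L]
    stop("sample(s) with no tissue label: ", paste(utils::head(bad, 10L), collapse = ", "))
  }
  design
}

#' Write a trait design back to the two-column TSV dialect
#' @param design Binary samples x tissues matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_traits <- function(design, path) {
  idx <- which(design == 1L, arr.ind = TRUE)
  df <- data.frame(sample_id = rownames(design)[idx[, 1L]],
                   tissue = colnames(design)[idx[, 2L]],
                   stringsAsFactors = FALSE)
  df <- df[order(match(df$sample_id, rownames(design)), df$tissue), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a term database
#'
#' A term database groups gene sets under term identifiers for one annotation
#' category (for example GO biological process under the keyword `"bp"`).
#'
#' @param category Short category keyword (e.g. a two-character code).
#' @param genes Named list of character vectors: term id -> gene ids.
#' @param descriptions Named character vector of term descriptions (optional;
#'   defaults to empty strings).
#' @return An object of class `term_db`.
#' @export
term_db <- function(category, genes, descriptions = NULL) {
  stopifnot(is.character(category), length(category) == 1L, is.list(genes))
  if (anyDuplicated(names(genes))) stop("term ids must be unique within a category")
  empty <- vapply(genes, length, 1L) == 0L
  if (any(empty)) {
    warning(sum(empty), " term(s) with empty gene sets dropped")
    genes <- genes[!empty]
  }
  genes <- lapply(genes, function(g) unique(as.character(g)))
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(genes)), names(genes))
  } else {
    descriptions <- stats::setNames(as.character(descriptions[names(genes)]), names(genes))
    descriptions[is.na(descriptions)] <- ""
  }
  structure(list(category = category, genes = genes, descriptions = descriptions),
            class = "term_db")
}

#' @export
print.term_db <- function(x, ...) {
  cat("<term_db> category '", x$category, "': ", length(x$genes), " terms, ",
      length(unique(unlist(x$genes, use.names = FALSE))), " distinct genes\n", sep = "")
  invisible(x)
}

#' Read a gene-term annotation database
#'
#' Two dialects are accepted and auto-detected per line count of fields:
#' GMT (`term<TAB>description<TAB>gene1<TAB>gene2...`) and two-column TSV
#' (`gene<TAB>term`, optional header). Terms that end up with empty gene sets
#' are dropped with a warning. Genes absent from any expression universe are
#' kept; filtering against a universe is the enrichment step's job.
#'
#' @param path Path to a `.gmt` or two-column `.tsv` file.
#' @param category Short keyword naming the annotation category.
#' @param format `"auto"` (default), `"gmt"`, or `"tsv"`.
#' @return A [term_db()] object.
#' @export
read_term_db <- function(path, category, format = c("auto", "gmt", "tsv")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(term_db(category, list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "auto") {
    format <- if (all(lengths(fields) == 2L)) "tsv" else "gmt"
  }
  if (format == "tsv") {
    first <- fields[[1L]]
    if (identical(tolower(first), c("gene", "term")) ||
        identical(tolower(first), c("gene_id", "term_id"))) {
      fields <- fields[-1L]
    }
    gene <- vapply(fields, `[`, "", 1L)
    term <- vapply(fields, `[`, "", 2L)
    genes <- split(gene, term)
    # split() sorts by term; preserve first-appearance order instead
    genes <- genes[unique(term)]
    term_db(category, genes)
  } else {
    ids <- vapply(fields, `[`, "", 1L)
    desc <- vapply(fields, function(f) if (length(f) >= 2L) f[2L] else "", "")
    genes <- lapply(fields, function(f) if (length(f) >= 3L) f[-(1:2)] else character())
    names(genes) <- ids
    term_db(category, genes, stats::setNames(desc, ids))
  }
}

#' Write a term database in GMT format
#' @param db A [term_db()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_term_db <- function(db, path) {
  stopifnot(inherits(db, "term_db"))
  lines <- vapply(names(db$genes), function(id) {
    paste(c(id, db$descriptions[[id]], db$genes[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
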