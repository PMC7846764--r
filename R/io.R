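# Readers and writers for the plain-text formats the pipeline speaks:
# TSV/CSV count matrices, the GCT 1.2 dialect ("#1.2" header + dims line +
# Name/Description columns), two-column label TSVs, and truth tables.

#' Read a count matrix from TSV, CSV or GCT 1.2
#'
#' @param path file path.
#' @param format one of `"tsv"`, `"csv"`, `"gct"`; default guessed from
#'   the file extension.
#' @param gene_lengths optional named vector or two-column file
#'   (gene_id, length); defaults to 1000 bp for every gene with a message
#'   (TPM then reduces to CPM).
#' @param labels optional factor / two-column TSV path (sample_id, class).
#' @return a [count_matrix].
#' @export
read_counts <- function(path, format = NULL, gene_lengths = NULL, labels = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (is.null(format))
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", gct = "gct", "tsv")
  format <- match.arg(format, c("tsv", "csv", "gct"))
  if (format == "gct") {
    m <- read_gct(path)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids))
      stopf("duplicate gene id(s) in %s: %s", path,
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- ids
  }
  if (is.character(labels) && length(labels) == 1L) labels <- read_labels(labels)
  if (!is.null(labels) && !is.null(names(labels)))
    labels <- labels[colnames(m)]
  if (is.character(gene_lengths) && length(gene_lengths) == 1L) {
    lt <- utils::read.table(gene_lengths, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    gene_lengths <- stats::setNames(lt[[2]], lt[[1]])
  }
  if (is.null(gene_lengths)) {
    message("no gene lengths supplied; assuming 1000 bp for all genes")
    gene_lengths <- rep(1000, nrow(m))
  } else if (!is.null(names(gene_lengths))) {
    gene_lengths <- gene_lengths[rownames(m)]
  }
  count_matrix(m, gene_lengths, labels)
}

read_gct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || trimws(lines[1]) != "#1.2")
    stopf("%s: line 1 must be '#1.2' (found '%s')", path, lines[1])
  dims <- suppressWarnings(as.numeric(strsplit(trimws(lines[2]), "\t")[[1]]))
  if (length(dims) != 2 || any(is.na(dims)))
    stopf("%s: line 2 must hold '<n_genes>\\t<n_samples>'", path)
  df <- utils::read.table(text = lines[-(1:2)], header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(tolower(names(df)[1:2]), c("name", "description")))
    stopf("%s: columns 1-2 must be Name and Description", path)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- df[[1]]
  if (nrow(m) != dims[1] || ncol(m) != dims[2])
    stopf("%s: dims line says %d x %d but data are %d x %d",
          path, dims[1], dims[2], nrow(m), ncol(m))
  if (anyDuplicated(rownames(m)))
    stopf("%s: duplicate gene id(s): %s", path,
          paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  m
}

#' Write a count matrix as TSV, CSV or GCT 1.2
#'
#' TSV/CSV carry genes as rows with the gene id in the first column; GCT
#' 1.2 adds the `#1.2` header, the dims line and Name/Description columns.
#'
#' @param cm a [count_matrix] (or plain matrix with dimnames).
#' @param path output path.
#' @param format `"tsv"`, `"csv"` or `"gct"`.
#' @export
write_counts <- function(cm, path, format = c("tsv", "csv", "gct")) {
  format <- match.arg(format)
  m <- if (inherits(cm, "count_matrix")) cm$counts else cm
  if (format == "gct") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(m), ncol(m), sep = "\t")), con)
    df <- data.frame(Name = rownames(m), Description = rownames(m),
                     m, check.names = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read / write a sample label table (TSV: sample_id, class)
#' @param path file path.
#' @return named factor of class labels.
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stats::setNames(factor(df[[2]]), df[[1]])
}

#' @rdname read_labels
#' @param labels named factor/character vector.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(
    data.frame(sample_id = names(labels), class = as.character(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a signature truth table as CSV
#' @param truth a `signature_truth`.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  utils::write.csv(as.data.frame(truth), path, row.names = FALSE)
  invisible(path)
}
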