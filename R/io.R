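#' Read / write an expression matrix as TSV
#'
#' First column holds probe ids; header holds sample ids; values are log2
#' intensities.
#'
#' @param path file path.
#' @return for the reader, a numeric matrix with probe rownames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression_tsv
#' @param matrix numeric matrix, probes in rows.
#' @export
write_expression_tsv <- function(matrix, path) {
  df <- data.frame(probe_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then member ids, tab-separated.
#' A [gene_set_partition()] is written as two lines named `inflammatory`
#' and `regulatory`.
#'
#' @param path file path.
#' @return for the reader, a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t")[[1L]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t")[[1L]][1L], character(1))
  sets
}

#' @rdname read_gmt
#' @param partition a [gene_set_partition()].
#' @export
write_partition_gmt <- function(partition, path) {
  lines <- c(
    paste(c("inflammatory", "index inflammatory probe set", partition$inflammatory),
          collapse = "\t"),
    paste(c("regulatory", "index regulatory probe set", partition$regulatory),
          collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname read_gmt
#' @export
partition_from_gmt <- function(path) {
  sets <- read_gmt(path)
  if (!all(c("inflammatory", "regulatory") %in% names(sets))) {
    stop("GMT must contain sets named 'inflammatory' and 'regulatory'")
  }
  gene_set_partition(sets$inflammatory, sets$regulatory)
}

#' Read / write an OTU table as TSV
#'
#' Rows are OTUs, columns are samples, and the final column `lineage` holds
#' the semicolon-delimited Greengenes-style lineage string.
#'
#' @param path file path.
#' @return for the reader, an [otu_count_table()].
#' @export
read_otu_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"lineage" %in% names(df)) stop("OTU TSV must have a 'lineage' column")
  lineage <- df$lineage
  m <- as.matrix(df[, setdiff(names(df), c(names(df)[1L], "lineage")), drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "integer"
  otu_count_table(m, lineage)
}

#' @rdname read_otu_tsv
#' @param table an [otu_count_table()].
#' @export
write_otu_tsv <- function(table, path) {
  df <- data.frame(otu_id = rownames(table$counts), table$counts,
                   lineage = table$lineage,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
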