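#' Gene-level methylation matrix
#'
#' The pipeline's substrate: a dense genes-by-samples matrix of methylation
#' levels (beta values) in \[0, 1\], with unique gene and sample identifiers
#' and an optional per-sample class label.  Labels distinguish the healthy
#' pool (eligible to serve as controls) from disease samples; any label other
#' than `"disease"` is treated as healthy downstream.
#'
#' @param values numeric matrix, genes as rows and samples as columns, with
#'   rownames (gene ids) and colnames (sample ids).
#' @param labels optional character vector of per-sample labels, either named
#'   by sample id or in column order.  Conventional values are `"control"`,
#'   `"healthy_test"` and `"disease"`.
#' @param validate check invariants (range, no missing values, unique ids).
#' @return an object of class `methylation_matrix`: a list with elements
#'   `values` and `labels`.
#' @export
methylation_matrix <- function(values, labels = NULL, validate = TRUE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_pn("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_pn("`values` must have rownames (gene ids) and colnames (sample ids)")
  if (!is.null(labels)) {
    if (!is.null(names(labels))) {
      miss <- setdiff(colnames(values), names(labels))
      if (length(miss))
        stop_pn("labels missing for samples: ", paste(head(miss, 5), collapse = ", "))
      labels <- labels[colnames(values)]
    } else {
      if (length(labels) != ncol(values))
        stop_pn("unnamed `labels` must have one entry per sample")
      names(labels) <- colnames(values)
    }
    labels <- as.character(labels)
    names(labels) <- colnames(values)
  }
  m <- structure(list(values = values, labels = labels),
                 class = "methylation_matrix")
  if (validate) validate_methylation_matrix(m)
  m
}

validate_methylation_matrix <- function(m) {
  v <- m$values
  if (anyDuplicated(rownames(v)))
    stop_pn("duplicate gene ids: ",
            paste(head(unique(rownames(v)[duplicated(rownames(v))]), 5), collapse = ", "))
  if (anyDuplicated(colnames(v)))
    stop_pn("duplicate sample ids: ",
            paste(head(unique(colnames(v)[duplicated(colnames(v))]), 5), collapse = ", "))
  bad <- which(is.na(v) | v < 0 | v > 1, arr.ind = TRUE)
  if (nrow(bad)) {
    loc <- paste0(rownames(v)[bad[, 1]], ",", colnames(v)[bad[, 2]])
    stop_pn("values missing or outside [0,1] at: ",
            paste(head(loc, 5), collapse = "; "))
  }
  invisible(m)
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat(sprintf("<methylation_matrix> %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.methylation_matrix <- function(x) dim(x$values)

gene_ids <- function(m) rownames(m$values)
sample_ids <- function(m) colnames(m$values)

infer_delim <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

read_table_checked <- function(path, what = "matrix") {
  if (!file.exists(path)) stop_pn("file not found: ", path)
  df <- read.delim(path, sep = infer_delim(path), check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_pn(what, " file needs an id column plus data columns: ", path)
  df
}

df_to_numeric_matrix <- function(df, what = "matrix") {
  ids <- as.character(df[[1L]])
  cols <- df[-1L]
  samples <- colnames(cols)
  m <- matrix(NA_real_, nrow(df), length(samples),
              dimnames = list(ids, samples))
  for (k in seq_along(cols)) {
    col <- cols[[k]]
    if (is.character(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & nzchar(trimws(col)) &
                     toupper(trimws(col)) != "NA")
      if (length(bad))
        stop_pn("non-numeric cell in ", what, " at: ",
                paste(head(paste0(ids[bad], ",", samples[k]), 5), collapse = "; "))
      col <- num
    }
    m[, k] <- as.numeric(col)
  }
  m
}

#' Read / write a gene-level methylation matrix
#'
#' The on-disk format is a delimited table (`.tsv` tab, `.csv` comma) with a
#' header row of sample ids and the gene id in the first column.  Labels are
#' joined from a two-column annotation table (sample_id, label).  Values are
#' written with 12 significant digits, so a write/read round trip preserves
#' them to that precision.
#'
#' @param path matrix file path.
#' @param labels optional path to the sample annotation table.
#' @return a [methylation_matrix()].
#' @export
read_matrix <- function(path, labels = NULL) {
  df <- read_table_checked(path, "methylation matrix")
  v <- df_to_numeric_matrix(df, "methylation matrix")
  lab <- if (!is.null(labels)) read_labels(labels)
  methylation_matrix(v, labels = lab)
}

#' @param m a [methylation_matrix()].
#' @rdname read_matrix
#' @export
write_matrix <- function(m, path) {
  v <- m$values
  out <- data.frame(gene_id = rownames(v),
                    apply(v, 2, fmt_num),
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out) <- c("gene_id", colnames(v))
  write.table(out, path, sep = infer_delim(path), quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read / write per-sample class labels
#'
#' Two-column delimited table: `sample_id`, `label`.
#'
#' @param path file path.
#' @return named character vector of labels.
#' @export
read_labels <- function(path) {
  df <- read_table_checked(path, "labels")
  lab <- as.character(df[[2L]])
  names(lab) <- as.character(df[[1L]])
  if (anyDuplicated(names(lab)))
    stop_pn("duplicate sample ids in labels file: ", path)
  lab
}

#' @param labels named character vector of labels.
#' @rdname read_labels
#' @export
write_labels <- function(labels, path) {
  write.table(data.frame(sample_id = names(labels), label = unname(labels)),
              path, sep = infer_delim(path), quote = FALSE, row.names = FALSE)
  invisible(path)
}
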