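#' Expression set container
#'
#' A minimal container pairing a genes-by-samples matrix of log2 intensities
#' with a two-group design. Both groups must be non-empty; gene and sample
#' identifiers must be unique; all values must be finite.
#'
#' @param values Numeric matrix (log2 scale), genes in rows, samples in
#'   columns. Row and column names are required and taken as gene and sample
#'   identifiers.
#' @param design `data.frame` with columns `sample` and `group`; `group`
#'   must take exactly the two values `"disease"` and `"control"` (in any
#'   mixture), and every column of `values` must appear in `sample`.
#' @return An object of class `cnc_expr`: a list with elements `values`
#'   (the matrix) and `design` (the design data frame, in sample order of
#'   the matrix).
#' @export
cnc_expr <- function(values, design) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene row names and sample column names")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicate gene ids: ", paste(utils::head(dup, 5), collapse = ", "))
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup))
    stop("duplicate sample ids: ", paste(dup, collapse = ", "))
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-finite expression value at gene '", rownames(values)[bad[1, 1]],
         "', sample '", colnames(values)[bad[1, 2]], "'")
  if (!is.data.frame(design) || !all(c("sample", "group") %in% names(design)))
    stop("'design' must be a data.frame with columns 'sample' and 'group'")
  design$sample <- as.character(design$sample)
  design$group <- as.character(design$group)
  missing <- setdiff(colnames(values), design$sample)
  if (length(missing))
    stop("sample not in design: ", paste(missing, collapse = ", "))
  if (!all(design$group %in% c("disease", "control")))
    stop("design groups must be 'disease' or 'control'")
  design <- design[match(colnames(values), design$sample), c("sample", "group")]
  rownames(design) <- NULL
  if (!all(c("disease", "control") %in% design$group))
    stop("both groups ('disease', 'control') must be present")
  structure(list(values = values, design = design), class = "cnc_expr")
}

#' @export
print.cnc_expr <- function(x, ...) {
  n <- table(x$design$group)
  cat(sprintf("cnc_expr: %d genes x %d samples (%d disease, %d control)\n",
              nrow(x$values), ncol(x$values), n[["disease"]], n[["control"]]))
  invisible(x)
}

#' Group membership of an expression set
#'
#' @param expr A [cnc_expr] object.
#' @return Named character vector mapping sample id to `"disease"` or
#'   `"control"`, in matrix column order.
#' @export
sample_groups <- function(expr) {
  stopifnot(inherits(expr, "cnc_expr"))
  stats::setNames(expr$design$group, expr$design$sample)
}

#' Read an expression matrix and its design
#'
#' The matrix file is TSV with a header row of sample identifiers and gene
#' identifiers in the first column. The design file is two-column TSV
#' (`sample`, `group`) and must list every sample present in the matrix.
#'
#' @param path_tsv Path to the expression TSV.
#' @param path_design Path to the design TSV.
#' @return A [cnc_expr] object, with row/column order as in the file.
#' @export
read_expression <- function(path_tsv, path_design) {
  tab <- utils::read.delim(path_tsv, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2)
    stop("expression file must have a gene id column plus >=1 sample column")
  gene_ids <- tab[[1]]
  vals <- tab[, -1, drop = FALSE]
  num <- suppressWarnings(
    vapply(vals, function(col) as.numeric(col), numeric(nrow(vals))))
  if (nrow(vals) == 1L) num <- matrix(num, nrow = 1)
  bad <- which(is.na(num) & !is.na(as.matrix(vals)), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-numeric cell at gene '", gene_ids[bad[1, 1]], "', sample '",
         colnames(vals)[bad[1, 2]], "'")
  values <- matrix(num, nrow = nrow(vals),
                   dimnames = list(gene_ids, colnames(vals)))
  design <- utils::read.delim(path_design, header = TRUE, sep = "\t",
                              colClasses = "character")
  cnc_expr(values, design)
}

#' Write an expression matrix and its design
#'
#' Inverse of [read_expression()]; values are written with full precision
#' (15 significant digits) so that a write/read round trip preserves them
#' to at least 12 decimal places.
#'
#' @param expr A [cnc_expr] object.
#' @param path_tsv Output path for the expression TSV.
#' @param path_design Output path for the design TSV.
#' @return Invisibly, `expr`.
#' @export
write_expression <- function(expr, path_tsv, path_design) {
  stopifnot(inherits(expr, "cnc_expr"))
  tab <- data.frame(gene_id = rownames(expr$values),
                    format(expr$values, digits = 15, trim = TRUE,
                           scientific = FALSE),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(expr$design, path_design, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(expr)
}
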