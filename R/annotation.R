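#' Transcript annotation table
#'
#' Internal representation of genomic features: a data frame with columns
#' `id`, `chrom`, `start`, `end`, `strand`, `biotype`. Coordinates are
#' 0-based half-open (BED convention) everywhere inside the package;
#' conversions happen only at I/O boundaries.
#'
#' @param df Data frame with the six columns above.
#' @return Validated annotation data frame (class `cnc_annotation`,
#'   still a plain data frame).
#' @export
cnc_annotation <- function(df) {
  req <- c("id", "chrom", "start", "end", "strand", "biotype")
  if (!is.data.frame(df) || !all(req %in% names(df)))
    stop("annotation must have columns: ", paste(req, collapse = ", "))
  df <- as.data.frame(df)[, req]
  df$id <- as.character(df$id)
  df$chrom <- as.character(df$chrom)
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  df$strand <- as.character(df$strand)
  df$biotype <- as.character(df$biotype)
  if (anyDuplicated(df$id))
    stop("duplicate feature ids: ",
         paste(utils::head(unique(df$id[duplicated(df$id)]), 5), collapse = ", "))
  bad <- df$start >= df$end
  if (any(bad))
    stop("start >= end for feature(s): ",
         paste(utils::head(df$id[bad], 5), collapse = ", "))
  if (any(df$start < 0)) stop("negative start coordinate")
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-' (found: ",
         paste(utils::head(setdiff(unique(df$strand), c("+", "-")), 5),
               collapse = ", "), ")")
  if (!all(df$biotype %in% c("lncRNA", "mRNA")))
    stop("biotype must be 'lncRNA' or 'mRNA'")
  rownames(df) <- NULL
  class(df) <- c("cnc_annotation", "data.frame")
  df
}

#' Read a transcript annotation (BED6 or GTF)
#'
#' BED input carries `id|biotype` in the name field and is already 0-based
#' half-open. GTF input (1-based, closed) is converted on read; `transcript`
#' rows are used and the attribute fields `transcript_id` and
#' `transcript_biotype` (falling back to `gene_biotype` / `biotype`) supply
#' the identifier and biotype.
#'
#' @param path Path to a `.bed`, `.gtf` or `.gff` file.
#' @param format Either `"auto"` (default, from the file extension),
#'   `"bed"` or `"gtf"`.
#' @return A [cnc_annotation] data frame.
#' @export
read_annotation <- function(path, format = c("auto", "bed", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, bed = "bed", gtf = "gtf", gff = "gtf",
                     stop("cannot infer annotation format from '.", ext,
                          "'; pass format='bed' or 'gtf'"))
  }
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GTF")
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*"))
    stop("undefined strand ('.') in annotation: every feature needs + or -")
  if (format == "bed") {
    name <- gr$name
    parts <- strsplit(name, "|", fixed = TRUE)
    if (any(lengths(parts) != 2))
      stop("BED name field must be 'id|biotype'")
    id <- vapply(parts, `[`, "", 1L)
    biotype <- vapply(parts, `[`, "", 2L)
  } else {
    type <- as.character(gr$type)
    keep <- type == "transcript"
    if (!any(keep)) stop("GTF contains no 'transcript' features")
    gr <- gr[keep]
    strand <- strand[keep]
    id <- gr$transcript_id
    biotype <- gr$transcript_biotype
    if (is.null(biotype) || all(is.na(biotype))) biotype <- gr$gene_biotype
    if (is.null(biotype) || all(is.na(biotype))) biotype <- gr$biotype
    if (is.null(id) || anyNA(id)) stop("GTF rows lack transcript_id")
    if (is.null(biotype) || anyNA(biotype))
      stop("GTF rows lack a biotype attribute")
  }
  # GRanges is 1-based closed for both formats: start-1 restores 0-based
  # half-open regardless of the on-disk convention.
  cnc_annotation(data.frame(
    id = id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    strand = strand,
    biotype = biotype,
    stringsAsFactors = FALSE))
}

#' Write a transcript annotation as BED6
#'
#' The name field is `id|biotype`, score is 0. Coordinates are written
#' unchanged (internal representation is already BED's 0-based half-open).
#'
#' @param annotation A [cnc_annotation] data frame.
#' @param path Output path.
#' @return Invisibly, `annotation`.
#' @export
write_annotation <- function(annotation, path) {
  annotation <- cnc_annotation(annotation)
  bed <- data.frame(chrom = annotation$chrom,
                    start = format(annotation$start, scientific = FALSE, trim = TRUE),
                    end = format(annotation$end, scientific = FALSE, trim = TRUE),
                    name = paste0(annotation$id, "|", annotation$biotype),
                    score = 0L,
                    strand = annotation$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(annotation)
}

#' Read a GMT term-to-gene map
#'
#' @param path Path to a GMT file (term, description, then member genes,
#'   tab-separated).
#' @return Named list of character vectors of gene identifiers.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}
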