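#' Classify the genomic relation of lncRNA-mRNA feature pairs
#'
#' Vectorised classification of one or more (lncRNA, mRNA) interval pairs
#' into `overlap`, `antisense`, `upstream`, `downstream` or `none`.
#' Intervals are 0-based half-open. Rules, in priority order:
#' different chromosomes give `none`; overlapping intervals give `overlap`
#' (same strand) or `antisense` (opposite strand) at distance 0;
#' otherwise the boundary gap must be strictly below `max_distance`
#' (else `none`), and orientation is judged relative to the mRNA's strand:
#' a lncRNA lying entirely 5' of the mRNA's transcription start is
#' `upstream`, entirely 3' of its transcription end is `downstream`.
#'
#' @param lnc,mrna Data frames (or single-row lists) with columns `chrom`,
#'   `start`, `end`, `strand`; recycled against each other if one has a
#'   single row.
#' @param max_distance Maximum boundary gap in bases (default 300000,
#'   strict `<`).
#' @param anchor Which gene's strand defines upstream/downstream:
#'   `"mrna"` (default) or `"lnc"`.
#' @return List with character vector `relation` and numeric vector
#'   `distance` (0 for overlapping relations, `NA` for `none`).
#' @export
classify_relation <- function(lnc, mrna, max_distance = 300000,
                              anchor = c("mrna", "lnc")) {
  anchor <- match.arg(anchor)
  lnc <- as.data.frame(lnc)
  mrna <- as.data.frame(mrna)
  req <- c("chrom", "start", "end", "strand")
  if (!all(req %in% names(lnc)) || !all(req %in% names(mrna)))
    stop("features need columns chrom, start, end, strand")
  n <- max(nrow(lnc), nrow(mrna))
  if (nrow(lnc) == 1 && n > 1) lnc <- lnc[rep(1, n), ]
  if (nrow(mrna) == 1 && n > 1) mrna <- mrna[rep(1, n), ]
  if (nrow(lnc) != nrow(mrna)) stop("incompatible numbers of features")
  if (any(lnc$start >= lnc$end) || any(mrna$start >= mrna$end))
    stop("malformed feature: start must be < end")
  if (!all(c(lnc$strand, mrna$strand) %in% c("+", "-")))
    stop("malformed feature: strand must be '+' or '-'")

  relation <- rep("none", n)
  distance <- rep(NA_real_, n)
  same_chr <- lnc$chrom == mrna$chrom
  overlaps <- same_chr & lnc$start < mrna$end & mrna$start < lnc$end
  relation[overlaps & lnc$strand == mrna$strand] <- "overlap"
  relation[overlaps & lnc$strand != mrna$strand] <- "antisense"
  distance[overlaps] <- 0

  apart <- same_chr & !overlaps
  gap <- pmax(0, pmax(lnc$start, mrna$start) - pmin(lnc$end, mrna$end))
  near <- apart & gap < max_distance
  ref_strand <- if (anchor == "mrna") mrna$strand else lnc$strand
  # genomic side of the lncRNA relative to the mRNA
  lnc_left <- lnc$end <= mrna$start
  is_up <- near & ((ref_strand == "+" & lnc_left) |
                   (ref_strand == "-" & !lnc_left))
  relation[is_up] <- "upstream"
  relation[near & !is_up] <- "downstream"
  distance[near] <- gap[near]
  list(relation = relation, distance = distance)
}

#' Find cis lncRNA-mRNA pairs among differentially expressed genes
#'
#' All (DE lncRNA) x (DE mRNA) pairs on a shared chromosome are classified
#' with [classify_relation()]; pairs with a non-`none` relation are
#' returned, each ordered pair exactly once, sorted by
#' (chrom, lncRNA start, mRNA start).
#'
#' @param annotation A [cnc_annotation] data frame.
#' @param de_lnc,de_mrna Named character vectors: names are feature ids,
#'   values their direction (`"up"`/`"down"`). All ids must exist in the
#'   annotation (with the matching biotype).
#' @param max_distance Maximum boundary gap (default 300000).
#' @param anchor Strand anchoring convention, see [classify_relation()].
#' @return Data frame of pair records: `lnc_id`, `mrna_id`, `relation`,
#'   `distance`, `lnc_direction`, `mrna_direction`, `concordant`.
#' @export
find_pairs <- function(annotation, de_lnc, de_mrna, max_distance = 300000,
                       anchor = c("mrna", "lnc")) {
  anchor <- match.arg(anchor)
  annotation <- cnc_annotation(annotation)
  empty <- data.frame(lnc_id = character(0), mrna_id = character(0),
                      relation = character(0), distance = numeric(0),
                      lnc_direction = character(0),
                      mrna_direction = character(0),
                      concordant = logical(0), stringsAsFactors = FALSE)
  if (length(de_lnc) == 0 || length(de_mrna) == 0) return(empty)
  miss <- c(setdiff(names(de_lnc), annotation$id[annotation$biotype == "lncRNA"]),
            setdiff(names(de_mrna), annotation$id[annotation$biotype == "mRNA"]))
  if (length(miss))
    stop("DE ids missing from annotation (or wrong biotype): ",
         paste(utils::head(miss, 10), collapse = ", "))
  lnc <- annotation[match(names(de_lnc), annotation$id), ]
  mrna <- annotation[match(names(de_mrna), annotation$id), ]
  # cross join restricted to shared chromosomes
  idx <- expand.grid(i = seq_len(nrow(lnc)), j = seq_len(nrow(mrna)))
  idx <- idx[lnc$chrom[idx$i] == mrna$chrom[idx$j], , drop = FALSE]
  if (!nrow(idx)) return(empty)
  cls <- classify_relation(lnc[idx$i, ], mrna[idx$j, ],
                           max_distance = max_distance, anchor = anchor)
  keep <- cls$relation != "none"
  if (!any(keep)) return(empty)
  i <- idx$i[keep]; j <- idx$j[keep]
  out <- data.frame(lnc_id = lnc$id[i],
                    mrna_id = mrna$id[j],
                    relation = cls$relation[keep],
                    distance = cls$distance[keep],
                    lnc_direction = unname(de_lnc[i]),
                    mrna_direction = unname(de_mrna[j]),
                    stringsAsFactors = FALSE)
  out$concordant <- out$lnc_direction == out$mrna_direction
  ord <- order(lnc$chrom[i], lnc$start[i], mrna$start[j], out$lnc_id,
               out$mrna_id)
  out <- out[ord, ]
  rownames(out) <- NULL
  out
}

#' Summarise a pair table
#'
#' Counts per relation category, the total, and the direction-concordance
#' fraction (reported to 4 decimals, and as a percentage to 1 decimal).
#' With zero pairs the fraction is `NA`.
#'
#' @param pairs Data frame from [find_pairs()].
#' @return Object of class `pair_summary`: list with `counts` (named,
#'   overlap/antisense/upstream/downstream), `total`, `n_concordant`,
#'   `n_discordant`, `concordance_fraction`, `concordance_percent`.
#' @export
summarize_pairs <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("relation", "concordant") %in% names(pairs)))
  cats <- c("overlap", "antisense", "upstream", "downstream")
  counts <- vapply(cats, function(k) sum(pairs$relation == k), integer(1))
  total <- sum(counts)
  ncon <- sum(pairs$concordant)
  frac <- if (total > 0) round(ncon / total, 4) else NA_real_
  pct <- if (total > 0) round(100 * ncon / total, 1) else NA_real_
  structure(list(counts = counts, total = total,
                 n_concordant = ncon, n_discordant = total - ncon,
                 concordance_fraction = frac,
                 concordance_percent = pct),
            class = "pair_summary")
}

#' @export
print.pair_summary <- function(x, ...) {
  cat("lncRNA-mRNA pair summary\n")
  cat(sprintf("  %-10s %d\n", names(x$counts), x$counts), sep = "")
  cat(sprintf("  total      %d\n", x$total))
  if (x$total > 0)
    cat(sprintf("  concordant %d/%d (%.1f%%)\n",
                x$n_concordant, x$total, x$concordance_percent))
  else cat("  concordance not available (no pairs)\n")
  invisible(x)
}
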