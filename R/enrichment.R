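#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact hypergeometric enumeration: the two-sided p-value is the sum of
#' the point probabilities of all tables (with the observed margins) that
#' are no more likely than the observed one.
#'
#' @param table 2x2 numeric matrix of non-negative counts
#'   (`rbind(c(a, b), c(c, d))` with a = DE-and-term, b = DE-not-term,
#'   c = term-not-DE, d = neither).
#' @return Two-sided p-value.
#' @export
fisher_two_sided <- function(table) {
  .check_2x2(table)
  stats::fisher.test(table)$p.value
}

#' Pearson chi-squared test on a 2x2 table
#'
#' One degree of freedom, no continuity correction. Expected counts are
#' returned; a warning is raised when any expected count is below 5.
#' A zero row or column margin leaves the statistic undefined and is an
#' error.
#'
#' @param table 2x2 numeric matrix of non-negative counts.
#' @return List with `statistic`, `p`, `expected`.
#' @export
chi2_test <- function(table) {
  .check_2x2(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("chi-squared test undefined: zero row or column margin")
  n <- sum(table)
  expected <- outer(rowSums(table), colSums(table)) / n
  if (any(expected < 5))
    warning("expected count below 5; chi-squared approximation is poor")
  stat <- sum((table - expected)^2 / expected)
  list(statistic = stat,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       expected = expected)
}

.check_2x2 <- function(table) {
  if (!is.matrix(table) || !all(dim(table) == c(2, 2)))
    stop("a 2x2 matrix is required")
  if (any(is.na(table)) || any(table < 0))
    stop("counts must be non-negative and non-missing")
  if (any(table != round(table))) stop("counts must be integers")
  invisible(table)
}

#' Over-representation analysis of a gene set
#'
#' For every term with at least one gene in the universe, a 2x2 table
#' (term membership vs DE membership) is tested with the two-sided Fisher
#' exact test and the chi-squared test; Benjamini-Hochberg q-values are
#' computed over all tested terms within this call (one stratum, i.e. one
#' mode/direction combination). Results are sorted by Fisher p ascending.
#'
#' In `"go"` mode a term is significant when
#' `p_fisher < go_p_threshold` and `q < go_fdr_threshold`
#' (defaults 0.01/0.01); in `"pathway"` mode when
#' `p_fisher < pathway_p_threshold` (default 0.05). Pathway mode is plain
#' over-representation; no topology-based impact scoring is performed.
#'
#' @param de_genes Character vector of selected genes (must be a subset of
#'   `universe`).
#' @param universe Character vector of all measured genes (non-empty).
#' @param term_map Named list mapping term id to member gene ids (GMT-style,
#'   see [read_gmt()]); genes outside the universe are ignored.
#' @param mode `"go"` or `"pathway"` (threshold policy only).
#' @param direction Optional label (`"up"`/`"down"`) recorded in the output.
#' @param go_p_threshold,go_fdr_threshold,pathway_p_threshold Thresholds.
#' @return Data frame: `term`, `direction`, `a`, `b`, `c`, `d`,
#'   `fold_enrichment`, `p_fisher`, `p_chi2`, `q`, `significant`.
#'   `p_chi2` is `NA` when a margin is degenerate (e.g. empty DE set).
#' @export
enrich <- function(de_genes, universe, term_map, mode = c("go", "pathway"),
                   direction = NA_character_,
                   go_p_threshold = 0.01, go_fdr_threshold = 0.01,
                   pathway_p_threshold = 0.05) {
  mode <- match.arg(mode)
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty universe")
  de_genes <- unique(as.character(de_genes))
  extra <- setdiff(de_genes, universe)
  if (length(extra))
    stop("DE genes outside the universe: ",
         paste(utils::head(extra, 10), collapse = ", "))
  terms <- lapply(term_map, function(g) intersect(unique(g), universe))
  terms <- terms[lengths(terms) > 0]
  n_univ <- length(universe)
  n_de <- length(de_genes)
  rows <- lapply(names(terms), function(tm) {
    g <- terms[[tm]]
    a <- length(intersect(g, de_genes))
    b <- n_de - a
    cc <- length(g) - a
    d <- n_univ - a - b - cc
    tab <- matrix(c(a, cc, b, d), 2, 2)
    p_f <- fisher_two_sided(tab)
    p_c <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) NA_real_
           else suppressWarnings(chi2_test(tab)$p)
    fe <- if (n_de > 0) (a / n_de) / (length(g) / n_univ) else NA_real_
    data.frame(term = tm, direction = direction,
               a = a, b = b, c = cc, d = d,
               fold_enrichment = fe, p_fisher = p_f, p_chi2 = p_c,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(0), direction = character(0),
                      a = integer(0), b = integer(0), c = integer(0),
                      d = integer(0), fold_enrichment = numeric(0),
                      p_fisher = numeric(0), p_chi2 = numeric(0),
                      q = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE))
  out$q <- bh_fdr(out$p_fisher)
  out$significant <- if (mode == "go")
    out$p_fisher < go_p_threshold & out$q < go_fdr_threshold else
    out$p_fisher < pathway_p_threshold
  out <- out[order(out$p_fisher, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
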