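#' Pearson correlation of two sample vectors
#'
#' Product-moment correlation, clamped to \[-1, 1\] against floating-point
#' rounding. Constant vectors have no defined correlation and are an error
#' here; [build_cnc_network()] skips such genes upstream with a logged
#' count.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Scalar correlation.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 3) stop("need >= 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  min(1, max(-1, stats::cor(x, y)))
}

#' Build a coding-noncoding coexpression network for one group
#'
#' Candidate nodes are the differentially expressed lncRNAs and mRNAs;
#' every unordered pair whose within-group Pearson correlation passes the
#' threshold becomes an edge (the sign is recorded). By default only
#' lncRNA-mRNA edges are formed (the coding-noncoding reading); set
#' `cnc_only = FALSE` to also allow same-biotype edges. Nodes with no
#' edge are dropped: only connected genes are network members.
#'
#' @param expr A [cnc_expr] object (all samples; the group is selected
#'   here).
#' @param group Which group's samples to use, `"disease"` or `"control"`.
#' @param de_lnc,de_mrna Character vectors of DE feature ids (must be rows
#'   of the matrix); biotypes are taken from these two arguments.
#' @param corr_threshold Correlation threshold (default 0.97).
#' @param use_absolute Threshold `|r|` (default `TRUE`); if `FALSE`, only
#'   `r >= corr_threshold` (signed) passes and no negative edge can occur.
#' @param cnc_only Restrict edges to lncRNA-mRNA pairs (default `TRUE`).
#' @return Object of class `cnc_network`: list with `nodes` (data frame
#'   `id`, `biotype`), `edges` (data frame `a`, `b`, `r`, `sign`),
#'   `group`, `corr_threshold`, `n_constant` (genes skipped as constant).
#' @export
build_cnc_network <- function(expr, group = c("disease", "control"),
                              de_lnc, de_mrna, corr_threshold = 0.97,
                              use_absolute = TRUE, cnc_only = TRUE) {
  stopifnot(inherits(expr, "cnc_expr"))
  group <- match.arg(group)
  samples <- expr$design$sample[expr$design$group == group]
  if (length(samples) < 3)
    stop("group '", group, "' has ", length(samples),
         " samples; >= 3 required for correlation")
  ids <- c(de_lnc, de_mrna)
  if (anyDuplicated(ids)) stop("duplicated ids across de_lnc/de_mrna")
  miss <- setdiff(ids, rownames(expr$values))
  if (length(miss))
    stop("DE ids missing from expression matrix: ",
         paste(utils::head(miss, 10), collapse = ", "))
  biotype <- stats::setNames(rep(c("lncRNA", "mRNA"),
                                 c(length(de_lnc), length(de_mrna))), ids)
  empty <- .cnc_network(ids[0], biotype[0],
                        data.frame(a = character(0), b = character(0),
                                   r = numeric(0), sign = character(0),
                                   stringsAsFactors = FALSE),
                        group, corr_threshold, 0L)
  if (length(ids) < 2) return(empty)
  x <- expr$values[ids, samples, drop = FALSE]
  sds <- apply(x, 1, stats::sd)
  n_constant <- sum(sds == 0)
  if (n_constant > 0) {
    message(n_constant, " constant gene(s) skipped (undefined correlation)")
    x <- x[sds > 0, , drop = FALSE]
  }
  if (nrow(x) < 2) return(empty)
  cmat <- stats::cor(t(x))
  cmat[cmat > 1] <- 1; cmat[cmat < -1] <- -1
  pass <- if (use_absolute) abs(cmat) >= corr_threshold
          else cmat >= corr_threshold
  pass[lower.tri(pass, diag = TRUE)] <- FALSE
  if (cnc_only) {
    bt <- biotype[rownames(cmat)]
    same <- outer(bt, bt, "==")
    pass[same] <- FALSE
  }
  idx <- which(pass, arr.ind = TRUE)
  edges <- data.frame(a = rownames(cmat)[idx[, 1]],
                      b = rownames(cmat)[idx[, 2]],
                      r = cmat[idx],
                      stringsAsFactors = FALSE)
  edges$sign <- ifelse(edges$r >= 0, "pos", "neg")
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  keep <- union(edges$a, edges$b)
  keep <- ids[ids %in% keep]  # stable id order
  .cnc_network(keep, biotype[keep], edges, group, corr_threshold, n_constant)
}

.cnc_network <- function(ids, biotype, edges, group, corr_threshold,
                         n_constant) {
  structure(list(nodes = data.frame(id = unname(ids),
                                    biotype = unname(biotype),
                                    stringsAsFactors = FALSE),
                 edges = edges, group = group,
                 corr_threshold = corr_threshold,
                 n_constant = n_constant),
            class = "cnc_network")
}

#' @export
print.cnc_network <- function(x, ...) {
  cat(sprintf(
    "cnc_network [%s]: %d nodes (%d lncRNA, %d mRNA), %d edges (|r| >= %g)\n",
    x$group, nrow(x$nodes), sum(x$nodes$biotype == "lncRNA"),
    sum(x$nodes$biotype == "mRNA"), nrow(x$edges), x$corr_threshold))
  invisible(x)
}

.as_igraph <- function(network) {
  igraph::graph_from_data_frame(network$edges[, c("a", "b", "r", "sign")],
                                directed = FALSE,
                                vertices = network$nodes)
}

#' Node degrees of a coexpression network
#'
#' @param network A [build_cnc_network()] result.
#' @return Named integer vector, one entry per network node.
#' @export
node_degrees <- function(network) {
  stopifnot(inherits(network, "cnc_network"))
  if (nrow(network$nodes) == 0) return(stats::setNames(integer(0), character(0)))
  g <- .as_igraph(network)
  stats::setNames(as.integer(igraph::degree(g)), igraph::V(g)$name)
}

#' k-core decomposition
#'
#' Core index per node: the largest k such that the node survives when
#' nodes of degree < k are iteratively removed (equivalently, the highest
#' k-core the node belongs to).
#'
#' @param network A [build_cnc_network()] result.
#' @return Named integer vector of core indices (empty for an empty
#'   network).
#' @export
k_core_decomposition <- function(network) {
  stopifnot(inherits(network, "cnc_network"))
  if (nrow(network$nodes) == 0) return(stats::setNames(integer(0), character(0)))
  g <- .as_igraph(network)
  cor_idx <- igraph::coreness(g)
  stats::setNames(as.integer(cor_idx), names(cor_idx))
}

#' Differential connectivity (diffK) between two networks
#'
#' Each node's degree is normalised within its network,
#' \eqn{K = degree / max(degree)} (or degree/(n-1) with
#' `normalization = "n_minus_1"`), with K = 0 for a node absent from a
#' network, and \eqn{diffK = K_{disease} - K_{control}}. Nodes are ranked
#' by \eqn{|diffK|} descending, ties broken by node id.
#'
#' @param net_disease,net_control Networks from [build_cnc_network()]
#'   built with the same configuration.
#' @param normalization `"max_degree"` (default) or `"n_minus_1"`.
#' @return Data frame ordered by rank: `id`, `biotype`,
#'   `degree_disease`, `degree_control`, `core_disease`, `core_control`,
#'   `K_disease`, `K_control`, `diffK`, `rank`.
#' @export
diffk <- function(net_disease, net_control,
                  normalization = c("max_degree", "n_minus_1")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(net_disease, "cnc_network"),
            inherits(net_control, "cnc_network"))
  if (nrow(net_disease$nodes) == 0 && nrow(net_control$nodes) == 0)
    warning("both networks are empty")
  deg_d <- node_degrees(net_disease)
  deg_c <- node_degrees(net_control)
  core_d <- k_core_decomposition(net_disease)
  core_c <- k_core_decomposition(net_control)
  ids <- sort(union(names(deg_d), names(deg_c)))
  biotype <- stats::setNames(
    c(net_disease$nodes$biotype, net_control$nodes$biotype),
    c(net_disease$nodes$id, net_control$nodes$id))[ids]
  get0 <- function(v, ids) unname(ifelse(is.na(v[ids]), 0, v[ids]))
  dd <- get0(deg_d, ids); dc <- get0(deg_c, ids)
  norm_const <- function(net, deg) {
    if (normalization == "max_degree") max(deg, 0) else
      max(nrow(net$nodes) - 1, 0)
  }
  nd <- norm_const(net_disease, deg_d)
  nc <- norm_const(net_control, deg_c)
  kd <- if (nd > 0) dd / nd else rep(0, length(ids))
  kc <- if (nc > 0) dc / nc else rep(0, length(ids))
  out <- data.frame(id = ids, biotype = unname(biotype),
                    degree_disease = as.integer(dd),
                    degree_control = as.integer(dc),
                    core_disease = as.integer(get0(core_d, ids)),
                    core_control = as.integer(get0(core_c, ids)),
                    K_disease = kd, K_control = kc,
                    diffK = kd - kc,
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$diffK), out$id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Export a network as SIF and GraphML
#'
#' SIF rows are `a <pos|neg> b`. The GraphML carries node attributes
#' `biotype`, `degree`, `core_index` and, when a [diffk()] table is
#' supplied, `K` and `diffK`; edges carry the correlation `r` and `sign`.
#'
#' @param network A [build_cnc_network()] result.
#' @param sif_path,graphml_path Output paths (either may be `NULL` to
#'   skip that format).
#' @param stats Optional [diffk()] table for K/diffK node attributes.
#' @return Invisibly, the igraph object written.
#' @export
export_network <- function(network, sif_path = NULL, graphml_path = NULL,
                           stats = NULL) {
  stopifnot(inherits(network, "cnc_network"))
  g <- .as_igraph(network)
  deg <- node_degrees(network)
  core <- k_core_decomposition(network)
  ids <- igraph::V(g)$name
  g <- igraph::set_vertex_attr(g, "degree", value = as.numeric(deg[ids]))
  g <- igraph::set_vertex_attr(g, "core_index", value = as.numeric(core[ids]))
  if (!is.null(stats)) {
    kcol <- if (network$group == "disease") "K_disease" else "K_control"
    m <- match(ids, stats$id)
    g <- igraph::set_vertex_attr(g, "K", value = stats[[kcol]][m])
    g <- igraph::set_vertex_attr(g, "diffK", value = stats$diffK[m])
  }
  if (!is.null(sif_path)) {
    lines <- if (nrow(network$edges))
      paste(network$edges$a, network$edges$sign, network$edges$b) else
      character(0)
    writeLines(lines, sif_path)
  }
  if (!is.null(graphml_path))
    igraph::write_graph(g, graphml_path, format = "graphml")
  invisible(g)
}
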