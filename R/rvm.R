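#' Per-gene pooled variances
#'
#' Two-sample pooled variance per gene,
#' \eqn{s^2 = ((n_1-1)s_1^2 + (n_2-1)s_2^2) / f} with residual degrees of
#' freedom \eqn{f = n_1 + n_2 - 2}.
#'
#' @param values Genes-by-samples numeric matrix.
#' @param group Character/factor vector of length `ncol(values)` with values
#'   `"disease"` and `"control"`; each group needs at least 2 samples.
#' @return List with `s2` (named numeric vector), `f` (scalar degrees of
#'   freedom), `mean_disease` and `mean_control` (named vectors of group
#'   means).
#' @export
pooled_variances <- function(values, group) {
  group <- as.character(group)
  stopifnot(length(group) == ncol(values))
  n1 <- sum(group == "disease")
  n2 <- sum(group == "control")
  if (n1 < 2 || n2 < 2)
    stop("each group needs >= 2 samples (got ", n1, " disease, ", n2,
         " control)")
  xd <- values[, group == "disease", drop = FALSE]
  xc <- values[, group == "control", drop = FALSE]
  md <- rowMeans(xd)
  mc <- rowMeans(xc)
  ss1 <- rowSums((xd - md)^2)
  ss2 <- rowSums((xc - mc)^2)
  f <- n1 + n2 - 2
  list(s2 = (ss1 + ss2) / f, f = f, n1 = n1, n2 = n2,
       mean_disease = md, mean_control = mc)
}

#' Fit the random variance model prior
#'
#' Under the random variance model the per-gene precision \eqn{1/\sigma^2}
#' follows a Gamma(a, b) law (shape a, scale b), so that across genes the
#' scaled pooled variances \eqn{a b s^2} follow an F distribution with
#' \eqn{(f, 2a)} degrees of freedom. The parameters are estimated by
#' maximum likelihood on that F law: quasi-Newton optimisation on
#' \eqn{(\log a, \log b)}, initialised from a coarse grid around a
#' log-moment matching estimate.
#'
#' @param s2 Numeric vector of per-gene pooled variances (>= 2 strictly
#'   positive values required). Zeros are excluded from fitting with a
#'   message; negative values are an error.
#' @param f Residual degrees of freedom the variances were computed with.
#' @return An object of class `rvm_prior`: list with `a`, `b`, `f`,
#'   `df_mod = f + 2a`, `n_used`, `n_zero`, `loglik`.
#' @export
fit_rvm_prior <- function(s2, f) {
  if (length(s2) == 0) stop("no variances supplied")
  if (any(is.na(s2)) || any(s2 < 0)) stop("variances must be non-negative")
  n_zero <- sum(s2 == 0)
  x <- s2[s2 > 0]
  if (length(x) < 2)
    stop("need >= 2 strictly positive variances to fit the prior")
  if (n_zero > 0)
    message(n_zero, " gene(s) with zero pooled variance excluded from prior fit")
  if (length(x) < 100)
    warning("prior fitted on ", length(x),
            " genes; estimates may be unstable below 100")
  # log(a b s^2) ~ log F(f, 2a): density of s2 is a*b*df(a*b*s2; f, 2a)
  nll <- function(theta) {
    a <- exp(theta[1]); b <- exp(theta[2])
    ll <- sum(stats::df(a * b * x, f, 2 * a, log = TRUE) + log(a * b))
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  init <- .rvm_log_moment_init(x, f)
  grid <- expand.grid(la = log(init["a"]) + seq(-2, 2, by = 1),
                      lb = log(init["b"]) + seq(-2, 2, by = 1))
  gval <- apply(grid, 1, nll)
  start <- as.numeric(grid[which.min(gval), ])
  opt <- stats::optim(start, nll, method = "BFGS",
                      control = list(reltol = 1e-12, maxit = 500))
  if (opt$convergence != 0)
    stop("RVM prior fit did not converge (code ", opt$convergence, "): ",
         opt$message)
  a <- exp(opt$par[1]); b <- exp(opt$par[2])
  structure(list(a = a, b = b, f = f, df_mod = f + 2 * a,
                 n_used = length(x), n_zero = n_zero, loglik = -opt$value),
            class = "rvm_prior")
}

# Moment matching on log(s2): E log s2 = -log b - digamma(a)
#   + digamma(f/2) - log(f/2); Var log s2 = trigamma(a) + trigamma(f/2).
# Robust starting values even when a <= 2 (where raw moments diverge).
.rvm_log_moment_init <- function(x, f) {
  lv <- log(x)
  vtarget <- max(stats::var(lv) - trigamma(f / 2), 1e-3)
  a <- tryCatch(
    stats::uniroot(function(a) trigamma(a) - vtarget,
                   lower = 1e-3, upper = 1e3, tol = 1e-9)$root,
    error = function(e) 1)
  b <- exp(-(mean(lv) - digamma(f / 2) + log(f / 2)) - digamma(a))
  c(a = a, b = b)
}

#' @export
print.rvm_prior <- function(x, ...) {
  cat(sprintf(
    "RVM prior: a = %.4f, b = %.4f (f = %g, moderated df = %.2f, n = %d)\n",
    x$a, x$b, x$f, x$df_mod, x$n_used))
  invisible(x)
}

#' Random variance model moderated t-test
#'
#' Moderated per-gene two-sample test: the pooled variance is shrunk toward
#' the prior, \eqn{\tilde s^2 = (f s^2 + 2/b) / (f + 2a)}, and
#' \eqn{t = (\bar x_d - \bar x_c) / \sqrt{\tilde s^2 (1/n_1 + 1/n_2)}} is
#' referred to a t distribution with \eqn{f + 2a} degrees of freedom
#' (two-sided p by symmetric tail doubling). Benjamini-Hochberg q-values
#' and linear fold changes \eqn{2^{\bar x_d - \bar x_c}} are attached.
#'
#' @param values Genes-by-samples log2 matrix.
#' @param group Group vector as in [pooled_variances()].
#' @param prior An [fit_rvm_prior()] result fitted at the same `f`.
#' @return Data frame with one row per gene: `gene_id`, `mean_disease`,
#'   `mean_control`, `fc`, `s2`, `s2_tilde`, `t_mod`, `df_mod`, `p`, `q`.
#' @export
rvm_t_test <- function(values, group, prior) {
  stopifnot(inherits(prior, "rvm_prior"))
  pv <- pooled_variances(values, group)
  if (pv$f != prior$f)
    stop("prior was fitted at f = ", prior$f, " but data have f = ", pv$f)
  s2_tilde <- (pv$f * pv$s2 + 2 / prior$b) / (pv$f + 2 * prior$a)
  delta <- pv$mean_disease - pv$mean_control
  se <- sqrt(s2_tilde * (1 / pv$n1 + 1 / pv$n2))
  df_mod <- pv$f + 2 * prior$a
  t_mod <- delta / se
  p <- 2 * stats::pt(-abs(t_mod), df = df_mod)
  degenerate <- se == 0
  if (any(degenerate)) {
    warning(sum(degenerate), " gene(s) with zero moderated variance")
    t_mod[degenerate] <- ifelse(delta[degenerate] != 0, Inf, 0)
    p[degenerate] <- ifelse(delta[degenerate] != 0, 0, 1)
  }
  data.frame(gene_id = rownames(values),
             mean_disease = pv$mean_disease,
             mean_control = pv$mean_control,
             fc = 2^delta,
             s2 = pv$s2,
             s2_tilde = s2_tilde,
             t_mod = t_mod,
             df_mod = df_mod,
             p = p,
             q = bh_fdr(p),
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in \[0, 1\]; `NA`/`NaN` is an error.
#' @return Vector of BH-adjusted q-values.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p))) stop("NA/NaN p-values are not allowed")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Select differentially expressed genes
#'
#' A gene is called up if `p < p_threshold` (strict) and `fc > 1`, down if
#' `p < p_threshold` and `fc < 1`; an optional linear fold-change gate
#' additionally requires `fc >= fc_threshold` (up) or `fc <= 1/fc_threshold`
#' (down). Selection uses the raw p-value by default, with q reported
#' alongside; set `use_q = TRUE` to gate on the q-value instead.
#'
#' @param results Data frame from [rvm_t_test()].
#' @param p_threshold Significance threshold (default 0.05, strict `<`).
#' @param fc_threshold Optional linear fold-change threshold (> 1), or
#'   `NULL` (default) for none.
#' @param use_q Gate on `q` instead of `p` (default `FALSE`).
#' @return `results` with a `direction` column (`"up"`, `"down"`, `"ns"`)
#'   and attributes `up`/`down` holding the selected gene ids.
#' @export
select_de <- function(results, p_threshold = 0.05, fc_threshold = NULL,
                      use_q = FALSE) {
  stopifnot(is.data.frame(results),
            all(c("gene_id", "p", "q", "fc") %in% names(results)))
  if (!is.null(fc_threshold) && fc_threshold <= 1)
    stop("fc_threshold must be > 1 (linear scale)")
  crit <- if (use_q) results$q else results$p
  sig <- crit < p_threshold
  up <- sig & results$fc > 1
  down <- sig & results$fc < 1
  if (!is.null(fc_threshold)) {
    up <- up & results$fc >= fc_threshold
    down <- down & results$fc <= 1 / fc_threshold
  }
  results$direction <- ifelse(up, "up", ifelse(down, "down", "ns"))
  attr(results, "up") <- results$gene_id[up]
  attr(results, "down") <- results$gene_id[down]
  results
}

#' Hierarchical clustering of significant genes
#'
#' Unsupervised agglomerative clustering with average linkage on a
#' correlation distance (1 - Pearson), on both genes (rows) and samples
#' (columns), for heatmap-style display of the selected genes.
#' Zero-variance rows, for which correlation is undefined, are excluded
#' with a warning. `hclust` leaf order is deterministic given input order.
#'
#' @param values Genes-by-samples matrix restricted to the genes of
#'   interest; needs >= 2 genes and >= 2 samples after exclusions.
#' @param cluster_samples Also cluster the columns (default `TRUE`).
#' @return List with `gene_hclust`, `sample_hclust` (or `NULL`),
#'   `gene_order`, `sample_order` (identifiers in dendrogram leaf order)
#'   and `excluded` (zero-variance gene ids).
#' @export
cluster_de_genes <- function(values, cluster_samples = TRUE) {
  if (is.null(rownames(values))) stop("'values' needs row names")
  v <- apply(values, 1, stats::var)
  excluded <- rownames(values)[v == 0]
  if (length(excluded)) {
    warning(length(excluded),
            " zero-variance gene(s) excluded from clustering")
    values <- values[v > 0, , drop = FALSE]
  }
  if (nrow(values) < 2 || ncol(values) < 2)
    stop("need >= 2 genes and >= 2 samples to cluster")
  gd <- stats::as.dist(1 - stats::cor(t(values)))
  gh <- stats::hclust(gd, method = "average")
  sh <- NULL
  if (cluster_samples) {
    sd_ <- stats::as.dist(1 - stats::cor(values))
    sh <- stats::hclust(sd_, method = "average")
  }
  list(gene_hclust = gh,
       sample_hclust = sh,
       gene_order = rownames(values)[gh$order],
       sample_order = if (is.null(sh)) colnames(values)
                      else colnames(values)[sh$order],
       excluded = excluded)
}
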