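mk_matrix <- function(rows, samples = NULL) {
  x <- do.call(rbind, rows)
  rownames(x) <- paste0("g", seq_len(nrow(x)))
  colnames(x) <- if (is.null(samples))
    c(paste0("D", seq_len(ncol(x) / 2)), paste0("C", seq_len(ncol(x) / 2)))
  else samples
  x
}
grp <- function(n) rep(c("disease", "control"), each = n)

test_that("pooled variance matches hand arithmetic", {
  x <- mk_matrix(list(c(0, 2, 0, 2), c(5, 5, 5, 5)))
  pv <- pooled_variances(x, grp(2))
  expect_equal(unname(pv$s2), c(2, 0))
  expect_equal(pv$f, 2)
  expect_error(pooled_variances(x[, 1:3], c("disease", "disease", "control")),
               ">= 2 samples")
})

test_that("pooled variances on synthetic null match the prior mean", {
  set.seed(3)
  n <- 20000
  sigma2 <- 1 / rgamma(n, shape = 3, scale = 0.5)  # E[1/tau] = 1/(b(a-1)) = 1
  x <- matrix(rnorm(n * 10, 0, sqrt(sigma2)), n,
              dimnames = list(paste0("g", 1:n), NULL))
  colnames(x) <- c(paste0("D", 1:5), paste0("C", 1:5))
  pv <- pooled_variances(x, grp(5))
  expect_equal(mean(pv$s2), 1, tolerance = 0.05)
})

test_that("prior MLE agrees with an independent grid search", {
  set.seed(8)
  tau <- rgamma(4000, shape = 2, scale = 0.5)
  s2 <- (1 / tau) * rchisq(4000, 8) / 8
  fit <- fit_rvm_prior(s2, 8)
  grid <- oracle_grid_mle(s2, 8)
  expect_equal(fit$a, unname(grid["a"]), tolerance = 0.05)
  expect_equal(fit$b, unname(grid["b"]), tolerance = 0.05)
  expect_gt(fit$df_mod, 8)
  expect_error(fit_rvm_prior(numeric(0), 8), "no variances")
  expect_error(fit_rvm_prior(rep(0, 50), 8), "strictly positive")
})

test_that("moderated t reproduces the closed-form worked example", {
  # f = 8, a = 2, b = 0.5, s2 = 1: s2_tilde = (8 + 4)/12 = 1, df = 12
  prior <- structure(list(a = 2, b = 0.5, f = 8, df_mod = 12),
                     class = "rvm_prior")
  base <- c(-2, -1, 0, 1, 2) / sqrt(2.5)   # sample variance exactly 1
  delta <- 1.2649
  x <- mk_matrix(list(c(base + delta, base), c(base, base)))
  res <- rvm_t_test(x, grp(5), prior)
  expect_equal(res$s2_tilde, c(1, 1), tolerance = 1e-12)
  expect_equal(res$t_mod[1], delta / sqrt(2 / 5), tolerance = 1e-12)
  expect_equal(res$t_mod[1], 2.0, tolerance = 1e-4)
  expect_equal(res$df_mod, c(12, 12))
  expect_equal(res$p[1], 2 * pt(-delta / sqrt(2 / 5), 12), tolerance = 1e-12)
  expect_equal(res$p[1], 0.0686, tolerance = 1e-3)
  # equal means give t = 0, p = 1
  expect_equal(res$t_mod[2], 0)
  expect_equal(res$p[2], 1)
})

test_that("a vanishing prior recovers the ordinary pooled t-test", {
  set.seed(4)
  n <- 1000
  x <- matrix(rnorm(n * 10, 0, runif(n, 0.5, 2)), n,
              dimnames = list(paste0("g", 1:n), NULL))
  colnames(x) <- c(paste0("D", 1:5), paste0("C", 1:5))
  prior <- structure(list(a = 1e-10, b = 1e10, f = 8, df_mod = 8 + 2e-10),
                     class = "rvm_prior")
  res <- rvm_t_test(x, grp(5), prior)
  t_plain <- apply(x, 1, function(r)
    stats::t.test(r[1:5], r[6:10], var.equal = TRUE)$statistic)
  expect_lt(max(abs(res$t_mod - t_plain)), 1e-6)
})

test_that("moderated variance is a convex combination of s2 and the prior", {
  set.seed(5)
  prior <- structure(list(a = 1.5, b = 0.8, f = 8, df_mod = 11),
                     class = "rvm_prior")
  x <- matrix(rnorm(2000, 0, rep(runif(200, 0.2, 3), 10)), 200,
              dimnames = list(paste0("g", 1:200), NULL))
  colnames(x) <- c(paste0("D", 1:5), paste0("C", 1:5))
  res <- rvm_t_test(x, grp(5), prior)
  prior_var <- (2 / prior$b) / (2 * prior$a)
  lo <- pmin(res$s2, prior_var); hi <- pmax(res$s2, prior_var)
  expect_true(all(res$s2_tilde >= lo - 1e-12 & res$s2_tilde <= hi + 1e-12))
})

test_that("|t| increases with the mean difference at fixed variance", {
  prior <- structure(list(a = 2, b = 0.5, f = 8, df_mod = 12),
                     class = "rvm_prior")
  base <- c(-2, -1, 0, 1, 2)
  deltas <- seq(0.2, 3, by = 0.2)
  t_abs <- vapply(deltas, function(d) {
    x <- mk_matrix(list(c(base + d, base)))
    abs(rvm_t_test(x, grp(5), prior)$t_mod)
  }, numeric(1))
  expect_true(all(diff(t_abs) > 0))
})

test_that("BH follows the step-up definition and is order-invariant", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_error(bh_fdr(c(0.1, NA)), "NA")
  set.seed(6)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
})

test_that("DE selection applies strict thresholds and stays disjoint", {
  res <- data.frame(gene_id = c("a", "b", "c", "d"),
                    p = c(0.049, 0.05, 0.01, 0.01),
                    q = c(0.2, 0.2, 0.05, 0.05),
                    fc = c(1.2, 1.2, 0.5, 1.0))
  out <- select_de(res, p_threshold = 0.05)
  expect_identical(out$direction, c("up", "ns", "down", "ns"))
  expect_identical(attr(out, "up"), "a")
  expect_identical(attr(out, "down"), "c")
  out2 <- select_de(res, p_threshold = 0.05, fc_threshold = 1.5)
  expect_identical(attr(out2, "up"), character(0))
  expect_identical(attr(out2, "down"), "c")
})

test_that("clustering splits duplicated profiles and merges exact copies", {
  set.seed(7)
  p1 <- rnorm(6); p2 <- rnorm(6) + 3
  x <- rbind(g1 = c(p1, p2), g2 = c(p1, p2) + 0.001,
             g3 = c(p2, p1), g4 = c(p2, p1) + 0.001)
  colnames(x) <- paste0("s", 1:12)
  cl <- cluster_de_genes(x)
  # exact copies (up to the tiny offset, correlation 1) merge first
  expect_equal(cl$gene_hclust$height[1], 0, tolerance = 1e-12)
  cut2 <- cutree(cl$gene_hclust, k = 2)
  expect_equal(cut2[["g1"]], cut2[["g2"]])
  expect_equal(cut2[["g3"]], cut2[["g4"]])
  expect_false(cut2[["g1"]] == cut2[["g3"]])
  # duplicated sample blocks split at the top of the sample dendrogram
  y <- rbind(a = rep(c(0, 5), each = 2), b = rep(c(5, 0), each = 2),
             c = rep(c(1, 4), each = 2))
  colnames(y) <- paste0("s", 1:4)
  y <- y + matrix(rnorm(12, 0, 0.01), 3)
  scl <- cluster_de_genes(y)
  scut <- cutree(scl$sample_hclust, k = 2)
  expect_equal(scut[["s1"]], scut[["s2"]])
  expect_equal(scut[["s3"]], scut[["s4"]])
  expect_false(scut[["s1"]] == scut[["s3"]])
})

test_that("two planted expression patterns are recovered exactly", {
  set.seed(10)
  n_per <- 25
  pat1 <- rnorm(8); pat2 <- rnorm(8)
  x <- rbind(
    t(replicate(n_per, pat1 + rnorm(8, 0, 0.05))),
    t(replicate(n_per, pat2 + rnorm(8, 0, 0.05))))
  rownames(x) <- paste0("g", 1:(2 * n_per))
  colnames(x) <- paste0("s", 1:8)
  truth <- rep(1:2, each = n_per)
  cl <- cluster_de_genes(x, cluster_samples = FALSE)
  got <- cutree(cl$gene_hclust, k = 2)
  # Rand index 1: the partition matches the planted labels exactly
  expect_true(all(table(truth, got) %in% c(0, n_per)))
})

test_that("zero-variance rows are excluded from clustering with a warning", {
  x <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 2, 2, 2), g3 = c(4, 3, 2, 1))
  colnames(x) <- paste0("s", 1:4)
  expect_warning(cl <- cluster_de_genes(x, cluster_samples = FALSE),
                 "zero-variance")
  expect_identical(cl$excluded, "g2")
  expect_setequal(cl$gene_order, c("g1", "g3"))
})
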