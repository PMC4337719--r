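# Independent oracles used across the suite. Each re-derives its result
# from first principles and shares no code path with the implementation.

# Exhaustive interval scan: classify every lncRNA x mRNA pair by direct
# geometry (vectorised over mRNAs for each lncRNA).
oracle_pair_scan <- function(ann, maxd = 300000) {
  lncs <- ann[ann$biotype == "lncRNA", ]
  ms <- ann[ann$biotype == "mRNA", ]
  res_l <- character(0); res_m <- character(0); res_r <- character(0)
  for (i in seq_len(nrow(lncs))) {
    ls <- lncs$start[i]; le <- lncs$end[i]
    sel <- ms$chrom == lncs$chrom[i]
    if (!any(sel)) next
    s <- ms$start[sel]; e <- ms$end[sel]; st <- ms$strand[sel]
    id <- ms$id[sel]
    ov <- ls < e & s < le
    rel <- rep(NA_character_, length(s))
    rel[ov] <- ifelse(st[ov] == lncs$strand[i], "overlap", "antisense")
    left <- le <= s                       # lnc fully left of the mRNA
    gap <- ifelse(left, s - le, ls - e)
    near <- !ov & gap < maxd
    five <- (st == "+" & left) | (st == "-" & !left)
    rel[near] <- ifelse(five[near], "upstream", "downstream")
    keep <- !is.na(rel)
    res_l <- c(res_l, rep(lncs$id[i], sum(keep)))
    res_m <- c(res_m, id[keep])
    res_r <- c(res_r, rel[keep])
  }
  data.frame(lnc_id = res_l, mrna_id = res_m, relation = res_r,
             stringsAsFactors = FALSE)
}

pair_key <- function(d) sort(paste(d$lnc_id, d$mrna_id, d$relation))

# Iterative-pruning k-core oracle on an edge list: repeatedly delete
# nodes of degree < k; a node's core index is the largest k it survives.
oracle_coreness <- function(node_ids, edge_a, edge_b) {
  core <- setNames(rep(0L, length(node_ids)), node_ids)
  k <- 1L
  alive <- node_ids
  ea <- edge_a; eb <- edge_b
  repeat {
    repeat {
      deg <- table(factor(c(ea, eb), levels = alive))
      drop <- alive[deg < k]
      if (!length(drop)) break
      alive <- setdiff(alive, drop)
      keep <- !(ea %in% drop) & !(eb %in% drop)
      ea <- ea[keep]; eb <- eb[keep]
    }
    if (!length(alive)) break
    core[alive] <- k
    k <- k + 1L
  }
  core
}

# Coarse grid-search MLE for the variance prior: maximises the same
# F(f, 2a) likelihood by direct evaluation on a log grid.
oracle_grid_mle <- function(s2, f, a_grid = exp(seq(log(0.2), log(20), length.out = 120)),
                            b_grid = exp(seq(log(0.02), log(5), length.out = 120))) {
  x <- s2[s2 > 0]
  best <- c(a = NA, b = NA); best_ll <- -Inf
  for (a in a_grid) {
    # profile over b for each a to keep the grid manageable
    ll <- vapply(b_grid, function(b)
      sum(stats::df(a * b * x, f, 2 * a, log = TRUE) + log(a * b)),
      numeric(1))
    i <- which.max(ll)
    if (ll[i] > best_ll) { best_ll <- ll[i]; best <- c(a = a, b = b_grid[i]) }
  }
  best
}

# Moment matching of the Gamma-precision law on log variances:
# E log s2 = -log b - digamma(a) + digamma(f/2) - log(f/2),
# Var log s2 = trigamma(a) + trigamma(f/2).
oracle_log_moment_fit <- function(s2, f) {
  lv <- log(s2[s2 > 0])
  a <- uniroot(function(a) trigamma(a) - (var(lv) - trigamma(f / 2)),
               lower = 1e-3, upper = 1e3, tol = 1e-10)$root
  b <- exp(-(mean(lv) - digamma(f / 2) + log(f / 2)) - digamma(a))
  c(a = a, b = b)
}

# Random annotation for pairing property tests.
random_annotation <- function(n, n_chrom = 2, span = 1500000,
                              max_len = 400000) {
  st <- sample(0:span, n, replace = TRUE)
  cnc_annotation(data.frame(
    id = sprintf("f%04d", seq_len(n)),
    chrom = sample(paste0("chr", seq_len(n_chrom)), n, replace = TRUE),
    start = st,
    end = st + sample(100:max_len, n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    biotype = sample(c("lncRNA", "mRNA"), n, replace = TRUE)))
}

all_de <- function(ann, biotype) {
  ids <- ann$id[ann$biotype == biotype]
  setNames(rep("up", length(ids)), ids)
}

# Small deterministic annotation with one feature per relation category.
toy_feature <- function(chrom, start, end, strand) {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

# Truth-derived DE direction vectors split by biotype.
truth_de_sets <- function(ann, truth) {
  bt <- setNames(ann$biotype, ann$id)
  list(lnc = truth$de[bt[names(truth$de)] == "lncRNA"],
       mrna = truth$de[bt[names(truth$de)] == "mRNA"])
}
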