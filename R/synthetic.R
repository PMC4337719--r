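#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the study design the package targets: a 5-vs-5
#' two-group comparison on arrays measuring tens of thousands of mRNAs and
#' thousands of lncRNAs, per-gene variances drawn from an inverse-gamma law
#' (Gamma-distributed precisions, the random variance model assumption),
#' planted differential expression, cis lncRNA-mRNA pairs in all four
#' relation categories within the 300 kb window, and coexpression modules
#' whose hub lncRNA is strongly connected in the disease group only.
#'
#' @param n_mrna,n_lnc Feature counts by biotype.
#' @param n_per_group Samples per group (default 5).
#' @param n_chromosomes,chrom_length Genome geometry; `chrom_length` must
#'   exceed 600,000 so all four relation categories are constructible.
#' @param frac_de Fraction of genes with planted differential expression.
#' @param effect_size_log2 Absolute log2 group-mean shift of DE genes.
#' @param rvm_a,rvm_b Shape and scale of the Gamma precision prior
#'   (reciprocal variance ~ Gamma(a, b)).
#' @param n_planted_pairs_per_category Planted cis pairs per relation
#'   category (overlap, antisense, upstream, downstream).
#' @param concordance_rate Probability that a planted pair's mRNA shares
#'   the lncRNA's direction.
#' @param n_modules,module_size Coexpression modules (hub lncRNA plus
#'   `module_size - 1` member mRNAs each; `module_size >= 3`).
#' @param hub_corr_disease,hub_corr_control Within-group Pearson
#'   correlation of module members to their hub, in (-1, 1].
#' @param seed Integer seed; all generator randomness derives from it.
#' @return Validated configuration list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_mrna = 15000, n_lnc = 3000, n_per_group = 5,
                             n_chromosomes = 24, chrom_length = 3e8,
                             frac_de = 0.05, effect_size_log2 = 1.5,
                             rvm_a = 2, rvm_b = 0.5,
                             n_planted_pairs_per_category = 10,
                             concordance_rate = 0.953,
                             n_modules = 2, module_size = 10,
                             hub_corr_disease = 0.99,
                             hub_corr_control = 0.3,
                             seed = 1L) {
  cfg <- list(n_mrna = n_mrna, n_lnc = n_lnc, n_per_group = n_per_group,
              n_chromosomes = n_chromosomes, chrom_length = chrom_length,
              frac_de = frac_de, effect_size_log2 = effect_size_log2,
              rvm_a = rvm_a, rvm_b = rvm_b,
              n_planted_pairs_per_category = n_planted_pairs_per_category,
              concordance_rate = concordance_rate,
              n_modules = n_modules, module_size = module_size,
              hub_corr_disease = hub_corr_disease,
              hub_corr_control = hub_corr_control,
              seed = as.integer(seed))
  counts <- c("n_mrna", "n_lnc", "n_per_group", "n_chromosomes",
              "n_planted_pairs_per_category", "n_modules", "module_size")
  for (nm in counts)
    if (length(cfg[[nm]]) != 1 || is.na(cfg[[nm]]) || cfg[[nm]] < 0 ||
        cfg[[nm]] != round(cfg[[nm]]))
      stop("'", nm, "' must be a non-negative integer")
  for (nm in c("frac_de", "concordance_rate"))
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop("'", nm, "' must lie in [0, 1]")
  if (cfg$effect_size_log2 < 0) stop("'effect_size_log2' must be >= 0")
  if (cfg$rvm_a <= 0 || cfg$rvm_b <= 0) stop("'rvm_a'/'rvm_b' must be > 0")
  if (cfg$n_modules > 0 && cfg$module_size < 3)
    stop("'module_size' must be >= 3")
  if (cfg$chrom_length <= 2 * 300000)
    stop("'chrom_length' must exceed 600,000 bases")
  for (nm in c("hub_corr_disease", "hub_corr_control"))
    if (cfg[[nm]] <= -1 || cfg[[nm]] > 1)
      stop("'", nm, "' must lie in (-1, 1]")
  if (cfg$n_chromosomes < 1) stop("need at least one chromosome")
  class(cfg) <- "synthetic_config"
  cfg
}

# isolation spacing between placement units: one base beyond the pairing
# window, so unrelated features can never fall inside it
.ISOLATION <- 300001

#' Generate a synthetic transcript annotation with planted cis pairs
#'
#' For each relation category, exactly `n_planted_pairs_per_category`
#' lncRNA-mRNA pairs are laid out so that [classify_relation()] recovers
#' exactly the intended relation; every remaining feature is placed at
#' least 300,001 bases from any other feature, so it takes part in no
#' relation. Features that cannot fit on the configured genome raise an
#' error rather than being placed within accidental proximity.
#'
#' @param config A [synthetic_config()].
#' @return List with `annotation` (a [cnc_annotation] data frame, sorted
#'   by chromosome and start) and `planted_pairs` (data frame `lnc_id`,
#'   `mrna_id`, `relation`).
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, .generate_annotation_impl(config))
}

.generate_annotation_impl <- function(config) {
  k <- config$n_planted_pairs_per_category
  if (config$n_lnc < 4 * k || config$n_mrna < 4 * k)
    stop("config infeasible: ", 4 * k, " planted pairs per biotype exceed ",
         "n_lnc/n_mrna")
  lnc_len <- function(n) sample(200:5000, n, replace = TRUE)
  mrna_len <- function(n) sample(1000:20000, n, replace = TRUE)
  flip <- function(s) ifelse(s == "+", "-", "+")

  # planted pairs: two features per unit, geometry fixed by the relation
  rels <- rep(c("overlap", "antisense", "upstream", "downstream"), each = k)
  n_pair <- length(rels)
  ll <- lnc_len(n_pair); lm <- mrna_len(n_pair)
  lid <- sprintf("lnc%05d", seq_len(n_pair))
  mid <- sprintf("mrna%05d", seq_len(n_pair))
  st <- sample(c("+", "-"), n_pair, replace = TRUE)   # pair/mRNA strand
  sl <- sample(c("+", "-"), n_pair, replace = TRUE)   # lnc strand (cis units)
  gap <- sample(1000:290000, n_pair, replace = TRUE)
  ov <- rels %in% c("overlap", "antisense")
  o <- floor(ll / 2)                                  # guarantees overlap
  # lnc on the genomic left when upstream of a + mRNA or downstream of a -
  lnc_left <- (rels == "upstream") == (st == "+")
  lnc_start <- ifelse(ov, 0, ifelse(lnc_left, 0, lm + gap))
  mrna_start <- ifelse(ov, o, ifelse(lnc_left, ll + gap, 0))
  pair_feats <- data.frame(
    id = c(lid, mid),
    start = c(lnc_start, mrna_start),
    end = c(lnc_start + ll, mrna_start + lm),
    strand = c(ifelse(ov, st, sl), ifelse(ov & rels == "antisense",
                                          flip(st), st)),
    biotype = rep(c("lncRNA", "mRNA"), each = n_pair),
    unit = rep(seq_len(n_pair), 2),
    stringsAsFactors = FALSE)

  n_bg_lnc <- config$n_lnc - 4 * k
  n_bg_mrna <- config$n_mrna - 4 * k
  bg_bio <- sample(rep(c("lncRNA", "mRNA"), c(n_bg_lnc, n_bg_mrna)))
  n_bg <- length(bg_bio)
  bg_len <- ifelse(bg_bio == "lncRNA", lnc_len(n_bg), mrna_len(n_bg))
  bg_id <- character(n_bg)
  bg_id[bg_bio == "lncRNA"] <- sprintf("lnc%05d", n_pair + seq_len(n_bg_lnc))
  bg_id[bg_bio == "mRNA"] <- sprintf("mrna%05d", n_pair + seq_len(n_bg_mrna))
  bg_feats <- data.frame(
    id = bg_id, start = 0, end = bg_len,
    strand = sample(c("+", "-"), n_bg, replace = TRUE),
    biotype = bg_bio, unit = n_pair + seq_len(n_bg),
    stringsAsFactors = FALSE)

  feats <- rbind(pair_feats, bg_feats)
  n_units <- n_pair + n_bg
  width <- vapply(split(feats$end, feats$unit), max,
                  numeric(1))[as.character(seq_len(n_units))]
  unit_order <- sample(n_units)

  # sequential layout with fixed isolation between unit bounding boxes
  chrom <- integer(n_units); offset <- numeric(n_units)
  cur_chrom <- 1L; cursor <- 0
  for (i in seq_len(n_units)) {
    u <- unit_order[i]
    w <- width[u]
    if (cursor + w > config$chrom_length) {
      cur_chrom <- cur_chrom + 1L
      cursor <- 0
      if (cur_chrom > config$n_chromosomes || w > config$chrom_length)
        stop("config infeasible: features do not fit on ",
             config$n_chromosomes, " chromosome(s) of length ",
             config$chrom_length, " with ", .ISOLATION, " bp isolation")
    }
    chrom[u] <- cur_chrom
    offset[u] <- cursor
    cursor <- cursor + w + .ISOLATION
  }
  feats$chrom <- paste0("chr", chrom[feats$unit])
  feats$start <- feats$start + offset[feats$unit]
  feats$end <- feats$end + offset[feats$unit]
  feats <- feats[order(feats$chrom, feats$start, feats$id), ]
  ann <- cnc_annotation(feats[, c("id", "chrom", "start", "end", "strand",
                                  "biotype")])
  pairs <- if (n_pair) data.frame(lnc_id = lid, mrna_id = mid,
                                  relation = rels, stringsAsFactors = FALSE)
  else data.frame(lnc_id = character(0), mrna_id = character(0),
                  relation = character(0), stringsAsFactors = FALSE)
  list(annotation = ann, planted_pairs = pairs)
}

#' Generate a synthetic expression matrix with known ground truth
#'
#' Per gene g a precision is drawn from Gamma(`rvm_a`, scale `rvm_b`) and
#' the gene's variance is its reciprocal; baseline means are uniform on
#' log2 \[6, 14\]. Planted DE genes (a random `frac_de` fraction, plus all
#' planted-pair members and module genes) receive a ±`effect_size_log2`
#' shift in the disease group. Planted-pair mRNAs share their lncRNA's
#' direction with probability `concordance_rate`. Module members are built
#' from their hub's realised profile so that the within-group sample
#' correlation to the hub is exactly `hub_corr_disease` (disease samples)
#' and `hub_corr_control` (control samples).
#'
#' @param annotation Annotation data frame from [generate_annotation()].
#' @param config The same [synthetic_config()].
#' @param planted_pairs The `planted_pairs` table from
#'   [generate_annotation()] (may be `NULL` for none).
#' @return List with `expr` (a [cnc_expr]) and `truth` (list: `de` named
#'   "up"/"down" vector over all planted DE genes, `per_gene_variance`,
#'   `module_membership` named integer vector, `hub_ids`, `pairs` with
#'   planted directions and concordance flags).
#' @export
generate_expression <- function(annotation, config, planted_pairs = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  annotation <- cnc_annotation(annotation)
  if (config$n_per_group < 2)
    stop("n_per_group must be >= 2 (within-group variance undefined)")
  if (config$n_modules > 0 && config$n_per_group < 3)
    stop("n_per_group must be >= 3 when modules are planted")
  withr::with_seed(config$seed + 1L,
                   .generate_expression_impl(annotation, config,
                                             planted_pairs))
}

.generate_expression_impl <- function(annotation, config, planted_pairs) {
  ids <- annotation$id
  n <- length(ids)
  m <- config$n_per_group
  samples <- c(sprintf("D%d", seq_len(m)), sprintf("C%d", seq_len(m)))
  group <- rep(c("disease", "control"), each = m)

  tau <- stats::rgamma(n, shape = config$rvm_a, scale = config$rvm_b)
  sigma <- sqrt(1 / tau)
  baseline <- stats::runif(n, 6, 14)
  names(sigma) <- names(baseline) <- ids

  if (is.null(planted_pairs))
    planted_pairs <- data.frame(lnc_id = character(0),
                                mrna_id = character(0),
                                relation = character(0),
                                stringsAsFactors = FALSE)
  pair_ids <- c(planted_pairs$lnc_id, planted_pairs$mrna_id)
  if (!all(pair_ids %in% ids))
    stop("planted pair members missing from annotation")

  # modules: hub lncRNA + (module_size - 1) member mRNAs, outside pairs
  free_lnc <- setdiff(ids[annotation$biotype == "lncRNA"], pair_ids)
  free_mrna <- setdiff(ids[annotation$biotype == "mRNA"], pair_ids)
  n_mem <- config$module_size - 1L
  if (config$n_modules > 0 &&
      (length(free_lnc) < config$n_modules ||
       length(free_mrna) < config$n_modules * n_mem))
    stop("not enough free features for ", config$n_modules, " module(s)")
  hub_ids <- if (config$n_modules > 0)
    sample(free_lnc, config$n_modules) else character(0)
  member_ids <- if (config$n_modules > 0)
    sample(free_mrna, config$n_modules * n_mem) else character(0)
  module_membership <- stats::setNames(
    c(rep(seq_len(config$n_modules), each = 1L),
      rep(seq_len(config$n_modules), each = n_mem)),
    c(hub_ids, member_ids))

  # planted DE: pair members and module genes always; random fill to frac_de
  dir_lnc <- stats::setNames(sample(c("up", "down"), nrow(planted_pairs),
                                    replace = TRUE), planted_pairs$lnc_id)
  conc <- stats::runif(nrow(planted_pairs)) < config$concordance_rate
  dir_mrna <- stats::setNames(
    ifelse(conc, dir_lnc, ifelse(dir_lnc == "up", "down", "up")),
    planted_pairs$mrna_id)
  forced <- c(dir_lnc, dir_mrna,
              stats::setNames(sample(c("up", "down"),
                                     length(module_membership),
                                     replace = TRUE),
                              names(module_membership)))
  n_target <- round(config$frac_de * n)
  extra_pool <- setdiff(ids, names(forced))
  n_extra <- max(0, min(length(extra_pool), n_target - length(forced)))
  extra <- if (n_extra > 0)
    stats::setNames(sample(c("up", "down"), n_extra, replace = TRUE),
                    sample(extra_pool, n_extra)) else
    stats::setNames(character(0), character(0))
  de <- c(forced, extra)

  effect <- stats::setNames(numeric(n), ids)
  effect[names(de)] <- ifelse(de == "up", 1, -1) * config$effect_size_log2

  z <- matrix(stats::rnorm(n * 2 * m), nrow = n,
              dimnames = list(ids, samples))
  x <- baseline + sigma * z
  x[, group == "disease"] <- x[, group == "disease"] + effect

  # overwrite module members with exact within-group correlation to the hub
  if (config$n_modules > 0) {
    for (g in c("disease", "control")) {
      cols <- which(group == g)
      rho <- if (g == "disease") config$hub_corr_disease else
        config$hub_corr_control
      for (mod in seq_len(config$n_modules)) {
        hub <- hub_ids[mod]
        h <- x[hub, cols]
        u <- h - mean(h)
        u <- u / sqrt(sum(u^2))
        mem <- member_ids[((mod - 1) * n_mem + 1):(mod * n_mem)]
        for (j in mem) {
          repeat {
            e <- stats::rnorm(m)
            w <- e - mean(e)
            w <- w - sum(w * u) * u
            nw <- sqrt(sum(w^2))
            if (nw > 1e-8) { w <- w / nw; break }
          }
          raw <- rho * u + sqrt(1 - rho^2) * w
          shift <- if (g == "disease") effect[j] else 0
          x[j, cols] <- baseline[j] + shift +
            sigma[j] * sqrt(m - 1) * raw
        }
      }
    }
  }

  expr <- cnc_expr(x, data.frame(sample = samples, group = group,
                                 stringsAsFactors = FALSE))
  pairs_truth <- planted_pairs
  if (nrow(pairs_truth)) {
    pairs_truth$lnc_direction <- unname(dir_lnc[pairs_truth$lnc_id])
    pairs_truth$mrna_direction <- unname(dir_mrna[pairs_truth$mrna_id])
    pairs_truth$concordant <- pairs_truth$lnc_direction ==
      pairs_truth$mrna_direction
  }
  truth <- list(de = de,
                per_gene_variance = sigma^2,
                module_membership = module_membership,
                hub_ids = hub_ids,
                pairs = pairs_truth)
  list(expr = expr, truth = truth)
}

#' Simulate a complete dataset bundle on disk
#'
#' Runs [generate_annotation()] and [generate_expression()] and writes
#' `annotation.bed`, `expression.tsv`, `design.tsv` and `truth.json` into
#' `outdir`.
#'
#' @param config A [synthetic_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with `annotation`, `expr`, `truth` and
#'   `paths`.
#' @export
simulate_dataset <- function(config, outdir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ann <- generate_annotation(config)
  ge <- generate_expression(ann$annotation, config, ann$planted_pairs)
  paths <- list(annotation = file.path(outdir, "annotation.bed"),
                expression = file.path(outdir, "expression.tsv"),
                design = file.path(outdir, "design.tsv"),
                truth = file.path(outdir, "truth.json"))
  write_annotation(ann$annotation, paths$annotation)
  write_expression(ge$expr, paths$expression, paths$design)
  truth_json <- list(
    de = as.list(ge$truth$de),
    per_gene_variance = as.list(ge$truth$per_gene_variance),
    module_membership = as.list(ge$truth$module_membership),
    hub_ids = ge$truth$hub_ids,
    pairs = ge$truth$pairs)
  jsonlite::write_json(truth_json, paths$truth, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(annotation = ann$annotation,
                 planted_pairs = ann$planted_pairs,
                 expr = ge$expr, truth = ge$truth, paths = paths))
}
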