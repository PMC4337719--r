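#' Pipeline configuration
#'
#' Central thresholds of the analysis: the DE gate (raw p < 0.05 by
#' default, no fold-change cutoff), the 300 kb cis-pairing window, the
#' 0.97 correlation threshold applied to |r|, and the enrichment cutoffs
#' (GO: p < 0.01 and FDR < 0.01; pathway: p < 0.05).
#'
#' @param de_p_threshold DE significance threshold (strict `<`).
#' @param de_fc_threshold Optional linear fold-change cutoff (`NULL` for
#'   none).
#' @param de_use_q Gate DE selection on BH q instead of raw p.
#' @param pair_max_distance Maximum cis-pair boundary gap, bases.
#' @param pair_anchor `"mrna"` or `"lnc"`: whose strand orients
#'   upstream/downstream.
#' @param corr_threshold Coexpression edge threshold.
#' @param corr_use_absolute Apply the threshold to |r| (default `TRUE`).
#' @param network_cnc_only Restrict edges to lncRNA-mRNA pairs (default
#'   `TRUE`).
#' @param diffk_normalization `"max_degree"` or `"n_minus_1"`.
#' @param go_p_threshold,go_fdr_threshold,pathway_p_threshold Enrichment
#'   cutoffs.
#' @param seed Seed recorded in the run log and used for any stochastic
#'   stage.
#' @return Configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(de_p_threshold = 0.05, de_fc_threshold = NULL,
                            de_use_q = FALSE,
                            pair_max_distance = 300000,
                            pair_anchor = "mrna",
                            corr_threshold = 0.97,
                            corr_use_absolute = TRUE,
                            network_cnc_only = TRUE,
                            diffk_normalization = "max_degree",
                            go_p_threshold = 0.01, go_fdr_threshold = 0.01,
                            pathway_p_threshold = 0.05,
                            seed = 1L) {
  cfg <- list(de_p_threshold = de_p_threshold,
              de_fc_threshold = de_fc_threshold,
              de_use_q = de_use_q,
              pair_max_distance = pair_max_distance,
              pair_anchor = match.arg(pair_anchor, c("mrna", "lnc")),
              corr_threshold = corr_threshold,
              corr_use_absolute = corr_use_absolute,
              network_cnc_only = network_cnc_only,
              diffk_normalization = match.arg(diffk_normalization,
                                              c("max_degree", "n_minus_1")),
              go_p_threshold = go_p_threshold,
              go_fdr_threshold = go_fdr_threshold,
              pathway_p_threshold = pathway_p_threshold,
              seed = as.integer(seed))
  for (nm in c("de_p_threshold", "go_p_threshold", "go_fdr_threshold",
               "pathway_p_threshold"))
    if (cfg[[nm]] <= 0 || cfg[[nm]] > 1)
      stop("'", nm, "' must lie in (0, 1]")
  if (cfg$pair_max_distance <= 0) stop("'pair_max_distance' must be > 0")
  if (cfg$corr_threshold < 0 || cfg$corr_threshold > 1)
    stop("'corr_threshold' must lie in [0, 1]")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Field names mirror the arguments of [pipeline_config()]; unknown keys
#' are an error, missing keys take the defaults.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Run the full analysis pipeline
#'
#' Differential expression (RVM moderated t-test, BH FDR, selection),
#' cis lncRNA-mRNA pairing with concordance summary, per-group
#' coding-noncoding coexpression networks with k-core and diffK ranking,
#' and (when a term map is given) over-representation analysis of the up-
#' and downregulated mRNA sets. All result tables, both networks (SIF and
#' GraphML), summaries and a run log recording every threshold and the
#' seed are written to `outdir`. No stage mutates its inputs, and the
#' outputs are a deterministic function of the inputs and the
#' configuration.
#'
#' @param expr A [cnc_expr] object.
#' @param annotation A [cnc_annotation] data frame covering the matrix
#'   rows used in pairing and networks.
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @param term_map Optional named list (term -> gene ids) for enrichment.
#' @return Invisibly, a list with `de`, `up`, `down`, `pairs`,
#'   `pair_summary`, `net_disease`, `net_control`, `node_stats`,
#'   `enrichment`, `paths`.
#' @export
run_pipeline <- function(expr, annotation, config = pipeline_config(),
                         outdir, term_map = NULL) {
  stopifnot(inherits(expr, "cnc_expr"), inherits(config, "pipeline_config"))
  annotation <- cnc_annotation(annotation)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, code)
    tryCatch(code, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  paths <- list(de = file.path(outdir, "de_results.tsv"),
                pairs = file.path(outdir, "pairs.tsv"),
                pair_summary = file.path(outdir, "pair_summary.json"),
                node_stats = file.path(outdir, "node_stats.tsv"),
                run_log = file.path(outdir, "run_log.json"))
  for (g in c("disease", "control")) {
    paths[[paste0("sif_", g)]] <- file.path(outdir, paste0("network_", g, ".sif"))
    paths[[paste0("graphml_", g)]] <- file.path(outdir,
                                                paste0("network_", g, ".graphml"))
  }

  group <- sample_groups(expr)
  de <- stage("differential_expression", {
    pv <- pooled_variances(expr$values, group)
    prior <- fit_rvm_prior(pv$s2, pv$f)
    res <- rvm_t_test(expr$values, group, prior)
    select_de(res, p_threshold = config$de_p_threshold,
              fc_threshold = config$de_fc_threshold,
              use_q = config$de_use_q)
  })
  up <- attr(de, "up"); down <- attr(de, "down")
  biotype <- stats::setNames(annotation$biotype, annotation$id)
  de_dir <- stats::setNames(de$direction, de$gene_id)
  de_ids <- de$gene_id[de$direction != "ns"]
  de_lnc <- de_dir[de_ids[biotype[de_ids] %in% "lncRNA"]]
  de_mrna <- de_dir[de_ids[biotype[de_ids] %in% "mRNA"]]

  pairs <- stage("pairing",
    find_pairs(annotation, de_lnc, de_mrna,
               max_distance = config$pair_max_distance,
               anchor = config$pair_anchor))
  pair_summary <- summarize_pairs(pairs)

  nets <- stage("network", {
    lapply(c(disease = "disease", control = "control"), function(g)
      build_cnc_network(expr, g, names(de_lnc), names(de_mrna),
                        corr_threshold = config$corr_threshold,
                        use_absolute = config$corr_use_absolute,
                        cnc_only = config$network_cnc_only))
  })
  node_stats <- stage("diffk",
    if (nrow(nets$disease$nodes) == 0 && nrow(nets$control$nodes) == 0)
      suppressWarnings(diffk(nets$disease, nets$control,
                             normalization = config$diffk_normalization))
    else diffk(nets$disease, nets$control,
               normalization = config$diffk_normalization))

  enr <- NULL
  if (!is.null(term_map)) {
    enr <- stage("enrichment", {
      universe <- intersect(rownames(expr$values),
                            annotation$id[annotation$biotype == "mRNA"])
      do.call(rbind, lapply(c("up", "down"), function(d) {
        genes <- intersect(if (d == "up") up else down, universe)
        enrich(genes, universe, term_map, mode = "go", direction = d,
               go_p_threshold = config$go_p_threshold,
               go_fdr_threshold = config$go_fdr_threshold)
      }))
    })
    paths$enrichment <- file.path(outdir, "enrichment_go.tsv")
  }

  write_tsv <- function(df, path)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  write_tsv(de, paths$de)
  write_tsv(pairs, paths$pairs)
  jsonlite::write_json(unclass(pair_summary), paths$pair_summary,
                       auto_unbox = TRUE, digits = NA)
  write_tsv(node_stats, paths$node_stats)
  for (g in c("disease", "control"))
    export_network(nets[[g]], sif_path = paths[[paste0("sif_", g)]],
                   graphml_path = paths[[paste0("graphml_", g)]],
                   stats = node_stats)
  if (!is.null(enr)) write_tsv(enr, paths$enrichment)
  run_log <- list(
    config = unclass(config),
    n_genes = nrow(expr$values),
    n_samples = ncol(expr$values),
    n_de_up = length(up), n_de_down = length(down),
    n_de_lnc = length(de_lnc), n_de_mrna = length(de_mrna),
    n_pairs = pair_summary$total,
    network_nodes = vapply(nets, function(n) nrow(n$nodes), integer(1)),
    network_edges = vapply(nets, function(n) nrow(n$edges), integer(1)))
  jsonlite::write_json(run_log, paths$run_log, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(list(de = de, up = up, down = down, pairs = pairs,
                 pair_summary = pair_summary,
                 net_disease = nets$disease, net_control = nets$control,
                 node_stats = node_stats, enrichment = enr, paths = paths))
}
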