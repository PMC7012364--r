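#' Run the full coexpression analysis pipeline
#'
#' Orchestrates every stage from one configuration: data loading (or
#' synthetic generation), lncRNA flagging, moderated differential
#' expression per pairwise contrast, Venn partitioning across the three
#' contrasts, per-contrast lncRNA-mRNA coexpression networks over all
#' samples, shared-target coregulation networks, optional gene-set
#' enrichment of the coregulated targets, and hierarchical clustering of
#' the selected probes.  All tables are written under `outdir` with a
#' stable layout and the run is summarized in a JSON report whose counts
#' equal the row counts of the emitted tables.  The same configuration
#' and seed reproduce the same report (timestamp aside).
#'
#' @param config configuration list, or path to a YAML file with the same
#'   structure:
#' \preformatted{
#' mode: synthetic            # or "real"
#' seed: 7
#' synthetic: {n_probes: 2000, n_control: 20, ...}   # simulation_config args
#' real:
#'   series_matrix: path      # GEO series-matrix file
#'   annotation: path         # platform annotation TSV
#'   gtf: path                # GENCODE-style GTF for lncRNA flagging
#' thresholds: {fold: 2, alpha: 0.05, r_threshold: 0.8,
#'              corr_alpha: 0.05, signed: false}
#' enrichment: {gmt: path}    # optional
#' outputs: {heatmap_png: true, max_cluster_probes: 2000}
#' }
#' @param outdir output directory (created).
#' @param seed overrides `config$seed` when not `NULL`.
#' @return Invisibly, the run-report list (also written to
#'   `outdir/report.json`).
#' @export
run_pipeline <- function(config, outdir, seed = NULL) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  thr <- utils::modifyList(list(fold = 2, alpha = 0.05, r_threshold = 0.8,
                                corr_alpha = 0.05, signed = FALSE),
                           config$thresholds %||% list())
  outs <- utils::modifyList(list(heatmap_png = TRUE,
                                 max_cluster_probes = 2000),
                            config$outputs %||% list())
  seed <- as.integer(seed %||% config$seed %||% 1L)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  log_path <- file.path(outdir, "pipeline.log")
  logs <- character(0)
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, rows_in, rows_out, params = "") {
    line <- sprintf("stage=%s rows_in=%s rows_out=%s %s elapsed=%.2fs",
                    name, rows_in, rows_out, params,
                    proc.time()[["elapsed"]] - t0)
    message(line)
    logs <<- c(logs, line)
  }
  set.seed(seed)

  mode <- config$mode %||% if (!is.null(config$synthetic)) "synthetic"
    else "real"
  if (mode == "synthetic") {
    cfg <- do.call(simulation_config,
                   utils::modifyList(config$synthetic %||% list(),
                                     list(seed = seed)))
    ds <- generate_dataset(cfg)
    em <- ds$matrix
    ann <- ds$annotation
    stage("load", cfg$n_probes, nrow(em$values), "source=synthetic")
  } else {
    paths <- config$real
    for (p in unlist(paths[c("series_matrix", "annotation")]))
      if (!file.exists(p)) stop("missing input file: ", p, call. = FALSE)
    em <- parse_series_matrix(paths$series_matrix)
    ann <- load_platform_annotation(paths$annotation)
    if (!is.null(paths$gtf)) {
      if (!file.exists(paths$gtf))
        stop("missing input file: ", paths$gtf, call. = FALSE)
      type_map <- parse_gtf_gene_types(paths$gtf)
      ann <- flag_lncrna_probes(ann, type_map)
    }
    stage("load", nrow(em$values), nrow(em$values), "source=real")
  }

  contrasts <- default_contrasts()
  report <- list(config = config, seed = seed, mode = mode,
                 thresholds = thr,
                 n_probes = nrow(em$values), n_samples = ncol(em$values),
                 n_lncrna_probes = sum(ann$is_lncrna),
                 n_gene_probes = sum(!ann$is_lncrna),
                 contrasts = list(), artifacts = list())

  deg_sets <- list(); lnc_sets <- list()
  flag <- stats::setNames(ann$is_lncrna, ann$probe_id)
  sym <- stats::setNames(ann$gene_symbol, ann$probe_id)
  for (ct in contrasts) {
    ab <- contrast_groups(ct)
    de <- de_contrast(em, ab[1], ab[2])
    degs <- select_degs(de, fold_bound = thr$fold, alpha = thr$alpha)
    parts <- split_lncrna(degs, ann)
    de_path <- file.path(outdir, paste0("de_", ct, ".tsv"))
    tab <- data.frame(de, gene_symbol = sym[de$probe_id],
                      is_lncrna = flag[de$probe_id],
                      selected = de$probe_id %in% degs$probe_id,
                      direction = ifelse(de$log2fc > 0, "up", "down"),
                      stringsAsFactors = FALSE)
    utils::write.table(tab, de_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    deg_sets[[ct]] <- degs$probe_id
    lnc_sets[[ct]] <- parts$lnc
    stage(paste0("de_", ct), nrow(de), nrow(degs),
          sprintf("fold=%g alpha=%g", thr$fold, thr$alpha))

    net <- build_coexpression(em, parts$lnc, parts$mrna,
                              r_threshold = thr$r_threshold,
                              alpha = thr$corr_alpha,
                              signed = isTRUE(thr$signed))
    net_path <- file.path(outdir, paste0("coexpression_", ct, ".tsv"))
    utils::write.table(net, net_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    export_network(net, "sif",
                   file.path(outdir, paste0("coexpression_", ct, ".sif")))
    coreg <- build_coregulation(net)
    coreg_path <- file.path(outdir, paste0("coregulation_", ct, ".tsv"))
    utils::write.table(coreg, coreg_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    stage(paste0("network_", ct),
          length(parts$lnc) * length(parts$mrna), nrow(net),
          sprintf("r>%g p<%g", thr$r_threshold, thr$corr_alpha))

    enr_n <- NA_integer_
    if (!is.null(config$enrichment$gmt) &&
        length(attr(coreg, "coregulated_targets"))) {
      collection <- parse_gmt(config$enrichment$gmt)
      universe <- unique(ann$gene_symbol[!is.na(ann$gene_symbol)])
      query <- unique(sym[attr(coreg, "coregulated_targets")])
      query <- query[!is.na(query)]
      enr <- enrich(query, universe, collection)
      utils::write.table(enr,
                         file.path(outdir, paste0("enrichment_", ct,
                                                  ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      enr_n <- sum(enr$adj_p < thr$alpha)
      stage(paste0("enrichment_", ct), length(query), nrow(enr), "")
    }

    report$contrasts[[ct]] <- list(
      n_deg = nrow(degs), n_lnc_de = length(parts$lnc),
      n_mrna_de = length(parts$mrna),
      n_coexpression_pairs = nrow(net),
      n_coexpressed_lnc = length(unique(net$lnc)),
      n_coregulation_pairs = nrow(coreg),
      n_coregulated_targets = length(attr(coreg, "coregulated_targets")),
      n_enriched_sets = enr_n,
      de_table = basename(de_path), coexpression_table = basename(net_path),
      coregulation_table = basename(coreg_path))
  }

  venn_deg <- venn_partition(deg_sets[[1]], deg_sets[[2]], deg_sets[[3]])
  venn_lnc <- venn_partition(lnc_sets[[1]], lnc_sets[[2]], lnc_sets[[3]])
  shared_lnc <- venn_lnc$abc
  report$n_deg_shared_all <- length(venn_deg$abc)
  report$n_lnc_shared_all <- length(shared_lnc)
  report$shared_lnc_symbols <- unname(sym[shared_lnc])
  venn_tab <- data.frame(
    region = names(venn_deg$counts),
    n_deg = unname(venn_deg$counts),
    n_lnc = unname(venn_lnc$counts), stringsAsFactors = FALSE)
  utils::write.table(venn_tab, file.path(outdir, "venn.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  stage("venn", length(unique(unlist(deg_sets))), sum(venn_deg$counts), "")

  all_deg <- sort(unique(unlist(deg_sets)))
  report$n_deg_union <- length(all_deg)
  if (length(all_deg) >= 2 && ncol(em$values) >= 2) {
    cl_ids <- utils::head(all_deg, outs$max_cluster_probes)
    sub <- em$values[cl_ids, , drop = FALSE]
    ok_rows <- apply(sub, 1, stats::sd) > 0
    sub <- sub[ok_rows, , drop = FALSE]
    if (nrow(sub) >= 2) {
      row_hc <- complete_linkage(correlation_distance(sub, "rows"))
      col_hc <- complete_linkage(correlation_distance(sub, "cols"))
      dendrogram_newick(col_hc, file.path(outdir, "samples.nwk"))
      heatmap_order(sub, row_hc, col_hc,
                    out_tsv = file.path(outdir, "heatmap_matrix.tsv"),
                    out_png = if (isTRUE(outs$heatmap_png))
                      file.path(outdir, "heatmap.png") else NULL)
      stage("clustering", nrow(sub), nrow(sub), "linkage=complete")
    }
  }

  report$artifacts <- list.files(outdir)
  report$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", na = "null")
  writeLines(logs, log_path)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
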