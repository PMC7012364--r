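#' Configuration for the synthetic three-group expression generator
#'
#' Defines a simulated malignant-transformation study: a log2-scale
#' probe-by-sample matrix with three labeled sample groups, a configurable
#' fraction of probes flagged as lncRNA, planted differential expression
#' for each pairwise contrast, and planted lncRNA-driven coexpression
#' modules with a specified latent Pearson correlation.
#'
#' The default group sizes (45 control / 17 dysplasia / 167 cancer) mirror
#' the composition of the public oral-cancer progression series this
#' pipeline was designed around; the default lncRNA fraction approximates
#' the share of lncRNA probes on a whole-genome 3'-IVT array.
#'
#' @param n_control,n_dysplasia,n_cancer sample counts per group.
#' @param n_probes total number of probes.
#' @param frac_lncrna fraction of probes flagged as lncRNA (0..1).
#' @param n_de_per_contrast number of planted differentially expressed
#'   probes for each of the three pairwise contrasts.
#' @param planted_log2fc magnitude of the planted group-mean shift
#'   (log2 units); direction alternates up/down by planted-probe index.
#' @param n_modules number of planted coexpression modules (one lncRNA
#'   hub per module).
#' @param module_size number of mRNA targets per module lncRNA.
#' @param module_rho latent Pearson correlation between a module lncRNA
#'   and each of its targets, in (-1, 1).
#' @param noise_sd residual standard deviation (log2 units).
#' @param baseline_range length-2 interval for per-probe baseline means.
#' @param var_prior optional `c(d0 = , s0_sq = )`: draw per-probe true
#'   variances from a scaled inverse-chi-square prior instead of the
#'   constant `noise_sd^2` (used for hyperparameter-recovery studies).
#' @param seed integer random seed; identical configurations produce
#'   bit-identical datasets.
#' @return A `"SimulationConfig"` list.
#' @seealso [generate_dataset()]
#' @export
simulation_config <- function(n_control = 45, n_dysplasia = 17,
                              n_cancer = 167, n_probes = 10000,
                              frac_lncrna = 0.055,
                              n_de_per_contrast = 100,
                              planted_log2fc = 2,
                              n_modules = 5, module_size = 10,
                              module_rho = 0.9, noise_sd = 0.5,
                              baseline_range = c(4, 12),
                              var_prior = NULL, seed = 1L) {
  baseline_range <- as.numeric(unlist(baseline_range))
  if (!is.null(var_prior)) var_prior <- unlist(var_prior)
  cfg <- list(n_control = n_control, n_dysplasia = n_dysplasia,
              n_cancer = n_cancer, n_probes = n_probes,
              frac_lncrna = frac_lncrna,
              n_de_per_contrast = n_de_per_contrast,
              planted_log2fc = planted_log2fc, n_modules = n_modules,
              module_size = module_size, module_rho = module_rho,
              noise_sd = noise_sd, baseline_range = baseline_range,
              var_prior = var_prior, seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "SimulationConfig")
}

validate_simulation_config <- function(cfg) {
  chk <- function(ok, what)
    if (!ok) stop("invalid simulation config: ", what, call. = FALSE)
  chk(cfg$n_control >= 1 && cfg$n_dysplasia >= 1 && cfg$n_cancer >= 1,
      "all group sizes must be >= 1")
  chk(cfg$n_probes >= 1, "n_probes must be >= 1")
  chk(cfg$frac_lncrna >= 0 && cfg$frac_lncrna <= 1,
      "frac_lncrna must lie in [0, 1]")
  chk(cfg$n_de_per_contrast >= 0, "n_de_per_contrast must be >= 0")
  chk(cfg$n_modules >= 0 && cfg$module_size >= 1,
      "n_modules must be >= 0 and module_size >= 1")
  chk(cfg$module_rho > -1 && cfg$module_rho < 1,
      "module_rho must lie strictly in (-1, 1)")
  chk(cfg$noise_sd > 0, "noise_sd must be > 0")
  chk(length(cfg$baseline_range) == 2 &&
        cfg$baseline_range[1] <= cfg$baseline_range[2],
      "baseline_range must be an ordered length-2 interval")
  planted <- cfg$n_modules * (cfg$module_size + 1) + 3 * cfg$n_de_per_contrast
  chk(planted <= cfg$n_probes,
      sprintf(paste0("planted probes (%d module + %d DE) exceed n_probes ",
                     "(%d)"),
              cfg$n_modules * (cfg$module_size + 1),
              3 * cfg$n_de_per_contrast, cfg$n_probes))
  if (!is.null(cfg$var_prior))
    chk(all(c("d0", "s0_sq") %in% names(cfg$var_prior)) &&
          cfg$var_prior[["d0"]] > 0 && cfg$var_prior[["s0_sq"]] > 0,
        "var_prior must be c(d0 = >0, s0_sq = >0)")
  invisible(cfg)
}

#' Names of the three pairwise contrasts
#'
#' Each contrast is `a_vs_b`, with the log2 fold change defined as
#' mean(a) - mean(b).
#' @return Character vector of length 3.
#' @export
default_contrasts <- function() {
  c("cancer_vs_control", "dysplasia_vs_control", "cancer_vs_dysplasia")
}

contrast_groups <- function(contrast) {
  parts <- strsplit(contrast, "_vs_", fixed = TRUE)[[1]]
  if (length(parts) != 2)
    stop("contrast name must have the form 'a_vs_b': ", contrast,
         call. = FALSE)
  parts
}

#' Generate a synthetic three-group dataset with planted structure
#'
#' Simulates a log2-intensity matrix under a Gaussian noise model: each
#' probe has a baseline drawn uniformly from `baseline_range` and residual
#' standard deviation `noise_sd` (or a probe-specific value under
#' `var_prior`).  Three kinds of structure are planted on top:
#'
#' * **Differential expression** — for each pairwise contrast `a_vs_b`,
#'   `n_de_per_contrast` dedicated probes receive a shift of
#'   `planted_log2fc` in group `a`, sign alternating up/down by probe
#'   index, so the population group-mean difference equals the planted
#'   value exactly.  Because a single-group shift perturbs two of the
#'   three pairwise contrasts, [implied_log2fc()] reports each planted
#'   probe's true mean difference under every contrast.
#' * **Coexpression modules** — each module has one lncRNA hub whose
#'   standardized signal `z` is shared with its `module_size` mRNA
#'   targets via `target = rho * z + sqrt(1 - rho^2) * eps`, giving an
#'   exact population Pearson correlation of `module_rho` between hub and
#'   each target.
#'
#' All remaining probes are independent noise.  A probe annotation is
#' emitted alongside: module hubs are always flagged lncRNA, module
#' targets never, and additional probes are flagged at random to reach
#' `frac_lncrna` of the total.
#'
#' @param config a [simulation_config()].
#' @return A `"SyntheticDataset"` list with elements
#'   `matrix` (an [expression_matrix()]),
#'   `annotation` (probe annotation data frame, see
#'   [load_platform_annotation()]), and
#'   `truth` (a `"SyntheticTruth"` list: `de` — per-contrast data frames of
#'   planted probe ids and signed log2 fold changes; `modules` — named list
#'   mapping each module lncRNA probe to its target probe ids;
#'   `module_rho`).
#' @examples
#' ds <- generate_dataset(simulation_config(
#'   n_control = 5, n_dysplasia = 5, n_cancer = 5, n_probes = 100,
#'   n_de_per_contrast = 5, n_modules = 2, module_size = 4, seed = 1))
#' dim(ds$matrix)
#' @export
generate_dataset <- function(config) {
  validate_simulation_config(config)
  set.seed(config$seed)
  n_samples <- config$n_control + config$n_dysplasia + config$n_cancer
  groups <- rep(c("control", "dysplasia", "cancer"),
                c(config$n_control, config$n_dysplasia, config$n_cancer))
  sample_ids <- sprintf("sample_%03d", seq_len(n_samples))
  names(groups) <- sample_ids
  n_probes <- config$n_probes
  width <- max(5L, nchar(as.character(n_probes)))
  probe_ids <- sprintf(paste0("probe_%0", width, "d"), seq_len(n_probes))

  # deterministic probe layout: module hubs, module targets, DE blocks, null
  n_mod_probes <- config$n_modules * (config$module_size + 1)
  hub_idx <- seq_len(config$n_modules)
  tgt_idx <- config$n_modules + seq_len(config$n_modules * config$module_size)
  de_idx <- lapply(seq_along(default_contrasts()), function(i)
    n_mod_probes + (i - 1) * config$n_de_per_contrast +
      seq_len(config$n_de_per_contrast))
  names(de_idx) <- default_contrasts()

  mu <- stats::runif(n_probes, config$baseline_range[1],
                     config$baseline_range[2])
  if (is.null(config$var_prior)) {
    sds <- rep(config$noise_sd, n_probes)
  } else {
    d0 <- config$var_prior[["d0"]]
    s0 <- config$var_prior[["s0_sq"]]
    sds <- sqrt(d0 * s0 / stats::rchisq(n_probes, df = d0))
  }

  values <- mu + sds * matrix(stats::rnorm(n_probes * n_samples),
                              n_probes, n_samples)
  dimnames(values) <- list(probe_ids, sample_ids)

  # planted modules: shared latent z per hub, exact population correlation
  modules <- list()
  if (config$n_modules > 0) {
    rho <- config$module_rho
    for (m in seq_len(config$n_modules)) {
      hub <- hub_idx[m]
      tgts <- tgt_idx[(m - 1) * config$module_size +
                        seq_len(config$module_size)]
      z <- stats::rnorm(n_samples)
      values[hub, ] <- mu[hub] + sds[hub] * z
      for (t in tgts) {
        eps <- stats::rnorm(n_samples)
        values[t, ] <- mu[t] + sds[t] * (rho * z + sqrt(1 - rho^2) * eps)
      }
      modules[[probe_ids[hub]]] <- probe_ids[tgts]
    }
  }

  # planted DE: shift the contrast's first-named group, alternating sign
  de <- list()
  for (ct in default_contrasts()) {
    idx <- de_idx[[ct]]
    if (length(idx) == 0) {
      de[[ct]] <- data.frame(probe_id = character(0), log2fc = numeric(0),
                             stringsAsFactors = FALSE)
      next
    }
    shift_group <- contrast_groups(ct)[1]
    cols <- groups == shift_group
    sgn <- ifelse(seq_along(idx) %% 2 == 1, 1, -1)
    lfc <- sgn * config$planted_log2fc
    values[idx, cols] <- values[idx, cols] + lfc
    de[[ct]] <- data.frame(probe_id = probe_ids[idx], log2fc = lfc,
                           stringsAsFactors = FALSE)
  }

  # lncRNA flags: hubs always, targets never, rest sampled to frac_lncrna
  is_lnc <- logical(n_probes)
  is_lnc[hub_idx] <- TRUE
  n_lnc_goal <- round(config$frac_lncrna * n_probes)
  extra <- n_lnc_goal - config$n_modules
  eligible <- setdiff(seq_len(n_probes), c(hub_idx, tgt_idx))
  if (extra > 0)
    is_lnc[sample(eligible, min(extra, length(eligible)))] <- TRUE
  symbol <- ifelse(is_lnc,
                   sprintf("LNC%05d", cumsum(is_lnc)),
                   sprintf("GENE%05d", cumsum(!is_lnc)))
  annotation <- data.frame(probe_id = probe_ids, gene_symbol = symbol,
                           gene_id = NA_character_, is_lncrna = is_lnc,
                           stringsAsFactors = FALSE)

  truth <- structure(list(de = de, modules = modules,
                          module_rho = config$module_rho),
                     class = "SyntheticTruth")
  structure(list(matrix = expression_matrix(values, groups),
                 annotation = annotation, truth = truth, config = config),
            class = "SyntheticDataset")
}

#' Implied population log2 fold change of planted probes per contrast
#'
#' A shift planted in one group changes the population mean difference of
#' the two pairwise contrasts that involve that group.  This expands the
#' planted assignments into the true mean difference of every planted
#' probe under every contrast, which is the correct ground truth for
#' sensitivity / false-discovery accounting.
#'
#' @param truth the `truth` element of a [generate_dataset()] result.
#' @return Data frame with columns `probe_id` and one numeric column per
#'   contrast holding the true population log2 mean difference.
#' @export
implied_log2fc <- function(truth) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  all_ids <- unique(unlist(lapply(truth$de, `[[`, "probe_id")))
  grp_names <- c("control", "dysplasia", "cancer")
  shift <- matrix(0, length(all_ids), 3,
                  dimnames = list(all_ids, grp_names))
  for (ct in names(truth$de)) {
    d <- truth$de[[ct]]
    if (nrow(d) == 0) next
    g <- contrast_groups(ct)[1]
    shift[d$probe_id, g] <- shift[d$probe_id, g] + d$log2fc
  }
  out <- data.frame(probe_id = all_ids, stringsAsFactors = FALSE)
  for (ct in default_contrasts()) {
    ab <- contrast_groups(ct)
    out[[ct]] <- shift[, ab[1]] - shift[, ab[2]]
  }
  rownames(out) <- NULL
  out
}

#' Write a synthetic dataset to disk as plain-text fixtures
#'
#' Emits the series-matrix expression file, the probe annotation table and
#' the planted-truth table; re-reading the series matrix with
#' [parse_series_matrix()] reproduces the values bit-exactly, and
#' [read_truth()] round-trips the truth.
#'
#' @param dataset a [generate_dataset()] result.
#' @param directory output directory (created if absent).
#' @return Named character vector of the three written paths
#'   (`series_matrix`, `annotation`, `truth`).
#' @export
write_fixture <- function(dataset, directory) {
  stopifnot(inherits(dataset, "SyntheticDataset"))
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  if (!dir.exists(directory))
    stop("cannot create directory: ", directory, call. = FALSE)
  paths <- c(series_matrix = file.path(directory, "series_matrix.txt"),
             annotation = file.path(directory, "annotation.tsv"),
             truth = file.path(directory, "truth.tsv"))
  write_series_matrix(dataset$matrix, paths[["series_matrix"]])
  utils::write.table(dataset$annotation[c("probe_id", "gene_symbol",
                                          "gene_id")],
                     paths[["annotation"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  write_truth(dataset$truth, paths[["truth"]])
  paths
}

# truth serialization: one row per planted fact
# role is the contrast name for DE rows, or module_lnc / module_target
write_truth <- function(truth, path) {
  rows <- list()
  for (ct in names(truth$de)) {
    d <- truth$de[[ct]]
    if (nrow(d) > 0)
      rows[[length(rows) + 1]] <-
        data.frame(probe_id = d$probe_id, role = ct, partner = "",
                   value = d$log2fc, stringsAsFactors = FALSE)
  }
  for (hub in names(truth$modules)) {
    rows[[length(rows) + 1]] <-
      data.frame(probe_id = hub, role = "module_lnc", partner = "",
                 value = truth$module_rho, stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <-
      data.frame(probe_id = truth$modules[[hub]], role = "module_target",
                 partner = hub, value = truth$module_rho,
                 stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(probe_id = character(0), role = character(0),
               partner = character(0), value = numeric(0))
  tab$value <- sprintf("%.17g", tab$value)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a planted-truth table written by [write_fixture()]
#'
#' @param path path to the truth TSV.
#' @return A `"SyntheticTruth"` list (see [generate_dataset()]).
#' @export
read_truth <- function(path) {
  tab <- utils::read.delim(path, colClasses = c("character", "character",
                                                "character", "numeric"))
  de <- list()
  for (ct in default_contrasts()) {
    d <- tab[tab$role == ct, , drop = FALSE]
    de[[ct]] <- data.frame(probe_id = d$probe_id, log2fc = d$value,
                           stringsAsFactors = FALSE)
    rownames(de[[ct]]) <- NULL
  }
  modules <- list()
  tg <- tab[tab$role == "module_target", , drop = FALSE]
  for (hub in tab$probe_id[tab$role == "module_lnc"])
    modules[[hub]] <- tg$probe_id[tg$partner == hub]
  rho <- unique(tab$value[tab$role %in% c("module_lnc", "module_target")])
  structure(list(de = de, modules = modules,
                 module_rho = if (length(rho)) rho[1] else NA_real_),
            class = "SyntheticTruth")
}
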