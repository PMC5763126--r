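#' Read a pipeline configuration file
#'
#' YAML configuration with input paths and analysis settings. Relative
#' paths are resolved against the config file's directory. Required keys:
#' `fasta`, `gff`, `ct`, `assay`, `lowry_standards`, `lowry_samples`,
#' `survival`, `out_dir`. Optional: `motifs` (TSV path; default motif
#' set when absent), `window_nt` (1000), `reference_gene` (`rp49`),
#' `calibrator` (`[naive, naive]`), `alpha` (0.05), `seed` (1).
#'
#' @param path Path to the YAML config.
#' @return A validated config list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  required <- c("fasta", "gff", "ct", "assay", "lowry_standards",
                "lowry_samples", "survival", "out_dir")
  miss <- setdiff(required, names(cfg))
  if (length(miss) > 0L) {
    stop("config is missing key(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  }
  for (key in c(required[required != "out_dir"], "motifs")) {
    cfg[[key]] <- resolve(cfg[[key]])
  }
  cfg$out_dir <- resolve(cfg$out_dir)
  cfg$window_nt <- as.integer(cfg$window_nt %||% 1000L)
  cfg$reference_gene <- cfg$reference_gene %||% "rp49"
  cfg$calibrator <- unlist(cfg$calibrator %||% c("naive", "naive"))
  cfg$alpha <- cfg$alpha %||% 0.05
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  for (key in required[required != "out_dir"]) {
    if (!file.exists(cfg[[key]])) {
      stop("input file for '", key, "' not found: ", cfg[[key]], call. = FALSE)
    }
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

log_stage <- function(name, n_in, n_out) {
  message(sprintf("[sodkit] %-12s in=%d out=%d", name, n_in, n_out))
}

#' Run the complete analysis pipeline
#'
#' Orchestrates every stage over the configured inputs and writes the
#' report bundle to `config$out_dir`: `motif_counts.tsv` (gene x
#' motif-orientation census of the promoter windows), `architecture.tsv`,
#' per-gene relative-expression tables (`rq.tsv`) with ANOVA + SNK
#' decisions (`expression_stats.json`), per-sample SOD activities
#' (`activity.tsv`) with their ANOVA/SNK per treatment cell, survival
#' proportions (`survival.tsv`) and pairwise Wilcoxon p-values
#' (`survival_wilcoxon.tsv`), and a deterministic `manifest.json`
#' (package version, config hash, seed). Outputs are byte-stable for a
#' fixed config and inputs.
#'
#' @param config Config list from [read_pipeline_config()], or a path to
#'   a YAML config file.
#' @return Invisibly, a list of the in-memory results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  genomes <- stage("read_fasta", read_fasta(config$fasta))
  genes <- stage("read_gff", read_gene_models(config$gff))
  motifs <- if (!is.null(config$motifs)) {
    stage("read_motifs", read_motifs(config$motifs))
  } else {
    default_motifs()
  }
  log_stage("inputs", nrow(genomes), nrow(genes))

  counts <- stage("motif_scan", suppressWarnings(
    build_count_table(genes, genomes, motifs, config$window_nt)))
  readr::write_tsv(counts, file.path(out, "motif_counts.tsv"))
  log_stage("motif_scan", nrow(genes), nrow(counts))

  arch <- stage("architecture", summarize_architecture(genes, genomes))
  readr::write_tsv(flatten_architecture(arch), file.path(out, "architecture.tsv"))
  log_stage("architecture", nrow(genes), nrow(arch))

  ct <- stage("read_ct", readr::read_csv(config$ct, show_col_types = FALSE))
  target_genes <- setdiff(unique(ct$gene), config$reference_gene)
  rq_all <- stage("qpcr", purrr::map_dfr(target_genes, function(g) {
    relative_expression(ct, g, reference_gene = config$reference_gene,
                        calibrator = config$calibrator)
  }))
  readr::write_tsv(
    dplyr::select(rq_all, -"rq_reps"), file.path(out, "rq.tsv"))
  log_stage("qpcr", nrow(ct), nrow(rq_all))

  expr_stats <- stage("expression_stats", purrr::map(target_genes, function(g) {
    d <- rq_all |>
      dplyr::filter(.data$gene == g) |>
      dplyr::select("priming", "challenge", "rq_reps") |>
      tidyr::unnest("rq_reps") |>
      dplyr::mutate(cell = paste(.data$priming, .data$challenge, sep = "/"))
    av <- one_way_anova(d, rq_reps, cell)
    snk <- snk_posthoc(d, rq_reps, cell, alpha = config$alpha)
    list(gene = g, anova = as.list(av),
         snk_significant_pairs = snk_pairs(snk))
  }))
  names(expr_stats) <- target_genes
  jsonlite::write_json(expr_stats, file.path(out, "expression_stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  assay <- stage("read_assay", readr::read_csv(config$assay, show_col_types = FALSE))
  lowry_std <- stage("read_lowry",
                     readr::read_csv(config$lowry_standards, show_col_types = FALSE))
  lowry_smp <- stage("read_lowry",
                     readr::read_csv(config$lowry_samples, show_col_types = FALSE))
  act <- stage("activity", sod_activity(assay, lowry_std, lowry_smp))
  readr::write_tsv(act, file.path(out, "activity.tsv"))
  log_stage("activity", nrow(assay), nrow(act))

  act_stats <- NULL
  if (all(c("priming", "challenge") %in% names(act))) {
    d <- dplyr::mutate(act, cell = paste(.data$priming, .data$challenge, sep = "/"))
    act_stats <- stage("activity_stats", list(
      anova = as.list(one_way_anova(d, specific_activity_u_per_mg, cell)),
      snk_significant_pairs = snk_pairs(
        snk_posthoc(d, specific_activity_u_per_mg, cell, alpha = config$alpha))
    ))
    jsonlite::write_json(act_stats, file.path(out, "activity_stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  surv_counts <- stage("read_survival",
                       readr::read_csv(config$survival, show_col_types = FALSE))
  surv <- stage("survival", survival_proportions(surv_counts))
  readr::write_tsv(
    dplyr::select(surv, -"proportions"), file.path(out, "survival.tsv"))
  surv_d <- surv_counts |>
    dplyr::mutate(prop = .data$alive / .data$total,
                  cell = paste(.data$priming, .data$challenge, sep = "/"))
  wx <- stage("survival_wilcoxon", pairwise_wilcoxon(surv_d, prop, cell))
  wx_tbl <- generics::tidy(wx)
  readr::write_tsv(wx_tbl, file.path(out, "survival_wilcoxon.tsv"))
  log_stage("survival", nrow(surv_counts), nrow(surv))

  manifest <- list(
    package = "sodkit",
    version = as.character(utils::packageVersion("sodkit")),
    seed = config$seed,
    window_nt = config$window_nt,
    reference_gene = config$reference_gene,
    calibrator = paste(config$calibrator, collapse = "/"),
    alpha = config$alpha,
    config_hash = rlang::hash(config[sort(setdiff(names(config), "out_dir"))]),
    outputs = sort(c("motif_counts.tsv", "architecture.tsv", "rq.tsv",
                     "expression_stats.json", "activity.tsv", "survival.tsv",
                     "survival_wilcoxon.tsv"))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(counts = counts, architecture = arch, rq = rq_all,
                 expression_stats = expr_stats, activity = act,
                 activity_stats = act_stats, survival = surv,
                 wilcoxon = wx, manifest = manifest))
}

# significant SNK pairs as "a|b" strings (stable order) for JSON reports
snk_pairs <- function(snk) {
  m <- snk$significant
  labs <- rownames(m)
  pairs <- character(0)
  for (i in seq_len(nrow(m) - 1L)) {
    for (j in (i + 1L):ncol(m)) {
      if (m[i, j]) pairs <- c(pairs, paste(labs[i], labs[j], sep = "|"))
    }
  }
  pairs
}
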