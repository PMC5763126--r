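# Default synthetic study: a 3 x 3 priming x challenge factorial on
# Tribolium-like Cu,Zn-SOD loci, 3 biological replicates, duplicate wells.

PRIMING_LEVELS <- c("naive", "PBS", "hkBt1")
CHALLENGE_LEVELS <- c("naive", "PBS", "Bt1")

#' Default synthetic locus plans
#'
#' Four loci mirroring the reported architecture of the Tribolium
#' castaneum Cu,Zn-SOD family: `soda` (462 nt ORF, 326/100 nt UTRs, one
#' 5'UTR intron, poly-A signal at transcript position 879), `sodb1`
#' (615 nt ORF, 2290/60 nt UTRs, five exons with the largest intron in the
#' 5' UTR), `sodb2` (501 nt ORF, 180/59 nt UTRs, three exons, poly-A at
#' 721) and `sodc` (684 nt ORF, 662/36 nt UTRs, four exons, one 5'UTR
#' intron). Promoter motif plans reproduce the characteristic cis-element
#' census: `soda` carries one reverse-orientation full ARE, six forward /
#' three reverse hARE half sites and one forward XRE; the `sodb` loci two
#' reverse hARE; `sodc` two forward and three reverse hARE.
#' `annotated_protein_aa` records the protein length stated in public
#' annotation (155 aa for soda, 217 aa for sodc), which disagrees with the
#' ORF arithmetic and is surfaced as a `length_discrepancy` flag by
#' [summarize_architecture()].
#'
#' @return Named list of per-locus plans accepted by [generate_locus()].
#' @export
sod_locus_plans <- function() {
  list(
    soda = list(
      gene_id = "soda", seq_id = "scaffold_34", strand = "+",
      architecture_plan = list(
        utr5_nt = 326L, orf_nt = 462L, utr3_nt = 100L,
        polya_at = 879L, annotated_protein_aa = 155L,
        introns = tibble::tibble(after_tx_nt = 150L, length = 300L)
      ),
      motif_plan = tibble::tibble(
        name = c("ARE", "hARE", "XRE"),
        fwd = c(0L, 6L, 1L), rev = c(1L, 3L, 0L)
      )
    ),
    sodb1 = list(
      gene_id = "sodb1", seq_id = "scaffold_67", strand = "+",
      architecture_plan = list(
        utr5_nt = 2290L, orf_nt = 615L, utr3_nt = 60L,
        polya_at = c(2910L, 2936L), annotated_protein_aa = 204L,
        introns = tibble::tibble(
          after_tx_nt = c(500L, 2400L, 2600L, 2800L),
          length = c(2000L, 150L, 120L, 90L)
        )
      ),
      motif_plan = tibble::tibble(
        name = c("ARE", "hARE", "XRE"),
        fwd = c(0L, 0L, 0L), rev = c(0L, 2L, 0L)
      )
    ),
    sodb2 = list(
      gene_id = "sodb2", seq_id = "scaffold_67b", strand = "-",
      architecture_plan = list(
        utr5_nt = 180L, orf_nt = 501L, utr3_nt = 59L,
        polya_at = 721L, annotated_protein_aa = 166L,
        introns = tibble::tibble(after_tx_nt = c(100L, 400L),
                                 length = c(200L, 180L))
      ),
      motif_plan = tibble::tibble(
        name = c("ARE", "hARE", "XRE"),
        fwd = c(0L, 0L, 0L), rev = c(0L, 2L, 0L)
      )
    ),
    sodc = list(
      gene_id = "sodc", seq_id = "scaffold_56", strand = "-",
      architecture_plan = list(
        utr5_nt = 662L, orf_nt = 684L, utr3_nt = 36L,
        polya_at = 1350L, annotated_protein_aa = 217L,
        introns = tibble::tibble(after_tx_nt = c(300L, 800L, 1100L),
                                 length = c(250L, 150L, 130L))
      ),
      motif_plan = tibble::tibble(
        name = c("ARE", "hARE", "XRE"),
        fwd = c(0L, 2L, 0L), rev = c(0L, 3L, 0L)
      )
    )
  )
}

#' Default planted expression fold changes
#'
#' Qualitative shape of the priming/challenge response used by the
#' synthetic study: the intracellular isoform (`soda`) is induced by
#' heat-killed-bacteria priming, one extracellular isoform (`sodb`) is
#' induced by priming only without challenge, the other (`sodc`) is
#' down-regulated in every treated cell, and the antimicrobial-peptide
#' control (`atta2`) responds strongly to challenge. The calibrator cell
#' (naive/naive) has fold 1 for every gene.
#'
#' @return Tibble `priming`, `challenge`, `gene`, `fold`.
#' @export
default_fold_changes <- function() {
  grid <- tidyr::expand_grid(
    priming = PRIMING_LEVELS, challenge = CHALLENGE_LEVELS,
    gene = c("soda", "sodb", "sodc", "atta2")
  )
  grid |>
    dplyr::mutate(fold = dplyr::case_when(
      gene == "soda" & priming == "hkBt1" & challenge == "naive" ~ 2.5,
      gene == "soda" & priming == "hkBt1" & challenge == "Bt1" ~ 2.0,
      gene == "sodb" & priming == "hkBt1" & challenge == "naive" ~ 2.0,
      gene == "sodc" & !(priming == "naive" & challenge == "naive") ~ 0.5,
      gene == "atta2" & challenge == "PBS" ~ 3.0,
      gene == "atta2" & challenge == "Bt1" ~ 8.0,
      TRUE ~ 1.0
    ))
}

#' Default true survival probabilities
#'
#' Unchallenged and wounding-control cells survive at ~0.95; under live
#' infection, primed individuals (`hkBt1`) survive markedly better (0.85)
#' than unprimed (0.55) or wounding controls (0.60).
#'
#' @return Tibble `priming`, `challenge`, `p`.
#' @export
default_survival_probs <- function() {
  tidyr::expand_grid(priming = PRIMING_LEVELS, challenge = CHALLENGE_LEVELS) |>
    dplyr::mutate(p = dplyr::case_when(
      challenge != "Bt1" ~ 0.95,
      priming == "hkBt1" ~ 0.85,
      priming == "PBS" ~ 0.60,
      TRUE ~ 0.55
    ))
}

#' Default true SOD activity samples
#'
#' One pooled sample per treatment cell per experiment. True 50%-inhibition
#' amounts encode the activity pattern: elevated activity (smaller `x50`)
#' in the unwounded PBS-challenge group and in primed/wounded infected
#' groups; 2 mg/mL total protein throughout.
#'
#' @param n_experiments Independent experiments.
#' @return Tibble `sample_id`, `priming`, `challenge`, `experiment`,
#'   `x50_ul`, `protein_mg_per_ml`.
#' @export
default_activity_samples <- function(n_experiments = 3L) {
  tidyr::expand_grid(
    priming = PRIMING_LEVELS, challenge = CHALLENGE_LEVELS,
    experiment = seq_len(n_experiments)
  ) |>
    dplyr::mutate(
      x50_ul = dplyr::case_when(
        challenge == "PBS" & priming == "naive" ~ 6,
        challenge == "Bt1" & priming %in% c("PBS", "hkBt1") ~ 6.5,
        TRUE ~ 10
      ),
      protein_mg_per_ml = 2,
      sample_id = paste(.data$priming, .data$challenge, .data$experiment,
                        sep = "_")
    ) |>
    dplyr::select("sample_id", "priming", "challenge", "experiment",
                  "x50_ul", "protein_mg_per_ml")
}

#' Write a complete synthetic input bundle with its ground truth
#'
#' Generates every input the pipeline consumes — genome FASTA, gene-model
#' GFF3, long-format Ct CSV, NBT assay CSV, Lowry CSVs and survival
#' CSV — plus `truth.json`, the machine-readable ground-truth ledger.
#' Deterministic: the same seed and plans yield byte-identical files.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer master seed; per-dataset sub-seeds are derived from
#'   it by a fixed splitting rule.
#' @param locus_plans,fold_changes,survival_probs,activity_samples Study
#'   design; defaults mirror the standard synthetic study.
#' @param window_nt Promoter window length used for motif planting.
#' @param noise_sd Ct noise SD (cycles).
#' @param activity_noise_sd Absorbance noise SD.
#' @param n_per_cell Individuals per survival cell per experiment.
#' @return Invisibly, a list with the generated objects and `truth`.
#' @export
write_synthetic_bundle <- function(dir, seed,
                                   locus_plans = sod_locus_plans(),
                                   fold_changes = default_fold_changes(),
                                   survival_probs = default_survival_probs(),
                                   activity_samples = default_activity_samples(),
                                   window_nt = 1000L,
                                   noise_sd = 0.2,
                                   activity_noise_sd = 0.01,
                                   n_per_cell = 30L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  loci <- purrr::map(locus_plans, function(p) {
    generate_locus(seed, gene_id = p$gene_id, seq_id = p$seq_id,
                   strand = p$strand, architecture_plan = p$architecture_plan,
                   motif_plan = p$motif_plan, window_nt = window_nt)
  })
  genome <- purrr::map_dfr(loci, "genome")
  genes <- purrr::map_dfr(loci, "genes")
  qpcr <- generate_qpcr_dataset(seed, fold_changes, noise_sd = noise_sd)
  act <- generate_activity_dataset(seed, activity_samples,
                                   noise_sd = activity_noise_sd)
  surv <- generate_survival_dataset(seed, survival_probs,
                                    n_per_cell = n_per_cell)

  write_fasta(genome, file.path(dir, "genome.fasta"))
  write_gene_models(genes, file.path(dir, "genes.gff3"))
  readr::write_csv(qpcr$ct, file.path(dir, "ct.csv"))
  readr::write_csv(act$assay, file.path(dir, "assay.csv"))
  readr::write_csv(act$lowry_standards, file.path(dir, "lowry_standards.csv"))
  readr::write_csv(act$lowry_samples, file.path(dir, "lowry_samples.csv"))
  readr::write_csv(surv$counts, file.path(dir, "survival.csv"))

  truth <- list(
    seed = seed,
    window_nt = window_nt,
    loci = purrr::map(loci, function(l) {
      tr <- l$truth
      tr$motif_counts <- as.data.frame(tr$motif_counts)
      tr
    }),
    qpcr = qpcr$truth,
    activity = as.data.frame(act$truth),
    survival = surv$truth
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(genome = genome, genes = genes, qpcr = qpcr,
                 activity = act, survival = surv, truth = truth))
}
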