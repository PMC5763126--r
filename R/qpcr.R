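#' Average technical qPCR replicates
#'
#' Collapses technical replicates to one mean Ct per sample x gene x
#' biological replicate, flagging any set whose Ct spread exceeds
#' `tolerance` cycles. Flagged rows are never dropped automatically.
#'
#' @param ct Long-format Ct tibble with columns `sample_id`, `priming`,
#'   `challenge`, `gene`, `bio_rep`, `tech_rep`, `ct`.
#' @param tolerance Maximum within-set Ct range (cycles) before flagging.
#' @return Tibble with one row per (sample, gene, bio_rep): mean `ct`,
#'   `n_tech`, and logical `flag_spread`.
#' @export
average_technical_reps <- function(ct, tolerance = 0.5) {
  needed <- c("sample_id", "priming", "challenge", "gene", "bio_rep", "ct")
  missing_cols <- setdiff(needed, names(ct))
  if (length(missing_cols) > 0L) {
    stop("Ct table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0)) {
    stop("Ct values must be finite and positive", call. = FALSE)
  }
  ct |>
    dplyr::group_by(.data$sample_id, .data$priming, .data$challenge,
                    .data$gene, .data$bio_rep) |>
    dplyr::summarise(
      n_tech = dplyr::n(),
      flag_spread = (max(.data$ct) - min(.data$ct)) > tolerance,
      ct = mean(.data$ct),
      .groups = "drop"
    )
}

#' Relative expression by the 2^-ddCt (Livak) method
#'
#' For each treatment cell and biological replicate r:
#' `dCt = Ct_target - Ct_reference`, `ddCt = dCt - dCt(calibrator, r)`,
#' `RQ = 2^-ddCt`. By default the calibration is per replicate (replicate r
#' of each cell is paired with replicate r of the calibrator cell, matching
#' a design of independent experiments); with
#' `per_replicate = FALSE`, or when a calibrator replicate is missing
#' (warning), the calibrator's mean dCt is used instead. Perfect doubling
#' per cycle is assumed; measured primer efficiencies are QC only
#' (see [standard_curve_efficiency()]).
#'
#' @param ct Long-format Ct tibble (see [average_technical_reps()];
#'   technical replicates are averaged internally if still present).
#' @param target_gene Gene to quantify.
#' @param reference_gene Housekeeping reference (default `"rp49"`).
#' @param calibrator Length-2 character vector `c(priming, challenge)` of
#'   the calibrator cell (default untreated `naive`/`naive`).
#' @param per_replicate Calibrate within each biological replicate
#'   (default) or against the pooled calibrator mean dCt.
#' @return A tibble of class `sod_rq`, one row per treatment cell:
#'   `priming`, `challenge`, `gene`, `n_rep`, `rq_reps` (list column of
#'   per-replicate RQ), `rq_mean`, `rq_se` (SE on the linear scale,
#'   `sd/sqrt(n)`), plus `log2_rq_mean`/`log2_rq_se`.
#' @export
relative_expression <- function(ct, target_gene, reference_gene = "rp49",
                                calibrator = c("naive", "naive"),
                                per_replicate = TRUE) {
  stopifnot(length(calibrator) == 2L)
  averaged <- average_technical_reps(ct)
  pick <- function(gene) {
    averaged |>
      dplyr::filter(.data$gene == !!gene) |>
      dplyr::select("priming", "challenge", "bio_rep", ct = "ct")
  }
  tgt <- pick(target_gene)
  ref <- pick(reference_gene)
  if (nrow(tgt) == 0L) stop("no Ct rows for target gene '", target_gene, "'", call. = FALSE)
  if (nrow(ref) == 0L) stop("no Ct rows for reference gene '", reference_gene, "'", call. = FALSE)

  dct <- dplyr::inner_join(tgt, ref, by = c("priming", "challenge", "bio_rep"),
                           suffix = c("_target", "_ref")) |>
    dplyr::mutate(dct = .data$ct_target - .data$ct_ref)
  lost <- dplyr::anti_join(tgt, ref, by = c("priming", "challenge", "bio_rep"))
  if (nrow(lost) > 0L) {
    stop("missing reference Ct for ", nrow(lost), " target observation(s) of '",
         target_gene, "'", call. = FALSE)
  }

  cal <- dplyr::filter(dct, .data$priming == calibrator[1],
                       .data$challenge == calibrator[2])
  if (nrow(cal) == 0L) {
    stop("calibrator cell ", calibrator[1], "/", calibrator[2],
         " absent from Ct table", call. = FALSE)
  }
  cal_mean <- mean(cal$dct)

  if (per_replicate) {
    out <- dct |>
      dplyr::left_join(dplyr::select(cal, "bio_rep", cal_dct = "dct"),
                       by = "bio_rep")
    if (anyNA(out$cal_dct)) {
      warning("calibrator replicate missing for some biological replicates; ",
              "falling back to the calibrator mean dCt", call. = FALSE)
      out$cal_dct[is.na(out$cal_dct)] <- cal_mean
    }
  } else {
    out <- dplyr::mutate(dct, cal_dct = cal_mean)
  }

  res <- out |>
    dplyr::mutate(rq = 2^(-(.data$dct - .data$cal_dct))) |>
    dplyr::group_by(.data$priming, .data$challenge) |>
    dplyr::summarise(
      n_rep = dplyr::n(),
      rq_reps = list(.data$rq),
      rq_mean = mean(.data$rq),
      rq_se = ifelse(dplyr::n() > 1, stats::sd(.data$rq) / sqrt(dplyr::n()), NA_real_),
      log2_rq_mean = mean(log2(.data$rq)),
      log2_rq_se = ifelse(dplyr::n() > 1, stats::sd(log2(.data$rq)) / sqrt(dplyr::n()), NA_real_),
      .groups = "drop"
    ) |>
    dplyr::mutate(gene = target_gene, .before = 1)
  class(res) <- c("sod_rq", class(res))
  res
}

#' Primer efficiency from a dilution standard curve
#'
#' Ordinary least squares of Ct on log10 template quantity. The
#' amplification efficiency is the fold amplification per cycle,
#' `10^(-1/slope)` (2.0 for perfect doubling, slope -3.3219); the
#' conventional QC bound accepts curves with efficiency above
#' `qc_threshold` (default 1.9).
#'
#' @param std Tibble with columns `log10_quantity` and `ct` (>= 3 points,
#'   distinct quantities).
#' @param qc_threshold Minimum acceptable efficiency.
#' @return An object of class `sod_std_curve`: `slope`, `intercept`, `r2`,
#'   `efficiency`, `qc_pass`, `n`, and the fitted `lm` object.
#' @examples
#' std <- tibble::tibble(log10_quantity = 0:4,
#'                       ct = 30 - (0:4) / log10(2))
#' standard_curve_efficiency(std)$efficiency  # 2
#' @export
standard_curve_efficiency <- function(std, qc_threshold = 1.9) {
  stopifnot(all(c("log10_quantity", "ct") %in% names(std)))
  if (nrow(std) < 3L) stop("at least 3 dilution points are required", call. = FALSE)
  if (anyDuplicated(std$log10_quantity)) {
    std <- std |>
      dplyr::group_by(.data$log10_quantity) |>
      dplyr::summarise(ct = mean(.data$ct), .groups = "drop")
    if (nrow(std) < 3L) stop("fewer than 3 distinct quantities", call. = FALSE)
  }
  fit <- stats::lm(ct ~ log10_quantity, data = std)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) {
    stop("standard curve slope is not negative (", format(slope),
         "): curve does not reflect amplification", call. = FALSE)
  }
  structure(
    list(
      slope = slope,
      intercept = unname(stats::coef(fit)[1]),
      r2 = 1 - sum(stats::residuals(fit)^2) / sum((std$ct - mean(std$ct))^2),
      efficiency = 10^(-1 / slope),
      qc_pass = 10^(-1 / slope) > qc_threshold,
      qc_threshold = qc_threshold,
      n = nrow(std),
      fit = fit
    ),
    class = "sod_std_curve"
  )
}

#' @export
print.sod_std_curve <- function(x, ...) {
  cat(sprintf(
    "<sod_std_curve> slope %.4f, R^2 %.4f, efficiency %.3f (QC %s, threshold %.2f)\n",
    x$slope, x$r2, x$efficiency, if (x$qc_pass) "pass" else "FAIL", x$qc_threshold
  ))
  invisible(x)
}
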