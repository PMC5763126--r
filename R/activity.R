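#' Percent inhibition of NBT reduction
#'
#' `100 * (A_blank - A_sample) / A_blank`, clamped into \[0, 100\].
#' Negative inhibition (sample absorbance above the blank, i.e. assay
#' noise) is clamped to 0 and flagged via the `clamped` attribute rather
#' than propagated as negative activity. Vectorised.
#'
#' @param a_blank Blank (no-enzyme) absorbance, > 0.
#' @param a_sample Sample absorbance.
#' @return Numeric vector of inhibition percentages with a logical
#'   attribute `clamped` marking values that were clamped.
#' @examples
#' percent_inhibition(0.8, 0.4)  # 50
#' @export
percent_inhibition <- function(a_blank, a_sample) {
  if (any(a_blank <= 0)) stop("blank absorbance must be positive", call. = FALSE)
  raw <- 100 * (a_blank - a_sample) / a_blank
  clamped <- raw < 0 | raw > 100
  out <- pmin(pmax(raw, 0), 100)
  attr(out, "clamped") <- clamped
  out
}

#' Enzyme amount producing 50% inhibition, and the implied activity
#'
#' One unit of SOD activity is the amount of enzyme giving 50% inhibition
#' of NBT reduction. Inhibition readings at duplicate amounts are averaged,
#' the resulting curve must be non-decreasing and must bracket 50%;
#' the 50% point `x50` is then found by piecewise-linear interpolation
#' between the bracketing readings (optionally on a log-amount axis), and
#' the activity of the preparation is `1 / x50` units per amount unit.
#'
#' @param curve Tibble with columns `amount` (strictly increasing after
#'   tie-averaging) and `inhibition_pct` (0-100).
#' @param log_amount Interpolate linearly in `log(amount)` instead of
#'   `amount`.
#' @return A one-row tibble: `x50` (amount at 50% inhibition) and
#'   `units_per_amount` (`1 / x50`).
#' @examples
#' units_at_50_inhibition(tibble::tibble(amount = c(5, 10, 20),
#'                                       inhibition_pct = c(30, 50, 70)))
#' @export
units_at_50_inhibition <- function(curve, log_amount = FALSE) {
  stopifnot(all(c("amount", "inhibition_pct") %in% names(curve)))
  cv <- curve |>
    dplyr::group_by(.data$amount) |>
    dplyr::summarise(inhibition_pct = mean(.data$inhibition_pct), .groups = "drop") |>
    dplyr::arrange(.data$amount)
  if (nrow(cv) < 2L) stop("at least 2 distinct amounts required", call. = FALSE)
  if (any(cv$amount <= 0)) stop("amounts must be positive", call. = FALSE)
  dec <- which(diff(cv$inhibition_pct) < 0)
  if (length(dec) > 0L) {
    stop(sprintf(
      "inhibition curve is not non-decreasing between amount %g (%.3g%%) and %g (%.3g%%)",
      cv$amount[dec[1]], cv$inhibition_pct[dec[1]],
      cv$amount[dec[1] + 1L], cv$inhibition_pct[dec[1] + 1L]), call. = FALSE)
  }
  if (min(cv$inhibition_pct) > 50 || max(cv$inhibition_pct) < 50) {
    stop("50% inhibition not bracketed by the curve (range ",
         sprintf("%.3g-%.3g%%", min(cv$inhibition_pct), max(cv$inhibition_pct)),
         ")", call. = FALSE)
  }
  exact <- which(cv$inhibition_pct == 50)
  if (length(exact) > 0L) {
    x50 <- cv$amount[exact[1]]
  } else {
    i <- max(which(cv$inhibition_pct < 50))
    x0 <- cv$amount[i]; x1 <- cv$amount[i + 1L]
    y0 <- cv$inhibition_pct[i]; y1 <- cv$inhibition_pct[i + 1L]
    frac <- (50 - y0) / (y1 - y0)
    x50 <- if (log_amount) {
      exp(log(x0) + frac * (log(x1) - log(x0)))
    } else {
      x0 + frac * (x1 - x0)
    }
  }
  tibble::tibble(x50 = x50, units_per_amount = 1 / x50)
}

#' Total protein concentration by the Lowry method
#'
#' Fits absorbance as an ordinary least-squares straight line in
#' concentration over the standards and inverts it at the sample
#' absorbance. Samples outside the standards' absorbance range are still
#' quantified but flagged as extrapolated.
#'
#' @param standards Tibble with columns `conc` (mg/mL, including a blank)
#'   and `absorbance` (>= 3 standards).
#' @param sample_abs Sample absorbance(s).
#' @return Tibble with one row per sample: `sample_abs`, `conc_mg_per_ml`,
#'   `extrapolated`.
#' @export
lowry_protein_conc <- function(standards, sample_abs) {
  stopifnot(all(c("conc", "absorbance") %in% names(standards)))
  if (nrow(standards) < 3L) stop("at least 3 standards required", call. = FALSE)
  fit <- stats::lm(absorbance ~ conc, data = standards)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) {
    stop("non-positive Lowry standard-curve slope", call. = FALSE)
  }
  intercept <- unname(stats::coef(fit)[1])
  conc <- (sample_abs - intercept) / slope
  rng <- range(standards$absorbance)
  tibble::tibble(
    sample_abs = sample_abs,
    conc_mg_per_ml = conc,
    extrapolated = sample_abs < rng[1] | sample_abs > rng[2]
  )
}

#' Specific activity
#'
#' @param units Enzyme units (U).
#' @param protein_mg Protein amount (mg), > 0.
#' @return Units per milligram protein.
#' @examples
#' specific_activity(10, 2)  # 5
#' @export
specific_activity <- function(units, protein_mg) {
  if (any(protein_mg <= 0)) stop("protein amount must be positive", call. = FALSE)
  units / protein_mg
}

#' Per-sample SOD activity from raw assay and Lowry tables
#'
#' For each sample: computes percent inhibition of every reading, finds the
#' 50%-inhibition amount (in uL of extract), converts to volumetric
#' activity `1/x50` U/uL, estimates total protein from the Lowry standards,
#' and reports the specific activity
#' `units_per_ul * 1000 / protein_mg_per_ml` in U/mg.
#'
#' @param assay Tibble with columns `sample_id`, `amount` (uL extract),
#'   `a_blank`, `a_sample`; optional `priming`/`challenge`/`experiment`
#'   columns are carried through.
#' @param lowry_standards Tibble with `conc` (mg/mL) and `absorbance`.
#' @param lowry_samples Tibble with `sample_id` and `absorbance`.
#' @param log_amount Passed to [units_at_50_inhibition()].
#' @return A tibble of class `sod_activity`, one row per sample: `x50_ul`,
#'   `units_per_ul`, `protein_mg_per_ml`, `specific_activity_u_per_mg`,
#'   `extrapolated`, plus any carried treatment columns.
#' @export
sod_activity <- function(assay, lowry_standards, lowry_samples,
                         log_amount = FALSE) {
  stopifnot(all(c("sample_id", "amount", "a_blank", "a_sample") %in% names(assay)))
  stopifnot(all(c("sample_id", "absorbance") %in% names(lowry_samples)))
  carry <- intersect(c("priming", "challenge", "experiment"), names(assay))
  out <- assay |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(function(d, key) {
      inh <- percent_inhibition(d$a_blank, d$a_sample)
      u <- units_at_50_inhibition(
        tibble::tibble(amount = d$amount, inhibition_pct = as.numeric(inh)),
        log_amount = log_amount
      )
      meta <- d[1, carry, drop = FALSE]
      dplyr::bind_cols(meta, u)
    }) |>
    dplyr::ungroup()
  prot <- lowry_protein_conc(lowry_standards,
                             lowry_samples$absorbance)
  prot$sample_id <- lowry_samples$sample_id
  res <- out |>
    dplyr::left_join(dplyr::select(prot, "sample_id",
                                   protein_mg_per_ml = "conc_mg_per_ml",
                                   "extrapolated"),
                     by = "sample_id") |>
    dplyr::rename(x50_ul = "x50", units_per_ul = "units_per_amount") |>
    dplyr::mutate(
      specific_activity_u_per_mg =
        .data$units_per_ul * 1000 / .data$protein_mg_per_ml
    )
  if (anyNA(res$protein_mg_per_ml)) {
    stop("missing Lowry reading for sample(s): ",
         paste(res$sample_id[is.na(res$protein_mg_per_ml)], collapse = ", "),
         call. = FALSE)
  }
  class(res) <- c("sod_activity", class(res))
  res
}
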