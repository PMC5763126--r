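#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a standard-curve fit
#'
#' @param x A `sod_std_curve` object.
#' @param ... Unused.
#' @return One row per coefficient: `term`, `estimate`.
#' @export
tidy.sod_std_curve <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' One-row summary of a standard-curve fit
#'
#' @param x A `sod_std_curve` object.
#' @param ... Unused.
#' @return Tibble: `slope`, `intercept`, `r2`, `efficiency`, `qc_pass`, `n`.
#' @export
glance.sod_std_curve <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept, r2 = x$r2,
    efficiency = x$efficiency, qc_pass = x$qc_pass, n = x$n
  )
}

#' Tidy a Student-Newman-Keuls result into pairwise decisions
#'
#' @param x A `sod_snk` object.
#' @param ... Unused.
#' @return One row per group pair: `group1`, `group2`, `mean_diff`,
#'   `significant`.
#' @export
tidy.sod_snk <- function(x, ...) {
  labs <- rownames(x$significant)
  means <- stats::setNames(x$means$mean, x$means$group)
  purrr::map_dfr(seq_len(length(labs) - 1L), function(i) {
    purrr::map_dfr((i + 1L):length(labs), function(j) {
      tibble::tibble(
        group1 = labs[i], group2 = labs[j],
        mean_diff = unname(means[labs[j]] - means[labs[i]]),
        significant = x$significant[i, j]
      )
    })
  })
}

#' One-row summary of a Student-Newman-Keuls result
#'
#' @param x A `sod_snk` object.
#' @param ... Unused.
#' @return Tibble: `k`, `df_within`, `ms_within`, `n_harmonic`, `alpha`,
#'   `n_significant`.
#' @export
glance.sod_snk <- function(x, ...) {
  tibble::tibble(
    k = nrow(x$means), df_within = x$df_within, ms_within = x$ms_within,
    n_harmonic = x$n_harmonic, alpha = x$alpha,
    n_significant = sum(x$significant[upper.tri(x$significant)])
  )
}

#' Tidy a pairwise Wilcoxon result
#'
#' @param x A `sod_pairwise_wilcoxon` object.
#' @param ... Unused.
#' @return One row per pair: `group1`, `group2`, `p_value`, `p_holm`.
#' @export
tidy.sod_pairwise_wilcoxon <- function(x, ...) {
  labs <- rownames(x$p_raw)
  purrr::map_dfr(seq_len(length(labs) - 1L), function(i) {
    purrr::map_dfr((i + 1L):length(labs), function(j) {
      tibble::tibble(
        group1 = labs[i], group2 = labs[j],
        p_value = x$p_raw[i, j], p_holm = x$p_holm[i, j]
      )
    })
  })
}
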