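# Cache for studentized-range quantiles (they are expensive to invert and
# requested repeatedly with identical arguments during SNK sweeps).
.srq_cache <- new.env(parent = emptyenv())

# P(range of k iid N(0,1) <= w): k * Int phi(z) [Phi(z) - Phi(z - w)]^(k-1) dz
.prange <- function(w, k) {
  if (w <= 0) return(0)
  f <- function(z) {
    k * stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - w))^(k - 1)
  }
  stats::integrate(f, -Inf, Inf, rel.tol = 1e-9)$value
}

#' CDF of the studentized range distribution
#'
#' `P(Q <= q)` for the range of `k` independent standard normals divided by
#' an independent scale estimate `s` with `df` degrees of freedom.
#' Computed by direct double numerical integration: the inner range
#' probability is an adaptive integral over the normal density, the outer
#' integral over the chi-distributed scale uses Gauss-Legendre quadrature.
#' `df = Inf` collapses to the plain normal-range CDF.
#'
#' @param q Quantile (scalar, > 0 for a non-trivial value).
#' @param k Number of groups spanned (>= 2).
#' @param df Error degrees of freedom (>= 1, may be `Inf`).
#' @param nodes Number of Gauss-Legendre nodes for the scale integral.
#' @return Probability in \[0, 1\].
#' @export
pstudrange <- function(q, k, df, nodes = 96L) {
  stopifnot(k >= 2, df >= 1)
  if (q <= 0) return(0)
  if (!is.finite(df) || df > 1e5) return(.prange(q, k))
  s_max <- sqrt(stats::qchisq(1 - 1e-13, df) / df)
  gl <- pracma::gaussLegendre(nodes, 0, s_max)
  # chi-scale density: s = sqrt(chi^2_df / df), evaluated in log space
  log_f <- (df / 2) * log(df) + (df - 1) * log(gl$x) - df * gl$x^2 / 2 -
    (df / 2 - 1) * log(2) - lgamma(df / 2)
  inner <- vapply(gl$x, function(s) .prange(q * s, k), numeric(1))
  sum(gl$w * exp(log_f) * inner)
}

#' Upper-alpha quantile of the studentized range distribution
#'
#' The critical value `q(alpha, k, df)` used by the Student-Newman-Keuls
#' procedure, obtained by bisection inversion of [pstudrange()] to an
#' absolute tolerance of 1e-5 on the quantile.
#'
#' @param alpha Significance level in (0, 1).
#' @param k Range size (number of ordered means spanned), >= 2.
#' @param df Error degrees of freedom (>= 1, may be `Inf`).
#' @param tol Bisection tolerance on the quantile.
#' @return The critical value `q` such that `P(Q > q) = alpha`.
#' @examples
#' studentized_range_quantile(0.05, 2, Inf)  # sqrt(2) * 1.95996... = 2.7718
#' @export
studentized_range_quantile <- function(alpha, k, df, tol = 1e-5) {
  stopifnot(alpha > 0, alpha < 1, k >= 2, df >= 1)
  key <- paste(format(alpha, digits = 12), k, format(df, digits = 12), sep = "|")
  hit <- .srq_cache[[key]]
  if (!is.null(hit)) return(hit)
  target <- 1 - alpha
  lo <- 0; hi <- 10
  while (pstudrange(hi, k, df) < target) {
    hi <- hi * 2
    if (hi > 1e4) stop("studentized-range inversion failed to bracket; ",
                       "P(", hi, ") still below ", target, call. = FALSE)
  }
  it <- 0L
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pstudrange(mid, k, df) < target) lo <- mid else hi <- mid
    it <- it + 1L
    if (it > 200L) stop("studentized-range bisection did not converge below ",
                        format(hi - lo), call. = FALSE)
  }
  q <- (lo + hi) / 2
  .srq_cache[[key]] <- q
  q
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA (between/within mean-square
#' ratio), delegated to [stats::aov()].
#'
#' @param data Data frame with one observation per row.
#' @param value Bare name of the numeric response column.
#' @param group Bare name of the grouping column.
#' @return A one-row tibble: `statistic` (F), `df_between`, `df_within`,
#'   `p_value`, `ms_within`, `n`, `k`.
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), each = 2), y = c(1, 2, 3, 4))
#' one_way_anova(d, y, g)  # F = 8 on (1, 2) df
#' @export
one_way_anova <- function(data, value, group) {
  value <- rlang::ensym(value); group <- rlang::ensym(group)
  y <- dplyr::pull(data, !!value)
  g <- factor(dplyr::pull(data, !!group))
  if (nlevels(g) < 2L) stop("ANOVA requires at least 2 groups", call. = FALSE)
  if (any(table(g) < 1L)) stop("empty group", call. = FALSE)
  n <- length(y); k <- nlevels(g)
  if (n - k < 1L) stop("no residual degrees of freedom (single observation per group?)",
                       call. = FALSE)
  fit <- stats::aov(y ~ g)
  tab <- summary(fit)[[1]]
  msw <- tab["Residuals", "Mean Sq"]
  if (!is.finite(msw) || msw <= 1e-10 * (stats::var(y) + .Machine$double.xmin)) {
    stop("zero within-group variance: F statistic is degenerate", call. = FALSE)
  }
  tibble::tibble(
    statistic = tab[1, "F value"],
    df_between = tab[1, "Df"],
    df_within = tab["Residuals", "Df"],
    p_value = tab[1, "Pr(>F)"],
    ms_within = msw,
    n = n, k = k
  )
}

#' Student-Newman-Keuls post hoc comparison
#'
#' Sorts the group means and tests ranges stepwise from the widest to the
#' narrowest: the span of `p` ordered means is significant when the
#' difference between its extreme means exceeds
#' `q(alpha, p, df_error) * sqrt(MSE / n~)`, with `n~` the harmonic mean
#' group size (the standard extension to unbalanced groups). Once a span
#' is declared non-significant, every span nested inside it is declared
#' non-significant without testing (stepwise closure), which keeps the
#' decision set internally consistent.
#'
#' @inheritParams one_way_anova
#' @param alpha Familywise level of each stepwise test (default 0.05).
#' @return An object of class `sod_snk`: `means` (ordered group means with
#'   sizes), `significant` (symmetric logical matrix over group labels),
#'   `q_crit` (critical values per span width), `alpha`, `ms_within`,
#'   `df_within`, `n_harmonic`. Use [generics::tidy()] for a pairwise
#'   tibble.
#' @export
snk_posthoc <- function(data, value, group, alpha = 0.05) {
  value <- rlang::ensym(value); group <- rlang::ensym(group)
  av <- one_way_anova(data, !!value, !!group)
  y <- dplyr::pull(data, !!value)
  g <- factor(dplyr::pull(data, !!group))
  k <- nlevels(g)
  means <- tapply(y, g, mean)
  sizes <- as.integer(table(g))
  ord <- order(means)
  m_sorted <- means[ord]
  labels <- levels(g)[ord]
  n_h <- k / sum(1 / sizes)
  se <- sqrt(av$ms_within / n_h)

  q_crit <- vapply(2:k, function(p) {
    studentized_range_quantile(alpha, p, av$df_within)
  }, numeric(1))
  names(q_crit) <- as.character(2:k)

  nonsig <- matrix(FALSE, k, k)  # over sorted positions; TRUE = declared NS
  sig <- matrix(FALSE, k, k)
  if (k >= 2) {
    for (p in k:2) {
      for (i in seq_len(k - p + 1L)) {
        j <- i + p - 1L
        if (nonsig[i, j]) next
        diff <- m_sorted[j] - m_sorted[i]
        if (diff >= q_crit[as.character(p)] * se) {
          sig[i, j] <- sig[j, i] <- TRUE
        } else {
          # closure: protect all nested spans
          for (a in i:j) for (b in i:j) nonsig[a, b] <- TRUE
        }
      }
    }
  }
  dimnames(sig) <- list(labels, labels)
  # re-order the matrix to the original factor level order
  sig <- sig[levels(g), levels(g)]
  structure(
    list(
      means = tibble::tibble(group = labels, mean = unname(m_sorted),
                             n = sizes[ord]),
      significant = sig,
      q_crit = q_crit,
      alpha = alpha,
      ms_within = av$ms_within,
      df_within = av$df_within,
      n_harmonic = n_h,
      anova = av
    ),
    class = "sod_snk"
  )
}

#' @export
print.sod_snk <- function(x, ...) {
  cat(sprintf("<sod_snk> %d groups, alpha %.3f, df %g, MSE %.4g\n",
              nrow(x$means), x$alpha, x$df_within, x$ms_within))
  print(x$means)
  cat("significant pairs:",
      sum(x$significant[upper.tri(x$significant)]), "\n")
  invisible(x)
}

#' Pairwise Wilcoxon rank-sum tests
#'
#' Two-sided Wilcoxon rank-sum tests for every pair of groups: exact
#' enumeration when both samples have at most `exact_max` observations and
#' no ties across the pair, otherwise the normal approximation with tie
#' correction (both via [stats::wilcox.test()]). Raw and Holm-adjusted
#' p-value matrices are returned; raw p-values are the default report.
#'
#' @inheritParams one_way_anova
#' @param exact_max Largest per-group size for which the exact distribution
#'   is enumerated (default 8).
#' @return An object of class `sod_pairwise_wilcoxon`: symmetric matrices
#'   `p_raw` and `p_holm` (diagonal `NA`), plus the group sizes.
#' @export
pairwise_wilcoxon <- function(data, value, group, exact_max = 8L) {
  value <- rlang::ensym(value); group <- rlang::ensym(group)
  y <- dplyr::pull(data, !!value)
  g <- factor(dplyr::pull(data, !!group))
  if (nlevels(g) < 2L) stop("at least 2 groups required", call. = FALSE)
  if (any(table(g) == 0L)) stop("empty group", call. = FALSE)
  lv <- levels(g)
  k <- length(lv)
  p_raw <- matrix(NA_real_, k, k, dimnames = list(lv, lv))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      a <- y[g == lv[i]]; b <- y[g == lv[j]]
      use_exact <- length(a) <= exact_max && length(b) <= exact_max &&
        !anyDuplicated(c(a, b))
      p <- suppressWarnings(
        stats::wilcox.test(a, b, exact = use_exact, correct = !use_exact,
                           alternative = "two.sided")$p.value
      )
      p_raw[i, j] <- p_raw[j, i] <- p
    }
  }
  up <- upper.tri(p_raw)
  holm <- p_raw
  holm[up] <- stats::p.adjust(p_raw[up], method = "holm")
  holm[lower.tri(holm)] <- t(holm)[lower.tri(holm)]
  structure(
    list(p_raw = p_raw, p_holm = holm,
         sizes = as.integer(table(g))),
    class = "sod_pairwise_wilcoxon"
  )
}

#' @export
print.sod_pairwise_wilcoxon <- function(x, ...) {
  cat("<sod_pairwise_wilcoxon> raw p-values:\n")
  print(round(x$p_raw, 4))
  invisible(x)
}

#' Survival proportions per treatment across experiments
#'
#' Computes the per-experiment survival proportion for each treatment cell
#' and summarises it as mean +/- SE across independent experiments
#' (`SE = sd / sqrt(n)`). With a single experiment the SE is undefined and
#' reported as `NA` with `flag_single_experiment` set.
#'
#' @param counts Tibble with columns `priming`, `challenge`, `experiment`,
#'   `alive`, `total`.
#' @return A tibble of class `sod_survival`, one row per treatment cell:
#'   `n_experiments`, `proportions` (list column), `mean`, `se`,
#'   `flag_single_experiment`.
#' @export
survival_proportions <- function(counts) {
  needed <- c("priming", "challenge", "experiment", "alive", "total")
  stopifnot(all(needed %in% names(counts)))
  if (any(counts$total <= 0)) stop("total must be positive", call. = FALSE)
  if (any(counts$alive > counts$total)) {
    stop("alive count exceeds total", call. = FALSE)
  }
  out <- counts |>
    dplyr::mutate(prop = .data$alive / .data$total) |>
    dplyr::group_by(.data$priming, .data$challenge) |>
    dplyr::summarise(
      n_experiments = dplyr::n(),
      proportions = list(.data$prop),
      mean = mean(.data$prop),
      se = ifelse(dplyr::n() > 1, stats::sd(.data$prop) / sqrt(dplyr::n()), NA_real_),
      flag_single_experiment = dplyr::n() == 1L,
      .groups = "drop"
    )
  class(out) <- c("sod_survival", class(out))
  out
}
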