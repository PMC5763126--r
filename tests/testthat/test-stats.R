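grp <- function(...) {
  vals <- list(...)
  tibble::tibble(
    g = rep(paste0("g", seq_along(vals)), lengths(vals)),
    y = unlist(vals)
  )
}

test_that("one-way ANOVA matches hand computation and handles degeneracy", {
  a <- one_way_anova(grp(c(1, 2), c(3, 4)), y, g)
  expect_equal(a$statistic, 8)          # SSB = 4, SSW = 1, df (1, 2)
  expect_equal(a$df_between, 1)
  expect_equal(a$df_within, 2)

  b <- one_way_anova(grp(c(1, 2, 3), c(1, 2, 3)), y, g)
  expect_equal(b$statistic, 0)
  expect_equal(b$p_value, 1)

  expect_error(one_way_anova(grp(c(1, 1), c(2, 2)), y, g), "zero within-group")
  expect_error(one_way_anova(grp(1, 2), y, g), "degrees of freedom")
  expect_error(one_way_anova(tibble::tibble(g = "a", y = 1), y, g), "2 groups")
})

test_that("studentized range quantile satisfies the k = 2 t identity", {
  # q(alpha, 2, nu) = sqrt(2) * t_{1 - alpha/2, nu}, to 4 significant digits
  for (nu in c(5, 10, 30, 120)) {
    q <- studentized_range_quantile(0.05, 2, nu)
    expect_equal(signif(q, 4), signif(sqrt(2) * stats::qt(0.975, nu), 4))
  }
  expect_equal(signif(studentized_range_quantile(0.05, 2, Inf), 4),
               signif(sqrt(2) * stats::qnorm(0.975), 4))
})

test_that("studentized range quantile agrees with the reference implementation", {
  cases <- expand.grid(alpha = c(0.05, 0.01), k = c(3, 4, 6), df = c(5, 10, 40))
  for (i in seq_len(nrow(cases))) {
    q <- studentized_range_quantile(cases$alpha[i], cases$k[i], cases$df[i])
    expect_equal(q, stats::qtukey(1 - cases$alpha[i], cases$k[i], cases$df[i]),
                 tolerance = 1e-3)
  }
  expect_equal(studentized_range_quantile(0.05, 3, 10), 3.88, tolerance = 1e-3)
})

test_that("the studentized range CDF inverts its own quantile", {
  q <- studentized_range_quantile(0.1, 4, 12)
  expect_equal(pstudrange(q, 4, 12), 0.9, tolerance = 1e-4)
})

test_that("SNK declares nothing on identical groups", {
  snk <- snk_posthoc(grp(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)), y, g)
  expect_false(any(snk$significant))
})

test_that("SNK with two groups reproduces the pooled t-test decision", {
  set.seed(61)
  for (i in 1:60) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    d <- grp(rnorm(n1, 0, 1), rnorm(n2, sample(c(0, 1.5), 1), 1))
    snk <- snk_posthoc(d, y, g, alpha = 0.05)
    tt <- t.test(y ~ g, data = d, var.equal = TRUE)
    expect_equal(unname(snk$significant[1, 2]), tt$p.value < 0.05)
  }
})

test_that("SNK flags an outlying mean but protects the inner pair", {
  spread <- c(-0.1, -0.05, 0, 0.05, 0.1)
  d <- grp(spread, spread + 0.1, spread + 10)
  snk <- snk_posthoc(d, y, g)
  expect_true(snk$significant["g1", "g3"])
  expect_true(snk$significant["g2", "g3"])
  expect_false(snk$significant["g1", "g2"])
  td <- generics::tidy(snk)
  expect_equal(sum(td$significant), 2)
})

test_that("SNK closure: pairs nested in a non-significant range stay non-significant", {
  set.seed(17)
  for (i in 1:40) {
    k <- sample(3:5, 1)
    d <- tibble::tibble(
      g = rep(paste0("g", 1:k), each = 6),
      y = rnorm(6 * k, mean = rep(runif(k, 0, 2), each = 6))
    )
    snk <- snk_posthoc(d, y, g)
    m <- sort(tapply(d$y, d$g, mean))
    labs <- names(m)
    # for every non-significant span, all nested pairs must be non-significant
    for (i1 in 1:(k - 1)) {
      for (j1 in (i1 + 1):k) {
        if (!snk$significant[labs[i1], labs[j1]]) {
          for (a in i1:(j1 - 1)) for (b in (a + 1):j1) {
            expect_false(snk$significant[labs[a], labs[b]])
          }
        }
      }
    }
    expect_true(isSymmetric(unname(snk$significant * 1)))
  }
})

test_that("pairwise Wilcoxon is exact for small samples and symmetric", {
  d <- grp(c(1, 2, 3), c(4, 5, 6))
  wx <- pairwise_wilcoxon(d, y, g)
  expect_equal(wx$p_raw["g1", "g2"], 0.1)
  expect_equal(wx$p_raw, t(wx$p_raw))

  ident <- grp(c(1, 2, 3), c(1, 2, 3))
  expect_equal(pairwise_wilcoxon(ident, y, g)$p_raw["g1", "g2"], 1)
})

test_that("exact Wilcoxon p equals full enumeration for all small group sizes", {
  set.seed(29)
  for (i in 1:60) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    vals <- sample(1000, n1 + n2)  # no ties
    x <- vals[seq_len(n1)]; y0 <- vals[-seq_len(n1)]
    d <- grp(x, y0)
    wx <- pairwise_wilcoxon(d, y, g)
    expect_equal(wx$p_raw["g1", "g2"], oracle_wilcoxon_p(x, y0))
  }
})

test_that("Holm adjustment never decreases a p-value", {
  set.seed(41)
  d <- grp(rnorm(5), rnorm(5, 2), rnorm(5, 4))
  wx <- pairwise_wilcoxon(d, y, g)
  up <- upper.tri(wx$p_raw)
  expect_true(all(wx$p_holm[up] >= wx$p_raw[up]))
  td <- generics::tidy(wx)
  expect_equal(nrow(td), 3)
})

test_that("survival proportions summarise across experiments", {
  counts <- tibble::tibble(
    priming = "hkBt1", challenge = "Bt1", experiment = 1:3,
    alive = c(8L, 9L, 10L), total = 10L
  )
  s <- survival_proportions(counts)
  expect_equal(s$mean, 0.9)
  expect_equal(s$se, sd(c(0.8, 0.9, 1.0)) / sqrt(3))

  single <- counts[1, ]
  single$alive <- 5L
  s1 <- survival_proportions(single)
  expect_equal(s1$mean, 0.5)
  expect_true(is.na(s1$se))
  expect_true(s1$flag_single_experiment)

  zero <- dplyr::mutate(counts, alive = 0L)
  s0 <- survival_proportions(zero)
  expect_equal(s0$mean, 0)
  expect_equal(s0$se, 0)

  expect_error(survival_proportions(dplyr::mutate(counts, alive = 11L)), "exceeds")
})
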