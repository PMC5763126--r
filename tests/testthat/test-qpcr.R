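make_ct <- function(cells, targets = "soda", ref = "rp49") {
  # cells: tibble(priming, challenge, bio_rep, gene, ct) in long form
  dplyr::mutate(cells,
                sample_id = paste(priming, challenge, bio_rep, sep = "_"),
                tech_rep = 1L)
}

test_that("technical replicates average with a 0.5-cycle spread flag", {
  ct <- tibble::tibble(
    sample_id = "s1", priming = "naive", challenge = "naive",
    gene = "soda", bio_rep = 1L, tech_rep = c(1L, 2L), ct = c(20.0, 20.4)
  )
  av <- average_technical_reps(ct)
  expect_equal(av$ct, 20.2)
  expect_false(av$flag_spread)

  ct$ct <- c(20.0, 21.0)
  av2 <- average_technical_reps(ct)
  expect_equal(av2$ct, 20.5)
  expect_true(av2$flag_spread)

  single <- ct[1, ]
  single$ct <- 25.0
  expect_equal(average_technical_reps(single)$ct, 25.0)

  bad <- ct; bad$ct[1] <- -1
  expect_error(average_technical_reps(bad), "positive")
})

test_that("the Livak chain reproduces hand-computed relative expressions", {
  # calibrator dCt = 6 (26 - 20); test cell dCt = 4 -> ddCt = -2 -> RQ = 4
  ct <- make_ct(tibble::tibble(
    priming = c("naive", "naive", "hkBt1", "hkBt1"),
    challenge = c("naive", "naive", "naive", "naive"),
    bio_rep = 1L,
    gene = c("soda", "rp49", "soda", "rp49"),
    ct = c(26, 20, 24, 20)
  ))
  rq <- relative_expression(ct, "soda")
  expect_equal(rq$rq_mean[rq$priming == "hkBt1"], 4)
  expect_equal(rq$rq_mean[rq$priming == "naive"], 1)

  # target 1 cycle lower than calibrator, reference unchanged -> RQ 2
  ct2 <- make_ct(tibble::tibble(
    priming = c("naive", "naive", "PBS", "PBS"),
    challenge = "naive", bio_rep = 1L,
    gene = c("soda", "rp49", "soda", "rp49"),
    ct = c(25, 20, 24, 20)
  ))
  rq2 <- relative_expression(ct2, "soda")
  expect_equal(rq2$rq_mean[rq2$priming == "PBS"], 2)
})

test_that("the calibrator cell has per-replicate RQ exactly 1", {
  q <- generate_qpcr_dataset(31, default_fold_changes(), noise_sd = 0.3)
  rq <- relative_expression(q$ct, "soda")
  cal <- rq[rq$priming == "naive" & rq$challenge == "naive", ]
  expect_equal(cal$rq_reps[[1]], rep(1, 3))
  expect_equal(cal$rq_mean, 1)
})

test_that("RQ is invariant to a constant Ct shift of one gene", {
  q <- generate_qpcr_dataset(17, default_fold_changes(), noise_sd = 0.2)
  rq1 <- relative_expression(q$ct, "sodb")
  shifted <- dplyr::mutate(q$ct, ct = ifelse(gene == "sodb", ct + 3.7, ct))
  rq2 <- relative_expression(shifted, "sodb")
  expect_equal(rq1$rq_mean, rq2$rq_mean)
  expect_equal(rq1$rq_se, rq2$rq_se)
})

test_that("per-replicate and pooled calibration agree on noiseless data", {
  q <- generate_qpcr_dataset(3, default_fold_changes(), noise_sd = 0)
  a <- relative_expression(q$ct, "atta2", per_replicate = TRUE)
  b <- relative_expression(q$ct, "atta2", per_replicate = FALSE)
  expect_equal(a$rq_mean, b$rq_mean)
  truth <- default_fold_changes() |> dplyr::filter(gene == "atta2")
  m <- dplyr::left_join(as.data.frame(a), truth, by = c("priming", "challenge"))
  expect_equal(m$rq_mean, m$fold)
})

test_that("missing reference or calibrator rows are reported", {
  ct <- make_ct(tibble::tibble(
    priming = c("naive", "PBS", "PBS"), challenge = "naive", bio_rep = 1L,
    gene = c("soda", "soda", "rp49"), ct = c(26, 24, 20)
  ))
  expect_error(relative_expression(ct, "soda"), "missing reference Ct")

  ct2 <- make_ct(tibble::tibble(
    priming = c("PBS", "PBS"), challenge = "naive", bio_rep = 1L,
    gene = c("soda", "rp49"), ct = c(24, 20)
  ))
  expect_error(relative_expression(ct2, "soda"), "calibrator")
})

test_that("a missing calibrator replicate falls back to the mean dCt with a warning", {
  q <- generate_qpcr_dataset(5, default_fold_changes(), noise_sd = 0.1)
  ct <- dplyr::filter(q$ct, !(priming == "naive" & challenge == "naive" & bio_rep == 3))
  expect_warning(rq <- relative_expression(ct, "soda"), "calibrator replicate missing")
  expect_true(all(is.finite(rq$rq_mean)))
})

test_that("standard-curve efficiency follows the closed form", {
  # perfect doubling: slope -1/log10(2) -> efficiency exactly 2
  std <- tibble::tibble(log10_quantity = 0:4, ct = 30 - (0:4) / log10(2))
  sc <- standard_curve_efficiency(std)
  expect_equal(sc$efficiency, 2, tolerance = 1e-12)
  expect_true(sc$qc_pass)
  expect_equal(sc$slope, -1 / log10(2), tolerance = 1e-12)
  expect_equal(sc$r2, 1)

  std2 <- tibble::tibble(log10_quantity = 0:3, ct = 30 - 3.45 * (0:3))
  sc2 <- standard_curve_efficiency(std2)
  expect_equal(sc2$efficiency, 10^(1 / 3.45), tolerance = 1e-12)
  expect_equal(round(sc2$efficiency, 3), 1.949)
  expect_true(sc2$qc_pass)

  expect_error(
    standard_curve_efficiency(tibble::tibble(log10_quantity = 0:3, ct = 30 + (0:3))),
    "not negative"
  )
  expect_error(
    standard_curve_efficiency(tibble::tibble(log10_quantity = 0:1, ct = c(30, 27))),
    "3 dilution points"
  )
  g <- generics::glance(sc)
  expect_equal(g$efficiency, 2, tolerance = 1e-12)
})
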