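test_that("segregation chi-square matches closed-form arithmetic", {
  # oracle: plain Pearson arithmetic for 212:82 against 3:1
  exp_dom <- 294 * 3 / 4
  exp_rec <- 294 * 1 / 4
  chisq_oracle <- (212 - exp_dom)^2 / exp_dom + (82 - exp_rec)^2 / exp_rec
  p_oracle <- pchisq(chisq_oracle, df = 1, lower.tail = FALSE)

  res <- segregation_test(212, 82)
  fit31 <- res$fits[res$fits$ratio == "3:1", ]
  expect_equal(fit31$chisq, chisq_oracle, tolerance = 1e-12)
  expect_equal(fit31$chisq, 1.3107, tolerance = 1e-4)
  expect_equal(fit31$p_value, p_oracle, tolerance = 1e-12)
  expect_equal(fit31$p_value, 0.2523, tolerance = 5e-4)
  expect_equal(fit31$df, 1L)

  # among the candidate Mendelian ratios, 3:1 fits best and is not rejected
  expect_equal(res$best_ratio, "3:1")
  expect_gt(fit31$p_value, 0.05)

  # a perfect 3:1 draw gives exactly zero
  expect_equal(
    segregation_test(75, 25, "3:1")$fits$chisq, 0
  )
})

test_that("segregation test is symmetric under class relabelling", {
  a <- segregation_test(212, 82, "3:1")$fits
  b <- segregation_test(82, 212, "1:3")$fits
  expect_equal(a$chisq, b$chisq)
  expect_equal(a$p_value, b$p_value)
  expect_error(segregation_test(0, 0), "not")
  expect_error(segregation_test(10, 5, "3:0"), "invalid ratio")
})

test_that("a true 3:1 cross is rejected at the nominal 5% rate", {
  set.seed(2024)
  n <- 294L
  reps <- 1000L
  dom <- rbinom(reps, n, 0.75)
  exp_dom <- n * 0.75
  exp_rec <- n * 0.25
  chisq <- (dom - exp_dom)^2 / exp_dom + ((n - dom) - exp_rec)^2 / exp_rec
  rate <- mean(pchisq(chisq, 1, lower.tail = FALSE) < 0.05)
  expect_lt(abs(rate - 0.05), 0.02)

  # spot-check one replicate against the package implementation
  one <- segregation_test(dom[1], n - dom[1], "3:1")$fits
  expect_equal(one$chisq, chisq[1], tolerance = 1e-12)
})

ct_table <- function(dct_by_sample, groups, target = "BraX",
                     reference = "BrActin", ref_ct = 20) {
  samples <- names(dct_by_sample)
  dplyr::bind_rows(
    tibble::tibble(
      sample = samples, group = groups, gene = target,
      ct = ref_ct + unlist(dct_by_sample)
    ),
    tibble::tibble(
      sample = samples, group = groups, gene = reference, ct = ref_ct
    )
  )
}

test_that("2^-ddCt recovers the textbook cases", {
  # identical target and reference Ct everywhere -> relative expression 1
  ct <- ct_table(c(s1 = 0, s2 = 0, s3 = 0), c("A", "A", "B"))
  res <- relative_expression(ct, "BrActin", calibrator = "s1")
  expect_equal(res$samples$rel_expr, c(1, 1, 1))

  # one cycle below the calibrator -> 2-fold expression
  ct <- ct_table(c(cal = 0, s2 = -1), c("A", "B"))
  res <- relative_expression(ct, "BrActin", calibrator = "cal")
  expect_equal(res$samples$rel_expr[res$samples$sample == "s2"], 2)
  expect_equal(res$samples$rel_expr[res$samples$sample == "cal"], 1)
})

test_that("relative expression is invariant to a global Ct shift", {
  set.seed(11)
  ct <- ct_table(
    setNames(rnorm(6), paste0("s", 1:6)),
    rep(c("W30", "082", "F1"), each = 2)
  )
  res1 <- relative_expression(ct, "BrActin", calibrator = "082")
  ct2 <- ct
  ct2$ct <- ct2$ct + 3.7
  res2 <- relative_expression(ct2, "BrActin", calibrator = "082")
  expect_equal(res1$samples$rel_expr, res2$samples$rel_expr)

  # technical replicates are averaged before dCt
  ct3 <- dplyr::bind_rows(ct, ct)
  res3 <- relative_expression(ct3, "BrActin", calibrator = "082")
  expect_equal(sort(res3$samples$rel_expr), sort(res1$samples$rel_expr))
})

test_that("samples without a reference Ct are excluded with a warning", {
  ct <- ct_table(c(s1 = 0, s2 = -1), c("A", "B"))
  ct <- ct[!(ct$sample == "s2" & ct$gene == "BrActin"), ]
  expect_warning(
    res <- relative_expression(ct, "BrActin", calibrator = "s1"),
    "s2"
  )
  expect_equal(res$samples$sample, "s1")
  suppressWarnings(expect_error(
    relative_expression(ct, "BrActin", calibrator = "nobody"),
    "nobody"
  ))
})

test_that("Tukey letters separate exactly the significantly different groups", {
  # identical observations: a single shared letter
  y <- rep(5, 9)
  g <- rep(c("a1", "a2", "a3"), each = 3)
  expect_equal(unname(tukey_letters(y, g)), c("a", "a", "a"))

  # zero variance, distinct means: all pairwise different
  y2 <- rep(c(1, 5, 9), each = 3)
  lt2 <- tukey_letters(y2, g)
  expect_equal(length(unique(lt2)), 3L)
  expect_equal(unname(lt2["a3"]), "a") # "a" goes to the largest mean

  # clearly separated groups with noise
  set.seed(3)
  y3 <- c(rnorm(5, 0, 0.1), rnorm(5, 10, 0.1))
  g3 <- rep(c("lo", "hi"), each = 5)
  lt3 <- tukey_letters(y3, g3)
  expect_equal(unname(lt3["hi"]), "a")
  expect_equal(unname(lt3["lo"]), "b")

  # overlapping middle group shares letters with both neighbours
  set.seed(4)
  y4 <- c(rnorm(4, 0, 1), rnorm(4, 1.2, 1), rnorm(4, 8, 1))
  g4 <- rep(c("low", "mid", "high"), each = 4)
  lt4 <- tukey_letters(y4, g4)
  expect_equal(unname(lt4["high"]), "a")
  expect_true(grepl("b", lt4["low"]))
  expect_true(grepl("b", lt4["mid"]))

  # grouping letters flow through relative_expression
  ct <- ct_table(
    setNames(c(0, 0.1, -0.05, 5, 5.1, 4.9), paste0("s", 1:6)),
    rep(c("high", "low"), each = 3)
  )
  res <- relative_expression(ct, "BrActin", calibrator = "s4")
  letters_by_group <- setNames(res$groups$letters, res$groups$group)
  expect_equal(unname(letters_by_group["high"]), "a")
  expect_equal(unname(letters_by_group["low"]), "b")
})
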