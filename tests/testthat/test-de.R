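# Textbook pooled-variance two-sample t-test, the independent oracle for
# the student variant.
oracle_student_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

quant_from_ln <- function(ln_ctrl, ln_trt) {
  design <- make_design()
  q <- tibble::tibble(id = "P1")
  for (i in 1:3) q[[paste0("ctrl_", i)]] <- exp(ln_ctrl[i])
  for (i in 1:3) q[[paste0("trt_", i)]] <- exp(ln_trt[i])
  list(quant = q, design = design)
}

test_that("identical groups give t = 0, p = 1, unchanged", {
  z <- quant_from_ln(c(1, 2, 3), c(1, 2, 3))
  de <- de_test(z$quant, z$design)
  expect_equal(de$t_stat, 0)
  expect_equal(de$p_value, 1)
  expect_equal(de$direction, "unchanged")
})

test_that("a strong shift is detected with the hand-computed t statistic", {
  z <- quant_from_ln(c(-5.0, -5.1, -4.9), c(-3.0, -3.1, -2.9))
  de <- de_test(z$quant, z$design)
  expect_equal(de$t_stat, 24.4949, tolerance = 1e-4)
  expect_equal(de$df, 4)
  expect_lt(de$p_value, 1e-4)
  expect_equal(de$direction, "increased")
})

test_that("the expression ratio is the ratio of linear means", {
  design <- make_design()
  q <- tibble::tibble(id = "P1",
                      ctrl_1 = 0.002, ctrl_2 = 0.002, ctrl_3 = 0.002,
                      trt_1 = 0.004, trt_2 = 0.004, trt_3 = 0.004)
  de <- de_test(q, design)
  expect_equal(de$ratio, 2)
  de_log <- de_test(q, design, ratio_mode = "log")
  expect_equal(de_log$ratio, 2)  # constant vectors: both definitions agree
})

test_that("student p-values match the textbook pooled formula to 1e-10", {
  set.seed(17)
  design <- make_design()
  q <- tibble::tibble(id = paste0("P", 1:30))
  for (s in design$sample_id) q[[s]] <- exp(rnorm(30, -6, 1))
  de <- de_test(q, design, variant = "student")
  for (i in seq_len(nrow(q))) {
    x <- log(as.numeric(q[i, paste0("trt_", 1:3)]))
    y <- log(as.numeric(q[i, paste0("ctrl_", 1:3)]))
    o <- oracle_student_t(x, y)
    expect_equal(de$t_stat[i], o$t, tolerance = 1e-10)
    expect_equal(de$p_value[i], o$p, tolerance = 1e-10)
  }
})

test_that("exchanging condition labels negates t, inverts the ratio, keeps p", {
  set.seed(23)
  design <- make_design()
  q <- tibble::tibble(id = paste0("P", 1:15))
  for (s in design$sample_id) q[[s]] <- exp(rnorm(15, -6, 1))
  fwd <- de_test(q, design, contrast = c("treatment", "control"))
  rev <- de_test(q, design, contrast = c("control", "treatment"))
  expect_equal(rev$t_stat, -fwd$t_stat)
  expect_equal(rev$ratio, 1 / fwd$ratio)
  expect_equal(rev$p_value, fwd$p_value)
})

test_that("degenerate zero-variance rows follow the stated convention", {
  design <- make_design()
  q <- tibble::tibble(id = "P1",
                      ctrl_1 = 0.01, ctrl_2 = 0.01, ctrl_3 = 0.01,
                      trt_1 = 0.01, trt_2 = 0.01, trt_3 = 0.01)
  expect_message(de <- de_test(q, design), "zero variance")
  expect_equal(de$t_stat, 0)
  expect_equal(de$p_value, 1)

  q2 <- q
  q2[, paste0("trt_", 1:3)] <- 0.02
  de2 <- suppressMessages(de_test(q2, design))
  expect_equal(de2$t_stat, Inf)
  expect_equal(de2$p_value, 0)
})

test_that("nonpositive NSpC and >2 unnamed conditions are rejected", {
  design <- make_design()
  q <- tibble::tibble(id = "P1",
                      ctrl_1 = 0, ctrl_2 = 0.01, ctrl_3 = 0.01,
                      trt_1 = 0.01, trt_2 = 0.01, trt_3 = 0.01)
  expect_error(de_test(q, design), "positive")

  design3 <- dplyr::bind_rows(design,
                              tibble::tibble(sample_id = c("x1", "x2"),
                                             condition = "extra"))
  q3 <- q
  q3[1, -1] <- 0.01
  q3$x1 <- 0.01; q3$x2 <- 0.01
  expect_error(de_test(q3, design3), "contrast")
})

test_that("DE summary counts are consistent and respect alpha", {
  set.seed(31)
  design <- make_design()
  q <- tibble::tibble(id = paste0("P", 1:40))
  for (s in design$sample_id) q[[s]] <- exp(rnorm(40, -6, 0.5))
  de <- de_test(q, design)
  s <- summarize_de(de)
  expect_equal(s$n_de, s$n_increased + s$n_decreased)
  expect_identical(glance(de), s)

  all_de <- summarize_de(de, alpha = 1)
  expect_equal(all_de$n_de, all_de$n_tested)

  z <- quant_from_ln(c(1, 2, 3), c(1, 2, 3))
  null_de <- de_test(z$quant, z$design)
  expect_equal(summarize_de(null_de)$n_de, 0)
})

test_that("the welch variant matches stats::t.test with var.equal = FALSE", {
  set.seed(41)
  design <- make_design()
  q <- tibble::tibble(id = paste0("P", 1:10))
  for (s in design$sample_id) q[[s]] <- exp(rnorm(10, -6, 1))
  de <- de_test(q, design, variant = "welch")
  i <- 4
  tt <- t.test(log(as.numeric(q[i, paste0("trt_", 1:3)])),
               log(as.numeric(q[i, paste0("ctrl_", 1:3)])))
  expect_equal(de$p_value[i], tt$p.value)
  expect_equal(de$df[i], unname(tt$parameter))
})
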