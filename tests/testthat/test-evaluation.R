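test_that("accuracy records keep difference and percent mutually consistent", {
  r <- accuracy_record("p1", "IIB", "virtual_vs_model", 40, 40)
  expect_equal(r$difference_mm, 0)
  expect_equal(r$percent, 100)
  r2 <- accuracy_record("p1", "IIB", "virtual_vs_model", 44.12, 43.97)
  expect_equal(round(r2$difference_mm, 2), -0.15)
  expect_equal(round(r2$percent, 2), 99.66)
  r3 <- accuracy_record("p1", "IIB", "virtual_vs_model", 40, 41.2)
  expect_gt(r3$percent, 100)
  expect_gt(r3$difference_mm, 0)
  expect_error(accuracy_record("p1", "IIB", "virtual_vs_model", 0, 40), "positive")
  # consistency identity on random records
  set.seed(67)
  for (rep in 1:20) {
    ref <- runif(1, 20, 60)
    meas <- ref + runif(1, -2, 2)
    r <- accuracy_record("x", NA, "model_vs_patient", ref, meas)
    expect_lt(abs(r$percent - 100 - 100 * r$difference_mm / ref), 1e-9)
  }
})

test_that("difference/percent pairs back-solve to consistent records", {
  tab <- data.frame(case_id = "p1", comparison = "virtual_vs_model",
                    difference_mm = -0.15, percent = 99.66)
  rec <- records_from_difference_percent(tab)
  expect_equal(round(rec$reference_mm, 2), 44.12)
  expect_equal(round(rec$measured_mm, 2), 43.97)
  # unsigned magnitude with percent < 100 gets its sign reconstructed
  tab2 <- data.frame(case_id = "p7", comparison = "model_vs_patient",
                     difference_mm = 0.40, percent = 99.32)
  rec2 <- records_from_difference_percent(tab2)
  expect_lt(rec2$difference_mm, 0)
  expect_equal(rec2$difference_mm, -0.40)
})

test_that("cohort accuracy summaries reproduce the published mean rows", {
  recs <- revision_cohort_accuracy(as_records = TRUE)
  s1 <- summarize_accuracy(recs, "virtual_vs_model")
  expect_equal(s1$mean_difference_mm, -0.12)
  expect_equal(s1$sd_difference_mm, 0.24)
  expect_equal(s1$mean_percent, 99.76)
  expect_equal(s1$sd_percent, 0.47)
  s2 <- summarize_accuracy(recs, "model_vs_patient")
  expect_equal(s2$mean_difference_mm, 0.27)
  expect_equal(s2$sd_difference_mm, 0.55)
  expect_equal(s2$mean_percent, 100.55)
  expect_equal(s2$sd_percent, 1.09)
  s3 <- summarize_accuracy(recs, "virtual_vs_patient")
  expect_equal(s3$mean_difference_mm, 0.15)
  expect_equal(s3$sd_difference_mm, 0.37)
  expect_equal(s3$mean_percent, 100.31)
  expect_equal(s3$sd_percent, 0.70)
})

test_that("summarize_accuracy is permutation invariant and handles edge cases", {
  recs <- revision_cohort_accuracy(as_records = TRUE)
  set.seed(71)
  shuffled <- recs[sample(nrow(recs)), ]
  expect_equal(summarize_accuracy(shuffled, "virtual_vs_model"),
               summarize_accuracy(recs, "virtual_vs_model"))
  identical_recs <- do.call(rbind, replicate(3, accuracy_record("p", NA, "virtual_vs_model", 40, 41),
                                             simplify = FALSE))
  s <- summarize_accuracy(identical_recs)
  expect_equal(s$sd_difference_mm, 0)
  expect_error(summarize_accuracy(recs[1L, , drop = FALSE]), "at least 2")
})

test_that("paired t matches the hand-computed oracle", {
  res <- paired_t(c(1, 2, 3), c(1.5, 2.5, 3.0))
  expect_equal(res$statistic, -2, tolerance = 1e-9)
  expect_equal(res$df, 2)
  same <- paired_t(c(4, 5, 6), c(4, 5, 6))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(paired_t(c(1, 2, 3), c(0, 1, 2)), "zero variance")
  # p-value against numerical integration of the t density
  res2 <- paired_t(c(2.1, 3.3, 1.7, 4.2, 2.8), c(1.9, 3.0, 2.2, 3.1, 2.5))
  dens <- function(x, df) gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
    (1 + x^2 / df)^(-(df + 1) / 2)
  p_quad <- 2 * integrate(dens, abs(res2$statistic), Inf, df = 4)$value
  expect_lt(abs(res2$p_value - p_quad), 1e-8)
})

test_that("pearson r matches the covariance-formula oracle", {
  a <- c(1, 2, 3, 4)
  expect_equal(pearson_r(a, 2 * a + 1)$statistic, 1)
  expect_equal(pearson_r(a, -a)$statistic, -1)
  expect_error(pearson_r(a, rep(2, 4)), "zero variance")
  set.seed(73)
  for (rep in 1:20) {
    x <- rnorm(8)
    y <- rnorm(8)
    res <- pearson_r(x, y)
    r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_lt(abs(res$statistic - r_oracle), 1e-12)
    t_oracle <- r_oracle * sqrt(6 / (1 - r_oracle^2))
    expect_lt(abs(res$p_value - 2 * pt(-abs(t_oracle), 6)), 1e-12)
  }
})

test_that("KS statistic matches hand enumeration and a grid-sup oracle", {
  res <- ks_statistic(c(-1, 0, 1), 0, 1)
  expect_lt(abs(res$statistic - 0.1746), 1e-4)
  # sample at the n-quantile midpoints gives exactly D = 1/(2n)
  n <- 8L
  x <- qnorm((seq_len(n) - 0.5) / n, mean = 2, sd = 3)
  expect_lt(abs(ks_statistic(x, 2, 3)$statistic - 1 / (2 * n)), 1e-12)
  # grid-sup oracle on random samples
  set.seed(79)
  for (rep in 1:10) {
    x <- rnorm(9, 1, 2)
    d_pkg <- ks_statistic(x, 1, 2)$statistic
    xs <- sort(x)
    ec <- seq_along(xs) / length(xs)
    fc <- pnorm(xs, 1, 2)
    d_oracle <- max(abs(ec - fc), abs(c(0, ec[-length(ec)]) - fc))
    expect_lt(abs(d_pkg - d_oracle), 1e-12)
  }
  expect_error(ks_statistic(c(1, 1, 2), 0, 1), "ties")
  expect_true(grepl("approximate", ks_statistic(rnorm(5), 0, 1, estimated = TRUE)$note))
})

test_that("plan-vs-postop comparison reports exact constructed effects", {
  fr <- build_pelvic_frame(symmetric_landmarks())
  set.seed(83)
  planned <- lapply(1:6, function(i) {
    list(cor = c(80 + rnorm(1), 70 + rnorm(1), 50 + rnorm(1)),
         inclination = 40 + rnorm(1), anteversion = 15 + rnorm(1))
  })
  # identical achieved: all differences 0, t = 0
  rep0 <- compare_plan_vs_postop(planned, planned, fr)
  expect_true(all(abs(rep0$summary$mean_difference) < 1e-12))
  expect_true(all(rep0$summary$t == 0))
  # constant 2 mm offset on the sagittal (x) distance only
  achieved <- lapply(planned, function(e) {
    e$cor <- e$cor + c(2, 0, 0)
    e
  })
  rep2 <- compare_plan_vs_postop(planned, achieved, fr)
  s <- rep2$summary
  expect_equal(s$mean_difference[s$measure == "x"], 2, tolerance = 1e-12)
  expect_true(all(abs(s$mean_difference[s$measure != "x"]) < 1e-12))
  expect_error(compare_plan_vs_postop(planned, planned[-1L], fr), "pairing")
})

test_that("cohort comparison equals an independent spreadsheet-style recomputation", {
  fr <- build_pelvic_frame(symmetric_landmarks())
  set.seed(89)
  mk <- function() lapply(1:8, function(i) {
    list(cor = c(85 + rnorm(1, 0, 3), 70 + rnorm(1, 0, 4), 52 + rnorm(1, 0, 2)),
         inclination = 42 + rnorm(1, 0, 4), anteversion = 16 + rnorm(1, 0, 3))
  })
  planned <- mk()
  achieved <- mk()
  rep <- compare_plan_vs_postop(planned, achieved, fr)
  # spreadsheet oracle: distances read off coordinates relative to plane anchors
  px <- vapply(planned, function(e) e$cor[1] - 0, numeric(1))
  ax_ <- vapply(achieved, function(e) e$cor[1] - 0, numeric(1))
  py <- vapply(planned, function(e) e$cor[2] - 10, numeric(1))
  ay <- vapply(achieved, function(e) e$cor[2] - 10, numeric(1))
  s <- rep$summary
  expect_equal(s$mean_difference[s$measure == "x"], mean(ax_) - mean(px), tolerance = 1e-12)
  expect_equal(s$mean_difference[s$measure == "y"], mean(ay) - mean(py), tolerance = 1e-12)
  d <- ax_ - px
  t_oracle <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(s$t[s$measure == "x"], t_oracle, tolerance = 1e-12)
  r_oracle <- cor(ax_, px)
  expect_equal(s$r[s$measure == "x"], r_oracle, tolerance = 1e-12)
})

test_that("compare_measure_tables matches compare_plan_vs_postop on the same cohort", {
  fr <- build_pelvic_frame(symmetric_landmarks())
  set.seed(97)
  planned <- lapply(1:5, function(i) list(cor = runif(3, 40, 90),
                                          inclination = 40 + rnorm(1),
                                          anteversion = 15 + rnorm(1)))
  achieved <- lapply(1:5, function(i) list(cor = runif(3, 40, 90),
                                           inclination = 44 + rnorm(1),
                                           anteversion = 13 + rnorm(1)))
  rep <- compare_plan_vs_postop(planned, achieved, fr)
  tabs <- lapply(list(rep$planned, rep$achieved), function(m) {
    cbind(data.frame(case_id = sprintf("c%d", 1:5)), as.data.frame(m))
  })
  flat <- compare_measure_tables(tabs[[1L]], tabs[[2L]])
  expect_equal(flat$mean_difference[flat$measure == "x"],
               rep$summary$mean_difference[rep$summary$measure == "x"])
  expect_equal(flat$t[flat$measure == "z"], rep$summary$t[rep$summary$measure == "z"])
})

test_that("the 2D triangle construction places the COR at the hypotenuse midpoint", {
  expect_equal(ranawat_cor_2d(200, c(0, 0), lateral_offset = 0), c(20, 20))
  expect_equal(ranawat_cor_2d(200, c(0, 0), lateral_offset = 5)[1L], 25)
  # linearity in pelvic height
  p1 <- ranawat_cor_2d(150, c(10, -5), lateral_offset = 5)
  p2 <- ranawat_cor_2d(300, c(10, -5), lateral_offset = 5)
  start <- c(15, -5)
  expect_equal(p2 - start, 2 * (p1 - start))
  expect_error(ranawat_cor_2d(-10, c(0, 0)), "positive")
})
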