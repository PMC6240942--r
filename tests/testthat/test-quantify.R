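peak_row <- function(strain, replicate, compound, area, timepoint_h = 72,
                     variant = strain) {
  tibble::tibble(strain = strain, variant = variant,
                 replicate = replicate, timepoint_h = timepoint_h,
                 compound = compound, area = area)
}

small_peaks <- function() {
  dplyr::bind_rows(
    peak_row("s1", 1, "1", 1000), peak_row("s1", 1, "IS", 500),
    peak_row("s1", 2, "1", 1500), peak_row("s1", 2, "IS", 500),
    peak_row("s1", 3, "1", 500),  peak_row("s1", 3, "IS", 500)
  )
}

test_that("relative yields are per-replicate IS ratios averaged with sd", {
  y <- relative_yield(small_peaks())
  expect_equal(nrow(y), 1L)
  expect_equal(y$mean_response, 2)   # (2 + 3 + 1) / 3
  expect_equal(y$sd_response, 1)
  expect_equal(y$n, 3L)
})

test_that("missing or zero IS rows are rejected, naming the group", {
  peaks <- small_peaks()[-2, ]  # drop s1/rep1 IS
  expect_error(relative_yield(peaks), "s1/rep1")
  zero <- small_peaks()
  zero$area[zero$compound == "IS" & zero$replicate == 2] <- 0
  expect_error(relative_yield(zero), "s1/rep2")
})

test_that("relative yields are invariant to a per-group area rescale", {
  base <- simulate_screen(screen_sim_config(seed = 3))$peaks
  y0 <- relative_yield(base)
  scaled <- base |>
    dplyr::mutate(area = area * dplyr::if_else(replicate == 2, 7.5, 1))
  y1 <- relative_yield(scaled)
  expect_equal(y1$mean_response, y0$mean_response, tolerance = 1e-12)
})

test_that("relative yields agree with an independent split-apply recompute", {
  peaks <- simulate_screen(screen_sim_config(seed = 5))$peaks
  y <- relative_yield(peaks)
  key <- interaction(peaks$strain, peaks$replicate, peaks$timepoint_h)
  manual <- lapply(split(as.data.frame(peaks), key), function(g) {
    is_area <- g$area[g$compound == "IS"]
    g <- g[g$compound != "IS", ]
    data.frame(strain = g$strain, timepoint_h = g$timepoint_h,
               compound = g$compound, response = g$area / is_area)
  })
  manual <- do.call(rbind, manual)
  agg <- stats::aggregate(response ~ strain + timepoint_h + compound,
                          manual, mean)
  merged <- merge(as.data.frame(y), agg,
                  by = c("strain", "timepoint_h", "compound"))
  expect_equal(merged$mean_response, merged$response, tolerance = 1e-12)
})

test_that("fold change reproduces ratios, self-ratio 1 and zero handling", {
  yields <- tibble::tibble(
    strain = c("WT", "A99I", "zero"), compound = "2",
    mean_response = c(23.4, 86.4, 0)
  )
  expect_equal(fold_change(yields, "A99I", "A99I", "2"), 1)
  expect_equal(round(fold_change(yields, "A99I", "WT", "2"), 1), 3.7)
  expect_warning(fc <- fold_change(yields, "WT", "zero", "2"), "zero")
  expect_equal(fc, Inf)
  # multiplicative under chained references
  y2 <- tibble::tibble(strain = c("a", "b", "c"), compound = "1",
                       mean_response = c(2, 6, 30))
  expect_equal(
    fold_change(y2, "c", "b", "1") * fold_change(y2, "b", "a", "1"),
    fold_change(y2, "c", "a", "1")
  )
})

test_that("standard curves are OLS fits matching the normal equations", {
  cal <- data.frame(compound = "2",
                    concentration_mg_per_L = c(0, 1, 2),
                    area = c(0, 1, 2), is_area = 1)
  cu <- fit_standard_curve(cal)
  expect_equal(cu$slope, 1)
  expect_equal(cu$intercept, 0)
  expect_equal(cu$r_squared, 1)

  set.seed(13)
  conc <- c(1, 2, 5, 10, 25, 50)
  resp <- 0.11 * conc + 0.02 + rnorm(6, 0, 0.05)
  noisy <- data.frame(compound = "2", concentration_mg_per_L = conc,
                      response = resp)
  cu2 <- fit_standard_curve(noisy)
  # independent oracle: closed-form normal equations
  X <- cbind(1, conc)
  beta <- solve(t(X) %*% X, t(X) %*% resp)
  expect_equal(cu2$intercept, beta[1], tolerance = 1e-10)
  expect_equal(cu2$slope, beta[2], tolerance = 1e-10)

  expect_error(
    fit_standard_curve(data.frame(compound = "2",
                                  concentration_mg_per_L = c(5, 5),
                                  response = c(1, 1.1))),
    "distinct"
  )
})

test_that("titers invert the mapped curve and share curves across compounds", {
  curves <- list(
    "1" = structure(list(compound = "1", slope = 0.09, intercept = 0.01,
                         r_squared = 1, range = c(1, 100), n = 5),
                    class = "standard_curve"),
    "2" = structure(list(compound = "2", slope = 0.11, intercept = 0.02,
                         r_squared = 1, range = c(1, 100), n = 5),
                    class = "standard_curve")
  )
  yields <- tibble::tibble(
    strain = "s", variant = "s", timepoint_h = 72,
    compound = c("1", "2", "7", "9"),
    mean_response = c(0.01, 1.12, 1.12, 3), sd_response = 0, n = 3L
  )
  expect_message(t <- absolute_titer(yields, curves), "9")
  expect_equal(t$compound, c("1", "2", "7"))
  # response at the intercept floors to 0
  expect_equal(t$titer_mg_per_L[t$compound == "1"], 0)
  # compound 7 rides compound 2's curve: identical response, same titer
  expect_equal(t$titer_mg_per_L[t$compound == "7"],
               t$titer_mg_per_L[t$compound == "2"])
  expect_equal(t$titer_mg_per_L[t$compound == "2"], 10)

  expect_error(absolute_titer(yields, curves["2"],
                              response_map = c("1" = "1")),
               "missing curve")
})

test_that("strain metrics reproduce the published derived columns", {
  wt <- strain_metrics(c("1" = 15.9, "2" = 23.4, "3" = 0.2, "7" = 4.3))
  expect_equal(wt$total, 43.8)
  expect_equal(round(wt$oxygenated_pct), 64)
  expect_equal(round(wt$content_target_pct), 53)

  a99i <- strain_metrics(c("1" = 0.9, "2" = 86.4, "3" = 0.4, "7" = 0),
                         reference_titers = wt$titers)
  expect_equal(a99i$total, 87.7)
  expect_equal(round(a99i$oxygenated_pct), 99)
  expect_equal(round(a99i$content_target_pct), 99)
  expect_equal(round(a99i$fold_change[["2"]], 1), 3.7)

  substrate_only <- strain_metrics(c("1" = 43.8))
  expect_equal(substrate_only$oxygenated_pct, 0)
  expect_equal(substrate_only$content_target_pct, 0)

  zero <- strain_metrics(c("1" = 0, "2" = 0))
  expect_equal(zero$oxygenated_pct, 0)
  expect_equal(zero$content_target_pct, 0)
})

test_that("group comparison is a two-sided Welch test with degenerate conventions", {
  expect_equal(compare_groups(c(1, 1, 1), c(1, 1, 1)), 1)
  expect_equal(compare_groups(c(1, 1), c(2, 2)), 0)
  set.seed(31)
  a <- c(0, 0, 0) + rnorm(3, 0, 1e-3)
  b <- c(1, 1, 1) + rnorm(3, 0, 1e-3)
  expect_lt(compare_groups(a, b), 0.001)
  x <- rnorm(8, 0, 1)
  y <- rnorm(8, 0.5, 2)
  expect_equal(compare_groups(x, y),
               stats::t.test(x, y, var.equal = FALSE)$p.value)
})

test_that("Welch p-values track a permutation oracle on exchangeable groups", {
  set.seed(47)
  a <- rnorm(15, 0, 1)
  b <- rnorm(15, 0.6, 1.1)
  p_t <- compare_groups(a, b)
  p_perm <- permutation_p(a, b, n_perm = 2e4)
  # Monte-Carlo SE plus the t-vs-permutation approximation gap
  expect_lt(abs(p_t - p_perm), 0.03)
})

test_that("stagnation flags follow the final-interval threshold", {
  series <- tibble::tibble(
    strain = rep(c("MO", "lin"), each = 3),
    compound = "1",
    timepoint_h = rep(c(24, 48, 72), 2),
    titer_mg_per_L = c(40, 43, 43.8, 10, 20, 40)
  )
  out <- timecourse_summary(series)
  expect_true(out$stagnated[out$strain == "MO"])
  expect_false(out$stagnated[out$strain == "lin"])
  expect_equal(out$final_value[out$strain == "MO"], 43.8)
  # threshold arithmetic at the boundary
  edge <- tibble::tibble(strain = "e", compound = "1",
                         timepoint_h = c(48, 72),
                         titer_mg_per_L = c(90, 100))
  expect_false(timecourse_summary(edge)$stagnated)        # 10 == 10% of 100
  expect_true(timecourse_summary(edge, threshold = 0.11)$stagnated)
})
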