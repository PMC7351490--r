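test_that("carryover fit recovers an exact noise-free construction", {
  stool <- c(a = 4000L, b = 3000L, c = 2000L, d = 800L, e = 200L)
  qs <- stool / sum(stool)
  n <- 1e6
  build_sample <- function(slope) {
    prop <- slope * qs
    prop[c("d", "e")] <- (1 - sum(prop[c("a", "b", "c")])) * c(0.6, 0.4)
    setNames(as.integer(round(prop * n)), names(stool))
  }

  # sample built as exactly 0.05 x stool on the depleted ASVs
  smp <- build_sample(0.05)
  fit <- fit_nonviable_fraction(smp, stool, fold_threshold = 10)
  expect_equal(fit$p_nv, 0.05, tolerance = 1e-3)
  expect_setequal(fit$qualifying, c("a", "b", "c"))

  # the robust median-of-ratios route agrees on clean data
  fit_r <- fit_nonviable_fraction(smp, stool, method = "ratio")
  expect_equal(fit_r$p_nv, 0.05, tolerance = 1e-3)

  # a 0.3 x stool construction needs a fold threshold that admits it
  smp3 <- build_sample(0.3)
  expect_equal(
    fit_nonviable_fraction(smp3, stool, fold_threshold = 3)$p_nv,
    0.30, tolerance = 1e-3
  )

  # nothing depleted: no fit
  expect_error(
    fit_nonviable_fraction(stool, stool, fold_threshold = 10),
    class = "dropcult_no_fit"
  )
})

test_that("the origin-slope estimator cannot exceed 1/fold_threshold", {
  # every qualifying ASV has ratio <= 1/fold, so the fitted slope is capped;
  # carryover fractions above that cap are structurally unrecoverable
  spec <- community_spec(seed = 31)
  stool <- sample_stool_profile(spec)
  cult <- simulate_droplet_culture(stool, spec)
  stc <- sequence_stool(stool, spec)
  smp <- add_carryover_and_sequence(cult$profile, stool, 0.2,
                                    spec$read_depth, seed = 31)
  # either no ASV clears the 10x depletion gate at all, or the few that do
  # (by downward sampling noise) pin the slope at or below the cap
  capped <- tryCatch(
    fit_nonviable_fraction(smp, stc, fold_threshold = 10)$p_nv <= 0.1,
    dropcult_no_fit = function(e) TRUE
  )
  expect_true(capped)
})

test_that("carryover fractions below the qualifying cap are recovered", {
  fitted <- sapply(1:10, function(s) {
    sp <- community_spec(seed = s)
    st <- sample_stool_profile(sp)
    cult <- simulate_droplet_culture(st, sp)
    stc <- sequence_stool(st, sp)
    smp <- add_carryover_and_sequence(cult$profile, st, 0.05, 1e5,
                                      seed = dropcult:::child_seed(s, 40))
    fit_nonviable_fraction(smp, stc)$p_nv
  })
  expect_lt(abs(mean(fitted) - 0.05), 0.02)
})

test_that("logit confidence interval matches its closed form and symmetry", {
  ci <- proportion_ci(10, 1000, level = 0.90)
  expect_equal(ci$lower_p, 0.0060, tolerance = 1e-2)
  expect_equal(ci$upper_p, 0.0168, tolerance = 1e-2)
  expect_equal(ci$z, qnorm(0.95), tolerance = 1e-6)

  # interval symmetric about theta = 0 at x = n/2
  s <- proportion_ci(500, 1000)
  expect_equal(s$theta_hat, 0)
  expect_equal(s$lower_p, 1 - s$upper_p, tolerance = 1e-12)

  # width shrinks monotonically with n at fixed p_hat
  widths <- sapply(c(1e2, 1e4, 1e6), function(n) {
    ci <- proportion_ci(n / 2, n)
    ci$upper_p - ci$lower_p
  })
  expect_true(all(diff(widths) < 0))

  # boundaries
  expect_error(proportion_ci(0, 100), class = "dropcult_degenerate")
  top <- proportion_ci(100, 100)
  expect_equal(top$upper_p, 1)
  expect_lt(top$lower_p, 1)
})

test_that("closed-form intervals agree with the numeric likelihood profile", {
  for (x in c(3, 10, 50, 500, 900)) {
    for (n in c(1000, 10000)) {
      ci <- proportion_ci(x, n)
      oracle <- numeric_logit_ci(x, n)
      theta_ci <- log(c(ci$lower_p, ci$upper_p) /
                        (1 - c(ci$lower_p, ci$upper_p)))
      expect_lt(max(abs(theta_ci - oracle)), 1e-6)
    }
  }
})

test_that("filtering keeps growth and discards carryover-level ASVs", {
  stool <- setNames(c(5000L, 3000L, 1500L, 400L, 100L, 0L),
                    paste0("ASV_", 1:6))
  n <- 1e5
  qs <- stool / sum(stool)
  fit <- structure(
    list(p_nv = 0.2, qualifying = "ASV_1", fold_threshold = 10,
         method = "ls"),
    class = "nonviable_fit"
  )
  # ASV_5 at 100x its carryover expectation; ASV_4 exactly at expectation;
  # ASV_6 absent from stool; ASV_3 absent from the sample
  smp <- setNames(integer(6), names(stool))
  smp["ASV_5"] <- as.integer(round(100 * fit$p_nv * qs["ASV_5"] * n))
  smp["ASV_4"] <- as.integer(round(fit$p_nv * qs["ASV_4"] * n))
  smp["ASV_6"] <- 50L
  smp["ASV_1"] <- as.integer(n - sum(smp))
  res <- filter_asvs(smp, stool, fit)
  expect_true("ASV_5" %in% res$retained)
  expect_false("ASV_4" %in% res$retained)   # CI contains its centre
  expect_true("ASV_6" %in% res$retained)    # zero carryover threshold
  expect_false("ASV_3" %in% res$log$asv_id) # absent ASVs pass through silently
  expect_equal(res$filtered_counts[["ASV_4"]], 0L)
  expect_setequal(res$log$decision[res$log$asv_id == "ASV_5"], "retain")
})

test_that("end-to-end: carryover-only ASVs are discarded, grown ASVs kept", {
  # a carryover-level ASV is retained only when it fluctuates above its
  # expectation at the one-sided ~5% level, so specificity sits near 95%
  # by construction; assert it on a multi-seed average
  spec_rates <- sapply(21:25, function(s) {
    spec <- community_spec(seed = s)
    stool <- sample_stool_profile(spec)
    cult <- simulate_droplet_culture(stool, spec)
    stc <- sequence_stool(stool, spec)
    smp <- add_carryover_and_sequence(cult$profile, stool, 0.05,
                                      spec$read_depth, seed = s)
    fit <- fit_nonviable_fraction(smp, stc)
    res <- filter_asvs(smp, stc, fit)

    grown_ids <- names(cult$profile)[cult$profile > 0]
    carry_ids <- setdiff(res$log$asv_id, grown_ids) # detected, never grew
    disc <- res$log$asv_id[res$log$decision == "discard"]
    n <- sum(smp)
    stool_prop <- stc / sum(stc)
    strong <- names(smp)[smp > 0 &
                           smp >= 10 * fit$p_nv * stool_prop * n &
                           smp >= 20]
    c(
      specificity = mean(carry_ids %in% disc),
      sensitivity = mean(strong %in% res$retained)
    )
  })
  expect_gte(mean(spec_rates["specificity", ]), 0.92)
  expect_gte(mean(spec_rates["sensitivity", ]), 0.95)
})

test_that("interval coverage is near nominal (slightly conservative)", {
  n <- 1000; p <- 0.01
  x <- dropcult:::with_seed(99, rbinom(1e4, n, p))
  theta_true <- log(p / (1 - p))
  covered <- vapply(x, function(xx) {
    if (xx == 0) return(FALSE)
    ci <- proportion_ci(xx, n)
    half <- ci$z / sqrt(n * ci$p_hat * (1 - ci$p_hat))
    abs(ci$theta_hat - theta_true) <= half
  }, logical(1))
  # exact coverage at these parameters is 92.3%; check the empirical run
  # sits near it (the Wald-on-logit interval over-covers at small p)
  expect_gt(mean(covered), 0.88)
  expect_lt(mean(covered), 0.96)
})
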