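test_that("normality gate passes Gaussians and fails skewed samples", {
  set.seed(51)
  pass <- mean(vapply(1:100, function(i) normality_gate(rnorm(50)),
                      logical(1)))
  expect_gt(pass, 0.85)   # ~95% by construction of the 0.05 gate
  fail <- mean(vapply(1:100, function(i) normality_gate(rexp(200)),
                      logical(1)))
  expect_lt(fail, 0.05)
  expect_warning(flag <- normality_gate(c(1, 2)), "convention")
  expect_false(flag)
})

test_that("two-group comparison selects the gated test and matches exact enumeration", {
  a <- c(1, 2, 3); b <- c(101, 102, 103)
  res <- compare_two(a, b, method = "mann-whitney")
  expect_equal(res$test, "Mann-Whitney U")
  expect_equal(res$p_value, 0.1, tolerance = 1e-10)
  # independent oracle: brute-force enumeration of all C(6,3) = 20
  # rank arrangements
  expect_equal(mw_exact_p_bruteforce(a, b), 0.1, tolerance = 1e-10)
  # tiny symmetric samples pass the gate, so the default route is the t-test
  expect_equal(compare_two(a, b)$test, "t-test")
  # interleaved tie-free groups -> large exact p under the null
  res_same <- compare_two(c(1, 3, 5), c(2, 4, 6), method = "mann-whitney")
  expect_gt(res_same$p_value, 0.6)
  expect_equal(compare_two(c(1, 2, 3), c(1.5, 2.5, 3.5),
                           method = "mann-whitney")$p_value,
               mw_exact_p_bruteforce(c(1, 2, 3), c(1.5, 2.5, 3.5)),
               tolerance = 1e-10)
  # Gaussian groups shifted by 2 SD at n = 50 are detected with a t-test
  set.seed(52)
  g1 <- rnorm(50); g2 <- rnorm(50, mean = 2)
  res_t <- compare_two(g1, g2)
  expect_equal(res_t$test, "t-test")
  expect_true(res_t$significant)
  # degenerate group -> NA
  expect_true(is.na(compare_two(1, c(1, 2, 3))$p_value))
})

test_that("p-values are invariant under group relabeling", {
  set.seed(53)
  a <- rnorm(20); b <- rexp(20)
  expect_equal(compare_two(a, b)$p_value, compare_two(b, a)$p_value)
  g <- list(x = rnorm(10), y = rnorm(10, 1), z = rexp(10))
  expect_equal(compare_k(g)$p_value, compare_k(rev(g))$p_value)
})

test_that("k-group comparison gates between ANOVA and Kruskal-Wallis", {
  set.seed(54)
  null3 <- list(a = rnorm(30), b = rnorm(30), c = rnorm(30))
  res0 <- compare_k(null3)
  expect_equal(res0$test, "ANOVA")
  expect_false(res0$significant)
  shifted <- list(a = rnorm(30), b = rnorm(30), c = rnorm(30, mean = 3))
  res1 <- compare_k(shifted)
  expect_equal(res1$test, "ANOVA")
  expect_true(res1$significant)
  heavy <- list(a = rexp(40), b = rexp(40), c = rexp(40))
  expect_equal(compare_k(heavy)$test, "Kruskal-Wallis")
  expect_true(is.na(compare_k(list(a = numeric(0), b = 1:3))$p_value))
})

test_that("subgroup_analysis runs the ladder per signal x grouping x metric", {
  set.seed(55)
  meta <- simulate_cohort(sim_config(seed = 5, n_patients = 40),
                          waveforms = FALSE)$meta
  optima <- data.frame(patient_id = meta$patient_id, signal = "ICP",
                       aic = rnorm(40), bic = rnorm(40), ll = rnorm(40))
  res <- subgroup_analysis(optima, meta)
  expect_true(all(res$metric %in% c("AIC", "BIC", "LL")))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1, na.rm = TRUE))
  expect_true(all(res$test[res$grouping == "pupils"] %in%
                    c("ANOVA", "Kruskal-Wallis")))
  # injected separation on one metric is found
  optima$aic <- optima$aic + ifelse(meta$marshall_group == ">=5", 50, 0)
  res2 <- subgroup_analysis(optima, meta)
  hit <- res2[res2$grouping == "marshall_group" & res2$metric == "AIC", ]
  expect_true(hit$significant)
  sig <- significant_subgroups(res2)
  expect_true(nrow(sig) >= 1)
  expect_equal(names(sig)[1:4],
               c("signal", "grouping", "subgroup_1", "subgroup_2"))
  # groupings with an absent level are skipped
  meta_onesex <- meta; meta_onesex$sex <- "M"
  res3 <- subgroup_analysis(optima, meta_onesex)
  expect_false("sex" %in% res3$grouping)
  # BH adjustment is exposed
  res4 <- subgroup_analysis(optima, meta, adjust = "BH")
  expect_true("p_adjusted" %in% names(res4))
})
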