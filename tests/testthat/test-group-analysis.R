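# independent brute-force enumeration oracle for the rank-sum test
enum_rank_sum <- function(x, y) {
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combs <- utils::combn(N, m)
  u_all <- apply(combs, 2, function(ix) sum(r[ix])) - m * (m + 1) / 2
  mid <- m * n / 2
  list(U = u_obs, p = mean(abs(u_all - mid) >= abs(u_obs - mid) - 1e-12))
}

test_that("rank-sum test matches enumeration and reference implementations", {
  # exhaustive enumeration of all 6 rank assignments: U = 0, p = 1/3
  rs <- rank_sum_test(c(1, 2), c(3, 4))
  expect_equal(rs$U, 0)
  expect_equal(rs$p, 1 / 3)
  expect_equal(rs$method, "exact")
  # identical multisets give p = 1 under the exact method
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3), method = "exact")$p, 1)
  # agreement with the independent oracle and with wilcox.test
  set.seed(14)
  for (i in 1:8) {
    x <- stats::rnorm(sample(3:6, 1))
    y <- stats::rnorm(sample(3:6, 1))
    ours <- rank_sum_test(x, y)
    oracle <- enum_rank_sum(x, y)
    expect_equal(ours$U, oracle$U)
    expect_equal(ours$p, oracle$p)
    w <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$U, unname(w$statistic))
    expect_equal(ours$p, w$p.value, tolerance = 1e-12)
  }
  # exact and approximate p agree within 0.02 at n = 10 per group
  set.seed(99)
  dev <- replicate(100, {
    x <- stats::rnorm(10); y <- stats::rnorm(10)
    abs(rank_sum_test(x, y, method = "exact")$p -
          rank_sum_test(x, y, method = "approx")$p)
  })
  expect_lt(max(dev), 0.02)
  expect_error(rank_sum_test(numeric(0), 1:3), "nonempty")
})

test_that("group comparison labels regions, directions and null cases", {
  set.seed(4)
  regions <- c("thalamus", "temporal")
  tab <- expand.grid(subject_id = sprintf("s%02d", 1:12), region = regions,
                     stringsAsFactors = FALSE)
  tab$cohort <- rep(c("ictal", "postictal"), each = 6)
  tab$value <- stats::rnorm(nrow(tab), 50, 5)
  # identical cohorts: copy ictal values into postictal -> all p = 1
  tab2 <- tab
  for (reg in regions) {
    v <- tab2$value[tab2$cohort == "ictal" & tab2$region == reg]
    tab2$value[tab2$cohort == "postictal" & tab2$region == reg] <- v
  }
  res <- compare_groups(tab2)
  expect_true(all(res$p == 1))
  expect_true(all(res$direction == "none"))
  # direction equals the sign of the median difference
  tab$value[tab$cohort == "ictal" & tab$region == "thalamus"] <- 100
  res2 <- compare_groups(tab)
  expect_equal(res2$direction[res2$region == "thalamus"], "ictal")
  # region absent from one cohort is skipped with a warning
  tab3 <- rbind(tab, data.frame(subject_id = "s99", region = "insula",
                                cohort = "ictal", value = 1))
  expect_warning(res3 <- compare_groups(tab3), "skipped")
  expect_false("insula" %in% res3$region)
  # BH adjustment only on request
  expect_false("p_adj" %in% names(res2))
  expect_true("p_adj" %in% names(compare_groups(tab, adjust = TRUE)))
})

test_that("thalamic sign counts preserve partition identities", {
  z <- data.frame(subject_id = rep(sprintf("s%d", 1:5), 2),
                  cohort = "ictal", name = "thalamus",
                  hemisphere = rep(c("left", "right"), each = 5),
                  z = c(2, -1, 0, 3, 1, -2, -3, 1, 0, 0))
  sc <- thalamic_sign_counts(z)
  expect_equal(sc$n_pos + sc$n_neg + sc$n_zero, sc$n)
  left <- sc[sc$side == "left", ]
  expect_equal(left$n_pos, 3)
  expect_equal(left$n_neg, 1)
  expect_equal(left$n_zero, 1)
  expect_error(thalamic_sign_counts(z[z$name != "thalamus", ]), "thalamus")
})

test_that("an injected thalamic effect is detected reliably across seeds", {
  tpl <- default_template()
  hits <- 0L
  for (s in 1:100) {
    co <- simulate_cohort(n_ictal = 10, n_postictal = 0, template = tpl,
                          seed = s)
    zt <- cohort_z_table(co)
    lt <- zt$z[zt$name == "thalamus" & zt$hemisphere == "left"]
    if (sum(lt > 0) >= 8) hits <- hits + 1L
  }
  # ictal thalamic multiplier 1.3 at 5% noise: >= 8/10 positive left-thalamic
  # z-scores in at least 90 of 100 seeds
  expect_gte(hits, 90L)
})

test_that("rejection rate grows monotonically with the injected effect", {
  rates <- vapply(c(1.0, 1.15, 1.3, 1.5), function(mult) {
    ict <- suppressWarnings(
      scenario_spec("ictal", thalamic_cbf_multiplier = mult,
                    focus_region = NULL, focus_cbf_multiplier = 1))
    pos <- scenario_spec("postictal", thalamic_cbf_multiplier = 0.85,
                         focus_region = NULL, focus_cbf_multiplier = 1)
    tpl <- cohort_template(phantom_spec(), ictal = ict, postictal = pos)
    mean(vapply(1:200, function(s) {
      co <- simulate_cohort(template = tpl, seed = s)
      tm <- thalamic_means(co)
      rank_sum_test(tm$value[tm$cohort == "ictal"],
                    tm$value[tm$cohort == "postictal"])$p < 0.05
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[4], rates[1])
})

test_that("categorical proportions reproduce printed-table arithmetic", {
  rep51 <- utils::read.csv(system.file("extdata",
                                       "visual_perfusion_categories.csv",
                                       package = "tpmaquant"))
  cp <- categorical_proportions(rep51)
  expect_equal(cp$sensitivity$percent, 94)
  pp <- cp$proportions
  expect_equal(pp$percent[pp$cohort == "postictal" & pp$category == "hypoperfusion"], 27)
  expect_equal(pp$percent[pp$cohort == "postictal" & pp$category == "normal"], 73)
  # single-subject report: fractions are 0 or 1
  one <- data.frame(subject_id = "s1", cohort = "ictal",
                    category = "hyperperfusion")
  cp1 <- categorical_proportions(one)
  expect_true(all(cp1$proportions$fraction %in% c(0, 1)))
  expect_error(categorical_proportions(
    data.frame(subject_id = "s1", cohort = "ictal", category = "odd")),
    "unknown")
  expect_error(categorical_proportions(rbind(one, one)), "one row")
})

test_that("chi-square independence matches hand-computed expected counts", {
  flat <- chi_square_independence(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$chisq, 0)
  expect_equal(flat$p, 1)
  # hand computation: all expected counts 12.5 -> X2 = 4*(7.5^2)/12.5 = 18
  res <- chi_square_independence(matrix(c(20, 5, 5, 20), 2))
  expect_equal(res$chisq, 18)
  expect_equal(res$df, 1)
  # invariant under transposition
  m <- matrix(c(12, 3, 7, 9, 4, 11), nrow = 2)
  expect_equal(chi_square_independence(m)$chisq,
               chi_square_independence(t(m))$chisq)
  expect_error(chi_square_independence(matrix(c(0, 0, 5, 5), 2)), "marginal")
})
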