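# Vickers conversion, two-way ANOVA against a projection oracle, Tukey HSD.

test_that("Vickers conversion follows HV = 1854.4 P / d^2", {
  expect_equal(vickers_hv(25, 11.6), 1854.4 * 25 / 11.6^2)
  expect_equal(round(vickers_hv(25, 11.6), 1), 344.5)
  # doubling the diagonal divides HV by exactly 4
  expect_equal(vickers_hv(25, 23.2), vickers_hv(25, 11.6) / 4)
  expect_error(vickers_hv(-1, 10), class = "enamelmat_validation_error")
  expect_error(vickers_hv(25, 0), class = "enamelmat_validation_error")
  # implausible values are flagged, not rejected
  expect_warning(v <- vickers_hv(25, 100), "plausibility")
  expect_equal(v, 1854.4 * 25 / 1e4)
})

test_that("degenerate ANOVA inputs resolve as documented", {
  # all responses equal: F = 0, p = 1 for every effect
  t_flat <- expand.grid(age_weeks = c(2, 4), level = c("below", "above"),
                        rep = 1:2)
  t_flat$hv <- 300
  res <- two_way_anova(t_flat, tukey = FALSE)
  expect_equal(res$effects$F, c(0, 0, 0))
  expect_equal(res$effects$p, c(1, 1, 1))

  # balanced 2x2, cell means (10,10,10,20), n = 2, zero residual SD:
  # every SS = 50, F infinite and flagged
  t22 <- expand.grid(rep = 1:2, age_weeks = c(2, 4),
                     level = c("below", "above"))
  t22$hv <- ifelse(t22$age_weeks == 4 & t22$level == "above", 20, 10)
  res22 <- two_way_anova(t22, tukey = FALSE)
  expect_equal(res22$effects$sum_sq, c(50, 50, 50))
  expect_true(all(res22$effects$infinite_F))
  expect_true(all(is.infinite(res22$effects$F)))
  # conservation: SS_A + SS_B + SS_AB + SS_resid = SS_total
  expect_equal(sum(res22$effects$sum_sq) + res22$residual_ss,
               res22$total_ss)

  # empty cells make the interaction inestimable
  t_empty <- t22[!(t22$age_weeks == 2 & t22$level == "below"), ]
  expect_error(two_way_anova(t_empty),
               class = "enamelmat_estimability_error")
})

test_that("Type III statistics match the projection-matrix oracle", {
  for (seed in c(3, 17, 29, 101)) {
    t <- random_anova_table(seed)
    res <- two_way_anova(t, tukey = FALSE)
    ora <- oracle_type3_anova(t$hv, t$age_weeks, t$level)
    for (i in 1:3) {
      nm <- c("A", "B", "AB")[i]
      expect_equal(res$effects$sum_sq[i], unname(ora[[nm]]["ss"]),
                   tolerance = 1e-8)
      expect_equal(res$effects$F[i], unname(ora[[nm]]["F"]),
                   tolerance = 1e-8)
      expect_equal(res$effects$p[i], unname(ora[[nm]]["p"]),
                   tolerance = 1e-8)
    }
    expect_equal(res$residual_df, ora$rdf)
  }
})

test_that("statistics are invariant to row permutation", {
  t <- random_anova_table(7)
  res1 <- two_way_anova(t, tukey = FALSE)
  set.seed(1)
  res2 <- two_way_anova(t[sample(nrow(t)), ], tukey = FALSE)
  expect_equal(res1$effects$F, res2$effects$F)
  expect_equal(res1$effects$p, res2$effects$p)
})

test_that("balanced-design SS decomposition conserves the total", {
  d <- hardness_design(residual_sd = 35, replicates_per_cell = 4, seed = 13)
  t <- make_hardness_table(d)
  res <- two_way_anova(t, tukey = FALSE)
  expect_lt(abs(sum(res$effects$sum_sq) + res$residual_ss - res$total_ss) /
              res$total_ss, 1e-8)
})

test_that("generated effects are detected at simulated power", {
  # strong age effect, null location effect: 200 replicates
  base <- matrix(250, 3, 3, dimnames = list(c("2", "4", "16"),
                                            c("below", "at", "above")))
  eff <- base; eff[2, ] <- eff[2, ] + 80; eff[3, ] <- eff[3, ] + 120
  reject_a <- reject_b <- 0L
  n_rep <- 200L
  for (i in seq_len(n_rep)) {
    t <- make_hardness_table(hardness_design(cell_means = eff,
                                             residual_sd = 40,
                                             replicates_per_cell = 3,
                                             seed = 5000L + i))
    res <- two_way_anova(t, tukey = FALSE)
    reject_a <- reject_a + (res$effects$p[1] < 0.05)
    reject_b <- reject_b + (res$effects$p[2] < 0.05)
  }
  expect_gt(reject_a / n_rep, 0.95)   # large true effect: high power
  # null effect: rejection near alpha (3 binomial SE margin)
  expect_lt(reject_b / n_rep, 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("aggregation reduces indents to per-animal means before ANOVA", {
  d <- hardness_design(residual_sd = 30, replicates_per_cell = 3,
                       indents_per_site = 9, seed = 2)
  t <- make_hardness_table(d)
  res <- two_way_anova(t, aggregate = "animal_id", tukey = FALSE)
  # 3 ages x 3 levels x 3 animals = 27 aggregated rows, 9 cells
  expect_equal(res$residual_df, 27 - 9)
})

test_that("Tukey HSD reduces to the t-test for two groups", {
  set.seed(31)
  t <- data.frame(age_weeks = rep(c(2, 4), each = 8),
                  hv = c(rnorm(8, 250, 30), rnorm(8, 290, 30)))
  tk <- tukey_hsd(t, "age_weeks")
  tt <- t.test(hv ~ age_weeks, data = t, var.equal = TRUE)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-8)

  # three identical groups: all adjusted p = 1
  t3 <- data.frame(age_weeks = rep(c(2, 4, 16), each = 4), hv = rep(300, 12))
  t3$hv <- t3$hv + rep(c(-1, 1), 6)   # identical within-pattern per group
  tk3 <- tukey_hsd(t3, "age_weeks")
  expect_true(all(abs(tk3$p_adj - 1) < 1e-9))
  expect_true(all(abs(tk3$estimate) < 1e-9))

  expect_error(tukey_hsd(data.frame(age_weeks = 2, hv = 1), "age_weeks"),
               class = "enamelmat_validation_error")
})

test_that("Tukey family-wise error stays at alpha under the null", {
  n_rep <- 400L
  fwer <- 0L
  for (i in seq_len(n_rep)) {
    set.seed(9000L + i)
    t <- data.frame(age_weeks = rep(c(2, 4, 16), each = 6),
                    hv = rnorm(18, 300, 40))
    tk <- tukey_hsd(t, "age_weeks")
    fwer <- fwer + any(tk$p_adj < 0.05)
  }
  expect_lt(fwer / n_rep, 0.05 + 2 * sqrt(0.05 * 0.95 / n_rep))
})
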