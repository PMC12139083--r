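test_that("single pairs classify by direction and threshold", {
  expect_equal(compare_pair(3, 4, "lower_better", tau = 0), "win")
  expect_equal(compare_pair(3, 4, "lower_better", tau = 2), "tie")
  expect_equal(compare_pair(1, 4, "lower_better", tau = 2), "win")
  expect_equal(compare_pair(4, 1, "lower_better", tau = 2), "loss")
  expect_equal(compare_pair(4, 3, "higher_better", tau = 0), "win")
  expect_equal(compare_pair(3, 3, "lower_better", tau = 0), "tie")
  expect_equal(compare_pair(NA, 3, "lower_better"), "tie")  # missing is neutral
  expect_error(compare_pair(1, 2, "lower_better", tau = -1), "tau")
})

test_that("unmatched GPC enumerates all active x placebo cross pairs", {
  d <- two_arm_trial(active_vals = c(3, 5), placebo_vals = c(4, 4))
  pl <- priority_list(priority("vas", 3, "lower_better", 0))
  g <- unmatched_gpc(d, pl)
  expect_equal(g$n_pairs, 4)
  expect_equal(g$wins, 2)
  expect_equal(g$losses, 2)
  expect_equal(g$net_benefit, 0)
})

test_that("identical arms give all ties and zero net benefit", {
  d <- two_arm_trial(c(2, 5, 7), c(2, 5, 7))
  # own-pairs tie; cross pairs may decide, so use equal values everywhere
  d$value <- 3
  pl <- priority_list(priority("vas", 3, "lower_better", 0))
  g <- unmatched_gpc(d, pl)
  expect_equal(g$ties, g$n_pairs)
  expect_equal(g$net_benefit, 0)
})

test_that("matched GPC compares each subject only with themselves", {
  d <- two_arm_trial(c(3), c(5))
  pl <- priority_list(priority("vas", 3, "lower_better", 0))
  g <- matched_gpc(d, pl)
  expect_equal(g$n_pairs, 1)
  expect_equal(g$net_benefit, 1)

  d3 <- two_arm_trial(c(3, 6, 4), c(5, 2, 4))  # win, loss, tie
  g3 <- matched_gpc(d3, pl)
  expect_equal(c(g3$wins, g3$losses, g3$ties), c(1, 1, 1))
  expect_equal(g3$net_benefit, 0)
})

test_that("hierarchy is decided by the first non-tie level", {
  # level 1 (time 3) ties everywhere, level 2 (time 4) decides
  d <- two_arm_trial(c(2, 2), c(2, 2), time = 3)
  for (k in 1:2) {
    id <- sprintf("S%02d", k)
    seqk <- d$sequence[match(id, d$subject_id)]
    act <- if (seqk == "AB") 1 else 2
    d$value[d$subject_id == id & d$period == act & d$time == 4] <- 1
    d$value[d$subject_id == id & d$period != act & d$time == 4] <- 6
  }
  pl <- priority_list(priority("vas", 3, "lower_better", 0),
                      priority("vas", 4, "lower_better", 0))
  g <- unmatched_gpc(d, pl)
  expect_equal(g$wins, g$n_pairs)
  expect_equal(g$net_benefit, 1)
})

test_that("net benefit matches exhaustive enumeration and the rank-sum oracle", {
  set.seed(20)
  for (i in 1:10) {
    d <- generate_trial(trial_config(n_per_sequence = sample(2:4, 1)),
                        seed = 300 + i)
    pl <- default_priorities(tau = sample(0:2, 1))
    g <- unmatched_gpc(d, pl)
    o <- gpc_enumeration_oracle(d, pl)
    expect_identical(c(g$wins, g$losses, g$ties), c(o$wins, o$losses, o$ties))
    expect_equal(g$net_benefit, o$net_benefit)
  }
  # single continuous priority, tau = 0: wins + ties/2 recovers Mann-Whitney U
  for (i in 1:10) {
    d <- generate_trial(trial_config(n_per_sequence = 4), seed = 400 + i)
    pl <- priority_list(priority("vas", 3, "lower_better", 0))
    g <- unmatched_gpc(d, pl)
    sub <- d[d$time == 3, ]
    act <- sub$value[sub$treatment == "active"]
    plc <- sub$value[sub$treatment == "placebo"]
    U <- sum(outer(act, plc, "<")) + 0.5 * sum(outer(act, plc, "=="))
    expect_equal((g$wins + 0.5 * g$ties) / g$n_pairs, U / (length(act) * length(plc)))
  }
})

test_that("swapping arm labels negates the net benefit", {
  d <- generate_trial(trial_config(n_per_sequence = 4), seed = 21)
  pl <- default_priorities()
  g <- unmatched_gpc(d, pl)
  d_sw <- d
  d_sw$sequence <- ifelse(d$sequence == "AB", "BA", "AB")
  d_sw$treatment <- expected_treatment(d_sw$sequence, d_sw$period)
  g_sw <- unmatched_gpc(as_long_trial(d_sw), pl)
  expect_equal(g_sw$net_benefit, -g$net_benefit)
  expect_equal(g_sw$wins, g$losses)
  expect_equal(g_sw$losses, g$wins)
})

test_that("raising the threshold never decreases the tie count", {
  d <- generate_trial(trial_config(n_per_sequence = 4), seed = 22)
  ties <- vapply(c(0, 1, 2, 4, 8), function(tau) {
    unmatched_gpc(d, default_priorities(tau = tau))$ties
  }, numeric(1))
  expect_true(all(diff(ties) >= 0))
})

test_that("classification at tau = 0 is invariant to monotone transforms", {
  d <- generate_trial(trial_config(n_per_sequence = 4), seed = 23)
  pl <- default_priorities(tau = 0)
  g1 <- unmatched_gpc(d, pl)
  d2 <- d
  d2$value <- exp(d$value / 4)  # strictly increasing
  g2 <- unmatched_gpc(d2, pl)
  expect_equal(c(g1$wins, g1$losses, g1$ties), c(g2$wins, g2$losses, g2$ties))
})

test_that("stratification pools within-stratum pairs", {
  d <- generate_trial(trial_config(n_per_sequence = 4), seed = 24)
  pl <- default_priorities()
  d$site <- "one"
  g1 <- unmatched_gpc(d, pl, strata = "site")
  g0 <- unmatched_gpc(d, pl)
  expect_equal(g1$net_benefit, g0$net_benefit)  # single stratum = unstratified

  subj <- unique(d$subject_id)
  d$site <- ifelse(d$subject_id %in% subj[1:4], "a", "b")
  g2 <- unmatched_gpc(d, pl, strata = "site")
  expect_equal(g2$n_pairs, 4^2 + 4^2)
  expect_equal(sum(g2$strata$wins), g2$wins)
  # pooled counts equal the sum of per-stratum analyses
  da <- d[d$subject_id %in% subj[1:4], ]
  db <- d[!d$subject_id %in% subj[1:4], ]
  ga <- unmatched_gpc(as_long_trial(da), pl)
  gb <- unmatched_gpc(as_long_trial(db), pl)
  expect_equal(g2$wins, ga$wins + gb$wins)
  expect_equal(g2$losses, ga$losses + gb$losses)
})

test_that("degenerate (all-tie) data has permutation p-value 1", {
  d <- as_long_trial(trial_skeleton(3, v0 = 4))
  pl <- default_priorities()
  g <- gpc_permutation_test(d, pl, n_perm = 99, seed = 25)
  expect_equal(g$net_benefit, 0)
  expect_equal(g$p_value, 1)
})

test_that("the permutation p-value has the add-one form and a valid floor", {
  # maximal separation: p can never undercut 1/(n_perm + 1)
  d <- two_arm_trial(rep(0, 8), rep(10, 8))
  pl <- priority_list(priority("vas", 3, "lower_better", 0))
  g <- gpc_permutation_test(d, pl, n_perm = 99, seed = 26)
  expect_equal(g$net_benefit, 1)
  expect_gte(g$p_value, 1 / 100)
  expect_lte(g$p_value, 5 / 100)
  expect_error(gpc_permutation_test(d, pl, n_perm = 0), "n_perm")
})

test_that("permutation testing is reproducible under a seed", {
  d <- generate_trial(trial_config(n_per_sequence = 4), seed = 27)
  pl <- default_priorities()
  g1 <- gpc_permutation_test(d, pl, n_perm = 59, seed = 28)
  g2 <- gpc_permutation_test(d, pl, n_perm = 59, seed = 28)
  expect_equal(g1$p_value, g2$p_value)
})

test_that("bad priority specifications error", {
  d <- generate_trial(trial_config(n_per_sequence = 2), seed = 29)
  expect_error(priority_list(), "at least one")
  expect_error(priority_list(priority("vas", 3, threshold = -1)), "threshold")
  expect_error(priority_list(priority("vas", 3), priority("vas", 3)), "unique")
  expect_error(unmatched_gpc(d, priority_list(priority("pain", 3))), "absent")
})

test_that("tidy() and autoplot() work on GPC results", {
  d <- generate_trial(trial_config(n_per_sequence = 3), seed = 30)
  g <- gpc_permutation_test(d, default_priorities(), n_perm = 19, seed = 31)
  td <- tidy(g)
  expect_equal(td$n_pairs, g$n_pairs)
  expect_s3_class(autoplot(g), "ggplot")
})
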