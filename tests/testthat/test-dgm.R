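test_that("the generator produces the full cross-over layout, reproducibly", {
  cfg <- trial_config(n_per_sequence = 8)
  d <- generate_trial(cfg, seed = 1)
  expect_equal(nrow(d), 2 * 8 * 2 * 4)
  expect_equal(length(unique(d$subject_id)), 16)
  expect_true(all(d$value %in% 0:20))
  expect_equal(as.integer(table(d$sequence)), c(64L, 64L))
  expect_identical(generate_trial(cfg, seed = 7), generate_trial(cfg, seed = 7))

  dc <- generate_trial(trial_config(n_per_sequence = 4, outcome_kind = "count"),
                       seed = 2)
  expect_true(all(dc$value >= 0 & dc$value == round(dc$value)))
  expect_equal(dc$outcome[1], "blister_count")
})

test_that("with no correlation the marginal category frequencies match the pmf", {
  pmf <- vas_marginal_pmf()
  cfg <- trial_config(n_per_sequence = 3200, rho = 0, subject_sd = 0)
  d <- generate_trial(cfg, seed = 3)  # 51,200 draws
  n <- nrow(d)
  freq <- tabulate(d$value + 1, nbins = 21) / n
  se <- sqrt(pmf * (1 - pmf) / n)
  expect_true(all(abs(freq - pmf) <= 3 * se + 1e-12))
})

test_that("latent correlation is monotone in rho (copula check)", {
  d_lo <- generate_trial(trial_config(n_per_sequence = 1500, rho = 0.1,
                                      subject_sd = 0), seed = 5)
  d_hi <- generate_trial(trial_config(n_per_sequence = 1500, rho = 0.8,
                                      subject_sd = 0), seed = 5)
  lag_cor <- function(d) {
    m <- matrix(d$value, ncol = 8, byrow = TRUE)
    cor(m[, 1], m[, 2], method = "kendall")
  }
  expect_gt(lag_cor(d_hi), lag_cor(d_lo))
})

test_that("a pmf with empty categories warns about unreachable categories", {
  pmf <- c(0.5, 0.5, rep(0, 19))
  expect_warning(trial_config(pmf = pmf), "unreachable")
})

test_that("permuting sequence labels preserves profiles and group sizes", {
  d <- generate_trial(trial_config(n_per_sequence = 4), seed = 8)
  p <- permute_null(d, seed = 9)
  profile_of <- function(x) {
    split(x$value[order(x$subject_id, x$period, x$time)],
          x$subject_id[order(x$subject_id, x$period, x$time)])
  }
  expect_identical(profile_of(p), profile_of(d))  # profiles intact
  expect_equal(sort(table(p$sequence)), sort(table(d$sequence)))
  expect_equal(p$treatment, expected_treatment(p$sequence, p$period))

  one <- as_long_trial(trial_skeleton(1)[1:8, ])
  expect_error(permute_null(one), "2 subjects")
})

test_that("with 2 subjects the permutation is identity or swap", {
  d <- as_long_trial(trial_skeleton(1))  # S01 AB, S02 BA
  set.seed(10)
  for (i in 1:20) {
    p <- permute_null(d)
    seqs <- p$sequence[match(c("S01", "S02"), p$subject_id)]
    expect_true(identical(seqs, c("AB", "BA")) || identical(seqs, c("BA", "AB")))
  }
})

test_that("each subject draws either sequence with probability 1/2", {
  d <- generate_trial(trial_config(n_per_sequence = 2), seed = 11)
  subjects <- unique(d$subject_id)
  n_perm <- 4000
  set.seed(12)
  hits <- setNames(rep(0, 4), subjects)
  for (i in seq_len(n_perm)) {
    p <- permute_null(d)
    ab <- subjects[p$sequence[match(subjects, p$subject_id)] == "AB"]
    hits[ab] <- hits[ab] + 1
  }
  se <- sqrt(0.25 / n_perm)
  expect_true(all(abs(hits / n_perm - 0.5) <= 3 * se))
})

test_that("effect injection is a no-op at zero magnitude and floors at zero", {
  d <- generate_trial(trial_config(n_per_sequence = 3), seed = 13)
  expect_equal(inject_effect(d, effect_spec("ordinal_shift", magnitude = 0)), d)
  dc <- generate_trial(trial_config(n_per_sequence = 3, outcome_kind = "count"),
                       seed = 13)
  expect_equal(inject_effect(dc, effect_spec("count_thinning", magnitude = 1)), dc)

  d1 <- d
  d1$value <- 1
  shifted <- inject_effect(d1, effect_spec("ordinal_shift", magnitude = 3))
  expect_true(all(shifted$value[shifted$treatment == "active" &
                                shifted$time %in% 2:4] == 0))
  # placebo records and baselines untouched
  expect_equal(shifted$value[shifted$treatment == "placebo"],
               d1$value[d1$treatment == "placebo"])
  expect_equal(shifted$value[shifted$time == 1], d1$value[d1$time == 1])
})

test_that("thinning keeps each count with the retention probability", {
  d <- as_long_trial(trial_skeleton(1700, outcome = "blister_count", v0 = 20))
  thinned <- inject_effect(d, effect_spec("count_thinning", magnitude = 0.5),
                           seed = 14)
  hit <- thinned$treatment == "active" & thinned$time %in% 2:4
  draws <- thinned$value[hit]
  expect_gte(length(draws), 10000)
  se <- sqrt(20 * 0.25 / length(draws))
  expect_lt(abs(mean(draws) - 10), 3 * se)
  # reduction-type effect: never negative, never above the input
  expect_true(all(draws >= 0 & draws <= 20))
})

test_that("mechanism/outcome mismatch and bad magnitudes error", {
  d <- generate_trial(trial_config(n_per_sequence = 2), seed = 15)
  d$value <- d$value + 0.25
  expect_error(inject_effect(d, effect_spec("ordinal_shift")), "integer")
  expect_error(effect_spec("count_thinning", magnitude = 0), "retention")
  expect_error(effect_spec("ordinal_shift", magnitude = -1), "magnitude")
  expect_error(effect_spec("ordinal_shift", occasions = 1:4), "occasions")
})
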