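# shared fixtures built in code

# complete 2x2x4 trial skeleton for `n` subjects per sequence, all values v0
trial_skeleton <- function(n_per_seq = 2, outcome = "vas", v0 = 0) {
  n <- 2L * n_per_seq
  grid <- expand.grid(time = 1:4, period = 1:2, subject = seq_len(n))
  tibble::tibble(
    subject_id = sprintf("S%02d", grid$subject),
    sequence = rep(c("AB", "BA"), each = n_per_seq)[grid$subject],
    period = grid$period,
    time = grid$time,
    outcome = outcome,
    value = v0
  )
}

# trial where each subject has fixed per-arm values at a single occasion
two_arm_trial <- function(active_vals, placebo_vals, time = 3,
                          outcome = "vas") {
  stopifnot(length(active_vals) == length(placebo_vals))
  n <- length(active_vals)
  d <- trial_skeleton(ceiling(n / 2), outcome = outcome)
  d <- d[d$subject_id %in% sprintf("S%02d", seq_len(n)), ]
  d$value <- 0
  for (k in seq_len(n)) {
    id <- sprintf("S%02d", k)
    seqk <- d$sequence[match(id, d$subject_id)]
    act_per <- if (seqk == "AB") 1 else 2
    d$value[d$subject_id == id & d$period == act_per & d$time == time] <- active_vals[k]
    d$value[d$subject_id == id & d$period != act_per & d$time == time] <- placebo_vals[k]
  }
  as_long_trial(d)
}

default_priorities <- function(tau = 2) {
  priority_list(priority("vas", 3, "lower_better", tau),
                priority("vas", 4, "lower_better", tau),
                priority("vas", 2, "lower_better", tau))
}

# brute-force unmatched GPC oracle: explicit loop over all ordered subject
# pairs and priority levels
gpc_enumeration_oracle <- function(data, priorities) {
  subjects <- unique(data$subject_id)
  wins <- losses <- ties <- 0L
  arm_value <- function(id, arm, l) {
    seqk <- data$sequence[match(id, data$subject_id)]
    per <- if ((seqk == "AB") == (arm == "active")) 1 else 2
    v <- data$value[data$subject_id == id & data$period == per &
                    data$outcome == priorities$outcome[l] &
                    data$time == priorities$time[l]]
    if (length(v) == 0) NA_real_ else v
  }
  for (i in subjects) {
    for (j in subjects) {
      res <- "tie"
      for (l in seq_len(nrow(priorities))) {
        r <- compare_pair(arm_value(i, "active", l), arm_value(j, "placebo", l),
                          priorities$direction[l], priorities$threshold[l])
        if (r != "tie") { res <- r; break }
      }
      if (res == "win") wins <- wins + 1L
      else if (res == "loss") losses <- losses + 1L
      else ties <- ties + 1L
    }
  }
  list(wins = wins, losses = losses, ties = ties,
       net_benefit = (wins - losses) / (wins + losses + ties))
}
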