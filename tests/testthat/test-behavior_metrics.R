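mk_trials <- function(rt, correct = TRUE, participant_id = "P001",
                      session = 1L, block = 1L, phase = "training") {
  tibble::tibble(participant_id = participant_id, session = session,
                 block = block, phase = phase,
                 rt = rt, correct = rep_len(correct, length(rt)))
}

# brute-force trimming oracle: sort and keep the closed interval between
# the two pooled interpolation quantiles
trim_oracle <- function(rt, tail) {
  q <- stats::quantile(rt, c(tail, 1 - tail), names = FALSE)
  which(rt >= q[1] & rt <= q[2])
}

test_that("pooled RT trimming removes exactly the tail fractions", {
  withr::with_seed(501, {
    t1 <- mk_trials(sample(seq(0.3, 3, length.out = 10000)))
    expect_equal(nrow(trim_rt(t1, 0.01)), 9800)
    t2 <- mk_trials(sample(seq(0.3, 3, length.out = 1000)))
    expect_equal(nrow(trim_rt(t2, 0.01)), 980)
    expect_identical(trim_rt(t2, 0), t2)
    # ties: identical RTs are all retained
    t3 <- mk_trials(rep(1.5, 200))
    expect_equal(nrow(trim_rt(t3, 0.01)), 200)
    # random tables agree with the sort-and-slice oracle
    for (rep in 1:10) {
      rt <- rlnorm(sample(50:500, 1), 0, 0.4)
      tt <- mk_trials(rt)
      expect_equal(trim_rt(tt, 0.05)$rt, rt[trim_oracle(rt, 0.05)])
    }
    expect_warning(trim_rt(mk_trials(numeric())), "empty")
  })
})

test_that("block accuracy is percent correct per cell and matches a loop recount", {
  t1 <- mk_trials(rep(1, 40), correct = c(rep(TRUE, 10), rep(FALSE, 30)))
  expect_equal(block_accuracy(t1)$accuracy_pct, 25.0)
  t0 <- mk_trials(rep(1, 12), correct = FALSE)
  expect_equal(block_accuracy(t0)$accuracy_pct, 0.0)
  withr::with_seed(502, {
    tt <- tibble::tibble(
      participant_id = sample(sprintf("P%02d", 1:5), 400, TRUE),
      session = sample(1:3, 400, TRUE),
      block = sample(1:7, 400, TRUE),
      rt = runif(400, 0.4, 2),
      correct = runif(400) < 0.5)
    tt$phase <- ifelse(tt$block == 7, "generalization", "training")
    ba <- block_accuracy(tt)
    for (k in sample(nrow(ba), 20)) {
      sel <- tt$participant_id == ba$participant_id[k] &
        tt$session == ba$session[k] & tt$block == ba$block[k]
      expect_equal(ba$accuracy_pct[k], 100 * mean(tt$correct[sel]))
      expect_equal(ba$n_trials[k], sum(sel))
    }
    # permutation invariance
    perm <- sample(nrow(tt))
    ba2 <- block_accuracy(tt[perm, ])
    expect_equal(dplyr::arrange(ba, participant_id, session, block),
                 dplyr::arrange(ba2, participant_id, session, block))
  })
})

test_that("learner classification uses the at-or-below-35% rule", {
  expect_equal(classify_learner(35.0), "non_learner")
  expect_equal(classify_learner(37.5), "learner")
  expect_equal(classify_learner(25.0), "non_learner")
  expect_equal(classify_learner(100 * 15 / 40), "learner")
  expect_true(is.na(classify_learner(NA)))
})

test_that("OSPAN scoring is all-or-nothing and order-sensitive", {
  rec <- tibble::tibble(
    trial_index = 1:3, span_length = c(3L, 4L, 5L),
    presented_letters = list(c("A", "B", "C"), c("A", "I", "D", "F"),
                             c("K", "L", "M", "N", "P")),
    recalled_letters = list(c("A", "B", "C"), c("A", "I", "D", "F"),
                            c("K", "L", "N", "M", "P")),
    n_math_correct = c(3L, 4L, 5L))
  expect_equal(ospan_score(rec), 7)  # 3 + 4 + 0 (one transposition)
  one4 <- rec[2, ]
  expect_equal(ospan_score(one4), 4)
  # permuting a correct span's recall zeroes its contribution
  perm <- rec
  perm$recalled_letters[[1]] <- c("B", "A", "C")
  expect_equal(ospan_score(perm), 4)
  # full recall over the 15-trial design scores the maximum 75
  full <- tibble::tibble(
    trial_index = 1:15, span_length = rep(3:7, each = 3),
    presented_letters = lapply(rep(3:7, each = 3), function(L) LETTERS[1:L]),
    n_math_correct = rep(3:7, each = 3))
  full$recalled_letters <- full$presented_letters
  expect_equal(ospan_score(full), 75)
  expect_error(ospan_score(full[, 1:2]), "malformed")
})

test_that("maintenance and generalization scores are the stated differences", {
  grid <- expand.grid(participant_id = "P001", session = 1:3, block = 1:7)
  grid$phase <- ifelse(grid$block == 7, "generalization", "training")
  grid$n_trials <- 40
  grid$mean_rt <- 1
  acc <- c("1.1" = 30, "1.2" = 35, "1.3" = 40, "1.4" = 45, "1.5" = 50,
           "1.6" = 60, "1.7" = 55,
           "2.1" = 50, "2.2" = 52, "2.3" = 54, "2.4" = 56, "2.5" = 58,
           "2.6" = 58, "2.7" = 58,
           "3.1" = 51, "3.2" = 55, "3.3" = 60, "3.4" = 62, "3.5" = 64,
           "3.6" = 64, "3.7" = 61)
  grid$accuracy_pct <- acc[paste(grid$session, grid$block, sep = ".")]
  m <- tibble::as_tibble(grid)
  mnt <- maintenance_scores(m)
  expect_equal(mnt$delta_pct[mnt$delay == "delay" & mnt$transition == 1],
               50 - 60)
  expect_equal(mnt$delta_pct[mnt$delay == "delay" & mnt$transition == 2],
               51 - 58)
  expect_equal(mnt$delta_pct[mnt$delay == "no_delay" &
                               mnt$transition == 1], 60 - 50)
  expect_equal(mnt$delta_pct[mnt$delay == "no_delay" &
                               mnt$transition == 2], 0)
  gen <- generalization_score(m)
  expect_equal(gen$generalization_score_pct[gen$session == 1], 55 - 60)
  expect_equal(gen$generalization_score_pct[gen$session == 2], 0)
  # missing block -> missing delta
  m2 <- m[!(m$session == 2 & m$block == 1), ]
  mnt2 <- maintenance_scores(m2)
  expect_true(is.na(mnt2$delta_pct[mnt2$delay == "delay" &
                                     mnt2$transition == 1]))
})

test_that("median split sends ties to the high group", {
  expect_equal(median_split(c(10, 46, 50)), c("low", "high", "high"))
  expect_equal(median_split(rep(40, 5)), rep("high", 5))
  s <- c(10, 20, 46, 46, 50, 60)
  expect_equal(sum(median_split(s) == "high"), 4)  # both 46s are high
})
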