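test_that("shipped schedule reproduces the deck economics", {
  sched <- default_schedule()
  bs <- schedule_block_sums(sched)
  expect_true(all(bs$net[bs$deck %in% c("A", "B")] == -250))
  expect_true(all(bs$net[bs$deck %in% c("C", "D")] == 250))
  # every card: gain >= 0, loss <= 0; first card of each deck is a pure gain
  expect_true(all(sched$gain >= 0))
  expect_true(all(sched$loss <= 0))
  expect_true(all(sched$gain[1, ] > 0))
  expect_true(all(sched$loss[1, ] == 0))
  # deck A: frequent smaller losses; deck B: one rare large loss per block
  expect_gt(sum(sched$loss[1:10, "A"] < 0), sum(sched$loss[1:10, "B"] < 0))
  expect_equal(min(sched$loss[1:10, "B"]), -1250)
})

test_that("deal is a pure cycling function of (deck, draw_count)", {
  sched <- default_schedule()
  first_a <- deal(sched, "A", 1)
  expect_gt(first_a[["gain"]], 0)
  expect_identical(first_a[["loss"]], 0)
  expect_identical(deal(sched, "A", 1), deal(sched, 1, 1))
  # cycling: one full pass of the 100-card fixture
  expect_identical(deal(sched, "B", 101), deal(sched, "B", 1))
  # single-card deck cycles onto itself
  one <- payoff_schedule(matrix(50, 1, 4), matrix(0, 1, 4))
  expect_identical(deal(one, "C", 7), deal(one, "C", 1))
  expect_error(deal(sched, 5, 1), "invalid deck")
  expect_error(deal(sched, "A", 0), "draw_count")
})

test_that("cohort files round-trip losslessly with letters accepted on read", {
  bundle <- generate_cohort(scenario_config(n = 2, n_trials = 15), seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(bundle$cohort, path)
  back <- read_cohort(path)
  expect_equal(back, bundle$cohort)
  # letters on read
  txt <- readr::read_csv(path, show_col_types = FALSE)
  txt$deck <- c("A", "B", "C", "D")[txt$deck]
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(txt, path2)
  expect_equal(read_cohort(path2), bundle$cohort)
})

test_that("cohort validation names the offending structure", {
  base <- tibble::tibble(subject = "a", session = 1, trial = 1:3,
                         deck = 1, gain = 50, loss = 0)
  gap <- base
  gap$trial <- c(1, 2, 4)
  expect_error(validate_cohort(gap), "consecutive.*subject a")
  dup <- dplyr::bind_rows(base, base[1, ])
  expect_error(validate_cohort(dup), "duplicated.*a 1 1")
  only_s2 <- base
  only_s2$session <- 2
  expect_error(validate_cohort(only_s2), "session 1 is required.*a")
  bad_deck <- base
  bad_deck$deck <- c(1, 2, 9)
  expect_error(validate_cohort(bad_deck), "invalid deck")
})

test_that("summary score counts good-deck choices and ignores trial order", {
  all_c <- make_session(rep(3L, 100), rep(50, 100), rep(0, 100))
  expect_equal(summary_score(all_c), 1.0)
  quarters <- rep(1:4, each = 25)
  expect_equal(summary_score(quarters), 0.5)
  expect_equal(summary_score(c("C", "A", "D", "B", "C")), 0.6)
  set.seed(1)
  shuffled <- sample(quarters)
  expect_equal(summary_score(shuffled), summary_score(quarters))
  expect_error(summary_score(integer(0)), "empty session")
})

test_that("summary_scores aggregates per subject and session", {
  bundle <- generate_cohort(
    scenario_config(n = 3, n_trials = 20, missing_session2 = 1), seed = 2)
  sc <- summary_scores(bundle$cohort)
  expect_equal(nrow(sc), 5)  # 3 subjects x 2 sessions - 1 missing
  expect_true(all(sc$score >= 0 & sc$score <= 1))
  expect_true(all(sc$n_trials == 20))
})
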