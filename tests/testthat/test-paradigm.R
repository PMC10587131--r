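test_that("quarter-octave ladder reproduces the many-deviant frequency set", {
  expect_equal(build_frequency_ladder(4.0, 0.25, 10, 1),
               c(4.0, 4.8, 5.7, 6.7, 8.0, 9.5, 11.3, 13.5, 16.0, 19.0))
  expect_equal(build_frequency_ladder(4.0, 0.25, 1, 1), 4.0)
  expect_equal(build_frequency_ladder(1.0, 1.0, 3, 1), c(1.0, 2.0, 4.0))
  expect_error(build_frequency_ladder(-1, 0.25, 10), class = "invalid_parameter")
  expect_error(build_frequency_ladder(4, 0.25, 0), class = "invalid_parameter")
})

test_that("half-octave contrasts resolve to the training pairs by ladder steps", {
  lad <- build_frequency_ladder(4.0, 0.25, 10, 1)
  expect_equal(frequency_for_contrast(8.0, 0.5, lad), 11.3)
  expect_equal(frequency_for_contrast(4.8, 0.5, lad), 6.7)
  expect_equal(frequency_for_contrast(8.0, 0, lad), 8.0)
  expect_equal(frequency_for_contrast(8.0, -0.5, lad), 5.7)
  expect_error(frequency_for_contrast(8.0, 1.5, lad), class = "out_of_range")
  expect_error(frequency_for_contrast(8.1, 0.5, lad), class = "invalid_parameter")
})

test_that("oddball sequences have exact counts and honour lead-in and min-run", {
  sp <- paradigm_spec("oddball", 700, 70, 8.0, 11.3, lead_in = 5, min_run = 3)
  for (seed in c(1, 7, 99)) {
    s <- make_oddball_sequence(sp, seed = seed)
    expect_equal(sum(s$role == "standard"), 630)
    expect_equal(sum(s$role == "deviant"), 70)
    expect_true(all(s$role[1:5] == "standard"))
    dev_i <- which(s$role == "deviant")
    expect_true(all(diff(dev_i) - 1L >= 3L))
    expect_equal(nrow(validate_sequence(s)), 0L)
  }
})

test_that("a single-deviant sequence is forced past the lead-in", {
  sp <- paradigm_spec("oddball", 10, 1, 8.0, 11.3, lead_in = 5, min_run = 3)
  s <- make_oddball_sequence(sp, seed = 0)
  expect_equal(sum(s$role == "deviant"), 1L)
  expect_gte(which(s$role == "deviant"), 6L)  # 0-based index >= 5
})

test_that("infeasible spacing errors report the largest feasible min_run", {
  sp <- paradigm_spec("oddball", 700, 207, 8.0, 11.3, lead_in = 5, min_run = 3)
  err <- tryCatch(make_oddball_sequence(sp, seed = 1), error = identity)
  expect_s3_class(err, "feasibility_error")
  expect_equal(err$max_feasible_min_run, 2L)  # floor((493 - 5) / 207)
  relaxed <- make_oddball_sequence(sp, seed = 1, auto_relax = TRUE)
  expect_equal(sum(relaxed$role == "deviant"), 207L)
  expect_true(all(diff(which(relaxed$role == "deviant")) - 1L >= 2L))
})

test_that("identical seeds reproduce sequences; different seeds move deviants", {
  sp <- paradigm_spec("oddball", 700, 70, 8.0, 11.3)
  a <- make_oddball_sequence(sp, seed = 11)
  b <- make_oddball_sequence(sp, seed = 11)
  c <- make_oddball_sequence(sp, seed = 12)
  expect_identical(a, b)
  expect_false(identical(which(a$role == "deviant"), which(c$role == "deviant")))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(make_oddball_sequence(paradigm_spec("oddball", 50, 5, 8, 11.3),
                                  seed = 4))
  expect_identical(runif(1), before)
})

test_that("many-deviant sequences balance candidate frequencies", {
  lad <- build_frequency_ladder(4.0, 0.25, 10, 1)
  cand <- setdiff(lad, 8.0)  # 9 candidates
  sp <- paradigm_spec("many_deviant", 720, 72, 8.0, cand)
  s <- make_many_deviant_sequence(sp, seed = 7)
  expect_equal(sum(s$role == "standard"), 648)
  counts <- table(s$frequency_khz[s$role == "deviant"])
  expect_equal(length(counts), 9L)
  expect_true(all(counts == 8L))
  # n_deviant = 9: each candidate exactly once
  sp1 <- paradigm_spec("many_deviant", 100, 9, 8.0, cand, min_run = 3)
  s1 <- make_many_deviant_sequence(sp1, seed = 2)
  expect_true(all(table(s1$frequency_khz[s1$role == "deviant"]) == 1L))
  # n_deviant = 10: one candidate doubles, seed-determined
  sp2 <- paradigm_spec("many_deviant", 100, 10, 8.0, cand, min_run = 3)
  s2 <- make_many_deviant_sequence(sp2, seed = 3)
  cc <- table(s2$frequency_khz[s2$role == "deviant"])
  expect_equal(sort(as.integer(cc)), c(rep(1L, 8), 2L))
})

test_that("the doubled many-deviant candidate is uniform across seeds", {
  lad <- build_frequency_ladder(4.0, 0.25, 10, 1)
  cand <- setdiff(lad, 8.0)
  sp <- paradigm_spec("many_deviant", 100, 10, 8.0, cand, min_run = 3)
  doubled <- vapply(1:180, function(sd) {
    s <- make_many_deviant_sequence(sp, seed = sd)
    cc <- table(s$frequency_khz[s$role == "deviant"])
    as.numeric(names(cc)[cc == 2L])
  }, numeric(1))
  tab <- table(factor(doubled, levels = cand))
  expect_true(all(tab > 0))  # every candidate doubles somewhere
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 1e-4)
})

test_that("spec construction rejects inconsistent parameters", {
  expect_error(paradigm_spec("oddball", 700, 0, 8, 11.3),
               class = "invalid_parameter")
  expect_error(paradigm_spec("oddball", 700, 70, 8, 11.3,
                             isi_s = 1.4, response_window_s = 1.49),
               class = "config_error")
  expect_error(paradigm_spec("oddball", 700, 70, 8, 8),
               class = "invalid_parameter")
  expect_error(paradigm_spec("many_deviant", 720, 72, 8,
                             c(4.0, 8.0, 9.5)),
               class = "invalid_parameter")
})

test_that("validate_sequence flags constructed violations with rule and index", {
  sp <- paradigm_spec("oddball", 10, 2, 8.0, 11.3, lead_in = 5, min_run = 3)
  roles <- c("standard", "standard", "deviant", "standard", "standard",
             "standard", "standard", "standard", "deviant", "standard")
  bad <- make_seq_from_roles(roles, sp)
  rep <- validate_sequence(bad)
  expect_true("lead_in" %in% rep$rule)
  expect_equal(rep$index[rep$rule == "lead_in"], 2L)
  roles2 <- c(rep("standard", 6), "deviant", "deviant", rep("standard", 2))
  rep2 <- validate_sequence(make_seq_from_roles(roles2, sp))
  expect_true("min_run" %in% rep2$rule)
})
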