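test_that("binned proportions are normalised by the relevant tone role", {
  tr <- data.frame(
    actual_onset_s = c(10, 20, 30, 40, 130, 140),
    role = c("deviant", "deviant", "deviant", "deviant", "standard", "standard"),
    outcome = c("HIT", "HIT", "HIT", "MISS", "FA", "CR"))
  tc <- response_timecourse(tr, bin_width_s = 120)
  b1 <- tc[tc$bin_center_s == 60, ]
  expect_equal(b1$value[b1$response_type == "HIT"], 0.75)
  expect_equal(b1$value[b1$response_type == "MISS"], 0.25)
  # first bin has no standards: no FA/CR rows there
  expect_false(any(b1$response_type %in% c("FA", "CR")))
  b2 <- tc[tc$bin_center_s == 180, ]
  expect_equal(b2$value[b2$response_type == "FA"], 0.5)
  expect_error(response_timecourse(tr[0, ]), class = "empty_input")
})

test_that("HIT+MISS and FA+CR sum to one within every bin", {
  sp <- paradigm_spec("oddball", 700, 70, 8.0, 11.3)
  s <- make_oddball_sequence(sp, seed = 8)
  log <- score_session(s, simulate_session(s, rat_agent_params(), seed = 8)$pokes)
  tc <- response_timecourse(log$trials)
  for (b in unique(tc$bin_center_s)) {
    d <- tc[tc$bin_center_s == b, ]
    if (any(d$response_type == "HIT")) {
      expect_equal(sum(d$value[d$response_type %in% c("HIT", "MISS")]), 1)
    }
    if (any(d$response_type == "FA")) {
      expect_equal(sum(d$value[d$response_type %in% c("FA", "CR")]), 1)
    }
  }
})

test_that("exponential fit recovers exact and degenerate models", {
  t <- seq(60, 1800, by = 120)
  f <- fit_exponential(t, 0.8 * exp(-0.001 * t))
  expect_lt(abs(f$a - 0.8), 1e-6)
  expect_lt(abs(f$b + 0.001), 1e-6)
  expect_equal(f$r_squared, 1)
  # constant data: amplitude c, rate 0
  fc <- fit_exponential(t, rep(0.4, length(t)))
  expect_lt(abs(fc$a - 0.4), 1e-8)
  expect_lt(abs(fc$b), 1e-8)
  expect_error(fit_exponential(t, rep(0, length(t))), class = "fit_error")
  expect_error(fit_exponential(1:2, c(1, 2)), class = "fit_error")
})

test_that("exponential rate is recovered under noise", {
  t <- seq(45, 1755, by = 90)  # 20 bins over ~1800 s
  set.seed(7)
  bs <- replicate(200, {
    y <- pmax(0, 0.8 * exp(-0.002 * t) + rnorm(length(t), 0, 0.03))
    fit_exponential(t, y)$b
  })
  expect_lt(abs(median(bs) + 0.002), 0.1 * 0.002)
})

test_that("intersection of exponential fits matches the closed form and root-finding", {
  f1 <- structure(list(a = 1, b = -0.1), class = "exp_fit")
  f2 <- structure(list(a = 0.2, b = 0.05), class = "exp_fit")
  res <- curve_intersection(f1, f2, 100)
  expect_equal(res$t_star_s, log(5) / 0.15)
  expect_lt(abs(res$t_star_s - 10.73), 0.01)
  # numerical cross-check
  root <- uniroot(function(t) f1$a * exp(f1$b * t) - f2$a * exp(f2$b * t),
                  c(0, 100), tol = 1e-12)$root
  expect_lt(abs(res$t_star_s - root), 1e-8)
  # random valid pairs: closed form equals root-finding to 1e-8
  set.seed(11)
  for (i in 1:25) {
    a1 <- runif(1, 0.2, 1); a2 <- runif(1, 0.01, 0.15)
    b1 <- runif(1, -0.01, -0.001); b2 <- runif(1, 0.0005, 0.005)
    r <- curve_intersection(structure(list(a = a1, b = b1), class = "exp_fit"),
                            structure(list(a = a2, b = b2), class = "exp_fit"),
                            1e5)
    nroot <- uniroot(function(t) a1 * exp(b1 * t) - a2 * exp(b2 * t),
                     c(0, 1e5), tol = 1e-13)$root
    expect_lt(abs(r$t_star_s - nroot), 1e-8)
  }
})

test_that("parallel and identical curves are handled explicitly", {
  f <- function(a, b) structure(list(a = a, b = b), class = "exp_fit")
  expect_equal(curve_intersection(f(1, 0), f(0.5, 0), 100),
               list(t_star_s = NULL, degenerate = FALSE))
  expect_true(curve_intersection(f(0.7, -0.01), f(0.7, -0.01), 100)$degenerate)
  expect_null(curve_intersection(f(1, -0.1), f(2, -0.1), 100)$t_star_s)
  expect_error(curve_intersection(f(-1, 0.1), f(1, 0.2), 100),
               class = "invalid_fit")
  # out-of-session intersections are suppressed
  expect_null(curve_intersection(f(1, -0.1), f(0.2, 0.05), 5)$t_star_s)
})

test_that("synthetic sessions decline in HIT/FA and rise in CR/MISS over time", {
  sp <- paradigm_spec("oddball", 700, 70, 8.0, 11.3)
  tabs <- lapply(1:8, function(i) {
    s <- make_oddball_sequence(sp, seed = 500 + i)
    score_session(s, simulate_session(s, rat_agent_params(), seed = 600 + i)$pokes)$trials
  })
  tc <- response_timecourse(tabs)
  edge_means <- function(ty) {
    d <- tc[tc$response_type == ty, ]
    q <- quantile(d$bin_center_s, c(0.25, 0.75))
    c(first = mean(d$value[d$bin_center_s <= q[1]]),
      last = mean(d$value[d$bin_center_s >= q[2]]))
  }
  for (ty in c("HIT", "FA")) {
    m <- edge_means(ty)
    expect_lt(m["last"], m["first"])
  }
  for (ty in c("CR", "MISS")) {
    m <- edge_means(ty)
    expect_gt(m["last"], m["first"])
  }
  # HIT and MISS fitted curves cross within the session
  fits <- fit_timecourses(tc)
  t_max <- max(tc$bin_center_s)
  inter <- curve_intersection(fits$HIT, fits$MISS, t_max)
  expect_false(inter$degenerate)
  expect_true(!is.null(inter$t_star_s))
})

test_that("slower engagement decay moves the HIT/MISS intersection later", {
  sp <- paradigm_spec("oddball", 700, 70, 8.0, 11.3)
  t_star <- vapply(c(1200, 3600), function(tau) {
    p <- rat_agent_params(tau_eng_s = tau)
    tabs <- lapply(1:6, function(i) {
      s <- make_oddball_sequence(sp, seed = 700 + i)
      score_session(s, simulate_session(s, p, seed = 800 + i)$pokes)$trials
    })
    tc <- response_timecourse(tabs)
    fits <- fit_timecourses(tc)
    r <- curve_intersection(fits$HIT, fits$MISS, 1e6)
    if (is.null(r$t_star_s)) Inf else r$t_star_s
  }, 0)
  expect_gt(t_star[2], t_star[1])
})
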