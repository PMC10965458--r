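test_that("normalized difference is the bounded contrast", {
  A <- makePowerMap(matrix(c(3, 2, 5, 0), 2, 2), condition = "PT")
  B <- makePowerMap(matrix(c(1, 2, 0, 0), 2, 2), condition = "Control")
  D <- normalizedDifference(A, B)
  expect_equal(diffValues(D)[1, 1], 0.5)
  expect_equal(diffValues(D)[2, 1], 0)           # A = B
  expect_equal(diffValues(D)[1, 2], 1)           # B = 0, upper bound
  expect_true(is.na(diffValues(D)[2, 2]))        # A + B = 0 masked
  v <- diffValues(D)[is.finite(diffValues(D))]
  expect_true(all(v >= -1 & v <= 1))
  B2 <- makePowerMap(matrix(1, 2, 2), freqs = c(9, 10))
  expect_error(normalizedDifference(A, B2), "different")
})

test_that("degenerate all-zero maps give p = 1 everywhere", {
  maps <- lapply(1:5, function(i)
    makeDiffMap(matrix(0, 2, 3), freqs = c(5, 6), times = c(.1, .2, .3),
                participant = paste0("s", i)))
  sr <- permutationTestVsZero(maps, n_perm = 500, seed = 1,
                              fmin = 3, fmax = 20)
  expect_true(all(pValues(sr) == 1))
  expect_true(all(!fdrSignificant(sr)))
})

test_that("exhaustive enumeration reproduces the closed-form sign-flip p", {
  n <- 10
  maps <- lapply(1:n, function(i)
    makeDiffMap(matrix(0.4, 1, 1), freqs = 5, times = 0.5,
                participant = paste0("s", i)))
  sr <- permutationTestVsZero(maps, seed = 1, exhaustive = TRUE)
  # only the all-plus and all-minus patterns reach |mean| of the observed
  expect_equal(pValues(sr)[1, 1], 2 / 2^n)
  expect_equal(sr@nPerm, 2^n)
})

test_that("random permutation converges to the exhaustive p (n <= 12)", {
  set.seed(88)
  M <- matrix(rnorm(10 * 6, mean = 0.3, sd = 1), 10, 6)
  ex <- permutationTestVsZero(M, exhaustive = TRUE)
  mc <- permutationTestVsZero(M, n_perm = 4000, seed = 9)
  pe <- as.numeric(pValues(ex)); pm <- as.numeric(pValues(mc))
  mc_err <- 3 * sqrt(pe * (1 - pe) / 4000) + 2 / 4000
  expect_true(all(abs(pm - pe) <= mc_err + 1e-12))
})

test_that("permutation p-values are valid under a symmetric null", {
  set.seed(303)
  rates <- replicate(30, {
    M <- matrix(rnorm(12 * 10), 12, 10)
    p <- as.numeric(pValues(permutationTestVsZero(
      M, n_perm = 400, seed = sample.int(1e6, 1))))
    mean(p <= 0.05)
  })
  # P(p <= .05) <= .05 for the +1-corrected estimator, up to MC error
  expect_lt(mean(rates), 0.05 + 2 * sd(rates) / sqrt(30) + 0.01)
})

test_that("BH mask matches the by-definition implementation", {
  # worked example: thresholds .0125/.025/.0375/.05
  fm <- fdrMask(c(.01, .02, .03, .5), q = .05)
  expect_equal(sum(fm$mask), 3)
  expect_equal(fm$cut, .03)
  expect_equal(sum(fdrMask(rep(1, 8), q = .05)$mask), 0)
  expect_true(fdrMask(.04, q = .05)$mask)
  # oracle: literal BH definition on random p-vectors
  bh_oracle <- function(p, q) {
    m <- length(p)
    o <- order(p)
    k <- which(p[o] <= q * seq_len(m) / m)
    rej <- rep(FALSE, m)
    if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
    rej
  }
  set.seed(12)
  for (i in 1:20) {
    p <- runif(50)^sample(c(1, 2, 3), 1)
    expect_identical(fdrMask(p, q = .05)$mask, bh_oracle(p, .05))
  }
  # NA handling preserves shape
  pm <- matrix(c(.01, NA, .2, .9), 2, 2)
  fm2 <- fdrMask(pm, q = .05)
  expect_true(is.na(fm2$mask[2, 1]))
  expect_equal(dim(fm2$mask), c(2, 2))
})

test_that("behavioral accuracy is percent correct over valid trials", {
  ev <- data.frame(
    trial_type = c(rep("CanSee", 4), rep("DoesNotSee", 4),
                   rep("Yellow", 4), rep("NotYellow", 4)),
    validity = c(rep("", 15), "verbalized"),
    correct = c(1, 1, 1, 0, 1, 1, 0, 0, 1, 1, 1, 1, 1, 1, 1, 0))
  out <- behaviorAccuracy(list(`sub-001` = ev))
  expect_equal(out$pt, 62.5)                 # 5 of 8
  expect_equal(out$can_see, 75)
  expect_equal(out$does_not_see, 50)
  expect_equal(out$yellow, 100)
  expect_equal(out$not_yellow, 100)          # coded trial excluded
  ev2 <- ev[ev$trial_type != "DoesNotSee", ]
  out2 <- behaviorAccuracy(list(`sub-002` = ev2))
  expect_true(is.na(out2$does_not_see))
  ev3 <- ev; ev3$correct <- 1
  expect_equal(behaviorAccuracy(list(s = ev3))$pt, 100)
})

test_that("group behavioral tests use the paired-t identity", {
  set.seed(2)
  n <- 12
  s <- data.frame(participant_id = paste0("s", 1:n),
                  pt = round(runif(n, 50, 100)),
                  control = round(runif(n, 60, 100)),
                  can_see = round(runif(n, 50, 100)),
                  does_not_see = round(runif(n, 40, 100)),
                  yellow = 0, not_yellow = 0)
  out <- behaviorTests(s)
  tt <- t.test(s$pt, mu = 50)
  expect_equal(out$statistic[out$test == "pt_vs_chance_t"],
               unname(tt$statistic))
  tp <- t.test(s$pt, s$control, paired = TRUE)
  expect_equal(out$statistic[out$test == "pt_vs_control_rm_anova_F"],
               unname(tp$statistic)^2)
  expect_equal(out$p[out$test == "pt_vs_control_rm_anova_F"], tp$p.value)
  # identical vectors: F = 0, p = 1
  s2 <- s; s2$control <- s2$pt
  out2 <- behaviorTests(s2)
  expect_equal(out2$statistic[out2$test == "pt_vs_control_rm_anova_F"], 0)
  expect_equal(out2$p[out2$test == "pt_vs_control_rm_anova_F"], 1)
  # noise-free constant shift: degenerate, flagged
  s3 <- s; s3$does_not_see <- s3$can_see - 5
  expect_error(behaviorTests(s3), "degenerate")
  s4 <- s; s4$pt <- 80
  expect_error(behaviorTests(s4), "degenerate")
})

test_that("brain-behavior correlations respect pairing and the q = .2 family", {
  set.seed(9)
  n <- 20
  s <- data.frame(participant_id = paste0("s", 1:n),
                  pt = rnorm(n, 80, 10), control = rnorm(n, 85, 10),
                  can_see = rnorm(n, 80, 10),
                  does_not_see = rnorm(n, 75, 10),
                  yellow = rnorm(n, 90, 5), not_yellow = rnorm(n, 88, 5))
  eff <- setNames(0.02 * s$does_not_see, s$participant_id)  # exact line
  out <- brainBehaviorCorrelations(eff, s)
  expect_equal(out$r[out$outcome == "does_not_see"], 1, tolerance = 1e-9)
  expect_equal(out$df[out$outcome == "does_not_see"], n - 2)
  expect_true(out$q_significant[out$outcome == "does_not_see"])
  # fewer than 4 pairs: skipped
  s$yellow[1:(n - 3)] <- NA
  out2 <- brainBehaviorCorrelations(eff, s)
  expect_true(is.na(out2$r[out2$outcome == "yellow"]))
  expect_equal(out2$n[out2$outcome == "yellow"], 3)
})

test_that("effect scalar averages D over the chosen region", {
  D1 <- makeDiffMap(matrix(1:6 / 10, 2, 3), freqs = c(5, 7),
                    times = c(.5, 1, 1.5), participant = "a")
  D2 <- makeDiffMap(matrix(rep(0.2, 6), 2, 3), freqs = c(5, 7),
                    times = c(.5, 1, 1.5), participant = "b")
  sc <- effectScalar(list(D1, D2),
                     region = list(band = c(6, 8), window = c(0.9, 1.6)))
  expect_equal(unname(sc["a"]), mean(c(0.4, 0.6)))
  expect_equal(unname(sc["b"]), 0.2)
})
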