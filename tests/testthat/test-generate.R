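test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_vars = 20), "at least 21")
  expect_error(sim_config(threshold = 1), "threshold")
  expect_error(sim_config(p_low = 0.9, p_high = 0.5), "p_low")
  expect_error(sim_config(competing_prob = 1.2), "probabilities")
  expect_s3_class(sim_config(n_obs = 10), "sim_config")
})

test_that("degenerate mixing proportions give the two dependence extremes", {
  # all weight on the shared component: every variable is the same
  # thresholded uniform, so all rows are identical and correlations are 1
  cfg1 <- sim_config(n_obs = 2000, p_low = 1, p_high = 1)
  set.seed(41)
  bm1 <- generate_correlated_binary(cfg1)
  expect_true(all(bm1$values == rep(bm1$values[1, ], each = nrow(bm1$values))))
  cs1 <- correlation_summary(bm1)
  expect_equal(cs1$mean, 1)
  expect_equal(cs1$sd, 0)

  # no weight on the shared component: variables are independent
  cfg0 <- sim_config(n_obs = 5000, p_low = 0, p_high = 0)
  set.seed(42)
  bm0 <- generate_correlated_binary(cfg0)
  expect_lt(abs(correlation_summary(bm0)$mean), 0.02)
})

test_that("marginal prevalence matches the trapezoidal tail and MC oracle", {
  expect_equal(marginal_prevalence(0, 0.75), 0.25)
  expect_equal(marginal_prevalence(1, 0.75), 0.25)
  # frozen value confirmed against a 1e7-draw Monte Carlo oracle (0.124911)
  expect_equal(marginal_prevalence(0.5, 0.75), 0.125)
  # symmetric in p vs 1-p, vectorised
  p <- c(0.2, 0.35, 0.6, 0.9)
  expect_equal(marginal_prevalence(p, 0.6), marginal_prevalence(1 - p, 0.6))
  expect_error(marginal_prevalence(0.5, 0), "threshold")
  expect_error(marginal_prevalence(-0.1, 0.5), "p_i")
})

test_that("empirical column prevalences match the analytic tail", {
  cfg <- sim_config(n_obs = 20000)
  set.seed(7)
  bm <- generate_correlated_binary(cfg)
  prev <- marginal_prevalence(bm$mixing_props, cfg$threshold)
  emp <- rowMeans(bm$values)
  mc_se <- sqrt(prev * (1 - prev) / cfg$n_obs)
  expect_true(all(abs(emp - prev) < 5 * mc_se))
})

test_that("correlation summary matches hand-computed phi and handles degeneracy", {
  M <- rbind(c(1, 0, 1, 1),
             c(1, 1, 0, 1),
             c(0, 0, 1, 0))
  cs <- correlation_summary(M)
  hand <- c(phi_from_counts(M[1, ], M[2, ]),
            phi_from_counts(M[1, ], M[3, ]),
            phi_from_counts(M[2, ], M[3, ]))
  expect_equal(cs$mean, mean(hand))
  expect_equal(cs$sd, sd(hand))
  expect_equal(cs$p50, sort(hand)[2])
  expect_equal(cs$n_pairs, 3L)

  ident <- rbind(c(1, 0, 1, 0), c(1, 0, 1, 0), c(1, 0, 1, 0))
  csi <- correlation_summary(ident)
  expect_equal(csi$mean, 1)
  expect_equal(csi$sd, 0)

  Mz <- rbind(M, 0)  # zero-variance row excluded with a warning
  expect_warning(csz <- correlation_summary(Mz), "zero-variance")
  expect_equal(csz$n_pairs, 3L)
  expect_error(correlation_summary(rbind(c(1, 1, 1), c(0, 1, 0))[1, , drop = FALSE]),
               "at least 2")
})

test_that("stronger shared weight yields stronger correlation", {
  set.seed(11)
  lo <- correlation_summary(generate_correlated_binary(
    sim_config(n_obs = 8000, p_low = 0.1, p_high = 0.4)))$mean
  hi <- correlation_summary(generate_correlated_binary(
    sim_config(n_obs = 8000, p_low = 0.6, p_high = 0.9)))$mean
  expect_gt(hi, lo)
})

test_that("causal structure honours forced entries and Bernoulli expectations", {
  cfg <- sim_config(n_obs = 10)
  set.seed(3)
  draws <- replicate(4000, draw_causal_structure(cfg))
  expect_true(all(draws[1, 1, ] == 1L))  # exposure pair causal for A
  expect_true(all(draws[2, 1, ] == 0L))  # ... not for B
  expect_true(all(draws[3, 1, ] == 0L))  # ... not for C
  # E[pairs for B] = 9 * 0.5; E[shared pairs B&C] = 9 * 0.25
  pairs_B <- colSums(draws[2, , ])
  shared_BC <- colSums(draws[2, , ] * draws[3, , ])
  expect_equal(mean(pairs_B), 4.5, tolerance = 0.03)
  expect_equal(mean(shared_BC), 2.25, tolerance = 0.03)
})

test_that("knowledge mask forces the exposure and hits block expectations", {
  cfg <- sim_config(n_obs = 10)
  set.seed(4)
  draws <- replicate(3000, draw_knowledge_mask(cfg))
  expect_true(all(draws[, 1, ] == 1L))
  # E[known factors per outcome] = 1 + 19 * 0.5 + 20 * 0.15 = 13.5
  expect_equal(mean(colSums(draws[1, , ])), 13.5, tolerance = 0.02)
  # rows for A and B are independent: disagreement rate 2 * 0.5 * 0.5 in 2..20
  dis <- mean(draws[1, 2:20, ] != draws[2, 2:20, ])
  expect_equal(dis, 0.5, tolerance = 0.02)
})

test_that("event matrix respects its probability", {
  set.seed(5)
  expect_true(all(draw_event_matrix(0, 3, 50) == 0L))
  expect_true(all(draw_event_matrix(1, 3, 50) == 1L))
  m <- draw_event_matrix(0.1, 3, 50000)
  expect_lt(abs(mean(m) - 0.1), 4 * sqrt(0.1 * 0.9 / length(m)))
  expect_error(draw_event_matrix(1.5, 2, 2), "p")
})

test_that("outcome rule and cause indicator match brute-force enumeration", {
  set.seed(8)
  for (case in 1:20) {
    n <- sample(1:16, 1)
    Xm <- matrix(rbinom(40 * n, 1L, runif(1, 0.2, 0.8)), 40, n)
    F_ <- matrix(rbinom(30, 1L, 0.5), 3, 10,
                 dimnames = list(c("A", "B", "C"), NULL))
    F_[, 1] <- c(1L, 0L, 0L)
    E <- matrix(rbinom(3 * n, 1L, 0.3), 3, n)
    Q <- matrix(rbinom(3 * n, 1L, 0.3), 3, n)
    for (qoc in c(TRUE, FALSE)) {
      Y <- determine_outcomes(Xm, F_, E, Q, q_overrides_competing = qoc)
      expect_identical(unname(Y), unname(brute_outcomes(Xm, F_, E, Q, qoc)))
    }
    G <- compute_cause_indicator(Xm, F_)
    expect_identical(unname(G), unname(brute_cause_indicator(Xm, F_)))
  }
})

test_that("outcome rule behaves at its forced corners", {
  n <- 6
  Xm <- matrix(1L, 40, n)
  F_ <- matrix(0L, 3, 10); F_[1, 1] <- 1L
  E1 <- matrix(1L, 3, n); E0 <- matrix(0L, 3, n)
  Q1 <- matrix(1L, 3, n); Q0 <- matrix(0L, 3, n)
  # Q = 1 forces the outcome, even under a competing event (default)
  expect_true(all(determine_outcomes(Xm, F_, E1, Q1) == 1L))
  # under the alternative precedence the competing event wins
  expect_true(all(determine_outcomes(Xm, F_, E1, Q1,
                                     q_overrides_competing = FALSE) == 0L))
  # competing event suppresses the causal path when Q = 0
  expect_true(all(determine_outcomes(Xm, F_, E1, Q0)["A", ] == 0L))
  expect_true(all(determine_outcomes(Xm, F_, E0, Q0)["A", ] == 1L))
  # pair 1 is excluded from G by construction
  expect_true(all(compute_cause_indicator(Xm, F_) == 0L))
  F_[1, 3] <- 1L
  expect_true(all(compute_cause_indicator(Xm, F_)["A", ] == 1L))
  expect_error(determine_outcomes(Xm, F_[, 1:9], E0, Q0), "3 x 10")
  expect_error(determine_outcomes(Xm, F_, E0[, 1:3], Q0), "n_obs")
})

test_that("flipping Q upward never turns an outcome off", {
  set.seed(9)
  for (case in 1:10) {
    n <- 12
    Xm <- matrix(rbinom(40 * n, 1L, 0.5), 40, n)
    F_ <- draw_causal_structure(sim_config(n_obs = n))
    E <- matrix(rbinom(3 * n, 1L, 0.4), 3, n)
    Q <- matrix(rbinom(3 * n, 1L, 0.4), 3, n)
    Y0 <- determine_outcomes(Xm, F_, E, Q)
    zero <- which(Q == 0L)
    flip <- sample(zero, 1)
    Q2 <- Q; Q2[flip] <- 1L
    Y1 <- determine_outcomes(Xm, F_, E, Q2)
    expect_true(all(Y1 >= Y0))
  }
})

test_that("replicate generation is bit-identical under a fixed seed", {
  cfg <- sim_config(n_obs = 300)
  d1 <- simulate_replicate_data(cfg, seed = 77)
  d2 <- simulate_replicate_data(cfg, seed = 77)
  expect_identical(d1, d2)
  d3 <- simulate_replicate_data(cfg, seed = 78)
  expect_false(identical(d1$X$values, d3$X$values))
})

test_that("replicate data round-trips through delimited text", {
  cfg <- sim_config(n_obs = 40)
  d <- simulate_replicate_data(cfg, seed = 21)
  dir <- withr::local_tempdir()
  write_replicate_data(d, dir)
  expect_true(file.exists(file.path(dir, "metadata.json")))
  d2 <- read_replicate_data(dir)
  expect_identical(d$X$values, d2$X$values)
  expect_equal(d$X$mixing_props, d2$X$mixing_props)
  for (f in c("F_", "E", "Q", "Y", "K", "G"))
    expect_identical(unname(d[[f]]), unname(d2[[f]]))
  expect_equal(unclass(d$config), unclass(d2$config))
  expect_equal(d$seed, d2$seed)
})

test_that("family survey encodes confounding but no direct child effect", {
  or_of <- function(y, x) {
    t <- table(factor(x, 0:1), factor(y, 0:1))
    (t["1", "1"] / t["1", "0"]) / (t["0", "1"] / t["0", "0"])
  }
  set.seed(31)
  # no direct effect: adult and child crude ORs agree (both confounded)
  fs <- generate_family_survey(100000)
  or_a <- or_of(fs$adult_outcome, fs$exposure)
  or_c <- or_of(fs$child_outcome, fs$exposure)
  expect_lt(or_a, 0.85)  # visibly confounded
  expect_equal(or_a, or_c, tolerance = 0.1)
  # no confounding: child OR near 1
  fs0 <- generate_family_survey(100000, confounder_sd = 0)
  expect_equal(or_of(fs0$child_outcome, fs0$exposure), 1, tolerance = 0.1)
  # direct effect log(2) without confounding: adult OR near 2
  fs2 <- generate_family_survey(100000, confounder_sd = 0,
                                exposure_effect_outcome = log(2))
  expect_equal(or_of(fs2$adult_outcome, fs2$exposure), 2, tolerance = 0.12)
  # CSV interface withholds the latent confounder
  path <- withr::local_tempfile(fileext = ".csv")
  write_family_survey(fs0[1:50, ], path)
  back <- read.csv(path)
  expect_named(back, c("family_id", "exposure", "adult_outcome", "child_outcome"))
})
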