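test_that("pair-configuration probabilities cover the four cases and sum to 1", {
  expect_equal(unname(pair_config_probs(0, 0)), c(1, 0, 0, 0))
  expect_equal(unname(pair_config_probs(1, 1)), c(0, 0, 0, 1))
  expect_equal(unname(pair_config_probs(0.5, 0.5)), rep(0.25, 4))
  withr::with_seed(1, {
    for (k in 1:20) {
      p <- stats::runif(2)
      expect_equal(sum(pair_config_probs(p[1], p[2])), 1)
    }
  })
  expect_error(pair_config_probs(-0.1, 0.5), "probability")
  expect_error(pair_config_probs(0.2, 1.5), "probability")
})

test_that("substructure probabilities reduce to p^l (1-p)^(6-l) when symmetric", {
  cat54 <- build_catalog()
  for (p in c(0.1, 0.37)) {
    probs <- substructure_prob(cat54$s_bm, cat54$s_bt, cat54$s_mt, p, p)
    expect_equal(unname(probs), p^cat54$links * (1 - p)^(6 - cat54$links))
  }
  expect_equal(unname(substructure_prob("none", "none", "none", 0.2, 0.2)),
               0.8^6)
})

test_that("configuration probabilities over all 64 codes sum to one", {
  codes <- enumerate_codes()
  withr::with_seed(2, {
    for (k in 1:10) {
      p <- stats::runif(2)
      total <- sum(substructure_prob(codes$s_bm, codes$s_bt, codes$s_mt,
                                     p[1], p[2]))
      expect_equal(total, 1)
    }
  })
})

test_that("symmetric model has 5 probability levels, constant within class", {
  ana <- analytic_spectrum(100, 0.1, 0.1)
  expect_equal(n_distinct_levels(ana$prob), 5L)
  by_class <- split(ana$prob, ana$class_id)
  for (v in by_class) expect_lt(diff(range(v)), 1e-15 * max(v))
})

test_that("asymmetric model has 13 statistical levels, not the class partition", {
  ana <- analytic_spectrum(100, 0.1, 0.03)
  expect_equal(n_distinct_levels(ana$prob), 13L)
  # statistical classes differ from isomorphism classes: at least one class
  # contains members with different probabilities
  spread <- vapply(split(ana$prob, ana$class_id),
                   function(v) diff(range(v)) / max(v), numeric(1))
  expect_true(any(spread > 0.1))
})

test_that("small asymmetric regime is dominated by the three two-up substructures", {
  ana <- analytic_spectrum(100, 0.1, 0.03)
  top3 <- ana[order(-ana$prob), ][1:3, ]
  expect_true(all(top3$n_up == 2 & top3$n_down == 0))
  expect_setequal(top3$code, c("none-up-up", "up-none-up", "up-up-none"))
})

test_that("swapping p_up and p_down mirrors every code's probability", {
  cat54 <- build_catalog()
  swap <- function(s) c(none = "none", down = "up", up = "down",
                        bidir = "bidir")[s]
  mirror_row <- match(
    paste(swap(cat54$s_mt), swap(cat54$s_bt), swap(cat54$s_bm), sep = "-"),
    cat54$code
  )
  a <- analytic_spectrum(50, 0.2, 0.05)
  b <- analytic_spectrum(50, 0.05, 0.2)
  expect_equal(b$prob[mirror_row], a$prob)
})

test_that("expected counts scale the probabilities by the number of triples", {
  ana <- analytic_spectrum(56, 0.1, 0.03)
  expect_equal(ana$expected, choose(56, 3) * ana$prob)
  expect_error(analytic_spectrum(2, 0.1, 0.1), ">= 3")
})

test_that("random network generator honours its edge probabilities", {
  expect_equal(nrow(generate_random_network(20, 0, 0, seed = 1)$edges), 0)
  full <- generate_random_network(10, 1, 1, seed = 1)
  expect_equal(nrow(full$edges), 10 * 9)
  # determinism
  a <- generate_random_network(15, 0.3, 0.1, seed = 42)
  b <- generate_random_network(15, 0.3, 0.1, seed = 42)
  expect_identical(a$edges, b$edges)
  # expected edge count N(N-1)(p_up+p_down)/2 within 4 sd of the binomial
  n <- 120; p_up <- 0.1; p_down <- 0.03
  m <- n * (n - 1) / 2
  net <- generate_random_network(n, p_up, p_down, seed = 7)
  mu <- m * (p_up + p_down)
  sd4 <- 4 * sqrt(m * p_up * (1 - p_up) + m * p_down * (1 - p_down))
  expect_lt(abs(nrow(net$edges) - mu), sd4)
})

test_that("ensemble mean spectra agree with the analytic expectation", {
  reps <- 60; n <- 60
  ens <- random_ensemble(n, 0.1, 0.03, reps = reps, seed = 3)
  ana <- analytic_spectrum(n, 0.1, 0.03)
  se <- pmax(ens$summary$sd / sqrt(reps),
             sqrt(choose(n, 3) * ana$prob * (1 - ana$prob) / reps))
  expect_true(all(abs(ens$summary$mean - ana$expected) <= 3 * se))
  # replicates are individually reproducible from the master seed
  ens2 <- random_ensemble(n, 0.1, 0.03, reps = reps, seed = 3)
  expect_identical(ens$eta, ens2$eta)
})
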