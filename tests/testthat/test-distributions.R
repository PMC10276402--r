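p_fig <- burst_params(mu = 50, a = 2, gamma = 1000)   # a = 2, b = 25

test_that("steady-state pmf matches the closed form", {
  expect_equal(nb_steady_state(0, burst_params(1, 1, 10)), 0.5)
  expect_equal(nb_steady_state(0, p_fig), (1 / 26)^2)
  # normalisation up to the far tail
  expect_equal(sum(nb_steady_state(0:2000, p_fig)), 1, tolerance = 1e-12)
  # log-space companion
  expect_equal(nb_steady_state(0:20, p_fig, log = TRUE),
               log(nb_steady_state(0:20, p_fig)))
})

test_that("projection bound is the smallest integer reaching the quantile", {
  b <- fsp_bound(burst_params(1, 1, 10), 0.9999)
  expect_identical(b$M, 13L)  # geometric case: 0.5^(M+1) first <= 1e-4 at 13
  expect_identical(fsp_bound(burst_params(1e-8, 5, 10))$M, 0L)

  set.seed(99)
  for (r in 1:100) {
    a <- runif(1, 0.1, 10); bb <- runif(1, 1, 300)
    pr <- burst_params(a * bb, a, 10)
    M <- fsp_bound(pr)$M
    tail <- 1 - pnbinom(M, size = a, prob = 1 / (1 + bb))
    expect_lte(tail, 1e-4)
    if (M > 0)
      expect_lt(pnbinom(M - 1, size = a, prob = 1 / (1 + bb)), 0.9999)
  }
})

test_that("capture model is Poisson and permits l > m", {
  expect_equal(capture_pmf(0, 0, 0.3), 1)
  expect_equal(capture_pmf(10, 100, 0.1), dpois(10, 10))
  expect_gt(capture_pmf(5, 3, 0.1), 0)
})

test_that("UMI marginal matches a Monte-Carlo oracle", {
  set.seed(7)
  n <- 2e5
  m <- rnbinom(n, size = 2, prob = 1 / 26)
  l <- rpois(n, m * 0.1)
  bound <- fsp_bound(p_fig)
  for (li in 0:10) {
    phat <- mean(l == li)
    se <- sqrt(phat * (1 - phat) / n)
    expect_lt(abs(umi_marginal(li, 0.1, p_fig, bound) - phat), 3 * se + 1e-9)
  }
  # negligible capture: l = 0 almost surely (up to the projection error 1e-4)
  expect_equal(umi_marginal(0, 1e-9, p_fig), 1, tolerance = 2e-4)
  expect_gte(sum(sapply(0:60, umi_marginal, alpha = 0.1, params = p_fig,
                        bound = bound)), 0.9999)
})

test_that("surviving-count distributions obey the thinning identity", {
  expect_equal(surviving_conditional(7, 7, 0), 1)
  expect_equal(surviving_conditional(0, 1, 1), 1 - exp(-1))
  expect_equal(surviving_conditional(3, 2, 1), 0)  # s > m
  for (tau in c(0.1, 1, 10))
    expect_equal(colSums(sapply(c(1, 10, 50), function(m)
      sapply(0:50, surviving_conditional, m = m, tau = tau))),
      rep(1, 3))

  # closed thinned form == explicit compound sum (far-tail truncation)
  bf <- sapply(0:100, function(s)
    sum(surviving_conditional(s, s:3000, 1) * nb_steady_state(s:3000, p_fig)))
  expect_equal(surviving_marginal(0:100, p_fig, 1), bf, tolerance = 1e-10)

  # limits: tau -> 0 gives the steady state, tau large collapses to zero
  expect_equal(surviving_marginal(0:50, p_fig, 0),
               nb_steady_state(0:50, p_fig))
  expect_equal(surviving_marginal(0, p_fig, 20), 1, tolerance = 1e-6)
})

test_that("new-transcript pmf matches closed forms and frozen oracle values", {
  # frozen arbitrary-precision reference values, a=2 b=25 tau=1
  frozen <- c(`0` = 0.15381438473588025, `1` = 0.018336721970867371,
              `2` = 0.018177958764919171, `5` = 0.017617636228999886,
              `10` = 0.016477006702280965, `25` = 0.012475010137465829,
              `60` = 0.0051279822405157911)
  np <- new_transcript_pmf(as.integer(names(frozen)), p_fig, tau = 1)
  expect_false(np$flag$unstable)
  expect_equal(unname(np$p), unname(frozen), tolerance = 1e-12)

  # n = 0 closed form for assorted stable points
  set.seed(3)
  for (r in 1:20) {
    a <- runif(1, 0.2, 5); b <- runif(1, 0.5, 60); tau <- runif(1, 0.3, 5)
    pr <- burst_params(a * b, a, 10)
    expect_equal(new_transcript_pmf(0, pr, tau)$p,
                 ((1 + b * exp(-tau)) / (1 + b))^a, tolerance = 1e-12)
  }

  # long-pulse limit: converges to the steady state
  np20 <- new_transcript_pmf(0:200, p_fig, tau = 20)
  expect_lt(max(abs(np20$p - nb_steady_state(0:200, p_fig))), 1e-6)

  # agrees with the plain-R terminating series
  expect_equal(new_transcript_pmf(0:80, p_fig, 1)$p,
               oracle_new_pmf(0:80, 2, 25, 1), tolerance = 1e-10)
})

test_that("instability is detected and reported, not raised", {
  un <- new_transcript_pmf(0:50, burst_params(2000, 20, 1000), tau = 0.005)
  expect_true(un$flag$unstable)
  expect_true(is.finite(un$flag$first_negative_n))
  expect_true(any(un$p < 0))
})

test_that("posterior over latent counts is a proper Bayes inversion", {
  bound <- fsp_bound(p_fig)
  post <- posterior_m_given_l(3, 0.1, p_fig, bound)
  expect_equal(sum(post), 1)
  # brute-force term-by-term check
  w <- dpois(3, (0:bound$M) * 0.1) * dnbinom(0:bound$M, size = 2, prob = 1 / 26)
  expect_equal(post, w / sum(w))
  # uninformative observation returns the prior
  post0 <- posterior_m_given_l(0, 1e-9, p_fig, bound)
  expect_equal(post0, nb_steady_state(0:bound$M, p_fig) /
                 sum(nb_steady_state(0:bound$M, p_fig)), tolerance = 1e-6)
})

test_that("new-given-total normalises and its normaliser tracks the steady state", {
  expect_equal(new_given_total(0, p_fig, 1)$p, 1)
  for (m in c(1, 10, 50, 100))
    expect_equal(sum(new_given_total(m, p_fig, 1)$p), 1)
  # the convolution approximates P(m) at the distribution bulk
  bulk <- 25:90  # around the mean of 50
  conv <- sapply(bulk, function(m) new_given_total(m, p_fig, 1)$normaliser)
  expect_lt(max(abs(conv / nb_steady_state(bulk, p_fig) - 1)), 0.05)
})

test_that("conversion mixtures collapse and normalise correctly", {
  ud <- poisson_uracil_pmf(60)
  # lambda_n = 0: independent of m, background only
  r0 <- conversion_rates(0.01, 0, 1000)
  bg <- sapply(0:10, function(i) sum(ud$p * dpois(i, ud$u * 0.01)))
  for (m in c(0, 5, 40)) {
    cg <- conversions_given_m(0:10, m, p_fig, r0, ud)
    expect_equal(cg$p, bg, tolerance = 1e-12)
  }
  # both rates zero: point mass at i = 0
  rz <- conversion_rates(0, 0, 1000)
  expect_equal(conversions_given_m(0:3, 10, p_fig, rz, ud)$p, c(1, 0, 0, 0))
  # normalisation at the illustrative technical settings
  rfig <- conversion_rates(0.01, 0.075, 1000)
  expect_equal(sum(conversions_given_m(0:40, 100, p_fig, rfig, ud)$p), 1,
               tolerance = 1e-8)
  # m = 0 convention: background-only mixture
  expect_equal(conversions_given_m(0:10, 0, p_fig, rfig, ud)$p, bg,
               tolerance = 1e-12)
})

test_that("cell-level conversion pmf matches oracle and Monte-Carlo draws", {
  ud <- structure(list(u = c(5L, 10L), p = c(0.4, 0.6)),
                  class = "uracil_dist")
  rates <- conversion_rates(0.02, 0.1, 500)
  pr <- burst_params(6, 1.5, 500)  # b = 4, tau = 1
  bound <- fsp_bound(pr)
  got <- conversions_given_umi(0:8, l = 2, alpha = 0.3, pr, rates, ud, bound)
  expect_false(got$flag$unstable)
  expect_equal(sum(conversions_given_umi(0:20, 2, 0.3, pr, rates, ud,
                                         bound)$p), 1, tolerance = 1e-8)
  ora <- oracle_conv_umi(0:8, 2, 0.3, 1.5, 4, 1, 0.02, 0.1, ud, bound$M)
  expect_equal(got$p, ora, tolerance = 1e-10)

  # generative Monte-Carlo oracle: sample m | l, then n | m, u, pool, i
  set.seed(21)
  ndraw <- 2e5
  post <- posterior_m_given_l(2, 0.3, pr, bound)
  m <- sample(0:bound$M, ndraw, TRUE, post)
  i <- integer(ndraw)
  for (mm in unique(m)) {
    sel <- which(m == mm)
    n <- if (mm == 0) rep(0L, length(sel)) else
      sample(0:mm, length(sel), TRUE, new_given_total(mm, pr, 1)$p)
    u <- sample(ud$u, length(sel), TRUE, ud$p)
    newread <- runif(length(sel)) < (if (mm == 0) 0 else n / mm)
    i[sel] <- rpois(length(sel), u * ifelse(newread, 0.12, 0.02))
  }
  for (ii in 0:5) {
    phat <- mean(i == ii)
    se <- sqrt(phat * (1 - phat) / ndraw)
    expect_lt(abs(got$p[ii + 1] - phat), 3 * se + 1e-9)
  }

  # lambda_n = 0 collapse for any l, alpha
  r0 <- conversion_rates(0.02, 0, 500)
  bg <- sapply(0:8, function(i) sum(ud$p * dpois(i, ud$u * 0.02)))
  expect_equal(conversions_given_umi(0:8, 7, 0.05, pr, r0, ud, bound)$p, bg,
               tolerance = 1e-10)
})

test_that("pooled conversion pmf mixes new and surviving reads by tau alone", {
  ud <- poisson_uracil_pmf(60)
  rates <- conversion_rates(0.01, 0.075, 1000)
  pr1 <- burst_params(50, 2, 1000)
  pr2 <- burst_params(400, 9, 1000)   # same gamma, different (mu, a)
  expect_equal(pooled_conversion_pmf(0:30, pr1, rates, ud),
               pooled_conversion_pmf(0:30, pr2, rates, ud))
  expect_equal(sum(pooled_conversion_pmf(0:40, pr1, rates, ud)), 1,
               tolerance = 1e-8)
  # lambda_n = 0: background only, any tau
  r0 <- conversion_rates(0.01, 0, 1000)
  bg <- sapply(0:10, function(i) sum(ud$p * dpois(i, ud$u * 0.01)))
  expect_equal(pooled_conversion_pmf(0:10, pr1, r0, ud), bg)
  # tau -> Inf: fully labelled mixture
  lab <- sapply(0:10, function(i) sum(ud$p * dpois(i, ud$u * 0.085)))
  prl <- burst_params(50, 2, 1)
  expect_equal(pooled_conversion_pmf(0:10, prl, rates, ud), lab,
               tolerance = 1e-12)
})

test_that("uracil distributions are proper and truncated sensibly", {
  emp <- empirical_uracil_pmf(c(3L, 3L, 5L, 7L, 3L))
  expect_equal(sum(emp$p), 1)
  expect_equal(emp$u, c(3L, 5L, 7L))
  expect_equal(emp$p, c(0.6, 0.2, 0.2))
  po <- poisson_uracil_pmf(60)
  expect_equal(sum(po$p), 1)
  expect_lt(1 - ppois(max(po$u), 60), 1e-8)
})
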