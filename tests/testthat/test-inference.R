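test_that("empirical initialisation follows the printed moment formulas", {
  ud <- poisson_uracil_pmf(10)
  g <- gene_observations(
    "e", data.frame(cell_id = c("c1", "c2"), l = c(1L, 2L),
                    alpha = c(0.1, 0.2)),
    y = list(c("0" = 1L), c("1" = 1L)), lambda_s = 0.01, udist = ud,
    total_T = 100, total_TC = 1)
  rates <- conversion_rates(0.01, 0.075, 240)
  set.seed(2)
  init <- empirical_init(g, rates)
  expect_equal(init$mu, 10)                    # (1/0.1 + 2/0.2)/2
  expect_equal(attr(init, "mu_hat"), 10)
  # lambda == lambda_s: clamp at 0.9
  expect_equal(attr(init, "gamma_hat"), -240 / log(0.9))
  expect_gte(init$a, 1); expect_lte(init$a, 10)

  # full labelling: lambda - lambda_s = lambda_n clamps at 0.1
  g2 <- gene_observations(
    "e2", g$cells, y = list(c("0" = 1L), c("1" = 1L)), lambda_s = 0.01,
    udist = ud, total_T = 1000, total_TC = 85)  # lambda = 0.085
  init2 <- empirical_init(g2, rates)
  expect_equal(attr(init2, "gamma_hat"), -240 / log(0.1))
  expect_equal(attr(init2, "gamma_hat"), 104.24, tolerance = 1e-4)

  # a is log-uniform on [1, 10]: check the distribution of many draws
  set.seed(8)
  draws <- replicate(2000, empirical_init(g, rates)$a)
  expect_gt(suppressWarnings(ks.test(log(draws), "punif", 0, log(10)))$p.value,
            1e-4)

  # redraws respect a positive-density requirement
  reject_all <- function(par) structure(-Inf, unstable = FALSE)
  expect_error(empirical_init(g, rates, target_fn = reject_all,
                              max_tries = 25),
               class = "slamburst_init_error")
})

test_that("Langevin proposal has the printed moments and is reproducible", {
  set.seed(5)
  x <- replicate(1e5, mala_propose(2, S_k = 0.01, grad_k = 1))
  expect_lt(abs(mean(x) - 2.01), 3 * sqrt(2 * 0.01) / sqrt(1e5))
  expect_lt(abs(sd(x) - sqrt(0.02)), 0.002)
  set.seed(42); a1 <- mala_propose(1, 0.5, 0)
  set.seed(42); a2 <- mala_propose(1, 0.5, 0)
  expect_identical(a1, a2)
  # zero gradient centres the proposal at the current value
  set.seed(6)
  y <- replicate(1e4, mala_propose(3, 0.04, 0))
  expect_lt(abs(mean(y) - 3), 3 * sqrt(2 * 0.04) / sqrt(1e4))
})

test_that("Metropolis decisions use the likelihood ratio", {
  set.seed(1)
  d <- mh_accept(-10, -10)
  expect_true(d$accepted); expect_equal(d$A, 1)
  expect_equal(mh_accept(-10, -10 + log(0.5))$A, 0.5)
  d <- mh_accept(-10, -Inf)
  expect_false(d$accepted); expect_equal(d$A, 0)
  # empirical acceptance frequency matches A
  set.seed(9)
  acc <- replicate(1e4, mh_accept(0, log(0.3))$accepted)
  expect_lt(abs(mean(acc) - 0.3), 3 * sqrt(0.3 * 0.7 / 1e4))
})

test_that("gradient estimate is the secant on acceptance, zero otherwise", {
  expect_identical(update_gradient(1, 2, -5, -4, accepted = FALSE), 0)
  expect_equal(update_gradient(1, 5, -5, -3, accepted = TRUE), 0.5)
  expect_identical(update_gradient(1, 1, -5, -5, accepted = TRUE), 0)
  # sign agrees with a finite difference of a known target
  f <- function(x) dnorm(x, 3, 1, log = TRUE)
  g <- update_gradient(1, 1.5, f(1), f(1.5), TRUE)
  expect_gt(g, 0)
  # above the mode the secant slope of the log-density is negative
  g2 <- update_gradient(5, 4.5, f(5), f(4.5), TRUE)
  expect_lt(g2, 0)
})

test_that("adaptive scaling update drives S toward the 0.574 target", {
  u <- update_adaptive(1, 0.1, A = 0.574)
  expect_equal(u$S, 1)
  expect_equal(u$eta, 0.0999)
  expect_equal(update_adaptive(1, 0.1, A = 1)$S, exp(0.1 * 0.426))
  expect_equal(update_adaptive(1, 0.1, A = 0)$S, exp(-0.1 * 0.574))
  eta <- 0.1
  for (k in 1:50) eta <- update_adaptive(1, eta, 0.5)$eta
  expect_equal(eta, 0.1 * 0.999^50)
})

test_that("a Gibbs sweep updates coordinates sequentially and is stationary under null proposals", {
  target <- function(theta) {
    structure(sum(dnorm(theta, c(10, 2, 50), c(1, 0.5, 5), log = TRUE)),
              unstable = FALSE)
  }
  st <- list(S = c(0.1, 0.1, 0.1), grad = c(0, 0, 0), eta = 0.1)
  th <- c(10, 2, 50)
  # proposals forced to the current value: the chain never moves
  sw <- gibbs_sweep(th, as.numeric(target(th)), target, st,
                    propose_fn = function(t, S, g) t)
  expect_identical(sw$theta, th)
  expect_identical(sw$accepted, rep(TRUE, 3))  # A = 1 at equal targets
  expect_false(sw$instab)
  # conditional semantics: coordinate k's target sees earlier updates
  seen <- list()
  spy <- function(theta) {
    seen[[length(seen) + 1]] <<- theta
    target(theta)
  }
  set.seed(77)
  sw2 <- gibbs_sweep(th, as.numeric(target(th)), spy, st)
  moved <- which(sw2$accepted)
  if (length(moved) && moved[1] < 3) {
    k <- moved[1]
    later <- seen[[length(seen)]]           # proposal for coordinate 3
    expect_equal(later[k], sw2$theta[k])    # carries the accepted update
  }
  expect_length(sw2$accepted, 3)
})

test_that("the accept/adapt machinery samples a known density (detailed balance smoke test)", {
  # symmetric proposal: gradient forced to zero, fixed scale, no adaptation
  set.seed(123)
  target <- function(x) dnorm(x, 1, 2, log = TRUE)
  x <- 1; lp <- target(x)
  out <- numeric(20000)
  for (j in seq_along(out)) {
    prop <- mala_propose(x, S_k = 2, grad_k = 0)
    dec <- mh_accept(lp, target(prop))
    if (dec$accepted) { x <- prop; lp <- target(prop) }
    out[j] <- x
  }
  keep <- out[5001:20000]
  qs <- quantile(keep, c(0.25, 0.5, 0.75))
  expect_equal(unname(qs), qnorm(c(0.25, 0.5, 0.75), 1, 2), tolerance = 0.12)
})

test_that("run_chain completes on a stable simulated gene, reproducibly", {
  sim <- fix_gene()
  rates <- fix_rates()
  cfg <- chain_config(n_steps = 240, window = 120, w = 100)
  res <- run_chain(sim$gene, rates, config = cfg, seed = 101)
  expect_s3_class(res, "posterior_chain")
  expect_identical(res$model, 2L)
  expect_true(is.na(res$switch_step))
  expect_identical(nrow(res$samples), 60L)   # window / thin
  expect_identical(colnames(res$samples),
                   c("mu", "a", "gamma", "b", "kappa", "delta"))
  # derived samples transform per draw
  expect_equal(res$samples[, "b"],
               res$samples[, "mu"] / res$samples[, "a"])
  expect_equal(res$samples[, "delta"], 1 / res$samples[, "gamma"])
  # CV definition
  expect_equal(res$summary$cv,
               apply(res$samples, 2, sd) / colMeans(res$samples),
               ignore_attr = TRUE)
  # bit-reproducible under the same seed
  res2 <- run_chain(sim$gene, rates, config = cfg, seed = 101)
  expect_identical(res2$samples, res$samples)
  expect_identical(res2$acceptance, res$acceptance)
  # different seed gives a different trajectory
  res3 <- run_chain(sim$gene, rates, config = cfg, seed = 102)
  expect_false(identical(res3$samples, res$samples))
})

test_that("thinned posterior sample counts match the printed chain rules", {
  cfg <- slamburst:::.resolve_config(chain_config(), mu_hat = 10)
  expect_identical(cfg$n_steps, 5000L)
  expect_identical(cfg$window, 2500L)
  expect_identical(cfg$w, 500L)
  expect_identical(length(seq(cfg$n_steps - cfg$window + cfg$thin,
                              cfg$n_steps, by = cfg$thin)), 1250L)
  cfg2 <- slamburst:::.resolve_config(chain_config(), mu_hat = 1e4)
  expect_identical(cfg2$n_steps, 1500L)
  expect_identical(cfg2$window, 1000L)
  expect_identical(cfg2$w, 100L)
  expect_identical(length(seq(cfg2$n_steps - cfg2$window + cfg2$thin,
                              cfg2$n_steps, by = cfg2$thin)), 500L)
})

test_that("gene selection filters on the worst CV and is monotone", {
  mk <- function(cv) structure(
    list(summary = data.frame(
      parameter = c("mu", "a", "gamma", "b", "kappa", "delta"),
      estimate = 1, sd = 1, cv = cv)),
    class = "posterior_chain")
  r1 <- mk(rep(0.1, 6))
  r2 <- mk(c(0.1, 0.1, 0.1, 0.5, 0.1, 0.1))   # cv(b) = 0.5
  r3 <- mk(c(0.1, 0.1, 0.1, 0.1, 0.1, 0.46))  # cv(delta) just over
  expect_length(select_genes(list(r1, r2, r3), cv_max = 0.45), 1)
  expect_length(select_genes(list(r1, r2, r3), cv_max = 0.46), 2)
  # raising cv_max never drops a previously kept gene
  ns <- sapply(c(0.05, 0.2, 0.45, 0.5, 0.7),
               function(cv) length(select_genes(list(r1, r2, r3), cv)))
  expect_true(all(diff(ns) >= 0))
})
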