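make_design <- function(x, sid, case) {
  structure(list(X = matrix(x, ncol = 1), stratum = as.integer(sid),
                 case = as.numeric(case), n_strata = length(unique(sid))),
            class = "clogit_design")
}

test_that("negative log-likelihood has its closed-form values", {
  # beta = 0: every stratum contributes log(n_s)
  d <- make_design(rnorm(10), rep(1:3, c(4, 3, 3)),
                   c(1, 0, 0, 0, 1, 0, 0, 1, 0, 0))
  expect_equal(as.numeric(clogit_negloglik(0, d)), log(4) + log(3) + log(3))
  # single stratum, case x = 1, controls 0,0,0, beta = log 3:
  # -log(3 / (3 + 3)) = log 2 by direct softmax evaluation
  d1 <- make_design(c(1, 0, 0, 0), rep(1, 4), c(1, 0, 0, 0))
  expect_equal(as.numeric(clogit_negloglik(log(3), d1)), log(2))
  d1$X[2, 1] <- NA
  expect_error(clogit_negloglik(0, d1), "non-finite")
})

test_that("analytic gradient matches central finite differences", {
  set.seed(8)
  for (rep in 1:5) {
    n_str <- 30; p <- 3
    sid <- rep(seq_len(n_str), each = 4)
    X <- matrix(rnorm(4 * n_str * p), ncol = p)
    case <- as.numeric(stats::ave(runif(4 * n_str), sid,
                                  FUN = function(u) u == max(u)))
    d <- structure(list(X = X, stratum = sid, case = case, n_strata = n_str),
                   class = "clogit_design")
    beta <- rnorm(p, sd = 0.5)
    g <- attr(clogit_negloglik(beta, d), "gradient")
    h <- 1e-5
    g_fd <- vapply(seq_len(p), function(j) {
      e <- numeric(p); e[j] <- h
      (as.numeric(clogit_negloglik(beta + e, d)) -
         as.numeric(clogit_negloglik(beta - e, d))) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(g - g_fd)), 1e-6)
  }
})

test_that("the fitter agrees with independent oracles", {
  # grid-search oracle on a small binary-covariate problem
  set.seed(9)
  sid <- rep(1:20, each = 4)
  x <- rbinom(80, 1, 0.5)
  case <- draw_cases(x, sid, b = 0.7)
  d <- make_design(x, sid, case)
  f <- clogit_fit(d)
  grid <- seq(-5, 5, by = 1e-3)
  ll <- vapply(grid, oracle_cloglik, numeric(1), x = x, sid = sid, case = case)
  expect_lt(abs(f$beta - grid[which.max(ll)]), 2e-3)
  # survival::coxph (exact conditional likelihood) cross-check on a larger
  # two-covariate problem
  skip_if_not_installed("survival")
  set.seed(10)
  sid2 <- rep(1:300, each = 4)
  X2 <- cbind(rnorm(1200), rnorm(1200))
  eta <- drop(X2 %*% c(0.5, -0.3))
  case2 <- numeric(1200)
  for (i in split(seq_len(1200), sid2)) {
    w <- exp(eta[i])
    case2[i[sample.int(4, 1, prob = w / sum(w))]] <- 1
  }
  d2 <- structure(list(X = X2, stratum = sid2, case = case2, n_strata = 300),
                  class = "clogit_design")
  f2 <- clogit_fit(d2)
  x1 <- X2[, 1]; x2c <- X2[, 2]
  sv <- survival::coxph(survival::Surv(rep(1, 1200), case2) ~ x1 + x2c +
                          survival::strata(sid2), method = "exact")
  expect_equal(unname(f2$beta), unname(coef(sv)), tolerance = 1e-5)
  expect_equal(unname(sqrt(diag(f2$vcov))),
               unname(sqrt(diag(vcov(sv)))), tolerance = 1e-4)
  expect_equal(f2$loglik, as.numeric(logLik(sv)), tolerance = 1e-6)
})

test_that("symmetric designs give a zero estimate", {
  # within each stratum the case covariate pattern is mirrored by a control,
  # so the conditional MLE is exactly 0
  sid <- rep(1:25, each = 2)
  x <- rep(c(1, 1), 25)
  case <- rep(c(1, 0), 25)
  d <- make_design(x, sid, case)
  expect_error(clogit_fit(d), "no informative strata")
  # mirrored pairs: half the strata have the case at x=0, half at x=1
  sid3 <- rep(1:30, each = 2)
  x3 <- rep(c(0, 1), 30)
  case3 <- unlist(lapply(1:30, function(i) if (i %% 2) c(1, 0) else c(0, 1)))
  d3 <- make_design(x3, sid3, case3)
  f3 <- clogit_fit(d3)
  expect_equal(f3$beta, 0, tolerance = 1e-8)
})

test_that("likelihood is invariant to stratum-constant covariate shifts", {
  set.seed(11)
  sid <- rep(1:50, each = 4)
  X <- matrix(rnorm(200 * 2), ncol = 2)
  case <- as.numeric(stats::ave(runif(200), sid, FUN = function(u) u == max(u)))
  d <- structure(list(X = X, stratum = sid, case = case, n_strata = 50),
                 class = "clogit_design")
  f <- clogit_fit(d)
  Xs <- X
  Xs[, 1] <- Xs[, 1] + rep(rnorm(50), each = 4)   # stratum-constant shift
  ds <- d; ds$X <- Xs
  fs <- clogit_fit(ds)
  expect_equal(fs$beta, f$beta, tolerance = 1e-6)
  expect_equal(fs$loglik, f$loglik, tolerance = 1e-8)
})

test_that("complete separation raises a diagnostic", {
  sid <- rep(1:15, each = 3)
  x <- rep(c(1, 0, 0), 15)       # case always has the strictly maximal x
  case <- rep(c(1, 0, 0), 15)
  d <- make_design(x, sid, case)
  expect_warning(f <- clogit_fit(d), "separation")
  expect_true(f$separation)
})

test_that("AIC is 2k - 2 loglik and penalizes pure-noise columns on average", {
  fake <- structure(list(beta = rep(0, 4), loglik = -100, converged = TRUE),
                    class = "clogit_fit")
  expect_equal(clogit_aic(fake), 208)
  fake$converged <- FALSE
  expect_error(clogit_aic(fake), "converged")
  set.seed(12)
  lin <- basis_spec("linear", boundary = c(0, 100), reference = 50)
  delta <- replicate(12, {
    st <- simulate_strata(400, 0.01, list(heat_pctl = lin), seed = sample.int(1e6, 1))
    st$noise <- rnorm(nrow(st))
    f1 <- clogit_fit(build_design(st, list(heat_pctl = lin)))
    f2 <- clogit_fit(build_design(st, list(
      heat_pctl = lin, noise = basis_spec("linear", boundary = c(-5, 5), reference = 0))))
    clogit_aic(f2) - clogit_aic(f1)
  })
  expect_gt(mean(delta), 0)
  # identical designs give identical AIC
  st <- simulate_strata(100, 0.01, list(heat_pctl = lin), seed = 1)
  f <- clogit_fit(build_design(st, list(heat_pctl = lin)))
  g <- clogit_fit(build_design(st, list(heat_pctl = lin)))
  expect_identical(clogit_aic(f), clogit_aic(g))
})

test_that("estimation error shrinks as strata accumulate", {
  lin <- basis_spec("linear", boundary = c(0, 100), reference = 50)
  b <- log(1.5) / 49
  err <- function(n, seeds) mean(vapply(seeds, function(s) {
    st <- simulate_strata(n, b, list(heat_pctl = lin), seed = s)
    abs(clogit_fit(build_design(st, list(heat_pctl = lin)))$beta - b)
  }, numeric(1)))
  expect_lt(err(20000, 1:3), err(1000, 1:3))
})

test_that("AIC df selection returns the argmin with small-df tie-breaking", {
  lin <- basis_spec("linear", boundary = c(0, 100), reference = 50)
  st <- simulate_strata(2000, log(2) / 49, list(heat_pctl = lin), seed = 13)
  sel <- select_df(st, "heat_pctl", candidate_dfs = 4L)
  expect_equal(sel$chosen_df, 4)           # single candidate returned trivially
  sel2 <- select_df(st, "heat_pctl", candidate_dfs = c(1L, 4L))
  expect_true(sel2$chosen_df %in% c(1L, 4L))
  expect_equal(nrow(sel2$aic_table), 2)
  expect_true(all(sel2$aic_table$converged))
})
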