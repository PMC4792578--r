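test_that("cox_univariate reproduces the analytic 3-subject worked example", {
  # partial likelihood e^b / ((2e^b + 1)(1 + e^b)) is maximised at
  # e^b = 1/sqrt(2), i.e. b = -ln(2)/2
  surv <- toy_surv(c(1, 2, 3), c(1, 1, 0))
  fit <- cox_univariate(c(1, 0, 1), surv)
  expect_equal(fit$coef, -log(2) / 2, tolerance = 1e-6)
  expect_equal(fit$hr, 1 / sqrt(2), tolerance = 1e-6)
  expect_true(fit$ci_low <= fit$hr && fit$hr <= fit$ci_high)
})

test_that("cox_univariate validates its inputs", {
  surv <- toy_surv(c(1, 2, 3, 4), c(1, 1, 0, 0))
  expect_error(cox_univariate(c(1, 1, 1, 1), surv), "constant")
  expect_error(cox_univariate(c(1, 0, 1, 0), toy_surv(1:4, c(1, 0, 0, 0))),
               "2 events")
  expect_error(cox_univariate(c(1, 0), surv), "length")
})

test_that("cox_univariate recovers a simulated hazard ratio of 2", {
  set.seed(1234)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  t_event <- rexp(n, rate = 0.05 * 2^x)
  cens <- runif(n, 0, 40)                 # roughly 30% censoring
  surv <- toy_surv(pmin(t_event, cens), as.integer(t_event <= cens),
                   ids = sprintf("p%04d", 1:n))
  fit <- cox_univariate(x, surv)
  expect_gt(fit$hr, 1.8)
  expect_lt(fit$hr, 2.2)
})

test_that("relabelling a binary covariate inverts the hazard ratio", {
  set.seed(55)
  n <- 120
  x <- rbinom(n, 1, 0.4)
  surv <- toy_surv(rexp(n, 0.05 * 3^x), rbinom(n, 1, 0.8),
                   ids = sprintf("p%03d", 1:n))
  f1 <- cox_univariate(x, surv)
  f2 <- cox_univariate(1 - x, surv)
  expect_equal(f1$coef, -f2$coef, tolerance = 1e-8)
  expect_equal(f1$hr, 1 / f2$hr, tolerance = 1e-8)
})

test_that("cox_multivariate reduces to the univariate fit and checks rank", {
  set.seed(77)
  n <- 80
  x <- rnorm(n)
  surv <- toy_surv(rexp(n, 0.05 * exp(0.5 * x)), rbinom(n, 1, 0.7),
                   ids = sprintf("p%03d", 1:n))
  uni <- cox_univariate(x, surv)
  multi <- cox_multivariate(data.frame(x = x), surv)
  expect_equal(multi$x$coef, uni$coef, tolerance = 1e-8)
  expect_equal(multi$x$se, uni$se, tolerance = 1e-8)
  expect_error(cox_multivariate(data.frame(x = x, y = x), surv),
               "rank-deficient")
})

test_that("cox_multivariate separates a planted effect from a null covariate", {
  set.seed(99)
  n <- 400
  x1 <- rbinom(n, 1, 0.5)       # true HR 3
  x2 <- rbinom(n, 1, 0.5)       # true HR 1
  surv <- toy_surv(rexp(n, 0.04 * 3^x1), rbinom(n, 1, 0.8),
                   ids = sprintf("p%04d", 1:n))
  res <- cox_multivariate(data.frame(risk = x1, null = x2), surv)
  expect_gt(res$risk$ci_low, 1)
  expect_true(res$null$ci_low <= 1 && res$null$ci_high >= 1)
})

test_that("cox_multivariate drops incomplete cases and reports the count", {
  set.seed(31)
  n <- 60
  x <- rnorm(n); x[1:5] <- NA
  surv <- toy_surv(rexp(n, 0.1), rbinom(n, 1, 0.8),
                   ids = sprintf("p%03d", 1:n))
  res <- cox_multivariate(data.frame(x = x), surv)
  expect_identical(attr(res, "n_dropped"), 5L)
  expect_identical(attr(res, "n_used"), 55L)
})

test_that("km_logrank handles identical, separated and degenerate groups", {
  # identical (time, event) multisets -> chi2 = 0, p = 1
  tm <- c(1, 2, 3, 4, 5); ev <- c(1, 1, 0, 1, 0)
  surv <- toy_surv(c(tm, tm), c(ev, ev), ids = sprintf("p%02d", 1:10))
  r <- km_logrank(rep(c("a", "b"), each = 5), surv)
  expect_equal(r$chi2, 0, tolerance = 1e-10)
  expect_equal(r$p, 1, tolerance = 1e-10)
  expect_named(r$curves, c("a", "b"))
  # strong planted separation
  set.seed(7)
  n <- 150
  surv2 <- toy_surv(c(rexp(n, 0.02), rexp(n, 0.08)),
                    rbinom(2 * n, 1, 0.8), ids = sprintf("p%03d", 1:(2 * n)))
  r2 <- km_logrank(rep(c("lo", "hi"), each = n), surv2)
  expect_lt(r2$p, 0.001)
  # single group is an error
  expect_error(km_logrank(rep("a", 10), surv), "2 non-empty groups")
})

test_that("harrell_c matches its definition on hand-worked fixtures", {
  # perfect discrimination
  expect_equal(harrell_c(c(3, 2, 1), toy_surv(c(1, 2, 3), c(1, 1, 1)))$c, 1)
  # derived fixture: usable pairs 3, concordant 2
  r <- harrell_c(c(5, 5, 2, 1), toy_surv(c(2, 1, 4, 3), c(1, 0, 1, 1)))
  expect_identical(r$n_usable, 3L)
  expect_identical(r$n_concordant, 2L)
  expect_equal(r$c, 2 / 3)
  # all tied scores
  expect_equal(harrell_c(rep(1, 4), toy_surv(1:4, rep(1, 4)))$c, 0.5)
  # only event sits at the latest time: no usable ordered pair exists
  expect_error(harrell_c(1:3, toy_surv(c(1, 2, 3), c(0, 0, 1))), "usable")
})

test_that("harrell_c equals the O(n^2) loop oracle and is rank-invariant", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- c(10, 50, 120, 200)[seed]
    time <- round(rexp(n, 0.1), 2)       # rounding forces some ties
    event <- rbinom(n, 1, 0.7)
    score <- sample(round(rnorm(n), 1))
    surv <- toy_surv(time, event, ids = sprintf("p%03d", 1:n))
    r <- harrell_c(score, surv)
    expect_equal(r$c, oracle_c_index(score, time, event), tolerance = 1e-12)
    # strictly increasing transform leaves C unchanged
    r2 <- harrell_c(exp(score / 2) + 7, surv)
    expect_equal(r2$c, r$c, tolerance = 1e-12)
  }
})

test_that("bh_fdr applies the step-up rule", {
  expect_equal(bh_fdr(c(0.002, 0.01, 0.03, 0.04)),
               c(0.008, 0.02, 0.04, 0.04))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(3)
  p <- runif(40)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  perm <- sample(40)
  expect_equal(bh_fdr(p[perm]), q[perm])
})

test_that("spearman_test handles exact small-n and approximate large-n cases", {
  expect_equal(spearman_test(1:4, 2 * (1:4))$rho, 1)
  expect_equal(spearman_test(1:5, -(1:5))$rho, -1)
  r <- spearman_test(c(1, 2, 3), c(3, 1, 2))
  expect_equal(r$rho, -0.5)               # 1 - 6*6/(3*8)
  expect_identical(r$method, "exact permutation")
  expect_error(spearman_test(1:5, rep(2, 5)), "constant")
  expect_error(spearman_test(1:4, 1:5), "equal length")
  # exact permutation p at n = 8 equals direct enumeration via cor.test
  set.seed(9)
  x <- rnorm(8); y <- x + rnorm(8)
  r8 <- spearman_test(x, y)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = TRUE))
  expect_equal(r8$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(r8$p, ct$p.value, tolerance = 1e-10)
  # large-n t approximation is close to cor.test's
  set.seed(10)
  x <- rnorm(40); y <- 0.5 * x + rnorm(40)
  r40 <- spearman_test(x, y)
  ct40 <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_identical(r40$method, "t approximation")
  expect_equal(r40$rho, unname(ct40$estimate), tolerance = 1e-12)
})

test_that("deg_concordance on identical cohorts gives p = 0.5^shared", {
  set.seed(42)
  n_genes <- 150; n <- 30
  m <- matrix(rnorm(n_genes * n), nrow = n_genes,
              dimnames = list(sprintf("g%03d", 1:n_genes),
                              sprintf("s%02d", 1:n)))
  labels <- rep(c("lo", "hi"), each = n / 2)
  m[1:40, labels == "hi"] <- m[1:40, labels == "hi"] +
    rep(c(2, -2), length.out = 40)       # planted DEGs, both directions
  r <- deg_concordance(m, labels, m, labels, fdr = 0.05)
  expect_gt(r$shared, 20)
  expect_identical(r$shared, r$same_direction)
  expect_equal(r$log_p, r$shared * log(0.5), tolerance = 1e-10)
  # no signal anywhere -> nothing shared, p = 1
  m0 <- matrix(rnorm(n_genes * n), nrow = n_genes, dimnames = dimnames(m))
  r0 <- deg_concordance(m0, labels, m0[, sample(n)], labels, fdr = 1e-6)
  expect_identical(r0$shared, 0L)
  expect_equal(r0$p, 1)
})
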