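# independent oracle: golden-section maximisation of the two binomial
# likelihoods over their proportions
oracle_lrt <- function(k_a, n_a, k_b, n_b) {
  ll <- function(p, k, n) sum(dbinom(k, n, p, log = TRUE))
  opt <- function(k, n) {
    o <- optimize(function(p) ll(p, k, n), c(1e-9, 1 - 1e-9), maximum = TRUE)
    o$objective
  }
  l1 <- opt(k_a, n_a) + opt(k_b, n_b)
  l0 <- opt(c(k_a, k_b), c(n_a, n_b))
  D <- max(0, 2 * (l1 - l0))
  list(statistic = D, p.value = pchisq(D, 1, lower.tail = FALSE))
}

test_that("identical groups give a zero statistic and p = 1", {
  r <- lrt_binomial_glm(rep(10L, 3), rep(100L, 3), rep(10L, 3), rep(100L, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)
  # boundary: all-zero edited in both groups
  r0 <- lrt_binomial_glm(c(0L, 0L), c(50L, 50L), c(0L, 0L, 0L), rep(50L, 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p.value, 1)
  # boundary: fully edited everywhere
  r1 <- lrt_binomial_glm(c(50L, 50L), c(50L, 50L), rep(50L, 3), rep(50L, 3))
  expect_equal(r1$statistic, 0)
  expect_false(is.nan(r1$p.value))
})

test_that("the LRT matches brute-force likelihood maximisation", {
  r <- lrt_binomial_glm(rep(10L, 3), rep(100L, 3), rep(30L, 3), rep(100L, 3))
  o <- oracle_lrt(rep(10L, 3), rep(100L, 3), rep(30L, 3), rep(100L, 3))
  expect_lt(abs(r$p.value - o$p.value), 1e-4)

  set.seed(53)
  for (i in 1:50) {
    na_ <- sample(10:200, sample(1:4, 1), replace = TRUE)
    nb <- sample(10:200, sample(1:4, 1), replace = TRUE)
    ka <- rbinom(length(na_), na_, runif(1, 0.05, 0.95))
    kb <- rbinom(length(nb), nb, runif(1, 0.05, 0.95))
    if (sum(ka) == 0 && sum(kb) == 0) next
    r <- lrt_binomial_glm(ka, na_, kb, nb)
    o <- oracle_lrt(ka, na_, kb, nb)
    expect_lt(abs(r$p.value - o$p.value), 1e-4)
  }
})

test_that("the LRT agrees with the binomial GLM deviance test", {
  set.seed(54)
  for (i in 1:10) {
    ka <- rbinom(3, 80, 0.2); kb <- rbinom(3, 80, 0.35)
    r <- lrt_binomial_glm(ka, rep(80L, 3), kb, rep(80L, 3))
    grp <- factor(rep(c("a", "b"), each = 3))
    fit <- glm(cbind(c(ka, kb), 80 - c(ka, kb)) ~ grp, family = binomial)
    null <- glm(cbind(c(ka, kb), 80 - c(ka, kb)) ~ 1, family = binomial)
    D_glm <- null$deviance - fit$deviance
    expect_equal(r$statistic, D_glm, tolerance = 1e-8)
  }
})

test_that("a single replicate per group reduces to the 2x2 G-test", {
  gtest <- function(k1, n1, k2, n2) {
    obs <- c(k1, n1 - k1, k2, n2 - k2)
    rs <- c(k1 + k2, (n1 - k1) + (n2 - k2))
    cs <- c(n1, n2)
    expd <- c(rs[1] * cs[1], rs[2] * cs[1], rs[1] * cs[2], rs[2] * cs[2]) /
      sum(cs)
    2 * sum(ifelse(obs > 0, obs * log(obs / expd), 0))
  }
  cases <- list(c(5L, 40L, 15L, 50L), c(0L, 30L, 10L, 30L),
                c(12L, 60L, 12L, 60L))
  for (cs in cases) {
    r <- lrt_binomial_glm(cs[1], cs[2], cs[3], cs[4])
    expect_equal(r$statistic, gtest(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-10)
  }
})

test_that("BH adjustment reproduces the hand step-up computation", {
  p <- c(0.01, 0.02, 0.03, 0.04, 0.05)
  expect_equal(bh_fdr(p), rep(0.05, 5))
  expect_equal(bh_fdr(0.031), 0.031)
  expect_equal(bh_fdr(rep(0.2, 4)), rep(0.2, 4))
  q <- bh_fdr(runif(100))
  expect_true(all(q >= 0 & q <= 1))
})

test_that("classification thresholds and nesting behave as defined", {
  res <- data.table(site = c("s1", "s2", "s3"),
                    delta = c(0.15, 0.5, -0.25),
                    q.value = c(0.01, 0.2, 0.01))
  cl <- classify_sites(res, fdr = 0.05, diffs = c(0.10, 0.20))
  expect_identical(cl$results$class_10p, c("up", "ns", "down"))
  expect_identical(cl$results$class_20p, c("ns", "ns", "down"))
  # 20p calls are a subset of 10p calls
  called20 <- cl$results[class_20p != "ns", site]
  called10 <- cl$results[class_10p != "ns", site]
  expect_true(all(called20 %in% called10))
})

sim_counts <- function(p_a, p_b, depth, reps, n_sites, seed) {
  set.seed(seed)
  rbindlist(lapply(seq_len(n_sites), function(i) {
    data.table(site = sprintf("s%04d", i),
               group = rep(c("A", "B"), each = reps),
               replicate = rep(seq_len(reps), 2L),
               k = c(rbinom(reps, depth, p_a[i]),
                     rbinom(reps, depth, p_b[i])),
               n = depth)
  }))
}

test_that("group-label symmetry flips up and down exactly", {
  p <- runif(200, 0.1, 0.6)
  cnt <- sim_counts(p, pmin(p + 0.25, 0.95), 60L, 3L, 200L, seed = 57)
  ab <- differential_editing(cnt, "A", "B")
  ba <- differential_editing(cnt, "B", "A")
  expect_equal(ab$results$statistic, ba$results$statistic)
  expect_equal(ab$results$delta, -ba$results$delta)
  expect_identical(ab$summary$up, ba$summary$down)
  expect_identical(ab$summary$down, ba$summary$up)
})

test_that("sites failing the per-replicate coverage rule are untestable", {
  cnt <- data.table(site = rep(c("s1", "s2"), each = 4L),
                    group = rep(c("A", "A", "B", "B"), 2L),
                    replicate = rep(1:2, 4L),
                    k = 3L, n = c(rep(50L, 4), 50L, 9L, 50L, 50L))
  out <- differential_editing(cnt, "A", "B", min_coverage = 10L)
  expect_identical(out$results$site, "s1")
  expect_identical(out$n_untestable, 1L)
})

test_that("pooled and replicate-mean deltas are both available", {
  cnt <- data.table(site = "s1", group = rep(c("A", "B"), each = 2L),
                    replicate = rep(1:2, 2L),
                    k = c(10L, 20L, 30L, 10L), n = c(100L, 50L, 100L, 50L))
  pooled <- differential_editing(cnt, "A", "B")$results$delta
  meaned <- differential_editing(cnt, "A", "B",
                                 delta_mode = "mean")$results$delta
  expect_equal(pooled, (30 + 10) / 150 - (10 + 20) / 150)
  expect_equal(meaned, mean(c(0.3, 0.2)) - mean(c(0.1, 0.4)))
})
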