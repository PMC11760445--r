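# Gated comparisons, variability tests, correlations and observed power.

test_that("identical groups give a null omnibus result", {
  v <- rep(c(1.1, 2.3, 0.4, 1.8, 0.9), 3L)
  g <- rep(c("A", "B", "C"), each = 5L)
  res <- gate_and_compare(v, g)
  expect_gt(res$omnibus_p, 0.99)
  expect_true(all(res$pairwise$p_adj > 0.99))
})

test_that("a 5-SD shift is detected through the parametric branch", {
  set.seed(12)
  v <- c(rnorm(10), rnorm(10), rnorm(10) + 5)
  g <- rep(c("A", "B", "C"), each = 10L)
  res <- gate_and_compare(v, g)
  expect_identical(res$test_used, "anova")
  expect_lt(res$omnibus_p, 0.001)
  expect_identical(unique(res$pairwise$method), "holm-sidak")
  expect_gt(res$observed_power, 0.99)
  # the shifted group separates from both others
  pc <- res$pairwise[res$pairwise$group1 == "C" | res$pairwise$group2 == "C", ]
  expect_true(all(pc$p_adj < 0.01))
})

test_that("non-normal data route to Kruskal-Wallis with Dunn-Bonferroni", {
  set.seed(23)
  v <- c(rcauchy(12), rcauchy(12), rcauchy(12) + 30)
  g <- rep(c("A", "B", "C"), each = 12L)
  res <- gate_and_compare(v, g)
  expect_identical(res$test_used, "kruskal")
  expect_identical(unique(res$pairwise$method), "dunn-bonferroni")
  # Bonferroni: adjusted p = min(1, m * raw p)
  expect_equal(res$pairwise$p_adj,
               pmin(1, nrow(res$pairwise) * res$pairwise$p_raw))
  expect_error(gate_and_compare(c(1, 2), c("A", "B")), "at least 2")
})

test_that("Holm-Sidak adjustment matches its closed form and is monotone", {
  p <- c(0.01, 0.04, 0.03)
  adj <- holm_sidak(p)
  expect_equal(adj[1L], 1 - (1 - 0.01)^3)
  expect_equal(adj[3L], max(1 - (1 - 0.03)^2, adj[1L]))
  expect_equal(adj[2L], max(1 - (1 - 0.04)^1, adj[3L]))
  expect_true(all(adj >= p))
  set.seed(2)
  for (i in 1:10) {
    pr <- runif(6L)
    a <- holm_sidak(pr)
    expect_true(all(a[order(pr)] == cummax(a[order(pr)])))
    expect_true(all(a >= pr & a <= 1))
  }
})

test_that("variability comparison agrees with the Brown-Forsythe reference", {
  set.seed(31)
  g <- rep(c("A", "B", "C"), each = 10L)
  for (i in 1:20) {
    v <- c(rnorm(10, 0, 1), rnorm(10, 0, sample(c(1, 4), 1L)), rnorm(10, 2, 1))
    mine <- compare_variability(v, g)$omnibus_p
    ref <- car::leveneTest(v ~ factor(g), center = median)[1L, "Pr(>F)"]
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("an inflated-spread group is detected; constant groups degenerate", {
  set.seed(41)
  v <- c(rnorm(12, 0, 1), rnorm(12, 0, 4), rnorm(12, 0, 1))
  g <- rep(c("A", "B", "C"), each = 12L)
  res <- compare_variability(v, g)
  expect_lt(res$omnibus_p, 0.05)
  pb <- res$pairwise[res$pairwise$group1 == "B" | res$pairwise$group2 == "B", ]
  expect_lt(min(pb$p_adj), 0.05)

  expect_warning(resc <- compare_variability(rep(c(1, 2, 3), each = 4L),
                                             rep(c("A", "B", "C"), each = 4L)),
                 "degenerate")
  expect_equal(resc$omnibus_p, 1)
})

test_that("correlation recovers exact and degenerate cases", {
  x <- 1:10
  res <- correlate(x, -2 * x + 3)
  expect_equal(res$r, -1)
  expect_error(correlate(rep(1, 5L), rnorm(5L)), "zero variance")
  expect_error(correlate(1:2, 1:2), "fewer than 3")
  # per-group computation
  set.seed(3)
  g <- rep(c("u", "v"), each = 20L)
  xs <- rnorm(40); ys <- ifelse(g == "u", xs, -xs) + rnorm(40, 0, 0.1)
  pg <- correlate(xs, ys, g)
  expect_gt(pg$r[pg$group == "u"], 0.9)
  expect_lt(pg$r[pg$group == "v"], -0.9)
})

test_that("observed power matches the noncentral-F model", {
  # zero sample effect: noncentrality 0, power = alpha exactly
  v0 <- rep(c(-1, 0, 1), 3L)
  g <- rep(c("A", "B", "C"), each = 3L)
  expect_equal(observed_power(v0, g, alpha = 0.05), 0.05)
  # huge effect
  set.seed(8)
  vb <- c(rnorm(10), rnorm(10) + 8, rnorm(10) + 16)
  gb <- rep(c("A", "B", "C"), each = 10L)
  expect_gt(observed_power(vb, gb), 0.99)
  expect_warning(p1 <- observed_power(rep(c(1, 2, 3), each = 3L),
                                      rep(c("A", "B", "C"), each = 3L)),
                 "zero residual")
  expect_equal(p1, 1)
})

test_that("observed power matches a Monte-Carlo rejection rate", {
  set.seed(55)
  means <- c(0, 0.8, 1.2); sdv <- 1.3; n <- 10L
  v <- c(rnorm(n, means[1L], sdv), rnorm(n, means[2L], sdv),
         rnorm(n, means[3L], sdv))
  g <- rep(c("A", "B", "C"), each = n)
  # power implied by the *sample* effect size
  pow <- observed_power(v, g)
  mu <- vapply(split(v, g), mean, numeric(1L))
  sig <- sqrt(sum(vapply(split(v, g), function(x)
    sum((x - mean(x))^2), numeric(1L))) / (3L * n - 3L))
  nsim <- 1000L
  rej <- mean(replicate(nsim, {
    y <- c(rnorm(n, mu[1L], sig), rnorm(n, mu[2L], sig),
           rnorm(n, mu[3L], sig))
    summary(stats::aov(y ~ factor(g)))[[1L]][["Pr(>F)"]][1L] < 0.05
  }))
  # Monte-Carlo draws re-estimate the effect, so allow CI width + bias slack
  expect_lt(abs(rej - pow), 4 * sqrt(pow * (1 - pow) / nsim) + 0.06)
})
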