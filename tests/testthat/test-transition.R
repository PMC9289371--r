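make_mixture <- function(n1, n2, p = 20, sep = 2, seed = 60) {
  set.seed(seed)
  list(
    l1 = matrix(rnorm(n1 * p, -sep), n1, p),
    l2 = matrix(rnorm(n2 * p, sep), n2, p)
  )
}

test_that("self-training scores are bounded and recover a planted mixture", {
  mx <- make_mixture(150, 150)
  u <- rbind(matrix(rnorm(150 * 20, -2), 150, 20),
             matrix(rnorm(150 * 20, 2), 150, 20))
  sc <- fit_semisupervised_scores(mx$l1, mx$l2, u, seed = 61)
  expect_true(all(sc >= 0 & sc <= 1))
  truth <- rep(c("class1-like", "class2-like"), each = 150)
  expect_gte(mean(split_subpops(sc) == truth), 0.9)

  # planted mixture proportions recovered within 5 points
  est <- mean(split_subpops(sc) == "class2-like")
  expect_lt(abs(est - 0.5), 0.05)
})

test_that("a duplicate of a labeled cell scores with its class", {
  mx <- make_mixture(80, 80, seed = 62)
  u <- rbind(mx$l1[1, , drop = FALSE], mx$l2[1, , drop = FALSE])
  sc <- fit_semisupervised_scores(mx$l1, mx$l2, u, seed = 63)
  expect_lte(sc[1], 0.05)
  expect_gte(sc[2], 0.95)
})

test_that("with an unreachable confidence threshold self-training is supervised", {
  mx <- make_mixture(60, 60, seed = 64)
  set.seed(65)
  u <- matrix(rnorm(50 * 20, 0), 50, 20)
  sc_self <- fit_semisupervised_scores(mx$l1, mx$l2, u, confidence = 1,
                                       seed = 66)
  expect_equal(attr(sc_self, "iterations"), 1L)
  base <- glmnet::glmnet(rbind(mx$l1, mx$l2), rep(0:1, each = 60),
                         family = "binomial", alpha = 0, lambda = 0.01,
                         standardize = FALSE)
  sc_sup <- drop(predict(base, u, type = "response"))
  expect_equal(as.numeric(sc_self), sc_sup, tolerance = 1e-8)
})

test_that("scores are monotone along the class-1 to class-2 axis", {
  mx <- make_mixture(100, 100, p = 2, seed = 67)
  c1 <- colMeans(mx$l1); c2 <- colMeans(mx$l2)
  ts <- seq(0, 1, length.out = 21)
  line <- t(vapply(ts, function(t) c1 + t * (c2 - c1), numeric(2)))
  sc <- fit_semisupervised_scores(mx$l1, mx$l2, line, seed = 68)
  expect_true(all(diff(sc) >= -1e-8))
})

test_that("subpopulation splitting applies the documented tie rule", {
  expect_equal(split_subpops(c(0.1, 0.9)), c("class1-like", "class2-like"))
  expect_equal(split_subpops(0.5), "class2-like")
  expect_equal(split_subpops(numeric(0)), character(0))
})

test_that("differential genes rank planted effects first and null is flat", {
  d <- synthetic_design(
    2, c(100, 100), 200,
    marker_plan = list(
      list(list(genes = 1:2, fold = 4, rate_in = 0.95, rate_out = 0.3)),
      NULL
    ),
    seed = 70
  )
  g <- generate_counts(d)
  nm <- lognormalize(g$matrix)
  dg <- diff_genes(nm, g$matrix, g$truth$cluster == 1, g$truth$cluster == 2)
  expect_true(all(g$matrix$gene_ids[1:2] %in% dg$gene[1:10]))

  # gene order permutation leaves the ranking invariant
  perm <- sample(nrow(g$matrix$counts))
  gp <- count_matrix(g$matrix$counts[perm, ], gene_ids = g$matrix$gene_ids[perm],
                     barcodes = g$matrix$barcodes, group = g$matrix$group,
                     mito_flags = g$matrix$mito_flags[perm])
  dgp <- diff_genes(lognormalize(gp), gp, g$truth$cluster == 1,
                    g$truth$cluster == 2)
  expect_equal(dgp$gene, dg$gene)

  # identical subpopulations: no small p-values
  h <- generate_counts(synthetic_design(1, 200, 150, seed = 71))
  nmh <- lognormalize(h$matrix)
  null <- diff_genes(nmh, h$matrix, 1:100, 101:200)
  expect_equal(sum(null$p_adjusted < 0.01), 0)
  expect_error(diff_genes(nmh, h$matrix, 1:2, 3:200), "at least 3")
})

test_that("co-expression fractions count strictly positive cells only", {
  counts <- rbind(c(1, 2, 0, 3), c(5, 1, 2, 0))
  m <- count_matrix(counts, gene_ids = c("a", "b"))
  expect_equal(coexpression_fraction(m, c("a", "b")), 50)
  expect_equal(coexpression_fraction(m, "a"), 75)
  expect_error(coexpression_fraction(m, character(0)), "non-empty")
  expect_error(coexpression_fraction(m, c("a", "zz")), "zz")
})

test_that("a planted triple-positive rate is estimated within 3 points", {
  set.seed(72)
  n <- 1000
  rate <- 0.38
  on <- runif(n) < rate
  counts <- matrix(0L, 3, n)
  counts[, on] <- 1L
  # off cells keep at most two of the three genes on
  off <- which(!on)
  counts[1, off] <- rbinom(length(off), 1, 0.5)
  counts[2, off] <- rbinom(length(off), 1, 0.5)
  counts[3, off] <- 0L
  m <- count_matrix(counts + 0L, gene_ids = c("PRKAG2", "NR4A3", "ATF3"))
  est <- coexpression_fraction(m, c("PRKAG2", "NR4A3", "ATF3"))
  expect_lt(abs(est / 100 - rate), 0.03)
})

test_that("the transition arithmetic multiplies the two percentages", {
  expect_equal(transition_estimate(38.15, 62.91), 24)
  expect_equal(transition_estimate(0, 80), 0)
  expect_equal(transition_estimate(100, 100), 100)
  expect_error(transition_estimate(120, 50), "percent")
  expect_error(transition_estimate(50, -1), "percent")
})
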