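test_that("separable training data yields all-zero slack", {
  X <- matrix(c(rep(2, 20), rep(-2, 20)), ncol = 1)
  y <- c(rep(1, 20), rep(-1, 20))
  for (C in c(1, 10)) {
    m <- fit_sparse(X, y, C = C)
    expect_equal(m$zero_slack_fraction, 1)
    expect_true(all(y * score_cells(m, X) >= 1 - 1e-6))
  }
})

test_that("the returned solution is feasible and locally optimal", {
  set.seed(50)
  X <- rbind(matrix(rnorm(30 * 4, 1), ncol = 4),
             matrix(rnorm(30 * 4, -1), ncol = 4))
  y <- rep(c(1, -1), each = 30)
  for (nt in c("l1", "l2")) {
    m <- fit_sparse(X, y, C = 1, norm_type = nt)
    # margin-constraint feasibility with the reported slacks
    expect_true(all(y * (X %*% m$w + m$b) + m$eps >= 1 - 1e-6))
    expect_true(all(m$eps >= 0))
    # no random feasible perturbation does better
    objective <- function(w, b) {
      eps <- pmax(0, 1 - y * (X %*% w + b))
      reg <- if (nt == "l1") 0.5 * sum(abs(w)) else 0.5 * sum(w^2)
      reg + sum(eps)
    }
    base <- objective(m$w, m$b)
    for (i in 1:1000) {
      pw <- m$w + rnorm(4, 0, 0.05)
      pb <- m$b + rnorm(1, 0, 0.05)
      expect_gte(objective(pw, pb), base - 1e-8)
    }
  }
})

test_that("the L1 norm concentrates weight on informative genes", {
  set.seed(51)
  n <- 100; p <- 105
  X <- matrix(rnorm(2 * n * p), 2 * n, p)
  X[1:n, 1:5] <- X[1:n, 1:5] + 2
  y <- c(rep(1, n), rep(-1, n))
  m <- fit_sparse(X, y, C = 1, norm_type = "l1")
  top5 <- order(abs(m$w), decreasing = TRUE)[1:5]
  expect_gte(sum(top5 <= 5), 4)
})

test_that("L2 mode matches a reference soft-margin classifier", {
  skip_if_not_installed("e1071")
  set.seed(52)
  for (i in 1:3) {
    n <- 40
    X <- rbind(matrix(rnorm(n * 3, 1), ncol = 3),
               matrix(rnorm(n * 3, -1), ncol = 3))
    y <- rep(c(1, -1), each = n)
    m <- fit_sparse(X, y, C = 1, norm_type = "l2")
    sv <- e1071::svm(X, factor(y), kernel = "linear", cost = 1,
                     scale = FALSE, tolerance = 1e-10)
    w_ref <- drop(t(sv$coefs) %*% sv$SV)
    b_ref <- -sv$rho
    if (sv$labels[1] == -1) { w_ref <- -w_ref; b_ref <- -b_ref }
    expect_lt(max(abs(score_cells(m, X) - (X %*% w_ref + b_ref))), 1e-4)
  }
})

test_that("scoring is the plain linear form", {
  m <- structure(list(w = c(a = 1), b = 0, genes = "a"),
                 class = "sparse_model")
  expect_equal(score_cells(m, matrix(2.5, 1, 1, dimnames = list(NULL, "a"))), 2.5)
  m0 <- structure(list(w = c(0, 0), b = 0, genes = NULL),
                  class = "sparse_model")
  expect_equal(score_cells(m0, matrix(rnorm(10), 5, 2)), rep(0, 5))
  expect_error(score_cells(m, matrix(1, 1, 3)), "expects")
  expect_error(fit_sparse(matrix(1:4, 2), c(1, 1)), "both classes")
})

test_that("categories follow the margin boundaries with middle closed", {
  ct <- categorize(c(1.5, -1.5, 0, 1, -1))
  expect_equal(as.character(ct$category),
               c("high", "low", "middle", "middle", "middle"))
  set.seed(53)
  sc <- rnorm(200)
  ct2 <- categorize(sc, labels = sample(letters[1:2], 200, TRUE))
  counts <- attr(ct2, "category_counts")
  expect_equal(sum(counts$n), 200)

  # shifting the bias moves categories monotonically
  up <- categorize(sc + 1)
  expect_true(all(as.integer(up$category) <= as.integer(categorize(sc)$category)))
  expect_error(categorize(c(1, NA)), "finite")
})

test_that("high-fraction comparison produces the textbook odds ratio", {
  categories <- categorize(
    c(rep(2, 90), rep(0, 10), rep(2, 50), rep(0, 50)),
    labels = rep(c("A", "B"), each = 100)
  )
  cmp <- compare_high_fraction(categories, "A", "B")
  expect_equal(cmp$odds_ratio, 9)

  eq <- categorize(rep(c(2, 0), 50), labels = rep(c("A", "B"), each = 50))
  cmp_eq <- compare_high_fraction(eq, "A", "B")
  expect_equal(cmp_eq$odds_ratio, 1)
  expect_false(cmp_eq$significant)
})

test_that("a planted program gradient separates clusters at p < 1e-6", {
  d <- synthetic_design(
    2, c(500, 500), 200,
    program_plan = list(cycle = list(genes = 1:20, activity = c(3, 1))),
    seed = 54
  )
  g <- generate_counts(d)
  nm <- scale_regress(lognormalize(g$matrix))
  Xp <- t(nm$scaled[1:20, ])
  y <- ifelse(g$truth$cluster == 1, 1, -1)
  # train on half, score everyone
  tr <- c(1:250, 501:750)
  m <- fit_sparse(Xp[tr, ], y[tr], C = 1)
  ct <- categorize(score_cells(m, Xp), labels = g$truth$cluster)
  cmp <- compare_high_fraction(ct, 1, 2)
  expect_gt(cmp$odds_ratio, 1)
  expect_true(cmp$significant)
})

test_that("program definitions validate and round-trip through JSON", {
  expect_error(gene_program("p", character(0), "a", "b"), "genes")
  expect_error(gene_program("p", "g1", "a", "a"), "disjoint")
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    list(list(name = "cycle", genes = c("g1", "g2"),
              positive = "fetal", negative = "adult")),
    path, auto_unbox = TRUE
  )
  progs <- read_gene_programs(path)
  expect_equal(progs[[1]]$name, "cycle")
  expect_equal(progs[[1]]$genes, c("g1", "g2"))
})
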