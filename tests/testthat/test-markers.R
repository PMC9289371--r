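test_that("Fisher's exact test matches its closed forms", {
  bal <- fisher_exact(rbind(c(10, 10), c(10, 10)))
  expect_equal(bal$odds_ratio, 1)
  expect_equal(bal$p_value, 1)

  diag <- fisher_exact(rbind(c(5, 0), c(0, 5)))
  expect_equal(diag$p_value, 2 / 252, tolerance = 1e-12)

  or <- fisher_exact(rbind(c(90, 10), c(50, 50)))
  expect_equal(or$odds_ratio, 9)

  # zero margin: undefined OR, p forced to 1
  zm <- fisher_exact(rbind(c(0, 0), c(3, 4)))
  expect_true(zm$undefined)
  expect_equal(zm$p_value, 1)

  # empty off-diagonal cell: infinite sample OR
  expect_equal(fisher_exact(rbind(c(5, 3), c(0, 4)))$odds_ratio, Inf)
  expect_error(fisher_exact(rbind(c(1, 2), c(-1, 3))), "non-negative")
})

test_that("Fisher p equals exhaustive enumeration for small margins", {
  worst <- 0
  for (n in 2:16) {
    for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
      d <- n - a - b - cc
      mine <- fisher_exact(rbind(c(a, b), c(cc, d)))
      if (mine$undefined) next
      ref <- oracle_fisher_p(a, b, cc, d)
      worst <- max(worst, abs(mine$p_value - ref))
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("Fisher p agrees with stats::fisher.test on random tables", {
  set.seed(40)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 20), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab)$p_value,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-10)
  }
})

test_that("planted markers pass and flat genes fail the three criteria", {
  d <- synthetic_design(
    2, c(300, 2700), 400,
    marker_plan = list(
      list(list(genes = 1:3, fold = 3, rate_in = 0.95, rate_out = 0.05)),
      NULL
    ),
    seed = 41
  )
  g <- generate_counts(d)
  mk <- find_markers(g$matrix, g$truth$cluster, 1)
  expect_true(all(g$matrix$gene_ids[1:3] %in% mk$gene))

  # a gene with an identical distribution everywhere is never a marker
  ev_flat <- mk[mk$gene == g$matrix$gene_ids[300], ]
  expect_equal(nrow(ev_flat), 0)

  expect_warning(out <- find_markers(g$matrix, c(9, 9, g$truth$cluster[-(1:2)]), 9),
                 "fewer than 3")
  expect_equal(nrow(out), 0)
})

test_that("criteria boundaries are inclusive at fraction 0.5 and fold 1.3", {
  # engineered counts: gene 1 has in-cluster detection exactly 0.5 and
  # counts-per-10k fold exactly 1.3; gene 2 pads totals to a constant 200
  n_in <- 200; n_out <- 1800
  g1 <- c(rep(26L, 100), rep(0L, 100),          # in-cluster mean 13
          rep(100L, 174), rep(0L, 1626))        # out mean 17400/1800
  g2 <- 200L - g1
  m <- count_matrix(rbind(g1, g2), gene_ids = c("edge", "filler"))
  labels <- c(rep(1, n_in), rep(2, n_out))
  mk <- find_markers(m, labels, 1)
  row <- mk[mk$gene == "edge", ]
  expect_equal(nrow(row), 1)
  expect_equal(row$expressing_fraction, 0.5)
  expect_equal(row$fold, 1.3, tolerance = 1e-12)
  expect_lt(row$p_value, 1e-6)

  # nudging the thresholds past the boundary drops the gene
  strict <- marker_config(min_fold = 1.3 + 1e-9)
  expect_false("edge" %in% find_markers(m, labels, 1, strict)$gene)
})

test_that("criterion counts convert to genome percentages exactly", {
  expect_equal(genome_percent(126), 0.49)
  expect_equal(genome_percent(74), 0.29)
  expect_equal(genome_percent(0), 0)

  g <- generate_counts(separated_design(2, cells = 60, genes = 150, seed = 42))
  cc <- criterion_counts(g$matrix, g$truth$cluster,
                         marker_config(genome_size = 150))
  expect_equal(nrow(cc), 2)
  expect_true(all(cc$n_joint <= pmin(cc$n_criterion1, cc$n_criterion2)))
  expect_equal(cc$pct_joint, round_half_up(cc$n_joint / 150 * 100, 2))
})

test_that("the overlap histogram counts marker sharing over the union", {
  h <- overlap_summary(list(A = c("g1", "g2"), B = "g2"))
  expect_equal(h$n_clusters, c(1L, 2L))
  expect_equal(h$n_genes, c(1L, 1L))
  expect_equal(h$percent, c(50, 50))

  disjoint <- overlap_summary(list(c("a", "b"), c("c")))
  expect_equal(disjoint$n_clusters, 1L)
  expect_equal(disjoint$n_genes, 3L)

  # histogram totals the union; percentages recompute from the integers
  sets <- list(letters[1:5], letters[3:8], letters[7:9])
  h2 <- overlap_summary(sets)
  expect_equal(sum(h2$n_genes), length(unique(unlist(sets))))
  expect_equal(h2$percent,
               round_half_up(h2$n_genes / sum(h2$n_genes) * 100, 2))
})

test_that("marker recovery is accurate on the reference design", {
  g <- generate_counts(separated_design(3, cells = 200, genes = 300, seed = 43))
  for (k in 1:3) {
    mk <- find_markers(g$matrix, g$truth$cluster, k)
    planted <- g$matrix$gene_ids[g$truth$marker_sets[[k]]]
    precision <- mean(mk$gene %in% planted)
    recall <- mean(planted %in% mk$gene)
    expect_gte(precision, 0.9)
    expect_gte(recall, 0.9)
  }
})
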