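test_that("predicted state changes encode determined transitions exactly", {
  src <- structure(c(A = 1, B = 0, C = 1, D = 0), class = "ternary_state")
  tgt <- structure(c(A = 0, B = 1, C = 1, D = 0), class = "ternary_state")
  em <- compute_Emod(src, tgt)
  expect_equal(unname(em[c("A", "B", "C", "D")]), c(-1, 1, 0, 0))
  expect_error(compute_Emod(src, tgt, genes = "Z"), "unknown gene")
})

test_that("NaN-involving pairs follow the configured mapping", {
  src <- structure(c(a = 1, b = 0, c = NaN, d = NaN, e = NaN),
                   class = "ternary_state")
  tgt <- structure(c(a = NaN, b = NaN, c = 1, d = 0, e = NaN),
                   class = "ternary_state")
  cons <- compute_Emod(src, tgt, mapping = "conservative")
  expect_true(all(cons == 0))
  dir_ <- compute_Emod(src, tgt, mapping = "directional")
  expect_equal(unname(dir_[c("a", "b", "c", "d", "e")]), c(-1, 1, 1, -1, 0))
})

test_that("fold changes, thresholds and discretization follow the log10 model", {
  expr <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                     ctrl = c(100, 100, 100, 100),
                     trt = c(1000, 100, 10, 100))
  fc <- fold_changes(expr, "ctrl", "trt")
  expect_equal(fc$table$Z[fc$table$gene == "g1"], 1)   # ten-fold up
  expect_equal(fc$table$Z[fc$table$gene == "g3"], -1)  # ten-fold down
  expect_equal(fc$mu, 0)
  ee <- compute_Eexp(fc)
  expect_equal(unname(ee[c("g1", "g2", "g3", "g4")]), c(1, 0, -1, 0))

  # degenerate distribution refuses thresholds
  flat <- data.frame(gene = letters[1:4], ctrl = 1:4, trt = 1:4)
  expect_error(fold_changes(flat, "ctrl", "trt"), "degenerate")
  # too few usable genes
  tiny <- data.frame(gene = c("a", "b", "c"), ctrl = c(1, -1, 0),
                     trt = c(2, 1, 1))
  expect_error(fold_changes(tiny, "ctrl", "trt"), "fewer than 3")
  # non-positive medians are excluded and reported
  mix <- data.frame(gene = letters[1:5], ctrl = c(1, 1, 1, 0, 1),
                    trt = c(10, 1, 0.1, 1, 2))
  fm <- fold_changes(mix, "ctrl", "trt")
  expect_equal(fm$excluded, "d")
  expect_equal(nrow(fm$table), 4)
})

test_that("a Z value exactly at a threshold counts as unchanged", {
  fc <- structure(list(table = data.frame(gene = c("a", "b", "c"),
                                          F = c(10, 1, 0.1),
                                          Z = c(1, 0, -1)),
                       mu = 0, sigma = 1, theta_up = 1, theta_down = -1,
                       multiplier = 1, excluded = character(0)),
                  class = "fold_change_set")
  ee <- compute_Eexp(fc)
  expect_equal(unname(ee), c(0, 0, 0))
})

test_that("the E_exp census is invariant under rescaling one condition", {
  pattern <- setNames(rep(c(-1, 0, 1), each = 20), sprintf("g%02d", 1:60))
  expr <- generate_expression(pattern, delta = 1, sigma_noise = 0.2, seed = 7)
  f1 <- fold_changes(expr, "source", "target")
  expr2 <- expr
  expr2$target <- expr2$target * 50
  f2 <- fold_changes(expr2, "source", "target")
  expect_equal(compute_Eexp(f1), compute_Eexp(f2))
})

test_that("gene matching is case-insensitive and expands merged-node aliases", {
  net <- signed_network(
    data.frame(source = "RAS", target = "TP53X", sign = 1L),
    nodes = data.frame(id = c("RAS", "TP53X"), role = "internal",
                       aliases = c("HRAS;KRAS;NRAS;RASD1", NA)))
  expr <- data.frame(gene = c("kras", "tp53x", "UNRELATED"),
                     a = c(1, 2, 3), b = c(1, 2, 3))
  m <- match_genes(net, expr)
  expect_equal(nrow(m), 2)
  expect_equal(m$node[m$gene == "kras"], "RAS")
  empty <- match_genes(net, data.frame(gene = character(), a = numeric()))
  expect_equal(nrow(empty), 0)
})

test_that("probe collapse takes medians per gene", {
  expr <- data.frame(gene = c("g1", "g1", "g1", "g2"),
                     a = c(1, 2, 30, 5), b = c(4, 6, 8, 7))
  cp <- collapse_probes(expr)
  expect_equal(cp$a[cp$gene == "g1"], 2)
  expect_equal(cp$b[cp$gene == "g1"], 6)
})

test_that("the significance tail matches a direct binomial sum", {
  expect_equal(significance(5, 5), (1/3)^5)
  for (n_total in c(10, 50)) for (n_true in c(0, 3, n_total %/% 2)) {
    direct <- sum(dbinom(n_true:n_total, n_total, 1/3))
    expect_equal(significance(n_true, n_total), direct, tolerance = 1e-12)
  }
  expect_equal(significance(0, 10), 1)
  expect_error(significance(6, 5), "invalid counts")
  expect_error(significance(-1, 5), "invalid counts")
})

test_that("scoring partitions genes into true/small/large with percentages", {
  em <- setNames(c(1, 0, -1, 1, 0), letters[1:5])
  ex <- setNames(c(1, 1, 1, 0, 0), letters[1:5])
  rep_ <- score_concordance(em, ex)
  expect_equal(rep_$n_true, 2)
  expect_equal(rep_$n_small, 2)
  expect_equal(rep_$n_large, 1)
  expect_equal(sum(rep_$pct), 100)
  expect_true(all(rep_$per_gene$diff %in% 0:2))
  perfect <- score_concordance(em, em)
  expect_equal(perfect$pct[["true"]], 100)
  expect_error(score_concordance(em, ex, genes = "zz"), "missing")
})

test_that("planted signals are recovered and recovery grows with effect size", {
  # sparse signal: 10% of genes shifted; recovery measured on those genes
  pattern <- setNames(rep(0, 600), sprintf("g%03d", 1:600))
  pattern[1:30] <- 1
  pattern[31:60] <- -1
  planted <- names(pattern)[pattern != 0]
  recov <- sapply(c(0.5, 1.5, 3), function(mult) {
    expr <- generate_expression(pattern, delta = mult * 0.25,
                                sigma_noise = 0.25, seed = 11)
    ee <- compute_Eexp(fold_changes(expr, "source", "target"))
    mean(ee[planted] == pattern[planted])
  })
  expect_true(all(diff(recov) > 0))
  expect_gte(recov[3], 0.85)
})
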