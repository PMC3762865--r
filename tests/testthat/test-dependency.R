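test_that("single edges and isolated pairs classify trivially", {
  inh <- signed_network(data.frame(source = "A", target = "B", sign = -1L))
  r <- signed_reachability(inh, method = "dfs")
  expect_true(r$neg["A", "B"])
  expect_false(r$pos["A", "B"])
  expect_equal(classify_effect(r, "A", "B"), "STRONG_INHIBITOR")

  act <- signed_network(data.frame(source = "A", target = "B", sign = 1L))
  ra <- signed_reachability(act, method = "dfs")
  expect_equal(classify_effect(ra, "A", "B"), "STRONG_ACTIVATOR")
  expect_equal(classify_effect(ra, "B", "A"), "NO_EFFECT")
  expect_error(classify_effect(ra, "A", "Z"), "unknown node")
})

test_that("a direct activation with an indirect negative route is ambivalent", {
  net <- motif_fixtures()$ambivalence
  r <- signed_reachability(net, method = "dfs")
  expect_true(r$pos["ATM", "CHEK2"])
  expect_true(r$neg["ATM", "CHEK2"])
  expect_equal(classify_effect(r, "ATM", "CHEK2"), "AMBIVALENT")
})

test_that("an edgeless network has a pure NO_EFFECT matrix", {
  net <- signed_network(nodes = data.frame(id = LETTERS[1:5], role = "internal"))
  dm <- dependency_matrix(net)
  expect_equal(unname(dm$census["NO_EFFECT"]), 25L)
  expect_equal(sum(dm$census), 25L)
})

test_that("dfs classification equals the brute-force simple-path oracle", {
  for (seed in 1:50) {
    net <- rand_net(seed, density = 2, frac_inh = 0.4)
    dm <- dependency_matrix(net, method = "dfs")
    expect_identical(dm$classes, oracle_classify_all(net))
    expect_equal(sum(dm$census), n_nodes(net)^2)
  }
})

test_that("closure reachability contains dfs reachability and matches it on acyclic graphs", {
  n_acyclic <- 0
  for (seed in 1:60) {
    net <- rand_net(seed, density = 1.6, frac_inh = 0.4)
    d <- signed_reachability(net, method = "dfs")
    cl <- signed_reachability(net, method = "closure")
    expect_false(any(d$pos & !cl$pos))
    expect_false(any(d$neg & !cl$neg))
    if (length(enumerate_cycles(net)) == 0) {
      n_acyclic <- n_acyclic + 1
      expect_identical(d$pos, cl$pos)
      expect_identical(d$neg, cl$neg)
      expect_identical(d$pos_touch, cl$pos_touch)
      expect_identical(d$neg_touch, cl$neg_touch)
    }
  }
  expect_gt(n_acyclic, 0)
})

test_that("acyclic networks never produce a WEAK class", {
  for (seed in 1:40) {
    net <- rand_net(seed, density = 1.4)
    if (length(enumerate_cycles(net)) > 0) next
    dm <- dependency_matrix(net, method = "dfs")
    expect_equal(unname(dm$census["WEAK_ACTIVATOR"]), 0L)
    expect_equal(unname(dm$census["WEAK_INHIBITOR"]), 0L)
  }
})

test_that("the matrix of the reversed network is the transpose", {
  for (seed in 1:20) {
    net <- rand_net(seed, density = 2, frac_inh = 0.4)
    rev_net <- signed_network(
      edges = data.frame(source = net$edges$target, target = net$edges$source,
                         sign = net$edges$sign),
      nodes = data.frame(id = node_ids(net), role = "internal"))
    fwd <- dependency_matrix(
      signed_network(net$edges,
                     nodes = data.frame(id = node_ids(net), role = "internal")),
      method = "dfs")
    bwd <- dependency_matrix(rev_net, method = "dfs")
    expect_identical(bwd$classes, t(fwd$classes))
  }
})

test_that("node-sharing and edge-sharing loop-intersection modes both run and differ only in weak/strong grading", {
  net <- example_damage_network()
  dm_node <- dependency_matrix(net, method = "dfs", loop_touch = "node")
  dm_edge <- dependency_matrix(net, method = "dfs", loop_touch = "edge")
  collapse <- function(m) {
    m[m %in% c("WEAK_ACTIVATOR", "STRONG_ACTIVATOR")] <- "ACT"
    m[m %in% c("WEAK_INHIBITOR", "STRONG_INHIBITOR")] <- "INH"
    m
  }
  expect_identical(collapse(dm_node$classes), collapse(dm_edge$classes))
  # edge-sharing is the stricter notion: strictly fewer or equal weak calls
  expect_lte(sum(dm_edge$classes %in% c("WEAK_ACTIVATOR", "WEAK_INHIBITOR")),
             sum(dm_node$classes %in% c("WEAK_ACTIVATOR", "WEAK_INHIBITOR")))
})

test_that("matrix differencing reports changed pairs with major flags", {
  net <- example_damage_network()
  base <- dependency_matrix(net, method = "dfs")
  expect_equal(nrow(compare_matrices(base, base)), 0)

  ko <- dependency_matrix(delete_node(net, "p53"), method = "dfs")
  d <- compare_matrices(base, ko)
  expect_gt(nrow(d), 0)
  fas <- d[d$effector == "DNAdamage" & d$target == "FAS", ]
  expect_equal(fas$before, "AMBIVALENT")
  expect_equal(fas$after, "STRONG_ACTIVATOR")
  expect_true(fas$major)
  expect_equal(attr(d, "n_shared"), (n_nodes(net) - 1)^2)

  bigger <- dependency_matrix(rand_net(1), method = "dfs")
  expect_error(compare_matrices(base, bigger), "incompatible node sets")
})
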