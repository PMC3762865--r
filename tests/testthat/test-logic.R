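test_that("rules are built from incoming arcs with OR semantics", {
  rules <- build_rules(motif_fixtures()$mdm_loop)
  # MDM4 both activates and inhibits MDM2: both literals appear
  expect_setequal(rules$MDM2$activators, c("p53", "MDM4"))
  expect_equal(rules$MDM2$inhibitors, "MDM4")
  # source nodes get no rule
  net <- signed_network(data.frame(source = "A", target = "B", sign = 1L))
  r2 <- build_rules(net)
  expect_named(r2, "B")
  # rule count equals number of nodes with indegree >= 1
  for (seed in 1:10) {
    rn <- rand_net(seed)
    expect_equal(length(build_rules(rn)), length(unique(rn$edges$target)))
  }
})

test_that("clamped activation chains propagate fully", {
  net <- motif_fixtures()$ladder
  st <- propagate_lss(net, scenario("on", clamps = c(IN = 1)))
  expect_true(all(st == 1))
  expect_equal(determined_fraction(st)$fraction, 1)
  off <- propagate_lss(net, scenario("off", clamps = c(IN = 0)))
  expect_true(all(off == 0))
})

test_that("an inhibitor-only target activates when its inhibitor is off", {
  net <- signed_network(data.frame(source = "A", target = "B", sign = -1L))
  st <- propagate_lss(net, scenario("s", clamps = c(A = 0)))
  expect_equal(unname(st[["B"]]), 1)
  st1 <- propagate_lss(net, scenario("s", clamps = c(A = 1)))
  expect_equal(unname(st1[["B"]]), 0)
})

test_that("unclamped source nodes stay undetermined", {
  net <- signed_network(data.frame(source = "A", target = "B", sign = 1L))
  st <- propagate_lss(net, scenario("free"))
  expect_true(is.nan(st[["A"]]))
  expect_true(is.nan(st[["B"]]))
})

test_that("the double-negative toggle has two steady states and no determined propagation", {
  net <- signed_network(data.frame(source = c("A", "B"), target = c("B", "A"),
                                   sign = -1L))
  sc <- scenario("free")
  lss <- enumerate_lss(net, sc)
  expect_equal(nrow(lss), 2)
  expect_setequal(apply(lss, 1, paste, collapse = ""), c("10", "01"))
  st <- propagate_lss(net, sc)
  expect_true(all(is.nan(st)))
})

test_that("infeasible clamps error in propagation and enumerate to nothing", {
  net <- signed_network(data.frame(source = "A", target = "B", sign = 1L))
  bad <- scenario("bad", clamps = c(A = 1, B = 0))
  expect_error(propagate_lss(net, bad), "infeasible.*'B'")
  expect_equal(nrow(enumerate_lss(net, bad)), 0)
})

test_that("scenario construction rejects malformed inputs", {
  expect_error(scenario("x", clamps = c(A = 2)), "0 or 1")
  expect_error(scenario("x", clamps = c(A = 1), removed = "A"),
               "both clamped and removed")
  net <- signed_network(data.frame(source = "A", target = "B", sign = 1L))
  expect_error(propagate_lss(net, scenario("x", clamps = c(Z = 1))),
               "unknown node")
})

test_that("knockout scenarios delete nodes structurally before rule building", {
  net <- motif_fixtures()$mdm_loop
  st <- propagate_lss(net, scenario("ko", removed = "p53"))
  expect_false("p53" %in% names(st))
  expect_equal(length(st), 2)
})

test_that("propagation is sound against exhaustive enumeration", {
  for (seed in 1:60) {
    net <- rand_net(seed, density = 1.8, frac_inh = 0.4)
    input <- node_ids(net)[net$nodes$role == "input"][1]
    sc <- scenario("s", clamps = setNames(seed %% 2, input))
    st <- propagate_lss(net, sc)
    lss <- enumerate_lss(net, sc)
    det <- names(st)[!is.nan(st)]
    if (nrow(lss) > 0) {
      for (v in det) expect_true(all(lss[, v] == st[[v]]))
    }
  }
})

test_that("adding a clamp never decreases the determined count", {
  for (seed in 1:30) {
    net <- rand_net(seed, density = 1.8)
    input <- node_ids(net)[net$nodes$role == "input"][1]
    sc <- scenario("s", clamps = setNames(1, input))
    st <- propagate_lss(net, sc)
    free <- setdiff(names(st)[is.nan(st)], input)
    if (length(free) == 0) next
    extra <- free[1]
    for (val in c(0, 1)) {
      sc2 <- scenario("s2", clamps = setNames(c(1, val), c(input, extra)))
      st2 <- tryCatch(propagate_lss(net, sc2), error = function(e) NULL)
      if (!is.null(st2))
        expect_gte(determined_fraction(st2)$count,
                   determined_fraction(st)$count)
    }
  }
})

test_that("propagation is independent of node declaration order", {
  for (seed in 1:15) {
    net <- rand_net(seed, density = 1.8)
    input <- node_ids(net)[net$nodes$role == "input"][1]
    sc <- scenario("s", clamps = setNames(1, input))
    st <- propagate_lss(net, sc)
    perm <- sample(seq_len(n_nodes(net)))
    shuffled <- signed_network(
      edges = net$edges[sample(seq_len(n_edges(net))), , drop = FALSE],
      nodes = net$nodes[perm, , drop = FALSE])
    st2 <- propagate_lss(shuffled, sc)
    expect_equal(st2[names(st)], st, ignore_attr = TRUE)
  }
})

test_that("state comparison labels and counts transitions", {
  a <- structure(c(A = 0, B = 1, C = 1, D = NaN), class = "ternary_state")
  b <- structure(c(A = 1, B = 0, C = 1, D = NaN), class = "ternary_state")
  cs <- compare_states(a, b)
  expect_equal(unname(cs$labels[c("A", "B", "C", "D")]),
               factor(c("up", "down", "unchanged", "unchanged"),
                      levels = c("up", "unchanged", "down")))
  expect_equal(cs$census, c(up = 1L, unchanged = 2L, down = 1L))
  same <- compare_states(a, a)
  expect_equal(unname(same$census["unchanged"]), 4L)
})
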