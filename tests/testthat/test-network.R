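test_that("construction validates structural invariants", {
  net <- signed_network(data.frame(source = "A", target = "B",
                                   relation = "activation"))
  expect_s3_class(net, "signed_network")
  expect_equal(n_nodes(net), 2)
  expect_equal(n_edges(net), 1)
  expect_equal(net$edges$sign, 1L)

  # duplicate identical edge is rejected; opposite-sign parallel edge is fine
  expect_error(signed_network(data.frame(source = c("A", "A"),
                                         target = c("B", "B"),
                                         sign = c(1L, 1L))),
               "duplicate edge")
  ok <- signed_network(data.frame(source = c("A", "A"), target = c("B", "B"),
                                  sign = c(1L, -1L)))
  expect_equal(n_edges(ok), 2)

  expect_error(signed_network(data.frame(source = "X", target = "IN", sign = 1L),
                              nodes = data.frame(id = c("IN", "X"),
                                                 role = c("input", "internal"))),
               "incoming")
  expect_error(signed_network(data.frame(source = "OUT", target = "X", sign = 1L),
                              nodes = data.frame(id = c("X", "OUT"),
                                                 role = c("internal", "output"))),
               "outgoing")
  expect_error(signed_network(data.frame(source = "A", target = "B",
                                         relation = "binds")),
               "unknown relation")
})

test_that("declared nodes without edges yield an isolated-node network", {
  net <- signed_network(nodes = data.frame(id = c("A", "B", "C"),
                                           role = "internal"))
  expect_equal(n_nodes(net), 3)
  expect_equal(n_edges(net), 0)
  expect_true(all(degree_distribution(net)$degree == 0))
})

test_that("read/write round trip is the identity in both dialects", {
  net <- example_damage_network()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, f)
  back <- read_network(f)
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$edges, net$edges)
  # canonical file is a fixed point of write(read(.))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_network(back, f2)
  expect_identical(readLines(f), readLines(f2))

  fc <- withr::local_tempfile(fileext = ".csv")
  write_network(net, fc, dialect = "csv")
  back_csv <- read_network(fc, dialect = "csv")
  expect_equal(back_csv$edges, net$edges)
})

test_that("aliases survive the tsv round trip", {
  net <- signed_network(
    data.frame(source = "RAS", target = "X", sign = 1L),
    nodes = data.frame(id = c("RAS", "X"), role = "internal",
                       aliases = c("HRAS;KRAS;NRAS;RASD1", NA)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, f)
  expect_equal(read_network(f)$nodes$aliases, net$nodes$aliases)
})

test_that("format errors name the offending line", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tactivation\tB", "B\tbinds\tC"), f)
  expect_error(read_network(f), "line 2.*binds")
  writeLines(c("A\tactivation"), f)
  expect_error(read_network(f), "line 1")
})

test_that("roles file applies roles and rejects dangling declarations", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("IN\tactivation\tA", "A\tactivation\tOUT"), f)
  rf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("IN\tinput", "OUT\toutput"), rf)
  net <- read_network(f, roles_file = rf)
  expect_equal(net$nodes$role[net$nodes$id == "IN"], "input")
  writeLines(c("GHOST\tinput"), rf)
  expect_error(read_network(f, roles_file = rf), "unknown node 'GHOST'")
})

test_that("node deletion removes incident edges and nothing else", {
  net <- example_damage_network()
  deg <- degree_distribution(net)
  d_p53 <- deg$degree[deg$id == "p53"]
  ko <- delete_node(net, "p53")
  expect_equal(n_nodes(ko), n_nodes(net) - 1)
  expect_equal(n_edges(ko), n_edges(net) - d_p53)
  expect_error(delete_node(ko, "p53"), "unknown node")

  iso <- signed_network(data.frame(source = "A", target = "B", sign = 1L),
                        nodes = data.frame(id = c("A", "B", "C"),
                                           role = "internal"))
  expect_equal(n_edges(delete_node(iso, "C")), 1)
})

test_that("node and edge counts are invariant under read-write-read", {
  for (seed in 1:5) {
    net <- rand_net(seed)
    f <- withr::local_tempfile(fileext = ".tsv")
    write_network(net, f)
    back <- read_network(f)
    expect_equal(n_nodes(back), n_nodes(net))
    expect_equal(n_edges(back), n_edges(net))
    expect_equal(back$edges, net$edges)
  }
})
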