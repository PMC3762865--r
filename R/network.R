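#' Construct a signed interaction network
#'
#' A `signed_network` is a directed multigraph of gene/protein nodes connected
#' by signed edges: `+1` for activation, `-1` for inhibition.  Antiparallel
#' edges and parallel edges of opposite sign between the same ordered pair are
#' permitted (e.g. a regulator that both activates and inhibits its target
#' through different mechanisms), but exact duplicates are not.  Every node
#' carries a role: `input` nodes (environmental signals such as DNA damage)
#' have no incoming edges, `output` nodes (phenotypic read-outs such as
#' apoptosis or senescence) have no outgoing edges, and `internal` nodes are
#' unconstrained.  Node order is fixed at construction so that matrix indices
#' derived from the network are stable.
#'
#' @param edges data.frame with columns `source`, `target` and either `sign`
#'   (`+1`/`-1`) or `relation` (`"activation"`/`"inhibition"`,
#'   case-insensitive).
#' @param nodes optional data.frame with columns `id`, `role` and optionally
#'   `aliases` (semicolon-separated alternative gene symbols, used only when
#'   matching expression data).  Nodes referenced by edges but not declared
#'   here are appended in order of first appearance with role `internal`.
#' @param validate run structural validation (recommended).
#' @return an object of class `signed_network` with components `nodes`
#'   (data.frame `id`, `role`, `aliases`) and `edges` (data.frame `source`,
#'   `target`, `sign`).
#' @export
#' @examples
#' net <- signed_network(data.frame(source = "A", target = "B",
#'                                  relation = "activation"))
#' n_nodes(net)
signed_network <- function(edges = NULL, nodes = NULL, validate = TRUE) {
  if (is.null(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        sign = integer())
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("source", "target") %in% names(edges)))
    stopf("edge table needs 'source' and 'target' columns")
  if (!"sign" %in% names(edges)) {
    if (!"relation" %in% names(edges))
      stopf("edge table needs a 'sign' or 'relation' column")
    edges$sign <- relation_to_sign(edges$relation)
  }
  edges <- edges[, c("source", "target", "sign")]
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$sign <- as.integer(edges$sign)

  if (is.null(nodes)) {
    nodes <- data.frame(id = character(), role = character(),
                        aliases = character())
  }
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (nrow(nodes) > 0 && !"id" %in% names(nodes))
    stopf("node table needs an 'id' column")
  if (!"role" %in% names(nodes)) nodes$role <- rep("internal", nrow(nodes))
  if (!"aliases" %in% names(nodes)) nodes$aliases <- rep(NA_character_, nrow(nodes))
  nodes <- nodes[, intersect(c("id", "role", "aliases"), names(nodes)), drop = FALSE]
  if (nrow(nodes) == 0)
    nodes <- data.frame(id = character(), role = character(), aliases = character())
  nodes$id <- as.character(nodes$id)
  nodes$role <- as.character(nodes$role)
  nodes$aliases <- as.character(nodes$aliases)

  # append undeclared endpoints in first-appearance order
  seen <- unique(c(rbind(edges$source, edges$target)))
  extra <- setdiff(seen, nodes$id)
  if (length(extra) > 0) {
    nodes <- rbind(nodes, data.frame(id = extra, role = "internal",
                                     aliases = NA_character_))
  }
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  net <- structure(list(nodes = nodes, edges = edges), class = "signed_network")
  if (validate) validate_network(net)
  net
}

relation_to_sign <- function(relation) {
  rel <- tolower(trimws(as.character(relation)))
  sign <- ifelse(rel == "activation", 1L, ifelse(rel == "inhibition", -1L, NA_integer_))
  if (anyNA(sign)) {
    bad <- which(is.na(sign))[1]
    stopf("unknown relation token '%s' in row %d (expected 'activation' or 'inhibition')",
          relation[bad], bad)
  }
  sign
}

sign_to_relation <- function(sign) ifelse(sign > 0, "activation", "inhibition")

#' Validate a signed network
#'
#' Checks the structural invariants: unique node ids, known roles, edge
#' endpoints declared, no duplicate `(source, target, sign)` triple, no edge
#' into an input node and no edge out of an output node.
#'
#' @param net a `signed_network`.
#' @return `net`, invisibly; errors otherwise.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  nodes <- net$nodes; edges <- net$edges
  if (anyDuplicated(nodes$id))
    stopf("duplicate node id: %s", nodes$id[duplicated(nodes$id)][1])
  bad_role <- setdiff(unique(nodes$role), NODE_ROLES)
  if (length(bad_role) > 0)
    stopf("unknown node role '%s'", bad_role[1])
  miss <- setdiff(unique(c(edges$source, edges$target)), nodes$id)
  if (length(miss) > 0)
    stopf("edge references undeclared node '%s'", miss[1])
  if (nrow(edges) > 0) {
    if (!all(edges$sign %in% c(-1L, 1L)))
      stopf("edge signs must be +1 or -1")
    key <- paste(edges$source, edges$target, edges$sign)
    if (anyDuplicated(key))
      stopf("duplicate edge: %s", key[duplicated(key)][1])
    inputs <- nodes$id[nodes$role == "input"]
    outputs <- nodes$id[nodes$role == "output"]
    if (any(edges$target %in% inputs))
      stopf("input node '%s' has an incoming edge",
            edges$target[edges$target %in% inputs][1])
    if (any(edges$source %in% outputs))
      stopf("output node '%s' has an outgoing edge",
            edges$source[edges$source %in% outputs][1])
  }
  invisible(net)
}

#' @export
print.signed_network <- function(x, ...) {
  n_in <- sum(x$nodes$role == "input")
  n_out <- sum(x$nodes$role == "output")
  cat(sprintf("signed_network: %d nodes (%d input, %d output), %d edges (%d activating, %d inhibiting)\n",
              nrow(x$nodes), n_in, n_out, nrow(x$edges),
              sum(x$edges$sign > 0), sum(x$edges$sign < 0)))
  invisible(x)
}

#' Number of nodes / edges
#' @param net a `signed_network`.
#' @return integer count.
#' @export
n_nodes <- function(net) nrow(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

#' Node ids in declaration order
#' @param net a `signed_network`.
#' @return character vector.
#' @export
node_ids <- function(net) net$nodes$id

#' Convert to an igraph object
#'
#' Edges carry a `sign` attribute; nodes carry `role`.  Used internally for
#' reachability queries and handy for plotting or export.
#'
#' @param net a `signed_network`.
#' @return an `igraph` directed graph.
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = net$edges$source, to = net$edges$target,
                   sign = net$edges$sign),
    directed = TRUE,
    vertices = data.frame(name = net$nodes$id, role = net$nodes$role))
  g
}

#' Remove a node and its incident edges (in-silico knockout)
#'
#' Structural deletion: the node disappears from the node table and every edge
#' touching it is dropped.  This mimics a loss-of-function mutation, as opposed
#' to clamping the node to 0 (which keeps its edges in place); logical rules
#' rebuilt from the reduced network no longer mention the node at all.
#'
#' @param net a `signed_network`.
#' @param node node id to remove.
#' @return the reduced `signed_network`.
#' @export
delete_node <- function(net, node) {
  stopifnot(inherits(net, "signed_network"))
  if (length(node) != 1 || !node %in% net$nodes$id)
    stopf("unknown node '%s'", as.character(node)[1])
  keep_e <- net$edges$source != node & net$edges$target != node
  signed_network(edges = net$edges[keep_e, , drop = FALSE],
                 nodes = net$nodes[net$nodes$id != node, , drop = FALSE])
}

#' Read a signed network from a file
#'
#' Two dialects are supported.  The `sif-tsv` dialect is a tab-separated file
#' with optional `#` comment lines, an optional node-declaration block of lines
#' `@node<TAB>id<TAB>role[<TAB>aliases]`, then one edge per line as
#' `source<TAB>relation<TAB>target` with relation `activation` or `inhibition`
#' (case-insensitive).  The `csv` dialect is a comma-separated table with
#' header `source,relation,target`; roles may be supplied through `roles_file`
#' (TSV `id<TAB>role`).  Row order is preserved as node/edge order, so
#' [write_network()] followed by [read_network()] is the identity.
#'
#' @param path file path.
#' @param dialect `"sif-tsv"` (default) or `"csv"`.
#' @param roles_file optional TSV file `id<TAB>role` assigning roles; every id
#'   mentioned must exist in the network.
#' @return a validated `signed_network`.
#' @export
read_network <- function(path, dialect = c("sif-tsv", "csv"), roles_file = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (dialect == "sif-tsv") {
    lines <- readLines(path)
    keep <- !grepl("^\\s*(#|$)", lines)
    idx <- which(keep)
    node_rows <- list(); edge_rows <- list()
    for (i in idx) {
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(f) > 0 && f[1] == "@node") {
        if (length(f) < 3)
          stopf("line %d: node declaration needs '@node<TAB>id<TAB>role'", i)
        node_rows[[length(node_rows) + 1L]] <-
          data.frame(id = f[2], role = f[3],
                     aliases = if (length(f) >= 4 && nzchar(f[4])) f[4] else NA_character_)
      } else {
        if (length(f) != 3)
          stopf("line %d: edge row needs 'source<TAB>relation<TAB>target'", i)
        rel <- tolower(trimws(f[2]))
        if (!rel %in% c("activation", "inhibition"))
          stopf("line %d: unknown relation token '%s'", i, f[2])
        edge_rows[[length(edge_rows) + 1L]] <-
          data.frame(source = f[1], target = f[3],
                     sign = if (rel == "activation") 1L else -1L)
      }
    }
    nodes <- if (length(node_rows)) do.call(rbind, node_rows) else NULL
    edges <- if (length(edge_rows)) do.call(rbind, edge_rows) else NULL
    net <- signed_network(edges = edges, nodes = nodes)
  } else {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("source", "relation", "target")
    if (!all(need %in% names(tab)))
      stopf("csv dialect needs header 'source,relation,target'")
    net <- signed_network(edges = tab)
  }
  if (!is.null(roles_file)) {
    roles <- utils::read.table(roles_file, sep = "\t", header = FALSE,
                               col.names = c("id", "role"),
                               stringsAsFactors = FALSE)
    miss <- setdiff(roles$id, net$nodes$id)
    if (length(miss) > 0)
      stopf("role declared for unknown node '%s'", miss[1])
    net$nodes$role[match(roles$id, net$nodes$id)] <- roles$role
    validate_network(net)
  }
  net
}

#' Write a signed network to a file
#'
#' Canonical form: in the `sif-tsv` dialect all nodes are declared first (in
#' declaration order, with role and aliases), then edges in order.  Re-reading
#' the file reproduces the network exactly, and re-writing the re-read network
#' reproduces the file byte for byte.
#'
#' @param net a `signed_network`.
#' @param path output file path.
#' @param dialect `"sif-tsv"` (default) or `"csv"` (edges only; roles and
#'   aliases are not representable in csv).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, dialect = c("sif-tsv", "csv")) {
  dialect <- match.arg(dialect)
  validate_network(net)
  if (dialect == "sif-tsv") {
    node_lines <- sprintf("@node\t%s\t%s%s", net$nodes$id, net$nodes$role,
                          ifelse(is.na(net$nodes$aliases), "",
                                 paste0("\t", net$nodes$aliases)))
    edge_lines <- sprintf("%s\t%s\t%s", net$edges$source,
                          sign_to_relation(net$edges$sign), net$edges$target)
    writeLines(c(node_lines, edge_lines), path)
  } else {
    utils::write.csv(data.frame(source = net$edges$source,
                                relation = sign_to_relation(net$edges$sign),
                                target = net$edges$target),
                     path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
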