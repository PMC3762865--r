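#' Layer classification around a centre node
#'
#' Partitions the node set into the layers commonly drawn for hub-centred
#' signalling models: the input signal(s), nodes upstream of the centre (a
#' directed path to the centre exists), the centre itself, nodes downstream of
#' the centre (reachable from it), nodes that are both, the output(s), and any
#' node connected in neither direction.  Roles take precedence: input and
#' output nodes keep their role label regardless of connectivity (an input can
#' only ever start paths and an output only end them).
#'
#' @param net a `signed_network`.
#' @param center node id of the hub (e.g. `"p53"`).
#' @return data.frame `id`, `layer` (factor with levels `input`, `upstream`,
#'   `center`, `downstream`, `both`, `output`, `unconnected`), with an attached
#'   attribute `counts`: named vector `upstream` / `downstream` (both inclusive
#'   of the `both` set, the convention used when such models report "n upstream
#'   nodes") and `both`.
#' @export
classify_layers <- function(net, center) {
  stopifnot(inherits(net, "signed_network"))
  if (!center %in% net$nodes$id) stopf("unknown center node '%s'", center)
  g <- as_igraph(net)
  up <- names(igraph::subcomponent(g, center, mode = "in"))
  down <- names(igraph::subcomponent(g, center, mode = "out"))
  up <- setdiff(up, center)
  down <- setdiff(down, center)
  ids <- net$nodes$id
  role <- net$nodes$role
  layer <- ifelse(ids == center, "center",
           ifelse(role == "input", "input",
           ifelse(role == "output", "output",
           ifelse(ids %in% up & ids %in% down, "both",
           ifelse(ids %in% up, "upstream",
           ifelse(ids %in% down, "downstream", "unconnected"))))))
  out <- data.frame(id = ids,
                    layer = factor(layer, levels = c("input", "upstream",
                                                     "center", "downstream",
                                                     "both", "output",
                                                     "unconnected")))
  special <- ids[role != "internal" | ids == center]
  attr(out, "counts") <- c(
    upstream = sum(!(ids %in% special) & ids %in% up),
    downstream = sum(!(ids %in% special) & ids %in% down),
    both = sum(!(ids %in% special) & ids %in% up & ids %in% down))
  out
}

#' Connectivity degree of every node
#'
#' Degree counts the number of interactions a node participates in
#' (in-degree + out-degree), with parallel edges of opposite sign counted
#' separately, since each corresponds to a distinct interaction.  The degree
#' sum therefore equals twice the edge count.
#'
#' @param net a `signed_network`.
#' @return data.frame `id`, `in_degree`, `out_degree`, `degree`, in node order.
#' @export
degree_distribution <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  ids <- net$nodes$id
  indeg <- as.integer(table(factor(net$edges$target, levels = ids)))
  outdeg <- as.integer(table(factor(net$edges$source, levels = ids)))
  data.frame(id = ids, in_degree = indeg, out_degree = outdeg,
             degree = indeg + outdeg)
}

#' Two-step feedback loops
#'
#' Finds all unordered node pairs `{a, b}` connected by at least one edge in
#' each direction.  Each pair is listed once, annotated with every loop sign
#' obtainable from the available edge-sign combinations: the sign of a
#' two-step loop is the product of its two edge signs, and when parallel
#' opposite-sign edges exist between a pair several combinations (possibly
#' both a positive and a negative loop) coexist.
#'
#' @param net a `signed_network`.
#' @return data.frame `node1`, `node2`, `signs` (comma-joined subset of
#'   `"positive"`, `"negative"`); zero rows when no such loop exists.
#' @export
two_step_feedback_loops <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  e <- net$edges
  empty <- data.frame(node1 = character(), node2 = character(),
                      signs = character())
  if (nrow(e) == 0) return(empty)
  ord <- match(net$nodes$id, net$nodes$id) # node order for pair orientation
  pairs <- unique(e[e$source != e$target, c("source", "target")])
  key <- function(a, b) paste(a, b, sep = "\r")
  fwd <- key(pairs$source, pairs$target)
  rev_ <- key(pairs$target, pairs$source)
  mutual <- pairs[fwd %in% rev_, , drop = FALSE]
  if (nrow(mutual) == 0) return(empty)
  # orient each pair by node declaration order and deduplicate
  i1 <- match(mutual$source, net$nodes$id)
  i2 <- match(mutual$target, net$nodes$id)
  a <- ifelse(i1 < i2, mutual$source, mutual$target)
  b <- ifelse(i1 < i2, mutual$target, mutual$source)
  pk <- key(a, b)
  keep <- !duplicated(pk)
  a <- a[keep]; b <- b[keep]
  signs <- vapply(seq_along(a), function(k) {
    s_ab <- unique(e$sign[e$source == a[k] & e$target == b[k]])
    s_ba <- unique(e$sign[e$source == b[k] & e$target == a[k]])
    prods <- sort(unique(as.vector(outer(s_ab, s_ba))), decreasing = TRUE)
    paste(ifelse(prods > 0, "positive", "negative"), collapse = ",")
  }, character(1))
  data.frame(node1 = a, node2 = b, signs = signs)
}

#' Census of links touching the input and output nodes
#'
#' For the input node, counts the nodes it feeds and how many of those links
#' are inhibitory.  For each output node, counts incoming links and distinct
#' source nodes, and classifies each source as promoting only (all its edges
#' to that output are activations), preventing only (all inhibitions), or
#' both.
#'
#' @param net a `signed_network`.
#' @param input input node id; defaults to the unique node with role `input`.
#' @param outputs output node ids; default all nodes with role `output`.
#' @return list with elements `input` (list `node`, `n_links`, `n_nodes`,
#'   `n_activating`, `n_inhibitory`) and `outputs` (named list per output:
#'   `n_links`, `n_nodes`, `n_pro_only`, `n_anti_only`, `n_both`).
#' @export
io_link_census <- function(net, input = NULL, outputs = NULL) {
  stopifnot(inherits(net, "signed_network"))
  if (is.null(input)) {
    input <- net$nodes$id[net$nodes$role == "input"]
    if (length(input) != 1)
      stopf("network has %d input nodes; specify 'input'", length(input))
  }
  if (is.null(outputs)) outputs <- net$nodes$id[net$nodes$role == "output"]
  miss <- setdiff(c(input, outputs), net$nodes$id)
  if (length(miss) > 0) stopf("unknown node '%s'", miss[1])
  e <- net$edges
  ein <- e[e$source == input, , drop = FALSE]
  res_in <- list(node = input,
                 n_links = nrow(ein),
                 n_nodes = length(unique(ein$target)),
                 n_activating = sum(ein$sign > 0),
                 n_inhibitory = sum(ein$sign < 0))
  res_out <- lapply(outputs, function(o) {
    eo <- e[e$target == o, , drop = FALSE]
    by_src <- split(eo$sign, eo$source)
    pro <- vapply(by_src, function(s) all(s > 0), logical(1))
    anti <- vapply(by_src, function(s) all(s < 0), logical(1))
    list(node = o,
         n_links = nrow(eo),
         n_nodes = length(by_src),
         n_pro_only = sum(pro),
         n_anti_only = sum(anti),
         n_both = sum(!pro & !anti))
  })
  names(res_out) <- outputs
  list(input = res_in, outputs = res_out)
}
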