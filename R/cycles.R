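#' Enumerate elementary cycles of a signed network
#'
#' An elementary cycle visits no node twice; its sign is the product of its
#' edge signs.  Cycles are enumerated as node sequences by a rooted
#' depth-first search (each cycle is reported once, rooted at its
#' smallest-index node).  Because parallel edges of opposite sign may connect
#' the same ordered pair, one node sequence can realize several signs; the set
#' of achievable signs is reported per cycle.
#'
#' @param net a `signed_network`.
#' @param max_cycles guard against combinatorial explosion; exceeded count
#'   raises an error suggesting the scalable SCC-based negative-loop test.
#' @return list of cycles, each a list with `nodes` (node ids in cycle order,
#'   starting node not repeated) and `signs` (subset of `c(1, -1)`).
#' @export
enumerate_cycles <- function(net, max_cycles = 100000L) {
  stopifnot(inherits(net, "signed_network"))
  ids <- net$nodes$id
  n <- length(ids)
  e <- net$edges
  if (nrow(e) == 0 || n == 0) return(list())
  src <- match(e$source, ids); tgt <- match(e$target, ids)
  # adjacency: per source node, target indices and achievable sign sets
  adj <- vector("list", n)
  for (v in seq_len(n)) adj[[v]] <- list(t = integer(), s = list())
  for (k in seq_len(nrow(e))) {
    v <- src[k]; w <- tgt[k]
    pos <- match(w, adj[[v]]$t)
    if (is.na(pos)) {
      adj[[v]]$t <- c(adj[[v]]$t, w)
      adj[[v]]$s <- c(adj[[v]]$s, list(e$sign[k]))
    } else {
      adj[[v]]$s[[pos]] <- sort(unique(c(adj[[v]]$s[[pos]], e$sign[k])),
                                decreasing = TRUE)
    }
  }
  cycles <- list()
  count <- 0L
  on_path <- logical(n)
  path <- integer(0)
  step_signs <- list()

  dfs <- function(v, root) {
    nb <- adj[[v]]
    for (i in seq_along(nb$t)) {
      w <- nb$t[i]
      if (w < root) next
      if (w == root) {
        count <<- count + 1L
        if (count > max_cycles)
          stopf("more than %d elementary cycles; use method = 'scc'", max_cycles)
        sset <- c(step_signs, list(nb$s[[i]]))
        signs <- Reduce(function(acc, s) unique(as.vector(outer(acc, s))),
                        sset, accumulate = FALSE)
        cycles[[count]] <<- list(nodes = ids[path],
                                 signs = sort(unique(signs), decreasing = TRUE))
      } else if (!on_path[w]) {
        on_path[w] <<- TRUE
        path <<- c(path, w)
        step_signs[[length(step_signs) + 1L]] <<- nb$s[[i]]
        dfs(w, root)
        step_signs[[length(step_signs)]] <<- NULL
        path <<- path[-length(path)]
        on_path[w] <<- FALSE
      }
    }
  }
  for (root in seq_len(n)) {
    on_path[root] <- TRUE
    path <- root
    step_signs <- list()
    dfs(root, root)
    on_path[root] <- FALSE
  }
  cycles
}

#' Nodes lying on a negative feedback loop
#'
#' A node belongs to the returned set iff some elementary cycle through it has
#' an odd number of inhibitory edges (i.e. negative sign).  Negative feedback
#' loops are what demote single-sign influences from "strong" to "weak" in the
#' six-class dependency classification.
#'
#' Two methods are available.  `"exact"` enumerates elementary cycles and is
#' the reference semantics.  `"scc"` is a polynomial over-approximation: a
#' strongly connected component contains a negative cycle iff its edges cannot
#' be sign-consistently two-coloured (every edge sign equal to the product of
#' its endpoint colours); when a component fails that test, all of its nodes
#' are returned, although individual nodes of the component might only lie on
#' positive elementary cycles.
#'
#' @param net a `signed_network`.
#' @param method `"exact"` (default) or `"scc"`.
#' @param max_cycles passed to [enumerate_cycles()] for the exact method.
#' @return character vector of node ids (possibly empty).
#' @export
negative_loop_nodes <- function(net, method = c("exact", "scc"),
                                max_cycles = 100000L) {
  method <- match.arg(method)
  stopifnot(inherits(net, "signed_network"))
  if (method == "exact") {
    cyc <- enumerate_cycles(net, max_cycles = max_cycles)
    neg <- Filter(function(cc) -1 %in% cc$signs, cyc)
    sort(unique(as.character(unlist(lapply(neg, `[[`, "nodes")))))
  } else {
    scc_negative_nodes(net)
  }
}

# SCC-based detection: a component has only positive cycles iff a vertex
# colouring sigma in {+1,-1} exists with sign(u->v) = sigma(u)*sigma(v) for
# every intra-component edge (switching characterization of balance).
scc_negative_nodes <- function(net) {
  ids <- net$nodes$id
  g <- as_igraph(net)
  comp <- igraph::components(g, mode = "strong")
  out <- character(0)
  for (ci in seq_len(comp$no)) {
    members <- ids[comp$membership == ci]
    if (length(members) == 0) next
    e <- net$edges[net$edges$source %in% members &
                   net$edges$target %in% members, , drop = FALSE]
    if (nrow(e) == 0) next   # trivial SCC (single node, no self loop)
    if (!scc_is_balanced(members, e)) out <- c(out, members)
  }
  sort(out)
}

scc_is_balanced <- function(members, e) {
  idx <- stats::setNames(seq_along(members), members)
  # parallel opposite-sign edges between one pair imply a negative cycle
  key <- paste(e$source, e$target)
  for (k in unique(key)) {
    if (length(unique(e$sign[key == k])) > 1) return(FALSE)
  }
  # undirected BFS colouring over the constraint sigma_u * sigma_v = sign
  m <- length(members)
  nb <- vector("list", m)
  for (r in seq_len(nrow(e))) {
    u <- idx[[e$source[r]]]; v <- idx[[e$target[r]]]
    if (u == v) { if (e$sign[r] < 0) return(FALSE); next }
    nb[[u]] <- rbind(nb[[u]], c(v, e$sign[r]))
    nb[[v]] <- rbind(nb[[v]], c(u, e$sign[r]))
  }
  colr <- rep(NA_integer_, m)
  for (start in seq_len(m)) {
    if (!is.na(colr[start])) next
    colr[start] <- 1L
    queue <- start
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      for (r in seq_len(NROW(nb[[u]]))) {
        v <- nb[[u]][r, 1]; s <- nb[[u]][r, 2]
        want <- colr[u] * s
        if (is.na(colr[v])) {
          colr[v] <- want
          queue <- c(queue, v)
        } else if (colr[v] != want) return(FALSE)
      }
    }
  }
  TRUE
}

# Edges participating in at least one negative elementary cycle, for the
# edge-sharing variant of the loop-intersection test.  Returns a character key
# "source\rtarget\rsign" set.
negative_loop_edges <- function(net, max_cycles = 100000L) {
  cyc <- enumerate_cycles(net, max_cycles = max_cycles)
  ids <- net$nodes$id
  e <- net$edges
  keys <- character(0)
  for (cc in cyc) {
    if (!(-1 %in% cc$signs)) next
    nodes <- cc$nodes
    len <- length(nodes)
    from <- nodes
    to <- nodes[c(seq_len(len)[-1], 1L)]
    # per step: achievable sign sets
    step_sets <- lapply(seq_len(len), function(i) {
      sort(unique(e$sign[e$source == from[i] & e$target == to[i]]),
           decreasing = TRUE)
    })
    # an edge (from_i, to_i, s) is on a negative instantiation iff the product
    # of the other steps can achieve -s
    for (i in seq_len(len)) {
      others <- step_sets[-i]
      prods <- Reduce(function(acc, s) unique(as.vector(outer(acc, s))),
                      others, 1)
      for (s in step_sets[[i]]) {
        if ((-s) %in% prods)
          keys <- c(keys, paste(from[i], to[i], s, sep = "\r"))
      }
    }
  }
  unique(keys)
}
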