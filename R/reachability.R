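#' Signed reachability between all ordered node pairs
#'
#' Computes, for every ordered pair `(i, j)`, whether a positive-net-sign and
#' whether a negative-net-sign directed path `i -> j` exists (the sign of a
#' path is the product of its edge signs), plus whether at least one path of
#' each sign intersects a negative feedback loop.  Diagonal entries refer to
#' cycles through the node.
#'
#' Two engines are provided.  `"dfs"` enumerates elementary paths (no repeated
#' nodes) exactly by depth-first search; it is the reference semantics but
#' exponential in the worst case, so it is used automatically only up to `cap`
#' nodes.  `"closure"` computes a signed transitive closure over walks by
#' repeated boolean matrix squaring; every simple path is a walk, so the
#' closure can only over-approximate the exact relation (a sign achievable
#' only by running around a cycle is counted by walks but not by elementary
#' paths).  Agreement and containment between the two engines are exercised by
#' the test suite on small random networks.
#'
#' @param net a `signed_network`.
#' @param method `"auto"` (dfs up to `cap` nodes, closure above), `"dfs"`, or
#'   `"closure"`.
#' @param cap node-count threshold for `"auto"`.
#' @param loop_touch how a negative feedback loop is deemed to intersect a
#'   path: `"node"` (shares at least one node, default) or `"edge"` (shares at
#'   least one edge).
#' @param loop_nodes optional precomputed character vector of nodes on
#'   negative elementary cycles; computed via [negative_loop_nodes()] when
#'   missing.
#' @param max_cycles passed to the cycle enumeration.
#' @param max_visits guard on the number of DFS extensions.
#' @return object of class `signed_reachability`: logical matrices `pos`,
#'   `neg`, `pos_touch`, `neg_touch` (node ids as dimnames) plus bookkeeping
#'   fields.
#' @export
signed_reachability <- function(net, method = c("auto", "dfs", "closure"),
                                cap = 12L,
                                loop_touch = c("node", "edge"),
                                loop_nodes = NULL,
                                max_cycles = 100000L,
                                max_visits = 5e6) {
  method <- match.arg(method)
  loop_touch <- match.arg(loop_touch)
  stopifnot(inherits(net, "signed_network"))
  if (method == "auto") method <- if (n_nodes(net) <= cap) "dfs" else "closure"

  loop_edges <- NULL
  if (loop_touch == "edge") {
    loop_edges <- negative_loop_edges(net, max_cycles = max_cycles)
    if (is.null(loop_nodes)) loop_nodes <- negative_loop_nodes(net, max_cycles = max_cycles)
  } else if (is.null(loop_nodes)) {
    loop_nodes <- tryCatch(
      negative_loop_nodes(net, method = "exact", max_cycles = max_cycles),
      error = function(e) {
        warning("cycle enumeration exceeded budget; using SCC over-approximation for loop nodes")
        negative_loop_nodes(net, method = "scc")
      })
  }

  res <- if (method == "dfs") {
    reach_dfs(net, loop_nodes, loop_touch, loop_edges, max_visits)
  } else {
    reach_closure(net, loop_nodes, loop_touch, loop_edges)
  }
  structure(c(res, list(nodes = node_ids(net), method = method,
                        loop_touch = loop_touch, loop_nodes = loop_nodes)),
            class = "signed_reachability")
}

#' @export
print.signed_reachability <- function(x, ...) {
  cat(sprintf("signed_reachability over %d nodes (method = %s, loop_touch = %s)\n",
              length(x$nodes), x$method, x$loop_touch))
  cat(sprintf("  positive-path pairs: %d; negative-path pairs: %d; loop nodes: %d\n",
              sum(x$pos), sum(x$neg), length(x$loop_nodes)))
  invisible(x)
}

reach_dfs <- function(net, loop_nodes, loop_touch, loop_edges, max_visits) {
  ids <- node_ids(net)
  n <- length(ids)
  zero <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  pos <- zero; neg <- zero; posT <- zero; negT <- zero
  if (n == 0 || n_edges(net) == 0)
    return(list(pos = pos, neg = neg, pos_touch = posT, neg_touch = negT))
  e <- net$edges
  src <- match(e$source, ids); tgt <- match(e$target, ids)
  in_loop <- ids %in% loop_nodes
  edge_in_loop <- if (loop_touch == "edge")
    paste(e$source, e$target, e$sign, sep = "\r") %in% loop_edges
  else rep(FALSE, nrow(e))
  adj <- split(data.frame(w = tgt, s = e$sign, lt = edge_in_loop),
               factor(src, levels = seq_len(n)))
  visits <- 0L

  for (root in seq_len(n)) {
    visited <- logical(n)
    visited[root] <- TRUE
    t0 <- if (loop_touch == "node") in_loop[root] else FALSE
    dfs <- function(v, sgn, touched) {
      a <- adj[[v]]
      for (k in seq_len(nrow(a))) {
        visits <<- visits + 1L
        if (visits > max_visits)
          stopf("DFS path enumeration exceeded %g steps; use method = 'closure'", max_visits)
        w <- a$w[k]
        s2 <- sgn * a$s[k]
        t2 <- touched ||
          (loop_touch == "node" && in_loop[w]) ||
          (loop_touch == "edge" && a$lt[k])
        if (w == root || !visited[w]) {
          if (s2 > 0) {
            pos[root, w] <<- TRUE
            if (t2) posT[root, w] <<- TRUE
          } else {
            neg[root, w] <<- TRUE
            if (t2) negT[root, w] <<- TRUE
          }
        }
        if (w != root && !visited[w]) {
          visited[w] <<- TRUE
          dfs(w, s2, t2)
          visited[w] <<- FALSE
        }
      }
    }
    dfs(root, 1L, t0)
  }
  list(pos = pos, neg = neg, pos_touch = posT, neg_touch = negT)
}

# Walk-based closure on the product graph (node x touched-flag), solved by
# boolean matrix squaring over the sign semiring.
reach_closure <- function(net, loop_nodes, loop_touch, loop_edges) {
  ids <- node_ids(net)
  n <- length(ids)
  zero <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  if (n == 0 || n_edges(net) == 0)
    return(list(pos = zero, neg = zero, pos_touch = zero, neg_touch = zero))
  e <- net$edges
  src <- match(e$source, ids); tgt <- match(e$target, ids)
  in_loop <- ids %in% loop_nodes
  edge_in_loop <- if (loop_touch == "edge")
    paste(e$source, e$target, e$sign, sep = "\r") %in% loop_edges
  else rep(FALSE, nrow(e))

  m <- 2L * n   # states: v (untouched) and v + n (touched)
  Ap <- matrix(0, m, m); An <- matrix(0, m, m)
  for (k in seq_len(nrow(e))) {
    u <- src[k]; v <- tgt[k]
    gain <- if (loop_touch == "node") in_loop[v] else edge_in_loop[k]
    M <- if (e$sign[k] > 0) "Ap" else "An"
    tv0 <- if (gain) v + n else v     # from untouched state
    if (M == "Ap") { Ap[u, tv0] <- 1; Ap[u + n, v + n] <- 1 }
    else           { An[u, tv0] <- 1; An[u + n, v + n] <- 1 }
  }
  P <- Ap; N <- An
  repeat {
    P2 <- ((P + (P %*% P) + (N %*% N)) > 0) * 1
    N2 <- ((N + (P %*% N) + (N %*% P)) > 0) * 1
    if (all(P2 == P) && all(N2 == N)) break
    P <- P2; N <- N2
  }
  start <- if (loop_touch == "node") ifelse(in_loop, seq_len(n) + n, seq_len(n))
           else seq_len(n)
  take <- function(M) {
    full <- (M[start, seq_len(n), drop = FALSE] +
             M[start, n + seq_len(n), drop = FALSE]) > 0
    dimnames(full) <- list(ids, ids)
    full
  }
  takeT <- function(M) {
    tt <- M[start, n + seq_len(n), drop = FALSE] > 0
    dimnames(tt) <- list(ids, ids)
    tt
  }
  list(pos = take(P), neg = take(N), pos_touch = takeT(P), neg_touch = takeT(N))
}

#' Classify the effect of one node on another
#'
#' Applies the six-class rule to a precomputed [signed_reachability()]:
#' no path of either sign means `NO_EFFECT`; both signs mean `AMBIVALENT`;
#' a single sign gives an activator (positive) or inhibitor (negative), graded
#' `STRONG` when no negative feedback loop intersects any path of that sign
#' and `WEAK` when at least one does.
#'
#' @param reach a `signed_reachability`.
#' @param i,j node ids (effector, target).
#' @return one of `NO_EFFECT`, `AMBIVALENT`, `WEAK_ACTIVATOR`,
#'   `WEAK_INHIBITOR`, `STRONG_ACTIVATOR`, `STRONG_INHIBITOR`.
#' @export
classify_effect <- function(reach, i, j) {
  stopifnot(inherits(reach, "signed_reachability"))
  if (!i %in% reach$nodes) stopf("unknown node '%s'", i)
  if (!j %in% reach$nodes) stopf("unknown node '%s'", j)
  p <- reach$pos[i, j]; ng <- reach$neg[i, j]
  if (p && ng) return("AMBIVALENT")
  if (!p && !ng) return("NO_EFFECT")
  if (p) {
    if (reach$pos_touch[i, j]) "WEAK_ACTIVATOR" else "STRONG_ACTIVATOR"
  } else {
    if (reach$neg_touch[i, j]) "WEAK_INHIBITOR" else "STRONG_INHIBITOR"
  }
}
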