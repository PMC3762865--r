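# Independent brute-force oracles built on igraph path/neighbour primitives.
# These deliberately share no code with the package's DFS/closure engines.

# all achievable signs of simple paths along a fixed node sequence,
# accounting for parallel edges of opposite sign
oracle_path_signs <- function(pn, el, es) {
  sgns <- 1
  for (k in seq_len(length(pn) - 1)) {
    ss <- unique(es[el[, 1] == pn[k] & el[, 2] == pn[k + 1]])
    sgns <- unique(as.vector(outer(sgns, ss)))
  }
  sgns
}

# positive/negative elementary-path reachability for every ordered pair,
# diagonal from elementary cycles
oracle_reach <- function(net) {
  ids <- node_ids(net)
  n <- length(ids)
  g <- as_igraph(net)
  el <- igraph::as_edgelist(g)
  es <- igraph::E(g)$sign
  pos <- neg <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) {
      preds <- names(igraph::neighbors(g, ids[i], mode = "in"))
      for (su in preds) {
        closing <- unique(es[el[, 1] == su & el[, 2] == ids[i]])
        sgset <- if (su == ids[i]) closing else {
          acc <- integer(0)
          for (p in igraph::all_simple_paths(g, from = ids[i], to = su))
            acc <- unique(c(acc, as.vector(outer(
              oracle_path_signs(names(p), el, es), closing))))
          acc
        }
        if (1 %in% sgset) pos[i, i] <- TRUE
        if (-1 %in% sgset) neg[i, i] <- TRUE
      }
    } else {
      for (p in igraph::all_simple_paths(g, from = ids[i], to = ids[j])) {
        sg <- oracle_path_signs(names(p), el, es)
        if (1 %in% sg) pos[i, j] <- TRUE
        if (-1 %in% sg) neg[i, j] <- TRUE
      }
    }
  }
  list(pos = pos, neg = neg)
}

# nodes on at least one negative elementary cycle: simple path v -> u closed
# by an edge u -> v with overall negative sign
oracle_negative_loop_nodes <- function(net) {
  ids <- node_ids(net)
  g <- as_igraph(net)
  el <- igraph::as_edgelist(g)
  es <- igraph::E(g)$sign
  out <- character(0)
  for (v in ids) {
    found <- FALSE
    for (su in names(igraph::neighbors(g, v, mode = "in"))) {
      closing <- unique(es[el[, 1] == su & el[, 2] == v])
      if (su == v) {
        if (-1 %in% closing) found <- TRUE
      } else {
        for (p in igraph::all_simple_paths(g, from = v, to = su)) {
          sg <- as.vector(outer(oracle_path_signs(names(p), el, es), closing))
          if (-1 %in% sg) { found <- TRUE; break }
        }
      }
      if (found) break
    }
    if (found) out <- c(out, v)
  }
  sort(out)
}

# full six-class oracle: enumerate simple paths per pair, recording per path
# whether it intersects the negative-loop node set
oracle_classify_all <- function(net) {
  ids <- node_ids(net)
  n <- length(ids)
  g <- as_igraph(net)
  el <- igraph::as_edgelist(g)
  es <- igraph::E(g)$sign
  L <- oracle_negative_loop_nodes(net)
  cls <- matrix("NO_EFFECT", n, n, dimnames = list(ids, ids))
  pair_paths <- function(i, j) {
    # list of (signs, touched) per node sequence, incl. diagonal cycles
    res <- list()
    if (i == j) {
      for (su in names(igraph::neighbors(g, ids[i], mode = "in"))) {
        closing <- unique(es[el[, 1] == su & el[, 2] == ids[i]])
        if (su == ids[i]) {
          res[[length(res) + 1]] <- list(signs = closing,
                                         touched = ids[i] %in% L)
        } else {
          for (p in igraph::all_simple_paths(g, from = ids[i], to = su)) {
            res[[length(res) + 1]] <- list(
              signs = unique(as.vector(outer(
                oracle_path_signs(names(p), el, es), closing))),
              touched = any(names(p) %in% L))
          }
        }
      }
    } else {
      for (p in igraph::all_simple_paths(g, from = ids[i], to = ids[j])) {
        res[[length(res) + 1]] <- list(
          signs = oracle_path_signs(names(p), el, es),
          touched = any(names(p) %in% L))
      }
    }
    res
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    pp <- pair_paths(i, j)
    has_pos <- any(vapply(pp, function(x) 1 %in% x$signs, logical(1)))
    has_neg <- any(vapply(pp, function(x) -1 %in% x$signs, logical(1)))
    if (has_pos && has_neg) cls[i, j] <- "AMBIVALENT"
    else if (has_pos) {
      touch <- any(vapply(pp, function(x) 1 %in% x$signs && x$touched, logical(1)))
      cls[i, j] <- if (touch) "WEAK_ACTIVATOR" else "STRONG_ACTIVATOR"
    } else if (has_neg) {
      touch <- any(vapply(pp, function(x) -1 %in% x$signs && x$touched, logical(1)))
      cls[i, j] <- if (touch) "WEAK_INHIBITOR" else "STRONG_INHIBITOR"
    }
  }
  cls
}

# convenience: small random test network
rand_net <- function(seed, n = NULL, density = 1.8, frac_inh = 0.35) {
  if (is.null(n)) n <- 5 + (seed %% 5)
  generate_network(n, edge_density = density, frac_inhibitory = frac_inh,
                   n_inputs = 1, n_outputs = 1, seed = seed)
}
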