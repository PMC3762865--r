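#' Build sum-of-products logical rules from a signed network
#'
#' Every node with at least one incoming edge receives one rule: the node is
#' active iff any of its activators is active OR any of its inhibitors is
#' inactive (each incoming arc contributes one literal, negated for an
#' inhibition; arcs combine by OR).  Source nodes (no incoming edges) have no
#' rule and are free unless clamped by a scenario.
#'
#' @param net a `signed_network`.
#' @return object of class `logical_rules`: named list (one entry per ruled
#'   node, in node order) of lists `target`, `activators`, `inhibitors`.
#' @export
build_rules <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  e <- net$edges
  ruled <- node_ids(net)[node_ids(net) %in% e$target]
  rules <- lapply(ruled, function(v) {
    inc <- e[e$target == v, , drop = FALSE]
    list(target = v,
         activators = unique(inc$source[inc$sign > 0]),
         inhibitors = unique(inc$source[inc$sign < 0]))
  })
  names(rules) <- ruled
  structure(rules, class = "logical_rules", nodes = node_ids(net))
}

#' @export
print.logical_rules <- function(x, ...) {
  cat(sprintf("logical_rules: %d rules over %d nodes\n",
              length(x), length(attr(x, "nodes"))))
  for (r in utils::head(x, 10)) {
    lits <- c(r$activators, if (length(r$inhibitors)) paste0("!", r$inhibitors))
    cat(sprintf("  %s = %s\n", r$target, paste(lits, collapse = " | ")))
  }
  if (length(x) > 10) cat(sprintf("  ... and %d more\n", length(x) - 10))
  invisible(x)
}

#' Define a simulation scenario
#'
#' A scenario names a set of input clamps (nodes fixed to 0 or 1, typically
#' the environmental input such as DNA damage) and a set of removed nodes
#' (structural knockouts applied before rules are built).
#'
#' @param name scenario label.
#' @param clamps named numeric vector or list, values 0/1.
#' @param removed character vector of knocked-out node ids.
#' @return object of class `scenario`.
#' @export
scenario <- function(name, clamps = c(), removed = character()) {
  clamps <- unlist(clamps)
  if (length(clamps) > 0) {
    if (is.null(names(clamps)) || any(!nzchar(names(clamps))))
      stopf("clamps must be named")
    if (!all(clamps %in% c(0, 1)))
      stopf("clamp values must be 0 or 1")
  }
  removed <- as.character(removed)
  overlap <- intersect(names(clamps), removed)
  if (length(overlap) > 0)
    stopf("node '%s' is both clamped and removed", overlap[1])
  structure(list(name = as.character(name), clamps = clamps,
                 removed = removed), class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cl <- if (length(x$clamps)) paste(names(x$clamps), x$clamps, sep = "=",
                                    collapse = ", ") else "none"
  rm_ <- if (length(x$removed)) paste(x$removed, collapse = ", ") else "none"
  cat(sprintf("scenario '%s': clamps: %s; removed: %s\n", x$name, cl, rm_))
  invisible(x)
}

apply_scenario_network <- function(net, scen) {
  miss <- setdiff(c(names(scen$clamps), scen$removed), node_ids(net))
  if (length(miss) > 0) stopf("scenario references unknown node '%s'", miss[1])
  for (v in scen$removed) net <- delete_node(net, v)
  net
}

#' Three-valued logical steady state by constraint propagation
#'
#' Computes the nodes whose value is identical across all logical steady
#' states compatible with the scenario's clamps, by monotone three-valued
#' (Kleene) fixpoint propagation: starting from the clamps, a ruled node
#' becomes 1 as soon as one of its literals is known true, 0 once all its
#' literals are known false, and stays `NaN` (undetermined) otherwise.
#' Unclamped source nodes remain `NaN` (they are free across steady states,
#' not defaulted to 0).  Removed nodes are deleted structurally before rules
#' are built.  Propagation is sound — every value it determines holds in every
#' steady state — but not complete: a value that is constant across all steady
#' states for a non-local reason (e.g. a node regulated by both an activating
#' and an inhibiting arc from the same undetermined regulator) may be left
#' `NaN`; [enumerate_lss()] is the exhaustive reference on small networks.
#'
#' @param x a `signed_network` (removed nodes are deleted, rules built), or a
#'   `logical_rules` object (scenario must not remove nodes in that case).
#' @param scen a [scenario()].
#' @return object of class `ternary_state`: named numeric vector over the
#'   scenario's nodes with values 0, 1 or `NaN`, scenario name attached as
#'   attribute `scenario`.
#' @export
propagate_lss <- function(x, scen) {
  stopifnot(inherits(scen, "scenario"))
  if (inherits(x, "signed_network")) {
    net <- apply_scenario_network(x, scen)
    rules <- build_rules(net)
  } else if (inherits(x, "logical_rules")) {
    if (length(scen$removed) > 0)
      stopf("scenario removes nodes; pass the signed_network instead of prebuilt rules")
    rules <- x
    miss <- setdiff(names(scen$clamps), attr(rules, "nodes"))
    if (length(miss) > 0) stopf("scenario references unknown node '%s'", miss[1])
  } else stopf("'x' must be a signed_network or logical_rules")

  ids <- attr(rules, "nodes")
  v <- stats::setNames(rep(NaN, length(ids)), ids)
  v[names(scen$clamps)] <- scen$clamps
  clamped <- names(scen$clamps)
  free_ruled <- setdiff(names(rules), clamped)

  eval_rule <- function(r) {
    lits <- c(v[r$activators], 1 - v[r$inhibitors])
    if (any(lits == 1, na.rm = TRUE)) return(1)
    if (length(lits) > 0 && !anyNA(lits) && all(lits == 0)) return(0)
    NaN
  }
  repeat {
    changed <- FALSE
    for (nm in free_ruled) {
      if (!is.nan(v[[nm]])) next
      val <- eval_rule(rules[[nm]])
      if (!is.nan(val)) { v[[nm]] <- val; changed <- TRUE }
    }
    if (!changed) break
  }
  # clamp consistency: a clamped ruled node whose rule is forced the other way
  for (nm in intersect(clamped, names(rules))) {
    val <- eval_rule(rules[[nm]])
    if (!is.nan(val) && val != v[[nm]])
      stopf("infeasible scenario '%s': clamp on node '%s' contradicts its rule",
            scen$name, nm)
  }
  structure(v, class = "ternary_state", scenario = scen$name)
}

#' @export
print.ternary_state <- function(x, ...) {
  df <- determined_fraction(x)
  cat(sprintf("ternary_state '%s': %d/%d nodes determined (%.1f%%)\n",
              attr(x, "scenario") %||% "?", df$count, df$n, 100 * df$fraction))
  invisible(x)
}

#' Exhaustively enumerate logical steady states
#'
#' Enumerates every fully determined 0/1 assignment consistent with all rules
#' and clamps, by brute force over the unclamped nodes.  Intended as the
#' reference oracle for [propagate_lss()] on small networks; refuses to run
#' when more than `cap` nodes are free.
#'
#' @inheritParams propagate_lss
#' @param cap maximum number of free (unclamped) nodes.
#' @return matrix with one row per steady state and one column per node
#'   (possibly zero rows when the clamps are infeasible).
#' @export
enumerate_lss <- function(x, scen, cap = 20L) {
  stopifnot(inherits(scen, "scenario"))
  if (inherits(x, "signed_network")) {
    net <- apply_scenario_network(x, scen)
    rules <- build_rules(net)
  } else rules <- x
  ids <- attr(rules, "nodes")
  clamped <- names(scen$clamps)
  free <- setdiff(ids, clamped)
  if (length(free) > cap)
    stopf("%d free nodes exceed enumeration cap %d", length(free), cap)
  k <- length(free)
  grid <- if (k > 0)
    as.matrix(expand.grid(rep(list(c(0, 1)), k), KEEP.OUT.ATTRS = FALSE))
  else matrix(numeric(0), nrow = 1, ncol = 0)
  M <- matrix(0, nrow(grid), length(ids), dimnames = list(NULL, ids))
  if (k > 0) M[, free] <- grid
  for (nm in clamped) M[, nm] <- scen$clamps[[nm]]
  ok <- rep(TRUE, nrow(M))
  for (r in rules) {
    any_on <- rep(FALSE, nrow(M))
    if (length(r$activators) > 0)
      any_on <- any_on | (rowSums(M[, r$activators, drop = FALSE] == 1) > 0)
    if (length(r$inhibitors) > 0)
      any_on <- any_on | (rowSums(M[, r$inhibitors, drop = FALSE] == 0) > 0)
    ok <- ok & (M[, r$target] == as.numeric(any_on))
  }
  M[ok, , drop = FALSE]
}

#' Determined-node count and fraction of a ternary state
#'
#' @param state a `ternary_state`.
#' @return list `count`, `n` (nodes present in the scenario's network) and
#'   `fraction`.
#' @export
determined_fraction <- function(state) {
  n <- length(state)
  count <- sum(!is.nan(state))
  list(count = count, n = n, fraction = if (n > 0) count / n else NaN)
}

#' Compare two ternary states gene by gene
#'
#' Labels each gene `up`, `down` or `unchanged` according to the predicted
#' state-change encoding of [compute_Emod()] (`+1`/`-1`/`0`), and reports the
#' census of labels.
#'
#' @param src,tgt `ternary_state` objects (source and target scenarios).
#' @param genes genes to compare; default all nodes present in both states.
#' @param mapping passed to [compute_Emod()].
#' @return list `labels` (named factor) and `census` (named integer vector
#'   `up`, `unchanged`, `down`).
#' @export
compare_states <- function(src, tgt, genes = NULL,
                           mapping = c("conservative", "directional")) {
  emod <- compute_Emod(src, tgt, genes = genes, mapping = mapping)
  labels <- factor(ifelse(emod > 0, "up", ifelse(emod < 0, "down", "unchanged")),
                   levels = c("up", "unchanged", "down"))
  names(labels) <- names(emod)
  census <- stats::setNames(as.integer(table(labels)),
                            c("up", "unchanged", "down"))
  list(labels = labels, census = census)
}
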