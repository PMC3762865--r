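#' Dependency matrix of a signed network
#'
#' Classifies every ordered node pair (diagonal included) into one of six
#' effect classes derived from signed path reachability and negative feedback
#' loops: `NO_EFFECT`, `AMBIVALENT` (both a positive and a negative path),
#' `WEAK_ACTIVATOR` / `WEAK_INHIBITOR` (single-sign influence whose supporting
#' paths are intersected by a negative feedback loop) and `STRONG_ACTIVATOR` /
#' `STRONG_INHIBITOR` (single-sign influence free of such interference).
#' Diagonal entries are classified from cycles through the node; a node on no
#' cycle has `NO_EFFECT` on itself.
#'
#' @param net a `signed_network`.
#' @inheritParams signed_reachability
#' @return object of class `dependency_matrix`: list with `classes` (n x n
#'   character matrix, node ids as dimnames), `census` (named integer vector
#'   over the six classes, summing to n^2), `nodes`, `method`, `loop_touch`.
#' @export
dependency_matrix <- function(net, method = c("auto", "dfs", "closure"),
                              cap = 12L, loop_touch = c("node", "edge"),
                              max_cycles = 100000L, max_visits = 5e6) {
  reach <- signed_reachability(net, method = method, cap = cap,
                               loop_touch = loop_touch,
                               max_cycles = max_cycles,
                               max_visits = max_visits)
  classes <- classify_all(reach)
  census <- effect_census(classes)
  structure(list(classes = classes, census = census, nodes = reach$nodes,
                 method = reach$method, loop_touch = reach$loop_touch),
            class = "dependency_matrix")
}

classify_all <- function(reach) {
  p <- reach$pos; ng <- reach$neg
  cls <- matrix("NO_EFFECT", nrow(p), ncol(p), dimnames = dimnames(p))
  cls[p & ng] <- "AMBIVALENT"
  only_p <- p & !ng
  only_n <- ng & !p
  cls[only_p] <- ifelse(reach$pos_touch[only_p], "WEAK_ACTIVATOR", "STRONG_ACTIVATOR")
  cls[only_n] <- ifelse(reach$neg_touch[only_n], "WEAK_INHIBITOR", "STRONG_INHIBITOR")
  cls
}

effect_census <- function(classes) {
  tab <- table(factor(classes, levels = EFFECT_CLASSES))
  stats::setNames(as.integer(tab), EFFECT_CLASSES)
}

#' @export
print.dependency_matrix <- function(x, ...) {
  cat(sprintf("dependency_matrix: %d x %d (method = %s, loop_touch = %s)\n",
              length(x$nodes), length(x$nodes), x$method, x$loop_touch))
  print(x$census)
  invisible(x)
}

#' Write a dependency matrix as TSV
#'
#' Node ids as row/column headers, class tokens as cells.
#'
#' @param dm a `dependency_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dependency_matrix <- function(dm, path) {
  stopifnot(inherits(dm, "dependency_matrix"))
  utils::write.table(dm$classes, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Difference between two dependency matrices
#'
#' Compares the matrices over the nodes of `after` (which must be a subset of
#' the nodes of `before`, as produced by a knockout) and lists every ordered
#' pair whose class changed.  A change is flagged `major` when an entry that
#' was `AMBIVALENT` or `NO_EFFECT` becomes a `STRONG_ACTIVATOR` or
#' `STRONG_INHIBITOR` — the transitions that turn a previously balanced or
#' absent influence into an unambiguous one; with `include_weak = TRUE` the
#' weak classes also qualify as major endpoints.
#'
#' @param before,after `dependency_matrix` objects.
#' @param include_weak also count transitions into weak classes as major.
#' @return object of class `matrix_diff`: data.frame `effector`, `target`,
#'   `before`, `after`, `major`, with attribute `n_shared` (number of shared
#'   matrix cells compared).
#' @export
compare_matrices <- function(before, after, include_weak = FALSE) {
  stopifnot(inherits(before, "dependency_matrix"),
            inherits(after, "dependency_matrix"))
  extra <- setdiff(after$nodes, before$nodes)
  if (length(extra) > 0)
    stopf("incompatible node sets: '%s' absent from baseline", extra[1])
  shared <- after$nodes
  b <- before$classes[shared, shared, drop = FALSE]
  a <- after$classes[shared, shared, drop = FALSE]
  idx <- which(b != a, arr.ind = TRUE)
  strong <- c("STRONG_ACTIVATOR", "STRONG_INHIBITOR")
  if (include_weak) strong <- c(strong, "WEAK_ACTIVATOR", "WEAK_INHIBITOR")
  d <- data.frame(effector = shared[idx[, 1]],
                  target = shared[idx[, 2]],
                  before = b[idx],
                  after = a[idx])
  d$major <- d$before %in% c("AMBIVALENT", "NO_EFFECT") & d$after %in% strong
  d <- d[order(d$effector, d$target), , drop = FALSE]
  rownames(d) <- NULL
  attr(d, "n_shared") <- length(shared)^2
  class(d) <- c("matrix_diff", "data.frame")
  d
}
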