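#' In-silico knockout screen over the dependency matrix
#'
#' Deletes each candidate node in turn, recomputes the dependency matrix on
#' the reduced network, and records the difference against the wild-type
#' matrix.  Candidates default to the hubs — every node whose connectivity
#' degree exceeds `min_degree` — optionally augmented through `include`
#' (poorly connected nodes rarely change the matrix when removed, so screening
#' hubs is where the signal is).  Results are sorted by the number of changed
#' matrix entries, descending.
#'
#' @param net a `signed_network`.
#' @param candidates explicit candidate node ids; overrides the degree rule.
#' @param min_degree degree threshold for the default candidate set.
#' @param include nodes added to the candidate set regardless of degree.
#' @param include_weak passed to [compare_matrices()].
#' @param ... passed to [dependency_matrix()] (method, cap, loop_touch, ...).
#' @return object of class `knockout_screen`: list of `knockout_result`
#'   objects (fields `removed`, `diff`, `n_changed`, `predictions`), sorted by
#'   `n_changed` descending; the wild-type `dependency_matrix` is attached as
#'   attribute `baseline`.
#' @export
knockout_screen <- function(net, candidates = NULL, min_degree = 10,
                            include = character(), include_weak = FALSE, ...) {
  stopifnot(inherits(net, "signed_network"))
  if (is.null(candidates)) {
    deg <- degree_distribution(net)
    candidates <- union(include, deg$id[deg$degree > min_degree])
  }
  candidates <- unique(as.character(candidates))
  miss <- setdiff(candidates, node_ids(net))
  if (length(miss) > 0) stopf("unknown candidate node '%s'", miss[1])
  if (length(candidates) == 0) stopf("empty candidate set")
  baseline <- dependency_matrix(net, ...)
  results <- lapply(candidates, function(v) {
    dm <- dependency_matrix(delete_node(net, v), ...)
    d <- compare_matrices(baseline, dm, include_weak = include_weak)
    preds <- d[d$major, c("effector", "target", "after"), drop = FALSE]
    names(preds)[3] <- "class_after"
    preds <- preds[order(preds$effector, preds$target), , drop = FALSE]
    rownames(preds) <- NULL
    structure(list(removed = v, diff = d, n_changed = nrow(d),
                   predictions = preds),
              class = "knockout_result")
  })
  ord <- order(vapply(results, `[[`, integer(1), "n_changed"), decreasing = TRUE)
  structure(results[ord], class = "knockout_screen", baseline = baseline)
}

#' @export
print.knockout_result <- function(x, ...) {
  cat(sprintf("knockout of %s: %d changed dependency entries, %d major predictions\n",
              x$removed, x$n_changed, nrow(x$predictions)))
  invisible(x)
}

#' @export
print.knockout_screen <- function(x, ...) {
  cat(sprintf("knockout_screen: %d candidates\n", length(x)))
  for (r in x)
    cat(sprintf("  %-12s %6d changed, %3d major\n", r$removed, r$n_changed,
                nrow(r$predictions)))
  invisible(x)
}

#' Render knockout predictions as readable rows
#'
#' One row per major change, in deterministic (effector, target) order, of the
#' form `"in <removed> knockout, <effector> strongly activates <target>"`.
#'
#' @param result a `knockout_result`.
#' @return character vector (possibly empty).
#' @export
extract_predictions <- function(result) {
  stopifnot(inherits(result, "knockout_result"))
  p <- result$predictions
  if (nrow(p) == 0) return(character(0))
  verb <- c(STRONG_ACTIVATOR = "strongly activates",
            STRONG_INHIBITOR = "strongly inhibits",
            WEAK_ACTIVATOR = "weakly activates",
            WEAK_INHIBITOR = "weakly inhibits")[p$class_after]
  sprintf("in %s knockout, %s %s %s", result$removed, p$effector, verb, p$target)
}
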