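#' Validate a pipeline run configuration
#'
#' Checks a YAML file (or an equivalent nested list) describing an end-to-end
#' analysis: the network source, the scenarios, which scenario pairs to
#' compare, the knockout screen and the concordance comparisons.  All
#' cross-references are checked before any computation; errors are aggregated
#' rather than reported one at a time.
#'
#' Recognised keys: `network` (path to an edge-list file, or the string
#' `"example"` for the built-in demonstration network), `scenarios` (list of
#' `{name, clamps, removed}`), `state_comparisons` (list of `{source, target}`
#' scenario names), `knockout` (`{min_degree}` and/or `{candidates}`; omit to
#' skip the screen), `concordance` (list of `{lss_source, lss_target,
#' expression, src_cond, tgt_cond}`), `options` (`emod_mapping`,
#' `threshold_multiplier`, `loop_touch`, `include_weak`, `method`), `out_dir`,
#' `seed`.
#'
#' @param x path to a YAML file, or a list.
#' @return list with `valid` (logical), `errors` (character vector,
#'   human-readable) and `config` (the parsed configuration, with defaults
#'   filled in when valid).
#' @export
validate_config <- function(x) {
  cfg <- if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) return(list(valid = FALSE,
                                     errors = sprintf("config file not found: %s", x),
                                     config = NULL))
    yaml::read_yaml(x)
  } else if (is.list(x)) x else {
    return(list(valid = FALSE, errors = "config must be a file path or a list",
                config = NULL))
  }
  errors <- character(0)
  err <- function(fmt, ...) errors <<- c(errors, sprintf(fmt, ...))

  if (is.null(cfg$network)) {
    err("missing 'network' entry")
  } else if (!identical(cfg$network, "example") && !file.exists(cfg$network)) {
    err("network file not found: %s", cfg$network)
  }
  scen_names <- character(0)
  if (is.null(cfg$scenarios) || length(cfg$scenarios) == 0) {
    err("at least one scenario is required")
  } else {
    for (i in seq_along(cfg$scenarios)) {
      s <- cfg$scenarios[[i]]
      if (is.null(s$name)) { err("scenario %d has no name", i); next }
      scen_names <- c(scen_names, s$name)
      bad <- intersect(names(s$clamps %||% c()), s$removed %||% character())
      if (length(bad) > 0)
        err("scenario '%s': node '%s' is both clamped and removed", s$name, bad[1])
      vals <- unlist(s$clamps %||% c())
      if (length(vals) > 0 && !all(vals %in% c(0, 1)))
        err("scenario '%s': clamp values must be 0 or 1", s$name)
    }
    if (anyDuplicated(scen_names))
      err("duplicate scenario name '%s'", scen_names[duplicated(scen_names)][1])
  }
  for (cmp in cfg$state_comparisons %||% list()) {
    for (role in c("source", "target")) {
      if (is.null(cmp[[role]]) || !cmp[[role]] %in% scen_names)
        err("state comparison references unknown scenario '%s'",
            cmp[[role]] %||% "<missing>")
    }
  }
  for (cc in cfg$concordance %||% list()) {
    for (role in c("lss_source", "lss_target")) {
      if (is.null(cc[[role]]) || !cc[[role]] %in% scen_names)
        err("concordance entry references unknown scenario '%s'",
            cc[[role]] %||% "<missing>")
    }
    if (is.null(cc$expression)) err("concordance entry lacks 'expression' path")
    else if (!file.exists(cc$expression))
      err("expression file not found: %s", cc$expression)
    if (is.null(cc$src_cond) || is.null(cc$tgt_cond))
      err("concordance entry lacks src_cond/tgt_cond")
  }
  opts <- cfg$options %||% list()
  defaults <- list(emod_mapping = "conservative", threshold_multiplier = 1,
                   loop_touch = "node", include_weak = FALSE, method = "auto")
  for (nm in names(defaults)) opts[[nm]] <- opts[[nm]] %||% defaults[[nm]]
  if (!opts$emod_mapping %in% c("conservative", "directional"))
    err("options$emod_mapping must be 'conservative' or 'directional'")
  if (!opts$loop_touch %in% c("node", "edge"))
    err("options$loop_touch must be 'node' or 'edge'")
  cfg$options <- opts

  list(valid = length(errors) == 0, errors = errors,
       config = if (length(errors) == 0) cfg else NULL)
}

#' Run the full analysis pipeline from one configuration
#'
#' Loads the network, propagates the logical steady state of every scenario,
#' compares the requested scenario pairs, runs the knockout screen and the
#' concordance comparisons, and returns (and optionally writes) a structured
#' report.  The run is deterministic for a fixed configuration and seed, and
#' the report records every semantic default (state-change mapping, threshold
#' multiplier, loop-intersection mode) for provenance.
#'
#' @param x configuration: YAML path or list (see [validate_config()]).
#' @return report list with components `network`, `determined` (per-scenario
#'   determined-node summary), `comparisons` (per-pair up/unchanged/down
#'   censuses), `knockout` (per-candidate changed-entry and prediction
#'   counts), `concordance` (per-comparison censuses with p-values) and
#'   `options`.  When `out_dir` is configured, writes `report.json` plus
#'   per-table TSV files there.
#' @export
run_all <- function(x) {
  v <- validate_config(x)
  if (!v$valid)
    stopf("invalid configuration:\n  %s", paste(v$errors, collapse = "\n  "))
  cfg <- v$config
  if (!is.null(cfg$seed)) set.seed(as.integer(cfg$seed))

  net <- if (identical(cfg$network, "example")) example_damage_network()
         else read_network(cfg$network)
  opts <- cfg$options

  scens <- lapply(cfg$scenarios, function(s)
    scenario(s$name, clamps = unlist(s$clamps %||% c()),
             removed = s$removed %||% character()))
  names(scens) <- vapply(scens, `[[`, character(1), "name")
  states <- lapply(scens, function(s) propagate_lss(net, s))

  determined <- do.call(rbind, lapply(names(states), function(nm) {
    df <- determined_fraction(states[[nm]])
    data.frame(scenario = nm, determined = df$count, n = df$n,
               pct = 100 * df$fraction)
  }))

  comparisons <- lapply(cfg$state_comparisons %||% list(), function(cmp) {
    cs <- compare_states(states[[cmp$source]], states[[cmp$target]],
                         mapping = opts$emod_mapping)
    c(list(source = cmp$source, target = cmp$target), as.list(cs$census))
  })

  ko <- NULL
  if (!is.null(cfg$knockout)) {
    scr <- knockout_screen(net,
                           candidates = cfg$knockout$candidates,
                           min_degree = cfg$knockout$min_degree %||% 10,
                           include_weak = isTRUE(opts$include_weak),
                           method = opts$method, loop_touch = opts$loop_touch)
    ko <- do.call(rbind, lapply(scr, function(r)
      data.frame(removed = r$removed, n_changed = r$n_changed,
                 n_major = nrow(r$predictions))))
  }

  conc <- lapply(cfg$concordance %||% list(), function(cc) {
    expr <- collapse_probes(read_expression(cc$expression))
    matched <- match_genes(net, expr)
    expr <- expr[expr$gene %in% matched$gene, , drop = FALSE]
    fc <- fold_changes(expr, cc$src_cond, cc$tgt_cond,
                       multiplier = opts$threshold_multiplier)
    eexp <- compute_Eexp(fc)
    names(eexp) <- matched$node[match(names(eexp), matched$gene)]
    emod <- compute_Emod(states[[cc$lss_source]], states[[cc$lss_target]],
                         genes = intersect(names(eexp),
                                           intersect(names(states[[cc$lss_source]]),
                                                     names(states[[cc$lss_target]]))),
                         mapping = opts$emod_mapping)
    rep_ <- score_concordance(emod, eexp, genes = names(emod))
    list(lss_source = cc$lss_source, lss_target = cc$lss_target,
         src_cond = cc$src_cond, tgt_cond = cc$tgt_cond,
         n_matched = nrow(matched), n_scored = rep_$n,
         n_true = rep_$n_true, n_small = rep_$n_small, n_large = rep_$n_large,
         p_value = rep_$p_value)
  })

  report <- list(
    network = list(n_nodes = n_nodes(net), n_edges = n_edges(net)),
    determined = determined,
    comparisons = comparisons,
    knockout = ko,
    concordance = conc,
    options = opts)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.table(determined, file.path(cfg$out_dir, "determined.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(ko))
      utils::write.table(ko, file.path(cfg$out_dir, "knockout.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    for (nm in names(states)) {
      st <- states[[nm]]
      utils::write.table(data.frame(node = names(st), value = as.numeric(st)),
                         file.path(cfg$out_dir, paste0("state_", nm, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  report
}
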