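#' Predicted state change between two scenarios (E_mod)
#'
#' Encodes, per gene, the model-predicted change of state from a source to a
#' target steady state as -1 (down), 0 (unchanged) or +1 (up).  Determined
#' pairs are unambiguous: 0 to 1 is +1, 1 to 0 is -1, equal determined values
#' are 0.  Pairs involving an undetermined (`NaN`) value follow the selected
#' mapping: `"conservative"` (default) maps every NaN-involving pair to 0 (no
#' confident prediction), while `"directional"` treats a move into or out of
#' indeterminacy as a half-step in the corresponding direction (1 to NaN and
#' NaN to 0 are -1; 0 to NaN and NaN to 1 are +1; NaN to NaN is 0).
#'
#' @param src,tgt `ternary_state` objects.
#' @param genes genes to encode; default all nodes present in both states.
#' @param mapping `"conservative"` or `"directional"`.
#' @return named numeric vector of -1/0/+1 values.
#' @export
compute_Emod <- function(src, tgt, genes = NULL,
                         mapping = c("conservative", "directional")) {
  mapping <- match.arg(mapping)
  if (is.null(genes)) genes <- intersect(names(src), names(tgt))
  miss <- setdiff(genes, intersect(names(src), names(tgt)))
  if (length(miss) > 0) stopf("unknown gene '%s'", miss[1])
  s <- as.numeric(src[genes]); t <- as.numeric(tgt[genes])
  out <- numeric(length(genes))
  det <- !is.nan(s) & !is.nan(t)
  out[det] <- t[det] - s[det]
  if (mapping == "directional") {
    out[!is.nan(s) & s == 1 & is.nan(t)] <- -1
    out[!is.nan(s) & s == 0 & is.nan(t)] <- 1
    out[is.nan(s) & !is.nan(t) & t == 1] <- 1
    out[is.nan(s) & !is.nan(t) & t == 0] <- -1
  }
  stats::setNames(out, genes)
}

#' Read an expression table of per-condition median intensities
#'
#' Expects a delimited text table with a gene-symbol column and one numeric
#' column of median intensities per condition.  The delimiter is inferred from
#' the file extension (`.csv` comma, otherwise tab).
#'
#' @param path file path.
#' @param gene_col name of the gene-symbol column (default `"gene"`).
#' @return data.frame with the gene column first.
#' @export
read_expression <- function(path, gene_col = "gene") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!gene_col %in% names(tab))
    stopf("expression table lacks gene column '%s'", gene_col)
  tab[, c(gene_col, setdiff(names(tab), gene_col))]
}

#' Collapse probe-level rows to one row per gene by median
#'
#' Multiple probes (or replicates) mapping to the same symbol are summarised
#' by the median of each condition column.
#'
#' @param expr expression data.frame.
#' @param gene_col gene-symbol column name.
#' @return data.frame with unique gene symbols.
#' @export
collapse_probes <- function(expr, gene_col = "gene") {
  conds <- setdiff(names(expr), gene_col)
  agg <- stats::aggregate(expr[conds], by = expr[gene_col], FUN = stats::median)
  agg[order(match(agg[[gene_col]], expr[[gene_col]])), , drop = FALSE]
}

#' Fold changes and discretization thresholds
#'
#' Computes per-gene fold change `F = M_tgt / M_src` between two condition
#' columns, its decimal log `Z = log10(F)`, and the discretization thresholds
#' `theta_up = mu + k*sigma`, `theta_down = mu - k*sigma` from the mean `mu`
#' and standard deviation `sigma` of the `Z` distribution (default multiplier
#' `k = 1`).  Setting the cutoffs from the observed distribution normalizes
#' comparisons across cell types with different global intensity scales: a
#' common rescaling of one condition shifts every `Z` (and `mu`) equally and
#' leaves the discretization unchanged.  Genes with missing or non-positive
#' median in either condition are excluded and reported.
#'
#' @param expr expression data.frame (one row per gene).
#' @param src_cond,tgt_cond condition column names (source and target).
#' @param multiplier threshold multiplier `k`.
#' @param gene_col gene-symbol column name.
#' @return object of class `fold_change_set`: list with `table` (data.frame
#'   `gene`, `F`, `Z`), `mu`, `sigma`, `theta_up`, `theta_down`, `excluded`.
#' @export
fold_changes <- function(expr, src_cond, tgt_cond, multiplier = 1,
                         gene_col = "gene") {
  for (cc in c(src_cond, tgt_cond))
    if (!cc %in% names(expr)) stopf("condition column '%s' not found", cc)
  src <- as.numeric(expr[[src_cond]])
  tgt <- as.numeric(expr[[tgt_cond]])
  ok <- !is.na(src) & !is.na(tgt) & src > 0 & tgt > 0
  excluded <- expr[[gene_col]][!ok]
  if (sum(ok) < 3)
    stopf("fewer than 3 genes with positive medians in both conditions")
  Fc <- tgt[ok] / src[ok]
  Z <- log10(Fc)
  mu <- mean(Z); sigma <- stats::sd(Z)
  if (sigma == 0)
    stopf("degenerate fold-change distribution (sd of log10 fold changes is 0); thresholds undefined")
  structure(list(table = data.frame(gene = expr[[gene_col]][ok], F = Fc, Z = Z),
                 mu = mu, sigma = sigma,
                 theta_up = mu + multiplier * sigma,
                 theta_down = mu - multiplier * sigma,
                 multiplier = multiplier,
                 excluded = as.character(excluded)),
            class = "fold_change_set")
}

#' @export
print.fold_change_set <- function(x, ...) {
  cat(sprintf("fold_change_set: %d genes (%d excluded); mu = %.4f, sigma = %.4f, thresholds [%.4f, %.4f]\n",
              nrow(x$table), length(x$excluded), x$mu, x$sigma,
              x$theta_down, x$theta_up))
  invisible(x)
}

#' Discretized experimental change (E_exp)
#'
#' `Z > theta_up` is up-regulated (+1), `Z < theta_down` down-regulated (-1),
#' anything else — including exact equality with a threshold — unchanged (0).
#'
#' @param fc a [fold_changes()] result.
#' @return named numeric vector of -1/0/+1 per retained gene.
#' @export
compute_Eexp <- function(fc) {
  stopifnot(inherits(fc, "fold_change_set"))
  z <- fc$table$Z
  stats::setNames(ifelse(z > fc$theta_up, 1, ifelse(z < fc$theta_down, -1, 0)),
                  fc$table$gene)
}

#' Match expression gene symbols to model nodes
#'
#' Case-insensitive symbol matching, with merged-node aliases expanded (a node
#' representing several paralogues matches any of its constituent symbols).
#' Call [collapse_probes()] first when the table has multiple rows per gene.
#'
#' @param net a `signed_network`.
#' @param expr expression data.frame.
#' @param gene_col gene-symbol column name.
#' @return data.frame `gene` (expression symbol), `node` (model node id).
#' @export
match_genes <- function(net, expr, gene_col = "gene") {
  stopifnot(inherits(net, "signed_network"))
  map <- list()
  for (i in seq_len(nrow(net$nodes))) {
    syms <- net$nodes$id[i]
    if (!is.na(net$nodes$aliases[i]))
      syms <- c(syms, strsplit(net$nodes$aliases[i], ";", fixed = TRUE)[[1]])
    for (s in toupper(trimws(syms))) map[[s]] <- net$nodes$id[i]
  }
  genes <- as.character(expr[[gene_col]])
  hit <- toupper(trimws(genes)) %in% names(map)
  data.frame(gene = genes[hit],
             node = unlist(map[toupper(trimws(genes[hit]))], use.names = FALSE))
}

#' Exact binomial significance of the true-prediction count
#'
#' One-sided exact binomial tail probability `P(X >= n_true)` with
#' `X ~ Binomial(n_total, p0)`.  The null `p0 = 1/3` corresponds to guessing
#' among three equiprobable outcomes (up / unchanged / down).
#'
#' @param n_true number of exact matches.
#' @param n_total number of scored genes.
#' @param p0 null match probability.
#' @return p-value.
#' @export
significance <- function(n_true, n_total, p0 = 1/3) {
  if (length(n_true) != 1 || length(n_total) != 1 || is.na(n_true) ||
      is.na(n_total) || n_true < 0 || n_total < 0 || n_true > n_total)
    stopf("invalid counts: n_true = %s, n_total = %s",
          as.character(n_true), as.character(n_total))
  stats::pbinom(n_true - 1, n_total, p0, lower.tail = FALSE)
}

#' Score model predictions against discretized expression
#'
#' Computes `|E_mod - E_exp|` per gene: 0 is a true prediction, 1 a small
#' error (one of the two calls a change the other does not), 2 a large error
#' (opposite directions).  Reports the census with percentages and the
#' one-sided binomial significance of the true-prediction count against the
#' random baseline of 1/3.
#'
#' @param Emod named -1/0/+1 vector from [compute_Emod()].
#' @param Eexp named -1/0/+1 vector from [compute_Eexp()].
#' @param genes genes to score; default the intersection of the two name
#'   sets.  Supplying genes absent from either vector is an error.
#' @param p0 null match probability for [significance()].
#' @return object of class `concordance_report`: list with `per_gene`
#'   (data.frame `gene`, `E_mod`, `E_exp`, `diff`), `n_true`, `n_small`,
#'   `n_large`, `pct` (named percentages), `n`, `p_value`.
#' @export
score_concordance <- function(Emod, Eexp, genes = NULL, p0 = 1/3) {
  if (is.null(genes)) genes <- intersect(names(Emod), names(Eexp))
  miss <- c(setdiff(genes, names(Emod)), setdiff(genes, names(Eexp)))
  if (length(miss) > 0) stopf("gene '%s' missing from E_mod/E_exp", miss[1])
  if (length(genes) == 0) stopf("no genes to score")
  d <- abs(Emod[genes] - Eexp[genes])
  per_gene <- data.frame(gene = genes, E_mod = as.numeric(Emod[genes]),
                         E_exp = as.numeric(Eexp[genes]), diff = as.numeric(d))
  n <- length(genes)
  n_true <- sum(d == 0); n_small <- sum(d == 1); n_large <- sum(d == 2)
  structure(list(per_gene = per_gene, n = n,
                 n_true = n_true, n_small = n_small, n_large = n_large,
                 pct = c(true = 100 * n_true / n, small = 100 * n_small / n,
                         large = 100 * n_large / n),
                 p_value = significance(n_true, n, p0 = p0)),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("concordance_report over %d genes: %d true (%.1f%%), %d small (%.1f%%), %d large (%.1f%%); p = %.3g\n",
              x$n, x$n_true, x$pct["true"], x$n_small, x$pct["small"],
              x$n_large, x$pct["large"], x$p_value))
  invisible(x)
}
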