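#' Generate a random signed network
#'
#' Directed random networks with designated input and output nodes, for
#' property-style testing of every analysis stage.  Role constraints are
#' enforced by construction: inputs receive no incoming edges and outputs emit
#' no outgoing ones.  Edge signs are i.i.d. inhibitory with probability
#' `frac_inhibitory`.  Two wiring models are available: `"erdos"` samples the
#' requested number of edges uniformly from all admissible ordered pairs;
#' `"hub"` grows a degree-skewed network by sampling endpoints with
#' probability proportional to current degree + 1, mimicking the hub-dominated
#' connectivity of curated signalling interactomes.
#'
#' @param n_nodes total number of nodes.
#' @param edge_density expected edges per node (total edges =
#'   `round(n_nodes * edge_density)`).
#' @param frac_inhibitory probability that an edge is an inhibition.
#' @param n_inputs,n_outputs numbers of input / output nodes (named `IN*`,
#'   `OUT*`; internal nodes are `G*`).
#' @param model `"erdos"` or `"hub"`.
#' @param seed RNG seed; identical seeds give identical networks.
#' @return a `signed_network`.
#' @export
generate_network <- function(n_nodes, edge_density = 2, frac_inhibitory = 0.3,
                             n_inputs = 1, n_outputs = 1,
                             model = c("erdos", "hub"), seed = NULL) {
  model <- match.arg(model)
  if (n_nodes < n_inputs + n_outputs + 1)
    stopf("n_nodes must exceed n_inputs + n_outputs")
  if (frac_inhibitory < 0 || frac_inhibitory > 1)
    stopf("frac_inhibitory must be in [0, 1]")
  if (edge_density <= 0) stopf("edge_density must be positive")
  n_int <- n_nodes - n_inputs - n_outputs
  ids <- c(sprintf("IN%d", seq_len(n_inputs)),
           sprintf("G%d", seq_len(n_int)),
           sprintf("OUT%d", seq_len(n_outputs)))
  role <- c(rep("input", n_inputs), rep("internal", n_int),
            rep("output", n_outputs))
  can_src <- which(role != "output")
  can_tgt <- which(role != "input")
  pairs <- expand.grid(src = can_src, tgt = can_tgt)
  pairs <- pairs[pairs$src != pairs$tgt, , drop = FALSE]
  m <- round(n_nodes * edge_density)
  if (m > nrow(pairs))
    stopf("edge_density %.2f requires %d edges but only %d admissible pairs exist",
          edge_density, m, nrow(pairs))
  with_seed(seed, {
    if (model == "erdos") {
      take <- sample.int(nrow(pairs), m)
    } else {
      deg <- rep(1, n_nodes)  # degree + 1 weights
      take <- integer(0)
      avail <- rep(TRUE, nrow(pairs))
      for (k in seq_len(m)) {
        w <- deg[pairs$src] * deg[pairs$tgt] * avail
        pick <- sample.int(nrow(pairs), 1, prob = w)
        take <- c(take, pick)
        avail[pick] <- FALSE
        deg[pairs$src[pick]] <- deg[pairs$src[pick]] + 1
        deg[pairs$tgt[pick]] <- deg[pairs$tgt[pick]] + 1
      }
    }
    sgn <- ifelse(stats::runif(m) < frac_inhibitory, -1L, 1L)
    signed_network(
      edges = data.frame(source = ids[pairs$src[take]],
                         target = ids[pairs$tgt[take]], sign = sgn),
      nodes = data.frame(id = ids, role = role))
  })
}

#' Generate an expression table with planted state changes
#'
#' Emulates summarized microarray medians for two conditions: each gene's
#' log10 fold change is drawn as `Z ~ Normal(delta * pattern, sigma_noise)`,
#' where `pattern` is the planted -1/0/+1 change per gene; the source median
#' is the baseline intensity and the target median is `baseline * 10^Z`.
#' Gaussian noise on the log10 scale matches the log10 discretization used by
#' [fold_changes()].  Intensities are positive by construction.
#'
#' @param pattern named vector of planted changes in `c(-1, 0, 1)` (names are
#'   gene symbols).
#' @param delta effect size in log10 units.
#' @param sigma_noise noise standard deviation in log10 units (>= 0).
#' @param baseline source-condition intensity.
#' @param src_cond,tgt_cond condition column names.
#' @param seed RNG seed.
#' @return data.frame `gene`, `<src_cond>`, `<tgt_cond>`.
#' @export
generate_expression <- function(pattern, delta = 1, sigma_noise = 0.3,
                                baseline = 1000,
                                src_cond = "source", tgt_cond = "target",
                                seed = NULL) {
  if (is.null(names(pattern)) || any(!nzchar(names(pattern))))
    stopf("'pattern' must be a named vector")
  if (!all(pattern %in% c(-1, 0, 1)))
    stopf("planted pattern values must be -1, 0 or 1")
  if (sigma_noise < 0) stopf("sigma_noise must be >= 0")
  with_seed(seed, {
    z <- stats::rnorm(length(pattern), mean = delta * as.numeric(pattern),
                      sd = sigma_noise)
    out <- data.frame(gene = names(pattern), src = baseline,
                      tgt = baseline * 10^z)
    names(out)[2:3] <- c(src_cond, tgt_cond)
    out
  })
}

#' Small named motif networks with documented expected behaviour
#'
#' Ships three hand-built fixtures used throughout the test suite:
#' * `mdm_loop` — the p53/MDM2/MDM4 feedback cluster (five edges: p53
#'   activates MDM2, MDM2 inhibits p53, MDM2 inhibits MDM4, MDM4 both
#'   activates and inhibits MDM2); contains the classic negative p53–MDM2
#'   feedback loop.
#' * `ambivalence` — a direct activation ATM to CHEK2 alongside the indirect
#'   negative route ATM activates p53, p53 inhibits MYC, MYC activates E2F1,
#'   E2F1 activates CHEK2; ATM is an ambivalent factor for CHEK2.
#' * `ladder` — input, three-node activation chain, output; clamping the
#'   input determines every node.
#'
#' @return named list of `signed_network` objects.
#' @export
motif_fixtures <- function() {
  mdm_loop <- signed_network(edges = data.frame(
    source = c("p53", "MDM2", "MDM2", "MDM4", "MDM4"),
    target = c("MDM2", "p53", "MDM4", "MDM2", "MDM2"),
    sign = c(1L, -1L, -1L, 1L, -1L)))
  ambivalence <- signed_network(edges = data.frame(
    source = c("ATM", "ATM", "p53", "MYC", "E2F1"),
    target = c("CHEK2", "p53", "MYC", "E2F1", "CHEK2"),
    sign = c(1L, 1L, -1L, 1L, 1L)))
  ladder <- signed_network(
    edges = data.frame(source = c("IN", "A", "B", "C"),
                       target = c("A", "B", "C", "OUT"),
                       sign = 1L),
    nodes = data.frame(id = c("IN", "A", "B", "C", "OUT"),
                       role = c("input", "internal", "internal", "internal",
                                "output")))
  list(mdm_loop = mdm_loop, ambivalence = ambivalence, ladder = ladder)
}

#' A curated small DNA-damage/p53 demonstration network
#'
#' A 20-node signed network assembled from well-established interactions of
#' the DNA-damage response: the DNA damage input signal feeds the ATM/ATR
#' kinases and checkpoint machinery, p53 sits at the hub with its MDM2/MDM4
#' regulators, and apoptosis and senescence are the phenotypic outputs.  The
#' network is intentionally small — a demonstration and test article, not a
#' genome-scale reconstruction — but reproduces the qualitative behaviours of
#' large curated p53 models: the negative p53–MDM2 feedback loop, ambivalent
#' influence of DNA damage on FAS through p53-dependent negative routes that
#' resolves to a strong activation when p53 is knocked out, and loss of
#' determinedness of the steady state in the p53-deleted background.
#'
#' @return a `signed_network` (20 nodes: 1 input `DNAdamage`, outputs
#'   `apoptosis` and `senescence`).
#' @export
example_damage_network <- function() {
  edges <- rbind(
    # input layer
    c("DNAdamage", "ATM", 1), c("DNAdamage", "ATR", 1),
    c("DNAdamage", "FAS", 1),
    c("DNAdamage", "PTTG1", -1), c("DNAdamage", "AURKA", -1),
    # kinases to p53 and checkpoints
    c("ATM", "p53", 1), c("ATM", "CHEK2", 1), c("ATM", "CHEK1", 1),
    c("ATR", "p53", 1), c("ATR", "CHEK1", 1),
    c("CHEK2", "p53", 1), c("CHEK1", "CDC25A", -1),
    c("AURKA", "p53", -1),
    # the MDM cluster
    c("p53", "MDM2", 1), c("MDM2", "p53", -1), c("MDM2", "MDM4", -1),
    c("MDM4", "MDM2", 1), c("MDM4", "MDM2", -1),
    # p53 targets
    c("p53", "MYC", -1), c("p53", "BAX", 1), c("p53", "CDKN1A", 1),
    c("p53", "p53AIP1", 1), c("p53", "LATS2", 1), c("p53", "FAS", 1),
    c("p53", "PTTG1", -1),
    # downstream wiring
    c("MYC", "E2F1", 1), c("E2F1", "CHEK2", 1), c("MYC", "FAS", 1),
    # outputs
    c("FAS", "apoptosis", 1), c("BAX", "apoptosis", 1),
    c("p53AIP1", "apoptosis", 1), c("LATS2", "apoptosis", 1),
    c("CDKN1A", "senescence", 1), c("MYC", "senescence", -1))
  edges <- data.frame(source = edges[, 1], target = edges[, 2],
                      sign = as.integer(edges[, 3]))
  nodes <- data.frame(
    id = c("DNAdamage", "ATM", "ATR", "CHEK1", "CHEK2", "AURKA", "PTTG1",
           "CDC25A", "p53", "MDM2", "MDM4", "MYC", "E2F1", "FAS", "BAX",
           "CDKN1A", "p53AIP1", "LATS2", "apoptosis", "senescence"),
    role = c("input", rep("internal", 17), "output", "output"))
  signed_network(edges = edges, nodes = nodes)
}
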