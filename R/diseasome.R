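# SNP-based diseasome networks: projection of the disease--SNP bipartite
# graph onto diseases, and the network-coherence z-score of node subsets.

#' Build a SNP-based diseasome network
#'
#' Nodes are diseases; an edge links two diseases when they share at least
#' `edge_threshold` SNPs of the prescribed class: `border` keeps only SNPs
#' in `border_snp_ids` (the majority-rule border set), `non_border` the
#' complement; `intergenic_only` further restricts to intergenic SNPs.
#' Diseases with no SNP of the prescribed type are dropped from the network.
#'
#' @param catalog a [disease_catalog] (SNPs need `category` when
#'   `intergenic_only = TRUE`).
#' @param border_snp_ids character vector of border SNP ids (from
#'   [majority_border_snp_set()]).
#' @param snp_class `"border"` or `"non_border"`.
#' @param intergenic_only restrict to intergenic SNPs?
#' @param edge_threshold minimum number of shared SNPs for an edge
#'   (default 1).
#' @param enriched_ids optional character vector of majority-enriched
#'   disease ids, stored as a node attribute.
#' @return An [igraph][igraph::igraph-package] graph with vertex attributes
#'   `isCancer`, `enriched`, `n_snps`, edge attribute `shared` and graph
#'   attributes `snp_class`, `intergenic_only`, `edge_threshold`.
#' @export
build_diseasome <- function(catalog, border_snp_ids,
                            snp_class = c("border", "non_border"),
                            intergenic_only = FALSE, edge_threshold = 1,
                            enriched_ids = character()) {
  snp_class <- match.arg(snp_class)
  snps <- catalog$snps
  keep <- if (snp_class == "border") {
    snps$snpId %in% border_snp_ids
  } else {
    !(snps$snpId %in% border_snp_ids)
  }
  if (intergenic_only) {
    if (!"category" %in% names(snps)) {
      stop_invalid("catalog SNPs carry no category; run classify_snps() first")
    }
    keep <- keep & snps$category == "intergenic"
  }
  kept_ids <- snps$snpId[keep]
  assoc <- catalog$assoc[catalog$assoc$snpId %in% kept_ids, , drop = FALSE]
  sets <- split(assoc$snpId, assoc$efoId)
  node_ids <- names(sets)

  edges <- data.frame(from = character(), to = character(),
                      shared = integer(), stringsAsFactors = FALSE)
  if (length(node_ids) >= 2) {
    # shared-SNP counts via the bipartite incidence product
    inc <- table(assoc$snpId, factor(assoc$efoId, levels = node_ids)) > 0
    sh <- crossprod(inc)  # diseases x diseases, shared SNP counts
    sel <- which(upper.tri(sh) & sh >= edge_threshold, arr.ind = TRUE)
    if (nrow(sel)) {
      edges <- data.frame(from = node_ids[sel[, 1]], to = node_ids[sel[, 2]],
                          shared = sh[sel], stringsAsFactors = FALSE)
    }
  }
  verts <- data.frame(
    name = node_ids,
    isCancer = catalog$diseases$isCancer[match(node_ids,
                                               catalog$diseases$efoId)],
    enriched = node_ids %in% enriched_ids,
    n_snps = lengths(sets),
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = verts)
  g <- igraph::set_graph_attr(g, "snp_class", snp_class)
  g <- igraph::set_graph_attr(g, "intergenic_only", intergenic_only)
  g <- igraph::set_graph_attr(g, "edge_threshold", edge_threshold)
  g
}

#' Number of edges induced by a node subset
#'
#' @param network an igraph graph.
#' @param subset character vector of node names (must all exist).
#' @return Count of edges with both endpoints in `subset`.
#' @export
induced_edge_count <- function(network, subset) {
  missing <- setdiff(subset, igraph::V(network)$name)
  if (length(missing)) {
    stop_invalid("unknown node id(s): %s", paste(missing, collapse = ", "))
  }
  igraph::ecount(igraph::induced_subgraph(network, subset))
}

#' Network coherence of a node subset
#'
#' z-score of the induced-subgraph edge count of `subset` against groups of
#' nodes of the same size drawn at random from the network: by default 1000
#' independent uniform draws without replacement within each draw; when the
#' number of possible subsets is small (`choose(|V|, s) <= enum_budget`) the
#' null is enumerated exactly instead. A random subset has vanishing
#' coherence; a positive value means the subset is more densely
#' interconnected than chance. The null standard deviation uses the
#' population formula over the draws; when it is zero (e.g., an edgeless
#' network or `s = |V|`) the z-score is flagged undefined rather than
#' reported as 0.
#'
#' @param network an igraph graph.
#' @param subset character vector of node names, `1 <= length(subset) <
#'   |V|`.
#' @param n_draws number of random groups (default 1000).
#' @param seed integer seed.
#' @param exact force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   default `NULL` switches automatically under `enum_budget`.
#' @param enum_budget maximum number of subsets enumerated exactly
#'   (default 1e5).
#' @return An object of class `coherence_result`: list with `subset_size`,
#'   `m_obs`, `mu`, `sigma`, `z`, `defined`, `method`, `n_draws`.
#' @examples
#' g <- igraph::graph_from_literal(A - B, B - C, A - C, D)
#' network_coherence(g, c("A", "B"))  # exact: mu 0.5, sigma 0.5, z 1
#' @export
network_coherence <- function(network, subset, n_draws = 1000, seed = NULL,
                              exact = NULL, enum_budget = 1e5) {
  nodes <- igraph::V(network)$name
  s <- length(subset)
  if (s < 1 || s >= length(nodes) + 1) {
    stop_invalid("subset size must be in [1, |V|]")
  }
  missing <- setdiff(subset, nodes)
  if (length(missing)) {
    stop_invalid("unknown node id(s): %s", paste(missing, collapse = ", "))
  }
  el <- igraph::as_edgelist(network, names = FALSE)
  memb_count <- function(idx) {
    inset <- logical(length(nodes))
    inset[idx] <- TRUE
    sum(inset[el[, 1]] & inset[el[, 2]])
  }
  m_obs <- memb_count(match(subset, nodes))

  use_exact <- exact %||% (choose(length(nodes), s) <= enum_budget)
  if (use_exact) {
    counts <- utils::combn(length(nodes), s, FUN = memb_count)
    method <- "exact"
    n_used <- length(counts)
  } else {
    counts <- with_seed(seed, {
      vapply(seq_len(n_draws),
             function(i) memb_count(sample.int(length(nodes), s)),
             numeric(1))
    })
    method <- "sampling"
    n_used <- n_draws
  }
  mu <- mean(counts)
  sigma <- sqrt(mean((counts - mu)^2))  # population formula
  defined <- sigma > 0
  structure(
    list(subset_size = s, m_obs = m_obs, mu = mu, sigma = sigma,
         z = if (defined) (m_obs - mu) / sigma else NA_real_,
         defined = defined, method = method, n_draws = n_used),
    class = "coherence_result"
  )
}

#' @export
print.coherence_result <- function(x, ...) {
  cat(sprintf(
    "Network coherence (%s, %d null groups): subset %d nodes, %d internal edges, null %.3f +/- %.3f, z = %s\n",
    x$method, x$n_draws, x$subset_size, x$m_obs, x$mu, x$sigma,
    if (x$defined) sprintf("%.3f", x$z) else "undefined (sigma = 0)"))
  invisible(x)
}

#' Coherence report over the four diseasome variants
#'
#' Builds the four networks (border / non-border SNPs, each with and without
#' the intergenic-only filter) and computes the coherence of six node types
#' in each: cancers and non-cancer diseases, split into all /
#' majority-enriched / not-enriched. Empty node types are skipped.
#'
#' @param catalog a [disease_catalog] with SNP categories.
#' @param border_snp_ids majority-rule border SNP ids.
#' @param enriched_ids majority-enriched disease ids.
#' @param n_draws,seed passed to [network_coherence()].
#' @param edge_threshold minimum shared SNPs per edge.
#' @return data.frame: `snp_class`, `intergenic_only`, `node_type`,
#'   `n_nodes`, `m_obs`, `mu`, `sigma`, `z`, `method`.
#' @export
coherence_report <- function(catalog, border_snp_ids, enriched_ids,
                             n_draws = 1000, seed = NULL,
                             edge_threshold = 1) {
  variants <- expand.grid(snp_class = c("border", "non_border"),
                          intergenic_only = c(FALSE, TRUE),
                          stringsAsFactors = FALSE)
  rows <- list()
  draw_i <- 0
  for (v in seq_len(nrow(variants))) {
    g <- build_diseasome(catalog, border_snp_ids,
                         snp_class = variants$snp_class[v],
                         intergenic_only = variants$intergenic_only[v],
                         edge_threshold = edge_threshold,
                         enriched_ids = enriched_ids)
    vs <- data.frame(name = igraph::V(g)$name,
                     isCancer = igraph::V(g)$isCancer,
                     enriched = igraph::V(g)$enriched,
                     stringsAsFactors = FALSE)
    node_types <- list(
      cancer_all = vs$name[vs$isCancer],
      cancer_enriched = vs$name[vs$isCancer & vs$enriched],
      cancer_not_enriched = vs$name[vs$isCancer & !vs$enriched],
      noncancer_all = vs$name[!vs$isCancer],
      noncancer_enriched = vs$name[!vs$isCancer & vs$enriched],
      noncancer_not_enriched = vs$name[!vs$isCancer & !vs$enriched]
    )
    for (nt in names(node_types)) {
      subset <- node_types[[nt]]
      draw_i <- draw_i + 1
      if (length(subset) == 0 || length(subset) >= nrow(vs)) next
      cr <- network_coherence(g, subset, n_draws = n_draws,
                              seed = if (is.null(seed)) NULL
                                     else derive_seed(seed, draw_i))
      rows[[length(rows) + 1L]] <- data.frame(
        snp_class = variants$snp_class[v],
        intergenic_only = variants$intergenic_only[v],
        node_type = nt, n_nodes = length(subset), m_obs = cr$m_obs,
        mu = cr$mu, sigma = cr$sigma, z = cr$z, method = cr$method,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows) %||%
    data.frame(snp_class = character(), intergenic_only = logical(),
               node_type = character(), n_nodes = integer(),
               m_obs = integer(), mu = numeric(), sigma = numeric(),
               z = numeric(), method = character())
  rownames(out) <- NULL
  out
}
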