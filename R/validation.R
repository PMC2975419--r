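# Network validation analyses: cross-species conservation of predicted
# pairs, pathway-hub degree comparison, and GO enrichment of seed-protein
# neighborhoods.

#' Map predicted pairs into reference organisms and look them up
#'
#' Each predicted pair is mapped through a reversed ortholog map (query
#' protein -> reference-organism orthologs); every cross-product pair is
#' searched in that organism's reference interactome. Pairs whose prediction
#' rests on orthology from an excluded organism are skipped, so a network
#' built from, say, yeast interologs is not "validated" against yeast again.
#'
#' @param predicted A `scored_network`.
#' @param maps Named list (by organism) of `ortholog_map`s targeting the
#'   reference organism.
#' @param references Named list (by organism) of reference pair tables
#'   (data.frames with `key`, or character key vectors).
#' @param exclude_sources Organisms whose ortholog evidence disqualifies a
#'   pair from being mapped to that same organism. A pair is treated as
#'   ortholog-derived when its `lr_ortholog` column exceeds 1.
#' @return data.frame with columns `query_a`, `query_b`, `organism`,
#'   `mapped_a`, `mapped_b`, `found_in_reference`.
#' @export
map_conservation <- function(predicted, maps, references,
                             exclude_sources = character(0)) {
  df <- as.data.frame(predicted)
  rows <- list()
  for (org in names(maps)) {
    ref <- references[[org]]
    ref_keys <- if (is.data.frame(ref)) ref$key else as.character(ref)
    use <- df
    if (org %in% exclude_sources && "lr_ortholog" %in% names(df)) {
      use <- df[df$lr_ortholog <= 1, , drop = FALSE]
    }
    mapping <- maps[[org]]$mapping
    for (i in seq_len(nrow(use))) {
      ta <- mapping[[use$protein_a[i]]]
      tb <- mapping[[use$protein_b[i]]]
      if (is.null(ta) || is.null(tb)) next
      grid <- expand.grid(a = ta, b = tb, stringsAsFactors = FALSE)
      grid <- grid[grid$a != grid$b, , drop = FALSE]
      if (nrow(grid) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        query_a = use$protein_a[i], query_b = use$protein_b[i],
        organism = org, mapped_a = grid$a, mapped_b = grid$b,
        found_in_reference = pair_key(grid$a, grid$b) %in% ref_keys,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(query_a = character(0), query_b = character(0),
                      organism = character(0), mapped_a = character(0),
                      mapped_b = character(0),
                      found_in_reference = logical(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare network degree of pathway hubs against all nodes
#'
#' Proteins participating in more than `hub_min_pathways` pathways are
#' called hubs; their mean network degree is contrasted with the mean degree
#' over all network nodes.
#'
#' @param network A `scored_network` or edge data.frame.
#' @param pathway_membership Named list: protein -> character vector of
#'   pathway ids.
#' @param hub_min_pathways Strict threshold: hubs join more than this many
#'   pathways (default 10).
#' @return List with `mean_degree_hubs` (`NA` when there are no hubs),
#'   `mean_degree_all`, `n_hubs`, `n_nodes`.
#' @export
hub_degree_report <- function(network, pathway_membership,
                              hub_min_pathways = 10L) {
  stopifnot(hub_min_pathways >= 1L)
  df <- as.data.frame(network)
  deg <- table(c(df$protein_a, df$protein_b))
  n_path <- lengths(lapply(pathway_membership, unique))
  hubs <- intersect(names(n_path)[n_path > hub_min_pathways], names(deg))
  list(
    mean_degree_hubs = if (length(hubs)) mean(as.numeric(deg[hubs])) else
      NA_real_,
    mean_degree_all = mean(as.numeric(deg)),
    n_hubs = length(hubs),
    n_nodes = length(deg)
  )
}

#' GO enrichment of the network neighborhood of a seed protein set
#'
#' Collects the first-level network neighbors of the seeds (seeds themselves
#' excluded by default), propagates annotations up the ontology, and tests
#' each term for overrepresentation among the neighbors with the
#' hypergeometric upper tail; Benjamini-Hochberg q-values are attached.
#'
#' @param seed_set Character vector of seed proteins (network nodes).
#' @param network A `scored_network` or edge data.frame.
#' @param annotations Annotation data.frame.
#' @param dag An `ontology_dag`.
#' @param background Character vector of background proteins (must contain
#'   the neighbor set).
#' @param aspect Ontology aspect(s) to test (default `"BP"`).
#' @param include_seeds Keep seed proteins inside their own neighbor set
#'   (default `FALSE`).
#' @return data.frame with columns `term_id`, `p_value`, `q_value`, `k`
#'   (hits in neighbor set), `K` (hits in background), `n` (neighbor set
#'   size), `N` (background size), sorted by p-value.
#' @export
neighborhood_enrichment <- function(seed_set, network, annotations, dag,
                                    background, aspect = "BP",
                                    include_seeds = FALSE) {
  adj <- network_adjacency(network)
  nbrs <- unique(unlist(adj[intersect(seed_set, names(adj))],
                        use.names = FALSE))
  if (!include_seeds) nbrs <- setdiff(nbrs, seed_set)
  if (length(nbrs) == 0L) stop("seed set has no network neighbors")
  missing_bg <- setdiff(nbrs, background)
  if (length(missing_bg)) {
    stop("background must contain every neighbor; missing: ",
         paste(utils::head(missing_bg, 5L), collapse = ", "))
  }
  prop <- propagate_annotations(annotations, dag, aspect)
  prop <- prop[intersect(names(prop), background)]
  term_prots <- split(rep(names(prop), lengths(prop)),
                      unlist(prop, use.names = FALSE))
  N <- length(unique(background))
  n <- length(nbrs)
  rows <- lapply(names(term_prots), function(t) {
    K <- length(term_prots[[t]])
    k <- length(intersect(term_prots[[t]], nbrs))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = t, p_value = p, k = k, K = K, n = n, N = N,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$term_id),
             c("term_id", "p_value", "q_value", "k", "K", "n", "N")]
  rownames(out) <- NULL
  out
}
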