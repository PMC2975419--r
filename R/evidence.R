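# The seven per-pair evidence signals. Each operation returns an
# `evidence_layer`: a named numeric vector of scores over the layer's
# coverage (the set of pairs for which the evidence is defined), plus the
# layer name and type. Two layer types exist:
#   * "flag"  - a positive-prediction set; coverage holds only pairs with
#               flag 1, every other pair is an implicit 0 when calibrating
#               and "evidence absent" (LR 1) when integrating.
#   * "score" - real-valued (or explicit 0/1) scores on the covered pairs;
#               pairs outside coverage are "evidence absent".

#' Construct an evidence layer
#'
#' @param name Layer name, one of `ortholog`, `coexpression`, `domain`,
#'   `ssbp`, `gene_neighbor`, `gene_fusion`, `phylo_profile`.
#' @param scores Named numeric vector: canonical pair key -> score/flag.
#' @param type `"flag"` or `"score"` (see file header).
#' @param organism Optional organism tag (ortholog layers).
#' @return An `evidence_layer`.
#' @export
new_evidence_layer <- function(name, scores, type = c("score", "flag"),
                               organism = NULL) {
  type <- match.arg(type)
  stopifnot(is.numeric(scores))
  if (length(scores) && is.null(names(scores))) {
    stop("scores must be named by canonical pair keys")
  }
  if (anyDuplicated(names(scores))) stop("duplicate pair keys in layer")
  if (length(scores) && any(!is.finite(scores))) {
    stop("evidence scores must be finite")
  }
  structure(list(name = name, type = type, organism = organism,
                 scores = scores),
            class = "evidence_layer")
}

#' @export
print.evidence_layer <- function(x, ...) {
  cat("Evidence layer '", x$name, "'",
      if (!is.null(x$organism)) paste0(" (", x$organism, ")"), ": ",
      length(x$scores), " covered pair(s), type ", x$type, "\n", sep = "")
  invisible(x)
}

#' Project a model-organism interactome onto the query proteome
#'
#' Every interacting source pair (x, y) is transferred to every pair of
#' query-organism orthologs (a, b) with a in orthologs(x), b in orthologs(y)
#' and a != b (the interolog rule). One layer per source organism.
#'
#' @param source_ppi Pair table (data.frame with `key`, or character keys) in
#'   source-organism identifiers.
#' @param map An `ortholog_map` (see [read_ortholog_map()]): source protein
#'   -> query-proteome orthologs.
#' @return Flag `evidence_layer` named `ortholog`.
#' @export
project_orthologs <- function(source_ppi, map) {
  keys <- if (is.data.frame(source_ppi)) source_ppi$key else source_ppi
  mapping <- map$mapping
  if (length(mapping) == 0L) {
    warning("empty ortholog mapping for organism ",
            map$organism %||% "<unknown>")
    return(new_evidence_layer("ortholog", setNames(numeric(0), character(0)),
                              "flag", organism = map$organism))
  }
  ab <- pair_split(keys)
  out <- character(0)
  for (i in seq_len(nrow(ab))) {
    tx <- mapping[[ab$protein_a[i]]]
    ty <- mapping[[ab$protein_b[i]]]
    if (is.null(tx) || is.null(ty)) next
    grid <- expand.grid(a = tx, b = ty, stringsAsFactors = FALSE)
    k <- pair_key(grid$a, grid$b)
    out <- c(out, k[!is.na(k)])
  }
  out <- unique(out)
  new_evidence_layer("ortholog", setNames(rep(1, length(out)), out), "flag",
                     organism = map$organism)
}

#' Coexpression evidence: Pearson correlation of expression profiles
#'
#' @param expr Numeric expression matrix, genes in rows (see
#'   [read_expression_matrix()]); at least 3 samples.
#' @param pairs Canonical pair keys to score, or `NULL` for all gene pairs.
#' @return Score `evidence_layer` named `coexpression`; pairs with a
#'   zero-variance vector or a missing gene are outside coverage.
#' @export
coexpression_scores <- function(expr, pairs = NULL) {
  if (ncol(expr) < 3L) stop("need >= 3 samples to compute correlations")
  sds <- apply(expr, 1L, stats::sd)
  ok <- is.finite(sds) & sds > 0
  expr <- expr[ok, , drop = FALSE]
  if (is.null(pairs)) pairs <- all_pairs(rownames(expr))
  ab <- pair_split(pairs)
  covered <- ab$protein_a %in% rownames(expr) & ab$protein_b %in% rownames(expr)
  ab <- ab[covered, , drop = FALSE]
  pairs <- pairs[covered]
  cm <- stats::cor(t(expr))
  r <- cm[cbind(match(ab$protein_a, rownames(expr)),
                match(ab$protein_b, rownames(expr)))]
  new_evidence_layer("coexpression", setNames(as.numeric(r), pairs), "score")
}

# unordered key for domain pairs; unlike protein pairs, homotypic
# domain-domain interactions (d, d) are legal
ddi_key <- function(a, b) {
  swap <- cmp_gt(a, b)
  paste(ifelse(swap, b, a), ifelse(swap, a, b), sep = "|")
}

#' Domain support: does any domain pair across the two proteins interact?
#'
#' Flag 1 iff some domain of protein a and some domain of protein b form a
#' known domain-domain interaction (homotypic pairs included). Proteins with
#' no domains give flag 0; all requested pairs are covered.
#'
#' @param protein_domains Named list: protein_id -> character vector of
#'   domain ids.
#' @param ddi Domain-domain interactions: data.frame with columns
#'   `protein_a`/`protein_b` (domain ids) or a 2-column matrix/data.frame.
#' @param pairs Canonical pair keys to evaluate.
#' @return Score `evidence_layer` named `domain` with values in {0, 1}.
#' @export
domain_support <- function(protein_domains, ddi, pairs) {
  if (is.data.frame(ddi) || is.matrix(ddi)) {
    dd <- as.data.frame(ddi, stringsAsFactors = FALSE)
    ddi_set <- unique(ddi_key(as.character(dd[[1L]]), as.character(dd[[2L]])))
  } else {
    ddi_set <- unique(as.character(ddi))
  }
  # enumerate protein pairs supported by some interacting domain pair, then
  # test membership; avoids a per-pair domain cross product
  dom_prot <- split(rep(names(protein_domains), lengths(protein_domains)),
                    unlist(protein_domains, use.names = FALSE))
  supported <- character(0)
  for (k in ddi_set) {
    de <- strsplit(k, PAIR_SEP, fixed = TRUE)[[1L]]
    pa <- dom_prot[[de[1L]]]
    pb <- dom_prot[[de[2L]]]
    if (is.null(pa) || is.null(pb)) next
    grid <- expand.grid(a = pa, b = pb, stringsAsFactors = FALSE)
    kk <- pair_key(grid$a, grid$b)
    supported <- c(supported, kk[!is.na(kk)])
  }
  supported <- unique(supported)
  flag <- as.numeric(pairs %in% supported)
  new_evidence_layer("domain", setNames(flag, pairs), "score")
}

# protein -> ancestor-propagated term set, restricted to one aspect
propagate_annotations <- function(annotations, dag, aspect = "BP") {
  ann <- annotations[annotations$aspect %in% aspect &
                       annotations$term_id %in% dag$terms, , drop = FALSE]
  direct <- lapply(split(ann$term_id, ann$protein_id), unique)
  closure <- ancestor_closure(dag)
  lapply(direct, function(ts) {
    unique(c(ts, unlist(closure[ts], use.names = FALSE)))
  })
}

#' Smallest shared biological process (SSBP) score
#'
#' Annotations are propagated up the ontology; for each pair the score is
#' the size (number of annotated proteins, after propagation) of the
#' smallest biological-process term shared by both proteins. Small shared
#' terms mean a specific shared function and hence a likely interaction;
#' pairs sharing no BP term are outside coverage.
#'
#' @param annotations Annotation data.frame; only BP rows are used.
#' @param dag An `ontology_dag`.
#' @param pairs Canonical pair keys to score.
#' @return Score `evidence_layer` named `ssbp` (integer-valued).
#' @export
ssbp_scores <- function(annotations, dag, pairs) {
  prop <- propagate_annotations(annotations, dag, "BP")
  tc <- table(unlist(prop, use.names = FALSE))
  term_count <- setNames(as.integer(tc), names(tc))
  ab <- pair_split(pairs)
  ia <- match(ab$protein_a, names(prop))
  ib <- match(ab$protein_b, names(prop))
  score <- vapply(seq_along(pairs), function(i) {
    if (is.na(ia[i]) || is.na(ib[i])) return(NA_real_)
    shared <- intersect(prop[[ia[i]]], prop[[ib[i]]])
    if (length(shared) == 0L) return(NA_real_)
    min(term_count[shared])
  }, 0)
  keep <- !is.na(score)
  new_evidence_layer("ssbp", setNames(score[keep], pairs[keep]), "score")
}

#' Gene fusion (Rosetta stone) evidence
#'
#' Flag 1 for a pair (a, b) iff homology hits of a and of b land on the same
#' target protein in essentially non-overlapping regions - the signature of
#' the two proteins being fused into one polypeptide in another genome.
#'
#' @param hits data.frame with columns `query_protein`, `target_protein`,
#'   `start`, `end` (aligned interval on the target, 1-based inclusive).
#' @param min_gap_fraction Two hits support fusion when their overlap is less
#'   than this fraction of the shorter interval (default 0.2).
#' @param pairs Optional candidate keys; `NULL` scans all pairs sharing a
#'   target.
#' @return Flag `evidence_layer` named `gene_fusion`.
#' @export
gene_fusion_pairs <- function(hits, min_gap_fraction = 0.2, pairs = NULL) {
  stopifnot(min_gap_fraction >= 0, min_gap_fraction < 1)
  if (nrow(hits) && any(hits$start > hits$end)) {
    stop("fusion hit with start > end")
  }
  flagged <- character(0)
  for (h in split(hits, hits$target_protein)) {
    qs <- unique(h$query_protein)
    if (length(qs) < 2L) next
    for (i in seq_len(nrow(h))) {
      for (j in seq_len(nrow(h))) {
        if (j <= i) next
        a <- h$query_protein[i]; b <- h$query_protein[j]
        if (a == b) next
        ov <- min(h$end[i], h$end[j]) - max(h$start[i], h$start[j]) + 1L
        shorter <- min(h$end[i] - h$start[i], h$end[j] - h$start[j]) + 1L
        if (ov < min_gap_fraction * shorter) {
          flagged <- c(flagged, pair_key(a, b))
        }
      }
    }
  }
  flagged <- unique(flagged)
  if (!is.null(pairs)) flagged <- intersect(flagged, pairs)
  new_evidence_layer("gene_fusion",
                     setNames(rep(1, length(flagged)), flagged), "flag")
}

#' Phylogenetic profile similarity
#'
#' Correlated presence/absence across reference genomes suggests a
#' functional linkage. Profiles that are all-zero or all-one carry no
#' information and exclude their protein from coverage.
#'
#' @param profiles 0/1 matrix, proteins in rows (rownames), genomes in
#'   columns; at least 4 genomes.
#' @param pairs Canonical pair keys, or `NULL` for all profiled pairs.
#' @param metric `"hamming_similarity"` (fraction of matching bits, default)
#'   or `"mutual_information"` (from the 2x2 co-occurrence table, in bits).
#' @return Score `evidence_layer` named `phylo_profile`.
#' @export
phylo_profile_scores <- function(profiles, pairs = NULL,
                                 metric = c("hamming_similarity",
                                            "mutual_information")) {
  metric <- match.arg(metric)
  if (ncol(profiles) < 4L) stop("need >= 4 reference genomes")
  storage.mode(profiles) <- "double"
  rs <- rowSums(profiles)
  informative <- rs > 0 & rs < ncol(profiles)
  profiles <- profiles[informative, , drop = FALSE]
  if (is.null(pairs)) pairs <- all_pairs(rownames(profiles))
  ab <- pair_split(pairs)
  covered <- ab$protein_a %in% rownames(profiles) &
    ab$protein_b %in% rownames(profiles)
  ab <- ab[covered, , drop = FALSE]
  pairs <- pairs[covered]
  pa <- profiles[ab$protein_a, , drop = FALSE]
  pb <- profiles[ab$protein_b, , drop = FALSE]
  if (metric == "hamming_similarity") {
    score <- rowMeans(pa == pb)
  } else {
    score <- vapply(seq_len(nrow(pa)), function(i) {
      mutual_information_bits(pa[i, ], pb[i, ])
    }, 0)
  }
  new_evidence_layer("phylo_profile", setNames(as.numeric(score), pairs),
                     "score")
}

mutual_information_bits <- function(x, y) {
  n <- length(x)
  mi <- 0
  for (u in c(0, 1)) for (v in c(0, 1)) {
    puv <- sum(x == u & y == v) / n
    if (puv > 0) {
      mi <- mi + puv * log2(puv / ((sum(x == u) / n) * (sum(y == v) / n)))
    }
  }
  mi
}

#' Gene neighbor (conserved chromosomal adjacency) evidence
#'
#' Flag 1 for a pair iff, in at least `min_genomes` reference genomes,
#' orthologs of the two proteins lie on the same contig separated by at most
#' `max_distance` bp of intergenic gap (overlapping genes count as gap 0).
#'
#' @param context Gene-context data.frame (see [read_gene_context()]); the
#'   `query_protein` column links genes to the query proteome.
#' @param max_distance Maximum intergenic gap in bp (default 5000).
#' @param min_genomes Minimum number of genomes in which the adjacency must
#'   hold (default 2).
#' @param pairs Optional candidate keys; `NULL` scans all adjacencies.
#' @return Flag `evidence_layer` named `gene_neighbor`.
#' @export
gene_neighbor_pairs <- function(context, max_distance = 5000L,
                                min_genomes = 2L, pairs = NULL) {
  stopifnot(max_distance > 0L, min_genomes >= 1L)
  ctx <- context[!is.na(context$query_protein), , drop = FALSE]
  hit <- list()
  for (g in split(ctx, ctx$genome)) {
    keys_g <- character(0)
    for (cc in split(g, g$contig)) {
      m <- nrow(cc)
      if (m < 2L) next
      for (i in seq_len(m - 1L)) {
        for (j in (i + 1L):m) {
          gap <- max(max(cc$start[i], cc$start[j]) -
                       min(cc$end[i], cc$end[j]) - 1L, 0L)
          if (gap <= max_distance &&
              cc$query_protein[i] != cc$query_protein[j]) {
            keys_g <- c(keys_g,
                        pair_key(cc$query_protein[i], cc$query_protein[j]))
          }
        }
      }
    }
    hit[[length(hit) + 1L]] <- unique(keys_g)
  }
  counts <- table(unlist(hit, use.names = FALSE))
  flagged <- names(counts)[counts >= min_genomes]
  if (!is.null(pairs)) flagged <- intersect(flagged, pairs)
  new_evidence_layer("gene_neighbor",
                     setNames(rep(1, length(flagged)), flagged), "flag")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
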