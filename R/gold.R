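# Gold standard construction: positives from curated pairs plus bounded
# enzyme-complex expansion, negatives from localization-disjoint protein
# pairs, then reconciliation of the two sets.

#' Expand enzyme complexes into member pairs
#'
#' Complexes with strictly fewer than `max_size` members contribute all their
#' unordered member pairs; larger complexes contribute nothing. Pairs within
#' large complexes are unreliable as interaction evidence because subunits of
#' big assemblies rarely all touch each other.
#'
#' @param complexes Named list: complex_id -> character vector of members.
#' @param max_size Exclusive size bound (default 18): only complexes with
#'   fewer members than this are expanded.
#' @return Character vector of canonical pair keys.
#' @export
expand_complexes <- function(complexes, max_size = 18L) {
  stopifnot(max_size >= 2L)
  sizes <- lengths(lapply(complexes, unique))
  keep <- complexes[sizes < max_size]
  unique(unlist(lapply(keep, function(m) all_pairs(m)), use.names = FALSE))
}

#' Build the gold standard positive set
#'
#' Union of curated interaction pairs and bounded complex expansion, with
#' per-pair provenance (`curated`, `complex`, or `both`).
#'
#' @param curated data.frame of curated pairs (as from [read_pair_table()])
#'   or a character vector of canonical keys.
#' @param complexes Named list of complex memberships (may be empty).
#' @param max_complex_size Exclusive complex-size bound passed to
#'   [expand_complexes()].
#' @return List with `pairs` (character keys) and `provenance` (named
#'   character).
#' @export
build_gsp <- function(curated, complexes = list(), max_complex_size = 18L) {
  cur <- if (is.data.frame(curated)) curated$key else as.character(curated)
  cur <- unique(cur)
  cx <- expand_complexes(complexes, max_complex_size)
  pairs <- union(cur, cx)
  if (length(pairs) == 0L) {
    stop("gold standard positive set is empty; cannot calibrate ",
         "likelihood ratios")
  }
  prov <- ifelse(pairs %in% cur & pairs %in% cx, "both",
                 ifelse(pairs %in% cur, "curated", "complex"))
  names(prov) <- pairs
  list(pairs = pairs, provenance = prov)
}

#' Build the gold standard negative set from disjoint subcellular locations
#'
#' A pair enters the negative set iff both proteins carry at least one
#' cellular-component annotation with an allowed evidence code and their
#' allowed-code CC term sets are disjoint. Disjointness tests directly
#' annotated terms by default; with `propagate = TRUE` terms are first closed
#' over their ancestors (root terms excluded, so the shared ontology root
#' does not void every pair).
#'
#' @param annotations Annotation data.frame (see [read_annotations()]); only
#'   CC-aspect rows are used.
#' @param allowed_codes Evidence codes that qualify an annotation
#'   (default `c("IC", "IDA", "IPI")`).
#' @param protein_universe Optional character vector restricting the proteins
#'   considered; default all annotated proteins.
#' @param ontology Optional `ontology_dag`, required when `propagate = TRUE`.
#' @param propagate Test disjointness on ancestor-closed term sets instead of
#'   direct annotations.
#' @param max_pairs Optional cap: subsample the result to this many pairs.
#' @param seed Seed used when subsampling.
#' @return Character vector of canonical pair keys (possibly empty, with a
#'   warning).
#' @export
build_gsn <- function(annotations, allowed_codes = c("IC", "IDA", "IPI"),
                      protein_universe = NULL, ontology = NULL,
                      propagate = FALSE, max_pairs = NULL, seed = 1L) {
  stopifnot(length(allowed_codes) > 0L)
  ann <- annotations[annotations$aspect %in% "CC" &
                       annotations$evidence_code %in% toupper(allowed_codes), ,
                     drop = FALSE]
  if (!is.null(protein_universe)) {
    ann <- ann[ann$protein_id %in% protein_universe, , drop = FALSE]
  }
  loc <- lapply(split(ann$term_id, ann$protein_id), unique)
  if (propagate) {
    if (is.null(ontology)) stop("propagate = TRUE requires an ontology")
    roots <- ontology$terms[lengths(ontology$parents) == 0L]
    loc <- lapply(loc, function(ts) {
      setdiff(ontology_ancestors(ontology, ts, include_self = TRUE), roots)
    })
    loc <- loc[lengths(loc) > 0L]
  }
  prots <- names(loc)
  n <- length(prots)
  if (n < 2L) {
    warning("fewer than two proteins with qualifying CC annotations; ",
            "gold standard negative set is empty")
    return(character(0))
  }
  idx <- utils::combn(n, 2L)
  disjoint <- vapply(seq_len(ncol(idx)), function(j) {
    length(intersect(loc[[idx[1L, j]]], loc[[idx[2L, j]]])) == 0L
  }, TRUE)
  keys <- pair_key(prots[idx[1L, disjoint]], prots[idx[2L, disjoint]])
  keys <- keys[!is.na(keys)]
  if (length(keys) == 0L) {
    warning("gold standard negative set is empty")
  }
  if (!is.null(max_pairs) && length(keys) > max_pairs) {
    keys <- with_seed(seed, sample(keys, max_pairs))
  }
  sort(keys)
}

#' Reconcile gold standard positives and negatives
#'
#' Pairs appearing in both sets are removed from both and recorded; the
#' returned sets are disjoint.
#'
#' @param positives,negatives Character vectors of canonical pair keys (or a
#'   `build_gsp()` result for `positives`).
#' @return A `gold_standard`: list with `positives`, `negatives`,
#'   `removed_overlap`, `provenance`.
#' @export
reconcile_gold <- function(positives, negatives) {
  prov <- NULL
  if (is.list(positives) && !is.null(positives$pairs)) {
    prov <- positives$provenance
    positives <- positives$pairs
  }
  positives <- unique(as.character(positives))
  negatives <- unique(as.character(negatives))
  overlap <- intersect(positives, negatives)
  pos <- setdiff(positives, overlap)
  neg <- setdiff(negatives, overlap)
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("gold standard empty after removing ", length(overlap),
         " overlapping pair(s)")
  }
  structure(list(positives = pos, negatives = neg,
                 removed_overlap = overlap,
                 provenance = if (is.null(prov)) NULL else prov[pos]),
            class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat("Gold standard: ", length(x$positives), " positives, ",
      length(x$negatives), " negatives (", length(x$removed_overlap),
      " overlapping pair(s) removed from both)\n", sep = "")
  invisible(x)
}

# run code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}
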