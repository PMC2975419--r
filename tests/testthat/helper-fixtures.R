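# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately naive re-implementations (explicit enumeration) used to
# verify the optimized production code paths.

write_lines_tmp <- function(lines, env = parent.frame()) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = env)
  writeLines(lines, f)
  f
}

make_gold <- function(positives, negatives) {
  structure(list(positives = positives, negatives = negatives,
                 removed_overlap = character(0)),
            class = "gold_standard")
}

# random DAG on n terms: term i may have parents among terms with lower index
random_dag <- function(n_terms, p_edge = 0.3, namespace = "BP") {
  terms <- sprintf("T%02d", seq_len(n_terms))
  parents <- setNames(vector("list", n_terms), terms)
  for (i in seq_len(n_terms)) {
    if (i == 1L) { parents[[i]] <- character(0); next }
    cand <- terms[seq_len(i - 1L)]
    parents[[i]] <- cand[stats::runif(i - 1L) < p_edge]
    if (length(parents[[i]]) == 0L && stats::runif(1) < 0.8) {
      parents[[i]] <- sample(cand, 1L)
    }
  }
  new_ontology_dag(terms, parents,
                   namespace = setNames(rep(namespace, n_terms), terms))
}

# brute-force transitive ancestor closure by repeated expansion
brute_ancestors <- function(dag, term) {
  anc <- character(0)
  frontier <- dag$parents[[term]]
  while (length(frontier)) {
    anc <- union(anc, frontier)
    frontier <- setdiff(unique(unlist(dag$parents[frontier],
                                      use.names = FALSE)), anc)
  }
  anc
}

# brute-force SSBP: explicit propagation and explicit per-term counting
brute_ssbp <- function(annotations, dag, pairs) {
  ann <- annotations[annotations$aspect == "BP", , drop = FALSE]
  prot_terms <- list()
  for (i in seq_len(nrow(ann))) {
    p <- ann$protein_id[i]; t <- ann$term_id[i]
    prot_terms[[p]] <- union(prot_terms[[p]],
                             c(t, brute_ancestors(dag, t)))
  }
  term_n <- sapply(dag$terms, function(t) {
    sum(vapply(prot_terms, function(ts) t %in% ts, TRUE))
  })
  out <- setNames(rep(NA_real_, length(pairs)), pairs)
  for (k in pairs) {
    ab <- strsplit(k, "|", fixed = TRUE)[[1L]]
    ta <- prot_terms[[ab[1L]]]; tb <- prot_terms[[ab[2L]]]
    if (is.null(ta) || is.null(tb)) next
    shared <- intersect(ta, tb)
    if (length(shared)) out[k] <- min(term_n[shared])
  }
  out
}

# brute-force likelihood-ratio estimation by direct counting
brute_lr_binary <- function(flagged, gold, c0) {
  np <- length(gold$positives); nn <- length(gold$negatives)
  kp <- sum(gold$positives %in% flagged)
  kn <- sum(gold$negatives %in% flagged)
  pr <- function(k, n) (k + c0) / (n + 2 * c0)
  c(present = pr(kp, np) / pr(kn, nn),
    absent = pr(np - kp, np) / pr(nn - kn, nn))
}

brute_lr_binned <- function(scores_pos, scores_neg, breaks, c0) {
  B <- length(breaks) - 1L
  bin <- function(x) findInterval(x, breaks, left.open = TRUE,
                                  rightmost.closed = TRUE)
  kp <- tabulate(bin(scores_pos), B)
  kn <- tabulate(bin(scores_neg), B)
  ((kp + c0) / (length(scores_pos) + c0 * B)) /
    ((kn + c0) / (length(scores_neg) + c0 * B))
}

# exhaustive minimum-energy assignment for small annotation instances
brute_ground_state <- function(edges, known, unknowns, vocab) {
  grids <- do.call(expand.grid,
                   c(setNames(rep(list(vocab), length(unknowns)), unknowns),
                     stringsAsFactors = FALSE))
  energy_of <- function(assign) {
    tset <- function(p) if (p %in% unknowns) assign[[p]] else known[[p]]
    -sum(vapply(seq_len(nrow(edges)), function(i) {
      tu <- tset(edges$protein_a[i]); tv <- tset(edges$protein_b[i])
      length(tu) > 0L && length(tv) > 0L && length(intersect(tu, tv)) > 0L
    }, TRUE))
  }
  min(vapply(seq_len(nrow(grids)), function(r) {
    energy_of(as.list(grids[r, , drop = FALSE]))
  }, 0))
}

# a fixed battery of connected graphs on <= 6 nodes (edge lists on 1..n)
graph_battery <- function() {
  list(
    path3 = rbind(c(1, 2), c(2, 3)),
    tri = rbind(c(1, 2), c(2, 3), c(1, 3)),
    star4 = rbind(c(1, 2), c(1, 3), c(1, 4)),
    cycle4 = rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)),
    path5 = rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5)),
    k4 = t(utils::combn(4, 2)),
    star6 = cbind(1, 2:6),
    bowtie6 = rbind(c(1, 2), c(2, 3), c(1, 3), c(3, 4), c(4, 5), c(5, 6),
                    c(4, 6)),
    k5 = t(utils::combn(5, 2)),
    tree6 = rbind(c(1, 2), c(1, 3), c(2, 4), c(2, 5), c(3, 6))
  )
}

edges_df <- function(m) {
  data.frame(protein_a = paste0("N", m[, 1]), protein_b = paste0("N", m[, 2]),
             stringsAsFactors = FALSE)
}

small_world <- function(seed = 7L, ...) {
  generate_world(world_params(n_proteins = 60L, n_modules = 4L, ...),
                 seed = seed)
}
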