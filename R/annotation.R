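# Guilt-by-association function annotation. Function-unknown proteins are
# assigned one candidate term each; simulated annealing minimizes the number
# of network edges whose endpoints share no term. Significance of each
# resulting (protein, term) call is assessed by permuting the known
# protein -> term labels network-wide.

# adjacency list (canonical keys -> named list node -> neighbors)
network_adjacency <- function(network, tiers = NULL) {
  df <- as.data.frame(network)
  if (!is.null(tiers)) df <- df[df$tier %in% tiers, , drop = FALSE]
  nodes <- unique(c(df$protein_a, df$protein_b))
  adj <- c(split(df$protein_b, factor(df$protein_a, levels = nodes)),
           split(df$protein_a, factor(df$protein_b, levels = nodes)))
  adj <- tapply(unlist(adj, use.names = FALSE),
                rep(names(adj), lengths(adj)), unique, simplify = FALSE)
  out <- setNames(vector("list", length(nodes)), nodes)
  out[names(adj)] <- adj
  out
}

#' Annotate function-unknown proteins by simulated annealing
#'
#' Each unknown protein is assigned a single term drawn from its candidate
#' vocabulary (the union of its neighbors' known terms, falling back to the
#' global known vocabulary for unknowns with no annotated neighbor). The
#' energy of an assignment is minus the number of network edges whose two
#' endpoints share at least one term (known or assigned); Metropolis moves
#' with geometric cooling minimize it, and the best state seen is returned.
#'
#' @param network A `scored_network` or plain edge data.frame with
#'   `protein_a`, `protein_b` (and `tier` if `tiers` is used).
#' @param known Named list: protein -> character vector of known term ids.
#' @param unknowns Character vector of function-unknown proteins (must be
#'   network nodes).
#' @param schedule List with `t0` (initial temperature), `alpha` (geometric
#'   cooling factor in (0,1)), `steps_per_t` (Metropolis proposals per
#'   temperature per unknown protein, i.e. sweeps, making the schedule
#'   independent of problem size), `t_min`.
#' @param seed Integer seed; runs are deterministic given the seed.
#' @param tiers Optional tier filter applied to the network (e.g.
#'   `c("high", "medium")`).
#' @return An `anneal_state`: list with `assignment` (named character),
#'   `energy`, `initial_energy`, `schedule`, `seed`.
#' @export
anneal_annotations <- function(network, known, unknowns,
                               schedule = list(t0 = 1, alpha = 0.9,
                                               steps_per_t = 100L,
                                               t_min = 1e-3),
                               seed = 1L, tiers = NULL) {
  if (length(unknowns) == 0L) stop("no unknown proteins to annotate")
  if (schedule$t0 <= schedule$t_min) stop("t0 must exceed t_min")
  stopifnot(schedule$alpha > 0, schedule$alpha < 1)
  adj <- network_adjacency(network, tiers)
  missing <- setdiff(unknowns, names(adj))
  if (length(missing)) {
    stop("unknown protein(s) not in the network: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  known <- lapply(known, unique)
  global_vocab <- unique(unlist(known, use.names = FALSE))
  if (length(global_vocab) == 0L) stop("no known annotations supplied")
  vocab <- lapply(unknowns, function(u) {
    v <- unique(unlist(known[intersect(adj[[u]], names(known))],
                       use.names = FALSE))
    if (length(v)) v else global_vocab
  })
  names(vocab) <- unknowns

  edges <- as.data.frame(network)
  if (!is.null(tiers)) edges <- edges[edges$tier %in% tiers, , drop = FALSE]
  edges <- edges[!duplicated(pair_key(edges$protein_a, edges$protein_b)), ,
                 drop = FALSE]

  terms <- sort(unique(c(global_vocab, unlist(vocab, use.names = FALSE))))
  # constant contribution: matches on edges between two annotated proteins
  kk <- !(edges$protein_a %in% unknowns) & !(edges$protein_b %in% unknowns)
  e_known <- -sum(vapply(which(kk), function(i) {
    tu <- known[[edges$protein_a[i]]]; tv <- known[[edges$protein_b[i]]]
    length(tu) > 0L && length(tv) > 0L && length(intersect(tu, tv)) > 0L
  }, TRUE))
  # K[u, t]: matches of unknown u's candidate term t among annotated
  # neighbors (constant during the run)
  K <- matrix(0L, length(unknowns), length(terms),
              dimnames = list(unknowns, terms))
  for (u in unknowns) {
    nbr_terms <- unlist(known[intersect(adj[[u]], names(known))],
                        use.names = FALSE)
    tab <- table(factor(nbr_terms, levels = terms))
    K[u, ] <- as.integer(tab)
  }
  unk_adj <- lapply(unknowns, function(u) {
    match(intersect(adj[[u]], unknowns), unknowns) - 1L
  })

  init <- with_seed(seed, vapply(vocab, function(v) {
    v[sample.int(length(v), 1L)]
  }, ""))
  res <- .anneal_core(
    init = match(init, terms) - 1L,
    vocab = lapply(vocab, function(v) match(v, terms) - 1L),
    unk_adj = unk_adj, K = K,
    t0 = schedule$t0, alpha = schedule$alpha,
    steps_per_t = as.integer(schedule$steps_per_t),
    t_min = schedule$t_min,
    seed = as.integer(seed %% .Machine$integer.max))
  assignment <- setNames(terms[res$assignment + 1L], unknowns)
  structure(list(assignment = assignment,
                 energy = e_known + res$energy,
                 initial_energy = e_known + res$initial_energy,
                 schedule = schedule, seed = seed, vocab = vocab),
            class = "anneal_state")
}

#' @export
print.anneal_state <- function(x, ...) {
  cat("Annealed annotation of ", length(x$assignment), " protein(s); ",
      "energy ", x$energy, " (initial ", x$initial_energy, ")\n", sep = "")
  invisible(x)
}

#' Permutation significance of annotation calls
#'
#' For each (protein, term) call the observed statistic is the number of
#' annotated neighbors carrying the term; the null redistributes the known
#' term labels uniformly over the annotated proteins network-wide. The
#' add-one permutation p-value is `(r + 1) / (n + 1)` with `r` the number of
#' permutations whose statistic reaches the observed one.
#'
#' @param network Network (as in [anneal_annotations()]).
#' @param known Named list: protein -> character vector of known terms.
#' @param result An `anneal_state`, or a data.frame with columns `protein`,
#'   `term` listing the calls to test.
#' @param n_permutations Number of label permutations (default 999).
#' @param seed Integer seed.
#' @param threshold Significance cutoff on the p-value (default 0.0517,
#'   an unusual but deliberate legacy choice; see the vignette).
#' @param tiers Optional tier filter.
#' @param all_candidates If `TRUE` and `result` is an `anneal_state`, test
#'   every term in each unknown's candidate vocabulary, not only the
#'   assigned one (multi-term reporting).
#' @return data.frame with columns `protein`, `term`, `observed`,
#'   `p_value`, `n_permutations`, `significant`.
#' @export
annotation_pvalues <- function(network, known, result,
                               n_permutations = 999L, seed = 1L,
                               threshold = 0.0517, tiers = NULL,
                               all_candidates = FALSE) {
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  adj <- network_adjacency(network, tiers)
  if (inherits(result, "anneal_state")) {
    if (all_candidates) {
      calls <- data.frame(
        protein = rep(names(result$vocab), lengths(result$vocab)),
        term = unlist(result$vocab, use.names = FALSE),
        stringsAsFactors = FALSE)
    } else {
      calls <- data.frame(protein = names(result$assignment),
                          term = unname(result$assignment),
                          stringsAsFactors = FALSE)
    }
  } else {
    calls <- as.data.frame(result, stringsAsFactors = FALSE)
  }
  kp <- intersect(names(known), names(adj))
  terms <- unique(unlist(known[kp], use.names = FALSE))
  M <- matrix(FALSE, length(kp), length(terms),
              dimnames = list(kp, terms))
  for (p in kp) M[p, known[[p]]] <- TRUE

  nbr_idx <- lapply(calls$protein, function(p) {
    match(intersect(adj[[p]], kp), kp)
  })
  term_col <- match(calls$term, terms)
  observed <- vapply(seq_len(nrow(calls)), function(i) {
    if (is.na(term_col[i]) || length(nbr_idx[[i]]) == 0L) return(0L)
    sum(M[nbr_idx[[i]], term_col[i]])
  }, 0L)

  r <- integer(nrow(calls))
  with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      perm <- sample.int(length(kp))
      for (i in seq_len(nrow(calls))) {
        if (is.na(term_col[i]) || length(nbr_idx[[i]]) == 0L) {
          stat <- 0L
        } else {
          stat <- sum(M[perm[nbr_idx[[i]]], term_col[i]])
        }
        if (stat >= observed[i]) r[i] <- r[i] + 1L
      }
    }
  })
  p <- (r + 1) / (n_permutations + 1)
  p[observed == 0L] <- 1
  data.frame(protein = calls$protein, term = calls$term,
             observed = observed, p_value = p,
             n_permutations = n_permutations,
             significant = p < threshold,
             stringsAsFactors = FALSE)
}
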