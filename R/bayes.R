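# Naive Bayes evidence integration. Each evidence layer is calibrated
# against the gold standard into a likelihood-ratio model; per-pair LRs are
# combined in two stages: (1) the four functional-linkage signals (gene
# neighbor, gene fusion, phylogenetic profile, SSBP) are reduced to their
# maximum LR and gated by domain support; (2) the gated functional LR, the
# best ortholog LR across source organisms, and the coexpression LR are
# multiplied. Posterior odds = prior odds x total LR; tiers follow fixed LR
# cutoffs.

#' Estimate a likelihood-ratio model for one evidence layer
#'
#' Counts gold-standard positives and negatives per evidence bin and forms
#' the smoothed likelihood ratio
#' `LR(bin) = [(n_pos_bin + c) / (N_pos + c*B)] / [(n_neg_bin + c) / (N_neg + c*B)]`
#' with `B` bins and pseudocount `c`. Flag layers use the two implicit bins
#' present/absent over the whole gold standard; score layers restrict the
#' counts to gold pairs inside the layer's coverage and bin the scores.
#'
#' @param layer An `evidence_layer`.
#' @param gold A `gold_standard` (see [reconcile_gold()]).
#' @param bins Binning spec for score layers: a numeric vector of interior
#'   cut points, a single integer number of quantile bins, or `NULL` to
#'   learn cut points with [supervised_discretize()]. Ignored for flag
#'   layers.
#' @param pseudocount Per-bin pseudocount `c` (default 0.5, Jeffreys-style),
#'   keeping every LR finite and positive.
#' @return An `lr_model`: list with `evidence_name`, `type`
#'   (`binary`/`binned`), `breaks`, `lr` (named positive numeric),
#'   `pseudocount`, `n_pos_used`, `n_neg_used`.
#' @export
estimate_lr <- function(layer, gold, bins = NULL, pseudocount = 0.5) {
  stopifnot(inherits(layer, "evidence_layer"), pseudocount >= 0)
  pos <- gold$positives
  neg <- gold$negatives
  if (layer$type == "flag") {
    cov <- names(layer$scores)
    n_pos_in <- sum(pos %in% cov)
    n_neg_in <- sum(neg %in% cov)
    lr <- smoothed_lr(c(present = n_pos_in, absent = length(pos) - n_pos_in),
                      c(present = n_neg_in, absent = length(neg) - n_neg_in),
                      pseudocount)
    return(structure(list(evidence_name = layer$name,
                          organism = layer$organism,
                          type = "binary", breaks = NULL, lr = lr,
                          pseudocount = pseudocount,
                          n_pos_used = length(pos), n_neg_used = length(neg)),
                     class = "lr_model"))
  }
  sc_pos <- layer$scores[pos[pos %in% names(layer$scores)]]
  sc_neg <- layer$scores[neg[neg %in% names(layer$scores)]]
  if (length(sc_pos) == 0L || length(sc_neg) == 0L) {
    stop("layer '", layer$name, "': gold standard has no ",
         if (length(sc_pos) == 0L) "positive" else "negative",
         " pairs inside the layer's coverage")
  }
  if (is.null(bins)) {
    bins <- supervised_discretize(
      c(sc_pos, sc_neg),
      c(rep("pos", length(sc_pos)), rep("neg", length(sc_neg))))
  } else if (length(bins) == 1L && bins == as.integer(bins) && bins > 1L &&
             is.null(attr(bins, "cutpoints"))) {
    qs <- stats::quantile(c(sc_pos, sc_neg),
                          probs = seq_len(bins - 1L) / bins, names = FALSE)
    bins <- unique(qs)
  }
  breaks <- c(-Inf, sort(unique(as.numeric(bins))), Inf)
  labs <- paste0("bin", seq_len(length(breaks) - 1L))
  bin_of <- function(x) labs[findInterval(x, breaks, left.open = TRUE,
                                          rightmost.closed = TRUE)]
  cnt <- function(x) {
    tab <- table(factor(bin_of(x), levels = labs))
    setNames(as.integer(tab), labs)
  }
  lr <- smoothed_lr(cnt(sc_pos), cnt(sc_neg), pseudocount)
  structure(list(evidence_name = layer$name, organism = layer$organism,
                 type = "binned", breaks = breaks, lr = lr,
                 pseudocount = pseudocount,
                 n_pos_used = length(sc_pos), n_neg_used = length(sc_neg)),
            class = "lr_model")
}

smoothed_lr <- function(npos, nneg, c0) {
  B <- length(npos)
  p_pos <- (npos + c0) / (sum(npos) + c0 * B)
  p_neg <- (nneg + c0) / (sum(nneg) + c0 * B)
  lr <- p_pos / p_neg
  if (any(!is.finite(lr) | lr <= 0)) {
    warning("zero-count bin gives a degenerate likelihood ratio (0, Inf ",
            "or NaN); use a positive pseudocount for downstream integration")
  }
  lr
}

#' @export
print.lr_model <- function(x, ...) {
  cat("LR model for '", x$evidence_name, "'",
      if (!is.null(x$organism)) paste0(" (", x$organism, ")"),
      " [", x$type, "], trained on ", x$n_pos_used, " pos / ",
      x$n_neg_used, " neg:\n", sep = "")
  print(round(x$lr, 3))
  invisible(x)
}

#' Look up per-pair likelihood ratios under a model
#'
#' @param model An `lr_model`.
#' @param layer The `evidence_layer` the model was trained on.
#' @param pairs Canonical pair keys to score.
#' @return Numeric vector of LRs; pairs outside the layer's coverage (or
#'   unflagged pairs of a flag layer) get the missing-evidence LR 1.
#' @export
lr_lookup <- function(model, layer, pairs) {
  out <- rep(1, length(pairs))
  if (model$type == "binary") {
    out[pairs %in% names(layer$scores)] <- model$lr[["present"]]
  } else {
    idx <- match(pairs, names(layer$scores))
    covered <- !is.na(idx)
    sc <- layer$scores[idx[covered]]
    bin <- findInterval(sc, model$breaks, left.open = TRUE,
                        rightmost.closed = TRUE)
    out[covered] <- unname(model$lr[bin])
  }
  out
}

#' Entropy-gain supervised discretization
#'
#' Recursive binary splitting of a numeric score against pos/neg labels,
#' maximizing information gain (best-first), in the spirit of decision-tree
#' discretization. Splitting stops when the leaf budget is exhausted, no
#' split gains information, or a split would create a leaf smaller than
#' `min_leaf`.
#'
#' @param scores Numeric vector.
#' @param labels Vector of two classes, same length as `scores`.
#' @param max_bins Maximum number of leaves (default 5).
#' @param min_leaf Minimum points per leaf (default 10).
#' @return Sorted numeric vector of interior cut points (possibly empty:
#'   a single bin, with a warning when all scores are identical).
#' @export
supervised_discretize <- function(scores, labels, max_bins = 5L,
                                  min_leaf = 10L) {
  stopifnot(length(scores) == length(labels), max_bins >= 1L, min_leaf >= 1L)
  scores <- unname(as.numeric(scores))
  if (length(unique(scores)) == 1L) {
    warning("all scores identical; single bin")
    return(numeric(0))
  }
  y <- as.integer(factor(labels))
  if (length(unique(y)) > 2L) stop("labels must have two classes")
  ord <- order(scores)
  s <- scores[ord]
  y <- y[ord]
  entropy <- function(counts) {
    p <- counts[counts > 0] / sum(counts)
    -sum(p * log2(p))
  }
  best_split <- function(lo, hi) {
    # best midpoint split of s[lo:hi]; returns c(gain, cut) or NULL
    seg_s <- s[lo:hi]; seg_y <- y[lo:hi]
    n <- length(seg_s)
    if (n < 2L * min_leaf) return(NULL)
    base <- entropy(tabulate(seg_y, 2L))
    # candidate boundaries between distinct adjacent values
    idx <- which(diff(seg_s) > 0)
    idx <- idx[idx >= min_leaf & n - idx >= min_leaf]
    if (length(idx) == 0L) return(NULL)
    left1 <- cumsum(seg_y == 1L)[idx]
    left2 <- cumsum(seg_y == 2L)[idx]
    tot1 <- sum(seg_y == 1L); tot2 <- sum(seg_y == 2L)
    ent2 <- function(a, b) {
      n <- a + b
      out <- numeric(length(n))
      nz <- n > 0
      pa <- a[nz] / n[nz]; pb <- b[nz] / n[nz]
      term <- function(p) ifelse(p > 0, -p * log2(p), 0)
      out[nz] <- term(pa) + term(pb)
      out
    }
    nl <- idx
    gains <- base -
      (nl / n) * ent2(left1, left2) -
      ((n - nl) / n) * ent2(tot1 - left1, tot2 - left2)
    k <- which.max(gains)
    if (gains[k] <= 1e-12) return(NULL)
    c(gain = gains[k], cut = (seg_s[idx[k]] + seg_s[idx[k] + 1L]) / 2,
      at = lo + idx[k] - 1L)
  }
  segments <- list(c(1L, length(s)))
  cuts <- numeric(0)
  while (length(segments) < max_bins) {
    cands <- lapply(segments, function(seg) best_split(seg[1L], seg[2L]))
    ok <- !vapply(cands, is.null, TRUE)
    if (!any(ok)) break
    gains <- vapply(cands[ok], `[[`, 0, "gain")
    pick <- which(ok)[which.max(gains)]
    sp <- cands[[pick]]
    seg <- segments[[pick]]
    cuts <- c(cuts, sp[["cut"]])
    segments[[pick]] <- c(seg[1L], as.integer(sp[["at"]]))
    segments[[length(segments) + 1L]] <- c(as.integer(sp[["at"]]) + 1L,
                                           seg[2L])
  }
  sort(cuts)
}

#' Combine functional-linkage evidence under the domain gate
#'
#' The four functional-linkage signals (gene neighbor, gene fusion,
#' phylogenetic profile, SSBP) indicate functional association rather than
#' physical contact, and share sequence information, so they are reduced to
#' a single factor: the maximum LR among those present - admitted only when
#' the pair is supported by an interacting domain pair. Without domain
#' support, or with no functional evidence at all, the factor is 1.
#'
#' @param lr_neighbor,lr_fusion,lr_profile,lr_ssbp Per-pair LRs (`NA` =
#'   evidence absent); vectors are recycled to a common length.
#' @param domain_flag Logical/0-1 vector: does the pair have domain support?
#' @return Numeric vector of functional LR factors.
#' @export
combine_functional <- function(lr_neighbor = NA_real_, lr_fusion = NA_real_,
                               lr_profile = NA_real_, lr_ssbp = NA_real_,
                               domain_flag = FALSE) {
  m <- cbind(lr_neighbor, lr_fusion, lr_profile, lr_ssbp)
  if (any(m <= 0, na.rm = TRUE)) stop("LR values must be positive")
  mx <- suppressWarnings(apply(m, 1L, max, na.rm = TRUE))
  mx[!is.finite(mx)] <- 1         # all four absent
  gate <- as.logical(domain_flag)
  out <- ifelse(rep_len(gate, length(mx)), mx, 1)
  as.numeric(out)
}

# reciprocal corrected by up to 2 ulp so that reciprocal_exact(p) * p == 1
# bit-exactly whenever some double satisfies it (the posterior-odds-1
# criterion is an identity; a plain 1/p misses it for ~15% of doubles)
reciprocal_exact <- function(p) {
  c0 <- 1 / p
  ulp <- 2^(floor(log2(abs(c0))) - 52)
  for (k in c(0, -1, 1, -2, 2)) {
    c1 <- c0 + k * ulp
    if (c1 * p == 1) return(c1)
  }
  c0
}

#' Integration configuration: prior odds and tier cutoffs
#'
#' The high-confidence cutoff defaults to `1 / prior_odds`, i.e. the LR at
#' which posterior odds reach 1 (even odds that the pair interacts).
#'
#' @param prior_odds Prior odds of interaction, `P(pos)/P(neg)` over the
#'   pair universe.
#' @param medium_cutoff LR cutoff for the medium tier (defaults to the high
#'   cutoff, collapsing the medium tier, when not supplied; in the pipeline
#'   it is derived from the weakest ortholog LR, see
#'   [derive_medium_cutoff()]).
#' @param high_cutoff LR cutoff for the high tier (default `1/prior_odds`).
#' @param missing_lr LR used for absent evidence (fixed at 1).
#' @return An `integration_config` list.
#' @export
integration_config <- function(prior_odds, medium_cutoff = NULL,
                               high_cutoff = NULL, missing_lr = 1) {
  stopifnot(is.numeric(prior_odds), prior_odds > 0)
  if (is.null(high_cutoff)) high_cutoff <- reciprocal_exact(prior_odds)
  if (is.null(medium_cutoff)) medium_cutoff <- high_cutoff
  stopifnot(high_cutoff >= medium_cutoff, medium_cutoff > 0)
  structure(list(prior_odds = prior_odds, high_cutoff = high_cutoff,
                 medium_cutoff = medium_cutoff, missing_lr = missing_lr),
            class = "integration_config")
}

#' Integrate the three independent evidence groups for one pair
#'
#' Total LR = (best ortholog LR across source organisms) x (coexpression LR)
#' x (domain-gated functional LR); posterior odds = prior odds x total LR.
#' Absent evidence contributes a factor of 1.
#'
#' @param lr_ortholog_by_organism Named numeric vector of per-organism
#'   ortholog LRs (may be empty).
#' @param lr_coexp Coexpression LR or `NA` when absent.
#' @param lr_functional Functional LR factor from [combine_functional()].
#' @param config An [integration_config()].
#' @return List with `lr_total` and `posterior_odds`.
#' @export
integrate_evidence <- function(lr_ortholog_by_organism, lr_coexp,
                               lr_functional, config) {
  lr_orth <- if (length(lr_ortholog_by_organism)) {
    max(lr_ortholog_by_organism)
  } else 1
  if (is.na(lr_coexp)) lr_coexp <- 1
  if (any(c(lr_orth, lr_coexp, lr_functional) <= 0)) {
    stop("LR values must be positive")
  }
  lr_total <- lr_orth * lr_coexp * lr_functional
  list(lr_total = lr_total,
       posterior_odds = config$prior_odds * lr_total)
}

#' Medium-tier cutoff from the weakest ortholog interactome
#'
#' Ortholog-projected interactions are the most trustworthy single evidence,
#' so the smallest per-organism ortholog LR serves as the medium-confidence
#' cutoff: any pair at least as well supported as the weakest interolog
#' source is medium confidence.
#'
#' @param lr_models_ortholog List of binary `lr_model`s, one per source
#'   organism.
#' @return The minimum `LR(present)` across organisms.
#' @export
derive_medium_cutoff <- function(lr_models_ortholog) {
  stopifnot(length(lr_models_ortholog) >= 1L)
  min(vapply(lr_models_ortholog, function(m) m$lr[["present"]], 0))
}

#' Assign confidence tiers to integrated LRs
#'
#' Tier `high` iff `lr_total >= high_cutoff`; `medium` iff
#' `medium_cutoff <= lr_total < high_cutoff`; `low` otherwise. Boundaries
#' are inclusive at the lower edge. Pairs supported by no evidence layer are
#' excluded from the network.
#'
#' @param lr_total Named numeric vector (canonical pair key -> total LR).
#' @param config An [integration_config()].
#' @param supported Logical vector (recycled): does the pair have >= 1
#'   supporting evidence layer? Default all `TRUE`.
#' @param evidence_lrs Optional data.frame of per-evidence LR columns, same
#'   order as `lr_total`, carried into the output.
#' @return A `scored_network` data.frame with columns `protein_a`,
#'   `protein_b`, the evidence columns, `lr_total`, `posterior_odds`,
#'   `tier`, `key`.
#' @export
assign_tiers <- function(lr_total, config, supported = TRUE,
                         evidence_lrs = NULL) {
  keys <- names(lr_total)
  stopifnot(!is.null(keys))
  supported <- rep_len(supported, length(lr_total))
  keep <- supported
  lr <- unname(lr_total[keep])
  keys <- keys[keep]
  tier <- ifelse(lr >= config$high_cutoff, "high",
                 ifelse(lr >= config$medium_cutoff, "medium", "low"))
  out <- pair_split(keys)
  if (!is.null(evidence_lrs)) {
    out <- cbind(out, evidence_lrs[keep, , drop = FALSE])
  }
  out$lr_total <- lr
  out$posterior_odds <- config$prior_odds * lr
  out$tier <- tier
  out$key <- keys
  rownames(out) <- NULL
  structure(out, class = c("scored_network", "data.frame"),
            config = config)
}

#' Calibrate LR models for a full set of evidence layers
#'
#' @param layers List of `evidence_layer`s: any number of ortholog layers
#'   (with distinct `organism` tags) plus at most one each of the other
#'   evidence types. The domain layer acts as a gate and gets no model.
#' @param gold A `gold_standard`.
#' @param pseudocount Pseudocount for [estimate_lr()].
#' @param bins Optional named list of binning specs per layer name.
#' @return List with `ortholog` (list of models by organism) and one model
#'   per other scored layer name.
#' @export
build_lr_models <- function(layers, gold, pseudocount = 0.5, bins = list()) {
  models <- list(ortholog = list())
  for (ly in layers) {
    if (ly$name == "domain") next
    b <- bins[[ly$name]]
    m <- estimate_lr(ly, gold, bins = b, pseudocount = pseudocount)
    if (ly$name == "ortholog") {
      models$ortholog[[ly$organism %||% paste0(
        "organism", length(models$ortholog) + 1L)]] <- m
    } else {
      models[[ly$name]] <- m
    }
  }
  models
}

#' Score a set of pairs into a tiered network
#'
#' Runs the full two-stage integration over every pair covered by at least
#' one evidence layer (the domain gate does not by itself support a pair).
#'
#' @param layers List of `evidence_layer`s, as for [build_lr_models()].
#' @param models Output of [build_lr_models()].
#' @param config An [integration_config()].
#' @param pairs Optional canonical keys to score; default: union of layer
#'   coverages.
#' @param raw_r_as_lr Compatibility mode: use the raw Pearson correlation,
#'   clamped below at 1e-6, directly as the coexpression LR instead of a
#'   calibrated model. Statistically improper (a correlation is not a
#'   likelihood ratio); off by default.
#' @return A `scored_network` (see [assign_tiers()]).
#' @export
score_pairs <- function(layers, models, config, pairs = NULL,
                        raw_r_as_lr = FALSE) {
  names(layers) <- vapply(layers, function(l) {
    if (l$name == "ortholog") paste0("ortholog:", l$organism) else l$name
  }, "")
  support_layers <- layers[vapply(layers, function(l) l$name != "domain", TRUE)]
  if (is.null(pairs)) {
    pairs <- unique(unlist(lapply(support_layers,
                                  function(l) names(l$scores)),
                           use.names = FALSE))
  }
  n <- length(pairs)
  if (n == 0L) stop("no pairs covered by any evidence layer")

  orth_names <- grep("^ortholog:", names(layers), value = TRUE)
  lr_orth <- rep(1, n)
  for (nm in orth_names) {
    org <- sub("^ortholog:", "", nm)
    lr_orth <- pmax(lr_orth,
                    lr_lookup(models$ortholog[[org]], layers[[nm]], pairs))
  }

  lr_of <- function(nm) {
    if (is.null(layers[[nm]]) || is.null(models[[nm]])) return(rep(1, n))
    lr_lookup(models[[nm]], layers[[nm]], pairs)
  }
  if (raw_r_as_lr && !is.null(layers$coexpression)) {
    idx <- match(pairs, names(layers$coexpression$scores))
    lr_coexp <- rep(1, n)
    lr_coexp[!is.na(idx)] <-
      pmax(layers$coexpression$scores[idx[!is.na(idx)]], 1e-6)
  } else {
    lr_coexp <- lr_of("coexpression")
  }

  # functional group: NA = absent (outside coverage / unflagged)
  fun_lr <- function(nm) {
    v <- lr_of(nm)
    covered <- if (is.null(layers[[nm]])) rep(FALSE, n) else {
      pairs %in% names(layers[[nm]]$scores)
    }
    v[!covered] <- NA_real_
    v
  }
  lr_nb <- fun_lr("gene_neighbor")
  lr_fu <- fun_lr("gene_fusion")
  lr_pp <- fun_lr("phylo_profile")
  lr_sb <- fun_lr("ssbp")
  domain_flag <- if (is.null(layers$domain)) rep(FALSE, n) else {
    idx <- match(pairs, names(layers$domain$scores))
    !is.na(idx) & layers$domain$scores[pmax(idx, 1L)] == 1
  }
  lr_functional <- combine_functional(lr_nb, lr_fu, lr_pp, lr_sb, domain_flag)

  lr_total <- lr_orth * lr_coexp * lr_functional
  names(lr_total) <- pairs

  supported <- Reduce(`|`, lapply(support_layers, function(l) {
    pairs %in% names(l$scores)
  }), rep(FALSE, n))

  ev <- data.frame(
    lr_ortholog = lr_orth,
    lr_coexpression = lr_coexp,
    lr_gene_neighbor = ifelse(is.na(lr_nb), 1, lr_nb),
    lr_gene_fusion = ifelse(is.na(lr_fu), 1, lr_fu),
    lr_phylo_profile = ifelse(is.na(lr_pp), 1, lr_pp),
    lr_ssbp = ifelse(is.na(lr_sb), 1, lr_sb),
    domain_flag = as.integer(domain_flag),
    lr_functional = lr_functional
  )
  assign_tiers(lr_total, config, supported = supported, evidence_lrs = ev)
}

#' @export
print.scored_network <- function(x, ...) {
  cat("Scored network: ", nrow(x), " pair(s); tiers: ", sep = "")
  print(table(factor(x$tier, levels = c("high", "medium", "low"))))
  invisible(x)
}
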