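# Self-contained synthetic world with planted ground truth. The generator
# emulates every input the pipeline consumes - proteome, true interactome,
# gold standards, and raw tables for all seven evidence layers - so each
# stage is testable with no external downloads. Topology is a planted
# partition (functional modules); boolean evidence layers are sampled
# conditionally independent given true/non-pair status, matching the naive
# Bayes assumption, so the integration's statistical contract is testable
# in-model.

#' Default parameters of the synthetic world
#'
#' @param n_proteins Number of proteins (default 300).
#' @param n_modules Number of functional modules (default 10).
#' @param p_within,p_between Edge probabilities of the planted-partition
#'   interactome (defaults 0.25 / 0.003).
#' @param evidence_signal Named list of `c(tpr, fpr)` per boolean layer:
#'   `ortholog` (per source organism), `domain`, `gene_neighbor`,
#'   `gene_fusion`.
#' @param organisms Source organisms for interolog projection.
#' @param n_samples,expr_noise_sd Expression matrix geometry and noise
#'   (20 samples, sd 0.5 around the module profile).
#' @param n_genomes,profile_flip_prob Phylogenetic profile length (20) and
#'   per-bit flip noise (0.1) around the module profile.
#' @param n_compartments Subcellular compartments for CC annotations (4).
#' @param frac_gold_pos Fraction of true pairs sampled into the gold
#'   positive set (0.5).
#' @param neg_pos_ratio Gold negatives per gold positive (10).
#' @param frac_unknown Fraction of proteins whose BP annotation is withheld
#'   (function-unknown proteins; 0.1).
#' @param n_complexes,complex_size_range Small enzyme complexes planted as
#'   cliques inside modules (5 complexes of 3-6 members); one oversized
#'   complex (20 members, not planted as interactions) is always added to
#'   exercise the complex-size bound.
#' @return Named list of parameters.
#' @export
world_params <- function(n_proteins = 300L, n_modules = 10L,
                         p_within = 0.25, p_between = 0.003,
                         evidence_signal = list(
                           ortholog = c(tpr = 0.35, fpr = 0.002),
                           domain = c(tpr = 0.7, fpr = 0.05),
                           gene_neighbor = c(tpr = 0.2, fpr = 0.001),
                           gene_fusion = c(tpr = 0.15, fpr = 0.001)),
                         organisms = c("yeast", "worm", "fly", "human"),
                         n_samples = 20L, expr_noise_sd = 0.5,
                         n_genomes = 20L, profile_flip_prob = 0.1,
                         n_compartments = 4L, frac_gold_pos = 0.5,
                         neg_pos_ratio = 10L, frac_unknown = 0.1,
                         n_complexes = 5L, complex_size_range = c(3L, 6L)) {
  p <- list(n_proteins = n_proteins, n_modules = n_modules,
            p_within = p_within, p_between = p_between,
            evidence_signal = evidence_signal, organisms = organisms,
            n_samples = n_samples, expr_noise_sd = expr_noise_sd,
            n_genomes = n_genomes, profile_flip_prob = profile_flip_prob,
            n_compartments = n_compartments, frac_gold_pos = frac_gold_pos,
            neg_pos_ratio = neg_pos_ratio, frac_unknown = frac_unknown,
            n_complexes = n_complexes, complex_size_range = complex_size_range)
  check_prob <- function(x, nm) {
    if (!is.numeric(x) || any(x <= 0) || any(x >= 1)) {
      stop("parameter out of range: ", nm, " must be in (0, 1)")
    }
  }
  check_prob(p_within, "p_within"); check_prob(p_between, "p_between")
  check_prob(frac_gold_pos, "frac_gold_pos")
  check_prob(frac_unknown, "frac_unknown")
  check_prob(profile_flip_prob, "profile_flip_prob")
  for (nm in names(evidence_signal)) {
    v <- evidence_signal[[nm]]
    if (any(v < 0) || any(v > 1)) {
      stop("parameter out of range: evidence_signal$", nm)
    }
  }
  if (p_within <= p_between) {
    stop("parameter out of range: p_within must exceed p_between")
  }
  if (n_proteins < n_modules) {
    stop("parameter out of range: n_proteins < n_modules")
  }
  p
}

#' Generate a synthetic world
#'
#' @param params Parameter list from [world_params()].
#' @param seed Integer seed; regeneration from (params, seed) is
#'   bit-identical.
#' @return A `synthetic_world` list; see the fields in the implementation
#'   and the methods vignette.
#' @export
generate_world <- function(params = world_params(), seed = 42L) {
  with_seed(seed, {
    n <- params$n_proteins
    proteins <- sprintf("P%04d", seq_len(n))
    module_ids <- sprintf("M%02d", seq_len(params$n_modules))
    modules <- setNames(sample(rep_len(module_ids, n)), proteins)

    # planted-partition true interactome
    idx <- utils::combn(n, 2L)
    a <- proteins[idx[1L, ]]; b <- proteins[idx[2L, ]]
    same <- modules[a] == modules[b]
    p_edge <- ifelse(same, params$p_within, params$p_between)
    universe <- pair_key(a, b)
    is_true <- stats::runif(length(universe)) < p_edge
    true_ppi <- universe[is_true]

    # planted complexes: small ones are cliques (added to the truth), one
    # oversized complex is NOT - big assemblies are not all-pairs contacts
    complexes <- list()
    for (ci in seq_len(params$n_complexes)) {
      mod <- sample(module_ids, 1L)
      members <- sample(proteins[modules == mod],
                        sample(seq(params$complex_size_range[1L],
                                   params$complex_size_range[2L]), 1L))
      complexes[[sprintf("CPX%02d", ci)]] <- members
      true_ppi <- union(true_ppi, all_pairs(members))
    }
    complexes[["CPXBIG"]] <- sample(proteins, 20L)
    non_pairs <- setdiff(universe, true_ppi)

    # compartments (CC) per module; BP term per module under a shared root
    compartment_ids <- sprintf("CC:C%02d", seq_len(params$n_compartments))
    mod_comp <- setNames(rep_len(compartment_ids, params$n_modules),
                         module_ids)
    compartments <- setNames(unname(mod_comp[modules]), proteins)
    bp_terms <- paste0("BP:", module_ids)
    terms <- c("BP:root", bp_terms, "CC:root", compartment_ids)
    parents <- c(list("BP:root" = character(0), "CC:root" = character(0)),
                 setNames(rep(list("BP:root"), length(bp_terms)), bp_terms),
                 setNames(rep(list("CC:root"), length(compartment_ids)),
                          compartment_ids))
    namespace <- setNames(c("BP", rep("BP", length(bp_terms)),
                            "CC", rep("CC", length(compartment_ids))), terms)
    ontology <- new_ontology_dag(terms, parents, namespace)

    unknowns <- sample(proteins, max(1L, round(params$frac_unknown * n)))
    bp_truth <- data.frame(
      protein_id = proteins,
      term_id = paste0("BP:", unname(modules[proteins])),
      aspect = "BP", evidence_code = "IDA", stringsAsFactors = FALSE)
    annotations <- rbind(
      bp_truth[!(bp_truth$protein_id %in% unknowns), , drop = FALSE],
      data.frame(protein_id = proteins,
                 term_id = unname(compartments[proteins]),
                 aspect = "CC", evidence_code = "IDA",
                 stringsAsFactors = FALSE))
    rownames(annotations) <- NULL

    # boolean layer flag sets: flag true pairs at tpr, non-pairs at fpr
    flag_set <- function(signal) {
      c(true_ppi[stats::runif(length(true_ppi)) < signal[["tpr"]]],
        non_pairs[stats::runif(length(non_pairs)) < signal[["fpr"]]])
    }

    # ortholog: per organism a 1-1 relabeling map and a noisy source PPI
    ortholog <- list()
    for (org in params$organisms) {
      prefix <- toupper(substr(org, 1L, 1L))
      src_ids <- setNames(paste0(prefix, "_", proteins), proteins)
      flags <- flag_set(params$evidence_signal$ortholog)
      ab <- pair_split(flags)
      src_ppi <- pair_key(src_ids[ab$protein_a], src_ids[ab$protein_b])
      # mapping runs source id -> query protein (the interolog direction)
      mapping <- setNames(as.list(proteins), unname(src_ids))
      ortholog[[org]] <- list(
        map = structure(list(organism = org, mapping = mapping),
                        class = "ortholog_map"),
        source_ppi = src_ppi)
    }

    # domain support: unique domain pair per flagged protein pair
    dflags <- flag_set(params$evidence_signal$domain)
    ab <- pair_split(dflags)
    protein_domains <- list()
    ddi <- data.frame(domain_a = character(0), domain_b = character(0),
                      stringsAsFactors = FALSE)
    if (length(dflags)) {
      da <- sprintf("D%05da", seq_along(dflags))
      db <- sprintf("D%05db", seq_along(dflags))
      for (i in seq_along(dflags)) {
        protein_domains[[ab$protein_a[i]]] <-
          c(protein_domains[[ab$protein_a[i]]], da[i])
        protein_domains[[ab$protein_b[i]]] <-
          c(protein_domains[[ab$protein_b[i]]], db[i])
      }
      ddi <- data.frame(domain_a = da, domain_b = db,
                        stringsAsFactors = FALSE)
    }

    # gene fusion: one synthetic fused target per flagged pair
    fflags <- flag_set(params$evidence_signal$gene_fusion)
    ab <- pair_split(fflags)
    fusion_hits <- data.frame(
      query_protein = c(ab$protein_a, ab$protein_b),
      target_protein = rep(sprintf("FUS%05d", seq_along(fflags)), 2L),
      start = rep(c(1L, 150L), each = length(fflags)),
      end = rep(c(100L, 250L), each = length(fflags)),
      stringsAsFactors = FALSE)

    # gene neighbor: adjacent ortholog genes on a dedicated contig in two
    # reference genomes per flagged pair
    nflags <- flag_set(params$evidence_signal$gene_neighbor)
    ab <- pair_split(nflags)
    ctx_rows <- list()
    for (g in c("refgenome1", "refgenome2")) {
      if (length(nflags)) {
        ctx_rows[[g]] <- data.frame(
          genome = g,
          gene = c(paste0(g, "_", seq_along(nflags), "_a"),
                   paste0(g, "_", seq_along(nflags), "_b")),
          contig = rep(sprintf("ctg%05d", seq_along(nflags)), 2L),
          start = rep(c(1L, 1201L), each = length(nflags)),
          end = rep(c(1000L, 2200L), each = length(nflags)),
          strand = "+",
          query_protein = c(ab$protein_a, ab$protein_b),
          stringsAsFactors = FALSE)
      }
    }
    context <- if (length(ctx_rows)) do.call(rbind, ctx_rows) else
      data.frame(genome = character(0), gene = character(0),
                 contig = character(0), start = integer(0), end = integer(0),
                 strand = character(0), query_protein = character(0),
                 stringsAsFactors = FALSE)
    rownames(context) <- NULL

    # expression: module latent profile + gaussian noise
    mod_profile <- matrix(stats::rnorm(params$n_modules * params$n_samples),
                          params$n_modules,
                          dimnames = list(module_ids, NULL))
    expr <- mod_profile[unname(modules[proteins]), , drop = FALSE] +
      matrix(stats::rnorm(n * params$n_samples, sd = params$expr_noise_sd), n)
    rownames(expr) <- proteins
    colnames(expr) <- sprintf("S%02d", seq_len(params$n_samples))

    # phylogenetic profiles: module bit pattern + per-bit flips
    mod_bits <- matrix(stats::rbinom(params$n_modules * params$n_genomes,
                                     1L, 0.5),
                       params$n_modules,
                       dimnames = list(module_ids, NULL))
    flips <- matrix(stats::runif(n * params$n_genomes) <
                      params$profile_flip_prob, n)
    profiles <- abs(mod_bits[unname(modules[proteins]), , drop = FALSE] -
                      flips)
    storage.mode(profiles) <- "double"
    rownames(profiles) <- proteins
    colnames(profiles) <- sprintf("G%02d", seq_len(params$n_genomes))

    # gold standards
    curated <- sort(sample(true_ppi,
                           max(2L, round(params$frac_gold_pos *
                                           length(true_ppi)))))
    disjoint <- non_pairs[{
      abp <- pair_split(non_pairs)
      compartments[abp$protein_a] != compartments[abp$protein_b]
    }]
    n_neg <- min(length(disjoint),
                 params$neg_pos_ratio * length(curated))
    negatives <- sort(sample(disjoint, n_neg))
    gsp <- build_gsp(curated, complexes, max_complex_size = 18L)
    gold <- reconcile_gold(gsp, negatives)

    structure(list(
      params = params, seed = seed,
      proteins = proteins, modules = modules, true_ppi = sort(true_ppi),
      complexes = complexes, compartments = compartments,
      ontology = ontology, annotations = annotations, bp_truth = bp_truth,
      unknowns = unknowns, curated = curated,
      expr = expr, profiles = profiles, ortholog = ortholog,
      protein_domains = protein_domains, ddi = ddi,
      fusion_hits = fusion_hits, context = context,
      gold = gold), class = "synthetic_world")
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("Synthetic world: ", length(x$proteins), " proteins in ",
      x$params$n_modules, " modules; ", length(x$true_ppi),
      " true interactions; seed ", x$seed, "\n", sep = "")
  print(x$gold)
  invisible(x)
}

#' Mask a fraction of the world's BP annotations
#'
#' Splits the visible (protein, BP term) annotations into a retained part
#' and a hidden part for annotation-recovery experiments. The sampler
#' retries (up to 100 times) until every module keeps at least one visible
#' annotation; otherwise the guilt-by-association vocabulary would lose a
#' whole module.
#'
#' @param world A `synthetic_world`.
#' @param frac Fraction of BP annotation rows to hide, in (0, 1).
#' @param seed Integer seed.
#' @return List with `masked_known` and `hidden_truth` annotation
#'   data.frames (a partition of the visible BP annotations).
#' @export
mask_annotations <- function(world, frac, seed = 1L) {
  stopifnot(frac > 0, frac < 1)
  bp <- world$annotations[world$annotations$aspect == "BP", , drop = FALSE]
  n_hide <- max(1L, round(frac * nrow(bp)))
  with_seed(seed, {
    for (try in seq_len(100L)) {
      hide <- sample(nrow(bp), n_hide)
      kept_terms <- unique(bp$term_id[-hide])
      if (all(unique(bp$term_id) %in% kept_terms)) {
        return(list(masked_known = bp[-hide, , drop = FALSE],
                    hidden_truth = bp[hide, , drop = FALSE]))
      }
    }
    stop("masking fraction hides every annotation of some module")
  })
}

#' Write every world input file in the package's TSV/OBO dialects
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  write_pair_table(pair_split(world$curated), fp("curated_pairs.tsv"))
  cx <- data.frame(
    complex_id = rep(names(world$complexes), lengths(world$complexes)),
    protein_id = unlist(world$complexes, use.names = FALSE))
  utils::write.table(cx, fp("complexes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(
    world$annotations[c("protein_id", "term_id", "evidence_code", "aspect")],
    fp("annotations.tsv"), sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  write_obo_file(world$ontology, fp("ontology.obo"))
  write_expression_matrix(world$expr, fp("expression.tsv"))
  write_expression_matrix(world$profiles, fp("profiles.tsv"))
  for (org in names(world$ortholog)) {
    o <- world$ortholog[[org]]
    write_pair_table(pair_split(o$source_ppi),
                     fp(paste0("ppi_", org, ".tsv")))
    om <- data.frame(
      source = rep(names(o$map$mapping), lengths(o$map$mapping)),
      target = unlist(o$map$mapping, use.names = FALSE))
    utils::write.table(om, fp(paste0("orthologs_", org, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  pd <- data.frame(
    protein_id = rep(names(world$protein_domains),
                     lengths(world$protein_domains)),
    domain_id = unlist(world$protein_domains, use.names = FALSE))
  utils::write.table(pd, fp("domains.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(world$ddi, fp("ddi.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(world$fusion_hits, fp("fusion_hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(world$context, fp("context.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_pair_table(pair_split(world$true_ppi), fp("true_ppi.tsv"))
  writeLines(world$unknowns, fp("unknown_proteins.txt"))
  invisible(dir)
}

# minimal OBO 1.2 writer (round-trips through read_obo)
write_obo_file <- function(dag, path) {
  ns_long <- c(BP = "biological_process", CC = "cellular_component",
               MF = "molecular_function")
  lines <- c("format-version: 1.2", "")
  for (t in dag$terms) {
    lines <- c(lines, "[Term]", paste0("id: ", t))
    ns <- dag$namespace[[t]]
    if (!is.na(ns)) lines <- c(lines, paste0("namespace: ", ns_long[[ns]]))
    for (p in dag$parents[[t]]) lines <- c(lines, paste0("is_a: ", p))
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Rank-based AUROC of pair scores against a positive set
#'
#' Mann-Whitney statistic: the probability that a uniformly drawn positive
#' pair outscores a uniformly drawn negative pair (ties count half).
#'
#' @param scores Named numeric vector (canonical pair key -> score).
#' @param positives Character vector of positive pair keys; every other
#'   scored pair counts as negative.
#' @return AUROC between 0 and 1.
#' @export
ranking_auroc <- function(scores, positives) {
  y <- names(scores) %in% positives
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) stop("need both positive and negative pairs")
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Naive Bayes calibration experiment
#'
#' Samples pair labels from the prior and K conditionally independent binary
#' evidence layers with known (tpr, fpr), calibrates LR models on the
#' labeled sample, integrates them, and compares the integrated posterior
#' probability with the analytically true posterior.
#'
#' @param n_pairs Number of simulated pairs (default 10000).
#' @param prior Prior interaction probability (default 0.2).
#' @param signals List of `c(tpr, fpr)` per layer (default 3 layers).
#' @param seed Integer seed.
#' @param pseudocount Pseudocount for calibration.
#' @return List with `mae` (mean absolute error of the posterior), and the
#'   per-pair `posterior` / `truth` vectors.
#' @export
nb_calibration_experiment <- function(n_pairs = 10000L, prior = 0.2,
                                      signals = list(c(tpr = 0.7, fpr = 0.1),
                                                     c(tpr = 0.5, fpr = 0.05),
                                                     c(tpr = 0.3, fpr = 0.02)),
                                      seed = 42L, pseudocount = 0.5) {
  with_seed(seed, {
    keys <- pair_key(sprintf("A%06d", seq_len(n_pairs)),
                     sprintf("B%06d", seq_len(n_pairs)))
    label <- stats::runif(n_pairs) < prior
    flags <- lapply(signals, function(s) {
      p <- ifelse(label, s[["tpr"]], s[["fpr"]])
      stats::runif(n_pairs) < p
    })
    gold <- structure(list(positives = keys[label], negatives = keys[!label],
                           removed_overlap = character(0)),
                      class = "gold_standard")
    lr <- rep(1, n_pairs)
    for (f in flags) {
      layer <- new_evidence_layer("ortholog",
                                  setNames(rep(1, sum(f)), keys[f]), "flag")
      m <- estimate_lr(layer, gold, pseudocount = pseudocount)
      lr <- lr * ifelse(f, m$lr[["present"]], m$lr[["absent"]])
    }
    odds <- (prior / (1 - prior)) * lr
    posterior <- odds / (1 + odds)
    true_lr <- rep(1, n_pairs)
    for (i in seq_along(signals)) {
      s <- signals[[i]]
      true_lr <- true_lr * ifelse(flags[[i]], s[["tpr"]] / s[["fpr"]],
                                  (1 - s[["tpr"]]) / (1 - s[["fpr"]]))
    }
    true_odds <- (prior / (1 - prior)) * true_lr
    truth <- true_odds / (1 + true_odds)
    list(mae = mean(abs(posterior - truth)), posterior = posterior,
         truth = truth)
  })
}
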