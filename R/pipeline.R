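# End-to-end pipeline: simulate -> build-gold -> score-evidence ->
# integrate -> annotate, driven by a single config (R list or YAML file).
# Each stage logs to stderr, writes its artifacts under the work directory,
# and contributes a stanza to report.json. One global seed; per-stage seeds
# are derived by stable hashing of (seed, stage name), so stochastic stages
# are reproducible and independent of each other.

#' Default pipeline configuration
#'
#' @param workdir Output directory.
#' @param seed Global seed.
#' @param simulate Generate a synthetic world as input (default `TRUE`;
#'   set to `FALSE` and fill `inputs` with file paths to run on real data).
#' @return Nested configuration list; see the vignette for the schema.
#' @export
default_config <- function(workdir = tempfile("ppibayes_run_"), seed = 42L,
                           simulate = TRUE) {
  list(
    workdir = workdir,
    seed = as.integer(seed),
    simulate = list(enabled = simulate, params = list()),
    inputs = list(),   # named file paths when simulate is disabled
    gold = list(codes = c("IC", "IDA", "IPI"), max_complex_size = 18L,
                gsn_propagate = FALSE, gsn_max_pairs = NULL),
    evidence = list(min_gap_fraction = 0.2, max_distance = 5000L,
                    min_genomes = 2L, profile_metric = "hamming_similarity"),
    integrate = list(prior_odds = "auto", medium_cutoff = "auto",
                     high_cutoff = "auto", pseudocount = 0.5,
                     raw_r_as_lr = FALSE),
    annotate = list(enabled = TRUE, tiers = c("high", "medium"),
                    n_permutations = 199L, threshold = 0.0517,
                    schedule = list(t0 = 1, alpha = 0.9,
                                    steps_per_t = 100L, t_min = 1e-3))
  )
}

stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

log_stage <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

validate_config <- function(config) {
  req <- c("workdir", "seed", "simulate", "gold", "evidence", "integrate",
           "annotate")
  missing <- setdiff(req, names(config))
  if (length(missing)) {
    stop("invalid config: missing block(s) ", paste(missing, collapse = ", "))
  }
  if (!isTRUE(config$simulate$enabled)) {
    req_in <- c("curated", "complexes", "annotations", "obo", "expression",
                "profiles", "domains", "ddi", "fusion_hits", "context")
    for (nm in req_in) {
      p <- config$inputs[[nm]]
      if (is.null(p) || !file.exists(p)) {
        stop("invalid config: input '", nm, "' missing or not a file")
      }
    }
  }
  invisible(config)
}

#' Run the full prediction pipeline
#'
#' Chains world simulation (optional), gold-standard construction, evidence
#' scoring, naive Bayes integration and network annotation; writes
#' `network.tsv`, `network.sif`, `annotations.tsv`, per-layer TSVs, and a
#' machine-readable `report.json` under the configured work directory.
#' Rerunning with an identical configuration reproduces identical outputs.
#'
#' @param config Configuration list (see [default_config()]) or path to a
#'   YAML file with the same structure.
#' @return Invisibly, a list with `network`, `annotations` (or `NULL`),
#'   `report`, and the `world` when simulated.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  dir.create(config$workdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed)
  t_start <- Sys.time()

  # --- stage: simulate -----------------------------------------------------
  world <- NULL
  if (isTRUE(config$simulate$enabled)) {
    log_stage("simulate", "generating synthetic world")
    world <- generate_world(do.call(world_params, config$simulate$params),
                            seed = stage_seed(config$seed, "simulate"))
    world_dir <- file.path(config$workdir, "world")
    write_world(world, world_dir)
    config$inputs <- c(
      list(curated = file.path(world_dir, "curated_pairs.tsv"),
           complexes = file.path(world_dir, "complexes.tsv"),
           annotations = file.path(world_dir, "annotations.tsv"),
           obo = file.path(world_dir, "ontology.obo"),
           expression = file.path(world_dir, "expression.tsv"),
           profiles = file.path(world_dir, "profiles.tsv"),
           domains = file.path(world_dir, "domains.tsv"),
           ddi = file.path(world_dir, "ddi.tsv"),
           fusion_hits = file.path(world_dir, "fusion_hits.tsv"),
           context = file.path(world_dir, "context.tsv")),
      list(organisms = lapply(
        stats::setNames(nm = names(world$ortholog)),
        function(org) list(
          ppi = file.path(world_dir, paste0("ppi_", org, ".tsv")),
          orthologs = file.path(world_dir,
                                paste0("orthologs_", org, ".tsv"))))))
    report$simulate <- list(n_proteins = length(world$proteins),
                            n_true_pairs = length(world$true_ppi),
                            seed = world$seed)
  }
  inp <- config$inputs

  # --- stage: build-gold ---------------------------------------------------
  log_stage("build-gold", "constructing gold standard sets")
  ontology <- read_obo(inp$obo)
  annotations <- read_annotations(inp$annotations, ontology = ontology)
  curated <- read_pair_table(inp$curated)
  complexes <- read_complex_table(inp$complexes)
  gsp <- build_gsp(curated, complexes,
                   max_complex_size = config$gold$max_complex_size)
  gsn <- build_gsn(annotations, allowed_codes = config$gold$codes,
                   ontology = ontology,
                   propagate = isTRUE(config$gold$gsn_propagate),
                   max_pairs = config$gold$gsn_max_pairs,
                   seed = stage_seed(config$seed, "build-gold"))
  gold <- reconcile_gold(gsp, gsn)
  write_pair_table(pair_split(gold$positives),
                   file.path(config$workdir, "gsp.tsv"))
  write_pair_table(pair_split(gold$negatives),
                   file.path(config$workdir, "gsn.tsv"))
  report$gold <- list(gsp_n = length(gold$positives),
                      gsn_n = length(gold$negatives),
                      removed_overlap_n = length(gold$removed_overlap))

  # --- stage: score-evidence ----------------------------------------------
  log_stage("score-evidence", "computing the seven evidence layers")
  expr <- read_expression_matrix(inp$expression)
  profiles <- read_expression_matrix(inp$profiles)
  protein_domains <- read_domain_table(inp$domains)
  ddi <- utils::read.delim(inp$ddi, header = FALSE, sep = "\t",
                           col.names = c("domain_a", "domain_b"),
                           stringsAsFactors = FALSE)
  fusion_hits <- utils::read.delim(inp$fusion_hits, header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE)
  context <- read_gene_context(inp$context)
  proteins <- sort(unique(c(rownames(expr), names(protein_domains),
                            annotations$protein_id)))
  universe <- all_pairs(proteins)

  layers <- list()
  for (org in names(inp$organisms)) {
    o <- inp$organisms[[org]]
    src <- read_pair_table(o$ppi)
    omap <- read_ortholog_map(o$orthologs, organism = org)
    layers[[paste0("ortholog:", org)]] <- project_orthologs(src, omap)
  }
  layers$coexpression <- coexpression_scores(expr, universe)
  layers$domain <- domain_support(protein_domains, ddi, universe)
  layers$ssbp <- ssbp_scores(annotations, ontology, universe)
  layers$gene_fusion <- gene_fusion_pairs(
    fusion_hits, min_gap_fraction = config$evidence$min_gap_fraction)
  layers$gene_neighbor <- gene_neighbor_pairs(
    context, max_distance = config$evidence$max_distance,
    min_genomes = config$evidence$min_genomes)
  layers$phylo_profile <- phylo_profile_scores(
    profiles, universe, metric = config$evidence$profile_metric)

  layer_dir <- file.path(config$workdir, "layers")
  dir.create(layer_dir, showWarnings = FALSE)
  for (nm in names(layers)) {
    ly <- layers[[nm]]
    df <- pair_split(names(ly$scores))
    df$score <- unname(ly$scores)
    utils::write.table(df, file.path(layer_dir,
                                     paste0(gsub(":", "_", nm), ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report$evidence <- lapply(layers, function(l) length(l$scores))

  # --- stage: integrate ----------------------------------------------------
  log_stage("integrate", "calibrating likelihood ratios and scoring pairs")
  models <- build_lr_models(unname(layers), gold,
                            pseudocount = config$integrate$pseudocount)
  prior_odds <- config$integrate$prior_odds
  if (identical(prior_odds, "auto")) {
    # P(pos)/P(neg) over the pair universe, with the gold positives as the
    # estimate of the interacting fraction
    n_pos <- length(gold$positives)
    prior_odds <- n_pos / (length(universe) - n_pos)
  }
  high_cutoff <- config$integrate$high_cutoff
  if (identical(high_cutoff, "auto")) {
    high_cutoff <- reciprocal_exact(prior_odds)
  }
  medium_cutoff <- config$integrate$medium_cutoff
  if (identical(medium_cutoff, "auto")) {
    medium_cutoff <- min(derive_medium_cutoff(models$ortholog), high_cutoff)
  }
  icfg <- integration_config(prior_odds, medium_cutoff = medium_cutoff,
                             high_cutoff = high_cutoff)
  network <- score_pairs(unname(layers), models, icfg,
                         raw_r_as_lr = isTRUE(config$integrate$raw_r_as_lr))
  write_network(network, file.path(config$workdir, "network.tsv"), "tsv")
  write_network(network, file.path(config$workdir, "network.sif"), "sif")
  report$integrate <- list(
    prior_odds = prior_odds, high_cutoff = high_cutoff,
    medium_cutoff = medium_cutoff,
    tiers = as.list(table(network$tier)),
    lr_models = lapply(models$ortholog, function(m) unclass(m$lr)))

  # --- stage: annotate -----------------------------------------------------
  ann_result <- NULL
  if (isTRUE(config$annotate$enabled)) {
    log_stage("annotate", "guilt-by-association annotation")
    bp <- annotations[annotations$aspect == "BP", , drop = FALSE]
    known <- lapply(split(bp$term_id, bp$protein_id), unique)
    sub <- network[network$tier %in% config$annotate$tiers, , drop = FALSE]
    nodes <- unique(c(sub$protein_a, sub$protein_b))
    unknowns <- setdiff(nodes, names(known))
    if (length(unknowns) && length(known)) {
      st <- anneal_annotations(network, known, unknowns,
                               schedule = config$annotate$schedule,
                               seed = stage_seed(config$seed, "annotate"),
                               tiers = config$annotate$tiers)
      ann_result <- annotation_pvalues(
        network, known, st,
        n_permutations = config$annotate$n_permutations,
        seed = stage_seed(config$seed, "annotate-pvalues"),
        threshold = config$annotate$threshold,
        tiers = config$annotate$tiers)
      utils::write.table(ann_result,
                         file.path(config$workdir, "annotations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$annotate <- list(
        n_unknowns = length(unknowns),
        n_significant = sum(ann_result$significant),
        energy = st$energy)
    } else {
      log_stage("annotate", "skipped: no unknown proteins in selected tiers")
    }
  }

  report$wall_time_s <- as.numeric(difftime(Sys.time(), t_start,
                                            units = "secs"))
  jsonlite::write_json(report, file.path(config$workdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(network = network, annotations = ann_result,
                 report = report, world = world, gold = gold,
                 models = models, config = icfg, layers = layers))
}
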