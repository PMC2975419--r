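omap <- function(organism, ...) {
  structure(list(organism = organism, mapping = list(...)),
            class = "ortholog_map")
}

test_that("interolog projection transfers pairs through the ortholog map", {
  m <- omap("yeast", X = "A", Y = "B")
  ly <- project_orthologs("X|Y", m)
  expect_equal(names(ly$scores), "A|B")

  # both map to the same protein: self-pair, nothing transferred
  expect_length(project_orthologs("X|Y", omap("y", X = "A", Y = "A"))$scores,
                0L)

  many <- project_orthologs("X|Y", omap("y", X = c("A1", "A2"), Y = "B"))
  expect_setequal(names(many$scores), c("A1|B", "A2|B"))
})

test_that("projection size equals the brute-force cross product minus self-pairs", {
  set.seed(31)
  for (rep in 1:10) {
    src_prot <- paste0("X", 1:6)
    tgt_prot <- paste0("A", 1:8)
    mapping <- lapply(setNames(nm = src_prot), function(p) {
      sample(tgt_prot, sample(0:3, 1))
    })
    mapping <- mapping[lengths(mapping) > 0]
    src_pairs <- sample(all_pairs(src_prot), 5)
    ly <- project_orthologs(src_pairs, structure(
      list(organism = "o", mapping = mapping), class = "ortholog_map"))
    # independent enumeration
    expected <- character(0)
    for (k in src_pairs) {
      xy <- strsplit(k, "|", fixed = TRUE)[[1]]
      for (a in mapping[[xy[1]]]) for (b in mapping[[xy[2]]]) {
        if (a != b) expected <- c(expected, pair_key(a, b))
      }
    }
    expect_setequal(names(ly$scores), unique(expected))
  }
})

test_that("coexpression reproduces closed-form Pearson correlations", {
  m <- rbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(3, 2, 1),
             d = c(1, 2, 4), flat = c(5, 5, 5))
  ly <- coexpression_scores(m)
  expect_equal(unname(ly$scores[["a|b"]]), 1.0)
  expect_equal(unname(ly$scores[["a|c"]]), -1.0)
  expect_equal(unname(ly$scores[["a|d"]]),
               cor(c(1, 2, 3), c(1, 2, 4)))
  expect_equal(unname(ly$scores[["a|d"]]), 0.9819805, tolerance = 1e-6)
  expect_false(any(grepl("flat", names(ly$scores))))  # zero variance
  expect_error(coexpression_scores(m[, 1:2]), "3 samples")
})

test_that("coexpression is bounded and invariant to positive affine rescaling", {
  set.seed(41)
  for (rep in 1:10) {
    m <- matrix(rnorm(40), 4, dimnames = list(paste0("g", 1:4), NULL))
    ly <- coexpression_scores(m)
    expect_true(all(ly$scores >= -1 & ly$scores <= 1))
    m2 <- m
    m2["g1", ] <- 3.7 * m["g1", ] + 11
    ly2 <- coexpression_scores(m2)
    expect_equal(ly2$scores, ly$scores, tolerance = 1e-12)
  }
})

test_that("domain support detects interacting domain pairs incl. homotypic", {
  pd <- list(a = "D1", b = "D2", c = "D3", d = character(0))
  ddi <- data.frame(x = "D1", y = "D2")
  ly <- domain_support(pd, ddi, c("a|b", "a|c", "a|d"))
  expect_equal(unname(ly$scores), c(1, 0, 0))
  expect_length(ly$scores, 3L)  # undomained pairs still covered

  homo <- domain_support(list(a = "D1", b = "D1"),
                         data.frame(x = "D1", y = "D1"), "a|b")
  expect_equal(unname(homo$scores[["a|b"]]), 1)
})

test_that("SSBP equals the propagated size of the smallest shared BP term", {
  # root annotates everything through propagation; leaf shared by 2 of 6
  dag <- new_ontology_dag(
    c("root", "mid", "leaf"),
    list(root = character(0), mid = "root", leaf = "mid"),
    namespace = c(root = "BP", mid = "BP", leaf = "BP"))
  ann <- data.frame(
    protein_id = c("p1", "p2", "p3", "p4", "p5", "p6"),
    term_id = c("leaf", "leaf", "mid", "mid", "root", "root"),
    aspect = "BP", evidence_code = "IDA", stringsAsFactors = FALSE)
  ly <- ssbp_scores(ann, dag, c("p1|p2", "p1|p3", "p1|p5", "p5|p6"))
  expect_equal(unname(ly$scores[["p1|p2"]]), 2)  # leaf: 2 proteins
  expect_equal(unname(ly$scores[["p1|p3"]]), 4)  # mid: p1..p4
  expect_equal(unname(ly$scores[["p1|p5"]]), 6)  # root only
  expect_equal(unname(ly$scores[["p5|p6"]]), 6)

  # no shared BP annotation at all -> uncovered
  ann2 <- ann[1:2, ]
  ly2 <- ssbp_scores(ann2, dag, c("p1|p2", "p1|p9"))
  expect_false("p1|p9" %in% names(ly2$scores))
})

test_that("SSBP agrees with the explicit propagate-and-count oracle", {
  set.seed(47)
  for (rep in 1:20) {
    dag <- random_dag(sample(5:40, 1))
    n_prot <- sample(5:30, 1)
    prots <- paste0("q", seq_len(n_prot))
    ann <- data.frame(
      protein_id = sample(prots, 2 * n_prot, replace = TRUE),
      term_id = sample(dag$terms, 2 * n_prot, replace = TRUE),
      aspect = "BP", evidence_code = "IDA", stringsAsFactors = FALSE)
    pairs <- sample(all_pairs(prots), min(25, choose(n_prot, 2)))
    got <- ssbp_scores(ann, dag, pairs)
    want <- brute_ssbp(ann, dag, pairs)
    for (k in pairs) {
      if (is.na(want[[k]])) {
        expect_false(k %in% names(got$scores))
      } else {
        expect_equal(unname(got$scores[[k]]), unname(want[[k]]))
      }
    }
  }
})

test_that("gene fusion flags near-disjoint hits on a shared target", {
  hits <- data.frame(
    query_protein = c("a", "b", "a", "b", "a", "b"),
    target_protein = c("t1", "t1", "t2", "t2", "t3", "t4"),
    start = c(1, 120, 1, 50, 1, 1),
    end = c(100, 220, 100, 150, 100, 100),
    stringsAsFactors = FALSE)
  ly1 <- gene_fusion_pairs(hits[1:2, ], 0.2)
  expect_equal(names(ly1$scores), "a|b")
  # overlap 51 of shorter 101 = 0.505 > 0.2: rejected
  ly2 <- gene_fusion_pairs(hits[3:4, ], 0.2)
  expect_length(ly2$scores, 0L)
  # hits on different targets only
  ly3 <- gene_fusion_pairs(hits[5:6, ], 0.2)
  expect_length(ly3$scores, 0L)

  bad <- hits[1:2, ]; bad$start[1] <- 500
  expect_error(gene_fusion_pairs(bad), "start > end")
})

test_that("phylogenetic profile similarity counts matching bits", {
  pf <- rbind(a = c(1, 1, 0, 0), b = c(1, 1, 0, 0), c = c(0, 0, 1, 1),
              d = c(1, 0, 1, 0), allone = c(1, 1, 1, 1))
  ly <- phylo_profile_scores(pf)
  expect_equal(unname(ly$scores[["a|b"]]), 1.0)
  expect_equal(unname(ly$scores[["a|c"]]), 0.0)
  expect_equal(unname(ly$scores[["a|d"]]), 0.5)   # 1100 vs 1010
  expect_false(any(grepl("allone", names(ly$scores))))
  expect_error(phylo_profile_scores(pf[, 1:3]), "4")

  mi <- phylo_profile_scores(pf, metric = "mutual_information")
  expect_equal(unname(mi$scores[["a|b"]]), 1.0)   # identical informative: 1 bit
  expect_gt(mi$scores[["a|b"]], mi$scores[["a|d"]])
})

test_that("gene neighbor requires proximity in enough genomes", {
  ctx <- function(genome, pa, pb, gap) {
    data.frame(genome = genome, gene = paste0(genome, c("_1", "_2")),
               contig = "c1", start = c(1L, 1000L + gap + 1L),
               end = c(999L, 2000L + gap), strand = "+",
               query_protein = c(pa, pb), stringsAsFactors = FALSE)
  }
  two <- rbind(ctx("g1", "a", "b", 200L), ctx("g2", "a", "b", 200L))
  expect_equal(names(gene_neighbor_pairs(two)$scores), "a|b")
  far <- rbind(ctx("g1", "a", "b", 50000L), ctx("g2", "a", "b", 50000L))
  expect_length(gene_neighbor_pairs(far)$scores, 0L)
  one <- ctx("g1", "a", "b", 200L)
  expect_length(gene_neighbor_pairs(one, min_genomes = 2)$scores, 0L)
  expect_equal(names(gene_neighbor_pairs(one, min_genomes = 1)$scores), "a|b")
})

test_that("all layer coverages use canonical symmetric keys", {
  w <- small_world()
  layers <- list(
    project_orthologs(w$ortholog$yeast$source_ppi, w$ortholog$yeast$map),
    coexpression_scores(w$expr),
    ssbp_scores(w$annotations, w$ontology, all_pairs(w$proteins)),
    gene_fusion_pairs(w$fusion_hits),
    gene_neighbor_pairs(w$context),
    phylo_profile_scores(w$profiles))
  for (ly in layers) {
    ab <- pair_split(names(ly$scores))
    expect_identical(names(ly$scores), pair_key(ab$protein_a, ab$protein_b))
  }
})
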