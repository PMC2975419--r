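mini_net <- function(edges, lr_orth = NULL) {
  df <- pair_split(edges)
  df$key <- edges
  if (!is.null(lr_orth)) df$lr_ortholog <- lr_orth
  structure(df, class = c("scored_network", "data.frame"))
}

test_that("conservation mapping looks up cross-product ortholog pairs", {
  net <- mini_net("A|B")
  maps <- list(yeast = structure(list(organism = "yeast",
                                      mapping = list(A = "X", B = "Y")),
                                 class = "ortholog_map"))
  refs <- list(yeast = "X|Y")
  rep1 <- map_conservation(net, maps, refs)
  expect_true(rep1$found_in_reference)

  refs2 <- list(yeast = "X|Z")
  expect_false(map_conservation(net, maps, refs2)$found_in_reference)

  # no ortholog for A: no mapped rows
  maps3 <- list(yeast = structure(list(organism = "yeast",
                                       mapping = list(B = "Y")),
                                  class = "ortholog_map"))
  expect_equal(nrow(map_conservation(net, maps3, refs)), 0L)
})

test_that("pairs inferred from the excluded organism's orthologs are skipped", {
  net <- mini_net(c("A|B", "C|D"), lr_orth = c(12, 1))
  maps <- list(yeast = structure(
    list(organism = "yeast",
         mapping = list(A = "X", B = "Y", C = "U", D = "V")),
    class = "ortholog_map"))
  refs <- list(yeast = c("X|Y", "U|V"))
  r <- map_conservation(net, maps, refs, exclude_sources = "yeast")
  expect_false("A" %in% r$query_a)        # ortholog-derived, excluded
  expect_true("C" %in% r$query_a)
})

test_that("conservation counts match a brute-force nested-loop search", {
  set.seed(43)
  for (rep in 1:10) {
    q <- paste0("Q", 1:12); t <- paste0("T", 1:15)
    net <- mini_net(sample(all_pairs(q), 20))
    mapping <- lapply(setNames(nm = q), function(p) sample(t, sample(0:2, 1)))
    mapping <- mapping[lengths(mapping) > 0]
    refk <- sample(all_pairs(t), 30)
    maps <- list(org = structure(list(organism = "org", mapping = mapping),
                                 class = "ortholog_map"))
    got <- map_conservation(net, maps, list(org = refk))
    found <- 0L
    for (k in net$key) {
      ab <- strsplit(k, "|", fixed = TRUE)[[1]]
      for (x in mapping[[ab[1]]]) for (y in mapping[[ab[2]]]) {
        if (x != y && pair_key(x, y) %in% refk) found <- found + 1L
      }
    }
    expect_equal(sum(got$found_in_reference), found)
  }
})

test_that("hub degree report contrasts pathway hubs with all nodes", {
  star <- mini_net(c("C|L1", "C|L2", "C|L3", "C|L4"))
  paths <- c(list(C = paste0("pw", 1:12)),
             setNames(rep(list("pw1"), 4), paste0("L", 1:4)))
  r <- hub_degree_report(star, paths, hub_min_pathways = 10)
  expect_equal(r$mean_degree_hubs, 4)
  expect_equal(r$mean_degree_all, 8 / 5)

  none <- hub_degree_report(star, list(), hub_min_pathways = 10)
  expect_true(is.na(none$mean_degree_hubs))

  edge <- mini_net("A|B")
  r2 <- hub_degree_report(edge, list(A = paste0("p", 1:11),
                                     B = paste0("p", 1:11)))
  expect_equal(r2$mean_degree_hubs, 1)
  expect_equal(r2$mean_degree_all, 1)
})

enrich_fixture <- function() {
  dag <- new_ontology_dag(c("root", "t1"), list(root = character(0),
                                                t1 = "root"),
                          namespace = c(root = "BP", t1 = "BP"))
  bg <- paste0("P", 1:10)
  # neighbors of seed S: P1..P5; term t1 annotates exactly P1..P5
  net <- mini_net(pair_key(rep("S", 5), paste0("P", 1:5)))
  ann <- data.frame(protein_id = paste0("P", 1:5), term_id = "t1",
                    aspect = "BP", evidence_code = "IDA",
                    stringsAsFactors = FALSE)
  list(dag = dag, bg = bg, net = net, ann = ann)
}

test_that("hypergeometric enrichment reproduces the closed form", {
  f <- enrich_fixture()
  r <- neighborhood_enrichment("S", f$net, f$ann, f$dag, f$bg)
  expect_equal(r$p_value[r$term_id == "t1"], 1 / choose(10, 5))
  expect_equal(r$p_value[r$term_id == "t1"], 0.003968254, tolerance = 1e-6)
  # the root annotates every annotated protein: K = k regardless, p = 1 when
  # K equals the full neighbor overlap ... saturated-term case below
  ann_all <- rbind(f$ann,
                   data.frame(protein_id = paste0("P", 6:10), term_id = "t1",
                              aspect = "BP", evidence_code = "IDA",
                              stringsAsFactors = FALSE))
  r2 <- neighborhood_enrichment("S", f$net, ann_all, f$dag, f$bg)
  expect_equal(r2$p_value[r2$term_id == "t1"], 1)
  # k = 0: term annotates only non-neighbors
  ann0 <- data.frame(protein_id = paste0("P", 6:8), term_id = "t1",
                     aspect = "BP", evidence_code = "IDA",
                     stringsAsFactors = FALSE)
  r0 <- neighborhood_enrichment("S", f$net, ann0, f$dag, f$bg)
  expect_equal(r0$p_value[r0$term_id == "t1"], 1)
})

test_that("hypergeometric p equals exhaustive enumeration for small universes", {
  set.seed(53)
  for (rep in 1:10) {
    N <- sample(6:12, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- max(0, K + n - N):min(K, n)
    k <- sample(k, 1)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    # enumerate all C(N, n) draws, count those with >= k hits
    draws <- utils::combn(N, n)
    hits <- colSums(draws <= K)   # elements 1..K carry the term
    expect_equal(p, mean(hits >= k), tolerance = 1e-12)
  }
})

test_that("enrichment is invariant to annotation row order", {
  f <- enrich_fixture()
  r1 <- neighborhood_enrichment("S", f$net, f$ann, f$dag, f$bg)
  r2 <- neighborhood_enrichment("S", f$net, f$ann[rev(seq_len(nrow(f$ann))), ],
                                f$dag, f$bg)
  expect_equal(r1, r2)
})

test_that("enrichment validates its inputs", {
  f <- enrich_fixture()
  expect_error(neighborhood_enrichment("Z", f$net, f$ann, f$dag, f$bg),
               "neighbors")
  expect_error(neighborhood_enrichment("S", f$net, f$ann, f$dag,
                                       paste0("P", 1:3)),
               "background")
})
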