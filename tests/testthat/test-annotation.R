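slow_schedule <- list(t0 = 5, alpha = 0.9, steps_per_t = 50L, t_min = 0.01)

test_that("a clique with one unknown is annotated with the shared term", {
  edges <- edges_df(t(utils::combn(5, 2)))
  known <- setNames(rep(list("G"), 4), paste0("N", 1:4))
  st <- anneal_annotations(edges, known, "N5", schedule = slow_schedule,
                           seed = 3)
  expect_equal(unname(st$assignment[["N5"]]), "G")
  expect_equal(st$energy, -10)  # every clique edge matches
  # confirmed against exhaustive enumeration
  expect_equal(st$energy, brute_ground_state(edges, known, "N5", "G"))
})

test_that("annealing is deterministic given the seed and respects the schedule", {
  edges <- edges_df(rbind(c(1, 2), c(2, 3), c(3, 4)))
  known <- list(N1 = "A", N4 = "B")
  s1 <- anneal_annotations(edges, known, c("N2", "N3"),
                           schedule = slow_schedule, seed = 11)
  s2 <- anneal_annotations(edges, known, c("N2", "N3"),
                           schedule = slow_schedule, seed = 11)
  expect_identical(s1$assignment, s2$assignment)
  expect_identical(s1$energy, s2$energy)

  # zero steps per temperature: initial random assignment comes back
  s0 <- anneal_annotations(edges, known, c("N2", "N3"),
                           schedule = list(t0 = 1, alpha = 0.5,
                                           steps_per_t = 0L, t_min = 1e-3),
                           seed = 11)
  expect_equal(s0$energy, s0$initial_energy)

  expect_error(anneal_annotations(edges, known, character(0)), "no unknown")
  expect_error(anneal_annotations(edges, known, "N2",
                                  schedule = list(t0 = 1e-4, alpha = 0.9,
                                                  steps_per_t = 1L,
                                                  t_min = 1e-3)),
               "t0")
})

test_that("best-seen energy never exceeds the initial energy", {
  set.seed(19)
  for (rep in 1:10) {
    m <- graph_battery()[[sample(length(graph_battery()), 1)]]
    edges <- edges_df(m)
    nodes <- unique(c(edges$protein_a, edges$protein_b))
    nk <- max(2L, length(nodes) - 2L)
    known <- setNames(as.list(sample(c("A", "B", "C"), nk, replace = TRUE)),
                      nodes[seq_len(nk)])
    unk <- setdiff(nodes, names(known))
    if (length(unk) == 0) next
    st <- anneal_annotations(edges, known, unk, schedule = slow_schedule,
                             seed = rep)
    expect_lte(st$energy, st$initial_energy)
  }
})

test_that("annealing reaches the exhaustive ground state on small graphs", {
  terms <- c("A", "B", "C")
  hits <- 0L; total <- 0L
  set.seed(29)
  for (gi in seq_along(graph_battery())) {
    m <- graph_battery()[[gi]]
    edges <- edges_df(m)
    nodes <- unique(c(edges$protein_a, edges$protein_b))
    nk <- ceiling(length(nodes) / 2)
    known <- setNames(as.list(sample(terms, nk, replace = TRUE)),
                      nodes[seq_len(nk)])
    unk <- setdiff(nodes, names(known))
    gs <- brute_ground_state(edges, known, unk, terms)
    for (run in 1:10) {
      st <- anneal_annotations(edges, known, unk, schedule = slow_schedule,
                               seed = 1000L * gi + run)
      total <- total + 1L
      if (st$energy == gs) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("permutation p-values follow the add-one formula", {
  # star: unknown u with 5 neighbors carrying term T among 100 labeled nodes
  chain <- cbind(6:104, 7:105)
  edges <- edges_df(rbind(cbind(200, 1:5), chain))
  known <- c(setNames(rep(list("T"), 5), paste0("N", 1:5)),
             setNames(as.list(paste0("t", 1:100)), paste0("N", 6:105)))
  calls <- data.frame(protein = "N200", term = "T",
                      stringsAsFactors = FALSE)
  res <- annotation_pvalues(edges, known, calls, n_permutations = 999,
                            seed = 1)
  expect_equal(res$observed, 5L)
  expect_equal(res$p_value, 1 / 1000)

  # zero observed support: p is 1 regardless
  calls0 <- data.frame(protein = "N200", term = "t50",
                       stringsAsFactors = FALSE)
  res0 <- annotation_pvalues(edges, known, calls0, n_permutations = 99,
                             seed = 1)
  expect_equal(res0$p_value, 1)

  expect_error(annotation_pvalues(edges, known, calls, n_permutations = 0),
               "n_permutations")
})

test_that("p-values are approximately uniform under a random network", {
  set.seed(37)
  n <- 60
  edges <- data.frame(protein_a = sample(paste0("N", 1:n), 150, TRUE),
                      protein_b = sample(paste0("N", 1:n), 150, TRUE),
                      stringsAsFactors = FALSE)
  edges <- edges[edges$protein_a != edges$protein_b, ]
  known <- setNames(as.list(sample(paste0("t", 1:4), n, TRUE)),
                    paste0("N", 1:n))
  calls <- data.frame(protein = sample(paste0("N", 1:n), 400, TRUE),
                      term = sample(paste0("t", 1:4), 400, TRUE),
                      stringsAsFactors = FALSE)
  res <- annotation_pvalues(edges, known, calls, n_permutations = 199,
                            seed = 2)
  for (a in c(0.05, 0.1, 0.25)) {
    expect_lte(mean(res$p_value <= a), a + 2 / 200 + 0.05)
  }
})

test_that("masked module annotations are recovered on the synthetic world", {
  w <- small_world(seed = 13)
  masked <- mask_annotations(w, 0.3, seed = 5)
  known <- lapply(split(masked$masked_known$term_id,
                        masked$masked_known$protein_id), unique)
  edges <- pair_split(w$true_ppi)
  nodes <- unique(c(edges$protein_a, edges$protein_b))
  hidden <- masked$hidden_truth[masked$hidden_truth$protein_id %in% nodes, ]
  st <- anneal_annotations(edges, known, unique(hidden$protein_id),
                           schedule = slow_schedule, seed = 23)
  got <- st$assignment[hidden$protein_id]
  expect_gte(mean(got == hidden$term_id), 0.7)
})
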