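flag_layer <- function(keys, organism = NULL) {
  new_evidence_layer("ortholog", setNames(rep(1, length(keys)), keys),
                     "flag", organism = organism)
}

test_that("binary LR estimation reproduces direct count ratios", {
  pos <- paste0("p", 1:10, "|q", 1:10)
  neg <- paste0("r", 1:10, "|s", 1:10)
  gold <- make_gold(pos, neg)
  m <- estimate_lr(flag_layer(c(pos[1:8], neg[1:2])), gold, pseudocount = 0)
  expect_equal(unname(m$lr[["present"]]), (8 / 10) / (2 / 10))
  expect_equal(unname(m$lr[["present"]]), 4.0)

  eq <- estimate_lr(flag_layer(c(pos[1:5], neg[1:5])), gold, pseudocount = 0)
  expect_equal(unname(eq$lr[["present"]]), 1.0)

  sm <- estimate_lr(flag_layer(pos[1:8]), gold, pseudocount = 1)
  expect_equal(unname(sm$lr[["present"]]), (9 / 12) / (1 / 12))
  expect_equal(unname(sm$lr[["present"]]), 9.0)
})

test_that("LR estimation matches the brute-force counting oracle", {
  set.seed(61)
  for (rep in 1:20) {
    u <- all_pairs(paste0("P", 1:25))
    pos <- sample(u, 40); rest <- setdiff(u, pos)
    neg <- sample(rest, 60)
    gold <- make_gold(pos, neg)
    flagged <- sample(u, sample(10:100, 1))
    for (c0 in c(0, 0.5, 1)) {
      m <- estimate_lr(flag_layer(flagged), gold, pseudocount = c0)
      want <- brute_lr_binary(flagged, gold, c0)
      expect_equal(unname(m$lr[c("present", "absent")]), unname(want),
                   tolerance = if (c0 == 0) 0 else 1e-12)
    }
    # binned layer against the binned counting oracle
    sc <- setNames(runif(length(u)), u)
    ly <- new_evidence_layer("coexpression", sc, "score")
    cuts <- sort(runif(3))
    m2 <- estimate_lr(ly, gold, bins = cuts, pseudocount = 0.5)
    want2 <- brute_lr_binned(sc[pos], sc[neg], c(-Inf, cuts, Inf), 0.5)
    expect_equal(unname(m2$lr), unname(want2), tolerance = 1e-12)
  }
})

test_that("class-conditional bin probabilities each sum to one without smoothing", {
  set.seed(67)
  u <- all_pairs(paste0("P", 1:20))
  gold <- make_gold(sample(u, 30), sample(setdiff(u, sample(u, 30)), 50))
  sc <- setNames(runif(length(u)), u)
  ly <- new_evidence_layer("coexpression", sc, "score")
  cuts <- c(0.3, 0.6)
  bin <- function(x) findInterval(x, c(-Inf, cuts, Inf), left.open = TRUE,
                                  rightmost.closed = TRUE)
  p_pos <- tabulate(bin(sc[gold$positives]), 3) / 30
  p_neg <- tabulate(bin(sc[gold$negatives]), 3) / 50
  expect_equal(sum(p_pos), 1)
  expect_equal(sum(p_neg), 1)
  m <- estimate_lr(ly, gold, bins = cuts, pseudocount = 0)
  expect_equal(unname(m$lr), p_pos / p_neg)
})

test_that("supervised discretization finds the informative cut", {
  cut <- supervised_discretize(c(1, 2, 3, 4), c("pos", "pos", "neg", "neg"),
                               min_leaf = 1)
  expect_length(cut, 1L)
  expect_gt(cut, 2); expect_lte(cut, 3)

  # label distribution identical within every score value: zero gain, no split
  s <- rep(1:10, each = 10)
  l <- rep(rep(c("pos", "neg"), 5), 10)
  expect_length(supervised_discretize(s, l, min_leaf = 5), 0L)
  # budget of one bin
  expect_length(supervised_discretize(c(1, 2, 3, 4), c("pos", "pos", "neg",
                                                       "neg"),
                                      max_bins = 1, min_leaf = 1), 0L)
  expect_warning(supervised_discretize(rep(1, 10), rep(c("pos", "neg"), 5)),
                 "identical")
})

test_that("supervised discretization matches exhaustive single-split search", {
  set.seed(73)
  for (rep in 1:20) {
    s <- round(runif(60, 0, 10), 1)
    y <- ifelse(s + rnorm(60) > 5, "pos", "neg")
    if (length(unique(y)) < 2 || length(unique(s)) < 2) next
    got <- supervised_discretize(s, y, max_bins = 2, min_leaf = 5)
    # exhaustive search over all midpoints
    ent <- function(lab) {
      p <- table(lab) / length(lab); -sum(p[p > 0] * log2(p[p > 0]))
    }
    vals <- sort(unique(s))
    mids <- (vals[-1] + vals[-length(vals)]) / 2
    gains <- vapply(mids, function(m) {
      l <- y[s <= m]; r <- y[s > m]
      if (length(l) < 5 || length(r) < 5) return(-Inf)
      ent(y) - length(l) / 60 * ent(l) - length(r) / 60 * ent(r)
    }, 0)
    if (max(gains) <= 1e-12) {
      expect_length(got, 0L)
    } else {
      expect_equal(got, mids[which.max(gains)])
    }
  }
})

test_that("functional evidence combines by max under the domain gate", {
  expect_equal(combine_functional(2, 5, 3, 4, TRUE), 5)
  expect_equal(combine_functional(2, 5, 3, 4, FALSE), 1)
  expect_equal(combine_functional(NA, NA, NA, NA, TRUE), 1)
  # vectorized over pairs
  expect_equal(combine_functional(c(2, NA), c(5, NA), c(3, 7), c(4, NA),
                                  c(TRUE, TRUE)), c(5, 7))
  expect_error(combine_functional(-1, 2, 3, 4, TRUE), "positive")
})

test_that("integration multiplies the three groups with max over organisms", {
  cfg <- integration_config(0.01)
  r <- integrate_evidence(c(yeast = 10, worm = 4), 5, 2, cfg)
  expect_equal(r$lr_total, 100)
  expect_equal(r$posterior_odds, 1)

  r0 <- integrate_evidence(numeric(0), NA, 1, cfg)
  expect_equal(r0$lr_total, 1)
  expect_equal(r0$posterior_odds, cfg$prior_odds)

  cfg559 <- integration_config(1 / 559)
  r559 <- integrate_evidence(numeric(0), NA, 559, cfg559)
  expect_equal(r559$posterior_odds, 1.0)
})

test_that("integration equals a brute-force product over the evidence list", {
  set.seed(79)
  for (rep in 1:25) {
    orgs <- runif(sample(0:4, 1), 0.5, 50)
    if (length(orgs)) names(orgs) <- paste0("o", seq_along(orgs))
    coexp <- if (runif(1) < 0.3) NA else runif(1, 0.5, 10)
    fun <- runif(1, 0.5, 20)
    cfg <- integration_config(runif(1, 1e-4, 0.5))
    r <- integrate_evidence(orgs, coexp, fun, cfg)
    factors <- c(if (length(orgs)) max(orgs) else 1,
                 if (is.na(coexp)) 1 else coexp, fun)
    expect_equal(r$lr_total, prod(factors), tolerance = 1e-12)
    expect_equal(r$posterior_odds, cfg$prior_odds * prod(factors),
                 tolerance = 1e-12)
  }
})

test_that("the auto high cutoff realizes the posterior-odds-1 criterion", {
  expect_identical(integration_config(1 / 559)$high_cutoff, 559)
  set.seed(83)
  for (p in 1 / runif(20, 1, 1000)) {
    cfg <- integration_config(p)
    expect_lte(abs(cfg$high_cutoff * p - 1), .Machine$double.eps)
  }
})

test_that("the medium cutoff is the weakest ortholog interactome LR", {
  mk <- function(lr) structure(list(lr = c(present = lr)), class = "lr_model")
  expect_equal(derive_medium_cutoff(list(mk(559), mk(301), mk(92), mk(410))),
               92)
  expect_equal(derive_medium_cutoff(list(mk(50))), 50)
  expect_equal(derive_medium_cutoff(list(mk(7), mk(7), mk(7))), 7)
})

test_that("tier assignment uses inclusive lower bounds and drops unsupported pairs", {
  cfg <- integration_config(1 / 559, medium_cutoff = 92, high_cutoff = 559)
  lr <- c("A|B" = 600, "C|D" = 92, "E|F" = 3, "G|H" = 1)
  net <- assign_tiers(lr, cfg, supported = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(net$tier, c("high", "medium", "low"))
  expect_false("G|H" %in% net$key)
  expect_equal(net$posterior_odds, net$lr_total / 559)
})

test_that("raising any single LR never lowers the total LR or the tier", {
  set.seed(89)
  cfg <- integration_config(0.01, medium_cutoff = 20)
  tier_rank <- c(low = 1, medium = 2, high = 3)
  for (rep in 1:20) {
    orgs <- c(a = runif(1, 1, 30), b = runif(1, 1, 30))
    coexp <- runif(1, 0.5, 5); fun <- runif(1, 0.5, 10)
    base <- integrate_evidence(orgs, coexp, fun, cfg)
    bump <- runif(1, 1, 3)
    for (variant in list(
      integrate_evidence(orgs * c(bump, 1), coexp, fun, cfg),
      integrate_evidence(orgs, coexp * bump, fun, cfg),
      integrate_evidence(orgs, coexp, fun * bump, cfg))) {
      expect_gte(variant$lr_total, base$lr_total)
      t0 <- assign_tiers(setNames(base$lr_total, "x|y"), cfg)$tier
      t1 <- assign_tiers(setNames(variant$lr_total, "x|y"), cfg)$tier
      expect_gte(tier_rank[[t1]], tier_rank[[t0]])
    }
  }
})

test_that("integrated posteriors converge to the truth on independent layers", {
  r <- nb_calibration_experiment(n_pairs = 4000, seed = 5)
  expect_lt(r$mae, 0.05)
})
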