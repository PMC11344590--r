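test_that("auroc matches hand-computed and brute-force values", {
  expect_equal(auroc(ranked_from_scores(c(0.9, 0.1), c(1, 0))), 1)
  expect_equal(auroc(ranked_from_scores(c(0.1, 0.9), c(1, 0))), 0)
  # 3 concordant of 4 positive-negative pairs
  expect_equal(auroc(ranked_from_scores(c(0.9, 0.6, 0.4, 0.2),
                                        c(1, 0, 1, 0))), 0.75)
  # tied pair gets half credit
  expect_equal(auroc(ranked_from_scores(c(0.5, 0.5), c(1, 0))), 0.5)
  expect_error(auroc(ranked_from_scores(c(0.4, 0.2), c(1, 1))), "undefined")
})

test_that("auroc and auprc equal their exhaustive oracles on random instances", {
  set.seed(21)
  for (i in 1:800) {
    inst <- random_instance(tie_prone = i %% 3 == 0)
    ranked <- ranked_from_scores(inst$scores, inst$labels)
    expect_equal(auroc(ranked), oracle_auroc(inst$scores, inst$labels),
                 tolerance = 1e-12)
    expect_equal(auprc(ranked), oracle_ap(ranked$label), tolerance = 1e-12)
  }
})

test_that("auprc follows the average-precision convention", {
  expect_equal(auprc(ranked_from_scores(c(0.9, 0.8, 0.2, 0.1),
                                        c(1, 1, 0, 0))), 1)
  # single positive ranked last of 5: AP = precision@5 = 0.2
  expect_equal(auprc(ranked_from_scores(c(0.9, 0.8, 0.7, 0.6, 0.1),
                                        c(0, 0, 0, 0, 1))), 0.2)
  # AP = 1 iff all positives precede all negatives
  r <- ranked_from_scores(c(0.9, 0.5, 0.8, 0.1), c(1, 1, 0, 0))
  expect_lt(auprc(r), 1)
})

test_that("null-model mean average precision matches a Monte-Carlo oracle", {
  set.seed(33)
  n <- 200L; n_pos <- 50L
  labels <- c(rep(1L, n_pos), rep(0L, n - n_pos))
  pkg_ap <- replicate(400, auprc(ranked_from_scores(runif(n), labels)))
  mc_ap <- replicate(400, oracle_ap(sample(labels)))
  se <- sqrt(var(pkg_ap) / 400 + var(mc_ap) / 400)
  expect_lt(abs(mean(pkg_ap) - mean(mc_ap)), 4 * se + 1e-3)
  # and at this positive count the mean is close to the prevalence
  expect_lt(abs(mean(pkg_ap) - n_pos / n), 0.03)
})

test_that("hit_at_k inspects the top-k labels with truncation", {
  expect_equal(hit_at_k(ranked_from_scores(c(0.9, 0.1), c(1, 0)), 1), 1L)
  pos_at_7 <- ranked_from_scores(seq(1, 0.1, length.out = 10),
                                 c(0, 0, 0, 0, 0, 0, 1, 0, 0, 0))
  expect_equal(hit_at_k(pos_at_7, 1), 0L)
  expect_equal(hit_at_k(pos_at_7, 10), 1L)
  short <- ranked_from_scores(c(0.4, 0.3, 0.2, 0.1), c(0, 0, 0, 1))
  expect_equal(hit_at_k(short, 10), 1L)  # evaluates the whole length-4 list
})

test_that("ranking metrics are invariant to strictly monotone transforms", {
  set.seed(14)
  for (i in 1:30) {
    inst <- random_instance()
    r1 <- ranked_from_scores(inst$scores, inst$labels)
    r2 <- ranked_from_scores(exp(2 * inst$scores + 1), inst$labels)
    expect_equal(auroc(r2), auroc(r1), tolerance = 1e-12)
    expect_equal(hit_at_k(r2, 1), hit_at_k(r1, 1))
    expect_equal(hit_at_k(r2, 10), hit_at_k(r1, 10))
    # reversing the score direction flips AUROC (tie-free instances)
    if (!anyDuplicated(inst$scores)) {
      r3 <- ranked_from_scores(-inst$scores, inst$labels)
      expect_equal(auroc(r3), 1 - auroc(r1), tolerance = 1e-12)
    }
  }
})

test_that("hit10 dominates hit1 per query and in aggregate", {
  set.seed(17)
  db <- generate_hierarchy(hierarchy_spec(2, 2, 2, 2, seed = 1,
                                          length_range = c(5L, 8L)))
  st <- generate_embeddings(db, signal_spec(dim = 6, superfamily_weight = 0.5,
                                            noise_sd = 1, seed = 2))
  rec <- evaluate_model(build_query_tasks(db, "superfamily"), store = st)
  expect_true(all(rec$hit10 >= rec$hit1))
  for (sc in c("weighted", "unweighted")) {
    agg <- aggregate_metrics(rec, sc, "superfamily")$overall
    expect_gte(agg[["hit10"]], agg[["hit1"]])
  }
})

test_that("aggregation schemes weight groups as specified", {
  rec <- data.frame(
    query_id = sprintf("q%d", 1:4),
    superfamily_id = c("a.1.1", "a.2.1", "a.2.1", "a.2.1"),
    fold_id = c("a.1", "a.2", "a.2", "a.2"),
    auroc = c(1.0, 0.5, 0.5, 0.5), auprc = c(1.0, 0.5, 0.5, 0.5),
    hit1 = c(1L, 0L, 0L, 0L), hit10 = c(1L, 1L, 0L, 0L),
    n_pos = 2L, n_neg = 5L, stringsAsFactors = FALSE)
  w <- aggregate_metrics(rec, "weighted", "superfamily")
  u <- aggregate_metrics(rec, "unweighted", "superfamily")
  expect_equal(w$overall[["auroc"]], 0.75)
  expect_equal(u$overall[["auroc"]], 0.625)
  expect_equal(w$per_group$n_queries, c(1L, 3L))

  # equal group sizes make the two schemes coincide
  rec_eq <- rec; rec_eq$superfamily_id <- c("a.1.1", "a.1.1", "a.2.1", "a.2.1")
  expect_equal(aggregate_metrics(rec_eq, "weighted", "superfamily")$overall,
               aggregate_metrics(rec_eq, "unweighted", "superfamily")$overall)

  # single group: both schemes equal the group mean
  rec_1 <- rec; rec_1$superfamily_id <- "a.1.1"
  expect_equal(aggregate_metrics(rec_1, "weighted", "superfamily")$overall,
               aggregate_metrics(rec_1, "unweighted", "superfamily")$overall)
})

test_that("spearman_rho reproduces the closed form and its invariants", {
  expect_equal(spearman_rho(c(3, 1, 4, 1.5), c(3, 1, 4, 1.5)), 1)
  expect_equal(spearman_rho(1:5, 5:1), -1)
  # ranks (1,2,3,4) vs (2,1,4,3): 1 - 6*4 / (4*15) = 0.6
  expect_equal(spearman_rho(c(10, 20, 30, 40), c(20, 10, 40, 30)), 0.6)
  set.seed(4)
  for (i in 1:30) {
    x <- rnorm(sample(3:20, 1)); y <- rnorm(length(x))
    expect_equal(spearman_rho(x, y), cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
    expect_equal(spearman_rho(x, y), spearman_rho(y, x))
    expect_equal(spearman_rho(x, 2.5 * x + 3), 1)
    xt <- round(x, 1); yt <- round(y, 1)  # ties take the midrank route
    if (var(rank(xt)) > 0 && var(rank(yt)) > 0) {
      expect_equal(spearman_rho(xt, yt), cor(xt, yt, method = "spearman"),
                   tolerance = 1e-12)
    }
  }
  expect_error(spearman_rho(1, 1), "n >= 2")
  expect_error(spearman_rho(c(1, 1, 1), c(1, 2, 3)), "zero rank variance")
})

make_records <- function(aurocs, groups = paste0("a.", seq_along(aurocs), ".1")) {
  data.frame(query_id = sprintf("q%d", seq_along(aurocs)),
             superfamily_id = groups,
             fold_id = sub("\\.\\d+$", "", groups),
             auroc = aurocs, auprc = aurocs,
             hit1 = 0L, hit10 = 0L, n_pos = 1L, n_neg = 5L,
             stringsAsFactors = FALSE)
}

test_that("agreement_matrix holds per-group (lower) and per-query (upper) rho", {
  m1 <- make_records(c(0.1, 0.2, 0.3, 0.4))
  m2 <- make_records(c(0.2, 0.1, 0.4, 0.3))
  m3 <- make_records(c(0.4, 0.3, 0.2, 0.1))
  am <- agreement_matrix(list(m1 = m1, m2 = m2, m3 = m3), "superfamily")
  expect_equal(diag(unclass(am)), c(m1 = 1, m2 = 1, m3 = 1))
  # hand-applied closed form per pair (one query per group, so both
  # triangles carry the same value here)
  expect_equal(am["m2", "m1"], 0.6)
  expect_equal(am["m3", "m1"], -1)
  expect_equal(am["m3", "m2"], -0.6)
  expect_equal(am["m1", "m2"], 0.6)

  # identical models agree perfectly everywhere
  ident <- agreement_matrix(list(a = m1, b = m1), "superfamily")
  expect_true(all(unclass(ident) == 1))

  # a model against its AUROC complement is a perfect rank reversal
  comp <- m1; comp$auroc <- 1 - comp$auroc
  rev <- agreement_matrix(list(a = m1, b = comp), "superfamily")
  expect_equal(rev["b", "a"], -1)
  expect_equal(rev["a", "b"], -1)

  # alignment uses the intersection of queries/groups
  m4 <- make_records(c(0.1, 0.2, 0.3, 0.4, 0.9),
                     groups = paste0("a.", 1:5, ".1"))
  am2 <- agreement_matrix(list(a = m1, b = m4), "superfamily")
  expect_equal(attr(am2, "n_group")["b", "a"], 4L)
  expect_error(agreement_matrix(list(a = m1), "superfamily"), "two models")
})
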