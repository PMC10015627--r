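test_that("birth-death transition probabilities match hand values and sum to 1", {
  expect_equal(bd_transition_prob(3, 0:5, 0, 0.7), c(0, 0, 0, 1, 0, 0))
  expect_equal(bd_transition_prob(1, 0, 1, 1), 0.5)      # a = 1/2
  expect_equal(bd_transition_prob(1, 1, 1, 1), 0.25)
  expect_equal(bd_transition_prob(0, 0, 2, 1), 1)        # absorbing at 0

  for (s in 1:10) for (a_target in c(0.1, 0.3, 0.45)) {
    t <- a_target / (1 - a_target)                       # lambda = 1
    expect_equal(sum(bd_transition_prob(s, 0:400, t, 1)), 1, tolerance = 1e-9)
  }
  # convolution-built matrix equals the closed form
  P <- phyloregime:::bd_transition_matrix(0.7, 0.9, 40)
  for (s in c(1, 4, 9)) {
    expect_equal(P[s + 1, ], bd_transition_prob(s, 0:40, 0.7, 0.9),
                 tolerance = 1e-12)
  }
})

test_that("family pruning matches identity cases and the enumeration oracle", {
  tr <- read_newick(text = "(A:1,B:1);")
  ll <- family_loglik(tr, c(A = 3, B = 3), 0,
                      root_prior = c(0, rep(1 / 10, 10)), N_max = 10)
  expect_equal(ll$total, -log(10))
  expect_equal(family_loglik(tr, c(A = 3, B = 5), 0, N_max = 10)$total, -Inf)

  set.seed(131)
  tr3 <- read_newick(text = "((A:0.6,B:0.9):0.5,C:1.1);")
  for (i in 1:8) {
    counts <- stats::setNames(sample(0:6, 3, replace = TRUE), c("A", "B", "C"))
    if (all(counts == 0)) counts["A"] <- 1
    lam <- stats::runif(1, 0.2, 1.5)
    expect_equal(family_loglik(tr3, counts, lam, N_max = 12)$total,
                 bd_enum_loglik(tr3, counts, lam, 12), tolerance = 1e-9)
  }
})

test_that("high-confidence filtering requires presence in half the taxa", {
  m <- rbind(a = c(1, 1, 0, 0), b = c(2, 0, 0, 0), c = c(1, 2, 3, 0))
  colnames(m) <- paste0("t", 1:4)
  expect_equal(unname(high_confidence_families(m)), c(TRUE, FALSE, TRUE))
})

test_that("turnover rates are recovered and bounded", {
  fx <- make_study_fixture(7)
  fams <- simulate_gene_families(fx$tree, 0.43, n_families = 400, seed = 51)
  f <- fit_turnover(fx$tree, fams, n_lambdas = 1)
  expect_equal(unname(f$lambda), 0.43, tolerance = 0.15)
  expect_false(f$at_lower_bound)

  f0 <- fit_turnover(fx$tree,
                     simulate_gene_families(fx$tree, 0, n_families = 100,
                                            seed = 52),
                     n_lambdas = 1)
  expect_true(f0$at_lower_bound)
})

test_that("two-rate models are preferred when branch classes truly differ", {
  fx <- make_study_fixture(8)
  cls <- phyloregime:::edge_states(fx$tree, fx$painting) + 1L
  wins <- 0L
  for (s in 1:10) {
    fams <- simulate_gene_families(fx$tree, c(0.6, 0.1), class_of_edge = cls,
                                   n_families = 300, seed = 700 + s)
    ct <- compare_turnover(fx$tree, fams, fx$painting, n_lambdas_range = 1:2)
    d <- ct$table
    gap <- d$aicc[d$n_lambdas == 1] - d$aicc[d$n_lambdas == 2]
    if (ct$best == 2 && gap > 2) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})

test_that("Monte-Carlo significance flags an extreme planted family", {
  fx <- make_study_fixture(9)
  base <- simulate_gene_families(fx$tree, 0.43, n_families = 200, seed = 53)
  ext <- matrix(c(rep(0L, 10), 50L), 1,
                dimnames = list("ext", fx$tree$tip.label))
  f <- fit_turnover(fx$tree, rbind(base, ext), n_lambdas = 1, filter = FALSE)
  s <- family_significance(f, M = 1000, seed = 54)
  expect_lt(s$p[s$family == "ext"], 0.01)
  # all-ties degenerate case: identical p inputs give identical q
  expect_equal(unname(as.numeric(storey_qvalue(rep(1, 30)))), rep(1, 30))
})

test_that("ancestral count reconstruction matches exhaustive argmax", {
  tr <- read_newick(text = "(A:1,B:1);")
  f <- fit_turnover(tr, matrix(c(5L, 5L), 1, dimnames = list("f1", c("A", "B"))),
                    n_lambdas = 1, filter = FALSE, lambda_bounds = c(0.01, 0.011))
  ch <- reconstruct_changes(f)
  expect_equal(unname(ch$node_counts[1L, 3L]), 5L)
  expect_true(all(ch$delta == 0))

  set.seed(141)
  tr3 <- read_newick(text = "((A:0.6,B:0.9):0.5,C:1.1);")
  for (i in 1:6) {
    counts <- matrix(sample(0:6, 3, replace = TRUE), 1,
                     dimnames = list("f1", c("A", "B", "C")))
    if (all(counts == 0)) counts[1] <- 2
    lam <- stats::runif(1, 0.2, 1.2)
    f <- fit_turnover(tr3, counts, n_lambdas = 1, filter = FALSE,
                      N_max = 10, lambda_bounds = c(lam, lam * 1.0001))
    ch <- reconstruct_changes(f)
    oracle <- bd_enum_argmax(tr3, counts[1L, ], f$lambda, 10)
    ll_pkg <- bd_enum_path_prob(tr3, ch$node_counts[1L, ], f$lambda, 10)
    ll_orc <- bd_enum_path_prob(tr3, oracle, f$lambda, 10)
    expect_equal(ll_pkg, ll_orc, tolerance = 1e-9)  # same joint probability
  }
})

test_that("parallel-change classification applies the Boolean rules", {
  fx <- make_study_fixture(10)
  tree <- fx$tree; painting <- fx$painting
  # hand-built change sets exercising each rule
  tipn <- ape::Ntip(tree)
  mk_counts <- function(tipvals, internal = 5L) {
    nc <- matrix(internal, 1L, tipn + tree$Nnode)
    nc[1L, seq_len(tipn)] <- tipvals
    rownames(nc) <- "f"
    nc
  }
  st <- painting$node_state[seq_len(tipn)]
  selfers <- which(st == 1L); outs <- which(st == 0L)
  v <- rep(5L, tipn); v[selfers] <- c(4L, 5L, 3L, 3L)
  cl <- classify_parallel(list(node_counts = mk_counts(v)), tree, painting)
  expect_equal(cl$category, "DecreasingInSelfers")
  v2 <- rep(5L, tipn); v2[outs[1:2]] <- 7L; v2[selfers[1L]] <- 4L
  expect_equal(classify_parallel(list(node_counts = mk_counts(v2)), tree,
                                 painting)$category, "DecreasingInSelfers")
  v3 <- rep(5L, tipn); v3[selfers] <- c(6L, 7L, 6L, 6L)
  expect_equal(classify_parallel(list(node_counts = mk_counts(v3)), tree,
                                 painting)$category, "IncreasingInSelfers")
  v4 <- rep(5L, tipn); v4[outs] <- 4L
  expect_equal(classify_parallel(list(node_counts = mk_counts(v4)), tree,
                                 painting)$category, "DecreasingInOutcrossers")
  v5 <- rep(5L, tipn); v5[outs[3L]] <- 8L
  expect_equal(classify_parallel(list(node_counts = mk_counts(v5)), tree,
                                 painting)$category, "IncreasingInOutcrossers")
  expect_equal(classify_parallel(list(node_counts = mk_counts(rep(5L, tipn))),
                                 tree, painting)$category, "Stable")
  v6 <- rep(5L, tipn); v6[selfers[1:2]] <- c(4L, 6L)
  expect_equal(classify_parallel(list(node_counts = mk_counts(v6)), tree,
                                 painting)$category, "Unclassified")
})

test_that("planted parallel losses are detected and classified", {
  fx <- make_study_fixture(11)
  selfers <- fixture_selfer_tips(fx)
  base <- simulate_gene_families(fx$tree, 0.43, n_families = 300,
                                 root_mean = 5, seed = 55)
  pl <- simulate_gene_families(fx$tree, 0.05, n_families = 40,
                               root_counts = rep(10L, 40), seed = 56)
  pl[, selfers] <- 0L
  rownames(pl) <- paste0("plant", seq_len(40))
  f <- fit_turnover(fx$tree, rbind(base, pl), n_lambdas = 1)
  sig <- family_significance(f, M = 1000, seed = 57)
  ch <- reconstruct_changes(f)
  cl <- classify_parallel(ch, fx$tree, fx$painting,
                          significant = sig$family[sig$q < 0.01])
  got <- cl$category[grepl("^plant", cl$family)]
  expect_gte(sum(got == "DecreasingInSelfers"), 32L)   # >= 80% of 40
  # determinism and family-order invariance of classification
  cl2 <- classify_parallel(ch, fx$tree, fx$painting,
                           significant = rev(sig$family[sig$q < 0.01]))
  m <- merge(cl, cl2, by = "family")
  expect_equal(m$category.x, m$category.y)
})

test_that("Fisher enrichment gives exact two-sided p and sample odds ratios", {
  fe <- fisher_enrichment(matrix(c(5, 0, 0, 5), 2))
  expect_equal(fe$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(fe$odds_ratio, Inf)
  expect_equal(fisher_enrichment(matrix(c(1, 1, 1, 1), 2))$p_value, 1)
  expect_equal(fisher_enrichment(matrix(c(3, 1, 2, 4), 2))$odds_ratio,
               (3 * 4) / (1 * 2))
  tab <- matrix(c(7, 2, 3, 9), 2)
  expect_equal(fisher_enrichment(t(tab))$p_value,
               fisher_enrichment(tab)$p_value)
  expect_equal(fisher_enrichment(matrix(c(0, 0, 3, 5), 2))$p_value, 1)
})

test_that("Storey q-values fall back to BH and stay monotone", {
  set.seed(151)
  p <- c(stats::runif(400), stats::rbeta(100, 0.2, 1))
  q <- storey_qvalue(p)
  expect_true(all(q >= p * 0 & q <= 1))
  expect_lte(attr(q, "pi0"), 1)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  p10 <- stats::runif(10)
  q2 <- storey_qvalue(p10)                       # too few: BH fallback
  expect_equal(attr(q2, "method"), "BH")
  expect_equal(as.numeric(q2), stats::p.adjust(p10, "BH"))
})
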