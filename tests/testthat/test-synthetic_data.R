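test_that("regime histories follow the two-state chain", {
  tr <- read_newick(text = "((A:1,B:1):1,C:2);")
  p0 <- simulate_regime_history(tr, 0, 0, root_state = 1L, seed = 1)
  expect_true(all(p0$node_state == 1L))
  p1 <- simulate_regime_history(tr, 2, 1, root_state = 0L, seed = 7)
  p2 <- simulate_regime_history(tr, 2, 1, root_state = 0L, seed = 7)
  expect_identical(p1$node_state, p2$node_state)

  # symmetric chain on a long branch reaches its stationary distribution;
  # a big star gives many independent replicates in one call
  star <- read_newick(text = paste0("(", paste0("t", 1:10000, ":10",
                                                collapse = ","), ");"))
  ps <- simulate_regime_history(star, 5, 5, root_state = 0L, seed = 11)
  expect_equal(mean(ps$node_state[1:10000]), 0.5, tolerance = 0.02)
})

test_that("trait simulation matches the exact transition moments", {
  trz <- read_newick(text = "((A:0,B:1):1,C:2);")
  pz <- regime_painting(trz, rep(0L, 5L))
  y <- simulate_trait(trz, pz, "OU", y0 = 1, sigma2 = 1, alpha = 2,
                      theta = c(outcrosser = 5, selfer = 1), seed = 3)
  nv <- attr(y, "node_values")
  expect_equal(y[["A"]], nv[5L])             # zero-length branch copies parent

  star <- read_newick(text = paste0("(", paste0("t", 1:20000, ":1",
                                                collapse = ","), ");"))
  yb <- simulate_trait(star, model = "BM", y0 = 0, sigma2 = 2, seed = 5)
  expect_equal(stats::var(as.numeric(yb)), 2, tolerance = 0.05)

  pstar <- regime_painting(star, rep(0L, 20001L))
  yo <- simulate_trait(star, pstar, "OU", y0 = 0, sigma2 = 1, alpha = log(2),
                       theta = c(outcrosser = 6.19, selfer = 0), seed = 6)
  expect_equal(mean(as.numeric(yo)), 6.19 / 2, tolerance = 0.03)

  y1 <- simulate_trait(star, model = "BM", y0 = 0, sigma2 = 2, seed = 5)
  expect_identical(as.numeric(yb), as.numeric(y1))   # seeded determinism
})

test_that("gene-family simulation follows the critical birth-death process", {
  tr2 <- read_newick(text = "(A:1,B:1);")
  m0 <- simulate_gene_families(tr2, 0, n_families = 50, seed = 8)
  expect_true(all(m0[, "A"] == attr(m0, "root_counts")))
  expect_true(all(m0[, "B"] == attr(m0, "root_counts")))

  # extinction probability from a single ancestral gene: a = t/(1+t) = 1/2
  me <- simulate_gene_families(tr2, 1, n_families = 20000,
                               root_counts = rep(1L, 20000), seed = 9)
  expect_equal(mean(me[, "A"] == 0), 0.5, tolerance = 0.01)

  # +/-1 misobservation model at eps = 0.2
  merr <- simulate_gene_families(tr2, 0, n_families = 20000, eps = 0.2,
                                 root_counts = rep(5L, 20000), seed = 10)
  obs <- c(merr[, "A"], merr[, "B"])
  expect_lt(abs(mean(obs == 5) - 0.8), 0.01)
  expect_lt(abs(mean(obs == 4) - 0.1), 0.01)
  expect_lt(abs(mean(obs == 6) - 0.1), 0.01)

  # critical branching is mean-preserving: tip mean = root-prior mean
  fx <- make_study_fixture(5)
  mm <- simulate_gene_families(fx$tree, 0.5, n_families = 3000, seed = 12)
  tipmean <- mean(mm)
  se <- stats::sd(rowMeans(mm)) / sqrt(nrow(mm))
  expect_lt(abs(tipmean - mean(attr(mm, "root_counts"))), 3 * se)
})

test_that("the study fixture has the designed shape and is reproducible", {
  fx <- make_study_fixture(1)
  expect_equal(ape::Ntip(fx$tree), 11L)
  expect_true(ape::is.binary(fx$tree))
  expect_true(is_ultrametric(fx$tree))
  expect_equal(max(node_depths(fx$tree)), 1)
  expect_equal(sum(fx$painting$node_state[1:11] == 1L), 4L)
  # three independent selfing origins: selfer branches form three clusters
  selfers <- fixture_selfer_tips(fx)
  expect_setequal(fx$tree$tip.label[selfers],
                  c("C_elegans", "C_briggsae", "C_tropicalis_JU1373",
                    "C_tropicalis_NIC58"))
  expect_equal(sum(fx$painting$node_state == 1L), 5L)  # 4 tips + 1 stem

  fx_t <- make_study_fixture(1, truncate = TRUE)
  expect_true(all(fx_t$traits$mutator_pct >= 0))

  fx2 <- make_study_fixture(1)
  expect_identical(fx$traits, fx2$traits)
  expect_identical(fx$families, fx2$families)
})

test_that("fixture bundles round-trip through plain-text files", {
  fx <- make_study_fixture(6, n_families = 40)
  dir <- withr::local_tempdir()
  write_fixture(fx, dir)
  tr <- read_newick(file = file.path(dir, "tree.nwk"))
  expect_equal(sort(tr$tip.label), sort(fx$tree$tip.label))
  reg <- read_regimes(file.path(dir, "regimes.tsv"))
  expect_equal(unname(reg[fx$tree$tip.label]),
               fx$painting$node_state[1:11])
  tt <- read_trait_table(file.path(dir, "traits.tsv"))
  expect_equal(tt$genome_size_mb, fx$traits$genome_size_mb, tolerance = 1e-6)
  fam <- read_families(file.path(dir, "families.tsv"))
  expect_true(all(fam == fx$families[rownames(fam), colnames(fam)]))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$seed, 6L)
  expect_equal(manifest$parameters$lambda, 0.43)
})
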