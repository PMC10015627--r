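test_that("Mk pruning matches closed-form and enumeration oracles", {
  tr <- read_newick(text = "(A:1,B:1);")
  st <- c(A = 0L, B = 0L)
  # closed form: P00(1) = 0.68394, P10(1) = 0.31606 at q = 0.5
  expect_equal(mk_loglik(tr, st, 0.5, 0.5),
               log(0.5 * (0.68394^2 + 0.31606^2)), tolerance = 1e-4)
  expect_equal(mk_loglik(tr, st, 0, 0), log(0.5))
  expect_equal(mk_loglik(tr, c(A = 0L, B = 1L), 0, 0), -Inf)

  set.seed(21)
  for (i in 1:25) {
    tr <- rand_tree(5)
    st <- rand_states(tr, p_na = if (i %% 3 == 0) 0.3 else 0)
    q01 <- stats::runif(1, 0.05, 2)
    q10 <- stats::runif(1, 0.05, 2)
    expect_equal(mk_loglik(tr, st, q01, q10),
                 mk_enum_loglik(tr, st, q01, q10), tolerance = 1e-9)
  }
})

test_that("Mk likelihood is invariant to zero-length polytomy resolution", {
  star <- read_newick(text = "(A:1,B:0.7,C:1.3,D:0.4);")
  st <- c(A = 0L, B = 1L, C = 0L, D = 1L)
  expect_equal(mk_loglik(resolve_polytomies(star), st, 0.8, 0.4),
               mk_loglik(star, st, 0.8, 0.4), tolerance = 1e-12)
})

test_that("ER and SYM are the same model for a binary character", {
  fx <- make_study_fixture(1)
  st <- stats::setNames(fx$painting$node_state[1:11], fx$tree$tip.label)
  fe <- fit_mk(fx$tree, st, "ER")
  fs <- fit_mk(fx$tree, st, "SYM")
  expect_equal(fe$loglik, fs$loglik, tolerance = 1e-9)
  expect_equal(fe$aicc, fs$aicc, tolerance = 1e-9)
  expect_identical(fe$k, fs$k)
})

test_that("fit_mk handles the all-identical boundary case", {
  tr <- rand_tree(8)
  st <- stats::setNames(rep(0L, 8), tr$tip.label)
  expect_warning(f <- fit_mk(tr, st, "ER"), "identical")
  expect_lt(f$q01, 1e-7)
  expect_equal(f$loglik, log(0.5), tolerance = 1e-4)
  expect_equal(f$aicc, 2 * f$k - 2 * f$loglik + 2 * f$k * (f$k + 1) / (8 - f$k - 1))
})

test_that("ARD is detected when transition rates are truly asymmetric", {
  set.seed(42)
  tr <- rand_tree(100)
  tr$edge.length <- tr$edge.length / max(node_depths(tr))
  wins <- 0L
  for (s in 1:20) {
    p <- simulate_regime_history(tr, q01 = 5, q10 = 1, root_state = 0L,
                                 seed = 500 + s)
    st <- stats::setNames(p$node_state[1:100], tr$tip.label)
    if (length(unique(st)) < 2L) next
    fe <- fit_mk(tr, st, "ER")
    fa <- fit_mk(tr, st, "ARD")
    if (fe$aicc - fa$aicc > 2) wins <- wins + 1L
  }
  expect_gte(wins, 14L)
})

test_that("marginal ancestral states match the enumeration posterior", {
  tr <- read_newick(text = "(A:1,B:1);")
  st <- c(A = 0L, B = 0L)
  m <- marginal_ancestral_states(list(q01 = 0.5, q10 = 0.5, root_prior = "flat"),
                                 tr, st)
  expect_equal(unname(m[3L, 1L]), 0.68394^2 / (0.68394^2 + 0.31606^2),
               tolerance = 1e-4)
  m0 <- marginal_ancestral_states(list(q01 = 1e-9, q10 = 1e-9,
                                       root_prior = "flat"), tr, st)
  expect_equal(m0[3L, ], c(P0 = 1, P1 = 0), tolerance = 1e-6)

  set.seed(31)
  for (i in 1:20) {
    tr <- rand_tree(5)
    st <- rand_states(tr, p_na = if (i %% 4 == 0) 0.3 else 0)
    q01 <- stats::runif(1, 0.05, 2)
    q10 <- stats::runif(1, 0.05, 2)
    m <- marginal_ancestral_states(list(q01 = q01, q10 = q10,
                                        root_prior = "flat"), tr, st)
    mo <- mk_enum_marginals(tr, st, q01, q10)
    internal <- (ape::Ntip(tr) + 1L):(ape::Ntip(tr) + tr$Nnode)
    expect_equal(unname(m[internal, ]), mo[internal, ], tolerance = 1e-9)
    expect_equal(unname(rowSums(m)), rep(1, nrow(m)), tolerance = 1e-9)
  }
})

test_that("paint_regimes discretizes by child-node argmax with tie rules", {
  tr <- read_newick(text = "((A:1,B:1):1,C:1);")
  st <- c(A = 1L, B = 1L, C = 0L)
  N <- 5L
  m <- matrix(0.5, N, 2L)
  m[4L, ] <- c(0.9, 0.1)            # root clearly outcrosser
  m[5L, ] <- c(0.1, 0.9)            # AB ancestor selfer
  p <- paint_regimes(m, tr, st)
  expect_equal(p$node_state[5L], 1L)
  expect_equal(p$node_state[4L], 0L)
  expect_equal(p$node_state[match(c("A", "B", "C"), tr$tip.label)], c(1L, 1L, 0L))

  # exact tie inherits the parent's state and is flagged
  m[5L, ] <- c(0.5, 0.5)
  p2 <- paint_regimes(m, tr, st)
  expect_equal(p2$node_state[5L], 0L)     # parent (root) is outcrosser
  expect_true(p2$tie[5L])
  # tip branches always match observed states, whatever the marginals
  m[match("C", tr$tip.label), ] <- c(0.1, 0.9)
  expect_equal(paint_regimes(m, tr, st)$node_state[match("C", tr$tip.label)], 0L)
})

test_that("the Mk ladder ranks models by AICc with simplicity tie-breaks", {
  fx <- make_study_fixture(2)
  st <- stats::setNames(fx$painting$node_state[1:11], fx$tree$tip.label)
  lad <- fit_mk_ladder(fx$tree, st)
  expect_setequal(lad$table$model, c("ER", "SYM", "ARD"))
  expect_true(all(diff(lad$table$aicc) >= 0))
  # ER/SYM coincide, so ARD can beat them by at most the AICc penalty gap
  expect_true(lad$best %in% c("ER", "SYM"))
})
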