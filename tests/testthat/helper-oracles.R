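# Independent reference implementations ("oracles") used to validate the
# package's pruning / GLS / dynamic-programming code paths, plus small
# random-instance generators. Everything here is deliberately brute force.

rand_tree <- function(n, min_len = 0.1, max_len = 1) {
  tr <- ape::rtree(n)
  tr$edge.length <- stats::runif(nrow(tr$edge), min_len, max_len)
  tr
}

rand_states <- function(tree, p1 = 0.5, p_na = 0) {
  n <- ape::Ntip(tree)
  st <- sample(0:1, n, replace = TRUE, prob = c(1 - p1, p1))
  if (p_na > 0) st[stats::runif(n) < p_na] <- NA
  stats::setNames(as.integer(st), tree$tip.label)
}

rand_painting <- function(tree) {
  N <- ape::Ntip(tree) + tree$Nnode
  regime_painting(tree, sample(0:1, N, replace = TRUE))
}

# exact multivariate-normal log-density via determinant() + solve(), a
# different numerical route from the package's Cholesky evaluator
mvn_loglik <- function(y, mu, Sigma) {
  n <- length(y)
  r <- y - mu
  ld <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
  as.numeric(-0.5 * (n * log(2 * pi) + ld + t(r) %*% solve(Sigma, r)))
}

# 2-state transition matrix by matrix exponential (independent of the
# package's closed form)
mk_P_expm <- function(q01, q10, t) {
  Q <- matrix(c(-q01, q01, q10, -q10), 2, 2, byrow = TRUE)
  as.matrix(Matrix::expm(Q * t))
}

# Mk likelihood by full enumeration over unobserved node states
mk_enum_loglik <- function(tree, tip_states, q01, q10, prior = c(0.5, 0.5)) {
  n <- ape::Ntip(tree)
  N <- n + tree$Nnode
  root <- n + 1L
  st <- tip_states[tree$tip.label]
  fixed <- rep(NA_integer_, N)
  fixed[seq_len(n)] <- st
  free <- which(is.na(fixed))
  total <- 0
  for (code in 0:(2^length(free) - 1)) {
    assign <- fixed
    assign[free] <- bitwAnd(bitwShiftR(code, seq_along(free) - 1L), 1L)
    pr <- prior[assign[root] + 1L]
    for (e in seq_len(nrow(tree$edge))) {
      P <- mk_P_expm(q01, q10, tree$edge.length[e])
      pr <- pr * P[assign[tree$edge[e, 1L]] + 1L, assign[tree$edge[e, 2L]] + 1L]
    }
    total <- total + pr
  }
  log(total)
}

# marginal node posteriors by the same enumeration
mk_enum_marginals <- function(tree, tip_states, q01, q10, prior = c(0.5, 0.5)) {
  n <- ape::Ntip(tree)
  N <- n + tree$Nnode
  root <- n + 1L
  st <- tip_states[tree$tip.label]
  fixed <- rep(NA_integer_, N)
  fixed[seq_len(n)] <- st
  free <- which(is.na(fixed))
  acc <- matrix(0, N, 2L)
  for (code in 0:(2^length(free) - 1)) {
    assign <- fixed
    assign[free] <- bitwAnd(bitwShiftR(code, seq_along(free) - 1L), 1L)
    pr <- prior[assign[root] + 1L]
    for (e in seq_len(nrow(tree$edge))) {
      P <- mk_P_expm(q01, q10, tree$edge.length[e])
      pr <- pr * P[assign[tree$edge[e, 1L]] + 1L, assign[tree$edge[e, 2L]] + 1L]
    }
    acc[cbind(seq_len(N), assign + 1L)] <- acc[cbind(seq_len(N), assign + 1L)] + pr
  }
  acc / rowSums(acc)
}

# birth-death family likelihood by enumeration over internal node counts
# (uses the package's closed-form transition probability, which is itself
# pinned against hand-computed values; the enumeration replaces the pruning)
bd_enum_loglik <- function(tree, counts, lambda, N_max, prior = NULL) {
  n <- ape::Ntip(tree)
  internals <- (n + 1L):(n + tree$Nnode)
  root <- n + 1L
  obs <- counts[tree$tip.label]
  if (is.null(prior)) prior <- c(0, rep(1 / N_max, N_max))
  grids <- rep(list(0:N_max), length(internals))
  combos <- as.matrix(expand.grid(grids))
  total <- 0
  for (k in seq_len(nrow(combos))) {
    assign <- integer(n + tree$Nnode)
    assign[seq_len(n)] <- obs
    assign[internals] <- combos[k, ]
    pr <- prior[assign[root] + 1L]
    if (pr == 0) next
    for (e in seq_len(nrow(tree$edge))) {
      s <- assign[tree$edge[e, 1L]]
      c2 <- assign[tree$edge[e, 2L]]
      pr <- pr * bd_transition_prob(s, c2, tree$edge.length[e], lambda)
      if (pr == 0) break
    }
    total <- total + pr
  }
  if (total <= 0) -Inf else log(total)
}

# joint max-likelihood ancestral counts by exhaustive argmax (3-tip trees)
bd_enum_argmax <- function(tree, counts, lambda, N_max, prior = NULL) {
  n <- ape::Ntip(tree)
  internals <- (n + 1L):(n + tree$Nnode)
  root <- n + 1L
  obs <- counts[tree$tip.label]
  if (is.null(prior)) prior <- c(0, rep(1 / N_max, N_max))
  combos <- as.matrix(expand.grid(rep(list(0:N_max), length(internals))))
  best <- -Inf
  best_assign <- NULL
  for (k in seq_len(nrow(combos))) {
    assign <- integer(n + tree$Nnode)
    assign[seq_len(n)] <- obs
    assign[internals] <- combos[k, ]
    pr <- prior[assign[root] + 1L]
    for (e in seq_len(nrow(tree$edge))) {
      s <- assign[tree$edge[e, 1L]]
      c2 <- assign[tree$edge[e, 2L]]
      pr <- pr * bd_transition_prob(s, c2, tree$edge.length[e], lambda)
      if (pr == 0) break
    }
    if (pr > best) { best <- pr; best_assign <- assign }
  }
  best_assign
}

# OU tip mean vector and covariance matrix built from first principles:
# node paths via ape::nodepath, shared depths via ape::vcv
ou_oracle_moments <- function(tree, painting, alpha, v, theta, y0) {
  n <- ape::Ntip(tree)
  V <- ape::vcv(tree)
  Tt <- diag(V)
  d <- ape::node.depth.edgelength(tree)
  root <- n + 1L
  ei <- rep(NA_integer_, n + tree$Nnode)
  ei[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  mu <- numeric(n)
  for (i in seq_len(n)) {
    path <- ape::nodepath(tree, root, i)
    m <- y0 * exp(-alpha * Tt[i])
    for (k in 2:length(path)) {
      v2 <- path[k]
      th <- theta[painting$node_state[v2] + 1L]
      m <- m + th * (exp(-alpha * (Tt[i] - d[v2])) -
                       exp(-alpha * (Tt[i] - d[path[k - 1L]])))
    }
    mu[i] <- m
  }
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    da <- V[i, j]
    S[i, j] <- v * exp(-alpha * (Tt[i] - da)) * exp(-alpha * (Tt[j] - da)) *
      (1 - exp(-2 * alpha * da))
  }
  list(mu = stats::setNames(mu, tree$tip.label), Sigma = S)
}

# joint log-probability of a full node-count assignment (root prior x
# branch transitions); used to compare argmax reconstructions up to ties
bd_enum_path_prob <- function(tree, assign, lambda, N_max, prior = NULL) {
  if (is.null(prior)) prior <- c(0, rep(1 / N_max, N_max))
  lp <- log(prior[assign[ape::Ntip(tree) + 1L] + 1L])
  for (e in seq_len(nrow(tree$edge))) {
    s <- assign[tree$edge[e, 1L]]
    c2 <- assign[tree$edge[e, 2L]]
    lp <- lp + log(bd_transition_prob(s, c2, tree$edge.length[e], lambda))
  }
  lp
}

fixture_selfer_tips <- function(fx) which(fx$painting$node_state[seq_len(11)] == 1L)
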