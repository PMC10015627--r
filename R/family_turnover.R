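# Gene-family turnover under a critical linear birth-death process (equal
# per-gene birth and death rate lambda per branch class), with Monte-Carlo
# family significance, Storey q-values, max-product ancestral count
# reconstruction, Boolean parallel-change classification and Fisher-exact
# enrichment.

#' Birth-death count transition probability
#'
#' Probability of observing `c` gene copies at the end of a branch of length
#' `t` given `s >= 1` copies at its start, under the equal-rate linear
#' birth-death process:
#' `P(c|s,t) = sum_j C(s,j) C(s+c-j-1, s-1) a^(s+c-2j) (1-2a)^j` with
#' `a = lambda t / (1 + lambda t)`. Zero copies is absorbing.
#'
#' @param s starting count (integer >= 0; 0 is absorbing).
#' @param c ending count (integer >= 0, vectorized).
#' @param t branch length (>= 0).
#' @param lambda per-gene birth = death rate (>= 0).
#' @return probability vector, one entry per `c`.
#' @export
bd_transition_prob <- function(s, c, t, lambda) {
  if (s < 0 || t < 0 || lambda < 0) stop("invalid s, t or lambda")
  a <- lambda * t / (1 + lambda * t)
  if (s == 0) return(as.numeric(c == 0))
  if (a == 0) return(as.numeric(c == s))
  out <- numeric(length(c))
  for (j in 0:s) {
    valid <- c >= j
    cc <- c[valid]
    term <- exp(lchoose(s, j) + lchoose(s + cc - j - 1, s - 1) +
                  (s + cc - 2 * j) * log(a)) * (1 - 2 * a)^j
    out[valid] <- out[valid] + term
  }
  pmin(pmax(out, 0), 1)
}

# (N+1)x(N+1) transition matrix over counts 0..N. Because descendants of the
# s starting genes are independent, row s is the s-fold convolution of the
# single-gene row P(0|1) = a, P(c|1) = (1-a)^2 a^(c-1); building rows by FFT
# convolution is much faster than the closed-form sum and agrees with
# bd_transition_prob to rounding error.
bd_transition_matrix <- function(t, lambda, N) {
  P <- matrix(0, N + 1L, N + 1L)
  P[1L, 1L] <- 1
  a <- lambda * t / (1 + lambda * t)
  if (a == 0) return(diag(N + 1L))
  row1 <- c(a, (1 - a)^2 * a^(0:(N - 1L)))
  P[2L, ] <- row1
  if (N >= 2L) for (s in 2:N) {
    conv <- stats::convolve(P[s, ], rev(row1), type = "open")[seq_len(N + 1L)]
    P[s + 1L, ] <- pmin(pmax(conv, 0), 1)
  }
  P
}

# symmetric +/-1 misobservation model: P(obs | true), rows = true 0..N.
# True 0 keeps its impossible -1 mass (stays 0); an overflow at N folds into
# staying, so rows always sum to 1.
bd_error_matrix <- function(N, eps) {
  E <- diag(N + 1L) * (1 - eps)
  if (eps > 0) {
    for (ctrue in 0:N) {
      i <- ctrue + 1L
      if (ctrue == 0L) E[i, 1L] <- 1 - eps / 2 else E[i, i - 1L] <- eps / 2
      if (ctrue == N) E[i, i] <- E[i, i] + eps / 2 else E[i, i + 1L] <- eps / 2
      if (ctrue == 0L) E[i, 2L] <- eps / 2
    }
  } else E <- diag(N + 1L)
  E
}

# uniform-on-{1..N} root count prior (CAFE's "at least one gene at the root")
bd_root_prior <- function(N, root_prior = "uniform") {
  if (is.numeric(root_prior)) {
    stopifnot(length(root_prior) == N + 1L, root_prior[1L] == 0)
    return(root_prior / sum(root_prior))
  }
  match.arg(root_prior, "uniform")
  c(0, rep(1 / N, N))
}

# per-edge transition matrices for an edge-class -> lambda map, cached by
# (length, lambda)
bd_edge_matrices <- function(tree, lambda_edge, N) {
  key <- paste(signif(tree$edge.length, 15), signif(lambda_edge, 15))
  uk <- unique(key)
  cache <- lapply(uk, function(k) {
    i <- match(k, key)
    bd_transition_matrix(tree$edge.length[i], lambda_edge[i], N)
  })
  cache[match(key, uk)]
}

lambda_per_edge <- function(tree, lambda, class_of_edge = NULL) {
  ne <- nrow(tree$edge)
  if (length(lambda) == 1L) return(rep(lambda, ne))
  if (is.null(class_of_edge)) stop("multi-lambda models need an edge-class map")
  stopifnot(length(class_of_edge) == ne)
  lambda[class_of_edge]
}

#' Gene-family log-likelihood by pruning over count states
#'
#' Pruning over `{0..N_max}` with tip emissions from the error model and a
#' root prior restricted to counts >= 1. Vectorized over families. An
#' impossible family (e.g. discordant counts under `lambda = 0`) gets
#' `-Inf`.
#'
#' @param tree an ultrametric binary `phylo` object.
#' @param counts family x taxon integer matrix (column names = tip labels);
#'   a single named vector is treated as one family.
#' @param lambda rate(s); scalar or one per class in `class_of_edge`.
#' @param class_of_edge optional integer class per edge (rows of
#'   `tree$edge`).
#' @param eps misobservation probability in `[0, 0.5)`.
#' @param root_prior `"uniform"` or a numeric prior over `0..N_max` with
#'   zero mass at 0.
#' @param N_max count-state truncation; defaults to
#'   `max(2 * max(counts), 30)`.
#' @return list with `total` and `per_family` log-likelihoods.
#' @export
family_loglik <- function(tree, counts, lambda, class_of_edge = NULL,
                          eps = 0, root_prior = "uniform", N_max = NULL) {
  stopifnot_phylo(tree)
  if (is.vector(counts)) counts <- matrix(counts, 1L, dimnames = list("f1", names(counts)))
  if (is.null(colnames(counts)) || !all(tree$tip.label %in% colnames(counts)))
    stop("counts must have one named column per tip")
  counts <- counts[, tree$tip.label, drop = FALSE]
  if (eps < 0 || eps >= 0.5) stop("eps must lie in [0, 0.5)")
  N <- N_max %||% max(2L * max(counts), 30L)
  if (max(counts) > N) stop("observed count exceeds N_max")
  lam_e <- lambda_per_edge(tree, lambda, class_of_edge)
  Pm <- bd_edge_matrices(tree, lam_e, N)
  E <- bd_error_matrix(N, eps)
  prior <- bd_root_prior(N, root_prior)
  n <- ape::Ntip(tree)
  Ntot <- n + tree$Nnode
  Fam <- nrow(counts)
  L <- vector("list", Ntot)
  logsc <- vector("list", Ntot)
  for (tip in seq_len(n)) {
    L[[tip]] <- E[, counts[, tip] + 1L, drop = FALSE]
    logsc[[tip]] <- numeric(Fam)
  }
  for (i in postorder_edges(tree)) {
    p <- tree$edge[i, 1L]
    v <- tree$edge[i, 2L]
    msg <- Pm[[i]] %*% L[[v]]
    if (is.null(L[[p]])) {
      L[[p]] <- msg
      logsc[[p]] <- logsc[[v]]
    } else {
      L[[p]] <- L[[p]] * msg
      logsc[[p]] <- logsc[[p]] + logsc[[v]]
    }
    m <- apply(L[[p]], 2L, max)
    pos <- m > 0
    L[[p]][, pos] <- sweep(L[[p]][, pos, drop = FALSE], 2L, m[pos], "/")
    logsc[[p]] <- logsc[[p]] + ifelse(pos, log(m), 0)
  }
  r <- root_node(tree)
  lik <- as.vector(prior %*% L[[r]])
  ll <- ifelse(lik > 0, log(lik), -Inf) + logsc[[r]]
  names(ll) <- rownames(counts)
  list(total = sum(ll), per_family = ll)
}

#' High-confidence family filter
#'
#' A family passes if it is present (count >= 1) in at least half of the
#' taxa -- the standard guard against contaminant or assembly-artifact
#' orthogroups.
#'
#' @param counts family x taxon matrix.
#' @return logical vector per family.
#' @export
high_confidence_families <- function(counts) {
  rowSums(counts >= 1L) >= ncol(counts) / 2
}

#' Fit birth-death turnover rates to a gene-family matrix
#'
#' Maximizes the summed per-family pruning log-likelihood over one rate per
#' branch class, on the log scale within `lambda_bounds`. With
#' `n_lambdas = 2` and a painting, the default partition assigns selfer and
#' outcrosser branches their own rates. The misobservation probability can
#' be profiled over a grid (`fit_error = TRUE`).
#'
#' @inheritParams family_loglik
#' @param painting optional [regime_painting] supplying the default 2-class
#'   branch partition.
#' @param n_lambdas number of rate classes.
#' @param branch_partition explicit integer class per edge (overrides the
#'   painting).
#' @param fit_error profile `eps` over `eps_grid`.
#' @param eps_grid grid for the error probability.
#' @param filter drop families failing [high_confidence_families()].
#' @param lambda_bounds search interval for each rate.
#' @return an object of class `turnover_fit` with rates, `eps`, total and
#'   per-family log-likelihoods, AICc (n = families), and everything needed
#'   by [family_significance()] and [reconstruct_changes()].
#' @export
fit_turnover <- function(tree, counts, painting = NULL, n_lambdas = 1L,
                         branch_partition = NULL, fit_error = FALSE,
                         eps = 0, eps_grid = seq(0, 0.2, by = 0.01),
                         root_prior = "uniform", N_max = NULL, filter = TRUE,
                         lambda_bounds = c(1e-4, 10)) {
  stopifnot_phylo(tree)
  if (is.null(dim(counts)) || nrow(counts) == 0L) stop("empty gene-family matrix")
  flags <- high_confidence_families(counts)
  used <- if (filter) counts[flags, , drop = FALSE] else counts
  if (nrow(used) == 0L) stop("no families pass the high-confidence filter")
  cls <- if (n_lambdas == 1L) rep(1L, nrow(tree$edge))
         else if (!is.null(branch_partition)) as.integer(branch_partition)
         else if (!is.null(painting) && n_lambdas == 2L) edge_states(tree, painting) + 1L
         else stop("n_lambdas > 1 requires `branch_partition` or (for 2) a painting")
  if (length(unique(cls)) != n_lambdas)
    stop("branch partition has ", length(unique(cls)), " classes; expected ", n_lambdas)
  N <- N_max %||% max(2L * max(used), 30L)
  obj <- function(log_lams, eps_val) {
    family_loglik(tree, used, exp(log_lams), cls, eps_val, root_prior, N)$total
  }
  fit_at_eps <- function(eps_val) {
    if (n_lambdas == 1L) {
      o <- stats::optimize(function(l) obj(l, eps_val), log(lambda_bounds),
                           maximum = TRUE, tol = 1e-6)
      list(lambda = exp(o$maximum), loglik = o$objective)
    } else {
      o <- stats::optim(rep(log(0.5), n_lambdas), function(l) -obj(l, eps_val),
                        method = "L-BFGS-B",
                        lower = rep(log(lambda_bounds[1L]), n_lambdas),
                        upper = rep(log(lambda_bounds[2L]), n_lambdas))
      list(lambda = exp(o$par), loglik = -o$value)
    }
  }
  if (fit_error) {
    sub <- lapply(eps_grid, fit_at_eps)
    ll <- vapply(sub, `[[`, numeric(1), "loglik")
    best <- which.max(ll)
    eps <- eps_grid[best]
    res <- sub[[best]]
  } else res <- fit_at_eps(eps)
  pf <- family_loglik(tree, used, res$lambda, cls, eps, root_prior, N)
  k <- n_lambdas + as.integer(fit_error)
  nfam <- nrow(used)
  ac <- if (nfam > k + 1L) aicc(res$loglik, k, nfam) else NA_real_
  structure(list(lambda = res$lambda, class_of_edge = cls, eps = eps,
                 loglik = res$loglik, per_family = pf$per_family,
                 counts = used, flags = flags, tree = tree, N_max = N,
                 root_prior = root_prior, k = k, n = nfam,
                 aicc = ac,
                 at_lower_bound = any(res$lambda <= lambda_bounds[1L] * 1.0001)),
            class = "turnover_fit")
}

#' @export
print.turnover_fit <- function(x, ...) {
  cat(sprintf("Birth-death turnover fit: lambda = %s, eps = %.3g, lnL = %.3f (n = %d families, AICc = %.3f)%s\n",
              paste(signif(x$lambda, 5), collapse = "/"), x$eps, x$loglik,
              x$n, x$aicc,
              if (x$at_lower_bound) " [rate at lower bound]" else ""))
  invisible(x)
}

#' Compare turnover models with different numbers of rate classes
#'
#' @inheritParams fit_turnover
#' @param n_lambdas_range integer vector of class counts to fit (multi-class
#'   models use the painting's selfer/outcrosser partition for 2 classes).
#' @return list with `table` (n_lambdas, k, lnL, AICc, delta) and `fits`.
#' @export
compare_turnover <- function(tree, counts, painting = NULL,
                             n_lambdas_range = 1:2, ...) {
  fits <- lapply(n_lambdas_range, function(k)
    fit_turnover(tree, counts, painting, n_lambdas = k, ...))
  a <- vapply(fits, `[[`, numeric(1), "aicc")
  tab <- data.frame(n_lambdas = n_lambdas_range,
                    k = vapply(fits, `[[`, numeric(1), "k"),
                    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
                    aicc = a, delta_aicc = a - min(a))
  list(table = tab[order(tab$aicc), ], fits = fits,
       best = n_lambdas_range[which.min(a)])
}

# posterior distribution over root counts per family: prior * root partial
# likelihood, normalized per family; returns an (N_max+1) x F matrix
bd_root_posterior <- function(fit, counts) {
  tree <- fit$tree
  N <- fit$N_max
  prior <- bd_root_prior(N, fit$root_prior)
  lam_e <- lambda_per_edge(tree, fit$lambda, fit$class_of_edge)
  Pm <- bd_edge_matrices(tree, lam_e, N)
  E <- bd_error_matrix(N, fit$eps)
  n <- ape::Ntip(tree)
  L <- vector("list", ape::Ntip(tree) + tree$Nnode)
  for (tip in seq_len(n)) L[[tip]] <- E[, counts[, tree$tip.label[tip]] + 1L, drop = FALSE]
  for (i in postorder_edges(tree)) {
    p <- tree$edge[i, 1L]; v <- tree$edge[i, 2L]
    msg <- Pm[[i]] %*% L[[v]]
    L[[p]] <- if (is.null(L[[p]])) msg else L[[p]] * msg
    m <- apply(L[[p]], 2L, max)
    pos <- m > 0
    L[[p]][, pos] <- sweep(L[[p]][, pos, drop = FALSE], 2L, m[pos], "/")
  }
  post <- prior * L[[root_node(tree)]]
  sweep(post, 2L, colSums(post), "/")
}

# forward-sample families from the fitted transition model (used for the
# Monte-Carlo null); returns an M x Ntip observed-count matrix
bd_simulate_null <- function(fit, M, root_counts = NULL) {
  tree <- fit$tree
  N <- fit$N_max
  prior <- bd_root_prior(N, fit$root_prior)
  lam_e <- lambda_per_edge(tree, fit$lambda, fit$class_of_edge)
  Pm <- bd_edge_matrices(tree, lam_e, N)
  E <- bd_error_matrix(N, fit$eps)
  n <- ape::Ntip(tree)
  Ntot <- n + tree$Nnode
  state <- matrix(0L, M, Ntot)
  state[, root_node(tree)] <- root_counts %||%
    (sample.int(N + 1L, M, replace = TRUE, prob = prior) - 1L)
  for (i in preorder_edges(tree)) {
    p <- tree$edge[i, 1L]; v <- tree$edge[i, 2L]
    s <- state[, p]
    for (u in unique(s)) {
      idx <- which(s == u)
      state[idx, v] <- sample.int(N + 1L, length(idx), replace = TRUE,
                                  prob = Pm[[i]][u + 1L, ]) - 1L
    }
  }
  obs <- state[, seq_len(n), drop = FALSE]
  if (fit$eps > 0) {
    for (tip in seq_len(n)) {
      s <- obs[, tip]
      for (u in unique(s)) {
        idx <- which(s == u)
        obs[idx, tip] <- sample.int(N + 1L, length(idx), replace = TRUE,
                                    prob = E[u + 1L, ]) - 1L
      }
    }
  }
  colnames(obs) <- tree$tip.label
  rownames(obs) <- paste0("null", seq_len(M))
  obs
}

# empirical-Bayes root-count prior: EM updates of the mixing distribution
# pi(r) = mean over families of P(r | y_f, pi), starting from the fit's
# root prior. A data-driven prior makes the root posterior (and hence the
# conditional significance sampling) match how ancestral sizes are actually
# distributed.
bd_eb_root_prior <- function(fit, counts, iterations = 3L) {
  prior <- bd_root_prior(fit$N_max, fit$root_prior)
  for (it in seq_len(iterations)) {
    fit$root_prior <- prior
    prior <- rowMeans(bd_root_posterior(fit, counts))
    prior[1L] <- 0
    prior <- prior / sum(prior)
  }
  prior
}

#' Monte-Carlo family significance with q-value correction
#'
#' Per-family likelihoods are not comparable across family sizes (a large
#' family spreads its probability over many more count configurations), so
#' each family's p-value conditions on its ancestral size. The distribution
#' of root counts is first estimated from the data by empirical Bayes (EM
#' on the mixing distribution, starting from the fit's root prior); each
#' family then draws a root count from its posterior under that prior --
#' by Bayes' rule the (root, data) pair is a draw from the joint null, so
#' the within-class Monte-Carlo rank of the family's pruning
#' log-likelihood among `M` null families forward-simulated from the same
#' root count is uniform under the fitted null. Because count patterns
#' repeat, likelihood ties are massive; ranks are randomized uniformly
#' across each tie block, the standard construction for discrete
#' Monte-Carlo tests. Rapidly expanding or contracting families have
#' unusually low likelihoods for their size and get small p-values.
#' Multiple testing is corrected by Storey q-values ([storey_qvalue()]).
#'
#' @param fit a `turnover_fit`.
#' @param M number of null replicates per root-count class (>= 100
#'   recommended; the attainable minimum p is `1/(M+1)`).
#' @param seed RNG seed (required).
#' @return data.frame with `family`, `loglik`, `root_map` (posterior-mode
#'   root count under the empirical-Bayes prior), `p`, `q`.
#' @export
family_significance <- function(fit, M = 1000L, seed) {
  stopifnot(inherits(fit, "turnover_fit"))
  if (M < 100L) warning("M < 100 gives very coarse p-values")
  obs <- fit$per_family
  nf <- length(obs)
  eb_prior <- bd_eb_root_prior(fit, fit$counts)
  eb_fit <- fit
  eb_fit$root_prior <- eb_prior
  post <- bd_root_posterior(eb_fit, fit$counts)
  with_seed(seed, {
    rstar <- vapply(seq_len(nf), function(f)
      sample.int(fit$N_max + 1L, 1L, prob = post[, f]) - 1L, integer(1))
    u_obs <- stats::runif(nf)
    p <- numeric(nf)
    for (r in sort(unique(rstar))) {
      idx <- which(rstar == r)
      nc <- bd_simulate_null(fit, M, root_counts = rep(r, M))
      null_ll <- sort(family_loglik(fit$tree, nc, fit$lambda,
                                    fit$class_of_edge, fit$eps,
                                    fit$root_prior, fit$N_max)$per_family)
      n_le <- findInterval(obs[idx], null_ll)
      n_lt <- findInterval(obs[idx], null_ll, left.open = TRUE)
      p[idx] <- (n_lt + u_obs[idx] * (n_le - n_lt + 1)) / (M + 1)
    }
  })
  q <- storey_qvalue(p)
  data.frame(family = names(obs), loglik = unname(obs),
             root_map = apply(post, 2L, which.max) - 1L,
             p = unname(p), q = unname(q), row.names = NULL)
}

#' Joint maximum-likelihood ancestral counts and per-branch changes
#'
#' Max-product dynamic programming over count states `{0..N_max}`: the
#' single jointly most probable assignment of ancestral family sizes, with
#' ties broken toward the smallest count (and flagged). Per-branch change is
#' child count minus parent count.
#'
#' @param fit a `turnover_fit`.
#' @param families family ids to reconstruct (default: all fitted).
#' @return list with `node_counts` (family x node matrix), `delta`
#'   (family x branch matrix, columns = child node ids), `tie` (per-family
#'   flag).
#' @export
reconstruct_changes <- function(fit, families = NULL) {
  stopifnot(inherits(fit, "turnover_fit"))
  tree <- fit$tree
  N <- fit$N_max
  lam_e <- lambda_per_edge(tree, fit$lambda, fit$class_of_edge)
  Pm <- bd_edge_matrices(tree, lam_e, N)
  logPm <- lapply(Pm, function(P) log(P))
  E <- bd_error_matrix(N, fit$eps)
  logE <- log(E)
  prior <- bd_root_prior(N, fit$root_prior)
  counts <- fit$counts
  ids <- families %||% rownames(counts)
  n <- ape::Ntip(tree)
  Ntot <- n + tree$Nnode
  po <- postorder_edges(tree)
  pre <- preorder_edges(tree)
  r <- root_node(tree)
  node_counts <- matrix(NA_integer_, length(ids), Ntot,
                        dimnames = list(ids, NULL))
  tie <- logical(length(ids))
  for (fi in seq_along(ids)) {
    obs <- counts[ids[fi], ]
    msg <- vector("list", Ntot)
    ptr <- vector("list", Ntot)
    for (tip in seq_len(n)) msg[[tip]] <- logE[, obs[tip] + 1L]
    for (i in po) {
      p <- tree$edge[i, 1L]; v <- tree$edge[i, 2L]
      B <- logPm[[i]] + matrix(msg[[v]], N + 1L, N + 1L, byrow = TRUE)
      arg <- max.col(B, ties.method = "first")
      sc <- B[cbind(seq_len(N + 1L), arg)]
      ptr[[v]] <- list(arg = arg - 1L,
                       tied = rowSums(B == sc & is.finite(B)) > 1L)
      msg[[p]] <- if (is.null(msg[[p]])) sc else msg[[p]] + sc
    }
    root_score <- msg[[r]] + log(prior)
    best <- which.max(root_score)
    if (sum(root_score == root_score[best]) > 1L) tie[fi] <- TRUE
    node_counts[fi, r] <- best - 1L
    for (i in pre) {
      p <- tree$edge[i, 1L]; v <- tree$edge[i, 2L]
      sp <- node_counts[fi, p] + 1L
      node_counts[fi, v] <- ptr[[v]]$arg[sp]
      if (ptr[[v]]$tied[sp]) tie[fi] <- TRUE
    }
  }
  child <- tree$edge[, 2L]
  delta <- node_counts[, child, drop = FALSE] -
    node_counts[, tree$edge[, 1L], drop = FALSE]
  colnames(delta) <- as.character(child)
  list(node_counts = node_counts, delta = delta, tie = tie)
}

#' Per-branch expansion/contraction totals
#'
#' @param changes output of [reconstruct_changes()].
#' @param tree the tree the fit used.
#' @return data.frame with one row per branch: child node id, child label
#'   (for tips), number of expanding families (`delta > 0`) and contracting
#'   families (`delta < 0`).
#' @export
branch_events <- function(changes, tree) {
  labs <- node_labels_all(tree)
  child <- tree$edge[, 2L]
  data.frame(branch = child,
             label = labs[child],
             expansions = colSums(changes$delta > 0),
             contractions = colSums(changes$delta < 0),
             row.names = NULL)
}

# per-tip net change: tip count minus the reconstructed count at the start
# of the tip's regime lineage (the parent node of the regime's origin
# branch; the root if the regime extends to the root)
lineage_net_changes <- function(node_counts_row, tree, painting) {
  n <- ape::Ntip(tree)
  par <- parent_of(tree)
  st <- painting$node_state
  vapply(seq_len(n), function(tip) {
    s <- st[tip]
    v <- tip
    while (par[v] != 0L && st[par[v]] == s) v <- par[v]
    start <- if (par[v] == 0L) v else par[v]
    node_counts_row[tip] - node_counts_row[start]
  }, numeric(1))
}

#' Classify significant families by parallel change across regimes
#'
#' For each family, the net change of every tip lineage is the tip count
#' minus the reconstructed count at the start of that tip's regime lineage
#' (where its current reproductive mode originated). A family whose selfing
#' lineages are all stable-or-decreasing (at least one strictly decreasing)
#' while all outcrossing lineages are stable-or-increasing is
#' `DecreasingInSelfers`; the three sibling categories are defined by the
#' analogous sign patterns with the focal regime showing the strict change.
#' All-zero nets are `Stable`; mixed signs within a regime class are
#' `Unclassified`.
#'
#' @param changes output of [reconstruct_changes()].
#' @param tree the tree.
#' @param painting the [regime_painting] (0 = outcrosser, 1 = selfer).
#' @param significant family ids to classify (e.g. those with q < 0.01);
#'   default all rows of `changes`.
#' @return data.frame with `family` and `category`.
#' @export
classify_parallel <- function(changes, tree, painting, significant = NULL) {
  st_tips <- painting$node_state[seq_len(ape::Ntip(tree))]
  if (anyNA(st_tips)) stop("painting missing for a tip")
  ids <- significant %||% rownames(changes$node_counts)
  cat_of <- function(nets) {
    self <- nets[st_tips == 1L]
    out <- nets[st_tips == 0L]
    if (all(nets == 0)) return("Stable")
    if (all(self <= 0) && all(out >= 0) && any(self < 0)) return("DecreasingInSelfers")
    if (all(self >= 0) && all(out <= 0) && any(self > 0)) return("IncreasingInSelfers")
    if (all(out <= 0) && all(self >= 0) && any(out < 0)) return("DecreasingInOutcrossers")
    if (all(out >= 0) && all(self <= 0) && any(out > 0)) return("IncreasingInOutcrossers")
    "Unclassified"
  }
  cats <- vapply(ids, function(id) {
    nets <- lineage_net_changes(changes$node_counts[id, ], tree, painting)
    cat_of(nets)
  }, character(1))
  data.frame(family = ids, category = unname(cats), row.names = NULL)
}

#' Fisher's exact enrichment test on a 2x2 table
#'
#' Two-sided exact p-value by hypergeometric enumeration (via
#' [stats::fisher.test()]); the odds ratio is the sample cross-product
#' `(a d)/(b c)` (infinite when a margin cell is empty), not the conditional
#' MLE. Degenerate margins give p = 1.
#'
#' @param tab 2x2 non-negative integer matrix.
#' @return list with `odds_ratio` and `p_value`.
#' @export
fisher_enrichment <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0), all(tab == round(tab)))
  p <- stats::fisher.test(tab)$p.value
  or <- (tab[1L, 1L] * tab[2L, 2L]) / (tab[1L, 2L] * tab[2L, 1L])
  if (is.nan(or)) or <- 1
  list(odds_ratio = or, p_value = min(p, 1))
}
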