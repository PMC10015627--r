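# Hansen-type adaptation models on a regime-painted tree: Brownian motion,
# single-optimum OU (OU1) and separate selfer/outcrosser-optima OU (OU2),
# compared by small-sample AICc with derived phylogenetic half-life,
# stationary variance, optima standard errors and GLS r-squared.

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = 2k - 2 lnL + 2k(k+1)/(n-k-1)`.
#'
#' @param loglik log-likelihood at the optimum.
#' @param k number of free parameters.
#' @param n sample size (here: number of tip genomes).
#' @return the AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1")
  2 * k - 2 * loglik + 2 * k * (k + 1) / (n - k - 1)
}

# shared-depth (BM unit-rate) covariance among tips
bm_tip_covariance <- function(tree) {
  n <- ape::Ntip(tree)
  m <- ape::mrca(tree)
  d <- node_depths(tree)
  V <- matrix(d[m], n, n, dimnames = list(tree$tip.label, tree$tip.label))
  V
}

#' Ornstein-Uhlenbeck tip moments under a regime painting
#'
#' For tip i at depth T_i, the expectation is a convex combination of the
#' root value and the regime optima: the root carries weight `exp(-a T_i)`
#' and each constant-regime path segment `[d0, d1)` with optimum `theta_s`
#' contributes `exp(-a (T_i - d1)) - exp(-a (T_i - d0))` to that regime's
#' weight, so each row sums to 1. The covariance, in units of the stationary
#' variance v, is `exp(-a (T_i - d)) exp(-a (T_j - d)) (1 - exp(-2 a d))`
#' with d the depth of the most recent common ancestor. Trees need not be
#' ultrametric.
#'
#' @param tree a `phylo` object.
#' @param painting a [regime_painting].
#' @param alpha rate of adaptation (> 0, per unit branch length).
#' @return list with `W` (tip x `c("y0","outcrosser","selfer")` weight
#'   matrix) and `V0` (tip covariance in units of the stationary variance).
#' @export
ou_moments <- function(tree, painting, alpha) {
  stopifnot_phylo(tree)
  ou_moments_from_cache(ou_cache(tree, painting), alpha)
}

# depth/segment/MRCA geometry shared by every alpha during profiling
ou_cache <- function(tree, painting) {
  n <- ape::Ntip(tree)
  d <- node_depths(tree)
  Tt <- d[seq_len(n)]
  segs <- lapply(seq_len(n), function(i) root_to_tip_segments(tree, painting, i))
  m <- ape::mrca(tree)
  da <- matrix(d[m], n, n)
  list(n = n, Tt = Tt, segs = segs, da = da, tips = tree$tip.label)
}

ou_moments_from_cache <- function(cache, alpha) {
  if (alpha <= 0) stop("OU requires alpha > 0")
  n <- cache$n
  Tt <- cache$Tt
  W <- matrix(0, n, 3L, dimnames = list(cache$tips, c("y0", "outcrosser", "selfer")))
  for (i in seq_len(n)) {
    seg <- cache$segs[[i]]
    W[i, "y0"] <- exp(-alpha * Tt[i])
    if (nrow(seg)) {
      w <- exp(-alpha * (Tt[i] - seg$end)) - exp(-alpha * (Tt[i] - seg$start))
      for (s in 0:1) W[i, s + 2L] <- W[i, s + 2L] + sum(w[seg$state == s])
    }
  }
  da <- cache$da
  V0 <- exp(-alpha * (outer(Tt, rep(1, n)) - da)) *
        exp(-alpha * (outer(rep(1, n), Tt) - da)) *
        (1 - exp(-2 * alpha * da))
  dimnames(V0) <- list(cache$tips, cache$tips)
  list(W = W, V0 = V0)
}

# Cholesky of a tip covariance with an informative error naming duplicated
# (zero-distance) tips when singular
chol_or_name_tips <- function(V) {
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) {
    dup <- which(duplicated(round(V, 12)))
    hint <- if (length(dup)) paste0(" (tips at zero distance: ",
                                    paste(rownames(V)[dup], collapse = ", "), ")")
            else ""
    stop("singular tip covariance", hint,
         "; zero-length sister tips cannot be distinguished")
  }
  R
}

# exact Gaussian log-density given mean vector and covariance
gaussian_loglik <- function(y, mu, Sigma) {
  R <- chol_or_name_tips(Sigma)
  z <- backsolve(R, y - mu, transpose = TRUE)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(R))) + sum(z^2))
}

#' Exact log-likelihood of a tip trait vector under BM, OU1 or OU2
#'
#' Evaluates the multivariate-normal density implied by the model's mean and
#' covariance structure at explicit parameter values (no fitting). Under the
#' default root rule the OU root value is tied to the optimum of the regime
#' painted at the root.
#'
#' @param tree a `phylo` object.
#' @param trait named numeric vector over tip labels.
#' @param painting a [regime_painting] (required for OU models).
#' @param model `"BM"`, `"OU1"` or `"OU2"`.
#' @param params list: BM needs `mu`, `sigma2`; OU needs `alpha`, `v`
#'   (stationary variance) and `theta` (scalar for OU1; named
#'   `c(outcrosser=, selfer=)` for OU2); optional `y0` overrides the
#'   root-regime rule.
#' @return log-likelihood (scalar).
#' @export
model_loglik <- function(tree, trait, painting = NULL,
                         model = c("BM", "OU1", "OU2"), params) {
  stopifnot_phylo(tree)
  model <- match.arg(model)
  y <- trait[tree$tip.label]
  if (anyNA(y)) stop("trait missing for some tips")
  n <- length(y)
  if (model == "BM") {
    V <- params$sigma2 * bm_tip_covariance(tree)
    return(gaussian_loglik(y, rep(params$mu, n), V))
  }
  if (is.null(painting)) stop("OU models require a regime painting")
  mom <- ou_moments(tree, painting, params$alpha)
  th <- if (model == "OU1") c(outcrosser = unname(params$theta[1L]),
                              selfer = unname(params$theta[1L]))
        else c(outcrosser = unname(params$theta[["outcrosser"]]),
               selfer = unname(params$theta[["selfer"]]))
  y0 <- params$y0 %||% th[[c("outcrosser", "selfer")[painting$node_state[root_node(tree)] + 1L]]]
  mu <- mom$W %*% c(y0, th[["outcrosser"]], th[["selfer"]])
  gaussian_loglik(y, as.vector(mu), params$v * mom$V0)
}

# GLS profile machinery: given unit covariance V0 and design X, profile the
# scale (v or sigma2) and regression coefficients analytically
gls_profile <- function(y, X, V0) {
  R <- chol_or_name_tips(V0)
  yt <- backsolve(R, y, transpose = TRUE)
  Xt <- backsolve(R, X, transpose = TRUE)
  XtX <- crossprod(Xt)
  beta <- solve(XtX, crossprod(Xt, yt))
  r <- yt - Xt %*% beta
  rss <- sum(r^2)
  n <- length(y)
  one <- backsolve(R, rep(1, n), transpose = TRUE)
  muw <- sum(one * yt) / sum(one * one)
  tss <- sum((yt - one * muw)^2)
  vhat <- rss / n
  ll <- -0.5 * (n * log(2 * pi * vhat) + 2 * sum(log(diag(R))) + n)
  list(beta = as.vector(beta), vhat = vhat, loglik = ll, rss = rss, tss = tss,
       cov_unit = solve(XtX))
}

ou_design <- function(mom, painting, tree, model, estimate_root) {
  root_state <- painting$node_state[root_node(tree)]
  if (model == "OU1") {
    X <- if (estimate_root) cbind(y0 = mom$W[, "y0"],
                                  theta = mom$W[, "outcrosser"] + mom$W[, "selfer"])
         else matrix(1, nrow(mom$W), 1L, dimnames = list(NULL, "theta"))
    return(X)
  }
  X <- mom$W[, c("outcrosser", "selfer"), drop = FALSE]
  if (estimate_root) return(cbind(y0 = mom$W[, "y0"], X))
  X[, root_state + 1L] <- X[, root_state + 1L] + mom$W[, "y0"]
  X
}

# standard errors of the optima from the observed information matrix of
# (theta..., [y0,] log alpha, log v), by central finite differences of the
# exact log-likelihood; NULL when the information matrix is not positive
# definite over the optima block (caller falls back to the GLS SEs)
ou_information_se <- function(tree, y, painting, model, beta, alpha, v,
                              estimate_root) {
  th_names <- names(beta)
  nb <- length(beta)
  par <- c(beta, log(alpha), log(v))
  fn <- function(p) {
    b <- p[seq_len(nb)]
    names(b) <- th_names
    theta <- if (model == "OU1") c(outcrosser = unname(b[["theta"]]),
                                   selfer = unname(b[["theta"]]))
             else c(outcrosser = unname(b[["outcrosser"]]),
                    selfer = unname(b[["selfer"]]))
    y0 <- if (estimate_root) unname(b[["y0"]]) else NULL
    tryCatch(model_loglik(tree, y, painting, "OU2",
                          list(alpha = exp(p[nb + 1L]), v = exp(p[nb + 2L]),
                               theta = theta, y0 = y0)),
             error = function(e) NA_real_)
  }
  np <- length(par)
  eps <- 1e-4 * pmax(abs(par), 1)
  H <- matrix(0, np, np)
  for (i in seq_len(np)) for (j in i:np) {
    ei <- ej <- numeric(np); ei[i] <- eps[i]; ej[j] <- eps[j]
    H[i, j] <- H[j, i] <- (fn(par + ei + ej) - fn(par + ei - ej) -
                             fn(par - ei + ej) + fn(par - ei - ej)) /
      (4 * eps[i] * eps[j])
  }
  if (anyNA(H)) return(NULL)
  V <- tryCatch(solve(-H), error = function(e) NULL)
  if (is.null(V)) return(NULL)
  d <- diag(V)[seq_len(nb)]
  if (any(!is.finite(d)) || any(d <= 0)) return(NULL)
  stats::setNames(sqrt(d), th_names)
}

#' Fit an adaptation model to tip traits on a painted tree
#'
#' BM is fit analytically by GLS. For the OU models the rate of adaptation is
#' profiled by a deterministic 1-D search over the phylogenetic half-life on
#' a 50-point log grid spanning `[1e-4, 10] x` tree height, refined by
#' golden-section search; the optima (and root value, if estimated) are
#' profiled by GLS and the stationary variance analytically. By default the
#' root trait value is tied to the optimum of the root regime, giving
#' `k = 2` (BM: ancestral mean, rate), `3` (OU1: optimum, alpha, v) and `4`
#' (OU2: two optima, alpha, v); `estimate_root = TRUE` adds the root value as
#' a free parameter.
#'
#' @inheritParams model_loglik
#' @param estimate_root free root value instead of tying it to the root
#'   regime's optimum.
#' @param grid_size number of half-life grid points.
#' @return an object of class `adaptation_fit`: parameter estimates with
#'   optima standard errors, derived half-life and stationary variance,
#'   log-likelihood, `k`, `n`, AICc, GLS r-squared and a boundary flag.
#' @export
fit_model <- function(tree, trait, painting = NULL,
                      model = c("BM", "OU1", "OU2"),
                      estimate_root = FALSE, grid_size = 50L) {
  stopifnot_phylo(tree)
  model <- match.arg(model)
  y <- trait[tree$tip.label]
  if (anyNA(y)) stop("trait missing for some tips")
  n <- length(y)
  if (n < 6L) stop("at least 6 tips are required for model fitting")
  height <- max(node_depths(tree)[seq_len(n)])

  if (model == "BM") {
    V0 <- bm_tip_covariance(tree)
    g <- gls_profile(y, matrix(1, n, 1L, dimnames = list(NULL, "mu")), V0)
    k <- 2L
    fit <- list(model = "BM", alpha = NA_real_, sigma2 = g$vhat,
                v = NA_real_, t_half = NA_real_, t_half_frac = NA_real_,
                theta = c(mu = g$beta[1L]),
                theta_se = c(mu = sqrt(g$cov_unit[1L, 1L] * g$vhat)),
                estimate_root = estimate_root, loglik = g$loglik,
                k = k, n = n, aicc = aicc(g$loglik, k, n),
                r2 = 1 - g$rss / g$tss, boundary = FALSE, height = height)
    class(fit) <- "adaptation_fit"
    return(fit)
  }

  if (is.null(painting)) stop("OU models require a regime painting")
  es <- edge_states(tree, painting)
  if (model == "OU2" && length(unique(es)) < 2L)
    stop("OU2 requires both regimes present in the painting")

  cache <- ou_cache(tree, painting)
  profile_ll <- function(log_thalf) {
    alpha <- log(2) / exp(log_thalf)
    mom <- ou_moments_from_cache(cache, alpha)
    X <- ou_design(mom, painting, tree, model, estimate_root)
    g <- tryCatch(gls_profile(y, X, mom$V0), error = function(e) NULL)
    if (is.null(g)) return(list(loglik = -Inf))
    c(g, list(alpha = alpha, X = X))
  }
  grid <- seq(log(1e-4 * height), log(10 * height), length.out = grid_size)
  ll <- vapply(grid, function(g) profile_ll(g)$loglik, numeric(1))
  ibest <- which.max(ll)
  lo <- grid[max(1L, ibest - 1L)]
  hi <- grid[min(length(grid), ibest + 1L)]
  opt <- stats::optimize(function(g) profile_ll(g)$loglik, c(lo, hi), maximum = TRUE)
  best_log_thalf <- if (opt$objective >= ll[ibest]) opt$maximum else grid[ibest]
  g <- profile_ll(best_log_thalf)
  boundary <- ibest %in% c(1L, length(grid))
  alpha <- g$alpha
  v <- g$vhat
  beta <- g$beta
  names(beta) <- colnames(g$X)
  se_gls <- sqrt(diag(g$cov_unit) * v)
  names(se_gls) <- colnames(g$X)
  # optima SEs from the observed information of (theta, log alpha, log v):
  # the conditional GLS covariance ignores the uncertainty in alpha, which
  # matters when a regime occupies only short terminal branches
  se <- ou_information_se(tree, y, painting, model, beta, alpha, v,
                          estimate_root) %||% se_gls
  k <- if (model == "OU1") 3L else 4L
  if (estimate_root) k <- k + 1L
  dq <- derived_quantities(alpha, 2 * alpha * v, height)
  fit <- list(model = model, alpha = alpha, sigma2 = 2 * alpha * v,
              v = v, t_half = dq$t_half, t_half_frac = dq$t_half_frac,
              theta = beta, theta_se = se, theta_se_gls = se_gls,
              estimate_root = estimate_root, loglik = g$loglik,
              k = k, n = n, aicc = aicc(g$loglik, k, n),
              r2 = 1 - g$rss / g$tss, boundary = boundary, height = height)
  class(fit) <- "adaptation_fit"
  fit
}

#' @export
print.adaptation_fit <- function(x, ...) {
  cat(sprintf("%s fit: lnL=%.4f k=%d AICc=%.4f r2=%.3f%s\n", x$model,
              x$loglik, x$k, x$aicc, x$r2,
              if (x$boundary) " [half-life grid boundary]" else ""))
  if (x$model != "BM")
    cat(sprintf("  alpha=%.5g  t1/2=%.5g (%.3g%% of height)  v=%.5g\n",
                x$alpha, x$t_half, 100 * x$t_half_frac, x$v))
  est <- paste(sprintf("%s=%.4g+/-%.3g", names(x$theta), x$theta, x$theta_se),
               collapse = "  ")
  cat(" ", est, "\n")
  invisible(x)
}

#' Phylogenetic half-life and stationary variance
#'
#' `t1/2 = ln 2 / alpha` is the time for the expected trait to move halfway
#' to its optimum; `v = sigma^2 / (2 alpha)` is the equilibrium among-species
#' variance within a niche.
#'
#' @param alpha rate of adaptation (> 0).
#' @param sigma2 diffusion variance per unit branch length.
#' @param height optional tree height, to express the half-life as a
#'   fraction of it.
#' @return list with `t_half`, `v`, and `t_half_frac` (NA without `height`).
#' @export
derived_quantities <- function(alpha, sigma2, height = NULL) {
  if (alpha <= 0) stop("alpha must be > 0")
  t_half <- log(2) / alpha
  list(t_half = t_half, v = sigma2 / (2 * alpha),
       t_half_frac = if (is.null(height)) NA_real_ else t_half / height)
}

#' Rank fitted models by AICc with the two-unit rule
#'
#' Accepts either a list of `adaptation_fit` objects (fitted to the same
#' data) or a named numeric vector of AICc values. Models within 2 AICc
#' units of the best form the "indistinguishable set" -- the conventional
#' threshold below which models are not considered significantly different.
#' Exact ties are ordered by model simplicity (fewest parameters first).
#'
#' @param fits list of `adaptation_fit` objects or named AICc vector.
#' @param threshold indistinguishability margin in AICc units (default 2).
#' @return data.frame sorted by AICc with `model`, `aicc`, `delta_aicc`,
#'   `indistinguishable`; attributes `best` (model name) and
#'   `margin` (AICc gap between best and runner-up).
#' @export
compare_models <- function(fits, threshold = 2) {
  if (is.numeric(fits)) {
    a <- fits
    kmap <- c(BM = 2, OU1 = 3, OU2 = 4)
    k <- unname(kmap[names(a)])
    k[is.na(k)] <- seq_along(a)[is.na(k)]
  } else {
    a <- vapply(fits, `[[`, numeric(1), "aicc")
    names(a) <- vapply(fits, `[[`, character(1), "model")
    k <- vapply(fits, `[[`, numeric(1), "k")
  }
  ord <- order(a, k)
  out <- data.frame(model = names(a)[ord], aicc = unname(a[ord]),
                    delta_aicc = unname(a[ord] - min(a)))
  out$indistinguishable <- out$delta_aicc <= threshold
  attr(out, "best") <- out$model[1L]
  attr(out, "margin") <- if (nrow(out) > 1L) out$delta_aicc[2L] else NA_real_
  out
}

#' Fit the BM/OU1/OU2 ladder for every trait column
#'
#' Replicates the repeat-class model-selection table layout: one row per
#' trait with the three AICc values, the best model, the margin to the
#' runner-up, and the OU2 half-life, stationary variance, per-regime optima
#' with standard errors and r-squared.
#'
#' @param tree a `phylo` object.
#' @param traits data.frame with a `taxon` column and one numeric column per
#'   trait.
#' @param painting a [regime_painting].
#' @param estimate_root passed to [fit_model()].
#' @return list with `table` (one summary row per trait) and `fits` (nested
#'   list of the underlying `adaptation_fit` objects).
#' @export
adaptation_table <- function(tree, traits, painting, estimate_root = FALSE) {
  stopifnot(is.data.frame(traits), "taxon" %in% names(traits))
  cols <- setdiff(names(traits), "taxon")
  fits <- list()
  rows <- lapply(cols, function(cn) {
    y <- stats::setNames(traits[[cn]], traits$taxon)
    f <- list(BM = fit_model(tree, y, painting, "BM", estimate_root),
              OU1 = fit_model(tree, y, painting, "OU1", estimate_root),
              OU2 = fit_model(tree, y, painting, "OU2", estimate_root))
    fits[[cn]] <<- f
    cmp <- compare_models(f)
    ou2 <- f$OU2
    data.frame(trait = cn,
               aicc_bm = f$BM$aicc, aicc_ou1 = f$OU1$aicc, aicc_ou2 = f$OU2$aicc,
               best = attr(cmp, "best"), margin = attr(cmp, "margin"),
               indistinguishable = paste(cmp$model[cmp$indistinguishable],
                                         collapse = "+"),
               t_half = ou2$t_half, v = ou2$v,
               theta_out = ou2$theta[["outcrosser"]],
               theta_out_se = ou2$theta_se[["outcrosser"]],
               theta_self = ou2$theta[["selfer"]],
               theta_self_se = ou2$theta_se[["selfer"]],
               r2 = ou2$r2)
  })
  list(table = do.call(rbind, rows), fits = fits)
}
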