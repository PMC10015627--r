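#' Run the full comparative pipeline from a configuration
#'
#' Orchestrates the stages -- simulate (fixture mode) or load inputs, regime
#' inference, ancestral genome-size reconstruction, adaptation-model
#' selection, gene-family turnover, parallel classification and enrichment
#' -- writing per-stage plain-text outputs, a `manifest.json` and a
#' `report.md` into `outdir`. Runs are deterministic: identical
#' (config, seed) pairs produce byte-identical tables.
#'
#' @param config a named list or path to a YAML file with entries:
#'   `outdir` (required); either `fixture = TRUE` (+ optional `seed`,
#'   default 1) or paths `tree`, `traits`, `regimes`, `families`;
#'   optional `stages` (character subset of `c("regimes", "ancestral",
#'   "adapt", "turnover")`), `genome_size_trait` (column name, default
#'   first trait column), `n_lambdas` (default 1), `q_threshold`
#'   (default 0.01), `aicc_rule` (default 2), `mc_replicates`
#'   (default 1000).
#' @return invisibly, a list with the per-stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(
    list(fixture = FALSE, seed = 1L,
         stages = c("regimes", "ancestral", "adapt", "turnover"),
         genome_size_trait = NULL, n_lambdas = 1L,
         q_threshold = 0.01, aicc_rule = 2, mc_replicates = 1000L,
         n_families = 1000L),
    config)
  if (is.null(cfg$outdir)) stop("config must name an `outdir`")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  out <- list()

  inputs <- stage("inputs", {
    if (isTRUE(cfg$fixture)) {
      fx <- make_study_fixture(cfg$seed, n_families = cfg$n_families)
      tips <- fx$tree$tip.label
      list(tree = fx$tree,
           traits = fx$traits,
           regimes = stats::setNames(fx$painting$node_state[seq_along(tips)], tips),
           families = fx$families)
    } else {
      for (p in c("tree", "traits", "regimes", "families"))
        if (is.null(cfg[[p]]) || !file.exists(cfg[[p]]))
          stop("missing input file for `", p, "`: ", cfg[[p]] %||% "(unset)")
      list(tree = read_newick(file = cfg$tree),
           traits = read_trait_table(cfg$traits),
           regimes = read_regimes(cfg$regimes),
           families = read_families(cfg$families))
    }
  })
  tree <- inputs$tree

  if ("regimes" %in% cfg$stages) {
    out$regimes <- stage("regimes", {
      lad <- fit_mk_ladder(tree, inputs$regimes)
      best <- lad$fits[[lad$best]]
      painting <- paint_regimes(best$marginals, tree, inputs$regimes)
      jsonlite::write_json(
        lapply(lad$fits, function(f)
          list(model = f$model, q01 = f$q01, q10 = f$q10,
               loglik = f$loglik, k = f$k, aicc = f$aicc)),
        file.path(cfg$outdir, "mk_fits.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
      write_painting(painting, tree, file.path(cfg$outdir, "painting.tsv"))
      list(ladder = lad, painting = painting)
    })
  }
  painting <- out$regimes$painting

  if ("ancestral" %in% cfg$stages) {
    out$ancestral <- stage("ancestral", {
      gcol <- cfg$genome_size_trait %||% setdiff(names(inputs$traits), "taxon")[1L]
      y <- stats::setNames(inputs$traits[[gcol]], inputs$traits$taxon)
      anc <- reconstruct_ancestral_bm(tree, y)
      attr(anc, "root_node") <- root_node(tree)
      write_tsv_stable(as.data.frame(anc), file.path(cfg$outdir, "ancestral.tsv"))
      jsonlite::write_json(
        list(trait = gcol, sigma2_reml = attr(anc, "sigma2"),
             log_restricted_lik = attr(anc, "log_restricted_lik"),
             tree = tree_summary(tree)),
        file.path(cfg$outdir, "ancestral_summary.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      anc
    })
  }

  if ("adapt" %in% cfg$stages) {
    out$adapt <- stage("adapt", {
      if (is.null(painting)) stop("adaptation models need the regimes stage")
      at <- adaptation_table(tree, inputs$traits, painting)
      write_tsv_stable(at$table, file.path(cfg$outdir, "model_table.tsv"))
      at
    })
  }

  if ("turnover" %in% cfg$stages) {
    out$turnover <- stage("turnover", {
      if (is.null(painting)) stop("turnover needs the regimes stage")
      tu_tree <- tree
      if (!is_binary_rooted(tu_tree)) tu_tree <- resolve_polytomies(tu_tree)
      if (!is_ultrametric(tu_tree)) tu_tree <- make_ultrametric(tu_tree)
      fit <- fit_turnover(tu_tree, inputs$families, painting,
                          n_lambdas = cfg$n_lambdas)
      sig <- family_significance(fit, M = cfg$mc_replicates,
                                 seed = cfg$seed + 17L)
      sig_ids <- sig$family[sig$q < cfg$q_threshold]
      ch <- reconstruct_changes(fit)
      cls <- classify_parallel(ch, tu_tree, painting, significant = sig_ids)
      stats_tab <- merge(sig, cls, by = "family", all.x = TRUE, sort = FALSE)
      stats_tab$category[is.na(stats_tab$category)] <- "NotSignificant"
      stats_tab <- stats_tab[order(stats_tab$family), ]
      ev <- branch_events(
        list(delta = ch$delta[rownames(ch$node_counts) %in% sig_ids, , drop = FALSE]),
        tu_tree)
      enr <- lapply(split(cls$category, cls$category), length)
      fish <- if (nrow(cls)) {
        n_dec <- sum(cls$category == "DecreasingInSelfers")
        tab <- matrix(c(n_dec, nrow(cls) - n_dec,
                        sum(fit$flags) - n_dec,
                        max(0L, length(fit$flags) - sum(fit$flags))), 2L, 2L)
        fisher_enrichment(tab)
      } else NULL
      jsonlite::write_json(
        list(lambda = as.list(stats::setNames(fit$lambda, paste0("class", seq_along(fit$lambda)))),
             eps = fit$eps, loglik = fit$loglik, aicc = fit$aicc,
             n_families = fit$n, n_significant = length(sig_ids),
             category_counts = enr,
             decreasing_in_selfers_fisher = fish),
        file.path(cfg$outdir, "turnover.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
      write_tsv_stable(stats_tab, file.path(cfg$outdir, "family_stats.tsv"))
      write_tsv_stable(ev, file.path(cfg$outdir, "branch_events.tsv"))
      list(fit = fit, significance = sig, significant = sig_ids,
           changes = ch, classification = cls, events = ev)
    })
  }

  stage("report", {
    jsonlite::write_json(
      list(package = "phyloregime",
           version = as.character(utils::packageVersion("phyloregime")),
           seed = cfg$seed,
           config = cfg[setdiff(names(cfg), "stages")],
           stages = cfg$stages),
      file.path(cfg$outdir, "manifest.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    writeLines(pipeline_report(cfg, out), file.path(cfg$outdir, "report.md"))
  })
  invisible(out)
}

pipeline_report <- function(cfg, out) {
  lines <- c("# phyloregime pipeline report", "",
             sprintf("Seed: %d", cfg$seed), "")
  if (!is.null(out$regimes)) {
    t <- out$regimes$ladder$table
    lines <- c(lines, "## Regime inference (Mk model ladder)", "",
               paste(utils::capture.output(print(t, row.names = FALSE)), collapse = "\n"),
               sprintf("\nBest model: %s; %d branches painted selfer.",
                       out$regimes$ladder$best,
                       sum(out$regimes$painting$node_state == 1L)), "")
  }
  if (!is.null(out$ancestral)) {
    rr <- which(out$ancestral$node == attr(out$ancestral, "root_node"))
    lines <- c(lines, "## Ancestral genome size (BM, REML)", "",
               sprintf("sigma2_REML = %.6g; root estimate %.4g [%.4g, %.4g] (95%% CI).",
                       attr(out$ancestral, "sigma2"),
                       out$ancestral$mean[rr], out$ancestral$ci_low[rr],
                       out$ancestral$ci_high[rr]), "")
  }
  if (!is.null(out$adapt)) {
    lines <- c(lines, "## Adaptation-model selection (BM / OU1 / OU2)", "",
               paste(utils::capture.output(print(out$adapt$table, row.names = FALSE)),
                     collapse = "\n"), "")
  }
  if (!is.null(out$turnover)) {
    tab <- table(out$turnover$classification$category)
    lines <- c(lines, "## Gene-family turnover", "",
               sprintf("lambda = %s; %d/%d families significant at q < %g.",
                       paste(signif(out$turnover$fit$lambda, 5), collapse = "/"),
                       length(out$turnover$significant), out$turnover$fit$n,
                       cfg$q_threshold),
               if (length(tab)) paste(sprintf("- %s: %d", names(tab), as.integer(tab)),
                                      collapse = "\n") else "- no significant families", "")
  }
  lines
}
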