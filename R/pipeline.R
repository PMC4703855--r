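#' Full localization-stability analysis of one network
#'
#' Runs the whole chain — parametrization, eigen-analysis, null-model
#' ensembles and perturbation amplitude — and assembles a one-row record.
#' All null statistics for a given model come from the same ensemble pass,
#' so the localization and attenuation classifications can never drift
#' apart.
#'
#' @param net A [bipartite_network()].
#' @param cfg A [param_config()].
#' @param models Character subset of `c("NM1", "NM2")`.
#' @param n_null Null realizations per model.
#' @param seed Optional integer seed (defaults to `cfg$seed`).
#' @param network_id Identifier stored in the record.
#' @param perturbation_kind Pulse type for the amplitude statistic.
#' @return One-row tibble with topology (`S`, `A`, `P`, `L`, `C`), strength
#'   variance `sigma_s2`, spectral summaries (`lambda1`, `lambdaH`, raw
#'   IPRs, localized counts), and per-model relative statistics
#'   `ripr_<vec>_<model>` / `rel_A1_<model>` with empirical p-values
#'   (`..._p`).
#' @examples
#' net <- powerlaw_bipartite(20, 12, 2.2, seed = 1)
#' rec <- analyze_network(net, param_config(seed = 1), n_null = 20)
#' rec$ripr_v1_NM1
#' @export
analyze_network <- function(net, cfg = param_config(),
                            models = c("NM1", "NM2"), n_null = 1000,
                            seed = NULL, network_id = "net",
                            perturbation_kind = "all") {
  stopifnot(inherits(net, "bipartite_network"))
  models <- match.arg(models, c("NM1", "NM2"), several.ok = TRUE)
  seed <- seed %||% cfg$seed
  s <- network_summary(net)
  W <- interaction_matrix(net, cfg)
  x_obs <- with_seed_(seed, draw_xstar(s$S, cfg))
  sp <- suppressWarnings(spectral_summary(community_matrix(W, x_obs)))
  g <- glance(sp)

  rec <- tibble(
    network_id = network_id,
    S = s$S, A = s$A, P = s$P, L = s$L, C = s$C,
    sigma_s2 = stats::var(W$strengths),
    lambda1 = g$lambda1, lambdaH = g$lambdaH,
    ipr_v1 = g$ipr_v1, ipr_u1 = g$ipr_u1, ipr_wH = g$ipr_wH,
    n_localized_v1 = g$n_localized_v1,
    n_localized_u1 = g$n_localized_u1,
    n_localized_wH = g$n_localized_wH
  )

  for (model in models) {
    res <- ensemble_statistics(
      net, cfg, model = model,
      stats = c("ipr_v1", "ipr_u1", "ipr_wH", "amplitude_A1"),
      n = n_null, seed = derive_seed(seed, match(model, c("NM1", "NM2"))),
      perturbation_kind = perturbation_kind
    )
    for (vec in c("v1", "u1", "wH")) {
      stat <- paste0("ipr_", vec)
      ne <- new_null_ensemble(stat, res$observed[[stat]],
                              res$null_values[, stat], model, n_null,
                              seed, "greater")
      rec[[paste0("ripr_", vec, "_", model)]] <- ne$ratio
      rec[[paste0("ripr_", vec, "_", model, "_p")]] <- ne$p_value
      rec[[paste0("ripr_", vec, "_", model, "_null_sd_ratio")]] <-
        ne$null_sd / ne$null_mean
    }
    na <- new_null_ensemble("amplitude_A1", res$observed[["amplitude_A1"]],
                            res$null_values[, "amplitude_A1"], model,
                            n_null, seed, "less")
    rec[[paste0("A1_", model)]] <- na$observed
    rec[[paste0("rel_A1_", model)]] <- na$ratio
    rec[[paste0("rel_A1_", model, "_p")]] <- na$p_value
    rec[[paste0("rel_A1_", model, "_null_sd_ratio")]] <-
      na$null_sd / na$null_mean
  }
  rec
}

#' Corpus-level Spearman correlations
#'
#' Rank correlations between network-level topological properties
#' (size `S`, connectance `C`, strength variance `sigma_s2`, resilience
#' `lambda1`) and the relative localization / attenuation statistics, over a
#' corpus of analyzed networks. Pairs with a constant column are flagged in
#' the `note` column rather than dropped.
#'
#' @param records Tibble of rows from [analyze_network()], at least 5.
#' @param model Which null model's relative statistics to correlate.
#' @return Tibble with columns `x`, `y`, `rho`, `p_value`, `n`, `note`.
#' @export
corpus_correlations <- function(records, model = "NM1") {
  if (nrow(records) < 5) abort("need at least 5 network records")
  pick <- function(stub) paste0(stub, "_", model)
  pairs <- list(
    c("S", pick("ripr_v1")), c("S", pick("ripr_u1")), c("S", pick("ripr_wH")),
    c("C", pick("ripr_v1")), c("C", pick("ripr_u1")), c("C", pick("ripr_wH")),
    c("S", pick("rel_A1")), c("C", pick("rel_A1")),
    c("lambda1", pick("rel_A1")),
    c("lambda1", pick("ripr_v1")), c("lambda1", pick("ripr_u1")),
    c("lambda1", pick("ripr_wH")),
    c("sigma_s2", pick("ripr_u1")), c("sigma_s2", pick("ripr_v1"))
  )
  pairs <- purrr::keep(pairs, ~ all(.x %in% names(records)))
  purrr::map_dfr(pairs, function(p) spearman_row(records[[p[1]]],
                                                 records[[p[2]]],
                                                 p[1], p[2]))
}

spearman_row <- function(x, y, xn, yn, exact_below = 10) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3 || length(unique(x[ok])) < 2 || length(unique(y[ok])) < 2) {
    return(tibble(x = xn, y = yn, rho = NA_real_, p_value = NA_real_,
                  n = n, note = "constant or insufficient data"))
  }
  ct <- suppressWarnings(
    cor.test(x[ok], y[ok], method = "spearman", exact = n < exact_below)
  )
  tibble(x = xn, y = yn, rho = unname(ct$estimate),
         p_value = ct$p.value, n = n, note = NA_character_)
}

#' Species-level centrality correlations
#'
#' Correlates the per-species leading eigenvector magnitudes (`|v1|`,
#' `|u1|`, `|wH|`) with four centralities of the weighted mutualistic graph:
#' degree, strength (weighted degree), eigenvector centrality and PageRank
#' (damping 0.85). Centralities are computed on the undirected graph whose
#' edge weights symmetrize the off-diagonal interaction weights by the
#' pairwise maximum.
#'
#' @param net A [bipartite_network()].
#' @param cfg A [param_config()].
#' @param seed Optional seed for the abundance draw (defaults to
#'   `cfg$seed`).
#' @return Tibble with one row per (eigenvector, centrality) pair:
#'   `x` (centrality), `y` (eigenvector), `rho`, `p_value`, `n`, `note`.
#' @export
node_centrality_correlations <- function(net, cfg = param_config(),
                                         seed = NULL) {
  stopifnot(inherits(net, "bipartite_network"))
  W <- interaction_matrix(net, cfg)
  S <- nrow(W$W)
  x_obs <- with_seed_(seed %||% cfg$seed, draw_xstar(S, cfg))
  sp <- suppressWarnings(spectral_summary(community_matrix(W, x_obs)))
  Wsym <- pmax(W$W, t(W$W))
  diag(Wsym) <- 0
  g <- igraph::graph_from_adjacency_matrix(Wsym, mode = "undirected",
                                           weighted = TRUE)
  cent <- list(
    degree = as.numeric(degrees(net)),
    strength = as.numeric(W$strengths),
    eigen_centrality = igraph::eigen_centrality(g)$vector,
    pagerank = igraph::page_rank(g, damping = 0.85)$vector
  )
  vecs <- list(v1 = abs(sp$v1), u1 = abs(sp$u1), wH = abs(sp$wH))
  purrr::map_dfr(names(cent), function(cn) {
    purrr::map_dfr(names(vecs), function(vn) {
      spearman_row(cent[[cn]], as.numeric(vecs[[vn]]), cn, vn)
    })
  })
}

#' Analyze a corpus of networks
#'
#' Maps [analyze_network()] over a list of networks (or incidence-file
#' paths) with stable per-network seeds derived from the corpus seed, and
#' summarizes the corpus: the records table, the corpus-level Spearman
#' correlations, and a census of localization (`rIPR > 1`, p < 0.05) and
#' attenuation (`rel A1 < 1`, p < 0.05) fractions per null model and
#' eigenvector.
#'
#' @param nets List of [bipartite_network()] objects and/or file paths
#'   readable by [read_incidence()].
#' @param cfg A [param_config()].
#' @param models Null models to run.
#' @param n_null Null realizations per model per network.
#' @param seed Corpus seed; network `i` runs under `derive_seed(seed, i)`.
#' @param output_dir Optional directory; when given, writes `records.csv`,
#'   `correlations.csv` and `census.json`.
#' @param alpha Significance level of the census (default 0.05).
#' @return List with `records` (tibble), `correlations` (tibble, one set
#'   per model), `census` (tibble), and `failures` (tibble of networks that
#'   errored; the run continues past individual failures).
#' @export
run_corpus <- function(nets, cfg = param_config(),
                       models = c("NM1", "NM2"), n_null = 1000,
                       seed = NULL, output_dir = NULL, alpha = 0.05) {
  if (length(nets) == 0) abort("empty corpus")
  ids <- names(nets) %||% rep(NA_character_, length(nets))
  results <- purrr::imap(nets, function(net, i) {
    idx <- if (is.character(i)) match(i, names(nets)) else i
    id <- if (is.character(i) && nzchar(i)) {
      i
    } else if (is.character(net)) {
      basename(net)
    } else {
      paste0("net", idx)
    }
    tryCatch({
      if (is.character(net)) net <- read_incidence(net)
      analyze_network(net, cfg, models = models, n_null = n_null,
                      seed = derive_seed(seed %||% cfg$seed %||% 0, idx),
                      network_id = id)
    }, error = function(e) {
      warn(sprintf("network '%s' failed: %s", id, conditionMessage(e)))
      tibble(network_id = id, error = conditionMessage(e))
    })
  })
  ok <- purrr::map_lgl(results, ~ !"error" %in% names(.x))
  records <- dplyr::bind_rows(results[ok])
  failures <- dplyr::bind_rows(results[!ok])
  correlations <- if (nrow(records) >= 5) {
    purrr::map_dfr(models, function(m) {
      dplyr::mutate(corpus_correlations(records, model = m), model = m)
    })
  } else {
    tibble()
  }
  census <- corpus_census(records, models = models, alpha = alpha)
  out <- list(records = records, correlations = correlations,
              census = census, failures = failures)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(records, file.path(output_dir, "records.csv"))
    if (nrow(correlations)) {
      readr::write_csv(correlations, file.path(output_dir, "correlations.csv"))
    }
    jsonlite::write_json(census, file.path(output_dir, "census.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Localization and attenuation census
#'
#' Fractions of networks classified as localized (`rIPR > 1` with empirical
#' p below `alpha`) per eigenvector, and as attenuating (`rel A1 < 1` with
#' p below `alpha`), for each null model.
#'
#' @param records Records tibble from [analyze_network()]/[run_corpus()].
#' @param models Null models present in the records.
#' @param alpha Significance level.
#' @return Tibble with columns `model`, `quantity`, `fraction`, `n`.
#' @export
corpus_census <- function(records, models = c("NM1", "NM2"), alpha = 0.05) {
  if (nrow(records) == 0) return(tibble())
  purrr::map_dfr(models, function(m) {
    rows <- purrr::map_dfr(c("v1", "u1", "wH"), function(vec) {
      r <- records[[paste0("ripr_", vec, "_", m)]]
      p <- records[[paste0("ripr_", vec, "_", m, "_p")]]
      tibble(model = m, quantity = paste0("localized_", vec),
             fraction = mean(r > 1 & p < alpha), n = length(r))
    })
    ra <- records[[paste0("rel_A1_", m)]]
    pa <- records[[paste0("rel_A1_", m, "_p")]]
    dplyr::bind_rows(rows, tibble(
      model = m, quantity = "attenuated_A1",
      fraction = mean(ra < 1 & pa < alpha), n = length(ra)
    ))
  })
}
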