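#' Selection-frequency experiment on random multistep networks
#'
#' Draws a random M-state network of true order `h_true`, repeatedly samples
#' sets of J trajectories from it, evaluates the selection criteria for each
#' candidate order, and tabulates how often each candidate is selected by
#' each criterion.  `network_mode = "fixed_network"` (the default) draws one
#' network and resamples trajectory sets from it; `"fresh_network"` redraws
#' the network every replicate, which spreads the selection frequencies
#' across the network distribution.
#'
#' @param M number of states (>= 3).
#' @param h_true true memory order of the generating network.
#' @param J trajectories per replicate.
#' @param h_candidates candidate orders to select among (default 0:5).
#' @param replicates number of replicates (default 2000).
#' @param seed integer seed for the whole experiment.
#' @param network_mode `"fixed_network"` or `"fresh_network"`.
#' @param criteria criteria to tabulate (default all except LHO-less cases;
#'   see [evaluate_all()]).
#' @param k_mode AIC/BIC parameter counting (default `"literal"`).
#' @param max_len trajectory length cap passed to the sampler.
#' @return A `"selection_table"`: numeric matrix criteria x candidates of
#'   selection fractions (rows sum to 1), with experiment metadata attached
#'   as attributes (`h_true`, `J`, `M`, `replicates`, `seed`,
#'   `network_mode`).
#' @export
selection_experiment <- function(M, h_true, J, h_candidates = 0:5,
                                 replicates = 2000, seed = 1,
                                 network_mode = c("fixed_network",
                                                  "fresh_network"),
                                 criteria = criterion_names,
                                 k_mode = "literal", max_len = 1e6) {
  network_mode <- match.arg(network_mode)
  if (replicates < 1) stop("replicates must be >= 1")
  set.seed(seed)
  net <- generate_network(M, h_true)
  specs <- lapply(h_candidates, function(h) memory_spec(order = h))
  tally <- matrix(0L, nrow = length(criteria), ncol = length(h_candidates),
                  dimnames = list(criteria, paste0("h=", h_candidates)))
  for (r in seq_len(replicates)) {
    if (network_mode == "fresh_network") net <- generate_network(M, h_true)
    trajs <- sample_trajectories(net, J, max_len = max_len)
    rep_df <- evaluate_all(trajs, specs, k_mode = k_mode, criteria = criteria,
                           pad = net$start)
    for (cr in criteria) {
      sel <- select_model(rep_df, cr)
      tally[cr, paste0("h=", sel$order)] <- tally[cr, paste0("h=", sel$order)] + 1L
    }
  }
  structure(tally / replicates, h_true = h_true, J = J, M = M,
            replicates = replicates, seed = seed, network_mode = network_mode,
            class = c("selection_table", "matrix"))
}

#' @export
print.selection_table <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Selection frequencies (%d replicates%s)\n", attr(x, "replicates"),
    if (!is.null(attr(x, "h_true")))
      sprintf(", h_true = %d, J = %d, M = %d", attr(x, "h_true"),
              attr(x, "J"), attr(x, "M"))
    else ""))
  print(round(unclass(x), digits))
  invisible(x)
}

#' Distributions of criteria relative to the true model
#'
#' For each replicate, computes `Delta Criterion(h) = Criterion(h) -
#' Criterion(h_true)` for every candidate order and criterion; positive
#' values mean the true order is favoured over h.
#'
#' @inheritParams selection_experiment
#' @return A `"delta_distribution"`: list with `delta` (per criterion, a
#'   replicates x candidates matrix of differences) and `summary` (min /
#'   mean / max per criterion and candidate), plus metadata attributes.
#' @export
delta_experiment <- function(M, h_true, J, h_candidates = 0:5,
                             replicates = 2000, seed = 1,
                             criteria = criterion_names,
                             k_mode = "literal", max_len = 1e6) {
  if (!(h_true %in% h_candidates)) stop("h_true must be among h_candidates")
  set.seed(seed)
  net <- generate_network(M, h_true)
  specs <- lapply(h_candidates, function(h) memory_spec(order = h))
  true_col <- match(h_true, h_candidates)
  delta <- lapply(stats::setNames(criteria, criteria), function(cr)
    matrix(NA_real_, replicates, length(h_candidates),
           dimnames = list(NULL, paste0("h=", h_candidates))))
  for (r in seq_len(replicates)) {
    trajs <- sample_trajectories(net, J, max_len = max_len)
    rep_df <- evaluate_all(trajs, specs, k_mode = k_mode, criteria = criteria,
                           pad = net$start)
    for (cr in criteria)
      delta[[cr]][r, ] <- rep_df[[cr]] - rep_df[[cr]][true_col]
  }
  summ <- lapply(delta, function(m)
    rbind(min = apply(m, 2L, min), mean = colMeans(m),
          max = apply(m, 2L, max)))
  structure(list(delta = delta, summary = summ),
            h_true = h_true, J = J, M = M, replicates = replicates,
            seed = seed, class = "delta_distribution")
}

#' @export
print.delta_distribution <- function(x, digits = 2, ...) {
  cat(sprintf("Delta-criterion distributions (h_true = %d, J = %d, M = %d, %d replicates)\n",
              attr(x, "h_true"), attr(x, "J"), attr(x, "M"),
              attr(x, "replicates")))
  for (cr in names(x$summary)) {
    cat(cr, ":\n", sep = "")
    print(round(x$summary[[cr]], digits))
  }
  invisible(x)
}

#' Power analysis of order selection on synthetic free-throw seasons
#'
#' Each replicate simulates a season with [simulate_season()], evaluates the
#' criteria for the candidate orders, and records which order each criterion
#' selects.  With `shuffle = TRUE` every simulated season is passed through
#' [shuffle_within_trajectories()] before evaluation (the shuffle control:
#' per-game outcome multisets kept, serial order destroyed).
#'
#' @param cfg a [freethrow_config()].
#' @param h_candidates candidate orders (default 0:3).
#' @param replicates number of simulated seasons.
#' @param seed integer seed for the whole experiment.
#' @param criteria criteria to tabulate.
#' @param k_mode AIC/BIC parameter counting; `"contexts"` (default) matches
#'   per-season parameter counting (3 parameters for h = 1 with the
#'   first-shot context, 1 for h = 0).
#' @param shuffle apply the within-game shuffle control before evaluating.
#' @return A `"selection_table"` of selection fractions, criteria x
#'   candidates.
#' @export
power_analysis_freethrow <- function(cfg, h_candidates = 0:3,
                                     replicates = 1000, seed = 1,
                                     criteria = criterion_names,
                                     k_mode = "contexts", shuffle = FALSE) {
  if (replicates < 1) stop("replicates must be >= 1")
  set.seed(seed)
  specs <- lapply(h_candidates, function(h) memory_spec(order = h))
  tally <- matrix(0L, nrow = length(criteria), ncol = length(h_candidates),
                  dimnames = list(criteria, paste0("h=", h_candidates)))
  for (r in seq_len(replicates)) {
    season <- simulate_season(cfg)
    if (shuffle) season <- shuffle_within_trajectories(season)
    rep_df <- evaluate_all(season, specs, k_mode = k_mode, criteria = criteria)
    for (cr in criteria) {
      sel <- select_model(rep_df, cr)
      tally[cr, paste0("h=", sel$order)] <- tally[cr, paste0("h=", sel$order)] + 1L
    }
  }
  structure(tally / replicates, cfg = cfg, replicates = replicates,
            seed = seed, shuffled = shuffle,
            class = c("selection_table", "matrix"))
}
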