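#' Fit a Dirichlet-multinomial multistep Markov model
#'
#' The central fitting function.  Counts the transitions of `trajectories`
#' under the requested memory specification and conjugately updates a shared
#' Dirichlet(alpha) prior on each context's transition-probability vector, so
#' the posterior for context x is Dirichlet(alpha + N_x).  No iterative
#' fitting is involved; everything downstream (coefficients, predictions,
#' selection criteria) is closed form.
#'
#' @param trajectories a [trajectory_set()], or a multi-line string /
#'   character vector parsed with `alphabet`.
#' @param order nonnegative integer memory order h (default 1).  Mutually
#'   exclusive with `spec`.
#' @param spec a [memory_spec()], for variable-length (context partition)
#'   models.
#' @param alpha Dirichlet prior vector of length M or scalar; default 1
#'   (uniform prior), `1/2` gives Jeffreys' prior.
#' @param alphabet required when `trajectories` is raw text.
#' @return An object of class `"markov_fit"`: a list with the count table
#'   (`counts`), the spec, prior, posterior parameters, posterior-mean and
#'   maximum-likelihood probability tables, and the plug-in log-likelihoods.
#' @examples
#' ab <- alphabet("-+")
#' fit <- fit_markov("+-++-++\n+--+-+++++-", order = 1, alphabet = ab)
#' coef(fit)                 # posterior-mean transition probabilities
#' coef(fit, "mle")
#' logLik(fit)
#' @seealso [evaluate_all()] to compare candidate orders, [simulate.markov_fit()]
#' @export
fit_markov <- function(trajectories, order = NULL, spec = NULL, alpha = 1,
                       alphabet = NULL) {
  if (!inherits(trajectories, "trajectory_set")) {
    if (is.null(alphabet))
      stop("supply 'alphabet' when 'trajectories' is not a trajectory_set")
    trajectories <- parse_trajectories(trajectories, alphabet)
  }
  if (is.null(spec)) {
    if (is.null(order)) order <- 1L
    spec <- memory_spec(order = order)
  } else if (!is.null(order)) {
    stop("give either 'order' or 'spec', not both")
  }
  counts <- count_transitions(trajectories, spec_base_order(spec))
  if (spec$kind == "partition") counts <- merge_contexts(counts, spec)
  a <- check_alpha(alpha, n_states(trajectories$alphabet))
  pm <- posterior_mean(counts, a)
  ml <- mle(counts)
  structure(list(trajectories = trajectories, counts = counts, spec = spec,
                 alpha = a, posterior = posterior_params(counts, a),
                 post_mean = pm, mle = ml,
                 logLik_mle = log_likelihood(counts, ml),
                 logLik_post_mean = log_likelihood(counts, pm)),
            class = "markov_fit")
}

#' @export
print.markov_fit <- function(x, digits = 4, ...) {
  cat("Dirichlet-multinomial multistep Markov model\n")
  cat("  model:", x$spec$label,
      sprintf(" (M = %d states, J = %d trajectories, %d transitions)\n",
              n_states(x$counts$alphabet), n_trajectories(x$counts),
              total_transitions(x$counts)))
  cat("  posterior-mean transition probabilities:\n")
  print(round(x$post_mean, digits))
  invisible(x)
}

#' @export
summary.markov_fit <- function(object, ...) {
  crit <- criteria_core(object$counts, object$alpha,
                        which = setdiff(criterion_names, "LHO"),
                        k_mode = if (object$counts$merged) "contexts" else "literal")
  structure(list(fit = object, criteria = crit), class = "summary.markov_fit")
}

#' @export
print.summary.markov_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("  log-likelihood (MLE plug-in):", round(x$fit$logLik_mle, digits), "\n")
  cat("  selection criteria (deviance scale):\n")
  v <- unlist(x$criteria[intersect(criterion_names, names(x$criteria))])
  print(round(v, digits))
  invisible(x)
}

#' Extract transition probabilities from a fitted model
#'
#' @param object a [fit_markov()] object.
#' @param type `"posterior_mean"` (default) or `"mle"`.
#' @param ... unused.
#' @return Matrix of transition probabilities, contexts (or blocks) by
#'   states.
#' @export
coef.markov_fit <- function(object, type = c("posterior_mean", "mle"), ...) {
  switch(match.arg(type), posterior_mean = object$post_mean, mle = object$mle)
}

#' @export
logLik.markov_fit <- function(object, ...) {
  k <- sum(rowSums(object$counts$pooled) > 0) *
    (n_states(object$counts$alphabet) - 1)
  structure(object$logLik_mle, df = k, nobs = total_transitions(object$counts),
            class = "logLik")
}

#' Predictive next-state distribution given a recent history
#'
#' Returns the posterior-mean (or MLE) probability vector of the next state
#' for each supplied history.  Histories shorter than the model order are
#' left-padded with the boundary marker; for variable-length models the
#' history's context is mapped to its block.  Histories whose context was
#' never observed fall back to the prior mean (posterior-mean type) or NA
#' (MLE type).
#'
#' @param object a [fit_markov()] object.
#' @param newdata character vector of history strings (possibly empty `""`
#'   for order-0 models or all-boundary histories).
#' @param type `"posterior_mean"` or `"mle"`.
#' @param ... unused.
#' @return Matrix of next-state probabilities, one row per history.
#' @export
predict.markov_fit <- function(object, newdata = "",
                               type = c("posterior_mean", "mle"), ...) {
  type <- match.arg(type)
  ab <- object$counts$alphabet
  M <- n_states(ab)
  h <- spec_base_order(object$spec)
  keys <- vapply(as.character(newdata), function(s) {
    sym <- if (nchar(s)) strsplit(s, "")[[1L]] else character(0L)
    bad <- !(sym %in% c(ab$symbols, ab$boundary))
    if (any(bad)) stop(sprintf("unknown symbol '%s' in history", sym[bad][1L]))
    if (length(sym) > h) sym <- sym[(length(sym) - h + 1L):length(sym)]
    paste(c(rep(ab$boundary, h - length(sym)), sym), collapse = "")
  }, character(1L))
  if (object$spec$kind == "partition") {
    labels <- vapply(object$spec$partition, paste, "", collapse = ",")
    block_of <- rep(labels, lengths(object$spec$partition))
    names(block_of) <- unlist(object$spec$partition, use.names = FALSE)
    mapped <- block_of[keys]
    if (anyNA(mapped))
      stop(sprintf("history context(s) not covered by the partition: %s",
                   paste(unique(keys[is.na(mapped)]), collapse = ", ")))
    keys <- mapped
  }
  tab <- coef(object, type)
  out <- matrix(NA_real_, length(keys), M,
                dimnames = list(unname(keys), ab$symbols))
  idx <- match(keys, rownames(tab))
  hit <- !is.na(idx)
  out[hit, ] <- tab[idx[hit], , drop = FALSE]
  if (type == "posterior_mean" && any(!hit))
    out[!hit, ] <- rep(object$alpha / sum(object$alpha), each = sum(!hit))
  out
}

#' Simulate trajectory sets from a fitted model
#'
#' Draws new trajectories from the fitted chain at its posterior-mean (or
#' MLE) transition probabilities, with histories initialized to boundary
#' padding.  Trajectory lengths are resampled from the observed lengths of
#' the training set (with replacement), mirroring the shape of the data the
#' model was fitted to.
#'
#' @param object a [fit_markov()] object.
#' @param nsim number of trajectory sets to simulate.
#' @param seed optional integer seed.
#' @param type probability table to simulate from.
#' @param ... unused.
#' @return A list of `nsim` [trajectory_set()] objects.
#' @export
simulate.markov_fit <- function(object, nsim = 1, seed = NULL,
                                type = c("posterior_mean", "mle"), ...) {
  type <- match.arg(type)
  if (!is.null(seed)) set.seed(seed)
  ab <- object$counts$alphabet
  h <- spec_base_order(object$spec)
  lens <- lengths(object$trajectories$sequences)
  M <- n_states(ab)
  one_set <- function() {
    seqs <- lapply(sample(lens, length(lens), replace = TRUE), function(L) {
      histo <- rep(ab$boundary, h)
      out <- character(L)
      for (l in seq_len(L)) {
        p <- predict(object, paste(histo, collapse = ""), type = type)[1L, ]
        if (anyNA(p)) p <- rep(1 / M, M)  # MLE of an unobserved context
        s <- ab$symbols[sample.int(M, 1L, prob = p)]
        out[l] <- s
        if (h > 0) histo <- c(histo[-1L][seq_len(h - 1L)], s)
      }
      out
    })
    trajectory_set(seqs, ab)
  }
  replicate(nsim, one_set(), simplify = FALSE)
}
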