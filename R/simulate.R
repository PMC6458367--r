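#' Generate a random multistep network
#'
#' An M-state system with designated start and absorbing states and a true
#' memory order `h_true`: one transition-probability vector per context in
#' `{states}^h_true`, each drawn independently from Dirichlet(1) over all M
#' states (so absorption probability is itself random, and revisiting the
#' start state is allowed).  Histories at the beginning of a trajectory are
#' initialized to `h_true` copies of the start state, so the start state
#' doubles as the boundary condition.
#'
#' @param M number of states (>= 3: start + absorbing + at least one other).
#' @param h_true true memory order; `0` gives a memoryless system with a
#'   single transition vector shared by every step.
#' @param seed optional integer seed.
#' @param symbols optional M single-character state labels; defaults to
#'   letters, with the first the start state and the last absorbing.
#' @return An object of class `"random_network"`: list with `M`, `h`,
#'   `symbols`, `start`, `absorbing`, and `transitions` (an `M^h_true` x M
#'   matrix with context-key rownames).
#' @export
generate_network <- function(M, h_true, seed = NULL, symbols = NULL) {
  if (M < 3) stop("need M >= 3 (start, absorbing and at least one other state)")
  if (h_true < 0) stop("h_true must be a nonnegative integer")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(symbols)) symbols <- letters[seq_len(M)]
  if (length(symbols) != M || anyDuplicated(symbols) || any(nchar(symbols) != 1L))
    stop("symbols must be M distinct single characters")
  if (h_true == 0) {
    keys <- ""
  } else {
    grid <- do.call(expand.grid,
                    c(rep(list(symbols), h_true),
                      list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
    # expand.grid varies the first column fastest; order columns so the key
    # reads oldest-state-first like context keys elsewhere
    keys <- do.call(paste0, rev(grid))
  }
  G <- matrix(stats::rgamma(length(keys) * M, shape = 1), ncol = M)
  trans <- G / rowSums(G)
  rownames(trans) <- keys
  colnames(trans) <- symbols
  structure(list(M = M, h = as.integer(h_true), symbols = symbols,
                 start = symbols[1L], absorbing = symbols[M],
                 transitions = trans),
            class = "random_network")
}

#' @export
print.random_network <- function(x, ...) {
  cat(sprintf(
    "Random multistep network: M = %d states, h_true = %d (%d contexts)\n",
    x$M, x$h, nrow(x$transitions)))
  cat(sprintf("  start = '%s', absorbing = '%s'\n", x$start, x$absorbing))
  invisible(x)
}

#' Hand-build a multistep network from a transition matrix
#'
#' For constructing fixtures with known dynamics rather than random ones.
#'
#' @param transitions numeric matrix, `M^h` x M, rows summing to 1, with
#'   context-key rownames (oldest state first) and state-symbol colnames.
#' @param start,absorbing state symbols.
#' @return A `"random_network"` object.
#' @export
build_network <- function(transitions, start, absorbing) {
  symbols <- colnames(transitions)
  M <- length(symbols)
  h <- nchar(rownames(transitions)[1L])
  if (nrow(transitions) != M^h)
    stop("need one row per context in {states}^h")
  if (any(abs(rowSums(transitions) - 1) > 1e-9))
    stop("every transition row must sum to 1")
  if (!(start %in% symbols) || !(absorbing %in% symbols))
    stop("start and absorbing must be state symbols")
  structure(list(M = M, h = as.integer(h), symbols = symbols, start = start,
                 absorbing = absorbing, transitions = transitions),
            class = "random_network")
}

#' Sample one trajectory from a multistep network until absorption
#'
#' States are drawn sequentially from the context-conditional vectors, the
#' history initialized to start-state padding; sampling stops when the
#' absorbing state is drawn (it is included as the final symbol).
#'
#' @param net a [generate_network()] or [build_network()] object.
#' @param max_len abort with an error if no absorption after this many steps.
#' @param seed optional integer seed.
#' @return Character vector of states, ending in the absorbing state.
#' @export
sample_trajectory <- function(net, max_len = 1e6, seed = NULL) {
  if (max_len < 1) stop("max_len must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  trans <- net$transitions
  key_index <- seq_len(nrow(trans))
  names(key_index) <- rownames(trans)
  histo <- rep(net$start, net$h)
  out <- character(0L)
  repeat {
    row <- if (net$h == 0L) 1L else key_index[[paste(histo, collapse = "")]]
    p <- trans[row, ]
    s <- net$symbols[sample.int(net$M, 1L, prob = p)]
    out <- c(out, s)
    if (s == net$absorbing) return(out)
    if (length(out) >= max_len)
      stop(sprintf("no absorption within max_len = %d steps", max_len))
    histo <- c(histo[-1L], s)[seq_len(net$h)]
  }
}

#' Sample a trajectory set of J trajectories from a network
#'
#' @inheritParams sample_trajectory
#' @param J number of trajectories.
#' @param boundary boundary marker for the resulting set's alphabet (must
#'   not be a state symbol).
#' @return A [trajectory_set()] over the network's states.
#' @export
sample_trajectories <- function(net, J, max_len = 1e6, seed = NULL,
                                boundary = ".") {
  if (!is.null(seed)) set.seed(seed)
  ab <- alphabet(net$symbols, boundary = boundary)
  trajectory_set(replicate(J, sample_trajectory(net, max_len), simplify = FALSE),
                 ab)
}

#' Configuration for a synthetic free-throw season
#'
#' Describes how to simulate a season of free-throw games: the number of
#' games, the mean attempts per game (attempt counts are drawn from a
#' zero-truncated Poisson whose truncated mean matches `mean_attempts` --
#' every counted game has at least one attempt), and the outcome process:
#' \describe{
#'   \item{`iid`}{every attempt succeeds independently with probability `p`
#'     (memoryless truth, h = 0).}
#'   \item{`markov1`}{single-step Markov outcomes with success probabilities
#'     `p_first` (first attempt of a game), `p_after_make`, `p_after_miss`.}
#'   \item{`vlmc`}{error-correction process: success probability is
#'     `p_after_miss` immediately after a miss and `p_otherwise` everywhere
#'     else (first attempt and after makes).}
#' }
#' Outcomes use the alphabet `"-+"` (miss, make).
#'
#' @param games number of games (trajectories) per season.
#' @param mean_attempts target mean attempts per game (> 1).
#' @param process `"iid"`, `"markov1"` or `"vlmc"`.
#' @param p make probability for `iid`.
#' @param p_first,p_after_make,p_after_miss `markov1` probabilities
#'   (`p_after_miss` also used by `vlmc`).
#' @param p_otherwise `vlmc` probability for first attempts and after makes.
#' @return An object of class `"freethrow_config"`.
#' @export
freethrow_config <- function(games = 91, mean_attempts = 7.6,
                             process = c("iid", "markov1", "vlmc"),
                             p = 0.68, p_first = NULL, p_after_make = NULL,
                             p_after_miss = NULL, p_otherwise = NULL) {
  process <- match.arg(process)
  if (games < 1) stop("games must be >= 1")
  if (mean_attempts <= 1) stop("mean_attempts must exceed 1")
  probs <- switch(process,
    iid = c(p = p),
    markov1 = c(p_first = p_first, p_after_make = p_after_make,
                p_after_miss = p_after_miss),
    vlmc = c(p_after_miss = p_after_miss, p_otherwise = p_otherwise))
  if (length(probs) != switch(process, iid = 1L, markov1 = 3L, vlmc = 2L) ||
      any(!is.finite(probs)))
    stop(sprintf("process '%s' is missing success probabilities", process))
  if (any(probs < 0 | probs > 1))
    stop("success probabilities must lie in [0, 1]")
  structure(list(games = as.integer(games), mean_attempts = mean_attempts,
                 process = process, probs = probs),
            class = "freethrow_config")
}

#' @export
print.freethrow_config <- function(x, ...) {
  cat(sprintf("Free-throw season config: %d games, mean %.3g attempts, %s(%s)\n",
              x$games, x$mean_attempts, x$process,
              paste(sprintf("%s=%.3g", names(x$probs), x$probs),
                    collapse = ", ")))
  invisible(x)
}

# Poisson rate whose zero-truncated mean lambda / (1 - exp(-lambda)) equals m.
zt_poisson_rate <- function(m) {
  stats::uniroot(function(l) l / (1 - exp(-l)) - m,
                 lower = 1e-8, upper = m, tol = 1e-12)$root
}

# Exact inverse-CDF draw of n zero-truncated Poisson(lambda) variates.
rzt_poisson <- function(n, lambda) {
  p0 <- stats::ppois(0, lambda)
  stats::qpois(p0 + stats::runif(n) * (1 - p0), lambda)
}

#' Simulate a season of free-throw games
#'
#' Draws `cfg$games` trajectories of make/miss outcomes (`"+"` / `"-"`) with
#' zero-truncated Poisson attempt counts and the configured outcome process.
#'
#' @param cfg a [freethrow_config()].
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used (so an outer experiment seeded once gets independent seasons).
#' @return A [trajectory_set()] over `alphabet("-+")`.
#' @export
simulate_season <- function(cfg, seed = NULL) {
  if (!inherits(cfg, "freethrow_config")) stop("expected a 'freethrow_config'")
  if (!is.null(seed)) set.seed(seed)
  lambda <- zt_poisson_rate(cfg$mean_attempts)
  lens <- rzt_poisson(cfg$games, lambda)
  pr <- cfg$probs
  seqs <- lapply(lens, function(L) {
    if (cfg$process == "iid") {
      return(c("-", "+")[(stats::runif(L) < pr[["p"]]) + 1L])
    }
    out <- character(L)
    for (l in seq_len(L)) {
      p_make <- if (cfg$process == "markov1") {
        if (l == 1L) pr[["p_first"]]
        else if (out[l - 1L] == "+") pr[["p_after_make"]]
        else pr[["p_after_miss"]]
      } else {
        if (l > 1L && out[l - 1L] == "-") pr[["p_after_miss"]]
        else pr[["p_otherwise"]]
      }
      out[l] <- if (stats::runif(1L) < p_make) "+" else "-"
    }
    out
  })
  trajectory_set(seqs, alphabet(c("-", "+")))
}
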