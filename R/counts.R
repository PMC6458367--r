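#' Transition count tables
#'
#' `count_transitions()` computes the sufficient statistics of a multistep
#' Markov chain of order `h`: for every position l of every trajectory, the
#' context is the h symbols preceding l, left-padded with the boundary marker
#' for the first positions, and the count for (context -> symbol at l) is
#' incremented.  Every observed symbol is counted exactly once, so counts
#' total sum(L_j) for any h; with h = 0 there is a single empty context.
#'
#' Contexts are stored sparsely: only contexts actually observed appear as
#' rows; unobserved contexts have implicit zero counts.  Context keys are
#' strings of h characters, oldest symbol first.
#'
#' @param trajs a [trajectory_set()].
#' @param h nonnegative integer memory order.
#' @param pad symbol used to left-pad the first histories of each
#'   trajectory: the alphabet's boundary marker by default, giving dedicated
#'   pre-trajectory contexts.  May instead be one of the alphabet symbols --
#'   appropriate when the generating process is known to start from a
#'   designated start state, so that early transitions pool with that
#'   state's genuine contexts.
#' @return An object of class `"count_table"`: a list with elements
#'   \describe{
#'     \item{h}{the order used for counting (base order, for merged tables).}
#'     \item{alphabet}{the state alphabet.}
#'     \item{pooled}{integer matrix, contexts x M, the pooled counts N_x.}
#'     \item{per_traj}{list of J matrices of per-trajectory counts N_x^(j),
#'       each holding only that trajectory's observed contexts.}
#'     \item{merged}{logical; `TRUE` after [merge_contexts()].}
#'   }
#' @examples
#' ab <- alphabet("-+")
#' ts <- parse_trajectories("+-++-++\n+--+-+++++-", ab)
#' count_transitions(ts, 1)$pooled
#' @export
count_transitions <- function(trajs, h, pad = NULL) {
  if (!inherits(trajs, "trajectory_set")) stop("expected a 'trajectory_set'")
  h <- as.integer(h)
  if (length(h) != 1L || is.na(h) || h < 0L) stop("h must be a nonnegative integer")
  ab <- trajs$alphabet
  if (is.null(pad)) pad <- ab$boundary
  if (!(pad %in% c(ab$symbols, ab$boundary)))
    stop("pad must be the boundary marker or an alphabet symbol")
  per <- lapply(trajs$sequences, count_one_sequence, h = h, ab = ab, pad = pad)
  pooled <- pool_count_matrices(per, n_states(ab))
  colnames(pooled) <- ab$symbols
  structure(list(h = h, alphabet = ab, pooled = pooled, per_traj = per,
                 merged = FALSE),
            class = "count_table")
}

# Count one symbol sequence at order h; returns contexts x M matrix with
# context-key rownames, rows ordered by first appearance.
count_one_sequence <- function(s, h, ab, pad = ab$boundary) {
  M <- n_states(ab)
  L <- length(s)
  m_idx <- match(s, ab$symbols)
  if (h == 0L) {
    mat <- matrix(tabulate(m_idx, nbins = M), nrow = 1L,
                  dimnames = list("", ab$symbols))
    return(mat)
  }
  padded <- paste(c(rep(pad, h), s), collapse = "")
  ctx <- substring(padded, seq_len(L), h + seq_len(L) - 1L)
  f <- factor(ctx, levels = unique(ctx))
  cnt <- tabulate((as.integer(f) - 1L) * M + m_idx, nbins = nlevels(f) * M)
  matrix(cnt, ncol = M, byrow = TRUE,
         dimnames = list(levels(f), ab$symbols))
}

# Sum a list of context-keyed count matrices over the union of their contexts.
pool_count_matrices <- function(mats, M) {
  keys <- unique(unlist(lapply(mats, rownames), use.names = FALSE))
  out <- matrix(0, nrow = length(keys), ncol = M, dimnames = list(keys, NULL))
  for (m in mats) {
    idx <- match(rownames(m), keys)
    out[idx, ] <- out[idx, ] + m
  }
  out
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("Transition counts: order h = %d%s, J = %d trajectories\n",
              x$h, if (x$merged) " (merged contexts)" else "",
              length(x$per_traj)))
  print(x$pooled)
  invisible(x)
}

n_trajectories <- function(counts) length(counts$per_traj)

#' An empty count table (no trajectories observed)
#'
#' Useful as the degenerate no-data case: every marginal criterion is 0 and
#' posteriors reduce to the prior.
#'
#' @param alphabet a [alphabet()] object.
#' @param h nonnegative integer order.
#' @return A `"count_table"` with zero contexts and zero trajectories.
#' @export
empty_count_table <- function(alphabet, h = 0) {
  stopifnot_alphabet(alphabet)
  M <- n_states(alphabet)
  pooled <- matrix(0, nrow = 0L, ncol = M,
                   dimnames = list(character(0L), alphabet$symbols))
  structure(list(h = as.integer(h), alphabet = alphabet, pooled = pooled,
                 per_traj = list(), merged = FALSE),
            class = "count_table")
}

total_transitions <- function(counts) sum(counts$pooled)

#' Split a count table into first-half and second-half trajectory blocks
#'
#' The first block holds trajectories 1..ceiling(J/2) (input order), the
#' second block the remainder; their pooled counts sum to the full pooled
#' counts.  This is the split used by leave-half-out cross-validation.
#'
#' @param counts a [count_transitions()] table with J >= 2 trajectories.
#' @return A list of two `"count_table"` objects, `first` and `second`.
#' @export
split_half <- function(counts) {
  J <- n_trajectories(counts)
  if (J < 2L) stop("LHO undefined: need at least two trajectories (J >= 2)")
  i1 <- seq_len(ceiling(J / 2))
  i2 <- setdiff(seq_len(J), i1)
  block <- function(idx) {
    per <- counts$per_traj[idx]
    pooled <- pool_count_matrices(per, n_states(counts$alphabet))
    colnames(pooled) <- colnames(counts$pooled)
    structure(list(h = counts$h, alphabet = counts$alphabet, pooled = pooled,
                   per_traj = per, merged = counts$merged),
              class = "count_table")
  }
  list(first = block(i1), second = block(i2))
}
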