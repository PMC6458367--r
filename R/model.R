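#' Memory specifications: fixed order or variable-length context partition
#'
#' A memory specification names one candidate model.  Either a fixed order
#' `h` (every length-h context gets its own transition-probability vector) or
#' a variable-length model: a partition of the order-`h_base` contexts into
#' disjoint blocks, the contexts within a block sharing a single parameter
#' vector.  The error-correction free-throw model, for example, partitions
#' the h = 1 contexts as `{"-"} | {"+", "."}`: outcomes are independent
#' except immediately after a miss.
#'
#' @param order nonnegative integer fixed order (mutually exclusive with
#'   `partition`).
#' @param partition list of character vectors of context keys (strings of
#'   `h_base` symbols, oldest first, boundary-padded); blocks must be
#'   disjoint.
#' @param h_base base order of the partitioned context set; inferred from the
#'   key lengths when omitted.
#' @param label optional display label.
#' @return An object of class `"memory_spec"`.
#' @examples
#' memory_spec(order = 1)
#' memory_spec(partition = list("-", c("+", ".")))   # error-correction model
#' @export
memory_spec <- function(order = NULL, partition = NULL, h_base = NULL,
                        label = NULL) {
  if (is.null(order) == is.null(partition))
    stop("give exactly one of 'order' or 'partition'")
  if (!is.null(order)) {
    order <- as.integer(order)
    if (length(order) != 1L || is.na(order) || order < 0L)
      stop("order must be a nonnegative integer")
    spec <- list(kind = "order", order = order,
                 label = if (is.null(label)) sprintf("h=%d", order) else label)
  } else {
    partition <- lapply(partition, as.character)
    if (!length(partition)) stop("partition must have at least one block")
    keys <- unlist(partition, use.names = FALSE)
    if (anyDuplicated(keys))
      stop("partition blocks must be disjoint")
    lens <- nchar(keys)
    if (is.null(h_base)) h_base <- max(lens)
    if (any(lens != h_base))
      stop("all contexts in a partition must have length h_base")
    spec <- list(kind = "partition", partition = partition,
                 h_base = as.integer(h_base),
                 label = if (is.null(label))
                   paste0("vlmc{", paste(vapply(partition, paste, "",
                                                collapse = ","),
                                         collapse = " | "), "}")
                 else label)
  }
  structure(spec, class = "memory_spec")
}

#' @export
print.memory_spec <- function(x, ...) {
  cat("Memory spec:", x$label, "\n")
  invisible(x)
}

spec_base_order <- function(spec) {
  if (spec$kind == "order") spec$order else spec$h_base
}

#' Serialize / deserialize a memory spec as JSON
#'
#' `{"order": h}` for fixed-order specs, `{"partition": [[keys], ...]}` for
#' variable-length specs.
#'
#' @param spec a [memory_spec()].
#' @param json a JSON string.
#' @return `memory_spec_to_json()` a JSON string; `memory_spec_from_json()` a
#'   [memory_spec()].
#' @export
memory_spec_to_json <- function(spec) {
  if (spec$kind == "order")
    jsonlite::toJSON(list(order = spec$order), auto_unbox = TRUE)
  else
    jsonlite::toJSON(list(partition = spec$partition))
}

#' @rdname memory_spec_to_json
#' @export
memory_spec_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  if (!is.null(x$order)) memory_spec(order = x$order)
  else if (!is.null(x$partition))
    memory_spec(partition = lapply(x$partition, unlist))
  else stop("JSON memory spec needs 'order' or 'partition'")
}

#' Merge contexts of a count table into shared-parameter blocks
#'
#' Pooled and per-trajectory counts are summed within each block of the
#' partition; the block (keyed by its contexts joined with commas) becomes
#' the new context.  Total counts are conserved.  Every context with nonzero
#' pooled count must be covered by some block.
#'
#' @param counts a [count_transitions()] table at the partition's base order.
#' @param spec a variable-length [memory_spec()].
#' @return A merged `"count_table"`.
#' @export
merge_contexts <- function(counts, spec) {
  if (!inherits(spec, "memory_spec") || spec$kind != "partition")
    stop("merge_contexts needs a variable-length (partition) memory spec")
  if (counts$merged) stop("count table is already merged")
  if (spec$h_base != counts$h)
    stop(sprintf("partition base order (%d) != count table order (%d)",
                 spec$h_base, counts$h))
  keys <- unlist(spec$partition, use.names = FALSE)
  observed <- rownames(counts$pooled)[rowSums(counts$pooled) > 0]
  uncovered <- setdiff(observed, keys)
  if (length(uncovered))
    stop(sprintf("partition does not cover observed context(s): %s",
                 paste(uncovered, collapse = ", ")))
  labels <- vapply(spec$partition, paste, character(1L), collapse = ",")
  block_of <- rep(labels, lengths(spec$partition))
  names(block_of) <- keys
  merge_one <- function(m) {
    g <- block_of[rownames(m)]
    g[is.na(g)] <- rownames(m)[is.na(g)]  # unreachable after cover check
    rowsum(m, group = factor(g, levels = unique(g)))
  }
  per <- lapply(counts$per_traj, merge_one)
  pooled <- pool_count_matrices(per, n_states(counts$alphabet))
  colnames(pooled) <- colnames(counts$pooled)
  structure(list(h = counts$h, alphabet = counts$alphabet, pooled = pooled,
                 per_traj = per, merged = TRUE),
            class = "count_table")
}

#' Maximum-likelihood transition probabilities
#'
#' For each context with positive total count, the MLE is the count vector
#' normalized by its total, `N_x / N_x.`; contexts with zero total are
#' omitted.  Unobserved transitions get probability zero, which is exactly
#' the pathology the Bayesian treatment avoids.
#'
#' @param counts a [count_transitions()] table.
#' @return Matrix of probabilities, one row per context with data.
#' @export
mle <- function(counts) {
  Np <- counts$pooled
  tot <- rowSums(Np)
  keep <- tot > 0
  sweep(Np[keep, , drop = FALSE], 1L, tot[keep], "/")
}

#' Dirichlet posterior parameters per context
#'
#' With prior Dirichlet(alpha) on each context's transition vector, the
#' posterior given multinomial counts is Dirichlet(alpha + N_x).  The same
#' alpha vector is shared across contexts.  Contexts absent from the table
#' (never observed) have posterior equal to the prior.
#'
#' @param counts a [count_transitions()] table.
#' @param alpha positive prior vector of length M, or a scalar recycled to
#'   length M.  `1` (default) is the uniform prior; `1/2` is Jeffreys'.
#' @return Matrix `alpha + N_x`, one row per context in the table.
#' @export
posterior_params <- function(counts, alpha = 1) {
  a <- check_alpha(alpha, n_states(counts$alphabet))
  sweep(counts$pooled, 2L, a, "+")
}

#' Posterior mean transition probabilities
#'
#' `(alpha_m + N_x,m) / (sum(alpha) + N_x.)` per context: every transition,
#' observed or not, gets positive probability.  Approaches the MLE as counts
#' grow.
#'
#' @inheritParams posterior_params
#' @return Matrix of probabilities, one row per context in the table.
#' @export
posterior_mean <- function(counts, alpha = 1) {
  post <- posterior_params(counts, alpha)
  sweep(post, 1L, rowSums(post), "/")
}

check_alpha <- function(alpha, M) {
  if (length(alpha) == 1L) alpha <- rep(as.numeric(alpha), M)
  if (length(alpha) != M) stop(sprintf("alpha must have length 1 or M = %d", M))
  if (any(!is.finite(alpha)) || any(alpha <= 0)) stop("alpha must be positive")
  alpha
}

#' Log-likelihood of counts under a transition-probability table
#'
#' `sum_x sum_m N_x,m log p_x,m` with the convention 0 log 0 = 0.  If some
#' observed transition has probability zero the result is -Inf (with a
#' warning): the probability table precludes the data.
#'
#' @param counts a [count_transitions()] table.
#' @param probs matrix of transition probabilities with context-key rownames
#'   covering every context of `counts` with nonzero counts, e.g. from
#'   [mle()] or [posterior_mean()].
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(counts, probs) {
  Np <- counts$pooled
  keep <- rowSums(Np) > 0
  Np <- Np[keep, , drop = FALSE]
  if (!nrow(Np)) return(0)
  idx <- match(rownames(Np), rownames(probs))
  if (anyNA(idx))
    stop(sprintf("no probabilities for context(s): %s",
                 paste(rownames(Np)[is.na(idx)], collapse = ", ")))
  P <- probs[idx, , drop = FALSE]
  if (any(P[Np > 0] == 0)) {
    warning("observed transition has probability zero; log-likelihood is -Inf")
    return(-Inf)
  }
  sum(Np[Np > 0] * log(P[Np > 0]))
}
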