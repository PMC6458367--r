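#' Trajectory sets
#'
#' A trajectory set holds J >= 1 ordered discrete-state trajectories over a
#' common alphabet.  Trajectory order is significant: leave-half-out
#' cross-validation splits the set into the first ceiling(J/2) trajectories
#' and the remainder, in input order.
#'
#' @param sequences list of character vectors, each a nonempty sequence of
#'   alphabet symbols.
#' @param alphabet a [alphabet()] object.
#' @return An object of class `"trajectory_set"` with elements `sequences`
#'   and `alphabet`.
#' @seealso [parse_trajectories()], [read_trajectories()]
#' @export
trajectory_set <- function(sequences, alphabet) {
  stopifnot_alphabet(alphabet)
  if (!is.list(sequences) || length(sequences) < 1L)
    stop("need at least one trajectory (J >= 1)")
  for (j in seq_along(sequences)) {
    s <- as.character(sequences[[j]])
    if (length(s) < 1L)
      stop(sprintf("trajectory %d is empty", j))
    bad <- which(!(s %in% alphabet$symbols))
    if (length(bad))
      stop(sprintf("trajectory %d: unknown symbol '%s' at position %d",
                   j, s[bad[1L]], bad[1L]))
    sequences[[j]] <- s
  }
  structure(list(sequences = sequences, alphabet = alphabet),
            class = "trajectory_set")
}

#' Parse trajectories from text, one trajectory per line
#'
#' Each nonblank line of `text` (whitespace stripped) becomes one trajectory;
#' line order is preserved.  Unknown characters are an error that names the
#' offending line and character position.
#'
#' @param text a single multi-line string, or a character vector of lines.
#' @param alphabet a [alphabet()] object.
#' @return A [trajectory_set()].
#' @examples
#' ab <- alphabet("-+")
#' ts <- parse_trajectories("+-++-++\n+--+-+++++-", ab)
#' lengths(ts$sequences)   # 7 11
#' @export
parse_trajectories <- function(text, alphabet) {
  stopifnot_alphabet(alphabet)
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  lines <- gsub("[[:space:]]", "", text)
  keep <- which(nzchar(lines))
  if (!length(keep)) stop("no nonblank lines: zero trajectories")
  seqs <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    s <- strsplit(lines[keep[i]], "")[[1L]]
    bad <- which(!(s %in% alphabet$symbols))
    if (length(bad))
      stop(sprintf("line %d, char %d: unknown symbol '%s'",
                   keep[i], bad[1L], s[bad[1L]]))
    seqs[[i]] <- s
  }
  trajectory_set(seqs, alphabet)
}

#' Read trajectories from a file
#'
#' Supports the plain-text format (one trajectory per line, UTF-8) and FASTA
#' (each record's sequence is one trajectory, in record order).
#'
#' @param path file path.
#' @param alphabet a [alphabet()] object.
#' @param format `"lines"` (default) or `"fasta"`.
#' @return A [trajectory_set()].
#' @export
read_trajectories <- function(path, alphabet, format = c("lines", "fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "lines") {
    parse_trajectories(readLines(path, warn = FALSE), alphabet)
  } else {
    recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                               seqtype = "AA")
    parse_trajectories(vapply(recs, as.character, character(1L)), alphabet)
  }
}

#' Serialize a trajectory set to lines of text
#'
#' Inverse of [parse_trajectories()]: one trajectory per line, in order.
#'
#' @param trajs a [trajectory_set()].
#' @return character vector of lines.
#' @export
format_trajectories <- function(trajs) {
  vapply(trajs$sequences, paste, character(1L), collapse = "")
}

#' Write a trajectory set to a plain-text file (one trajectory per line)
#'
#' @param trajs a [trajectory_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajs, path) {
  writeLines(format_trajectories(trajs), path)
  invisible(path)
}

#' @export
print.trajectory_set <- function(x, ...) {
  J <- length(x$sequences)
  L <- lengths(x$sequences)
  cat(sprintf("Trajectory set: J = %d trajectories, %d transitions total\n",
              J, sum(L)))
  cat("Alphabet: {", paste(x$alphabet$symbols, collapse = ", "), "}\n", sep = "")
  show <- utils::head(format_trajectories(x), 5L)
  cat(paste0("  ", show, collapse = "\n"), "\n")
  if (J > 5L) cat(sprintf("  ... and %d more\n", J - 5L))
  invisible(x)
}

#' @export
length.trajectory_set <- function(x) length(x$sequences)

#' Independently permute the symbols within each trajectory
#'
#' Each trajectory is replaced by a uniform random permutation of its own
#' symbols, so per-trajectory symbol multisets (and hence all order-0 counts)
#' are preserved while any serial dependency between consecutive outcomes is
#' destroyed.  Used as a shuffle control in power analyses.
#'
#' @param trajs a [trajectory_set()].
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used.
#' @return A [trajectory_set()] with permuted trajectories.
#' @export
shuffle_within_trajectories <- function(trajs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seqs <- lapply(trajs$sequences, function(s) {
    if (length(s) == 1L) s else s[sample.int(length(s))]
  })
  trajectory_set(seqs, trajs$alphabet)
}
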