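#' Define a finite state alphabet
#'
#' A state alphabet is an ordered set of M distinct single-character symbols,
#' together with a reserved boundary marker used to left-pad histories at the
#' start of a trajectory.  The ordering of `symbols` fixes the ordering of the
#' components of every count and probability vector produced downstream, so
#' for free-throw data declared as `alphabet(c("-", "+"))` all vectors read
#' `[miss, make]`.
#'
#' @param symbols character vector of M >= 2 distinct single-character state
#'   labels.  A single string such as `"-+"` is also accepted and split into
#'   characters.
#' @param boundary single character used as the boundary (pre-trajectory)
#'   sentinel; must not be one of `symbols`.  Default `"."`.
#' @return An object of class `"state_alphabet"`.
#' @examples
#' alphabet("-+")                  # miss/make, miss first
#' alphabet(c("a", "b", "c"))
#' @export
alphabet <- function(symbols, boundary = ".") {
  if (length(symbols) == 1L && nchar(symbols) > 1L)
    symbols <- strsplit(symbols, "")[[1L]]
  symbols <- as.character(symbols)
  if (length(symbols) < 2L)
    stop("an alphabet needs at least two states (M >= 2)")
  if (any(nchar(symbols) != 1L))
    stop("alphabet symbols must be single characters")
  if (anyDuplicated(symbols))
    stop("alphabet symbols must be distinct")
  if (!is.character(boundary) || length(boundary) != 1L || nchar(boundary) != 1L)
    stop("boundary marker must be a single character")
  if (boundary %in% symbols)
    stop("boundary marker must not be an alphabet symbol")
  structure(list(symbols = symbols, boundary = boundary),
            class = "state_alphabet")
}

#' @export
print.state_alphabet <- function(x, ...) {
  cat("State alphabet: {", paste(x$symbols, collapse = ", "),
      "}  (M = ", length(x$symbols), ", boundary = '", x$boundary, "')\n",
      sep = "")
  invisible(x)
}

n_states <- function(ab) length(ab$symbols)

stopifnot_alphabet <- function(ab) {
  if (!inherits(ab, "state_alphabet")) stop("expected a 'state_alphabet' object")
  ab
}
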