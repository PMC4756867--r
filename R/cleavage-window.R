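# P4-P4' window arithmetic and serialization.

#' Extract the P4-P4' window around a scissile bond
#'
#' Returns the eight residues flanking the peptide bond between
#' `p1_position` and `p1_position + 1` (1-based UniProt numbering).
#' Positions before the N-terminus or after the C-terminus are returned
#' as empty slots.
#'
#' @param sequence amino-acid string (one-letter codes).
#' @param p1_position 1-based residue number of the P1 residue; must have a
#'   P1' neighbour, i.e. `1 <= p1_position < nchar(sequence)`.
#' @return named character vector of length 8 (`P4` ... `P4'`); empty slots
#'   are `""`.
#' @export
#' @examples
#' extract_window("ACDEFGHIKL", 5)
extract_window <- function(sequence, p1_position) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  n <- nchar(sequence)
  p1_position <- as.integer(p1_position)
  if (is.na(p1_position) || p1_position < 1L || p1_position > n) {
    stop("p1_position ", p1_position, " out of range for sequence of length ",
         n, call. = FALSE)
  }
  if (p1_position == n) {
    stop("p1_position ", p1_position,
         " is the last residue: no P1' residue exists", call. = FALSE)
  }
  pos <- p1_position + POCKET_OFFSETS
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  w <- ifelse(pos >= 1L & pos <= n, chars[pmax(pos, 1L)], EMPTY)
  w <- toupper(w)
  names(w) <- POCKET_LABELS
  w
}

# Normalize a window token: standard residue or X kept, lowercase raised,
# anything else (non-standard residue, blocking/reporter group) becomes X.
# Returns list(token, label) where label is the original token when masked.
normalize_window_tokens <- function(tokens) {
  original <- trimws(tokens)
  tokens <- toupper(original)
  ok <- tokens %in% c(AA20, "X", EMPTY)
  labels <- ifelse(ok, "", original)  # keep the source token as written
  tokens[!ok] <- "X"
  list(tokens = tokens, labels = labels)
}

# A valid window: 8 slots, P1 non-empty, EMPTY only as contiguous runs at
# the outer edges.
window_is_valid <- function(tokens) {
  if (length(tokens) != 8L) return(FALSE)
  if (!all(tokens %in% c(AA20, "X", EMPTY))) return(FALSE)
  if (tokens[4L] == EMPTY) return(FALSE)
  filled <- which(tokens != EMPTY)
  # contiguous filled block covering P1
  all(seq(min(filled), max(filled)) %in% filled)
}

format_window <- function(tokens) paste(tokens, collapse = "-")

# Inverse of format_window; returns NULL for a malformed serialization.
parse_window <- function(x) {
  nsep <- lengths(regmatches(x, gregexpr("-", x, fixed = TRUE)))
  if (nsep != 7L) return(NULL)
  tokens <- strsplit(x, "-", fixed = TRUE)[[1L]]
  # strsplit drops trailing empty strings (EMPTY prime-side slots)
  if (length(tokens) < 8L) tokens <- c(tokens, rep(EMPTY, 8L - length(tokens)))
  tokens
}
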