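# Shared vocabulary: subsite labels, amino-acid alphabet and property groups.

#' @keywords internal
"_PACKAGE"

# Internal pocket column names (prime marked "p") and display labels.
POCKETS <- c("P4", "P3", "P2", "P1", "P1p", "P2p", "P3p", "P4p")
POCKET_LABELS <- c("P4", "P3", "P2", "P1", "P1'", "P2'", "P3'", "P4'")
# Offset of each pocket's residue relative to the P1 residue number.
POCKET_OFFSETS <- c(-3L, -2L, -1L, 0L, 1L, 2L, 3L, 4L)
names(POCKET_OFFSETS) <- POCKETS

EMPTY <- ""

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Display row order groups amino acids of similar properties; X last.
AA_DISPLAY_ORDER <- c("I", "L", "V", "F", "W", "Y", "D", "E", "R", "H", "K",
                      "A", "C", "G", "S", "N", "Q", "M", "P", "T", "X")

AA_GROUPS <- list(
  aliphatic = c("I", "L", "V"),
  aromatic  = c("F", "W", "Y"),
  acidic    = c("D", "E"),
  basic     = c("R", "H", "K"),
  small     = c("A", "C", "G", "S"),
  other     = c("N", "Q", "M", "P", "T")
)

GROUP_SYMBOLS <- c(
  aliphatic = "λ",  # lambda
  aromatic  = "@",
  acidic    = "+",
  basic     = "−",  # minus sign
  small     = "Σ",  # Sigma
  other     = "Ω"   # Omega
)

ACTIVITY_CLASSES <- c("endopeptidase", "aminopeptidase", "carboxypeptidase",
                      "dipeptidyl-peptidase", "peptidyl-dipeptidase",
                      "dipeptidase")

# Pockets that cannot structurally exist for each activity class.
MASKED_POCKETS <- list(
  endopeptidase          = character(0),
  aminopeptidase         = c("P4", "P3", "P2"),
  carboxypeptidase       = c("P2p", "P3p", "P4p"),
  `dipeptidyl-peptidase` = c("P4", "P3"),
  `peptidyl-dipeptidase` = c("P3p", "P4p"),
  dipeptidase            = c("P4", "P3", "P2", "P2p", "P3p", "P4p")
)

CLEAVAGE_CLASSES <- c("physiological", "pathological", "non-physiological",
                      "synthetic", "theoretical", "unclassified")

# Shade bands used in preference displays: percentage of substrates.
SHADE_BANDS <- c("50-59", "60-69", "70-79", "80-89", "90+")

#' Validate a MEROPS identifier
#'
#' Peptidase-level identifiers consist of a catalytic-type letter, two
#' alphanumeric family characters, a dot, and a three-character peptidase
#' code (e.g. `"M12.217"`, `"A01.004"`, `"U9G.075"`). Family-level
#' identifiers are the letter plus 2-3 alphanumerics with no dot
#' (e.g. `"M24"`).
#'
#' @param x character vector of candidate identifiers.
#' @return logical vector.
#' @export
#' @examples
#' is_merops_id(c("M12.217", "M24", "bogus"))
is_merops_id <- function(x) {
  is_merops_peptidase(x) | is_merops_family(x)
}

#' @rdname is_merops_id
#' @export
is_merops_peptidase <- function(x) {
  !is.na(x) & grepl("^[A-Z][A-Za-z0-9]{2}\\.[A-Za-z0-9]{3}$", x)
}

#' @rdname is_merops_id
#' @export
is_merops_family <- function(x) {
  !is.na(x) & grepl("^[A-Z][A-Za-z0-9]{2,3}$", x)
}

pocket_index <- function(pocket) {
  i <- match(pocket, POCKETS)
  bad <- is.na(i)
  i[bad] <- match(pocket[bad], POCKET_LABELS)
  if (anyNA(i)) {
    stop("unknown pocket name(s): ",
         paste(pocket[is.na(i)], collapse = ", "), call. = FALSE)
  }
  i
}

masked_pockets <- function(activity_class) {
  activity_class <- match.arg(activity_class, ACTIVITY_CLASSES)
  MASKED_POCKETS[[activity_class]]
}

shade_band <- function(pct) {
  out <- rep(NA_character_, length(pct))
  out[pct >= 50] <- SHADE_BANDS[1L]
  out[pct >= 60] <- SHADE_BANDS[2L]
  out[pct >= 70] <- SHADE_BANDS[3L]
  out[pct >= 80] <- SHADE_BANDS[4L]
  out[pct >= 90] <- SHADE_BANDS[5L]
  out
}
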