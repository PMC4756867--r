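# Independent oracles and fixture builders shared across test files.

# Exhaustive double-loop pairwise-difference oracle for the reliability
# score: compares every unordered record pair pocket by pocket over the
# positions occupied in at least one record. Deliberately naive and
# independent of the package's tabulation-based implementation.
oracle_reliability <- function(windows) {
  n <- nrow(windows)
  considered <- which(apply(windows, 2, function(col) any(col != "")))
  diffs <- 0
  n_pairs <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      n_pairs <- n_pairs + 1
      for (k in considered) {
        a <- windows[i, k]
        b <- windows[j, k]
        # X vs X and empty vs empty are equal; any other difference counts
        if (a != b) diffs <- diffs + 1
      }
    }
  }
  100 * diffs / (n_pairs * length(considered))
}

# Linear-scan oracle for residue-to-column mapping: walk the gapped row
# counting non-gap characters until the requested residue is reached.
oracle_residue_column <- function(gapped, residue_number) {
  chars <- strsplit(gapped, "", fixed = TRUE)[[1]]
  seen <- 0
  for (col in seq_along(chars)) {
    if (!chars[col] %in% c("-", ".")) {
      seen <- seen + 1
      if (seen == residue_number) return(col)
    }
  }
  NA_integer_
}

AA_STD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
POCKET_NAMES <- c("P4", "P3", "P2", "P1", "P1'", "P2'", "P3'", "P4'")

# Wrap an n x 8 character window matrix (tokens: residues, "X", "") as a
# cleavage collection for one peptidase.
collection_from_windows <- function(windows, peptidase = "X01.001",
                                    activity_class = "endopeptidase",
                                    cleavage_class = "physiological") {
  n <- nrow(windows)
  records <- data.frame(
    peptidase = rep(peptidase, n),
    substrate_accession = sprintf("SUB%04d", seq_len(n)),
    substrate_name = sprintf("substrate %d", seq_len(n)),
    p1_position = rep(10L, n),
    stringsAsFactors = FALSE)
  cols <- c("P4", "P3", "P2", "P1", "P1p", "P2p", "P3p", "P4p")
  for (j in 1:8) records[[cols[j]]] <- windows[, j]
  records$cleavage_class <- cleavage_class
  cleavage_collection(
    records,
    peptidases = peptidase_entry(peptidase,
                                 activity_class = activity_class))
}

# Random valid windows: residues or X, with contiguous empty runs allowed
# at the outer edges (P1 and P1' always filled).
random_windows <- function(n, x_prob = 0.1, allow_empty = TRUE) {
  t(vapply(seq_len(n), function(i) {
    w <- sample(c(AA_STD, "X"), 8, replace = TRUE,
                prob = c(rep((1 - x_prob) / 20, 20), x_prob))
    if (allow_empty) {
      left <- sample(0:3, 1)
      right <- sample(0:3, 1)
      if (left > 0) w[seq_len(left)] <- ""
      if (right > 0) w[seq(9 - right, 8)] <- ""
    }
    w
  }, character(8)))
}

# Minimal UniProt DAT fixture text.
make_dat <- function(accession = "P99999", id = "TEST_HUMAN",
                     lineage = "Eukaryota; Metazoa; Chordata.",
                     features = character(0), sequence = NULL,
                     crc = NULL) {
  if (is.null(sequence)) {
    sequence <- paste(rep("MKWVTFISLLFLFSSAYSRGVFRRDAHKSE", 2),
                      collapse = "")
  }
  blocks <- chunked <- gsub("(.{10})", "\\1 ", sequence)
  sq <- if (is.null(crc)) {
    sprintf("SQ   SEQUENCE   %d AA;  9999 MW;", nchar(sequence))
  } else {
    sprintf("SQ   SEQUENCE   %d AA;  9999 MW;  %s CRC64;",
            nchar(sequence), crc)
  }
  c(sprintf("ID   %s              Reviewed;         %d AA.", id,
            nchar(sequence)),
    sprintf("AC   %s;", accession),
    sprintf("OC   %s", lineage),
    features,
    sq,
    paste0("     ", trimws(chunked)),
    "//")
}

ft_line <- function(kind, loc, qualifiers = character(0)) {
  c(sprintf("FT   %-15s %s", kind, loc),
    sprintf("FT                   %s", qualifiers))
}
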