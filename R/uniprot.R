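# Deriving processing-event cleavage records from UniProt/SwissProt
# flat-file (DAT) annotations, with sequence-drift quality control.
#
# SwissProt entries annotate removal of the initiating methionine, signal
# and transit peptides, and propeptide/chain/peptide processing events.
# Experimentally supported events are converted into cleavage records;
# predicted ("by similarity") features are skipped -- theoretical cleavages
# are not collected.

INGEST_FEATURES <- c("INIT_MET", "SIGNAL", "TRANSIT", "PROPEP", "CHAIN",
                     "PEPTIDE")

#' Configuration for UniProt-derived cleavage mapping
#'
#' The MEROPS identifiers for the general processing enzymes are
#' configuration values, not hard-coded: initiator-methionine removal maps
#' to a methionyl aminopeptidase for prokaryotes and to the M24 family for
#' eukaryotes (any of the eukaryotic methionyl aminopeptidases may be
#' responsible); signal-peptide removal maps to signal peptidase
#' (prokaryote) or the signal peptidase complex (eukaryote). Viral entries
#' are processed by host machinery and use the eukaryote-style mappings.
#' Features whose evidence matches any of `predicted_markers` are treated
#' as predicted and skipped.
#'
#' @param metap_prokaryote MEROPS id for prokaryotic methionyl
#'   aminopeptidase.
#' @param metap_eukaryote family-level id for eukaryotic initiator-Met
#'   removal.
#' @param signal_prokaryote MEROPS id for prokaryotic signal peptidase.
#' @param signal_eukaryote family-level id for the eukaryotic signal
#'   peptidase complex.
#' @param transit_peptidase optional id for transit-peptide removal
#'   (`NA` = unmapped).
#' @param predicted_markers substrings of evidence/description text that
#'   mark a feature as predicted.
#' @return named list of class `ingest_config`.
#' @export
ingest_config <- function(metap_prokaryote = "M24.001",
                          metap_eukaryote = "M24",
                          signal_prokaryote = "S26.001",
                          signal_eukaryote = "S26",
                          transit_peptidase = NA_character_,
                          predicted_markers = c("ECO:0000250",
                                                "ECO:0000255",
                                                "ECO:0000256",
                                                "ECO:0000259",
                                                "By similarity",
                                                "Potential", "Probable")) {
  structure(list(metap_prokaryote = metap_prokaryote,
                 metap_eukaryote = metap_eukaryote,
                 signal_prokaryote = signal_prokaryote,
                 signal_eukaryote = signal_eukaryote,
                 transit_peptidase = transit_peptidase,
                 predicted_markers = predicted_markers),
            class = "ingest_config")
}

#' Simple sequence checksum
#'
#' A stable rolling hash of an amino-acid sequence used to detect sequence
#' drift between a stored cleavage record and the current entry when the
#' flat file does not carry a CRC64 token. Only token equality is ever
#' compared, so any stable hash suffices.
#'
#' @param sequence amino-acid string.
#' @return 16-character uppercase hexadecimal string.
#' @export
sequence_checksum <- function(sequence) {
  codes <- utf8ToInt(toupper(sequence))
  if (length(codes) == 0L) return(paste(rep("0", 16L), collapse = ""))
  h1 <- (sum(codes) + length(codes)) %% 2^32
  h2 <- sum(codes * seq_along(codes)) %% 2^32
  sprintf("%08X%08X", h1, h2)
}

parse_ft_location <- function(loc) {
  m <- regmatches(loc, regexec("^(\\?|[<]?\\d+)(?:\\.\\.(\\?|[>]?\\d+))?$",
                               loc))[[1L]]
  if (length(m) == 0L) return(NULL)
  from_tok <- m[2L]
  to_tok <- if (is.na(m[3L]) || m[3L] == "") from_tok else m[3L]
  from_unknown <- from_tok == "?" || startsWith(from_tok, "<")
  to_unknown <- to_tok == "?" || startsWith(to_tok, ">")
  list(
    from = if (from_tok == "?") NA_integer_ else
      as.integer(sub("^<", "", from_tok)),
    to = if (to_tok == "?") NA_integer_ else
      as.integer(sub("^>", "", to_tok)),
    from_unknown = from_unknown, to_unknown = to_unknown
  )
}

#' Parse a UniProt flat-file (DAT) entry
#'
#' Handles the ID/AC/OC/FT/SQ blocks of both the current (`FT   SIGNAL
#' 1..22`) and classic (`FT   SIGNAL  1  22`) feature layouts, including
#' `?`/`<`/`>` endpoints (flagged unknown, never coerced) and
#' `/evidence=`/`/note=` continuation lines. The taxonomy division is
#' taken from the OC line (Bacteria/Archaea -> prokaryote, Eukaryota ->
#' eukaryote, Viruses -> virus). The checksum is the CRC64 token of the SQ
#' line when present, otherwise [sequence_checksum()] of the reassembled
#' sequence.
#'
#' @param file path to a DAT file.
#' @param text optional character vector of lines, used instead of `file`.
#' @param config an [ingest_config()] (supplies the predicted-evidence
#'   markers).
#' @return object of class `uniprot_entry`: list with `accession`, `id`,
#'   `sequence`, `taxonomy_division`, `features` (data frame: `kind`,
#'   `from`, `to`, `from_unknown`, `to_unknown`, `description`,
#'   `predicted`), `checksum`.
#' @export
read_uniprot <- function(file = NULL, text = NULL,
                         config = ingest_config()) {
  lines <- text %||% readLines(file, warn = FALSE)
  code <- substr(lines, 1L, 2L)
  body <- trimws(substr(lines, 6L, nchar(lines)))
  id <- NA_character_
  if (any(code == "ID")) {
    id <- strsplit(body[code == "ID"][1L], "\\s+")[[1L]][1L]
  }
  accession <- NA_character_
  if (any(code == "AC")) {
    accession <- sub(";.*$", "", body[code == "AC"][1L])
  }
  oc <- paste(body[code == "OC"], collapse = " ")
  division <- if (grepl("^Viruses", oc)) "virus"
    else if (grepl("^Eukaryota", oc)) "eukaryote"
    else if (grepl("^(Bacteria|Archaea)", oc)) "prokaryote"
    else "unknown"
  # features: a new feature starts with a key; continuations are indented
  # (body starting with "/") or bare qualifier text
  feats <- list()
  ft_lines <- body[code == "FT"]
  cur <- NULL
  flush <- function() {
    if (!is.null(cur)) feats[[length(feats) + 1L]] <<- cur
  }
  for (ln in ft_lines) {
    toks <- strsplit(ln, "\\s+")[[1L]]
    is_new <- length(toks) >= 2L && grepl("^[A-Z_]+$", toks[1L]) &&
      grepl("^[?<]?\\d|^\\?", toks[2L])
    if (is_new) {
      flush()
      loc_tok <- if (length(toks) >= 3L &&
                     grepl("^[?>]?\\d+$|^\\?$", sub("^>", "", toks[3L]))) {
        paste0(toks[2L], "..", toks[3L])   # classic two-column layout
      } else {
        toks[2L]
      }
      loc <- parse_ft_location(loc_tok)
      cur <- list(kind = toks[1L],
                  loc = loc,
                  loc_raw = loc_tok,
                  description = if (length(toks) > 3L)
                    paste(toks[-(1:3)], collapse = " ") else "")
    } else if (!is.null(cur)) {
      cur$description <- trimws(paste(cur$description, ln))
    }
  }
  flush()
  features <- do.call(rbind, lapply(feats, function(f) {
    loc <- f$loc
    unparseable <- is.null(loc)
    data.frame(
      kind = f$kind,
      from = if (unparseable) NA_integer_ else loc$from,
      to = if (unparseable) NA_integer_ else loc$to,
      from_unknown = if (unparseable) TRUE else loc$from_unknown,
      to_unknown = if (unparseable) TRUE else loc$to_unknown,
      description = f$description,
      predicted = any(vapply(config$predicted_markers, grepl,
                             logical(1), x = f$description,
                             fixed = TRUE)),
      stringsAsFactors = FALSE)
  }))
  if (is.null(features)) {
    features <- data.frame(kind = character(0), from = integer(0),
                           to = integer(0), from_unknown = logical(0),
                           to_unknown = logical(0),
                           description = character(0),
                           predicted = logical(0), stringsAsFactors = FALSE)
  }
  sq_at <- which(code == "SQ")
  if (length(sq_at) == 0L) stop("missing SQ block", call. = FALSE)
  sq_header <- lines[sq_at[1L]]
  crc <- regmatches(sq_header,
                    regexec("([0-9A-Fa-f]+)\\s+CRC64", sq_header))[[1L]]
  seq_lines <- lines[seq(sq_at[1L] + 1L, length(lines))]
  seq_lines <- seq_lines[!startsWith(seq_lines, "//")]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  checksum <- if (length(crc) >= 2L) toupper(crc[2L]) else
    sequence_checksum(sequence)
  structure(list(accession = accession, id = id, sequence = sequence,
                 taxonomy_division = division, features = features,
                 checksum = checksum),
            class = "uniprot_entry")
}

#' @export
print.uniprot_entry <- function(x, ...) {
  cat("uniprot_entry", x$accession, "(", x$id, "):", nchar(x$sequence),
      "aa,", x$taxonomy_division, ",", nrow(x$features), "feature(s)\n")
  invisible(x)
}

#' Derive processing-event cleavage records from a UniProt entry
#'
#' Converts experimentally supported processing features into cleavage
#' records: initiator-Met removal (`INIT_MET`) cleaves after residue 1,
#' mapped to methionyl aminopeptidase (prokaryote) or the M24 family
#' (eukaryote); signal-peptide removal (`SIGNAL 1..k`) cleaves after
#' residue k, mapped to signal peptidase or the signal peptidase complex;
#' transit peptides and propeptide/chain/peptide boundaries become
#' cleavages left unmapped (peptidase `NA`) unless a mapping is
#' configured, since the responsible enzyme is generally unknown. Features
#' flagged predicted or with unknown endpoints are skipped (theoretical
#' cleavages are not collected). Emitted records carry cleavage class
#' `"physiological"`, windows from [extract_window()], the full residue
#' range and the entry checksum.
#'
#' @param entry a [read_uniprot()] entry.
#' @param config an [ingest_config()].
#' @return records data frame (collection layout) with an attribute
#'   `skipped` (data frame: `kind`, `from`, `to`, `reason`).
#' @export
derive_processing_cleavages <- function(entry, config = ingest_config()) {
  len <- nchar(entry$sequence)
  euk_style <- entry$taxonomy_division %in% c("eukaryote", "virus",
                                              "unknown")
  skipped <- list()
  skip <- function(f, reason) {
    skipped[[length(skipped) + 1L]] <<- data.frame(
      kind = f$kind, from = f$from, to = f$to, reason = reason,
      stringsAsFactors = FALSE)
  }
  cuts <- list()  # (peptidase, p1)
  add <- function(peptidase, p1) {
    if (p1 >= 1L && p1 < len) {
      cuts[[length(cuts) + 1L]] <<- list(peptidase = peptidase, p1 = p1)
    }
  }
  for (i in seq_len(nrow(entry$features))) {
    f <- as.list(entry$features[i, ])
    if (!f$kind %in% INGEST_FEATURES) next
    if (f$predicted) { skip(f, "predicted evidence"); next }
    if (is.na(f$from) || is.na(f$to) || f$from_unknown || f$to_unknown) {
      skip(f, "unknown endpoint"); next
    }
    if (f$kind == "INIT_MET") {
      add(if (euk_style) config$metap_eukaryote else
            config$metap_prokaryote, 1L)
    } else if (f$kind == "SIGNAL") {
      add(if (euk_style) config$signal_eukaryote else
            config$signal_prokaryote, f$to)
    } else if (f$kind == "TRANSIT") {
      add(config$transit_peptidase, f$to)
    } else {  # PROPEP / CHAIN / PEPTIDE boundaries, peptidase unknown
      if (f$from > 1L) add(NA_character_, f$from - 1L)
      add(NA_character_, f$to)
    }
  }
  if (length(cuts)) {
    key <- vapply(cuts, function(x)
      paste(x$peptidase %||% NA, x$p1), character(1))
    cuts <- cuts[!duplicated(key)]
  }
  rows <- lapply(cuts, function(x) {
    w <- extract_window(entry$sequence, x$p1)
    row <- data.frame(peptidase = x$peptidase,
                      substrate_accession = entry$accession,
                      substrate_name = entry$id,
                      p1_position = x$p1,
                      residue_start = 1L, residue_end = len,
                      stringsAsFactors = FALSE)
    for (k in seq_along(POCKETS)) row[[POCKETS[k]]] <- unname(w[k])
    row$group_labels <- ""
    row$cleavage_class <- "physiological"
    row$evidence <- "uniprot-feature"
    row$km <- NA_real_; row$kcat <- NA_real_; row$kcat_over_km <- NA_real_
    row$reference_id <- NA_character_
    row$checksum <- entry$checksum
    row
  })
  records <- if (length(rows)) do.call(rbind, rows) else empty_records()
  rownames(records) <- NULL
  attr(records, "skipped") <- if (length(skipped)) {
    do.call(rbind, skipped)
  } else {
    data.frame(kind = character(0), from = integer(0), to = integer(0),
               reason = character(0), stringsAsFactors = FALSE)
  }
  records
}

#' Quality-control check of a stored record against the current entry
#'
#' Re-derives the P4-P4' window from the entry's current sequence and
#' compares it with the stored window (ignoring `X` wildcards and empty
#' slots), and compares the stored sequence checksum with the entry's.
#' Fails when any stored slot disagrees or the checksum has drifted --
#' the signature of a UniProt sequence update since curation.
#'
#' @param record one-row data frame or list in the record layout.
#' @param entry a [read_uniprot()] entry for the record's accession.
#' @return list with `pass` (logical), `mismatched_pockets` (character)
#'   and `checksum_drift` (logical).
#' @export
qc_window_check <- function(record, entry) {
  record <- as.list(record)
  mism <- character(0)
  p1 <- as.integer(record$p1_position)
  if (!is.na(p1) && p1 >= 1L && p1 < nchar(entry$sequence)) {
    expected <- extract_window(entry$sequence, p1)
    for (k in seq_along(POCKETS)) {
      s <- as.character(record[[POCKETS[k]]])
      if (is.na(s) || s == EMPTY || s == "X") next
      if (s != expected[k]) mism <- c(mism, POCKET_LABELS[k])
    }
  } else {
    mism <- POCKET_LABELS  # position no longer valid in current sequence
  }
  drift <- !is.na(record$checksum %||% NA) &&
    record$checksum != entry$checksum
  list(pass = length(mism) == 0L && !drift,
       mismatched_pockets = mism, checksum_drift = drift)
}
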