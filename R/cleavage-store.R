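# Cleavage-collection data model and TSV/FASTA I/O.
#
# A collection holds one record per annotated scissile-bond event: the
# peptidase (MEROPS identifier), the substrate, the 1-based UniProt residue
# number of the P1 residue, the P4-P4' window, the cleavage class and any
# evidence/kinetics. Coordinates are 1-based and intervals inclusive,
# matching UniProt feature conventions; the scissile bond lies between
# p1_position and p1_position + 1.

RECORD_COLUMNS <- c("peptidase", "substrate_accession", "substrate_name",
                    "p1_position", "residue_start", "residue_end",
                    POCKETS, "group_labels", "cleavage_class", "evidence",
                    "km", "kcat", "kcat_over_km", "reference_id", "checksum")

TSV_COLUMNS <- c("peptidase", "substrate_accession", "substrate_name",
                 "p1_position", "residue_start", "residue_end",
                 "window", "group_labels", "cleavage_class", "evidence",
                 "km", "kcat", "kcat_over_km", "reference_id", "checksum")

empty_records <- function() {
  df <- data.frame(
    peptidase = character(0), substrate_accession = character(0),
    substrate_name = character(0), p1_position = integer(0),
    residue_start = integer(0), residue_end = integer(0),
    stringsAsFactors = FALSE
  )
  for (p in POCKETS) df[[p]] <- character(0)
  df$group_labels <- character(0)
  df$cleavage_class <- character(0)
  df$evidence <- character(0)
  df$km <- numeric(0)
  df$kcat <- numeric(0)
  df$kcat_over_km <- numeric(0)
  df$reference_id <- character(0)
  df$checksum <- character(0)
  df
}

#' Construct a cleavage collection
#'
#' @param records data frame of cleavage records (see [read_cleavages()] for
#'   the column layout); missing optional columns are added as `NA`.
#' @param peptidases optional data frame with columns `id`, `name`,
#'   `activity_class` registering the peptidases referenced by the records.
#' @param sequences optional named character vector of substrate amino-acid
#'   sequences keyed by accession.
#' @return an object of class `cleavage_collection`.
#' @export
cleavage_collection <- function(records = empty_records(),
                                peptidases = NULL, sequences = NULL) {
  tmpl <- empty_records()
  for (col in RECORD_COLUMNS) {
    if (is.null(records[[col]])) {
      na_val <- c(tmpl[[col]], NA)[1L]  # NA of the column's type
      records[[col]] <- rep(na_val, length.out = nrow(records))
    }
  }
  records$p1_position <- as.integer(records$p1_position)
  records$residue_start <- as.integer(records$residue_start)
  records$residue_end <- as.integer(records$residue_end)
  records$group_labels <- as.character(records$group_labels)
  records$group_labels[is.na(records$group_labels)] <- ""
  records <- records[RECORD_COLUMNS]
  rownames(records) <- NULL
  if (is.null(peptidases)) {
    peptidases <- data.frame(id = character(0), name = character(0),
                             activity_class = character(0),
                             stringsAsFactors = FALSE)
  }
  structure(
    list(records = records, peptidases = peptidases,
         sequences = sequences %||% character(0)),
    class = "cleavage_collection"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cleavage_collection <- function(x, ...) {
  cat("cleavage_collection:", nrow(x$records), "records,",
      length(unique(stats::na.omit(x$records$peptidase))), "peptidases,",
      length(x$sequences), "sequences\n")
  issues <- attr(x, "issues")
  if (!is.null(issues) && nrow(issues)) {
    cat("  ", nrow(issues), "parse issue(s); see attr(x, \"issues\")\n")
  }
  invisible(x)
}

#' Register a peptidase entry
#'
#' @param id MEROPS identifier.
#' @param name peptidase name.
#' @param activity_class one of the six activity classes
#'   (`"endopeptidase"`, `"aminopeptidase"`, `"carboxypeptidase"`,
#'   `"dipeptidyl-peptidase"`, `"peptidyl-dipeptidase"`, `"dipeptidase"`).
#' @return one-row data frame suitable for the `peptidases` slot.
#' @export
peptidase_entry <- function(id, name = id,
                            activity_class = "endopeptidase") {
  stopifnot(is_merops_id(id))
  activity_class <- match.arg(activity_class, ACTIVITY_CLASSES)
  data.frame(id = id, name = name, activity_class = activity_class,
             stringsAsFactors = FALSE)
}

activity_class_of <- function(collection, peptidase) {
  i <- match(peptidase, collection$peptidases$id)
  if (is.na(i)) "endopeptidase" else collection$peptidases$activity_class[i]
}

#' Read a cleavage-collection TSV
#'
#' The dialect is UTF-8 tab-separated text with a header line. Required
#' columns: `peptidase`, `substrate_accession`, `p1_position`, `window`,
#' `cleavage_class`; all others are optional. `"."` marks an absent
#' optional value. The window is serialized as 8 tokens joined by `"-"`
#' (P4 first), with empty slots rendered as the empty string. Unknown
#' residue symbols are normalized to `X` with the original token preserved
#' in `group_labels`; cleavage classes are lower-cased, and values outside
#' the closed six-term vocabulary map to `"unclassified"` with an issue.
#' Malformed lines are collected in `attr(x, "issues")`, never silently
#' dropped.
#'
#' @param file path to a TSV file (or a character vector of lines via
#'   `text`).
#' @param text optional character vector of lines, used instead of `file`.
#' @param sequences optional named character vector of substrate sequences.
#' @return a [cleavage_collection()] with an `issues` attribute
#'   (data frame: `line`, `message`).
#' @export
read_cleavages <- function(file = NULL, text = NULL, sequences = NULL) {
  lines <- text %||% readLines(file, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty cleavage file", call. = FALSE)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  required <- c("peptidase", "substrate_accession", "p1_position",
                "window", "cleavage_class")
  missing_cols <- setdiff(required, header)
  if (length(missing_cols)) {
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  issues <- list()
  note <- function(line, msg) {
    issues[[length(issues) + 1L]] <<- data.frame(
      line = line, message = msg, stringsAsFactors = FALSE)
  }
  rows <- vector("list", max(length(lines) - 1L, 0L))
  for (i in seq_along(rows)) {
    lineno <- i + 1L
    fields <- strsplit(lines[lineno], "\t", fixed = TRUE)[[1L]]
    length(fields) <- length(header)   # pad short lines with NA
    fields[is.na(fields)] <- "."
    rec <- as.list(fields)
    names(rec) <- header
    get <- function(col) {
      v <- rec[[col]]
      if (is.null(v) || identical(v, ".")) NA_character_ else v
    }
    tokens <- parse_window(get("window") %||% "")
    if (is.na(get("window")) || is.null(tokens)) {
      note(lineno, "malformed window (expected 8 '-'-joined tokens)")
      next
    }
    norm <- normalize_window_tokens(tokens)
    if (!window_is_valid(norm$tokens)) {
      note(lineno, "invalid window (P1 empty or non-contiguous slots)")
      next
    }
    p1 <- suppressWarnings(as.integer(get("p1_position")))
    if (is.na(p1) || p1 < 1L) {
      note(lineno, "p1_position is not a positive integer")
      next
    }
    cls <- tolower(get("cleavage_class"))
    if (is.na(cls) || !cls %in% CLEAVAGE_CLASSES) {
      note(lineno, paste0("unknown cleavage_class '", get("cleavage_class"),
                          "' mapped to 'unclassified'"))
      cls <- "unclassified"
    }
    pep <- get("peptidase")
    if (!is.na(pep) && !is_merops_id(pep)) {
      note(lineno, paste0("malformed MEROPS identifier '", pep, "'"))
    }
    glab <- get("group_labels")
    if (is.na(glab)) glab <- ""
    if (any(nzchar(norm$labels))) {
      # merge labels recovered from masked tokens
      from_tokens <- paste(norm$labels, collapse = "|")
      glab <- if (nzchar(glab)) glab else from_tokens
    }
    row <- data.frame(
      peptidase = pep,
      substrate_accession = get("substrate_accession"),
      substrate_name = get("substrate_name"),
      p1_position = p1,
      residue_start = suppressWarnings(as.integer(get("residue_start"))),
      residue_end = suppressWarnings(as.integer(get("residue_end"))),
      stringsAsFactors = FALSE
    )
    for (k in seq_along(POCKETS)) row[[POCKETS[k]]] <- norm$tokens[k]
    row$group_labels <- glab
    row$cleavage_class <- cls
    row$evidence <- get("evidence")
    row$km <- suppressWarnings(as.numeric(get("km")))
    row$kcat <- suppressWarnings(as.numeric(get("kcat")))
    row$kcat_over_km <- suppressWarnings(as.numeric(get("kcat_over_km")))
    row$reference_id <- get("reference_id")
    row$checksum <- get("checksum")
    if (!is.na(row$residue_start) && !is.na(row$residue_end) &&
        (p1 < row$residue_start || p1 >= row$residue_end)) {
      note(lineno,
           "p1_position outside residue range (or lacks a P1' residue)")
      next
    }
    rows[[i]] <- row
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  records <- if (length(rows)) do.call(rbind, rows) else empty_records()
  out <- cleavage_collection(records, sequences = sequences)
  attr(out, "issues") <- if (length(issues)) {
    do.call(rbind, issues)
  } else {
    data.frame(line = integer(0), message = character(0),
               stringsAsFactors = FALSE)
  }
  out
}

#' Write a cleavage collection as TSV
#'
#' Inverse of [read_cleavages()]: `read_cleavages()` on the written file
#' reproduces the collection record-for-record (round-trip identity on the
#' normalized form).
#'
#' @param collection a [cleavage_collection()].
#' @param file output path; when `NULL` the lines are returned invisibly
#'   without writing.
#' @return invisibly, the character vector of lines.
#' @export
write_cleavages <- function(collection, file = NULL) {
  r <- collection$records
  dot <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x == ""] <- "."
    x
  }
  win <- apply(as.matrix(r[POCKETS]), 1L, format_window)
  if (nrow(r) == 0L) win <- character(0)
  glab <- r$group_labels
  glab[is.na(glab) | glab == ""] <- "."
  body <- paste(
    dot(r$peptidase), dot(r$substrate_accession), dot(r$substrate_name),
    dot(r$p1_position), dot(r$residue_start), dot(r$residue_end),
    win, glab, dot(r$cleavage_class), dot(r$evidence),
    dot(r$km), dot(r$kcat), dot(r$kcat_over_km),
    dot(r$reference_id), dot(r$checksum),
    sep = "\t"
  )
  lines <- c(paste(TSV_COLUMNS, collapse = "\t"), body)
  if (!is.null(file)) writeLines(lines, file, useBytes = TRUE)
  invisible(lines)
}

#' Read substrate sequences from FASTA
#'
#' @param file FASTA path.
#' @return named character vector of upper-case sequences.
#' @export
read_substrate_fasta <- function(file) {
  seqs <- Biostrings::readAAStringSet(file)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Validate one cleavage record
#'
#' Checks the MEROPS identifier, the P1 position against the stored residue
#' range, and (when a sequence is supplied) each non-`X`, non-empty window
#' slot against [extract_window()] at the same position (sequence-drift
#' detection). `X` acts as a wildcard and never raises an issue.
#'
#' @param record one-row data frame or list in the record layout.
#' @param sequence optional amino-acid sequence of the substrate.
#' @return character vector of issues (empty when the record is clean).
#' @export
validate_record <- function(record, sequence = NULL) {
  record <- as.list(record)
  issues <- character(0)
  pep <- record$peptidase
  if (!is.null(pep) && !is.na(pep) && !is_merops_id(pep)) {
    issues <- c(issues, paste0("malformed MEROPS identifier '", pep, "'"))
  }
  p1 <- as.integer(record$p1_position)
  rs <- as.integer(record$residue_start %||% NA)
  re <- as.integer(record$residue_end %||% NA)
  if (!is.na(rs) && !is.na(re) && (p1 < rs || p1 >= re)) {
    issues <- c(issues, "p1_position outside residue range")
  }
  if (!is.null(sequence) && !is.na(p1) && p1 >= 1L &&
      p1 < nchar(sequence)) {
    expected <- extract_window(sequence, p1)
    stored <- vapply(POCKETS, function(p) as.character(record[[p]]),
                     character(1))
    for (k in seq_along(POCKETS)) {
      s <- stored[k]
      if (is.na(s) || s == EMPTY || s == "X") next
      if (s != expected[k]) {
        issues <- c(issues, paste0("window mismatch at ", POCKET_LABELS[k],
                                   ": stored ", s, ", sequence ",
                                   ifelse(expected[k] == EMPTY, "(empty)",
                                          expected[k])))
      }
    }
  }
  issues
}

#' Substrate processing map
#'
#' Collapses a substrate's cleavage records into an ordered list of scissile
#' bonds and the protein fragments they imply. Duplicate
#' (position, peptidase) pairs are collapsed; the map can be filtered by
#' cleavage class as on the substrate display.
#'
#' @param collection a [cleavage_collection()].
#' @param accession substrate accession.
#' @param cleavage_class optional vector of classes to retain.
#' @return object of class `processing_map` with elements `accession`,
#'   `sites` (data frame: `p1_position`, `peptidases`, `classes`),
#'   `fragments` (data frame: `start`, `end`) and `sequence_length`
#'   (`NA` when the sequence is unknown).
#' @export
substrate_map <- function(collection, accession, cleavage_class = NULL) {
  r <- collection$records
  r <- r[!is.na(r$substrate_accession) & r$substrate_accession == accession, ,
         drop = FALSE]
  unknown <- nrow(r) == 0L
  if (unknown) warning("no cleavage records for accession ", accession)
  if (!is.null(cleavage_class)) {
    r <- r[r$cleavage_class %in% cleavage_class, , drop = FALSE]
  }
  seq_len_ <- NA_integer_
  if (accession %in% names(collection$sequences)) {
    seq_len_ <- nchar(collection$sequences[[accession]])
  }
  if (nrow(r)) {
    pep <- ifelse(is.na(r$peptidase), "unmapped", r$peptidase)
    key <- paste(r$p1_position, pep)
    r <- r[!duplicated(key), , drop = FALSE]
    pep <- pep[!duplicated(key)]
    pos <- sort(unique(r$p1_position))
    sites <- data.frame(
      p1_position = pos,
      peptidases = vapply(pos, function(p) {
        paste(sort(unique(pep[r$p1_position == p])), collapse = ",")
      }, character(1)),
      classes = vapply(pos, function(p) {
        paste(sort(unique(r$cleavage_class[r$p1_position == p])),
              collapse = ",")
      }, character(1)),
      stringsAsFactors = FALSE
    )
  } else {
    sites <- data.frame(p1_position = integer(0), peptidases = character(0),
                        classes = character(0), stringsAsFactors = FALSE)
  }
  ends <- c(sites$p1_position, seq_len_)
  starts <- c(1L, sites$p1_position + 1L)
  fragments <- data.frame(start = starts, end = ends)
  structure(list(accession = accession, sites = sites,
                 fragments = fragments, sequence_length = seq_len_,
                 empty = unknown),
            class = "processing_map")
}

#' Render a processing map as text
#'
#' The scissile bond is marked with `+` in the sequence line when the
#' substrate sequence is known.
#'
#' @param map a `processing_map`.
#' @param sequence optional substrate sequence for the cut-marked line.
#' @return character vector of lines.
#' @export
render_processing_map <- function(map, sequence = NULL) {
  lines <- sprintf("substrate %s: %d cleavage site(s)", map$accession,
                   nrow(map$sites))
  if (nrow(map$sites)) {
    lines <- c(lines, sprintf("  %6d  %s  [%s]", map$sites$p1_position,
                              map$sites$peptidases, map$sites$classes))
    frag_end <- ifelse(is.na(map$fragments$end), "end",
                       as.character(map$fragments$end))
    lines <- c(lines, paste0("  fragments: ",
                             paste(sprintf("[%d-%s]", map$fragments$start,
                                           frag_end), collapse = " ")))
  }
  if (!is.null(sequence)) {
    chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
    cut <- rep("", length(chars))
    cut[map$sites$p1_position] <- "+"
    lines <- c(lines, paste0("  ", paste0(chars, cut, collapse = "")))
  }
  lines
}

#' @export
print.processing_map <- function(x, ...) {
  cat(render_processing_map(x), sep = "\n")
  invisible(x)
}
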