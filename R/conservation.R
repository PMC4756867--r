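# Cleavage-site conservation scoring across orthologue alignments
# (the "analyse substrates" service).
#
# The working hypothesis: a cleavage site is likely physiologically
# relevant if it is conserved in orthologues -- conserved not merely in
# sequence but in terms of which residues the peptidase is known to accept
# in each binding pocket. A substitution is acceptable only if that amino
# acid has been observed in the same pocket in at least one other substrate
# cleaved by the same peptidase; otherwise it is an unacceptable
# replacement, and those are counted per pocket P4-P4'.

GAP_CHARS <- c("-", ".")

# Published service limits.
MAX_SUBMISSION_LINES <- 5000L
MAX_SUBMISSION_BYTES <- 10L * 2L^20L

#' Read an analyse-substrates submission file
#'
#' The submission dialect is plain text, one cleavage per line, three
#' whitespace/tab-separated fields: MEROPS identifier of the peptidase,
#' UniProt accession of the substrate, and the 1-based position of the P1
#' residue in the full coding sequence. An optional single header line is
#' skipped. Files with more than 5000 data lines, or larger than 10 MiB,
#' are rejected outright.
#'
#' @param file path to the submission file.
#' @param text optional character vector of lines, used instead of `file`.
#' @param max_lines,max_bytes service limits (overridable).
#' @return data frame of class `submission` with columns `merops_id`,
#'   `substrate_accession`, `p1_position`, plus an `issues` attribute
#'   (data frame: `line`, `message`) for malformed lines.
#' @export
read_submission <- function(file = NULL, text = NULL,
                            max_lines = MAX_SUBMISSION_LINES,
                            max_bytes = MAX_SUBMISSION_BYTES) {
  if (is.null(text)) {
    sz <- file.size(file)
    if (!is.na(sz) && sz > max_bytes) {
      stop("submission rejected: file size ", sz, " bytes exceeds the ",
           max_bytes, "-byte limit", call. = FALSE)
    }
    text <- readLines(file, warn = FALSE)
  } else if (sum(nchar(text, type = "bytes")) > max_bytes) {
    stop("submission rejected: input exceeds the ", max_bytes,
         "-byte limit", call. = FALSE)
  }
  lines <- text[nzchar(trimws(text))]
  first <- if (length(lines)) strsplit(trimws(lines[1L]), "\t|\\s+")[[1L]]
           else character(0)
  has_header <- length(lines) > 0L &&
    (length(first) < 3L || is.na(suppressWarnings(as.integer(first[3L]))) ||
     !is_merops_id(first[1L]))
  # header lines like "MEROPS ID  UniProt  Cleavage position" split into
  # more than 3 whitespace tokens; detect on the tab-split form too
  if (length(lines) && !has_header) {
    tabs <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    if (length(tabs) >= 3L &&
        is.na(suppressWarnings(as.integer(trimws(tabs[3L]))))) {
      has_header <- TRUE
    }
  }
  data_lines <- if (has_header) lines[-1L] else lines
  if (length(data_lines) > max_lines) {
    stop("submission rejected: ", length(data_lines),
         " data lines exceed the ", max_lines, "-line limit",
         call. = FALSE)
  }
  issues <- list()
  rows <- vector("list", length(data_lines))
  for (i in seq_along(data_lines)) {
    lineno <- i + as.integer(has_header)
    fields <- strsplit(trimws(data_lines[i]), "\t|\\s+")[[1L]]
    p1 <- if (length(fields) == 3L) {
      suppressWarnings(as.integer(fields[3L]))
    } else {
      NA_integer_
    }
    if (length(fields) != 3L || !is_merops_id(fields[1L]) ||
        is.na(p1) || p1 < 1L) {
      issues[[length(issues) + 1L]] <- data.frame(
        line = lineno, message = paste0("malformed submission line: '",
                                        data_lines[i], "'"),
        stringsAsFactors = FALSE)
      next
    }
    rows[[i]] <- data.frame(merops_id = fields[1L],
                            substrate_accession = fields[2L],
                            p1_position = p1, stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(merops_id = character(0), substrate_accession = character(0),
               p1_position = integer(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "issues") <- if (length(issues)) do.call(rbind, issues) else {
    data.frame(line = integer(0), message = character(0),
               stringsAsFactors = FALSE)
  }
  class(out) <- c("submission", "data.frame")
  out
}

#' Construct an orthologue alignment
#'
#' @param seqs named character vector of gapped sequences, all the same
#'   length; gaps are `-` or `.`.
#' @param reference_id name of the row whose cleavage is scored (defaults
#'   to the first row).
#' @return object of class `orthologue_alignment` with elements `ids`,
#'   `seqs`, `reference_id`, `ncol`.
#' @export
orthologue_alignment <- function(seqs, reference_id = NULL) {
  stopifnot(is.character(seqs), length(seqs) >= 1L, !is.null(names(seqs)))
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    stop("alignment rows differ in length", call. = FALSE)
  }
  reference_id <- reference_id %||% names(seqs)[1L]
  if (!reference_id %in% names(seqs)) {
    stop("reference row '", reference_id, "' missing from alignment",
         call. = FALSE)
  }
  structure(list(ids = names(seqs), seqs = toupper(seqs),
                 reference_id = reference_id, ncol = widths[[1L]]),
            class = "orthologue_alignment")
}

#' Read an aligned FASTA file as an orthologue alignment
#'
#' @param file aligned FASTA path (emulating a UniRef50 cluster alignment).
#' @param reference_id reference row id; defaults to the first record.
#' @return an [orthologue_alignment()].
#' @export
read_alignment <- function(file, reference_id = NULL) {
  aa <- Biostrings::readAAStringSet(file)
  seqs <- as.character(aa)
  names(seqs) <- sub("\\s.*$", "", names(aa))
  orthologue_alignment(seqs, reference_id)
}

#' Write an orthologue alignment as aligned FASTA
#'
#' @param alignment an [orthologue_alignment()].
#' @param file output path.
#' @export
write_alignment <- function(alignment, file) {
  writeLines(as.vector(rbind(paste0(">", alignment$ids), alignment$seqs)),
             file, useBytes = TRUE)
  invisible(file)
}

#' @export
print.orthologue_alignment <- function(x, ...) {
  cat("orthologue_alignment:", length(x$ids), "rows x", x$ncol,
      "columns; reference", x$reference_id, "\n")
  invisible(x)
}

alignment_chars <- function(alignment) {
  do.call(rbind, strsplit(alignment$seqs, "", fixed = TRUE))
}

ungap <- function(gapped) {
  gsub("[-.]", "", gapped)
}

#' Amino acids observed in a binding pocket across a peptidase's substrates
#'
#' The allowed set for a pocket is every standard amino acid observed
#' (non-`X`, non-empty) at that pocket across the peptidase's cleavage
#' records, excluding the query cleavage itself ("at least one *other*
#' substrate"): records matching the excluded peptidase/accession/position
#' triple do not contribute, but other cleavages of the same substrate do.
#' `X` never enters the set. All cleavage classes are pooled unless the
#' collection was pre-filtered.
#'
#' @param collection a [cleavage_collection()].
#' @param peptidase MEROPS identifier.
#' @param pocket pocket name (`"P4"` ... `"P4'"`).
#' @param exclude optional list/row with `substrate_accession` and
#'   `p1_position` identifying the query cleavage to leave out.
#' @return character vector of standard amino acids (possibly empty; a
#'   warning is raised when the peptidase has no records at all).
#' @export
allowed_residues <- function(collection, peptidase, pocket,
                             exclude = NULL) {
  r <- records_for(collection, peptidase)
  if (nrow(r) == 0L) {
    warning("no cleavage records for peptidase ", peptidase,
            "; allowed set is empty")
    return(character(0))
  }
  if (!is.null(exclude)) {
    exclude <- as.list(exclude)
    drop <- !is.na(r$substrate_accession) &
      r$substrate_accession == exclude$substrate_accession &
      r$p1_position == as.integer(exclude$p1_position)
    r <- r[!drop, , drop = FALSE]
  }
  col <- POCKETS[pocket_index(pocket)]
  obs <- r[[col]]
  sort(unique(obs[obs %in% AA20]))
}

#' Map P4-P4' window slots to alignment columns
#'
#' Gap-aware coordinate translation: for each pocket, the alignment column
#' holding the corresponding residue of the ungapped reference row. Slots
#' beyond the reference termini are `NA` (absent pocket).
#'
#' @param alignment an [orthologue_alignment()].
#' @param p1_position 1-based P1 residue number in the ungapped reference.
#' @return named integer vector of length 8 (1-based columns, `NA` for
#'   absent slots).
#' @export
map_window_columns <- function(alignment, p1_position) {
  ref <- alignment$seqs[[match(alignment$reference_id, alignment$ids)]]
  chars <- strsplit(ref, "", fixed = TRUE)[[1L]]
  nongap <- which(!chars %in% GAP_CHARS)
  nres <- length(nongap)
  p1_position <- as.integer(p1_position)
  if (is.na(p1_position) || p1_position < 1L || p1_position > nres) {
    stop("p1_position ", p1_position,
         " beyond the ungapped reference length ", nres, call. = FALSE)
  }
  pos <- p1_position + POCKET_OFFSETS
  cols <- ifelse(pos >= 1L & pos <= nres, nongap[pmax(pmin(pos, nres), 1L)],
                 NA_integer_)
  stats::setNames(as.integer(cols), POCKET_LABELS)
}

#' Classify one aligned residue against the reference and allowed set
#'
#' @param observed character(s) from an alignment row at a mapped column.
#' @param reference the reference residue at that column.
#' @param allowed allowed amino-acid set for the pocket (from
#'   [allowed_residues()]).
#' @return character vector over the closed vocabulary `"identical"`,
#'   `"acceptable"`, `"unacceptable"`, `"undetermined"`, `"gap"`.
#' @export
classify_substitution <- function(observed, reference, allowed) {
  observed <- toupper(observed)
  reference <- toupper(reference)
  out <- rep("unacceptable", length(observed))
  out[observed %in% allowed] <- "acceptable"
  out[observed == reference] <- "identical"
  out[!observed %in% AA20] <- "undetermined"  # X / non-standard symbols
  out[observed %in% GAP_CHARS] <- "gap"
  out
}

#' Score conservation of one cleavage site
#'
#' For each pocket P4-P4', counts the alignment rows (other than the
#' reference) whose residue at the mapped column is an unacceptable
#' replacement: a standard amino acid, different from the reference
#' residue, never observed in that pocket in any other substrate of the
#' peptidase. Identical residues, acceptable substitutions, undetermined
#' residues (`X`) and gaps never count. Pockets absent from the reference
#' (cleavage near a terminus) score 0.
#'
#' @param collection a [cleavage_collection()].
#' @param alignment an [orthologue_alignment()] whose reference is the
#'   submitted substrate.
#' @param item list/row with `merops_id`, `substrate_accession`,
#'   `p1_position`.
#' @return object of class `conservation_result`: list with `merops_id`,
#'   `total_cleavages`, `substrate_accession`, `n_homologues` (all rows,
#'   reference included), `p1_position`, `unacceptable_counts` (named
#'   length-8 integer), `calls` (row x pocket matrix of residue calls) and
#'   `columns` (the mapped alignment columns).
#' @export
analyse_cleavage <- function(collection, alignment, item) {
  item <- as.list(item)
  if (!identical(alignment$reference_id, item$substrate_accession)) {
    stop("alignment reference '", alignment$reference_id,
         "' does not match submitted accession '",
         item$substrate_accession, "'", call. = FALSE)
  }
  total <- nrow(records_for(collection, item$merops_id))
  if (total == 0L) {
    warning("peptidase ", item$merops_id,
            " has no records in the collection")
  }
  cols <- map_window_columns(alignment, item$p1_position)
  chars <- alignment_chars(alignment)
  ref_row <- match(alignment$reference_id, alignment$ids)
  other <- setdiff(seq_along(alignment$ids), ref_row)
  calls <- matrix(NA_character_, nrow = length(alignment$ids), ncol = 8L,
                  dimnames = list(alignment$ids, POCKET_LABELS))
  counts <- stats::setNames(integer(8L), POCKET_LABELS)
  for (j in seq_len(8L)) {
    if (is.na(cols[j])) next
    refch <- chars[ref_row, cols[j]]
    # the missing-peptidase warning was already raised once above
    allowed <- suppressWarnings(
      allowed_residues(collection, item$merops_id, POCKET_LABELS[j],
                       exclude = item))
    calls[, j] <- classify_substitution(chars[, cols[j]], refch, allowed)
    counts[j] <- sum(calls[other, j] == "unacceptable")
  }
  structure(list(merops_id = item$merops_id, total_cleavages = total,
                 substrate_accession = item$substrate_accession,
                 n_homologues = length(alignment$ids),
                 p1_position = as.integer(item$p1_position),
                 unacceptable_counts = counts, calls = calls,
                 columns = cols),
            class = "conservation_result")
}

#' @export
print.conservation_result <- function(x, ...) {
  cat("conservation_result:", x$merops_id, "cleaving",
      x$substrate_accession, "after residue", x$p1_position, "\n")
  cat("  homologues:", x$n_homologues, " known cleavages:",
      x$total_cleavages, "\n  unacceptable replacements:\n")
  print(x$unacceptable_counts)
  invisible(x)
}

RESULT_COLUMNS <- c("merops_id", "total_cleavages", "substrate_accession",
                    "n_homologues", "p1_position",
                    paste0(POCKETS, "_count"), "alignment", "status")

#' Run a batch of conservation analyses
#'
#' One output row per submission item, in file order, with the result
#' columns in the service's layout: MEROPS identifier, total cleavages
#' known for the peptidase, substrate accession, number of homologues
#' aligned, cleavage position, the eight unacceptable-replacement counts
#' P4-P4', and an alignment locator (a local file path here). Items
#' without an alignment are emitted with status `"no-alignment"` rather
#' than dropped. Output is deterministic: the same inputs yield a
#' byte-identical table.
#'
#' @param submission a [read_submission()] data frame.
#' @param collection a [cleavage_collection()].
#' @param alignments either a named list of [orthologue_alignment()]
#'   objects keyed by accession, or a directory containing
#'   `<accession>.fasta` files.
#' @param cleavage_class optional class filter applied to the collection
#'   before allowed sets are built.
#' @return data frame in the result-column layout above, plus the list of
#'   `conservation_result` objects in `attr(, "results")`.
#' @export
run_batch <- function(submission, collection, alignments,
                      cleavage_class = NULL) {
  if (!is.null(cleavage_class)) {
    collection$records <- collection$records[
      collection$records$cleavage_class %in% cleavage_class, ,
      drop = FALSE]
  }
  fetch <- function(acc) {
    if (is.character(alignments)) {
      for (ext in c(".fasta", ".fa", ".afa")) {
        f <- file.path(alignments, paste0(acc, ext))
        if (file.exists(f)) return(list(aln = read_alignment(f, acc),
                                        locator = f))
      }
      return(NULL)
    }
    if (!is.null(alignments[[acc]])) {
      return(list(aln = alignments[[acc]], locator = acc))
    }
    NULL
  }
  rows <- vector("list", nrow(submission))
  results <- vector("list", nrow(submission))
  for (i in seq_len(nrow(submission))) {
    item <- submission[i, ]
    src <- fetch(item$substrate_accession)
    if (is.null(src)) {
      counts <- stats::setNames(rep(NA_integer_, 8L), POCKETS)
      rows[[i]] <- data.frame(
        merops_id = item$merops_id,
        total_cleavages = nrow(records_for(collection, item$merops_id)),
        substrate_accession = item$substrate_accession,
        n_homologues = NA_integer_, p1_position = item$p1_position,
        t(counts), alignment = NA_character_, status = "no-alignment",
        stringsAsFactors = FALSE)
      next
    }
    res <- withCallingHandlers(
      analyse_cleavage(collection, src$aln, item),
      warning = function(w) invokeRestart("muffleWarning"))
    results[[i]] <- res
    counts <- stats::setNames(res$unacceptable_counts, POCKETS)
    rows[[i]] <- data.frame(
      merops_id = res$merops_id, total_cleavages = res$total_cleavages,
      substrate_accession = res$substrate_accession,
      n_homologues = res$n_homologues, p1_position = res$p1_position,
      t(counts), alignment = src$locator,
      status = if (res$total_cleavages == 0L) "unknown-peptidase" else "ok",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  names(out) <- RESULT_COLUMNS
  rownames(out) <- NULL
  attr(out, "results") <- results
  out
}

#' Write a batch-results table as TSV
#'
#' @param results data frame from [run_batch()].
#' @param file output path.
#' @export
write_results <- function(results, file) {
  lines <- c(paste(RESULT_COLUMNS, collapse = "\t"),
             apply(results, 1L, function(row) {
               row[is.na(row)] <- "."
               paste(trimws(row), collapse = "\t")
             }))
  if (nrow(results) == 0L) lines <- lines[1L]
  writeLines(lines, file, useBytes = TRUE)
  invisible(file)
}

#' Render an annotated substrate alignment
#'
#' Text rendering of the per-row residue calls across the P4-P4' window:
#' `=K=` identical to the reference, `+R+` acceptable (observed in the
#' same pocket in another substrate), `!H!` unacceptable, `?X?`
#' undetermined, bare `-` for gaps. The reference row is marked with `>`.
#'
#' @param alignment an [orthologue_alignment()].
#' @param item submission item (`merops_id`, `substrate_accession`,
#'   `p1_position`).
#' @param collection a [cleavage_collection()].
#' @return character vector of lines (invisibly printable).
#' @export
render_alignment <- function(alignment, item, collection) {
  res <- analyse_cleavage(collection, alignment, item)
  chars <- alignment_chars(alignment)
  idw <- max(nchar(alignment$ids))
  header <- sprintf("%s cleaves %s after residue %d (window P4-P4')",
                    res$merops_id, res$substrate_accession,
                    res$p1_position)
  lines <- c(header, paste(format("", width = idw + 2L),
                           paste(sprintf("%-3s", POCKET_LABELS),
                                 collapse = " ")))
  for (i in seq_along(alignment$ids)) {
    marks <- vapply(seq_len(8L), function(j) {
      if (is.na(res$columns[j])) return("   ")
      ch <- chars[i, res$columns[j]]
      switch(res$calls[i, j],
             identical = paste0("=", ch, "="),
             acceptable = paste0("+", ch, "+"),
             unacceptable = paste0("!", ch, "!"),
             undetermined = paste0("?", ch, "?"),
             gap = " - ")
    }, character(1))
    tag <- if (alignment$ids[i] == alignment$reference_id) "> " else "  "
    lines <- c(lines, paste0(tag, format(alignment$ids[i], width = idw),
                             " ", paste(marks, collapse = " ")))
  }
  structure(lines, class = "alignment_render")
}

#' @export
print.alignment_render <- function(x, ...) {
  cat(unclass(x), sep = "\n")
  invisible(x)
}
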