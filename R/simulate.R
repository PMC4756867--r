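# Seeded synthetic-data generators: cleavage collections with controlled
# per-pocket preference distributions, and orthologue alignments with
# controlled identity, indels and planted substitutions. All generators
# are pure functions of their spec (seed included).

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification for a simulated cleavage collection
#'
#' Defines the per-pocket categorical distributions windows are drawn
#' from. Each pocket's distribution is a named numeric vector over the 20
#' standard amino acids plus optionally `"EMPTY"` (for exopeptidase-style
#' windows); it is normalized to sum to 1. Unspecified pockets default to
#' the uniform distribution over the 20 amino acids; pockets masked by the
#' activity class are forced to an `EMPTY` point mass. `P1` may not carry
#' `EMPTY` mass.
#'
#' @param peptidase MEROPS identifier for the simulated peptidase.
#' @param activity_class activity class (controls which pockets are
#'   structurally empty).
#' @param n_records number of cleavage records to draw.
#' @param pocket_probs optional named list (`"P4"` ... `"P4'"`) of named
#'   probability vectors.
#' @param cleavage_class class assigned to the simulated records.
#' @param seed RNG seed.
#' @return list of class `profile_spec`.
#' @export
profile_spec <- function(peptidase = "X01.001",
                         activity_class = "endopeptidase",
                         n_records = 100L, pocket_probs = NULL,
                         cleavage_class = "physiological",
                         seed = 1L) {
  stopifnot(is_merops_id(peptidase))
  activity_class <- match.arg(activity_class, ACTIVITY_CLASSES)
  cleavage_class <- match.arg(cleavage_class, CLEAVAGE_CLASSES)
  masked <- masked_pockets(activity_class)
  probs <- stats::setNames(vector("list", 8L), POCKETS)
  uniform <- stats::setNames(rep(1 / 20, 20L), AA20)
  for (j in seq_len(8L)) {
    pocket <- POCKETS[j]
    if (pocket %in% masked) {
      probs[[pocket]] <- c(EMPTY = 1)
      next
    }
    p <- pocket_probs[[pocket]] %||% pocket_probs[[POCKET_LABELS[j]]] %||%
      uniform
    if (any(p < 0) || sum(p) <= 0) {
      stop("invalid distribution for pocket ", POCKET_LABELS[j],
           call. = FALSE)
    }
    bad <- setdiff(names(p), c(AA20, "EMPTY"))
    if (length(bad)) {
      stop("unknown symbols in pocket ", POCKET_LABELS[j], ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (pocket == "P1" && "EMPTY" %in% names(p) && p[["EMPTY"]] > 0) {
      stop("P1 may not carry EMPTY mass", call. = FALSE)
    }
    probs[[pocket]] <- p / sum(p)
  }
  structure(list(peptidase = peptidase, activity_class = activity_class,
                 n_records = as.integer(n_records), pocket_probs = probs,
                 cleavage_class = cleavage_class, seed = as.integer(seed)),
            class = "profile_spec")
}

#' Simulate a cleavage collection
#'
#' Draws `n_records` P4-P4' windows i.i.d. per pocket from the spec's
#' distributions and wraps them as a [cleavage_collection()] with the
#' peptidase registered at its activity class. Each record is a distinct
#' synthetic substrate. Reproducible: the same spec (seed included)
#' yields an identical collection.
#'
#' @param spec a [profile_spec()].
#' @return a [cleavage_collection()].
#' @export
simulate_collection <- function(spec) {
  stopifnot(inherits(spec, "profile_spec"))
  n <- spec$n_records
  with_seed(spec$seed, {
    win <- matrix(EMPTY, nrow = n, ncol = 8L,
                  dimnames = list(NULL, POCKETS))
    for (j in seq_len(8L)) {
      p <- spec$pocket_probs[[j]]
      syms <- names(p)
      syms[syms == "EMPTY"] <- EMPTY
      win[, j] <- sample(syms, n, replace = TRUE, prob = p)
    }
    records <- data.frame(
      peptidase = rep(spec$peptidase, n),
      substrate_accession = sprintf("SYN%04d", seq_len(n)),
      substrate_name = sprintf("synthetic substrate %d", seq_len(n)),
      p1_position = rep(10L, n),
      stringsAsFactors = FALSE)
    for (j in seq_len(8L)) records[[POCKETS[j]]] <- win[, j]
    records$cleavage_class <- spec$cleavage_class
    cleavage_collection(
      records,
      peptidases = peptidase_entry(spec$peptidase,
                                   activity_class = spec$activity_class))
  })
}

#' Specification for a simulated orthologue alignment
#'
#' Emulates a UniRef50 cluster alignment around one reference substrate:
#' homologue rows diverge from the reference by per-site substitutions and
#' indels, while the P4-P4' window around `p1_position` is held invariant
#' (conserved) except where substitutions are explicitly planted.
#' Insertions are global column events in which the reference carries a
#' gap, so reference residue coordinates stay stable; deletions are
#' per-row gaps. Planted residues override every other process.
#'
#' @param reference reference amino-acid sequence; when `NULL`, a random
#'   sequence of `ref_length` residues is drawn.
#' @param reference_id id of the reference row (the substrate accession).
#' @param ref_length length used when `reference` is `NULL`.
#' @param n_rows total alignment rows, reference included.
#' @param p1_position P1 residue number of the cleavage being emulated.
#' @param sub_prob per-site substitution probability in homologue rows.
#' @param indel_prob per-site indel probability (split evenly between
#'   per-row deletions and global insertion events).
#' @param max_indel maximum insertion length (columns per event).
#' @param conserve_window hold the window positions invariant in every
#'   row (planted substitutions still apply).
#' @param planted data frame with columns `row` (homologue index, 1 = the
#'   first non-reference row), `pocket` (`"P4"` ... `"P4'"`), `residue`.
#' @param seed RNG seed.
#' @return list of class `orthologue_spec`.
#' @export
orthologue_spec <- function(reference = NULL, reference_id = "REF0001",
                            ref_length = 120L, n_rows = 10L,
                            p1_position = 60L, sub_prob = 0.05,
                            indel_prob = 0.02, max_indel = 3L,
                            conserve_window = TRUE, planted = NULL,
                            seed = 1L) {
  stopifnot(n_rows >= 1L, sub_prob >= 0, sub_prob <= 1,
            indel_prob >= 0, indel_prob <= 1)
  if (!is.null(planted)) {
    stopifnot(all(c("row", "pocket", "residue") %in% names(planted)))
  }
  structure(list(reference = reference, reference_id = reference_id,
                 ref_length = as.integer(ref_length),
                 n_rows = as.integer(n_rows),
                 p1_position = as.integer(p1_position),
                 sub_prob = sub_prob, indel_prob = indel_prob,
                 max_indel = as.integer(max_indel),
                 conserve_window = conserve_window, planted = planted,
                 seed = as.integer(seed)),
            class = "orthologue_spec")
}

#' Simulate an orthologue alignment
#'
#' @param spec an [orthologue_spec()].
#' @return an [orthologue_alignment()] whose reference row, once
#'   ungapped, equals the input reference sequence.
#' @export
simulate_orthologues <- function(spec) {
  stopifnot(inherits(spec, "orthologue_spec"))
  with_seed(spec$seed, {
    ref_chars <- if (is.null(spec$reference)) {
      sample(AA20, spec$ref_length, replace = TRUE)
    } else {
      strsplit(toupper(spec$reference), "", fixed = TRUE)[[1L]]
    }
    L <- length(ref_chars)
    p1 <- spec$p1_position
    if (p1 < 1L || p1 >= L) {
      stop("p1_position must lie within the reference (with a P1' residue)",
           call. = FALSE)
    }
    win_pos <- p1 + POCKET_OFFSETS
    win_pos <- win_pos[win_pos >= 1L & win_pos <= L]
    conserved <- if (spec$conserve_window) win_pos else integer(0)
    free <- setdiff(seq_len(L), conserved)
    n_hom <- spec$n_rows - 1L
    mat <- matrix(rep(ref_chars, each = spec$n_rows), nrow = spec$n_rows)
    for (r in seq_len(n_hom)) {
      i <- r + 1L
      subs <- free[stats::runif(length(free)) < spec$sub_prob]
      for (pos in subs) {
        mat[i, pos] <- sample(setdiff(AA20, ref_chars[pos]), 1L)
      }
      dels <- free[stats::runif(length(free)) < spec$indel_prob / 2]
      mat[i, dels] <- "-"
    }
    # planted substitutions override substitutions and deletions
    if (!is.null(spec$planted)) {
      for (k in seq_len(nrow(spec$planted))) {
        pl <- spec$planted[k, ]
        pos <- p1 + POCKET_OFFSETS[pocket_index(pl$pocket)]
        if (pos < 1L || pos > L) {
          stop("planted position for pocket ", pl$pocket,
               " falls outside the reference", call. = FALSE)
        }
        if (pl$row < 1L || pl$row > n_hom) {
          stop("planted row index ", pl$row, " out of range", call. = FALSE)
        }
        mat[pl$row + 1L, pos] <- toupper(pl$residue)
      }
    }
    # global insertion events: reference (and non-carrying rows) get gaps
    n_events <- if (n_hom > 0L) stats::rbinom(1L, L, spec$indel_prob / 2)
                else 0L
    events <- list()
    if (n_events > 0L) {
      bounds <- sample(0:L, n_events, replace = TRUE)
      for (b in bounds) {
        len <- sample.int(spec$max_indel, 1L)
        carriers <- which(stats::runif(n_hom) < 0.5) + 1L
        block <- matrix("-", nrow = spec$n_rows, ncol = len)
        for (ci in carriers) {
          block[ci, ] <- sample(AA20, len, replace = TRUE)
        }
        events[[length(events) + 1L]] <- list(after = b, block = block)
      }
    }
    pieces <- list()
    prev <- 0L
    for (ev in events[order(vapply(events, `[[`, integer(1), "after"))]) {
      if (ev$after > prev) {
        pieces[[length(pieces) + 1L]] <- mat[, seq(prev + 1L, ev$after),
                                             drop = FALSE]
      }
      pieces[[length(pieces) + 1L]] <- ev$block
      prev <- max(prev, ev$after)
    }
    if (prev < L) {
      pieces[[length(pieces) + 1L]] <- mat[, seq(prev + 1L, L),
                                           drop = FALSE]
    }
    full <- do.call(cbind, pieces)
    seqs <- apply(full, 1L, paste, collapse = "")
    names(seqs) <- c(spec$reference_id,
                     sprintf("HOM%04d", seq_len(n_hom)))
    orthologue_alignment(seqs, spec$reference_id)
  })
}
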