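# Specificity matrices, logo weights, the reliability score and rule-based
# preference calling per peptidase.

records_for <- function(collection, peptidase) {
  r <- collection$records
  r[!is.na(r$peptidase) & r$peptidase == peptidase, , drop = FALSE]
}

# n x 8 character matrix of window tokens, non-standard symbols masked to X.
windows_matrix <- function(records) {
  m <- as.matrix(records[POCKETS])
  m[!(m %in% c(AA20, "X", EMPTY))] <- "X"
  m
}

#' Build a specificity count matrix
#'
#' Tallies every non-empty window slot for one peptidase into a 21 x 8 table
#' (20 standard amino acids plus `X` for non-standard residues and
#' blocking/reporter groups, by pocket P4-P4'). Percentages are taken
#' against the total number of cleavages, not per-pocket occupancy;
#' occupancy (non-empty observations per pocket) is carried alongside so
#' sparse pockets stay interpretable.
#'
#' @param collection a [cleavage_collection()].
#' @param peptidase MEROPS identifier with at least one record.
#' @return object of class `specificity_matrix`: list with `peptidase`,
#'   `n_cleavages`, `counts` (21 x 8 integer matrix, rows in
#'   property-grouped display order), `occupancy` (length-8 integer).
#' @export
build_matrix <- function(collection, peptidase) {
  r <- records_for(collection, peptidase)
  if (nrow(r) == 0L) {
    stop("no cleavage records for peptidase ", peptidase, call. = FALSE)
  }
  m <- windows_matrix(r)
  counts <- matrix(0L, nrow = length(AA_DISPLAY_ORDER), ncol = 8L,
                   dimnames = list(AA_DISPLAY_ORDER, POCKET_LABELS))
  for (j in seq_len(8L)) {
    tab <- table(factor(m[, j], levels = AA_DISPLAY_ORDER))
    counts[, j] <- as.integer(tab)
  }
  occupancy <- colSums(counts)
  structure(list(peptidase = peptidase, n_cleavages = nrow(r),
                 counts = counts,
                 occupancy = stats::setNames(as.integer(occupancy),
                                             POCKET_LABELS)),
            class = "specificity_matrix")
}

#' @export
print.specificity_matrix <- function(x, ...) {
  cat("specificity_matrix for", x$peptidase, "(", x$n_cleavages,
      "cleavages )\n")
  print(x$counts)
  invisible(x)
}

#' Percentage form of a specificity matrix
#'
#' @param matrix a `specificity_matrix`.
#' @return 21 x 8 numeric matrix of `count / n_cleavages * 100`.
#' @export
matrix_percentages <- function(matrix) {
  matrix$counts / matrix$n_cleavages * 100
}

#' Decile shading of a specificity matrix
#'
#' Each cell is assigned the decile bin `floor(pct / 10)` (a cell at 100%
#' falls in bin 10), mirroring the green-shade display; amino acids with
#' zero count across all eight pockets are flagged as unobserved anywhere
#' (rendered white-on-black on the website display).
#'
#' @param matrix a `specificity_matrix`.
#' @return list with `bins` (21 x 8 integer matrix) and
#'   `unobserved_anywhere` (named logical).
#' @export
shade_matrix <- function(matrix) {
  pct <- matrix_percentages(matrix)
  bins <- pmin(floor(pct / 10), 10)
  storage.mode(bins) <- "integer"
  unobserved <- rowSums(matrix$counts) == 0L
  list(bins = bins, unobserved_anywhere = unobserved)
}

#' Sequence-logo letter heights
#'
#' Per pocket, relative frequencies over observed standard residues (`X`
#' excluded) are scaled by the Shannon information content
#' `R = log2(20) - H`, WebLogo style, without small-sample correction.
#' Pockets with zero occupancy get all-zero heights. The pocket axis is
#' conventionally numbered 1-8 for S4-S4'.
#'
#' @param matrix a `specificity_matrix`.
#' @return 20 x 8 numeric matrix of letter heights in bits; columns carry
#'   the pocket labels, with the 1-8 axis in `attr(, "position")`.
#' @export
logo_weights <- function(matrix) {
  counts <- matrix$counts[AA20, , drop = FALSE]
  heights <- matrix(0, nrow = length(AA20), ncol = 8L,
                    dimnames = list(AA20, POCKET_LABELS))
  for (j in seq_len(8L)) {
    tot <- sum(counts[, j])
    if (tot == 0L) next
    p <- counts[, j] / tot
    nz <- p > 0
    H <- -sum(p[nz] * log2(p[nz]))
    R <- log2(20) - H
    heights[, j] <- p * R
  }
  attr(heights, "position") <- seq_len(8L)
  heights
}

#' Reliability score: average pairwise window difference
#'
#' The reliability score for a peptidase is the average percentage
#' difference between the P4-P4' windows of all its substrates: every
#' unordered pair of records is compared pocket-by-pocket, differences are
#' summed, and the sum is divided by the number of comparisons times the
#' number of positions considered. Non-standard residues and blocking or
#' reporter groups are replaced by `X` before comparison. The number of
#' positions considered is calculated from the data (pockets occupied in at
#' least one record), not assumed from the activity class: typically 8 for
#' endopeptidases, 5 for amino-/carboxypeptidases, 6 for
#' dipeptidyl-/peptidyl-dipeptidases, 2 for dipeptidases. Two `X` slots (or
#' two empty slots) are equal; `X` against a residue, or empty against a
#' residue at a considered pocket, counts as a difference.
#'
#' A score above 75 indicates varied substrates and trustworthy inferred
#' preferences (band `"green"`); 50-74 less reliable (`"yellow"`); below 50
#' should be treated with caution (`"red"`).
#'
#' @param collection a [cleavage_collection()].
#' @param peptidase MEROPS identifier with at least two records.
#' @return list with `score` (percent in [0, 100]), `band`,
#'   `n_positions_considered`, `n_records`, `n_pairs`.
#' @export
reliability_score <- function(collection, peptidase) {
  r <- records_for(collection, peptidase)
  if (nrow(r) < 2L) {
    stop("reliability score needs >= 2 records for ", peptidase,
         call. = FALSE)
  }
  m <- windows_matrix(r)
  n <- nrow(m)
  n_pairs <- n * (n - 1) / 2
  considered <- which(colSums(m != EMPTY) > 0L)
  diff_sum <- 0
  for (j in considered) {
    same <- sum(choose(table(m[, j]), 2))
    diff_sum <- diff_sum + (n_pairs - same)
  }
  score <- 100 * diff_sum / (n_pairs * length(considered))
  list(score = score, band = reliability_band(score),
       n_positions_considered = length(considered),
       n_records = n, n_pairs = n_pairs)
}

#' Reliability band for a score
#'
#' @param score percentage in [0, 100].
#' @return `"green"` (>= 75), `"yellow"` (50-74) or `"red"` (< 50).
#' @export
reliability_band <- function(score) {
  ifelse(score >= 75, "green", ifelse(score >= 50, "yellow", "red"))
}

#' Low-confidence caution flag
#'
#' At least 40 cleavages in disparate substrates are required for
#' specificity analysis to be meaningful; profiles built from fewer carry
#' this caution flag.
#'
#' @param n_cleavages integer count of known cleavages.
#' @return `TRUE` iff `n_cleavages < 40`.
#' @export
low_confidence_flag <- function(n_cleavages) {
  n_cleavages < 40
}

# Minimum cleavages before a specificity display (logo + matrix) is shown.
MIN_DISPLAY_CLEAVAGES <- 10L
# Minimum cleavages before negative (never-observed) preferences are shown.
MIN_NEGATIVE_CLEAVAGES <- 200L

#' Call pocket preferences from a specificity matrix
#'
#' Applies the display rules pocket by pocket. With `p(a)` the percentage
#' of cleavages carrying amino acid `a` at the pocket:
#' \itemize{
#'   \item if the largest single `p(a)` reaches 50%, the pocket is called
#'     for the top one or two amino acids (the second only if its own
#'     percentage also reaches 50%), with a shade band from the combined
#'     percentage: `"50-59"`, `"60-69"`, `"70-79"`, `"80-89"` or `"90+"`;
#'   \item otherwise, if an amino-acid property group's summed percentage
#'     reaches 50% and exceeds every single amino acid's percentage, the
#'     group symbol is called: aliphatic (I/L/V), aromatic (F/W/Y), acidic
#'     (D/E), basic (R/H/K), small (A/C/G/S), other (N/Q/M/P/T);
#'   \item otherwise, when 200 or more cleavages are known, up to two
#'     never-observed amino acids are reported as a negative preference
#'     (picked by lowest whole-matrix frequency, then alphabetically) --
#'     absence only becomes meaningful at that depth because some amino
#'     acids (Cys, Trp) are rare near cleavage sites;
#'   \item otherwise the pocket has no call.
#' }
#' Pockets that cannot structurally exist for the activity class (e.g.
#' P4-P2 for an aminopeptidase) are masked regardless of counts, and a
#' pocket never observed occupied yields no negative call. Ties are broken
#' by higher count first, then alphabetically by one-letter code.
#'
#' @param matrix a `specificity_matrix`.
#' @param activity_class activity class of the peptidase (controls
#'   masking).
#' @param score optional reliability score result from
#'   [reliability_score()], attached to the profile.
#' @return object of class `preference_profile`: data frame with one row
#'   per pocket (`pocket`, `state`, `call`, `symbol`, `pct`, `band`) and
#'   attributes `peptidase`, `n_cleavages`, `reliability_score`,
#'   `reliability_band`, `low_confidence`.
#' @export
call_preferences <- function(matrix, activity_class = "endopeptidase",
                             score = NULL) {
  activity_class <- match.arg(activity_class, ACTIVITY_CLASSES)
  masked <- masked_pockets(activity_class)
  n <- matrix$n_cleavages
  pct <- matrix_percentages(matrix)[AA20, , drop = FALSE]
  total_counts <- rowSums(matrix$counts[AA20, , drop = FALSE])
  rows <- vector("list", 8L)
  for (j in seq_len(8L)) {
    pocket <- POCKETS[j]
    if (pocket %in% masked) {
      rows[[j]] <- data.frame(pocket = POCKET_LABELS[j], state = "masked",
                              call = NA_character_, symbol = NA_character_,
                              pct = NA_real_, band = NA_character_,
                              stringsAsFactors = FALSE)
      next
    }
    p <- pct[, j]
    cnt <- matrix$counts[AA20, j]
    ord <- order(-cnt, AA20)
    lead <- AA20[ord[1L]]
    state <- "none"; call <- NA_character_; symbol <- NA_character_
    cell_pct <- NA_real_; band <- NA_character_
    if (p[lead] >= 50) {
      picked <- lead
      second <- AA20[ord[2L]]
      if (p[second] >= 50) picked <- c(picked, second)
      state <- "preferred"
      call <- paste(picked, collapse = ",")
      symbol <- call
      cell_pct <- sum(p[picked])
      band <- shade_band(cell_pct)
    } else {
      gsum <- vapply(AA_GROUPS, function(g) sum(p[g]), numeric(1))
      gbest <- names(gsum)[order(-gsum)][1L]
      if (gsum[gbest] >= 50 && gsum[gbest] > max(p)) {
        state <- "preferred"
        call <- gbest
        symbol <- GROUP_SYMBOLS[[gbest]]
        cell_pct <- gsum[[gbest]]
        band <- shade_band(cell_pct)
      } else if (n >= MIN_NEGATIVE_CLEAVAGES &&
                 matrix$occupancy[j] > 0L) {
        zeros <- AA20[cnt == 0L]
        if (length(zeros)) {
          zeros <- zeros[order(total_counts[zeros], zeros)]
          picked <- zeros[seq_len(min(2L, length(zeros)))]
          state <- "negative"
          call <- paste(picked, collapse = ",")
          symbol <- call
        }
      }
    }
    rows[[j]] <- data.frame(pocket = POCKET_LABELS[j], state = state,
                            call = call, symbol = symbol, pct = cell_pct,
                            band = band, stringsAsFactors = FALSE)
  }
  profile <- do.call(rbind, rows)
  attr(profile, "peptidase") <- matrix$peptidase
  attr(profile, "n_cleavages") <- n
  attr(profile, "reliability_score") <-
    if (is.null(score)) NA_real_ else score$score
  attr(profile, "reliability_band") <-
    if (is.null(score)) NA_character_ else score$band
  attr(profile, "low_confidence") <- low_confidence_flag(n)
  class(profile) <- c("preference_profile", "data.frame")
  profile
}

#' @export
print.preference_profile <- function(x, ...) {
  cat("preference_profile for", attr(x, "peptidase"), "(",
      attr(x, "n_cleavages"), "cleavages )\n")
  if (isTRUE(attr(x, "low_confidence"))) {
    cat("  caution: fewer than 40 cleavages; preferences may be",
        "unreliable\n")
  }
  rs <- attr(x, "reliability_score")
  if (!is.na(rs)) {
    cat(sprintf("  reliability: %.1f%% (%s)\n", rs,
                attr(x, "reliability_band")))
  }
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Full specificity display for a peptidase
#'
#' Bundles the count matrix, decile shading, logo weights, reliability
#' score and called preferences. The display is only emitted when ten or
#' more cleavages are known (the threshold used for showing a logo and
#' matrix on a peptidase summary); below that `NULL` is returned with a
#' message. Profiles from fewer than 40 cleavages carry the low-confidence
#' caution.
#'
#' @param collection a [cleavage_collection()].
#' @param peptidase MEROPS identifier.
#' @param activity_class optional activity class; defaults to the
#'   registered entry (or `"endopeptidase"`).
#' @return list with `matrix`, `shades`, `logo`, `reliability`, `profile`,
#'   `low_confidence`; or `NULL` below the display threshold.
#' @export
specificity_display <- function(collection, peptidase,
                                activity_class = NULL) {
  r <- records_for(collection, peptidase)
  if (nrow(r) < MIN_DISPLAY_CLEAVAGES) {
    message("specificity display suppressed: only ", nrow(r),
            " cleavage(s) known for ", peptidase, " (need ",
            MIN_DISPLAY_CLEAVAGES, ")")
    return(invisible(NULL))
  }
  activity_class <- activity_class %||% activity_class_of(collection,
                                                          peptidase)
  m <- build_matrix(collection, peptidase)
  rel <- if (nrow(r) >= 2L) reliability_score(collection, peptidase) else NULL
  list(matrix = m,
       shades = shade_matrix(m),
       logo = logo_weights(m),
       reliability = rel,
       profile = call_preferences(m, activity_class, rel),
       low_confidence = low_confidence_flag(m$n_cleavages))
}
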