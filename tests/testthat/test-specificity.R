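# Specificity matrices, logo weights, reliability score and preference
# calling.

test_that("build_matrix tallies occurrences against total cleavages", {
  win <- matrix(rep(c("G", "A", "A", "K", "S", "V", "L", "M"), 10),
                nrow = 10, byrow = TRUE)
  coll <- collection_from_windows(win)
  m <- build_matrix(coll, "X01.001")
  expect_equal(m$n_cleavages, 10L)
  expect_equal(m$counts["G", "P4"], 10L)
  expect_equal(unname(matrix_percentages(m)["G", "P4"]), 100)
  expect_equal(unname(m$occupancy["P1"]), 10L)

  # two windows differing only at P1
  win2 <- rbind(c("A", "C", "D", "R", "F", "G", "H", "I"),
                c("A", "C", "D", "K", "F", "G", "H", "I"))
  m2 <- build_matrix(collection_from_windows(win2), "X01.001")
  expect_equal(unname(m2$counts[c("R", "K"), "P1"]), c(1L, 1L))
  expect_equal(unname(matrix_percentages(m2)["R", "P1"]), 50)

  # aminopeptidase-style empty non-prime side
  win3 <- rbind(c("", "", "", "K", "F", "G", "H", "I"),
                c("", "", "", "R", "F", "G", "H", "I"))
  m3 <- build_matrix(collection_from_windows(win3), "X01.001")
  expect_equal(unname(m3$occupancy[c("P4", "P3", "P2")]), c(0L, 0L, 0L))
  expect_equal(sum(m3$counts[, "P4"]), 0L)

  expect_error(build_matrix(cleavage_collection(), "X01.001"),
               "no cleavage records")
})

test_that("shade_matrix bins by decile and flags unobserved amino acids", {
  win <- matrix(rep(c("G", "A", "A", "K", "S", "V", "L", "M"), 10),
                nrow = 10, byrow = TRUE)
  m <- build_matrix(collection_from_windows(win), "X01.001")
  sh <- shade_matrix(m)
  expect_equal(unname(sh$bins["G", "P4"]), 10L)   # 100% capped at bin 10
  expect_equal(unname(sh$bins["G", "P3"]), 0L)
  expect_true(sh$unobserved_anywhere[["W"]])
  expect_false(sh$unobserved_anywhere[["G"]])

  # 9.9% falls in bin 0 (floor rule)
  expect_equal(unname(shade_matrix(list(counts = matrix(
    c(99, 901), nrow = 2, dimnames = list(c("A", "C"), "P1")),
    n_cleavages = 1000))$bins["A", "P1"]), 0L)
})

test_that("logo weights follow Shannon information content", {
  # single residue type: full information, log2(20) bits
  win <- matrix(rep(c("G", "A", "A", "K", "S", "V", "L", "M"), 4),
                nrow = 4, byrow = TRUE)
  lw <- logo_weights(build_matrix(collection_from_windows(win), "X01.001"))
  expect_equal(unname(lw["G", "P4"]), log2(20), tolerance = 1e-12)
  expect_equal(sum(lw[, "P4"]), log2(20), tolerance = 1e-12)

  # uniform counts over all 20 residues: zero information
  win_u <- cbind(AA_STD, "A", "A", "A", "A", "A", "A", "A")
  lw_u <- logo_weights(build_matrix(collection_from_windows(win_u),
                                    "X01.001"))
  expect_equal(unname(lw_u[, "P4"]), rep(0, 20), tolerance = 1e-12)

  # counts {A:3, L:1}: heights from an independent hand computation
  win_m <- rbind(matrix(rep(c("A", "G", "G", "K", "S", "V", "L", "M"), 3),
                        nrow = 3, byrow = TRUE),
                 c("L", "G", "G", "K", "S", "V", "L", "M"))
  lw_m <- logo_weights(build_matrix(collection_from_windows(win_m),
                                    "X01.001"))
  H <- -(0.75 * log2(0.75) + 0.25 * log2(0.25))
  R <- log2(20) - H
  expect_equal(unname(lw_m["A", "P4"]), 0.75 * R, tolerance = 1e-12)
  expect_equal(unname(lw_m["L", "P4"]), 0.25 * R, tolerance = 1e-12)

  # empty pocket: all-zero heights
  win_e <- rbind(c("", "", "", "K", "F", "G", "H", "I"))
  lw_e <- logo_weights(build_matrix(collection_from_windows(win_e),
                                    "X01.001"))
  expect_equal(sum(lw_e[, "P4"]), 0)
})

test_that("reliability score matches the exhaustive pairwise oracle", {
  # identical windows score 0 (red)
  win_same <- matrix(rep(c("A", "C", "D", "E", "F", "G", "H", "I"), 2),
                     nrow = 2, byrow = TRUE)
  rel0 <- reliability_score(collection_from_windows(win_same), "X01.001")
  expect_equal(rel0$score, 0)
  expect_equal(rel0$band, "red")

  # two windows differing at all eight pockets score 100 (green)
  win_diff <- rbind(c("A", "C", "D", "E", "F", "G", "H", "I"),
                    c("K", "L", "M", "N", "P", "Q", "R", "S"))
  rel100 <- reliability_score(collection_from_windows(win_diff), "X01.001")
  expect_equal(rel100$score, 100)
  expect_equal(rel100$band, "green")

  # random small collections agree with the double-loop oracle
  set.seed(31)
  for (rep in 1:25) {
    win <- random_windows(sample(2:8, 1))
    coll <- collection_from_windows(win)
    rel <- reliability_score(coll, "X01.001")
    expect_equal(rel$score, oracle_reliability(win), tolerance = 1e-9)
  }

  expect_error(reliability_score(collection_from_windows(
    random_windows(1)), "X01.001"), ">= 2 records")
})

test_that("reliability is invariant under record order permutation", {
  set.seed(32)
  win <- random_windows(6)
  base <- reliability_score(collection_from_windows(win), "X01.001")$score
  for (rep in 1:5) {
    perm <- win[sample(nrow(win)), , drop = FALSE]
    expect_equal(reliability_score(collection_from_windows(perm),
                                   "X01.001")$score, base)
  }
})

test_that("positions considered is computed from occupancy", {
  full <- random_windows(5, allow_empty = FALSE)
  expect_equal(reliability_score(collection_from_windows(full),
                                 "X01.001")$n_positions_considered, 8L)
  amino <- full
  amino[, 1:3] <- ""
  expect_equal(reliability_score(collection_from_windows(amino),
                                 "X01.001")$n_positions_considered, 5L)
})

test_that("preference calling applies the single / group / negative rules", {
  # 19 of 20 windows carry K at P1 (95%)
  win <- matrix(rep(c("A", "C", "D", "K", "F", "G", "H", "I"), 20),
                nrow = 20, byrow = TRUE)
  win[1, 4] <- "R"
  prof <- call_preferences(build_matrix(collection_from_windows(win),
                                        "X01.001"))
  p1 <- prof[prof$pocket == "P1", ]
  expect_equal(p1$state, "preferred")
  expect_equal(p1$call, "K")
  expect_equal(p1$band, "90+")

  # split aliphatic preference: I 30%, L 25%, V 20% -> group call
  p1col <- c(rep("I", 6), rep("L", 5), rep("V", 4),
             "G", "A", "S", "T", "N")
  win_g <- cbind("A", "C", "D", p1col, "F", "G", "H", "I")
  prof_g <- call_preferences(build_matrix(collection_from_windows(win_g),
                                          "X01.001"))
  p1g <- prof_g[prof_g$pocket == "P1", ]
  expect_equal(p1g$state, "preferred")
  expect_equal(p1g$call, "aliphatic")
  expect_equal(p1g$symbol, "λ")
  expect_equal(p1g$band, "70-79")

  # two residues each at exactly 50%
  win_two <- cbind("A", "C", "D", rep(c("K", "R"), 10), "F", "G", "H", "I")
  prof_two <- call_preferences(build_matrix(
    collection_from_windows(win_two), "X01.001"))
  expect_equal(prof_two$call[prof_two$pocket == "P1"], "K,R")
  expect_equal(prof_two$band[prof_two$pocket == "P1"], "90+")
})

test_that("negative preferences require 200 cleavages and an occupied pocket", {
  # P2 cycles through 19 residues, tryptophan never observed
  make_win <- function(n) {
    cbind("A", "C", rep(setdiff(AA_STD, "W"), length.out = n),
          "K", "F", "G", "H", "I")
  }
  prof_150 <- call_preferences(build_matrix(
    collection_from_windows(make_win(150)), "X01.001"))
  expect_equal(prof_150$state[prof_150$pocket == "P2"], "none")

  prof_200 <- call_preferences(build_matrix(
    collection_from_windows(make_win(200)), "X01.001"))
  p2 <- prof_200[prof_200$pocket == "P2", ]
  expect_equal(p2$state, "negative")
  expect_true("W" %in% strsplit(p2$call, ",")[[1]])
})

test_that("masked pockets follow the activity class", {
  win <- matrix(rep(c("A", "C", "D", "K", "F", "G", "H", "I"), 10),
                nrow = 10, byrow = TRUE)
  m <- build_matrix(collection_from_windows(win), "X01.001")
  carbo <- call_preferences(m, "carboxypeptidase")
  expect_equal(carbo$state[carbo$pocket %in% c("P2'", "P3'", "P4'")],
               rep("masked", 3))
  amino <- call_preferences(m, "aminopeptidase")
  expect_equal(amino$state[amino$pocket %in% c("P4", "P3", "P2")],
               rep("masked", 3))
  endo <- call_preferences(m, "endopeptidase")
  expect_false(any(endo$state == "masked"))
})

test_that("a dominant single amino acid beats every group symbol", {
  groups <- list(c("I", "L", "V"), c("F", "W", "Y"), c("D", "E"),
                 c("R", "H", "K"), c("A", "C", "G", "S"),
                 c("N", "Q", "M", "P", "T"))
  set.seed(33)
  for (rep in 1:10) {
    # one residue planted at >= 60%, filler drawn outside its group so the
    # residue's own percentage exceeds every group sum
    aa <- sample(AA_STD, 1)
    own_group <- groups[[which(vapply(groups, function(g) aa %in% g,
                                      logical(1)))]]
    n <- 40
    k <- sample(24:36, 1)  # 60% .. 90%
    filler <- sample(setdiff(AA_STD, own_group), n - k, replace = TRUE)
    win <- cbind("A", "C", "D", c(rep(aa, k), filler), "F", "G", "H", "I")
    m <- build_matrix(collection_from_windows(win), "X01.001")
    pct <- matrix_percentages(m)[AA_STD, "P1"]
    gmax <- max(vapply(groups, function(g) sum(pct[g]), numeric(1)))
    stopifnot(pct[aa] >= 50, pct[aa] >= gmax)
    prof <- call_preferences(m)
    expect_match(prof$call[prof$pocket == "P1"], aa)
    expect_false(prof$call[prof$pocket == "P1"] %in%
                   c("aliphatic", "aromatic", "acidic", "basic",
                     "small", "other"))
  }
})

test_that("band boundaries and the low-confidence flag sit at the published values", {
  expect_equal(reliability_band(75), "green")
  expect_equal(reliability_band(74.9), "yellow")
  expect_equal(reliability_band(50), "yellow")
  expect_equal(reliability_band(49.9), "red")

  expect_true(low_confidence_flag(39))
  expect_false(low_confidence_flag(40))
  expect_true(low_confidence_flag(0))
})

test_that("the specificity display is gated at ten cleavages", {
  coll9 <- simulate_collection(profile_spec(n_records = 9, seed = 41))
  expect_message(d9 <- specificity_display(coll9, "X01.001"),
                 "suppressed")
  expect_null(d9)

  coll10 <- simulate_collection(profile_spec(n_records = 10, seed = 41))
  d10 <- specificity_display(coll10, "X01.001")
  expect_s3_class(d10$matrix, "specificity_matrix")
  expect_true(d10$low_confidence)   # 10 < 40
})
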