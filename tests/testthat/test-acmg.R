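test_that("numeric scores discretize per the published per-tool intervals", {
  cases <- list(
    # predictor, value, category, points
    list("vest", 0.66, "damaging", 1),
    list("vest", 0.65, "damaging", 1),     # closed boundary per footnote
    list("vest", 0.64, "possibly_damaging", 0.5),
    list("vest", 0.16, "benign", 0),
    list("sift", 0.5, "benign", 0),
    list("sift", 0.06, "damaging", 1),     # closed boundary per footnote
    list("sift", 0.1, "possibly_damaging", 0.5),
    list("cadd", 25, "damaging", 1),
    list("cadd", 12, "possibly_damaging", 0.5),
    list("cadd", 11, "possibly_damaging", 0.5),
    list("cadd", 5, "benign", 0),
    list("polyphen2", 0.5, "damaging", 1),
    list("polyphen2", 0.1, "possibly_damaging", 0.5),
    list("polyphen2", 0.01, "benign", 0),
    list("mutassessor", 2.5, "damaging", 1),
    list("mutassessor", 1.5, "possibly_damaging", 0.5),
    list("mutassessor", 1.12, "possibly_damaging", 0.5),
    list("mutassessor", 0.5, "benign", 0))
  for (cs in cases) {
    got <- discretizeCall(cs[[1]], cs[[2]])
    expect_equal(got$category, cs[[3]], info = paste(cs[[1]], cs[[2]]))
    expect_equal(got$points, cs[[4]], info = paste(cs[[1]], cs[[2]]))
  }
})

test_that("boundary values unassigned by the published ranges follow the policy", {
  # default: more damaging side; strict: less damaging side
  expect_equal(discretizeCall("cadd", 14)$category, "damaging")
  expect_equal(discretizeCall("cadd", 14, "strict")$category,
               "possibly_damaging")
  expect_equal(discretizeCall("sift", 0.23)$category, "possibly_damaging")
  expect_equal(discretizeCall("sift", 0.23, "strict")$category, "benign")
  expect_equal(discretizeCall("mutassessor", 1.8)$category, "damaging")
  expect_equal(discretizeCall("mutassessor", 1.8, "strict")$category,
               "possibly_damaging")
  expect_equal(discretizeCall("polyphen2", 0.03)$category,
               "possibly_damaging")
  expect_equal(discretizeCall("polyphen2", 0.03, "strict")$category,
               "benign")
  # footnote-assigned boundaries are policy-invariant
  expect_equal(discretizeCall("vest", 0.65, "strict")$category, "damaging")
  expect_equal(discretizeCall("sift", 0.06, "strict")$category, "damaging")
})

test_that("categorical labels, missing cells and errors are handled", {
  expect_equal(discretizeCall("cadd", NA)$category, "missing")
  expect_equal(discretizeCall("cadd", NA)$points, 0)
  expect_equal(discretizeCall("annovar_impact", "HIGH")$points, 1)
  expect_equal(discretizeCall("annovar_impact", "MODERATE")$points, 0.5)
  expect_equal(discretizeCall("annovar_impact", "MODIFIER")$points, 0)
  expect_equal(discretizeCall("fathmm", "Damaging")$points, 1)
  expect_equal(discretizeCall("fathmm", "Benign")$points, 0)
  # only the literal Damaging/High labels earn 1: PolyPhen-2's
  # "Probably damaging" scores 0.5
  expect_equal(discretizeCall("polyphen2", "Probably damaging")$points, 0.5)
  expect_error(discretizeCall("notatool", 1), "notatool")
  expect_error(discretizeCall("sift", 1.5), "range")
  expect_error(discretizeCall("fathmm", 0.5), "categorical")
})

test_that("aggregateScore reproduces printed 7-point scores", {
  # verbal-call profiles transcribed from the packaged fixture rows
  p1429 <- list(annovar_impact = "MODERATE", cadd = "Damaging",
                sift = "Damaging", polyphen2 = "Damaging",
                mutassessor = "Possibly damaging", fathmm = "Damaging",
                vest = "Damaging")
  expect_equal(aggregateScore(p1429), 6)
  p211 <- list(annovar_impact = NA, cadd = "Damaging", sift = "Damaging",
               polyphen2 = "Probably damaging", mutassessor = "Damaging",
               fathmm = "Damaging", vest = "Damaging")
  expect_equal(aggregateScore(p211), 5.5)
  allMax <- as.list(setNames(rep("Damaging", 7),
                             c("annovar_impact", "cadd", "sift", "polyphen2",
                               "mutassessor", "fathmm", "vest")))
  allMax$annovar_impact <- "HIGH"
  expect_equal(aggregateScore(allMax), 7)
  expect_error(aggregateScore(list(cadd = NA)), "non-missing")
})

test_that("score bands map to computational evidence with PVS1 override", {
  expect_equal(scoreToEvidence(4, "missense"), "PP3")
  expect_equal(scoreToEvidence(2.5, "missense"), "none")
  expect_equal(scoreToEvidence(1, "frameshift"), "PVS1")
  expect_equal(scoreToEvidence(7, "exon_skipping_confirmed"), "PVS1")
  expect_equal(scoreToEvidence(0, "intronic_splice"), "BP4")
  expect_error(scoreToEvidence(2.3, "missense"), "grid")
  expect_error(scoreToEvidence(7.5, "missense"), "grid")
})

test_that("every grid score maps to exactly one evidence band", {
  grid <- seq(0, 7, by = 0.5)
  codes <- vapply(grid, scoreToEvidence, character(1),
                  variantClass = "missense")
  expect_length(codes, 15)
  expect_true(all(codes %in% c("BP4", "none", "PP3")))
  expect_equal(codes[grid < 2], rep("BP4", 4))
  expect_equal(codes[grid >= 2 & grid < 4], rep("none", 4))
  expect_equal(codes[grid >= 4], rep("PP3", 7))
})

test_that("aggregate score is monotone over all 3^7 categorical profiles", {
  labels <- c(benign = "Benign", possibly_damaging = "Possibly damaging",
              damaging = "Damaging")
  annovar <- c(benign = "LOW", possibly_damaging = "MODERATE",
               damaging = "HIGH")
  lev <- names(labels)
  grid <- expand.grid(rep(list(1:3), 7))  # category index per predictor
  preds <- c("annovar_impact", "cadd", "sift", "polyphen2", "mutassessor",
             "fathmm", "vest")
  scoreOf <- function(idx) {
    prof <- lapply(seq_len(7), function(j)
      if (preds[j] == "annovar_impact") annovar[[lev[idx[j]]]]
      else labels[[lev[idx[j]]]])
    names(prof) <- preds
    aggregateScore(prof)
  }
  scores <- apply(as.matrix(grid), 1, scoreOf)
  # the 0.5 grid in [0, 7]
  expect_true(all(scores >= 0 & scores <= 7))
  expect_true(all((scores * 2) %% 1 == 0))
  # raising any one predictor by one category never lowers the score;
  # compare via the known per-category point values
  key <- apply(as.matrix(grid), 1, paste, collapse = "")
  lookup <- setNames(scores, key)
  for (j in 1:7) {
    canRaise <- grid[[j]] < 3
    raised <- as.matrix(grid[canRaise, ])
    raised[, j] <- raised[, j] + 1L
    expect_true(all(lookup[apply(raised, 1, paste, collapse = "")] >=
                      scores[canRaise]))
  }
})

test_that("combineEvidence matches the published rules and the brute-force oracle", {
  expect_equal(combineEvidence(c("PVS1", "PM2")), "likely_pathogenic")
  expect_equal(combineEvidence(character()), "VUS")
  expect_equal(combineEvidence("PP3"), "VUS")
  expect_equal(combineEvidence(c("PVS1", "PS3")), "pathogenic")
  expect_equal(combineEvidence(c("BA1")), "benign")
  expect_equal(combineEvidence(c("BS1", "BP4")), "likely_benign")
  expect_equal(combineEvidence(c("PVS1", "PM2", "BA1")), "VUS")
  expect_error(combineEvidence("XX9"), "unknown")
  # exhaustive agreement with an independent implementation for all
  # evidence sets of size <= 3
  vocab <- acmgVocabulary()
  sets <- c(list(character()),
            lapply(vocab, identity),
            combn(vocab, 2, simplify = FALSE),
            combn(vocab, 3, simplify = FALSE))
  got <- vapply(sets, combineEvidence, character(1))
  want <- vapply(sets, oracleCombine, character(1))
  expect_identical(got, want)
})

test_that("classifyVariants reproduces the printed 11-variant score column", {
  tab <- readVariantTable(predictorFixture())
  res <- classifyVariants(tab)
  expect_equal(nrow(res), 12)
  expect_identical(res$variant_id, tab$variant_id)  # order preserved
  abcc8 <- res[tab$gene == "ABCC8", ]
  expect_equal(abcc8$score, c(5.5, 2.5, 6, 5.5, 2.5, 4.5, 1, 2.5, 1, 6, 4))
  # all-missing predictor rows are only admissible for null-variant classes
  expect_true(is.na(res$score[res$variant_id == "SMAD1:c.27delinsGTAAAG"]))
  badRow <- tab[tab$variant_id == "c.211C>T", ]
  badRow$variant_class <- "missense"
  for (p in c("cadd", "sift", "polyphen2", "mutassessor", "fathmm", "vest"))
    badRow[[p]] <- NA
  badRow$annovar_impact <- NA
  expect_error(classifyVariants(badRow), "row 1")
})

test_that("classifyVariants handles empty tables and duplicate ids", {
  tab <- readVariantTable(predictorFixture())
  expect_equal(nrow(classifyVariants(tab[0, ])), 0)
  dup <- rbind(tab[1, ], tab[1, ])
  res <- classifyVariants(dup)
  expect_equal(res$score, c(5.5, 5.5))  # scored independently, no dedup
})
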