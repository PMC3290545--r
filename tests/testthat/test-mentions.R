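test_that("standard residue mention surface forms normalize correctly", {
  cases <- list(
    list(txt = "The role of Asp104 in catalysis.", wt = "ASP", pos = 104L),
    list(txt = "His-554 coordinates the zinc ion.", wt = "HIS", pos = 554L),
    list(txt = "mutating glycine 23 abolished binding", wt = "GLY", pos = 23L),
    list(txt = "an aspartic acid 104 variant", wt = "ASP", pos = 104L),
    list(txt = "the aspartate 99 side chain", wt = "ASP", pos = 99L),
    list(txt = "residue D104 is buried", wt = "ASP", pos = 104L))
  for (cs in cases) {
    m <- extract_mentions(cs$txt)
    expect_equal(nrow(m), 1, info = cs$txt)
    expect_equal(m$wt_code, cs$wt, info = cs$txt)
    expect_equal(m$position, cs$pos, info = cs$txt)
    expect_true(is.na(m$mut_code), info = cs$txt)
  }
})

test_that("a bare amino-acid name without a position is never a mention", {
  expect_equal(nrow(extract_mentions("Glycine is abundant in loops.")), 0)
  expect_equal(nrow(extract_mentions("rich in cysteine and proline")), 0)
})

test_that("enumerations expand to one mention per position", {
  m <- extract_mentions("cysteines at positions 6, 24, and 393 form bridges")
  expect_equal(nrow(m), 3)
  expect_equal(m$wt_code, rep("CYS", 3))
  expect_equal(sort(m$position), c(6L, 24L, 393L))
})

test_that("mutation mentions capture both codes in short and linguistic forms", {
  m <- extract_mentions("The G146A mutant lost activity.")
  expect_equal(m$wt_code, "GLY"); expect_equal(m$position, 146L)
  expect_equal(m$mut_code, "ALA")
  m2 <- extract_mentions("His-554 mutated to glutamine impairs folding")
  expect_equal(m2$wt_code, "HIS"); expect_equal(m2$position, 554L)
  expect_equal(m2$mut_code, "GLN")
  m3 <- extract_mentions("the Gly23Ala substitution")
  expect_equal(m3$mut_code, "ALA")
  m4 <- extract_mentions("Asp104→Ala abolished catalysis")
  expect_equal(m4$wt_code, "ASP"); expect_equal(m4$mut_code, "ALA")
})

test_that("unicode connectors (em dash, arrow) are handled", {
  m <- extract_mentions("His—554 is catalytic")
  expect_equal(m$wt_code, "HIS"); expect_equal(m$position, 554L)
})

test_that("paper-compat mode reproduces documented error behaviours", {
  # citation confusion: "tyrosine (6)"
  m <- extract_mentions("as shown for tyrosine (6) previously")
  expect_equal(nrow(m), 1)
  expect_equal(m$wt_code, "TYR"); expect_equal(m$position, 6L)
  expect_equal(nrow(extract_mentions("as shown for tyrosine (6) previously",
                                     strict = TRUE)), 0)
  # trailing chain letter read as a mutation
  m2 <- extract_mentions("The catalytic residues Cys105L and His262L")
  expect_equal(m2$wt_code, c("CYS", "HIS"))
  expect_equal(m2$mut_code, c("LEU", "LEU"))
  m2s <- extract_mentions("The catalytic residues Cys105L and His262L",
                          strict = TRUE)
  expect_true(all(is.na(m2s$mut_code)))
  # gene-name lookalikes are not filtered in paper-compat mode
  m3 <- extract_mentions("regulated by the E2F transcription factor")
  expect_equal(nrow(m3), 1)
  expect_equal(m3$mut_code, "PHE")
})

test_that("every span's substring is the matched text", {
  txt <- paste("Asp104 and His-554 mutated to glutamine;",
               "cysteines at positions 6, 24, and 393; G146A and E2F.")
  m <- extract_mentions(txt)
  expect_gt(nrow(m), 4)
  for (i in seq_len(nrow(m))) {
    expect_equal(substr(txt, m$start[i], m$end[i]), m$text[i])
  }
})

test_that("extraction is idempotent on canonical forms", {
  txt <- "Asp104, G146A, His-554 mutated to glutamine, and lysine 88."
  m <- extract_mentions(txt)
  for (i in seq_len(nrow(m))) {
    canon <- if (is.na(m$mut_code[i])) {
      paste0(substr(m$wt_code[i], 1, 1),
             tolower(substr(m$wt_code[i], 2, 3)), m$position[i])
    } else {
      paste0(substr(m$wt_code[i], 1, 1),
             tolower(substr(m$wt_code[i], 2, 3)), m$position[i],
             substr(m$mut_code[i], 1, 1),
             tolower(substr(m$mut_code[i], 2, 3)))
    }
    m2 <- extract_mentions(canon)
    expect_equal(nrow(m2), 1, info = canon)
    expect_equal(m2$wt_code, m$wt_code[i], info = canon)
    expect_equal(m2$position, m$position[i], info = canon)
    expect_equal(m2$mut_code, m$mut_code[i], info = canon)
  }
})

test_that("precision and recall follow the standard count formulas", {
  r <- evaluate_counts(extracted = 454, correct = 435, gold = 550)
  expect_equal(r$tp, 435); expect_equal(r$fp, 19); expect_equal(r$fn, 115)
  expect_equal(r$precision, 435 / 454, tolerance = 1e-12)
  expect_equal(r$recall, 435 / 550, tolerance = 1e-12)
  expect_equal(round(r$precision, 3), 0.958)
  expect_equal(round(r$recall, 3), 0.791)
})

test_that("evaluation of mention tables handles perfect, empty and span modes", {
  gold <- extract_mentions("Asp104 and Gly23Ala and His9", source = "d1")
  expect_equal(nrow(gold), 3)
  perfect <- evaluate_mentions(gold, gold)
  expect_equal(perfect$precision, 1); expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)
  none <- evaluate_mentions(gold, gold[0, ])
  expect_equal(none$recall, 0)
  expect_equal(none$precision, 0)
  expect_true(none$undefined)
  # span mode: same normalized forms at shifted spans do not match
  shifted <- gold; shifted$start <- shifted$start + 1
  expect_equal(evaluate_mentions(gold, shifted, span_mode = TRUE)$tp, 0)
  expect_equal(evaluate_mentions(gold, shifted, span_mode = FALSE)$tp, 3)
  # duplicate gold keys warn and count once
  expect_warning(dup <- evaluate_mentions(rbind(gold, gold[1, ]), gold),
                 "duplicate")
  expect_equal(dup$tp, 3)
})

test_that("corpus evaluation pools counts and validates document ids", {
  texts <- c(d1 = "Asp104 is catalytic.", d2 = "the G146A mutant")
  gold <- rbind(extract_mentions(texts[["d1"]], source = "d1"),
                extract_mentions(texts[["d2"]], source = "d2"))
  r <- corpus_report(texts, gold)
  expect_equal(r$precision, 1); expect_equal(r$recall, 1)
  expect_error(corpus_report(character(0), gold), "empty corpus")
  bad_gold <- gold; bad_gold$source <- "d9"
  expect_error(corpus_report(texts, bad_gold), "absent from the corpus")
})

test_that("generator-planted false positives depress precision as designed", {
  res <- data.frame(wt_code = c("ASP", "HIS", "CYS", "GLY", "LYS", "TRP",
                                "SER", "PHE", "THR"),
                    position = c(104L, 54L, 61L, 77L, 88L, 91L, 12L, 33L,
                                 45L),
                    mut_code = NA_character_)
  ab <- make_abstract(res, styles = c("three", "full", "hyphen"),
                      n_distractors = 1, seed = 4, pmid = "p1")
  r <- corpus_report(c(p1 = ab$text), ab$gold)
  expect_equal(r$fn, 0)                       # every planted mention found
  expect_equal(r$fp, 1)                       # exactly the distractor
  expect_equal(r$precision, 9 / 10, tolerance = 1e-12)
})
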