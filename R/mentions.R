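# Composable regular-expression fragments for residue/mutation mentions.
# All patterns are built from these pieces: amino-acid name alternations
# (full name / 3-letter / 1-letter), a position, connectors and boundaries.
# Unicode connectors (em dash U+2014, arrow U+2192) are first-class.

aa_fragments <- function() {
  tab <- aa_table()
  full <- c(tab$name, names(aa_alt_names()))
  # longest alternatives first so "glutamic acid" beats "glutamic"
  full <- full[order(nchar(full), decreasing = TRUE)]
  list(
    full = paste0("(?:", paste(gsub(" ", "[ ]", full), collapse = "|"), ")"),
    three = paste0("(?:", paste(tab$three, collapse = "|"), ")"),
    one = "[ACDEFGHIKLMNPQRSTVWY]",
    pos = "[1-9][0-9]{0,4}",
    conn = "[-— ]?",          # hyphen, em dash, space or nothing
    arrow = "(?:→|->|/)"
  )
}

aa_to_three <- function(s) {
  s <- tolower(trimws(s))
  tab <- aa_table()
  alt <- aa_alt_names()
  if (s %in% tab$name) return(tab$three[match(s, tab$name)])
  if (s %in% names(alt)) return(unname(alt[s]))
  up <- toupper(s)
  if (up %in% tab$three) return(up)
  if (nchar(up) == 1 && up %in% tab$one) return(tab$three[match(up, tab$one)])
  NA_character_
}

new_mention <- function(wt, pos, mut = NA_character_, start, end, text,
                        source = NA_character_) {
  data.frame(source = source, wt_code = wt, position = as.integer(pos),
             mut_code = mut, start = as.integer(start), end = as.integer(end),
             text = text, stringsAsFactors = FALSE)
}

empty_mentions <- function() {
  new_mention(character(0), integer(0), character(0), integer(0), integer(0),
              character(0), character(0))[0, ]
}

#' Extract residue and point-mutation mentions from text
#'
#' Scans plain text for mentions of specific residues — an amino-acid name
#' (full name, 3-letter or 1-letter abbreviation) tied to a sequence
#' position — and for point mutations in short form (`"G146A"`,
#' `"Gly23Ala"`, `"Asp104→Ala"`) or linguistic form (`"His-554 mutated
#' to glutamine"`). Enumerations such as `"cysteines at positions 6, 24, and
#' 393"` are expanded to one mention per position. A bare amino-acid name
#' without a position never yields a mention. Each match is normalized to
#' the wild-type 3-letter code, position, optional mutant 3-letter code, and
#' its character span in the source text.
#'
#' Two pattern modes are provided. The default mode additionally accepts a
#' name followed by a parenthesised number (`"tyrosine (6)"`) and reads a
#' trailing capital letter after a 3-letter+position mention (`"Cys105L"`)
#' as a mutation; `strict = TRUE` suppresses these two pattern classes,
#' which are known false-positive sources in full-text articles.
#'
#' @param text a character string (Unicode; em dash and arrow connectors
#'   handled).
#' @param source optional document id (e.g. PMID) recorded on each mention.
#' @param strict suppress the two permissive pattern classes (default
#'   FALSE).
#' @return data.frame of normalized mentions: `source`, `wt_code`,
#'   `position`, `mut_code` (NA unless a mutation), `start`, `end` (1-based
#'   inclusive character span), `text` (the matched substring).
#' @export
extract_mentions <- function(text, source = NA_character_, strict = FALSE) {
  f <- aa_fragments()
  out <- list()
  taken <- integer(0)     # character offsets already consumed

  grab <- function(pattern, handler, ignore_case = TRUE) {
    m <- gregexpr(pattern, text, perl = TRUE, ignore.case = ignore_case)[[1]]
    if (m[1] == -1) return(invisible())
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    cap_s <- attr(m, "capture.start")
    cap_l <- attr(m, "capture.length")
    for (i in seq_along(starts)) {
      span <- starts[i]:(starts[i] + lens[i] - 1L)
      if (any(span %in% taken)) next
      caps <- character(ncol(cap_s))
      for (j in seq_len(ncol(cap_s))) {
        caps[j] <- if (cap_s[i, j] > 0)
          substr(text, cap_s[i, j], cap_s[i, j] + cap_l[i, j] - 1L) else ""
      }
      res <- handler(caps, starts[i], starts[i] + lens[i] - 1L,
                     substr(text, starts[i], starts[i] + lens[i] - 1L))
      if (!is.null(res)) {
        out[[length(out) + 1L]] <<- res
        taken <<- c(taken, span)
      }
    }
    invisible()
  }

  mk <- function(wt, pos, mut, s, e, txt) {
    wt3 <- aa_to_three(wt)
    mut3 <- if (is.na(mut) || mut == "") NA_character_ else aa_to_three(mut)
    if (is.na(wt3)) return(NULL)
    if (!is.na(mut3) && mut3 == wt3) mut3 <- NA_character_
    new_mention(wt3, pos, mut3, s, e, txt, source)
  }

  # --- enumerations: "cysteines at positions 6, 24, and 393" -------------
  enum_pat <- paste0("\\b(", f$full, ")s?\\s+(?:residues?\\s+)?at\\s+",
                     "positions?\\s+(", f$pos,
                     "(?:\\s*,\\s*", f$pos, ")*",
                     "(?:\\s*,?\\s*(?:and|or)\\s+", f$pos, ")?)")
  grab(enum_pat, function(caps, s, e, txt) {
    nums <- regmatches(caps[2], gregexpr("[0-9]+", caps[2]))[[1]]
    rows <- lapply(nums, function(p) mk(caps[1], p, NA, s, e, txt))
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) == 0) NULL else do.call(rbind, rows)
  })

  # --- linguistic mutations: "His-554 mutated to glutamine" --------------
  verb <- "(?:was\\s+|is\\s+|were\\s+)?(?:mutated|substituted|replaced|changed|converted)\\s+(?:to|by|with|into)"
  ling_pat <- paste0("\\b(", f$full, "|", f$three, ")", f$conn, "(", f$pos,
                     ")\\s+", verb, "\\s+(?:a\\s+|an\\s+)?(", f$full, "|",
                     f$three, ")\\b")
  grab(ling_pat, function(caps, s, e, txt) {
    mk(caps[1], caps[2], caps[3], s, e, txt)
  })

  # --- short-form mutations ---------------------------------------------
  # Gly23Ala, Asp104->Ala, Gly-23-Ala, aspartate 104 -> alanine
  m3_pat <- paste0("\\b(", f$full, "|", f$three, ")", f$conn, "(", f$pos,
                   ")(?:", f$conn, "|\\s*", f$arrow, "\\s*)(", f$full, "|",
                   f$three, ")\\b")
  grab(m3_pat, function(caps, s, e, txt) {
    mk(caps[1], caps[2], caps[3], s, e, txt)
  })
  # G146A, D104->A: one-letter codes are matched case-sensitively so prose
  # around numbers ("a 104 kDa band") cannot read as codes
  m1_pat <- paste0("\\b(", f$one, ")(", f$pos, ")(?:\\s*", f$arrow,
                   "\\s*)?(", f$one, ")\\b")
  grab(m1_pat, function(caps, s, e, txt) {
    mk(caps[1], caps[2], caps[3], s, e, txt)
  }, ignore_case = FALSE)

  # paper-compat: "Cys105L" -- trailing capital after a 3-letter mention is
  # read as a mutant one-letter code (a documented false-positive source)
  if (!strict) {
    trail_pat <- paste0("\\b((?i:", f$three, "))", f$conn, "(", f$pos, ")(",
                        f$one, ")\\b")
    grab(trail_pat, function(caps, s, e, txt) {
      mk(caps[1], caps[2], caps[3], s, e, txt)
    }, ignore_case = FALSE)
  }

  # --- plain residue mentions: Asp104, His-554, aspartic acid 104 --------
  res_pat <- paste0("\\b(", f$full, "|", f$three, ")", f$conn, "(", f$pos,
                    ")\\b")
  grab(res_pat, function(caps, s, e, txt) {
    mk(caps[1], caps[2], NA, s, e, txt)
  })

  # paper-compat: "tyrosine (6)" (citation-style false positive)
  if (!strict) {
    paren_pat <- paste0("\\b(", f$full, ")\\s*\\((", f$pos, ")\\)")
    grab(paren_pat, function(caps, s, e, txt) {
      mk(caps[1], caps[2], NA, s, e, txt)
    })
  }

  # one-letter with position: "D104" (positional context present)
  one_pat <- paste0("\\b(", f$one, ")(", f$pos, ")\\b")
  grab(one_pat, function(caps, s, e, txt) {
    mk(caps[1], caps[2], NA, s, e, txt)
  }, ignore_case = FALSE)

  if (length(out) == 0) return(empty_mentions())
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Evaluate extracted mentions against a gold standard
#'
#' Computes true positives, false positives and false negatives by the
#' normalized-match rules: a residue mention matches when the 3-letter code
#' and position agree; a mutation mention additionally requires the mutant
#' code to agree. With `span_mode = TRUE` the character span (start and end)
#' must also match, the protocol used for span-annotated corpora; without
#' it, matching is on the normalized form only, and duplicate normalized
#' entries within a document are counted once (with a warning when the gold
#' side contains duplicates).
#'
#' @param gold,pred mention data.frames (see [extract_mentions()]).
#' @param span_mode require span agreement (default FALSE).
#' @return `eval_result`: list with `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f1` (undefined ratios reported as 0 with `undefined` flag).
#' @export
evaluate_mentions <- function(gold, pred, span_mode = FALSE) {
  keyof <- function(d) {
    k <- paste(d$source, d$wt_code, d$position,
               ifelse(is.na(d$mut_code), "-", d$mut_code))
    if (span_mode) k <- paste(k, d$start, d$end)
    k
  }
  gk <- if (nrow(gold)) keyof(gold) else character(0)
  pk <- if (nrow(pred)) keyof(pred) else character(0)
  if (anyDuplicated(gk)) {
    warning("duplicate gold entries at the same key; counted once")
  }
  gk <- unique(gk); pk <- unique(pk)
  tp <- length(intersect(gk, pk))
  fp <- length(setdiff(pk, gk))
  fn <- length(setdiff(gk, pk))
  eval_result(tp, fp, fn)
}

#' Evaluation result from raw counts
#'
#' Builds precision/recall/F1 from TP/FP/FN with the standard formulas.
#' `evaluate_counts()` is the convenience form taking the three numbers a
#' corpus evaluation reports: mentions extracted, extracted-and-correct, and
#' gold mentions.
#'
#' @param tp,fp,fn true positive, false positive, false negative counts.
#' @return `eval_result` list: `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f1`, `undefined` (TRUE when a denominator was zero).
#' @export
eval_result <- function(tp, fp, fn) {
  undef <- FALSE
  p <- if (tp + fp > 0) tp / (tp + fp) else { undef <- TRUE; 0 }
  r <- if (tp + fn > 0) tp / (tp + fn) else { undef <- TRUE; 0 }
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else { undef <- TRUE; 0 }
  structure(list(tp = tp, fp = fp, fn = fn, precision = p, recall = r,
                 f1 = f1, undefined = undef),
            class = "eval_result")
}

#' @rdname eval_result
#' @param extracted number of mentions the system extracted.
#' @param correct number of extracted mentions that were correct.
#' @param gold number of gold-standard mentions.
#' @export
evaluate_counts <- function(extracted, correct, gold) {
  stopifnot(correct <= extracted, correct <= gold)
  eval_result(tp = correct, fp = extracted - correct, fn = gold - correct)
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("P = %.1f%%  R = %.1f%%  F1 = %.3f  (TP %d / FP %d / FN %d)\n",
              100 * x$precision, 100 * x$recall, x$f1, x$tp, x$fp, x$fn))
  invisible(x)
}

#' Micro-averaged evaluation over a corpus
#'
#' Runs [extract_mentions()] on every document, compares against the gold
#' table per document, and micro-averages the TP/FP/FN counts.
#'
#' @param texts named character vector of document texts (names = doc ids).
#' @param gold gold mention data.frame with a `source` column of doc ids.
#' @param span_mode require span agreement (default FALSE).
#' @param strict strict pattern mode (default FALSE).
#' @return `eval_result` of the pooled counts.
#' @export
corpus_report <- function(texts, gold, span_mode = FALSE, strict = FALSE) {
  if (length(texts) == 0) stop("empty corpus")
  if (is.null(names(texts)) || any(names(texts) == "")) {
    stop("texts must be named by document id")
  }
  extra <- setdiff(unique(gold$source), names(texts))
  if (length(extra) > 0) {
    stop("gold references document id(s) absent from the corpus: ",
         paste(extra, collapse = ", "))
  }
  tp <- fp <- fn <- 0L
  for (id in names(texts)) {
    pred <- extract_mentions(texts[[id]], source = id, strict = strict)
    g <- gold[gold$source == id, , drop = FALSE]
    r <- evaluate_mentions(g, pred, span_mode = span_mode)
    tp <- tp + r$tp; fp <- fp + r$fp; fn <- fn + r$fn
  }
  eval_result(tp, fp, fn)
}

#' Read a normalized gold-mention file
#'
#' Tab-delimited dialect with columns `source`, `start`, `end`, `wt_code`,
#' `position`, `mut_code` (blank or `-` when not a mutation). Span columns
#' may be `-1` for corpora without span annotation.
#'
#' @param path TSV file path.
#' @return mention data.frame in the [extract_mentions()] layout.
#' @export
read_gold_mentions <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  d$mut_code[d$mut_code %in% c("", "-")] <- NA_character_
  d$text <- if (is.null(d$text)) NA_character_ else d$text
  d[, c("source", "wt_code", "position", "mut_code", "start", "end", "text")]
}
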