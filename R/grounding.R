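#' Group one abstract's mentions into text residues
#'
#' Step 1 of the text-to-structure mapping: all mentions from one abstract
#' sharing a sequence position form one text residue. Mutation mentions
#' contribute their wild-type code as a primary name and the mutant code to
#' the mutation set.
#'
#' @param mentions mention data.frame from [extract_mentions()] for a single
#'   document.
#' @return list of `text_residue`: `pmid`, `position`, `primary_codes`
#'   (distinct primary 3-letter codes seen), `mutation_codes`,
#'   `n_occurrences`.
#' @export
group_text_residues <- function(mentions) {
  if (nrow(mentions) == 0) return(list())
  pmid <- unique(mentions$source)
  if (length(pmid) > 1) stop("mentions from more than one document")
  lapply(split(mentions, mentions$position), function(g) {
    structure(list(
      pmid = pmid,
      position = g$position[1],
      primary_codes = unique(g$wt_code),
      mutation_codes = setdiff(unique(g$mut_code[!is.na(g$mut_code)]),
                               character(0)),
      n_occurrences = nrow(g)),
      class = "text_residue")
  })
}

#' Check a text residue for amino-acid name ambiguity
#'
#' Step 2: a text residue is unambiguous when a single primary amino-acid
#' name is attached to the position (mutant names do not count against
#' this). Ambiguous groups are excluded from grounding.
#'
#' @param group a `text_residue`.
#' @return TRUE (pass) or FALSE (ambiguous).
#' @export
check_text_ambiguity <- function(group) {
  length(group$primary_codes) == 1L
}

#' Match a text residue to physical residues in linked structures
#'
#' Step 3: candidates are residues in any protein chain of a linked entry
#' whose author residue number equals the text position and whose component
#' code equals the primary or (unless `strict`) any mutation code. Matching
#' is exact on position; residues carrying insertion codes are not matched.
#'
#' @param text_residue a `text_residue` passing [check_text_ambiguity()].
#' @param struct a `protein_structure` for one linked PDB entry.
#' @param pdb_id entry id recorded on the matches.
#' @param strict disable mutation-code matching (default FALSE).
#' @return data.frame of candidate matches (pdb, chain, resno, comp_id,
#'   entity, via) — zero rows when nothing matches.
#' @export
match_physical <- function(text_residue, struct, pdb_id, strict = FALSE) {
  at <- struct$atoms
  at <- at[!at$het, , drop = FALSE]
  res <- at[!duplicated(residue_key(at$chain, at$resno, at$icode)),
            c("chain", "resno", "icode", "resid", "entity"), drop = FALSE]
  codes <- text_residue$primary_codes
  via <- rep("primary", length(codes))
  if (!strict && length(text_residue$mutation_codes) > 0) {
    codes <- c(codes, text_residue$mutation_codes)
    via <- c(via, rep("mutation", length(text_residue$mutation_codes)))
  }
  hit <- res$resno == text_residue$position & res$icode == "" &
    res$resid %in% codes
  out <- res[hit, , drop = FALSE]
  if (nrow(out) == 0) {
    return(data.frame(pdb = character(0), chain = character(0),
                      resno = integer(0), comp_id = character(0),
                      entity = character(0), via = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(pdb = pdb_id, chain = out$chain, resno = out$resno,
             comp_id = out$resid, entity = out$entity,
             via = via[match(out$resid, codes)], stringsAsFactors = FALSE)
}

#' Resolve entity ambiguity among physical matches
#'
#' Step 4: multiple physical residues matching one text residue within a
#' single entry are unambiguous when they all derive from a single
#' molecular entity (e.g. the two chains of a homodimer); otherwise the
#' text residue is ambiguous at the physical level and excluded.
#'
#' @param text_residue the `text_residue` being grounded.
#' @param candidates candidate data.frame from [match_physical()] for one
#'   entry.
#' @return `grounded_text_residue`: `text_residue`, `matches`, `status` in
#'   `{"grounded", "ambiguous_physical", "unmatched"}`.
#' @export
resolve_entity_ambiguity <- function(text_residue, candidates) {
  status <- if (nrow(candidates) == 0) {
    "unmatched"
  } else if (length(unique(candidates$entity)) == 1L) {
    "grounded"
  } else {
    "ambiguous_physical"
  }
  structure(list(
    text_residue = text_residue,
    matches = if (status == "grounded") candidates else candidates[0, ],
    status = status),
    class = "grounded_text_residue")
}

#' Ground one abstract's mentions against its linked structures
#'
#' Runs Steps 1-4 for a single document: group mentions into text residues,
#' drop name-ambiguous groups (`ambiguous_text`), match the rest against
#' every linked structure, and resolve entity ambiguity per entry. A text
#' residue matched in several linked entries yields one grounding per
#' entry.
#'
#' @param mentions mention data.frame for one document.
#' @param structures named list of `protein_structure` (names = PDB ids)
#'   linked to the document.
#' @param strict disable mutation-code matching (default FALSE).
#' @return list of `grounded_text_residue` (including the ambiguous and
#'   unmatched ones, with their status).
#' @export
ground_abstract <- function(mentions, structures, strict = FALSE) {
  groups <- group_text_residues(mentions)
  out <- list()
  for (g in groups) {
    if (!check_text_ambiguity(g)) {
      out[[length(out) + 1L]] <- structure(
        list(text_residue = g, matches = NULL, status = "ambiguous_text"),
        class = "grounded_text_residue")
      next
    }
    if (length(structures) == 0) {
      out[[length(out) + 1L]] <- structure(
        list(text_residue = g, matches = NULL, status = "unmatched"),
        class = "grounded_text_residue")
      next
    }
    for (pdb_id in names(structures)) {
      cand <- match_physical(g, structures[[pdb_id]], pdb_id,
                             strict = strict)
      out[[length(out) + 1L]] <- resolve_entity_ambiguity(g, cand)
    }
  }
  out
}

#' Grounding results as a flat table
#'
#' @param grounded list of `grounded_text_residue`.
#' @return data.frame: pmid, position, primary code, status, pdb, chain,
#'   resno, entity (one row per physical match; ungrounded residues keep one
#'   row with NA match fields).
#' @export
grounding_table <- function(grounded) {
  rows <- lapply(grounded, function(g) {
    tr <- g$text_residue
    base <- data.frame(pmid = tr$pmid, position = tr$position,
                       primary = tr$primary_codes[1], status = g$status,
                       stringsAsFactors = FALSE)
    if (g$status == "grounded" && nrow(g$matches) > 0) {
      cbind(base[rep(1, nrow(g$matches)), , drop = FALSE],
            g$matches[, c("pdb", "chain", "resno", "entity")])
    } else {
      cbind(base, data.frame(pdb = NA, chain = NA, resno = NA, entity = NA))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
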