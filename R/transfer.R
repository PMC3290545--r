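#' Read an aligned FASTA multiple sequence alignment
#'
#' Thin wrapper around `bio3d::read.fasta` returning the alignment matrix
#' and row ids.
#'
#' @param path aligned-FASTA file.
#' @return list with `ids` (character) and `ali` (character matrix, one row
#'   per sequence, `-` for gaps).
#' @export
read_msa <- function(path) {
  a <- bio3d::read.fasta(path)
  list(ids = a$id, ali = unname(a$ali))
}

# per-row maps between ungapped residue index and alignment column
row_colmap <- function(row) which(row != "-")          # residue k -> column
row_resmap <- function(row) {                           # column -> residue k
  out <- rep(NA_integer_, length(row))
  out[row != "-"] <- seq_len(sum(row != "-"))
  out
}

#' Select family representatives
#'
#' One representative domain per protein id: the longest domain, ties broken
#' by first SID in alphabetical order.
#'
#' @param domains data.frame with columns `sid`, `protein_id`, `length`.
#' @return named character vector protein_id -> representative SID.
#' @export
select_representatives <- function(domains) {
  vapply(split(domains, domains$protein_id), function(d) {
    d <- d[order(-d$length, d$sid), , drop = FALSE]
    d$sid[1]
  }, character(1))
}

#' Merge protein-level and family-level alignments into a virtual alignment
#'
#' Each family-MSA row is the representative of one protein. Every domain
#' reachable through its representative gets family columns by composing
#' the two alignments: domain residue -> protein-MSA column ->
#' representative residue -> family-MSA column. Gaps propagate as unmapped
#' positions. A protein whose representative is absent from the family MSA
#' keeps protein-level mapping only (with a warning). Family-level mapping
#' requires at least two distinct protein ids in the family MSA.
#'
#' @param protein_msas named list (protein id -> MSA from [read_msa()]) of
#'   protein-level alignments; rows are domain SIDs. Proteins with a single
#'   domain may be omitted.
#' @param family_msa family-level MSA of the representatives (or NULL for a
#'   single-protein family).
#' @param domains data.frame with columns `sid`, `protein_id`.
#' @param family_id family identifier.
#' @return `virtual_alignment`: list with `family_id`, `domains`
#'   (data.frame sid, protein_id), `seq` (per-domain 1-letter residue
#'   vectors), `pcol` (per-domain protein-MSA column per residue, NA when no
#'   protein MSA), `fcol` (per-domain family column per residue, NA
#'   unmapped).
#' @export
merge_alignments <- function(protein_msas, family_msa, domains,
                             family_id = "family") {
  seqs <- list(); pcol <- list(); fcol <- list()
  # protein-level maps
  for (pid in unique(domains$protein_id)) {
    sids <- domains$sid[domains$protein_id == pid]
    msa <- protein_msas[[pid]]
    for (sid in sids) {
      if (!is.null(msa) && sid %in% msa$ids) {
        row <- msa$ali[match(sid, msa$ids), ]
        seqs[[sid]] <- row[row != "-"]
        pcol[[sid]] <- row_colmap(row)
      } else {
        seqs[[sid]] <- NULL     # filled from family MSA below if possible
        pcol[[sid]] <- NULL
      }
      fcol[[sid]] <- NULL
    }
  }
  nprot <- if (is.null(family_msa)) 0L else
    length(unique(domains$protein_id[domains$sid %in% family_msa$ids]))
  if (!is.null(family_msa) && nprot >= 2) {
    rep_sids <- family_msa$ids
    rep_of <- structure(rep_sids,
                        names = domains$protein_id[match(rep_sids, domains$sid)])
    for (pid in unique(domains$protein_id)) {
      rsid <- rep_of[[pid]]
      if (is.null(rsid) || is.na(rsid)) {
        warning("representative of protein '", pid,
                "' missing from family MSA; protein-level mapping only")
        next
      }
      frow <- family_msa$ali[match(rsid, family_msa$ids), ]
      rep_fcol <- row_colmap(frow)                  # rep residue -> fam col
      if (is.null(seqs[[rsid]])) seqs[[rsid]] <- frow[frow != "-"]
      fcol[[rsid]] <- rep_fcol
      # cohorts: compose through the protein MSA
      msa <- protein_msas[[pid]]
      if (is.null(msa) || !(rsid %in% msa$ids)) next
      rep_prow <- msa$ali[match(rsid, msa$ids), ]
      rep_res_at_pcol <- row_resmap(rep_prow)       # prot col -> rep residue
      for (sid in domains$sid[domains$protein_id == pid]) {
        if (sid == rsid || is.null(pcol[[sid]])) next
        repres <- rep_res_at_pcol[pcol[[sid]]]      # rep residue per residue
        fc <- rep(NA_integer_, length(repres))
        ok <- !is.na(repres)
        fc[ok] <- rep_fcol[repres[ok]]
        fcol[[sid]] <- fc
      }
    }
  }
  # any domain never seen in an MSA: unknown sequence, drop with warning
  known <- !vapply(domains$sid, function(s) is.null(seqs[[s]]), logical(1))
  if (any(!known)) {
    warning("domain(s) absent from all alignments dropped: ",
            paste(domains$sid[!known], collapse = ", "))
  }
  structure(list(family_id = family_id,
                 domains = domains[known, c("sid", "protein_id")],
                 seq = seqs, pcol = pcol, fcol = fcol),
            class = "virtual_alignment")
}

#' Fuzzy amino-acid compatibility
#'
#' Two amino acids are compatible when identical or members of the same
#' fuzzy group (see [fuzzy_groups_default()]). Accepts 1-letter or 3-letter
#' codes; unknown codes are incompatible with everything (with a warning).
#'
#' @param aa1,aa2 amino-acid codes.
#' @param groups fuzzy grouping (list of character vectors of 3-letter
#'   codes).
#' @return logical.
#' @export
fuzzy_compatible <- function(aa1, aa2, groups = fuzzy_groups_default()) {
  to3 <- function(a) {
    a <- toupper(a)
    if (nchar(a) == 1) a <- aa_one2three(a)
    a
  }
  a1 <- to3(aa1); a2 <- to3(aa2)
  tab <- aa_table()
  if (is.na(a1) || is.na(a2) ||
      !(a1 %in% tab$three) || !(a2 %in% tab$three)) {
    warning("unknown amino-acid code: ",
            paste(c(aa1, aa2)[!(c(a1, a2) %in% tab$three) | is.na(c(a1, a2))],
                  collapse = ", "))
    return(FALSE)
  }
  if (a1 == a2) return(TRUE)
  any(vapply(groups, function(g) a1 %in% g && a2 %in% g, logical(1)))
}

#' Transfer annotations across a virtual alignment
#'
#' Propagates residue annotations to aligned residues in other domains.
#' `level = "protein"` transfers only between domains of the same protein
#' (through protein-MSA columns); `level = "family"` transfers between any
#' two family members (through the merged virtual alignment). A transfer is
#' made only when the source and target amino acids are fuzzy-compatible.
#' Direct annotations are retained with `level = "direct"`; duplicates are
#' collapsed.
#'
#' @param annotations data.frame with columns `domain` (SID), `res_index`
#'   (1-based ungapped residue index), `type` (annotation label).
#' @param valign a `virtual_alignment`.
#' @param level `"protein"` or `"family"`.
#' @param groups fuzzy grouping table.
#' @return data.frame: `domain`, `res_index`, `type`, `source_domain`,
#'   `source_res`, `level`.
#' @export
transfer_annotations <- function(annotations, valign,
                                 level = c("protein", "family"),
                                 groups = fuzzy_groups_default()) {
  level <- match.arg(level)
  doms <- valign$domains
  out <- list()
  add <- function(domain, res, type, sdom, sres, lev) {
    out[[length(out) + 1L]] <<- data.frame(
      domain = domain, res_index = res, type = type, source_domain = sdom,
      source_res = sres, level = lev, stringsAsFactors = FALSE)
  }
  colmap <- if (level == "protein") valign$pcol else valign$fcol
  for (i in seq_len(nrow(annotations))) {
    d <- annotations$domain[i]; k <- annotations$res_index[i]
    typ <- annotations$type[i]
    add(d, k, typ, d, k, "direct")
    cm <- colmap[[d]]
    if (is.null(cm) || k > length(cm) || is.na(cm[k])) next
    col <- cm[k]
    aa_src <- valign$seq[[d]][k]
    targets <- if (level == "protein") {
      doms$sid[doms$protein_id == doms$protein_id[match(d, doms$sid)]]
    } else {
      doms$sid
    }
    for (t in setdiff(targets, d)) {
      tm <- colmap[[t]]
      if (is.null(tm)) next
      k2 <- match(col, tm)
      if (is.na(k2)) next
      if (!fuzzy_compatible(aa_src, valign$seq[[t]][k2], groups)) next
      add(t, k2, typ, d, k, level)
    }
  }
  if (length(out) == 0) {
    return(data.frame(domain = character(0), res_index = integer(0),
                      type = character(0), source_domain = character(0),
                      source_res = integer(0), level = character(0)))
  }
  res <- do.call(rbind, out)
  res <- res[!duplicated(res[, c("domain", "res_index", "type", "level")]), ]
  rownames(res) <- NULL
  res
}
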