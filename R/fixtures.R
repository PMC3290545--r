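# Synthetic-data generators: every pipeline stage is testable offline.
# Files are written in genuine PDB / aligned-FASTA dialects so the
# production readers are the ones exercised.

format_pdb_atom <- function(serial, name, resname, chain, resno, x, y, z,
                            element, het = FALSE) {
  rec <- if (het) "HETATM" else "ATOM  "
  name4 <- if (nchar(element) == 1) sprintf(" %-3s", name) else
    sprintf("%-4s", name)
  sprintf("%s%5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, name4, resname, chain, resno, x, y, z, 1, 0, element)
}

#' Generate a synthetic domain structure with a pocket and optional ligand
#'
#' Builds a compact sheet-like C-alpha scaffold: residues occupy a
#' serpentine grid (3.8 A spacing along the chain, 4.8 A between strands,
#' 5.2 A between layers) forming a brick, with a 2 x 2 notch carved out of
#' the centre of the top layer as a concave pocket. One sidechain-proxy
#' heavy atom (CB) per non-glycine residue points away from the brick
#' centroid, a small seeded jitter perturbs all coordinates, and a
#' three-atom small molecule is optionally placed inside the pocket. The
#' gold NSM residue set is exactly the residues with a heavy atom within
#' 5 A of a ligand heavy atom, computed by a brute-force all-pairs scan at
#' generation time. Identical seeds give byte-identical files.
#'
#' @param path output PDB file path.
#' @param n_residues number of residues (>= 10).
#' @param ligand place the small molecule (default TRUE).
#' @param seed RNG seed.
#' @param jitter coordinate jitter amplitude in Angstrom (default 0.2).
#' @return invisible list: `path`, `gold_nsm` (data.frame chain, resno of
#'   the planted NSM residues; zero rows when `ligand = FALSE`), `sequence`
#'   (3-letter codes), `pocket` (pocket-centre coordinates).
#' @export
make_structure <- function(path, n_residues = 30, ligand = TRUE, seed = 1,
                           jitter = 0.2) {
  if (n_residues < 10) stop("need n_residues >= 10")
  set.seed(seed)
  aa3 <- aa_table()$three
  seqres <- sample(aa3, n_residues, replace = TRUE)
  # grid dimensions: room for the residues plus the 4-cell notch
  need <- n_residues + 4L
  nz <- if (need >= 40) 3L else 2L
  ny <- max(4L, ceiling(sqrt(need / nz)))
  nx <- ceiling(need / (ny * nz))
  cells <- expand.grid(ix = 0:(nx - 1), iy = 0:(ny - 1), iz = 0:(nz - 1))
  # serpentine chain order: x runs alternate direction along each strand
  ord <- order(cells$iz, cells$iy,
               ifelse(cells$iy %% 2 == 0, cells$ix, -cells$ix))
  cells <- cells[ord, ]
  mx <- floor((nx - 1) / 2); my <- floor((ny - 1) / 2)
  notch <- cells$ix %in% c(mx, mx + 1) & cells$iy %in% c(my, my + 1) &
    cells$iz == nz - 1
  cells <- cells[!notch, ][seq_len(n_residues), ]
  ca <- cbind(cells$ix * 3.8, cells$iy * 4.8, cells$iz * 5.2)
  ca <- ca + matrix(stats::runif(3 * n_residues, -jitter, jitter), ncol = 3)
  pocket <- c((mx + 0.5) * 3.8, (my + 0.5) * 4.8, (nz - 1) * 5.2)
  # sidechain proxy: away from the brick centroid
  ctr <- colMeans(ca)
  dir <- ca - matrix(ctr, n_residues, 3, byrow = TRUE)
  dir <- dir / pmax(sqrt(rowSums(dir^2)), 1e-6)
  cb <- ca + 1.5 * dir
  i <- seq_len(n_residues)
  lines <- character(0)
  serial <- 0L
  for (k in i) {
    serial <- serial + 1L
    lines <- c(lines, format_pdb_atom(serial, "CA", seqres[k], "A", k,
                                      ca[k, 1], ca[k, 2], ca[k, 3], "C"))
    if (seqres[k] != "GLY") {
      serial <- serial + 1L
      lines <- c(lines, format_pdb_atom(serial, "CB", seqres[k], "A", k,
                                        cb[k, 1], cb[k, 2], cb[k, 3], "C"))
    }
  }
  gold <- data.frame(chain = character(0), resno = integer(0))
  if (ligand) {
    seat <- pocket - c(0, 0, 1.8)   # seated into the notch
    lig <- rbind(seat, seat + c(1.4, 0, 0), seat + c(0, 1.4, 0))
    lines <- c(lines, "TER")
    nm <- c("C1", "O1", "N1"); el <- c("C", "O", "N")
    for (j in 1:3) {
      serial <- serial + 1L
      lines <- c(lines, format_pdb_atom(serial, nm[j], "LIG", "L", 900L,
                                        lig[j, 1], lig[j, 2], lig[j, 3],
                                        el[j], het = TRUE))
    }
    # brute-force gold: residues with any heavy atom within 5 A of ligand
    near <- logical(n_residues)
    for (k in i) {
      atoms <- rbind(ca[k, ], if (seqres[k] != "GLY") cb[k, ])
      dmin <- min(apply(atoms, 1, function(a) {
        min(sqrt(rowSums((lig - matrix(a, 3, 3, byrow = TRUE))^2)))
      }))
      near[k] <- dmin <= 5
    }
    gold <- data.frame(chain = "A", resno = i[near])
  }
  writeLines(c(lines, "END"), path)
  invisible(list(path = path, gold_nsm = gold, sequence = seqres,
                 pocket = pocket))
}

# text styles for planting a residue mention; each returns the phrase and
# the relative span of the normalized mention inside it
style_phrase <- function(wt3, pos, mut3, style) {
  tab <- aa_table()
  nm <- tab$name[match(wt3, tab$three)]
  t3 <- paste0(toupper(substr(wt3, 1, 1)), tolower(substr(wt3, 2, 3)))
  one <- tab$one[match(wt3, tab$three)]
  switch(style,
    three = paste0(t3, pos),
    hyphen = paste0(t3, "-", pos),
    full = paste0(nm, " ", pos),
    one = paste0(one, pos),
    short_mut = paste0(one, pos, tab$one[match(mut3, tab$three)]),
    three_mut = paste0(t3, pos,
                       paste0(toupper(substr(mut3, 1, 1)),
                              tolower(substr(mut3, 2, 3)))),
    ling_mut = paste0(t3, "-", pos, " was mutated to ",
                      tab$name[match(mut3, tab$three)]),
    stop("unknown style: ", style))
}

#' Generate a synthetic abstract with planted residue mentions
#'
#' Plants the given residues (optionally as mutations) in a mix of surface
#' styles — `"three"` (Asp104), `"hyphen"` (Asp-104), `"full"` (aspartic
#' acid 104), `"one"` (D104), `"short_mut"` (D104A), `"three_mut"`
#' (Asp104Ala), `"ling_mut"` (Asp-104 was mutated to alanine) — inside
#' filler prose, together with distractor tokens. Extractable distractors
#' (gene/plasmid lookalikes such as `"E2F"` or `"R377"`) are recorded in
#' `planted_fp`: gold marks them as non-mentions, so they are controlled
#' false positives. Every planted mention's character span is recorded.
#'
#' @param residues data.frame with columns `wt_code`, `position` and
#'   optional `mut_code` (NA for plain residues).
#' @param styles style per residue (recycled).
#' @param n_distractors number of extractable distractor tokens.
#' @param seed RNG seed.
#' @param pmid document id recorded on the gold mentions.
#' @param distractor_pool tokens to draw distractors from; the defaults all
#'   extract as (false-positive) mentions.
#' @return list: `text`, `gold` (mention data.frame with spans),
#'   `planted_fp` (character vector of distractor tokens).
#' @export
make_abstract <- function(residues, styles = "three", n_distractors = 0,
                          seed = 1, pmid = "1000001",
                          distractor_pool = c("E2F", "R377", "L23A", "H2A")) {
  set.seed(seed)
  styles <- rep_len(styles, nrow(residues))
  lead <- c("Analysis of the enzyme showed that ",
            "Activity assays demonstrated that ",
            "The crystal structure reveals that ",
            "Kinetic measurements indicate that ")
  tail <- c(" is required for catalysis.",
            " lies in the substrate pocket.",
            " stabilizes the transition state.",
            " contributes to ligand binding.")
  text <- "We determined the structure of a model protein."
  gold <- empty_mentions()
  for (i in seq_len(nrow(residues))) {
    wt <- residues$wt_code[i]; pos <- residues$position[i]
    mut <- if ("mut_code" %in% names(residues)) residues$mut_code[i] else NA
    phrase <- style_phrase(wt, pos, if (is.na(mut)) "ALA" else mut,
                           if (is.na(mut) &&
                               grepl("mut", styles[i])) "three" else styles[i])
    pre <- paste0(" ", sample(lead, 1))
    start <- nchar(text) + nchar(pre) + 1L
    text <- paste0(text, pre, phrase, sample(tail, 1))
    gold <- rbind(gold, new_mention(
      wt, pos,
      if (is.na(mut) || !grepl("mut", styles[i])) NA_character_ else mut,
      start, start + nchar(phrase) - 1L, phrase, pmid))
  }
  fps <- character(0)
  if (n_distractors > 0) {
    pool <- distractor_pool
    fps <- sample(pool, n_distractors, replace = n_distractors > length(pool))
    for (fp in fps) {
      text <- paste0(text, " Expression was driven in the ", fp,
                     " background.")
    }
  }
  text <- paste0(text, " No other residues were characterized.")
  rownames(gold) <- NULL
  list(text = text, gold = gold, planted_fp = fps)
}

#' Generate protein-level and family-level alignment fixtures
#'
#' Builds a synthetic SCOP-style family of `n_proteins` proteins with
#' `domains_per_protein` domains each. Sequences share fully conserved
#' columns (gold H.norm = 1) at the requested positions; remaining columns
#' are drawn near-uniformly over the amino-acid alphabet (low gold H.norm).
#' The first domain of each protein is full length (hence the
#' representative); later domains are truncated at the N-terminus, showing
#' up as leading gaps in the protein-level alignment. Aligned FASTA files
#' are written for each protein-level MSA and for the family-level MSA of
#' the representatives.
#'
#' @param dir output directory.
#' @param n_proteins number of distinct proteins (>= 2 for family level).
#' @param domains_per_protein domains per protein.
#' @param ncol alignment width.
#' @param conserved_columns indices of fully conserved columns.
#' @param seed RNG seed.
#' @return list: `family_msa` (path), `protein_msas` (named paths),
#'   `domains` (data.frame sid, protein_id, length), `conserved_columns`.
#' @export
make_msa <- function(dir, n_proteins = 3, domains_per_protein = 2,
                     ncol = 40, conserved_columns = c(5, 12, 20), seed = 1) {
  if (n_proteins < 2) stop("need n_proteins >= 2 for a family-level MSA")
  set.seed(seed)
  one <- aa_table()$one
  cons <- sample(one, length(conserved_columns), replace = TRUE)
  prot_seqs <- lapply(seq_len(n_proteins), function(p) {
    s <- sample(one, ncol, replace = TRUE)
    s[conserved_columns] <- cons
    s
  })
  domains <- data.frame(sid = character(0), protein_id = character(0),
                        length = integer(0), stringsAsFactors = FALSE)
  protein_paths <- character(0)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in seq_len(n_proteins)) {
    pid <- sprintf("P%04d", p)
    rows <- character(0); ids <- character(0)
    for (d in seq_len(domains_per_protein)) {
      sid <- sprintf("d%02dx%d_", p, d)
      trunc <- if (d == 1) 0L else 5L * (d - 1L)
      ali <- prot_seqs[[p]]
      if (trunc > 0) ali[seq_len(trunc)] <- "-"
      ids <- c(ids, sid); rows <- c(rows, paste(ali, collapse = ""))
      domains <- rbind(domains, data.frame(
        sid = sid, protein_id = pid, length = ncol - trunc,
        stringsAsFactors = FALSE))
    }
    path <- file.path(dir, paste0(pid, "_protein.fasta"))
    writeLines(paste0(">", ids, "\n", rows), path)
    protein_paths[pid] <- path
  }
  reps <- select_representatives(domains)
  fam_rows <- vapply(names(reps), function(pid) {
    p <- as.integer(sub("P", "", pid))
    paste(prot_seqs[[p]], collapse = "")
  }, character(1))
  fam_path <- file.path(dir, "family.fasta")
  writeLines(paste0(">", reps, "\n", fam_rows), fam_path)
  list(family_msa = fam_path, protein_msas = protein_paths,
       domains = domains, conserved_columns = conserved_columns)
}

#' Generate a complete synthetic study
#'
#' One call produces a coherent miniature study: a structure with a pocket
#' and ligand, an abstract whose planted mentions reference real residues
#' of that structure, a PMID-to-PDB link table, family alignments, and the
#' gold tables for every planted feature.
#'
#' @param dir output directory.
#' @param n_residues residues in the synthetic domain.
#' @param seed RNG seed.
#' @param n_mentions number of planted residue mentions.
#' @param n_distractors extractable distractor tokens in the abstract.
#' @return list with the generated paths and gold tables: `structure`
#'   (path), `gold_nsm`, `sequence`, `abstract` (text), `gold_mentions`,
#'   `pmid`, `pdb_id`, `links` (path to the PMID->PDB TSV), `msa` (the
#'   [make_msa()] result).
#' @export
make_study <- function(dir, n_residues = 56, seed = 1, n_mentions = 3,
                       n_distractors = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  st <- make_structure(file.path(dir, "synthetic_domain.pdb"),
                       n_residues = n_residues, ligand = TRUE, seed = seed)
  set.seed(seed + 1)
  picks <- sort(sample(seq_len(n_residues), n_mentions))
  residues <- data.frame(wt_code = st$sequence[picks], position = picks,
                         mut_code = NA_character_, stringsAsFactors = FALSE)
  styles <- rep_len(c("three", "full", "hyphen"), n_mentions)
  ab <- make_abstract(residues, styles = styles,
                      n_distractors = n_distractors, seed = seed + 2,
                      pmid = "1000001",
                      distractor_pool = "R377")
  pdb_id <- "sy01"
  links_path <- file.path(dir, "pmid2pdb.tsv")
  utils::write.table(data.frame(pmid = ab$gold$source[1], pdb_id = pdb_id),
                     links_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  msa <- make_msa(file.path(dir, "msa"), seed = seed + 3)
  list(structure = st$path, gold_nsm = st$gold_nsm, sequence = st$sequence,
       abstract = ab$text, gold_mentions = ab$gold, planted_fp = ab$planted_fp,
       pmid = "1000001", pdb_id = pdb_id, links = links_path, msa = msa)
}
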