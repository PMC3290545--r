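#' Read a protein structure (PDB or mmCIF)
#'
#' Parses a structure file into a flat atom table. Both formats are handled
#' by bio3d (`read.pdb` / `read.cif`); the table is normalised to one row per
#' atom with author chain id, author residue number, insertion code,
#' 3-letter component code, chemical element, heavy-atom flag and a
#' molecular-entity label. When several alternate locations exist for an
#' atom the first (altloc A) is kept.
#'
#' Entity labels come from `label_entity_id` for mmCIF input. PDB format has
#' no entity records, so protein chains with identical residue sequences are
#' assigned a shared entity (the mmCIF convention for homomers); hetero
#' molecules get entities of their own.
#'
#' @param path path to a `.pdb` or `.cif` file.
#' @param format `"auto"` (default, by extension), `"pdb"` or `"cif"`.
#' @return An object of class `protein_structure`: a list with `atoms` (the
#'   atom data.frame with columns `eleno, elety, resid, chain, resno, icode,
#'   x, y, z, element, is_heavy, het, entity`) and `path`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  if (!file.exists(path)) stop("structure file not found: ", path)
  raw <- tryCatch(
    if (format == "cif") suppressWarnings(bio3d::read.cif(path))
    else suppressWarnings(bio3d::read.pdb(path)),
    error = function(e) stop("unparseable structure file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- raw$atom
  if (is.null(at) || nrow(at) == 0L) {
    stop("empty structure: no atom records in ", path)
  }
  element <- toupper(at$elesy)
  element[is.na(element) | element == ""] <-
    toupper(substr(gsub("[^A-Za-z].*", "", at$elety[is.na(element) | element == ""]), 1, 1))
  atoms <- data.frame(
    eleno = at$eleno,
    elety = at$elety,
    resid = toupper(at$resid),
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    icode = ifelse(is.na(at$insert), "", as.character(at$insert)),
    x = at$x, y = at$y, z = at$z,
    element = element,
    het = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  atoms$is_heavy <- !(atoms$element %in% c("H", "D"))
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in ", path)
  }
  atoms$entity <- if (format == "cif" && !all(is.na(at$segid))) {
    as.character(at$segid)
  } else {
    assign_entities(atoms)
  }
  structure(list(atoms = atoms, path = path, format = format),
            class = "protein_structure")
}

# Assign entity labels for PDB input: protein (ATOM) chains sharing one
# residue sequence share an entity; each hetero molecule chain gets its own.
assign_entities <- function(atoms) {
  ent <- character(nrow(atoms))
  prot <- !atoms$het
  chains <- unique(atoms$chain[prot])
  seqs <- vapply(chains, function(ch) {
    a <- atoms[prot & atoms$chain == ch, ]
    paste(a$resid[!duplicated(paste(a$resno, a$icode))], collapse = "-")
  }, character(1))
  ids <- match(seqs, unique(seqs))
  for (i in seq_along(chains)) {
    ent[prot & atoms$chain == chains[i]] <- as.character(ids[i])
  }
  nexti <- length(unique(seqs))
  hchains <- unique(atoms$chain[atoms$het])
  for (ch in hchains) {
    nexti <- nexti + 1L
    sel <- atoms$het & atoms$chain == ch & ent == ""
    ent[sel] <- as.character(nexti)
  }
  ent
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("protein_structure:", x$path, "\n",
      nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain)), "chains\n")
  invisible(x)
}

residue_key <- function(chain, resno, icode = "") {
  icode[is.na(icode)] <- ""
  paste(chain, resno, icode, sep = "|")
}

#' Parse a SCOP-style domain definition
#'
#' Accepts region strings of the dir.cla dialect: `"A:"` (whole chain),
#' `"A:2-209"` (chain with residue range), or several comma-separated
#' regions.
#'
#' @param def definition string.
#' @return data.frame with columns `chain`, `start`, `end` (NA = open end).
#' @export
parse_domain_def <- function(def) {
  parts <- strsplit(def, ",", fixed = TRUE)[[1]]
  out <- lapply(trimws(parts), function(p) {
    m <- regmatches(p, regexec("^([A-Za-z0-9]):?(?:(-?[0-9]+)-(-?[0-9]+))?$", p))[[1]]
    if (length(m) == 0) stop("cannot parse domain region: '", p, "'")
    data.frame(chain = m[2],
               start = ifelse(m[3] == "", NA, as.integer(m[3])),
               end = ifelse(m[4] == "", NA, as.integer(m[4])),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Extract a domain (and its co-crystallized molecules) from a structure
#'
#' Restricts a parsed structure to one domain, defined by chain and residue
#' range. All atoms outside the domain's protein chains become candidate
#' "small molecules": any chain not associated with the domain, including
#' short peptides, nucleic acids, ions and organic compounds. Waters are
#' dropped by default.
#'
#' @param struct a `protein_structure`.
#' @param domain_def a definition string (see [parse_domain_def()]).
#' @param domain_id identifier for the domain (SCOP SID style).
#' @param exclude_water drop HOH/DOD molecules from the cochains (default
#'   TRUE).
#' @return A `domain_structure`: list with `domain_id`, `atoms` (domain
#'   atoms), `residues` (one row per domain residue with `key`), and
#'   `cochains` (non-domain atoms with a `mol_id` column, one id per
#'   molecule).
#' @export
extract_domain <- function(struct, domain_def, domain_id = "domain",
                           exclude_water = TRUE) {
  stopifnot(inherits(struct, "protein_structure"))
  defs <- parse_domain_def(domain_def)
  atoms <- struct$atoms
  missing_ch <- setdiff(defs$chain, atoms$chain)
  if (length(missing_ch) > 0) {
    stop("domain definition references absent chain(s): ",
         paste(missing_ch, collapse = ", "))
  }
  in_dom <- rep(FALSE, nrow(atoms))
  for (i in seq_len(nrow(defs))) {
    sel <- atoms$chain == defs$chain[i] & !atoms$het
    if (!is.na(defs$start[i])) sel <- sel & atoms$resno >= defs$start[i]
    if (!is.na(defs$end[i])) sel <- sel & atoms$resno <= defs$end[i]
    in_dom <- in_dom | sel
  }
  dom <- atoms[in_dom, , drop = FALSE]
  if (nrow(dom) == 0L) stop("domain definition matches zero residues")
  other <- atoms[!in_dom, , drop = FALSE]
  # non-domain atoms in the domain's protein chains (e.g. residues outside
  # the range) are neither domain nor small molecule: drop them
  other <- other[other$het | !(other$chain %in% defs$chain), , drop = FALSE]
  if (exclude_water && nrow(other) > 0) {
    other <- other[!(other$resid %in% c("HOH", "DOD", "WAT")), , drop = FALSE]
  }
  other$mol_id <- if (nrow(other) > 0) assign_molecules(other) else character(0)
  key <- residue_key(dom$chain, dom$resno, dom$icode)
  residues <- dom[!duplicated(key), c("chain", "resno", "icode", "resid", "entity")]
  residues$key <- key[!duplicated(key)]
  rownames(residues) <- NULL
  structure(list(domain_id = domain_id, atoms = dom, residues = residues,
                 cochains = other),
            class = "domain_structure")
}

# Split non-domain atoms into molecules. Polymer (ATOM) chains are one
# molecule per chain (the mmCIF single-molecule chain notion); HETATM
# residues sharing an author chain are split into maximal runs of
# consecutive residue numbers, so a covalently linked hetero tripeptide
# (e.g. GGL-CYS-GLY numbered n, n+1, n+2) stays one molecule while separate
# ligand copies split.
assign_molecules <- function(atoms) {
  mol <- character(nrow(atoms))
  for (ch in unique(atoms$chain)) {
    sel <- which(atoms$chain == ch)
    a <- atoms[sel, ]
    if (all(!a$het)) {
      mol[sel] <- paste0("chain:", ch)
      next
    }
    resu <- unique(data.frame(resno = a$resno, icode = a$icode,
                              stringsAsFactors = FALSE))
    resu <- resu[order(resu$resno, resu$icode), , drop = FALSE]
    run <- cumsum(c(1L, diff(resu$resno) > 1L))
    resu$mol <- paste0("het:", ch, ":", run)
    idx <- match(paste(a$resno, a$icode), paste(resu$resno, resu$icode))
    mol[sel] <- resu$mol[idx]
  }
  mol
}

#' @export
print.domain_structure <- function(x, ...) {
  cat("domain_structure", x$domain_id, "-", nrow(x$residues), "residues,",
      length(unique(x$cochains$mol_id)), "co-crystallized molecule(s)\n")
  invisible(x)
}

#' Find sites near a small molecule (NSM)
#'
#' An NSM site is the set of domain residues with a heavy atom within
#' `cutoff` of a heavy atom of one co-crystallized small molecule (any
#' non-domain chain). Hydrogens are ignored on both sides; molecules with no
#' residue within the cutoff yield no site.
#'
#' @param domain a `domain_structure`.
#' @param cutoff distance in Angstrom (default 5).
#' @return list of `nsm_site` objects: `site_id`, `molecule` (ordered
#'   hetero-code list), `residues` (residue keys), `validity`
#'   (`"uncurated"` until matched against curation records).
#' @export
find_nsm_sites <- function(domain, cutoff = 5) {
  stopifnot(inherits(domain, "domain_structure"))
  co <- domain$cochains
  if (is.null(co) || nrow(co) == 0) return(list())
  dom <- domain$atoms[domain$atoms$is_heavy, , drop = FALSE]
  dxyz <- as.matrix(dom[, c("x", "y", "z")])
  sites <- list()
  for (mid in unique(co$mol_id)) {
    m <- co[co$mol_id == mid & co$is_heavy, , drop = FALSE]
    if (nrow(m) == 0) next
    mxyz <- as.matrix(m[, c("x", "y", "z")])
    near <- apply(dxyz, 1, function(p) {
      min(sqrt(colSums((t(mxyz) - p)^2))) <= cutoff
    })
    if (!any(near)) next
    keys <- unique(residue_key(dom$chain[near], dom$resno[near],
                               dom$icode[near]))
    codes <- m$resid[!duplicated(paste(m$resno, m$icode))]
    sites[[length(sites) + 1L]] <- structure(
      list(site_id = mid, molecule = codes, residues = keys,
           validity = "uncurated"),
      class = "nsm_site")
  }
  sites
}

#' Read MOAD-style ligand validity records
#'
#' Reads `every_bind.csv`-dialect rows. The expected columns (header
#' optional) are: `pdb_id` (4-character entry id), `hetero_codes` (the
#' ligand as an ordered list of 3-letter hetero codes joined by `-` or
#' spaces, e.g. `"GLU-CYS-GLY"`), and `validity` (`valid` or `invalid`).
#' Malformed rows are skipped with a warning.
#'
#' @param path CSV file path.
#' @return data.frame with columns `pdb_id`, `hetero_codes` (list column of
#'   character vectors), `validity`.
#' @export
read_moad <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, header = TRUE)
  need <- c("pdb_id", "hetero_codes", "validity")
  if (!all(need %in% names(raw))) {
    stop("MOAD file must have columns: ", paste(need, collapse = ", "))
  }
  ok <- !is.na(raw$pdb_id) & raw$pdb_id != "" &
    tolower(raw$validity) %in% c("valid", "invalid")
  if (any(!ok)) {
    warning(sum(!ok), " malformed MOAD record(s) skipped")
    raw <- raw[ok, , drop = FALSE]
  }
  data.frame(
    pdb_id = tolower(raw$pdb_id),
    hetero_codes = I(strsplit(toupper(raw$hetero_codes), "[- ]+")),
    validity = tolower(raw$validity),
    stringsAsFactors = FALSE
  )
}

#' Label NSM sites with MOAD validity
#'
#' Matches each site's ordered hetero-code list against the MOAD records for
#' one PDB entry; an exact ordered match labels the site with the record's
#' validity, unmatched sites stay `uncurated`. An optional synonym map (named
#' character vector, e.g. `c(GGL = "GLU")`) translates structure-side codes
#' before matching, covering naming drift between the PDB and curation
#' records. One record labels every site with a matching molecule (multiple
#' copies of the same ligand all get the record's label).
#'
#' @param sites list of `nsm_site` from [find_nsm_sites()].
#' @param moad data.frame from [read_moad()].
#' @param pdb_id entry id the sites belong to.
#' @param synonyms optional named character vector of hetero-code aliases.
#' @return the site list with `validity` filled in.
#' @export
match_moad <- function(sites, moad, pdb_id, synonyms = NULL) {
  recs <- moad[moad$pdb_id == tolower(pdb_id), , drop = FALSE]
  if (nrow(recs) == 0) return(sites)
  canon <- function(codes) {
    if (!is.null(synonyms)) {
      hit <- codes %in% names(synonyms)
      codes[hit] <- synonyms[codes[hit]]
    }
    paste(codes, collapse = "-")
  }
  rec_keys <- vapply(recs$hetero_codes, canon, character(1))
  lapply(sites, function(s) {
    i <- match(canon(s$molecule), rec_keys)
    if (!is.na(i)) s$validity <- recs$validity[i]
    s
  })
}

#' Load CSA-style catalytic-residue annotations
#'
#' Reads a Catalytic Site Atlas dialect CSV with columns `pdb_id`,
#' `chain_id`, `res_num`, `res_name`, `evidence`. Only literature-evidenced
#' rows (`evidence == "LIT"`) are retained; PSI-BLAST (transitive) rows are
#' dropped and unknown evidence strings are skipped with a warning.
#'
#' @param path CSV file path.
#' @return data.frame of LIT annotations keyed by (pdb_id, chain_id,
#'   res_num).
#' @export
load_csa <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pdb_id", "chain_id", "res_num", "res_name", "evidence")
  if (!all(need %in% names(raw))) {
    stop("CSA file must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(raw) == 0) return(raw[, need])
  ev <- toupper(raw$evidence)
  unknown <- !(ev %in% c("LIT", "PSI-BLAST", "PSIBLAST"))
  if (any(unknown)) {
    warning(sum(unknown), " CSA row(s) with unknown evidence type skipped")
  }
  out <- raw[ev == "LIT", need, drop = FALSE]
  out$pdb_id <- tolower(out$pdb_id)
  out$res_num <- as.integer(out$res_num)
  rownames(out) <- NULL
  out
}
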