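#' Amino-acid code tables
#'
#' Lookup tables linking 1-letter codes, 3-letter codes and full names of the
#' 20 standard amino acids, including common alternative full names
#' (aspartate for aspartic acid, etc.). Used by the mention extractor and by
#' annotation transfer.
#'
#' @return `aa_table()` returns a data.frame with columns `one`, `three`,
#'   `name` (one row per standard amino acid, canonical full name).
#' @export
aa_table <- function() {
  data.frame(
    one = c("A","R","N","D","C","Q","E","G","H","I",
            "L","K","M","F","P","S","T","W","Y","V"),
    three = c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
              "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL"),
    name = c("alanine","arginine","asparagine","aspartic acid","cysteine",
             "glutamine","glutamic acid","glycine","histidine","isoleucine",
             "leucine","lysine","methionine","phenylalanine","proline",
             "serine","threonine","tryptophan","tyrosine","valine"),
    stringsAsFactors = FALSE
  )
}

# alternative full names -> 3-letter code (beyond the canonical names)
aa_alt_names <- function() {
  c(aspartate = "ASP", glutamate = "GLU")
}

#' @rdname aa_table
#' @param code character vector of 1-letter codes.
#' @return `aa_one2three()` returns the matching 3-letter codes (NA when not
#'   a standard code).
#' @export
aa_one2three <- function(code) {
  tab <- aa_table()
  tab$three[match(toupper(code), tab$one)]
}

#' @rdname aa_table
#' @param three character vector of 3-letter codes.
#' @export
aa_three2one <- function(three) {
  tab <- aa_table()
  tab$one[match(toupper(three), tab$three)]
}

#' Fuzzy amino-acid groups for annotation transfer
#'
#' Equivalence classes of amino acids within which annotations may be
#' transferred across aligned positions. The default grouping follows the
#' convention used by catalytic-site template matching: acidic \{D,E\},
#' basic \{K,R,H\}, hydroxyl \{S,T\}, amide \{N,Q\}, aliphatic/hydrophobic
#' \{I,L,V,M\}, aromatic \{F,Y,W\}, small \{A,G\}, and singletons \{C\},
#' \{P\}. The table is explicit and overridable: any list of character
#' vectors of 3-letter codes is accepted wherever a `groups` argument
#' appears.
#'
#' @return Named list of character vectors of 3-letter codes.
#' @export
fuzzy_groups_default <- function() {
  list(
    acidic     = c("ASP", "GLU"),
    basic      = c("LYS", "ARG", "HIS"),
    hydroxyl   = c("SER", "THR"),
    amide      = c("ASN", "GLN"),
    aliphatic  = c("ILE", "LEU", "VAL", "MET"),
    aromatic   = c("PHE", "TYR", "TRP"),
    small      = c("ALA", "GLY"),
    cysteine   = "CYS",
    proline    = "PRO"
  )
}

# van der Waals radii (A) by element, Bondi values; default for unknowns
vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
    FE = 2.00, ZN = 1.39, MG = 1.73, CA = 2.00, MN = 2.00, "NA" = 2.27,
    K = 2.75, CU = 1.40, NI = 1.63, CO = 2.00)
}
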