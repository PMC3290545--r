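#' Normalized Shannon entropy of an alignment column
#'
#' Conservation of one alignment column over the 22-symbol alphabet (20
#' amino acids, gap `-`, wildcard `X`): `H = -sum p_i ln p_i` over the
#' symbol frequencies and `H.norm = 1 - H / ln(22)`, so 1 marks a fully
#' conserved column and 0 a maximally diverse one. Symbols outside the
#' alphabet are mapped to the wildcard with a warning.
#'
#' @param column character vector of 1-letter symbols (one per sequence).
#' @return H.norm in `[0, 1]`.
#' @export
column_entropy <- function(column) {
  if (length(column) == 0) stop("empty column")
  alphabet <- c(aa_table()$one, "-", "X")
  sym <- toupper(column)
  bad <- !(sym %in% alphabet)
  if (any(bad)) {
    warning(sum(bad), " symbol(s) outside the 22-letter alphabet mapped to X")
    sym[bad] <- "X"
  }
  p <- table(factor(sym, levels = alphabet))
  p <- p[p > 0] / length(sym)
  h <- -sum(p * log(p))
  1 - h / log(22)
}

#' Conservation profile of a family alignment
#'
#' H.norm per column of a (non-redundant, family-level) alignment.
#'
#' @param msa alignment from [read_msa()].
#' @return numeric vector of per-column H.norm values.
#' @export
conservation_profile <- function(msa) {
  apply(msa$ali, 2, column_entropy)
}

#' Percentile rankings of residues by conservation
#'
#' Ranks a domain's residues in descending conservation (highest H.norm
#' first, ties averaged) and returns the percentile `rank / N` in `(0, 1]`
#' — small percentiles mark the most conserved residues, so a product of
#' percentiles is small for a jointly conserved site.
#'
#' @param hnorm per-residue H.norm values for one domain.
#' @return percentile per residue in `(0, 1]`.
#' @export
rank_residues <- function(hnorm) {
  if (length(hnorm) == 0) stop("no scored residues")
  rank(-hnorm, ties.method = "average") / length(hnorm)
}

#' P-value of a lumped (product-of-percentiles) site score
#'
#' The lumped score of a site is `z`, the product of the conservation
#' percentile rankings of its `L` scored residues. Under a null model in
#' which residues are drawn at random, the percentiles are independent
#' uniform(0,1) variables, and the probability of a product at most `z` has
#' the closed form `P = z * sum_{k=0}^{L-1} (-ln z)^k / k!` (equivalently
#' the upper tail of a Gamma(L, 1) at `-ln z`).
#'
#' @param z product of percentile rankings, `0 < z <= 1`.
#' @param L number of scored residues in the site, `L >= 1`.
#' @return P in `(0, 1]`.
#' @export
lumped_pvalue <- function(z, L) {
  if (any(z <= 0 | z > 1)) stop("z must be in (0, 1]")
  if (any(L < 1)) stop("L must be >= 1")
  vapply(seq_along(z), function(i) {
    zi <- z[i]; Li <- if (length(L) > 1) L[i] else L
    if (zi == 1) return(1)
    if (Li > 50) {
      return(stats::pgamma(-log(zi), shape = Li, lower.tail = FALSE))
    }
    t <- -log(zi)
    term <- 1
    s <- 1
    for (k in seq_len(Li - 1)) {
      term <- term * t / k
      s <- s + term
    }
    min(zi * s, 1)
  }, numeric(1))
}

#' Lumped conservation score of a site
#'
#' Multiplies the percentile rankings of the site's scored residues and
#' attaches the analytic p-value. Residues without conservation data are
#' excluded from `L` rather than imputed.
#'
#' @param percentiles percentile rankings of the site residues (NA allowed;
#'   excluded).
#' @return list `L`, `z`, `p_value` (NULL if no residue is scored).
#' @export
lumped_score <- function(percentiles) {
  p <- percentiles[!is.na(percentiles)]
  if (length(p) == 0) return(NULL)
  z <- prod(p)
  list(L = length(p), z = z, p_value = lumped_pvalue(z, length(p)))
}

#' Fractional conservation scores within a domain
#'
#' Fractional ranking of each residue's conservation against all residues
#' of the same domain, 0 = least conserved, 1 = most conserved, ties
#' averaged. Requires a conservation alignment of at least `min_seqs`
#' distinct sequences; smaller families return a not-scored result.
#'
#' @param hnorm per-residue H.norm values for one domain.
#' @param n_seqs number of sequences in the conservation alignment.
#' @param min_seqs minimum alignment depth to score (default 10).
#' @return numeric vector in `[0, 1]`, or NULL (not scored) when the
#'   alignment is too small.
#' @export
fractional_conservation <- function(hnorm, n_seqs = Inf, min_seqs = 10) {
  if (n_seqs < min_seqs) return(NULL)
  n <- length(hnorm)
  if (n == 1) return(0.5)
  (rank(hnorm, ties.method = "average") - 1) / (n - 1)
}
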