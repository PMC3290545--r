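#' Residue-wise recall of an NSM site by the DPA predictions
#'
#' `|R_NSM intersect R_DPA_all| / |R_NSM|`, where `R_NSM` is the residue set
#' of one NSM site and `R_DPA_all` the union of residues over all DPA
#' predictions for the structure.
#'
#' @param nsm_residues residue keys of one NSM site (nonempty).
#' @param dpa_all_residues union of residue keys over all DPA sites.
#' @return fraction in `[0, 1]`.
#' @export
site_recall <- function(nsm_residues, dpa_all_residues) {
  if (length(nsm_residues) == 0) stop("empty NSM site")
  length(intersect(unique(nsm_residues), unique(dpa_all_residues))) /
    length(unique(nsm_residues))
}

#' Residue-wise precision of a DPA site against a reference set
#'
#' `|R_DPA intersect R_ref| / |R_DPA|`, with the reference the union of all
#' NSM residues or of NSM-valid residues.
#'
#' @param dpa_residues residue keys of one DPA site (nonempty).
#' @param reference_residues reference residue keys.
#' @return fraction in `[0, 1]`.
#' @export
site_precision <- function(dpa_residues, reference_residues) {
  if (length(dpa_residues) == 0) stop("empty DPA site")
  length(intersect(unique(dpa_residues), unique(reference_residues))) /
    length(unique(dpa_residues))
}

#' Threshold curve of a per-site metric
#'
#' Fraction of sites whose metric is at least `t`, for each threshold;
#' nonincreasing in `t` by construction.
#'
#' @param values per-site metric values in `[0, 1]`.
#' @param thresholds thresholds (default 0.1, 0.2, ..., 1.0).
#' @return data.frame `t`, `fraction`.
#' @export
threshold_curve <- function(values, thresholds = seq(0.1, 1, by = 0.1)) {
  data.frame(t = thresholds,
             fraction = vapply(thresholds,
                               function(t) mean(values >= t), numeric(1)))
}

#' Fold enrichment of a hit rate between two residue populations
#'
#' Compares the annotation rate `n_hit_A / n_A` against `n_hit_B / n_B`.
#' In `"paper"` mode each rate is first rounded to a whole percent and the
#' rounded percentages are divided (the arithmetic used for printed
#' whole-percent rates); `"exact"` mode divides the raw fractions.
#'
#' @param n_hit_A,n_A hits and total in population A.
#' @param n_hit_B,n_B hits and total in population B. `n_B` may be omitted
#'   with `rate_B` given directly (e.g. a nominal p-value cutoff as the
#'   expected rate).
#' @param rate_B optional baseline rate replacing `n_hit_B / n_B`.
#' @param rounding `"paper"` (whole-percent) or `"exact"`.
#' @return fold enrichment (NA with a warning when the baseline percentage
#'   rounds to zero).
#' @export
enrichment <- function(n_hit_A, n_A, n_hit_B = NULL, n_B = NULL,
                       rate_B = NULL, rounding = c("paper", "exact")) {
  rounding <- match.arg(rounding)
  if (n_A <= 0) stop("n_A must be positive")
  ra <- n_hit_A / n_A
  rb <- if (!is.null(rate_B)) rate_B else {
    if (is.null(n_hit_B) || is.null(n_B) || n_B <= 0) {
      stop("need n_hit_B and positive n_B, or rate_B")
    }
    n_hit_B / n_B
  }
  if (rounding == "paper") {
    pa <- round(100 * ra)
    pb <- round(100 * rb, digits = if (100 * rb < 1) 1 else 0)
    if (pb == 0) {
      warning("baseline percentage rounds to zero; enrichment undefined")
      return(NA_real_)
    }
    pa / pb
  } else {
    if (rb == 0) {
      warning("baseline rate is zero; enrichment undefined")
      return(NA_real_)
    }
    ra / rb
  }
}

report_columns <- c(
  "DPA_CLUSTER_ID", "ENTITY_ID", "CHAIN_ID", "RES_SEQ_NUM", "ICODE",
  "RES_NAME", "IS_LIT_MATCH", "IS_CSA_LIT", "IS_NSM_VALID", "IS_NSM",
  "IS_CURATED_FAMILY", "IS_NSM_FAMILY", "NSM_HETERO_CODES")

#' Combined per-residue report of DPA sites with text and annotation flags
#'
#' One record per (DPA site, residue) pair — a residue in several sites
#' appears once per site. Flags mark whether the residue matches a grounded
#' text residue, a literature-evidenced catalytic annotation, an NSM or
#' NSM-valid site, and family-transferred curated/NSM annotations. The
#' hetero-code column lists the codes of nearby small molecules with their
#' curation status in parentheses.
#'
#' @param domain a `domain_structure`.
#' @param dpa_sites list of `dpa_site` from [dpa_predict()].
#' @param nsm_sites labelled NSM sites from [match_moad()] (or
#'   [find_nsm_sites()]).
#' @param text_residue_keys residue keys grounded to a text residue.
#' @param csa_keys residue keys with a direct CSA-LIT annotation.
#' @param family_curated_keys residue keys aligned with a family-level
#'   curated (CSA-LIT or NSM-valid) annotation.
#' @param family_nsm_keys residue keys aligned with any family-level NSM
#'   annotation.
#' @return data.frame with the 13 fixed report columns.
#' @export
build_report <- function(domain, dpa_sites, nsm_sites = list(),
                         text_residue_keys = character(0),
                         csa_keys = character(0),
                         family_curated_keys = character(0),
                         family_nsm_keys = character(0)) {
  res <- domain$residues
  nsm_keys <- unique(unlist(lapply(nsm_sites, `[[`, "residues")))
  valid_keys <- unique(unlist(lapply(
    nsm_sites[vapply(nsm_sites, function(s) s$validity == "valid",
                     logical(1))],
    `[[`, "residues")))
  hetero_of <- function(key) {
    labs <- vapply(nsm_sites, function(s) {
      if (!(key %in% s$residues)) return(NA_character_)
      codes <- paste(s$molecule, collapse = "-")
      if (s$validity == "uncurated") codes
      else paste0(codes, " (", s$validity, ")")
    }, character(1))
    paste(labs[!is.na(labs)], collapse = ",")
  }
  rows <- lapply(dpa_sites, function(s) {
    idx <- match(s$residues, res$key)
    if (anyNA(idx)) {
      stop("site ", s$site_label, " references residue key(s) absent from ",
           "the domain: ", paste(s$residues[is.na(idx)], collapse = ", "))
    }
    r <- res[idx, , drop = FALSE]
    data.frame(
      DPA_CLUSTER_ID = paste0(domain$domain_id, ".", s$site_label),
      ENTITY_ID = r$entity,
      CHAIN_ID = r$chain,
      RES_SEQ_NUM = r$resno,
      ICODE = r$icode,
      RES_NAME = r$resid,
      IS_LIT_MATCH = as.integer(r$key %in% text_residue_keys),
      IS_CSA_LIT = as.integer(r$key %in% csa_keys),
      IS_NSM_VALID = as.integer(r$key %in% valid_keys),
      IS_NSM = as.integer(r$key %in% nsm_keys),
      IS_CURATED_FAMILY = as.integer(r$key %in% family_curated_keys),
      IS_NSM_FAMILY = as.integer(r$key %in% family_nsm_keys),
      NSM_HETERO_CODES = vapply(r$key, hetero_of, character(1)),
      stringsAsFactors = FALSE)
  })
  out <- if (length(rows) == 0) {
    as.data.frame(stats::setNames(rep(list(character(0)),
                                      length(report_columns)),
                                  report_columns), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  rownames(out) <- NULL
  out[, report_columns]
}

#' Write the per-residue report as tab-delimited text
#'
#' @param report data.frame from [build_report()].
#' @param path output file.
#' @export
write_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
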