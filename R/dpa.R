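#' Deterministic molecular-surface test points
#'
#' Generates test points near the solvent-accessible molecular surface with
#' an internal spherical-lattice construction: every heavy atom is decorated
#' with a deterministic Fibonacci lattice on a sphere of radius
#' `r_vdw + probe`, lattice size chosen so the areal density matches
#' `density`, and points buried inside any other atom's expanded sphere are
#' removed. The construction is fully deterministic, so repeated runs on the
#' same structure give identical points. A vertex file produced by an
#' external surface triangulation can be supplied instead via `import`
#' (whitespace-delimited x y z per line) for bit-compatibility studies.
#'
#' @param domain a `domain_structure` or an atom data.frame with columns
#'   `x,y,z,element,is_heavy`.
#' @param probe probe radius in Angstrom (default 1.5).
#' @param density target areal density in points per square Angstrom
#'   (default 1).
#' @param import optional path to an external surface-vertex file; when
#'   given, the lattice construction is skipped.
#' @return M x 3 matrix of surface points.
#' @export
generate_surface_points <- function(domain, probe = 1.5, density = 1,
                                    import = NULL) {
  if (!is.null(import)) {
    pts <- as.matrix(utils::read.table(import)[, 1:3])
    colnames(pts) <- c("x", "y", "z")
    return(pts)
  }
  atoms <- if (inherits(domain, "domain_structure")) domain$atoms else domain
  atoms <- atoms[atoms$is_heavy, , drop = FALSE]
  if (nrow(atoms) == 0) stop("no heavy atoms: cannot generate surface points")
  rad <- vdw_radii()
  r <- rad[atoms$element]
  r[is.na(r)] <- 1.7
  rexp <- r + probe
  centers <- as.matrix(atoms[, c("x", "y", "z")])
  out <- vector("list", nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    n <- max(8L, ceiling(4 * pi * rexp[i]^2 * density))
    sph <- fibonacci_sphere(n) * rexp[i]
    pts <- sweep(sph, 2, centers[i, ], `+`)
    # buried-point removal: drop points inside another atom's expanded sphere
    keep <- rep(TRUE, n)
    for (j in seq_len(nrow(atoms))) {
      if (j == i) next
      if (sqrt(sum((centers[j, ] - centers[i, ])^2)) > rexp[i] + rexp[j]) next
      dj <- sqrt(colSums((t(pts) - centers[j, ])^2))
      keep <- keep & dj >= rexp[j] - 1e-9
    }
    out[[i]] <- pts[keep, , drop = FALSE]
  }
  pts <- do.call(rbind, out)
  colnames(pts) <- c("x", "y", "z")
  pts
}

# Deterministic Fibonacci lattice of n points on the unit sphere.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (sqrt(5) - 1) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

#' Gumbel distribution functions
#'
#' Density, distribution and quantile functions for the Gumbel
#' (type-I extreme value) distribution used to threshold the D_x field.
#'
#' @param x,q,p numeric vectors.
#' @param loc,scale location and scale parameters (scale > 0).
#' @name gumbel
#' @export
dgumbel <- function(x, loc = 0, scale = 1) {
  z <- (x - loc) / scale
  exp(-z - exp(-z)) / scale
}

#' @rdname gumbel
#' @export
pgumbel <- function(q, loc = 0, scale = 1) {
  exp(-exp(-(q - loc) / scale))
}

#' @rdname gumbel
#' @export
qgumbel <- function(p, loc = 0, scale = 1) {
  loc - scale * log(-log(p))
}

#' Select high-perturbation surface points by an extreme-value fit
#'
#' Fits a Gumbel distribution to the D_x values by maximum likelihood
#' (moment-based start values) and selects the points whose fitted CDF is at
#' least `quantile` — i.e. the upper tail of the fitted extreme-value
#' distribution, about 4% of points at the default 0.96.
#'
#' @param dx numeric vector of D_x values (>= 30 recommended for a stable
#'   fit).
#' @param quantile fitted-CDF cutoff (default 0.96).
#' @return logical mask, TRUE for selected points; attributes `loc` and
#'   `scale` carry the fitted parameters.
#' @export
select_high_dx <- function(dx, quantile = 0.96) {
  if (length(unique(dx)) < 2) {
    stop("degenerate D_x distribution: all values equal")
  }
  if (length(dx) < 30) {
    warning("fewer than 30 D_x values; extreme-value fit may be unstable")
  }
  scale0 <- stats::sd(dx) * sqrt(6) / pi
  loc0 <- mean(dx) - 0.5772156649 * scale0
  fit <- tryCatch(
    fitdistrplus::fitdist(dx, "gumbel",
                          start = list(loc = loc0, scale = scale0)),
    error = function(e) NULL)
  par <- if (is.null(fit)) c(loc = loc0, scale = scale0) else fit$estimate
  mask <- pgumbel(dx, par[["loc"]], par[["scale"]]) >= quantile
  attr(mask, "loc") <- par[["loc"]]
  attr(mask, "scale") <- par[["scale"]]
  mask
}

#' Spatially cluster selected surface points
#'
#' Groups the selected points into density-connected clusters: points within
#' `eps` of each other are connected, and connected components with at least
#' `min_pts` members become clusters. Selected points left outside any
#' cluster are the "XX" leftovers.
#'
#' @param points M x 3 coordinate matrix of the selected points.
#' @param eps connection distance threshold in Angstrom (default 5).
#' @param min_pts minimum cluster size (default 3).
#' @return integer vector of cluster ids per point (0 = unclustered),
#'   cluster ids numbered 1..K in input order of first appearance.
#' @export
cluster_points <- function(points, eps = 5, min_pts = 3) {
  m <- nrow(points)
  if (m == 0) return(integer(0))
  d <- as.matrix(stats::dist(points))
  adj <- d <= eps
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  sizes <- table(comp)
  keep <- as.integer(names(sizes)[sizes >= min_pts])
  lab <- integer(m)
  nxt <- 0L
  for (i in seq_len(m)) {
    if (comp[i] %in% keep && lab[i] == 0L) {
      nxt <- nxt + 1L
      lab[comp == comp[i]] <- nxt
    }
  }
  lab
}

# Site letters: O has the highest mean D_x, then P, Q, R, ...
site_letters <- function(k) {
  base <- LETTERS[15:26]                  # O..Z
  if (k <= length(base)) return(base[seq_len(k)])
  c(base, paste0("Z", seq_len(k - length(base))))
}

#' Define ranked predicted sites from point clusters
#'
#' For each cluster, the site is the set of domain residues owning a heavy
#' atom within `cutoff` of at least one cluster point. Sites are ranked by
#' the mean D_x over their cluster's points and labelled O (highest), P, Q,
#' ... in descending order. A residue close to two clusters belongs to both
#' sites.
#'
#' @param domain a `domain_structure`.
#' @param points M x 3 matrix of the clustered points.
#' @param dx D_x value per point.
#' @param labels integer cluster ids from [cluster_points()] (0 ignored).
#' @param cutoff residue-selection distance in Angstrom (default 5).
#' @return list of `dpa_site`: `site_label`, `residues` (keys), `mean_dx`.
#' @export
define_sites <- function(domain, points, dx, labels, cutoff = 5) {
  stopifnot(inherits(domain, "domain_structure"))
  heavy <- domain$atoms[domain$atoms$is_heavy, , drop = FALSE]
  hxyz <- as.matrix(heavy[, c("x", "y", "z")])
  ids <- setdiff(sort(unique(labels)), 0L)
  sites <- list()
  for (cid in ids) {
    cpts <- points[labels == cid, , drop = FALSE]
    near <- apply(hxyz, 1, function(p) {
      min(sqrt(colSums((t(cpts) - p)^2))) <= cutoff
    })
    keys <- unique(residue_key(heavy$chain[near], heavy$resno[near],
                               heavy$icode[near]))
    if (length(keys) == 0) {
      warning("cluster ", cid, " yields no residues; site dropped")
      next
    }
    sites[[length(sites) + 1L]] <- list(
      cluster_id = cid,
      residues = keys,
      mean_dx = mean(dx[labels == cid]))
  }
  if (length(sites) == 0) return(list())
  ord <- order(vapply(sites, `[[`, numeric(1), "mean_dx"), decreasing = TRUE)
  sites <- sites[ord]
  lets <- site_letters(length(sites))
  for (i in seq_along(sites)) {
    sites[[i]]$site_label <- lets[i]
    class(sites[[i]]) <- "dpa_site"
  }
  sites
}

#' Relative-entropy field over surface test points
#'
#' Computes D_x for every test point: the Gaussian relative entropy between
#' the unperturbed conformational distribution of the elastic network and
#' the distribution with the network coupled to the (fixed) point by
#' springs of strength `gamma_s` to all nodes within `r_s`. The six
#' rigid-body null modes of the unperturbed Hessian are projected out. The
#' computation uses the low-rank (Woodbury / determinant-lemma) identity:
#' the point adds `gamma_s * sum_i u_i u_i'` over the c contacted nodes, so
#' with `G = U' A0^{-1} U` (c x c, `A0` diagonal in the projection basis)
#' and `mu` the eigenvalues of `G`,
#' `KL(Pm||P0) = sum( log(1 + gamma_s mu) - gamma_s mu/(1 + gamma_s mu) )/2`
#' and `KL(P0||Pm) = sum( gamma_s mu - log(1 + gamma_s mu) )/2` — exact,
#' and equal to [relative_entropy()] on the corresponding full Hessians
#' without the per-point 3N eigenproblem.
#'
#' @param enm an `elastic_network`.
#' @param points M x 3 matrix of test-point coordinates.
#' @param r_s point-node cutoff in Angstrom (default 15.5).
#' @param gamma_s point-node spring constant (default `12 * enm$gamma`).
#' @param direction `"m_vs_0"` (default) or `"0_vs_m"`, see
#'   [relative_entropy()].
#' @return numeric vector of D_x values (nats), one per point; 0 for points
#'   contacting no node.
#' @export
dpa_field <- function(enm, points, r_s = 15.5, gamma_s = 12 * enm$gamma,
                      direction = c("m_vs_0", "0_vs_m")) {
  direction <- match.arg(direction)
  stopifnot(inherits(enm, "elastic_network"))
  points <- matrix(points, ncol = 3)
  e0 <- eigen(enm$hessian, symmetric = TRUE)
  keep <- e0$values > 1e-9 * max(e0$values)
  v <- e0$vectors[, keep, drop = FALSE]
  lam0 <- e0$values[keep]
  vinv <- v / rep(sqrt(lam0), each = nrow(v))  # A0^{-1/2}-scaled basis
  nodes <- enm$nodes
  vapply(seq_len(nrow(points)), function(m) {
    p <- points[m, ]
    dvec <- sqrt(colSums((t(nodes) - p)^2))
    hit <- which(dvec <= r_s & dvec > 0)
    c_n <- length(hit)
    if (c_n == 0) return(0)
    us <- matrix(0, c_n, ncol(v))              # rows: u_i' V A0^{-1/2}
    for (j in seq_len(c_n)) {
      i <- hit[j]
      u <- (p - nodes[i, ]) / dvec[i]
      us[j, ] <- u %*% vinv[(3 * i - 2):(3 * i), , drop = FALSE]
    }
    g <- tcrossprod(us)
    eg <- eigen((g + t(g)) / 2, symmetric = TRUE, only.values = TRUE)$values
    eg <- pmax(eg, 0)
    d <- if (direction == "m_vs_0") {
      0.5 * sum(log1p(gamma_s * eg) - gamma_s * eg / (1 + gamma_s * eg))
    } else {
      0.5 * sum(gamma_s * eg - log1p(gamma_s * eg))
    }
    max(d, 0)
  }, numeric(1))
}

#' Run the full Dynamics Perturbation Analysis pipeline on one domain
#'
#' Builds the elastic network, decorates the domain with surface test
#' points, computes the relative-entropy field D_x (one point-perturbed
#' Hessian per test point), thresholds the field with an extreme-value fit,
#' clusters the selected points and derives ranked predicted sites.
#'
#' @param domain a `domain_structure`.
#' @param r_c node-node cutoff in Angstrom (default 10.5).
#' @param r_s point-node cutoff in Angstrom (default 15.5).
#' @param gamma base spring constant (default 1).
#' @param gamma_s_ratio point interaction strength as a multiple of `gamma`
#'   (default 12).
#' @param probe probe radius for surface-point generation (default 1.5).
#' @param density surface-point density per square Angstrom (default 1).
#' @param quantile extreme-value CDF cutoff (default 0.96).
#' @param eps clustering distance threshold (default 5).
#' @param min_pts minimum points per cluster (default 3).
#' @param site_cutoff residue-selection distance (default 5).
#' @param points optional pre-generated surface points (M x 3 matrix);
#'   overrides the internal generator.
#' @param direction relative-entropy direction, see [relative_entropy()].
#' @return `dpa_result`: list with `points` (data.frame x, y, z, dx, label
#'   where label is the site letter, `"NN"` below threshold or `"XX"` above
#'   threshold but unclustered), `sites` (list of `dpa_site`), `enm`, and
#'   the parameters used.
#' @export
dpa_predict <- function(domain, r_c = 10.5, r_s = 15.5, gamma = 1,
                        gamma_s_ratio = 12, probe = 1.5, density = 1,
                        quantile = 0.96, eps = 5, min_pts = 3,
                        site_cutoff = 5, points = NULL,
                        direction = "m_vs_0") {
  stopifnot(inherits(domain, "domain_structure"))
  enm <- build_enm(domain, r_c = r_c, gamma = gamma)
  if (is.null(points)) {
    points <- generate_surface_points(domain, probe = probe, density = density)
  }
  dx <- dpa_field(enm, points, r_s = r_s, gamma_s = gamma_s_ratio * gamma,
                  direction = direction)
  mask <- select_high_dx(dx, quantile = quantile)
  lab_int <- integer(length(dx))
  sel_idx <- which(mask)
  if (length(sel_idx) > 0) {
    cl <- cluster_points(points[sel_idx, , drop = FALSE], eps = eps,
                         min_pts = min_pts)
    lab_int[sel_idx] <- cl
  }
  sites <- define_sites(domain, points, dx, lab_int, cutoff = site_cutoff)
  label <- rep("NN", length(dx))
  label[mask] <- "XX"
  for (s in sites) label[lab_int == s$cluster_id] <- s$site_label
  pts_df <- data.frame(x = points[, 1], y = points[, 2], z = points[, 3],
                       dx = dx, label = label, stringsAsFactors = FALSE)
  structure(list(points = pts_df, sites = sites, enm = enm,
                 params = list(r_c = r_c, r_s = r_s, gamma = gamma,
                               gamma_s_ratio = gamma_s_ratio, probe = probe,
                               density = density, quantile = quantile,
                               eps = eps, min_pts = min_pts,
                               site_cutoff = site_cutoff,
                               direction = direction)),
            class = "dpa_result")
}

#' @export
print.dpa_result <- function(x, ...) {
  cat("DPA result:", nrow(x$points), "surface points,",
      length(x$sites), "predicted site(s)\n")
  for (s in x$sites) {
    cat("  site", s$site_label, "-", length(s$residues),
        "residues, mean D_x =", signif(s$mean_dx, 4), "\n")
  }
  invisible(x)
}

#' Write the two DPA output tables
#'
#' Writes (1) the surface-point table (x, y, z, D_x, label) and (2) the site
#' table (site label, chain, residue number, insertion code, residue name)
#' as tab-delimited text.
#'
#' @param result a `dpa_result`.
#' @param domain the `domain_structure` it was computed from.
#' @param points_file,sites_file output paths.
#' @return invisibly, the site table data.frame.
#' @export
write_dpa_tables <- function(result, domain, points_file, sites_file) {
  utils::write.table(result$points, points_file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  res <- domain$residues
  rows <- do.call(rbind, lapply(result$sites, function(s) {
    r <- res[match(s$residues, res$key), , drop = FALSE]
    data.frame(site = s$site_label, chain = r$chain, resno = r$resno,
               icode = r$icode, resid = r$resid, stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(site = character(), chain = character(),
                       resno = integer(), icode = character(),
                       resid = character())
  }
  utils::write.table(rows, sites_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(rows)
}
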