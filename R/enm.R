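#' Build an anisotropic elastic network model
#'
#' Connects C-alpha nodes within a cutoff `r_c` by Hookean springs of
#' strength `gamma` and assembles the 3N x 3N Hessian from pairwise 3x3
#' blocks `-gamma * u u^T` (u the unit bond vector), with diagonal blocks
#' chosen so every row of 3-blocks sums to zero (translational invariance).
#' The thermal factor k_B*T is absorbed into `gamma`: only ratios of spring
#' constants enter the relative-entropy field, so `gamma = 1` is a pure
#' choice of units.
#'
#' @param domain a `domain_structure`, or an N x 3 coordinate matrix of
#'   nodes.
#' @param r_c node-node interaction cutoff in Angstrom (default 10.5).
#' @param gamma base spring constant (default 1).
#' @return `elastic_network`: list with `nodes` (N x 3 matrix), `hessian`
#'   (3N x 3N), `gamma`, `r_c`, and `node_keys` (residue keys when built
#'   from a domain).
#' @export
build_enm <- function(domain, r_c = 10.5, gamma = 1) {
  if (inherits(domain, "domain_structure")) {
    ca <- domain$atoms[domain$atoms$elety == "CA" & !domain$atoms$het, ,
                       drop = FALSE]
    ca <- ca[!duplicated(residue_key(ca$chain, ca$resno, ca$icode)), ,
             drop = FALSE]
    nodes <- as.matrix(ca[, c("x", "y", "z")])
    keys <- residue_key(ca$chain, ca$resno, ca$icode)
  } else {
    nodes <- as.matrix(domain)
    keys <- as.character(seq_len(nrow(nodes)))
  }
  n <- nrow(nodes)
  if (n < 2) stop("need at least 2 C-alpha nodes to build an elastic network")
  dimnames(nodes) <- NULL
  h <- matrix(0, 3 * n, 3 * n)
  dmat <- as.matrix(stats::dist(nodes))
  deg <- integer(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- dmat[i, j]
      if (d > r_c || d == 0) next
      u <- (nodes[j, ] - nodes[i, ]) / d
      blk <- gamma * tcrossprod(u)
      ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
      h[ii, jj] <- h[ii, jj] - blk
      h[jj, ii] <- h[jj, ii] - blk
      h[ii, ii] <- h[ii, ii] + blk
      h[jj, jj] <- h[jj, jj] + blk
      deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
    }
  }
  if (any(deg == 0)) {
    warning(sum(deg == 0), " node(s) with no neighbors within r_c = ", r_c,
            " A: the network is disconnected")
  }
  structure(list(nodes = nodes, hessian = h, gamma = gamma, r_c = r_c,
                 node_keys = keys),
            class = "elastic_network")
}

#' Perturb an elastic network with a fixed surface test point
#'
#' Adds, for every node within `r_s` of the point, the 3x3 block
#' `gamma_s * u u^T` (u the unit vector from node to point) to that node's
#' diagonal Hessian block. The point is held fixed, so only diagonal blocks
#' change; the result stays symmetric positive semidefinite.
#'
#' @param enm an `elastic_network`.
#' @param point length-3 coordinate of the test point.
#' @param r_s point-node cutoff in Angstrom (default 15.5).
#' @param gamma_s point-node spring constant (default `12 * enm$gamma`).
#' @return the perturbed 3N x 3N Hessian; attribute `n_contacts` carries the
#'   number of interacting nodes (0 means the Hessian is returned unchanged).
#' @export
perturbed_hessian <- function(enm, point, r_s = 15.5, gamma_s = 12 * enm$gamma) {
  stopifnot(inherits(enm, "elastic_network"))
  h <- enm$hessian
  dvec <- sqrt(colSums((t(enm$nodes) - point)^2))
  hit <- which(dvec <= r_s & dvec > 0)
  for (i in hit) {
    u <- (point - enm$nodes[i, ]) / dvec[i]
    ii <- (3 * i - 2):(3 * i)
    h[ii, ii] <- h[ii, ii] + gamma_s * tcrossprod(u)
  }
  attr(h, "n_contacts") <- length(hit)
  h
}

#' Gaussian relative entropy between unperturbed and perturbed networks
#'
#' Both Hessians define Gaussian conformational distributions
#' `P(x) ~ exp(-x' H x / 2)`. The six rigid-body null modes of `h0` (and any
#' further near-zero modes of a degenerate network) are projected out of
#' both quadratic forms, and the closed-form Gaussian Kullback-Leibler
#' divergence is evaluated on the remaining subspace. The default direction
#' is `KL(P_m || P_0)` (perturbed against unperturbed); the opposite
#' direction is available via `direction`.
#'
#' @param h0 unperturbed Hessian.
#' @param hm perturbed Hessian (same node set).
#' @param direction `"m_vs_0"` (default) for KL(P_m || P_0) or `"0_vs_m"`.
#' @param tol relative eigenvalue tolerance for the null space of `h0`.
#' @return D_x in nats (dimensionless, >= 0).
#' @export
relative_entropy <- function(h0, hm, direction = c("m_vs_0", "0_vs_m"),
                             tol = 1e-9) {
  direction <- match.arg(direction)
  h0 <- as.matrix(h0); hm <- as.matrix(hm)
  if (!all(dim(h0) == dim(hm))) stop("Hessian size mismatch")
  e0 <- eigen(h0, symmetric = TRUE)
  keep <- e0$values > tol * max(e0$values)
  if (!any(keep)) stop("h0 has no positive modes")
  lam0 <- e0$values[keep]
  v <- e0$vectors[, keep, drop = FALSE]
  k <- length(lam0)
  am <- crossprod(v, hm %*% v)
  am <- (am + t(am)) / 2
  em <- eigen(am, symmetric = TRUE)
  if (min(em$values) <= tol * max(em$values)) {
    stop("residual near-zero mode after null-space projection: ",
         "perturbed network is numerically rank deficient")
  }
  # KL(Pm||P0) = (tr(A0 Am^-1) - k + logdet Am - logdet A0) / 2
  logdet0 <- sum(log(lam0))
  logdetm <- sum(log(em$values))
  if (direction == "m_vs_0") {
    aminv <- em$vectors %*% (t(em$vectors) / em$values)
    tr <- sum(diag(aminv) * lam0)
    d <- 0.5 * (tr - k + logdetm - logdet0)
  } else {
    # tr(Am A0^-1): A0 is diagonal in the projection basis
    tr <- sum(diag(am) / lam0)
    d <- 0.5 * (tr - k + logdet0 - logdetm)
  }
  max(d, 0)
}
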