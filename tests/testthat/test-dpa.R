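test_that("surface points for one atom lie on the probe sphere at the target density", {
  atom <- data.frame(x = 0, y = 0, z = 0, element = "C", is_heavy = TRUE)
  pts <- generate_surface_points(atom, probe = 1.5, density = 1)
  r <- sqrt(rowSums(pts^2))
  expect_true(all(abs(r - 3.2) < 1e-9))      # r_vdw 1.7 + probe 1.5
  expect_equal(nrow(pts), ceiling(4 * pi * 3.2^2), tolerance = 0.02)
  # doubling the density about doubles the count
  pts2 <- generate_surface_points(atom, density = 2)
  expect_equal(nrow(pts2) / nrow(pts), 2, tolerance = 0.05)
})

test_that("no surface point is buried inside another atom's sphere", {
  atoms <- data.frame(x = c(0, 2.5), y = 0, z = 0, element = "C",
                      is_heavy = TRUE)
  pts <- generate_surface_points(atoms)
  d1 <- sqrt(rowSums(sweep(pts, 2, c(0, 0, 0))^2))
  d2 <- sqrt(rowSums(sweep(pts, 2, c(2.5, 0, 0))^2))
  expect_true(all(pmax(d1, d2) >= 3.2 - 1e-6))
  expect_true(all(pmin(d1, d2) >= 3.2 - 1e-6))
  expect_error(generate_surface_points(atoms[0, ]), "no heavy atoms")
})

test_that("the extreme-value threshold selects the fitted upper tail", {
  set.seed(10)
  dx <- qgumbel(runif(10000), loc = 2, scale = 0.7)
  mask <- select_high_dx(dx, quantile = 0.96)
  expect_equal(mean(mask), 0.04, tolerance = 0.2)
  # location shift moves the fitted location, not the mask
  mask2 <- select_high_dx(dx + 5, quantile = 0.96)
  expect_equal(mask, mask2, ignore_attr = TRUE)
  expect_equal(attr(mask2, "loc") - attr(mask, "loc"), 5, tolerance = 0.05)
  expect_error(select_high_dx(rep(1, 100)), "degenerate")
})

test_that("density-connected clustering honours eps and the size minimum", {
  tri <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0))
  expect_equal(cluster_points(tri), c(1L, 1L, 1L))
  iso <- rbind(c(0, 0, 0), c(30, 0, 0))
  expect_equal(cluster_points(iso), c(0L, 0L))
  two <- rbind(tri, sweep(tri, 2, c(20, 0, 0), `+`))
  expect_equal(length(setdiff(unique(cluster_points(two)), 0L)), 2)
  # pair below the size minimum stays unclustered
  pair <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_equal(cluster_points(pair), c(0L, 0L))
})

test_that("sites are ranked by mean D_x and share residues when adjacent", {
  ca <- cbind(3.8 * (0:9), 0, 0)
  dom <- toy_domain(ca)
  # cluster 1 near residues 1-2, cluster 2 near residues 9-10,
  # cluster 3 overlapping residue 2 as well
  pts <- rbind(c(0, 4, 0), c(1, 4, 0), c(2, 4, 0),
               c(30.4, 4, 0), c(31.4, 4, 0), c(32.4, 4, 0),
               c(4, -4, 0), c(5, -4, 0), c(6, -4, 0))
  labels <- c(1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L)
  dx <- c(2, 2, 2, 3, 3, 3, 1, 1, 1)
  sites <- define_sites(dom, pts, dx, labels)
  expect_equal(vapply(sites, `[[`, character(1), "site_label"),
               c("O", "P", "Q"))
  expect_equal(vapply(sites, `[[`, numeric(1), "mean_dx"), c(3, 2, 1))
  # residue 2 (x = 3.8) is within 5 A of cluster-1 and cluster-3 points
  in_sites <- vapply(sites, function(s) "A|2|" %in% s$residues, logical(1))
  expect_gte(sum(in_sites), 2)
})

test_that("the DPA pipeline is deterministic and its top site sits at the pocket", {
  st <- make_structure(tempfile(fileext = ".pdb"), n_residues = 56, seed = 3)
  dom <- extract_domain(read_structure(st$path), "A:", domain_id = "dsyn")
  res1 <- dpa_predict(dom)
  res2 <- dpa_predict(dom)
  expect_identical(res1$points, res2$points)
  expect_identical(lapply(res1$sites, `[[`, "residues"),
                   lapply(res2$sites, `[[`, "residues"))
  expect_gte(length(res1$sites), 1)
  # labels follow the output convention
  expect_true(all(res1$points$label %in%
                    c("NN", "XX", vapply(res1$sites, `[[`, character(1),
                                         "site_label"))))
  # the top-ranked site covers the planted NSM (pocket) residues
  top <- res1$sites[[1]]
  expect_true(all(st$gold_nsm$resno %in% resno_of_keys(top$residues)))
})

test_that("site residues lie on the molecular surface near cluster points", {
  st <- make_structure(tempfile(fileext = ".pdb"), n_residues = 56, seed = 8)
  dom <- extract_domain(read_structure(st$path), "A:")
  res <- dpa_predict(dom)
  heavy <- dom$atoms[dom$atoms$is_heavy, ]
  for (s in res$sites) {
    cpts <- as.matrix(res$points[res$points$label == s$site_label,
                                 c("x", "y", "z")])
    for (key in s$residues) {
      ra <- heavy[residue_keys_of(heavy) == key, c("x", "y", "z")]
      dmin <- min(apply(as.matrix(ra), 1, function(a) {
        min(sqrt(colSums((t(cpts) - a)^2)))
      }))
      expect_lte(dmin, 5)
    }
  }
})

test_that("DPA table output mirrors the two-file convention", {
  st <- make_structure(tempfile(fileext = ".pdb"), n_residues = 56, seed = 3)
  dom <- extract_domain(read_structure(st$path), "A:", domain_id = "dsyn")
  res <- dpa_predict(dom)
  pf <- tempfile(); sf <- tempfile()
  tab <- write_dpa_tables(res, dom, pf, sf)
  pts <- read.delim(pf)
  expect_equal(names(pts), c("x", "y", "z", "dx", "label"))
  expect_equal(nrow(pts), nrow(res$points))
  sites <- read.delim(sf)
  expect_equal(names(sites), c("site", "chain", "resno", "icode", "resid"))
  expect_equal(nrow(sites), sum(lengths(lapply(res$sites, `[[`, "residues"))))
})
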