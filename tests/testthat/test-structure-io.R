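test_that("PDB parsing keeps first altloc, flags hydrogens and hetero atoms", {
  ps <- read_structure(write_mini_pdb())
  # three protein residues despite the altloc duplicate
  prot <- ps$atoms[!ps$atoms$het, ]
  expect_equal(length(unique(paste(prot$chain, prot$resno))), 3)
  # altloc A coordinates kept for GLY 2
  gly <- prot[prot$resno == 2 & prot$elety == "CA", ]
  expect_equal(nrow(gly), 1)
  expect_equal(gly$x, 8.304)
  # hydrogen flagged non-heavy
  expect_false(ps$atoms$is_heavy[ps$atoms$elety == "HA"])
  expect_true(ps$atoms$het[ps$atoms$resid == "SAS"])
})

test_that("mmCIF atoms are partitioned by molecular entity", {
  ps <- read_structure(write_mini_cif())
  ent <- tapply(ps$atoms$entity, ps$atoms$chain, function(e) unique(e))
  expect_equal(sort(unique(ps$atoms$entity)), c("1", "2", "3"))
  expect_equal(unname(unlist(ent[["A"]])), "1")
  expect_equal(sort(unname(unlist(ent[["B"]]))), c("2", "3"))
})

test_that("PDB homodimer chains share an inferred entity", {
  a <- matrix(c(0, 0, 0, 3.8, 0, 0), ncol = 3, byrow = TRUE)
  b <- a + 20
  path <- write_chain_pdb(list(A = a, B = b, C = b + 20),
                          resid = list(A = c("ALA", "GLY"),
                                       B = c("ALA", "GLY"),
                                       C = c("SER", "GLY")))
  ps <- read_structure(path)
  ent <- vapply(c("A", "B", "C"),
                function(ch) unique(ps$atoms$entity[ps$atoms$chain == ch]),
                character(1))
  expect_equal(ent[["A"]], ent[["B"]])
  expect_false(ent[["C"]] == ent[["A"]])
})

test_that("unreadable or empty structure files raise errors", {
  bad <- tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), bad)
  expect_error(read_structure(bad))
  expect_error(read_structure(tempfile(fileext = ".pdb")), "not found")
})

test_that("domain extraction respects ranges, gaps and absent chains", {
  ca <- cbind(3.8 * (0:99), 0, 0)
  path <- write_chain_pdb(list(A = ca))
  ps <- read_structure(path)
  expect_equal(nrow(extract_domain(ps, "A:1-50")$residues), 50)
  expect_equal(nrow(extract_domain(ps, "A:")$residues), 100)
  # range spanning residues beyond the chain: only present ones returned
  expect_equal(nrow(extract_domain(ps, "A:90-150")$residues), 11)
  expect_error(extract_domain(ps, "B:1-10"), "absent chain")
  expect_error(extract_domain(ps, "A:500-600"), "zero residues")
})

test_that("NSM membership respects the 5 A heavy-atom boundary", {
  ca <- cbind(3.8 * (0:4), 0, 0)
  # ligand atom 4.9 A from residue 1's CA, far from everything else
  lig <- matrix(c(0, 4.9, 0), ncol = 3)
  dom <- extract_domain(read_structure(write_chain_pdb(list(A = ca), lig)),
                        "A:")
  sites <- find_nsm_sites(dom)
  expect_length(sites, 1)
  expect_true("A|1|" %in% sites[[1]]$residues)
  # at 5.1 A the residue is excluded and no site remains
  lig2 <- matrix(c(0, 5.1, 0), ncol = 3)
  dom2 <- extract_domain(read_structure(write_chain_pdb(list(A = ca), lig2)),
                         "A:")
  expect_length(find_nsm_sites(dom2), 0)
})

test_that("a non-domain peptide chain is treated as a small molecule", {
  ca <- cbind(3.8 * (0:4), 0, 0)
  pep <- cbind(3.8 * (0:2), 4.5, 0)   # 3-residue peptide chain near chain A
  path <- write_chain_pdb(list(A = ca, B = pep))
  ps <- read_structure(path)
  dom <- extract_domain(ps, "A:")
  sites <- find_nsm_sites(dom)
  expect_length(sites, 1)
  expect_equal(sites[[1]]$molecule, c("ALA", "ALA", "ALA"))
  expect_gt(length(sites[[1]]$residues), 0)
})

test_that("NSM sites agree with a brute-force scan and shrink monotonically", {
  set.seed(11)
  st <- make_structure(tempfile(fileext = ".pdb"), n_residues = 30, seed = 11)
  dom <- extract_domain(read_structure(st$path), "A:")
  sites <- find_nsm_sites(dom, cutoff = 5)
  # brute force over all heavy-atom pairs
  heavy <- dom$atoms[dom$atoms$is_heavy, ]
  lig <- dom$cochains[dom$cochains$is_heavy, ]
  d <- as.matrix(dist(rbind(as.matrix(heavy[, c("x", "y", "z")]),
                            as.matrix(lig[, c("x", "y", "z")]))))
  nd <- nrow(heavy)
  near <- apply(d[seq_len(nd), -seq_len(nd), drop = FALSE], 1,
                function(r) any(r <= 5))
  brute <- sort(unique(paste(heavy$chain[near], heavy$resno[near], "",
                             sep = "|")))
  expect_equal(sort(sites[[1]]$residues), brute)
  expect_equal(resno_of_keys(sites[[1]]$residues), st$gold_nsm$resno)
  # monotonicity: tighter cutoff never adds residues
  tight <- find_nsm_sites(dom, cutoff = 4)
  tight_res <- if (length(tight)) tight[[1]]$residues else character(0)
  expect_true(all(tight_res %in% sites[[1]]$residues))
})

test_that("MOAD matching labels sites, with synonyms, copies and leftovers", {
  moad_path <- tempfile(fileext = ".csv")
  writeLines(c("pdb_id,hetero_codes,validity",
               "13gs,SAS,valid",
               "13gs,GLU-CYS-GLY,valid",
               "13gs,MES,invalid"), moad_path)
  moad <- read_moad(moad_path)
  mk_site <- function(id, codes) {
    structure(list(site_id = id, molecule = codes,
                   residues = "A|1|", validity = "uncurated"),
              class = "nsm_site")
  }
  sites <- list(mk_site("s1", "SAS"), mk_site("s2", "MES"),
                mk_site("s3", c("GGL", "CYS", "GLY")),   # PDB-side naming
                mk_site("s4", "SAS"),                    # second copy
                mk_site("s5", "NAG"))                    # no MOAD row
  out <- match_moad(sites, moad, "13GS", synonyms = c(GGL = "GLU"))
  expect_equal(vapply(out, `[[`, character(1), "validity"),
               c("valid", "invalid", "valid", "valid", "uncurated"))
  # without the synonym map the tripeptide stays uncurated
  out2 <- match_moad(sites, moad, "13gs")
  expect_equal(out2[[3]]$validity, "uncurated")
})

test_that("malformed MOAD rows are skipped with a warning", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("pdb_id,hetero_codes,validity",
               "1abc,ATP,valid", ",GOL,maybe"), p)
  expect_warning(moad <- read_moad(p), "malformed")
  expect_equal(nrow(moad), 1)
})

test_that("CSA loader keeps LIT evidence only", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("pdb_id,chain_id,res_num,res_name,evidence",
               "1abc,A,57,HIS,LIT",
               "1abc,A,102,ASP,PSI-BLAST",
               "1abc,B,195,SER,LIT",
               "1abc,B,42,GLU,FOO"), p)
  expect_warning(csa <- load_csa(p), "unknown evidence")
  expect_equal(nrow(csa), 2)
  expect_equal(csa$res_num, c(57, 195))
  # empty file
  p2 <- tempfile(fileext = ".csv")
  writeLines("pdb_id,chain_id,res_num,res_name,evidence", p2)
  expect_equal(nrow(load_csa(p2)), 0)
})
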