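test_that("PDB parsing keeps heavy atoms and resolves altlocs by occupancy", {
  f <- tempfile(fileext = ".pdb")
  atoms <- toy_atoms_linear()
  write_toy_pdb(f, atoms)
  s <- parse_structure(f)
  expect_s3_class(s, "structure3d")
  expect_equal(nrow(s$atoms), 4)
  expect_equal(s$chains$A$seq, "AGS")
  expect_equal(s$atoms$x, c(0, 1.5, 4.0, 9.4))

  # altloc A at 0.4 / B at 0.6: the higher-occupancy B wins
  alt <- rbind(atoms,
               data.frame(name = "CB", alt = "A", resn = "SER",
                          chain = "A", resno = 3L, x = 50, y = 0, z = 0,
                          occ = 0.4),
               data.frame(name = "CB", alt = "B", resn = "SER",
                          chain = "A", resno = 3L, x = 60, y = 0, z = 0,
                          occ = 0.6))
  f2 <- tempfile(fileext = ".pdb")
  write_toy_pdb(f2, alt)
  s2 <- parse_structure(f2)
  cb <- s2$atoms[s2$atoms$elety == "CB", ]
  expect_equal(nrow(cb), 1)
  expect_equal(cb$x, 60)

  # waters and hydrogens are dropped; a non-protein file errors
  fw <- tempfile(fileext = ".pdb")
  writeLines(c(pdb_atom_line(1, "O", "", "HOH", "A", 1, 0, 0, 0),
               "END"), fw)
  expect_error(parse_structure(fw), "heavy protein atoms|protein chain")
})

test_that("mmCIF and PDB of the same model parse identically", {
  atoms <- toy_atoms_linear()
  fp <- tempfile(fileext = ".pdb")
  fc <- tempfile(fileext = ".cif")
  write_toy_pdb(fp, atoms)
  write_toy_cif(fc, atoms)
  sp <- parse_structure(fp)
  sc <- parse_structure(fc)
  expect_equal(sc$atoms$x, sp$atoms$x)
  expect_equal(sc$atoms$resno, sp$atoms$resno)
  expect_equal(sc$chains$A$seq, sp$chains$A$seq)
})

test_that("chain-to-query mapping handles offsets and refuses nonsense", {
  f <- tempfile(fileext = ".pdb")
  atoms <- data.frame(
    name = "CA", alt = "", resn = c("ALA", "GLY", "SER", "LEU", "LYS"),
    chain = "A", resno = 1:5, x = (0:4) * 4, y = 0, z = 0, occ = 1)
  write_toy_pdb(f, atoms)
  s <- parse_structure(f)
  # identical sequence -> identity map
  s1 <- map_to_query(s, "AGSLK")
  expect_equal(unname(s1$to_query$A), 1:5)
  # query with 5 extra N-terminal residues -> map offset by 5
  s2 <- map_to_query(s, paste0("MWYFV", "AGSLK"))
  expect_equal(unname(s2$to_query$A), 6:10)
  expect_equal(names(s2$to_query$A), as.character(1:5))
  # unrelated sequence -> refusal
  expect_error(map_to_query(s, "DDDDDDDDDD"), "identity")
})

test_that("contact cutoffs behave at the boundary and across chains", {
  mk <- function(d13) data.frame(
    name = "CA", alt = "", resn = c("ALA", "GLY", "SER"), chain = "A",
    resno = 1:3, x = c(0, 30, d13), y = 0, z = 0, occ = 1)
  f <- tempfile(fileext = ".pdb")
  write_toy_pdb(f, mk(7.9))
  s <- map_to_query(parse_structure(f), "AGS")
  cm <- contact_map(s)
  expect_true(any(cm$intra$i == 1 & cm$intra$j == 3))
  write_toy_pdb(f, mk(8.1))
  s <- map_to_query(parse_structure(f), "AGS")
  cm2 <- contact_map(s)
  expect_false(any(cm2$intra$i == 1 & cm2$intra$j == 3))

  # homodimer whose only close approach is A2-B1 at 9.5 A: an
  # interchain contact (<= 10) but not an intrachain one (> 8)
  dimer <- data.frame(
    name = "CA", alt = "",
    resn = c("ALA", "GLY", "ALA", "GLY"),
    chain = c("A", "A", "B", "B"),
    resno = c(1, 2, 1, 2),
    x = c(0, 30, 30, 60), y = c(0, 0, 9.5, 9.5), z = 0, occ = 1)
  fd <- tempfile(fileext = ".pdb")
  write_toy_pdb(fd, dimer)
  sd_ <- map_to_query(parse_structure(fd), "AG")
  cmd <- contact_map(sd_, min_separation = 1)
  expect_equal(cmd$inter, data.frame(i = 1, j = 2))
  expect_equal(nrow(cmd$intra), 0)

  # sequential pairs are excluded at min_separation = 2
  adj <- data.frame(name = "CA", alt = "",
                    resn = c("ALA", "GLY"), chain = "A", resno = 1:2,
                    x = c(0, 3.8), y = 0, z = 0, occ = 1)
  fa <- tempfile(fileext = ".pdb")
  write_toy_pdb(fa, adj)
  sa <- map_to_query(parse_structure(fa), "AG")
  expect_equal(nrow(contact_map(sa, min_separation = 1)$intra), 1)
  expect_equal(nrow(contact_map(sa, min_separation = 2)$intra), 0)

  # cutoff monotonicity: contact sets grow with the cutoff
  f3 <- tempfile(fileext = ".pdb")
  set.seed(41)
  n <- 8
  rnd <- data.frame(name = "CA", alt = "",
                    resn = sample(c("ALA", "GLY", "SER"), n, TRUE),
                    chain = "A", resno = 1:n,
                    x = cumsum(runif(n, 2, 6)), y = runif(n, 0, 4),
                    z = runif(n, 0, 4), occ = 1)
  write_toy_pdb(f3, rnd)
  s3 <- map_to_query(parse_structure(f3),
                     paste(bio3d::aa321(rnd$resn), collapse = ""))
  for (cut in c(6, 8, 10)) {
    a <- contact_map(s3, intra_cutoff = cut)$intra
    b <- contact_map(s3, intra_cutoff = cut + 2)$intra
    expect_true(all(paste(a$i, a$j) %in% paste(b$i, b$j)))
  }
})

test_that("dual-fold maps partition contacts into unique and common sets", {
  dm <- toy_dualmap12()
  expect_equal(dm$unique_a, data.frame(i = c(1, 2), j = c(5, 6)))
  expect_equal(dm$unique_b, data.frame(i = c(2, 5), j = c(10, 11)))
  expect_equal(dm$common, data.frame(i = c(3, 4), j = c(9, 10)))
  # identical folds -> both unique sets empty
  ca <- as_contact_sets(data.frame(i = 1, j = 9), L = 12)
  dm2 <- build_dual_fold_map(ca, ca)
  expect_equal(nrow(dm2$unique_a), 0)
  expect_equal(nrow(dm2$unique_b), 0)
  expect_equal(nrow(dm2$common), 1)
  # disjoint folds -> one unique contact each, no common
  cb <- as_contact_sets(data.frame(i = 2, j = 12), L = 12)
  dm3 <- build_dual_fold_map(ca, cb)
  expect_equal(nrow(dm3$common), 0)
  expect_equal(nrow(dm3$unique_a), 1)
  expect_equal(nrow(dm3$unique_b), 1)
  # symmetry modulo label swap
  dm4 <- build_dual_fold_map(cb, ca)
  expect_equal(dm4$unique_a, dm3$unique_b)
  expect_equal(dm4$unique_b, dm3$unique_a)
})

test_that("dominance goes to the fold matching the deep-alignment run", {
  dm <- toy_dualmap12()
  expect_equal(determine_dominant(dm, data.frame(i = 1, j = 5)), "a")
  expect_equal(determine_dominant(dm, data.frame(i = c(2, 5), j = c(10, 11))),
               "b")
  expect_warning(
    id <- determine_dominant(dm, data.frame(i = 12, j = 40)), "equal")
  expect_equal(id, "a")
})

test_that("categorization follows common > dominant > alternative precedence", {
  dm <- toy_dualmap12()
  dm$dominant_id <- "a"
  # hand-enumerated 10-prediction toy (tol = 2):
  #  (3,9)  exact common hit                     -> common
  #  (4,12) box of common (4,10)                 -> common
  #  (1,5)  exact dominant-unique hit            -> dominant
  #  (2,4)  box of dominant (1,5) and (2,6)      -> dominant
  #  (4,9)  boxes of common and both uniques     -> common (precedence)
  #  (7,11) box of alternative (5,11) only       -> alternative
  #  (7,13) box-corner of alternative (5,11)     -> alternative
  #  (7,9)  (i+2, j-2) corner of (5,11)          -> alternative (edge)
  #  (8,12) nothing within 2                     -> unobserved
  #  (10,12) nothing within 2                    -> unobserved
  preds <- data.frame(i = c(3, 4, 1, 2, 4, 7, 7, 7, 8, 10),
                      j = c(9, 12, 5, 4, 9, 11, 13, 9, 12, 12))
  cats <- categorize_predictions(preds, dm)
  expect_equal(nrow(cats$common), 3)
  expect_equal(nrow(cats$dominant), 2)
  expect_equal(nrow(cats$alternative), 3)
  expect_equal(nrow(cats$unobserved), 2)
  # partition invariant
  expect_equal(nrow(cats$common) + nrow(cats$dominant) +
                 nrow(cats$alternative) + nrow(cats$unobserved), cats$n)
  # undetermined dominance refuses
  dm$dominant_id <- NA_character_
  expect_error(categorize_predictions(preds, dm), "determine_dominant")
})

test_that("categorization partitions random predictions exactly", {
  set.seed(43)
  for (rep in 1:10) {
    toy <- generate_toy_dualfold(L = 40, n_dominant = 6, n_alternative = 5,
                                 n_common = 4, seed = rep)
    dm <- toy$map
    dm$dominant_id <- "foldA"
    preds <- data.frame(i = sample(1:38, 50, TRUE))
    preds$j <- preds$i + sample(2:15, 50, TRUE)
    preds <- preds[preds$j <= 40, ]
    cats <- categorize_predictions(preds, dm)
    expect_equal(nrow(cats$common) + nrow(cats$dominant) +
                   nrow(cats$alternative) + nrow(cats$unobserved),
                 nrow(preds))
  }
})
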