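# Shared fixtures built in code: random alignments, tiny structures in
# PDB/mmCIF text, and hand-laid contact tables.

aa20 <- AA_ALPHABET[1:20]

# msa from plain strings (rows of equal length), query first by default
msa_from_strings <- function(..., labels = NULL, query = 1L) {
  seqs <- c(...)
  if (is.null(labels)) labels <- sprintf("seq%d", seq_along(seqs))
  new_msa(do.call(rbind, strsplit(seqs, "")), labels, query)
}

# random gap-free alignment with per-row identity to a random query
random_msa <- function(n, L, identities = runif(n - 1, 0.1, 0.9)) {
  q <- sample(aa20, L, replace = TRUE)
  rows <- matrix("", n, L)
  rows[1, ] <- q
  for (r in 2:n) {
    keep <- runif(L) < identities[r - 1]
    alt <- sample(aa20, L, replace = TRUE)
    rows[r, ] <- ifelse(keep, q, alt)
  }
  new_msa(rows, sprintf("s%03d", seq_len(n)), 1L)
}

# one PDB ATOM line in strict fixed-column format
pdb_atom_line <- function(serial, name, alt, resn, chain, resno,
                          x, y, z, occ = 1, elem = substr(trimws(name), 1, 1)) {
  sprintf("ATOM  %5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, sprintf(" %-3s", name), alt, resn, chain, resno,
          x, y, z, occ, 0, elem)
}

write_toy_pdb <- function(path, atoms) {
  # atoms: data.frame(name, alt, resn, chain, resno, x, y, z, occ)
  lines <- vapply(seq_len(nrow(atoms)), function(k) {
    a <- atoms[k, ]
    pdb_atom_line(k, a$name, a$alt, a$resn, a$chain, a$resno,
                  a$x, a$y, a$z, a$occ)
  }, character(1))
  writeLines(c(lines, "TER", "END"), path)
  path
}

write_toy_cif <- function(path, atoms) {
  hdr <- c("data_toy", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "auth_seq_id", "auth_comp_id",
                    "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num")))
  rows <- vapply(seq_len(nrow(atoms)), function(k) {
    a <- atoms[k, ]
    alt <- if (a$alt == "") "." else a$alt
    sprintf("ATOM %d %s %s %s %s %s 1 %d ? %.3f %.3f %.3f %.2f 0.00 %d %s %s %s 1",
            k, substr(trimws(a$name), 1, 1), trimws(a$name), alt, a$resn,
            a$chain, a$resno, a$x, a$y, a$z, a$occ, a$resno, a$resn,
            a$chain, trimws(a$name))
  }, character(1))
  writeLines(c(hdr, rows), path)
  path
}

# three-residue single-chain toy used across structure tests: residues at
# controlled CA distances (1-2 at ~4.0 A, 1-3 at 9.4 A, 2-3 at 5.4 A)
toy_atoms_linear <- function() {
  data.frame(
    name = c("N", "CA", "CA", "CA"),
    alt = c("", "", "", ""),
    resn = c("ALA", "ALA", "GLY", "SER"),
    chain = "A",
    resno = c(1L, 1L, 2L, 3L),
    x = c(0, 1.5, 4.0, 9.4), y = 0, z = 0, occ = 1,
    stringsAsFactors = FALSE)
}

# hand-laid 12-residue dual-fold toy used by categorization tests:
#   fold a intra: (1,5) (2,6) (3,9) (4,10)
#   fold b intra: (3,9) (4,10) (2,10) (5,11)
#   => unique_a {(1,5),(2,6)}, unique_b {(2,10),(5,11)}, common {(3,9),(4,10)}
toy_dualmap12 <- function() {
  ca <- as_contact_sets(data.frame(i = c(1, 2, 3, 4), j = c(5, 6, 9, 10)),
                        L = 12, id = "a")
  cb <- as_contact_sets(data.frame(i = c(3, 4, 2, 5), j = c(9, 10, 10, 11)),
                        L = 12, id = "b")
  build_dual_fold_map(ca, cb)
}

# Chebyshev-box overlap of planted pairs against a prediction table
recovered_fraction <- function(truth, predicted, tol = 2) {
  if (!nrow(truth)) return(NA_real_)
  if (!nrow(predicted)) return(0)
  mean(vapply(seq_len(nrow(truth)), function(k) {
    any(abs(predicted$i - truth$i[k]) <= tol &
          abs(predicted$j - truth$j[k]) <= tol)
  }, logical(1)))
}
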