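rec <- function(id, residues, description = "") {
  seq_record(id, residues, description)
}

random_peptide <- function(n, alphabet = CANONICAL_ALPHABET) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
CANONICAL_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                        "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
REDUCED_ALPHABET <- c("A", "C", "G", "W")

random_peptide_seeded <- function(n, seed) {
  withr::with_seed(seed, random_peptide(n))
}

# A short query with known target positions, for fast design tests:
# 60 residues, 'C' at 10, 25, 40, 55.
toy_query <- function() {
  res <- strsplit(paste0(
    "MKVLAEHGQTR", "LNDFYPSWIEK", "AGHTMLVQRNE", "SDFKLWPYTAG", "HQERMVLNIKS", "TNSAG"
  ), "")[[1]]
  res <- res[1:60]
  res[c(10, 25, 40, 55)] <- "C"
  seq_record("toy_query", paste(res, collapse = ""))
}
TOY_CLUSTERS <- list(c(10L, 25L), 40L, 55L)

write_pdb_fixture <- function(path, atoms) {
  # atoms: data.frame serial, name, alt, resname, chain, resno, x, y, z, occ
  fmt <- "ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  name4 <- ifelse(nchar(atoms$name) < 4, paste0(" ", atoms$name), atoms$name)
  elem <- toupper(substr(gsub("[0-9]", "", atoms$name), 1, 1))
  lines <- sprintf(fmt, atoms$serial, name4, atoms$alt, atoms$resname,
                   atoms$chain, atoms$resno, atoms$x, atoms$y, atoms$z,
                   atoms$occ, 0, elem)
  writeLines(c(lines, "END"), path)
  path
}

pdb_atom <- function(serial, name, resno, x, y, z, alt = "", chain = "A",
                     resname = "ALA", occ = 1) {
  data.frame(serial = serial, name = name, alt = alt, resname = resname,
             chain = chain, resno = resno, x = x, y = y, z = z, occ = occ)
}
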