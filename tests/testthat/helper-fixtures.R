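# Shared fixture builders (all generated in code; no files).

# minimal atom-table row
atom_row <- function(name, x, y, z, resname = "GLY", chain = "A",
                     resseq = 1L, element = NULL, serial = 1L,
                     occupancy = 1.0) {
  if (is.null(element)) element <- substr(gsub("[0-9]", "", name), 1, 1)
  data.frame(serial = serial, name = name, alt = "", resname = resname,
             chain = chain, resseq = as.integer(resseq), icode = "",
             x = x, y = y, z = z, occupancy = occupancy, element = element,
             is_h = element == "H", het = FALSE, stringsAsFactors = FALSE)
}

structure_from_rows <- function(...) {
  atoms <- do.call(rbind, list(...))
  atoms$serial <- seq_len(nrow(atoms))
  new_structure(atoms)
}

# a 3-atom single-residue PDB document
minimal_pdb_text <- function() {
  paste(c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       1.450   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   GLY A   1       2.200   1.300   0.000  1.00  0.00           C",
    "END"), collapse = "\n")
}

# rigid-body transform of a structure
transform_structure <- function(st, R = diag(3), t = c(0, 0, 0)) {
  xyz <- coords(st$atoms) %*% t(R)
  st$atoms$x <- xyz[, 1] + t[1]
  st$atoms$y <- xyz[, 2] + t[2]
  st$atoms$z <- xyz[, 3] + t[3]
  st
}

rotation_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta),  cos(theta), 0,
           0, 0, 1), 3, byrow = TRUE)
}

# random proper rotation
random_rotation <- function() {
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# records reduced to (kind, residue pair) keys for recovery comparisons
pair_keys <- function(rec) {
  unique(paste(rec$kind, rec$chain_a, rec$res_a, rec$chain_b, rec$res_b,
               sep = "|"))
}

# the record kinds implied by a planted contact list (a salt bridge implies
# its hbond and ionic components)
implied_kinds <- function(kind) {
  if (kind == "salt_bridge") c("salt_bridge", "hbond", "ionic") else kind
}
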