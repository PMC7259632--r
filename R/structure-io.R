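# PDB reading/writing and the structure/trajectory data model.
#
# A `structure` holds one coordinate model as a single atom table; a
# `trajectory` is an ordered list of structures sharing one topology (same
# atoms, same order). Multi-MODEL PDB files are the trajectory format.

.atom_columns <- c("serial", "name", "alt", "resname", "chain", "resseq",
                   "icode", "x", "y", "z", "occupancy", "element", "is_h",
                   "het")

.empty_atoms <- function() {
  data.frame(serial = integer(), name = character(), alt = character(),
             resname = character(), chain = character(), resseq = integer(),
             icode = character(), x = double(), y = double(), z = double(),
             occupancy = double(), element = character(), is_h = logical(),
             het = logical(), stringsAsFactors = FALSE)
}

#' Construct a structure from an atom table
#'
#' @param atoms data.frame with columns serial, name, alt, resname, chain,
#'   resseq, icode, x, y, z, occupancy, element, is_h, het.
#' @param model_id integer model identifier.
#' @param source free-text provenance string.
#' @return An object of class `structure3d`.
#' @export
new_structure <- function(atoms, model_id = 1L, source = "") {
  stopifnot(is.data.frame(atoms), all(.atom_columns %in% names(atoms)))
  if (nrow(atoms) == 0L) stop("a structure must contain at least one atom")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in atom table")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms[, .atom_columns], model_id = as.integer(model_id),
                 source = source),
            class = "structure3d")
}

#' Construct a trajectory from a list of structures
#'
#' All frames must share an identical topology (same atoms in the same order).
#'
#' @param frames list of `structure3d` objects (>= 1).
#' @return An object of class `trajectory3d` with fields `frames` and
#'   `topology_key`.
#' @export
new_trajectory <- function(frames) {
  stopifnot(length(frames) >= 1L)
  keys <- lapply(frames, function(f) topology_key(f))
  for (k in keys[-1]) {
    if (!identical(k, keys[[1]]))
      stop("topology error: frames do not share an identical atom list")
  }
  structure(list(frames = frames, topology_key = keys[[1]]),
            class = "trajectory3d")
}

#' Canonical atom-identity key of a structure
#'
#' @param structure a `structure3d`.
#' @return Character vector, one entry per atom: `chain|resseq|icode|name`.
#' @export
topology_key <- function(structure) {
  a <- structure$atoms
  paste(a$chain, a$resseq, a$icode, a$name, sep = "|")
}

#' @export
print.structure3d <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<structure3d> model %d: %d atoms, %d residues, chains %s\n",
              x$model_id, nrow(a),
              length(unique(paste(a$chain, a$resseq, a$icode))),
              paste(unique(a$chain), collapse = "")))
  invisible(x)
}

#' @export
print.trajectory3d <- function(x, ...) {
  cat(sprintf("<trajectory3d> %d frame(s), %d atoms per frame\n",
              length(x$frames), length(x$topology_key)))
  invisible(x)
}

.infer_element <- function(name, field) {
  field <- toupper(trimws(field))
  known <- names(vdw_radii())
  if (nzchar(field) && field %in% known) return(field)
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  if (!nzchar(nm)) return("")
  two <- substr(nm, 1, 2)
  # Names like "1HB"/"HB2" are hydrogens; two-letter elements only when the
  # alphabetic prefix matches a known symbol that is not a C/N/O/S remote name.
  if (substr(nm, 1, 1) == "H") return("H")
  if (two %in% c("CL", "BR", "SE", "FE", "ZN", "MG", "NA") && two %in% known)
    return(two)
  substr(nm, 1, 1)
}

.parse_atom_line <- function(line, lineno) {
  sub_f <- function(a, b) substr(line, a, b)
  num <- function(a, b, what) {
    txt <- trimws(sub_f(a, b))
    v <- suppressWarnings(as.numeric(txt))
    if (is.na(v))
      stop(sprintf("parse error at line %d: malformed %s field '%s'",
                   lineno, what, txt))
    v
  }
  name <- trimws(sub_f(13, 16))
  el <- .infer_element(name, sub_f(77, 78))
  occ_txt <- trimws(sub_f(55, 60))
  occ <- suppressWarnings(as.numeric(occ_txt))
  if (!nzchar(occ_txt) || is.na(occ)) occ <- 1.0
  list(serial = suppressWarnings(as.integer(trimws(sub_f(7, 11)))),
       name = name,
       alt = trimws(sub_f(17, 17)),
       resname = toupper(trimws(sub_f(18, 20))),
       chain = sub_f(22, 22),
       resseq = {
         rs <- suppressWarnings(as.integer(trimws(sub_f(23, 26))))
         if (is.na(rs))
           stop(sprintf("parse error at line %d: malformed residue number", lineno))
         rs
       },
       icode = trimws(sub_f(27, 27)),
       x = num(31, 38, "x coordinate"),
       y = num(39, 46, "y coordinate"),
       z = num(47, 54, "z coordinate"),
       occupancy = occ,
       element = el,
       is_h = identical(el, "H"),
       het = startsWith(line, "HETATM"))
}

.dedup_altloc <- function(atoms) {
  if (all(atoms$alt == "")) return(atoms)
  key <- paste(atoms$chain, atoms$resseq, atoms$icode, atoms$name, sep = "|")
  keep <- rep(TRUE, nrow(atoms))
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    best <- idx[which.max(atoms$occupancy[idx])]  # ties: first encountered
    keep[setdiff(idx, best)] <- FALSE
  }
  atoms[keep, , drop = FALSE]
}

#' Read a PDB document into a trajectory
#'
#' One frame is produced per MODEL record; a file without MODEL records yields
#' exactly one frame. Author residue numbers, insertion codes and HETATM
#' residues are preserved verbatim. For alternate locations, the
#' highest-occupancy conformer is kept (ties: first encountered). The element
#' is taken from columns 77-78 when present, otherwise inferred from the atom
#' name.
#'
#' @param path_or_text path to a PDB file, or a character vector of PDB lines
#'   (anything containing a newline or of length > 1 is treated as text).
#' @return A `trajectory3d`.
#' @export
read_pdb <- function(path_or_text) {
  if (length(path_or_text) == 1L && !grepl("\n", path_or_text) &&
      file.exists(path_or_text)) {
    lines <- readLines(path_or_text, warn = FALSE)
    src <- path_or_text
  } else {
    lines <- unlist(strsplit(path_or_text, "\n", fixed = TRUE))
    src <- "<text>"
  }
  rec <- substr(lines, 1, 6)
  is_atom <- startsWith(rec, "ATOM") | startsWith(rec, "HETATM")
  if (!any(is_atom)) stop("parse error: document contains no ATOM/HETATM records")
  model_starts <- which(startsWith(rec, "MODEL"))
  frames <- list()
  if (length(model_starts) == 0L) {
    blocks <- list(which(is_atom))
    model_ids <- 1L
  } else {
    ends <- c(model_starts[-1] - 1L, length(lines))
    blocks <- lapply(seq_along(model_starts), function(i) {
      rng <- model_starts[i]:ends[i]
      rng[is_atom[rng]]
    })
    model_ids <- vapply(model_starts, function(i) {
      id <- suppressWarnings(as.integer(trimws(substr(lines[i], 7, 80))))
      if (is.na(id)) NA_integer_ else id
    }, integer(1))
    model_ids[is.na(model_ids)] <- seq_along(model_ids)[is.na(model_ids)]
  }
  for (b in seq_along(blocks)) {
    idx <- blocks[[b]]
    if (length(idx) == 0L) stop("parse error: MODEL block without atoms")
    parsed <- lapply(idx, function(i) .parse_atom_line(lines[i], i))
    atoms <- do.call(rbind, lapply(parsed, function(p)
      as.data.frame(p, stringsAsFactors = FALSE)))
    atoms <- .dedup_altloc(atoms)
    frames[[b]] <- new_structure(atoms, model_id = model_ids[b], source = src)
  }
  new_trajectory(frames)
}

.format_atom_name <- function(name, element) {
  # Standard PDB alignment: names of <4 chars with 1-letter elements start in
  # column 14; everything else is left-aligned from column 13.
  if (nchar(name) < 4L && nchar(element) <= 1L)
    formatC(paste0(" ", name), width = -4)
  else
    formatC(name, width = -4)
}

#' Write a trajectory or structure as a PDB document
#'
#' Multi-frame trajectories are written as MODEL/ENDMDL blocks. Coordinates
#' are emitted at 3-decimal precision; reading the output back reproduces all
#' residue identifiers exactly.
#'
#' @param x a `trajectory3d` or `structure3d`.
#' @param path optional file path; when `NULL` the document is returned as a
#'   character vector of lines.
#' @return Invisibly, the character vector of PDB lines.
#' @export
write_pdb <- function(x, path = NULL) {
  if (inherits(x, "structure3d")) x <- new_trajectory(list(x))
  stopifnot(inherits(x, "trajectory3d"))
  fmt_frame <- function(fr) {
    a <- fr$atoms
    bad <- abs(a$x) > 9999.999 | abs(a$y) > 9999.999 | abs(a$z) > 9999.999 |
      a$x < -999.999 | a$y < -999.999 | a$z < -999.999
    if (any(bad))
      stop("format error: coordinate magnitude exceeds PDB fixed-width field")
    vapply(seq_len(nrow(a)), function(i) {
      sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
              if (a$het[i]) "HETATM" else "ATOM",
              a$serial[i] %% 100000L,
              .format_atom_name(a$name[i], a$element[i]),
              a$alt[i], a$resname[i], a$chain[i], a$resseq[i], a$icode[i],
              a$x[i], a$y[i], a$z[i], a$occupancy[i], 0,
              a$element[i])
    }, character(1))
  }
  lines <- character(0)
  multi <- length(x$frames) > 1L
  for (fr in x$frames) {
    if (multi) lines <- c(lines, sprintf("MODEL     %4d", fr$model_id))
    lines <- c(lines, fmt_frame(fr))
    if (multi) lines <- c(lines, "ENDMDL")
  }
  lines <- c(lines, "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Select atoms of a structure
#'
#' All criteria are combined with AND; `NULL` means "any". An empty selection
#' is legal and returns a 0-row atom table in file order.
#'
#' @param structure a `structure3d`.
#' @param chain chain identifier(s) or `NULL`.
#' @param res_range inclusive residue-number interval `c(lo, hi)`, or `NULL`.
#' @param atom_names atom-name set or `NULL`.
#' @return data.frame of matching atoms (same columns as `structure$atoms`).
#' @export
select_atoms <- function(structure, chain = NULL, res_range = NULL,
                         atom_names = NULL) {
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(res_range)) {
    stopifnot(length(res_range) == 2L)
    keep <- keep & a$resseq >= res_range[1] & a$resseq <= res_range[2]
  }
  if (!is.null(atom_names)) keep <- keep & a$name %in% atom_names
  a[keep, , drop = FALSE]
}

#' Coordinates of an atom table as a numeric matrix
#'
#' @param atoms atom table (as returned by [select_atoms()]).
#' @return n x 3 matrix of coordinates in Angstrom.
#' @export
coords <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])
}
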