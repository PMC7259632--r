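# Six-class non-covalent interaction detection across an antibody-antigen
# interface, plus the composite salt-bridge rule. All detectors report only
# cross-interface pairs and are symmetric in the two selections.

#' Interaction distance cutoffs
#'
#' Defaults follow the conventions of the standard protein-interaction
#' calculators: 3.5 Angstrom donor-acceptor distance for hydrogen bonds, 5 for
#' hydrophobic side-chain carbon contacts, 6 for ionic group pairs, a
#' 4.5-7 band for aromatic ring centroids, 4.3 for aromatic-sulphur, and 6 for
#' cation-pi.
#'
#' @param hbond,hydrophobic,ionic,aromatic_min,aromatic_max,aromatic_sulphur,cation_pi
#'   cutoffs in Angstrom.
#' @return List of class `interaction_cutoffs`.
#' @export
interaction_cutoffs <- function(hbond = 3.5, hydrophobic = 5.0, ionic = 6.0,
                                aromatic_min = 4.5, aromatic_max = 7.0,
                                aromatic_sulphur = 4.3, cation_pi = 6.0) {
  vals <- list(hbond = hbond, hydrophobic = hydrophobic, ionic = ionic,
               aromatic_min = aromatic_min, aromatic_max = aromatic_max,
               aromatic_sulphur = aromatic_sulphur, cation_pi = cation_pi)
  stopifnot(all(unlist(vals) > 0), aromatic_min < aromatic_max)
  structure(vals, class = "interaction_cutoffs")
}

#' Interface split: the two disjoint selections to compare
#'
#' @param chains_a,chains_b disjoint, non-empty chain-identifier sets (e.g.
#'   antibody chains vs antigen chains).
#' @return List of class `interface_split`.
#' @export
interface_split <- function(chains_a, chains_b) {
  stopifnot(length(chains_a) >= 1, length(chains_b) >= 1,
            length(intersect(chains_a, chains_b)) == 0)
  structure(list(chains_a = chains_a, chains_b = chains_b),
            class = "interface_split")
}

.empty_records <- function() {
  data.frame(kind = character(),
             chain_a = character(), res_a = integer(), icode_a = character(),
             resname_a = character(), name_a = character(),
             group_a = character(), side_a = character(),
             chain_b = character(), res_b = integer(), icode_b = character(),
             resname_b = character(), name_b = character(),
             group_b = character(), side_b = character(),
             distance = double(), stringsAsFactors = FALSE)
}

.make_record <- function(kind, ra, rb, name_a, name_b, group_a, group_b,
                         side_a, side_b, distance) {
  data.frame(kind = kind,
             chain_a = ra$chain, res_a = ra$resseq, icode_a = ra$icode,
             resname_a = ra$resname, name_a = name_a, group_a = group_a,
             side_a = side_a,
             chain_b = rb$chain, res_b = rb$resseq, icode_b = rb$icode,
             resname_b = rb$resname, name_b = name_b, group_b = group_b,
             side_b = side_b,
             distance = distance, stringsAsFactors = FALSE)
}

.order_records <- function(rec) {
  if (nrow(rec) == 0L) return(rec)
  o <- order(rec$kind, rec$chain_a, rec$res_a, rec$name_a,
             rec$chain_b, rec$res_b, rec$name_b, rec$distance)
  rec <- rec[o, , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

# residue-level bookkeeping for one selection
.residue_table <- function(structure, chains) {
  a <- structure$atoms
  a <- a[a$chain %in% chains, , drop = FALSE]
  key <- paste(a$chain, a$resseq, a$icode, sep = "|")
  first <- !duplicated(key)
  list(atoms = a,
       residues = data.frame(key = key[first], chain = a$chain[first],
                             resseq = a$resseq[first], icode = a$icode[first],
                             resname = a$resname[first],
                             stringsAsFactors = FALSE),
       key = key)
}

.residue_atoms <- function(side, key) {
  side$atoms[side$key == key, , drop = FALSE]
}

# terminal residues (first/last residue of each chain in file order)
.terminal_keys <- function(side) {
  out <- list(n = character(0), c = character(0))
  for (ch in unique(side$residues$chain)) {
    keys <- side$residues$key[side$residues$chain == ch]
    out$n <- c(out$n, keys[1])
    out$c <- c(out$c, keys[length(keys)])
  }
  out
}

.dist3 <- function(p, q) sqrt(sum((p - q)^2))

# list of hbond-capable atoms for one selection: data.frame of atom rows plus
# role; includes backbone and side chain, honoring terminal OXT.
.polar_atoms <- function(side, typing_donors = .hbond_donors,
                         typing_acceptors = .hbond_acceptors) {
  a <- side$atoms
  a <- a[!a$is_h, , drop = FALSE]
  don <- (a$name == "N" & a$resname != "PRO")
  acc <- a$name %in% c("O", "OXT")
  for (i in seq_len(nrow(a))) {
    rn <- a$resname[i]
    if (a$name[i] %in% typing_donors[[rn]]) don[i] <- TRUE
    if (a$name[i] %in% typing_acceptors[[rn]]) acc[i] <- TRUE
  }
  list(donors = a[don, , drop = FALSE], acceptors = a[acc, , drop = FALSE])
}

# hydrogens attached to a donor atom (within 1.25 A, same residue)
.attached_h <- function(side, donor_row) {
  a <- side$atoms
  h <- a[a$is_h & a$chain == donor_row$chain & a$resseq == donor_row$resseq &
           a$icode == donor_row$icode, , drop = FALSE]
  if (nrow(h) == 0L) return(h)
  d <- sqrt((h$x - donor_row$x)^2 + (h$y - donor_row$y)^2 +
              (h$z - donor_row$z)^2)
  h[d <= 1.25, , drop = FALSE]
}

.angle_deg <- function(p1, p2, p3) {
  v1 <- p1 - p2; v2 <- p3 - p2
  cosv <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cosv))) * 180 / pi
}

#' Detect hydrogen bonds across an interface
#'
#' A record is produced for every (donor heavy atom, acceptor heavy atom) pair
#' across the interface with distance at or below the cutoff. When explicit
#' hydrogens are attached to the donor, a donor-H-acceptor angle of at least
#' 120 degrees is additionally required; hydrogen-free structures are judged
#' on distance alone.
#'
#' @param frame a `structure3d`.
#' @param split an [interface_split()].
#' @param cutoffs an [interaction_cutoffs()].
#' @return Interaction-record data.frame (see [fingerprint()]); `group_a`
#'   and `group_b` carry the donor/acceptor roles.
#' @export
detect_hbonds <- function(frame, split, cutoffs = interaction_cutoffs()) {
  sa <- .residue_table(frame, split$chains_a)
  sb <- .residue_table(frame, split$chains_b)
  pa <- .polar_atoms(sa); pb <- .polar_atoms(sb)
  out <- list(.empty_records())
  scan <- function(side_d, pol_d, pol_a, a_is_donor) {
    don <- pol_d$donors; acc <- pol_a$acceptors
    if (nrow(don) == 0L || nrow(acc) == 0L) return()
    for (i in seq_len(nrow(don))) {
      dpos <- c(don$x[i], don$y[i], don$z[i])
      dd <- sqrt((acc$x - dpos[1])^2 + (acc$y - dpos[2])^2 +
                   (acc$z - dpos[3])^2)
      hits <- which(dd <= cutoffs$hbond)
      if (length(hits) == 0L) next
      hs <- .attached_h(side_d, don[i, ])
      for (j in hits) {
        if (nrow(hs) > 0L) {
          apos <- c(acc$x[j], acc$y[j], acc$z[j])
          ang <- max(vapply(seq_len(nrow(hs)), function(k)
            .angle_deg(dpos, c(hs$x[k], hs$y[k], hs$z[k]), apos), double(1)))
          if (ang < 120) next
        }
        if (a_is_donor) {
          out[[length(out) + 1L]] <<- .make_record(
            "hbond", don[i, ], acc[j, ], don$name[i], acc$name[j],
            "donor", "acceptor",
            if (.is_mainchain(don$name[i])) "main" else "side",
            if (.is_mainchain(acc$name[j])) "main" else "side", dd[j])
        } else {
          out[[length(out) + 1L]] <<- .make_record(
            "hbond", acc[j, ], don[i, ], acc$name[j], don$name[i],
            "acceptor", "donor",
            if (.is_mainchain(acc$name[j])) "main" else "side",
            if (.is_mainchain(don$name[i])) "main" else "side", dd[j])
        }
      }
    }
  }
  scan(sa, pa, pb, TRUE)    # donors in a, acceptors in b
  scan(sb, pb, pa, FALSE)   # donors in b, acceptors in a
  .order_records(do.call(rbind, out))
}

#' Detect hydrophobic contacts across an interface
#'
#' One record per apolar residue pair (both residues in the apolar set
#' ALA/VAL/LEU/ILE/MET/PHE/TRP/PRO/TYR) whose side-chain carbon atoms approach
#' within the cutoff; the reported distance and atom names are those of the
#' closest carbon pair.
#'
#' @inheritParams detect_hbonds
#' @return Interaction-record data.frame.
#' @export
detect_hydrophobic <- function(frame, split, cutoffs = interaction_cutoffs()) {
  sa <- .residue_table(frame, split$chains_a)
  sb <- .residue_table(frame, split$chains_b)
  sc_carbons <- function(side, key) {
    at <- .residue_atoms(side, key)
    at[toupper(at$element) == "C" & !(at$name %in% .backbone_names) &
         !at$is_h, , drop = FALSE]
  }
  out <- list(.empty_records())
  ra <- sa$residues[sa$residues$resname %in% .apolar_residues, , drop = FALSE]
  rb <- sb$residues[sb$residues$resname %in% .apolar_residues, , drop = FALSE]
  for (i in seq_len(nrow(ra))) {
    ca_at <- sc_carbons(sa, ra$key[i])
    if (nrow(ca_at) == 0L) next
    for (j in seq_len(nrow(rb))) {
      cb_at <- sc_carbons(sb, rb$key[j])
      if (nrow(cb_at) == 0L) next
      dm <- outer(seq_len(nrow(ca_at)), seq_len(nrow(cb_at)),
                  Vectorize(function(p, q)
                    .dist3(c(ca_at$x[p], ca_at$y[p], ca_at$z[p]),
                           c(cb_at$x[q], cb_at$y[q], cb_at$z[q]))))
      if (min(dm) <= cutoffs$hydrophobic) {
        w <- which(dm == min(dm), arr.ind = TRUE)[1, ]
        out[[length(out) + 1L]] <- .make_record(
          "hydrophobic", ra[i, ], rb[j, ],
          ca_at$name[w[1]], cb_at$name[w[2]], "apolar", "apolar",
          "side", "side", min(dm))
      }
    }
  }
  .order_records(do.call(rbind, out))
}

# charged groups of one selection: list of (residue row, atom table, label)
.charged_groups <- function(side, include_his = FALSE, termini = TRUE) {
  cat_tab <- .cationic_groups(include_his)
  term <- .terminal_keys(side)
  cats <- list(); anis <- list()
  for (i in seq_len(nrow(side$residues))) {
    r <- side$residues[i, ]
    at <- .residue_atoms(side, r$key)
    cn <- cat_tab[[r$resname]]
    if (!is.null(cn)) {
      ga <- at[at$name %in% cn, , drop = FALSE]
      if (nrow(ga) > 0L)
        cats[[length(cats) + 1L]] <- list(res = r, atoms = ga,
                                          label = "sidechain", terminal = FALSE)
    }
    an <- .anionic_groups[[r$resname]]
    if (!is.null(an)) {
      ga <- at[at$name %in% an, , drop = FALSE]
      if (nrow(ga) > 0L)
        anis[[length(anis) + 1L]] <- list(res = r, atoms = ga,
                                          label = "sidechain", terminal = FALSE)
    }
    if (termini) {
      if (r$key %in% term$n) {
        ga <- at[at$name == "N", , drop = FALSE]
        if (nrow(ga) > 0L)
          cats[[length(cats) + 1L]] <- list(res = r, atoms = ga,
                                            label = "n-terminus",
                                            terminal = TRUE)
      }
      if (r$key %in% term$c) {
        ga <- at[at$name %in% c("O", "OXT"), , drop = FALSE]
        if (nrow(ga) > 0L)
          anis[[length(anis) + 1L]] <- list(res = r, atoms = ga,
                                            label = "c-terminus",
                                            terminal = TRUE)
      }
    }
  }
  list(cations = cats, anions = anis)
}

.min_group_dist <- function(g1, g2) {
  best <- Inf; ba <- bb <- NA_character_
  for (p in seq_len(nrow(g1))) {
    d <- sqrt((g2$x - g1$x[p])^2 + (g2$y - g1$y[p])^2 + (g2$z - g1$z[p])^2)
    q <- which.min(d)
    if (d[q] < best) { best <- d[q]; ba <- g1$name[p]; bb <- g2$name[q] }
  }
  list(distance = best, name_1 = ba, name_2 = bb)
}

#' Detect ionic interactions across an interface
#'
#' Cationic groups (LYS NZ; ARG NH1/NH2/NE; optionally HIS ring nitrogens;
#' chain N-terminal amine) are paired with anionic groups (ASP OD1/OD2,
#' GLU OE1/OE2, chain C-terminal carboxylate) across the interface; the
#' reported distance is the minimum over the two groups' atom pairs.
#'
#' @inheritParams detect_hbonds
#' @param include_his count histidine as cationic (default FALSE: pH 7).
#' @return Interaction-record data.frame.
#' @export
detect_ionic <- function(frame, split, cutoffs = interaction_cutoffs(),
                         include_his = FALSE) {
  sa <- .residue_table(frame, split$chains_a)
  sb <- .residue_table(frame, split$chains_b)
  ga <- .charged_groups(sa, include_his)
  gb <- .charged_groups(sb, include_his)
  out <- list(.empty_records())
  pair_up <- function(cats, anis, a_first) {
    for (cg in cats) for (ag in anis) {
      m <- .min_group_dist(cg$atoms, ag$atoms)
      if (m$distance <= cutoffs$ionic) {
        if (a_first) {
          out[[length(out) + 1L]] <<- .make_record(
            "ionic", cg$res, ag$res, m$name_1, m$name_2,
            paste0("cation:", cg$label), paste0("anion:", ag$label),
            if (cg$terminal) "main" else "side",
            if (ag$terminal) "main" else "side", m$distance)
        } else {
          out[[length(out) + 1L]] <<- .make_record(
            "ionic", ag$res, cg$res, m$name_2, m$name_1,
            paste0("anion:", ag$label), paste0("cation:", cg$label),
            if (ag$terminal) "main" else "side",
            if (cg$terminal) "main" else "side", m$distance)
        }
      }
    }
  }
  pair_up(ga$cations, gb$anions, TRUE)
  pair_up(gb$cations, ga$anions, FALSE)
  .order_records(do.call(rbind, out))
}

# aromatic ring centroids of one selection; incomplete rings are skipped with
# a warning.
.ring_centroids <- function(side) {
  out <- list()
  for (i in seq_len(nrow(side$residues))) {
    r <- side$residues[i, ]
    rings <- .aromatic_rings[[r$resname]]
    if (is.null(rings)) next
    at <- .residue_atoms(side, r$key)
    for (rn in names(rings)) {
      ring_at <- at[at$name %in% rings[[rn]], , drop = FALSE]
      if (nrow(ring_at) < length(rings[[rn]])) {
        warning(sprintf("skipping incomplete %s ring of %s %s%d", rn,
                        r$resname, r$chain, r$resseq))
        next
      }
      out[[length(out) + 1L]] <- list(
        res = r, label = paste0("ring:", rn),
        centroid = colMeans(coords(ring_at)))
    }
  }
  out
}

#' Detect aromatic-aromatic interactions across an interface
#'
#' Pairs of aromatic ring centroids (PHE/TYR six-ring, TRP five- and six-ring,
#' HIS five-ring) whose distance lies inside the configured band.
#'
#' @inheritParams detect_hbonds
#' @return Interaction-record data.frame.
#' @export
detect_aromatic_aromatic <- function(frame, split,
                                     cutoffs = interaction_cutoffs()) {
  sa <- .residue_table(frame, split$chains_a)
  sb <- .residue_table(frame, split$chains_b)
  ra <- .ring_centroids(sa); rb <- .ring_centroids(sb)
  out <- list(.empty_records())
  for (g1 in ra) for (g2 in rb) {
    d <- .dist3(g1$centroid, g2$centroid)
    if (d >= cutoffs$aromatic_min && d <= cutoffs$aromatic_max)
      out[[length(out) + 1L]] <- .make_record(
        "aromatic_aromatic", g1$res, g2$res, g1$label, g2$label,
        "ring", "ring", "side", "side", d)
  }
  .order_records(do.call(rbind, out))
}

#' Detect aromatic-sulphur interactions across an interface
#'
#' Pairs of sulfur atoms (CYS SG, MET SD) and aromatic ring centroids within
#' the cutoff.
#'
#' @inheritParams detect_hbonds
#' @return Interaction-record data.frame.
#' @export
detect_aromatic_sulphur <- function(frame, split,
                                    cutoffs = interaction_cutoffs()) {
  sa <- .residue_table(frame, split$chains_a)
  sb <- .residue_table(frame, split$chains_b)
  s_atoms <- function(side) {
    a <- side$atoms
    keep <- rep(FALSE, nrow(a))
    for (i in seq_len(nrow(a)))
      keep[i] <- a$name[i] %in% .sulphur_atoms[[a$resname[i]]]
    a[keep, , drop = FALSE]
  }
  out <- list(.empty_records())
  scan <- function(s_at, rings, s_is_a) {
    for (i in seq_len(nrow(s_at))) for (g in rings) {
      d <- .dist3(c(s_at$x[i], s_at$y[i], s_at$z[i]), g$centroid)
      if (d <= cutoffs$aromatic_sulphur) {
        sr <- s_at[i, ]
        if (s_is_a)
          out[[length(out) + 1L]] <<- .make_record(
            "aromatic_sulphur", sr, g$res, sr$name, g$label,
            "sulphur", "ring", "side", "side", d)
        else
          out[[length(out) + 1L]] <<- .make_record(
            "aromatic_sulphur", g$res, sr, g$label, sr$name,
            "ring", "sulphur", "side", "side", d)
      }
    }
  }
  scan(s_atoms(sa), .ring_centroids(sb), TRUE)
  scan(s_atoms(sb), .ring_centroids(sa), FALSE)
  .order_records(do.call(rbind, out))
}

# cation positions for cation-pi (termini excluded); ARG uses the guanidinium
# centroid CZ/NH1/NH2.
.cation_points <- function(side, include_his = FALSE) {
  out <- list()
  for (i in seq_len(nrow(side$residues))) {
    r <- side$residues[i, ]
    at <- .residue_atoms(side, r$key)
    if (r$resname == "LYS") {
      nz <- at[at$name == "NZ", , drop = FALSE]
      if (nrow(nz) == 1L)
        out[[length(out) + 1L]] <- list(res = r, label = "NZ",
                                        point = c(nz$x, nz$y, nz$z))
    } else if (r$resname == "ARG") {
      gu <- at[at$name %in% c("CZ", "NH1", "NH2"), , drop = FALSE]
      if (nrow(gu) == 3L)
        out[[length(out) + 1L]] <- list(res = r, label = "guanidinium",
                                        point = colMeans(coords(gu)))
    } else if (include_his && r$resname == "HIS") {
      rg <- at[at$name %in% .aromatic_rings$HIS$five, , drop = FALSE]
      if (nrow(rg) == 5L)
        out[[length(out) + 1L]] <- list(res = r, label = "imidazolium",
                                        point = colMeans(coords(rg)))
    }
  }
  out
}

#' Detect cation-pi interactions across an interface
#'
#' Pairs of side-chain cationic centers (LYS NZ, ARG guanidinium centroid,
#' optionally HIS) and aromatic ring centroids within the cutoff; chain
#' termini are not counted as cations here.
#'
#' @inheritParams detect_ionic
#' @return Interaction-record data.frame.
#' @export
detect_cation_pi <- function(frame, split, cutoffs = interaction_cutoffs(),
                             include_his = FALSE) {
  sa <- .residue_table(frame, split$chains_a)
  sb <- .residue_table(frame, split$chains_b)
  out <- list(.empty_records())
  scan <- function(cats, rings, cat_is_a) {
    for (cg in cats) for (g in rings) {
      d <- .dist3(cg$point, g$centroid)
      if (d <= cutoffs$cation_pi) {
        if (cat_is_a)
          out[[length(out) + 1L]] <<- .make_record(
            "cation_pi", cg$res, g$res, cg$label, g$label,
            "cation", "ring", "side", "side", d)
        else
          out[[length(out) + 1L]] <<- .make_record(
            "cation_pi", g$res, cg$res, g$label, cg$label,
            "ring", "cation", "side", "side", d)
      }
    }
  }
  scan(.cation_points(sa, include_his), .ring_centroids(sb), TRUE)
  scan(.cation_points(sb, include_his), .ring_centroids(sa), FALSE)
  .order_records(do.call(rbind, out))
}

#' Label salt bridges from hydrogen-bond and ionic records
#'
#' A residue pair simultaneously forming a hydrogen bond and an ionic
#' interaction is labelled a salt bridge; the recorded distance is the ionic
#' one. Input records are left unmodified.
#'
#' @param hbonds,ionic record data.frames computed on the same frame/split.
#' @return Interaction-record data.frame of kind `salt_bridge`.
#' @export
label_salt_bridges <- function(hbonds, ionic) {
  if (nrow(hbonds) == 0L || nrow(ionic) == 0L) return(.empty_records())
  pair_key <- function(r) paste(r$chain_a, r$res_a, r$icode_a,
                                r$chain_b, r$res_b, r$icode_b, sep = "|")
  hb_keys <- unique(pair_key(hbonds))
  sb <- ionic[pair_key(ionic) %in% hb_keys, , drop = FALSE]
  if (nrow(sb) == 0L) return(.empty_records())
  sb$kind <- "salt_bridge"
  # one salt bridge per residue pair: keep the closest ionic group pair
  k <- pair_key(sb)
  sb <- sb[order(k, sb$distance), , drop = FALSE]
  sb <- sb[!duplicated(pair_key(sb)), , drop = FALSE]
  .order_records(sb)
}

#' Full interaction fingerprint of one frame
#'
#' Runs all six detectors plus the salt-bridge rule and returns the union,
#' deterministically ordered by kind and partner identity.
#'
#' @inheritParams detect_ionic
#' @return Interaction-record data.frame with columns `kind`, partner
#'   identities (`chain_a`, `res_a`, `icode_a`, `resname_a`, `name_a`,
#'   `group_a`, `side_a`; same for `_b`) and `distance` (Angstrom).
#' @export
fingerprint <- function(frame, split, cutoffs = interaction_cutoffs(),
                        include_his = FALSE) {
  hb <- detect_hbonds(frame, split, cutoffs)
  io <- detect_ionic(frame, split, cutoffs, include_his)
  rec <- rbind(hb,
               detect_hydrophobic(frame, split, cutoffs),
               io,
               detect_aromatic_aromatic(frame, split, cutoffs),
               detect_aromatic_sulphur(frame, split, cutoffs),
               detect_cation_pi(frame, split, cutoffs, include_his),
               label_salt_bridges(hb, io))
  .order_records(rec)
}
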