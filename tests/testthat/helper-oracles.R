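# Independent brute-force oracles. These deliberately re-declare the typing
# tables and use plain all-pairs loops so they share no code path with the
# package detectors.

.orc_backbone <- c("N", "CA", "C", "O", "OXT")

.orc_donors <- list(
  ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2", HIS = c("ND1", "NE2"),
  LYS = "NZ", SER = "OG", THR = "OG1", TRP = "NE1", TYR = "OH"
)
.orc_acceptors <- list(
  ASN = "OD1", ASP = c("OD1", "OD2"), GLN = "OE1", GLU = c("OE1", "OE2"),
  HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH"
)
.orc_apolar <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP", "PRO", "TYR")
.orc_rings <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TRP = list(c("CG", "CD1", "CD2", "NE1", "CE2"),
             c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2"))
)

.orc_split <- function(st, chains_a, chains_b) {
  a <- st$atoms
  list(a = a[a$chain %in% chains_a & !a$is_h, ],
       b = a[a$chain %in% chains_b & !a$is_h, ])
}

.orc_d <- function(a, i, b, j) {
  sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 + (a$z[i] - b$z[j])^2)
}

# keys "chainA|resA|chainB|resB" (A side first) for each kind

oracle_hbond_pairs <- function(st, chains_a, chains_b, cutoff = 3.5) {
  s <- .orc_split(st, chains_a, chains_b)
  is_don <- function(side, i) {
    rn <- side$resname[i]; nm <- side$name[i]
    (nm == "N" && rn != "PRO") || nm %in% .orc_donors[[rn]]
  }
  is_acc <- function(side, i) {
    rn <- side$resname[i]; nm <- side$name[i]
    nm %in% c("O", "OXT") || nm %in% .orc_acceptors[[rn]]
  }
  keys <- character(0)
  for (i in seq_len(nrow(s$a))) for (j in seq_len(nrow(s$b))) {
    ok <- (is_don(s$a, i) && is_acc(s$b, j)) ||
      (is_acc(s$a, i) && is_don(s$b, j))
    if (ok && .orc_d(s$a, i, s$b, j) <= cutoff)
      keys <- c(keys, paste(s$a$chain[i], s$a$resseq[i], s$b$chain[j],
                            s$b$resseq[j], sep = "|"))
  }
  sort(unique(keys))
}

oracle_hydrophobic_pairs <- function(st, chains_a, chains_b, cutoff = 5.0) {
  s <- .orc_split(st, chains_a, chains_b)
  sc_c <- function(side)
    side[side$resname %in% .orc_apolar & side$element == "C" &
           !(side$name %in% .orc_backbone), ]
  a <- sc_c(s$a); b <- sc_c(s$b)
  keys <- character(0)
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b)))
    if (.orc_d(a, i, b, j) <= cutoff)
      keys <- c(keys, paste(a$chain[i], a$resseq[i], b$chain[j], b$resseq[j],
                            sep = "|"))
  sort(unique(keys))
}

oracle_ionic_pairs <- function(st, chains_a, chains_b, cutoff = 6.0) {
  # side-chain groups plus chain termini (first residue N, last residue O/OXT)
  charged <- function(side, full_atoms) {
    cat_k <- character(0); ani_k <- character(0); idx_c <- list(); idx_a <- list()
    add <- function(lst, keys, key, rows) {
      if (length(rows) == 0) return(list(lst, keys))
      if (key %in% keys) lst[[key]] <- c(lst[[key]], rows)
      else { lst[[key]] <- rows; keys <- c(keys, key) }
      list(lst, keys)
    }
    for (i in seq_len(nrow(side))) {
      rn <- side$resname[i]; nm <- side$name[i]
      key <- paste(side$chain[i], side$resseq[i], sep = "|")
      if ((rn == "LYS" && nm == "NZ") ||
          (rn == "ARG" && nm %in% c("NH1", "NH2", "NE"))) {
        r <- add(idx_c, cat_k, key, i); idx_c <- r[[1]]; cat_k <- r[[2]]
      }
      if ((rn == "ASP" && nm %in% c("OD1", "OD2")) ||
          (rn == "GLU" && nm %in% c("OE1", "OE2"))) {
        r <- add(idx_a, ani_k, key, i); idx_a <- r[[1]]; ani_k <- r[[2]]
      }
    }
    for (ch in unique(side$chain)) {
      rows <- which(side$chain == ch)
      first_res <- side$resseq[rows[1]]; last_res <- side$resseq[rows[length(rows)]]
      nt <- rows[side$resseq[rows] == first_res & side$name[rows] == "N"]
      ct <- rows[side$resseq[rows] == last_res &
                   side$name[rows] %in% c("O", "OXT")]
      if (length(nt)) {
        key <- paste(ch, first_res, sep = "|")
        r <- add(idx_c, cat_k, key, nt); idx_c <- r[[1]]; cat_k <- r[[2]]
      }
      if (length(ct)) {
        key <- paste(ch, last_res, sep = "|")
        r <- add(idx_a, ani_k, key, ct); idx_a <- r[[1]]; ani_k <- r[[2]]
      }
    }
    list(cations = idx_c, anions = idx_a)
  }
  s <- .orc_split(st, chains_a, chains_b)
  ga <- charged(s$a); gb <- charged(s$b)
  keys <- character(0)
  pair <- function(side1, g1, side2, g2, a_first) {
    for (k1 in names(g1)) for (k2 in names(g2)) {
      dmin <- Inf
      for (i in g1[[k1]]) for (j in g2[[k2]])
        dmin <- min(dmin, .orc_d(side1, i, side2, j))
      if (dmin <= cutoff) {
        key <- if (a_first) paste(k1, k2, sep = "|") else paste(k2, k1, sep = "|")
        keys <<- c(keys, key)
      }
    }
  }
  pair(s$a, ga$cations, s$b, gb$anions, TRUE)
  pair(s$b, gb$cations, s$a, ga$anions, FALSE)
  sort(unique(keys))
}

.orc_ring_centroids <- function(side) {
  out <- list()
  res_keys <- unique(paste(side$chain, side$resseq, sep = "|"))
  for (rk in res_keys) {
    parts <- strsplit(rk, "|", fixed = TRUE)[[1]]
    rows <- side[side$chain == parts[1] & side$resseq == as.integer(parts[2]), ]
    rings <- .orc_rings[[rows$resname[1]]]
    if (is.null(rings)) next
    for (ring in rings) {
      ra <- rows[rows$name %in% ring, ]
      if (nrow(ra) < length(ring)) next
      out[[length(out) + 1]] <- list(key = rk,
                                     c = c(mean(ra$x), mean(ra$y), mean(ra$z)))
    }
  }
  out
}

oracle_aromatic_pairs <- function(st, chains_a, chains_b, lo = 4.5, hi = 7.0) {
  s <- .orc_split(st, chains_a, chains_b)
  ra <- .orc_ring_centroids(s$a); rb <- .orc_ring_centroids(s$b)
  keys <- character(0)
  for (g1 in ra) for (g2 in rb) {
    d <- sqrt(sum((g1$c - g2$c)^2))
    if (d >= lo && d <= hi) keys <- c(keys, paste(g1$key, g2$key, sep = "|"))
  }
  sort(unique(keys))
}

oracle_aromatic_sulphur_pairs <- function(st, chains_a, chains_b,
                                          cutoff = 4.3) {
  s <- .orc_split(st, chains_a, chains_b)
  s_atoms <- function(side)
    side[(side$resname == "CYS" & side$name == "SG") |
           (side$resname == "MET" & side$name == "SD"), ]
  keys <- character(0)
  scan <- function(sa, rings, s_first) {
    for (i in seq_len(nrow(sa))) for (g in rings) {
      d <- sqrt((sa$x[i] - g$c[1])^2 + (sa$y[i] - g$c[2])^2 +
                  (sa$z[i] - g$c[3])^2)
      if (d <= cutoff) {
        k1 <- paste(sa$chain[i], sa$resseq[i], sep = "|")
        keys <<- c(keys, if (s_first) paste(k1, g$key, sep = "|")
                   else paste(g$key, k1, sep = "|"))
      }
    }
  }
  scan(s_atoms(s$a), .orc_ring_centroids(s$b), TRUE)
  scan(s_atoms(s$b), .orc_ring_centroids(s$a), FALSE)
  sort(unique(keys))
}

oracle_cation_pi_pairs <- function(st, chains_a, chains_b, cutoff = 6.0) {
  s <- .orc_split(st, chains_a, chains_b)
  cat_pts <- function(side) {
    out <- list()
    res_keys <- unique(paste(side$chain, side$resseq, sep = "|"))
    for (rk in res_keys) {
      parts <- strsplit(rk, "|", fixed = TRUE)[[1]]
      rows <- side[side$chain == parts[1] &
                     side$resseq == as.integer(parts[2]), ]
      rn <- rows$resname[1]
      if (rn == "LYS") {
        nz <- rows[rows$name == "NZ", ]
        if (nrow(nz) == 1)
          out[[length(out) + 1]] <- list(key = rk, p = c(nz$x, nz$y, nz$z))
      } else if (rn == "ARG") {
        gu <- rows[rows$name %in% c("CZ", "NH1", "NH2"), ]
        if (nrow(gu) == 3)
          out[[length(out) + 1]] <- list(key = rk,
                                         p = c(mean(gu$x), mean(gu$y),
                                               mean(gu$z)))
      }
    }
    out
  }
  keys <- character(0)
  scan <- function(cats, rings, cat_first) {
    for (cp in cats) for (g in rings) {
      if (sqrt(sum((cp$p - g$c)^2)) <= cutoff)
        keys <<- c(keys, if (cat_first) paste(cp$key, g$key, sep = "|")
                   else paste(g$key, cp$key, sep = "|"))
    }
  }
  scan(cat_pts(s$a), .orc_ring_centroids(s$b), TRUE)
  scan(cat_pts(s$b), .orc_ring_centroids(s$a), FALSE)
  sort(unique(keys))
}

# residue-pair keys of a package record set, matching the oracle key format
record_pair_set <- function(rec) {
  sort(unique(paste(rec$chain_a, rec$res_a, rec$chain_b, rec$res_b,
                    sep = "|")))
}

# minimum RMSD via quaternion-parameterized numeric minimization (independent
# of the SVD path): multiple random restarts of Nelder-Mead over unit
# quaternions, centered coordinates.
oracle_min_rmsd <- function(mobile, reference, n_starts = 12) {
  P <- sweep(as.matrix(mobile), 2, colMeans(mobile))
  Q <- sweep(as.matrix(reference), 2, colMeans(reference))
  quat_rot <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, byrow = TRUE)
  }
  obj <- function(q) {
    R <- quat_rot(q)
    sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
  }
  best <- Inf
  for (k in seq_len(n_starts)) {
    q0 <- rnorm(4)
    o <- optim(q0, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
    o <- optim(o$par, obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}
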