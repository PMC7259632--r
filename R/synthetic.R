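# Deterministic, seeded generators for every fixture class the analyses need:
# turn peptides with a target Calpha span, two-chain interfaces with planted
# contacts, trajectories with planted contact occupancy, multimeric stacks
# with controlled spacing, and randomized interfaces for oracle comparisons.
#
# Chemistry-grade realism is a non-goal: the detectors operate on geometry and
# atom typing only, so residues are built from idealized local templates.

.norm3 <- function(v) v / sqrt(sum(v^2))
.cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])

# run code with an isolated, seeded RNG stream; the caller's RNG state is
# untouched, so adding a fixture never perturbs existing ones
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Local residue templates: backbone N-CA-C-O in the z=0 plane with CA at the
# origin and the side chain extending along -y. Approximate bond geometry.
.residue_templates <- local({
  bb <- list(N = c(-1.46, 0, 0), CA = c(0, 0, 0), C = c(1.52, 0, 0),
             O = c(2.15, 1.06, 0))
  ring6 <- list(CG = c(0, -2.9, 0), CD1 = c(1.2, -3.6, 0),
                CE1 = c(1.2, -5.0, 0), CZ = c(0, -5.7, 0),
                CE2 = c(-1.2, -5.0, 0), CD2 = c(-1.2, -3.6, 0))
  list(
    GLY = bb,
    ALA = c(bb, list(CB = c(0, -1.53, 0))),
    SER = c(bb, list(CB = c(0, -1.53, 0), OG = c(0, -2.95, 0))),
    CYS = c(bb, list(CB = c(0, -1.53, 0), SG = c(0, -3.3, 0))),
    THR = c(bb, list(CB = c(0, -1.53, 0), OG1 = c(0.7, -2.7, 0),
                     CG2 = c(-0.7, -2.7, 0.7))),
    VAL = c(bb, list(CB = c(0, -1.53, 0), CG1 = c(0.7, -2.8, 0),
                     CG2 = c(-0.7, -2.8, 0.7))),
    LEU = c(bb, list(CB = c(0, -1.53, 0), CG = c(0, -3.0, 0),
                     CD1 = c(0.7, -4.3, 0), CD2 = c(-0.7, -4.3, 0.7))),
    ILE = c(bb, list(CB = c(0, -1.53, 0), CG1 = c(0.7, -2.8, 0),
                     CG2 = c(-0.7, -2.8, 0.7), CD1 = c(0.7, -4.3, 0))),
    MET = c(bb, list(CB = c(0, -1.53, 0), CG = c(0, -3.0, 0),
                     SD = c(0, -4.8, 0), CE = c(1.3, -5.8, 0))),
    PRO = c(bb, list(CB = c(0, -1.53, 0), CG = c(1.2, -2.2, 0),
                     CD = c(2.0, -1.0, 0))),
    PHE = c(bb, list(CB = c(0, -1.53, 0)), ring6),
    TYR = c(bb, list(CB = c(0, -1.53, 0)), ring6, list(OH = c(0, -7.1, 0))),
    TRP = c(bb, list(CB = c(0, -1.53, 0), CG = c(0, -2.9, 0),
                     CD1 = c(1.1, -3.7, 0), NE1 = c(0.8, -5.0, 0),
                     CE2 = c(-0.6, -5.2, 0), CD2 = c(-1.0, -3.9, 0),
                     CE3 = c(-2.4, -3.5, 0), CZ3 = c(-3.4, -4.4, 0),
                     CH2 = c(-3.1, -5.7, 0), CZ2 = c(-1.7, -6.1, 0))),
    HIS = c(bb, list(CB = c(0, -1.53, 0), CG = c(0, -2.9, 0),
                     ND1 = c(1.1, -3.7, 0), CD2 = c(-1.1, -3.6, 0),
                     CE1 = c(0.7, -5.0, 0), NE2 = c(-0.7, -4.9, 0))),
    LYS = c(bb, list(CB = c(0, -1.53, 0), CG = c(0, -3.0, 0),
                     CD = c(0, -4.5, 0), CE = c(0, -6.0, 0),
                     NZ = c(0, -7.4, 0))),
    ARG = c(bb, list(CB = c(0, -1.53, 0), CG = c(0, -3.0, 0),
                     CD = c(0, -4.5, 0), NE = c(0, -5.9, 0),
                     CZ = c(0, -7.2, 0), NH1 = c(1.1, -8.0, 0),
                     NH2 = c(-1.1, -8.0, 0))),
    ASP = c(bb, list(CB = c(0, -1.53, 0), CG = c(0, -3.0, 0),
                     OD1 = c(1.1, -3.7, 0), OD2 = c(-1.1, -3.7, 0))),
    GLU = c(bb, list(CB = c(0, -1.53, 0), CG = c(0, -3.0, 0),
                     CD = c(0, -4.5, 0), OE1 = c(1.1, -5.2, 0),
                     OE2 = c(-1.1, -5.2, 0))),
    ASN = c(bb, list(CB = c(0, -1.53, 0), CG = c(0, -3.0, 0),
                     OD1 = c(1.1, -3.7, 0), ND2 = c(-1.1, -3.7, 0))),
    GLN = c(bb, list(CB = c(0, -1.53, 0), CG = c(0, -3.0, 0),
                     CD = c(0, -4.5, 0), OE1 = c(1.1, -5.2, 0),
                     NE2 = c(-1.1, -5.2, 0)))
  )
})

# rows of an atom table for one residue given absolute atom coordinates
.residue_rows <- function(resname, chain, resseq, coords_list, icode = "") {
  do.call(rbind, lapply(names(coords_list), function(nm) {
    p <- coords_list[[nm]]
    el <- .infer_element(nm, "")
    data.frame(serial = 0L, name = nm, alt = "", resname = resname,
               chain = chain, resseq = as.integer(resseq), icode = icode,
               x = p[1], y = p[2], z = p[3], occupancy = 1.0, element = el,
               is_h = identical(el, "H"), het = FALSE,
               stringsAsFactors = FALSE)
  }))
}

.finish_structure <- function(atom_rows, model_id = 1L, source = "synthetic") {
  atoms <- do.call(rbind, atom_rows)
  atoms$serial <- seq_len(nrow(atoms))
  new_structure(atoms, model_id = model_id, source = source)
}

# apply a rigid placement (rotation matrix R, then translation t) to a template
.place_template <- function(tpl, R = diag(3), t = c(0, 0, 0)) {
  lapply(tpl, function(p) as.numeric(R %*% p) + t)
}

#' Generate a turn peptide with a target Calpha span
#'
#' Builds a single chain whose epitope residues lie on a circular Calpha arc
#' with 3.8 Angstrom virtual bonds, bent so the Calpha(start)-Calpha(end)
#' distance hits `span_target`. The key residue is a lysine with a full side
#' chain pointing outward from the turn (solvent-exposed); flanking residues
#' extend along the arc tangents. With `bridged_partner = TRUE` an aspartate
#' is placed at the partner position with its carboxylate within salt-bridge
#' range of the lysine amine, emulating the K28-D23 sequestration seen in
#' fibril models.
#'
#' @param span_target Calpha(start)-Calpha(end) distance in Angstrom; must be
#'   geometrically feasible for the residue count at 3.8 Angstrom steps.
#' @param n_res number of residues in the chain (default 11).
#' @param seed integer seed (generation is deterministic; the seed isolates
#'   the call's RNG stream).
#' @param chain chain identifier (default "A").
#' @param first_res author number of the first residue (default 22).
#' @param start_res,end_res,key_res epitope turn boundaries and key lysine
#'   (defaults 25/29/28).
#' @param bridged_partner plant an aspartate carboxylate next to the key
#'   lysine amine (default FALSE).
#' @return A `structure3d`; attribute `span_target` records the request.
#' @export
make_turn_peptide <- function(span_target, n_res = 11L, seed = 1L,
                              chain = "A", first_res = 22L, start_res = 25L,
                              end_res = 29L, key_res = 28L,
                              bridged_partner = FALSE) {
  b <- 3.8
  n_steps <- end_res - start_res
  stopifnot(n_steps >= 2, start_res >= first_res,
            end_res <= first_res + n_res - 1L, key_res > start_res,
            key_res < end_res)
  if (span_target >= n_steps * b || span_target < 1.0)
    stop(sprintf("feasibility error: span %.2f not reachable with %d x %.1f A steps",
                 span_target, n_steps, b))
  f <- function(theta) b * sin(n_steps * theta / 2) / sin(theta / 2) - span_target
  theta <- stats::uniroot(f, c(1e-6, 2 * pi / n_steps - 1e-6), tol = 1e-12)$root
  R_arc <- b / (2 * sin(theta / 2))
  phi <- pi / 2 + n_steps * theta / 2 - (0:n_steps) * theta
  arc <- cbind(R_arc * cos(phi), R_arc * sin(phi), 0)

  last_res <- first_res + n_res - 1L
  resnums <- first_res:last_res
  ca <- matrix(NA_real_, n_res, 3)
  rownames(ca) <- resnums
  ca[as.character(start_res:end_res), ] <- arc
  t0 <- .norm3(arc[1, ] - arc[2, ])
  tn <- .norm3(arc[n_steps + 1, ] - arc[n_steps, ])
  pre <- rev(seq_len(start_res - first_res))
  for (k in seq_along(pre))
    ca[as.character(start_res - k), ] <- arc[1, ] + k * b * t0
  for (k in seq_len(last_res - end_res))
    ca[as.character(end_res + k), ] <- arc[n_steps + 1, ] + k * b * tn

  resname_of <- function(r) {
    if (r == key_res) "LYS"
    else if (bridged_partner && r == key_res - 5L) "ASP"
    else if (r == start_res || r == end_res) "GLY"
    else if (r == key_res - 1L) "ASN"
    else if (r == key_res - 2L) "SER"
    else "ALA"
  }

  rows <- list()
  nz_pos <- NULL
  for (i in seq_len(n_res)) {
    r <- resnums[i]
    c0 <- ca[i, ]
    nxt <- if (i < n_res) ca[i + 1, ] else ca[i, ] + (ca[i, ] - ca[i - 1, ])
    d <- .norm3(nxt - c0)
    u <- .norm3(c(c0[1], c0[2], 0))          # radially outward from the arc center
    if (!all(is.finite(u))) u <- c(0, 1, 0)
    w <- .norm3(.cross3(d, u))
    at <- list(N = c0 - 1.2 * d + 0.3 * w, CA = c0, C = c0 + 1.2 * d + 0.3 * w)
    at$O <- at$C + 1.23 * w
    rn <- resname_of(r)
    if (rn == "LYS") {
      for (k in seq_along(c(CB = 1, CG = 2, CD = 3, CE = 4, NZ = 5)))
        at[[c("CB", "CG", "CD", "CE", "NZ")[k]]] <- c0 + 1.5 * k * u
      nz_pos <- at$NZ
    } else if (rn == "SER") {
      at$CB <- c0 + 1.5 * u; at$OG <- c0 + 2.9 * u
    } else if (rn == "ASN") {
      at$CB <- c0 + 1.5 * u; at$CG <- c0 + 3.0 * u
      at$OD1 <- c0 + 3.0 * u + 1.2 * w; at$ND2 <- c0 + 4.2 * u
    } else if (rn == "ALA") {
      at$CB <- c0 + 1.5 * u
    }
    rows[[i]] <- list(resname = rn, resseq = r, atoms = at)
  }
  if (bridged_partner) {
    # point the aspartate carboxylate at the lysine amine
    i_asp <- which(resnums == key_res - 5L)
    c_asp <- ca[i_asp, ]
    od1 <- nz_pos + c(0, 0, 2.8)
    cg <- c_asp + 0.6 * (od1 - c_asp) / sqrt(sum((od1 - c_asp)^2)) *
      (sqrt(sum((od1 - c_asp)^2)) - 1.3)
    rows[[i_asp]]$atoms$CB <- c_asp + 0.35 * (cg - c_asp)
    rows[[i_asp]]$atoms$CG <- cg
    rows[[i_asp]]$atoms$OD1 <- od1
    rows[[i_asp]]$atoms$OD2 <- od1 + c(1.1, 0.6, 0.4)
  }
  out <- .with_seed(seed, .finish_structure(
    lapply(rows, function(rr)
      .residue_rows(rr$resname, chain, rr$resseq, rr$atoms)),
    source = sprintf("synthetic turn peptide span=%.2f", span_target)))
  attr(out, "span_target") <- span_target
  out
}

.contact_kinds <- c("hbond", "hydrophobic", "ionic", "aromatic_aromatic",
                    "aromatic_sulphur", "cation_pi", "salt_bridge")

# (residue template, anchor atom) pairs per planted kind; chosen so that a
# planted contact of one kind cannot trigger a detector of another kind at the
# same site (e.g. HIS is aromatic but not apolar).
.site_recipes <- list(
  hbond = list(a = c("GLY", "O"), b = c("GLY", "N"),
               range = c(2.4, 3.5)),
  hydrophobic = list(a = c("LEU", "CD1"), b = c("VAL", "CG1"),
                     range = c(3.0, 5.0)),
  ionic = list(a = c("GLU", "OE1"), b = c("LYS", "NZ"),
               range = c(3.51, 6.0)),
  salt_bridge = list(a = c("GLU", "OE1"), b = c("LYS", "NZ"),
                     range = c(2.6, 3.5)),
  aromatic_aromatic = list(a = c("HIS", "ring"), b = c("PHE", "ring"),
                           range = c(4.5, 7.0)),
  aromatic_sulphur = list(a = c("CYS", "SG"), b = c("PHE", "ring"),
                          range = c(3.3, 4.3)),
  cation_pi = list(a = c("LYS", "NZ"), b = c("PHE", "ring"),
                   range = c(4.0, 6.0))
)

#' Feasible distance range for a planted contact kind
#'
#' @param kind one of the seven interaction kinds.
#' @return c(min, max) in Angstrom for [make_contact_interface()].
#' @export
contact_distance_range <- function(kind) {
  stopifnot(kind %in% names(.site_recipes))
  .site_recipes[[kind]]$range
}

.anchor_point <- function(resname, anchor) {
  tpl <- .residue_templates[[resname]]
  if (anchor == "ring") {
    ring <- .aromatic_rings[[resname]][[1]]
    colMeans(do.call(rbind, tpl[ring]))
  } else tpl[[anchor]]
}

.anchored_template <- function(resname, anchor, flip) {
  tpl <- .residue_templates[[resname]]
  a0 <- .anchor_point(resname, anchor)
  lapply(tpl, function(p) {
    q <- p - a0
    if (flip) q <- c(q[1], -q[2], q[3])  # body toward -y (chain A side)
    q
  })
}

#' Generate a two-chain interface with planted contacts
#'
#' Builds chains A and B such that [fingerprint()] recovers exactly the
#' requested contact list at the residue-pair level. Each contact occupies its
#' own site spaced `site_spacing` apart along x, with residue-type pairs
#' chosen so no accidental contacts of other kinds arise; isolated glycine
#' spacers terminate each chain so the chain-terminus charged groups sit far
#' from every site. A planted `salt_bridge` implies (and is recovered
#' together with) its hydrogen-bond and ionic components.
#'
#' @param contacts list of `list(kind =, distance =)` entries, or a data.frame
#'   with columns `kind` and `distance`; see [contact_distance_range()] for
#'   the feasible distance per kind.
#' @param seed integer seed (placement is deterministic).
#' @param site_spacing distance between consecutive sites in Angstrom
#'   (default 30; must exceed every cutoff by a wide margin).
#' @return A `structure3d` with chains "A" and "B"; attribute `contacts` is a
#'   data.frame of the planted contacts with the residue numbers used.
#' @export
make_contact_interface <- function(contacts, seed = 1L, site_spacing = 30) {
  if (is.data.frame(contacts))
    contacts <- lapply(seq_len(nrow(contacts)), function(i)
      list(kind = contacts$kind[i], distance = contacts$distance[i]))
  stopifnot(length(contacts) >= 1L)
  for (ct in contacts) {
    stopifnot(ct$kind %in% names(.site_recipes))
    rng <- .site_recipes[[ct$kind]]$range
    if (ct$distance < rng[1] || ct$distance > rng[2])
      stop(sprintf("placement error: %s distance %.2f outside feasible range [%.2f, %.2f]",
                   ct$kind, ct$distance, rng[1], rng[2]))
  }
  n <- length(contacts)
  rows_a <- list(); rows_b <- list()
  planted <- list()
  # leading spacers
  spacer <- .residue_templates$GLY
  rows_a[[1]] <- .residue_rows("GLY", "A", 1L,
                               .place_template(spacer, t = c(-site_spacing, -15, 0)))
  rows_b[[1]] <- .residue_rows("GLY", "B", 1L,
                               .place_template(spacer, t = c(-site_spacing, 15, 0)))
  for (i in seq_len(n)) {
    ct <- contacts[[i]]
    rc <- .site_recipes[[ct$kind]]
    x0 <- i * site_spacing
    tpl_a <- .anchored_template(rc$a[1], rc$a[2], flip = TRUE)
    tpl_b <- .anchored_template(rc$b[1], rc$b[2], flip = FALSE)
    res <- i + 1L
    rows_a[[length(rows_a) + 1L]] <- .residue_rows(
      rc$a[1], "A", res, lapply(tpl_a, function(p) p + c(x0, 0, 0)))
    rows_b[[length(rows_b) + 1L]] <- .residue_rows(
      rc$b[1], "B", res, lapply(tpl_b, function(p) p + c(x0, ct$distance, 0)))
    planted[[i]] <- data.frame(kind = ct$kind, distance = ct$distance,
                               chain_a = "A", res_a = res,
                               resname_a = rc$a[1], chain_b = "B", res_b = res,
                               resname_b = rc$b[1], stringsAsFactors = FALSE)
  }
  # trailing spacers
  rows_a[[length(rows_a) + 1L]] <- .residue_rows(
    "GLY", "A", n + 2L,
    .place_template(spacer, t = c((n + 1) * site_spacing, -15, 0)))
  rows_b[[length(rows_b) + 1L]] <- .residue_rows(
    "GLY", "B", n + 2L,
    .place_template(spacer, t = c((n + 1) * site_spacing, 15, 0)))
  out <- .with_seed(seed, .finish_structure(
    c(rows_a, rows_b), source = "synthetic contact interface"))
  attr(out, "contacts") <- do.call(rbind, planted)
  out
}

#' Generate a trajectory with planted contact occupancy
#'
#' Replicates `base` over `n_frames` frames; in frames where the contact is
#' absent, the mobile residue is displaced along +y by `displacement`
#' Angstrom, putting it beyond every detection cutoff plus 2 Angstrom.
#' Presence is controlled either by an explicit `frame_mask` (occupancy
#' recovered exactly) or by a per-frame Bernoulli probability `p` (occupancy
#' recovered within binomial tolerance).
#'
#' @param base a `structure3d` (typically from [make_contact_interface()]).
#' @param mobile_chain,mobile_res residue to displace.
#' @param n_frames number of frames.
#' @param frame_mask logical (or 0/1) vector of length `n_frames`; TRUE keeps
#'   the contact in that frame. Exactly one of `frame_mask`/`p` must be given.
#' @param p per-frame presence probability.
#' @param seed integer seed for probability mode.
#' @param displacement displacement in Angstrom (default 15).
#' @return A `trajectory3d` with `n_frames` frames; attribute `mask` records
#'   the realized presence vector.
#' @export
make_occupancy_trajectory <- function(base, mobile_chain, mobile_res,
                                      n_frames, frame_mask = NULL, p = NULL,
                                      seed = 1L, displacement = 15) {
  stopifnot(inherits(base, "structure3d"), n_frames >= 1L)
  if (is.null(frame_mask) == is.null(p))
    stop("give exactly one of frame_mask or p")
  mask <- if (!is.null(frame_mask)) {
    stopifnot(length(frame_mask) == n_frames)
    as.logical(frame_mask)
  } else {
    .with_seed(seed, stats::runif(n_frames) < p)
  }
  idx <- base$atoms$chain == mobile_chain & base$atoms$resseq == mobile_res
  if (!any(idx)) stop("mobile residue not found in base structure")
  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    fr <- base
    fr$model_id <- k
    if (!mask[k]) fr$atoms$y[idx] <- fr$atoms$y[idx] + displacement
    frames[[k]] <- fr
  }
  out <- new_trajectory(frames)
  attr(out, "mask") <- mask
  out
}

#' Generate a multimeric stack from a unit structure
#'
#' Places `n_chains` translated copies of `unit` along the z axis at the given
#' spacing (fibril layers stack at ~4.8 Angstrom; dispersed oligomer turns sit
#' much farther apart). Chains are relabeled A, B, C, ... so epitope-turn
#' centroid spacing between neighbors equals `spacing` exactly.
#'
#' @param unit a single-chain `structure3d` (e.g. from [make_turn_peptide()]).
#' @param n_chains number of copies (>= 1, at most 26).
#' @param spacing inter-chain translation in Angstrom.
#' @param seed integer seed (generation is deterministic).
#' @return A `structure3d` with `n_chains` chains.
#' @export
make_multimer_stack <- function(unit, n_chains, spacing, seed = 1L) {
  stopifnot(inherits(unit, "structure3d"), n_chains >= 1L, n_chains <= 26L)
  rows <- list()
  for (i in seq_len(n_chains)) {
    a <- unit$atoms
    a$chain <- LETTERS[i]
    a$z <- a$z + (i - 1) * spacing
    rows[[i]] <- a
  }
  .with_seed(seed, .finish_structure(
    rows, source = sprintf("synthetic stack n=%d spacing=%.2f", n_chains,
                           spacing)))
}

#' Generate a randomized two-chain interface
#'
#' Scatters randomly chosen, randomly oriented residues in two slabs facing
#' each other across the y = 0 plane. No contacts are planted; the fixture
#' exists so detector output can be compared against brute-force oracles on
#' arbitrary geometry.
#'
#' @param n_a,n_b residues per side (<= 50 each).
#' @param seed integer seed; identical seeds give byte-identical structures.
#' @param box x/z extent of each slab in Angstrom (default 25).
#' @param depth y extent of each slab (default 10).
#' @param residue_pool residue names to draw from (default: all templates).
#' @return A `structure3d` with chains "A" and "B".
#' @export
make_random_interface <- function(n_a, n_b, seed = 1L, box = 25, depth = 10,
                                  residue_pool = names(.residue_templates)) {
  stopifnot(n_a >= 1L, n_a <= 50L, n_b >= 1L, n_b <= 50L)
  .with_seed(seed, {
    rand_rot <- function() {
      # uniform random rotation via QR of a Gaussian matrix
      qr_d <- qr(matrix(stats::rnorm(9), 3))
      R <- qr.Q(qr_d)
      if (det(R) < 0) R[, 1] <- -R[, 1]
      R
    }
    one_side <- function(chain, n, y_sign) {
      lapply(seq_len(n), function(i) {
        rn <- sample(residue_pool, 1)
        t <- c(stats::runif(1, -box, box),
               y_sign * stats::runif(1, 1, depth),
               stats::runif(1, -box, box))
        .residue_rows(rn, chain, i, .place_template(.residue_templates[[rn]],
                                                    rand_rot(), t))
      })
    }
    .finish_structure(c(one_side("A", n_a, -1), one_side("B", n_b, +1)),
                      source = "synthetic random interface")
  })
}
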