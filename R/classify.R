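# Composite epitope-accessibility classification of an aggregate: a chain
# supports binding when its epitope turn is sharp, the key lysine side chain
# is solvent-exposed and not sequestered in a salt bridge, and the turn is not
# crowded by equivalent turns of neighboring chains.

#' Epitope definition
#'
#' Defaults describe the amyloid-beta turn epitope: residues 25-29 (GSNKG)
#' with K28 as the key solvent-exposed lysine, screened for salt bridges
#' against D23 and the chain C-terminal carboxylate.
#'
#' @param start_res,end_res first/last residue of the turn (default 25, 29).
#' @param key_residue the key lysine (default 28; must lie in the turn).
#' @param key_partner_res residue numbers whose side-chain carboxylates are
#'   screened as salt-bridge partners of the key residue (default 23); the
#'   chain C-terminal carboxylate is always screened in addition.
#' @return List of class `epitope_definition`.
#' @export
epitope_definition <- function(start_res = 25L, end_res = 29L,
                               key_residue = 28L, key_partner_res = 23L) {
  stopifnot(start_res < end_res, key_residue >= start_res,
            key_residue <= end_res)
  structure(list(start_res = as.integer(start_res),
                 end_res = as.integer(end_res),
                 key_residue = as.integer(key_residue),
                 key_partner_res = as.integer(key_partner_res)),
            class = "epitope_definition")
}

#' Classifier configuration
#'
#' Bundles every tunable of the epitope assessment with its documented
#' default: turn-class thresholds, SASA parameters and exposure threshold, the
#' clearance radius between equivalent epitope turns, the ionic cutoff used
#' for salt-bridge screening of the key lysine, and the minimum number of
#' qualifying chains for a positive verdict.
#'
#' @param sharp_max,wide_max turn-class thresholds in Angstrom (see
#'   [classify_turn()]).
#' @param probe,n_points SASA parameters (see [shrake_rupley_sasa()]).
#' @param exposure_threshold minimum key-residue side-chain SASA in
#'   Angstrom^2 (default 20).
#' @param clearance minimum distance between equivalent epitope-turn Calpha
#'   centroids for a turn to count as accessible (default 10 Angstrom;
#'   fibril-like 4.8 Angstrom stacking fails, dispersed oligomer turns pass).
#' @param min_chains chains that must pass all criteria for a positive
#'   aggregate verdict (default 1).
#' @param cutoffs an [interaction_cutoffs()]; its `ionic` entry is the
#'   salt-bridge screening distance.
#' @param high_occupancy threshold for [label_occupancy()] (default 0.6).
#' @param include_his count histidine as cationic (default FALSE).
#' @return List of class `classifier_config`.
#' @export
classifier_config <- function(sharp_max = 8.5, wide_max = 13.5, probe = 1.4,
                              n_points = 960, exposure_threshold = 20,
                              clearance = 10, min_chains = 1L,
                              cutoffs = interaction_cutoffs(),
                              high_occupancy = 0.6, include_his = FALSE) {
  structure(list(sharp_max = sharp_max, wide_max = wide_max, probe = probe,
                 n_points = n_points,
                 exposure_threshold = exposure_threshold,
                 clearance = clearance, min_chains = as.integer(min_chains),
                 cutoffs = cutoffs, high_occupancy = high_occupancy,
                 include_his = include_his),
            class = "classifier_config")
}

.epitope_centroid <- function(structure, chain, epitope) {
  at <- select_atoms(structure, chain = chain,
                     res_range = c(epitope$start_res, epitope$end_res),
                     atom_names = "CA")
  if (nrow(at) == 0L) return(NULL)
  colMeans(coords(at))
}

# carboxylate atoms screened as partners of the key lysine, over all chains:
# ASP/GLU side-chain oxygens at the configured partner residues, plus every
# chain's C-terminal O/OXT.
.partner_carboxylates <- function(structure, epitope) {
  a <- structure$atoms
  keep <- rep(FALSE, nrow(a))
  keep <- keep | (a$resseq %in% epitope$key_partner_res &
                    ((a$resname == "ASP" & a$name %in% c("OD1", "OD2")) |
                       (a$resname == "GLU" & a$name %in% c("OE1", "OE2"))))
  for (ch in unique(a$chain)) {
    idx <- which(a$chain == ch)
    last_res <- a$resseq[idx[length(idx)]]
    keep <- keep | (a$chain == ch & a$resseq == last_res &
                      a$name %in% c("O", "OXT"))
  }
  a[keep, , drop = FALSE]
}

#' Assess one chain's epitope
#'
#' Computes the turn span and class, the key residue's side-chain SASA in the
#' context of the whole aggregate, whether the key residue's cationic group is
#' within the ionic cutoff of any screened carboxylate (intra- or
#' inter-chain), and the crowding distance to the nearest equivalent epitope
#' turn of another chain.
#'
#' @param structure a `structure3d` (the whole aggregate).
#' @param chain chain to assess.
#' @param epitope an [epitope_definition()].
#' @param config a [classifier_config()].
#' @param sasa optional precomputed [shrake_rupley_sasa()] result for
#'   `structure` (recomputed when NULL).
#' @return One-row data.frame with columns `chain`, `evaluable`, `span`,
#'   `turn_class`, `key_sasa`, `key_exposed`, `key_salt_bridged`,
#'   `bridge_partners`, `crowding_distance`, `accessible`, `pass`.
#' @export
assess_chain <- function(structure, chain, epitope = epitope_definition(),
                         config = classifier_config(), sasa = NULL) {
  na_row <- data.frame(chain = chain, evaluable = FALSE, span = NA_real_,
                       turn_class = NA_character_, key_sasa = NA_real_,
                       key_exposed = NA, key_salt_bridged = NA,
                       bridge_partners = "", crowding_distance = NA_real_,
                       accessible = NA, pass = FALSE,
                       stringsAsFactors = FALSE)
  span <- tryCatch(ca_span(structure, chain, epitope$start_res,
                           epitope$end_res),
                   error = function(e) NULL)
  key_at <- select_atoms(structure, chain = chain,
                         res_range = rep(epitope$key_residue, 2))
  if (is.null(span) || nrow(key_at) == 0L) return(na_row)
  turn_class <- classify_turn(span, config$sharp_max, config$wide_max)

  if (is.null(sasa))
    sasa <- shrake_rupley_sasa(structure, probe = config$probe,
                               n_points = config$n_points)
  key_sasa <- sidechain_sasa(sasa, chain, epitope$key_residue)
  key_exposed <- key_sasa >= config$exposure_threshold

  nz <- key_at[key_at$name == "NZ", , drop = FALSE]
  if (nrow(nz) == 0L)  # fall back to outermost side-chain nitrogen
    nz <- key_at[!key_at$is_h & toupper(key_at$element) == "N" &
                   key_at$name != "N", , drop = FALSE]
  bridged <- FALSE; partners <- character(0)
  if (nrow(nz) > 0L) {
    carb <- .partner_carboxylates(structure, epitope)
    if (nrow(carb) > 0L) {
      d <- sqrt((carb$x - nz$x[1])^2 + (carb$y - nz$y[1])^2 +
                  (carb$z - nz$z[1])^2)
      hit <- d <= config$cutoffs$ionic
      if (any(hit)) {
        bridged <- TRUE
        partners <- unique(sprintf("%s:%s%d:%s", carb$chain[hit],
                                   carb$resname[hit], carb$resseq[hit],
                                   carb$name[hit]))
      }
    }
  }

  own <- .epitope_centroid(structure, chain, epitope)
  others <- setdiff(unique(structure$atoms$chain), chain)
  crowding <- Inf
  for (ch in others) {
    cen <- .epitope_centroid(structure, ch, epitope)
    if (!is.null(cen)) crowding <- min(crowding, .dist3(own, cen))
  }
  accessible <- crowding >= config$clearance

  data.frame(chain = chain, evaluable = TRUE, span = span,
             turn_class = turn_class, key_sasa = key_sasa,
             key_exposed = key_exposed, key_salt_bridged = bridged,
             bridge_partners = paste(partners, collapse = ","),
             crowding_distance = crowding, accessible = accessible,
             pass = identical(turn_class, "sharp") && key_exposed &&
               !bridged && accessible,
             stringsAsFactors = FALSE)
}

#' Classify an aggregate as epitope-positive or negative
#'
#' An aggregate is positive when at least `min_chains` chains pass all three
#' structural criteria: a sharp epitope turn, a solvent-exposed key lysine
#' not sequestered in a salt bridge, and an uncrowded turn (clearance from
#' equivalent turns of other chains). Chains lacking the epitope residues are
#' skipped (marked non-evaluable); if no chain is evaluable the verdict is NA.
#'
#' @param x a `structure3d` or a `trajectory3d` (first frame is used).
#' @param epitope an [epitope_definition()].
#' @param config a [classifier_config()].
#' @return List of class `aggregate_verdict` with `positive` (logical, NA when
#'   not evaluable), `supporting_chains`, `chains` (per-chain criteria trace),
#'   `epitope`, `config`.
#' @export
classify_aggregate <- function(x, epitope = epitope_definition(),
                               config = classifier_config()) {
  if (inherits(x, "trajectory3d")) x <- x$frames[[1]]
  stopifnot(inherits(x, "structure3d"))
  chains <- unique(x$atoms$chain)
  sasa <- shrake_rupley_sasa(x, probe = config$probe,
                             n_points = config$n_points)
  rows <- lapply(chains, assess_chain, structure = x, epitope = epitope,
                 config = config, sasa = sasa)
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  evaluable <- tab$evaluable
  positive <- if (!any(evaluable)) NA else sum(tab$pass) >= config$min_chains
  structure(list(positive = positive,
                 supporting_chains = tab$chain[tab$pass],
                 chains = tab, epitope = epitope, config = config),
            class = "aggregate_verdict")
}

#' @export
print.aggregate_verdict <- function(x, ...) {
  verdict <- if (is.na(x$positive)) "not evaluable"
  else if (x$positive) "POSITIVE" else "negative"
  cat(sprintf("<aggregate_verdict> %s (%d supporting chain(s): %s)\n",
              verdict, length(x$supporting_chains),
              paste(x$supporting_chains, collapse = ",")))
  print(x$chains)
  invisible(x)
}
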