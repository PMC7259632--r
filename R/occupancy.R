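# Per-pair contact occupancy across a trajectory: the fraction of frames in
# which an interaction exists, the stability measure used for MD contacts.

.occ_key <- function(rec) {
  paste(rec$kind, rec$chain_a, rec$res_a, rec$icode_a, rec$name_a, rec$group_a,
        rec$chain_b, rec$res_b, rec$icode_b, rec$name_b, rec$group_b,
        sep = "|")
}

#' Contact occupancy over a trajectory
#'
#' Fingerprints every frame in `frame_range` and reports, for each interaction
#' key ever observed, the fraction of frames containing it. Keys distinguish
#' the atom/group identities, so two different hydrogen bonds between the same
#' residues are separate rows; set `rollup = TRUE` to aggregate per
#' (residue pair, kind) instead (a frame counts if any record of that kind
#' joins the pair).
#'
#' @param traj a `trajectory3d`.
#' @param split an [interface_split()].
#' @param cutoffs an [interaction_cutoffs()].
#' @param frame_range integer vector of frame indices (default: all frames).
#' @param rollup aggregate to residue-pair level (default FALSE).
#' @param include_his passed to the detectors.
#' @return data.frame of class `occupancy_table`: record identity columns plus
#'   `count`, `n_frames`, `occupancy`; attribute `n_frames`.
#' @export
occupancy_table <- function(traj, split, cutoffs = interaction_cutoffs(),
                            frame_range = NULL, rollup = FALSE,
                            include_his = FALSE) {
  if (is.null(frame_range)) frame_range <- seq_along(traj$frames)
  frame_range <- as.integer(frame_range)
  if (length(frame_range) == 0L) stop("domain error: empty frame range")
  stopifnot(all(frame_range >= 1L), all(frame_range <= length(traj$frames)))
  nf <- length(frame_range)
  counts <- new.env(parent = emptyenv())
  exemplar <- new.env(parent = emptyenv())
  for (k in frame_range) {
    rec <- fingerprint(traj$frames[[k]], split, cutoffs, include_his)
    if (nrow(rec) == 0L) next
    if (rollup) {
      key <- paste(rec$kind, rec$chain_a, rec$res_a, rec$icode_a,
                   rec$chain_b, rec$res_b, rec$icode_b, sep = "|")
    } else {
      key <- .occ_key(rec)
    }
    seen <- unique(key)
    for (s in seen) {
      counts[[s]] <- (if (is.null(counts[[s]])) 0L else counts[[s]]) + 1L
      if (is.null(exemplar[[s]]))
        exemplar[[s]] <- rec[which(key == s)[1], , drop = FALSE]
    }
  }
  keys <- sort(ls(counts))
  if (length(keys) == 0L) {
    out <- .empty_records()
    out$count <- integer(0); out$n_frames <- integer(0)
    out$occupancy <- double(0)
  } else {
    out <- do.call(rbind, lapply(keys, function(s) exemplar[[s]]))
    out$count <- vapply(keys, function(s) counts[[s]], integer(1))
    out$n_frames <- nf
    out$occupancy <- out$count / nf
    if (rollup) out$distance <- NULL
  }
  rownames(out) <- NULL
  attr(out, "n_frames") <- nf
  class(out) <- c("occupancy_table", class(out))
  out
}

#' Label occupancies as high or low
#'
#' @param table an [occupancy_table()].
#' @param high_threshold fraction in (0, 1]; occupancy at or above it is
#'   labelled `high` (default 0.6).
#' @return The table with a `label` column added.
#' @export
label_occupancy <- function(table, high_threshold = 0.6) {
  stopifnot(high_threshold > 0, high_threshold <= 1)
  table$label <- ifelse(table$occupancy >= high_threshold, "high", "low")
  table
}
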