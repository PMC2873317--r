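#' Detect candidate low-complexity windows
#'
#' Emits every window, at every calibrated length, whose entropy falls
#' strictly below the threshold `t_w` for its length, together with its
#' standardised score `Z = (H - mu_w)/sigma_w`. Candidates typically overlap
#' heavily; see [resolve_overlaps()].
#'
#' @param seqs Named character vector of protein sequences.
#' @param cal An `lcr_calibration` table covering the window lengths to scan.
#' @param skip_ambiguous Drop windows containing non-standard residues.
#' @return `data.frame` with columns `protein_id`, `start`, `end` (1-based,
#'   inclusive), `w`, `H`, `Z`.
#' @export
detect_lcrs <- function(seqs, cal, skip_ambiguous = FALSE) {
  seqs <- check_proteome(seqs)
  stopifnot(inherits(cal, "lcr_calibration"))
  usable <- cal$n > 0L & !is.na(cal$t) & !is.na(cal$sigma) & cal$sigma > 0
  if (!all(usable)) {
    warning("skipping ", sum(!usable), " uncalibrated/degenerate window length(s)")
  }
  ws <- cal$w[usable]
  ts <- cal$t[usable]
  alphabet <- if (skip_ambiguous) STD_AA else ""
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    hit <- cpp_detect_windows(seqs[[i]], ws, ts, alphabet)
    if (length(hit$start) == 0L) next
    out[[i]] <- data.frame(protein_id = names(seqs)[i], start = hit$start,
                           end = hit$start + hit$w - 1L, w = hit$w, H = hit$H)
  }
  cand <- do.call(rbind, out)
  if (is.null(cand)) {
    cand <- data.frame(protein_id = character(), start = integer(),
                       end = integer(), w = integer(), H = numeric())
  }
  cand$Z <- if (nrow(cand)) zscore(cal, cand$w, cand$H) else numeric(0)
  rownames(cand) <- NULL
  cand
}

# Greedy selection for one protein's candidates: repeatedly keep the candidate
# with the most extreme Z (ties: longer window, then smaller start), discard
# everything sharing >= 1 residue with it.
resolve_one <- function(cand, literal_z = FALSE) {
  z <- if (literal_z) -cand$Z else cand$Z
  ord <- order(z, -cand$w, cand$start)
  s <- cand$start[ord]
  e <- cand$end[ord]
  alive <- rep(TRUE, length(ord))
  keep <- integer(0)
  while (any(alive)) {
    i <- which.max(alive)  # first TRUE: best remaining candidate
    keep <- c(keep, ord[i])
    alive <- alive & !(s <= e[i] & e >= s[i])
  }
  cand[keep[order(cand$start[keep])], , drop = FALSE]
}

#' Resolve overlapping candidate regions
#'
#' When multiple candidate low-complexity windows overlap, only the region
#' with the most extreme standardised score is retained: greedily keep the
#' candidate with the lowest Z (i.e. the entropy most extreme for its window
#' length), discard all candidates overlapping it by at least one residue, and
#' repeat. Ties are broken towards the longer region, then the smaller start,
#' so resolution is deterministic. Setting `literal_z = TRUE` instead retains
#' the numerically highest Z.
#'
#' @param candidates Candidate `data.frame` from [detect_lcrs()] (one or more
#'   proteins).
#' @param literal_z Prefer the numerically largest Z instead of the most
#'   extreme (most negative) one.
#' @return The retained, pairwise-disjoint regions, sorted by protein then
#'   start.
#' @export
resolve_overlaps <- function(candidates, literal_z = FALSE) {
  if (nrow(candidates) == 0L) return(candidates)
  parts <- split(candidates, candidates$protein_id, drop = TRUE)
  res <- do.call(rbind, lapply(parts, resolve_one, literal_z = literal_z))
  res <- res[order(res$protein_id, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Normalised and folded LCR centre positions
#'
#' The position of a region is the coordinate of its centre divided by the
#' protein length, on a 0–1 scale; folding maps it to `[0, 0.5]` with 0 at
#' either extremity and 0.5 at the exact centre.
#'
#' @param start,end 1-based inclusive region coordinates (vectors).
#' @param protein_length Protein length(s) in residues.
#' @return `data.frame` with `centre_norm` and `folded`.
#' @export
position_metrics <- function(start, end, protein_length) {
  stopifnot(all(start >= 1L), all(end >= start), all(end <= protein_length))
  centre_norm <- ((start + end) / 2) / protein_length
  data.frame(centre_norm = centre_norm,
             folded = pmin(centre_norm, 1 - centre_norm))
}

#' Terminal / central / intermediate classification
#'
#' A region is terminal when it starts or ends at no more than `t_cut`
#' residues from either sequence extremity (N-margin `start - 1` or C-margin
#' `L - end` at most `t_cut`), central when both margins are at least `c_cut`,
#' and intermediate in the deliberate buffer zone between the two cut-offs.
#'
#' @inheritParams position_metrics
#' @param t_cut Terminal margin cut-off in residues (default 25).
#' @param c_cut Central margin cut-off in residues (default 50).
#' @return Character vector over `{"terminal", "central", "intermediate"}`.
#' @export
classify_position <- function(start, end, protein_length, t_cut = 25L,
                              c_cut = 50L) {
  stopifnot(all(start >= 1L), all(end >= start), all(end <= protein_length))
  n_margin <- start - 1L
  c_margin <- protein_length - end
  ifelse(n_margin <= t_cut | c_margin <= t_cut, "terminal",
         ifelse(n_margin >= c_cut & c_margin >= c_cut, "central",
                "intermediate"))
}

#' Restrict an annotation to single-LCR proteins
#'
#' The positional and network analyses deal only with proteins containing a
#' single resolved LCR; this drops every protein whose resolved region count
#' differs from one.
#'
#' @param lcrs Resolved region `data.frame` (post [resolve_overlaps()]).
#' @return The rows of proteins carrying exactly one region.
#' @export
single_lcr_filter <- function(lcrs) {
  if (nrow(lcrs) == 0L) return(lcrs)
  cnt <- table(lcrs$protein_id)
  keep <- names(cnt)[cnt == 1L]
  out <- lcrs[lcrs$protein_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate a proteome with non-redundant LCRs
#'
#' Runs detection, overlap resolution, positional metrics and terminal/central
#' classification in one pass.
#'
#' @inheritParams detect_lcrs
#' @param t_cut,c_cut Classification cut-offs, see [classify_position()].
#' @param literal_z See [resolve_overlaps()].
#' @return List with `lcrs` (resolved regions with `protein_length`,
#'   `centre_norm`, `folded`, `pos_class`) and `counts`
#'   (`n_proteins`, `n_with_lcr`, `n_single_lcr`).
#' @export
annotate_proteome <- function(seqs, cal, t_cut = 25L, c_cut = 50L,
                              literal_z = FALSE, skip_ambiguous = FALSE) {
  seqs <- check_proteome(seqs)
  cand <- detect_lcrs(seqs, cal, skip_ambiguous = skip_ambiguous)
  lcrs <- resolve_overlaps(cand, literal_z = literal_z)
  if (nrow(lcrs)) {
    lcrs$protein_length <- nchar(seqs)[lcrs$protein_id]
    pm <- position_metrics(lcrs$start, lcrs$end, lcrs$protein_length)
    lcrs$centre_norm <- pm$centre_norm
    lcrs$folded <- pm$folded
    lcrs$pos_class <- classify_position(lcrs$start, lcrs$end,
                                        lcrs$protein_length, t_cut, c_cut)
  } else {
    lcrs$protein_length <- integer(0)
    lcrs$centre_norm <- lcrs$folded <- numeric(0)
    lcrs$pos_class <- character(0)
  }
  n_per <- table(lcrs$protein_id)
  list(lcrs = lcrs,
       counts = c(n_proteins = length(seqs),
                  n_with_lcr = length(n_per),
                  n_single_lcr = sum(n_per == 1L)))
}

#' Export an LCR table
#'
#' Writes a tab-separated interval file using the 0-based half-open coordinate
#' convention (`start0 = start - 1`, `end_excl = end`); internal coordinates
#' stay 1-based inclusive.
#'
#' @param lcrs Annotated region `data.frame` from [annotate_proteome()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_lcr_table <- function(lcrs, path) {
  out <- data.frame(protein_id = lcrs$protein_id,
                    start0 = lcrs$start - 1L,
                    end_excl = lcrs$end,
                    w = lcrs$w, H = lcrs$H, Z = lcrs$Z,
                    centre_norm = lcrs$centre_norm,
                    folded = lcrs$folded,
                    pos_class = lcrs$pos_class)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
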