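#' Re-insertion null positions for one region
#'
#' Simulates removing a region of length `w` from its protein of length `L`
#' and re-inserting it at a uniformly random admissible start
#' `s in {1, ..., L - w + 1}`, returning the normalised centre position
#' `(2s + w - 1) / (2L)` of each replicate. Sequence content is irrelevant to
#' the position null — only the two lengths matter — so re-insertion is
#' simulated arithmetically.
#'
#' Uses the session RNG: set a seed (or use [null_positions()]' `seed`
#' argument) for reproducibility.
#'
#' @param protein_length Protein length `L` (residues).
#' @param lcr_length Region length `w <= L` (residues).
#' @param n_reps Number of random re-insertions (default 1000).
#' @return Numeric vector of `n_reps` normalised centre positions in (0, 1).
#' @export
reinsertion_null <- function(protein_length, lcr_length, n_reps = 1000L) {
  stopifnot(length(protein_length) == 1L, length(lcr_length) == 1L,
            n_reps >= 1L)
  if (lcr_length > protein_length) {
    stop("region length exceeds protein length")
  }
  s <- sample.int(protein_length - lcr_length + 1L, n_reps, replace = TRUE)
  (2 * s + lcr_length - 1) / (2 * protein_length)
}

#' Pooled re-insertion null over an LCR annotation
#'
#' Draws `n_reps` re-insertion replicates for every region (each region
#' weighted equally) and pools them into one empirical null distribution of
#' normalised centre positions.
#'
#' @param lcrs Annotated region `data.frame` with columns `w` and
#'   `protein_length` (e.g. from [annotate_proteome()]).
#' @param n_reps Replicates per region (default 1000).
#' @param seed Optional integer seed applied via [set.seed()] before drawing.
#' @return Numeric vector of length `n_reps * nrow(lcrs)`.
#' @export
null_positions <- function(lcrs, n_reps = 1000L, seed = NULL) {
  stopifnot(nrow(lcrs) >= 1L)
  if (!is.null(seed)) set.seed(seed)
  unlist(lapply(seq_len(nrow(lcrs)), function(i) {
    reinsertion_null(lcrs$protein_length[i], lcrs$w[i], n_reps)
  }), use.names = FALSE)
}

#' Kolmogorov–Smirnov test of positional bias
#'
#' Two-sample KS test comparing observed region centre positions with the
#' pooled re-insertion null. By default both samples are folded
#' (`min(x, 1 - x)`) so N- and C-terminal distances share one
#' centre-to-extremity scale; `folded = FALSE` compares the raw normalised
#' positions. The asymptotic p-value is used (the pooled null is large and
#' its support is discrete, so the exact tie-free computation does not apply).
#'
#' @param observed Observed normalised centre positions (at least 3).
#' @param null_pos Pooled null of normalised centre positions.
#' @param folded Compare folded positions (default) or unfolded.
#' @return List with `D`, `p`, `n_obs`, `n_null`, `folded`.
#' @export
positional_test <- function(observed, null_pos, folded = TRUE) {
  observed <- observed[!is.na(observed)]
  if (length(observed) < 3L) {
    stop("need at least 3 observed positions for a meaningful KS test")
  }
  if (length(null_pos) == 0L) stop("empty null sample")
  if (folded) {
    observed <- pmin(observed, 1 - observed)
    null_pos <- pmin(null_pos, 1 - null_pos)
  }
  kt <- suppressWarnings(ks.test(observed, null_pos, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value,
       n_obs = length(observed), n_null = length(null_pos), folded = folded)
}
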