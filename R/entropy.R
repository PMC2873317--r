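#' Shannon entropy of a residue window
#'
#' Computes the compositional Shannon entropy \eqn{H = -\sum_a f_a \log_2 f_a}
#' over the distinct symbols present in the window, with \eqn{f_a} the
#' within-window frequency of residue \eqn{a}. Every distinct character counts
#' as its own symbol, so ambiguity codes (X, B, Z, U, *) simply enter the
#' composition.
#'
#' @param window Single residue string (non-empty).
#' @param unit `"bits"` (log base 2, the default) or `"nats"` (natural log).
#' @return Entropy of the window composition; `0 <= H <= log2(n_distinct)`.
#' @examples
#' window_entropy(strrep("A", 16))                    # 0
#' window_entropy(paste0(strrep("A", 8), strrep("L", 8)))  # 1 bit
#' @export
window_entropy <- function(window, unit = c("bits", "nats")) {
  unit <- match.arg(unit)
  if (!is.character(window) || length(window) != 1L || is.na(window) ||
      nchar(window) < 1L) {
    stop("'window' must be a single non-empty string")
  }
  h <- cpp_window_entropy(window)
  if (unit == "nats") h <- h * log(2) else h
}

#' Sliding-window entropies over a proteome
#'
#' Emits the entropy of every window of every length `w` in
#' `[w_min, min(w_max, L)]` at stride 1 for each sequence, computed with
#' incremental count updates (amortised O(L) per window length). Intended for
#' small inputs and cross-checks; [build_calibration()] streams the same scan
#' without materialising a row per window.
#'
#' @param seqs Named character vector of protein sequences (names are IDs).
#' @param w_min,w_max Window length bounds in residues.
#' @param skip_ambiguous If `TRUE`, windows containing characters outside the
#'   20 standard residues are dropped.
#' @return `data.frame` with columns `protein_id`, `start` (1-based), `w`, `H`
#'   (bits). Proteins shorter than `w_min` contribute no rows.
#' @export
scan_entropies <- function(seqs, w_min = 16L, w_max = 300L,
                           skip_ambiguous = FALSE) {
  seqs <- check_proteome(seqs)
  stopifnot(w_min >= 1L, w_min <= w_max)
  alphabet <- if (skip_ambiguous) STD_AA else ""
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    L <- nchar(seqs[[i]])
    if (L < w_min) next
    ws <- seq.int(w_min, min(w_max, L))
    per_w <- lapply(ws, function(w) {
      h <- cpp_sliding_entropy(seqs[[i]], w, alphabet)
      data.frame(start = seq_along(h), w = w, H = h)
    })
    df <- do.call(rbind, per_w)
    df <- cbind(protein_id = names(seqs)[i], df)
    out[[i]] <- df
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(protein_id = character(), start = integer(),
                      w = integer(), H = numeric())
  }
  if (skip_ambiguous) res <- res[!is.na(res$H), , drop = FALSE]
  rownames(res) <- NULL
  res
}

STD_AA <- "ACDEFGHIKLMNPQRSTVWY"

check_proteome <- function(seqs) {
  if (inherits(seqs, "AAStringSet")) seqs <- as.character(seqs)
  if (!is.character(seqs) || length(seqs) == 0L) {
    stop("'seqs' must be a non-empty named character vector or AAStringSet")
  }
  if (is.null(names(seqs)) || any(names(seqs) == "") || anyDuplicated(names(seqs))) {
    stop("sequences must carry non-empty, unique names")
  }
  if (any(nchar(seqs) < 1L)) stop("zero-length sequence in proteome")
  seqs
}

#' Calibrate per-window-length low-complexity thresholds
#'
#' Scans the corpus at every window length `w` in `[w_min, w_max]`, and for
#' each `w` records the window count `n`, mean `mu` and standard deviation
#' `sigma` of the empirical entropy distribution, and the low-complexity
#' threshold `t`: the lower `alpha`-quantile taken as an order statistic
#' (`sort(H)[ceiling(alpha * n)]`), so `t` is always an observed entropy value
#' and the fraction of calibration windows with `H < t` never exceeds `alpha`.
#' A window is later called low-complexity when its entropy falls strictly
#' below `t` for its length.
#'
#' The calibration corpus defaults to the proteome under study; tables are
#' serialisable ([write_calibration()]) so a table built on a larger corpus
#' can be reused.
#'
#' @inheritParams scan_entropies
#' @param alpha Tail mass held below the threshold (fraction in (0, 0.5);
#'   default 0.005, i.e. 0.5%).
#' @return An object of class `lcr_calibration`: a `data.frame` with columns
#'   `w`, `n`, `mu`, `sigma`, `t` and attributes `alpha`, `w_min`, `w_max`.
#'   Window lengths with no windows in the corpus get `n = 0` and `NA`
#'   statistics (detection at those lengths is disabled, with a warning).
#' @export
build_calibration <- function(seqs, w_min = 16L, w_max = 300L, alpha = 0.005,
                              skip_ambiguous = FALSE) {
  seqs <- check_proteome(seqs)
  stopifnot(w_min >= 1L, w_min <= w_max, alpha > 0, alpha < 0.5)
  alphabet <- if (skip_ambiguous) STD_AA else ""
  ws <- seq.int(w_min, w_max)
  n <- integer(length(ws))
  mu <- sigma <- tt <- rep(NA_real_, length(ws))
  for (i in seq_along(ws)) {
    h <- cpp_entropies_for_w(seqs, ws[i], alphabet)
    h <- h[!is.na(h)]
    n[i] <- length(h)
    if (n[i] == 0L) next
    mu[i] <- mean(h)
    sigma[i] <- if (n[i] > 1L) sd(h) else 0
    k <- max(1L, as.integer(ceiling(alpha * n[i])))
    tt[i] <- sort(h, partial = k)[k]
  }
  if (any(n == 0L)) {
    warning(sum(n == 0L), " window length(s) had no windows in the corpus; ",
            "detection at those lengths is disabled")
  }
  cal <- data.frame(w = ws, n = n, mu = mu, sigma = sigma, t = tt)
  attr(cal, "alpha") <- alpha
  attr(cal, "w_min") <- as.integer(w_min)
  attr(cal, "w_max") <- as.integer(w_max)
  class(cal) <- c("lcr_calibration", "data.frame")
  cal
}

#' Standardised entropy score
#'
#' `Z = (H - mu_w) / sigma_w`, standardising window entropies against the
#' calibration distribution of the matching window length so candidate regions
#' of different lengths are comparable.
#'
#' @param cal An `lcr_calibration` table.
#' @param w Window length(s); must be calibrated (`n > 0`, `sigma > 0`).
#' @param H Entropy value(s) in bits, recycled against `w`.
#' @return Numeric vector of Z-scores.
#' @export
zscore <- function(cal, w, H) {
  stopifnot(inherits(cal, "lcr_calibration"))
  idx <- match(w, cal$w)
  if (anyNA(idx) || any(cal$n[idx] == 0L) || anyNA(cal$sigma[idx])) {
    stop("uncalibrated window length(s): ",
         paste(unique(w[is.na(idx) | cal$n[idx] == 0L]), collapse = ", "))
  }
  if (any(cal$sigma[idx] == 0)) {
    stop("degenerate calibration (sigma = 0) for window length(s): ",
         paste(unique(w[cal$sigma[idx] == 0]), collapse = ", "))
  }
  (H - cal$mu[idx]) / cal$sigma[idx]
}

#' Write / read a calibration table
#'
#' The table is stored as TSV (columns `w`, `n`, `mu`, `sigma`, `t`) with a
#' JSON sidecar `<path>.json` carrying `alpha` and the window-length bounds.
#'
#' @param cal An `lcr_calibration` object.
#' @param path TSV file path.
#' @return `write_calibration()` returns `path` invisibly; `read_calibration()`
#'   returns the `lcr_calibration` object.
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "lcr_calibration"))
  write.table(as.data.frame(cal), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  meta <- list(alpha = attr(cal, "alpha"), w_min = attr(cal, "w_min"),
               w_max = attr(cal, "w_max"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  cal <- read.delim(path)
  stopifnot(all(c("w", "n", "mu", "sigma", "t") %in% names(cal)))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  attr(cal, "alpha") <- meta$alpha
  attr(cal, "w_min") <- as.integer(meta$w_min)
  attr(cal, "w_max") <- as.integer(meta$w_max)
  class(cal) <- c("lcr_calibration", "data.frame")
  cal
}

#' Read a protein FASTA file
#'
#' @param path FASTA file (wrapped or unwrapped). The record ID is the header
#'   up to the first whitespace.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  seqs <- as.character(x)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  check_proteome(seqs)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- check_proteome(seqs)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}
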