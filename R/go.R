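#' Read a gene–GO-term annotation table
#'
#' Supports a minimal two/three-column TSV (`gene`, `term`, optional `branch`)
#' and GAF 2.x. GAF rows carrying the `NOT` qualifier are dropped, duplicate
#' gene–term pairs are collapsed, and the GAF aspect column supplies the
#' ontology branch (P/F/C).
#'
#' @param path Annotation file.
#' @param format `"tsv"` or `"gaf"`.
#' @return `data.frame` with columns `gene`, `term`, `branch` (one row per
#'   distinct gene–term pair). For TSV input without a branch column, branch
#'   is `"P"`.
#' @export
read_annotations <- function(path, format = c("tsv", "gaf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    ann <- read.delim(path, stringsAsFactors = FALSE)
    if (ncol(ann) < 2L) stop("annotation TSV needs at least gene and term columns")
    names(ann)[1:2] <- c("gene", "term")
    if (ncol(ann) >= 3L) names(ann)[3L] <- "branch" else ann$branch <- "P"
    ann <- ann[, c("gene", "term", "branch")]
  } else {
    raw <- read.delim(path, header = FALSE, comment.char = "!",
                      stringsAsFactors = FALSE)
    if (ncol(raw) < 9L) stop("not a GAF 2.x file: fewer than 9 columns")
    not <- grepl("(^|\\|)NOT($|\\|)", raw[[4L]])
    ann <- data.frame(gene = raw[[3L]], term = raw[[5L]], branch = raw[[9L]],
                      stringsAsFactors = FALSE)[!not, ]
  }
  ann <- ann[!is.na(ann$gene) & !is.na(ann$term) & ann$gene != "" & ann$term != "", ]
  ann <- ann[!duplicated(ann[, c("gene", "term")]), ]
  if (nrow(ann) == 0L) stop("no annotations read")
  rownames(ann) <- NULL
  ann
}

#' One-sided Fisher over-representation p-values
#'
#' For each annotated term, tests over-representation of the term in the study
#' set against the background using the hypergeometric upper tail
#' `p = P(X >= k)` with `X ~ Hypergeometric(N, K, n)`, where `k`/`K` are study
#' and background counts of genes carrying the term and `n`/`N` the study and
#' background sizes. Terms absent from the study set (`k = 0`) are reported
#' with `p = 1`.
#'
#' @param study Character vector of study gene identifiers (must be a subset
#'   of `background`).
#' @param background Character vector of background gene identifiers.
#' @param annotations Annotation `data.frame` from [read_annotations()]
#'   (columns `gene`, `term`, `branch`). Annotations of genes outside the
#'   background are ignored.
#' @return `data.frame` with one row per term: `term`, `branch`, `k`, `n`,
#'   `K`, `N`, `p`.
#' @export
fisher_enrichment <- function(study, background, annotations) {
  study <- unique(study)
  background <- unique(background)
  if (length(study) == 0L) stop("empty study set")
  bad <- setdiff(study, background)
  if (length(bad)) {
    stop("study genes missing from background: ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ...")
  }
  ann <- annotations[annotations$gene %in% background, , drop = FALSE]
  if (nrow(ann) == 0L) stop("no annotations overlap the background")
  terms <- unique(ann[, c("term", "branch")])
  N <- length(background)
  n <- length(study)
  K <- as.integer(table(ann$term)[terms$term])
  in_study <- ann$gene %in% study
  k_tab <- table(ann$term[in_study])
  k <- as.integer(k_tab[terms$term])
  k[is.na(k)] <- 0L
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  data.frame(term = terms$term, branch = terms$branch,
             k = k, n = n, K = K, N = N, p = p, row.names = NULL)
}

#' Benjamini–Hochberg q-values
#'
#' Step-up FDR adjustment `q_(i) = min_(j >= i) p_(j) * m / j`, capped at 1,
#' with input order preserved. A thin wrapper over [stats::p.adjust()] kept so
#' the adjustment used throughout the enrichment reports is a single,
#' documented choice.
#'
#' @param p Vector of p-values in (0, 1].
#' @return Vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p > 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' GO-term over-representation with FDR control
#'
#' Runs [fisher_enrichment()] and adds BH q-values. By default the correction
#' is applied within each ontology branch separately (`per_branch = TRUE`);
#' `per_branch = FALSE` pools all terms into one correction.
#'
#' @inheritParams fisher_enrichment
#' @param per_branch Apply BH within each ontology branch (default) or pooled.
#' @return The [fisher_enrichment()] table with a `q` column appended.
#' @export
go_enrichment <- function(study, background, annotations, per_branch = TRUE) {
  rows <- fisher_enrichment(study, background, annotations)
  if (per_branch) {
    rows$q <- NA_real_
    for (b in unique(rows$branch)) {
      sel <- rows$branch == b
      rows$q[sel] <- bh_adjust(rows$p[sel])
    }
  } else {
    rows$q <- bh_adjust(rows$p)
  }
  rows
}

#' Filter and sort an enrichment table
#'
#' Keeps rows with `q < q_threshold`, sorted by branch then p-value — the
#' layout of a standard over-representation report (counts, background counts,
#' p, q, branch, term).
#'
#' @param rows Output of [go_enrichment()].
#' @param q_threshold FDR threshold (default 0.1).
#' @return The filtered, sorted `data.frame`.
#' @export
enrichment_report <- function(rows, q_threshold = 0.1) {
  out <- rows[rows$q < q_threshold, , drop = FALSE]
  out <- out[order(out$branch, out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
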