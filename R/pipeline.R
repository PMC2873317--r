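#' Run the full LCR analysis pipeline
#'
#' Orchestrates calibration, detection, overlap resolution, the single-LCR
#' restriction, positional classification, the re-insertion positional test,
#' per-network degree analyses, and GO enrichment, returning one
#' machine-readable report. Every statistic in the report is computed by the
#' corresponding exported function.
#'
#' @param seqs Named character vector of protein sequences (or an
#'   `AAStringSet`).
#' @param networks Named list of [igraph::graph]s, or of edge `data.frame`s
#'   (converted via [network_from_edges()]); one set of degree analyses is
#'   reported per network.
#' @param annotations Optional annotation `data.frame` (`gene`, `term`,
#'   `branch`); `NULL` skips enrichment.
#' @param cal Optional pre-built `lcr_calibration`; by default the input
#'   proteome calibrates itself.
#' @param w_min,w_max,alpha Calibration parameters (see [build_calibration()]).
#' @param t_cut,c_cut Terminal/central cut-offs in residues.
#' @param n_reps Re-insertions per region for the positional null.
#' @param q_threshold FDR threshold of the enrichment reports.
#' @param seed Seed for the re-insertion null.
#' @param folded Run the KS test on folded positions (default).
#' @param literal_z See [resolve_overlaps()].
#' @return A list report: `counts`, `positional` (KS D/p and sample sizes),
#'   `networks` (per network: group degree comparisons, per-subset
#'   length–degree regressions, LCR enrichment value), `enrichment` (per
#'   subset: full table and thresholded report), `lcrs` (the single-LCR
#'   annotation), `params`.
#' @export
run_lcr_pipeline <- function(seqs, networks = list(), annotations = NULL,
                             cal = NULL, w_min = 16L, w_max = 120L,
                             alpha = 0.005, t_cut = 25L, c_cut = 50L,
                             n_reps = 1000L, q_threshold = 0.1, seed = 1L,
                             folded = TRUE, literal_z = FALSE) {
  seqs <- check_proteome(seqs)
  if (is.null(cal)) {
    cal <- build_calibration(seqs, w_min = w_min, w_max = w_max, alpha = alpha)
  }
  ann <- annotate_proteome(seqs, cal, t_cut = t_cut, c_cut = c_cut,
                           literal_z = literal_z)
  single <- single_lcr_filter(ann$lcrs)
  counts <- c(ann$counts, n_terminal = sum(single$pos_class == "terminal"),
              n_central = sum(single$pos_class == "central"),
              n_intermediate = sum(single$pos_class == "intermediate"))

  positional <- NULL
  if (nrow(single) >= 3L) {
    nullp <- null_positions(single, n_reps = n_reps, seed = seed)
    positional <- positional_test(single$centre_norm, nullp, folded = folded)
    positional$n_reps <- n_reps
    positional$seed <- seed
  }

  proteome_ids <- names(seqs)
  lcr_ids <- unique(ann$lcrs$protein_id)
  single_ids <- single$protein_id
  term_ids <- single$protein_id[single$pos_class == "terminal"]
  cent_ids <- single$protein_id[single$pos_class == "central"]
  non_lcr_ids <- setdiff(proteome_ids, lcr_ids)

  net_reports <- list()
  for (nm in names(networks)) {
    g <- networks[[nm]]
    if (!inherits(g, "igraph")) g <- network_from_edges(g, name = nm)
    deg <- network_degrees(g)
    cmp <- function(a, b, la, lb) {
      tryCatch(compare_degrees(g, a, b, labels = c(la, lb)),
               error = function(e) list(error = conditionMessage(e)))
    }
    reg <- function(ids, label) {
      sub <- single[single$protein_id %in% ids & single$protein_id %in% names(deg), ]
      if (nrow(sub) < 3L) return(list(label = label, error = "fewer than 3 points"))
      length_degree_regression(sub$w, deg[sub$protein_id], label = label)
    }
    net_reports[[nm]] <- list(
      n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g),
      lcr_vs_nonlcr = cmp(single_ids, non_lcr_ids, "single_lcr", "non_lcr"),
      terminal_vs_central = cmp(term_ids, cent_ids, "terminal", "central"),
      terminal_vs_nonlcr = cmp(term_ids, non_lcr_ids, "terminal", "non_lcr"),
      central_vs_nonlcr = cmp(cent_ids, non_lcr_ids, "central", "non_lcr"),
      regression_terminal = reg(term_ids, "terminal"),
      regression_central = reg(cent_ids, "central"),
      lcr_enrichment = tryCatch(
        network_lcr_enrichment(g, lcr_ids, proteome_ids),
        error = function(e) NA_real_, warning = function(w) {
          suppressWarnings(network_lcr_enrichment(g, lcr_ids, proteome_ids))
        }))
  }

  enr <- NULL
  if (!is.null(annotations)) {
    run_enr <- function(ids) {
      if (length(ids) == 0L) return(NULL)
      rows <- go_enrichment(ids, proteome_ids, annotations)
      list(table = rows, report = enrichment_report(rows, q_threshold))
    }
    enr <- list(all_lcr = run_enr(single_ids),
                terminal = run_enr(term_ids),
                central = run_enr(cent_ids))
  }

  list(counts = counts, positional = positional, networks = net_reports,
       enrichment = enr, lcrs = single,
       params = list(w_min = w_min, w_max = w_max, alpha = alpha,
                     t_cut = t_cut, c_cut = c_cut, n_reps = n_reps,
                     q_threshold = q_threshold, seed = seed, folded = folded,
                     literal_z = literal_z))
}
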