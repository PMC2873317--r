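AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Yeast-like amino-acid background frequencies
#'
#' Rounded S. cerevisiae proteome composition, for generating backgrounds more
#' realistic than the uniform default.
#'
#' @return Named numeric vector over the 20 standard residues, summing to 1.
#' @export
yeast_aa_freqs <- function() {
  f <- c(A = 0.055, C = 0.013, D = 0.058, E = 0.065, F = 0.045, G = 0.050,
         H = 0.022, I = 0.066, K = 0.073, L = 0.096, M = 0.021, N = 0.061,
         P = 0.044, Q = 0.039, R = 0.044, S = 0.090, T = 0.059, V = 0.056,
         W = 0.010, Y = 0.034)
  f / sum(f)
}

#' Synthetic study configuration
#'
#' Defines the data regime the synthetic benchmark emulates: a proteome with
#' compositionally biased segments planted with a positional bias towards the
#' sequence extremities, a network whose degrees are elevated for LCR proteins
#' and coupled to LCR length only for terminal LCRs, and annotations with one
#' planted term per positional subset.
#'
#' Defaults are the study conditions used throughout the package's validation:
#' 1300 proteins of 150–600 residues, 35% carrying one planted LCR of 20–90
#' residues built from 2 dominant residues holding 95% of the composition,
#' terminal placement probability 0.7 within a 25-residue margin; network
#' degrees with a gamma baseline (mean 5, shape 8), +3 expected interactions
#' for any LCR protein and +0.05 interactions per residue of terminal LCR
#' length; 20 GO terms per branch at base rate 0.05 with planted odds ratio 8.
#' The LCR fraction sits a little above the ~21% seen for yeast so the
#' positional subsets stay large enough for the network contrasts at this
#' proteome size; keeping planted windows a small share of all scanned windows
#' is what lets the self-calibrated 0.5% tail recover whole planted segments.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Protein length bounds (residues), uniform law.
#' @param background_freqs Residue frequencies (named over the 20 standard
#'   residues); `NULL` = uniform.
#' @param fraction_with_lcr Fraction of proteins receiving one planted LCR.
#' @param lcr_length_range Planted LCR length bounds (residues), uniform law.
#' @param n_dominant Number of dominant residues per planted segment (1–3).
#' @param dominant_mass Total composition mass shared by the dominant residues.
#' @param p_terminal Probability a planted LCR is placed terminally (otherwise
#'   its start is uniform over all admissible starts).
#' @param terminal_margin Margin (residues) within which terminal placements
#'   start or end.
#' @param degree_baseline_mean,degree_baseline_shape Gamma law of the baseline
#'   expected degree.
#' @param degree_lcr_boost Constant expected-degree increment for any LCR
#'   protein.
#' @param degree_boost_terminal Expected-degree increment per residue of
#'   terminal LCR length (interactions/aa).
#' @param degree_boost_central Same for central LCRs (default 0: no planted
#'   length–degree coupling for central regions).
#' @param n_terms_per_branch GO terms per ontology branch (P, F, C).
#' @param annotation_base_rate Probability a gene carries any given background
#'   term.
#' @param planted_term_odds Odds multiplier for the planted term within its
#'   target subset (1 = no enrichment).
#' @param seed Mandatory integer seed (< 2^31 - 16; offsets are derived for
#'   the bundle stages).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_proteins = 1300L,
                             length_range = c(150L, 600L),
                             background_freqs = NULL,
                             fraction_with_lcr = 0.35,
                             lcr_length_range = c(20L, 90L),
                             n_dominant = 2L,
                             dominant_mass = 0.95,
                             p_terminal = 0.7,
                             terminal_margin = 25L,
                             degree_baseline_mean = 5,
                             degree_baseline_shape = 8,
                             degree_lcr_boost = 3,
                             degree_boost_terminal = 0.05,
                             degree_boost_central = 0,
                             n_terms_per_branch = 20L,
                             annotation_base_rate = 0.05,
                             planted_term_odds = 8,
                             seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  stopifnot(seed == as.integer(seed), seed < 2^31 - 16, seed >= 0,
            fraction_with_lcr >= 0, fraction_with_lcr <= 1,
            p_terminal >= 0, p_terminal <= 1,
            dominant_mass > 0, dominant_mass <= 1,
            n_dominant >= 1L, n_dominant <= 3L,
            lcr_length_range[2L] < length_range[1L],
            annotation_base_rate > 0, annotation_base_rate < 1,
            planted_term_odds >= 1)
  if (is.null(background_freqs)) {
    background_freqs <- stats::setNames(rep(1 / 20, 20), AA20)
  }
  stopifnot(abs(sum(background_freqs) - 1) < 1e-8)
  cfg <- as.list(environment())
  class(cfg) <- "synthetic_config"
  cfg
}

sample_seq <- function(n, freqs) {
  paste(sample(names(freqs), n, replace = TRUE, prob = freqs), collapse = "")
}

#' Generate a synthetic proteome with planted LCRs
#'
#' Background residues are drawn i.i.d. from the configured frequencies;
#' planted LCRs are contiguous segments drawn from a biased composition
#' (`n_dominant` residues sharing `dominant_mass`), placed within
#' `terminal_margin` of a randomly chosen extremity with probability
#' `p_terminal` and uniformly over admissible starts otherwise. Deterministic
#' given the seed.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed (default `config$seed`).
#' @param sequences If `FALSE`, only the ground truth is generated (lengths,
#'   planted coordinates and classes) — enough for simulation studies of the
#'   statistical stages that never touch residues. The RNG stream is shared
#'   with the `sequences = TRUE` path, so truth tables match.
#' @return List with `seqs` (named character vector, or `NULL`) and `truth`:
#'   a `data.frame` with one row per protein (`protein_id`, `length`,
#'   `lcr_start`, `lcr_end`, `lcr_length`, `placement`, `pos_class`,
#'   `dominant`), `NA` fields for proteins without a planted LCR.
#' @export
generate_proteome <- function(config, seed = config$seed, sequences = TRUE) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  n <- config$n_proteins
  ids <- sprintf("P%04d", seq_len(n))
  L <- sample.int(config$length_range[2L] - config$length_range[1L] + 1L, n,
                  replace = TRUE) + config$length_range[1L] - 1L
  has <- runif(n) < config$fraction_with_lcr
  len <- start <- rep(NA_integer_, n)
  placement <- rep(NA_character_, n)
  dominant <- rep(NA_character_, n)
  rng <- config$lcr_length_range
  margin <- config$terminal_margin
  for (i in which(has)) {
    li <- sample.int(rng[2L] - rng[1L] + 1L, 1L) + rng[1L] - 1L
    while (li >= L[i]) {  # infeasible placement: resample length
      li <- sample.int(rng[2L] - rng[1L] + 1L, 1L) + rng[1L] - 1L
    }
    len[i] <- li
    if (runif(1) < config$p_terminal) {
      placement[i] <- "terminal"
      if (runif(1) < 0.5) {               # N-terminal: start within margin
        start[i] <- sample.int(min(margin + 1L, L[i] - li + 1L), 1L)
      } else {                            # C-terminal: end within margin
        end_i <- L[i] - sample.int(min(margin + 1L, L[i] - li + 1L), 1L) + 1L
        start[i] <- end_i - li + 1L
      }
    } else {
      placement[i] <- "uniform"
      start[i] <- sample.int(L[i] - li + 1L, 1L)
    }
    dominant[i] <- paste(sample(AA20, config$n_dominant), collapse = "")
  }
  end <- start + len - 1L
  pos_class <- rep(NA_character_, n)
  pos_class[has] <- classify_position(start[has], end[has], L[has])
  truth <- data.frame(protein_id = ids, length = L,
                      lcr_start = start, lcr_end = end, lcr_length = len,
                      placement = placement, pos_class = pos_class,
                      dominant = dominant, stringsAsFactors = FALSE)
  seqs <- NULL
  if (sequences) {
    seqs <- character(n)
    for (i in seq_len(n)) {
      s <- sample_seq(L[i], config$background_freqs)
      if (has[i]) {
        dom <- strsplit(dominant[i], "")[[1]]
        pr <- rep((1 - config$dominant_mass) / (20 - length(dom)), 20)
        names(pr) <- AA20
        pr[dom] <- config$dominant_mass / length(dom)
        seg <- sample_seq(len[i], pr)
        substr(s, start[i], end[i]) <- seg
      }
      seqs[i] <- s
    }
    names(seqs) <- ids
  }
  list(seqs = seqs, truth = truth)
}

#' Generate a degree-structured synthetic PPI network
#'
#' Each protein's expected degree is `baseline + lcr_boost * has_lcr +
#' boost_t * terminal_LCR_length + boost_c * central_LCR_length`, with a gamma
#' baseline. Edges are realised by an expected-degree (Chung–Lu style)
#' Bernoulli pairing `P(i~j) = min(1, w_i w_j / sum(w))`, giving no self-loops
#' or duplicates. Deterministic given the seed.
#'
#' @param truth Proteome ground truth from [generate_proteome()].
#' @param config A [synthetic_config()].
#' @param seed Integer seed (default `config$seed + 1`).
#' @return List with `edges` (`data.frame`: `protein_a`, `protein_b`, `type`)
#'   and `expected_degree` (named numeric vector, the planted degree drivers).
#' @export
generate_network <- function(truth, config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  n <- nrow(truth)
  base <- rgamma(n, shape = config$degree_baseline_shape,
                 scale = config$degree_baseline_mean / config$degree_baseline_shape)
  has <- !is.na(truth$lcr_start)
  wts <- base + config$degree_lcr_boost * has
  term <- has & truth$pos_class == "terminal"
  cent <- has & truth$pos_class == "central"
  wts[term] <- wts[term] + config$degree_boost_terminal * truth$lcr_length[term]
  wts[cent] <- wts[cent] + config$degree_boost_central * truth$lcr_length[cent]
  S <- sum(wts)
  if (mean(wts) >= n - 1) stop("requested mean degree incompatible with node count")
  pm <- outer(wts, wts) / S
  ut <- upper.tri(pm)
  pr <- pmin(pm[ut], 1)
  if (mean(pm[ut] > 1) > 0.01) {
    warning("over 1% of pair probabilities truncated at 1; ",
            "expected degrees will be deflated")
  }
  hit <- runif(length(pr)) < pr
  ii <- row(pm)[ut][hit]
  jj <- col(pm)[ut][hit]
  edges <- data.frame(protein_a = truth$protein_id[ii],
                      protein_b = truth$protein_id[jj],
                      type = "physical", stringsAsFactors = FALSE)
  list(edges = edges,
       expected_degree = stats::setNames(wts, truth$protein_id))
}

#' Generate synthetic gene–term annotations with planted enrichments
#'
#' Every term is assigned to every gene at the base rate; in addition, one
#' planted term per positional subset (terminal, central) is assigned to its
#' target subset at odds multiplied by `planted_term_odds`. Branch labels are
#' assigned round-robin over P, F, C. Deterministic given the seed.
#'
#' @inheritParams generate_network
#' @param seed Integer seed (default `config$seed + 2`).
#' @return List with `annotations` (`data.frame`: `gene`, `term`, `branch`)
#'   and `planted_terms` (`data.frame`: `term`, `branch`, `target`, `odds`).
#' @export
generate_annotations <- function(truth, config, seed = config$seed + 2L) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  branches <- c("P", "F", "C")
  terms <- data.frame(
    term = sprintf("T%s%02d", rep(branches, each = config$n_terms_per_branch),
                   seq_len(config$n_terms_per_branch)),
    branch = rep(branches, each = config$n_terms_per_branch),
    stringsAsFactors = FALSE)
  base <- config$annotation_base_rate
  odds <- config$planted_term_odds
  p_boost <- (odds * base / (1 - base)) / (1 + odds * base / (1 - base))
  planted <- data.frame(term = c("TP01", "TP02"), branch = "P",
                        target = c("terminal", "central"), odds = odds,
                        stringsAsFactors = FALSE)
  genes <- truth$protein_id
  has <- !is.na(truth$lcr_start)
  subset_of <- function(cls) genes[has & truth$pos_class == cls]
  out <- vector("list", nrow(terms))
  for (t in seq_len(nrow(terms))) {
    p <- rep(base, length(genes))
    pi <- match(terms$term[t], planted$term)
    if (!is.na(pi)) {
      p[genes %in% subset_of(planted$target[pi])] <- p_boost
    }
    hit <- runif(length(genes)) < p
    if (any(hit)) {
      out[[t]] <- data.frame(gene = genes[hit], term = terms$term[t],
                             branch = terms$branch[t], stringsAsFactors = FALSE)
    }
  }
  list(annotations = do.call(rbind, out), planted_terms = planted)
}

#' Generate a full synthetic study bundle
#'
#' Proteome, two networks (a dense full network plus a sparser
#' "high-confidence-like" subnetwork retaining each edge with probability
#' `hc_keep`, mirroring cross-dataset validation), annotations, and the ground
#' truth. Byte-identical outputs for identical config + seed.
#'
#' @param config A [synthetic_config()].
#' @param hc_keep Edge retention probability of the subsampled network.
#' @param sequences Generate residue sequences (see [generate_proteome()]).
#' @return List with `seqs`, `truth`, `networks` (named list of edge
#'   `data.frame`s), `expected_degree`, `annotations`, `planted_terms`,
#'   `config`.
#' @export
generate_bundle <- function(config, hc_keep = 0.35, sequences = TRUE) {
  prot <- generate_proteome(config, sequences = sequences)
  net <- generate_network(prot$truth, config)
  ann <- generate_annotations(prot$truth, config)
  set.seed(config$seed + 3L)
  keep <- runif(nrow(net$edges)) < hc_keep
  networks <- list(full = net$edges,
                   highconf = net$edges[keep, , drop = FALSE])
  list(seqs = prot$seqs, truth = prot$truth, networks = networks,
       expected_degree = net$expected_degree,
       annotations = ann$annotations, planted_terms = ann$planted_terms,
       config = config)
}

#' Write a synthetic bundle to disk
#'
#' Emits standard plain-text formats: `proteome.fasta`, one
#' `network_<name>.tsv` per network (3 columns: ids and type = "physical"),
#' `annotations.tsv`, and `truth.json`.
#'
#' @param bundle Output of [generate_bundle()] (with sequences).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(bundle$seqs, file.path(dir, "proteome.fasta"))
  for (nm in names(bundle$networks)) {
    write.table(bundle$networks[[nm]],
                file.path(dir, paste0("network_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(bundle$annotations, file.path(dir, "annotations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(truth = bundle$truth,
                            planted_terms = bundle$planted_terms,
                            seed = bundle$config$seed),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(dir)
}
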