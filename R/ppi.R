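#' Build an undirected PPI network from an edge table
#'
#' Symmetrises, removes self-loops and duplicate edges, and (optionally) keeps
#' only physical interactions according to a type column.
#'
#' @param edges `data.frame` whose first two columns are protein identifiers;
#'   an optional type column marks the interaction class.
#' @param physical_only Keep only rows whose type is in `physical_types`.
#' @param physical_types Whitelist of interaction-type labels treated as
#'   physical (default `"physical"`, the BioGrid experimental-system-type
#'   label).
#' @param type_col Name or index of the type column (default: third column if
#'   present).
#' @param name Network label carried into reports.
#' @param synonyms Optional two-column `data.frame` (alias, canonical id)
#'   applied to both identifier columns before deduplication; identifiers
#'   without a synonym are kept as-is (a message reports how many matched).
#' @return An undirected, simple [igraph::graph] with vertex names.
#' @export
network_from_edges <- function(edges, physical_only = FALSE,
                               physical_types = "physical",
                               type_col = NULL, name = "network",
                               synonyms = NULL) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 2L)
  a <- as.character(edges[[1L]])
  b <- as.character(edges[[2L]])
  if (!is.null(synonyms)) {
    stopifnot(is.data.frame(synonyms), ncol(synonyms) >= 2L)
    map <- stats::setNames(as.character(synonyms[[2L]]),
                           as.character(synonyms[[1L]]))
    hit_a <- a %in% names(map); hit_b <- b %in% names(map)
    a[hit_a] <- unname(map[a[hit_a]])
    b[hit_b] <- unname(map[b[hit_b]])
    message(sum(hit_a) + sum(hit_b), " endpoint(s) renamed via synonym map, ",
            sum(!hit_a) + sum(!hit_b), " left unchanged")
  }
  keep <- !is.na(a) & !is.na(b) & a != "" & b != ""
  if (sum(!keep)) message(sum(!keep), " malformed edge row(s) skipped")
  if (physical_only) {
    if (is.null(type_col)) {
      if (ncol(edges) < 3L) stop("physical_only requires an interaction-type column")
      type_col <- 3L
    }
    ty <- as.character(edges[[type_col]])
    phys <- keep & ty %in% physical_types
    message(sum(keep & !phys), " non-physical edge row(s) dropped, ",
            sum(phys), " kept")
    keep <- phys
  }
  a <- a[keep]; b <- b[keep]
  sel <- a != b            # self-loops out
  a <- a[sel]; b <- b[sel]
  if (length(a) == 0L) stop("no edges left after filtering")
  lo <- pmin(a, b); hi <- pmax(a, b)
  dup <- duplicated(data.frame(lo, hi))
  lo <- lo[!dup]; hi <- hi[!dup]
  g <- igraph::graph_from_data_frame(data.frame(from = lo, to = hi),
                                     directed = FALSE)
  g$name <- name
  g
}

#' Read a tab-delimited PPI edge list
#'
#' Minimal two-column TSV, optionally with an interaction-type column
#' (BioGrid-tab-like layouts are supported by pointing `id_cols`/`type_col`
#' at the right positions).
#'
#' @param path Edge-list TSV path.
#' @param id_cols Indices of the two identifier columns (default 1:2).
#' @param header Does the file carry a header row?
#' @inheritParams network_from_edges
#' @return An undirected simple [igraph::graph].
#' @export
read_network <- function(path, physical_only = FALSE,
                         physical_types = "physical", id_cols = 1:2,
                         type_col = NULL, header = TRUE,
                         name = basename(path), synonyms = NULL) {
  raw <- read.delim(path, header = header, stringsAsFactors = FALSE)
  other <- setdiff(seq_len(ncol(raw)), id_cols)
  df <- raw[, c(id_cols, other), drop = FALSE]
  if (!is.null(type_col)) {
    type_col <- match(if (is.character(type_col)) match(type_col, names(raw))
                      else type_col, c(id_cols, other))
  }
  network_from_edges(df, physical_only = physical_only,
                     physical_types = physical_types, type_col = type_col,
                     name = name, synonyms = synonyms)
}

#' Node degrees of a network
#'
#' @param network An [igraph::graph] with vertex names.
#' @return Named integer vector of degrees.
#' @export
network_degrees <- function(network) {
  d <- igraph::degree(network)
  stats::setNames(as.integer(d), igraph::V(network)$name)
}

#' Compare degree distributions of two protein groups
#'
#' Wilcoxon–Mann–Whitney test on the degrees of the two groups' members that
#' are present in the network (proteins absent from the network are excluded,
#' not assigned degree 0). The exact null distribution is used when both
#' groups have at most 50 members in the network and there are no ties;
#' otherwise the tie-corrected normal approximation.
#'
#' @param network An [igraph::graph].
#' @param group_a,group_b Disjoint character vectors of protein identifiers.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#'   (relative to `group_a`).
#' @param labels Length-2 labels for the report.
#' @return List with `labels`, `n` (per-group sizes in the network), `U`,
#'   `p`, `alternative`.
#' @export
compare_degrees <- function(network, group_a, group_b,
                            alternative = c("two.sided", "greater", "less"),
                            labels = c("group_a", "group_b")) {
  alternative <- match.arg(alternative)
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  deg <- network_degrees(network)
  da <- deg[names(deg) %in% group_a]
  db <- deg[names(deg) %in% group_b]
  if (length(da) == 0L) stop("no members of '", labels[1], "' in the network")
  if (length(db) == 0L) stop("no members of '", labels[2], "' in the network")
  ties <- anyDuplicated(c(da, db)) > 0L
  exact <- length(da) <= 50L && length(db) <= 50L && !ties
  wt <- suppressWarnings(wilcox.test(da, db, alternative = alternative,
                                     exact = exact, correct = !exact))
  list(labels = labels, n = c(length(da), length(db)),
       U = unname(wt$statistic), p = wt$p.value, alternative = alternative)
}

#' LCR length versus protein degree regression
#'
#' Ordinary least squares of network degree on LCR length for one positional
#' subset, as used to contrast terminal and central regions.
#'
#' @param lengths Region lengths (residues).
#' @param degrees Matching protein degrees.
#' @param label Subset label for the report.
#' @return List with `label`, `n`, `slope` (interactions per residue),
#'   `intercept`, `r2`, `p` (two-sided slope p-value).
#' @export
length_degree_regression <- function(lengths, degrees, label = "subset") {
  ok <- complete.cases(lengths, degrees)
  lengths <- lengths[ok]; degrees <- degrees[ok]
  if (length(lengths) < 3L) stop("need at least 3 points for a regression")
  if (stats::var(lengths) == 0) stop("zero variance in region lengths")
  fit <- lm(degrees ~ lengths)
  sm <- summary(fit)
  list(label = label, n = length(lengths),
       slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       slope_se = sm$coefficients[2L, 2L],
       r2 = sm$r.squared, p = sm$coefficients[2L, 4L])
}

#' LCR enrichment of a network
#'
#' `(Observed - Expected) / Expected`, where Observed is the number of network
#' nodes carrying an LCR and Expected is the node count times the proteome-wide
#' LCR fraction.
#'
#' @param network An [igraph::graph].
#' @param lcr_ids Identifiers of LCR-containing proteins.
#' @param proteome_ids All proteome identifiers (should cover the network's
#'   nodes; a warning is issued otherwise).
#' @return Single enrichment value.
#' @export
network_lcr_enrichment <- function(network, lcr_ids, proteome_ids) {
  nodes <- igraph::V(network)$name
  if (!all(nodes %in% proteome_ids)) {
    warning(sum(!nodes %in% proteome_ids),
            " network node(s) missing from the proteome")
  }
  observed <- sum(nodes %in% lcr_ids)
  expected <- length(nodes) * (length(unique(lcr_ids)) / length(unique(proteome_ids)))
  if (expected == 0) stop("expected count is zero; enrichment undefined")
  (observed - expected) / expected
}
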