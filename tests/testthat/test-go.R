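test_that("annotation tables collapse duplicates and honour GAF NOT qualifiers", {
  tsv <- file.path(tempdir(), "ann.tsv")
  writeLines(c("gene\tterm\tbranch", "g1\tGO:X\tP", "g1\tGO:X\tP", "g2\tGO:X\tP",
               "g1\tGO:Y\tF"), tsv)
  ann <- read_annotations(tsv)
  expect_identical(nrow(ann), 3L)
  expect_identical(sum(ann$term == "GO:X"), 2L)

  gaf <- file.path(tempdir(), "ann.gaf")
  row <- function(gene, qual, term, aspect) {
    paste(c("DB", paste0("ID_", gene), gene, qual, term, "PMID:1", "IDA", "",
            aspect, "name", "", "protein", "taxon:559292", "20260101", "SGD",
            "", ""), collapse = "\t")
  }
  writeLines(c("!gaf-version: 2.1",
               row("g1", "", "GO:0006950", "P"),
               row("g2", "NOT", "GO:0006950", "P"),
               row("g2", "", "GO:0003676", "F"),
               row("g3", "NOT|contributes_to", "GO:0003676", "F"),
               row("g3", "", "GO:0005730", "C")), gaf)
  ann <- read_annotations(gaf, format = "gaf")
  expect_identical(nrow(ann), 3L)
  expect_false(any(ann$gene == "g2" & ann$term == "GO:0006950"))
  expect_identical(ann$branch[ann$term == "GO:0005730"], "C")
})

test_that("term set sizes match a hand count on a small fixture", {
  ann <- data.frame(gene = c("g1", "g2", "g3", "g1", "g4", "g5", "g1"),
                    term = c("T1", "T1", "T1", "T2", "T2", "T3", "T3"),
                    branch = "P")
  rows <- fisher_enrichment(c("g1", "g2"), paste0("g", 1:5), ann)
  expect_equal(rows$K[match(c("T1", "T2", "T3"), rows$term)], c(3L, 2L, 2L))
  expect_equal(rows$k[match(c("T1", "T2", "T3"), rows$term)], c(2L, 1L, 1L))
})

test_that("Fisher over-representation p equals the hypergeometric tail sum", {
  bg <- sprintf("g%03d", 1:100)
  study <- bg[1:10]
  ann <- data.frame(gene = c(bg[1:5], bg[11:15]), term = "T", branch = "P")
  rows <- fisher_enrichment(study, bg, ann)   # k=5, n=10, K=10, N=100
  expect_equal(rows$p, hyper_tail(5, 10, 10, 100), tolerance = 1e-14)
  # K = N: the term covers the whole background
  full <- fisher_enrichment(study, bg, data.frame(gene = bg, term = "ALL", branch = "P"))
  expect_equal(full$p, 1)
  # study = background: every k = K, p = 1
  eq <- fisher_enrichment(bg, bg, ann)
  expect_equal(eq$p, 1)
  expect_error(fisher_enrichment(c("zz"), bg, ann), "missing from background")
})

test_that("Fisher p matches brute-force tail summation across small cases", {
  set.seed(101)
  for (rep in 1:60) {
    N <- sample(10:60, 1)
    n <- sample(3:min(30, N), 1)
    K <- sample(1:N, 1)
    bg <- sprintf("x%03d", 1:N)
    study <- sample(bg, n)
    ann <- data.frame(gene = sample(bg, K), term = "T", branch = "P")
    k <- length(intersect(study, ann$gene))
    p <- fisher_enrichment(study, bg, ann)$p
    expect_equal(p, hyper_tail(k, K, n, N), tolerance = 1e-12)
  }
})

test_that("BH adjustment follows the step-up formula and stays monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(102)
  for (rep in 1:20) {
    p <- runif(sample(3:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_hand(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("per-branch correction adjusts each ontology branch separately", {
  ann <- data.frame(gene = "g1", term = c("P1", "P2", "F1"),
                    branch = c("P", "P", "F"))
  bg <- c("g1", sprintf("h%02d", 1:20))
  rows <- go_enrichment("g1", bg, ann)
  expect_equal(rows$q[rows$term == "F1"], rows$p[rows$term == "F1"])  # branch of size 1
  pooled <- go_enrichment("g1", bg, ann, per_branch = FALSE)
  expect_equal(pooled$q, bh_hand(pooled$p))
})

test_that("a strongly planted term is recovered and the report is threshold-faithful", {
  set.seed(103)
  bg <- sprintf("g%04d", 1:3000)
  study <- bg[1:150]
  carriers <- c(sample(study, 60), sample(setdiff(bg, study), round(0.05 * 2850)))
  ann <- rbind(data.frame(gene = carriers, term = "PLANT", branch = "P"),
               data.frame(gene = sample(bg, 300), term = "BGT", branch = "P"))
  rows <- go_enrichment(study, bg, ann)
  expect_lt(rows$q[rows$term == "PLANT"], 0.01)
  expect_identical(nrow(enrichment_report(rows, 1.0 + 1e-9)), nrow(rows))
  expect_identical(nrow(enrichment_report(rows, min(rows$q) / 2)), 0L)
  rep01 <- enrichment_report(rows, 0.01)
  expect_identical(rep01$term, "PLANT")
})

test_that("the FDR is controlled under a null study draw", {
  set.seed(104)
  bg <- sprintf("g%04d", 1:1000)
  terms <- sprintf("T%02d", 1:30)
  fracs <- vapply(1:200, function(i) {
    ann <- do.call(rbind, lapply(terms, function(tt) {
      data.frame(gene = bg[runif(1000) < 0.05], term = tt, branch = "P")
    }))
    study <- sample(bg, 100)
    rows <- go_enrichment(study, bg, ann)
    mean(rows$q < 0.05)
  }, numeric(1))
  expect_lte(mean(fracs), 0.05)
})

test_that("disjoint planted subsets yield disjoint significant term sets", {
  set.seed(105)
  bg <- sprintf("g%04d", 1:2000)
  half_a <- bg[1:120]; half_b <- bg[121:240]
  mk_ann <- function(term, target) {
    carriers <- unique(c(sample(target, 45), bg[runif(2000) < 0.04]))
    data.frame(gene = carriers, term = term, branch = "P")
  }
  ann <- rbind(mk_ann("TERM_A", half_a), mk_ann("TERM_B", half_b),
               do.call(rbind, lapply(sprintf("N%02d", 1:10), function(tt) {
                 data.frame(gene = bg[runif(2000) < 0.05], term = tt, branch = "P")
               })))
  sig <- function(study) {
    r <- enrichment_report(go_enrichment(study, bg, ann), 0.01)
    r$term
  }
  sa <- sig(half_a); sb <- sig(half_b)
  expect_true("TERM_A" %in% sa)
  expect_true("TERM_B" %in% sb)
  expect_length(intersect(sa, sb), 0L)
})
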