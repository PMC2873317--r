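test_that("a planted homopolymer run is detected inside a random protein", {
  set.seed(71)
  seqs <- random_proteome(50, c(200, 400))
  target <- random_protein(400)
  substr(target, 181, 220) <- strrep("A", 40)
  seqs <- c(seqs, lcrp = target)
  cal <- build_calibration(seqs, 16, 20)
  cand <- detect_lcrs(seqs, cal)
  inside <- cand$protein_id == "lcrp" & cand$start >= 181 & cand$end <= 220
  expect_gt(sum(inside), 0)
  expect_true(any(cand$H[inside] == 0))
  expect_true(all(cand$H < cal$t[match(cand$w, cal$w)]))
})

test_that("proteins shorter than the smallest calibrated window yield no candidates", {
  set.seed(72)
  seqs <- random_proteome(20, c(40, 80))
  cal <- build_calibration(seqs, 16, 18)
  cand <- detect_lcrs(c(tiny = random_protein(12)), cal)
  expect_identical(nrow(cand), 0L)
})

test_that("overlap resolution keeps the most extreme region and drops its overlaps", {
  mk <- function(start, end, Z) data.frame(protein_id = "p", start = start,
                                           end = end, w = end - start + 1L,
                                           H = 1, Z = Z)
  ab <- rbind(mk(10, 40, -3), mk(30, 60, -5))
  expect_equal(resolve_overlaps(ab)$start, 30)
  disj <- rbind(mk(10, 40, -3), mk(50, 60, -5))
  expect_equal(nrow(resolve_overlaps(disj)), 2L)
  chain <- rbind(mk(10, 40, -4), mk(35, 70, -6), mk(65, 90, -5))
  res <- resolve_overlaps(chain)
  expect_equal(res$start, 35)    # B beats A and C even though {A, C} is larger
})

test_that("greedy resolution matches exhaustive subset search on random instances", {
  set.seed(73)
  for (rep in 1:200) {
    n <- sample(2:10, 1)
    start <- sample(1:80, n, replace = TRUE)
    w <- sample(5:30, n, replace = TRUE)
    cand <- data.frame(protein_id = "p", start = start, end = start + w - 1L,
                       w = w, H = 1, Z = round(rnorm(n), 2))  # rounding makes ties
    got <- resolve_overlaps(cand)
    want <- cand[resolve_exhaustive(cand), ]
    want <- want[order(want$start), ]
    expect_equal(got$start, want$start)
    expect_equal(got$Z, want$Z)
    # disjoint and idempotent
    if (nrow(got) > 1) {
      expect_true(all(got$start[-1] > got$end[-nrow(got)]))
    }
    expect_equal(resolve_overlaps(got)$start, got$start)
  }
})

test_that("the literal-Z reading retains the numerically largest score", {
  cand <- data.frame(protein_id = "p", start = c(10, 30), end = c(40, 60),
                     w = c(31, 31), H = 1, Z = c(-3, -5))
  expect_equal(resolve_overlaps(cand, literal_z = TRUE)$Z, -3)
})

test_that("single-LCR filter keeps exactly the one-region proteins", {
  lcrs <- data.frame(protein_id = c("a", "b", "b", "c"),
                     start = c(1, 1, 50, 5), end = c(20, 20, 70, 24),
                     w = 20, H = 1, Z = -4)
  out <- single_lcr_filter(lcrs)
  expect_setequal(out$protein_id, c("a", "c"))
})

test_that("positional metrics follow the normalised-centre definition", {
  pm <- position_metrics(1, 21, 100)
  expect_equal(pm$centre_norm, 0.11)
  expect_equal(pm$folded, 0.11)
  whole <- position_metrics(1, 100, 100)
  expect_equal(whole$centre_norm, (1 + 100) / 200)
  expect_equal(whole$folded, 0.495)
  expect_equal(position_metrics(85, 95, 100)$folded, 0.1)
  set.seed(74)
  s <- sample(1:50, 20, replace = TRUE); e <- s + sample(0:30, 20, replace = TRUE)
  pm <- position_metrics(s, e, 100)
  expect_equal(pm$folded, pmin(pm$centre_norm, 1 - pm$centre_norm))
})

test_that("terminal/central classification respects margins and buffer zone", {
  expect_identical(classify_position(10, 40, 500), "terminal")
  expect_identical(classify_position(60, 120, 500), "central")
  expect_identical(classify_position(31, 170, 200), "intermediate")
  # boundaries: "no more than 25" inclusive, "at least 50" inclusive
  expect_identical(classify_position(26, 100, 400), "terminal")
  expect_identical(classify_position(27, 100, 150), "intermediate")  # N margin 26 in buffer
  expect_identical(classify_position(51, 100, 150), "central")       # both margins 50
  set.seed(75)
  cls <- classify_position(sample(1:100, 50, TRUE), sample(101:200, 50, TRUE), 300)
  expect_true(all(cls %in% c("terminal", "central", "intermediate")))
})

test_that("planted homopolymer runs of length >= 30 are recovered at >= 95% recall", {
  cfg <- synthetic_config(seed = 4242, n_proteins = 300L,
                          length_range = c(300L, 500L),
                          fraction_with_lcr = 12 / 300,
                          lcr_length_range = c(30L, 60L),
                          n_dominant = 1L, dominant_mass = 1)
  b <- generate_proteome(cfg)
  cal <- build_calibration(b$seqs, 16, 40)
  ann <- annotate_proteome(b$seqs, cal)
  tr <- b$truth[!is.na(b$truth$lcr_start), ]
  hit <- vapply(seq_len(nrow(tr)), function(i) {
    d <- ann$lcrs[ann$lcrs$protein_id == tr$protein_id[i], ]
    nrow(d) > 0 && any(d$start <= tr$lcr_end[i] & d$end >= tr$lcr_start[i])
  }, logical(1))
  expect_gte(mean(hit), 0.95)
  expect_true(all(ann$lcrs$H < cal$t[match(ann$lcrs$w, cal$w)]))
})

test_that("annotation counts and exported interval coordinates are consistent", {
  set.seed(76)
  seqs <- random_proteome(60, c(100, 200))
  substr(seqs[[5]], 20, 60) <- strrep("Q", 41)
  cal <- build_calibration(seqs, 16, 20)
  ann <- annotate_proteome(seqs, cal)
  expect_identical(unname(ann$counts["n_proteins"]), 60L)
  expect_identical(unname(ann$counts["n_with_lcr"]),
                   length(unique(ann$lcrs$protein_id)))
  path <- file.path(tempdir(), "lcrs.tsv")
  write_lcr_table(ann$lcrs, path)
  back <- read.delim(path)
  expect_equal(back$start0, ann$lcrs$start - 1L)  # 0-based half-open export
  expect_equal(back$end_excl, ann$lcrs$end)
})
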