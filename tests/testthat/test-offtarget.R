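spacer20 <- "ACGTACGGACTGACGGTCAG"

test_that("planted sites at distance 0-6 are reported only below the bound", {
  m <- pam_model("SpCas9-NGG")
  g <- random_genome(1, 20000, seed = 3)
  sites <- tibble::tibble(record = "ctg01",
                          offset = as.integer(seq(1000, by = 200, length.out = 7)),
                          strand = c("+", "-", "+", "+", "-", "+", "+"),
                          n_mismatch = 0:6)
  pl <- plant_sites(g, spacer20, m, sites, seed = 5, clean_within = 6)
  expect_equal(pl$truth$mismatch_count, 0:6)
  hits <- find_offtargets(spacer20, pl$genome, m, max_diff_exclusive = 5)
  expect_equal(nrow(hits), 5)
  expect_equal(sort(hits$mismatch_count), 0:4)
  # hits coincide with the truth table rows below the bound
  truth_lt5 <- pl$truth[pl$truth$mismatch_count < 5, ]
  expect_equal(sort(paste(hits$start, hits$strand)),
               sort(paste(truth_lt5$start, truth_lt5$strand)))
  # exact self-hit scores 1.0; mismatch detail sizes agree
  expect_equal(hits$cfd[hits$mismatch_count == 0], 1.0)
  expect_equal(vapply(hits$mismatch_detail, nrow, integer(1)), hits$mismatch_count)
})

test_that("bound 1 returns exact matches only and hit sets nest as the bound grows", {
  m <- pam_model("SpCas9-NGG")
  g <- random_genome(1, 20000, seed = 3)
  sites <- tibble::tibble(record = "ctg01",
                          offset = as.integer(seq(1000, by = 200, length.out = 5)),
                          strand = "+", n_mismatch = 0:4)
  pl <- plant_sites(g, spacer20, m, sites, seed = 5)
  prev <- 0
  for (bound in 1:6) {
    hits <- find_offtargets(spacer20, pl$genome, m, max_diff_exclusive = bound)
    expect_true(all(hits$mismatch_count < bound))
    expect_gte(nrow(hits), prev)
    prev <- nrow(hits)
    if (bound == 1) expect_true(all(hits$mismatch_count == 0))
  }
})

test_that("exclusion drops the on-target locus only", {
  m <- pam_model("SpCas9-NGG")
  g <- random_genome(1, 15000, seed = 8)
  sites <- tibble::tibble(record = "ctg01", offset = c(2000L, 9000L),
                          strand = "+", n_mismatch = c(0L, 1L))
  pl <- plant_sites(g, spacer20, m, sites, seed = 2)
  all_hits <- find_offtargets(spacer20, pl$genome, m)
  expect_equal(nrow(all_hits), 2)
  excl <- tibble::tibble(record = "ctg01", start = 2000L, end = 2020L)
  rest <- find_offtargets(spacer20, pl$genome, m, exclude = excl)
  expect_equal(nrow(rest), 1)
  expect_equal(rest$start, 9000L)
})

test_that("search equals the exhaustive scan for all bounds 1..6", {
  m <- pam_model("SpCas9-NGG")
  g <- random_genome(1, 30000, seed = 41)
  relax <- "NNG"  # NGG with its 5'-most fixed position widened
  set.seed(77)
  cand <- enumerate_protospacers(g[[1]], m)
  guides <- cand$spacer[sample(nrow(cand), 8)]
  for (sp in guides) {
    for (bound in c(1, 3, 5, 6)) {
      got <- find_offtargets(sp, g, m, max_diff_exclusive = bound)
      want <- oracle_offtargets(g, sp, m, bound, pam_pattern = relax)
      expect_identical(hit_key(got), hit_key(want),
                       info = sprintf("%s bound %d", sp, bound))
    }
  }
})

test_that("canonical-only mode restricts PAM admission", {
  m <- pam_model("SpCas9-NGG")
  g <- random_genome(1, 30000, seed = 42)
  cand <- enumerate_protospacers(g[[1]], m)
  sp <- cand$spacer[5]
  got <- find_offtargets(sp, g, m, max_diff_exclusive = 5, pam_mode = "canonical")
  want <- oracle_offtargets(g, sp, m, 5, pam_pattern = "NGG")
  expect_identical(hit_key(got), hit_key(want))
  expect_true(all(substr(got$site_pam, 2, 3) == "GG"))
})

test_that("CFD score is the product of table entries times the PAM penalty", {
  tab <- penalty_table("SpCas9-NGG")
  sp <- spacer20
  expect_equal(cfd_score(sp, sp, "AGG", tab), 1.0)
  # single mismatch equals the table entry exactly
  hit <- sp
  substr(hit, 7, 7) <- "T"  # guide G > genome T at position 7
  expect_equal(cfd_score(sp, hit, "CGG", tab),
               unname(tab$mismatch[["7:G:T"]]))
  # non-canonical PAM multiplies in the PAM penalty
  expect_equal(cfd_score(sp, sp, "CAG", tab),
               tab$pam$penalty[tab$pam$pam_pattern == "NAG"])
  # random pairs: product rule against a positional loop oracle
  set.seed(5)
  bases <- c("A", "C", "G", "T")
  for (i in 1:200) {
    k <- sample(0:4, 1)
    hit <- sp
    pos <- if (k > 0) sample(20, k) else integer(0)
    for (p in pos) {
      substr(hit, p, p) <- sample(setdiff(bases, substr(sp, p, p)), 1)
    }
    pamv <- sample(c("AGG", "TGG", "CAG", "GCG", "ATG"), 1)
    gch <- strsplit(sp, "")[[1]]; dch <- strsplit(hit, "")[[1]]
    expected <- tab$pam$penalty[match(paste0("N", substr(pamv, 2, 3)),
                                      tab$pam$pam_pattern)]
    for (p in which(gch != dch)) {
      expected <- expected * tab$mismatch[[paste(p, gch[p], dch[p], sep = ":")]]
    }
    expect_equal(cfd_score(sp, hit, pamv, tab), unname(expected))
  }
})

test_that("adding a mismatch never increases the CFD score", {
  tab <- penalty_table("SpCas9-NGG")
  set.seed(11)
  bases <- c("A", "C", "G", "T")
  for (i in 1:50) {
    hit <- spacer20
    score_prev <- cfd_score(spacer20, hit, "AGG", tab)
    for (p in sample(20, 6)) {
      old <- substr(hit, p, p)
      if (old != substr(spacer20, p, p)) next
      substr(hit, p, p) <- sample(setdiff(bases, old), 1)
      score_new <- cfd_score(spacer20, hit, "AGG", tab)
      expect_lte(score_new, score_prev)
      score_prev <- score_new
    }
  }
})

test_that("missing penalty entries raise a configuration error naming the triple", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("position\tguide_base\tgenome_base\tpenalty",
               "1\tA\tC\t0.5"), tf)
  tab <- penalty_table("SpCas9-NGG", mismatch_path = tf)
  hit <- spacer20
  substr(hit, 3, 3) <- "A"  # G>A at position 3: not in the 1-entry table
  expect_error(cfd_score(spacer20, hit, "AGG", tab), "3:G:A")
  expect_error(cfd_score(spacer20, spacer20, "AGT", tab), "AGT")
})

test_that("specificity aggregates hits with the harmonic form", {
  expect_equal(specificity_score(numeric(0)), 1.0)
  expect_equal(specificity_score(1.0), 0.5)
  expect_equal(specificity_score(c(0.2, 0.3)), 1 / 1.5)
  expect_equal(specificity_score(tibble::tibble(cfd = c(0.2, 0.3))), 1 / 1.5)
  # strictly decreasing in any hit's cfd
  expect_lt(specificity_score(c(0.5, 0.3)), specificity_score(c(0.4, 0.3)))
})

test_that("guide length must match the model", {
  g <- random_genome(1, 1000, seed = 1)
  expect_error(find_offtargets("ACGT", g, "SpCas9-NGG"), "length")
})
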