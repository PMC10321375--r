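design_fixture <- function(seed = 21, len = 20000) {
  g <- random_genome(1, len, seed = seed)
  target <- substr(g[[1]], 5001, 6000)
  idx <- build_index(g, "SpCas9-NGG")
  list(genome = g, target = target, index = idx)
}

test_that("a cleanly embedded target yields unique, fully specific guides", {
  fx <- design_fixture()
  d <- design_for_sequence(fx$target, fx$index, fx$genome, design_params(),
                           target_id = "geneA")
  expect_gt(nrow(d), 0)
  expect_true(all(d$is_unique))
  expect_true(all(d$specificity == 1))
  expect_true(all(d$n_offtargets == 0))
  expect_equal(d$rank, seq_len(nrow(d)))
  # every reported guide is a real candidate of the target
  cand <- enumerate_protospacers(fx$target, "SpCas9-NGG")
  expect_setequal(d$spacer, cand$spacer)
})

test_that("a duplicated target region marks every guide not unique", {
  fx <- design_fixture()
  g2 <- fx$genome
  g2[["ctg01"]] <- paste0(fx$genome[[1]], substr(fx$genome[[1]], 4901, 6100))
  idx2 <- build_index(g2, "SpCas9-NGG")
  d <- design_for_sequence(fx$target, idx2, g2, design_params(), target_id = "geneA")
  expect_true(all(!d$is_unique))
  expect_true(all(d$occurrence_count >= 2))
})

test_that("a planted near-match surfaces as exactly one guide's off-target hit", {
  fx <- design_fixture(seed = 55)
  cand <- enumerate_protospacers(fx$target, "SpCas9-NGG")
  victim <- cand$spacer[10]
  pl <- plant_sites(fx$genome, victim, "SpCas9-NGG",
                    tibble::tibble(record = "ctg01", offset = 15000L,
                                   strand = "+", n_mismatch = 2L),
                    seed = 3, clean_within = -1)  # keep the on-target site intact
  idx <- build_index(pl$genome, "SpCas9-NGG")
  d <- design_for_sequence(fx$target, idx, pl$genome, design_params(),
                           target_id = "geneA")
  with_hits <- d[d$n_offtargets > 0, ]
  expect_equal(with_hits$spacer, victim)
  expect_equal(with_hits$hits[[1]]$mismatch_count, 2L)
  expect_equal(with_hits$hits[[1]]$start, 15000L)
  expect_lt(with_hits$specificity, 1)
  # ranking puts the fully specific guides ahead of the victim
  expect_gt(with_hits$rank, 1)
  # rankings agree with a direct recomputation from the table
  key <- order(-as.integer(d$is_unique), -d$specificity,
               -ifelse(is.na(d$activity), -Inf, d$activity), d$start, match(d$strand, c("+", "-")))
  expect_equal(d$rank[key], seq_len(nrow(d)))
})

test_that("index/genome provenance and model mismatches are caught", {
  fx <- design_fixture()
  other <- random_genome(1, 5000, seed = 99)
  expect_error(design_for_sequence(fx$target, fx$index, other, design_params()),
               "provenance")
  expect_error(design_for_sequence(fx$target, fx$index, fx$genome,
                                   design_params(pam_model_name = "SpCas9-NAG")),
               "model")
})

test_that("require_unique toggling reorders but never drops candidates", {
  fx <- design_fixture()
  g2 <- fx$genome
  # duplicate half the target so some guides are non-unique
  g2[["ctg01"]] <- paste0(fx$genome[[1]], substr(fx$genome[[1]], 5001, 5500))
  idx2 <- build_index(g2, "SpCas9-NGG")
  d_pref <- design_for_sequence(fx$target, idx2, g2,
                                design_params(require_unique = TRUE))
  d_flat <- design_for_sequence(fx$target, idx2, g2,
                                design_params(require_unique = FALSE))
  expect_setequal(d_pref$spacer, d_flat$spacer)
  expect_true(any(!d_pref$is_unique) && any(d_pref$is_unique))
  # with preference on, every unique guide outranks every non-unique one
  expect_lt(max(d_pref$rank[d_pref$is_unique]), min(d_pref$rank[!d_pref$is_unique]))
})

test_that("design output is deterministic across runs", {
  fx <- design_fixture(seed = 77)
  d1 <- design_for_sequence(fx$target, fx$index, fx$genome, design_params())
  d2 <- design_for_sequence(fx$target, fx$index, fx$genome, design_params())
  expect_identical(tidy(d1), tidy(d2))
})

test_that("shared guides are the brute-force intersection across genes", {
  fx <- make_shared_fixture()
  idx <- build_index(fx$genome, "SpCas9-NGG")
  sh <- shared_guides(fx$genes, idx, fx$genome, design_params())
  # brute-force: intersect per-gene candidate spacer sets
  per_gene <- lapply(fx$genes, function(s) {
    unique(oracle_protospacers(s, pam_model("SpCas9-NGG"))$spacer)
  })
  want <- Reduce(intersect, per_gene)
  expect_setequal(sh$spacer, want)
  row <- sh[sh$spacer == fx$spacer, ]
  expect_equal(nrow(row), 1)
  expect_equal(row$occurrence_count, 3L)
  expect_true(row$is_unique)          # count == number of target genes
  expect_equal(nrow(row$gene_hits[[1]]), 3)
  expect_setequal(row$gene_hits[[1]]$target_id, c("gene1", "gene2", "gene3"))
})

test_that("shared guides of identical sequences equal the single candidate set", {
  g <- random_genome(1, 10000, seed = 61)
  idx <- build_index(g, "SpCas9-NGG")
  tgt <- substr(g[[1]], 2001, 2400)
  sh <- shared_guides(c(a = tgt, b = tgt), idx, g, design_params())
  cand <- enumerate_protospacers(tgt, "SpCas9-NGG")
  expect_setequal(sh$spacer, unique(cand$spacer))
})

test_that("disjoint gene pairs share nothing and <2 targets is an error", {
  g <- random_genome(1, 10000, seed = 62)
  idx <- build_index(g, "SpCas9-NGG")
  sh <- shared_guides(c(a = strrep("GC", 50), b = strrep("AT", 50)),
                      idx, g, design_params())
  expect_equal(nrow(sh), 0)
  expect_error(shared_guides(c(a = "ACGT"), idx, g, design_params()),
               "at least 2")
})

test_that("batch design matches independent per-target runs, in input order", {
  fx <- make_shared_fixture(seed = 83)
  idx <- build_index(fx$genome, "SpCas9-NGG")
  batch <- batch_design(fx$genes, idx, fx$genome, design_params())
  expect_equal(names(batch), names(fx$genes))
  for (id in names(fx$genes)) {
    solo <- design_for_sequence(fx$genes[[id]], idx, fx$genome, design_params(),
                                target_id = id)
    expect_identical(tidy(batch[[id]]), tidy(solo))
  }
  expect_error(batch_design(character(0), idx, fx$genome), "at least one")
  dup <- fx$genes[c(1, 1)]
  expect_error(batch_design(dup, idx, fx$genome), "duplicate")
})
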