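fixture_ann <- function(seed_g = 11, seed_a = 2, n_genes = 6) {
  g <- random_genome(2, c(9000, 8000), seed = seed_g)
  ann <- toy_annotation(g, n_genes, seed = seed_a)
  list(genome = g, gff = ann$gff, truth = ann$models)
}

test_that("GFF3 parses back into the truth gene models field by field", {
  fx <- fixture_ann()
  models <- load_annotation(fx$gff, fx$genome)
  expect_equal(nrow(models), nrow(fx$truth))
  for (i in seq_len(nrow(models))) {
    tm <- fx$truth[fx$truth$gene_id == models$gene_id[i], ]
    expect_equal(models$record_id[i], tm$record_id)
    expect_equal(models$strand[i], tm$strand)
    expect_equal(models$gene_start[i], tm$gene_start)
    expect_equal(models$gene_end[i], tm$gene_end)
    for (col in c("exons", "cds", "utr5", "utr3")) {
      expect_equal(as.data.frame(models[[col]][[i]]),
                   as.data.frame(tm[[col]][[1]]),
                   info = paste(models$gene_id[i], col))
    }
  }
})

test_that("single-exon plus-strand gene: exons equal the gene span, mRNA is the slice", {
  g <- c(chr1 = random_genome(1, 2000, seed = 4)[[1]])
  gff <- c("##gff-version 3",
           "chr1\ttest\tgene\t201\t500\t.\t+\t.\tID=g1",
           "chr1\ttest\tmRNA\t201\t500\t.\t+\t.\tID=g1.t1;Parent=g1",
           "chr1\ttest\texon\t201\t500\t.\t+\t.\tParent=g1.t1",
           "chr1\ttest\tCDS\t251\t430\t.\t+\t0\tParent=g1.t1")
  models <- load_annotation(gff, g)
  expect_equal(as.data.frame(models$exons[[1]]),
               data.frame(start = 200L, end = 500L))
  expect_equal(extract_region(models[1, ], g, "mRNA"),
               substr(g[[1]], 201, 500))
  # UTRs derived from exon minus CDS
  expect_equal(extract_region(models[1, ], g, "UTR5"), substr(g[[1]], 201, 250))
  expect_equal(extract_region(models[1, ], g, "UTR3"), substr(g[[1]], 431, 500))
})

test_that("minus-strand extraction reverse-complements into transcript orientation", {
  g <- c(chr1 = random_genome(1, 2000, seed = 6)[[1]])
  gff <- c("##gff-version 3",
           "chr1\ttest\tgene\t201\t500\t.\t-\t.\tID=g1",
           "chr1\ttest\tmRNA\t201\t500\t.\t-\t.\tID=g1.t1;Parent=g1",
           "chr1\ttest\texon\t201\t500\t.\t-\t.\tParent=g1.t1",
           "chr1\ttest\tCDS\t251\t430\t.\t-\t0\tParent=g1.t1")
  models <- load_annotation(gff, g)
  expect_equal(extract_region(models[1, ], g, "mRNA"),
               revcomp(substr(g[[1]], 201, 500)))
  # derived 5' UTR sits genomically RIGHT of the CDS on the minus strand
  expect_equal(extract_region(models[1, ], g, "UTR5"),
               revcomp(substr(g[[1]], 431, 500)))
})

test_that("two-exon mRNA concatenates exon slices in transcript order", {
  g <- c(chr1 = random_genome(1, 3000, seed = 7)[[1]])
  gff <- c("##gff-version 3",
           "chr1\ttest\tgene\t101\t900\t.\t+\t.\tID=g1",
           "chr1\ttest\tmRNA\t101\t900\t.\t+\t.\tID=g1.t1;Parent=g1",
           "chr1\ttest\texon\t101\t300\t.\t+\t.\tParent=g1.t1",
           "chr1\ttest\texon\t601\t900\t.\t+\t.\tParent=g1.t1",
           "chr1\ttest\tCDS\t101\t300\t.\t+\t0\tParent=g1.t1",
           "chr1\ttest\tCDS\t601\t900\t.\t+\t0\tParent=g1.t1")
  models <- load_annotation(gff, g)
  want <- paste0(substr(g[[1]], 101, 300), substr(g[[1]], 601, 900))
  expect_equal(extract_region(models[1, ], g, "mRNA"), want)
  expect_equal(nchar(extract_region(models[1, ], g, "mRNA")),
               sum(models$exons[[1]]$end - models$exons[[1]]$start))
})

test_that("mRNA equals UTR5 + CDS + UTR3 and CDS length is a multiple of 3", {
  fx <- fixture_ann(seed_g = 21, seed_a = 9)
  models <- load_annotation(fx$gff, fx$genome)
  for (i in seq_len(nrow(models))) {
    cds <- extract_region(models[i, ], fx$genome, "CDS")
    expect_equal(nchar(cds) %% 3, 0)
    expect_equal(extract_region(models[i, ], fx$genome, "mRNA"),
                 paste0(extract_region(models[i, ], fx$genome, "UTR5"),
                        cds,
                        extract_region(models[i, ], fx$genome, "UTR3")))
  }
})

test_that("promoter is strand-aware and truncates at the record boundary", {
  g <- c(chr1 = random_genome(1, 3000, seed = 14)[[1]])
  gff <- c("##gff-version 3",
           "chr1\ttest\tgene\t151\t400\t.\t+\t.\tID=g1",
           "chr1\ttest\tmRNA\t151\t400\t.\t+\t.\tID=g1.t1;Parent=g1",
           "chr1\ttest\texon\t151\t400\t.\t+\t.\tParent=g1.t1",
           "chr1\ttest\tCDS\t151\t400\t.\t+\t0\tParent=g1.t1",
           "chr1\ttest\tgene\t2501\t2900\t.\t-\t.\tID=g2",
           "chr1\ttest\tmRNA\t2501\t2900\t.\t-\t.\tID=g2.t1;Parent=g2",
           "chr1\ttest\texon\t2501\t2900\t.\t-\t.\tParent=g2.t1",
           "chr1\ttest\tCDS\t2501\t2900\t.\t-\t0\tParent=g2.t1")
  models <- load_annotation(gff, g)
  # + strand: gene starts at 0-based 150 < 2000 -> promoter truncated to 150 nt
  p1 <- extract_region(models[1, ], g, "promoter", promoter_len = 2000)
  expect_equal(nchar(p1), 150)
  expect_equal(p1, substr(g[[1]], 1, 150))
  # short promoter request
  p2 <- extract_region(models[1, ], g, "promoter", promoter_len = 50)
  expect_equal(p2, substr(g[[1]], 101, 150))
  # - strand: upstream means genomically right, reverse-complemented
  p3 <- extract_region(models[2, ], g, "promoter", promoter_len = 2000)
  expect_equal(nchar(p3), 100)  # 3000 - 2900
  expect_equal(p3, revcomp(substr(g[[1]], 2901, 3000)))
})

test_that("absent feature sets yield an empty result distinct from an error", {
  g <- c(chr1 = random_genome(1, 1000, seed = 15)[[1]])
  gff <- c("##gff-version 3",
           "chr1\ttest\tgene\t101\t400\t.\t+\t.\tID=g1",
           "chr1\ttest\tmRNA\t101\t400\t.\t+\t.\tID=g1.t1;Parent=g1",
           "chr1\ttest\texon\t101\t400\t.\t+\t.\tParent=g1.t1")
  models <- load_annotation(gff, g)
  expect_length(extract_region(models[1, ], g, "UTR5"), 0)
  expect_length(extract_region(models[1, ], g, "CDS"), 0)
  regions <- extract_regions(models, g, "UTR5")
  expect_true(is.na(regions$seq[1]))
  expect_equal(regions$length[1], 0L)
})

test_that("malformed annotations are rejected with named errors", {
  g <- c(chr1 = strrep("ACGT", 100))
  base <- c("##gff-version 3",
            "chr1\ttest\tgene\t1\t100\t.\t+\t.\tID=g1",
            "chr1\ttest\tmRNA\t1\t100\t.\t+\t.\tID=g1.t1;Parent=g1")
  # exon past the record end
  expect_error(load_annotation(c("##gff-version 3",
    "chr1\ttest\tgene\t1\t900\t.\t+\t.\tID=g1",
    "chr1\ttest\tmRNA\t1\t900\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\ttest\texon\t1\t900\t.\t+\t.\tParent=g1.t1"), g), "beyond")
  # orphan parent link
  expect_error(load_annotation(c(base,
    "chr1\ttest\texon\t1\t100\t.\t+\t.\tParent=ghost.t1"), g), "ghost")
  # gene on an unknown record
  expect_error(load_annotation(c("##gff-version 3",
    "chrX\ttest\tgene\t1\t100\t.\t+\t.\tID=g1",
    "chrX\ttest\tmRNA\t1\t100\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chrX\ttest\texon\t1\t100\t.\t+\t.\tParent=g1.t1"), g), "chrX")
})

test_that("longest transcript is selected with lexicographic tie-break", {
  g <- c(chr1 = random_genome(1, 2000, seed = 16)[[1]])
  gff <- c("##gff-version 3",
           "chr1\ttest\tgene\t101\t900\t.\t+\t.\tID=g1",
           "chr1\ttest\tmRNA\t101\t900\t.\t+\t.\tID=g1.t2;Parent=g1",
           "chr1\ttest\texon\t101\t900\t.\t+\t.\tParent=g1.t2",
           "chr1\ttest\tmRNA\t101\t400\t.\t+\t.\tID=g1.t1;Parent=g1",
           "chr1\ttest\texon\t101\t400\t.\t+\t.\tParent=g1.t1")
  models <- load_annotation(gff, g)
  expect_equal(models$transcript_id, "g1.t2")
})
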