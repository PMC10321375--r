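#' Load a GFF3 annotation into gene models
#'
#' Parses GFF3 (via [rtracklayer::import()]) and assembles one gene
#' model per gene: the gene span, the chosen transcript's exons, CDS
#' and UTR intervals, all converted to 0-based half-open coordinates.
#' When a gene has several mRNA children the longest transcript is
#' used (ties broken by lexicographically smallest ID). UTRs come from
#' explicit `five_prime_UTR`/`three_prime_UTR` features when present
#' and are otherwise derived as exon-minus-CDS, split at the CDS into
#' transcript-5' and transcript-3' parts.
#'
#' @param gff_source Path to a GFF3 file, or a character vector of GFF3
#'   lines.
#' @param genome Genome input accepted by [as_genome()]; used to reject
#'   genes on unknown records or with out-of-bounds coordinates.
#' @return Tibble with one row per gene: `gene_id`, `transcript_id`,
#'   `record_id`, `strand`, `gene_start`, `gene_end` and list-columns
#'   `exons`, `cds`, `utr5`, `utr3` of interval tibbles
#'   (`start`, `end`; 0-based half-open, genomic order).
#' @export
load_annotation <- function(gff_source, genome) {
  genome <- as_genome(genome)
  if (length(gff_source) > 1 || !file.exists(gff_source)) {
    tf <- tempfile(fileext = ".gff3")
    writeLines(gff_source, tf)
    gff_source <- tf
    on.exit(unlink(tf), add = TRUE)
  }
  gr <- rtracklayer::import(gff_source, format = "gff3")
  md <- as.data.frame(gr)
  md$type <- as.character(md$type)
  md$ID <- as.character(md$ID)
  md$Parent <- vapply(as.list(md$Parent), function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[1])
  }, character(1))

  genes <- md[md$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0) abort("annotation contains no gene features")
  mrnas <- md[md$type == "mRNA", , drop = FALSE]
  parts <- md[md$type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR"), ,
              drop = FALSE]
  if (any(is.na(mrnas$Parent))) {
    abort(sprintf("mRNA feature '%s' has no Parent attribute",
                  mrnas$ID[is.na(mrnas$Parent)][1]))
  }
  if (any(is.na(parts$Parent))) {
    bad <- parts[is.na(parts$Parent), ][1, ]
    abort(sprintf("%s feature at %s:%d has no Parent attribute",
                  bad$type, bad$seqnames, bad$start))
  }
  orphan <- !(mrnas$Parent %in% genes$ID)
  if (any(orphan)) {
    abort(sprintf("mRNA '%s' refers to unknown gene parent '%s'",
                  mrnas$ID[orphan][1], mrnas$Parent[orphan][1]))
  }
  orphan2 <- !(parts$Parent %in% mrnas$ID)
  if (any(orphan2)) {
    abort(sprintf("%s feature refers to unknown transcript parent '%s'",
                  parts$type[orphan2][1], parts$Parent[orphan2][1]))
  }

  out <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    rec <- as.character(g$seqnames)
    if (!rec %in% names(genome)) {
      abort(sprintf("gene '%s' lies on record '%s' absent from the genome",
                    g$ID, rec))
    }
    if (g$end > nchar(genome[[rec]]) || g$start < 1) {
      abort(sprintf("gene '%s' extends beyond record '%s' (length %d)",
                    g$ID, rec, nchar(genome[[rec]])))
    }
    tx <- mrnas[mrnas$Parent == g$ID, , drop = FALSE]
    if (nrow(tx) == 0) {
      abort(sprintf("gene '%s' has no mRNA child", g$ID))
    }
    tx_len <- vapply(tx$ID, function(id) {
      ex <- parts[parts$Parent == id & parts$type == "exon", , drop = FALSE]
      sum(ex$end - ex$start + 1)
    }, numeric(1))
    pick <- order(-tx_len, tx$ID)[1]
    tx_id <- tx$ID[pick]

    iv <- function(type) {
      p <- parts[parts$Parent == tx_id & parts$type == type, , drop = FALSE]
      p <- p[order(p$start), , drop = FALSE]
      if (any(p$end > nchar(genome[[rec]]))) {
        abort(sprintf("%s of '%s' extends beyond record '%s'", type, tx_id, rec))
      }
      tibble(start = as.integer(p$start - 1L), end = as.integer(p$end))
    }
    exons <- iv("exon")
    if (nrow(exons) == 0) exons <- tibble(start = as.integer(g$start - 1L),
                                          end = as.integer(g$end))
    cds <- iv("CDS")
    utr5 <- iv("five_prime_UTR")
    utr3 <- iv("three_prime_UTR")
    strand <- as.character(g$strand)
    if (nrow(utr5) == 0 && nrow(utr3) == 0 && nrow(cds) > 0) {
      der <- derive_utrs(exons, cds, strand)
      utr5 <- der$utr5
      utr3 <- der$utr3
    }
    tibble(gene_id = g$ID, transcript_id = tx_id, record_id = rec,
           strand = strand,
           gene_start = as.integer(g$start - 1L), gene_end = as.integer(g$end),
           exons = list(exons), cds = list(cds),
           utr5 = list(utr5), utr3 = list(utr3))
  })
  bind_rows(out)
}

# Exon-minus-CDS, split at the CDS span into the transcript-5' and
# transcript-3' sides (strand-aware).
derive_utrs <- function(exons, cds, strand) {
  cds_lo <- min(cds$start)
  cds_hi <- max(cds$end)
  left <- list(); right <- list()
  for (i in seq_len(nrow(exons))) {
    s <- exons$start[i]; e <- exons$end[i]
    if (s < cds_lo) {
      left[[length(left) + 1]] <- tibble(start = s, end = min(e, cds_lo))
    }
    if (e > cds_hi) {
      right[[length(right) + 1]] <- tibble(start = max(s, cds_hi), end = e)
    }
  }
  empty <- tibble(start = integer(0), end = integer(0))
  left <- if (length(left)) bind_rows(left) else empty
  right <- if (length(right)) bind_rows(right) else empty
  if (strand == "+") list(utr5 = left, utr3 = right)
  else list(utr5 = right, utr3 = left)
}

#' Extract a design-ready sequence for one gene
#'
#' Returns the requested region 5'-to-3' in transcript orientation:
#' minus-strand results are reverse-complemented, multi-exon regions
#' are concatenated in transcript order. The promoter is the
#' `promoter_len` bases immediately upstream of the transcription
#' start, strand-aware and truncated at the record boundary. A kind
#' whose feature set is absent (e.g. an unannotated 5' UTR) returns
#' `character(0)` — an empty result, not an error.
#'
#' @param gene One row of the [load_annotation()] tibble (or a tibble
#'   from which the row for `gene$gene_id` is taken).
#' @param genome Genome input accepted by [as_genome()].
#' @param kind One of `"promoter"`, `"gene"`, `"mRNA"`, `"CDS"`,
#'   `"UTR5"`, `"UTR3"`.
#' @param promoter_len Promoter length in nt (default 2000).
#' @return A single sequence string, or `character(0)` for an absent
#'   feature set.
#' @export
extract_region <- function(gene, genome, kind = c("promoter", "gene", "mRNA",
                                                  "CDS", "UTR5", "UTR3"),
                           promoter_len = 2000) {
  kind <- match.arg(kind)
  genome <- as_genome(genome)
  gene <- as_tibble(gene)
  stopifnot(nrow(gene) == 1)
  if (!gene$record_id %in% names(genome)) {
    abort(sprintf("record '%s' absent from genome", gene$record_id))
  }
  rec <- genome[[gene$record_id]]
  strand <- gene$strand
  slice <- function(iv) {
    if (nrow(iv) == 0) return(character(0))
    pieces <- substring(rec, iv$start + 1, iv$end)
    joined <- paste(pieces, collapse = "")
    if (strand == "-") revcomp(joined) else joined
  }
  switch(kind,
    gene = slice(tibble(start = gene$gene_start, end = gene$gene_end)),
    mRNA = slice(gene$exons[[1]]),
    CDS = slice(gene$cds[[1]]),
    UTR5 = slice(gene$utr5[[1]]),
    UTR3 = slice(gene$utr3[[1]]),
    promoter = {
      stopifnot(promoter_len >= 1)
      exons <- gene$exons[[1]]
      if (strand == "+") {
        tss <- min(exons$start)
        lo <- max(0L, tss - as.integer(promoter_len))
        if (tss <= 0) return("")
        substring(rec, lo + 1, tss)
      } else {
        tss <- max(exons$end)
        hi <- min(nchar(rec), tss + as.integer(promoter_len))
        if (tss >= nchar(rec)) return("")
        revcomp(substring(rec, tss + 1, hi))
      }
    }
  )
}

#' Extract regions for many genes as a tibble
#'
#' Pipe-friendly wrapper around [extract_region()].
#'
#' @param models A [load_annotation()] tibble (optionally filtered).
#' @inheritParams extract_region
#' @return Tibble with `gene_id`, `kind`, `seq`, `length` (absent
#'   features yield a zero-length row with `seq = NA`).
#' @export
extract_regions <- function(models, genome, kind = "mRNA", promoter_len = 2000) {
  rows <- lapply(seq_len(nrow(models)), function(i) {
    s <- extract_region(models[i, ], genome, kind, promoter_len)
    tibble(gene_id = models$gene_id[i], kind = kind,
           seq = if (length(s) == 0) NA_character_ else s,
           length = if (length(s) == 0) 0L else nchar(s))
  })
  bind_rows(rows)
}

#' Write extracted regions to FASTA
#'
#' Headers follow `geneID|kind|record:start-end|strand` (1-based
#' inclusive coordinates of the gene span).
#'
#' @param regions Output of [extract_regions()].
#' @param models The matching [load_annotation()] tibble.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_regions_fasta <- function(regions, models, path) {
  keep <- !is.na(regions$seq)
  regions <- regions[keep, , drop = FALSE]
  hdr <- vapply(seq_len(nrow(regions)), function(i) {
    m <- models[models$gene_id == regions$gene_id[i], ][1, ]
    sprintf("%s|%s|%s:%d-%d|%s", regions$gene_id[i], regions$kind[i],
            m$record_id, m$gene_start + 1L, m$gene_end, m$strand)
  }, character(1))
  seqs <- Biostrings::DNAStringSet(setNames(regions$seq, hdr))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
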