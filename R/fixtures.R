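#' Deterministic random genome generator
#'
#' Generates i.i.d. nucleotide sequences at a target GC content; a pure
#' function of `(n_records, lengths, gc, seed)` (the global RNG state
#' is left untouched). Used throughout the test-suite so every module
#' is exercised with no external download.
#'
#' @param n_records Number of records.
#' @param lengths Integer vector of record lengths (recycled to
#'   `n_records`); all positive.
#' @param gc Target GC fraction in `(0, 1)`; default 0.5.
#' @param seed Integer seed.
#' @return Named character vector (records `ctg01`, `ctg02`, ...).
#' @export
#' @examples
#' random_genome(2, c(500, 300), seed = 1)
random_genome <- function(n_records, lengths, gc = 0.5, seed = 1) {
  stopifnot(n_records >= 1)
  lengths <- rep_len(as.integer(lengths), n_records)
  if (any(lengths <= 0)) abort("all record lengths must be positive")
  if (gc <= 0 || gc >= 1) abort("gc must lie strictly between 0 and 1")
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  with_seed(seed, {
    seqs <- vapply(lengths, function(len) {
      paste(sample(names(probs), len, replace = TRUE, prob = probs), collapse = "")
    }, character(1))
    setNames(seqs, sprintf("ctg%02d", seq_len(n_records)))
  })
}

# Concretise an IUPAC pattern to a plain sequence (first base of each
# class, alphabetically) — used to write canonical PAMs for plants.
concretize_pattern <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  paste(vapply(chars, function(ch) IUPAC[[ch]][1], character(1)), collapse = "")
}

apply_edits <- function(spacer, edits) {
  if (is.null(edits) || nrow(edits) == 0) return(spacer)
  chars <- strsplit(spacer, "")[[1]]
  if (any(edits$pos < 1 | edits$pos > length(chars))) abort("edit position out of range")
  if (any(chars[edits$pos] == edits$new_base)) abort("edits must change the base")
  chars[edits$pos] <- edits$new_base
  paste(chars, collapse = "")
}

#' Plant on- and near-target sites into a genome
#'
#' Writes copies of a spacer (with a canonical PAM and optional
#' per-site mismatch edits) at requested positions, then re-randomises
#' any accidental background window within `clean_within` mismatches of
#' the spacer (either orientation, PAM-independent) so the returned
#' truth table is exhaustive: a brute-force scan of the edited genome
#' finds exactly the planted sites within that distance.
#'
#' @param genome Genome input accepted by [as_genome()].
#' @param spacer The guide spacer to plant.
#' @param model A `pam_model` or model name (supplies PAM pattern/side).
#' @param sites Tibble with columns `record`, `offset` (0-based start
#'   of the planted spacer), `strand` (`"+"`/`"-"`), and either
#'   `n_mismatch` (integer; seeded random edits) or a list-column
#'   `edits` of tibbles `(pos, new_base)`.
#' @param seed Integer seed driving edit choice and re-randomisation.
#' @param clean_within Background windows at Hamming distance <= this
#'   value are rewritten (default 4, matching the default off-target
#'   bound "less than five"); a negative value disables the cleaning
#'   step entirely (use when the genome already contains wanted
#'   occurrences of the spacer, e.g. an on-target site).
#' @return List with elements `genome` (edited) and `truth` (tibble:
#'   `record`, `start`, `end`, `strand`, `site_spacer`, `site_pam`,
#'   `mismatch_count`).
#' @export
plant_sites <- function(genome, spacer, model, sites, seed = 1,
                        clean_within = 4) {
  genome <- as_genome(genome)
  model <- pam_model(model)
  spacer <- toupper(spacer)
  stopifnot(nchar(spacer) == model$spacer_length)
  L <- model$spacer_length
  P <- model$pam_length
  pam_seq <- concretize_pattern(model$pattern)

  sites <- as_tibble(sites)
  if (!all(c("record", "offset", "strand") %in% names(sites))) {
    abort("sites needs columns record, offset, strand")
  }
  if (!"edits" %in% names(sites)) sites$edits <- vector("list", nrow(sites))
  if (!"n_mismatch" %in% names(sites)) sites$n_mismatch <- 0L

  with_seed(seed, {
    # materialise random edits for rows given as a mismatch count
    for (i in seq_len(nrow(sites))) {
      if (is.null(sites$edits[[i]]) && sites$n_mismatch[i] > 0) {
        k <- sites$n_mismatch[i]
        pos <- sort(sample(L, k))
        chars <- strsplit(spacer, "")[[1]]
        newb <- vapply(pos, function(p) {
          sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
        }, character(1))
        sites$edits[[i]] <- tibble(pos = pos, new_base = newb)
      } else if (is.null(sites$edits[[i]])) {
        sites$edits[[i]] <- tibble(pos = integer(0), new_base = character(0))
      }
    }

    # full planted cassette footprint (spacer + PAM), forward coords
    cass <- lapply(seq_len(nrow(sites)), function(i) {
      rec <- sites$record[i]
      if (!rec %in% names(genome)) abort(sprintf("unknown record '%s'", rec))
      site_spacer <- apply_edits(spacer, sites$edits[[i]])
      if (model$side == "three_prime") {
        fwd_insert <- paste0(site_spacer, pam_seq)
      } else {
        fwd_insert <- paste0(pam_seq, site_spacer)
      }
      off <- sites$offset[i]
      if (sites$strand[i] == "-") fwd_insert <- revcomp(fwd_insert)
      win_start <- if (model$side == "three_prime") {
        if (sites$strand[i] == "+") off else off - P
      } else {
        if (sites$strand[i] == "+") off - P else off
      }
      win_end <- win_start + L + P
      if (win_start < 0 || win_end > nchar(genome[[rec]])) {
        abort(sprintf("planted site %d does not fit in record '%s'", i, rec))
      }
      list(record = rec, win_start = win_start, win_end = win_end,
           insert = fwd_insert, site_spacer = site_spacer,
           sp_start = sites$offset[i], sp_end = sites$offset[i] + L,
           strand = sites$strand[i],
           mismatch_count = nrow(sites$edits[[i]]))
    })

    # overlap check between plants
    for (i in seq_along(cass)) for (j in seq_along(cass)) {
      if (i < j && cass[[i]]$record == cass[[j]]$record &&
          cass[[i]]$win_start < cass[[j]]$win_end &&
          cass[[j]]$win_start < cass[[i]]$win_end) {
        abort("planted sites overlap")
      }
    }

    for (cs in cass) {
      s <- genome[[cs$record]]
      substr(s, cs$win_start + 1, cs$win_end) <- cs$insert
      genome[[cs$record]] <- s
    }

    # rejection: rewrite background windows close to the spacer
    protected <- lapply(cass, function(cs) {
      c(cs$win_start - L, cs$win_end + L)  # margin so rewrites never touch plants
    })
    for (iter in 1:50) {
      coll <- background_collisions(genome, spacer, clean_within, cass, L)
      if (nrow(coll) == 0) break
      for (k in seq_len(nrow(coll))) {
        rec <- coll$record[k]
        s0 <- coll$start[k]
        repl <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                      collapse = "")
        s <- genome[[rec]]
        substr(s, s0 + 1, s0 + L) <- repl
        genome[[rec]] <- s
      }
    }
    if (nrow(background_collisions(genome, spacer, clean_within, cass, L)) > 0) {
      abort("could not clean background near-matches after 50 rounds")
    }

    truth <- bind_rows(lapply(cass, function(cs) {
      tibble(record = cs$record, start = as.integer(cs$sp_start),
             end = as.integer(cs$sp_end), strand = cs$strand,
             site_spacer = cs$site_spacer, site_pam = pam_seq,
             mismatch_count = as.integer(cs$mismatch_count))
    }))
    list(genome = genome, truth = arrange(truth, .data$record, .data$start))
  })
}

# All background windows (either orientation, no PAM requirement)
# within `d` mismatches of `spacer`, excluding a margin around plants.
background_collisions <- function(genome, spacer, d, cass, L) {
  hits <- hamming_scan(genome, spacer, d)
  if (nrow(hits) == 0) return(hits)
  keep <- vapply(seq_len(nrow(hits)), function(i) {
    for (cs in cass) {
      if (cs$record == hits$record[i] &&
          hits$start[i] < cs$win_end + L && hits$start[i] + L > cs$win_start - L) {
        return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  hits[keep, , drop = FALSE]
}

# Vectorised Hamming scan: all windows of length nchar(spacer) on both
# strands of each record with distance <= d. Internal; also the basis
# of the brute-force oracles in the test-suite.
hamming_scan <- function(genome, spacer, d) {
  genome <- as_genome(genome)
  L <- nchar(spacer)
  g <- strsplit(spacer, "")[[1]]
  out <- list()
  for (rec in names(genome)) {
    for (str in c("+", "-")) {
      s <- if (str == "+") genome[[rec]] else revcomp(genome[[rec]])
      n <- nchar(s)
      if (n < L) next
      v <- strsplit(s, "")[[1]]
      npos <- n - L + 1
      mm <- integer(npos)
      for (i in seq_len(L)) {
        mm <- mm + (v[i:(i + npos - 1)] != g[i])
      }
      sel <- which(mm <= d)
      if (length(sel) == 0) next
      start0 <- if (str == "+") sel - 1L else n - (sel + L - 1L)
      out[[length(out) + 1]] <- tibble(record = rec,
                                       start = as.integer(start0),
                                       strand = str,
                                       mismatch_count = as.integer(mm[sel]))
    }
  }
  if (length(out) == 0) {
    return(tibble(record = character(0), start = integer(0),
                  strand = character(0), mismatch_count = integer(0)))
  }
  arrange(bind_rows(out), .data$record, .data$start, .data$strand)
}

#' Toy gene annotation generator
#'
#' Lays out non-overlapping multi-exon genes along the records of a
#' genome and emits both syntactically valid GFF3 text and the matching
#' truth gene models (same shape as [load_annotation()] output), so
#' extraction can be tested round-trip. Each gene gets an explicit
#' 5' UTR, a CDS whose length is a multiple of 3, and a 3' UTR, split
#' over 1-3 exons; strands alternate deterministically under the seed.
#'
#' @param genome Genome input accepted by [as_genome()].
#' @param n_genes Number of genes to place.
#' @param seed Integer seed.
#' @return List with `gff` (character vector of GFF3 lines) and
#'   `models` (truth tibble of gene models).
#' @export
toy_annotation <- function(genome, n_genes, seed = 1) {
  genome <- as_genome(genome)
  with_seed(seed, {
    rec_ids <- names(genome)
    gff <- c("##gff-version 3")
    models <- list()
    cursor <- setNames(rep(100L, length(genome)), rec_ids)
    for (gi in seq_len(n_genes)) {
      gene_id <- sprintf("gene%03d", gi)
      tx_id <- paste0(gene_id, ".t1")
      rec <- rec_ids[(gi - 1) %% length(rec_ids) + 1]
      strand <- if (gi %% 2 == 1) "+" else "-"
      n_exons <- sample(1:3, 1)
      utr5_len <- sample(30:80, 1)
      utr3_len <- sample(30:80, 1)
      cds_len <- 3 * sample(40:120, 1)
      intron_lens <- if (n_exons > 1) sample(50:150, n_exons - 1) else integer(0)
      tx_len <- utr5_len + cds_len + utr3_len
      # split the transcript into exons (genomic order on the + layout)
      cuts <- if (n_exons > 1) sort(sample(seq(20, tx_len - 20, by = 1), n_exons - 1)) else integer(0)
      exon_lens <- diff(c(0, cuts, tx_len))
      start0 <- cursor[[rec]]
      gene_len <- sum(exon_lens) + sum(intron_lens)
      if (start0 + gene_len + 100 > nchar(genome[[rec]])) {
        abort(sprintf("record '%s' too short to place %s", rec, gene_id))
      }
      exon_starts <- integer(n_exons)
      pos <- start0
      exons <- list()
      for (e in seq_len(n_exons)) {
        exons[[e]] <- c(pos, pos + exon_lens[e])
        pos <- pos + exon_lens[e] + if (e < n_exons) intron_lens[e] else 0L
      }
      gene_end0 <- exons[[n_exons]][2]
      cursor[[rec]] <- gene_end0 + sample(150:300, 1)

      # transcript-coordinate segmentation: 5' UTR | CDS | 3' UTR
      # (transcript orientation; on "-" the genomic-leftmost exon is the
      # transcript 3' end)
      seg_tx <- c(utr5 = utr5_len, cds = cds_len, utr3 = utr3_len)
      exon_tbl <- tibble(start = vapply(exons, `[`, numeric(1), 1),
                         end = vapply(exons, `[`, numeric(1), 2))
      tx_map <- genomic_segments(exon_tbl, seg_tx, strand)

      models[[gi]] <- tibble(
        gene_id = gene_id, transcript_id = tx_id, record_id = rec,
        strand = strand,
        gene_start = as.integer(start0), gene_end = as.integer(gene_end0),
        exons = list(mutate(exon_tbl, start = as.integer(.data$start),
                            end = as.integer(.data$end))),
        cds = list(tx_map$cds), utr5 = list(tx_map$utr5), utr3 = list(tx_map$utr3)
      )

      g1 <- function(iv) sprintf("%d\t%d", iv$start + 1L, iv$end)  # to 1-based inclusive
      gff <- c(gff,
        sprintf("%s\tguidecraft\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                rec, start0 + 1L, gene_end0, strand, gene_id),
        sprintf("%s\tguidecraft\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                rec, start0 + 1L, gene_end0, strand, tx_id, gene_id),
        sprintf("%s\tguidecraft\texon\t%s\t.\t%s\t.\tParent=%s",
                rec, g1(exon_tbl), strand, tx_id),
        sprintf("%s\tguidecraft\tfive_prime_UTR\t%s\t.\t%s\t.\tParent=%s",
                rec, g1(tx_map$utr5), strand, tx_id),
        sprintf("%s\tguidecraft\tCDS\t%s\t.\t%s\t0\tParent=%s",
                rec, g1(tx_map$cds), strand, tx_id),
        sprintf("%s\tguidecraft\tthree_prime_UTR\t%s\t.\t%s\t.\tParent=%s",
                rec, g1(tx_map$utr3), strand, tx_id)
      )
    }
    list(gff = gff, models = bind_rows(models))
  })
}

# Map transcript-coordinate segments (5'UTR, CDS, 3'UTR lengths) onto
# genomic exon intervals, honouring strand. Returns genomic-order
# interval tibbles per segment.
genomic_segments <- function(exon_tbl, seg_tx, strand) {
  exon_order <- if (strand == "+") seq_len(nrow(exon_tbl)) else rev(seq_len(nrow(exon_tbl)))
  bounds <- cumsum(seg_tx)
  seg_names <- names(seg_tx)
  res <- setNames(vector("list", length(seg_tx)), seg_names)
  for (nm in seg_names) res[[nm]] <- list()
  tx_pos <- 0
  for (ei in exon_order) {
    ex_start <- exon_tbl$start[ei]; ex_end <- exon_tbl$end[ei]
    ex_len <- ex_end - ex_start
    for (si in seq_along(seg_names)) {
      seg_lo <- if (si == 1) 0 else bounds[si - 1]
      seg_hi <- bounds[si]
      ov_lo <- max(tx_pos, seg_lo)
      ov_hi <- min(tx_pos + ex_len, seg_hi)
      if (ov_hi <= ov_lo) next
      if (strand == "+") {
        g_lo <- ex_start + (ov_lo - tx_pos)
        g_hi <- ex_start + (ov_hi - tx_pos)
      } else {
        g_hi <- ex_end - (ov_lo - tx_pos)
        g_lo <- ex_end - (ov_hi - tx_pos)
      }
      res[[seg_names[si]]][[length(res[[seg_names[si]]]) + 1]] <-
        tibble(start = as.integer(g_lo), end = as.integer(g_hi))
    }
    tx_pos <- tx_pos + ex_len
  }
  lapply(res, function(lst) {
    if (length(lst) == 0) {
      tibble(start = integer(0), end = integer(0))
    } else {
      arrange(bind_rows(lst), .data$start)
    }
  })
}

#' Write a genome to FASTA
#'
#' @param genome Genome input accepted by [as_genome()].
#' @param path Output path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  genome <- as_genome(genome)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
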