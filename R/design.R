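#' Design parameters
#'
#' Bundles the tunable knobs of the design pipeline. `max_mismatch` is
#' INCLUSIVE (default 4: off-target sites with 0-4 base differences are
#' reported, i.e. "less than five"). Non-unique guides are retained and
#' marked, never dropped; `require_unique` only controls whether
#' uniqueness dominates the ranking.
#'
#' @param pam_model_name Registered PAM model name.
#' @param max_mismatch Inclusive off-target mismatch bound (>= 0).
#' @param require_unique Rank unique guides first? Default TRUE.
#' @param gc_bounds Length-2 numeric in `[0,1]`: guides outside are
#'   marked `gc_ok = FALSE` (marking only).
#' @param top_k Keep the top k ranked guides (`Inf` = all).
#' @param exclude_on_target Exclude the on-target locus from the
#'   off-target hit list? Default TRUE.
#' @param pam_mode Off-target PAM admission (`"relaxed"`/`"canonical"`).
#' @param scaffold Scaffold sequence appended 3' of the spacer for the
#'   hairpin check ("" = spacer only).
#' @param min_stem,min_loop Hairpin scan parameters.
#' @return A `design_params` list.
#' @export
design_params <- function(pam_model_name = "SpCas9-NGG", max_mismatch = 4,
                          require_unique = TRUE, gc_bounds = c(0, 1),
                          top_k = Inf, exclude_on_target = TRUE,
                          pam_mode = "relaxed", scaffold = "",
                          min_stem = 4, min_loop = 3) {
  stopifnot(max_mismatch >= 0, length(gc_bounds) == 2,
            gc_bounds[1] >= 0, gc_bounds[1] <= gc_bounds[2], gc_bounds[2] <= 1)
  structure(
    list(pam_model_name = pam_model_name,
         max_mismatch = as.integer(max_mismatch),
         require_unique = isTRUE(require_unique),
         gc_bounds = as.numeric(gc_bounds),
         top_k = top_k,
         exclude_on_target = isTRUE(exclude_on_target),
         pam_mode = pam_mode,
         scaffold = toupper(scaffold),
         min_stem = as.integer(min_stem), min_loop = as.integer(min_loop)),
    class = "design_params"
  )
}

# Exact full-length occurrences of `target` in the genome, both
# strands; used as on-target loci when the caller gives no locus.
locate_target <- function(target, genome, subjects = NULL) {
  genome <- as_genome(genome)
  if (is.null(subjects)) subjects <- make_subjects(genome)
  rows <- list()
  for (ri in seq_along(genome)) {
    n <- subjects$n[ri]
    for (str in c("+", "-")) {
      subj <- if (str == "+") subjects$plus[[ri]] else subjects$minus[[ri]]
      m <- Biostrings::matchPattern(target, subj, max.mismatch = 0, fixed = TRUE)
      for (s in Biostrings::start(m)) {
        e <- s + nchar(target) - 1L
        if (str == "+") {
          rows[[length(rows) + 1]] <- tibble(record = names(genome)[ri],
                                             start = s - 1L, end = e)
        } else {
          rows[[length(rows) + 1]] <- tibble(record = names(genome)[ri],
                                             start = n - e, end = n - s + 1L)
        }
      }
    }
  }
  if (length(rows) == 0) {
    tibble(record = character(0), start = integer(0), end = integer(0))
  } else {
    bind_rows(rows)
  }
}

# Spacer context on the target for the activity model: flank_5 bases
# before the spacer, flank_3 after (strand aware). NA when flanks run
# off the target.
spacer_context <- function(target, start, end, strand, amodel) {
  want <- amodel$context_length
  flank5 <- amodel$spacer_window[1] - 1L
  flank3 <- want - amodel$spacer_window[2]
  n <- nchar(target)
  vapply(seq_along(start), function(i) {
    if (strand[i] == "+") {
      lo <- start[i] - flank5
      hi <- end[i] + flank3
      if (lo < 0 || hi > n) return(NA_character_)
      substring(target, lo + 1, hi)
    } else {
      lo <- start[i] - flank3
      hi <- end[i] + flank5
      if (lo < 0 || hi > n) return(NA_character_)
      revcomp(substring(target, lo + 1, hi))
    }
  }, character(1))
}

#' Design sgRNAs for one target sequence
#'
#' The full pipeline: enumerate PAM-adjacent candidates on the target,
#' mark genome-wide uniqueness against the pre-built index, search
#' off-target sites in the genome (the on-target locus excluded),
#' compute quality features (GC, poly-T/A, hairpin, activity,
#' specificity) and rank. The index must have been built from the same
#' genome with the same PAM model (checked via the genome digest).
#'
#' Ranking key: unique first (when `require_unique`), then specificity
#' desc, activity desc (missing last), then position; final tie-break
#' `(start, strand)` makes the order fully deterministic.
#'
#' @param target Target sequence (a single string over `{A,C,G,T,N}`).
#' @param index A [build_index()] / [load_index()] result.
#' @param genome Genome input accepted by [as_genome()].
#' @param params A [design_params()].
#' @param target_locus Optional tibble (`record`, `start`, `end`;
#'   0-based half-open) giving the target's genomic location(s). When
#'   omitted, exact full-length matches of `target` in the genome are
#'   used.
#' @param target_id Label used in reports (default `"target"`).
#' @return A `guide_design` tibble (one row per candidate, ranked) with
#'   a `hits` list-column of off-target tables; parameters and
#'   provenance in attributes.
#' @export
design_for_sequence <- function(target, index, genome, params = design_params(),
                                target_locus = NULL, target_id = "target") {
  stopifnot(inherits(index, "uniqueness_index"), inherits(params, "design_params"))
  genome <- as_genome(genome)
  model <- pam_model(params$pam_model_name)
  if (model$name != index$model_name) {
    abort(sprintf("index was built with PAM model '%s' but params request '%s'",
                  index$model_name, params$pam_model_name))
  }
  dig <- genome_digest(genome)
  if (dig != index$genome_digest) {
    abort("index/genome provenance mismatch: the index was built from a different sequence set")
  }
  target <- toupper(target)
  cands <- enumerate_protospacers(target, model)
  subjects <- make_subjects(genome)
  ptab <- penalty_table(model)
  amodel <- activity_model()

  loci <- if (!params$exclude_on_target) {
    NULL
  } else if (!is.null(target_locus)) {
    target_locus
  } else {
    locate_target(target, genome, subjects)
  }

  annotate_candidates(cands, target, target_id, index, genome, model, params,
                      loci, subjects, ptab, amodel)
}

annotate_candidates <- function(cands, target, target_id, index, genome, model,
                                params, loci, subjects, ptab, amodel) {
  n_c <- nrow(cands)
  if (n_c == 0) {
    res <- tibble(target_id = character(0), guide_id = character(0),
                  start = integer(0), end = integer(0), strand = character(0),
                  spacer = character(0), pam = character(0),
                  occurrence_count = integer(0), is_unique = logical(0),
                  gc = numeric(0), gc_ok = logical(0), poly_ta = logical(0),
                  hairpin = logical(0), activity = numeric(0),
                  specificity = numeric(0), n_offtargets = integer(0),
                  hits = list(), rank = integer(0))
    return(new_guide_design(res, params, target_id, nchar(target),
                            index$genome_digest))
  }
  occ <- occurrence_count(index, cands$spacer)
  hits <- lapply(seq_len(n_c), function(i) {
    h <- find_offtargets(cands$spacer[i], genome, model,
                         max_diff_exclusive = params$max_mismatch + 1L,
                         exclude = loci, table = ptab,
                         pam_mode = params$pam_mode)
    h
  })
  spac_scaffold <- paste0(cands$spacer, params$scaffold)
  can_activity <- model$side == "three_prime" &&
    model$spacer_length == (amodel$spacer_window[2] - amodel$spacer_window[1] + 1L)
  activity <- if (can_activity) {
    ctx <- spacer_context(target, cands$start, cands$end, cands$strand, amodel)
    vapply(ctx, function(x) if (is.na(x)) NA_real_ else activity_score(x, amodel),
           numeric(1), USE.NAMES = FALSE)
  } else {
    rep(NA_real_, n_c)
  }
  res <- mutate(cands,
    target_id = target_id,
    occurrence_count = occ,
    is_unique = occ == 1L,
    gc = gc_content(.data$spacer),
    gc_ok = .data$gc >= params$gc_bounds[1] & .data$gc <= params$gc_bounds[2],
    poly_ta = poly_ta_flag(.data$spacer),
    hairpin = map_lgl(spac_scaffold, hairpin_flag,
                      min_stem = params$min_stem, min_loop = params$min_loop),
    activity = activity,
    specificity = map_dbl(hits, specificity_score),
    n_offtargets = map_int(hits, nrow),
    hits = hits
  )
  act_key <- ifelse(is.na(res$activity), -Inf, res$activity)  # missing sorts last
  ord <- order(
    if (params$require_unique) -as.integer(res$is_unique) else rep(0L, n_c),
    -res$specificity,
    -act_key,
    res$start,
    match(res$strand, c("+", "-"))  # locale-independent tie-break
  )
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(n_c)
  res$guide_id <- sprintf("%s_sg%03d", target_id, res$rank)
  if (is.finite(params$top_k)) res <- head(res, params$top_k)
  res <- select(res, "target_id", "guide_id", "start", "end", "strand",
                "spacer", "pam", "occurrence_count", "is_unique", "gc",
                "gc_ok", "poly_ta", "hairpin", "activity", "specificity",
                "n_offtargets", "hits", "rank")
  new_guide_design(res, params, target_id, nchar(target), index$genome_digest)
}

new_guide_design <- function(tbl, params, target_id, target_length, digest) {
  structure(tbl,
            class = c("guide_design", class(tibble())),
            params = params, target_id = target_id,
            target_length = target_length, genome_digest = digest)
}

#' @export
print.guide_design <- function(x, ...) {
  cat(sprintf("<guide_design> %d guide(s) for '%s' (%d nt target); %d unique, %d flagged poly-T/A\n",
              nrow(x), attr(x, "target_id"), attr(x, "target_length"),
              sum(x$is_unique), sum(x$poly_ta)))
  NextMethod()
}

#' Search shared sgRNAs across a group of genes
#'
#' Returns guides whose spacer occurs with a valid PAM in EVERY target
#' sequence — candidates for multiplex editing of polygenic traits.
#' For a shared guide, the ideal genome-wide occurrence count equals
#' the number of target genes (each occurrence accounted for by one
#' target); `is_unique` encodes that condition, and surplus genomic
#' occurrences surface as mismatch-0 off-target hits.
#'
#' @param targets Named character vector (or named list) of >= 2 target
#'   sequences.
#' @param index,genome,params As in [design_for_sequence()].
#' @return A `guide_design` tibble with an extra `gene_hits`
#'   list-column giving per-gene occurrence coordinates.
#' @export
shared_guides <- function(targets, index, genome, params = design_params()) {
  targets <- unlist(targets)
  if (length(targets) < 2) abort("shared_guides() needs at least 2 target sequences")
  if (is.null(names(targets)) || anyDuplicated(names(targets))) {
    abort("targets must have unique names")
  }
  stopifnot(inherits(index, "uniqueness_index"))
  genome <- as_genome(genome)
  model <- pam_model(params$pam_model_name)
  dig <- genome_digest(genome)
  if (dig != index$genome_digest) {
    abort("index/genome provenance mismatch: the index was built from a different sequence set")
  }
  targets <- toupper(targets)
  per_gene <- lapply(targets, enumerate_protospacers, model = model)
  shared <- Reduce(intersect, lapply(per_gene, function(x) x$spacer))
  subjects <- make_subjects(genome)
  ptab <- penalty_table(model)

  loci <- bind_rows(lapply(targets, locate_target, genome = genome,
                           subjects = subjects))

  n_genes <- length(targets)
  rows <- lapply(shared, function(sp) {
    gene_hits <- bind_rows(imap(per_gene, function(cand, gid) {
      hit <- filter(cand, .data$spacer == sp)
      tibble(target_id = gid, start = hit$start, end = hit$end,
             strand = hit$strand, pam = hit$pam)
    }))
    occ <- occurrence_count(index, sp)
    hits <- find_offtargets(sp, genome, model,
                            max_diff_exclusive = params$max_mismatch + 1L,
                            exclude = if (params$exclude_on_target) loci else NULL,
                            table = ptab, pam_mode = params$pam_mode)
    first <- gene_hits[1, ]
    tibble(
      spacer = sp, pam = first$pam,
      start = first$start, end = first$end, strand = first$strand,
      occurrence_count = occ,
      is_unique = occ == n_genes,
      n_genes_hit = length(unique(gene_hits$target_id)),
      gc = gc_content(sp),
      poly_ta = poly_ta_flag(sp),
      hairpin = hairpin_flag(paste0(sp, params$scaffold),
                             params$min_stem, params$min_loop),
      specificity = specificity_score(hits),
      n_offtargets = nrow(hits),
      gene_hits = list(gene_hits), hits = list(hits)
    )
  })
  res <- if (length(rows) == 0) {
    tibble(spacer = character(0), pam = character(0), start = integer(0),
           end = integer(0), strand = character(0),
           occurrence_count = integer(0), is_unique = logical(0),
           n_genes_hit = integer(0), gc = numeric(0), poly_ta = logical(0),
           hairpin = logical(0), specificity = numeric(0),
           n_offtargets = integer(0), gene_hits = list(), hits = list())
  } else {
    bind_rows(rows)
  }
  if (nrow(res) > 0) {
    ord <- order(-as.integer(res$is_unique), -res$specificity, res$spacer)
    res <- res[ord, , drop = FALSE]
    res$rank <- seq_len(nrow(res))
    res$guide_id <- sprintf("shared_sg%03d", res$rank)
    res$target_id <- "shared"
    res$activity <- NA_real_
  } else {
    res$rank <- integer(0)
    res$guide_id <- character(0)
    res$target_id <- character(0)
    res$activity <- numeric(0)
  }
  new_guide_design(res, params, "shared",
                   as.integer(max(nchar(targets))), index$genome_digest)
}

#' Batch sgRNA design over many targets
#'
#' Runs [design_for_sequence()] for each target independently;
#' per-target output is identical to a single-target run, iterated in
#' input order.
#'
#' @param targets Named character vector (or named list) of target
#'   sequences with unique, non-empty IDs.
#' @inheritParams design_for_sequence
#' @return Named list of `guide_design` objects, one per target.
#' @export
batch_design <- function(targets, index, genome, params = design_params()) {
  targets <- unlist(targets)
  if (length(targets) == 0) abort("batch_design() needs at least one target")
  if (is.null(names(targets)) || any(!nzchar(names(targets)))) {
    abort("all targets must be named")
  }
  if (anyDuplicated(names(targets))) {
    abort(sprintf("duplicate target ID(s): %s",
                  paste(unique(names(targets)[duplicated(names(targets))]),
                        collapse = ", ")))
  }
  out <- lapply(names(targets), function(id) {
    design_for_sequence(targets[[id]], index, genome, params, target_id = id)
  })
  setNames(out, names(targets))
}
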