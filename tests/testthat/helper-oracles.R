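# Independent brute-force oracles. These deliberately share no code
# path with the package internals: plain whole-vector scans over
# character arrays, with their own IUPAC table.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(x, function(s) {
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# logical vector over window start positions (1-based) where the IUPAC
# pattern matches; windows containing N never match.
oracle_pam_ok <- function(chars, pattern) {
  pc <- strsplit(pattern, "")[[1]]
  P <- length(pc)
  n <- length(chars)
  if (n < P) return(logical(0))
  npos <- n - P + 1
  ok <- rep(TRUE, npos)
  for (i in seq_len(P)) {
    ok <- ok & chars[i:(i + npos - 1)] %in% ORACLE_IUPAC[[pc[i]]]
  }
  ok
}

# Exhaustive protospacer scan of one sequence: every window matching
# the PAM with a full-length N-free spacer next to it, both strands.
oracle_protospacers <- function(seq, model, both_strands = TRUE) {
  L <- model$spacer_length
  P <- nchar(model$pattern)
  scan <- function(s) {
    chars <- strsplit(s, "")[[1]]
    n <- length(chars)
    empty <- data.frame(start = integer(0), end = integer(0),
                        strand = character(0), spacer = character(0),
                        pam = character(0), stringsAsFactors = FALSE)
    if (n < L + P) return(empty)
    pam_pos <- which(oracle_pam_ok(chars, model$pattern))
    if (model$side == "three_prime") {
      sp_s <- pam_pos - L
    } else {
      sp_s <- pam_pos + P
    }
    keep <- sp_s >= 1 & sp_s + L - 1 <= n
    sp_s <- sp_s[keep]; pam_pos <- pam_pos[keep]
    if (length(sp_s) == 0) return(empty)
    spacer <- substring(s, sp_s, sp_s + L - 1)
    ok <- !grepl("N", spacer, fixed = TRUE)
    data.frame(start = sp_s[ok] - 1L, end = sp_s[ok] + L - 1L,
               strand = rep("+", sum(ok)), spacer = spacer[ok],
               pam = substring(s, pam_pos[ok], pam_pos[ok] + P - 1),
               stringsAsFactors = FALSE)
  }
  out <- scan(seq)
  if (both_strands) {
    n <- nchar(seq)
    mn <- scan(oracle_revcomp(seq))
    if (nrow(mn) > 0) {
      mn$strand <- "-"
      tmp_start <- n - mn$end
      mn$end <- n - mn$start
      mn$start <- tmp_start
      out <- rbind(out, mn)
    }
  }
  out[order(out$start, out$strand, method = "radix"), , drop = FALSE]
}

# Exhaustive bounded-Hamming off-target scan with PAM admission.
# `pam_pattern` is the admission pattern (pass the relaxed pattern to
# mirror the default search). Skips windows containing N.
oracle_offtargets <- function(genome, spacer, model, max_diff_exclusive,
                              pam_pattern = model$pattern) {
  L <- nchar(spacer)
  P <- nchar(model$pattern)
  g <- strsplit(spacer, "")[[1]]
  rows <- list()
  for (rec in names(genome)) {
    for (str in c("+", "-")) {
      s <- if (str == "+") genome[[rec]] else oracle_revcomp(genome[[rec]])
      chars <- strsplit(s, "")[[1]]
      n <- length(chars)
      if (n < L + P) next
      npos <- n - L + 1
      mm <- integer(npos)
      hasN <- rep(FALSE, npos)
      for (i in seq_len(L)) {
        w <- chars[i:(i + npos - 1)]
        mm <- mm + (w != g[i])
        hasN <- hasN | w == "N"
      }
      pam_ok_vec <- oracle_pam_ok(chars, pam_pattern)
      cand <- which(mm < max_diff_exclusive & !hasN)
      if (model$side == "three_prime") {
        pam_s <- cand + L
        good <- pam_s + P - 1 <= n
        good[good] <- pam_ok_vec[pam_s[good]]
      } else {
        pam_s <- cand - P
        good <- pam_s >= 1
        good[good] <- pam_ok_vec[pam_s[good]]
      }
      cand <- cand[good]; pam_s <- pam_s[good]
      if (length(cand) == 0) next
      if (str == "+") {
        start0 <- cand - 1L; end0 <- cand + L - 1L
      } else {
        start0 <- n - (cand + L - 1L); end0 <- n - (cand - 1L)
      }
      rows[[length(rows) + 1]] <- data.frame(
        record_id = rec, start = as.integer(start0), end = as.integer(end0),
        strand = str,
        site_spacer = substring(s, cand, cand + L - 1),
        site_pam = substring(s, pam_s, pam_s + P - 1),
        mismatch_count = as.integer(mm[cand]), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(record_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      site_spacer = character(0), site_pam = character(0),
                      mismatch_count = integer(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$record_id, out$start, out$strand, method = "radix"), , drop = FALSE]
}

# Brute-force spacer occurrence dictionary over a whole genome.
oracle_spacer_counts <- function(genome, model) {
  all_spacers <- unlist(lapply(names(genome), function(rec) {
    oracle_protospacers(genome[[rec]], model)$spacer
  }))
  if (length(all_spacers) == 0) return(integer(0))
  tab <- table(all_spacers)
  stats::setNames(as.integer(tab), names(tab))
}

# Sorted comparable view of a hit table (implementation or oracle).
hit_key <- function(df) {
  if (nrow(df) == 0) return(character(0))
  sort(paste(df$record_id, df$start, df$end, df$strand, df$site_spacer,
             df$site_pam, df$mismatch_count, sep = "|"))
}

# Shared fixture: a genome with a region copied into three synthetic
# gene sequences, used by shared-guide tests.
make_shared_fixture <- function(seed = 31) {
  cassette <- "ACGTACGGACTGACGGTCAGTGG"  # 20-nt spacer + TGG PAM
  g <- random_genome(1, 30000, seed = seed)
  genes <- list()
  pos <- c(2000, 10000, 20000)
  gg <- g[[1]]
  for (i in 1:3) {
    gene <- random_genome(1, 600, seed = 100 + i)[[1]]
    substr(gene, 301, 323) <- cassette
    substr(gg, pos[i] + 1, pos[i] + 600) <- gene
    genes[[paste0("gene", i)]] <- gene
  }
  g[["ctg01"]] <- gg
  list(genome = g, genes = unlist(genes),
       spacer = substr(cassette, 1, 20))
}
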