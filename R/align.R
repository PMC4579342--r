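# Built-in exact mini-mapper for desk-scale references: exact 31-mer seeds
# (Aho-Corasick via Biostrings::matchPDict) extended ungapped with a
# mismatch cap. Replaces an external short-read aligner for references up to
# a few tens of Mb; the pass-1 and pass-2 SAM dialects match what an
# external aligner would feed the pipeline.

# Deterministic per-(read, position) hash for tie-breaking; mimics the
# randomized best-hit choice of production aligners while staying
# reproducible for a given seed.
.tie_hash <- function(read_id, rname, pos, seed) {
  v <- utf8ToInt(read_id)
  h <- sum(v * (seq_along(v) %% 13L + 1L))
  ((h * 2654435761) %% 2147483647 + pos * 97 + nchar(rname) * 131 +
     seed * 16807) %% 1e9
}

#' Align reads with the built-in exact-seed mini-mapper
#'
#' Seeds: exact 31-mers at up to three offsets per orientation; extension:
#' ungapped comparison of the full read against the reference with at most
#' `max_mismatch` mismatches. `single` mode returns the best hit per read
#' (ties broken by a seeded deterministic hash) with a weight-based MAPQ;
#' `multi` mode returns up to `max_hits` scored hits per read in
#' deterministic order (score desc, then reference, position, strand).
#'
#' @param reads data frame with `read_id`, `seq`, `qual`, `end_marker`.
#' @param reference named character vector of reference sequences.
#' @param mode `"single"` (pass-1 contract) or `"multi"` (pass-2 contract).
#' @param max_hits cap on reported hits per read in multi mode.
#' @param max_mismatch mismatch cap for a valid hit.
#' @param seed_k seed length (bp).
#' @param base_error assumed per-base error rate for the weight-based MAPQ.
#' @param seed integer seed for the tie-break hash.
#' @return SAM-style data frame (`qname`, `flag`, `rname`, `pos` 1-based,
#'   `mapq`, `cigar`, `seq` reference-oriented, `qual`, `nm`, `score`, `em`)
#'   with one record per hit; unmapped reads get flag 4 records. Single mode
#'   adds `n_best` (count of score-tied best hits) and `n_hits`.
#' @export
mini_align <- function(reads, reference, mode = c("single", "multi"),
                       max_hits = 20, max_mismatch = 5, seed_k = 31,
                       base_error = 0.002, seed = 1) {
  mode <- match.arg(mode)
  n <- nrow(reads)
  if (n == 0L) return(.empty_sam(mode))
  L <- nchar(reads$seq[1])
  stopifnot(all(nchar(reads$seq) == L), L >= seed_k)

  fwd <- reads$seq
  rev <- revcomp(fwd)
  offs <- unique(c(1L, as.integer(L / 2) - seed_k %/% 2L, L - seed_k + 1L))
  offs <- offs[offs >= 1L & offs + seed_k - 1L <= L]

  # pattern block: for each orientation and seed offset, one 31-mer per read
  pats <- c(vapply(offs, function(o) substring(fwd, o, o + seed_k - 1L),
                   character(n)),
            vapply(offs, function(o) substring(rev, o, o + seed_k - 1L),
                   character(n)))
  block <- length(offs) * n
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(pats))

  cand <- NULL
  for (ri in seq_along(reference)) {
    subj <- Biostrings::DNAString(reference[[ri]])
    hits <- Biostrings::matchPDict(pd, subj)
    cnt <- S4Vectors::elementNROWS(hits)
    if (sum(cnt) == 0L) next
    pidx <- rep(seq_along(pats), cnt)
    pos <- unlist(Biostrings::startIndex(hits), use.names = FALSE)
    is_rev <- pidx > block
    k <- ifelse(is_rev, pidx - block, pidx)
    seed_off <- offs[(k - 1L) %/% n + 1L]
    ridx <- (k - 1L) %% n + 1L
    start <- pos - (seed_off - 1L)              # 1-based candidate read start
    ok <- start >= 1L & start + L - 1L <= nchar(reference[[ri]])
    cand <- rbind(cand, data.frame(ridx = ridx[ok], ref = ri,
                                   start = start[ok], rev = is_rev[ok]))
  }
  if (is.null(cand)) cand <- data.frame(ridx = integer(), ref = integer(),
                                        start = integer(), rev = logical())
  cand <- cand[!duplicated(cand), , drop = FALSE]

  # extension: mismatch count of oriented read vs reference window
  if (nrow(cand)) {
    rseq <- ifelse(cand$rev, rev[cand$ridx], fwd[cand$ridx])
    gseq <- substring(reference[cand$ref], cand$start, cand$start + L - 1L)
    raw_r <- lapply(rseq, charToRaw)
    raw_g <- lapply(gseq, charToRaw)
    cand$nm <- mapply(function(a, b) sum(a != b), raw_r, raw_g)
    cand <- cand[cand$nm <= max_mismatch, , drop = FALSE]
  } else cand$nm <- integer()

  ref_names <- names(reference)
  log_w1 <- log10(base_error / 3) - log10(1 - base_error)  # per mismatch
  qual_rev <- vapply(reads$qual, function(q)
    intToUtf8(base::rev(utf8ToInt(q))), "", USE.NAMES = FALSE)

  keep <- NULL
  if (nrow(cand)) {
    cand$score <- L - 6L * cand$nm
    cand$rname <- ref_names[cand$ref]
    nh <- tabulate(cand$ridx, nbins = n)
    if (mode == "single") {
      best_score <- vapply(split(cand$score, cand$ridx), max, 0)
      cand$is_best <- cand$score == best_score[as.character(cand$ridx)]
      cand$tb <- vapply(seq_len(nrow(cand)), function(k)
        .tie_hash(reads$read_id[cand$ridx[k]], cand$rname[k], cand$start[k],
                  seed), 0)
      # weight-based posterior of the picked hit among all hits of the read
      w <- 10^(cand$nm * log_w1)
      wsum <- rowsum(w, cand$ridx)
      wtot <- numeric(n)
      wtot[as.integer(rownames(wsum))] <- wsum
      ord <- order(cand$ridx, -cand$score, cand$tb)
      keep <- cand[ord[!duplicated(cand$ridx[ord])], , drop = FALSE]
      keep$n_best <- vapply(split(cand$is_best, cand$ridx), sum,
                            0L)[as.character(keep$ridx)]
      keep$n_hits <- nh[keep$ridx]
      keep$mapq <- posterior_to_mapq(10^(keep$nm * log_w1) / wtot[keep$ridx])
    } else {
      ord <- order(cand$ridx, -cand$score, cand$ref, cand$start, cand$rev)
      cand <- cand[ord, , drop = FALSE]
      rank <- sequence(rle(cand$ridx)$lengths)
      keep <- cand[rank <= max_hits, , drop = FALSE]
      keep$mapq <- 255L
      keep$n_best <- NA_integer_
      keep$n_hits <- nh[keep$ridx]
    }
  }
  mk <- function(h) data.frame(
    qname = reads$read_id[h$ridx],
    flag = ifelse(h$rev, 16L, 0L),
    rname = h$rname, pos = h$start, mapq = h$mapq,
    cigar = sprintf("%dM", L),
    seq = ifelse(h$rev, rev[h$ridx], fwd[h$ridx]),
    qual = ifelse(h$rev, qual_rev[h$ridx], reads$qual[h$ridx]),
    nm = h$nm, score = h$score,
    em = as.integer(reads$end_marker[h$ridx]),
    n_best = h$n_best, n_hits = h$n_hits,
    stringsAsFactors = FALSE)
  out <- if (is.null(keep) || nrow(keep) == 0L) .empty_sam(mode) else mk(keep)
  un <- setdiff(seq_len(n), unique(cand$ridx))
  if (length(un)) {
    out <- rbind(out, data.frame(
      qname = reads$read_id[un], flag = 4L, rname = "*", pos = 0L, mapq = 0L,
      cigar = "*", seq = reads$seq[un], qual = reads$qual[un],
      nm = NA_integer_, score = NA_integer_,
      em = as.integer(reads$end_marker[un]), n_best = 0L, n_hits = 0L,
      stringsAsFactors = FALSE))
  }
  out[order(match(out$qname, reads$read_id)), , drop = FALSE]
}

.empty_sam <- function(mode) {
  data.frame(qname = character(), flag = integer(), rname = character(),
             pos = integer(), mapq = integer(), cigar = character(),
             seq = character(), qual = character(), nm = integer(),
             score = integer(), em = integer(), n_best = integer(),
             n_hits = integer(), stringsAsFactors = FALSE)
}
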