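# Shared fixtures: a small deterministic well prior, tiny molecules and
# hand-built read fragments that bypass the aligner.

# A well prior with simple, known scalars and a KDE fitted to synthetic
# features; deterministic given the seed.
toy_prior <- function(seed = 42, n = 200, genome_length = 1e5,
                      theta = 1e-3, p_exist = 0.5, lambda_mean = 0.015,
                      size_meanlog = 9.2, size_sdlog = 0.3) {
  set.seed(seed)
  feats <- data.frame(
    size_bp = pmax(2, round(rlnorm(n, size_meanlog, size_sdlog))),
    read_count = 1L,
    lambda = rlnorm(n, log(lambda_mean), 0.2),
    left_marker = runif(n) < 0.77,
    right_marker = runif(n) < 0.77)
  feats$read_count <- pmax(1L, round(feats$size_bp * feats$lambda))
  pr <- fit_prior(feats, genome_length = genome_length, well_fraction = 0.02,
                  n_wells = 10, theta = theta)
  pr$p_exist <- p_exist
  pr
}

# Prior scaled to the tiny molecules of the oracle-suite instances
# (~25 bp fragments covered by ~6 bp reads).
toy_prior_small <- function(seed = 42) {
  toy_prior(seed = seed, genome_length = 1e4, size_meanlog = log(25),
            size_sdlog = 0.4, lambda_mean = 0.25)
}

random_seq <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Perfect-quality string of a given length.
qual_str <- function(len, q = 30) {
  paste(rep(intToUtf8(q + 33L), len), collapse = "")
}

# Build a read-fragment list entry (the collect_pass2 output shape) from a
# plain description of its candidate alignments.
make_fragment <- function(read_id, seq, qual = qual_str(nchar(seq)),
                          end_marker = FALSE, high_copy = FALSE,
                          contigs = character(), cloud_ids = integer(),
                          offsets = integer(), strands = NULL,
                          scores = NULL, n_indel = NULL) {
  k <- length(contigs)
  aln <- data.frame(
    contig = contigs,
    cloud_id = if (length(cloud_ids)) cloud_ids else seq_len(k),
    offset = offsets,
    strand = if (is.null(strands)) rep("+", k) else strands,
    score = if (is.null(scores)) rep(0, k) else scores,
    nm = rep(0L, k),
    n_indel = if (is.null(n_indel)) rep(0L, k) else n_indel,
    stringsAsFactors = FALSE)
  aln$segs <- rep(list(NULL), k)
  list(read_id = read_id, seq = seq, qual = qual, end_marker = end_marker,
       high_copy = high_copy, aln = aln)
}

# Abbreviated-reference object from raw contig sequences.
make_abbrev <- function(seqs, origin_chrom = "chr1",
                        origin_starts = NULL) {
  n <- length(seqs)
  if (is.null(origin_starts)) origin_starts <- (seq_len(n) - 1L) * 100000L
  contigs <- data.frame(
    contig = names(seqs), cloud_id = seq_len(n),
    origin_chrom = rep(origin_chrom, n), origin_start = origin_starts,
    length = nchar(seqs), stringsAsFactors = FALSE)
  structure(list(contigs = contigs, seqs = seqs), class = "abbrev_ref")
}

# Exhaustive maximisation of the assignment objective by enumeration of the
# full joint domain, with per-molecule potential memoisation. Independent of
# map_inference's search; scoring goes through compute_log_potential.
exhaustive_map <- function(graph) {
  nr <- length(graph$reads)
  doms <- lapply(graph$reads, function(r) 0L:r$K)
  memo <- new.env(parent = emptyenv())
  pot <- function(c, members, choice) {
    key <- paste0(c, "|", paste(members, choice[members], collapse = ","))
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    sel <- members[choice[members] > 0L]
    sel <- sel[vapply(sel, function(n)
      graph$reads[[n]]$opts[[choice[n]]]$mol == c, TRUE)]
    if (length(sel) == 0L) {
      v <- log(1 - graph$prior$p_exist)
    } else {
      rd <- data.frame(
        seq = vapply(sel, function(n) graph$reads[[n]]$seq_str, ""),
        qual = vapply(sel, function(n) graph$reads[[n]]$qual_str, ""),
        offset = vapply(sel, function(n)
          graph$reads[[n]]$opts[[choice[n]]]$offset, 0L),
        end_marker = vapply(sel, function(n)
          graph$reads[[n]]$end_marker, TRUE),
        stringsAsFactors = FALSE)
      v <- compute_log_potential(graph$mol[[c]]$seq_str, rd, graph$prior,
                                 graph$read_length)
    }
    memo[[key]] <- v
    v
  }
  best <- -Inf
  best_choice <- NULL
  choice <- integer(nr)
  states <- expand.grid(rev(doms))
  for (i in seq_len(nrow(states))) {
    choice <- as.integer(rev(unlist(states[i, ])))
    total <- 0
    for (c in seq_along(graph$mol))
      total <- total + pot(c, graph$attach[[c]], choice)
    total <- total + sum(vapply(which(choice == 0L),
                                function(n) graph$reads[[n]]$off_lp, 0))
    if (total > best + 1e-12) {
      best <- total
      best_choice <- choice
    }
  }
  list(objective = best, choice = best_choice)
}

# Build an mrf_graph from raw contig seqs + fragments, stashing the raw
# strings needed by exhaustive_map.
toy_graph <- function(seqs, frags, prior, read_length = 4) {
  ab <- make_abbrev(seqs)
  g <- build_mrf(frags, ab, prior, read_length)
  for (n in seq_along(g$reads)) {
    g$reads[[n]]$seq_str <- frags[[n]]$seq
    g$reads[[n]]$qual_str <- frags[[n]]$qual
  }
  for (c in seq_along(g$mol))
    g$mol[[c]]$seq_str <- ab$seqs[[g$mol[[c]]$contig]]
  g
}

# Brute-force potential: enumerate every molecule sequence X over ACGT^s and
# integrate the density grid directly.
brute_potential_acc <- function(contig_seq, reads, prior, read_length) {
  n <- nrow(reads)
  if (n == 0L) return(log(1 - prior$p_exist))
  s <- nchar(contig_seq)
  ref <- rfaligner:::encode_bases(contig_seq)
  theta <- prior$theta
  starts <- reads$offset
  ends <- reads$offset + nchar(reads$seq)
  em <- if (is.null(reads$end_marker)) rep(FALSE, n) else reads$end_marker
  lo <- min(starts); hi <- max(ends)
  b <- paste0(as.integer(any(em & starts <= lo + read_length)),
              as.integer(any(em & ends >= hi - read_length)))
  span <- max(hi - lo, read_length)

  kbin <- round(log(span) * 32)
  dens <- prior_slambda_logdens(prior, b, exp(kbin / 32), prior$lambda_grid)
  count_term <- rfaligner:::logsumexp(
    log(prior$lambda_weights) + dens +
      dpois(n, prior$lambda_grid * span, log = TRUE))

  # sum over all 4^s hidden sequences
  obs <- lapply(seq_len(n), function(i) rfaligner:::encode_bases(reads$seq[i]))
  e <- lapply(seq_len(n), function(i)
    10^(-(utf8ToInt(reads$qual[i]) - 33L) / 10))
  total <- 0
  grid <- as.matrix(expand.grid(rep(list(1:4), s)))
  for (g in seq_len(nrow(grid))) {
    x <- grid[g, ]
    p <- prod(ifelse(x == ref, 1 - theta, theta / 3))
    for (i in seq_len(n)) {
      pos <- (starts[i] + 1):(ends[i])
      match_x <- obs[[i]] == x[pos]
      p <- p * prod(ifelse(match_x, 1 - e[[i]], e[[i]] / 3))
    }
    total <- total + p
  }
  log(prior$p_exist) + log(prior$pB[[b]]) - log(prior$genome_length) -
    n * log(span) + count_term + log(total)
}


# Random ambiguous instances: two near-identical repeat copies, reads drawn
# from one of them, domains spanning both.
acc_random_instance <- function(seed, max_reads = 8) {
  set.seed(seed)
  len <- sample(20:30, 1)
  a <- random_seq(len)
  b_chars <- strsplit(a, "")[[1]]
  nmut <- sample(1:3, 1)
  mi <- sample(len, nmut)
  b_chars[mi] <- vapply(b_chars[mi], function(ch)
    sample(setdiff(c("A", "C", "G", "T"), ch), 1), "")
  seqs <- c(cA = a, cB = paste(b_chars, collapse = ""))
  nr <- sample(3:max_reads, 1)
  frags <- lapply(seq_len(nr), function(i) {
    l <- sample(5:8, 1)
    off <- sample(0:(len - l), 1)
    src <- sample(1:2, 1)
    sq <- substring(seqs[[src]], off + 1, off + l)
    if (runif(1) < 0.2) {     # sequencing error
      p <- sample(l, 1)
      substr(sq, p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    ks <- if (runif(1) < 0.7) 1:2 else src
    make_fragment(paste0("r", i), sq, qual = qual_str(l, sample(20:35, 1)),
                  contigs = c("cA", "cB")[ks], cloud_ids = ks,
                  offsets = rep(off, length(ks)),
                  end_marker = runif(1) < 0.2)
  })
  toy_graph(seqs, frags, toy_prior_small(), read_length = 5)
}

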