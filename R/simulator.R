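# Read-cloud well simulator: repeat-bearing genomes, stencil-based read
# clouds, a first-order base-quality error model, and per-read ground truth.

#' Simulation configuration for read-cloud wells
#'
#' Defaults describe a shallow-sequenced TruSeq-style read-cloud library:
#' each well receives ~2% of the genome as long fragments (log-normal size,
#' mean ~10 kb), every fragment is covered at `C_R` = 1.5x with 100-bp reads,
#' fragment ends carry an adapter-derived end-marker read with probability
#' `marker_eff` = 0.77, and base qualities follow a first-order chain along a
#' Q35 plateau decaying to Q25.
#'
#' @param genome_length target genome length in bp (used by
#'   [make_repeat_genome()]).
#' @param dup_count number of segmental-duplication pairs to plant.
#' @param dup_len_range duplication length range in bp.
#' @param dup_identity_range sequence identity range between copies.
#' @param C_R short-read coverage of each long fragment.
#' @param well_fraction fraction of the genome received by one well.
#' @param frag_meanlog,frag_sdlog log-normal fragment size parameters
#'   (defaults give a ~10.4 kb mean).
#' @param read_length short-read length in bp.
#' @param paired emit mate pairs (mates are simulated from opposite fragment
#'   ends of a ~400 bp insert; the alignment pipeline treats them as
#'   independent fragments).
#' @param marker_eff probability that a fragment end produces an end-marker
#'   read.
#' @param collision_rate probability that a fragment is deliberately placed
#'   overlapping an earlier fragment of the same well (matching the ~2%
#'   per-well genome coverage, which is the chance of a natural collision).
#' @param q_max,q_min,plateau_frac quality-profile parameters: plateau at
#'   `q_max` for the first `plateau_frac` of the read, then linear decay to
#'   `q_min`.
#' @param min_frag minimum fragment size in bp.
#' @return a `sim_config` list.
#' @export
sim_config <- function(genome_length = 5e6, dup_count = 10,
                       dup_len_range = c(5000, 20000),
                       dup_identity_range = c(0.94, 0.99),
                       C_R = 1.5, well_fraction = 0.02,
                       frag_meanlog = 9.2, frag_sdlog = 0.3,
                       read_length = 100, paired = FALSE,
                       marker_eff = 0.77, collision_rate = 0.02,
                       q_max = 35, q_min = 25, plateau_frac = 0.6,
                       min_frag = 1000) {
  stopifnot(well_fraction > 0, well_fraction < 1, C_R > 0, read_length > 30)
  structure(list(
    genome_length = genome_length, dup_count = dup_count,
    dup_len_range = dup_len_range, dup_identity_range = dup_identity_range,
    C_R = C_R, well_fraction = well_fraction,
    frag_meanlog = frag_meanlog, frag_sdlog = frag_sdlog,
    read_length = read_length, paired = paired,
    marker_eff = marker_eff, collision_rate = collision_rate,
    q_max = q_max, q_min = q_min, plateau_frac = plateau_frac,
    min_frag = min_frag
  ), class = "sim_config")
}

#' Generate a random genome carrying segmental-duplication pairs
#'
#' A uniform-random base genome in which `dup_count` source intervals are
#' copied to non-overlapping destinations and mutated by uniform substitution
#' down to a target identity, emulating recent segmental duplications
#' (>5 kb, >94% identity) without requiring any reference download.
#'
#' @param config a [sim_config()].
#' @param seed integer seed for reproducibility.
#' @return list with `genome` (named character vector, one chromosome) and
#'   `bed` (data frame of both copies of each duplication: `chrom`, `start`,
#'   `end` 0-based half-open, `pair_id`, `role` source/copy, `identity`).
#' @export
make_repeat_genome <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  G <- as.integer(config$genome_length)
  lens <- if (config$dup_count > 0)
    as.integer(round(stats::runif(config$dup_count, config$dup_len_range[1],
                                  config$dup_len_range[2]))) else integer()
  if (sum(lens) * 2 > G / 2)
    stop("total duplication length must stay below a quarter of the genome per copy set")
  genome <- sample(c("A", "C", "G", "T"), G, replace = TRUE)

  occupied <- matrix(numeric(0), ncol = 2)  # rows: [start, end) 0-based
  place <- function(len) {
    for (i in 1:1000) {
      s <- sample.int(G - len, 1L) - 1L
      if (nrow(occupied) == 0 ||
          all(s + len <= occupied[, 1] | s >= occupied[, 2])) {
        occupied <<- rbind(occupied, c(s, s + len))
        return(s)
      }
    }
    stop("could not place duplication without overlap after 1000 tries")
  }

  bed <- NULL
  ids <- if (config$dup_count > 0)
    stats::runif(config$dup_count, config$dup_identity_range[1],
                 config$dup_identity_range[2]) else numeric()
  for (d in seq_len(config$dup_count)) {
    len <- lens[d]
    src <- place(len)
    dst <- place(len)
    seqv <- genome[(src + 1):(src + len)]
    mut <- stats::runif(len) < (1 - ids[d])
    if (any(mut)) {
      alt <- vapply(seqv[mut], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
      seqv[mut] <- alt
    }
    genome[(dst + 1):(dst + len)] <- seqv
    bed <- rbind(bed,
      data.frame(chrom = "sim1", start = c(src, dst), end = c(src, dst) + len,
                 pair_id = d, role = c("source", "copy"), identity = ids[d],
                 stringsAsFactors = FALSE))
  }
  list(genome = c(sim1 = paste(genome, collapse = "")),
       bed = if (is.null(bed)) data.frame(chrom = character(), start = integer(),
                                          end = integer(), pair_id = integer(),
                                          role = character(), identity = numeric())
             else bed)
}

#' Step-distribution of the first-order quality chain
#'
#' The base-quality chain moves in integer steps of -2..2; the step weights
#' depend only on whether the current quality sits below, at, or above the
#' positional target profile.
#' @param q current quality.
#' @param target target quality at this position.
#' @return probability vector over steps `-2:2`.
#' @export
quality_step_weights <- function(q, target) {
  if (q < target)      c(0.02, 0.08, 0.30, 0.35, 0.25)
  else if (q > target) c(0.25, 0.35, 0.30, 0.08, 0.02)
  else                 c(0.05, 0.20, 0.50, 0.20, 0.05)
}

# Positional quality target: plateau then linear decay.
.quality_profile <- function(L, config) {
  pl <- max(1L, floor(config$plateau_frac * L))
  tgt <- rep(config$q_max, L)
  if (pl < L)
    tgt[(pl + 1):L] <- config$q_max -
      (config$q_max - config$q_min) * ((pl + 1):L - pl) / (L - pl)
  round(tgt)
}

#' Apply the first-order error model to error-free read sequences
#'
#' Base qualities are drawn from a first-order (Markov-on-position) chain
#' that mean-reverts to the plateau/decay target profile; a substitution
#' error is then introduced per base with probability `10^(-q/10)`, uniform
#' among the three alternative bases.
#'
#' @param seqs character vector of error-free read sequences (equal length).
#' @param config a [sim_config()].
#' @param perfect if TRUE, skip both quality noise and substitutions
#'   (all bases at `q_max`).
#' @return list with `seq` (mutated sequences), `qual` (Phred+33 strings) and
#'   `n_errors` (per-read substitution counts).
#' @export
apply_error_model <- function(seqs, config = sim_config(), perfect = FALSE) {
  n <- length(seqs)
  if (n == 0L) return(list(seq = seqs, qual = character(), n_errors = integer()))
  L <- nchar(seqs[1])
  stopifnot(all(nchar(seqs) == L))
  if (perfect) {
    return(list(seq = seqs, qual = rep(quals_to_string(rep(config$q_max, L)), n),
                n_errors = integer(n)))
  }
  tgt <- .quality_profile(L, config)
  Q <- matrix(0L, n, L)
  Q[, 1] <- config$q_max
  steps <- -2:2
  for (j in 2:L) {
    prev <- Q[, j - 1]
    rel <- sign(tgt[j] - prev)  # -1 above target, 0 at, +1 below
    st <- integer(n)
    for (r in c(-1L, 0L, 1L)) {
      idx <- which(rel == r)
      if (length(idx))
        st[idx] <- sample(steps, length(idx), replace = TRUE,
                          prob = quality_step_weights(30 - r, 30))
    }
    Q[, j] <- pmin(41L, pmax(2L, prev + st))
  }
  # substitution errors
  base_mat <- matrix(.BASE_LOOKUP[utf8ToInt(paste0(seqs, collapse = ""))],
                     n, L, byrow = TRUE)
  err <- matrix(stats::runif(n * L), n, L) < 10^(-Q / 10)
  n_err <- as.integer(rowSums(err))
  if (any(err)) {
    shift <- sample.int(3L, sum(err), replace = TRUE)
    base_mat[err] <- ((base_mat[err] - 1L + shift) %% 4L) + 1L
  }
  seq_out <- vapply(seq_len(n), function(i) decode_bases(base_mat[i, ]), "")
  qual_out <- vapply(seq_len(n), function(i) quals_to_string(Q[i, ]), "")
  list(seq = seq_out, qual = qual_out, n_errors = n_err)
}

#' Draw a read-position stencil for one long fragment
#'
#' Parametric mode: the number of reads is Poisson with mean
#' `C_R * fragment_size / read_length` and start offsets are uniform on the
#' fragment; the first and last slots carry an end-marker flag independently
#' with probability `marker_eff`. Empirical mode: pass `stencils`, a list of
#' relative-offset integer vectors (e.g. from [stencils_from_sam()]), and one
#' is drawn and cropped to the fragment.
#'
#' @param config a [sim_config()].
#' @param fragment_size fragment size in bp (> read length).
#' @param stencils optional list of empirical offset vectors.
#' @return list with `offsets` (0-based sorted starts) and `marker` (logical).
#' @export
draw_stencil <- function(config, fragment_size, stencils = NULL) {
  L <- config$read_length
  stopifnot(fragment_size > L)
  if (!is.null(stencils)) {
    offs <- stencils[[sample.int(length(stencils), 1L)]]
    offs <- sort(offs[offs <= fragment_size - L])
  } else {
    n <- stats::rpois(1L, config$C_R * fragment_size / L)
    offs <- sort(sample.int(fragment_size - L + 1L, n, replace = TRUE) - 1L)
  }
  marker <- logical(length(offs))
  if (length(offs) > 0) {
    marker[1L] <- stats::runif(1) < config$marker_eff
    marker[length(offs)] <- marker[length(offs)] |
      (stats::runif(1) < config$marker_eff)
  }
  list(offsets = offs, marker = marker)
}

#' Extract empirical stencils from single-cloud SAM records
#'
#' Groups mapped records by reference name and returns each group's read
#' starts relative to the group's leftmost read.
#' @param sam data frame from [read_sam()].
#' @return list of integer offset vectors, one per reference sequence.
#' @export
stencils_from_sam <- function(sam) {
  sam <- sam[bitwAnd(sam$flag, 4L) == 0L, ]
  lapply(split(sam$pos, sam$rname), function(p) sort(p - min(p)))
}

#' Simulate one read-cloud well
#'
#' Long fragments are drawn uniformly at random on the genome until the well
#' holds `well_fraction` of the genome; each fragment is covered by a stencil
#' of short reads at `C_R`, reads are passed through the error model, and
#' every read gets a truth record (source fragment, genome position, strand).
#' With probability `collision_rate` a fragment is placed overlapping an
#' earlier one (a well collision); otherwise overlaps are avoided.
#'
#' @param genome named character vector (from [make_repeat_genome()] or
#'   [read_genome_fasta()]).
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param well integer well identifier used in read names.
#' @param perfect_reads disable the error model (for oracle-style tests).
#' @param stencils optional empirical stencils for [draw_stencil()].
#' @return list with `reads` (data frame: `read_id`, `seq`, `qual`,
#'   `end_marker`), `truth` (data frame: `read_id`, `well`, `frag_id`,
#'   `chrom`, `pos` 0-based, `strand`, `marker`) and `fragments`
#'   (data frame: `frag_id`, `chrom`, `start`, `size`, `collided`).
#' @export
simulate_well <- function(genome, config = sim_config(), seed = 1, well = 1,
                          perfect_reads = FALSE, stencils = NULL) {
  set.seed(seed)
  chrom <- names(genome)[1]
  gseq <- genome[[1]]
  G <- nchar(gseq)
  L <- config$read_length
  target <- config$well_fraction * G

  frags <- NULL
  tot <- 0
  fid <- 0L
  while (tot < target) {
    fid <- fid + 1L
    S <- max(config$min_frag, min(G - 1,
             round(stats::rlnorm(1, config$frag_meanlog, config$frag_sdlog))))
    if (tot + S > target) {
      # thin the crossing fragment so the expected well coverage hits the
      # target exactly (no systematic overshoot)
      if (stats::runif(1) > (target - tot) / S) break
    }
    collided <- FALSE
    if (!is.null(frags) && stats::runif(1) < config$collision_rate) {
      # force an overlap with a previously placed fragment
      i <- sample.int(nrow(frags), 1L)
      lo <- max(0L, frags$start[i] - S + 500L)
      hi <- min(G - S, frags$start[i] + frags$size[i] - 500L)
      st <- if (hi >= lo) round(stats::runif(1, lo, hi)) else sample.int(G - S, 1L) - 1L
      collided <- TRUE
    } else {
      st <- sample.int(G - S, 1L) - 1L
      if (!is.null(frags)) {
        for (try in 1:200) {
          if (all(st + S <= frags$start | st >= frags$start + frags$size)) break
          st <- sample.int(G - S, 1L) - 1L
        }
      }
    }
    frags <- rbind(frags, data.frame(frag_id = fid, chrom = chrom, start = st,
                                     size = S, collided = collided))
    tot <- tot + S
  }

  all_reads <- vector("list", nrow(frags))
  all_truth <- vector("list", nrow(frags))
  for (i in seq_len(nrow(frags))) {
    S <- frags$size[i]; st <- frags$start[i]
    stc <- draw_stencil(config, S, stencils = stencils)
    n <- length(stc$offsets)
    if (n == 0L) next
    pos <- st + stc$offsets                       # 0-based genome starts
    strand <- ifelse(stats::runif(n) < 0.5, "+", "-")
    seqs <- substring(gseq, pos + 1L, pos + L)
    neg <- strand == "-"
    if (any(neg)) seqs[neg] <- revcomp(seqs[neg])
    ids <- sprintf("w%d_f%d_r%d", well, frags$frag_id[i], seq_len(n))
    all_reads[[i]] <- data.frame(read_id = ids, seq = seqs, qual = "",
                                 end_marker = stc$marker,
                                 stringsAsFactors = FALSE)
    all_truth[[i]] <- data.frame(read_id = ids, well = well,
                                 frag_id = frags$frag_id[i], chrom = chrom,
                                 pos = pos, strand = strand,
                                 marker = stc$marker, stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, all_reads)
  truth <- do.call(rbind, all_truth)
  if (is.null(reads)) {
    reads <- data.frame(read_id = character(), seq = character(),
                        qual = character(), end_marker = logical())
    truth <- data.frame(read_id = character(), well = integer(),
                        frag_id = integer(), chrom = character(),
                        pos = integer(), strand = character(), marker = logical())
  } else {
    em <- apply_error_model(reads$seq, config, perfect = perfect_reads)
    reads$seq <- em$seq
    reads$qual <- em$qual
  }
  list(reads = reads, truth = truth, fragments = frags)
}
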