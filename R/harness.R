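# End-to-end orchestration: per-well pipeline (pass1 -> clouds -> abbreviated
# reference -> pass2 -> MRF -> MAP -> queries), the Baseline/Naive/RFA/Oracle
# comparators, the evaluation report, and the simulation study driver.

#' Pipeline configuration
#'
#' @param max_gap pass-1 clustering gap in bp.
#' @param min_reads minimum reads per candidate cloud.
#' @param read_length read length in bp.
#' @param pad abbreviated-reference padding per side in bp.
#' @param max_alignments pass-2 domain cap per read.
#' @param restarts,sweeps MAP search parameters.
#' @param seed RNG seed for the well.
#' @param mapq_cutoff confidence filter used in reports.
#' @param existence_cutoff molecules below this existence posterior are
#'   marked excluded.
#' @param cap_local,joint_cap read-posterior marginalisation caps.
#' @param lowq_null shuffled replicates for the low-quality cloud null
#'   (0 disables the flag).
#' @return configuration list.
#' @export
rfa_config <- function(max_gap = 3500, min_reads = 6, read_length = 100,
                       pad = 1000, max_alignments = 15, restarts = 3,
                       sweeps = 100, seed = 1, mapq_cutoff = 10,
                       existence_cutoff = 0.9, cap_local = 12,
                       joint_cap = 256, lowq_null = 3) {
  as.list(environment())
}

# Pass-1 SAM records -> clustering input.
.pass1_alignments <- function(pass1) {
  mapped <- pass1[bitwAnd(pass1$flag, 4L) == 0L, , drop = FALSE]
  data.frame(read_id = mapped$qname, chrom = mapped$rname,
             start = mapped$pos - 1L,
             strand = ifelse(bitwAnd(mapped$flag, 16L) > 0L, "-", "+"),
             end_marker = mapped$em == 1L,
             unique_hit = if (!is.null(mapped$n_best)) mapped$n_best == 1L else NA,
             stringsAsFactors = FALSE)
}

# Cluster + end-marker split + renumber.
.call_clouds <- function(aln, config) {
  clouds <- cluster_pass1(aln, config$max_gap, config$min_reads,
                          config$read_length)
  if (nrow(clouds) == 0L) return(clouds)
  out <- do.call(rbind, lapply(seq_len(nrow(clouds)), function(i)
    split_on_end_markers(clouds[i, ], aln, config$min_reads,
                         config$read_length)))
  out$cloud_id <- seq_len(nrow(out))
  if (!is.null(aln$unique_hit)) {
    out$unique_frac <- vapply(out$members, function(ids)
      mean(aln$unique_hit[match(ids, aln$read_id)]), 0)
  }
  out
}

#' Align one read-cloud well
#'
#' Runs the five pipeline steps: (1) single-hit alignment of all reads to
#' the full reference, (2) candidate-cloud calling and the abbreviated
#' reference, (3) multi-hit realignment and MRF construction, (4) MAP
#' inference, (5) read/cloud quality queries. Returns genome-lifted
#' placements and per-cloud confidence.
#'
#' @param reads data frame (`read_id`, `seq`, `qual`, `end_marker`).
#' @param genome named character vector of reference sequences.
#' @param prior a `well_prior`.
#' @param config an [rfa_config()].
#' @param pass1 optional precomputed pass-1 single-hit SAM data frame.
#' @return list with `placements` (per read: `read_id`, `placed`, `chrom`,
#'   `pos` 0-based, `strand`, `mapq`, `posterior`, `multimapped`,
#'   `excluded`), `cloud_bed`, plus the intermediate `pass1`, `pass2`,
#'   `clouds`, `abbrev`, `graph`, `map` for downstream comparators.
#' @export
run_well <- function(reads, genome, prior, config = rfa_config(),
                     pass1 = NULL) {
  empty <- list(
    placements = data.frame(read_id = character(), placed = logical(),
                            chrom = character(), pos = integer(),
                            strand = character(), mapq = integer(),
                            posterior = numeric(), multimapped = logical(),
                            excluded = logical()),
    cloud_bed = data.frame(chrom = character(), start = integer(),
                           end = integer(), cloud_id = integer(),
                           log_quality = numeric(),
                           existence_posterior = numeric(),
                           excluded = logical()))
  if (nrow(reads) == 0L) return(empty)
  if (is.null(pass1))
    pass1 <- mini_align(reads, genome, "single", seed = config$seed)
  aln <- .pass1_alignments(pass1)
  clouds <- .call_clouds(aln, config)
  if (nrow(clouds) == 0L) {
    empty$pass1 <- pass1
    return(empty)
  }
  abbrev <- build_abbreviated_reference(clouds, genome, config$pad)
  pass2 <- mini_align(reads, abbrev$seqs, "multi",
                      max_hits = config$max_alignments + 5L,
                      seed = config$seed)
  frags <- collect_pass2(reads, abbrev, pass2, config$max_alignments)
  graph <- build_mrf(frags, abbrev, prior, config$read_length)
  map <- map_inference(graph, config)

  # collision exclusion from end-markers
  coll <- suppressMessages(
    detect_collisions(clouds, aln, prior$marker_eff, config$read_length))
  lowq <- if (config$lowq_null > 0L)
    flag_low_quality_clouds(graph, map, n_null = config$lowq_null,
                            seed = config$seed) else
    logical(length(graph$mol))

  n_reads <- length(graph$reads)
  exist_post <- vapply(seq_along(graph$mol), function(c)
    existence_posterior(graph, map, c), 0)
  mol_excluded <- exist_post < config$existence_cutoff | lowq
  coll_cloud_ids <- coll$flagged

  placed <- logical(n_reads); chrom <- rep(NA_character_, n_reads)
  pos <- rep(NA_integer_, n_reads); strand <- rep(NA_character_, n_reads)
  postv <- rep(NA_real_, n_reads); excl <- logical(n_reads)
  for (n in seq_len(n_reads)) {
    j <- map$choice[n]
    if (j == 0L) next
    o <- graph$reads[[n]]$opts[[j]]
    m <- graph$mol[[o$mol]]
    rp <- read_posterior(graph, map, n, config$cap_local, config$joint_cap)
    placed[n] <- TRUE
    chrom[n] <- m$chrom
    pos[n] <- m$gstart + o$offset
    strand[n] <- o$strand
    postv[n] <- rp$posterior * exist_post[o$mol]
    excl[n] <- m$cloud_id %in% coll_cloud_ids || mol_excluded[o$mol]
  }
  placements <- data.frame(
    read_id = vapply(graph$reads, function(r) r$read_id, ""),
    placed = placed, chrom = chrom, pos = pos, strand = strand,
    mapq = ifelse(excl, 0L, posterior_to_mapq(postv)),
    posterior = postv,
    multimapped = vapply(seq_len(n_reads), function(n)
      graph$reads[[n]]$high_copy ||
        .n_distinct_placements(graph, n) >= 2L, TRUE),
    excluded = excl, stringsAsFactors = FALSE)
  placements$mapq[!placed] <- 0L

  cloud_bed <- data.frame(
    chrom = vapply(graph$mol, function(m) m$chrom, ""),
    start = vapply(graph$mol, function(m) as.numeric(m$gstart), 0),
    end = vapply(graph$mol, function(m) as.numeric(m$gstart + m$slen), 0),
    cloud_id = vapply(graph$mol, function(m) as.numeric(m$cloud_id), 0),
    log_quality = vapply(seq_along(graph$mol), function(c)
      cloud_quality(graph, map, c), 0),
    existence_posterior = exist_post,
    excluded = mol_excluded |
      vapply(graph$mol, function(m) m$cloud_id %in% coll_cloud_ids, TRUE),
    stringsAsFactors = FALSE)

  list(placements = placements, cloud_bed = cloud_bed, pass1 = pass1,
       pass2 = pass2, clouds = clouds, abbrev = abbrev, graph = graph,
       map = map)
}

#' Emit a well result as a genome-coordinate SAM file
#' @param result a [run_well()] result.
#' @param reads the well's read data frame.
#' @param genome named character vector (for `@SQ` lines).
#' @param path output SAM path.
#' @export
emit_sam <- function(result, reads, genome, path) {
  pl <- result$placements
  i <- match(reads$read_id, pl$read_id)
  placed <- !is.na(i) & pl$placed[i]
  rc <- placed & pl$strand[i] == "-"
  seqs <- reads$seq
  quals <- reads$qual
  seqs[rc] <- revcomp(seqs[rc])
  quals[rc] <- vapply(quals[rc], function(q)
    intToUtf8(base::rev(utf8ToInt(q))), "")
  rec <- data.frame(
    qname = reads$read_id,
    flag = ifelse(placed, ifelse(rc, 16L, 0L), 4L),
    rname = ifelse(placed, pl$chrom[i], "*"),
    pos = ifelse(placed, pl$pos[i] + 1L, 0L),
    mapq = ifelse(placed, pl$mapq[i], 0L),
    cigar = ifelse(placed, sprintf("%dM", nchar(reads$seq)), "*"),
    seq = seqs, qual = quals,
    em = as.integer(reads$end_marker), stringsAsFactors = FALSE)
  write_sam(rec, path, ref_lengths = vapply(genome, nchar, 0L))
  invisible(path)
}

# ---- comparators ------------------------------------------------------------

#' Baseline placements: pass-1 single-hit alignments
#' @param pass1 single-mode [mini_align()] output.
#' @return placements data frame (`read_id`, `placed`, `chrom`, `pos`,
#'   `strand`, `mapq`).
#' @export
baseline_placements <- function(pass1) {
  data.frame(read_id = pass1$qname,
             placed = bitwAnd(pass1$flag, 4L) == 0L,
             chrom = ifelse(pass1$rname == "*", NA, pass1$rname),
             pos = pass1$pos - 1L,
             strand = ifelse(bitwAnd(pass1$flag, 16L) > 0L, "-", "+"),
             mapq = pass1$mapq, stringsAsFactors = FALSE)
}

#' Naive placements: best pass-2 hit with score-gap MAPQ, lifted to genome
#'
#' The conventional short-read treatment of the abbreviated reference: pick
#' each read's best-scoring hit (seeded deterministic tie-break) and derive
#' MAPQ from the mismatch-weight gap between the best and remaining hits.
#' @param result a [run_well()] result.
#' @param base_error assumed per-base error for the hit weights.
#' @param seed tie-break seed.
#' @return placements data frame.
#' @export
naive_placements <- function(result, base_error = 0.002, seed = 1) {
  pass2 <- result$pass2
  mapped <- pass2[bitwAnd(pass2$flag, 4L) == 0L, , drop = FALSE]
  ids <- unique(pass2$qname)
  out <- data.frame(read_id = ids, placed = FALSE, chrom = NA_character_,
                    pos = NA_integer_, strand = NA_character_, mapq = 0L,
                    stringsAsFactors = FALSE)
  lw1 <- log10(base_error / 3) - log10(1 - base_error)
  if (nrow(mapped)) {
    g <- lift_to_genome(result$abbrev, mapped$rname, mapped$pos - 1L)
    # overlapping padded contigs duplicate the same genome placement; keep
    # one record per distinct placement
    key <- paste(mapped$qname, g$chrom, g$pos, bitwAnd(mapped$flag, 16L))
    keep <- !duplicated(key)
    mapped <- mapped[keep, , drop = FALSE]
  }
  by_read <- split(seq_len(nrow(mapped)), mapped$qname)
  for (rid in names(by_read)) {
    h <- mapped[by_read[[rid]], , drop = FALSE]
    best <- which(h$score == max(h$score))
    tb <- vapply(best, function(k)
      .tie_hash(rid, h$rname[k], h$pos[k], seed), 0)
    pick <- best[which.min(tb)]
    lw <- h$nm * lw1
    p <- 10^(lw[pick] - max(lw)) / sum(10^(lw - max(lw)))
    g <- lift_to_genome(result$abbrev, h$rname[pick], h$pos[pick] - 1L)
    i <- match(rid, out$read_id)
    out$placed[i] <- TRUE
    out$chrom[i] <- g$chrom
    out$pos[i] <- g$pos
    out$strand[i] <- if (bitwAnd(h$flag[pick], 16L) > 0L) "-" else "+"
    out$mapq[i] <- posterior_to_mapq(p)
  }
  out
}

#' Oracle placements: the true hit among the pass-2 candidates, if present
#'
#' The theoretical upper limit: each read is placed at its true position
#' whenever the multi-hit aligner returned that position, and left unplaced
#' otherwise.
#' @param result a [run_well()] result.
#' @param truth truth data frame (`read_id`, `chrom`, `pos`, `strand`).
#' @param tol placement tolerance in bp.
#' @return placements data frame.
#' @export
oracle_placements <- function(result, truth, tol = 5) {
  pass2 <- result$pass2
  mapped <- pass2[bitwAnd(pass2$flag, 4L) == 0L, , drop = FALSE]
  out <- data.frame(read_id = truth$read_id, placed = FALSE,
                    chrom = NA_character_, pos = NA_integer_,
                    strand = NA_character_, mapq = 0L,
                    stringsAsFactors = FALSE)
  if (nrow(mapped) == 0L) return(out)
  g <- lift_to_genome(result$abbrev, mapped$rname, mapped$pos - 1L)
  mapped$gchrom <- g$chrom
  mapped$gpos <- g$pos
  mapped$gstrand <- ifelse(bitwAnd(mapped$flag, 16L) > 0L, "-", "+")
  by_read <- split(seq_len(nrow(mapped)), mapped$qname)
  for (i in seq_len(nrow(truth))) {
    idx <- by_read[[truth$read_id[i]]]
    if (is.null(idx)) next
    h <- mapped[idx, , drop = FALSE]
    hit <- which(h$gchrom == truth$chrom[i] &
                 abs(h$gpos - truth$pos[i]) <= tol &
                 h$gstrand == truth$strand[i])
    if (length(hit)) {
      out$placed[i] <- TRUE
      out$chrom[i] <- h$gchrom[hit[1]]
      out$pos[i] <- h$gpos[hit[1]]
      out$strand[i] <- h$gstrand[hit[1]]
      out$mapq[i] <- 60L
    }
  }
  out
}

#' RFA placements from a well result
#' @param result a [run_well()] result.
#' @return placements data frame.
#' @export
rfa_placements <- function(result) {
  result$placements[, c("read_id", "placed", "chrom", "pos", "strand", "mapq")]
}

# ---- evaluation -------------------------------------------------------------

#' Evaluate per-method placements against truth
#'
#' A read is correctly placed iff its reported genome position is within
#' `tol` bp of truth on the same chromosome and strand. Reports, per method
#' and per well plus aggregated: the fraction of all reads placed correctly
#' at `mapq >= threshold`, the same fraction restricted to multimapped
#' reads, and the wrong-placement rate among confident multimapped reads.
#'
#' @param methods named list of placements data frames.
#' @param truth truth data frame (`read_id`, `well`, `chrom`, `pos`,
#'   `strand`).
#' @param multimapped character vector of read ids with more than one
#'   pass-2 candidate alignment.
#' @param mapq_threshold confidence filter (default 10, i.e. 90%).
#' @param tol placement tolerance in bp.
#' @return list with `aggregate` (one row per method) and `per_well`.
#' @export
evaluate <- function(methods, truth, multimapped, mapq_threshold = 10,
                     tol = 5) {
  agg <- NULL
  pw <- NULL
  for (meth in names(methods)) {
    pl <- methods[[meth]]
    i <- match(truth$read_id, pl$read_id)
    if (anyNA(i)) stop("placements for method '", meth,
                       "' do not cover all truth reads")
    placed <- pl$placed[i]
    correct <- placed & pl$chrom[i] == truth$chrom &
      abs(pl$pos[i] - truth$pos) <= tol & pl$strand[i] == truth$strand
    correct[is.na(correct)] <- FALSE
    confident <- placed & pl$mapq[i] >= mapq_threshold
    mm <- truth$read_id %in% multimapped
    stat <- function(sel) {
      n_conf <- sum(confident & sel)
      c(frac_correct_confident = sum(correct & confident & sel) / max(1, sum(sel)),
        wrong_rate_confident = if (n_conf > 0)
          sum(confident & !correct & sel) / n_conf else NA_real_,
        n = sum(sel), n_confident = n_conf)
    }
    agg <- rbind(agg, data.frame(
      method = meth,
      all_correct_confident = stat(rep(TRUE, length(mm)))[[1]],
      mm_correct_confident = stat(mm)[[1]],
      mm_wrong_rate = stat(mm)[[2]],
      n_reads = length(mm), n_multimapped = sum(mm),
      stringsAsFactors = FALSE))
    for (w in unique(truth$well)) {
      sel_w <- truth$well == w
      pw <- rbind(pw, data.frame(
        method = meth, well = w,
        all_correct_confident = sum(correct & confident & sel_w) / max(1, sum(sel_w)),
        mm_correct_confident = sum(correct & confident & sel_w & mm) /
          max(1, sum(sel_w & mm)),
        n_multimapped = sum(sel_w & mm), stringsAsFactors = FALSE))
    }
  }
  list(aggregate = agg, per_well = pw)
}

# ---- simulation study -------------------------------------------------------

#' Run the full scaled-down simulation study
#'
#' Generates a repeat-bearing genome, simulates `n_wells` read-cloud wells,
#' trains the well prior on the wells' uniquely mapped pass-1 clouds, aligns
#' every well with the full pipeline, and evaluates Baseline, Naive, RFA and
#' Oracle against the simulation truth.
#'
#' @param n_wells number of wells.
#' @param seed master seed; all per-well seeds derive from it.
#' @param config a [sim_config()].
#' @param rconfig an [rfa_config()].
#' @param quiet suppress progress messages.
#' @return list with `report` (from [evaluate()]), `calibration` (per-MAPQ-bin
#'   error table for RFA on multimapped reads), `prior`, `genome_bed`, and
#'   scalars `rfa_mm_wrong_pct` (wrong-placement % among confident
#'   multimapped RFA reads) and `rfa_vs_oracle_pct` (RFA's
#'   confident-correct multimapped fraction as % of Oracle's).
#' @export
sim_study <- function(n_wells = 50, seed = 1, config = sim_config(),
                      rconfig = rfa_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  g <- make_repeat_genome(config, seed)
  wells <- lapply(seq_len(n_wells), function(w)
    simulate_well(g$genome, config, seed = (seed * 97 + w) %% 2147483647L,
                  well = w))
  say("simulated %d wells (%d reads)", n_wells,
      sum(vapply(wells, function(x) nrow(x$reads), 0L)))

  pass1 <- lapply(seq_len(n_wells), function(w)
    mini_align(wells[[w]]$reads, g$genome, "single",
               seed = seed + w))
  clouds_all <- do.call(rbind, lapply(seq_len(n_wells), function(w) {
    cl <- .call_clouds(.pass1_alignments(pass1[[w]]), rconfig)
    if (nrow(cl)) cl$well <- w
    cl
  }))
  feats <- extract_features(clouds_all)
  prior <- fit_prior(feats, genome_length = nchar(g$genome[[1]]),
                     well_fraction = config$well_fraction, n_wells = n_wells,
                     clouds_per_well = nrow(clouds_all) / n_wells)
  say("prior trained on %d clouds (p_exist=%.2f, marker_eff=%.2f)",
      nrow(feats), prior$p_exist, prior$marker_eff)

  methods0 <- list(baseline = NULL, naive = NULL, rfa = NULL, oracle = NULL)
  multimapped <- character(0)
  truth_all <- NULL
  for (w in seq_len(n_wells)) {
    rc <- rconfig
    rc$seed <- (seed * 131 + w) %% 2147483647L
    res <- run_well(wells[[w]]$reads, g$genome, prior, rc,
                    pass1 = pass1[[w]])
    tr <- wells[[w]]$truth
    methods0$baseline <- rbind(methods0$baseline,
                               baseline_placements(pass1[[w]]))
    methods0$naive <- rbind(methods0$naive,
                            naive_placements(res, seed = rc$seed))
    methods0$rfa <- rbind(methods0$rfa, rfa_placements(res))
    methods0$oracle <- rbind(methods0$oracle, oracle_placements(res, tr))
    mm <- res$placements$read_id[res$placements$multimapped]
    multimapped <- c(multimapped, mm)
    truth_all <- rbind(truth_all, tr)
    if (w %% 10 == 0) say("aligned %d/%d wells", w, n_wells)
  }
  report <- evaluate(methods0, truth_all, multimapped,
                     mapq_threshold = rconfig$mapq_cutoff)

  # calibration table: RFA error by MAPQ bin among multimapped reads
  pl <- methods0$rfa
  i <- match(truth_all$read_id, pl$read_id)
  correct <- pl$placed[i] & pl$chrom[i] == truth_all$chrom &
    abs(pl$pos[i] - truth_all$pos) <= 5 & pl$strand[i] == truth_all$strand
  correct[is.na(correct)] <- FALSE
  mm <- truth_all$read_id %in% multimapped
  bins <- cut(pl$mapq[i], c(-1, 9, 39, 60),
              labels = c("0-9", "10-39", "40-60"))
  calib <- do.call(rbind, lapply(levels(bins), function(b) {
    sel <- mm & bins == b & pl$placed[i]
    data.frame(bin = b, n = sum(sel),
               error = if (sum(sel)) mean(!correct[sel]) else NA_real_)
  }))

  ag <- report$aggregate
  rfa_row <- ag[ag$method == "rfa", ]
  ora_row <- ag[ag$method == "oracle", ]
  list(report = report, calibration = calib, prior = prior,
       genome_bed = g$bed,
       rfa_mm_wrong_pct = 100 * rfa_row$mm_wrong_rate,
       rfa_vs_oracle_pct = 100 * rfa_row$mm_correct_confident /
         ora_row$mm_correct_confident)
}
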