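# Candidate-molecule seeding: cluster single-hit (pass-1) alignments into
# candidate clouds, split on interior end-markers, cut the abbreviated
# reference, and collect multi-hit (pass-2) alignments as read domains.

#' Cluster pass-1 alignments into candidate clouds
#'
#' Single-linkage clustering of read start positions per chromosome: reads
#' within `max_gap` bp of one another join the same cluster, and clusters
#' with fewer than `min_reads` members are discarded. The defaults (3.5 kbp,
#' six reads) were tuned for shallow TruSeq read clouds to keep superfluous
#' candidate clouds rare without losing true fragments.
#'
#' @param alignments data frame with columns `read_id`, `chrom`, `start`
#'   (0-based), `strand`, `end_marker`.
#' @param max_gap maximum linkage distance in bp.
#' @param min_reads minimum cluster size to call a candidate cloud.
#' @param read_length read length in bp (sets the right cloud boundary).
#' @return data frame of clouds: `cloud_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `n_reads`, `left_marker`, `right_marker`, and a list-column
#'   `members` of read ids.
#' @export
cluster_pass1 <- function(alignments, max_gap = 3500, min_reads = 6,
                          read_length = 100) {
  stopifnot(max_gap > 0, min_reads >= 1)
  empty <- data.frame(cloud_id = integer(), chrom = character(),
                      start = integer(), end = integer(), n_reads = integer(),
                      left_marker = logical(), right_marker = logical())
  empty$members <- list()
  if (is.null(alignments) || nrow(alignments) == 0L) return(empty)

  out <- NULL
  cid <- 0L
  for (chr in unique(alignments$chrom)) {
    a <- alignments[alignments$chrom == chr, , drop = FALSE]
    a <- a[order(a$start), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(diff(a$start) > max_gap)))
    for (g in unique(grp)) {
      m <- a[grp == g, , drop = FALSE]
      if (nrow(m) < min_reads) next
      cid <- cid + 1L
      cl <- data.frame(cloud_id = cid, chrom = chr,
                       start = min(m$start),
                       end = max(m$start) + read_length,
                       n_reads = nrow(m),
                       left_marker = FALSE, right_marker = FALSE)
      cl$members <- list(m$read_id)
      cl$left_marker <- any(m$end_marker & m$start <= cl$start + read_length)
      cl$right_marker <- any(m$end_marker & m$start + read_length >= cl$end - read_length)
      out <- rbind(out, cl)
    }
  }
  if (is.null(out)) empty else out
}

#' Split a candidate cloud at an interior end-marker
#'
#' Two long fragments that land within the clustering gap of one another are
#' merged by [cluster_pass1()]; an end-marker read strictly interior to the
#' cloud (more than one read length from both boundaries) reveals the join.
#' If such a marker partitions the members into two groups of at least
#' `min_reads` reads each, the cloud is split there; markers at the cloud
#' boundaries only set the `left_marker`/`right_marker` flags.
#'
#' @param cloud one row of the [cluster_pass1()] data frame.
#' @param alignments the pass-1 alignment data frame (for member lookups).
#' @param min_reads minimum size of each half.
#' @param read_length read length in bp.
#' @return data frame of one (unchanged) or two clouds in the same layout.
#' @export
split_on_end_markers <- function(cloud, alignments, min_reads = 6,
                                 read_length = 100) {
  mem <- alignments[alignments$read_id %in% cloud$members[[1]], , drop = FALSE]
  marks <- mem[mem$end_marker, , drop = FALSE]
  if (nrow(marks) == 0L) return(cloud)
  interior <- marks$start - cloud$start > read_length &
    cloud$end - (marks$start + read_length) > read_length
  cand <- marks$start[interior]
  split_at <- NA_integer_
  for (m in cand[order(abs(cand - (cloud$start + cloud$end) / 2))]) {
    if (sum(mem$start < m) >= min_reads && sum(mem$start >= m) >= min_reads) {
      split_at <- m
      break
    }
  }
  if (is.na(split_at)) return(cloud)
  left_ids <- mem$read_id[mem$start < split_at]
  right_ids <- mem$read_id[mem$start >= split_at]
  mk_half <- function(ids, start, end, suffix) {
    h <- mem[mem$read_id %in% ids, , drop = FALSE]
    cl <- data.frame(cloud_id = cloud$cloud_id * 2L + suffix, chrom = cloud$chrom,
                     start = start, end = end, n_reads = nrow(h),
                     left_marker = any(h$end_marker & h$start <= start + read_length),
                     right_marker = any(h$end_marker & h$start + read_length >= end - read_length))
    cl$members <- list(ids)
    cl
  }
  rbind(mk_half(left_ids, cloud$start, split_at + read_length, 0L),
        mk_half(right_ids, split_at, cloud$end, 1L))
}

#' Build the abbreviated reference for a set of candidate clouds
#'
#' Cuts one contig per candidate cloud from the genome, padded by `pad` bp on
#' each side (reads of the true fragment can precede the first clustered
#' read), and records a bidirectional coordinate lift between contig offsets
#' and genome coordinates.
#'
#' @param clouds data frame from [cluster_pass1()] / [split_on_end_markers()].
#' @param genome named character vector of chromosome sequences.
#' @param pad padding in bp on each side of the cloud interval.
#' @return an `abbrev_ref` list: `contigs` (data frame `contig`, `cloud_id`,
#'   `origin_chrom`, `origin_start` 0-based, `length`) and `seqs` (named
#'   character vector of contig sequences).
#' @export
build_abbreviated_reference <- function(clouds, genome, pad = 1000) {
  n <- nrow(clouds)
  contigs <- data.frame(contig = character(n), cloud_id = integer(n),
                        origin_chrom = character(n), origin_start = integer(n),
                        length = integer(n), stringsAsFactors = FALSE)
  seqs <- character(n)
  for (i in seq_len(n)) {
    chr <- clouds$chrom[i]
    glen <- nchar(genome[[chr]])
    s <- clouds$start[i] - pad
    e <- clouds$end[i] + pad
    if (s < 0 || e > glen) {
      warning(sprintf("cloud %d interval clipped to chromosome bounds",
                      clouds$cloud_id[i]))
      s <- max(0L, s)
      e <- min(glen, e)
    }
    contigs$contig[i] <- sprintf("cloud%d", clouds$cloud_id[i])
    contigs$cloud_id[i] <- clouds$cloud_id[i]
    contigs$origin_chrom[i] <- chr
    contigs$origin_start[i] <- s
    contigs$length[i] <- e - s
    seqs[i] <- substring(genome[[chr]], s + 1L, e)
  }
  names(seqs) <- contigs$contig
  structure(list(contigs = contigs, seqs = seqs), class = "abbrev_ref")
}

#' Lift a contig offset to a genome coordinate
#' @param abbrev an `abbrev_ref` from [build_abbreviated_reference()].
#' @param contig contig name(s).
#' @param offset 0-based offset(s) on the contig.
#' @return data frame with `chrom` and `pos` (0-based).
#' @export
lift_to_genome <- function(abbrev, contig, offset) {
  i <- match(contig, abbrev$contigs$contig)
  if (anyNA(i)) stop("unknown contig in lift_to_genome")
  data.frame(chrom = abbrev$contigs$origin_chrom[i],
             pos = abbrev$contigs$origin_start[i] + offset,
             stringsAsFactors = FALSE)
}

#' Lift a genome coordinate back to a contig offset
#' @param abbrev an `abbrev_ref`.
#' @param chrom chromosome name(s).
#' @param pos 0-based genome coordinate(s).
#' @return data frame with `contig` and `offset` (NA where the coordinate is
#'   not covered by any contig; the first covering contig wins).
#' @export
lift_to_contig <- function(abbrev, chrom, pos) {
  ct <- abbrev$contigs
  contig <- rep(NA_character_, length(pos))
  offset <- rep(NA_integer_, length(pos))
  for (j in seq_along(pos)) {
    hit <- which(ct$origin_chrom == chrom[j] & pos[j] >= ct$origin_start &
                 pos[j] < ct$origin_start + ct$length)
    if (length(hit)) {
      contig[j] <- ct$contig[hit[1]]
      offset[j] <- pos[j] - ct$origin_start[hit[1]]
    }
  }
  data.frame(contig = contig, offset = offset, stringsAsFactors = FALSE)
}

# Parse a CIGAR string into ungapped segments and an indel event count.
# Returns list(segs = matrix[read_start0, ref_start0, len], n_indel).
parse_cigar <- function(cigar, offset0) {
  if (cigar %in% c("*", "")) return(list(segs = NULL, n_indel = 0L))
  ops <- gregexpr("\\d+[MIDSH=X]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("\\d+[MIDSH=X]", cigar))[[1]]
  lens <- as.integer(sub("[MIDSH=X]", "", toks))
  kinds <- sub("\\d+", "", toks)
  rpos <- 0L; gpos <- offset0; n_indel <- 0L
  segs <- NULL
  for (k in seq_along(toks)) {
    if (kinds[k] %in% c("M", "=", "X")) {
      segs <- rbind(segs, c(rpos, gpos, lens[k]))
      rpos <- rpos + lens[k]; gpos <- gpos + lens[k]
    } else if (kinds[k] %in% c("S", "H")) {
      rpos <- rpos + if (kinds[k] == "S") lens[k] else 0L
    } else if (kinds[k] == "I") {
      rpos <- rpos + lens[k]; n_indel <- n_indel + 1L
    } else if (kinds[k] == "D") {
      gpos <- gpos + lens[k]; n_indel <- n_indel + 1L
    }
  }
  list(segs = segs, n_indel = n_indel)
}

#' Collect pass-2 alignments into per-read candidate domains
#'
#' Each read's domain is its set of distinct (contig, offset, strand)
#' alignments against the abbreviated reference, truncated to
#' `max_alignments` by descending aligner score (ties: leftmost contig and
#' offset, then forward strand). Reads whose domain exceeded the cap before
#' truncation are flagged `high_copy`: reads with that many placements were
#' judged uninformative for placing other reads and are later reported with
#' MAPQ 0.
#'
#' @param reads data frame with `read_id`, `seq`, `qual`, `end_marker`.
#' @param abbrev an `abbrev_ref`.
#' @param sam data frame of pass-2 records ([read_sam()] or
#'   [mini_align()] multi-mode output) whose `rname` values are contigs of
#'   `abbrev`.
#' @param max_alignments domain cap (default 15).
#' @return list of read fragments; each is a list with `read_id`, `seq`,
#'   `qual`, `end_marker`, `high_copy`, and `aln`, a data frame with
#'   `contig`, `cloud_id`, `offset` (0-based), `strand`, `score`, `nm`,
#'   `n_indel` and a list-column `segs` of aligned-segment matrices.
#' @export
collect_pass2 <- function(reads, abbrev, sam, max_alignments = 15) {
  mapped <- sam[bitwAnd(sam$flag, 4L) == 0L, , drop = FALSE]
  unknown <- setdiff(unique(mapped$rname), abbrev$contigs$contig)
  if (length(unknown))
    stop("pass-2 SAM names unknown contig(s): ", paste(unknown, collapse = ", "))

  # vectorised dedupe / ordering / capping over all records at once
  strand <- ifelse(bitwAnd(mapped$flag, 16L) > 0L, "-", "+")
  keep <- !duplicated(paste(mapped$qname, mapped$rname, mapped$pos, strand))
  rec <- mapped[keep, , drop = FALSE]
  strand <- strand[keep]
  ci <- match(rec$rname, abbrev$contigs$contig)
  big <- data.frame(qname = rec$qname, contig = rec$rname,
                    cloud_id = abbrev$contigs$cloud_id[ci],
                    offset = rec$pos - 1L, strand = strand,
                    score = ifelse(is.na(rec$score), -rec$nm, rec$score),
                    nm = rec$nm, n_indel = 0L, stringsAsFactors = FALSE)
  simple <- grepl("^\\d+M$", rec$cigar)
  big$segs <- vector("list", nrow(big))
  if (any(!simple)) {
    parsed <- lapply(which(!simple),
                     function(k) parse_cigar(rec$cigar[k], rec$pos[k] - 1L))
    big$segs[!simple] <- lapply(parsed, function(p) p$segs)
    big$n_indel[!simple] <- vapply(parsed, function(p) p$n_indel, 0L)
  }
  ord <- order(big$qname, -big$score, big$cloud_id, big$offset,
               match(big$strand, c("+", "-")))
  big <- big[ord, , drop = FALSE]
  rank <- if (nrow(big)) sequence(rle(big$qname)$lengths) else integer()
  n_hits <- table(big$qname)
  by_read <- split(which(rank <= max_alignments),
                   big$qname[rank <= max_alignments])

  out <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    rid <- reads$read_id[i]
    idx <- by_read[[rid]]
    if (is.null(idx)) {
      aln <- data.frame(contig = character(), cloud_id = integer(),
                        offset = integer(), strand = character(),
                        score = numeric(), nm = integer(), n_indel = integer())
      aln$segs <- list()
      high_copy <- FALSE
    } else {
      aln <- big[idx, c("contig", "cloud_id", "offset", "strand", "score",
                        "nm", "n_indel", "segs"), drop = FALSE]
      high_copy <- n_hits[[rid]] > max_alignments
    }
    out[[i]] <- list(read_id = rid, seq = reads$seq[i], qual = reads$qual[i],
                     end_marker = reads$end_marker[i], high_copy = high_copy,
                     aln = aln)
  }
  out
}
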