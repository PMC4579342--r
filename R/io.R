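# File-format boundaries: FASTA/FASTQ through Biostrings, SAM and BED as
# plain text, prior serialisation as JSON (see prior.R).

#' Write a genome to FASTA
#' @param genome named character vector (one element per chromosome).
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(unname(genome))
  names(x) <- names(genome)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read a genome from FASTA
#' @param path FASTA file.
#' @return named character vector of chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write simulated (or real) reads to FASTQ
#'
#' End-marker reads get the read-name suffix `:EM` so the flag survives
#' round-trips through plain FASTQ.
#' @param reads data frame with columns `read_id`, `seq`, `qual`
#'   (Phred+33 string) and `end_marker` (logical).
#' @param path output file.
#' @export
write_well_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- paste0(reads$read_id, ifelse(reads$end_marker, ":EM", ""))
  q <- Biostrings::PhredQuality(reads$qual)
  Biostrings::writeXStringSet(x, filepath = path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a well's reads from FASTQ
#' @param path FASTQ file.
#' @return data frame with `read_id`, `seq`, `qual`, `end_marker`.
#' @export
read_well_fastq <- function(path) {
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  nm <- sub("\\s.*$", "", names(x))
  em <- grepl(":EM$", nm)
  data.frame(
    read_id = sub(":EM$", "", nm),
    seq = as.character(x),
    qual = as.character(Biostrings::quality(x)),
    end_marker = em,
    stringsAsFactors = FALSE
  )
}

#' Write alignment records as a SAM text file
#'
#' Minimal SAM dialect used throughout the package: ungapped alignments with a
#' full-length `M` CIGAR, multiple hits for one read as separate records
#' sharing QNAME, tags `NM:i` (mismatches), `AS:i` (aligner score) and `EM:i`
#' (end-marker flag). Unmapped reads get flag 4 and `*` fields.
#'
#' @param records data frame with columns `qname`, `flag`, `rname`, `pos`
#'   (1-based), `mapq`, `cigar`, `seq`, `qual` and optional `nm`, `score`, `em`.
#' @param path output file.
#' @param ref_lengths named integer vector for `@SQ` header lines.
#' @export
write_sam <- function(records, path, ref_lengths = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  if (!is.null(ref_lengths)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                       as.integer(ref_lengths)), con)
  }
  if (nrow(records) == 0L) return(invisible(path))
  tags <- character(nrow(records))
  add_tag <- function(tags, col, fmt) {
    if (!is.null(records[[col]])) {
      paste0(tags, ifelse(is.na(records[[col]]), "",
                          sprintf(fmt, as.integer(records[[col]]))))
    } else tags
  }
  tags <- add_tag(tags, "nm", "\tNM:i:%d")
  tags <- add_tag(tags, "score", "\tAS:i:%d")
  tags <- add_tag(tags, "em", "\tEM:i:%d")
  lines <- paste0(records$qname, "\t", as.integer(records$flag), "\t",
                  records$rname, "\t", as.integer(records$pos), "\t",
                  as.integer(records$mapq), "\t", records$cigar,
                  "\t*\t0\t0\t", records$seq, "\t", records$qual, tags)
  writeLines(lines, con)
  invisible(path)
}

#' Read a SAM text file written by [write_sam()] (or a compatible aligner)
#' @param path SAM file.
#' @return data frame of records with parsed optional tags.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) {
    return(data.frame(qname = character(), flag = integer(), rname = character(),
                      pos = integer(), mapq = integer(), cigar = character(),
                      seq = character(), qual = character(), nm = integer(),
                      score = integer(), em = integer(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  grab_tag <- function(p, key) {
    hit <- grep(paste0("^", key, ":i:"), p[-(1:11)], value = TRUE)
    if (length(hit)) as.integer(sub(".*:", "", hit[1L])) else NA_integer_
  }
  data.frame(
    qname = vapply(parts, `[`, "", 1L),
    flag = as.integer(vapply(parts, `[`, "", 2L)),
    rname = vapply(parts, `[`, "", 3L),
    pos = as.integer(vapply(parts, `[`, "", 4L)),
    mapq = as.integer(vapply(parts, `[`, "", 5L)),
    cigar = vapply(parts, `[`, "", 6L),
    seq = vapply(parts, `[`, "", 10L),
    qual = vapply(parts, `[`, "", 11L),
    nm = vapply(parts, grab_tag, 1L, "NM"),
    score = vapply(parts, grab_tag, 1L, "AS"),
    em = vapply(parts, grab_tag, 1L, "EM"),
    stringsAsFactors = FALSE
  )
}

#' Write per-cloud confidence records as BED
#' @param clouds data frame with `chrom`, `start`, `end`, `cloud_id`,
#'   `log_quality`, `existence_posterior`, `excluded`.
#' @param path output file.
#' @export
write_cloud_bed <- function(clouds, path) {
  lines <- sprintf("%s\t%d\t%d\tcloud%d\t%.4f\t%.6f\t%d",
                   clouds$chrom, as.integer(clouds$start), as.integer(clouds$end),
                   as.integer(clouds$cloud_id), clouds$log_quality,
                   clouds$existence_posterior, as.integer(clouds$excluded))
  writeLines(lines, path)
  invisible(path)
}
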