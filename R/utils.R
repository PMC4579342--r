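# Shared numeric and sequence helpers.

#' Numerically stable log(sum(exp(x)))
#' @param x numeric vector of log-space values.
#' @return scalar log-sum-exp; `-Inf` for an empty or all `-Inf` input.
#' @keywords internal
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise logsumexp for a 4-row matrix (the ACGT elimination hot path).
.lse4 <- function(m) {
  mx <- pmax(m[1L, ], m[2L, ], m[3L, ], m[4L, ])
  r <- mx + log(exp(m[1L, ] - mx) + exp(m[2L, ] - mx) +
                exp(m[3L, ] - mx) + exp(m[4L, ] - mx))
  # columns that are uniformly -Inf (uncovered) come out NaN; they carry no mass
  r[!is.finite(mx)] <- -Inf
  r
}

.BASE_LOOKUP <- local({
  x <- integer(256L)
  x[utf8ToInt("A")] <- 1L; x[utf8ToInt("C")] <- 2L
  x[utf8ToInt("G")] <- 3L; x[utf8ToInt("T")] <- 4L
  x[utf8ToInt("a")] <- 1L; x[utf8ToInt("c")] <- 2L
  x[utf8ToInt("g")] <- 3L; x[utf8ToInt("t")] <- 4L
  x
})

#' Encode a DNA string as integer codes A=1, C=2, G=3, T=4 (0 = other)
#' @param s single character string.
#' @keywords internal
encode_bases <- function(s) .BASE_LOOKUP[utf8ToInt(s)]

#' Decode integer base codes back to a string
#' @keywords internal
decode_bases <- function(v) intToUtf8(c(65L, 67L, 71L, 84L, 78L)[ifelse(v %in% 1:4, v, 5L)])

#' Reverse-complement character DNA sequences
#' @param x character vector of sequences.
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Phred-scale a posterior probability into a MAPQ score
#'
#' Standard contract: `round(-10 * log10(1 - p))`, capped at 60 (and at 0 from
#' below). A posterior of exactly 0.9 maps to MAPQ 10.
#' @param p posterior probability (vectorised).
#' @param cap maximum reported MAPQ.
#' @return integer MAPQ vector.
#' @export
posterior_to_mapq <- function(p, cap = 60L) {
  q <- round(-10 * log10(pmax(1 - p, 0)))
  q[!is.finite(q)] <- cap
  as.integer(pmax(0L, pmin(as.integer(cap), q)))
}

# Phred+33 encode/decode for FASTQ quality strings.
quals_to_string <- function(q) intToUtf8(as.integer(q) + 33L)
string_to_quals <- function(s) utf8ToInt(s) - 33L

#' Total sequencing depth of a read-cloud design
#'
#' The depth identity of the read-cloud protocol: genome coverage with long
#' fragments `C_F` times short-read coverage of each fragment `C_R` gives the
#' total short-read depth `C = C_F * C_R`.
#' @param C_F long-fragment coverage of the genome.
#' @param C_R short-read coverage of each long fragment.
#' @return total depth `C`.
#' @export
total_depth <- function(C_F, C_R) C_F * C_R

#' Genome-equivalents of a sequencing budget
#' @param C total depth.
#' @param per_genome depth of one standard genome (default 30).
#' @return how many standard genomes the budget corresponds to.
#' @export
genome_equivalents <- function(C, per_genome = 30) C / per_genome
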