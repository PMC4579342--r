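# Confidence queries: read posteriors / MAPQ, cloud quality, existence
# posteriors, collision detection.

# Two-copy fixture: cB is cA with `nmut` substitutions at given positions;
# reads are drawn from cA and multimap to both copies.
two_copy_graph <- function(read_offsets, read_len = 20, mut_pos = integer(),
                           qual = 30, seed = 5,
                           prior = toy_prior(size_meanlog = log(40),
                                             size_sdlog = 0.4,
                                             lambda_mean = 0.1,
                                             genome_length = 1e4)) {
  set.seed(seed)
  len <- 60
  a <- random_seq(len)
  b_chars <- strsplit(a, "")[[1]]
  for (p in mut_pos)
    b_chars[p] <- setdiff(c("A", "C", "G", "T"), b_chars[p])[1]
  seqs <- c(cA = a, cB = paste(b_chars, collapse = ""))
  frags <- lapply(seq_along(read_offsets), function(i) {
    off <- read_offsets[i]
    make_fragment(paste0("r", i),
                  substring(a, off + 1, off + read_len),
                  qual = qual_str(read_len, qual),
                  contigs = c("cA", "cB"), cloud_ids = 1:2,
                  offsets = c(off, off))
  })
  toy_graph(seqs, frags, prior, read_length = read_len)
}

test_that("a read with a single live placement gets full confidence", {
  g <- two_copy_graph(c(0, 20, 40), mut_pos = c(6, 25, 46))
  map <- map_inference(g, list(seed = 1))
  # three distinguishing sites: all reads on copy A
  expect_true(all(vapply(seq_along(g$reads), function(n)
    g$reads[[n]]$opts[[map$choice[n]]]$mol, 0L) ==
      g$reads[[1]]$opts[[map$choice[1]]]$mol))
  rp <- read_posterior(g, map, 1)
  expect_gt(rp$posterior, 0.99)
  expect_equal(rp$mapq, 60L)
})

test_that("perfect repeat symmetry halves the posterior (MAPQ 3)", {
  g <- two_copy_graph(5, mut_pos = integer())  # identical copies, one read

  map <- map_inference(g, list(seed = 2))
  rp <- read_posterior(g, map, 1)
  expect_equal(rp$posterior, 0.5, tolerance = 1e-6)
  expect_equal(rp$mapq, 3L)
})

test_that("MAPQ obeys the Phred contract", {
  expect_equal(posterior_to_mapq(0.9), 10L)
  expect_equal(posterior_to_mapq(0.5), 3L)
  expect_equal(posterior_to_mapq(1), 60L)
  expect_equal(posterior_to_mapq(0), 0L)
  p <- seq(0, 0.999999, length.out = 2000)
  q <- posterior_to_mapq(p)
  expect_true(all(q[p >= 0.9] >= 10L))
  expect_true(all(diff(q) >= 0L))
  expect_true(all(q <= 60L))
})

test_that("cloud quality matches the potential and its closed-form deltas", {
  pr <- toy_prior_small()
  theta <- pr$theta
  contig <- random_seq(30, seed = 9)
  reads0 <- data.frame(seq = c(substring(contig, 1, 10),
                               substring(contig, 8, 17)),
                       qual = qual_str(10, 30), offset = c(0L, 7L),
                       stringsAsFactors = FALSE)
  base_q <- compute_log_potential(contig, reads0, pr, read_length = 10)
  # a unanimous variant position (both reads overlap position 9)
  reads1 <- reads0
  v <- setdiff(c("A", "C", "G", "T"), substring(contig, 9, 9))[1]
  substr(reads1$seq[1], 9, 9) <- v
  substr(reads1$seq[2], 2, 2) <- v
  e <- 1e-3
  num <- (1 - theta) * (e / 3)^2 + (theta / 3) * (1 - e)^2 +
    (theta / 3) * (e / 3)^2 * 2
  den <- (1 - theta) * (1 - e)^2 + (theta / 3) * (e / 3)^2 * 3
  want <- log(num / den)
  got <- compute_log_potential(contig, reads1, pr, read_length = 10) - base_q
  expect_equal(got, want, tolerance = 1e-9)
  # all-matching reads score above any single-substitution perturbation
  set.seed(10)
  for (rep in 1:15) {
    pr_reads <- reads0
    i <- sample(2, 1); p <- sample(10, 1)
    ch <- substring(pr_reads$seq[i], p, p)
    substr(pr_reads$seq[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), ch), 1)
    expect_lt(compute_log_potential(contig, pr_reads, pr, read_length = 10),
              base_q)
  }
})

test_that("empty molecules carry the inactive prior as their quality", {
  g <- two_copy_graph(c(0, 20), mut_pos = 4)
  map <- map_inference(g, list(seed = 3))
  active <- g$reads[[1]]$opts[[map$choice[1]]]$mol
  other <- setdiff(seq_along(g$mol), active)
  expect_equal(cloud_quality(g, map, other),
               log(1 - g$prior$p_exist))
  expect_lt(cloud_quality(g, map, active), 0)
})

test_that("existence posterior is 1 without alternatives, 0.5 under symmetry", {
  # unique molecule: read r2 pins cA, no inactive alternative can host all
  pr <- toy_prior_small()
  seqs <- c(cA = random_seq(30, seed = 21))
  frags <- list(make_fragment("r1", substring(seqs[["cA"]], 3, 10),
                              contigs = "cA", cloud_ids = 1L, offsets = 2L))
  g <- toy_graph(seqs, frags, pr, read_length = 8)
  map <- map_inference(g, list(seed = 1))
  expect_equal(existence_posterior(g, map, 1), 1)

  # identical copies at distant loci: perfect ambiguity
  g2 <- two_copy_graph(c(0, 20, 40), mut_pos = integer())
  map2 <- map_inference(g2, list(seed = 4))
  active <- g2$reads[[1]]$opts[[map2$choice[1]]]$mol
  expect_equal(existence_posterior(g2, map2, active), 0.5, tolerance = 1e-6)
})

test_that("existence posterior matches the pooled-site likelihood ratio", {
  # copies differing at one site covered by all three reads (quality 30):
  # unanimous disagreement pools into a single SNP-like event, so the
  # alternative placement is only ~theta times less likely, not theta^3
  g <- two_copy_graph(c(10, 12, 14), mut_pos = 25, qual = 30)
  map <- map_inference(g, list(seed = 6))
  active <- g$reads[[1]]$opts[[map$choice[1]]]$mol
  theta <- g$prior$theta
  e <- 1e-3
  num <- (1 - theta) * (e / 3)^3 + (theta / 3) * (1 - e)^3 +
    (2 * theta / 3) * (e / 3)^3
  den <- (1 - theta) * (1 - e)^3 + theta * (e / 3)^3
  delta <- log(num / den)
  expect_equal(existence_posterior(g, map, active), 1 / (1 + exp(delta)),
               tolerance = 1e-4)
})

test_that("posterior mass pools over placements, not duplicated contigs", {
  # same genome locus cut into two overlapping contigs: not real ambiguity
  pr <- toy_prior_small()
  a <- random_seq(40, seed = 31)
  seqs <- c(c1 = substring(a, 1, 30), c2 = substring(a, 6, 40))
  ab <- make_abbrev(seqs, origin_starts = c(0L, 5L))
  frags <- list(make_fragment("r1", substring(a, 11, 20),
                              contigs = c("c1", "c2"), cloud_ids = 1:2,
                              offsets = c(10L, 5L)),
                make_fragment("r2", substring(a, 13, 22),
                              contigs = c("c1", "c2"), cloud_ids = 1:2,
                              offsets = c(12L, 7L)))
  g <- build_mrf(frags, ab, pr, read_length = 10)
  for (n in seq_along(g$reads)) {
    g$reads[[n]]$seq_str <- frags[[n]]$seq
    g$reads[[n]]$qual_str <- frags[[n]]$qual
  }
  map <- map_inference(g, list(seed = 7))
  rp <- read_posterior(g, map, 1)
  expect_gt(rp$posterior, 0.99)
  expect_equal(rp$mapq, 60L)
  # and the same-locus inactive twin is not an existence alternative
  act <- g$reads[[1]]$opts[[map$choice[1]]]$mol
  expect_equal(existence_posterior(g, map, act), 1)
})

test_that("collision detection flags interior markers and reports both rates", {
  starts <- c(seq(0, 3900, by = 300), seq(4000, 7900, by = 300))
  a <- data.frame(read_id = sprintf("r%02d", seq_along(starts)),
                  chrom = "chr1", start = starts, strand = "+",
                  end_marker = starts == 4000, stringsAsFactors = FALSE)
  cl <- cluster_pass1(a, 3500, 6)
  msg <- capture_messages(res <- detect_collisions(cl, a, marker_eff = 0.77))
  expect_equal(res$flagged, cl$cloud_id[1])
  expect_setequal(res$excluded_reads, a$read_id)
  expect_equal(res$detection_rate, 1 - 0.23^2)
  expect_equal(res$naive_rate, 1 - 0.77^2)
  expect_match(paste(msg, collapse = " "), "94.7")

  suppressMessages(r2 <- detect_collisions(cl, a, marker_eff = 1))
  expect_equal(r2$detection_rate, 1)

  # clean clouds stay unflagged
  a2 <- a; a2$end_marker <- FALSE
  cl2 <- cluster_pass1(a2, 3500, 6)
  suppressMessages(r3 <- detect_collisions(cl2, a2, 0.77))
  expect_length(r3$flagged, 0)
})

test_that("low-quality cloud flag spares ordinary clouds", {
  g <- two_copy_graph(c(0, 13, 26, 39), mut_pos = c(3, 30))
  map <- map_inference(g, list(seed = 8))
  lowq <- flag_low_quality_clouds(g, map, n_null = 5, seed = 1)
  active <- g$reads[[1]]$opts[[map$choice[1]]]$mol
  expect_false(lowq[active])
})
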