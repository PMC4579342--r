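# MRF construction, potentials by variable elimination, assignment scoring,
# and MAP inference, each checked against independent oracles.

test_that("read-molecule incidence matches a brute-force membership scan", {
  pr <- toy_prior()
  set.seed(31)
  seqs <- c(cA = random_seq(60), cB = random_seq(60), cC = random_seq(60))
  frags <- list(
    make_fragment("r1", substring(seqs[["cA"]], 11, 20),
                  contigs = c("cA", "cC"), cloud_ids = c(1L, 3L),
                  offsets = c(10L, 30L)),
    make_fragment("r2", substring(seqs[["cB"]], 1, 10),
                  contigs = "cB", cloud_ids = 2L, offsets = 0L),
    make_fragment("r3", substring(seqs[["cA"]], 31, 40),
                  contigs = "cA", cloud_ids = 1L, offsets = 30L))
  g <- build_mrf(frags, make_abbrev(seqs), pr, read_length = 10)
  names(g$mol) <- vapply(g$mol, function(m) m$contig, "")
  expect_setequal(g$attach[[match("cA", names(g$mol))]], c(1L, 3L))
  expect_setequal(g$attach[[match("cC", names(g$mol))]], 1L)
  expect_setequal(g$attach[[match("cB", names(g$mol))]], 2L)
  # random fixture: incidence equals an O(N*C) scan of the membership rule
  set.seed(32)
  for (rep in 1:10) {
    nr <- sample(3:8, 1)
    fr <- lapply(seq_len(nr), function(i) {
      ks <- sample(1:3, sample(1:2, 1))
      make_fragment(paste0("x", i), random_seq(10),
                    contigs = names(seqs)[ks], cloud_ids = ks,
                    offsets = sample(0:50, length(ks), replace = TRUE))
    })
    gg <- build_mrf(fr, make_abbrev(seqs), pr, read_length = 10)
    for (c in seq_along(gg$mol)) {
      want <- which(vapply(fr, function(f)
        gg$mol[[c]]$contig %in% f$aln$contig, TRUE))
      expect_setequal(gg$attach[[c]], want)
    }
  }
})

test_that("an alignment at offset s_c (one past the end) is not attached", {
  pr <- toy_prior()
  seqs <- c(cA = random_seq(50, seed = 4))
  fr <- list(make_fragment("r1", substring(seqs[["cA"]], 31, 40),
                           contigs = "cA", cloud_ids = 1L, offsets = 30L))
  g <- build_mrf(fr, make_abbrev(seqs), pr, read_length = 10,
                 molecule_sizes = c(cA = 30L))
  expect_equal(length(g$mol), 0L)    # molecule dropped: nothing attached
  g2 <- build_mrf(fr, make_abbrev(seqs), pr, read_length = 10,
                  molecule_sizes = c(cA = 31L))
  expect_equal(length(g2$mol), 1L)
})

test_that("potential equals exhaustive enumeration over hidden sequences", {
  pr <- toy_prior(theta = 0.25)
  set.seed(41)
  for (rep in 1:8) {
    contig <- random_seq(4)
    reads <- data.frame(
      seq = vapply(1:2, function(i) random_seq(sample(2:3, 1)), ""),
      qual = NA, offset = NA, end_marker = sample(c(TRUE, FALSE), 2, TRUE),
      stringsAsFactors = FALSE)
    reads$offset <- vapply(nchar(reads$seq), function(l)
      sample(0:(4 - l), 1), 0)
    reads$qual <- vapply(nchar(reads$seq), function(l)
      qual_str(l, sample(c(15, 25, 30), 1)), "")
    got <- compute_log_potential(contig, reads, pr, read_length = 2)
    want <- brute_potential_acc(contig, reads, pr, read_length = 2)
    expect_equal(got, want, tolerance = 1e-9)
  }
  # empty molecule
  expect_equal(compute_log_potential(random_seq(4), NULL, pr),
               log(1 - pr$p_exist))
})

test_that("a single mismatch shifts the potential by the closed-form ratio", {
  pr <- toy_prior(theta = 1e-3)
  theta <- pr$theta
  e <- 1e-3                       # quality 30
  contig <- random_seq(40, seed = 51)
  rd_match <- data.frame(seq = substring(contig, 11, 30),
                         qual = qual_str(20, 30), offset = 10L,
                         stringsAsFactors = FALSE)
  rd_mm <- rd_match
  mid <- substring(rd_mm$seq, 10, 10)
  sub <- setdiff(c("A", "C", "G", "T"), mid)[1]
  substr(rd_mm$seq, 10, 10) <- sub
  d <- compute_log_potential(contig, rd_mm, pr) -
    compute_log_potential(contig, rd_match, pr)
  want <- log(((1 - theta) * e / 3 + (theta / 3) * (1 - e) +
                 (2 * theta / 3) * (e / 3)) /
                ((1 - theta) * (1 - e) + theta * e / 3))
  expect_equal(d, want, tolerance = 1e-9)
})

test_that("alignments poking outside the molecule are clipped with warning", {
  pr <- toy_prior()
  contig <- random_seq(30, seed = 6)
  rd <- data.frame(seq = paste0(substring(contig, 21, 30), "ACGTACGTAC"),
                   qual = qual_str(20, 30), offset = 20L,
                   stringsAsFactors = FALSE)
  expect_warning(v <- compute_log_potential(contig, rd, pr, read_length = 20),
                 "clipped")
  expect_true(is.finite(v))
})

test_that("assignment scoring matches hand identities and symmetries", {
  pr <- toy_prior(p_exist = 0.3)
  seqs <- c(cA = random_seq(30, seed = 61), cB = random_seq(30))
  frags <- list(
    make_fragment("r1", substring(seqs[["cA"]], 3, 12),
                  contigs = c("cA", "cB"), cloud_ids = 1:2,
                  offsets = c(2L, 2L)),
    make_fragment("r2", substring(seqs[["cB"]], 11, 20),
                  contigs = "cB", cloud_ids = 2L, offsets = 10L))
  g <- toy_graph(seqs, frags, pr, read_length = 10)
  # (a) all reads unassigned: sum of inactive-molecule priors
  sc0 <- score_assignment(g, c(0L, 0L))
  expect_equal(as.numeric(sc0), 2 * log(1 - 0.3))
  # (b) matches the standalone potential computation molecule by molecule
  sc <- score_assignment(g, c(1L, 1L))
  byhand <- compute_log_potential(
    seqs[["cA"]], data.frame(seq = frags[[1]]$seq, qual = frags[[1]]$qual,
                             offset = 2L), pr, 10) +
    compute_log_potential(
      seqs[["cB"]], data.frame(seq = frags[[2]]$seq, qual = frags[[2]]$qual,
                               offset = 10L), pr, 10)
  expect_equal(as.numeric(sc), byhand, tolerance = 1e-9)
  # (c) invariant under relabeling of the molecules
  g2 <- toy_graph(rev(seqs), rev(frags), pr, read_length = 10)
  sc2 <- score_assignment(g2, c(1L, 1L))
  expect_equal(as.numeric(sc2), as.numeric(sc), tolerance = 1e-9)
})

test_that("incremental engine agrees with from-scratch recomputation", {
  pr <- toy_prior()
  set.seed(71)
  for (rep in 1:10) {
    seqs <- c(cA = random_seq(40), cB = random_seq(40))
    nr <- sample(3:7, 1)
    frags <- lapply(seq_len(nr), function(i) {
      l <- sample(6:10, 1)
      off <- sample(0:(40 - l), 1)
      sq <- substring(seqs[["cA"]], off + 1, off + l)
      ks <- if (runif(1) < 0.5) 1:2 else 1L
      make_fragment(paste0("r", i), sq, contigs = c("cA", "cB")[ks],
                    cloud_ids = ks,
                    offsets = rep(off, length(ks)),
                    end_marker = runif(1) < 0.3)
    })
    g <- toy_graph(seqs, frags, pr, read_length = 6)
    eng <- rfaligner:::.engine_new(g)
    choice <- vapply(g$reads, function(r) sample(0:r$K, 1), 0L)
    for (n in seq_along(choice))
      if (choice[n] > 0L) rfaligner:::.apply_move(eng, n, choice[n])
    sc <- score_assignment(g, choice)
    expect_equal(eng$objective, attr(sc, "objective"), tolerance = 1e-6)
    expect_equal(sum(vapply(eng$ms, function(m) m$term, 0)), as.numeric(sc),
                 tolerance = 1e-6)
  }
})

test_that("single-candidate wells converge in one sweep to the only option", {
  pr <- toy_prior(size_meanlog = log(60), size_sdlog = 0.4,
                  lambda_mean = 0.1, genome_length = 1e4)
  seqs <- c(cA = random_seq(60, seed = 81))
  frags <- lapply(1:5, function(i) {
    off <- (i - 1) * 10
    make_fragment(paste0("r", i), substring(seqs[["cA"]], off + 1, off + 10),
                  contigs = "cA", cloud_ids = 1L, offsets = off)
  })
  g <- toy_graph(seqs, frags, pr, read_length = 10)
  map <- map_inference(g, list(seed = 1, restarts = 1))
  expect_equal(map$choice, rep(1L, 5))
  expect_true(map$converged)
})

test_that("MAP inference matches exhaustive enumeration on small instances", {
  n_exact <- 0L
  for (seed in 1:60) {
    g <- acc_random_instance(seed)
    states <- prod(vapply(g$reads, function(r) r$K + 1, 0))
    if (states > 2000) next
    map <- map_inference(g, list(seed = seed, restarts = 3, sweeps = 50))
    ex <- exhaustive_map(g)
    expect_equal(map$objective, ex$objective, tolerance = 1e-6,
                 label = sprintf("instance %d", seed))
    n_exact <- n_exact + 1L
  }
  expect_gte(n_exact, 40L)
})

test_that("accepted moves never decrease the objective and runs are
           deterministic", {
  g <- acc_random_instance(999, max_reads = 10)
  m1 <- map_inference(g, list(seed = 5, restarts = 3))
  m2 <- map_inference(g, list(seed = 5, restarts = 3))
  expect_identical(m1$choice, m2$choice)
  expect_equal(m1$objective, m2$objective)
  # local optimality: no single-read move improves the returned assignment
  eng <- m1$engine
  for (n in seq_along(g$reads)) {
    for (j in setdiff(0:g$reads[[n]]$K, eng$choice[n])) {
      expect_lte(rfaligner:::.eval_move(eng, n, j), 1e-9)
    }
  }
  # greedy start is never better than the final objective
  eng0 <- rfaligner:::.engine_new(g)
  rfaligner:::.engine_init_greedy(eng0)
  expect_gte(m1$objective + 1e-9, eng0$objective)
})

test_that("potential cost tracks aligned bases, not molecule size", {
  pr <- toy_prior()
  # same read set on a short and a long contig: elimination touches only
  # covered columns, so both must give identical covered-position sums and
  # the objective must differ only through the size-dependent prior terms
  short <- random_seq(60, seed = 91)
  long <- paste0(short, random_seq(4000))
  rd <- data.frame(seq = substring(short, 11, 40), qual = qual_str(30, 30),
                   offset = 10L, stringsAsFactors = FALSE)
  a <- compute_log_potential(short, rd, pr, read_length = 30)
  b <- compute_log_potential(long, rd, pr, read_length = 30)
  expect_equal(a, b, tolerance = 1e-9)   # span identical; uncovered = no-op
})
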