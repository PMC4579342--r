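# Mini-mapper, SAM round trips, the per-well pipeline and the evaluation
# harness.

test_that("coverage identities of the read-cloud design hold", {
  expect_equal(total_depth(C_F = 20, C_R = 50), 1000)
  expect_equal(genome_equivalents(1000, per_genome = 30), 1000 / 30)
  expect_equal(total_depth(C_F = 20, C_R = 1.5), 30)
})

test_that("mini-mapper finds unique and duplicated placements exactly", {
  set.seed(55)
  base <- random_seq(20000)
  dup <- substring(base, 2001, 5000)
  genome <- c(chr1 = paste0(base, dup))   # exact two-copy repeat at the end
  reads <- data.frame(
    read_id = c("uniq", "rep", "revd"),
    seq = c(substring(base, 10001, 10100),
            substring(base, 3001, 3100),
            revcomp(substring(base, 12001, 12100))),
    qual = qual_str(100, 30), end_marker = FALSE, stringsAsFactors = FALSE)
  multi <- mini_align(reads, genome, "multi", seed = 1)
  u <- multi[multi$qname == "uniq", ]
  expect_equal(nrow(u), 1L)
  expect_equal(u$pos, 10001L)
  expect_equal(bitwAnd(u$flag, 16L), 0L)
  r <- multi[multi$qname == "rep", ]
  expect_equal(nrow(r), 2L)
  expect_setequal(r$pos, c(3001L, 21001L))
  expect_equal(r$score[1], r$score[2])
  v <- multi[multi$qname == "revd", ]
  expect_equal(v$pos, 12001L)
  expect_equal(bitwAnd(v$flag, 16L), 16L)
  # single mode: unique reads confident, exact-repeat reads not
  single <- mini_align(reads, genome, "single", seed = 1)
  expect_gte(single$mapq[single$qname == "uniq"], 10L)
  expect_lt(single$mapq[single$qname == "rep"], 10L)
  expect_equal(single$n_best[single$qname == "rep"], 2L)
})

test_that("mini-mapper hit sets match a brute-force scan under errors", {
  set.seed(56)
  genome <- c(g = random_seq(6000))
  L <- 100
  for (rep in 1:5) {
    pos <- sample(6000 - L, 1)
    sq <- substring(genome[["g"]], pos + 1, pos + L)
    nerr <- sample(0:2, 1)
    if (nerr > 0) {
      at <- sample(L, nerr)
      for (p in at)
        substr(sq, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                           substring(sq, p, p)), 1)
    }
    reads <- data.frame(read_id = "r", seq = sq, qual = qual_str(L, 30),
                        end_marker = FALSE)
    got <- mini_align(reads, genome, "multi", max_hits = 50, seed = 1)
    got <- got[bitwAnd(got$flag, 4L) == 0L & bitwAnd(got$flag, 16L) == 0L, ]
    # brute force: every start position with <= 5 mismatches (forward)
    wins <- substring(genome[["g"]], 1:(6000 - L + 1), L:6000)
    mm <- vapply(wins, function(w)
      sum(charToRaw(w) != charToRaw(sq)), 0L, USE.NAMES = FALSE)
    want <- which(mm <= 5)
    # seeds require one exact 31-mer, satisfied here (<=2 errors in 100 bp
    # leaves at least one clean seed window)
    expect_setequal(got$pos, want)
    expect_equal(sort(got$nm), sort(mm[want]))
  }
})

test_that("SAM text round-trips records exactly", {
  set.seed(57)
  rec <- data.frame(
    qname = sprintf("q%d", 1:6),
    flag = c(0L, 16L, 4L, 0L, 16L, 0L),
    rname = c("c1", "c1", "*", "c2", "c2", "c1"),
    pos = c(1L, 500L, 0L, 42L, 7L, 9999L),
    mapq = c(60L, 3L, 0L, 10L, 42L, 17L),
    cigar = c("100M", "100M", "*", "50M", "100M", "100M"),
    seq = vapply(1:6, function(i) random_seq(20), ""),
    qual = qual_str(20, 30),
    nm = c(0L, 2L, NA, 1L, 0L, 5L),
    score = c(100L, 88L, NA, 44L, 100L, 70L),
    em = c(0L, 1L, 0L, 0L, 1L, 0L), stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".sam")
  write_sam(rec, f, ref_lengths = c(c1 = 10000L, c2 = 5000L))
  back <- read_sam(f)
  for (col in c("qname", "flag", "rname", "pos", "mapq", "cigar", "nm",
                "score", "em"))
    expect_equal(back[[col]], rec[[col]], label = col)
})

# Small end-to-end fixture shared by the pipeline tests.
e2e_fixture <- function() {
  cfg <- sim_config(genome_length = 4e5, dup_count = 2,
                    dup_len_range = c(6000, 10000),
                    dup_identity_range = c(0.96, 0.98),
                    well_fraction = 0.15)
  g <- make_repeat_genome(cfg, seed = 12)
  wells <- lapply(1:12, function(w)
    simulate_well(g$genome, cfg, seed = 300 + w, well = w))
  pass1 <- lapply(wells, function(w)
    mini_align(w$reads, g$genome, "single", seed = 9))
  rc <- rfa_config(restarts = 2)
  clouds_all <- do.call(rbind, lapply(seq_along(wells), function(w) {
    cl <- rfaligner:::.call_clouds(rfaligner:::.pass1_alignments(pass1[[w]]), rc)
    cl$well <- w
    cl
  }))
  prior <- fit_prior(extract_features(clouds_all, min_unique_frac = 0.8),
                     genome_length = 4e5, well_fraction = 0.15, n_wells = 12)
  list(cfg = cfg, g = g, wells = wells, pass1 = pass1, rc = rc,
       prior = prior)
}

fx_cache <- new.env()
get_fixture <- function() {
  if (is.null(fx_cache$fx)) fx_cache$fx <- e2e_fixture()
  fx_cache$fx
}

test_that("the per-well pipeline runs, lifts correctly, and is idempotent", {
  fx <- get_fixture()
  res <- run_well(fx$wells[[1]]$reads, fx$g$genome, fx$prior, fx$rc,
                  pass1 = fx$pass1[[1]])
  # step-2 contig count equals cloud count
  expect_equal(nrow(res$abbrev$contigs), nrow(res$clouds))
  # every placement lies inside its source cloud's padded interval
  pl <- res$placements[res$placements$placed, ]
  expect_gt(nrow(pl), 0)
  for (i in seq_len(nrow(pl))) {
    ok <- any(res$abbrev$contigs$origin_start <= pl$pos[i] &
              res$abbrev$contigs$origin_start + res$abbrev$contigs$length >
                pl$pos[i])
    expect_true(ok)
  }
  # determinism: identical seed, identical SAM bytes
  res2 <- run_well(fx$wells[[1]]$reads, fx$g$genome, fx$prior, fx$rc,
                   pass1 = fx$pass1[[1]])
  f1 <- tempfile(fileext = ".sam"); f2 <- tempfile(fileext = ".sam")
  emit_sam(res, fx$wells[[1]]$reads, fx$g$genome, f1)
  emit_sam(res2, fx$wells[[1]]$reads, fx$g$genome, f2)
  expect_identical(readLines(f1), readLines(f2))
  # cloud BED writes
  fb <- tempfile(fileext = ".bed")
  write_cloud_bed(res$cloud_bed, fb)
  expect_equal(length(readLines(fb)), nrow(res$cloud_bed))
})

test_that("an empty well yields empty outputs without error", {
  fx <- get_fixture()
  res <- run_well(fx$wells[[1]]$reads[0, ], fx$g$genome, fx$prior, fx$rc)
  expect_equal(nrow(res$placements), 0L)
  expect_equal(nrow(res$cloud_bed), 0L)
})

test_that("the four comparators satisfy their defining relations", {
  fx <- get_fixture()
  truth_all <- NULL
  methods <- list(baseline = NULL, naive = NULL, rfa = NULL, oracle = NULL)
  mm <- character()
  for (w in 1:8) {
    # clouds at the chromosome edge legitimately warn about clipping
    res <- suppressWarnings(
      run_well(fx$wells[[w]]$reads, fx$g$genome, fx$prior, fx$rc,
               pass1 = fx$pass1[[w]]))
    tr <- fx$wells[[w]]$truth
    methods$baseline <- rbind(methods$baseline,
                              baseline_placements(fx$pass1[[w]]))
    methods$naive <- rbind(methods$naive, naive_placements(res))
    methods$rfa <- rbind(methods$rfa, rfa_placements(res))
    methods$oracle <- rbind(methods$oracle, oracle_placements(res, tr))
    mm <- c(mm, res$placements$read_id[res$placements$multimapped])
    truth_all <- rbind(truth_all, tr)
  }
  rep <- evaluate(methods, truth_all, mm)
  ag <- rep$aggregate
  expect_setequal(ag$method, c("baseline", "naive", "rfa", "oracle"))
  expect_true(all(ag$mm_wrong_rate <= 1, na.rm = TRUE))
  # Oracle never makes a wrong confident call and upper-bounds RFA per well
  ora_wrong <- ag$mm_wrong_rate[ag$method == "oracle"]
  if (!is.na(ora_wrong)) expect_equal(ora_wrong, 0)
  pw <- rep$per_well
  for (w in unique(pw$well)) {
    expect_gte(pw$mm_correct_confident[pw$method == "oracle" & pw$well == w],
               pw$mm_correct_confident[pw$method == "rfa" & pw$well == w])
  }
  # truth/read-set mismatch is a hard error
  expect_error(evaluate(list(rfa = methods$rfa[-1, ]), truth_all, mm),
               "cover")
})

test_that("all methods coincide on a duplication-free genome", {
  cfg <- sim_config(genome_length = 2e5, dup_count = 0, well_fraction = 0.2)
  g <- make_repeat_genome(cfg, seed = 44)
  well <- simulate_well(g$genome, cfg, seed = 45, well = 1)
  pass1 <- mini_align(well$reads, g$genome, "single", seed = 3)
  rc <- rfa_config(restarts = 1)
  clouds <- rfaligner:::.call_clouds(rfaligner:::.pass1_alignments(pass1), rc)
  clouds$well <- 1L
  cl10 <- do.call(rbind, replicate(12, clouds, simplify = FALSE))
  cl10$well <- rep(1:12, each = nrow(clouds))
  prior <- fit_prior(extract_features(cl10, min_unique_frac = 0),
                     genome_length = 2e5, well_fraction = 0.2, n_wells = 12)
  res <- run_well(well$reads, g$genome, prior, rc, pass1 = pass1)
  methods <- list(baseline = baseline_placements(pass1),
                  naive = naive_placements(res),
                  rfa = rfa_placements(res),
                  oracle = oracle_placements(res, well$truth))
  mm <- res$placements$read_id[res$placements$multimapped]
  rep <- evaluate(methods, well$truth, mm)
  ag <- rep$aggregate
  # without ambiguity every method confidently recovers nearly all reads
  expect_true(all(ag$all_correct_confident > 0.95))
  expect_lt(diff(range(ag$all_correct_confident)), 0.05)
})
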