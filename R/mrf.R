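# The per-well Markov random field: one potential per candidate long
# molecule, computed by variable elimination of the molecule's hidden
# sequence (per-position sum over ACGT) and read density (numeric
# quadrature on the prior's lambda grid); plus the incremental engine and
# the iterated-conditional-modes MAP search.

.INDEL_LOGPEN <- log(1e-4)

# ---- graph construction -----------------------------------------------------

#' Build the read-molecule MRF for one well
#'
#' One molecule per abbreviated-reference contig; a read is attached to a
#' molecule iff at least one of its candidate alignments starts inside the
#' molecule's coordinate range `[0, size)` on that contig. Molecules with no
#' attached reads are dropped. Reads flagged `high_copy` contribute no
#' options (they are excluded from potentials and reported with MAPQ 0).
#'
#' @param fragments read list from [collect_pass2()].
#' @param abbrev the `abbrev_ref` the pass-2 alignments refer to.
#' @param prior a `well_prior`.
#' @param read_length read length in bp (floors the molecule span).
#' @param molecule_sizes optional named vector (by contig) restricting each
#'   molecule's range below its contig length.
#' @return an `mrf_graph` list: `mol` (per-molecule static data), `reads`
#'   (per-read option lists), `opt_mols` (per-read molecule index sets),
#'   `attach` (per-molecule attached read indices), `prior`, `read_length`.
#' @export
build_mrf <- function(fragments, abbrev, prior, read_length = 100,
                      molecule_sizes = NULL) {
  ct <- abbrev$contigs
  theta <- prior$theta
  mol <- vector("list", nrow(ct))
  for (c in seq_len(nrow(ct))) {
    ref <- encode_bases(abbrev$seqs[[ct$contig[c]]])
    s <- length(ref)
    logpi <- matrix(log(theta / 3), 4L, s)
    logpi[cbind(ref, seq_len(s))] <- log(1 - theta)
    size <- if (!is.null(molecule_sizes) && ct$contig[c] %in% names(molecule_sizes))
      molecule_sizes[[ct$contig[c]]] else s
    mol[[c]] <- list(contig = ct$contig[c], cloud_id = ct$cloud_id[c],
                     chrom = ct$origin_chrom[c], gstart = ct$origin_start[c],
                     ref = ref, logpi = logpi, size = size, slen = s)
  }
  names(mol) <- ct$contig

  reads <- vector("list", length(fragments))
  opt_mols <- vector("list", length(fragments))
  rc_all <- if (length(fragments))
    revcomp(vapply(fragments, function(f) f$seq, "")) else character()
  for (n in seq_along(fragments)) {
    fr <- fragments[[n]]
    codes_f <- encode_bases(fr$seq)
    quals_f <- string_to_quals(fr$qual)
    codes_r <- encode_bases(rc_all[n])
    quals_r <- base::rev(quals_f)
    opts <- list()
    if (!fr$high_copy && nrow(fr$aln) > 0) {
      for (k in seq_len(nrow(fr$aln))) {
        ci <- match(fr$aln$contig[k], names(mol))
        if (is.na(ci)) next
        if (fr$aln$offset[k] < 0 || fr$aln$offset[k] >= mol[[ci]]$size) next
        rc <- fr$aln$strand[k] == "-"
        obs_all <- if (rc) codes_r else codes_f
        q_all <- if (rc) quals_r else quals_f
        segs <- fr$aln$segs[[k]]
        if (is.null(segs))
          segs <- matrix(c(0L, fr$aln$offset[k], length(obs_all)), 1L)
        cols <- integer(0); ridx <- integer(0)
        for (sgi in seq_len(nrow(segs))) {
          len <- segs[sgi, 3]
          cols <- c(cols, segs[sgi, 2] + seq_len(len))       # 1-based contig
          ridx <- c(ridx, segs[sgi, 1] + seq_len(len))
        }
        keep <- cols >= 1L & cols <= mol[[ci]]$slen
        cols <- cols[keep]; ridx <- ridx[keep]
        if (length(cols) == 0L) next
        obs <- obs_all[ridx]
        e <- 10^(-q_all[ridx] / 10)
        m <- matrix(rep(log(e / 3), each = 4L), 4L)
        m[cbind(obs, seq_along(cols))] <- log1p(-e)
        opts[[length(opts) + 1L]] <- list(
          mol = ci, cols = cols, m = m,
          mP = m + mol[[ci]]$logpi[, cols, drop = FALSE],
          n_indel = fr$aln$n_indel[k], score = fr$aln$score[k],
          offset = fr$aln$offset[k], strand = fr$aln$strand[k],
          start = min(cols) - 1L, end = max(cols))
      }
    }
    reads[[n]] <- list(read_id = fr$read_id, end_marker = fr$end_marker,
                       high_copy = fr$high_copy, opts = opts,
                       K = length(opts),
                       # off-target hypothesis still emits the bases, under
                       # a uniform background
                       off_lp = log(prior$p_offtarget) +
                         length(codes_f) * log(0.25))
    opt_mols[[n]] <- unique(vapply(opts, function(o) o$mol, 0L))
  }

  attach <- lapply(seq_along(mol), function(c)
    which(vapply(opt_mols, function(v) c %in% v, TRUE)))
  keep_mol <- vapply(attach, length, 0L) > 0L
  remap <- cumsum(keep_mol)
  for (n in seq_along(reads)) {
    keep_opt <- vapply(reads[[n]]$opts, function(o) keep_mol[o$mol], TRUE)
    reads[[n]]$opts <- lapply(reads[[n]]$opts[keep_opt], function(o) {
      o$mol <- remap[o$mol]; o
    })
    reads[[n]]$K <- length(reads[[n]]$opts)
    opt_mols[[n]] <- unique(vapply(reads[[n]]$opts, function(o) o$mol, 0L))
  }
  structure(list(mol = mol[keep_mol], reads = reads, opt_mols = opt_mols,
                 attach = attach[keep_mol], prior = prior,
                 read_length = read_length),
            class = "mrf_graph")
}

# ---- standalone potential ---------------------------------------------------

# Scalar molecule term given summary state. parts of the potential that do
# not involve the per-position elimination sum.
.term_static <- function(prior, n, s, b_key, n_indel_sum, read_length) {
  s <- max(s, read_length)
  log(prior$p_exist) + log(prior$pB[[b_key]]) - log(prior$genome_length) -
    n * log(s) + .count_logterm(prior, b_key, n, s) +
    n_indel_sum * .INDEL_LOGPEN
}

.b_from_reads <- function(em, starts, ends, read_length) {
  if (!length(starts)) return("00")
  lo <- min(starts); hi <- max(ends)
  .B_STATES[1L + 2L * any(em & starts <= lo + read_length) +
              any(em & ends >= hi - read_length)]
}

# Full potential from option-like parts (list of cols/m/n_indel/em/start/end).
.potential_from_parts <- function(prior, logpi, parts, read_length) {
  if (length(parts) == 0L) return(log(1 - prior$p_exist))
  s <- ncol(logpi)
  LL <- matrix(0, 4L, s)
  depth <- integer(s)
  n_indel <- 0L
  for (p in parts) {
    LL[, p$cols] <- LL[, p$cols, drop = FALSE] + p$m
    depth[p$cols] <- depth[p$cols] + 1L
    n_indel <- n_indel + p$n_indel
  }
  cov <- which(depth > 0L)
  elim <- .lse4(LL[, cov, drop = FALSE] + logpi[, cov, drop = FALSE])
  starts <- vapply(parts, function(p) as.numeric(p$start), 0)
  ends <- vapply(parts, function(p) as.numeric(p$end), 0)
  em <- vapply(parts, function(p) isTRUE(p$em), TRUE)
  b <- .b_from_reads(em, starts, ends, read_length)
  span <- max(ends) - min(starts)
  .term_static(prior, length(parts), span, b, n_indel, read_length) + sum(elim)
}

#' Compute one molecule's log-potential by variable elimination
#'
#' The potential is `sum over M_c of P(M_c) P(R_c | M_c)` for the given
#' assigned read set: the hidden molecule sequence is eliminated
#' position-by-position (sum over ACGT weighted by the SNP-rate prior and
#' the per-base error model of every covering read), the read density is
#' integrated on the prior's lambda grid against the (size, density | marker
#' state) KDE together with a Poisson read-count term, read starts are
#' uniform on the molecule, and indel-containing alignments contribute a
#' fixed per-event penalty. An empty read set gives `log(1 - p_exist)`.
#'
#' @param contig_seq the molecule's reference sequence (character scalar).
#' @param reads data frame with `seq`, `qual` (Phred+33, reference-oriented),
#'   `offset` (0-based start on the contig), optional `n_indel` and
#'   `end_marker`.
#' @param prior a `well_prior`.
#' @param read_length read length (floors the molecule span).
#' @return scalar log-potential.
#' @export
compute_log_potential <- function(contig_seq, reads, prior, read_length = 100) {
  theta <- prior$theta
  ref <- encode_bases(contig_seq)
  s <- length(ref)
  logpi <- matrix(log(theta / 3), 4L, s)
  logpi[cbind(ref, seq_len(s))] <- log(1 - theta)
  if (is.null(reads) || nrow(reads) == 0L)
    return(log(1 - prior$p_exist))
  parts <- lapply(seq_len(nrow(reads)), function(i) {
    obs <- encode_bases(reads$seq[i])
    e <- 10^(-string_to_quals(reads$qual[i]) / 10)
    L <- length(obs)
    cols <- reads$offset[i] + seq_len(L)
    keep <- cols >= 1L & cols <= s
    if (!all(keep)) {
      warning("alignment extends outside the molecule; clipped",
              call. = FALSE)
      obs <- obs[keep]; e <- e[keep]; cols <- cols[keep]
    }
    m <- matrix(rep(log(e / 3), each = 4L), 4L)
    m[cbind(obs, seq_along(cols))] <- log1p(-e)
    list(cols = cols, m = m,
         n_indel = if (is.null(reads$n_indel)) 0L else reads$n_indel[i],
         em = if (is.null(reads$end_marker)) FALSE else reads$end_marker[i],
         start = min(cols) - 1L, end = max(cols))
  })
  .potential_from_parts(prior, logpi, parts, read_length)
}

#' Score a joint assignment by full recomputation
#'
#' Sums per-molecule log-potentials under the read sets the assignment
#' induces, computed from scratch (independent of the incremental engine).
#' The attribute `"objective"` additionally carries the unassigned-read
#' penalty `n_unassigned * log(p_offtarget)` that the optimizer maximises.
#'
#' @param graph an `mrf_graph`.
#' @param choice integer vector, one entry per read: option index in the
#'   read's domain, or 0 for unassigned.
#' @return total log score (sum of molecule potentials) with attribute
#'   `"objective"`.
#' @export
score_assignment <- function(graph, choice) {
  prior <- graph$prior
  total <- 0
  for (c in seq_along(graph$mol)) {
    parts <- list()
    for (n in graph$attach[[c]]) {
      j <- choice[n]
      if (j > 0L && graph$reads[[n]]$opts[[j]]$mol == c) {
        o <- graph$reads[[n]]$opts[[j]]
        parts[[length(parts) + 1L]] <-
          list(cols = o$cols, m = o$m, n_indel = o$n_indel,
               em = graph$reads[[n]]$end_marker, start = o$start, end = o$end)
      }
    }
    total <- total + .potential_from_parts(prior, graph$mol[[c]]$logpi, parts,
                                           graph$read_length)
  }
  off <- sum(vapply(which(choice == 0L),
                    function(n) graph$reads[[n]]$off_lp, 0))
  attr(total, "objective") <- total + off
  total
}

# ---- incremental engine -----------------------------------------------------

# Engine state: one environment per molecule plus global bookkeeping.
.engine_new <- function(graph) {
  eng <- new.env(parent = emptyenv())
  eng$graph <- graph
  eng$ms <- lapply(seq_along(graph$mol), function(c) {
    m <- new.env(parent = emptyenv())
    s <- graph$mol[[c]]$slen
    m$LL <- matrix(0, 4L, s)
    m$depth <- integer(s)
    m$elim <- numeric(s)
    m$sum_elim <- 0
    m$idx <- integer(0)      # assigned read indices
    m$optk <- integer(0)     # their option index
    m$starts <- integer(0)
    m$ends <- integer(0)
    m$em <- logical(0)
    m$n_indel <- 0L
    m$term <- log(1 - graph$prior$p_exist)
    m$version <- 0L
    m
  })
  eng$choice <- integer(length(graph$reads))
  eng$n_unassigned <- length(graph$reads)
  eng$objective <- sum(vapply(eng$ms, function(m) m$term, 0)) +
    sum(vapply(graph$reads, function(r) r$off_lp, 0))
  eng
}

# Scalar term from a molecule env's summary vectors (no elimination work).
.term_of <- function(eng, n, starts, ends, em, n_indel, sum_elim) {
  prior <- eng$graph$prior
  if (n == 0L) return(log(1 - prior$p_exist))
  b <- .b_from_reads(em, starts, ends, eng$graph$read_length)
  span <- max(ends) - min(starts)
  .term_static(prior, n, span, b, n_indel, eng$graph$read_length) + sum_elim
}

# Non-mutating: molecule c's term after adding read n via option o.
.term_plus <- function(eng, c, n, o) {
  m <- eng$ms[[c]]
  LLc <- m$LL[, o$cols, drop = FALSE]
  d <- sum(.lse4(LLc + o$mP)) - sum(m$elim[o$cols])
  rd <- eng$graph$reads[[n]]
  .term_of(eng, length(m$idx) + 1L, c(m$starts, o$start), c(m$ends, o$end),
           c(m$em, rd$end_marker), m$n_indel + o$n_indel, m$sum_elim + d)
}

# Non-mutating: molecule c's term after removing read n (currently assigned).
.term_minus <- function(eng, c, n) {
  m <- eng$ms[[c]]
  i <- match(n, m$idx)
  o <- eng$graph$reads[[n]]$opts[[m$optk[i]]]
  if (length(m$idx) == 1L) return(log(1 - eng$graph$prior$p_exist))
  LLc <- m$LL[, o$cols, drop = FALSE]
  d <- sum(.lse4(LLc - o$m + eng$graph$mol[[c]]$logpi[, o$cols, drop = FALSE])) -
    sum(m$elim[o$cols])
  .term_of(eng, length(m$idx) - 1L, m$starts[-i], m$ends[-i], m$em[-i],
           m$n_indel - o$n_indel, m$sum_elim + d)
}

.do_add <- function(eng, c, n, k) {
  m <- eng$ms[[c]]
  o <- eng$graph$reads[[n]]$opts[[k]]
  m$LL[, o$cols] <- m$LL[, o$cols, drop = FALSE] + o$m
  m$depth[o$cols] <- m$depth[o$cols] + 1L
  new_elim <- .lse4(m$LL[, o$cols, drop = FALSE] +
                    eng$graph$mol[[c]]$logpi[, o$cols, drop = FALSE])
  m$sum_elim <- m$sum_elim + sum(new_elim) - sum(m$elim[o$cols])
  m$elim[o$cols] <- new_elim
  m$idx <- c(m$idx, n)
  m$optk <- c(m$optk, k)
  m$starts <- c(m$starts, o$start)
  m$ends <- c(m$ends, o$end)
  m$em <- c(m$em, eng$graph$reads[[n]]$end_marker)
  m$n_indel <- m$n_indel + o$n_indel
  old <- m$term
  m$term <- .term_of(eng, length(m$idx), m$starts, m$ends, m$em, m$n_indel,
                     m$sum_elim)
  m$version <- m$version + 1L
  m$term - old
}

.do_remove <- function(eng, c, n) {
  m <- eng$ms[[c]]
  i <- match(n, m$idx)
  o <- eng$graph$reads[[n]]$opts[[m$optk[i]]]
  m$LL[, o$cols] <- m$LL[, o$cols, drop = FALSE] - o$m
  m$depth[o$cols] <- m$depth[o$cols] - 1L
  zero <- m$depth[o$cols] == 0L
  new_elim <- .lse4(m$LL[, o$cols, drop = FALSE] +
                    eng$graph$mol[[c]]$logpi[, o$cols, drop = FALSE])
  new_elim[zero] <- 0
  if (any(zero)) m$LL[, o$cols[zero]] <- 0   # clear float residue
  m$sum_elim <- m$sum_elim + sum(new_elim) - sum(m$elim[o$cols])
  m$elim[o$cols] <- new_elim
  m$idx <- m$idx[-i]
  m$optk <- m$optk[-i]
  m$starts <- m$starts[-i]
  m$ends <- m$ends[-i]
  m$em <- m$em[-i]
  m$n_indel <- m$n_indel - o$n_indel
  old <- m$term
  m$term <- .term_of(eng, length(m$idx), m$starts, m$ends, m$em, m$n_indel,
                     m$sum_elim)
  m$version <- m$version + 1L
  m$term - old
}

# Mutating move of read n to option j (0 = unassign). Returns the objective
# delta.
.apply_move <- function(eng, n, j) {
  cur <- eng$choice[n]
  if (cur == j) return(0)
  off_lp <- eng$graph$reads[[n]]$off_lp
  delta <- 0
  if (cur > 0L) {
    delta <- delta + .do_remove(eng, eng$graph$reads[[n]]$opts[[cur]]$mol, n)
  } else {
    eng$n_unassigned <- eng$n_unassigned - 1L
    delta <- delta - off_lp
  }
  if (j > 0L) {
    delta <- delta + .do_add(eng, eng$graph$reads[[n]]$opts[[j]]$mol, n, j)
  } else {
    eng$n_unassigned <- eng$n_unassigned + 1L
    delta <- delta + off_lp
  }
  eng$choice[n] <- j
  eng$objective <- eng$objective + delta
  delta
}

# Objective delta of moving read n to option j, without mutating the engine.
.eval_move <- function(eng, n, j) {
  cur <- eng$choice[n]
  if (cur == j) return(0)
  prior <- eng$graph$prior
  opts <- eng$graph$reads[[n]]$opts
  src <- if (cur > 0L) opts[[cur]]$mol else 0L
  dst <- if (j > 0L) opts[[j]]$mol else 0L
  if (src > 0L && src == dst) {          # same-molecule offset change: trial
    snap <- eng$ms[[src]]$version
    d <- .apply_move(eng, n, j)
    .apply_move(eng, n, cur)
    eng$ms[[src]]$version <- snap        # trial, not a state change
    return(d)
  }
  off_lp <- eng$graph$reads[[n]]$off_lp
  delta <- 0
  if (src > 0L) delta <- delta + .term_minus(eng, src, n) - eng$ms[[src]]$term
  else delta <- delta - off_lp
  if (dst > 0L) delta <- delta + .term_plus(eng, dst, n, opts[[j]]) -
      eng$ms[[dst]]$term
  else delta <- delta + off_lp
  delta
}

# Greedy initialisation: every read to its best-scoring option.
.engine_init_greedy <- function(eng) {
  for (n in seq_along(eng$graph$reads)) {
    rd <- eng$graph$reads[[n]]
    if (rd$K > 0L) {
      best <- which.max(vapply(rd$opts, function(o) o$score, 0))
      .apply_move(eng, n, best)
    }
  }
  invisible(eng)
}

# Deep copy of an engine (fresh state per restart without re-running the
# greedy initialisation).
.engine_clone <- function(eng) {
  e2 <- new.env(parent = emptyenv())
  e2$graph <- eng$graph
  e2$ms <- lapply(eng$ms, function(m) {
    m2 <- new.env(parent = emptyenv())
    m2$LL <- m$LL + 0
    m2$depth <- m$depth + 0L
    m2$elim <- m$elim + 0
    m2$sum_elim <- m$sum_elim
    m2$idx <- m$idx + 0L
    m2$optk <- m$optk + 0L
    m2$starts <- m$starts + 0L
    m2$ends <- m$ends + 0L
    m2$em <- m$em | FALSE
    m2$n_indel <- m$n_indel
    m2$term <- m$term
    m2$version <- m$version
    m2
  })
  e2$choice <- eng$choice + 0L
  e2$n_unassigned <- eng$n_unassigned
  e2$objective <- eng$objective
  e2
}

# Whole-cloud block move: try to relocate all reads of molecule c into
# another molecule that can accommodate every one of them.
.try_block_moves <- function(eng) {
  moved <- FALSE
  graph <- eng$graph
  if (is.null(eng$block_memo)) eng$block_memo <- new.env(parent = emptyenv())
  for (c in seq_along(eng$ms)) {
    m <- eng$ms[[c]]
    if (length(m$idx) == 0L) next
    members <- m$idx
    # whole-cloud dissolution: unassign every read of the molecule
    key0 <- paste0(c, ">off")
    if (!identical(eng$block_memo[[key0]], m$version)) {
      sig0 <- m$version
      old_opts <- eng$choice[members]
      delta <- 0
      for (n in members) delta <- delta + .apply_move(eng, n, 0L)
      if (delta > 1e-9) {
        moved <- TRUE
        next
      }
      for (i in seq_along(members)) .apply_move(eng, members[i], old_opts[i])
      m$version <- sig0
      eng$block_memo[[key0]] <- sig0
    }
    # relocation into another molecule: move every member that has an
    # option there (the movable subset)
    cand <- setdiff(unique(unlist(graph$opt_mols[members])), c)
    for (cp in cand) {
      movable <- members[vapply(graph$opt_mols[members],
                                function(v) cp %in% v, TRUE)]
      key <- paste0(c, ">", cp)
      sig <- c(m$version, eng$ms[[cp]]$version)
      if (identical(eng$block_memo[[key]], sig)) next  # unchanged, known bad
      snap_c <- m$version
      snap_cp <- eng$ms[[cp]]$version
      old_opts <- eng$choice[movable]
      delta <- 0
      for (n in movable) {
        ks <- which(vapply(graph$reads[[n]]$opts, function(o) o$mol, 0L) == cp)
        k <- ks[which.max(vapply(graph$reads[[n]]$opts[ks],
                                 function(o) o$score, 0))]
        delta <- delta + .apply_move(eng, n, k)
      }
      if (delta > 1e-9) {
        moved <- TRUE
        members <- m$idx
        if (length(members) == 0L) break  # molecule dissolved entirely
      } else {
        for (i in seq_along(movable))
          .apply_move(eng, movable[i], old_opts[i])
        m$version <- snap_c        # rejected trial, not a state change
        eng$ms[[cp]]$version <- snap_cp
        eng$block_memo[[key]] <- sig
      }
    }
  }
  moved
}

# Pair escape: when no single-read move improves, tentatively move one
# multi-option read and look for a compensating move among the reads of the
# two affected molecules. Accept the pair iff the combined delta improves.
.try_pair_moves <- function(eng, max_responders = 30L) {
  graph <- eng$graph
  for (n in seq_along(graph$reads)) {
    if (graph$reads[[n]]$K < 2L) next        # only genuinely ambiguous reads
    cur <- eng$choice[n]
    for (j in setdiff(0L:graph$reads[[n]]$K, cur)) {
      mols <- unique(c(
        if (cur > 0L) graph$reads[[n]]$opts[[cur]]$mol,
        if (j > 0L) graph$reads[[n]]$opts[[j]]$mol))
      snaps <- lapply(mols, function(c) eng$ms[[c]]$version)
      d1 <- .apply_move(eng, n, j)
      if (d1 > 1e-9) return(TRUE)      # plain improvement surfaced
      others <- setdiff(unique(c(unlist(lapply(mols, function(c)
        eng$ms[[c]]$idx)), unlist(graph$attach[mols]))), n)
      others <- others[vapply(others, function(m)
        graph$reads[[m]]$K, 0L) >= 2L]
      if (length(others) > max_responders)
        others <- others[seq_len(max_responders)]
      best_d2 <- 0; best_m <- 0L; best_k <- -1L
      for (m in others) {
        for (k in setdiff(0L:graph$reads[[m]]$K, eng$choice[m])) {
          d2 <- .eval_move(eng, m, k)
          if (d2 > best_d2) { best_d2 <- d2; best_m <- m; best_k <- k }
        }
      }
      if (d1 + best_d2 > 1e-9 && best_m > 0L) {
        .apply_move(eng, best_m, best_k)
        return(TRUE)
      }
      .apply_move(eng, n, cur)
      for (i in seq_along(mols)) eng$ms[[mols[i]]]$version <- snaps[[i]]
    }
  }
  FALSE
}

# Exact MAP by depth-first enumeration of the joint domain with incremental
# engine moves; only used when the joint state count is small.
.exact_map <- function(graph, eng) {
  nr <- length(graph$reads)
  best <- -Inf
  best_choice <- eng$choice
  saved <- eng$choice
  rec <- function(n) {
    if (n > nr) {
      if (eng$objective > best + 1e-12) {
        best <<- eng$objective
        best_choice <<- eng$choice + 0L
      }
      return(invisible())
    }
    for (j in 0L:graph$reads[[n]]$K) {
      .apply_move(eng, n, j)
      rec(n + 1L)
    }
    invisible()
  }
  rec(1L)
  for (n in seq_len(nr)) .apply_move(eng, n, best_choice[n])
  list(objective = best, choice = best_choice)
}

#' MAP inference over the well MRF
#'
#' When the joint assignment space is small (at most `exact_cap` states) the
#' MAP is found exactly by depth-first enumeration with incremental
#' rescoring. Beyond that: local search — greedy initialisation (each read
#' at its best aligner-score alignment), then iterated-conditional-modes
#' sweeps in random order over reads (single-read moves: change alignment or
#' unassign; accepted iff they increase the objective), interleaved each
#' sweep with whole-cloud block moves (relocation, dissolution) and, at
#' stalls, pair-escape moves. Terminates when a full sweep makes no move or
#' at the sweep cap. The best assignment over `restarts` randomised runs is
#' returned (the first run starts greedy, later runs are randomly
#' perturbed); on ties the earlier run is kept. Identical seed and input
#' give an identical assignment.
#'
#' @param graph an `mrf_graph`.
#' @param config list with `seed` (default 1), `restarts` (3), `sweeps`
#'   (100), `exact_cap` (4096).
#' @return an `rfa_assignment` list: `choice` (0 = unassigned), `score`
#'   (sum of molecule log-potentials), `objective` (score plus the
#'   unassigned penalty), `converged`, `sweeps_used`, and `engine` (the
#'   incremental engine at the returned state, for downstream queries).
#' @export
map_inference <- function(graph, config = list()) {
  seed <- config$seed %||% 1L
  restarts <- config$restarts %||% 3L
  sweeps <- config$sweeps %||% 100L
  exact_cap <- config$exact_cap %||% 4096
  n_states <- prod(vapply(graph$reads, function(r) r$K + 1, 0))
  if (length(graph$reads) > 0L && n_states <= exact_cap) {
    eng <- .engine_new(graph)
    ex <- .exact_map(graph, eng)
    return(structure(list(choice = ex$choice,
                          score = sum(vapply(eng$ms, function(m) m$term, 0)),
                          objective = eng$objective, converged = TRUE,
                          sweeps_used = 0L, exact = TRUE, engine = eng),
                     class = "rfa_assignment"))
  }
  best <- NULL
  eng0 <- .engine_new(graph)
  .engine_init_greedy(eng0)
  for (r in seq_len(restarts)) {
    set.seed(seed * 1000L + r)
    eng <- if (r == restarts) eng0 else .engine_clone(eng0)
    if (r > 1L) {
      # diversify later restarts: re-draw a random subset of reads to a
      # random option before the sweeps
      kick <- which(vapply(graph$reads, function(x) x$K, 0L) > 0L)
      kick <- kick[stats::runif(length(kick)) < 0.3]
      for (n in kick)
        .apply_move(eng, n, sample.int(graph$reads[[n]]$K, 1L))
    }
    last_sig <- rep(-1, length(graph$reads))
    converged <- FALSE
    sw <- 0L
    while (sw < sweeps) {
      sw <- sw + 1L
      moved <- FALSE
      for (n in sample.int(length(graph$reads))) {
        rd <- graph$reads[[n]]
        if (rd$K == 0L) next
        sig <- sum(vapply(eng$ms[graph$opt_mols[[n]]],
                          function(m) m$version, 0L))
        if (sig == last_sig[n]) next
        cur <- eng$choice[n]
        alts <- setdiff(0L:rd$K, cur)
        deltas <- vapply(alts, function(j) .eval_move(eng, n, j), 0)
        bi <- which.max(deltas)
        if (deltas[bi] > 1e-9) {
          .apply_move(eng, n, alts[bi])
          moved <- TRUE
        }
        last_sig[n] <- sum(vapply(eng$ms[graph$opt_mols[[n]]],
                                  function(m) m$version, 0L))
      }
      if (.try_block_moves(eng)) moved <- TRUE
      if (!moved && .try_pair_moves(eng)) moved <- TRUE
      if (!moved) { converged <- TRUE; break }
    }
    if (is.null(best) || eng$objective > best$objective + 1e-9) {
      best <- list(choice = eng$choice,
                   score = sum(vapply(eng$ms, function(m) m$term, 0)),
                   objective = eng$objective, converged = converged,
                   sweeps_used = sw, engine = eng)
    }
  }
  if (!best$converged)
    message("map_inference: sweep cap reached before convergence")
  structure(best, class = "rfa_assignment")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
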