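# Post-MAP confidence queries: per-read posteriors and MAPQ, per-cloud
# quality, molecule existence posteriors, and the end-marker collision
# filter.

# Engine for a MAP result (reuse the one map_inference kept, else rebuild).
.engine_at <- function(graph, map) {
  if (!is.null(map$engine)) return(map$engine)
  eng <- .engine_new(graph)
  for (n in seq_along(map$choice))
    if (map$choice[n] > 0L) .apply_move(eng, n, map$choice[n])
  map$engine <- eng
  eng
}

# Reads whose candidate alignments share at least one covered reference
# position with any candidate alignment of read n.
.local_reads <- function(graph, n) {
  opts_n <- graph$reads[[n]]$opts
  out <- integer(0)
  for (c in unique(vapply(opts_n, function(o) o$mol, 0L))) {
    rng_n <- range(unlist(lapply(opts_n[vapply(opts_n, function(o) o$mol, 0L) == c],
                                 function(o) c(o$start, o$end))))
    for (m in graph$attach[[c]]) {
      if (m == n) next
      for (o in graph$reads[[m]]$opts) {
        if (o$mol == c && o$start < rng_n[2] && o$end > rng_n[1]) {
          out <- c(out, m)
          break
        }
      }
    }
  }
  unique(out)
}

#' Posterior confidence of one read's MAP alignment
#'
#' Computes `P(R_n | R_{l-} = r^MAP_{l-})`: reads outside the local
#' neighbourhood are fixed at the MAP assignment. If the local read set is
#' small (at most `cap_local` reads and at most `joint_cap` joint states)
#' the neighbourhood is marginalised jointly with read n over all domains
#' (hidden molecule sequence eliminated inside each potential); otherwise
#' neighbours too are fixed at MAP and only read n is marginalised. The
#' posterior is the normalised mass of the read's MAP option; its MAPQ is
#' `round(-10 log10(1 - posterior))` capped at 60.
#'
#' @param graph an `mrf_graph`.
#' @param map an `rfa_assignment`.
#' @param n read index.
#' @param cap_local joint-marginalisation cap on the local read count.
#' @param joint_cap cap on the number of enumerated joint states.
#' @return list with `read_id`, `posterior`, `mapq`, `joint` (whether the
#'   joint path was used).
#' @export
read_posterior <- function(graph, map, n, cap_local = 12, joint_cap = 256) {
  eng <- .engine_at(graph, map)
  rd <- graph$reads[[n]]
  if (rd$high_copy || rd$K == 0L)
    return(list(read_id = rd$read_id, posterior = 0, mapq = 0L, joint = FALSE))
  cur <- eng$choice[n]
  # options lifting to the same genome placement (overlapping padded
  # contigs) are one hypothesis: posterior mass is pooled over the group
  grp <- c("unassigned", .option_groups(graph, n))
  if (length(unique(grp[-1L])) < 2L) {   # unique placement: vs unassigned only
    deltas <- vapply(0L:rd$K, function(j) .eval_move(eng, n, j), 0)
    w <- exp(deltas - max(deltas))
    post <- sum(w[grp == grp[cur + 1L]]) / sum(w)
    return(list(read_id = rd$read_id, posterior = post,
                mapq = posterior_to_mapq(post), joint = FALSE))
  }
  loc <- .local_reads(graph, n)
  loc <- loc[vapply(loc, function(m) graph$reads[[m]]$K > 0L, TRUE)]
  n_states <- prod(vapply(loc, function(m) graph$reads[[m]]$K + 1L, 0)) *
    (rd$K + 1L)
  use_joint <- length(loc) + 1L <= cap_local && n_states <= joint_cap
  if (!use_joint) {
    deltas <- vapply(0L:rd$K, function(j) .eval_move(eng, n, j), 0)
    w <- exp(deltas - max(deltas))
    post <- sum(w[grp == grp[cur + 1L]]) / sum(w)
    return(list(read_id = rd$read_id, posterior = post,
                mapq = posterior_to_mapq(post), joint = FALSE))
  }
  # depth-first enumeration over joint states of {n, local reads} with
  # incremental apply/revert; weights accumulated per option of read n
  members <- c(n, loc)
  saved <- eng$choice[members]
  wsum <- numeric(rd$K + 1L)
  acc <- 0
  rec <- function(i) {
    if (i > length(members)) {
      wsum[eng$choice[n] + 1L] <<- wsum[eng$choice[n] + 1L] + exp(acc)
      return(invisible())
    }
    m <- members[i]
    old <- eng$choice[m]
    for (j in 0L:graph$reads[[m]]$K) {
      d <- .apply_move(eng, m, j)
      acc <<- acc + d
      rec(i + 1L)
      acc <<- acc - d
      .apply_move(eng, m, old)
    }
    invisible()
  }
  rec(1L)
  for (i in seq_along(members))    # restore exactly
    .apply_move(eng, members[i], saved[i])
  post <- sum(wsum[grp == grp[saved[1L] + 1L]]) / sum(wsum)
  list(read_id = rd$read_id, posterior = post,
       mapq = posterior_to_mapq(post), joint = TRUE)
}

# Genome-placement group key of each option of read n: options of distinct
# molecules that lift to the same (chrom, position, strand) describe the
# same placement hypothesis.
.option_groups <- function(graph, n) {
  vapply(graph$reads[[n]]$opts, function(o) {
    m <- graph$mol[[o$mol]]
    paste0(m$chrom, ":", m$gstart + o$offset, ":", o$strand)
  }, "")
}

# Number of distinct genome placements in a read's domain.
.n_distinct_placements <- function(graph, n) {
  length(unique(.option_groups(graph, n)))
}

#' Cloud quality: log P(R_c) at the MAP assignment
#'
#' Identical computation to the molecule potential at the MAP read set; in
#' log space the value decreases with every variant the assignment implies
#' in the long fragment.
#' @param graph an `mrf_graph`.
#' @param map an `rfa_assignment`.
#' @param c molecule index.
#' @return scalar log-quality.
#' @export
cloud_quality <- function(graph, map, c) {
  eng <- .engine_at(graph, map)
  eng$ms[[c]]$term
}

#' Existence posterior of a molecule
#'
#' Enumerates whole-cloud alternative placements: every inactive candidate
#' molecule that can accommodate all of molecule `c`'s assigned reads
#' receives the full read set (each read at its best-scoring option there),
#' the placement's potential delta is recorded, and the masses are
#' softmax-renormalised. The returned value is the mass of the MAP
#' placement; with no alternatives it is exactly 1.
#'
#' @param graph an `mrf_graph`.
#' @param map an `rfa_assignment`.
#' @param c molecule index.
#' @return posterior probability that the molecule is where MAP placed it.
#' @export
existence_posterior <- function(graph, map, c) {
  eng <- .engine_at(graph, map)
  m <- eng$ms[[c]]
  if (length(m$idx) == 0L) return(1)
  members <- m$idx
  cand <- setdiff(Reduce(intersect, graph$opt_mols[members]), c)
  cand <- cand[vapply(cand, function(cp) length(eng$ms[[cp]]$idx) == 0L, TRUE)]
  # a candidate whose genome interval overlaps this molecule's is the same
  # placement hypothesis (padded/split contig duplicates), not an alternative
  mc <- graph$mol[[c]]
  cand <- cand[vapply(cand, function(cp) {
    mp <- graph$mol[[cp]]
    mp$chrom != mc$chrom || mp$gstart + mp$slen <= mc$gstart ||
      mp$gstart >= mc$gstart + mc$slen
  }, TRUE)]
  if (length(cand) == 0L) return(1)
  deltas <- vapply(cand, function(cp) {
    old <- eng$choice[members]
    snap_c <- eng$ms[[c]]$version
    snap_cp <- eng$ms[[cp]]$version
    d <- 0
    for (n in members) {
      ks <- which(vapply(graph$reads[[n]]$opts, function(o) o$mol, 0L) == cp)
      k <- ks[which.max(vapply(graph$reads[[n]]$opts[ks],
                               function(o) o$score, 0))]
      d <- d + .apply_move(eng, n, k)
    }
    for (i in seq_along(members)) .apply_move(eng, members[i], old[i])
    eng$ms[[c]]$version <- snap_c
    eng$ms[[cp]]$version <- snap_cp
    d
  }, 0)
  1 / (1 + sum(exp(pmin(deltas, 50))))
}

#' Detect end-marker collisions among candidate clouds
#'
#' Two long fragments of one well that overlap in genome coordinates merge
#' into a single candidate cloud; the adapter-derived end-markers reveal
#' most such collisions. A cloud is flagged when it shows more than two
#' distinct marker positions (one fragment has only two ends) or an interior
#' marker that the cloud-splitting rule could not act on; all its reads are
#' excluded from variant-ready output. With marker efficiency `p` and
#' independent markers, the at-least-one-marker detection probability is
#' `1 - (1 - p)^2` — 0.947 for `p = 0.77`, the ~95% figure (the literal
#' expression `1 - p^2` evaluates to 0.41 and is reported alongside for
#' transparency).
#'
#' @param clouds data frame from [cluster_pass1()] (post-splitting).
#' @param alignments pass-1 alignment data frame.
#' @param marker_eff end-marker efficiency `p`.
#' @param read_length read length in bp.
#' @return list with `flagged` (cloud ids), `excluded_reads` (read ids),
#'   `detection_rate` (analytic, `1 - (1-p)^2`) and `naive_rate`
#'   (`1 - p^2`).
#' @export
detect_collisions <- function(clouds, alignments, marker_eff = 0.77,
                              read_length = 100) {
  flagged <- integer(0)
  excluded <- character(0)
  # map each alignment row to its cloud once (members lists can be large)
  cloud_of <- rep(seq_len(nrow(clouds)),
                  vapply(clouds$members, length, 0L))
  row_of <- match(unlist(clouds$members), alignments$read_id)
  by_cloud <- split(row_of, cloud_of)
  for (i in seq_len(nrow(clouds))) {
    idx <- by_cloud[[as.character(i)]]
    if (is.null(idx)) next
    mem <- alignments[idx, , drop = FALSE]
    marks <- mem[mem$end_marker, , drop = FALSE]
    if (nrow(marks) == 0L) next
    distinct <- unique(marks$start)
    interior <- marks$start - clouds$start[i] > read_length &
      clouds$end[i] - (marks$start + read_length) > read_length
    if (length(distinct) > 2L || any(interior)) {
      flagged <- c(flagged, clouds$cloud_id[i])
      excluded <- c(excluded, mem$read_id)
    }
  }
  det <- 1 - (1 - marker_eff)^2
  message(sprintf(
    "collision detection: %d cloud(s) flagged; analytic detection %.1f%% (at-least-one-marker); literal 1-p^2 would give %.1f%%",
    length(flagged), 100 * det, 100 * (1 - marker_eff^2)))
  list(flagged = flagged, excluded_reads = unique(excluded),
       detection_rate = det, naive_rate = 1 - marker_eff^2)
}

#' Flag clouds with unusually low quality against a shuffled-read null
#'
#' Each assigned read's bases are shuffled within coarse base-quality strata
#' (destroying reference agreement while preserving composition and
#' qualities) and the cloud is re-scored; clouds whose observed quality
#' falls below the `q` quantile of the pooled per-well null are flagged.
#' @param graph an `mrf_graph`.
#' @param map an `rfa_assignment`.
#' @param n_null shuffled replicates per cloud.
#' @param q lower quantile of the pooled null used as cutoff.
#' @param seed RNG seed.
#' @return logical vector over molecules (`TRUE` = low quality).
#' @export
flag_low_quality_clouds <- function(graph, map, n_null = 5, q = 0.01,
                                    seed = 1) {
  set.seed(seed)
  eng <- .engine_at(graph, map)
  active <- which(vapply(eng$ms, function(m) length(m$idx) > 0L, TRUE))
  nulls <- numeric(0)
  obs <- numeric(length(graph$mol))
  for (c in active) {
    m <- eng$ms[[c]]
    obs[c] <- m$term
    parts0 <- lapply(seq_along(m$idx), function(i) {
      o <- graph$reads[[m$idx[i]]]$opts[[m$optk[i]]]
      list(cols = o$cols, m = o$m, n_indel = o$n_indel,
           em = graph$reads[[m$idx[i]]]$end_marker,
           start = o$start, end = o$end)
    })
    for (r in seq_len(n_null)) {
      parts <- lapply(parts0, function(p) {
        mm <- p$m
        # stratify columns by the (rounded) error level encoded in mm and
        # permute observed-base columns within strata
        lte <- pmax(mm[1L, ], mm[2L, ], mm[3L, ], mm[4L, ])
        strat <- round(lte * 200)
        for (sgrp in split(seq_along(strat), strat)) {
          if (length(sgrp) > 1L) mm[, sgrp] <- mm[, sample(sgrp)]
        }
        p$m <- mm
        p
      })
      nulls <- c(nulls, .potential_from_parts(graph$prior,
                                              graph$mol[[c]]$logpi, parts,
                                              graph$read_length))
    }
  }
  cutoff <- if (length(nulls)) stats::quantile(nulls, q) else -Inf
  out <- logical(length(graph$mol))
  out[active] <- obs[active] < cutoff
  out
}
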