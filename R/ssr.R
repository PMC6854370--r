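# Microsatellite (SSR) detection: perfect tandem repeats of 1-6 nt units
# with MISA-style minimum repeat counts, compound merging of nearby runs,
# and flagging of target sites whose flanks contain an SSR. Slippage at
# such loci produces indel signal indistinguishable from editing, so the
# flag feeds the background filter of the classification stage.

#' Microsatellite detection thresholds
#'
#' Defaults follow the canonical MISA settings: minimum repeat counts of
#' 10/6/5/5/5/5 for unit lengths 1-6 and a 100-base maximum interruption
#' between members of a compound. `min_adjacent_units` governs "extension
#' mode": a tandem run of a different unit repeated at least this often
#' and immediately adjacent (zero gap) to a qualifying SSR is absorbed
#' into the compound record, which is how sub-threshold members such as
#' the (GA)2 of "(CA)8(GA)2" get represented.
#'
#' @param min_repeats named integer vector, unit length -> minimum repeat
#'   count.
#' @param max_interruption maximum bases between compound members.
#' @param min_adjacent_units minimum repeats for an adjacent sub-threshold
#'   run to be absorbed (extension mode).
#' @return object of class `ssr_thresholds`.
#' @export
ssr_thresholds <- function(min_repeats = c("1" = 10L, "2" = 6L, "3" = 5L,
                                           "4" = 5L, "5" = 5L, "6" = 5L),
                           max_interruption = 100L,
                           min_adjacent_units = 2L) {
  if (any(min_repeats < 1L) || max_interruption < 1L ||
      min_adjacent_units < 1L) {
    stop("all thresholds must be >= 1", call. = FALSE)
  }
  structure(list(min_repeats = min_repeats,
                 max_interruption = as.integer(max_interruption),
                 min_adjacent_units = as.integer(min_adjacent_units)),
            class = "ssr_thresholds")
}

#' Expand a motif composition string
#'
#' Compositions are sequences of `(MOTIF)count` blocks with optional
#' literal bases between, before or after them, e.g. `"(CA)8(GA)2"`,
#' `"A(CA)7GA"`, `"(A)10"`.
#'
#' @param composition composition string.
#' @return the literal expanded sequence.
#' @export
expand_composition <- function(composition) {
  x <- composition
  out <- ""
  while (nchar(x) > 0L) {
    m <- regmatches(x, regexec("^\\(([ACGTacgt]+)\\)([0-9]+)", x))[[1]]
    if (length(m) == 3L) {
      out <- paste0(out, strrep(toupper(m[2]), as.integer(m[3])))
      x <- substr(x, nchar(m[1]) + 1L, nchar(x))
    } else if (grepl("^[ACGTacgt]", x)) {
      out <- paste0(out, toupper(substr(x, 1L, 1L)))
      x <- substr(x, 2L, nchar(x))
    } else {
      stop("malformed composition string: '", composition, "'",
           call. = FALSE)
    }
  }
  if (nchar(out) == 0L) {
    stop("malformed composition string: '", composition, "'", call. = FALSE)
  }
  out
}

# Is `unit` itself periodic (e.g. "CACA", "AA")? Such strings are not
# primitive repeat units.
.unit_periodic <- function(unit) {
  u <- nchar(unit)
  if (u == 1L) return(FALSE)
  for (d in seq_len(u - 1L)) {
    if (u %% d == 0L && unit == strrep(substr(unit, 1L, d), u %/% d)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Find perfect microsatellites
#'
#' Reports all maximal tandem runs of a primitive 1-6 nt unit whose repeat
#' count meets the per-unit-length threshold. Runs are reported leftmost
#' and trimmed to whole units; where threshold-passing runs of different
#' unit lengths overlap, the longer run wins (ties broken leftmost), so no
#' two reported SSRs overlap.
#'
#' @param seq DNA sequence.
#' @param t an [ssr_thresholds()].
#' @return data.frame of SSRs: start, end (0-based half-open), unit,
#'   unit_len, n_repeats, composition (e.g. "(CA)8"), kind ("perfect").
#' @export
find_perfect_ssrs <- function(seq, t = ssr_thresholds()) {
  seq <- toupper(as.character(seq[1]))
  L <- nchar(seq)
  ch <- .chars(seq)
  runs <- list()
  for (u in 1:6) {
    min_rep <- t$min_repeats[[as.character(u)]]
    if (L < u * min_rep) next
    eq <- ch[seq_len(L - u)] == ch[seq_len(L - u) + u]
    # maximal stretches of TRUE in eq: positions i..j with s[i]==s[i+u]
    r <- rle(eq)
    pos <- 1L
    for (ri in seq_along(r$lengths)) {
      len <- r$lengths[ri]
      if (r$values[ri]) {
        span_start <- pos               # 1-based
        span_len <- len + u             # periodic region length
        n_rep <- span_len %/% u
        if (n_rep >= min_rep) {
          unit <- substr(seq, span_start, span_start + u - 1L)
          if (!.unit_periodic(unit)) {
            runs[[length(runs) + 1L]] <- data.frame(
              start = span_start - 1L,          # 0-based
              end = span_start - 1L + n_rep * u,
              unit = unit, unit_len = u, n_repeats = n_rep,
              stringsAsFactors = FALSE)
          }
        }
      }
      pos <- pos + len
    }
  }
  if (length(runs) == 0L) {
    return(data.frame(start = integer(), end = integer(), unit = character(),
                      unit_len = integer(), n_repeats = integer(),
                      composition = character(), kind = character(),
                      stringsAsFactors = FALSE))
  }
  runs <- do.call(rbind, runs)
  # overlap resolution: longer run wins, ties broken leftmost
  runs <- runs[order(-(runs$end - runs$start), runs$start), , drop = FALSE]
  keep <- logical(nrow(runs))
  occ_start <- integer(0); occ_end <- integer(0)
  for (i in seq_len(nrow(runs))) {
    if (!any(occ_start < runs$end[i] & runs$start[i] < occ_end)) {
      keep[i] <- TRUE
      occ_start <- c(occ_start, runs$start[i])
      occ_end <- c(occ_end, runs$end[i])
    }
  }
  runs <- runs[keep, , drop = FALSE]
  runs <- runs[order(runs$start), , drop = FALSE]
  runs$composition <- sprintf("(%s)%d", runs$unit, runs$n_repeats)
  runs$kind <- "perfect"
  rownames(runs) <- NULL
  runs
}

# Find the best sub-threshold tandem run starting exactly at 0-based
# position `pos` (direction = +1) or ending exactly at `pos` (direction
# = -1); returns NULL or list(unit, n, start, end).
.adjacent_run <- function(seq, pos, direction, min_units, exclude_unit) {
  L <- nchar(seq)
  best <- NULL
  for (u in 2:6) {   # mononucleotide doublets are noise, not motif members
    if (direction > 0) {
      if (pos + u > L) break
      unit <- substr(seq, pos + 1L, pos + u)
      if (.unit_periodic(unit)) next
      n <- 1L
      while (pos + (n + 1L) * u <= L &&
             substr(seq, pos + n * u + 1L, pos + (n + 1L) * u) == unit) {
        n <- n + 1L
      }
      run <- list(unit = unit, n = n, start = pos, end = pos + n * u)
    } else {
      if (pos - u < 0L) break
      unit <- substr(seq, pos - u + 1L, pos)
      if (.unit_periodic(unit)) next
      n <- 1L
      while (pos - (n + 1L) * u >= 0L &&
             substr(seq, pos - (n + 1L) * u + 1L, pos - n * u) == unit) {
        n <- n + 1L
      }
      run <- list(unit = run_unit_leftmost(seq, pos, u, n), n = n,
                  start = pos - n * u, end = pos)
    }
    if (run$n >= min_units && run$unit != exclude_unit &&
        (is.null(best) || run$n * nchar(run$unit) >
           best$n * nchar(best$unit))) {
      best <- run
    }
  }
  best
}

# For a leftward extension ending at `pos`, re-read the unit from the
# run's left edge so the composition expands to the genomic substring.
run_unit_leftmost <- function(seq, pos, u, n) {
  substr(seq, pos - n * u + 1L, pos - n * u + u)
}

#' Merge perfect SSRs into compound microsatellites
#'
#' Two qualifying SSRs within `t$max_interruption` bases merge into one
#' compound record whose composition interleaves the motif blocks with
#' the literal interruption bases. With extension mode on (the default), a
#' tandem run of a different unit repeated at least
#' `t$min_adjacent_units` times and immediately adjacent to a qualifying
#' SSR is absorbed as well, so "(CA)8(GA)2"-type motifs are represented
#' even though (GA)2 alone is below threshold.
#'
#' @param ssrs output of [find_perfect_ssrs()] on the same `seq`.
#' @param seq the sequence the SSRs were found in.
#' @param t an [ssr_thresholds()].
#' @param extend absorb adjacent sub-threshold runs (extension mode).
#' @return data.frame like [find_perfect_ssrs()], with compound rows
#'   where merging applied (`kind == "compound"`); re-expanding each
#'   composition reproduces the genomic substring exactly.
#' @export
merge_compound <- function(ssrs, seq, t = ssr_thresholds(), extend = TRUE) {
  seq <- toupper(as.character(seq[1]))
  if (nrow(ssrs) == 0L) return(ssrs)
  recs <- lapply(seq_len(nrow(ssrs)), function(i) {
    list(start = ssrs$start[i], end = ssrs$end[i],
         blocks = list(list(unit = ssrs$unit[i], n = ssrs$n_repeats[i])),
         compound = FALSE)
  })
  if (extend) {
    # one absorbed run per side: enough to represent "(CA)8(GA)2"-type
    # motifs without chaining through incidental doublets in random flanks
    recs <- lapply(recs, function(r) {
      right <- .adjacent_run(seq, r$end, +1L, t$min_adjacent_units,
                             exclude_unit = r$blocks[[length(r$blocks)]]$unit)
      if (!is.null(right)) {
        r$blocks[[length(r$blocks) + 1L]] <- list(unit = right$unit,
                                                  n = right$n)
        r$end <- right$end
        r$compound <- TRUE
      }
      left <- .adjacent_run(seq, r$start, -1L, t$min_adjacent_units,
                            exclude_unit = r$blocks[[1L]]$unit)
      if (!is.null(left)) {
        r$blocks <- c(list(list(unit = left$unit, n = left$n)), r$blocks)
        r$start <- left$start
        r$compound <- TRUE
      }
      r
    })
    # extension may have made neighbours touch or overlap; drop any record
    # fully contained in another (longer wins)
    ord <- order(vapply(recs, function(r) r$start - r$end, integer(1)),
                 vapply(recs, function(r) r$start, integer(1)))
    kept <- list()
    for (r in recs[ord]) {
      contained <- any(vapply(kept, function(kx)
        kx$start <= r$start && r$end <= kx$end, logical(1)))
      if (!contained) kept[[length(kept) + 1L]] <- r
    }
    recs <- kept[order(vapply(kept, function(r) r$start, integer(1)))]
  }
  # distance-based merging of consecutive records
  merged <- list(recs[[1L]])
  if (length(recs) > 1L) {
    for (r in recs[-1L]) {
      lastr <- merged[[length(merged)]]
      gap <- r$start - lastr$end
      if (gap <= t$max_interruption) {
        if (gap > 0L) {
          lastr$blocks[[length(lastr$blocks) + 1L]] <-
            list(literal = substr(seq, lastr$end + 1L, r$start))
        }
        lastr$blocks <- c(lastr$blocks, r$blocks)
        lastr$end <- r$end
        lastr$compound <- TRUE
        merged[[length(merged)]] <- lastr
      } else {
        merged[[length(merged) + 1L]] <- r
      }
    }
  }
  comp_str <- function(blocks) {
    paste(vapply(blocks, function(b) {
      if (!is.null(b$literal)) b$literal else sprintf("(%s)%d", b$unit, b$n)
    }, character(1)), collapse = "")
  }
  out <- data.frame(
    start = vapply(merged, function(r) r$start, integer(1)),
    end = vapply(merged, function(r) r$end, integer(1)),
    unit = vapply(merged, function(r) r$blocks[[1L]]$unit, character(1)),
    unit_len = vapply(merged, function(r) nchar(r$blocks[[1L]]$unit),
                      integer(1)),
    n_repeats = vapply(merged, function(r) r$blocks[[1L]]$n, integer(1)),
    composition = vapply(merged, function(r) comp_str(r$blocks),
                         character(1)),
    kind = ifelse(vapply(merged, function(r) r$compound, logical(1)),
                  "compound", "perfect"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Scan a sequence for perfect and compound microsatellites
#'
#' Convenience wrapper: [find_perfect_ssrs()] followed by
#' [merge_compound()].
#'
#' @inheritParams merge_compound
#' @param seq DNA sequence.
#' @return SSR table (see [merge_compound()]).
#' @export
scan_ssrs <- function(seq, t = ssr_thresholds(), extend = TRUE) {
  merge_compound(find_perfect_ssrs(seq, t), seq, t, extend = extend)
}

#' Flag target sites whose flanks contain a microsatellite
#'
#' For each site the window `[start - flank, end + flank)` (clamped to the
#' contig) is scanned; `ssr_flag` is set when any perfect or compound SSR
#' overlaps the window. The per-guide flagged proportion is attached as
#' attribute `"ssr_proportion"`.
#'
#' @param sites site table from [find_offtargets()].
#' @param genome named character vector of contigs.
#' @param flank flank size in bases (default 100, giving ~200 bp windows).
#' @param t an [ssr_thresholds()].
#' @param extend extension mode for [merge_compound()].
#' @return `sites` with `ssr_flag` filled in.
#' @export
flag_sites <- function(sites, genome, flank = 100L, t = ssr_thresholds(),
                       extend = TRUE) {
  if (flank < 0L) stop("flank must be >= 0", call. = FALSE)
  margin <- 100L   # catch repeats straddling the window edge
  flags <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    contig <- sites$contig[i]
    if (!contig %in% names(genome)) {
      stop("site on missing contig: ", contig, call. = FALSE)
    }
    L <- nchar(genome[[contig]])
    w1 <- sites$start[i] - flank
    w2 <- sites$end[i] + flank
    if (w1 < 0L || w2 > L) {
      warning("flanked window for site ", i, " clamped to contig bounds")
      w1 <- max(0L, w1); w2 <- min(L, w2)
    }
    s1 <- max(0L, w1 - margin); s2 <- min(L, w2 + margin)
    sub <- substr(genome[[contig]], s1 + 1L, s2)
    ssrs <- scan_ssrs(sub, t, extend = extend)
    if (nrow(ssrs) > 0L) {
      abs_start <- ssrs$start + s1
      abs_end <- ssrs$end + s1
      flags[i] <- any(abs_start < w2 & w1 < abs_end)
    }
  }
  sites$ssr_flag <- flags
  prop <- stats::aggregate(list(n_flagged = flags),
                           by = list(guide_id = sites$guide_id), FUN = sum)
  tot <- as.data.frame(table(guide_id = sites$guide_id),
                       stringsAsFactors = FALSE)
  names(tot)[2] <- "n_total"
  prop <- merge(prop, tot, by = "guide_id")
  prop$proportion <- prop$n_flagged / prop$n_total
  attr(sites, "ssr_proportion") <- prop
  sites
}
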