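# Amplicon-sequencing indel quantification: read QC, semi-global pairwise
# alignment of reads against reference amplicons (both orientations,
# affine gaps), indel calling restricted to a window around the cut site,
# and per-site editing efficiency. Substitutions never count as edits, so
# sequencing errors do not inflate efficiency; indels are left-aligned
# within repeat context before window testing so placement at
# microsatellites is deterministic.

ALN_MATCH <- 2; ALN_MISMATCH <- -3; ALN_GAP_OPEN <- 8; ALN_GAP_EXT <- 1

#' Reference amplicon descriptor
#'
#' @param id amplicon/site id.
#' @param sequence amplicon sequence.
#' @param guide_id id of the guide cutting this amplicon.
#' @param cut_pos 0-based cut-site offset within the amplicon.
#' @param quant_window half-width (bases) of the indel-counting window
#'   around `cut_pos`.
#' @param genome_start 0-based genomic offset of the amplicon's first base
#'   (bookkeeping for extracted regions).
#' @return object of class `amplicon_ref`.
#' @export
amplicon_ref <- function(id, sequence, guide_id = NA_character_,
                         cut_pos, quant_window = 10L, genome_start = NA_integer_) {
  sequence <- toupper(sequence)
  if (cut_pos < 0 || cut_pos >= nchar(sequence)) {
    stop("cut_pos must lie within the amplicon", call. = FALSE)
  }
  structure(list(id = id, sequence = sequence, guide_id = guide_id,
                 cut_pos = as.integer(cut_pos),
                 quant_window = as.integer(quant_window),
                 genome_start = genome_start),
            class = "amplicon_ref")
}

#' Quality-filter and adapter-trim reads
#'
#' Adapter handling is exact-prefix matching at the read 3' end with at
#' least 8 bases of overlap. Reads containing N are discarded, as are
#' reads shorter than `min_len` after trimming. Order is preserved.
#'
#' @param reads reads table (`read_id`, `seq`, `qual`).
#' @param min_len minimum post-trim length (default 35).
#' @param adapters character vector of adapter sequences.
#' @return filtered reads table.
#' @export
qc_filter <- function(reads, min_len = 35L, adapters = character()) {
  if (min_len < 1L) stop("min_len must be >= 1", call. = FALSE)
  if (!all(c("read_id", "seq", "qual") %in% names(reads))) {
    stop("reads must have read_id/seq/qual columns", call. = FALSE)
  }
  bad <- which(nchar(reads$seq) != nchar(reads$qual))
  if (length(bad) > 0L) {
    stop("malformed read record at index ", bad[1L], call. = FALSE)
  }
  seqs <- toupper(reads$seq); quals <- reads$qual
  for (ad in toupper(adapters)) {
    for (i in seq_along(seqs)) {
      L <- nchar(seqs[i])
      max_o <- min(nchar(ad), L)
      if (max_o < 8L) next
      for (o in max_o:8L) {
        if (substr(seqs[i], L - o + 1L, L) == substr(ad, 1L, o)) {
          seqs[i] <- substr(seqs[i], 1L, L - o)
          quals[i] <- substr(quals[i], 1L, L - o)
          break
        }
      }
    }
  }
  keep <- !grepl("N", seqs, fixed = TRUE) & nchar(seqs) >= min_len
  out <- data.frame(read_id = reads$read_id[keep], seq = seqs[keep],
                    qual = quals[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.no_indels <- function() {
  data.frame(size = integer(), ref_start = integer(),
             ins_seq = character(), stringsAsFactors = FALSE)
}

# Convert pairwiseAlignment indel ranges (alignment-column coordinates,
# relative to the aligned region) into reference-coordinate events.
# ins/del: IRanges of insertion (subject-gap) and deletion (pattern-gap)
# blocks; ref_off0: 0-based reference offset of the aligned region's first
# column; read: the read sequence (to recover inserted bases).
# Returns data.frame(size, ref_start, ins_seq), 0-based ref coordinates.
.indels_from_ranges <- function(ins, del, ref_off0, read) {
  ni <- length(ins); nd <- length(del)
  if (ni + nd == 0L) return(.no_indels())
  col_start <- c(BiocGenerics::start(ins), BiocGenerics::start(del))
  col_end <- c(BiocGenerics::end(ins), BiocGenerics::end(del))
  is_ins <- rep(c(TRUE, FALSE), c(ni, nd))
  o <- order(col_start)
  col_start <- col_start[o]; col_end <- col_end[o]; is_ins <- is_ins[o]
  ins_before <- 0L; del_before <- 0L
  out <- vector("list", length(col_start))
  for (e in seq_along(col_start)) {
    w <- col_end[e] - col_start[e] + 1L
    ref_pos <- ref_off0 + (col_start[e] - 1L) - ins_before
    if (is_ins[e]) {
      p1 <- col_start[e] - del_before  # pattern coordinates of the block
      out[[e]] <- data.frame(size = w, ref_start = ref_pos,
                             ins_seq = substr(read, p1, p1 + w - 1L),
                             stringsAsFactors = FALSE)
      ins_before <- ins_before + w
    } else {
      out[[e]] <- data.frame(size = -w, ref_start = ref_pos, ins_seq = "",
                             stringsAsFactors = FALSE)
      del_before <- del_before + w
    }
  }
  do.call(rbind, out)
}

# Shift an indel maximally left within repeat context (deterministic
# placement at SSRs). ref is the full reference string; coordinates are
# 0-based.
.left_align_indel <- function(size, ref_start, ins_seq, ref) {
  if (size < 0L) {           # deletion of ref[ref_start, ref_start - size)
    s <- ref_start
    while (s > 0L &&
           substr(ref, s, s) == substr(ref, s - size, s - size)) {
      s <- s - 1L
    }
    list(size = size, ref_start = s, ins_seq = "")
  } else {                   # insertion of ins_seq at ref_start
    s <- ref_start
    ins <- ins_seq
    while (s > 0L &&
           substr(ref, s, s) == substr(ins, size, size)) {
      ins <- paste0(substr(ins, size, size), substr(ins, 1L, size - 1L))
      s <- s - 1L
    }
    list(size = size, ref_start = s, ins_seq = ins)
  }
}

#' Align one read to a reference amplicon
#'
#' Best-scoring semi-global pairwise alignment (read global, free end gaps
#' on the reference) of the read and its reverse complement, with affine
#' gap penalties (match +2, mismatch -3, gap open -8, gap extend -1).
#' Reads with fewer matches than `min_identity` times the read length are
#' `discarded_unaligned`.
#'
#' @param read read sequence.
#' @param ref an [amplicon_ref()].
#' @param min_identity identity floor as a fraction of read length.
#' @return list: `status` ("aligned" or "discarded_unaligned"), `strand`,
#'   `score`, `indels` (left-aligned, reference coordinates), `n_match`.
#' @export
align_to_amplicon <- function(read, ref, min_identity = 0.6) {
  if (nchar(read) == 0L) stop("empty read", call. = FALSE)
  res <- .align_batch(c(read), ref, min_identity)
  res[[1L]]
}

# Batch alignment of many reads against one reference. Returns a list of
# per-read results (same shape as align_to_amplicon). A fast path bypasses
# dynamic programming for reads identical in length to the reference with
# few mismatches: with these scoring parameters such reads cannot profit
# from gaps, so they are substitution-only alignments.
.align_batch <- function(reads, ref, min_identity = 0.6) {
  refseq <- ref$sequence
  L <- nchar(refseq)
  ref_int <- utf8ToInt(refseq)
  n <- length(reads)
  out <- vector("list", n)
  todo <- integer(0)
  for (i in seq_len(n)) {
    r <- reads[i]
    if (nchar(r) == L) {
      h <- sum(utf8ToInt(r) != ref_int)
      if (h <= 5L) {
        out[[i]] <- list(status = "aligned", strand = "+",
                         score = ALN_MATCH * (L - h) + ALN_MISMATCH * h,
                         indels = .no_indels(), n_match = L - h)
        next
      }
    }
    todo <- c(todo, i)
  }
  if (length(todo) > 0L) {
    pats <- Biostrings::DNAStringSet(reads[todo])
    mat <- Biostrings::nucleotideSubstitutionMatrix(ALN_MATCH, ALN_MISMATCH)
    subj <- Biostrings::DNAString(refseq)
    fwd <- Biostrings::pairwiseAlignment(pats, subj, type = "global-local",
                                         substitutionMatrix = mat,
                                         gapOpening = ALN_GAP_OPEN,
                                         gapExtension = ALN_GAP_EXT)
    rev <- Biostrings::pairwiseAlignment(
      Biostrings::reverseComplement(pats), subj, type = "global-local",
      substitutionMatrix = mat, gapOpening = ALN_GAP_OPEN,
      gapExtension = ALN_GAP_EXT)
    sf <- Biostrings::score(fwd); sr <- Biostrings::score(rev)
    use_rev <- sr > sf
    nm_f <- Biostrings::nmatch(fwd)
    off_f <- BiocGenerics::start(Biostrings::subject(fwd))
    ins_f <- Biostrings::insertion(Biostrings::indel(fwd))
    del_f <- Biostrings::deletion(Biostrings::indel(fwd))
    nm_r <- Biostrings::nmatch(rev)
    off_r <- BiocGenerics::start(Biostrings::subject(rev))
    ins_r <- Biostrings::insertion(Biostrings::indel(rev))
    del_r <- Biostrings::deletion(Biostrings::indel(rev))
    rc_reads <- as.character(Biostrings::reverseComplement(pats))
    for (j in seq_along(todo)) {
      i <- todo[j]
      if (use_rev[j]) {
        sc <- sr[j]; nm <- nm_r[j]; off <- off_r[j]; strand <- "-"
        ins <- ins_r[[j]]; del <- del_r[[j]]; aligned_read <- rc_reads[j]
      } else {
        sc <- sf[j]; nm <- nm_f[j]; off <- off_f[j]; strand <- "+"
        ins <- ins_f[[j]]; del <- del_f[[j]]; aligned_read <- reads[i]
      }
      if (nm < min_identity * nchar(reads[i])) {
        out[[i]] <- list(status = "discarded_unaligned", strand = strand,
                         score = sc, indels = .no_indels(), n_match = nm)
        next
      }
      ind <- .indels_from_ranges(ins, del, off - 1L, aligned_read)
      if (nrow(ind) > 0L) {
        for (e in seq_len(nrow(ind))) {
          la <- .left_align_indel(ind$size[e], ind$ref_start[e],
                                  ind$ins_seq[e], refseq)
          ind$ref_start[e] <- la$ref_start
          ind$ins_seq[e] <- la$ins_seq
        }
      }
      out[[i]] <- list(status = "aligned", strand = strand, score = sc,
                       indels = ind, n_match = nm)
    }
  }
  out
}

#' Call the editing status of one aligned read
#'
#' A read is an `indel` call iff the alignment contains at least one
#' insertion or deletion whose reference interval intersects
#' `[cut_pos - quant_window, cut_pos + quant_window]`. Substitutions never
#' count. `indel_size` is the sum of signed in-window indel lengths;
#' out-of-window indels leave the read `WT` with `in_window = FALSE`.
#'
#' @param aln result of [align_to_amplicon()].
#' @param ref the [amplicon_ref()] aligned against.
#' @param read_id id carried through to the call record.
#' @return one-row data.frame: read_id, status
#'   (`WT`/`indel`/`discarded_unaligned`), indel_size, indel_start,
#'   in_window.
#' @export
call_read <- function(aln, ref, read_id = NA_character_) {
  if (aln$status == "discarded_unaligned") {
    return(data.frame(read_id = read_id, status = "discarded_unaligned",
                      indel_size = 0L, indel_start = NA_integer_,
                      in_window = NA, stringsAsFactors = FALSE))
  }
  ind <- aln$indels
  if (nrow(ind) == 0L) {
    return(data.frame(read_id = read_id, status = "WT", indel_size = 0L,
                      indel_start = NA_integer_, in_window = NA,
                      stringsAsFactors = FALSE))
  }
  w1 <- ref$cut_pos - ref$quant_window
  w2 <- ref$cut_pos + ref$quant_window
  iv_start <- ind$ref_start
  iv_end <- ifelse(ind$size < 0L, ind$ref_start - ind$size, ind$ref_start)
  inw <- iv_start <= w2 & iv_end >= w1
  if (any(inw)) {
    data.frame(read_id = read_id, status = "indel",
               indel_size = sum(ind$size[inw]),
               indel_start = min(ind$ref_start[inw]), in_window = TRUE,
               stringsAsFactors = FALSE)
  } else {
    data.frame(read_id = read_id, status = "WT", indel_size = 0L,
               indel_start = min(ind$ref_start), in_window = FALSE,
               stringsAsFactors = FALSE)
  }
}

#' Quantify editing at one site
#'
#' Runs [qc_filter()], alignment and [call_read()] over a read set and
#' summarises: `efficiency` is the percentage of aligned reads carrying an
#' in-window indel (qualified-read denominator).
#'
#' @param reads reads table.
#' @param ref an [amplicon_ref()].
#' @param min_len,adapters QC parameters, see [qc_filter()].
#' @param min_identity alignment identity floor.
#' @return object of class `site_quant`: site_id, n_total, n_aligned,
#'   n_indel, efficiency (percent), allele spectrum (indel_size x
#'   indel_start counts), per-read `calls`.
#' @export
quantify_site <- function(reads, ref, min_len = 35L, adapters = character(),
                          min_identity = 0.6) {
  n_total <- nrow(reads)
  if (n_total == 0L) {
    warning("empty read set for site ", ref$id)
    return(structure(list(site_id = ref$id, n_total = 0L, n_aligned = 0L,
                          n_indel = 0L, efficiency = 0,
                          spectrum = data.frame(indel_size = integer(),
                                                indel_start = integer(),
                                                count = integer()),
                          calls = data.frame()),
                     class = "site_quant"))
  }
  q <- qc_filter(reads, min_len = min_len, adapters = adapters)
  alns <- .align_batch(q$seq, ref, min_identity)
  calls <- do.call(rbind, lapply(seq_along(alns), function(i)
    call_read(alns[[i]], ref, q$read_id[i])))
  if (is.null(calls)) {
    calls <- data.frame(read_id = character(), status = character(),
                        indel_size = integer(), indel_start = integer(),
                        in_window = logical(), stringsAsFactors = FALSE)
  }
  n_aligned <- sum(calls$status != "discarded_unaligned")
  n_indel <- sum(calls$status == "indel")
  if (n_aligned == 0L && n_total > 0L) {
    warning("no aligned reads for site ", ref$id)
  }
  eff <- if (n_aligned > 0L) 100 * n_indel / n_aligned else 0
  spec <- calls[calls$status == "indel", c("indel_size", "indel_start")]
  spectrum <- if (nrow(spec) > 0L) {
    agg <- stats::aggregate(list(count = rep(1L, nrow(spec))),
                            by = list(indel_size = spec$indel_size,
                                      indel_start = spec$indel_start),
                            FUN = sum)
    agg[order(agg$indel_size, agg$indel_start), , drop = FALSE]
  } else {
    data.frame(indel_size = integer(), indel_start = integer(),
               count = integer())
  }
  structure(list(site_id = ref$id, n_total = n_total, n_aligned = n_aligned,
                 n_indel = n_indel, efficiency = eff, spectrum = spectrum,
                 calls = calls),
            class = "site_quant")
}

#' Extract amplicon regions around target sites
#'
#' One amplicon per site: `genome[cut - flank, cut + flank)` with
#' `cut_pos = flank`, clamped at contig edges (the clamp offset is
#' recorded via `genome_start` and the resulting `cut_pos`).
#'
#' @param genome named character vector of contigs.
#' @param sites site table from [find_offtargets()].
#' @param flank flank size in bases (default 100, ~200 bp amplicons).
#' @param quant_window window half-width passed to [amplicon_ref()].
#' @return list of [amplicon_ref()] objects, one per site row.
#' @export
extract_target_regions <- function(genome, sites, flank = 100L,
                                   quant_window = 10L) {
  lapply(seq_len(nrow(sites)), function(i) {
    contig <- sites$contig[i]
    if (!contig %in% names(genome)) {
      stop("site on missing contig: ", contig, call. = FALSE)
    }
    L <- nchar(genome[[contig]])
    cut <- sites$cut_site[i]
    a1 <- max(0L, cut - flank)
    a2 <- min(L, cut + flank)
    id <- if ("site_id" %in% names(sites)) sites$site_id[i] else
      sprintf("%s_%d_%s", contig, sites$start[i], sites$strand[i])
    amplicon_ref(id = id,
                 sequence = substr(genome[[contig]], a1 + 1L, a2),
                 guide_id = sites$guide_id[i],
                 cut_pos = cut - a1,
                 quant_window = quant_window,
                 genome_start = a1)
  })
}
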