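# Guide design and off-target enumeration for variable-length (17-20 nt)
# spacers. On-target design uses an NGG PAM; off-target search relaxes the
# PAM to NRG and allows up to five spacer mismatches (mismatch-only: no
# bulges). Mismatch positions are numbered 1..spacer_len from the
# PAM-proximal base; the seed region is positions 1-12.

SEED_LEN <- 12L

#' Cut-site coordinate of a guide or site
#'
#' SpCas9 cleaves (blunt) between spacer positions 3 and 4 counting from
#' the PAM, i.e. 3 bp 5' of the PAM. The returned value is the 0-based
#' coordinate of the cut boundary on the forward strand.
#'
#' @param start,end 0-based half-open locus span (spacer + PAM).
#' @param strand "+" or "-".
#' @return integer cut coordinates.
#' @export
cut_site_coord <- function(start, end, strand) {
  ifelse(strand == "+", end - 3L - 3L, start + 3L + 3L)
}

# Vectorised per-window spacer mismatch counts on one strand.
# g_int: genome as integer codes; sp_int: spacer codes (length k).
# Returns mismatch count for every window start 0..L-k-np (spacer first,
# PAM after), as an integer vector indexed by start+1.
.window_mismatches <- function(g_int, sp_int, np) {
  L <- length(g_int); k <- length(sp_int)
  nw <- L - k - np + 1L
  if (nw <= 0L) return(integer(0))
  mm <- integer(nw)
  for (j in seq_len(k)) {
    mm <- mm + as.integer(g_int[j:(j + nw - 1L)] != sp_int[j])
  }
  mm
}

# Vectorised PAM-pattern match for windows whose PAM starts at offset
# k (0-based) within each window. Returns logical vector aligned with
# .window_mismatches output.
.window_pam_ok <- function(g_chars, k, np, pam_pattern) {
  L <- length(g_chars)
  nw <- L - k - np + 1L
  if (nw <= 0L) return(logical(0))
  ok <- rep(TRUE, nw)
  pat <- .chars(toupper(pam_pattern))
  for (j in seq_len(np)) {
    allowed <- .iupac_allowed(pat[j])
    ok <- ok & (g_chars[(k + j):(k + j + nw - 1L)] %in% allowed)
  }
  ok
}

#' Enumerate candidate guides in a sequence
#'
#' Finds every position on both strands where `pam_pattern` matches with
#' `spacer_len` bases 5' of it. Minus-strand guides are reported in
#' forward-strand coordinates (locus spans spacer + PAM).
#'
#' @param seq DNA sequence (single contig) or named length-1 vector.
#' @param spacer_len spacer length, one of 17, 18, 19, 20.
#' @param pam_pattern IUPAC PAM pattern (default "NGG").
#' @param contig contig name used in coordinates.
#' @return data.frame of guides: id, spacer, spacer_len, pam_pattern,
#'   observed pam, contig, start, end, strand, cut_site; zero rows if the
#'   sequence is too short.
#' @export
enumerate_guides <- function(seq, spacer_len, pam_pattern = "NGG",
                             contig = NULL) {
  if (!spacer_len %in% 17:20) {
    stop("spacer_len must be one of 17, 18, 19, 20", call. = FALSE)
  }
  if (is.null(contig)) contig <- if (!is.null(names(seq))) names(seq)[1] else "seq"
  seq <- toupper(as.character(seq[1]))
  L <- nchar(seq)
  np <- nchar(pam_pattern)
  k <- as.integer(spacer_len)
  empty <- data.frame(id = character(), spacer = character(),
                      spacer_len = integer(), pam_pattern = character(),
                      pam = character(), contig = character(),
                      start = integer(), end = integer(),
                      strand = character(), cut_site = integer(),
                      stringsAsFactors = FALSE)
  if (L < k + np) return(empty)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    ch <- .chars(s)
    ok <- .window_pam_ok(ch, k, np, pam_pattern)
    starts0 <- which(ok) - 1L          # 0-based window starts on this strand
    if (length(starts0) == 0L) next
    spacer <- substr(rep(s, length(starts0)), starts0 + 1L, starts0 + k)
    pam <- substr(rep(s, length(starts0)), starts0 + k + 1L, starts0 + k + np)
    if (strand == "+") {
      start <- starts0
    } else {
      start <- L - (starts0 + k + np)
    }
    out[[strand]] <- data.frame(
      spacer = spacer, spacer_len = k, pam_pattern = pam_pattern, pam = pam,
      contig = contig, start = start, end = start + k + np, strand = strand,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  g <- do.call(rbind, out)
  g <- g[order(g$start, g$strand), , drop = FALSE]
  g$cut_site <- cut_site_coord(g$start, g$end, g$strand)
  g <- cbind(id = sprintf("%s_%dnt_%d%s", contig, k, g$start, g$strand), g,
             stringsAsFactors = FALSE)
  rownames(g) <- NULL
  g
}

#' Truncate a guide at its 5' (PAM-distal) end
#'
#' Shortening the spacer from the 5' end leaves the PAM-proximal sequence,
#' the 12-nt seed and the genomic cut site unchanged.
#'
#' @param g one or more guide rows (data.frame as from
#'   [enumerate_guides()]).
#' @param new_len target spacer length, `17 <= new_len < spacer_len`.
#' @return guide data.frame with trimmed spacers and updated loci.
#' @export
truncate_guide <- function(g, new_len) {
  if (any(new_len >= g$spacer_len)) {
    stop("new_len must be shorter than the current spacer length",
         call. = FALSE)
  }
  if (new_len < 17L) stop("new_len must be >= 17", call. = FALSE)
  drop <- g$spacer_len - as.integer(new_len)
  g$spacer <- substr(g$spacer, drop + 1L, nchar(g$spacer))
  g$spacer_len <- as.integer(new_len)
  plus <- g$strand == "+"
  g$start[plus] <- g$start[plus] + drop[plus]
  g$end[!plus] <- g$end[!plus] - drop[!plus]
  # cut site is measured from the PAM and does not move
  g
}

# Annotate mismatch details for accepted windows (internal).
# starts0 are 0-based spacer starts on the scanned strand string `s`.
.describe_hits <- function(s, starts0, sp_chars, k, np) {
  n <- length(starts0)
  proto <- substr(rep(s, n), starts0 + 1L, starts0 + k)
  pam <- substr(rep(s, n), starts0 + k + 1L, starts0 + k + np)
  mmpos <- character(n); seedmm <- integer(n); nmm <- integer(n)
  for (i in seq_len(n)) {
    pc <- .chars(proto[i])
    mism <- which(pc != sp_chars)
    # positions 1..k counted from the PAM-proximal base
    pos_from_pam <- sort(k - mism + 1L)
    nmm[i] <- length(mism)
    mmpos[i] <- paste(pos_from_pam, collapse = ",")
    seedmm[i] <- sum(pos_from_pam <= SEED_LEN)
  }
  list(protospacer = proto, pam = pam, n_mismatch = nmm,
       mismatch_positions = mmpos, seed_mismatches = seedmm)
}

#' Enumerate off-target sites of a guide
#'
#' Complete scan of both strands of every contig for loci where the PAM
#' matches `pam_pattern` and the spacer Hamming distance is at most
#' `max_mm`. The on-target locus is itself reported (with
#' `n_mismatch = 0`). Ambiguous genome bases count as spacer mismatches;
#' in the PAM, "N" matches any base and other IUPAC codes expand as usual.
#'
#' @param g a single guide (one-row data.frame or list with `id`,
#'   `spacer`), or a spacer string.
#' @param genome named character vector of contig sequences (as from
#'   [read_fasta()]).
#' @param max_mm maximum spacer mismatches, 0-5.
#' @param pam_pattern IUPAC PAM pattern for the search (default "NRG").
#' @return data.frame of sites sorted by (contig, start): guide_id,
#'   contig, start, end, strand, protospacer, pam, n_mismatch,
#'   mismatch_positions (1-based from the PAM-proximal end),
#'   seed_mismatches, cut_site, ssr_flag (NA until [flag_sites()]).
#' @export
find_offtargets <- function(g, genome, max_mm = 5L, pam_pattern = "NRG") {
  if (is.character(g)) g <- data.frame(id = "guide", spacer = g,
                                       stringsAsFactors = FALSE)
  if (max_mm > 5L || max_mm < 0L) stop("max_mm must be in 0..5", call. = FALSE)
  spacer <- toupper(g$spacer[1])
  if (grepl("[^ACGT]", spacer)) {
    stop("guide spacer contains non-ACGT characters", call. = FALSE)
  }
  k <- nchar(spacer); np <- nchar(pam_pattern)
  sp_chars <- .chars(spacer)
  sp_int <- utf8ToInt(spacer)
  hits <- list()
  for (contig in names(genome)) {
    cs <- toupper(genome[[contig]])
    L <- nchar(cs)
    if (L < k + np) next
    for (strand in c("+", "-")) {
      s <- if (strand == "+") cs else revcomp(cs)
      g_int <- utf8ToInt(s)
      ch <- .chars(s)
      mm <- .window_mismatches(g_int, sp_int, np)
      ok <- .window_pam_ok(ch, k, np, pam_pattern)
      keep0 <- which(ok & mm <= max_mm) - 1L
      if (length(keep0) == 0L) next
      det <- .describe_hits(s, keep0, sp_chars, k, np)
      start <- if (strand == "+") keep0 else L - (keep0 + k + np)
      hits[[paste0(contig, strand)]] <- data.frame(
        guide_id = g$id[1], contig = contig, start = start,
        end = start + k + np, strand = strand,
        protospacer = det$protospacer, pam = det$pam,
        n_mismatch = det$n_mismatch,
        mismatch_positions = det$mismatch_positions,
        seed_mismatches = det$seed_mismatches,
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(guide_id = character(), contig = character(),
                      start = integer(), end = integer(),
                      strand = character(), protospacer = character(),
                      pam = character(), n_mismatch = integer(),
                      mismatch_positions = character(),
                      seed_mismatches = integer(), cut_site = integer(),
                      ssr_flag = logical(), stringsAsFactors = FALSE))
  }
  sites <- do.call(rbind, hits)
  sites <- sites[order(sites$contig, sites$start, sites$strand), ,
                 drop = FALSE]
  sites$cut_site <- cut_site_coord(sites$start, sites$end, sites$strand)
  sites$ssr_flag <- NA
  rownames(sites) <- NULL
  sites
}

#' Tally off-target sites by mismatch count
#'
#' @param sites site table from [find_offtargets()].
#' @param max_mm largest mismatch class to report.
#' @return named integer vector over mismatch counts `0..max_mm`; the sum
#'   equals `nrow(sites)` when `max_mm` covers every site.
#' @export
count_by_mismatch <- function(sites, max_mm = 5L) {
  counts <- integer(max_mm + 1L)
  names(counts) <- as.character(0:max_mm)
  if (nrow(sites) > 0L) {
    tab <- table(factor(sites$n_mismatch, levels = 0:max_mm))
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}

#' Venn-style overlap of off-target sets across spacer lengths
#'
#' Sites are keyed by (contig, cut-site coordinate, strand) so loci found
#' at different spacer lengths collapse onto one key. Returns per-region
#' membership counts; the full intersection is the shared candidate panel.
#'
#' @param site_sets named list mapping spacer length to a site table.
#' @return list with `regions` (data.frame: membership pattern such as
#'   "20&19", count), `n_intersection`, `n_union`, and the logical
#'   `membership` matrix (one row per locus key).
#' @export
overlap_across_lengths <- function(site_sets) {
  if (length(site_sets) < 2L) {
    stop("need site sets for at least two spacer lengths", call. = FALSE)
  }
  keys <- lapply(site_sets, function(s)
    unique(paste(s$contig, s$cut_site, s$strand, sep = ":")))
  all_keys <- sort(unique(unlist(keys)))
  membership <- vapply(keys, function(k) all_keys %in% k,
                       logical(length(all_keys)))
  if (length(all_keys) == 1L) {
    membership <- matrix(membership, nrow = 1L,
                         dimnames = list(all_keys, names(site_sets)))
  }
  rownames(membership) <- all_keys
  pattern <- apply(membership, 1L, function(r)
    paste(colnames(membership)[r], collapse = "&"))
  regions <- as.data.frame(table(pattern), stringsAsFactors = FALSE)
  names(regions) <- c("region", "count")
  full <- paste(names(site_sets), collapse = "&")
  list(regions = regions,
       n_intersection = sum(rowSums(membership) == ncol(membership)),
       n_union = nrow(membership),
       membership = membership)
}
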