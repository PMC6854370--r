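# Synthetic-data generator: toy genomes with planted protospacer and
# microsatellite loci, and simulated amplicon read sets with known truth.
# Everything is driven by one integer seed so outputs are byte-identical
# across runs with the same configuration.

#' Simulation configuration
#'
#' Bundles every tunable of the read simulator. The default indel-size
#' spectrum is a typical NHEJ outcome mix dominated by small deletions;
#' sizes are signed (negative = deletion) and size 0 is forbidden.
#'
#' @param genome_length genome length in bases.
#' @param gc_fraction genomic GC content in `[0,1]`.
#' @param edit_rate per-read probability of carrying one induced indel at
#'   the cut site.
#' @param indel_size_dist named numeric vector mapping signed indel size to
#'   probability; must sum to 1 and contain no entry for size 0.
#' @param subst_error_rate per-base substitution error probability.
#' @param stutter_rate per-read probability of gaining or losing one whole
#'   repeat unit at a microsatellite locus (replication/PCR slippage).
#' @param n_reads number of reads per simulated sample.
#' @param seed integer seed fixing all random draws.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(genome_length = 20000L,
                       gc_fraction = 0.41,
                       edit_rate = 0,
                       indel_size_dist = c("-1" = 0.40, "1" = 0.15,
                                           "-2" = 0.15, "-3" = 0.10,
                                           "-4" = 0.05, "-5" = 0.05,
                                           "-6" = 0.04, "-9" = 0.03,
                                           "2" = 0.03),
                       subst_error_rate = 0.001,
                       stutter_rate = 0.05,
                       n_reads = 300L,
                       seed = 1L) {
  if (genome_length <= 0) stop("genome_length must be positive", call. = FALSE)
  .check_prob(gc_fraction, "gc_fraction")
  .check_prob(edit_rate, "edit_rate")
  .check_prob(subst_error_rate, "subst_error_rate")
  .check_prob(stutter_rate, "stutter_rate")
  sizes <- as.integer(names(indel_size_dist))
  if (anyNA(sizes)) stop("indel_size_dist names must be integers", call. = FALSE)
  if (any(sizes == 0L)) {
    stop("indel_size_dist must not contain size 0", call. = FALSE)
  }
  if (any(indel_size_dist < 0) ||
      abs(sum(indel_size_dist) - 1) > 1e-9) {
    stop("indel_size_dist probabilities must be >= 0 and sum to 1",
         call. = FALSE)
  }
  if (n_reads < 0) stop("n_reads must be >= 0", call. = FALSE)
  structure(list(genome_length = as.integer(genome_length),
                 gc_fraction = gc_fraction,
                 edit_rate = edit_rate,
                 indel_size_dist = indel_size_dist,
                 subst_error_rate = subst_error_rate,
                 stutter_rate = stutter_rate,
                 n_reads = as.integer(n_reads),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a random genome sequence
#'
#' Bases are drawn i.i.d. with G and C each at `gc_fraction / 2` and A and
#' T each at `(1 - gc_fraction) / 2`.
#'
#' @param length genome length in bases (> 0).
#' @param gc_fraction target GC content in `[0,1]`.
#' @param seed integer seed.
#' @return uppercase A/C/G/T string of exactly `length` bases, carrying a
#'   `planted` attribute used to keep later insertions disjoint.
#' @export
make_genome <- function(length, gc_fraction, seed) {
  if (length <= 0) stop("length must be positive", call. = FALSE)
  .check_prob(gc_fraction, "gc_fraction")
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  g <- with_seed(seed, sample(BASES, length, replace = TRUE, prob = p))
  genome <- paste(g, collapse = "")
  attr(genome, "planted") <- data.frame(start = integer(), end = integer())
  genome
}

# Record a planted interval on the genome, refusing overlap with any
# previously planted interval (0-based half-open).
.plant_interval <- function(genome, start, end) {
  planted <- attr(genome, "planted")
  if (is.null(planted)) planted <- data.frame(start = integer(), end = integer())
  if (any(planted$start < end & start < planted$end)) {
    stop("planted site [", start, ",", end,
         ") overlaps a previously planted site", call. = FALSE)
  }
  attr(genome, "planted") <- rbind(planted, data.frame(start = start, end = end))
  genome
}

#' Plant a protospacer + PAM copy into a genome
#'
#' Overwrites `n_mismatches` spacer positions (chosen by the seeded
#' generator) so the genome carries a copy of `spacer + pam` at exactly
#' that Hamming distance, with the PAM intact. On the minus strand the
#' reverse complement is written, so the site reads as `spacer + pam` on
#' the minus strand.
#'
#' @param genome genome string from [make_genome()].
#' @param spacer guide spacer sequence (ACGT).
#' @param pam concrete PAM sequence to plant (e.g. "AGG", "GAG").
#' @param n_mismatches number of spacer mismatches to introduce (0-5).
#' @param position 0-based offset of the site's left edge on the forward
#'   strand.
#' @param strand "+" or "-".
#' @param seed integer seed for mismatch placement.
#' @return list with elements `genome` (modified sequence) and `site`
#'   (one-row truth record: start, end, strand, planted protospacer, pam,
#'   n_mismatch).
#' @export
plant_site <- function(genome, spacer, pam, n_mismatches, position,
                       strand = "+", seed = 1L) {
  spacer <- toupper(spacer); pam <- toupper(pam)
  k <- nchar(spacer); np <- nchar(pam)
  L <- nchar(genome)
  if (n_mismatches < 0 || n_mismatches > 5) {
    stop("n_mismatches must be in 0..5", call. = FALSE)
  }
  if (position < 0 || position + k + np > L) {
    stop("site does not fit in the genome at position ", position,
         call. = FALSE)
  }
  if (!strand %in% c("+", "-")) stop("strand must be + or -", call. = FALSE)
  sp <- .chars(spacer)
  mut <- with_seed(seed, {
    idx <- sample.int(k, n_mismatches)
    repl <- vapply(idx, function(i) sample(setdiff(BASES, sp[i]), 1L),
                   character(1))
    list(idx = idx, repl = repl)
  })
  proto <- sp
  proto[mut$idx] <- mut$repl
  site_seq <- paste0(paste(proto, collapse = ""), pam)
  if (strand == "-") site_seq <- revcomp(site_seq)
  start <- as.integer(position); end <- start + k + np
  planted <- attr(genome, "planted")
  out <- paste0(substr(genome, 1L, start), site_seq,
                substr(genome, end + 1L, L))
  attr(out, "planted") <- planted
  out <- .plant_interval(out, start, end)
  list(genome = out,
       site = data.frame(start = start, end = end, strand = strand,
                         protospacer = paste(proto, collapse = ""),
                         pam = pam, n_mismatch = as.integer(n_mismatches),
                         stringsAsFactors = FALSE))
}

#' Plant a microsatellite into a genome
#'
#' Overwrites the genome at `position` with the literal expansion of a
#' motif composition string such as `"(CA)8(GA)2"` or `"A(CA)7GA"`.
#'
#' @param genome genome string.
#' @param composition motif composition string; see
#'   [expand_composition()].
#' @param position 0-based offset.
#' @return modified genome string.
#' @export
plant_ssr <- function(genome, composition, position) {
  expansion <- expand_composition(composition)
  L <- nchar(genome)
  n <- nchar(expansion)
  if (position < 0 || position + n > L) {
    stop("microsatellite does not fit at position ", position, call. = FALSE)
  }
  planted <- attr(genome, "planted")
  out <- paste0(substr(genome, 1L, position), expansion,
                substr(genome, position + n + 1L, L))
  attr(out, "planted") <- planted
  .plant_interval(out, as.integer(position), as.integer(position + n))
}

# Dominant tandem run within a (possibly compound) microsatellite span:
# the longest perfect run of a 1-6 nt unit repeated at least twice.
# Returns list(unit, offset) with offset 0-based within the span.
.dominant_unit <- function(span_seq) {
  runs <- find_perfect_ssrs(span_seq,
                            ssr_thresholds(min_repeats = stats::setNames(
                              rep(2L, 6L), as.character(1:6))))
  if (nrow(runs) == 0L) {
    return(list(unit = span_seq, offset = 0L))
  }
  best <- which.max(runs$end - runs$start)
  list(unit = runs$unit[best], offset = runs$start[best])
}

#' Simulate amplicon reads with known truth
#'
#' Each read is a full-length copy of the amplicon. With probability
#' `cfg$edit_rate` a read carries one indel whose left edge sits at
#' `cut_pos` (size drawn from `cfg$indel_size_dist`); independently each
#' base mutates with probability `cfg$subst_error_rate`; if `ssr_span` is
#' given, with probability `cfg$stutter_rate` the read gains or loses one
#' whole repeat unit inside the span (equiprobable direction), regardless
#' of editing. Draws are made stage-wise in a documented order (edit
#' flags, indel sizes, inserted bases, stutter flags and directions,
#' substitutions), all from one generator seeded with `cfg$seed`.
#'
#' @param amplicon reference amplicon sequence.
#' @param cut_pos 0-based cut-site offset (indel left edge).
#' @param cfg a [sim_config()].
#' @param ssr_span optional 0-based half-open `c(start, end)` interval of a
#'   microsatellite within the amplicon.
#' @param id_prefix prefix for read ids.
#' @return list with `reads` (data.frame read_id/seq/qual, constant Q30
#'   qualities) and `truth` (per-read data.frame: read_id, edited,
#'   indel_size, stutter, stutter_size, n_subst).
#' @export
simulate_reads <- function(amplicon, cut_pos, cfg, ssr_span = NULL,
                           id_prefix = "read") {
  L <- nchar(amplicon)
  if (L == 0L) stop("empty amplicon", call. = FALSE)
  if (cut_pos < 0 || cut_pos >= L) {
    stop("cut_pos out of range", call. = FALSE)
  }
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_reads
  sizes <- as.integer(names(cfg$indel_size_dist))
  unit_len <- 0L
  unit <- ""
  if (!is.null(ssr_span)) {
    s0 <- ssr_span[1]; e0 <- ssr_span[2]
    if (s0 < 0 || e0 > L || s0 >= e0) stop("invalid ssr_span", call. = FALSE)
    span_seq <- substr(amplicon, s0 + 1L, e0)
    dom <- .dominant_unit(span_seq)
    unit <- dom$unit
    unit_len <- nchar(unit)
    slip_at <- s0 + dom$offset   # 0-based slippage point in the amplicon
  }

  draws <- with_seed(cfg$seed, {
    edited <- stats::runif(n) < cfg$edit_rate
    indel_size <- integer(n)
    if (any(edited)) {
      indel_size[edited] <- sample(sizes, sum(edited), replace = TRUE,
                                   prob = cfg$indel_size_dist)
    }
    ins_bases <- character(n)
    for (i in which(edited & indel_size > 0L)) {
      ins_bases[i] <- paste(sample(BASES, indel_size[i], replace = TRUE),
                            collapse = "")
    }
    stutter <- if (is.null(ssr_span)) rep(FALSE, n) else
      stats::runif(n) < cfg$stutter_rate
    stutter_dir <- integer(n)
    if (any(stutter)) {
      stutter_dir[stutter] <- sample(c(-1L, 1L), sum(stutter), replace = TRUE)
    }
    n_subst <- stats::rbinom(n, L, cfg$subst_error_rate)
    list(edited = edited, indel_size = indel_size, ins_bases = ins_bases,
         stutter = stutter, stutter_dir = stutter_dir, n_subst = n_subst,
         sub_seed = sample.int(2^30, 1L))
  })

  seqs <- rep(amplicon, n)
  # induced indel, left-anchored at the cut site
  for (i in which(draws$edited)) {
    sz <- draws$indel_size[i]
    if (sz < 0L) {
      if (cut_pos - sz > L) { # deletion would run off the amplicon
        draws$edited[i] <- FALSE; draws$indel_size[i] <- 0L
        next
      }
      seqs[i] <- paste0(substr(amplicon, 1L, cut_pos),
                        substr(amplicon, cut_pos - sz + 1L, L))
    } else {
      seqs[i] <- paste0(substr(amplicon, 1L, cut_pos), draws$ins_bases[i],
                        substr(amplicon, cut_pos + 1L, L))
    }
  }
  # SSR stutter: +/- one whole repeat unit at the span start
  stutter_size <- integer(n)
  for (i in which(draws$stutter)) {
    shift <- if (draws$edited[i] && cut_pos < slip_at) draws$indel_size[i] else 0L
    s0 <- slip_at + shift
    if (s0 < 0L || s0 + unit_len > nchar(seqs[i])) next
    if (draws$stutter_dir[i] > 0L) {
      seqs[i] <- paste0(substr(seqs[i], 1L, s0), unit,
                        substr(seqs[i], s0 + 1L, nchar(seqs[i])))
      stutter_size[i] <- unit_len
    } else {
      seqs[i] <- paste0(substr(seqs[i], 1L, s0),
                        substr(seqs[i], s0 + unit_len + 1L, nchar(seqs[i])))
      stutter_size[i] <- -unit_len
    }
  }
  # substitution errors, uniform over the final read
  if (any(draws$n_subst > 0L)) {
    seqs <- with_seed(draws$sub_seed, {
      for (i in which(draws$n_subst > 0L)) {
        li <- nchar(seqs[i])
        k <- min(draws$n_subst[i], li)
        pos <- sample.int(li, k)
        ch <- .chars(seqs[i])
        for (p in pos) ch[p] <- sample(setdiff(BASES, ch[p]), 1L)
        seqs[i] <- paste(ch, collapse = "")
      }
      seqs
    })
  }
  ids <- sprintf("%s_%05d", id_prefix, seq_len(n))
  reads <- data.frame(read_id = ids, seq = seqs,
                      qual = strrep("?", nchar(seqs)),  # constant Q30
                      stringsAsFactors = FALSE)
  truth <- data.frame(read_id = ids, edited = draws$edited,
                      indel_size = draws$indel_size,
                      stutter = draws$stutter & stutter_size != 0L,
                      stutter_size = stutter_size,
                      n_subst = draws$n_subst,
                      stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

#' Build a complete synthetic test fixture
#'
#' Generates a genome carrying one on-target site for a 20-nt guide plus
#' planted off-target sites, and paired control/edited read sets per site:
#' true off-targets are edited in the edited sample only; SSR-noise sites
#' carry microsatellite stutter in both samples; clean sites carry neither.
#' Per-site editing rates for the true off-targets default to the rates the
#' capture experiment is designed to detect (51.4, 31.7 and 10.5 percent,
#' recycled), and the on-target rate defaults to 67.4 percent.
#'
#' @param cfg a [sim_config()]; `cfg$seed` drives every draw.
#' @param n_true_offtargets number of genuinely edited off-target sites.
#' @param n_ssr_noise_sites number of sites with a planted
#'   `"(CA)8(GA)2"`-type microsatellite and slippage in both samples.
#' @param n_clean_sites number of unedited, SSR-free sites.
#' @param ontarget_rate editing rate at the on-target site.
#' @param offtarget_rates editing rates recycled over the true off-targets.
#' @param ssr_composition motif composition planted at SSR-noise sites.
#' @return list of class `fixture`: `genome`, `guides` (lengths
#'   20/19/18/17), `sites` (site table incl. the on-target), `amplicons`,
#'   `reads` (per site: `control` and `edited` read tables), `truth`
#'   (per-site truth incl. role and true rate), `read_truth`, `cfg`.
#' @export
make_fixture <- function(cfg = sim_config(),
                         n_true_offtargets = 3L,
                         n_ssr_noise_sites = 5L,
                         n_clean_sites = 20L,
                         ontarget_rate = 0.674,
                         offtarget_rates = c(0.514, 0.317, 0.105),
                         ssr_composition = "(CA)8(GA)2") {
  if (n_true_offtargets < 0 || n_ssr_noise_sites < 0 || n_clean_sites < 0) {
    stop("site counts must be >= 0", call. = FALSE)
  }
  if (n_true_offtargets + n_ssr_noise_sites + n_clean_sites == 0L) {
    stop("fixture needs at least one off-target/noise/clean site",
         call. = FALSE)
  }
  n_sites <- 1L + n_true_offtargets + n_ssr_noise_sites + n_clean_sites
  spacing <- 600L
  margin <- 500L
  need <- margin * 2L + n_sites * spacing
  glen <- max(cfg$genome_length, need)
  genome <- make_genome(glen, cfg$gc_fraction, cfg$seed)

  spacer <- with_seed(cfg$seed + 1L,
                      paste(sample(BASES, 20L, replace = TRUE), collapse = ""))
  pams <- c("AGG", "GAG", "TAG", "CAG")   # concrete NRG PAMs, recycled
  ssr_len <- nchar(expand_composition(ssr_composition))

  roles <- c("on_target",
             rep("true_offtarget", n_true_offtargets),
             rep("ssr_noise", n_ssr_noise_sites),
             rep("clean", n_clean_sites))
  mm_for <- function(role, i) switch(role,
    on_target = 0L,
    true_offtarget = ((i - 1L) %% 3L) + 1L,   # 1-3 mismatches
    ssr_noise = 3L,
    clean = 4L)
  rates <- c(ontarget_rate,
             rep(offtarget_rates, length.out = n_true_offtargets),
             rep(0, n_ssr_noise_sites + n_clean_sites))

  sites <- NULL
  for (i in seq_len(n_sites)) {
    role <- roles[i]
    pos <- margin + (i - 1L) * spacing
    pam <- if (role == "on_target") "AGG" else pams[((i - 1L) %% 4L) + 1L]
    # SSR-noise sites stay on the plus strand: the microsatellite sits
    # immediately 3' of the PAM, so its left-aligned slippage indels fall
    # inside the default quantification window around the cut site
    strand <- if (role == "ssr_noise") "+" else
      if (i %% 5L == 0L) "-" else "+"
    res <- plant_site(genome, spacer, pam, mm_for(role, i), pos, strand,
                      seed = cfg$seed + 100L + i)
    genome <- res$genome
    rec <- res$site
    rec$site_id <- sprintf("site_%02d", i)
    rec$contig <- "chrS"
    rec$role <- role
    rec$true_edit_rate <- rates[i]
    rec$ssr <- role == "ssr_noise"
    rec$composition <- if (rec$ssr) ssr_composition else NA_character_
    if (rec$ssr) {
      # microsatellite immediately 3' of the PAM (plus strand) so slippage
      # indels fall inside the cut-site quantification window
      ssr_pos <- if (strand == "+") rec$end else rec$start - ssr_len
      genome <- plant_ssr(genome, ssr_composition, ssr_pos)
      rec$ssr_start <- as.integer(ssr_pos)
      rec$ssr_end <- as.integer(ssr_pos + ssr_len)
    } else {
      rec$ssr_start <- NA_integer_; rec$ssr_end <- NA_integer_
    }
    sites <- rbind(sites, rec)
  }
  # guide set: the 20-nt guide over the on-target locus plus truncations
  on <- sites[sites$role == "on_target", ]
  g20 <- data.frame(id = "g20", spacer = spacer, spacer_len = 20L,
                    pam_pattern = "NGG", contig = "chrS",
                    start = on$start, end = on$end, strand = on$strand,
                    cut_site = cut_site_coord(on$start, on$end, on$strand),
                    stringsAsFactors = FALSE)
  guides <- g20
  for (len in c(19L, 18L, 17L)) {
    g <- truncate_guide(g20, len)
    g$id <- paste0("g", len)
    guides <- rbind(guides, g)
  }

  # per-site amplicons and paired read sets
  flank <- 100L
  site_tab <- data.frame(guide_id = "g20", contig = sites$contig,
                         start = sites$start, end = sites$end,
                         strand = sites$strand,
                         protospacer = sites$protospacer, pam = sites$pam,
                         n_mismatch = sites$n_mismatch,
                         mismatch_positions = "", seed_mismatches = NA_integer_,
                         cut_site = cut_site_coord(sites$start, sites$end,
                                                   sites$strand),
                         ssr_flag = NA, site_id = sites$site_id,
                         stringsAsFactors = FALSE)
  amplicons <- extract_target_regions(c(chrS = as.character(genome)),
                                      site_tab, flank = flank)
  reads <- list(); read_truth <- list()
  for (i in seq_len(n_sites)) {
    ref <- amplicons[[i]]
    span <- NULL
    if (sites$ssr[i]) {
      a0 <- ref$genome_start
      span <- c(sites$ssr_start[i] - a0, sites$ssr_end[i] - a0)
    }
    ctl_cfg <- cfg; ctl_cfg$edit_rate <- 0
    ctl_cfg$stutter_rate <- if (sites$ssr[i]) cfg$stutter_rate else 0
    ctl_cfg$seed <- cfg$seed + 1000L + 2L * i
    edt_cfg <- cfg; edt_cfg$edit_rate <- sites$true_edit_rate[i]
    edt_cfg$stutter_rate <- ctl_cfg$stutter_rate
    edt_cfg$seed <- cfg$seed + 1000L + 2L * i + 1L
    ctl <- simulate_reads(ref$sequence, ref$cut_pos, ctl_cfg, ssr_span = span,
                          id_prefix = paste0(sites$site_id[i], "_ctl"))
    edt <- simulate_reads(ref$sequence, ref$cut_pos, edt_cfg, ssr_span = span,
                          id_prefix = paste0(sites$site_id[i], "_edt"))
    reads[[sites$site_id[i]]] <- list(control = ctl$reads, edited = edt$reads)
    read_truth[[sites$site_id[i]]] <- list(control = ctl$truth,
                                           edited = edt$truth)
  }
  truth <- sites[, c("site_id", "role", "true_edit_rate", "n_mismatch",
                     "ssr", "composition", "protospacer", "pam",
                     "start", "end", "strand")]
  structure(list(genome = c(chrS = as.character(genome)),
                 guides = guides, sites = site_tab, amplicons = amplicons,
                 reads = reads, truth = truth, read_truth = read_truth,
                 cfg = cfg),
            class = "fixture")
}

#' Write a fixture bundle to disk
#'
#' Emits genome FASTA, per-site control/edited FASTQ, site BED and the
#' truth table TSV under `dir`.
#'
#' @param fixture a [make_fixture()] bundle.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(fixture$genome, file.path(dir, "genome.fa"))
  write_bed(fixture$sites, file.path(dir, "sites.bed"))
  utils::write.table(fixture$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (sid in names(fixture$reads)) {
    write_fastq(fixture$reads[[sid]]$control,
                file.path(dir, paste0(sid, "_control.fq")))
    write_fastq(fixture$reads[[sid]]$edited,
                file.path(dir, paste0(sid, "_edited.fq")))
  }
  amp <- vapply(fixture$amplicons, function(a) a$sequence, character(1))
  names(amp) <- vapply(fixture$amplicons, function(a) a$id, character(1))
  write_fasta(amp, file.path(dir, "amplicons.fa"))
  invisible(dir)
}
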