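# Read QC, semi-global alignment, cut-site indel calling and per-site
# efficiency, cross-checked against a Gotoh dynamic-programming oracle
# and binomial truth recovery from the simulator.

mkread <- function(seq, id = "r") {
  data.frame(read_id = id, seq = seq, qual = strrep("?", nchar(seq)),
             stringsAsFactors = FALSE)
}

test_that("qc_filter discards N-reads and short reads, trims adapters", {
  reads <- rbind(
    mkread(strrep("ACGT", 25), "clean"),
    mkread(paste0(strrep("ACGT", 20), "N"), "with_n"),
    mkread(strrep("AC", 10), "short"))
  out <- qc_filter(reads, min_len = 35)
  expect_identical(out$read_id, "clean")
  expect_identical(out$seq, strrep("ACGT", 25))

  # 40-base read whose last 10 bases are an adapter prefix: trimmed to 30,
  # then discarded because 30 < 35
  adapter <- "GGTTCCAAGGTTCCAA"
  r40 <- mkread(paste0(random_seq(30, seed = 2), substr(adapter, 1, 10)))
  expect_equal(nrow(qc_filter(r40, 35, adapters = adapter)), 0)
  # same read against a longer floor check: trimmed content is 30 bases
  kept <- qc_filter(r40, 30, adapters = adapter)
  expect_equal(nchar(kept$seq), 30)
  # overlap below 8 bases is not trimmed
  r_small <- mkread(paste0(random_seq(40, seed = 3), substr(adapter, 1, 7)))
  expect_equal(nchar(qc_filter(r_small, 35, adapters = adapter)$seq), 47)
})

test_that("alignment reproduces constructed indels at the cut site", {
  refseq <- random_seq(200, seed = 41)
  ref <- amplicon_ref("amp", refseq, cut_pos = 100, quant_window = 10)

  # perfect read
  a <- align_to_amplicon(refseq, ref)
  expect_identical(a$status, "aligned")
  expect_equal(nrow(a$indels), 0)
  expect_identical(call_read(a, ref)$status, "WT")

  # 3-base deletion with left edge at the cut site
  del3 <- paste0(substr(refseq, 1, 100), substr(refseq, 104, 200))
  a <- align_to_amplicon(del3, ref)
  expect_equal(a$indels$size, -3)
  cc <- call_read(a, ref)
  expect_identical(cc$status, "indel")
  expect_equal(cc$indel_size, -3)
  expect_true(cc$in_window)

  # 2-base insertion 50 bases away: recorded but not counted as an edit
  ins_off <- paste0(substr(refseq, 1, 150), "GT", substr(refseq, 151, 200))
  a <- align_to_amplicon(ins_off, ref)
  cc <- call_read(a, ref)
  expect_identical(cc$status, "WT")
  expect_false(cc$in_window)

  # reverse-complemented read gives the identical call on the minus strand
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(del3)))
  a <- align_to_amplicon(rc, ref)
  expect_identical(a$strand, "-")
  expect_equal(a$indels$size, -3)
  expect_identical(call_read(a, ref)$status, "indel")

  # unalignable garbage is discarded, not an error
  a <- align_to_amplicon(strrep("T", 80), ref)
  expect_identical(a$status, "discarded_unaligned")
  expect_identical(call_read(a, ref)$status, "discarded_unaligned")
})

test_that("alignment scores agree with an exhaustive affine-gap oracle", {
  set.seed(99)
  for (i in 1:12) {
    refseq <- random_seq(60, seed = 500 + i)
    ref <- amplicon_ref("t", refseq, cut_pos = 30, quant_window = 10)
    type <- i %% 4
    read <- if (type == 0) {
      p <- sample(20:40, 1)
      paste0(substr(refseq, 1, p), substr(refseq, p + 4, 60))   # 3-del
    } else if (type == 1) {
      p <- sample(20:40, 1)
      paste0(substr(refseq, 1, p), "CGTA", substr(refseq, p + 1, 60)) # 4-ins
    } else if (type == 2) {
      ch <- strsplit(refseq, "")[[1]]
      idx <- sample(60, 7)                                      # subs only
      for (j in idx) ch[j] <- sample(setdiff(c("A","C","G","T"), ch[j]), 1)
      paste(ch, collapse = "")
    } else {
      substr(refseq, 10, 50)                                    # partial
    }
    got <- align_to_amplicon(read, ref)
    expect_equal(got$score, oracle_align_score(read, refseq),
                 info = paste("case", i))
  }
})

test_that("indels are left-aligned within repeat context", {
  # deletion of one CA unit inside (CA)8: placement must be at the
  # leftmost equivalent position
  left <- random_seq(50, seed = 61)
  right <- random_seq(50, seed = 62)
  refseq <- paste0(left, strrep("CA", 8), right)
  ref <- amplicon_ref("ssr", refseq, cut_pos = 50, quant_window = 10)
  # delete the *last* CA unit (positions 65,66 in 0-based 64..66)
  read <- paste0(substr(refseq, 1, 64), substr(refseq, 67, 116))
  a <- align_to_amplicon(read, ref)
  expect_equal(a$indels$size, -2)
  expect_equal(a$indels$ref_start, 50)  # shifted to the repeat's left edge
})

test_that("per-site efficiency recovers the simulated editing rate", {
  amp <- random_seq(200, seed = 71)
  ref <- amplicon_ref("site", amp, cut_pos = 100, quant_window = 10)

  cfg0 <- sim_config(edit_rate = 0, n_reads = 500, seed = 5)
  q0 <- quantify_site(simulate_reads(amp, 100, cfg0)$reads, ref)
  expect_equal(q0$efficiency, 0)

  cfg <- sim_config(edit_rate = 0.15, n_reads = 2000, seed = 6)
  sim <- simulate_reads(amp, 100, cfg)
  q <- quantify_site(sim$reads, ref)
  # the estimate matches the realised edited fraction, which is itself
  # within 3 binomial SE of 15%
  realised <- 100 * mean(sim$truth$edited)
  expect_lt(abs(q$efficiency - realised), 0.5)
  expect_lt(abs(q$efficiency - 15), 300 * sqrt(0.15 * 0.85 / 2000))
  expect_equal(sum(q$spectrum$count), q$n_indel)
  expect_true(all(q$spectrum$indel_size != 0))
})

test_that("substitution errors alone never create indel calls", {
  amp <- random_seq(200, seed = 81)
  ref <- amplicon_ref("site", amp, cut_pos = 100, quant_window = 10)
  cfg <- sim_config(edit_rate = 0, subst_error_rate = 0.005,
                    n_reads = 1000, seed = 9)
  q <- quantify_site(simulate_reads(amp, 100, cfg)$reads, ref)
  expect_lt(q$efficiency, 0.5)
  expect_equal(q$n_indel, 0)
})

test_that("window width controls whether distant SSR stutter is counted", {
  # stutter indel planted ~50 bases from the cut site: invisible at the
  # default +/-10 window, counted once the window spans it (why SSR loci
  # inflate apparent editing when quantified with wide windows)
  left <- random_seq(100, seed = 91)
  right <- random_seq(60, seed = 92)
  amp <- paste0(left, strrep("CA", 10), right)
  span <- c(100, 120)
  cfg <- sim_config(edit_rate = 0, subst_error_rate = 0, stutter_rate = 1,
                    n_reads = 50, seed = 10)
  reads <- simulate_reads(amp, 50, cfg, ssr_span = span)$reads
  narrow <- quantify_site(reads, amplicon_ref("s", amp, cut_pos = 50,
                                              quant_window = 10))
  wide <- quantify_site(reads, amplicon_ref("s", amp, cut_pos = 50,
                                            quant_window = 50))
  expect_equal(narrow$efficiency, 0)
  expect_equal(wide$efficiency, 100)
})

test_that("quantification is additive over concatenated read sets", {
  amp <- random_seq(150, seed = 95)
  ref <- amplicon_ref("s", amp, cut_pos = 75, quant_window = 10)
  cfg1 <- sim_config(edit_rate = 0.3, n_reads = 200, seed = 1)
  cfg2 <- sim_config(edit_rate = 0.1, n_reads = 300, seed = 2)
  r1 <- simulate_reads(amp, 75, cfg1, id_prefix = "a")$reads
  r2 <- simulate_reads(amp, 75, cfg2, id_prefix = "b")$reads
  qa <- quantify_site(r1, ref); qb <- quantify_site(r2, ref)
  qc <- quantify_site(rbind(r1, r2), ref)
  expect_equal(qc$n_total, qa$n_total + qb$n_total)
  expect_equal(qc$n_indel, qa$n_indel + qb$n_indel)
  spec_sum <- sum(qa$spectrum$count) + sum(qb$spectrum$count)
  expect_equal(sum(qc$spectrum$count), spec_sum)
})

test_that("extract_target_regions centres the cut site and clamps edges", {
  gseq <- random_seq(3000, seed = 97)
  sites <- data.frame(guide_id = "g", contig = "chr",
                      start = c(1500, 10), end = c(1523, 33),
                      strand = "+", n_mismatch = 0,
                      site_id = c("mid", "edge"), stringsAsFactors = FALSE)
  sites$cut_site <- cut_site_coord(sites$start, sites$end, sites$strand)
  refs <- extract_target_regions(c(chr = gseq), sites, flank = 100)
  expect_equal(nchar(refs[[1]]$sequence), 200)
  expect_equal(refs[[1]]$cut_pos, 100)
  # site near the contig start: shorter amplicon, cut_pos = distance to edge
  expect_equal(refs[[2]]$cut_pos, sites$cut_site[2])
  expect_equal(nchar(refs[[2]]$sequence), sites$cut_site[2] + 100)
  expect_error(extract_target_regions(c(other = gseq), sites, 100),
               "missing contig")

  # round trip: the extracted window still contains the site at 0 mm
  spacer <- substr(gseq, 1501, 1520)
  hits <- find_offtargets(spacer, c(chr = refs[[1]]$sequence), max_mm = 0,
                          pam_pattern = "NNN")
  expect_true(any(hits$n_mismatch == 0))
})
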