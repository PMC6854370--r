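# Readers and writers for the standard formats the pipeline touches:
# FASTA, FASTQ (Phred+33), BED (0-based half-open) and an extended
# 1-based site TSV. All writers are deterministic given their inputs.

#' Read a FASTA file
#'
#' Supports multi-record, line-wrapped FASTA. Sequences are uppercased and
#' record ids are truncated at the first whitespace.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  out <- toupper(as.character(x))
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    stop("all sequences must be named", call. = FALSE)
  }
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read a FASTQ file into a reads table
#'
#' Strict 4-line-record FASTQ (Phred+33). Malformed records are reported
#' with the line number at which the problem was detected.
#'
#' @param path path to a FASTQ file.
#' @return data.frame with columns `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0L) {
    return(data.frame(read_id = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE))
  }
  if (length(lines) %% 4L != 0L) {
    stop("truncated FASTQ record starting at line ",
         4L * (length(lines) %/% 4L) + 1L, call. = FALSE)
  }
  hdr <- lines[seq(1L, length(lines), by = 4L)]
  seq <- lines[seq(2L, length(lines), by = 4L)]
  sep <- lines[seq(3L, length(lines), by = 4L)]
  qual <- lines[seq(4L, length(lines), by = 4L)]
  bad_hdr <- which(!startsWith(hdr, "@"))
  if (length(bad_hdr) > 0L) {
    stop("malformed FASTQ header at line ", 4L * (bad_hdr[1L] - 1L) + 1L,
         call. = FALSE)
  }
  bad_sep <- which(!startsWith(sep, "+"))
  if (length(bad_sep) > 0L) {
    stop("malformed FASTQ separator at line ", 4L * (bad_sep[1L] - 1L) + 3L,
         call. = FALSE)
  }
  bad_len <- which(nchar(seq) != nchar(qual))
  if (length(bad_len) > 0L) {
    stop("sequence/quality length mismatch at line ",
         4L * (bad_len[1L] - 1L) + 2L, call. = FALSE)
  }
  ids <- sub("^@", "", hdr)
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1L)
  data.frame(read_id = ids, seq = toupper(seq), qual = qual,
             stringsAsFactors = FALSE)
}

#' Write a reads table to FASTQ
#'
#' @param reads data.frame with columns `read_id`, `seq`, `qual`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "seq", "qual") %in% names(reads)))
  if (any(nchar(reads$seq) != nchar(reads$qual))) {
    stop("sequence/quality length mismatch", call. = FALSE)
  }
  if (nrow(reads) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  out <- rbind(paste0("@", reads$read_id), reads$seq, "+", reads$qual)
  writeLines(as.vector(out), path)
  invisible(path)
}

#' Write off-target sites as BED
#'
#' Six-column BED: chrom, start, end, name, score (= mismatch count),
#' strand; 0-based half-open coordinates.
#'
#' @param sites site table as returned by [find_offtargets()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(sites, path) {
  if (any(sites$start >= sites$end)) {
    stop("BED requires start < end for every site", call. = FALSE)
  }
  name <- if ("site_id" %in% names(sites)) sites$site_id else
    paste0(sites$guide_id, "_", seq_len(nrow(sites)))
  bed <- data.frame(chrom = sites$contig, start = sites$start,
                    end = sites$end, name = name,
                    score = sites$n_mismatch, strand = sites$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 6-column BED file
#'
#' @param path path to a BED file.
#' @return data.frame with columns `contig`, `start`, `end`, `site_id`,
#'   `n_mismatch`, `strand` (0-based half-open).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand"))
  if (any(bed$start >= bed$end)) {
    stop("invalid BED: start >= end", call. = FALSE)
  }
  data.frame(contig = bed$chrom, start = bed$start, end = bed$end,
             site_id = bed$name, n_mismatch = bed$score,
             strand = bed$strand, stringsAsFactors = FALSE)
}

#' Write the extended site report TSV
#'
#' Human-readable companion to the BED output: 1-based inclusive
#' coordinates (declared in a header comment) plus protospacer, PAM,
#' mismatch annotation and SSR flag.
#'
#' @param sites site table as returned by [find_offtargets()], optionally
#'   after [flag_sites()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites_tsv <- function(sites, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 1-based inclusive", con)
  out <- data.frame(
    guide_id = sites$guide_id, contig = sites$contig,
    start = sites$start + 1L, end = sites$end, strand = sites$strand,
    protospacer = sites$protospacer, pam = sites$pam,
    n_mismatch = sites$n_mismatch,
    mismatch_positions = sites$mismatch_positions,
    seed_mismatches = sites$seed_mismatches,
    ssr_flag = if ("ssr_flag" %in% names(sites)) sites$ssr_flag else NA,
    stringsAsFactors = FALSE)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read or write a run configuration
#'
#' Configurations are plain YAML mirrors of the argument lists of
#' [sim_config()], [ssr_thresholds()] and [class_thresholds()]; the round
#' trip is lossless for scalar fields.
#'
#' @param path YAML path.
#' @return for `read_config`, a named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

#' @rdname read_config
#' @param cfg named list to serialise.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
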