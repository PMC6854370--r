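# Independent oracles used to cross-check the package implementations.
# These deliberately take different routes: the off-target oracle goes
# through Biostrings::matchPattern, the SSR oracle is a position-by-
# position enumeration, and the alignment oracle is a small Gotoh DP.

# --- off-target oracle -----------------------------------------------------

# All loci (both strands) where `spacer` matches within max_mm mismatches
# and the adjacent 3-mer matches the IUPAC PAM pattern. Returns a sorted
# key vector "start:strand:n_mismatch" in forward 0-based coordinates.
oracle_offtargets <- function(spacer, genome_seq, max_mm, pam = "NRG") {
  k <- nchar(spacer)
  np <- nchar(pam)
  pam_chars <- strsplit(pam, "")[[1]]
  allowed <- lapply(pam_chars, function(p)
    strsplit(Biostrings::IUPAC_CODE_MAP[[p]], "")[[1]])
  keys <- character(0)
  L <- nchar(genome_seq)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") genome_seq else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(genome_seq)))
    hits <- Biostrings::matchPattern(Biostrings::DNAString(spacer),
                                     Biostrings::DNAString(s),
                                     max.mismatch = max_mm)
    for (h in seq_along(hits)) {
      st <- BiocGenerics::start(hits)[h]          # 1-based spacer start
      if (st + k + np - 1L > nchar(s)) next
      pam_seq <- strsplit(substr(s, st + k, st + k + np - 1L), "")[[1]]
      if (!all(vapply(seq_len(np),
                      function(i) pam_seq[i] %in% allowed[[i]],
                      logical(1)))) next
      proto <- substr(s, st, st + k - 1L)
      mm <- sum(strsplit(proto, "")[[1]] != strsplit(spacer, "")[[1]])
      start0 <- if (strand == "+") st - 1L else L - (st - 1L + k + np)
      keys <- c(keys, paste(start0, strand, mm, sep = ":"))
    }
  }
  sort(keys)
}

site_keys <- function(sites) {
  sort(paste(sites$start, sites$strand, sites$n_mismatch, sep = ":"))
}

# --- SSR oracle ------------------------------------------------------------

# Position-by-position enumeration of leftmost-maximal tandem runs meeting
# thresholds, followed by the documented overlap rule (longer run wins,
# ties leftmost). Returns data.frame(start, end, composition), 0-based.
oracle_ssrs <- function(seq, min_repeats = c("1" = 10, "2" = 6, "3" = 5,
                                             "4" = 5, "5" = 5, "6" = 5)) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  is_periodic <- function(unit) {
    u <- nchar(unit)
    if (u == 1) return(FALSE)
    for (d in seq_len(u - 1)) {
      if (u %% d == 0 &&
          unit == strrep(substr(unit, 1, d), u / d)) return(TRUE)
    }
    FALSE
  }
  found <- list()
  for (u in 1:6) {
    min_rep <- min_repeats[[as.character(u)]]
    for (s in seq_len(L - u + 1)) {
      # leftmost: cannot shift the periodic frame one base left
      if (s > 1 && s - 1 + u <= L && ch[s - 1] == ch[s - 1 + u]) next
      unit <- substr(seq, s, s + u - 1)
      # cheap early exit: no second unit follows
      if (s + 2 * u - 1 > L ||
          substr(seq, s + u, s + 2 * u - 1) != unit) next
      if (is_periodic(unit)) next
      n <- 2
      while (s + (n + 1) * u - 1 <= L &&
             substr(seq, s + n * u, s + (n + 1) * u - 1) == unit) n <- n + 1
      if (n >= min_rep) {
        found[[length(found) + 1]] <- data.frame(
          start = s - 1, end = s - 1 + n * u,
          composition = sprintf("(%s)%d", unit, n),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(found) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      composition = character(), stringsAsFactors = FALSE))
  }
  runs <- do.call(rbind, found)
  runs <- runs[order(-(runs$end - runs$start), runs$start), , drop = FALSE]
  keep <- rep(FALSE, nrow(runs))
  occ <- data.frame(start = integer(), end = integer())
  for (i in seq_len(nrow(runs))) {
    if (!any(occ$start < runs$end[i] & runs$start[i] < occ$end)) {
      keep[i] <- TRUE
      occ <- rbind(occ, runs[i, c("start", "end")])
    }
  }
  runs <- runs[keep, , drop = FALSE]
  runs[order(runs$start), , drop = FALSE]
}

# --- alignment oracle ------------------------------------------------------

# Gotoh affine-gap semi-global DP (read global, free end gaps on the
# reference). Gap of length l costs open + l * ext. Returns the optimal
# score.
oracle_align_score <- function(read, ref, match = 2, mismatch = -3,
                               open = 8, ext = 1) {
  r <- strsplit(read, "")[[1]]; s <- strsplit(ref, "")[[1]]
  n <- length(r); m <- length(s)
  NEG <- -1e9
  # M[i,j]: best score aligning r[1..i], s[1..j] with r_i aligned to s_j
  # X[i,j]: gap in reference (insertion in read) ending at i
  # Y[i,j]: gap in read (deletion) ending at j
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, ] <- 0                      # free leading reference gap
  for (i in 2:(n + 1)) {
    X[i, 1] <- -(open + (i - 1) * ext)
    for (j in 2:(m + 1)) {
      sub <- if (r[i - 1] == s[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + sub
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
    }
  }
  max(M[n + 1, ], X[n + 1, ])      # free trailing reference gap
}

# --- misc helpers ----------------------------------------------------------

random_seq <- function(n, seed, gc = 0.5) {
  set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

gc_fraction_of <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  mean(ch %in% c("G", "C"))
}
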