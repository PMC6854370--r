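# Specificity pipeline: capture-coverage summary, the paired
# control/edited decision rules (read-depth floor, control-background
# ceiling, microsatellite attribution), the T7 endonuclease I densitometry
# formula, and per-guide-length comparison reports.

#' Site classification thresholds
#'
#' Defaults mirror the capture-sequencing decision rules: sites with fewer
#' than 10 control reads are discarded as low-coverage, and a control
#' (wild-type) editing signal of 1 percent or more marks a site as
#' unstable background rather than a validated off-target.
#'
#' @param min_reads minimum aligned control reads.
#' @param control_max_efficiency control-sample efficiency ceiling
#'   (percent).
#' @param edited_min_efficiency efficiency (percent) the edited sample
#'   must reach for validation; defaults to the same 1 percent.
#' @return object of class `class_thresholds`.
#' @export
class_thresholds <- function(min_reads = 10L, control_max_efficiency = 1.0,
                             edited_min_efficiency = control_max_efficiency) {
  if (min_reads < 1L) stop("min_reads must be >= 1", call. = FALSE)
  if (control_max_efficiency < 0 || control_max_efficiency > 100) {
    stop("control_max_efficiency must be in [0,100]", call. = FALSE)
  }
  structure(list(min_reads = as.integer(min_reads),
                 control_max_efficiency = control_max_efficiency,
                 edited_min_efficiency = edited_min_efficiency),
            class = "class_thresholds")
}

#' Capture-coverage summary
#'
#' Partitions sites into covered (`n_total >= min_reads`), shallow
#' (`1 <= n_total < min_reads`) and uncaptured (`n_total == 0`); the three
#' fractions sum to 1.
#'
#' @param quants list of `site_quant` objects.
#' @param min_reads coverage floor.
#' @return list with counts and fractions per class and `n_sites`.
#' @export
capture_coverage <- function(quants, min_reads = 10L) {
  n <- vapply(quants, function(q) q$n_total, numeric(1))
  n_sites <- length(n)
  covered <- sum(n >= min_reads)
  shallow <- sum(n >= 1L & n < min_reads)
  uncaptured <- sum(n == 0L)
  list(n_sites = n_sites, covered = covered, shallow = shallow,
       uncaptured = uncaptured,
       frac_covered = if (n_sites) covered / n_sites else NA_real_,
       frac_shallow = if (n_sites) shallow / n_sites else NA_real_,
       frac_uncaptured = if (n_sites) uncaptured / n_sites else NA_real_)
}

#' Classify one site from paired control/edited quantifications
#'
#' Rule order: (1) control coverage below `min_reads` gives
#' `low_coverage`; (2) control efficiency at or above
#' `control_max_efficiency` gives `background_unstable` (with the SSR flag
#' recorded as the suspected cause when set); (3) otherwise an edited
#' efficiency at or above `edited_min_efficiency` gives
#' `validated_offtarget`; (4) otherwise `clean`. Background sites are
#' retained and labelled, not dropped, so noise accounting stays
#' reportable.
#'
#' @param control,edited `site_quant` objects for the same site.
#' @param ssr_flag logical microsatellite flag for the site.
#' @param t a [class_thresholds()].
#' @return one-row data.frame: site_id, status, control_reads,
#'   control_efficiency, edited_reads, edited_efficiency, ssr_flag,
#'   suspected_ssr_background.
#' @export
classify_site <- function(control, edited, ssr_flag = FALSE,
                          t = class_thresholds()) {
  if (!identical(control$site_id, edited$site_id)) {
    stop("control and edited quantifications refer to different sites: ",
         control$site_id, " vs ", edited$site_id, call. = FALSE)
  }
  status <- if (control$n_aligned < t$min_reads) {
    "low_coverage"
  } else if (control$efficiency >= t$control_max_efficiency) {
    "background_unstable"
  } else if (edited$efficiency >= t$edited_min_efficiency) {
    "validated_offtarget"
  } else {
    "clean"
  }
  data.frame(site_id = control$site_id, status = status,
             control_reads = control$n_aligned,
             control_efficiency = control$efficiency,
             edited_reads = edited$n_aligned,
             edited_efficiency = edited$efficiency,
             ssr_flag = isTRUE(ssr_flag),
             suspected_ssr_background =
               status == "background_unstable" && isTRUE(ssr_flag),
             stringsAsFactors = FALSE)
}

#' T7 endonuclease I indel percentage
#'
#' Densitometry estimate of the modified fraction from gel band
#' intensities: `100 * (1 - sqrt(1 - (b + c) / (a + b + c)))`, where `a`
#' is the integrated intensity of the uncut PCR product and `b`, `c` those
#' of the two cleavage products. Strictly increasing in the cut fraction
#' and bounded in [0, 100].
#'
#' @param a uncut band intensity (>= 0).
#' @param b,c cut band intensities (>= 0).
#' @return indel percentage in [0, 100]; vectorised.
#' @export
t7e1_indel_pct <- function(a, b, c) {
  if (any(a < 0 | b < 0 | c < 0)) {
    stop("band intensities must be >= 0", call. = FALSE)
  }
  tot <- a + b + c
  if (any(tot == 0)) stop("all band intensities are zero", call. = FALSE)
  100 * (1 - sqrt(1 - (b + c) / tot))
}

#' Run the full specificity pipeline on a fixture bundle
#'
#' Stages: off-target prediction for the selected guide, SSR flagging of
#' the panel sites, amplicon quantification of the paired control/edited
#' read sets, and site classification. Every threshold used is recorded in
#' the returned log.
#'
#' @param fixture a [make_fixture()] bundle (or an equivalent list).
#' @param guide_id id of the guide driving prediction (default the 20-nt
#'   guide).
#' @param thresholds a [class_thresholds()].
#' @param ssr_t an [ssr_thresholds()].
#' @param flank flank used for SSR windows.
#' @param max_mm mismatch ceiling for prediction.
#' @param quants optional precomputed quantifications (as returned in
#'   `$quants` of a previous run on the same fixture) to avoid
#'   re-aligning when only the guide changes.
#' @return list of class `pipeline_report`: `sites` (per-site report),
#'   `status_counts`, `predicted` (predicted off-target table),
#'   `coverage`, `ontarget_efficiency`, `ssr_proportion`, `quants`, `log`.
#' @export
run_pipeline <- function(fixture, guide_id = "g20",
                         thresholds = class_thresholds(),
                         ssr_t = ssr_thresholds(), flank = 100L,
                         max_mm = 5L, quants = NULL) {
  stage <- "offtarget-prediction"
  report <- tryCatch({
    g <- fixture$guides[fixture$guides$id == guide_id, ]
    if (nrow(g) == 0L) stop("no guide with id ", guide_id, call. = FALSE)
    predicted <- find_offtargets(g, fixture$genome, max_mm = max_mm,
                                 pam_pattern = "NRG")

    stage <- "ssr-flagging"
    sites <- flag_sites(fixture$sites, fixture$genome, flank = flank,
                        t = ssr_t)
    ssr_prop <- attr(sites, "ssr_proportion")

    stage <- "quantification"
    if (is.null(quants)) {
      quants <- lapply(seq_len(nrow(sites)), function(i) {
        sid <- sites$site_id[i]
        ref <- fixture$amplicons[[i]]
        list(control = quantify_site(fixture$reads[[sid]]$control, ref),
             edited = quantify_site(fixture$reads[[sid]]$edited, ref))
      })
      names(quants) <- sites$site_id
    }

    stage <- "classification"
    rows <- lapply(seq_len(nrow(sites)), function(i) {
      q <- quants[[sites$site_id[i]]]
      classify_site(q$control, q$edited, ssr_flag = sites$ssr_flag[i],
                    t = thresholds)
    })
    site_report <- do.call(rbind, rows)
    counts <- table(factor(site_report$status,
                           levels = c("validated_offtarget", "clean",
                                      "background_unstable",
                                      "low_coverage")))
    on_idx <- which(fixture$truth$role == "on_target")
    on_eff <- if (length(on_idx) == 1L) {
      site_report$edited_efficiency[
        site_report$site_id == fixture$truth$site_id[on_idx]]
    } else NA_real_
    cov <- capture_coverage(lapply(quants, `[[`, "control"),
                            min_reads = thresholds$min_reads)
    log <- c(sprintf("guide_id=%s spacer_len=%d", guide_id, g$spacer_len),
             sprintf("max_mm=%d pam=NRG flank=%d", max_mm, flank),
             sprintf("min_reads=%d control_max_efficiency=%g edited_min_efficiency=%g",
                     thresholds$min_reads, thresholds$control_max_efficiency,
                     thresholds$edited_min_efficiency),
             sprintf("ssr min_repeats=%s max_interruption=%d",
                     paste(names(ssr_t$min_repeats), ssr_t$min_repeats,
                           sep = ":", collapse = ","),
                     ssr_t$max_interruption))
    structure(list(sites = site_report, status_counts = counts,
                   predicted = predicted, coverage = cov,
                   ontarget_efficiency = on_eff,
                   ssr_proportion = ssr_prop, quants = quants,
                   guide_id = guide_id,
                   spacer_len = g$spacer_len, log = log),
              class = "pipeline_report")
  }, error = function(e) {
    stop("pipeline stage [", stage, "] failed: ", conditionMessage(e),
         call. = FALSE)
  })
  report
}

#' Compare pipeline reports across spacer lengths
#'
#' @param reports named list mapping spacer length (as character) to a
#'   [run_pipeline()] report.
#' @return data.frame with one row per length: spacer_len, n_predicted,
#'   n_validated, n_background, n_clean, n_low_coverage,
#'   ontarget_efficiency, ssr_flagged_fraction. Status counts cover the
#'   whole panel including the on-target site, which lands in
#'   `validated_offtarget` whenever it is genuinely edited.
#' @export
compare_lengths <- function(reports) {
  if (length(reports) < 2L) {
    stop("need reports for at least two spacer lengths", call. = FALSE)
  }
  rows <- lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    sp <- r$ssr_proportion
    frac <- if (!is.null(sp)) sum(sp$n_flagged) / sum(sp$n_total) else NA_real_
    data.frame(spacer_len = as.integer(r$spacer_len),
               n_predicted = nrow(r$predicted),
               n_validated = unname(r$status_counts["validated_offtarget"]),
               n_background = unname(r$status_counts["background_unstable"]),
               n_clean = unname(r$status_counts["clean"]),
               n_low_coverage = unname(r$status_counts["low_coverage"]),
               ontarget_efficiency = r$ontarget_efficiency,
               ssr_flagged_fraction = frac,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$spacer_len), , drop = FALSE]
}

#' Write a pipeline report to disk
#'
#' Emits `sites_report.tsv`, `guide_summary.tsv` and `run_log.txt`.
#'
#' @param report a [run_pipeline()] report.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$sites, file.path(dir, "sites_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- data.frame(guide_id = report$guide_id,
                        spacer_len = report$spacer_len,
                        n_predicted = nrow(report$predicted),
                        t(as.matrix(report$status_counts)),
                        ontarget_efficiency = report$ontarget_efficiency)
  utils::write.table(summary, file.path(dir, "guide_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(report$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
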