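#' Run the full synthetic-mode analysis pipeline
#'
#' Orchestrates generation -> library simulation -> exact mapping ->
#' profiling -> *PHAS* locus scan (21 and 24 nt) -> phasiRNA enumeration and
#' trigger annotation -> target prediction (including dinucleotide-shuffled
#' decoy sRNAs) -> degradome simulation, mapping and target validation ->
#' mutant-dependence classification -> recovery evaluation against the
#' planted truth. All stages are deterministic under the config seed.
#'
#' @param config A [synthetic_config()].
#' @param outdir Optional output directory; when given, all tables (TSV),
#'   loci (GFF3), sequences (FASTA) and a run log are written.
#' @param score_threshold,min_phased_positions Locus-calling thresholds.
#' @param scheme A [penalty_scheme()].
#' @param min_tags,min_fraction Degradome target-calling thresholds.
#' @param fold,fdr_max Dependence thresholds.
#' @param n_decoys Number of dinucleotide-shuffled decoy sRNAs drawn from
#'   the detected 21-nt phasiRNAs.
#' @param write_libraries Also write the simulated libraries (can be large).
#' @return A list (`bundle`) with the reference, truth, profile, loci,
#'   phasiRNAs, candidate and validated-target tables, dependence calls and
#'   a `recovery` report.
#' @export
run_pipeline <- function(config, outdir = NULL, score_threshold = 15,
                         min_phased_positions = 4L, scheme = penalty_scheme(),
                         min_tags = 4, min_fraction = 0.10, fold = 2,
                         fdr_max = 0.05, n_decoys = 50L,
                         write_libraries = TRUE) {
  stopifnot(inherits(config, "synthetic_config"))
  gen <- generate_reference(config)
  wt <- simulate_srna_library(gen, "wildtype")
  mut <- simulate_srna_library(gen, "mutant")
  libs <- c(wt, mut)

  pooled <- collapse_reads(do.call(rbind, libs))
  pooled <- filter_reads(pooled)
  aligned <- align_exact(pooled, gen$reference)
  profile <- build_position_profile(aligned, gen$reference)
  mapped <- unique(aligned$sequence)
  lib_totals <- vapply(libs, function(lb) {
    len <- nchar(lb$sequence)
    sum(lb$count[len >= 18 & len <= 30 & lb$sequence %in% mapped])
  }, numeric(1))

  loci <- rbind(
    scan_phas_loci(profile, 21L, score_threshold, min_phased_positions),
    scan_phas_loci(profile, 24L, score_threshold, min_phased_positions))

  refchar <- as.character(gen$reference)
  phasirnas <- list()
  loci$trigger <- NA_character_
  loci$trigger_score <- NA_real_
  loci$trigger_cleavage1 <- NA_integer_
  loci$trigger_register_consistent <- NA
  for (k in seq_len(nrow(loci))) {
    ph <- enumerate_phasirnas(loci[k, ], profile, gen$reference)
    phasirnas[[length(phasirnas) + 1L]] <- ph
    ann <- annotate_trigger(loci[k, ], refchar[[loci$ref[k]]],
                            config$trigger_sequences, scheme,
                            max_score = scheme$max_score)
    if (!is.null(ann)) {
      loci$trigger[k] <- ann$trigger
      loci$trigger_score[k] <- ann$score
      loci$trigger_cleavage1[k] <- ann$cleavage1
      loci$trigger_register_consistent[k] <- ann$register_consistent
    }
  }
  phasirnas <- if (length(phasirnas)) do.call(rbind, phasirnas) else
    enumerate_phasirnas_empty()
  phasirnas$period <- nchar(phasirnas$sequence)

  # per-library counts and RPM per condition for every detected phasiRNA
  libmat <- vapply(libs, function(lb) {
    v <- setNames(lb$count, lb$sequence)
    cnt <- v[phasirnas$sequence]
    ifelse(is.na(cnt), 0, cnt)
  }, numeric(nrow(phasirnas)))
  libmat <- matrix(libmat, nrow = nrow(phasirnas),
                   dimnames = list(phasirnas$name, names(libs)))
  iwt <- seq_len(config$replicates)
  imut <- config$replicates + seq_len(config$replicates)
  if (nrow(phasirnas)) {
    phasirnas$rpm_wt <- rowMeans(sweep(libmat[, iwt, drop = FALSE], 2L,
                                       lib_totals[iwt], "/") * 1e6)
    phasirnas$rpm_mut <- rowMeans(sweep(libmat[, imut, drop = FALSE], 2L,
                                        lib_totals[imut], "/") * 1e6)
  } else {
    phasirnas$rpm_wt <- numeric(0)
    phasirnas$rpm_mut <- numeric(0)
  }

  # candidate targets: detected phasiRNAs plus shuffled decoys
  uniq <- phasirnas[!duplicated(phasirnas$sequence), , drop = FALSE]
  srnas <- setNames(uniq$sequence, uniq$name)
  set.seed(stage_seed(config$seed, 4L))
  cand21 <- which(uniq$period == 21L)
  nd <- min(n_decoys, length(cand21))
  decoys <- if (nd > 0) {
    src <- sample(cand21, nd)
    # a rare Eulerian walk nearly reproduces its source and would still hit
    # the source's planted site; negative controls must not retain residual
    # complementarity to it, so such shuffles are redrawn
    sh <- vapply(uniq$sequence[src], function(sq) {
      site <- revcomp_chr(sq)
      for (try in 1:20) {
        cand <- shuffle_dinucleotide(sq)
        if (score_duplex(cand, site, scheme)$score > scheme$max_score + 1)
          return(cand)
      }
      NA_character_
    }, character(1), USE.NAMES = FALSE)
    sh <- sh[!is.na(sh)]
    setNames(sh, sprintf("decoy%03d", seq_along(sh)))
  } else character(0)
  candidates <- predict_targets(c(srnas, decoys), gen$reference, scheme)
  candidates$is_decoy <- startsWith(candidates$srna_id, "decoy")

  deg <- simulate_degradome_library(gen)
  truth <- deg$truth
  deg_profiles <- map_tags(deg$tags[, c("sequence", "count")], gen$reference)
  calls <- call_targets(candidates, deg_profiles, min_tags, min_fraction)
  calls$is_decoy <- startsWith(calls$srna_id, "decoy")

  dependence <- if (nrow(phasirnas) && config$replicates >= 2L)
    classify_dependence(libmat[, iwt, drop = FALSE],
                        libmat[, imut, drop = FALSE],
                        lib_totals[iwt], lib_totals[imut], fold, fdr_max)
  else NULL

  recovery <- evaluate_against_truth(loci, calls[!calls$is_decoy, , drop = FALSE],
                                     truth)
  recovery$decoy_validated <- sum(calls$validated & calls$is_decoy)
  recovery$threshold_sensitivity <- locus_threshold_sensitivity(
    profile, truth, thresholds = c(5, 10, 15, 20, 30, 50),
    min_phased_positions = min_phased_positions)
  if (!is.null(dependence))
    recovery$dependence <- list(
      n = nrow(dependence), n_dependent = sum(dependence$dependent),
      fraction_dependent = mean(dependence$dependent))

  bundle <- list(config = config, reference = gen$reference, truth = truth,
                 libraries = libs, lib_totals = lib_totals, profile = profile,
                 loci = loci, phasirnas = phasirnas, candidates = candidates,
                 degradome = deg_profiles, target_calls = calls,
                 dependence = dependence, recovery = recovery)
  if (!is.null(outdir))
    write_bundle(bundle, outdir, score_threshold, min_phased_positions,
                 scheme, min_tags, min_fraction, fold, fdr_max,
                 write_libraries = write_libraries,
                 degradome_tags = deg$tags)
  invisible(bundle)
}

enumerate_phasirnas_empty <- function() {
  data.frame(name = character(0), locus_id = character(0), offset = integer(0),
             strand = character(0), five0 = integer(0), start1 = integer(0),
             end1 = integer(0), sequence = character(0), count = numeric(0),
             stringsAsFactors = FALSE)
}

locus_threshold_sensitivity <- function(profile, truth, thresholds,
                                        min_phased_positions) {
  planted <- truth$loci
  do.call(rbind, lapply(thresholds, function(th) {
    calls <- rbind(scan_phas_loci(profile, 21L, th, min_phased_positions),
                   scan_phas_loci(profile, 24L, th, min_phased_positions))
    m <- match_loci(calls, planted)
    data.frame(score_threshold = th, n_called = nrow(calls),
               recall = m$recall, precision = m$precision)
  }))
}

match_loci <- function(calls, planted) {
  if (!nrow(planted))
    return(list(tp = 0L, fp = nrow(calls), fn = 0L,
                precision = if (nrow(calls)) 0 else 1, recall = 1,
                matched_truth = logical(0)))
  matched_truth <- logical(nrow(planted))
  matched_call <- logical(nrow(calls))
  for (i in seq_len(nrow(planted))) {
    hit <- which(calls$ref == planted$ref[i] &
                   calls$period == planted$period[i] &
                   calls$register == planted$register[i] &
                   calls$start1 <= planted$region_end1[i] &
                   calls$end1 >= planted$region_start1[i])
    if (length(hit)) {
      matched_truth[i] <- TRUE
      matched_call[hit] <- TRUE
    }
  }
  tp <- sum(matched_truth)
  list(tp = tp, fp = sum(!matched_call), fn = sum(!matched_truth),
       precision = if (nrow(calls)) mean(matched_call) else 1,
       recall = mean(matched_truth), matched_truth = matched_truth)
}

#' Evaluate calls against the planted ground truth
#'
#' Loci match a planted locus when reference, period and register agree and
#' the spans overlap; validated targets match on exact (transcript, cleavage
#' site). Precision and recall are reported for both.
#'
#' @param locus_calls Locus table from [scan_phas_loci()].
#' @param target_calls Validated-target call table (decoys excluded).
#' @param truth Ground truth from a `synthetic_reference` (or the updated
#'   truth returned by [simulate_degradome_library()]).
#' @return A `recovery_report` list.
#' @export
evaluate_against_truth <- function(locus_calls, target_calls, truth) {
  if (is.null(truth)) stop("ground truth is required")
  lm <- match_loci(locus_calls, truth$loci)

  planted <- truth$targets[truth$targets$validatable, , drop = FALSE]
  val <- target_calls[which(target_calls$validated), , drop = FALSE]
  key_truth <- paste(planted$transcript, planted$cleavage1)
  key_call <- paste(val$transcript, val$site_1based)
  t_tp <- sum(key_truth %in% key_call)
  t_fp <- sum(!key_call %in% key_truth)
  structure(list(
    loci = list(tp = lm$tp, fp = lm$fp, fn = lm$fn,
                precision = lm$precision, recall = lm$recall,
                n_planted = nrow(truth$loci), n_called = nrow(locus_calls)),
    targets = list(tp = t_tp, fp = t_fp, fn = nrow(planted) - t_tp,
                   precision = if (nrow(val)) 1 - t_fp / nrow(val) else 1,
                   recall = if (nrow(planted)) t_tp / nrow(planted) else 1,
                   n_planted = nrow(planted), n_validated = nrow(val))),
    class = "recovery_report")
}

write_bundle <- function(bundle, outdir, score_threshold, min_phased_positions,
                         scheme, min_tags, min_fraction, fold, fdr_max,
                         write_libraries = TRUE, degradome_tags = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(outdir, ...)
  Biostrings::writeXStringSet(bundle$reference, fp("reference.fa"))
  write_config(bundle$config, fp("config.yaml"))
  write_tsv(bundle$truth$loci, fp("truth_loci.tsv"))
  write_tsv(bundle$truth$phasirnas, fp("truth_phasirnas.tsv"))
  write_tsv(bundle$truth$targets, fp("truth_targets.tsv"))
  write_tsv(bundle$loci, fp("loci.tsv"))
  write_loci_gff3(bundle$loci, fp("loci.gff3"))
  write_tsv(bundle$phasirnas, fp("phasirnas.tsv"))
  if (nrow(bundle$phasirnas)) {
    ss <- Biostrings::DNAStringSet(setNames(bundle$phasirnas$sequence,
                                            bundle$phasirnas$name))
    Biostrings::writeXStringSet(ss, fp("phasirnas.fa"))
  }
  write_tsv(bundle$candidates, fp("candidate_targets.tsv"))
  write_tsv(bundle$target_calls, fp("target_calls.tsv"))
  if (!is.null(bundle$dependence))
    write_tsv(bundle$dependence, fp("dependence.tsv"))
  rec <- bundle$recovery
  write_tsv(data.frame(
    metric = c("locus_tp", "locus_fp", "locus_fn", "locus_precision",
               "locus_recall", "target_tp", "target_fp", "target_fn",
               "target_precision", "target_recall", "decoy_validated"),
    value = c(rec$loci$tp, rec$loci$fp, rec$loci$fn, rec$loci$precision,
              rec$loci$recall, rec$targets$tp, rec$targets$fp,
              rec$targets$fn, rec$targets$precision, rec$targets$recall,
              rec$decoy_validated)), fp("recovery.tsv"))
  write_tsv(rec$threshold_sensitivity, fp("threshold_sensitivity.tsv"))
  if (write_libraries) {
    for (nm in names(bundle$libraries))
      write_srna_fasta(bundle$libraries[[nm]], fp(paste0("srna_", nm, ".fa")))
    if (!is.null(degradome_tags))
      write_tsv(degradome_tags, fp("degradome_tags.tsv"))
  }
  log <- c("phasir run log",
           sprintf("package_version: %s", as.character(packageVersion("phasir"))),
           sprintf("seed: %d", bundle$config$seed),
           sprintf("phase_score_threshold: %g", score_threshold),
           sprintf("min_phased_positions: %d", as.integer(min_phased_positions)),
           sprintf("duplex_max_score: %g", scheme$max_score),
           sprintf("degradome_min_tags: %g", min_tags),
           sprintf("degradome_min_site_fraction: %g", min_fraction),
           sprintf("dependence_fold: %g", fold),
           sprintf("dependence_fdr: %g", fdr_max))
  writeLines(log, fp("run_log.txt"))
  invisible(outdir)
}
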