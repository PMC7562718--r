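#' Map degradome tags to transcripts
#'
#' Tags are either pre-placed records (`transcript`, `pos1`, `count`) or raw
#' tag sequences (`sequence`, `count`), in which case each tag is placed at
#' every exact match on the forward strand of the transcripts (degradome
#' tags are sense to the mRNA; antisense matches are ignored). Tag 5' ends
#' define the profile positions. Multi-matching tags contribute to every
#' match under `"count-all"`, or 1/n of their count under `"fractional"`.
#'
#' @param tags Data frame of tag records or tag sequences.
#' @param transcriptome Named [Biostrings::DNAStringSet] (or named character).
#' @param policy Multi-match policy.
#' @param min_tag_len Tags shorter than this are rejected (MmeI-type
#'   libraries yield ~20-nt tags).
#' @return A `degradome_profile_set`: list of per-transcript profiles
#'   (`pos1`, `count`, `total`, `length`), plus `library_total` and an
#'   `unmapped` count.
#' @export
map_tags <- function(tags, transcriptome, policy = c("count-all", "fractional"),
                     min_tag_len = 15L) {
  policy <- match.arg(policy)
  if (is.character(transcriptome))
    transcriptome <- Biostrings::DNAStringSet(transcriptome)
  lens <- setNames(Biostrings::width(transcriptome), names(transcriptome))
  unmapped <- 0
  if (all(c("transcript", "pos1", "count") %in% names(tags))) {
    placed <- tags[tags$transcript %in% names(lens), , drop = FALSE]
    unmapped <- sum(tags$count) - sum(placed$count)
    bad <- placed$pos1 < 1L | placed$pos1 > lens[placed$transcript]
    if (any(bad)) stop("tag position outside its transcript")
  } else if (all(c("sequence", "count") %in% names(tags))) {
    tags$sequence <- normalize_seq(tags$sequence)
    hasN <- grepl("[^ACGT]", tags$sequence)
    if (any(hasN)) {
      warning(sprintf("skipping %d tag(s) with ambiguity codes", sum(hasN)))
      tags <- tags[!hasN, , drop = FALSE]
    }
    short <- nchar(tags$sequence) < min_tag_len
    if (any(short)) {
      warning(sprintf("skipping %d tag(s) shorter than %d nt", sum(short), min_tag_len))
      tags <- tags[!short, , drop = FALSE]
    }
    aln <- align_exact(tags, transcriptome)
    aln <- aln[aln$strand == "+", , drop = FALSE]
    # re-derive placement multiplicity on the forward strand only
    nplace <- table(aln$sequence)
    placed <- data.frame(transcript = aln$ref, pos1 = aln$start0 + 1L,
                         count = if (policy == "count-all") aln$count
                           else aln$count / as.numeric(nplace[aln$sequence]),
                         stringsAsFactors = FALSE)
    unmapped <- sum(tags$count[!tags$sequence %in% aln$sequence])
  } else stop("tags must carry (transcript, pos1, count) or (sequence, count)")

  profiles <- list()
  for (tx in names(lens)) {
    p <- placed[placed$transcript == tx, , drop = FALSE]
    if (nrow(p)) {
      agg <- rowsum(as.numeric(p$count), group = p$pos1)
      pos1 <- as.integer(rownames(agg))
      ord <- order(pos1)
      profiles[[tx]] <- list(transcript = tx, pos1 = pos1[ord],
                             count = as.numeric(agg[ord, 1L]),
                             total = sum(agg[, 1L]), length = lens[[tx]])
    } else {
      profiles[[tx]] <- list(transcript = tx, pos1 = integer(0),
                             count = numeric(0), total = 0, length = lens[[tx]])
    }
    class(profiles[[tx]]) <- "degradome_profile"
  }
  structure(list(profiles = profiles, transcript_lengths = lens,
                 library_total = sum(placed$count), unmapped = unmapped),
            class = "degradome_profile_set")
}

#' Cleavage-site category (0-4)
#'
#' Classifies the degradome signal at a position relative to the
#' transcript's tag profile: 4 = a single tag; 3 = more than one but at most
#' the average; 2 = above the average but below the maximum; 1 = equal to
#' the maximum which is shared by more than one site; 0 = the unique maximum
#' with more than one tag. The average is computed over occupied positions
#' by default (`average = "all"` divides by every position of the
#' transcript instead).
#'
#' @param profile A `degradome_profile` (one transcript).
#' @param position 1-based transcript coordinate; must carry at least 1 tag.
#' @param average Averaging convention.
#' @return Integer category in 0..4.
#' @export
categorize_site <- function(profile, position, average = c("occupied", "all")) {
  average <- match.arg(average)
  idx <- match(position, profile$pos1)
  t <- if (is.na(idx)) 0 else profile$count[idx]
  if (t <= 0) stop("no degradome tags at the queried position")
  if (t == 1) return(4L)
  mx <- max(profile$count)
  nmax <- sum(profile$count == mx)
  avg <- if (average == "occupied") mean(profile$count)
    else profile$total / profile$length
  if (t == mx) {
    if (nmax == 1L) return(0L) else return(1L)
  }
  if (t > avg) return(2L)
  3L
}

#' Validate one candidate cleavage site against a degradome profile
#'
#' Reads the tag count at exactly the predicted cleavage coordinate (the
#' target position paired with sRNA nucleotide 10), assigns the category,
#' and applies the target-calling filter: validated iff category 0 or 1,
#' at least `min_tags` tags at the site, and the site holding at least
#' `min_fraction` of the transcript's total degradome tags (both bounds
#' inclusive).
#'
#' @param candidate List or one-row data frame with at least `cleavage1`
#'   (and optionally `srna_id`, `transcript`, `score`).
#' @param profile A `degradome_profile`.
#' @param min_tags Minimum tags at the site.
#' @param min_fraction Minimum site fraction of the transcript total.
#' @param library_total Optional degradome library size for RP10M.
#' @return A one-row `data.frame` cleavage call with `tags_at_site`,
#'   `rp10m`, `category`, `site_fraction`, `validated`.
#' @export
validate_cleavage <- function(candidate, profile, min_tags = 4,
                              min_fraction = 0.10, library_total = NULL) {
  site <- candidate$cleavage1
  tags <- 0
  if (!is.na(site) && site >= 1L && site <= profile$length) {
    idx <- match(site, profile$pos1)
    if (!is.na(idx)) tags <- profile$count[idx]
  }
  category <- if (tags > 0) categorize_site(profile, site) else NA_integer_
  frac <- if (profile$total > 0) tags / profile$total else 0
  data.frame(
    srna_id = if (!is.null(candidate$srna_id)) candidate$srna_id else NA_character_,
    transcript = profile$transcript,
    site_1based = if (is.na(site)) NA_integer_ else as.integer(site),
    duplex_score = if (!is.null(candidate$score)) candidate$score else NA_real_,
    tags_at_site = tags,
    rp10m = if (!is.null(library_total) && library_total > 0)
      normalize_rp10m(tags, library_total) else NA_real_,
    category = category,
    site_fraction = frac,
    validated = !is.na(category) && category %in% c(0L, 1L) &&
      tags >= min_tags && frac >= min_fraction,
    stringsAsFactors = FALSE)
}

#' Call validated sRNA targets
#'
#' Applies [validate_cleavage()] to every candidate row and returns the full
#' call table sorted by transcript then site.
#'
#' @param candidates Candidate table from [predict_targets()].
#' @param profile_set A `degradome_profile_set` from [map_tags()].
#' @param min_tags,min_fraction Target-calling thresholds.
#' @return Data frame of cleavage calls (one per candidate with a profile).
#' @export
call_targets <- function(candidates, profile_set, min_tags = 4,
                         min_fraction = 0.10) {
  empty <- validate_cleavage(list(cleavage1 = NA_integer_),
                             structure(list(transcript = NA_character_,
                                            pos1 = integer(0), count = numeric(0),
                                            total = 0, length = 0L),
                                       class = "degradome_profile"))[0, ]
  if (!nrow(candidates)) return(empty)
  rows <- lapply(seq_len(nrow(candidates)), function(k) {
    cand <- candidates[k, ]
    prof <- profile_set$profiles[[cand$transcript]]
    if (is.null(prof)) return(NULL)
    validate_cleavage(cand, prof, min_tags, min_fraction,
                      library_total = profile_set$library_total)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$transcript, out$site_1based, out$srna_id,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export one transcript's degradome profile for t-plots
#'
#' @param profile_set A `degradome_profile_set`.
#' @param transcript Transcript id.
#' @return `data.frame(transcript, pos1, count, rp10m)`.
#' @export
degradome_tplot_table <- function(profile_set, transcript) {
  p <- profile_set$profiles[[transcript]]
  if (is.null(p)) stop("unknown transcript: ", transcript)
  data.frame(transcript = transcript, pos1 = p$pos1, count = p$count,
             rp10m = if (profile_set$library_total > 0)
               normalize_rp10m(p$count, profile_set$library_total)
             else rep(0, length(p$pos1)),
             stringsAsFactors = FALSE)
}
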