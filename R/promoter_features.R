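# Comparative genomic/epigenomic feature statistics for promoter sets: CGI
# overlap, G4 coverage, conservation sums, TFBS density/diversity, ChIP peak
# counts, CAGE directionality, chromatin-state fold enrichment.

#' Per-region feature statistics
#'
#' Computes, per region: `cgi` -> any-overlap boolean; `g4` -> percent of
#' region base pairs covered by (merged) annotations; `conservation_base` ->
#' sum of per-base scores over the region (score columns on wider tiles are
#' weighted by overlap width); `chip_peak` -> count of distinct (TF, peak)
#' pairs and distinct biotypes.
#'
#' @param regions BED-convention data.frame with `region_id`.
#' @param track BED-convention data.frame; `conservation_base` needs a
#'   `score` column, `chip_peak` needs `tf` and `biotype`.
#' @param kind one of `"cgi"`, `"g4"`, `"conservation_base"`, `"chip_peak"`.
#' @return data.frame keyed by `region_id` with the per-kind statistic.
#' @export
region_feature_stats <- function(regions, track,
                                 kind = c("cgi", "g4", "conservation_base",
                                          "chip_peak")) {
  kind <- match.arg(kind)
  stopifnot("region_id" %in% names(regions))
  out <- data.frame(region_id = regions$region_id, stringsAsFactors = FALSE)
  ov <- overlap_pairs(regions, track)
  if (kind == "cgi") {
    out$has_cgi <- seq_len(nrow(regions)) %in% ov$a_idx
  } else if (kind == "g4") {
    len <- regions$end - regions$start
    pct <- numeric(nrow(regions))
    if (nrow(ov) > 0) {
      # merge overlapping annotations within each region before measuring
      for (i in unique(ov$a_idx)) {
        sub <- ov[ov$a_idx == i, ]
        pieces <- data.frame(
          chrom = regions$chrom[i],
          start = pmax(track$start[sub$b_idx], regions$start[i]),
          end = pmin(track$end[sub$b_idx], regions$end[i])
        )
        pct[i] <- covered_bp(pieces) / len[i] * 100
      }
    }
    out$g4_percent <- pct
  } else if (kind == "conservation_base") {
    stopifnot("score" %in% names(track))
    s <- numeric(nrow(regions))
    if (nrow(ov) > 0) {
      w_start <- pmax(track$start[ov$b_idx], regions$start[ov$a_idx])
      w_end <- pmin(track$end[ov$b_idx], regions$end[ov$a_idx])
      contrib <- track$score[ov$b_idx] * (w_end - w_start)
      agg <- tapply(contrib, ov$a_idx, sum)
      s[as.integer(names(agg))] <- agg
    }
    out$conservation_sum <- s
  } else {
    stopifnot(all(c("tf", "biotype") %in% names(track)))
    key <- paste(track$tf, track$chrom, track$start, track$end)
    dedup <- !duplicated(key)
    ov <- overlap_pairs(regions, track[dedup, , drop = FALSE])
    tr <- track[dedup, , drop = FALSE]
    n_peaks <- integer(nrow(regions))
    n_biotypes <- integer(nrow(regions))
    if (nrow(ov) > 0) {
      np <- tapply(ov$b_idx, ov$a_idx, length)
      nb <- tapply(tr$biotype[ov$b_idx], ov$a_idx,
                   function(x) length(unique(x)))
      n_peaks[as.integer(names(np))] <- np
      n_biotypes[as.integer(names(nb))] <- nb
    }
    out$n_peaks <- n_peaks
    out$n_biotypes <- n_biotypes
  }
  out
}

#' TF binding-site density and family diversity per region
#'
#' Sites with score <= `min_score` (strict filter, P-value-derived) are
#' dropped; density is the number of retained sites overlapping the region,
#' diversity the number of distinct TF families among them.
#'
#' @param regions BED-convention data.frame with `region_id`.
#' @param tfbs_track BED-convention data.frame with `score` and `family`.
#' @param min_score score threshold, strict (default 400).
#' @return data.frame (`region_id`, `density`, `diversity`).
#' @export
tfbs_density_diversity <- function(regions, tfbs_track, min_score = 400) {
  stopifnot(all(c("score", "family") %in% names(tfbs_track)))
  keep <- tfbs_track[tfbs_track$score > min_score, , drop = FALSE]
  out <- data.frame(region_id = regions$region_id,
                    density = 0L, diversity = 0L, stringsAsFactors = FALSE)
  if (nrow(keep) == 0 || nrow(regions) == 0) return(out)
  ov <- overlap_pairs(regions, keep)
  if (nrow(ov) > 0) {
    dn <- tapply(ov$b_idx, ov$a_idx, length)
    dv <- tapply(keep$family[ov$b_idx], ov$a_idx,
                 function(x) length(unique(x)))
    out$density[as.integer(names(dn))] <- dn
    out$diversity[as.integer(names(dv))] <- dv
  }
  out
}

#' CAGE directionality and strand-partitioned signal around the TSS
#'
#' Each promoter is widened to TSS +/- `flank` bp. A promoter is `divergent`
#' iff both a sense-strand and an antisense-strand CAGE peak overlap the
#' window (orientation relative to the gene strand), `unidirectional` iff
#' sense only, otherwise `unclassified`. Forward/reverse signal is the
#' summed signal (score x overlap bp) on the sense and antisense strands.
#'
#' @param promoters promoter table from [define_promoters()] (`tss`,
#'   `strand`, `chrom`, `promoter_id`).
#' @param cage_peaks BED-convention data.frame with `strand`.
#' @param cage_signal BED-convention data.frame with `strand` and `score`
#'   (per-bp signal); optional.
#' @param flank half-window in bp (default 500).
#' @return data.frame (`promoter_id`, `class`, `forward_signal`,
#'   `reverse_signal`).
#' @export
cage_directionality <- function(promoters, cage_peaks, cage_signal = NULL,
                                flank = 500L) {
  if (any(is.na(promoters$strand) | !(promoters$strand %in% c("+", "-")))) {
    stop("promoter without gene strand")
  }
  win <- data.frame(chrom = promoters$chrom,
                    start = pmax(0L, promoters$tss - flank),
                    end = promoters$tss + flank)
  sense_hit <- antisense_hit <- logical(nrow(promoters))
  ov <- overlap_pairs(win, cage_peaks)
  if (nrow(ov) > 0) {
    sense <- cage_peaks$strand[ov$b_idx] == promoters$strand[ov$a_idx]
    sense_hit[unique(ov$a_idx[sense])] <- TRUE
    antisense_hit[unique(ov$a_idx[!sense])] <- TRUE
  }
  class <- ifelse(sense_hit & antisense_hit, "divergent",
                  ifelse(sense_hit, "unidirectional", "unclassified"))
  fwd <- rev <- numeric(nrow(promoters))
  if (!is.null(cage_signal) && nrow(cage_signal) > 0) {
    ovs <- overlap_pairs(win, cage_signal)
    if (nrow(ovs) > 0) {
      w <- pmin(cage_signal$end[ovs$b_idx], win$end[ovs$a_idx]) -
        pmax(cage_signal$start[ovs$b_idx], win$start[ovs$a_idx])
      contrib <- cage_signal$score[ovs$b_idx] * w
      sense <- cage_signal$strand[ovs$b_idx] == promoters$strand[ovs$a_idx]
      f <- tapply(contrib[sense], ovs$a_idx[sense], sum)
      r <- tapply(contrib[!sense], ovs$a_idx[!sense], sum)
      fwd[as.integer(names(f))] <- f
      rev[as.integer(names(r))] <- r
    }
  }
  data.frame(promoter_id = promoters$promoter_id, class = class,
             forward_signal = fwd, reverse_signal = rev,
             stringsAsFactors = FALSE)
}

#' Chromatin-state fold enrichment of a region set
#'
#' For each state s: fold(s) = [overlap_bp(s, regions) / total_bp(s)] /
#' [bp(regions) / genome_size]. States with zero genomic bp are skipped with
#' a warning.
#'
#' @param regions BED-convention data.frame.
#' @param state_segments BED-convention data.frame with a `state` column;
#'   segments of one state must not overlap each other.
#' @param genome_size total genome size in bp.
#' @return data.frame (`state`, `state_bp`, `overlap_bp`, `fold`).
#' @export
state_fold_enrichment <- function(regions, state_segments, genome_size) {
  region_bp <- covered_bp(regions)
  states <- sort(unique(state_segments$state))
  rows <- lapply(states, function(s) {
    seg <- state_segments[state_segments$state == s, , drop = FALSE]
    total <- sum(seg$end - seg$start)
    if (total == 0) {
      warning("state ", s, " has zero genomic bp; skipped")
      return(NULL)
    }
    ov <- overlap_pairs(regions, seg)
    obp <- if (nrow(ov) == 0) 0 else sum(ov$overlap_bp)
    data.frame(state = s, state_bp = total, overlap_bp = obp,
               fold = (obp / total) / (region_bp / genome_size),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Log2 ratio of state fold enrichments between two region sets
#'
#' @param fold_a,fold_b data.frames from [state_fold_enrichment()].
#' @return data.frame (`state`, `fold_a`, `fold_b`, `log2_ratio`).
#' @export
state_fold_log2ratio <- function(fold_a, fold_b) {
  m <- merge(fold_a[, c("state", "fold")], fold_b[, c("state", "fold")],
             by = "state", suffixes = c("_a", "_b"))
  m$log2_ratio <- log2(m$fold_a / m$fold_b)
  m
}
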