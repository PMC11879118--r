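# Promoter definition, Epromoter calling (>=50%-of-either overlap with active
# enhancers), >=1-nt merging, cross-dataset sharing, distal-enhancer set.

#' Define transcript-level promoters from a gene annotation
#'
#' The promoter of a coding transcript is the window upstream of its TSS:
#' `[tss - window, tss)` on the plus strand, `[tss, tss + window)` on the
#' minus strand, clipped at chromosome bounds. Duplicate (region, gene)
#' records arising from transcripts sharing a TSS are collapsed.
#'
#' @param annotation data.frame with columns `gene_id`, `transcript_id`,
#'   `chrom`, `strand` (`"+"`/`"-"`), `tss` (0-based coordinate).
#' @param window promoter length in bp (default 500).
#' @param chrom_sizes optional named vector for boundary clipping.
#' @return data.frame of promoter records: `promoter_id`, `gene_id`,
#'   `transcript_id`, `chrom`, `start`, `end`, `strand`, `tss`.
#' @export
define_promoters <- function(annotation, window = 500L, chrom_sizes = NULL) {
  need <- c("gene_id", "transcript_id", "chrom", "strand", "tss")
  stopifnot(all(need %in% names(annotation)))
  bad <- is.na(annotation$strand) | !(annotation$strand %in% c("+", "-"))
  if (any(bad)) {
    stop(sprintf("transcript %s has no usable strand",
                 annotation$transcript_id[which(bad)[1]]))
  }
  plus <- annotation$strand == "+"
  start <- ifelse(plus, annotation$tss - window, annotation$tss)
  end <- ifelse(plus, annotation$tss, annotation$tss + window)
  start <- pmax(0L, as.integer(start))
  if (!is.null(chrom_sizes)) {
    end <- pmin(unname(chrom_sizes[annotation$chrom]), as.integer(end))
  }
  pr <- data.frame(
    gene_id = annotation$gene_id,
    transcript_id = annotation$transcript_id,
    chrom = annotation$chrom,
    start = as.integer(start),
    end = as.integer(end),
    strand = annotation$strand,
    tss = annotation$tss,
    stringsAsFactors = FALSE
  )
  dup <- duplicated(pr[, c("gene_id", "chrom", "start", "end")])
  pr <- pr[!dup, , drop = FALSE]
  pr <- pr[order(pr$chrom, pr$start, pr$gene_id), , drop = FALSE]
  pr$promoter_id <- sprintf("%s|%s:%d-%d", pr$gene_id, pr$chrom, pr$start, pr$end)
  rownames(pr) <- NULL
  pr[, c("promoter_id", "gene_id", "transcript_id", "chrom", "start", "end",
         "strand", "tss")]
}

#' Flag promoters overlapping active enhancers (either-fraction rule)
#'
#' A promoter is an Epromoter iff some enhancer overlap covers at least
#' `min_frac` of the promoter or (with `either = TRUE`, the
#' `bedtools intersect -f 0.5 -F 0.5 -e` semantics) at least `min_frac` of
#' the enhancer.
#'
#' @param promoters data.frame from [define_promoters()].
#' @param enhancers BED-convention data.frame of active enhancer intervals.
#' @param min_frac minimum overlap fraction (default 0.5).
#' @param either apply the fraction to either feature (default) rather than
#'   to the promoter alone.
#' @return `promoters` with a logical `is_epromoter` column.
#' @export
call_epromoters <- function(promoters, enhancers, min_frac = 0.5,
                            either = TRUE) {
  promoters$is_epromoter <- FALSE
  if (nrow(promoters) == 0 || is.null(enhancers) || nrow(enhancers) == 0) {
    return(promoters)
  }
  ov <- overlap_pairs(promoters, enhancers)
  if (nrow(ov) > 0) {
    p_len <- promoters$end[ov$a_idx] - promoters$start[ov$a_idx]
    e_len <- enhancers$end[ov$b_idx] - enhancers$start[ov$b_idx]
    hit <- ov$overlap_bp >= min_frac * p_len
    if (either) hit <- hit | ov$overlap_bp >= min_frac * e_len
    promoters$is_epromoter[unique(ov$a_idx[hit])] <- TRUE
  }
  promoters
}

#' Merge flagged Epromoter regions overlapping by at least 1 nt
#'
#' Single-linkage merge of the flagged promoter regions; abutting regions
#' stay separate. Gene and dataset membership is unioned per merged region.
#'
#' @param flagged data.frame of promoter records with `is_epromoter`; only
#'   flagged rows are merged. An optional `dataset` column records provenance.
#' @return List of class `epromoter_set`: `regions` (data.frame `merged_id`,
#'   `chrom`, `start`, `end`, `n_members`), `members` (data.frame
#'   `promoter_id`, `gene_id`, `merged_id`, and `dataset` if present).
#' @export
merge_epromoters <- function(flagged) {
  if ("is_epromoter" %in% names(flagged)) {
    flagged <- flagged[flagged$is_epromoter, , drop = FALSE]
  }
  if (nrow(flagged) == 0) {
    return(structure(list(
      regions = data.frame(merged_id = character(), chrom = character(),
                           start = integer(), end = integer(),
                           n_members = integer()),
      members = data.frame(promoter_id = character(), gene_id = character(),
                           merged_id = character())
    ), class = "epromoter_set"))
  }
  merged <- merge_overlapping(flagged)
  merged_id <- sprintf("EPM_%05d", seq_len(nrow(merged)))
  member_rows <- lapply(seq_len(nrow(merged)), function(i) {
    m <- flagged[merged$members[[i]], , drop = FALSE]
    out <- data.frame(promoter_id = m$promoter_id, gene_id = m$gene_id,
                      merged_id = merged_id[i], stringsAsFactors = FALSE)
    if ("dataset" %in% names(m)) out$dataset <- m$dataset
    out
  })
  regions <- data.frame(
    merged_id = merged_id, chrom = merged$chrom,
    start = merged$start, end = merged$end,
    n_members = lengths(merged$members), stringsAsFactors = FALSE
  )
  structure(list(regions = regions, members = do.call(rbind, member_rows)),
            class = "epromoter_set")
}

#' Cross-dataset Epromoter sharing
#'
#' Unions the merged Epromoter regions of all datasets (>= 1 nt merge), and
#' counts, per union region, how many datasets contain an overlapping
#' Epromoter.
#'
#' @param per_dataset named list of `epromoter_set`s (>= 2 datasets).
#' @return List: `per_region` (union regions with `n_datasets`), `summary`
#'   (data.frame `n_datasets`, `n_regions`, `fraction`), and
#'   `fraction_shared` = fraction of union regions present in >= 2 datasets.
#' @export
sharing_stats <- function(per_dataset) {
  stopifnot(length(per_dataset) >= 2, !is.null(names(per_dataset)))
  all_regions <- do.call(rbind, lapply(names(per_dataset), function(d) {
    r <- per_dataset[[d]]$regions
    if (nrow(r) == 0) return(NULL)
    data.frame(chrom = r$chrom, start = r$start, end = r$end, dataset = d)
  }))
  if (is.null(all_regions) || nrow(all_regions) == 0) {
    return(list(per_region = data.frame(), summary = data.frame(),
                fraction_shared = NA_real_))
  }
  union <- merge_overlapping(all_regions)
  n_datasets <- vapply(union$members, function(idx) {
    length(unique(all_regions$dataset[idx]))
  }, integer(1))
  per_region <- data.frame(chrom = union$chrom, start = union$start,
                           end = union$end, n_datasets = n_datasets)
  tab <- table(n_datasets)
  summary <- data.frame(n_datasets = as.integer(names(tab)),
                        n_regions = as.integer(tab),
                        fraction = as.numeric(tab) / nrow(per_region))
  list(per_region = per_region, summary = summary,
       fraction_shared = mean(n_datasets >= 2))
}

#' Derive the distal-enhancer comparison set
#'
#' STARR enhancers overlapping any Epromoter are excluded; the remainder is
#' intersected with reference (e.g. ENCODE candidate) enhancers at the
#' >=50%-of-either rule, and the central 500 bp of each retained reference
#' enhancer is emitted (whole region if shorter than 500 bp).
#'
#' @param starr_enhancers,reference_enhancers,epromoters BED-convention
#'   data.frames (`epromoters` may be an `epromoter_set`).
#' @param center_bp emitted width (default 500).
#' @param min_frac overlap fraction for the STARR/reference intersection.
#' @return BED-convention data.frame of distal enhancers.
#' @export
define_distal_enhancers <- function(starr_enhancers, reference_enhancers,
                                    epromoters, center_bp = 500L,
                                    min_frac = 0.5) {
  if (inherits(epromoters, "epromoter_set")) epromoters <- epromoters$regions
  keep <- rep(TRUE, nrow(starr_enhancers))
  if (nrow(epromoters) > 0 && nrow(starr_enhancers) > 0) {
    ov <- overlap_pairs(starr_enhancers, epromoters)
    keep[unique(ov$a_idx)] <- FALSE
  }
  cand <- starr_enhancers[keep, , drop = FALSE]
  if (nrow(cand) == 0 || nrow(reference_enhancers) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  }
  ov <- overlap_pairs(cand, reference_enhancers)
  c_len <- cand$end[ov$a_idx] - cand$start[ov$a_idx]
  r_len <- reference_enhancers$end[ov$b_idx] - reference_enhancers$start[ov$b_idx]
  hit <- ov$overlap_bp >= min_frac * c_len | ov$overlap_bp >= min_frac * r_len
  ref_idx <- sort(unique(ov$b_idx[hit]))
  ref <- reference_enhancers[ref_idx, , drop = FALSE]
  len <- ref$end - ref$start
  mid <- (ref$start + ref$end) %/% 2L
  short <- len < center_bp
  out <- data.frame(
    chrom = ref$chrom,
    start = ifelse(short, ref$start, mid - center_bp %/% 2L),
    end = ifelse(short, ref$end, mid + center_bp %/% 2L)
  )
  rownames(out) <- NULL
  out
}
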