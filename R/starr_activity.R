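# STARR-seq / CapSTARR-seq activity quantification: fragment extension, FPKM,
# fold-change, knee-point thresholding, replicate merging, allelic counts.

#' Create a fragment set
#'
#' A fragment set bundles the mapped fragments of one sequencing library
#' (input = non-transfected plasmid library, output = transfected/transcribed
#' library) with its total mapped read count, which is the FPKM denominator.
#'
#' @param fragments BED-convention data.frame (`chrom`, `start`, `end`,
#'   optional `strand`, optional `allele`).
#' @param library one of `"input"` or `"output"`.
#' @param replicate replicate index (1-based).
#' @param condition free-text condition label (e.g. `"NS"`, `"IFNa"`).
#' @param total_mapped total mapped reads of the library; defaults to the
#'   number of fragments. Must be at least the number of fragments (captured
#'   fragments are a subset of all mapped reads).
#' @return An object of class `fragment_set`.
#' @export
fragment_set <- function(fragments, library = c("input", "output"),
                         replicate = 1L, condition = "NS",
                         total_mapped = nrow(fragments)) {
  library <- match.arg(library)
  stopifnot(nrow(fragments) > 0, total_mapped >= nrow(fragments))
  ord <- order(fragments$chrom, fragments$start)
  structure(
    list(fragments = fragments[ord, , drop = FALSE],
         library = library, replicate = as.integer(replicate),
         condition = condition, total_mapped = as.numeric(total_mapped)),
    class = "fragment_set"
  )
}

#' Extend fragments to a fixed length from their 5' start
#'
#' Sequenced read intervals are extended to the average captured-fragment
#' size (default 314 nt) before coverage is computed. Extension runs from the
#' 5' end in the fragment's strand direction (unstranded fragments are
#' treated as plus strand) and is clipped at chromosome bounds.
#'
#' @param fragments a `fragment_set` or a bare BED-convention data.frame.
#' @param target_length extension length in nt.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @return Same type as `fragments`, with each interval of width
#'   `target_length` (shorter only where clipped).
#' @export
extend_fragments <- function(fragments, target_length = 314L, chrom_sizes) {
  fs <- if (inherits(fragments, "fragment_set")) fragments$fragments else fragments
  stopifnot(target_length > 0, !missing(chrom_sizes))
  unknown <- !(fs$chrom %in% names(chrom_sizes))
  if (any(unknown)) {
    i <- which(unknown)[1]
    stop(sprintf("fragment %s:%d-%d on unknown chromosome",
                 fs$chrom[i], fs$start[i], fs$end[i]))
  }
  strand <- if ("strand" %in% names(fs)) fs$strand else rep("+", nrow(fs))
  strand[is.na(strand) | strand == "*"] <- "+"
  minus <- strand == "-"
  new_start <- ifelse(minus, fs$end - target_length, fs$start)
  new_end <- ifelse(minus, fs$end, fs$start + target_length)
  lim <- unname(chrom_sizes[fs$chrom])
  fs$start <- pmax(0L, as.integer(new_start))
  fs$end <- pmin(lim, as.integer(new_end))
  if (inherits(fragments, "fragment_set")) {
    fragments$fragments <- fs
    fragments
  } else {
    fs
  }
}

#' Fragments per kilobase per million mapped reads
#'
#' A fragment counts towards a region if it overlaps it by at least 1 bp
#' (`bedtools coverage` membership).
#'
#' @param regions BED-convention data.frame with a `region_id` column.
#' @param fragments a `fragment_set`.
#' @return Named numeric vector of FPKM, one entry per region.
#' @export
compute_fpkm <- function(regions, fragments) {
  stopifnot(inherits(fragments, "fragment_set"),
            fragments$total_mapped > 0,
            "region_id" %in% names(regions))
  len <- regions$end - regions$start
  if (any(len <= 0)) stop("zero-length region")
  n <- GenomicRanges::countOverlaps(as_granges(regions),
                                    as_granges(fragments$fragments),
                                    minoverlap = 1L)
  fpkm <- n / ((len / 1000) * (fragments$total_mapped / 1e6))
  stats::setNames(fpkm, regions$region_id)
}

#' Knee of a ranked descending curve
#'
#' Both axes (rank and value) are min-max normalised, and the knee is the
#' rank maximising perpendicular distance to the chord joining the first and
#' last points. Ties break towards the smaller rank (higher threshold, fewer
#' active calls). A flat curve degenerates to the common value, above which
#' nothing lies strictly.
#'
#' @param sorted_values numeric vector sorted in descending order, length >= 3.
#' @return The value at the knee rank, used as an activity threshold with
#'   strict-greater membership.
#' @export
find_inflection_point <- function(sorted_values) {
  n <- length(sorted_values)
  stopifnot(n >= 3)
  if (any(diff(sorted_values) > 0)) stop("values must be sorted descending")
  rng <- sorted_values[1] - sorted_values[n]
  if (rng == 0) return(sorted_values[1])
  u <- (seq_len(n) - 1) / (n - 1)
  y <- (sorted_values - sorted_values[n]) / rng
  # chord runs from (0, 1) to (1, 0); |u + y - 1| / sqrt(2) is the distance
  d <- abs(u + y - 1)
  sorted_values[which.max(d)]
}

#' Call active regions from input and output FPKM
#'
#' Regions with input FPKM below `min_input_fpkm` are removed, fold-change
#' (output/input FPKM) is computed on the remainder, regions are ranked by
#' descending fold-change, and a region is active iff its fold-change is
#' strictly greater than the knee-point threshold of the ranked curve.
#'
#' @param input_fpkm,output_fpkm named numeric vectors over the same regions.
#' @param min_input_fpkm input-library FPKM filter (default 1).
#' @param regions optional BED-convention data.frame with `region_id`, carried
#'   through to the result so active calls keep their coordinates.
#' @return data.frame (`region_id`, `fpkm_input`, `fpkm_output`,
#'   `fold_change`, `rank`, `active`) ordered by rank, with the threshold as
#'   attribute `"threshold"`.
#' @export
call_active_regions <- function(input_fpkm, output_fpkm, min_input_fpkm = 1,
                                regions = NULL) {
  stopifnot(setequal(names(input_fpkm), names(output_fpkm)))
  output_fpkm <- output_fpkm[names(input_fpkm)]
  keep <- input_fpkm >= min_input_fpkm
  if (sum(keep) < 3) stop("fewer than 3 regions pass the input filter; knee undefined")
  ids <- names(input_fpkm)[keep]
  fc <- unname(output_fpkm[keep] / input_fpkm[keep])
  ord <- order(-fc, ids)  # stable: ties by region id
  res <- data.frame(
    region_id = ids[ord],
    fpkm_input = unname(input_fpkm[keep])[ord],
    fpkm_output = unname(output_fpkm[keep])[ord],
    fold_change = fc[ord],
    rank = seq_along(ord),
    stringsAsFactors = FALSE
  )
  thr <- find_inflection_point(res$fold_change)
  res$active <- res$fold_change > thr
  if (!is.null(regions)) {
    res <- merge(res, regions[, c("region_id", "chrom", "start", "end")],
                 by = "region_id", sort = FALSE)
    res <- res[order(res$rank), , drop = FALSE]
    rownames(res) <- NULL
  }
  attr(res, "threshold") <- thr
  res
}

#' Merge replicate activity calls
#'
#' Keeps regions present in all replicates and averages their activity
#' (fold-change). For peak-style inputs, where each replicate's table holds
#' its called peaks, the averaged common-peak curve is re-ranked and
#' re-thresholded at its knee (`rethreshold = TRUE`). For captured-region
#' designs, where every replicate was already thresholded over the same
#' region keys, pass each replicate's active calls and set
#' `rethreshold = FALSE`: the common regions were active in every replicate
#' and a second knee on an already-selected set would truncate it.
#' Membership is by shared region key (`mode = "key"`) or >= 1 bp positional
#' overlap against the first replicate (`mode = "overlap"`).
#'
#' @param replicate_calls list (length >= 2) of data.frames as returned by
#'   [call_active_regions()].
#' @param mode `"key"` or `"overlap"`.
#' @param rethreshold re-run [find_inflection_point()] on the averaged curve.
#' @return data.frame of merged calls with averaged FPKM and fold-change.
#' @export
merge_replicate_calls <- function(replicate_calls, mode = c("key", "overlap"),
                                  rethreshold = TRUE) {
  mode <- match.arg(mode)
  stopifnot(length(replicate_calls) >= 2)
  if (mode == "key") {
    common <- Reduce(intersect, lapply(replicate_calls, `[[`, "region_id"))
  } else {
    ref <- replicate_calls[[1]]
    keep <- rep(TRUE, nrow(ref))
    for (other in replicate_calls[-1]) {
      ov <- overlap_pairs(ref, other)
      keep <- keep & seq_len(nrow(ref)) %in% ov$a_idx
    }
    common <- ref$region_id[keep]
  }
  if (length(common) == 0) {
    warning("no regions common to all replicates")
    out <- replicate_calls[[1]][0, , drop = FALSE]
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  mats <- lapply(replicate_calls, function(x) {
    if (mode == "overlap") {
      # average each common region with its positional matches per replicate
      ov <- overlap_pairs(replicate_calls[[1]], x)
      val <- tapply(x$fold_change[ov$b_idx], replicate_calls[[1]]$region_id[ov$a_idx], mean)
      fi <- tapply(x$fpkm_input[ov$b_idx], replicate_calls[[1]]$region_id[ov$a_idx], mean)
      fo <- tapply(x$fpkm_output[ov$b_idx], replicate_calls[[1]]$region_id[ov$a_idx], mean)
      list(fc = val[common], fi = fi[common], fo = fo[common])
    } else {
      i <- match(common, x$region_id)
      list(fc = x$fold_change[i], fi = x$fpkm_input[i], fo = x$fpkm_output[i])
    }
  })
  fc <- Reduce(`+`, lapply(mats, `[[`, "fc")) / length(mats)
  fi <- Reduce(`+`, lapply(mats, `[[`, "fi")) / length(mats)
  fo <- Reduce(`+`, lapply(mats, `[[`, "fo")) / length(mats)
  ord <- order(-fc, common)
  res <- data.frame(
    region_id = common[ord],
    fpkm_input = unname(fi)[ord],
    fpkm_output = unname(fo)[ord],
    fold_change = unname(fc)[ord],
    rank = seq_along(ord),
    stringsAsFactors = FALSE
  )
  if (rethreshold) {
    thr <- find_inflection_point(res$fold_change)
    res$active <- res$fold_change > thr
  } else {
    thr <- NA_real_
    res$active <- TRUE
  }
  ref <- replicate_calls[[1]]
  if (all(c("chrom", "start", "end") %in% names(ref))) {
    i <- match(res$region_id, ref$region_id)
    res$chrom <- ref$chrom[i]; res$start <- ref$start[i]; res$end <- ref$end[i]
  }
  attr(res, "threshold") <- thr
  res
}

#' Allele-partitioned read counts at a SNP across stimulation conditions
#'
#' Counts fragments carrying each allele at the SNP position, averages
#' replicates within each condition, and normalises each allele's mean to its
#' mean in the reference (no-stimulation) condition, so the reference
#' condition is 1 by construction.
#'
#' @param fragments_by_condition named list: condition -> list of
#'   `fragment_set`s (replicates) whose fragments carry an `allele` column.
#' @param snp list or one-row data.frame with `chrom` and `pos` (0-based
#'   position of the variant base).
#' @param reference_condition condition used as the normalisation baseline.
#' @return data.frame (`condition`, `allele`, `mean_count`, `normalized`);
#'   `normalized` is `NA` for alleles with zero baseline mean.
#' @export
allelic_read_counts <- function(fragments_by_condition, snp,
                                reference_condition = "NS") {
  stopifnot(reference_condition %in% names(fragments_by_condition))
  alleles <- sort(unique(unlist(lapply(fragments_by_condition, function(reps) {
    unlist(lapply(reps, function(fs) unique(fs$fragments$allele)))
  }))))
  count_one <- function(fs, allele) {
    fr <- fs$fragments
    sum(fr$chrom == snp$chrom & fr$start <= snp$pos & fr$end > snp$pos &
          !is.na(fr$allele) & fr$allele == allele)
  }
  rows <- do.call(rbind, lapply(names(fragments_by_condition), function(cond) {
    reps <- fragments_by_condition[[cond]]
    do.call(rbind, lapply(alleles, function(a) {
      data.frame(condition = cond, allele = a,
                 mean_count = mean(vapply(reps, count_one, numeric(1), a)))
    }))
  }))
  base <- rows[rows$condition == reference_condition, ]
  base_mean <- stats::setNames(base$mean_count, base$allele)
  rows$normalized <- ifelse(base_mean[rows$allele] > 0,
                            rows$mean_count / base_mean[rows$allele],
                            NA_real_)
  rownames(rows) <- NULL
  rows
}
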