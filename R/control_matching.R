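# Tau tissue-specificity index and expression-matched control promoters.

#' Tau tissue-specificity index
#'
#' For a gene expressed across N tissues, tau = sum_i (1 - x_i) / (N - 1)
#' where x_i is the expression in tissue i divided by the maximum over
#' tissues. Tau is 0 for perfectly broad expression and 1 for expression
#' confined to a single tissue.
#'
#' @param x numeric vector (one gene, length >= 2) or matrix (genes x
#'   tissues) of non-negative expression values.
#' @return Numeric tau in `[0, 1]` per gene; `NA` with a warning for
#'   all-zero profiles (undefined).
#' @export
tau_index <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) >= 2, all(x >= 0, na.rm = TRUE))
    mx <- apply(x, 1, max)
    zero <- mx == 0
    if (any(zero)) warning(sum(zero), " all-zero expression profile(s); tau undefined")
    tau <- rowSums(1 - x / ifelse(mx == 0, NA, mx)) / (ncol(x) - 1)
    tau[zero] <- NA_real_
    return(tau)
  }
  stopifnot(length(x) >= 2, all(x >= 0))
  if (max(x) == 0) {
    warning("all-zero expression profile; tau undefined")
    return(NA_real_)
  }
  sum(1 - x / max(x)) / (length(x) - 1)
}

#' Match control genes to Epromoter genes by expression proximity
#'
#' Each Epromoter-associated gene, processed in lexicographic gene-ID order,
#' is assigned the not-yet-assigned non-Epromoter gene whose tissue
#' expression vector is nearest in Euclidean distance (ties broken
#' lexicographically). The assignment is injective (without replacement), so
#' the control set has the same size as the Epromoter gene set.
#'
#' @param expr numeric matrix genes x tissues with gene IDs as rownames.
#' @param epromoter_genes character vector of Epromoter-associated gene IDs
#'   (must be rows of `expr`).
#' @param log1p transform expression by `log1p` before computing distances.
#' @return data.frame (`epromoter_gene`, `control_gene`, `distance`) in
#'   processing order.
#' @export
match_controls <- function(expr, epromoter_genes, log1p = FALSE) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  epromoter_genes <- sort(unique(epromoter_genes))
  stopifnot(all(epromoter_genes %in% rownames(expr)))
  pool <- sort(setdiff(rownames(expr), epromoter_genes))
  if (length(pool) < length(epromoter_genes)) {
    stop("candidate pool smaller than the Epromoter gene set")
  }
  m <- if (log1p) log1p(expr) else expr
  cand <- m[pool, , drop = FALSE]
  taken <- rep(FALSE, length(pool))
  out <- data.frame(epromoter_gene = epromoter_genes,
                    control_gene = NA_character_, distance = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(epromoter_genes)) {
    v <- m[epromoter_genes[i], ]
    d <- sqrt(colSums((t(cand) - v)^2))
    d[taken] <- Inf
    j <- which(d == min(d))[1]  # pool is sorted, so ties go lexicographic
    taken[j] <- TRUE
    out$control_gene[i] <- pool[j]
    out$distance[i] <- d[j]
  }
  out
}
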