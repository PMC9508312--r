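#' Directed block sum of a connectivity matrix
#'
#' Sums the directed weights from every source-set channel to every
#' target-set channel, excluding self-pairs.  Block "XY" convention:
#' X is the source set and Y the target set (e.g. the frontal-to-central
#' block sums edges leaving frontal channels and entering central ones).
#'
#' @param mat a `pdc_connectivity` (or weight matrix with labelled dims).
#' @param sources,targets character vectors of channel labels.
#' @return scalar sum.
#' @export
block_sum <- function(mat, sources, targets) {
  W <- .conn_weights(mat)
  labels <- rownames(W)
  bad <- setdiff(c(sources, targets), labels)
  if (length(bad) > 0) {
    stop("unknown channel label(s): ", paste(bad, collapse = ", "))
  }
  # weights[i, j] is j -> i, so sources index columns, targets rows
  sum(W[labels %in% targets, labels %in% sources, drop = FALSE])
}

#' Number of ordered channel pairs in a block
#'
#' The count of (source, target) pairs with source != target; the
#' denominator for per-edge ("normalized") block connectivity.
#'
#' @inheritParams block_sum
#' @return integer pair count.
#' @export
block_size <- function(sources, targets) {
  length(sources) * length(targets) - length(intersect(sources, targets))
}

#' Hemispheric, midline, and regional block summary
#'
#' Computes all directed block sums over the hemisphere/midline partition
#' (LL, LR, RL, RR between the lateral sets; MM, LM, ML, RM, MR involving
#' the midline) and over the five lobe regions (all 25 ordered
#' source -> target pairs, e.g. FC = frontal-to-central).  Both partitions
#' conserve the total off-diagonal weight: the nine hemisphere/midline
#' blocks and the 25 region blocks each sum to it exactly.
#'
#' @param mat a `pdc_connectivity` over the montage's labels.
#' @param montage a montage from [montage_1020_30()] (or compatible list).
#' @return list of class `pdc_blocks` with `hemisphere` and `region` named
#'   numeric vectors, `sizes` (pair counts per block), and `total` (the
#'   off-diagonal weight sum).
#' @export
summarize_blocks <- function(mat, montage = montage_1020_30()) {
  W <- .conn_weights(mat)
  if (!setequal(rownames(W), montage$labels)) {
    stop("connectivity labels do not match the montage")
  }
  sets <- list(L = montage$left, R = montage$right, M = montage$midline)
  hemi_pairs <- c("LL", "LR", "RL", "RR", "MM", "LM", "ML", "RM", "MR")
  hemi <- vapply(hemi_pairs, function(p) {
    block_sum(W, sets[[substr(p, 1, 1)]], sets[[substr(p, 2, 2)]])
  }, numeric(1))
  hemi_sizes <- vapply(hemi_pairs, function(p) {
    block_size(sets[[substr(p, 1, 1)]], sets[[substr(p, 2, 2)]])
  }, numeric(1))

  rg <- montage$regions
  region_pairs <- as.vector(t(outer(names(rg), names(rg), paste0)))
  region <- vapply(region_pairs, function(p) {
    block_sum(W, rg[[substr(p, 1, 1)]], rg[[substr(p, 2, 2)]])
  }, numeric(1))
  region_sizes <- vapply(region_pairs, function(p) {
    block_size(rg[[substr(p, 1, 1)]], rg[[substr(p, 2, 2)]])
  }, numeric(1))

  structure(
    list(hemisphere = hemi, region = region,
         sizes = c(hemi_sizes, region_sizes),
         total = sum(W)),
    class = "pdc_blocks"
  )
}

#' @export
print.pdc_blocks <- function(x, ...) {
  cat("<pdc_blocks> total off-diagonal weight:", format(x$total), "\n")
  cat("  hemisphere:",
      paste(sprintf("%s=%.2f", names(x$hemisphere), x$hemisphere),
            collapse = " "), "\n")
  invisible(x)
}

#' Per-edge (normalized) block connectivity
#'
#' Block sum divided by the number of ordered channel pairs in the block;
#' the per-subject quantity correlated against symptom scores.
#'
#' @param blocks a `pdc_blocks` from [summarize_blocks()].
#' @param names which blocks to normalize (default all).
#' @return named numeric vector of per-edge means.
#' @export
normalize_blocks <- function(blocks, names = NULL) {
  v <- c(blocks$hemisphere, blocks$region)
  if (!is.null(names)) v <- v[names]
  v / blocks$sizes[base::names(v)]
}

#' Block summary table for a set of subjects
#'
#' @param blocks_list named list (by subject id) of `pdc_blocks`.
#' @param condition,band tags repeated on every row.
#' @return long data.frame: subject, condition, band, block, value.
#' @export
blocks_table <- function(blocks_list, condition = NA, band = NA) {
  do.call(rbind, lapply(names(blocks_list), function(id) {
    b <- blocks_list[[id]]
    v <- c(b$hemisphere, b$region)
    data.frame(subject = id, condition = condition, band = band,
               block = names(v), value = unname(v), row.names = NULL)
  }))
}
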