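#' Intervals consistent across comparisons
#'
#' Combines the peak sets of several comparisons. With
#' `require_all = TRUE`, returns the interval intersection of peaks
#' present in every comparison; otherwise the union of stretches
#' covered by peaks of at least two comparisons.
#'
#' @param peak_sets named list of peak data.frames (see [call_peaks()]).
#' @param require_all logical.
#' @return data.frame with `scaffold`, `start`, `end` (1-based
#'   inclusive) and `supporting_comparisons` (comma-separated names of
#'   comparisons with an overlapping peak), ordered by coordinate.
#' @export
intersect_peaks <- function(peak_sets, require_all = TRUE) {
  stopifnot(length(peak_sets) >= 1L)
  if (is.null(names(peak_sets))) {
    names(peak_sets) <- paste0("comparison_", seq_along(peak_sets))
  }
  scaffolds <- sort(unique(unlist(lapply(peak_sets, function(p) p$scaffold))))
  rows <- list()
  for (sc in scaffolds) {
    irl <- lapply(peak_sets, function(p) {
      pp <- p[p$scaffold == sc, , drop = FALSE]
      IRanges::reduce(IRanges::IRanges(pp$start, pp$end))
    })
    res <- if (require_all) {
      Reduce(IRanges::intersect, irl)
    } else {
      W <- max(c(1L, unlist(lapply(irl, function(ir) {
        if (length(ir) > 0L) max(IRanges::end(ir)) else integer(0)
      }))))
      cov <- Reduce(`+`, lapply(irl, function(ir) IRanges::coverage(ir, width = W)))
      sl <- IRanges::slice(cov, lower = 2L)
      IRanges::IRanges(IRanges::start(sl), IRanges::end(sl))
    }
    if (length(res) == 0L) next
    support <- vapply(seq_along(res), function(i) {
      hit <- vapply(irl, function(ir) {
        any(IRanges::start(ir) <= IRanges::end(res)[i] &
              IRanges::end(ir) >= IRanges::start(res)[i])
      }, logical(1))
      paste(names(peak_sets)[hit], collapse = ",")
    }, character(1))
    rows[[sc]] <- data.frame(scaffold = sc,
                             start = IRanges::start(res),
                             end = IRanges::end(res),
                             supporting_comparisons = support)
  }
  if (length(rows) == 0L) {
    return(data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0),
                      supporting_comparisons = character(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Delimit candidate regulatory elements
#'
#' Each consistent interval becomes a candidate element, optionally
#' clipped to a previously published prior interval on the same
#' scaffold, with contained diagnostic SNPs counted. Elements with zero
#' diagnostic SNPs are retained but flagged. Splitting of co-located
#' signals is inherited from [call_peaks()] gap behavior; this function
#' never merges across gaps.
#'
#' @param intervals data.frame from [intersect_peaks()] (or any
#'   `scaffold`/`start`/`end` data.frame).
#' @param snps optional diagnostic-SNP data.frame
#'   (see [diagnostic_fixed_snps()]).
#' @param priors optional `scaffold`/`start`/`end` data.frame of
#'   previously published constraining intervals. Intervals overlapping
#'   a prior are clipped to it; intervals on a scaffold that has priors
#'   but overlapping none are dropped; scaffolds without priors are
#'   left unconstrained. Priors on scaffolds absent from the intervals
#'   raise an error.
#' @return data.frame of elements: `name`, `scaffold`, `start`, `end`,
#'   `supporting_comparisons`, `n_diagnostic_snps`, `flagged`.
#' @export
delimit_elements <- function(intervals, snps = NULL, priors = NULL) {
  iv <- intervals
  if (!is.null(priors) && nrow(priors) > 0L) {
    bad <- setdiff(priors$scaffold, iv$scaffold)
    if (length(bad) > 0L && nrow(iv) > 0L) {
      stop("prior interval(s) on scaffold(s) absent from the intervals: ",
           paste(unique(bad), collapse = ", "))
    }
    keep <- logical(nrow(iv))
    for (i in seq_len(nrow(iv))) {
      pr <- priors[priors$scaffold == iv$scaffold[i], , drop = FALSE]
      if (nrow(pr) == 0L) {
        keep[i] <- TRUE
        next
      }
      ov <- which(pr$start <= iv$end[i] & pr$end >= iv$start[i])
      if (length(ov) == 0L) next
      j <- ov[1]
      iv$start[i] <- max(iv$start[i], pr$start[j])
      iv$end[i] <- min(iv$end[i], pr$end[j])
      keep[i] <- TRUE
    }
    iv <- iv[keep, , drop = FALSE]
  }
  n <- nrow(iv)
  nsnp <- integer(n)
  if (!is.null(snps) && nrow(snps) > 0L) {
    for (i in seq_len(n)) {
      nsnp[i] <- sum(snps$scaffold == iv$scaffold[i] &
                       snps$pos >= iv$start[i] & snps$pos <= iv$end[i])
    }
  }
  out <- data.frame(name = if (n > 0L) paste0("element_", seq_len(n)) else character(0),
                    scaffold = iv$scaffold, start = iv$start, end = iv$end,
                    supporting_comparisons =
                      if ("supporting_comparisons" %in% names(iv))
                        iv$supporting_comparisons else rep("", n),
                    n_diagnostic_snps = nsnp,
                    flagged = nsnp == 0L)
  rownames(out) <- NULL
  out
}

#' Export intervals as BED text
#'
#' Converts the package's 1-based inclusive intervals to BED's 0-based
#' half-open convention.
#'
#' @param x data.frame with `scaffold`, `start`, `end` and optionally a
#'   `name` column.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_bed <- function(x, path) {
  bed <- data.frame(x$scaffold, x$start - 1L, x$end,
                    if ("name" %in% names(x)) x$name else ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
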