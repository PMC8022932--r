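#' Hard-filter thresholds
#'
#' The seven GATK-style exclusion criteria applied to caller quality
#' annotations.  A variant is removed when any printed inequality is
#' strictly true for a metric that is present:
#' \code{QD < 2.0}, \code{MQ < 40.0}, \code{QUAL < 100},
#' \code{MQRankSum < -12.5}, \code{SOR > 4.0}, \code{FS > 60.0},
#' \code{ReadPosRankSum < -8.0}.  Boundary values pass; absent metrics
#' never fail their criterion.
#'
#' @param qd_min,mq_min,qual_min,mqranksum_min,readpos_min lower cutoffs
#'   (fail when metric is strictly below).
#' @param sor_max,fs_max upper cutoffs (fail when metric is strictly above).
#' @return a \code{filter_thresholds} list.
#' @export
filter_thresholds <- function(qd_min = 2.0, mq_min = 40.0, qual_min = 100.0,
                              mqranksum_min = -12.5, sor_max = 4.0,
                              fs_max = 60.0, readpos_min = -8.0) {
  t <- list(qd_min = qd_min, mq_min = mq_min, qual_min = qual_min,
            mqranksum_min = mqranksum_min, sor_max = sor_max,
            fs_max = fs_max, readpos_min = readpos_min)
  if (any(!vapply(t, is.finite, TRUE))) stop("all thresholds must be finite")
  structure(t, class = "filter_thresholds")
}

# criterion-by-criterion failure matrix; NA metrics never fail.
# `metrics` is a data.frame with the seven metric columns.
failure_matrix <- function(metrics, t) {
  below <- function(x, cut) !is.na(x) & x < cut
  above <- function(x, cut) !is.na(x) & x > cut
  cbind(QD = below(metrics$QD, t$qd_min),
        MQ = below(metrics$MQ, t$mq_min),
        QUAL = below(metrics$QUAL, t$qual_min),
        MQRankSum = below(metrics$MQRankSum, t$mqranksum_min),
        SOR = above(metrics$SOR, t$sor_max),
        FS = above(metrics$FS, t$fs_max),
        ReadPosRankSum = below(metrics$ReadPosRankSum, t$readpos_min))
}

#' Evaluate one variant's quality metrics against the hard filter
#'
#' @param metrics a named list or one-row data.frame with (a subset of)
#'   \code{QD, MQ, QUAL, MQRankSum, SOR, FS, ReadPosRankSum}; missing or
#'   \code{NA} entries are treated as absent.
#' @param thresholds a \code{\link{filter_thresholds}} object.
#' @return a list with \code{passed} (logical) and \code{failed_criteria}
#'   (character vector naming every failing criterion).
#' @export
evaluate_variant <- function(metrics, thresholds = filter_thresholds()) {
  row <- as.list(metrics)
  for (k in METRIC_COLS) if (is.null(row[[k]])) row[[k]] <- NA_real_
  fm <- failure_matrix(as.data.frame(row[METRIC_COLS]), thresholds)
  failed <- colnames(fm)[fm[1, ]]
  list(passed = length(failed) == 0L, failed_criteria = failed)
}

#' Partition a callset into hard-filter passes and failures
#'
#' Every input variant lands in exactly one of the two outputs; input order
#' is preserved within each.
#'
#' @param variants a variant data.frame (see \code{\link{read_vcf}}).
#' @param thresholds a \code{\link{filter_thresholds}} object.
#' @return a list with \code{passed} (variant data.frame) and \code{failed}
#'   (variant data.frame plus a \code{failed_criteria} column of
#'   comma-separated criterion names).
#' @export
filter_callset <- function(variants, thresholds = filter_thresholds()) {
  if (!nrow(variants)) {
    failed <- variants
    failed$failed_criteria <- character(0)
    return(list(passed = variants, failed = failed))
  }
  fm <- failure_matrix(variants, thresholds)
  nfail <- rowSums(fm)
  passed <- variants[nfail == 0L, , drop = FALSE]
  failed <- variants[nfail > 0L, , drop = FALSE]
  failed$failed_criteria <- apply(fm[nfail > 0L, , drop = FALSE], 1L,
                                  function(r) paste(colnames(fm)[r], collapse = ","))
  rownames(passed) <- rownames(failed) <- NULL
  list(passed = passed, failed = failed)
}

#' Hard-filter every line of a cohort
#'
#' @param cohort a \code{cohort_callset}.
#' @param thresholds a \code{\link{filter_thresholds}} object.
#' @return a list with \code{passed} and \code{failed}, both
#'   \code{cohort_callset}s (the failed tables carry
#'   \code{failed_criteria}).
#' @export
filter_cohort <- function(cohort, thresholds = filter_thresholds()) {
  res <- lapply(cohort, filter_callset, thresholds = thresholds)
  list(passed = structure(lapply(res, `[[`, "passed"),
                          class = c("cohort_callset", "list")),
       failed = structure(lapply(res, `[[`, "failed"),
                          class = c("cohort_callset", "list")))
}
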