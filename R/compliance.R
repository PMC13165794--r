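# Route-compliance analysis: pairwise R^2 between participants per
# parameter, per-participant medians/IQRs, outlier rule, rank table,
# rank sums, Kendall's W and the Friedman test.

#' Pairwise R-squared matrix across participants
#'
#' Correlates every unordered pair of distance-aligned profiles and returns
#' the squared Pearson correlation. Because the course is the only variable
#' shared between participants, R^2 measures how strongly the parameter is
#' driven by route conditions. Constant profiles yield NA entries (flagged,
#' not errors).
#'
#' @param profiles Named list of numeric vectors, all on the same distance
#'   grid (trimmed to the shortest common length).
#' @return Symmetric matrix with unit diagonal, entries in `[0, 1]`.
#' @export
pairwise_r2 <- function(profiles) {
  n <- length(profiles)
  stopifnot(n >= 2L)
  len <- min(lengths(profiles))
  m <- vapply(profiles, function(p) p[seq_len(len)], numeric(len))
  r2 <- matrix(NA_real_, n, n,
               dimnames = list(names(profiles), names(profiles)))
  diag(r2) <- 1
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- is.finite(m[, i]) & is.finite(m[, j])
      if (sum(ok) < 3L || stats::sd(m[ok, i]) == 0 || stats::sd(m[ok, j]) == 0) {
        next  # flagged undefined
      }
      r2[i, j] <- r2[j, i] <- stats::cor(m[ok, i], m[ok, j])^2
    }
  }
  r2
}

#' Per-participant median and IQR of off-diagonal R-squared values
#'
#' For each participant the `n - 1` R^2 values against the other participants
#' are summarised by their median and interquartile range. Quartiles use
#' linear interpolation between order statistics (R's default type 7); the
#' same convention is used by [outlier_flags()].
#'
#' @param r2 A matrix from [pairwise_r2()].
#' @return Data.frame with `participant`, `median`, `iqr`, `n_valid`.
#' @export
participant_medians <- function(r2) {
  stopifnot(is.matrix(r2), nrow(r2) == ncol(r2), nrow(r2) >= 3L)
  out <- lapply(seq_len(nrow(r2)), function(i) {
    v <- r2[i, -i]
    v <- v[is.finite(v)]
    if (length(v) < 2L) stop("fewer than 2 valid R^2 values for participant ", i)
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(participant = if (!is.null(rownames(r2))) rownames(r2)[i] else as.character(i),
               median = q[2L], iqr = q[3L] - q[1L], n_valid = length(v))
  })
  do.call(rbind, out)
}

#' Low-side outlier flags on participant medians
#'
#' Flags a participant whose median R^2 lies below `Q1 - 1.5 * IQR` of the
#' cohort's medians (quartiles by linear interpolation, type 7). In the
#' study this identifies the most individualistic participant as a true
#' outlier.
#'
#' @param medians Numeric vector of per-participant medians.
#' @return Logical vector of flags.
#' @export
outlier_flags <- function(medians) {
  if (length(medians) < 4L) stop("need at least 4 participants")
  q <- stats::quantile(medians, c(0.25, 0.75), names = FALSE, type = 7)
  medians < q[1L] - 1.5 * (q[2L] - q[1L])
}

#' Rank table and rank sums over parameters
#'
#' Within each parameter, participants are ranked by their median R^2 with
#' rank 1 for the smallest (ties get average ranks); the rank sum per
#' participant adds the ranks across parameters. A high rank sum marks a
#' route-driven participant, a low one an individualistic participant.
#'
#' @param medians Numeric matrix, participants x parameters (e.g., columns
#'   velocity, COPx, COPy).
#' @return List with `ranks` (same shape), `rank_sums` (per participant).
#' @export
rank_table <- function(medians) {
  m <- as.matrix(medians)
  stopifnot(all(is.finite(m)))
  ranks <- apply(m, 2, rank)
  list(ranks = ranks, rank_sums = rowSums(ranks))
}

#' Kendall's coefficient of concordance W
#'
#' Measures agreement among `m` rankings (judges) of `n` items:
#' `W = 12 S / (m^2 (n^3 - n) - m T)` where `S` is the sum of squared
#' deviations of the item rank sums from their mean and `T` the tie
#' correction `sum(t^3 - t)` over tied groups in each ranking. The
#' associated chi-squared statistic is `m (n - 1) W` on `n - 1` degrees of
#' freedom. Here the three parameters (speed, COPx, COPy) act as judges and
#' the participants as items.
#'
#' @param ranks Matrix of ranks, items x judges (each column a ranking of
#'   the items), or raw scores which are ranked per column.
#' @param already_ranked If FALSE (default), columns are ranked first.
#' @return List with `W`, `chi2`, `df`, `p`, `rank_sums`, `S`.
#' @export
kendalls_w <- function(ranks, already_ranked = TRUE) {
  r <- as.matrix(ranks)
  n <- nrow(r)  # items
  m <- ncol(r)  # judges
  if (n < 2L) stop("need at least 2 items")
  if (m < 2L) stop("need at least 2 judges")
  if (!already_ranked) r <- apply(r, 2, rank)
  rs <- rowSums(r)
  S <- sum((rs - mean(rs))^2)
  tie_T <- sum(apply(r, 2, function(col) {
    t <- table(col)
    sum(t^3 - t)
  }))
  denom <- m^2 * (n^3 - n) - m * tie_T
  if (denom <= 0) stop("degenerate ranking: all items tied")
  W <- 12 * S / denom
  chi2 <- m * (n - 1) * W
  list(W = W, chi2 = chi2, df = n - 1L,
       p = stats::pchisq(chi2, n - 1L, lower.tail = FALSE),
       rank_sums = rs, S = S)
}

#' Friedman rank-sum test on complete blocks
#'
#' Thin wrapper over [stats::friedman.test()] for repeated measures laid out
#' as blocks x conditions.
#'
#' @param x Numeric matrix, blocks (participants) x conditions.
#' @return List with `chi2`, `df`, `p`.
#' @export
friedman_test <- function(x) {
  m <- as.matrix(x)
  if (any(!is.finite(m))) stop("unequal block sizes: incomplete blocks")
  ft <- stats::friedman.test(m)
  chi2 <- unname(ft$statistic)
  p <- ft$p.value
  if (is.nan(chi2)) {
    # complete ties in every block: the statistic sits at its minimum
    chi2 <- 0
    p <- 1
  }
  list(chi2 = chi2, df = unname(ft$parameter), p = p)
}

#' Full route-compliance report
#'
#' Runs the compliance pipeline for the three parameters: pairwise R^2
#' matrices, per-participant medians/IQRs, low-side outlier flags, the rank
#' table with rank sums, and Kendall's W with its chi-squared test.
#'
#' @param aligned Named list of `aligned_run`s (one per participant) on the
#'   same distance grid.
#' @param parameters Character vector of parameters (default v, copx, copy).
#' @return List of class `compliance_report`: `r2` (list of matrices),
#'   `summary` (participant x parameter medians/IQRs), `outliers`,
#'   `ranks`, `rank_sums`, `concordance` (Kendall's W result).
#' @export
compliance_report <- function(aligned, parameters = c("v", "copx", "copy")) {
  stopifnot(length(aligned) >= 3L)
  ids <- names(aligned)
  if (is.null(ids)) ids <- paste0("P", seq_along(aligned))
  r2 <- list()
  med <- matrix(NA_real_, length(aligned), length(parameters),
                dimnames = list(ids, parameters))
  iqr <- med
  for (p in parameters) {
    profiles <- lapply(aligned, function(a) a[[p]])
    names(profiles) <- ids
    r2[[p]] <- pairwise_r2(profiles)
    pm <- participant_medians(r2[[p]])
    med[, p] <- pm$median
    iqr[, p] <- pm$iqr
  }
  rt <- rank_table(med)
  structure(
    list(r2 = r2,
         summary = list(median = med, iqr = iqr),
         outliers = if (nrow(med) >= 4L) apply(med, 2, outlier_flags) else NULL,
         ranks = rt$ranks, rank_sums = rt$rank_sums,
         concordance = kendalls_w(rt$ranks)),
    class = "compliance_report"
  )
}

#' @export
print.compliance_report <- function(x, ...) {
  cat("Route-compliance report\n")
  cat("Median R^2 (participant x parameter):\n")
  print(round(x$summary$median, 3))
  cat("Rank sums:\n")
  print(x$rank_sums)
  cat(sprintf("Kendall's W = %.4f (chi2 = %.3f, df = %d, p = %.4f)\n",
              x$concordance$W, x$concordance$chi2, x$concordance$df,
              x$concordance$p))
  invisible(x)
}
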