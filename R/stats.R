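# Within-specimen comparison of model-generating techniques: Friedman rank
# ANOVA with tie correction and Dunn-type pairwise z-tests with Bonferroni
# adjustment, plus the per-pair difference summary table.

#' Friedman rank test across model types
#'
#' Ranks the `k` model types within each of the `n` specimens (ties share
#' the mean rank) and computes the tie-corrected Friedman chi-square
#' statistic with `k - 1` degrees of freedom.
#'
#' @param m numeric matrix, `n specimens x k model types` (`n >= 2`,
#'   `k >= 2`, no missing cells), columns named by model.
#' @return list with `chi2`, `df`, `p`, and `mean_ranks` (per column).
#' @export
friedmanTest <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 2) stop("need at least 2 specimens (rows)")
  if (k < 2) stop("need at least 2 model types (columns)")
  if (any(!is.finite(m))) stop("matrix must have no missing cells")
  R <- t(apply(m, 1, rank))
  Rj <- colSums(R)
  stat <- (12 / (n * k * (k + 1))) * sum(Rj^2) - 3 * n * (k + 1)
  # tie correction: 1 - sum(t^3 - t) / (n k (k^2 - 1))
  ties <- sum(apply(m, 1, function(row) {
    tt <- table(row)
    sum(tt^3 - tt)
  }))
  corr <- 1 - ties / (n * k * (k^2 - 1))
  chi2 <- if (corr > 0) stat / corr else 0
  list(chi2 = chi2, df = k - 1,
       p = pchisq(chi2, df = k - 1, lower.tail = FALSE),
       mean_ranks = colMeans(R))
}

#' Bonferroni-adjusted pairwise comparisons after a Friedman test
#'
#' Dunn-type post hoc on the within-specimen mean ranks: for each column
#' pair `z = (mean rank difference) / sqrt(k (k + 1) / (6 n))`, two-sided
#' p multiplied by the number of pairs and capped at 1.
#'
#' @param m numeric matrix, `n x k` as in [friedmanTest()].
#' @return data.frame with columns `pair`, `z`, `p_raw`, `p_adjusted`.
#' @export
pairwiseBonferroni <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (k < 2) stop("need at least 2 model types (columns)")
  cn <- colnames(m)
  if (is.null(cn)) cn <- paste0("model", seq_len(k))
  mr <- colMeans(t(apply(m, 1, rank)))
  se <- sqrt(k * (k + 1) / (6 * n))
  pairs <- utils::combn(k, 2)
  npair <- ncol(pairs)
  out <- data.frame(pair = character(npair), z = numeric(npair),
                    p_raw = numeric(npair), p_adjusted = numeric(npair),
                    stringsAsFactors = FALSE)
  for (i in seq_len(npair)) {
    a <- pairs[1, i]; b <- pairs[2, i]
    z <- (mr[a] - mr[b]) / se
    p <- 2 * pnorm(-abs(z))
    out$pair[i] <- paste(cn[a], cn[b], sep = " vs ")
    out$z[i] <- z
    out$p_raw[i] <- p
    out$p_adjusted[i] <- min(1, p * npair)
  }
  out
}

#' Per-pair difference table of morphometric reports
#'
#' For each parameter and each pair of model types, the per-specimen
#' difference (first-listed, the reference, minus second), summarised as
#' mean, sample SD, min and max -- the standard agreement table with the
#' gold standard listed first.
#'
#' @param reports named list of model types, each a list (or data.frame)
#'   of per-specimen [MorphometricReport-class]s (or their data-frame
#'   rows); all model types must cover the same specimens in order.
#' @return data.frame with columns `parameter`, `pair`, `mean`, `sd`,
#'   `min`, `max`.
#' @export
differenceTable <- function(reports) {
  toDf <- function(x) {
    if (is.data.frame(x)) return(x)
    do.call(rbind, lapply(x, as.data.frame))
  }
  dfs <- lapply(reports, toDf)
  ns <- vapply(dfs, nrow, 0L)
  if (length(unique(ns)) != 1)
    stop("specimen sets mismatch across model types")
  params <- c("coronal_diameter_mm", "sagittal_diameter_mm",
              "medial_thickness_mm", "lateral_thickness_mm",
              "disc_depth_mm")
  models <- names(dfs)
  pairs <- utils::combn(length(models), 2)
  rows <- list()
  for (pp in seq_len(ncol(pairs))) {
    a <- pairs[1, pp]; b <- pairs[2, pp]
    for (par in params) {
      d <- dfs[[a]][[par]] - dfs[[b]][[par]]
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = par,
        pair = paste(models[a], models[b], sep = " vs "),
        mean = mean(d), sd = sd(d), min = min(d), max = max(d))
    }
  }
  do.call(rbind, rows)
}
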