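#' Paired effect size and test
#'
#' Cohen's d for paired samples in the difference-score convention:
#' `d = mean(diff) / sd(diff)` with `diff = altered - baseline` and the
#' sample (n-1) standard deviation; the paired two-sided t statistic is
#' `t = d * sqrt(n)` with `n - 1` degrees of freedom, and
#' `se_d = sqrt(1/n + d^2 / (2n))` (the standard large-sample approximation).
#' An averaged-SD d (`sd` of the pooled condition SDs) is available via
#' `convention = "av"`.
#'
#' @param baseline,altered aligned per-subject values (length >= 3).
#' @param convention `"dz"` (difference-score, default) or `"av"`.
#' @return list with `d`, `seD`, `t`, `p`, `n`, and `undefined` (`TRUE` when
#'   the differences have zero variance or contain undefined values, in
#'   which case the estimates are `NA`).
#' @examples
#' pairedEffect(c(0, 0, 0), c(1, 2, 3))$d  # 2
#' @export
pairedEffect <- function(baseline, altered, convention = c("dz", "av")) {
  convention <- match.arg(convention)
  if (length(baseline) != length(altered))
    stop("baseline and altered must be aligned by subject")
  n <- length(baseline)
  if (n < 3L) stop("need at least 3 paired observations")
  diff <- altered - baseline
  sdd <- sd(diff)
  if (anyNA(diff) || sdd == 0)
    return(list(d = NA_real_, seD = NA_real_, t = NA_real_, p = NA_real_,
                n = n, undefined = TRUE))
  t <- mean(diff) / (sdd / sqrt(n))
  d <- if (convention == "dz") mean(diff) / sdd
       else mean(diff) / sqrt((sd(baseline)^2 + sd(altered)^2) / 2)
  list(d = d, seD = sqrt(1 / n + d^2 / (2 * n)), t = t,
       p = 2 * pt(-abs(t), df = n - 1L), n = n, undefined = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone in rank and capped at 1. Thin wrapper
#' over `stats::p.adjust(method = "BH")` with input validation; `NA` entries
#' (undefined effects) are passed through.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
fdrAdjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Per-recording metric values for a whole cohort
#'
#' Runs the three analytical metrics on every recording and stacks the
#' level-wise values into the long format consumed by [buildEffectTable()]:
#' one row per recording x metric x level x contrast.
#'
#' @param cohort a [StateCohort-class].
#' @param metrics subset of `c("FC", "EFF", "CPLX")`.
#' @param width complexity window width (frames).
#' @param nNull efficiency null realizations; the efficiency stage draws from
#'   R's RNG, so seed the stream for reproducibility.
#' @param pooling FC global pooling convention (see [summarizeLevels()]).
#' @param verbose print per-recording progress.
#' @return long data.frame with columns `id`, `subject`, `state`, `class`,
#'   `condition`, `metric`, `level`, `contrast`, `value`.
#' @export
cohortMetrics <- function(cohort, metrics = c("FC", "EFF", "CPLX"),
                          width = 5L, nNull = 100L,
                          pooling = c("block", "pairs"), verbose = FALSE) {
  stopifnot(is(cohort, "StateCohort"))
  metrics <- match.arg(metrics, several.ok = TRUE)
  pooling <- match.arg(pooling)
  man <- manifest(cohort)
  out <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    id <- man$id[i]
    ts <- cohort@series[[id]]
    fc <- if (any(c("FC", "EFF") %in% metrics)) computeFC(ts)
    rows <- list()
    if ("FC" %in% metrics)
      rows$fc <- .levelsToLong(summarizeLevels(fc, cohort@partition,
                                               pooling), "FC")
    if ("EFF" %in% metrics)
      rows$eff <- .levelsToLong(efficiencyLevels(fc, cohort@partition,
                                                 nNull), "EFF")
    if ("CPLX" %in% metrics)
      rows$cplx <- .levelsToLong(complexityLevels(ts, cohort@partition,
                                                  width), "CPLX")
    long <- do.call(rbind, rows)
    out[[i]] <- cbind(man[rep(i, nrow(long)),
                          c("id", "subject", "state", "class", "condition")],
                      long, row.names = NULL)
    if (verbose) message("  [", i, "/", nrow(man), "] ", id)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Paired effect-size table across states, metrics and analyses
#'
#' For every state x metric x level x contrast cell, pairs each subject's
#' altered value with that subject's baseline value and applies
#' [pairedEffect()]; FDR correction is then applied within the chosen family
#' (default: all states x contrasts sharing one metric x level panel).
#' Significance flags mirror the asterisk/hash convention: `sigFdr` for
#' FDR-adjusted p < 0.05, `sigRaw` for raw p < 0.05.
#'
#' @param metricsLong long data.frame from [cohortMetrics()].
#' @param fdrFamily `"metric_level"` (default), `"metric"`, `"all"` or
#'   `"none"`.
#' @param convention Cohen's d convention, see [pairedEffect()].
#' @return data.frame with one row per state x metric x level x contrast:
#'   `state`, `class`, `metric`, `level`, `contrast`, `n`, `d`, `seD`, `t`,
#'   `p`, `pFdr`, `sigFdr`, `sigRaw`, `undefined`.
#' @export
buildEffectTable <- function(metricsLong,
                             fdrFamily = c("metric_level", "metric", "all",
                                           "none"),
                             convention = c("dz", "av")) {
  fdrFamily <- match.arg(fdrFamily)
  convention <- match.arg(convention)
  need <- c("subject", "state", "class", "condition", "metric", "level",
            "contrast", "value")
  if (!all(need %in% names(metricsLong)))
    stop("metricsLong needs columns: ", paste(need, collapse = ", "))
  base <- metricsLong[metricsLong$condition == "baseline", ]
  alt <- metricsLong[metricsLong$condition == "altered", ]
  key <- function(d) paste(d$subject, d$state, d$metric, d$level, d$contrast,
                           sep = "\r")
  ib <- match(key(alt), key(base))
  if (anyNA(ib)) {
    miss <- alt$subject[which(is.na(ib))[1L]]
    stop("missing baseline partner for subject ", miss)
  }
  alt$baseline <- base$value[ib]
  cells <- unique(alt[c("state", "class", "metric", "level", "contrast")])
  res <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- alt$state == cells$state[i] & alt$metric == cells$metric[i] &
      alt$level == cells$level[i] & alt$contrast == cells$contrast[i]
    pe <- pairedEffect(alt$baseline[sel], alt$value[sel], convention)
    cbind(cells[i, ], as.data.frame(pe[c("n", "d", "seD", "t", "p",
                                         "undefined")]), row.names = NULL)
  })
  tab <- do.call(rbind, c(res, make.row.names = FALSE))
  fam <- switch(fdrFamily,
                metric_level = paste(tab$metric, tab$level),
                metric = tab$metric,
                all = rep("all", nrow(tab)),
                none = seq_len(nrow(tab)))
  tab$pFdr <- NA_real_
  for (f in unique(fam)) {
    sel <- fam == f
    tab$pFdr[sel] <- fdrAdjust(tab$p[sel])
  }
  tab$sigFdr <- !is.na(tab$pFdr) & tab$pFdr < 0.05
  tab$sigRaw <- !is.na(tab$p) & tab$p < 0.05
  tab
}
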