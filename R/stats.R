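# Group statistics: thin, contract-checked wrappers around the standard
# base-R machinery, plus the explicit t-transform for correlation
# p-values so printed (r, p) pairs can be checked directly.

#' Unpaired two-sample Student t test
#'
#' Pooled-variance two-sided t test with `df = nA + nB - 2`. Degenerate
#' inputs (zero pooled variance) are resolved by convention: equal means
#' give p = 1, unequal means p = 0, with a `degenerate` flag.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @return list `statistic`, `df`, `p`, `test`, `degenerate`.
#' @export
#' @examples
#' unpairedT(c(1, 2, 3), c(4, 5, 6)) # t = -3.674, p = 0.0213
unpairedT <- function(a, b) {
  stopIfNot(length(a) >= 2 && length(b) >= 2,
            "both groups need at least 2 values")
  df <- length(a) + length(b) - 2
  if (stats::var(a) + stats::var(b) <= 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(statistic = if (eq) 0 else sign(mean(a) - mean(b)) * Inf,
                df = df, p = if (eq) 1 else 0,
                test = "unpaired t (pooled)", degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, test = "unpaired t (pooled)", degenerate = FALSE)
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return the sample correlation; `NA` (with a warning) when either
#'   variable has zero variance.
#' @export
pearsonR <- function(x, y) {
  stopIfNot(length(x) == length(y) && length(x) >= 3,
            "need paired vectors of length >= 3")
  if (stats::var(x) <= 0 || stats::var(y) <= 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Two-tailed p-value for a Pearson correlation
#'
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` referred to a Student-t
#' distribution with `n - 2` degrees of freedom. This is the transform
#' that lets printed correlation tables be checked: feeding a reported r
#' and the group size must give back the reported p at its printed
#' rounding.
#'
#' @param r correlation in `[-1, 1]`.
#' @param n number of pairs (>= 3).
#' @return two-tailed p-value; 0 when `|r| = 1`.
#' @export
#' @examples
#' round(pearsonP(-0.935, 7), 3) # 0.002
pearsonP <- function(r, n) {
  stopIfNot(n >= 3, "need n >= 3")
  stopIfNot(abs(r) <= 1, "r must lie in [-1, 1]")
  if (abs(r) >= 1) return(0)
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(tstat), df = n - 2)
}

#' Repeated-measures ANOVA for escape latency
#'
#' Two-factor mixed ANOVA — group between animals, day within — on a
#' balanced, complete table of per-animal daily latencies, fitted with
#' `stats::aov` using an `Error(animal)` stratum. Under sphericity the
#' group effect has `(1, N - 2)` df and the day and interaction effects
#' `(5, 5(N - 2))` df for 6 days. Degenerate strata (zero error mean
#' square with zero effect mean square) are reported as F = 0, p = 1.
#'
#' @param latency data.frame with columns `animal, group, day, latency_s`
#'   (one row per animal-day; average trials first, e.g. with
#'   [dayMeans()]).
#' @return data.frame with rows `group`, `day`, `group:day`: `F`, `df1`,
#'   `df2`, `p`.
#' @export
rmAnova <- function(latency) {
  need <- c("animal", "group", "day", "latency_s")
  stopIfNot(all(need %in% names(latency)),
            paste("latency needs columns:", paste(need, collapse = ", ")))
  tab <- table(latency$animal, latency$day)
  stopIfNot(all(tab == 1),
            "design must be complete and balanced (one row per animal-day)")
  d <- data.frame(
    y = latency$latency_s,
    animal = factor(latency$animal),
    group = factor(latency$group),
    day = factor(latency$day))
  fit <- stats::aov(y ~ group * day + Error(animal), data = d)
  sm <- summary(fit)
  btw <- sm[["Error: animal"]][[1]]
  wth <- sm[["Error: Within"]][[1]]
  pick <- function(strat, term) {
    i <- match(term, trimws(rownames(strat)))
    ierr <- which(trimws(rownames(strat)) == "Residuals")
    ssE <- strat[ierr, "Sum Sq"]; dfE <- strat[ierr, "Df"]
    ss <- strat[i, "Sum Sq"]; dfT <- strat[i, "Df"]
    if (!is.finite(ssE) || ssE <= 1e-12 * max(1, ss)) {
      if (ss <= 1e-12) return(c(0, dfT, dfE, 1)) # flat data convention
      return(c(Inf, dfT, dfE, 0))
    }
    f <- (ss / dfT) / (ssE / dfE)
    c(f, dfT, dfE, stats::pf(f, dfT, dfE, lower.tail = FALSE))
  }
  res <- rbind(pick(btw, "group"), pick(wth, "day"), pick(wth, "group:day"))
  data.frame(effect = c("group", "day", "group:day"),
             F = res[, 1], df1 = res[, 2], df2 = res[, 3], p = res[, 4],
             stringsAsFactors = FALSE)
}

#' Collapse latency trials to animal-day means
#'
#' @param latency tidy latency table from [latencies()].
#' @return data.frame `animal, group, day, latency_s` (trial means).
#' @export
dayMeans <- function(latency) {
  agg <- stats::aggregate(latency_s ~ animal + group + day, data = latency,
                          FUN = mean)
  agg[order(agg$animal, agg$day), ]
}

#' Structure-behaviour correlation table
#'
#' Per group, the Pearson correlation (and its two-tailed p) between
#' final-day escape latency and each capillary total (length, volume,
#' surface area).
#'
#' @param df data.frame with columns `group, latency, L_m, Vcap_mm3,
#'   Scap_mm2` (one row per animal).
#' @return data.frame `group, measure, r, p, n`.
#' @export
buildTable1 <- function(df) {
  need <- c("group", "latency", "L_m", "Vcap_mm3", "Scap_mm2")
  stopIfNot(all(need %in% names(df)),
            paste("df needs columns:", paste(need, collapse = ", ")))
  meas <- c(length = "L_m", volume = "Vcap_mm3", surface = "Scap_mm2")
  out <- list()
  for (g in unique(df$group)) {
    sub <- df[df$group == g, ]
    for (m in names(meas)) {
      r <- pearsonR(sub$latency, sub[[meas[m]]])
      p <- if (is.na(r)) NA_real_ else pearsonP(r, nrow(sub))
      out[[length(out) + 1]] <- data.frame(
        group = g, measure = m, r = r, p = p, n = nrow(sub),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Per-group summaries
#'
#' Mean, SD, SEM and n per group for the given variables. Stereological
#' results are conventionally reported as mean +/- SD and behavioural
#' results as mean +/- SEM; both dispersions are returned so the report
#' can label each correctly.
#'
#' @param df data.frame with a `group` column.
#' @param vars character vector of numeric columns to summarise.
#' @return data.frame `group, variable, mean, sd, sem, n`.
#' @export
groupSummary <- function(df, vars) {
  out <- list()
  for (g in unique(df$group)) {
    sub <- df[df$group == g, ]
    for (v in vars) {
      x <- sub[[v]]
      out[[length(out) + 1]] <- data.frame(
        group = g, variable = v, mean = mean(x), sd = stats::sd(x),
        sem = stats::sd(x) / sqrt(length(x)), n = length(x),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
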