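# Reliability and accuracy statistics: ICC(1,1) with exact F-based
# confidence bounds, MAD +/- SD, paired t-tests, reliability classification.

#' Intraclass correlation ICC(1,1): one-way random effects, single measures
#'
#' From the one-way ANOVA decomposition over subjects (rows) with k raters
#' (columns): \code{ICC = (MSB - MSW) / (MSB + (k - 1) MSW)}, with the exact
#' 95 percent confidence bounds from the F distribution. The estimate can be
#' negative. If all values are identical the ICC is 1 by convention with a
#' degenerate confidence interval (flagged).
#'
#' @param x,y the two raters' values (index-aligned by subject), or \code{x}
#'   an n x k matrix with \code{y} missing.
#' @param conf confidence level (default 0.95).
#' @return list with \code{icc}, \code{ci} (length 2), \code{msb},
#'   \code{msw}, \code{n}, \code{k}, \code{degenerate}.
#' @export
iccOnewaySingle <- function(x, y = NULL, conf = 0.95) {
  M <- if (is.null(y)) as.matrix(x) else cbind(x, y)
  if (any(!is.finite(M))) stop("non-finite values in ICC input")
  n <- nrow(M); k <- ncol(M)
  if (n < 2) stop("ICC requires at least 2 subjects")
  if (k < 2) stop("ICC requires at least 2 raters")
  gm <- mean(M)
  rm_ <- rowMeans(M)
  ssb <- k * sum((rm_ - gm)^2)
  ssw <- sum((M - rm_)^2)
  if (ssb + ssw < 1e-300 * max(1, abs(gm))) {
    return(list(icc = 1, ci = c(NA_real_, NA_real_), msb = 0, msw = 0,
                n = n, k = k, degenerate = TRUE))
  }
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  if (msw == 0) {
    return(list(icc = 1, ci = c(NA_real_, NA_real_), msb = msb, msw = 0,
                n = n, k = k, degenerate = TRUE))
  }
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  alpha <- 1 - conf
  Fobs <- msb / msw
  FL <- Fobs / qf(1 - alpha / 2, n - 1, n * (k - 1))
  FU <- Fobs * qf(1 - alpha / 2, n * (k - 1), n - 1)
  ci <- c((FL - 1) / (FL + k - 1), (FU - 1) / (FU + k - 1))
  list(icc = icc, ci = ci, msb = msb, msw = msw, n = n, k = k,
       degenerate = FALSE)
}

#' Mean absolute difference and its standard deviation
#'
#' \code{mad} is the mean of the absolute inter-observer differences;
#' \code{sd} is the sample standard deviation (n - 1 denominator) of those
#' absolute differences, matching the "MAD (SD)" presentation.
#' @param x,y index-aligned measurement vectors.
#' @return named numeric: \code{mad}, \code{sd}.
#' @export
madSd <- function(x, y) {
  if (length(x) != length(y)) stop("madSd: length mismatch")
  a <- abs(x - y)
  c(mad = mean(a), sd = if (length(a) > 1) sd(a) else 0)
}

#' Paired t-test between two methods' measurements
#'
#' Classical two-sided paired t on the differences; n - 1 degrees of
#' freedom. Zero-variance differences are a degenerate-case error, never
#' p = 0.
#' @param a,b index-aligned measurement vectors (pairing unit: ramus).
#' @return named numeric: \code{t}, \code{p}, \code{df}, \code{meanDiff}.
#' @export
pairedT <- function(a, b) {
  if (length(a) != length(b)) stop("pairedT: length mismatch")
  if (length(a) < 2) stop("pairedT requires n >= 2 pairs")
  d <- a - b
  if (var(d) == 0)
    stop("degenerate paired t-test: zero-variance differences")
  tt <- t.test(a, b, paired = TRUE)
  c(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
    meanDiff = unname(tt$estimate))
}

#' Classify an ICC value
#'
#' Default convention: below 0.5 poor, 0.5-0.75 moderate, 0.75-0.9 good,
#' above 0.9 excellent. The alternative "koo-li" usage treats the published
#' 0.82-1.00 range as excellent by classifying from 0.75 up as excellent;
#' both conventions are available so the discrepancy stays visible.
#'
#' @param icc finite ICC value.
#' @param thresholds increasing numeric(3) cut points.
#' @param convention "default" or "published-range".
#' @export
classifyIcc <- function(icc, thresholds = c(0.5, 0.75, 0.9),
                        convention = c("default", "published-range")) {
  convention <- match.arg(convention)
  if (!is.finite(icc)) stop("icc must be finite")
  if (convention == "published-range")
    return(if (icc >= 0.75) "excellent"
           else if (icc >= 0.5) "moderate" else "poor")
  if (icc < thresholds[1]) "poor"
  else if (icc < thresholds[2]) "moderate"
  else if (icc <= thresholds[3]) "good"
  else "excellent"
}

#' Reliability summary over a cohort table
#'
#' For each region x method x quantity: ICC(1,1) with 95 percent CI between
#' the two observers, the MAD and its SD, and (per region x quantity) the
#' paired t comparing the two registration methods on observer-averaged
#' values. Holm correction of the per-region p-values is available but off
#' by default, mirroring per-region reporting at p < 0.05.
#'
#' @param df data.frame with columns case, method, observer, region, and one
#'   column per quantity (e.g. distance_mm, volume_pct).
#' @param quantities character vector of quantity column names.
#' @param holm apply Holm correction to the method-comparison p-values.
#' @return list of data.frames: \code{reliability}, \code{methodComparison}.
#' @export
reliabilityReport <- function(df, quantities = c("distance_mm", "volume_pct"),
                              holm = FALSE) {
  stopifnot(all(c("case", "method", "observer", "region") %in% names(df)))
  rel <- list()
  for (m in unique(df$method)) for (q in quantities) {
    sub <- df[df$method == m, c("case", "observer", "region", q)]
    for (r in unique(sub$region)) {
      rr <- sub[sub$region == r, ]
      o1 <- rr[rr$observer == "obs1", ]
      o2 <- rr[rr$observer == "obs2", ]
      common <- intersect(o1$case, o2$case)
      if (length(common) < 2) next
      v1 <- o1[[q]][match(common, o1$case)]
      v2 <- o2[[q]][match(common, o2$case)]
      ok <- is.finite(v1) & is.finite(v2)
      if (sum(ok) < 2) next
      ic <- iccOnewaySingle(v1[ok], v2[ok])
      ms <- madSd(v1[ok], v2[ok])
      rel[[length(rel) + 1]] <- data.frame(
        region = r, method = m, quantity = q, n = sum(ok), icc = ic$icc,
        ci_low = ic$ci[1], ci_high = ic$ci[2], mad = ms[["mad"]],
        sd = ms[["sd"]],
        classification = classifyIcc(ic$icc))
    }
  }
  rel <- do.call(rbind, rel)
  cmpRows <- list()
  methods <- unique(df$method)
  if (length(methods) == 2) {
    # observer-mean value per case x region x method
    for (q in quantities) {
      agg <- aggregate(df[[q]], by = df[c("case", "region", "method")],
                       FUN = mean)
      for (r in unique(agg$region)) {
        a <- agg[agg$region == r & agg$method == methods[1], ]
        b <- agg[agg$region == r & agg$method == methods[2], ]
        common <- intersect(a$case, b$case)
        va <- a$x[match(common, a$case)]; vb <- b$x[match(common, b$case)]
        ok <- is.finite(va) & is.finite(vb)
        if (sum(ok) < 2) next
        pt <- tryCatch(pairedT(va[ok], vb[ok]),
                       error = function(e) c(t = NA, p = NA, df = NA,
                                             meanDiff = mean(va[ok] - vb[ok])))
        cmpRows[[length(cmpRows) + 1]] <- data.frame(
          region = r, quantity = q, n = sum(ok), t = pt[["t"]], p = pt[["p"]],
          meanDiff = pt[["meanDiff"]])
      }
    }
  }
  cmp <- if (length(cmpRows)) do.call(rbind, cmpRows) else NULL
  if (!is.null(cmp) && holm) cmp$p_holm <- p.adjust(cmp$p, "holm")
  list(reliability = rel, methodComparison = cmp)
}
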