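#' Regression agreement between manual and automated counts
#'
#' Ordinary least squares of the second sample on the first, with free
#' intercept, returning the slope and its two-sided p-value for slope = 0 —
#' the agreement statistic used to validate automated against manual spine
#' counts.
#'
#' @param manual,auto Equal-length paired numeric vectors (n >= 3).
#' @return A list: `beta` (slope), `p` (two-sided p-value), `intercept`,
#'   `n`.
#' @examples
#' regress_counts(1:10, 1:10)$beta   # 1
#' @export
regress_counts <- function(manual, auto) {
  stopifnot(length(manual) == length(auto), length(manual) >= 3)
  if (sd(manual) == 0) stop("zero variance in predictor")
  fit <- lm(auto ~ manual)
  sm <- summary(fit)$coefficients
  list(beta = unname(coef(fit)[2]), p = unname(sm[2, 4]),
       intercept = unname(coef(fit)[1]), n = length(manual))
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' D is the supremum over x of the gap between the two empirical cumulative
#' distribution functions; the p-value is the asymptotic Kolmogorov
#' approximation, appropriate at the sample sizes (hundreds of spines) this
#' statistic is used with here.
#'
#' @param a,b Non-empty numeric samples.
#' @return A list: `D`, `p`, `n_a`, `n_b`.
#' @examples
#' ks_two_sample(c(1, 2, 3), c(1.5, 2.5, 3.5))$D  # 1/3
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("both samples must be non-empty")
  kt <- suppressWarnings(ks.test(a, b, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value,
       n_a = length(a), n_b = length(b))
}

#' Summary statistics for a geometry sample
#'
#' Mean, sample SD (n - 1), coefficient of variation (SD/mean), adjusted
#' Fisher-Pearson skewness (the SPSS default), median and range — the
#' population descriptors used to compare measurement precision between
#' methods. CV is flagged undefined (NA) when the mean is 0; skewness is NA
#' for constant samples or n < 3.
#'
#' @param x Numeric sample, n >= 2.
#' @return A list: `n`, `mean`, `sd`, `cv`, `skewness`, `median`, `range`
#'   (max - min).
#' @export
summary_stats <- function(x) {
  stopifnot(length(x) >= 2, all(is.finite(x)))
  m <- mean(x); s <- sd(x)
  cv <- if (m == 0) NA_real_ else s / m
  sk <- if (length(x) >= 3 && s > 0) e1071::skewness(x, type = 2) else NA_real_
  list(n = length(x), mean = m, sd = s, cv = cv, skewness = sk,
       median = median(x), range = max(x) - min(x))
}

#' Score detections against phantom ground truth
#'
#' Greedy one-to-one nearest matching of detected attachment points to true
#' attachment points under a distance tolerance; reports precision, recall,
#' and per-matched-spine absolute geometry errors.
#'
#' @param detected Data frame with `attach_x/y/z` and geometry columns
#'   (from [detect_spines()] / [analyze_spines()]).
#' @param truth Phantom truth table (from [rasterize()]).
#' @param tol Matching tolerance in um (default 0.5, > 0).
#' @return A list of class `detection_score`: `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `matches` (data frame with detected id, truth
#'   id, distance and absolute errors in head width, neck width, length,
#'   head volume).
#' @export
score_detection <- function(detected, truth, tol = 0.5) {
  if (tol <= 0) stop("matching tolerance must be positive")
  nd <- nrow(detected); nt <- nrow(truth)
  matches <- data.frame(det = integer(0), truth = integer(0),
                        dist = numeric(0), err_head = numeric(0),
                        err_neck = numeric(0), err_length = numeric(0),
                        err_volume = numeric(0))
  if (nd > 0 && nt > 0) {
    dmat <- sqrt(outer(detected$attach_x, truth$attach_x, "-")^2 +
                   outer(detected$attach_y, truth$attach_y, "-")^2 +
                   outer(detected$attach_z, truth$attach_z, "-")^2)
    free_d <- rep(TRUE, nd); free_t <- rep(TRUE, nt)
    repeat {
      dmat2 <- dmat
      dmat2[!free_d, ] <- Inf; dmat2[, !free_t] <- Inf
      k <- which.min(dmat2)
      if (!length(k) || !is.finite(dmat2[k]) || dmat2[k] > tol) break
      i <- (k - 1) %% nd + 1; j <- (k - 1) %/% nd + 1
      free_d[i] <- FALSE; free_t[j] <- FALSE
      matches <- rbind(matches, data.frame(
        det = detected$id[i], truth = truth$id[j], dist = dmat[i, j],
        err_head = abs(detected$head_width[i] - truth$head_width[j]),
        err_neck = abs(detected$neck_width[i] - truth$neck_width[j]),
        err_length = abs(detected$length[i] - truth$length[j]),
        err_volume = abs(detected$head_volume[i] - truth$head_volume[j])))
    }
  }
  tp <- nrow(matches)
  out <- list(tp = tp, fp = nd - tp, fn = nt - tp,
              precision = if (nd > 0) tp / nd else NA_real_,
              recall = if (nt > 0) tp / nt else NA_real_,
              matches = matches)
  class(out) <- "detection_score"
  out
}

#' @export
print.detection_score <- function(x, ...) {
  cat(sprintf("detection_score: TP %d, FP %d, FN %d; precision %.3f, recall %.3f\n",
              x$tp, x$fp, x$fn, x$precision, x$recall))
  if (nrow(x$matches) > 0)
    cat(sprintf("  mean |error|: head %.3f um, neck %.3f um, length %.3f um\n",
                mean(x$matches$err_head, na.rm = TRUE),
                mean(x$matches$err_neck, na.rm = TRUE),
                mean(x$matches$err_length, na.rm = TRUE)))
  invisible(x)
}

#' Empirical cumulative distribution curve
#'
#' Convenience export of (x, ECDF) pairs for cumulative-distribution plots
#' of spine geometry.
#'
#' @param x Numeric sample.
#' @return Data frame with sorted `x` and `ecdf` in (0, 1].
#' @export
ecdf_curve <- function(x) {
  xs <- sort(x)
  data.frame(x = xs, ecdf = seq_along(xs) / length(xs))
}
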