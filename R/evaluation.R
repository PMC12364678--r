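#' Cohen's kappa from a confusion matrix
#'
#' \eqn{\kappa = (p_o - p_e) / (1 - p_e)} with \eqn{p_o} the diagonal
#' fraction and \eqn{p_e = \sum_i row_i col_i / n^2}. Degenerate marginals
#' (\eqn{p_e = 1}) leave kappa undefined and return NA.
#'
#' @param m square numeric matrix of cross-tabulated calls (total > 0).
#' @return kappa in [-1, 1], or NA when undefined.
#' @export
cohensKappa <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) .stopf("confusion matrix must be square")
  n <- sum(m)
  if (n <= 0) .stopf("confusion matrix total must be > 0")
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (abs(1 - pe) < .Machine$double.eps^0.5) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Interpret a kappa value on the clinical agreement scale
#'
#' Half-open bins, closed at 1: [0, 0.2) slight, [0.2, 0.4) fair,
#' [0.4, 0.6) moderate, [0.6, 0.8) substantial, [0.8, 1] near-perfect.
#' Negative values fall outside the scale and are labeled "poor".
#'
#' @param k kappa value.
#' @return the agreement label.
#' @export
interpretKappa <- function(k) {
  if (is.na(k)) return(NA_character_)
  if (k < 0) return("poor")
  if (k < 0.2) return("slight agreement")
  if (k < 0.4) return("fair agreement")
  if (k < 0.6) return("moderate agreement")
  if (k < 0.8) return("substantial agreement")
  "near-perfect agreement"
}

#' Agreement between AI-derived and reference PD-L1 calls
#'
#' Matches slides by id (unmatched ids error, listed), builds the 2x2
#' confusion matrix of binary calls (AI rows, reference columns), and
#' computes Cohen's kappa plus accuracy/sensitivity/specificity with
#' percentile-bootstrap 95\% CIs. Slides with a \code{not_evaluable} AI
#' call are excluded (with a warning).
#'
#' @param ai_calls data.frame \code{slide_id, call} (AI side), calls
#'   \code{positive}/\code{negative}.
#' @param reference_calls data.frame \code{slide_id, call} (reference).
#' @param n_bootstrap bootstrap resamples (default 1000).
#' @param seed bootstrap seed.
#' @return an \linkS4class{AgreementResult}.
#' @export
cohortAgreement <- function(ai_calls, reference_calls, n_bootstrap = 1000L,
                            seed = 1L) {
  unmatched <- c(setdiff(ai_calls$slide_id, reference_calls$slide_id),
                 setdiff(reference_calls$slide_id, ai_calls$slide_id))
  if (length(unmatched))
    .stopf("unmatched slide ids: %s", paste(unmatched, collapse = ", "))
  ref <- reference_calls$call[match(ai_calls$slide_id,
                                    reference_calls$slide_id)]
  ai <- ai_calls$call
  ok <- ai %in% c("positive", "negative")
  if (!all(ok)) {
    warning(sum(!ok), " not-evaluable slide(s) excluded from agreement")
    ai <- ai[ok]; ref <- ref[ok]
  }
  if (!length(ai)) .stopf("no evaluable slides")
  lv <- c("positive", "negative")
  conf <- table(factor(ai, lv), factor(ref, lv))
  conf <- matrix(as.integer(conf), 2, 2,
                 dimnames = list(ai = lv, reference = lv))
  k <- cohensKappa(conf)
  point <- function(a, r) {
    tp <- sum(a == "positive" & r == "positive")
    tn <- sum(a == "negative" & r == "negative")
    fp <- sum(a == "positive" & r == "negative")
    fn <- sum(a == "negative" & r == "positive")
    sdiv <- function(x, y) if (y == 0) NA_real_ else x / y
    c(accuracy = sdiv(tp + tn, length(a)),
      sensitivity = sdiv(tp, tp + fn),
      specificity = sdiv(tn, tn + fp))
  }
  est <- point(ai, ref)
  lo <- hi <- rep(NA_real_, 3L)
  if (n_bootstrap > 0L && length(ai) > 1L) {
    .withSeed(seed, {
      boot <- replicate(n_bootstrap, {
        i <- sample.int(length(ai), replace = TRUE)
        point(ai[i], ref[i])
      })
      qsafe <- function(v, p) if (all(is.na(v))) NA_real_ else
        stats::quantile(v, p, na.rm = TRUE, names = FALSE)
      lo <- apply(boot, 1, qsafe, p = 0.025)
      hi <- apply(boot, 1, qsafe, p = 0.975)
    })
  }
  new("AgreementResult", confusion = conf, kappa = k,
      interpretation = if (is.na(k)) NA_character_ else interpretKappa(k),
      metrics = data.frame(metric = names(est), estimate = unname(est),
                           ci_lower = lo, ci_upper = hi,
                           stringsAsFactors = FALSE))
}

#' Benchmark the gated vs ungated pipeline arms
#'
#' Scores every slide with both arms on identical inputs (gated: segmenter
#' only on classifier-positive tiles; ungated: segmenter on all tissue
#' tiles) and reports per-slide stage times and patch counts plus a
#' summary. Efficiency is summarized by the hardware-independent ratio of
#' segmentation invocations; wall-time ratios are informational.
#'
#' @param slides list of \linkS4class{SlideImage}, or of
#'   \code{list(slide, truth)} bundles.
#' @param models model list as in \code{\link{scoreSlide}} (a list of two
#'   such lists named \code{gated}/\code{ungated} allows per-arm models;
#'   with oracle stand-ins pass a function \code{function(truth)} via
#'   \code{models_fn} instead).
#' @param config a \code{\link{runConfig}}.
#' @param models_fn optional \code{function(truth)} building per-slide
#'   models (used with oracle stand-ins).
#' @return list with \code{records} (one row per slide x arm:
#'   wall/stage times, patch counts, seg invocations, CPS, call) and
#'   \code{summary} (seg-invocation ratio, time ratio, call agreement).
#' @export
benchmarkPipeline <- function(slides, models = NULL, config = runConfig(),
                              models_fn = NULL) {
  if (!length(slides)) .stopf("need at least one slide")
  records <- NULL
  calls <- list(gated = character(0), ungated = character(0))
  for (i in seq_along(slides)) {
    b <- slides[[i]]
    slide <- if (is(b, "SlideImage")) b else b$slide
    m <- if (!is.null(models_fn)) models_fn(b$truth) else models
    for (arm in c("gated", "ungated")) {
      cfg <- config
      cfg$bypass_classifier <- arm == "ungated"
      marm <- if (!is.null(m$gated)) m[[arm]] else m
      sc <- scoreSlide(slide, marm, cfg)
      calls[[arm]] <- c(calls[[arm]], pdl1Call(sc$result))
      records <- rbind(records, data.frame(
        slide_id = sc$slide_id, arm = arm,
        wall_time = sc$timings$total,
        time_classify = sc$timings$classify,
        time_segment = sc$timings$segment,
        time_detect = sc$timings$detect,
        n_tiles_tissue = sc$n_patches$tissue,
        n_tiles_consensus = sc$n_patches$consensus,
        seg_invocations = sc$seg_invocations,
        det_invocations = sc$det_invocations,
        cps = cpsValue(sc$result), call = pdl1Call(sc$result),
        stringsAsFactors = FALSE))
    }
  }
  g <- records[records$arm == "gated", ]; u <- records[records$arm == "ungated", ]
  summary <- list(
    n_slides = length(slides),
    seg_invocation_ratio = sum(g$seg_invocations) /
      max(1L, sum(u$seg_invocations)),
    time_ratio = sum(g$wall_time) / max(1e-9, sum(u$wall_time)),
    call_agreement = mean(calls$gated == calls$ungated))
  list(records = records, summary = summary)
}
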