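#' Regression of template correlation on developmental time
#'
#' Ordinary least squares of per-sample template correlation on the time
#' covariate, with a t-test on the slope coefficient. A positive,
#' significant slope indicates the transcriptome is progressing toward the
#' template's adult state. Two-sided by default (`alternative = "greater"`
#' gives the one-sided test).
#'
#' An exact (zero-residual) fit makes the t-statistic infinite; the p-value
#' is reported as 0 and `degenerate = TRUE` is flagged and logged, avoiding
#' NaN propagation.
#'
#' @param times nonnegative time values (units are the caller's, recorded
#'   via `time_unit`).
#' @param corrs correlations in `[-1, 1]`, same length as `times`.
#' @param tissue tissue label recorded in the fit.
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @param time_unit free-text unit label (e.g. "days post conception").
#' @return list of class `get_trajectory_fit`: `tissue`, `slope`,
#'   `intercept`, `p_value`, `n`, `degenerate`, `time_unit`.
#' @export
fit_trajectory <- function(times, corrs, tissue = NA_character_,
                           alternative = c("two.sided", "greater"),
                           time_unit = "unspecified") {
  alternative <- match.arg(alternative)
  if (length(times) != length(corrs)) stop("times and corrs differ in length")
  if (length(times) < 3) stop("need at least 3 points for a slope t-test")
  if (any(!is.finite(times)) || any(times < 0))
    stop("times must be finite and nonnegative")
  if (any(!is.finite(corrs))) stop("corrs must be finite")
  if (stats::sd(times) == 0) stop("degenerate times: all equal")

  fit <- stats::lm(corrs ~ times)
  co <- stats::coef(fit)
  # summary.lm warns on zero-residual fits; that case is handled explicitly
  # below (p reported as 0 with the degenerate flag)
  s <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  # zero-residual fit: sigma ~ 0 relative to the response scale
  scale_ref <- max(abs(corrs), 1e-8)
  degenerate <- s$sigma < 1e-10 * scale_ref
  if (degenerate) {
    p <- 0
    log_msg("fit_trajectory: exact fit (zero residual); p-value reported as 0",
            level = "WARN")
  } else {
    tval <- s$coefficients["times", "t value"]
    df <- fit$df.residual
    p <- if (alternative == "two.sided") 2 * stats::pt(-abs(tval), df)
         else stats::pt(tval, df, lower.tail = FALSE)
  }
  structure(list(tissue = tissue,
                 slope = unname(co["times"]),
                 intercept = unname(co["(Intercept)"]),
                 p_value = p,
                 n = length(times),
                 degenerate = degenerate,
                 time_unit = time_unit),
            class = "get_trajectory_fit")
}

#' @export
print.get_trajectory_fit <- function(x, ...) {
  cat(sprintf("trajectory fit%s: slope %.4g (%s), intercept %.4g, p = %.3g, n = %d\n",
              if (is.na(x$tissue)) "" else paste0(" [", x$tissue, "]"),
              x$slope, x$time_unit, x$intercept, x$p_value, x$n))
  invisible(x)
}

#' Rank all tissue templates by trajectory slope
#'
#' For every template tissue: compute each sample's correlation to that
#' template, regress correlation on time, and rank tissues by descending
#' slope (ties lexicographic). The developmental target tissue is expected
#' to rank first.
#'
#' @param m time-course expression matrix (genes x samples).
#' @param meta sample metadata with a `time` column covering every sample.
#' @param ts `get_templates`.
#' @param method correlation method passed to [predict_matrix()].
#' @return data.frame sorted by descending slope: `tissue`, `slope`,
#'   `intercept`, `p_value`, `n`.
#' @export
rank_template_slopes <- function(m, meta, ts,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  validate_metadata(meta)
  if (!"time" %in% names(meta)) stop("metadata must carry a time column")
  times <- meta$time[match(colnames(m), meta$sample_id)]
  if (anyNA(times)) stop("samples without time metadata: ",
                         paste(colnames(m)[is.na(times)], collapse = ", "))
  if (length(unique(times)) < 3)
    stop("need at least 3 distinct time points")
  preds <- predict_matrix(m, ts, method = method)
  fits <- lapply(ts$tissues, function(tt) {
    r <- vapply(preds, function(p) unname(p$correlations[tt]), numeric(1))
    fit_trajectory(times, r, tissue = tt)
  })
  out <- data.frame(tissue = vapply(fits, `[[`, "", "tissue"),
                    slope = vapply(fits, `[[`, 0, "slope"),
                    intercept = vapply(fits, `[[`, 0, "intercept"),
                    p_value = vapply(fits, `[[`, 0, "p_value"),
                    n = vapply(fits, `[[`, 0L, "n"),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$slope, out$tissue), ]
  rownames(out) <- NULL
  out
}
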