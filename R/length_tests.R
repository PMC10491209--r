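# Per-transcript differential read-length tests: linear model, linear mixed
# model with a per-library random intercept, and Wilcoxon rank-sum, with
# Benjamini-Hochberg correction across transcripts.

# Normalise a condition vector to a 0/1 integer (1 = non-reference).
.as_condition01 <- function(condition) {
  if (is.logical(condition)) return(as.integer(condition))
  if (is.factor(condition)) return(as.integer(condition != levels(condition)[1L]))
  if (is.numeric(condition)) {
    u <- sort(unique(condition))
    if (!all(u %in% c(0, 1))) stop("numeric condition must be 0/1", call. = FALSE)
    return(as.integer(condition))
  }
  u <- sort(unique(as.character(condition)))
  if (length(u) > 2L) stop("condition has more than 2 levels", call. = FALSE)
  as.integer(as.character(condition) != u[1L])
}

.new_fit <- function(estimate = NA_real_, std_error = NA_real_,
                     statistic = NA_real_, p_value = NA_real_,
                     model_used = "ttest", fallback_flag = FALSE,
                     degenerate = FALSE, random_effect_sd = NA_real_,
                     n_control = NA_integer_, n_condition = NA_integer_) {
  structure(list(estimate = estimate, std_error = std_error,
                 statistic = statistic, p_value = p_value,
                 model_used = model_used, fallback_flag = fallback_flag,
                 degenerate = degenerate, random_effect_sd = random_effect_sd,
                 n_control = n_control, n_condition = n_condition),
            class = "length_test_fit")
}

.prepare_response <- function(lengths, logscale) {
  if (logscale) {
    if (any(lengths <= 0)) stop("logscale requires all lengths > 0", call. = FALSE)
    log2(lengths)
  } else {
    as.numeric(lengths)
  }
}

#' Linear-model (t-test) differential length fit
#'
#' Fits `Y = b0 + b_cond * cond (+ covariates) + e` where Y is the read
#' length (log2 when `logscale`), equivalent to a two-sample equal-variance
#' t-test when no covariates are given. The estimate is the condition effect
#' (condition minus control): a length difference in nucleotides, or a log2
#' fold-change of length under `logscale`.
#'
#' Zero residual variance yields a degenerate fit rather than an error: the
#' estimate is still reported, the p-value is 1 when the estimate is zero
#' (identical groups) and NA otherwise, and `degenerate` is set.
#'
#' @param lengths Numeric vector of read lengths (> 0 when `logscale`).
#' @param condition Binary vector (0/1, logical, or 2-level factor whose
#'   first level is the control) aligned with `lengths`.
#' @param covariates Optional numeric matrix / data.frame of extra per-read
#'   covariates.
#' @param logscale Model log2(length) instead of length (default FALSE).
#' @return A `length_test_fit` list: `estimate`, `std_error`, `statistic`
#'   (t), `p_value` (two-sided, residual-df t reference), `model_used`,
#'   `degenerate`, read counts.
#' @export
fit_linear <- function(lengths, condition, covariates = NULL, logscale = FALSE) {
  cond <- .as_condition01(condition)
  if (length(unique(cond)) < 2L) {
    stop("only a single condition present", call. = FALSE)
  }
  n0 <- sum(cond == 0L); n1 <- sum(cond == 1L)
  if (n0 < 2L || n1 < 2L) {
    stop("need at least 2 reads per condition for the linear model", call. = FALSE)
  }
  y <- .prepare_response(lengths, logscale)
  dat <- data.frame(y = y, cond = cond)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  fit <- stats::lm(y ~ ., data = dat)
  est <- unname(stats::coef(fit)["cond"])
  # degenerate (zero-residual) fits are handled explicitly below
  sm <- suppressWarnings(summary(fit))
  tol <- 1e-10 * max(1, mean(abs(y)))
  if (sm$sigma <= tol) {
    p <- if (abs(est) <= tol) 1 else NA_real_
    return(.new_fit(estimate = est, std_error = 0, statistic = NA_real_,
                    p_value = p, model_used = "ttest", degenerate = TRUE,
                    n_control = n0, n_condition = n1))
  }
  co <- sm$coefficients["cond", ]
  .new_fit(estimate = est, std_error = unname(co["Std. Error"]),
           statistic = unname(co["t value"]),
           p_value = unname(co["Pr(>|t|)"]),
           model_used = "ttest", n_control = n0, n_condition = n1)
}

#' Linear-mixed-model differential length fit
#'
#' Fits `Y = b0 + b_cond * cond + lib + e` with a random intercept per
#' sequencing library (REML), so that between-library fluctuation does not
#' masquerade as a condition effect and deep libraries do not dominate. The
#' condition effect is tested with the Wald statistic `b_cond / SE` referred
#' to a t distribution with Satterthwaite degrees of freedom; with the
#' typical 3-versus-3 library design the effective degrees of freedom are
#' close to 4, so a normal reference would be sharply anticonservative.
#'
#' When a condition has fewer than two libraries the random intercept is not
#' identifiable and the function falls back to [fit_linear()] on the pooled
#' reads, setting `fallback_flag`; the same fallback handles singular and
#' non-converging fits. Transcripts are never silently dropped.
#'
#' @inheritParams fit_linear
#' @param library Vector of library identifiers aligned with `lengths`.
#' @return A `length_test_fit` list; `random_effect_sd` carries the
#'   estimated between-library SD (on the modelling scale) when the mixed
#'   model was used.
#' @export
fit_lmm <- function(lengths, condition, library, covariates = NULL,
                    logscale = FALSE) {
  cond <- .as_condition01(condition)
  if (length(unique(cond)) < 2L) {
    stop("only a single condition present", call. = FALSE)
  }
  library <- as.character(library)
  libs_per_cond <- tapply(library, cond, function(x) length(unique(x)))
  if (any(libs_per_cond < 2L)) {
    res <- fit_linear(lengths, cond, covariates = covariates, logscale = logscale)
    res$fallback_flag <- TRUE
    return(res)
  }
  y <- .prepare_response(lengths, logscale)
  dat <- data.frame(y = y, cond = cond, lib = library)
  fixed <- "y ~ cond"
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    dat <- cbind(dat, covariates)
    fixed <- paste(fixed, "+", paste(names(covariates), collapse = " + "))
  }
  form <- stats::as.formula(paste(fixed, "+ (1 | lib)"))
  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(
      form, data = dat, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore",
                                  calc.derivs = FALSE))),
    error = function(e) NULL, warning = function(w) NULL
  )
  fallback <- function() {
    res <- fit_linear(lengths, cond, covariates = covariates, logscale = logscale)
    res$fallback_flag <- TRUE
    res
  }
  if (is.null(fit)) return(fallback())
  if (lme4::isSingular(fit, tol = 1e-5)) return(fallback())
  co <- tryCatch(stats::coef(summary(fit)), error = function(e) NULL)
  if (is.null(co) || !"cond" %in% rownames(co)) return(fallback())
  est <- unname(co["cond", "Estimate"])
  se <- unname(co["cond", "Std. Error"])
  stat <- est / se
  p <- unname(co["cond", "Pr(>|t|)"])
  if (!is.finite(p)) p <- 2 * stats::pnorm(-abs(stat))  # Satterthwaite failed
  re_sd <- sqrt(unname(lme4::VarCorr(fit)$lib[1, 1]))
  .new_fit(estimate = est, std_error = se, statistic = stat, p_value = p,
           model_used = "lmm", random_effect_sd = re_sd,
           n_control = sum(cond == 0L), n_condition = sum(cond == 1L))
}

#' Wilcoxon rank-sum differential length test
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test of the condition against
#' the control lengths. The p-value is exact (enumeration) for untied
#' samples with both group sizes below 50, and uses the normal approximation
#' with tie correction otherwise. The reported estimate is the difference of
#' group medians (condition minus control) and is descriptive only.
#'
#' The test is restricted to the condition variable and cannot adjust for
#' covariates; supplying any is an error.
#'
#' @inheritParams fit_linear
#' @return A `length_test_fit` list with the rank-sum statistic W.
#' @export
fit_wilcoxon <- function(lengths, condition, covariates = NULL) {
  if (!is.null(covariates)) {
    stop("the Wilcoxon test cannot adjust for covariates", call. = FALSE)
  }
  cond <- .as_condition01(condition)
  if (length(unique(cond)) < 2L) {
    stop("only a single condition present", call. = FALSE)
  }
  y0 <- as.numeric(lengths[cond == 0L])
  y1 <- as.numeric(lengths[cond == 1L])
  w <- suppressWarnings(stats::wilcox.test(y1, y0, alternative = "two.sided"))
  p <- w$p.value
  if (!is.finite(p)) p <- 1  # fully tied groups: no rank evidence either way
  .new_fit(estimate = stats::median(y1) - stats::median(y0),
           statistic = unname(w$statistic), p_value = p,
           model_used = "wilcoxon",
           n_control = length(y0), n_condition = length(y1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: the i-th smallest p-value is
#' multiplied by m/i, the running minimum is taken from the largest p down,
#' and values are clipped to 1. NA entries are passed through and do not
#' count towards m.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return Adjusted p-values, same length and order as the input.
#' @export
#' @examples
#' adjust_bh(c(0.01, 0.02, 0.03))
adjust_bh <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Per-transcript differential read-length testing
#'
#' The full testing pipeline: reads are filtered (optional flag filters,
#' then a per-condition minimum read count per transcript), the chosen model
#' is fitted per transcript, and p-values are Benjamini-Hochberg adjusted
#' across all tested transcripts. Significance is called both on the raw
#' p-value (`sig_raw`) and on the adjusted one (`sig_adj`, recommended) at
#' the chosen `alpha`.
#'
#' @param table A `read_length_table`.
#' @param design A `length_design` covering all libraries in `table`.
#' @param model One of `"lmm"` (default; linear mixed model with library
#'   random intercept), `"ttest"` (linear model), `"wilcoxon"`.
#' @param logscale Model log2(length) so estimates are log2 fold-changes
#'   (default TRUE).
#' @param min_reads_per_condition Minimum reads per transcript per condition
#'   (default 10).
#' @param alpha Significance level for the call columns (default 0.05).
#' @param covariates Character vector of design column names to adjust for
#'   (lmm/ttest only; the Wilcoxon test rejects covariates).
#' @param adaptor_only,polya_only Flag filters, see [filter_reads()].
#' @return data.frame sorted by p-value, one row per tested transcript:
#'   `transcript_id`, `n_control`, `n_condition`, `estimate`, `std_error`,
#'   `statistic`, `p_value`, `p_adjusted`, `model_used`, `fallback_flag`,
#'   `degenerate`, `random_effect_sd`, `sig_raw`, `sig_adj`.
#' @export
run_differential_length <- function(table, design,
                                    model = c("lmm", "ttest", "wilcoxon"),
                                    logscale = TRUE,
                                    min_reads_per_condition = 10,
                                    alpha = 0.05, covariates = NULL,
                                    adaptor_only = FALSE, polya_only = FALSE) {
  model <- match.arg(model)
  .check_design_covers(table, design)
  if (!is.null(covariates)) {
    missing_cov <- setdiff(covariates, names(design))
    if (length(missing_cov) > 0L) {
      stop("covariate(s) not in design: ", paste(missing_cov, collapse = ", "),
           call. = FALSE)
    }
  }
  filtered <- filter_reads(table, design, min_reads_per_condition,
                           adaptor_only = adaptor_only, polya_only = polya_only)
  empty <- data.frame(transcript_id = character(), n_control = integer(),
                      n_condition = integer(), estimate = numeric(),
                      std_error = numeric(), statistic = numeric(),
                      p_value = numeric(), p_adjusted = numeric(),
                      model_used = character(), fallback_flag = logical(),
                      degenerate = logical(), random_effect_sd = numeric(),
                      sig_raw = logical(), sig_adj = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(filtered) == 0L) {
    warning("no transcripts pass the read filter; empty result", call. = FALSE)
    return(empty)
  }
  ind <- .condition_indicator(design)
  cond <- ind[filtered$library_id]
  covs <- NULL
  if (!is.null(covariates)) {
    covs <- as.data.frame(design)[match(filtered$library_id, design$library_id),
                                  covariates, drop = FALSE]
  }
  idx <- split(seq_len(nrow(filtered)), filtered$transcript_id)
  rows <- lapply(names(idx), function(tx) {
    i <- idx[[tx]]
    cv <- if (is.null(covs)) NULL else covs[i, , drop = FALSE]
    fit <- switch(model,
      lmm = fit_lmm(filtered$length[i], cond[i], filtered$library_id[i],
                    covariates = cv, logscale = logscale),
      ttest = fit_linear(filtered$length[i], cond[i], covariates = cv,
                         logscale = logscale),
      wilcoxon = fit_wilcoxon(filtered$length[i], cond[i], covariates = cv)
    )
    data.frame(transcript_id = tx, n_control = fit$n_control,
               n_condition = fit$n_condition, estimate = fit$estimate,
               std_error = fit$std_error, statistic = fit$statistic,
               p_value = fit$p_value, model_used = fit$model_used,
               fallback_flag = fit$fallback_flag, degenerate = fit$degenerate,
               random_effect_sd = fit$random_effect_sd,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- adjust_bh(out$p_value)
  out$sig_raw <- !is.na(out$p_value) & out$p_value < alpha
  out$sig_adj <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  out <- out[order(out$p_value), c("transcript_id", "n_control", "n_condition",
                                   "estimate", "std_error", "statistic",
                                   "p_value", "p_adjusted", "model_used",
                                   "fallback_flag", "degenerate",
                                   "random_effect_sd", "sig_raw", "sig_adj")]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "model") <- model
  attr(out, "logscale") <- logscale
  out
}

#' Write differential-length results as TSV
#'
#' Columns: `feature, n_ctrl, n_cond, estimate, se, stat, pval, padj, model,
#' fallback, sig_raw, sig_adj`.
#'
#' @param results Result table from [run_differential_length()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_length_results <- function(results, path) {
  df <- data.frame(feature = results$transcript_id,
                   n_ctrl = results$n_control, n_cond = results$n_condition,
                   estimate = results$estimate, se = results$std_error,
                   stat = results$statistic, pval = results$p_value,
                   padj = results$p_adjusted, model = results$model_used,
                   fallback = results$fallback_flag,
                   sig_raw = results$sig_raw, sig_adj = results$sig_adj,
                   stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}
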