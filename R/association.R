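# Copy-number / methylation association, case-control comparison, and
# cross-platform validation.

# fast OLS for one bin: returns beta, se, p for the first non-intercept column
ols_meth_term <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  df <- length(y) - fit$rank
  if (df < 1L || fit$rank < ncol(X)) return(NULL)
  R <- qr.R(fit$qr)
  XtX_inv <- chol2inv(R[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE])
  sigma2 <- sum(fit$residuals^2) / df
  se <- sqrt(diag(XtX_inv) * sigma2)
  beta <- fit$coefficients
  t <- beta / se
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  list(beta = beta[2], se = se[2], p = p[2], df = df)
}

#' Per-bin regression of copy number on bin methylation
#'
#' For every filter-passing bin, fits ordinary least squares with the
#' sample's copy number as the response and the bin's mean methylation as the
#' predictor of interest, adjusted for age, sex and (when present and
#' variable) disease group:
#' `cn ~ mean_meth + age + sex + group`. The two-sided p-value of the
#' methylation coefficient is reported and Benjamini-Hochberg adjusted across
#' all tested bins (the FDR family is the set of bins supplied, i.e., one
#' segment at a time). With `meth_as_response = TRUE` the symmetric model
#' `mean_meth ~ cn + ...` is fitted instead.
#'
#' @param cn data.frame with `sample_id` and `cn` (one segment).
#' @param bins data.frame with `sample_id`, `start`, `end`, `mean_meth`,
#'   `pass` — stacked per-sample output of [bin_methylation()].
#' @param covariates data.frame with `sample_id`, `age`, `sex` and optional
#'   `group`.
#' @param min_samples minimum complete samples per bin (default: number of
#'   predictors + 2).
#' @param meth_as_response flip response and predictor of interest.
#' @param alpha significance threshold on the q-value (default 0.05).
#' @return data.frame, one row per distinct bin: `start`, `end`, `n`,
#'   `beta`, `se`, `p_value`, `q_value`, `significant`, `reason`
#'   (NA for tested bins, otherwise why the bin was skipped).
#' @export
per_bin_regression <- function(cn, bins, covariates,
                               min_samples = NULL,
                               meth_as_response = FALSE,
                               alpha = 0.05) {
  need <- c("sample_id", "age", "sex")
  if (!all(need %in% names(covariates))) {
    stop2("covariates need columns: ", paste(need, collapse = ", "))
  }
  covs <- c("age", "sex")
  if ("group" %in% names(covariates) &&
      length(unique(stats::na.omit(covariates$group))) > 1L) {
    covs <- c(covs, "group")
  }
  meta <- merge(cn[, c("sample_id", "cn")], covariates, by = "sample_id")
  if (anyNA(meta[, c("cn", covs)])) {
    bad <- meta$sample_id[!stats::complete.cases(meta[, c("cn", covs)])]
    stop2("missing covariate or CN for sample(s) entering regression: ",
          paste(bad, collapse = ", "))
  }
  if (is.null(min_samples)) min_samples <- length(covs) + 1L + 2L
  use <- bins[bins$pass, , drop = FALSE]
  keys <- unique(use[, c("start", "end")])
  keys <- keys[order(keys$start), , drop = FALSE]
  rows <- lapply(seq_len(nrow(keys)), function(k) {
    b <- use[use$start == keys$start[k] & use$end == keys$end[k], ,
             drop = FALSE]
    d <- merge(meta, b[, c("sample_id", "mean_meth")], by = "sample_id")
    d <- d[stats::complete.cases(d[, c("cn", "mean_meth", covs)]), ,
           drop = FALSE]
    out <- data.frame(start = keys$start[k], end = keys$end[k],
                      n = nrow(d), beta = NA_real_, se = NA_real_,
                      p_value = NA_real_, reason = NA_character_,
                      stringsAsFactors = FALSE)
    if (nrow(d) < min_samples) {
      out$reason <- "too_few_samples"
      return(out)
    }
    if (meth_as_response) {
      X <- cbind(1, d$cn, as.matrix(d[, covs]))
      y <- d$mean_meth
    } else {
      X <- cbind(1, d$mean_meth, as.matrix(d[, covs]))
      y <- d$cn
    }
    if (qr(X)$rank < ncol(X)) {
      out$reason <- "collinear"
      return(out)
    }
    fit <- ols_meth_term(X, y)
    if (is.null(fit)) {
      out$reason <- "not_estimable"
      return(out)
    }
    out$beta <- fit$beta
    out$se <- fit$se
    out$p_value <- fit$p
    out
  })
  res <- do.call(rbind, rows)
  res$q_value <- NA_real_
  tested <- !is.na(res$p_value)
  if (any(tested)) res$q_value[tested] <- bh_fdr(res$p_value[tested])
  res$significant <- !is.na(res$q_value) & res$q_value < alpha
  res[, c("start", "end", "n", "beta", "se", "p_value", "q_value",
          "significant", "reason")]
}

#' Benjamini-Hochberg step-up false discovery rate adjustment
#'
#' `q_i = min_{j: p_(j) >= p_(i)} ( m * p_(j) / j )`, capped at 1, returned
#' in the input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop2("p-values must lie in [0, 1]")
  }
  m <- length(p_values)
  o <- order(p_values, decreasing = TRUE)
  q <- pmin(1, cummin(m / (m:1) * p_values[o]))
  q[order(o)]
}

#' Case-control comparison of copy number by logistic regression
#'
#' Fits `group ~ cn + age + sex` by maximum likelihood and reports the Wald
#' p-value of the copy-number term. Perfect separation or a degenerate CN
#' distribution is reported as non-estimable rather than an error.
#'
#' @param cn data.frame with `sample_id` and `cn`.
#' @param covariates data.frame with `sample_id`, `age`, `sex`, `group`
#'   (binary 0/1).
#' @param segment label carried into the result.
#' @return one-row data.frame: `segment`, `n`, `coef_cn`, `se`, `p_value`,
#'   `estimable`, `note`.
#' @export
group_comparison <- function(cn, covariates, segment = NA_character_) {
  d <- merge(cn[, c("sample_id", "cn")], covariates, by = "sample_id")
  d <- d[stats::complete.cases(d[, c("cn", "age", "sex", "group")]), ,
         drop = FALSE]
  res <- data.frame(segment = segment, n = nrow(d), coef_cn = NA_real_,
                    se = NA_real_, p_value = NA_real_, estimable = FALSE,
                    note = NA_character_, stringsAsFactors = FALSE)
  if (nrow(d) < 8L) {
    res$note <- "fewer than 8 complete samples"
    return(res)
  }
  if (length(unique(d$group)) < 2L) {
    res$note <- "only one group present"
    return(res)
  }
  if (stats::sd(d$cn) == 0) {
    res$note <- "CN constant across samples"
    return(res)
  }
  fit <- suppressWarnings(
    stats::glm(group ~ cn + age + sex, data = d, family = stats::binomial()))
  co <- summary(fit)$coefficients
  if (!fit$converged || !"cn" %in% rownames(co) ||
      co["cn", "Std. Error"] > 1e3 * max(abs(co["cn", "Estimate"]), 1)) {
    res$note <- "non-estimable (separation or non-convergence)"
    return(res)
  }
  res$coef_cn <- co["cn", "Estimate"]
  res$se <- co["cn", "Std. Error"]
  res$p_value <- co["cn", "Pr(>|z|)"]
  res$estimable <- TRUE
  res
}

#' Cross-platform copy-number correlation
#'
#' Validates one quantification route against another (e.g., standard WGS vs
#' bisulphite libraries from the same individuals) by Spearman rank
#' correlation on sample-matched CN estimates, plus the Pearson r-squared.
#' Ties receive average ranks. The Spearman p-value uses the exact
#' permutation distribution for fewer than 10 tie-free pairs and the
#' t-approximation otherwise.
#'
#' @param cn_a,cn_b data.frames with `sample_id` and `cn`; matched by id.
#' @return one-row data.frame: `n`, `spearman_r`, `spearman_p`,
#'   `pearson_r2`.
#' @export
platform_correlation <- function(cn_a, cn_b) {
  unmatched <- c(setdiff(cn_a$sample_id, cn_b$sample_id),
                 setdiff(cn_b$sample_id, cn_a$sample_id))
  if (length(unmatched)) {
    stop2("unmatched sample ids: ", paste(unique(unmatched), collapse = ", "))
  }
  d <- merge(cn_a[, c("sample_id", "cn")], cn_b[, c("sample_id", "cn")],
             by = "sample_id", suffixes = c("_a", "_b"))
  if (nrow(d) < 4L) stop2("need at least 4 matched pairs")
  ties <- anyDuplicated(d$cn_a) || anyDuplicated(d$cn_b)
  ct <- suppressWarnings(
    stats::cor.test(d$cn_a, d$cn_b, method = "spearman",
                    exact = nrow(d) < 10L && !ties))
  r2 <- stats::cor(d$cn_a, d$cn_b)^2
  data.frame(n = nrow(d), spearman_r = unname(ct$estimate),
             spearman_p = ct$p.value, pearson_r2 = r2)
}
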