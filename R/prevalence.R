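#' Covariate-adjusted prevalence by marginal standardization
#'
#' Fits a weighted logistic regression of a binary outcome on an exposure
#' factor plus adjustment covariates, then reports for each exposure
#' level the weighted mean of the predicted probabilities obtained by
#' substituting that level for every child (marginal standardization).
#' With no covariates the adjusted prevalence equals the weighted crude
#' prevalence in each level. Standard errors come from a seeded
#' nonparametric bootstrap over children.
#'
#' Weights are treated as single-level sampling weights (normalized to
#' mean 1 inside the fit); design-based clustered variance is out of
#' scope. Complete separation is reported as an estimation failure, never
#' silently returned.
#'
#' @param data Cohort table, one row per child.
#' @param outcome Bare column name of the binary outcome (logical or
#'   0/1).
#' @param exposure Bare column name of the factor whose level-specific
#'   prevalences are wanted; omit for the overall prevalence.
#' @param covariates Character vector of adjustment covariate column
#'   names (default none).
#' @param weights Bare column name of the sampling weights.
#' @param n_boot Bootstrap replicates for the SE (default 200; 0
#'   disables).
#' @param seed Seed for the bootstrap.
#' @return An object of class `adjusted_prevalence`; see [tidy()] for the
#'   per-level table (`level`, `n`, `prevalence`, `se`, `conf_low`,
#'   `conf_high`).
#' @export
adjusted_prevalence <- function(data, outcome, exposure = NULL,
                                covariates = character(),
                                weights = sampling_weight,
                                n_boot = 200, seed = NULL) {
  y <- dplyr::pull(data, {{ outcome }})
  if (!all(y %in% c(0, 1, TRUE, FALSE))) {
    abort("outcome must be binary.", class = "accel_argument_error")
  }
  w <- dplyr::pull(data, {{ weights }})
  exp_quo <- rlang::enquo(exposure)
  has_exposure <- !rlang::quo_is_null(exp_quo)
  df <- data.frame(.y = as.numeric(y), .w = w / mean(w))
  if (has_exposure) {
    df$.exposure <- factor(dplyr::pull(data, {{ exposure }}))
  }
  for (cv in covariates) df[[cv]] <- data[[cv]]
  rhs <- c(if (has_exposure) ".exposure", covariates)
  form <- stats::as.formula(
    paste(".y ~", if (length(rhs)) paste(rhs, collapse = " + ") else "1")
  )

  fit_once <- function(d) {
    fit <- suppressWarnings(
      glm(form, family = quasibinomial(), data = d, weights = .w)
    )
    if (!fit$converged || any(abs(coef(fit)) > 15, na.rm = TRUE) ||
        anyNA(coef(fit))) {
      abort("logistic model did not converge (possible separation or empty level); adjusted prevalences are not estimable.",
            class = "accel_estimation_error")
    }
    fit
  }
  standardize <- function(fit, d) {
    if (!has_exposure) {
      return(setNames(weighted.mean(predict(fit, type = "response"), d$.w),
                      "overall"))
    }
    lv <- levels(d$.exposure)
    vapply(lv, function(l) {
      nd <- d
      nd$.exposure <- factor(l, levels = lv)
      weighted.mean(predict(fit, newdata = nd, type = "response"), d$.w)
    }, numeric(1))
  }

  fit <- fit_once(df)
  est <- standardize(fit, df)
  boot <- NULL
  if (n_boot > 0) {
    boot <- with_seed(seed, {
      reps <- purrr::map(seq_len(n_boot), function(i) {
        idx <- sample.int(nrow(df), replace = TRUE)
        d <- df[idx, , drop = FALSE]
        tryCatch(standardize(fit_once(d), d),
                 error = function(e) rep(NA_real_, length(est)))
      })
      do.call(rbind, reps)
    })
  }
  tab <- tibble::tibble(
    level = names(est),
    n = if (has_exposure) as.integer(table(df$.exposure)[names(est)]) else nrow(df),
    prevalence = as.numeric(est)
  )
  if (!is.null(boot)) {
    tab$se <- apply(boot, 2L, sd, na.rm = TRUE)
    tab$conf_low <- apply(boot, 2L, quantile, 0.025, na.rm = TRUE)
    tab$conf_high <- apply(boot, 2L, quantile, 0.975, na.rm = TRUE)
  }
  structure(
    list(estimates = tab, model = fit, n = nrow(df), n_boot = n_boot,
         covariates = covariates, boot = boot),
    class = "adjusted_prevalence"
  )
}

#' @export
print.adjusted_prevalence <- function(x, ...) {
  cat(sprintf("Adjusted prevalence (marginal standardization, n = %d, %d bootstrap reps)\n",
              x$n, x$n_boot))
  print(x$estimates)
  invisible(x)
}

#' Benjamini-Hochberg annotation of pairwise comparisons
#'
#' Applies the Benjamini-Hochberg step-up rule at level `q` to a vector
#' of pairwise p-values: with sorted p-values p(1) <= ... <= p(m), all
#' hypotheses up to the largest k with p(k) <= k q / m are rejected.
#' Adjusted p-values come from [stats::p.adjust()] (`method = "BH"`);
#' rejection at `q` of the adjusted value is equivalent to the step-up
#' rule. Significant pairs are labelled with letter superindices (a, b,
#' ...) in input order, the convention used to annotate summary tables.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param q False discovery rate level (default 0.05).
#' @param labels Optional character labels (e.g. "boys vs girls").
#' @return Tibble with `label`, `p_value`, `p_adjusted`, `significant`,
#'   `marker` (letter for significant pairs, `""` otherwise).
#' @examples
#' pairwise_bh(c(0.01, 0.02, 0.20))
#' @export
pairwise_bh <- function(p, q = 0.05, labels = NULL) {
  if (length(p) < 1L || any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1].", class = "accel_argument_error")
  }
  adj <- p.adjust(p, method = "BH")
  sig <- adj <= q
  marker <- character(length(p))
  marker[sig] <- letters[seq_len(sum(sig))]
  tibble::tibble(
    label = labels %||% paste0("pair_", seq_along(p)),
    p_value = p,
    p_adjusted = adj,
    significant = sig,
    marker = marker
  )
}

#' Bootstrap pairwise group comparisons
#'
#' For every pair of levels of a grouping factor, computes a two-sided
#' bootstrap p-value for the difference of either season-adjusted group
#' medians or adjusted prevalences (percentile method: the p-value is
#' twice the smaller tail proportion of bootstrap differences on either
#' side of zero), then applies [pairwise_bh()] across the pairs.
#'
#' @param data Cohort table.
#' @param outcome Bare outcome column.
#' @param by Bare grouping column.
#' @param type `"median"` (season-adjusted median difference) or
#'   `"prevalence"` (crude weighted prevalence difference).
#' @param weights,season Bare weight/season columns.
#' @param n_boot Bootstrap replicates (default 199).
#' @param q FDR level for the BH annotation.
#' @param seed Seed.
#' @return The [pairwise_bh()] tibble with `level_a`/`level_b` columns.
#' @export
pairwise_group_tests <- function(data, outcome, by,
                                 type = c("median", "prevalence"),
                                 weights = sampling_weight, season = season,
                                 n_boot = 199, q = 0.05, seed = NULL) {
  type <- match.arg(type)
  df <- tibble::tibble(
    y = as.numeric(dplyr::pull(data, {{ outcome }})),
    w = dplyr::pull(data, {{ weights }}),
    s = as.character(dplyr::pull(data, {{ season }})),
    g = as.character(dplyr::pull(data, {{ by }}))
  )
  season_w <- tapply(df$w, df$s, sum)
  season_w <- season_w / sum(season_w)
  stat_one <- function(d) {
    if (type == "prevalence") return(weighted.mean(d$y, d$w))
    pi_t <- season_w[unique(d$s)] / sum(season_w[unique(d$s)])
    pi_g <- tapply(d$w, d$s, sum)[names(pi_t)]
    pi_g <- pi_g / sum(pi_g)
    weighted_quantile(d$y, d$w * as.numeric(pi_t[d$s] / pi_g[d$s]), 0.5)
  }
  groups <- split(df, df$g)
  lv <- names(groups)
  boot_stats <- with_seed(seed, {
    purrr::map(groups, function(d) {
      replicate(n_boot, stat_one(d[sample.int(nrow(d), replace = TRUE), ,
                                   drop = FALSE]))
    })
  })
  pairs <- utils::combn(lv, 2L)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    diff <- boot_stats[[a]] - boot_stats[[b]]
    p_lo <- (1 + sum(diff <= 0)) / (n_boot + 1)
    p_hi <- (1 + sum(diff >= 0)) / (n_boot + 1)
    tibble::tibble(level_a = a, level_b = b,
                   p = min(1, 2 * min(p_lo, p_hi)))
  })
  out <- pairwise_bh(res$p, q = q,
                     labels = paste(res$level_a, "vs", res$level_b))
  dplyr::bind_cols(res[c("level_a", "level_b")], out)
}
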