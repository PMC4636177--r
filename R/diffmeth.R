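# Per-probe two-group comparison on the beta scale with empirical-Bayes
# variance moderation. The screen compares NLRP7-mutated moles against
# pooled normal placenta; any group pairing can be requested.

#' Per-probe group difference and pooled variance
#'
#' For each probe, the mean beta difference between a case group and a
#' (possibly pooled) control group, the pooled two-group residual variance
#' and its degrees of freedom. Tests are run on beta values directly —
#' not logit-transformed M-values — because the screen's effect-size
#' threshold is stated on the beta scale.
#'
#' @param dataset a `MethylationDataset`.
#' @param case_group sample group(s) forming the case side (default
#'   `"NLRP7_RHM"`).
#' @param control_groups sample group(s) pooled as controls (default first
#'   trimester plus term placenta).
#' @return data.frame with columns `probe_id`, `delta_beta`
#'   (mean case - mean control), `s_sq` (pooled residual variance),
#'   `df_residual` (n1 + n2 - 2), `n_case`, `n_control`.
#' @export
group_difference <- function(dataset, case_group = "NLRP7_RHM",
                             control_groups = c("PLACENTA_FIRST", "PLACENTA_TERM")) {
  case_ids <- samples_in_group(dataset, case_group)
  ctrl_ids <- samples_in_group(dataset, control_groups)
  n1 <- length(case_ids); n2 <- length(ctrl_ids)
  if (n1 < 2 || n2 < 2) {
    stop("each side needs at least 2 samples (case ", n1, ", control ", n2, ")")
  }
  b1 <- dataset$beta[, case_ids, drop = FALSE]
  b2 <- dataset$beta[, ctrl_ids, drop = FALSE]
  m1 <- rowMeans(b1); m2 <- rowMeans(b2)
  ss1 <- rowSums((b1 - m1)^2)
  ss2 <- rowSums((b2 - m2)^2)
  data.frame(probe_id = dataset$annotation$probe_id,
             delta_beta = m1 - m2,
             s_sq = (ss1 + ss2) / (n1 + n2 - 2),
             df_residual = n1 + n2 - 2L,
             n_case = n1, n_control = n2,
             stringsAsFactors = FALSE)
}

#' Inverse of the trigamma function
#'
#' Solves `trigamma(y) = x` for `y > 0` by Newton iteration on the
#' reciprocal scale (monotone and well conditioned); used to moment-match
#' the prior degrees of freedom of the variance prior.
#'
#' @param x positive value; `x <= 0` maps to `Inf`.
#' @return The positive solution `y`.
#' @export
trigamma_inverse <- function(x) {
  if (!is.finite(x) || x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in seq_len(50)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

#' Empirical-Bayes variance moderation and moderated t-statistics
#'
#' Fits a scaled inverse-chi-square prior (`d0` prior degrees of freedom,
#' `s0_sq` prior variance) to the per-probe sample variances by moment
#' matching on the log scale: with `e_g = log(s2_g) - digamma(df/2) +
#' log(df/2)`, `E[e] = log(s0_sq) - digamma(d0/2) + log(d0/2)` and
#' `Var[e] = trigamma(df/2) + trigamma(d0/2)`, so `d0` comes from a
#' trigamma inversion of the excess log-variance spread and `s0_sq` from the
#' corrected mean. The posterior variance is the weighted combination
#' `(d0 * s0_sq + df * s2_g) / (d0 + df)`; the moderated t is the mean
#' difference over its posterior standard error and its two-sided p-value is
#' referred to a t distribution on `d0 + df` degrees of freedom (a normal
#' reference when `d0` is infinite, which is also the no-excess-spread
#' branch, e.g. when all sample variances are identical).
#'
#' Zero (or tiny) sample variances are floored at `var_floor` before the
#' log-moment fit so degenerate probes cannot poison the prior; the
#' posterior combination uses the raw variances.
#'
#' @param stats data.frame from [group_difference()] (columns `delta_beta`,
#'   `s_sq`, `df_residual`, `n_case`, `n_control`; `probe_id` carried
#'   through if present). All probes must share one `df_residual`
#'   (balanced design), and at least 50 probes are required when the prior
#'   is estimated (the moment fit needs mass).
#' @param d0_override force the prior degrees of freedom instead of
#'   estimating (0 gives the ordinary pooled t for every probe).
#' @param s0_override force the prior variance (only meaningful together
#'   with a finite nonzero `d0_override`).
#' @param var_floor variance floor applied before the log-moment fit.
#' @return `list(params = list(d0, s0_sq), stats = data.frame)` where the
#'   stats table adds `s_sq_post`, `t_mod` and `p_value`.
#' @export
ebayes_moderate <- function(stats, d0_override = NULL, s0_override = NULL,
                            var_floor = 1e-8) {
  df <- unique(stats$df_residual)
  if (length(df) != 1) stop("all probes must share one residual df")
  df <- as.numeric(df)
  n <- nrow(stats)
  s2_floored <- pmax(stats$s_sq, var_floor)

  estimate_prior <- is.null(d0_override) || is.null(s0_override)
  if (is.null(d0_override)) {
    if (n < 50) stop("need at least 50 probes for the log-variance moment fit")
    e <- log(s2_floored) - digamma(df / 2) + log(df / 2)
    emean <- mean(e)
    excess <- var(e) - trigamma(df / 2)
    if (is.finite(excess) && excess > 0) {
      d0 <- 2 * trigamma_inverse(excess)
      s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s0_sq <- exp(emean)
    }
  } else {
    d0 <- d0_override
    s0_sq <- if (!is.null(s0_override)) s0_override else {
      if (d0 == 0) NA_real_ else exp(mean(log(s2_floored)))
    }
  }

  if (is.infinite(d0)) {
    s_post <- rep(s0_sq, n)
  } else if (d0 == 0) {
    s_post <- stats$s_sq
  } else {
    s_post <- (d0 * s0_sq + df * stats$s_sq) / (d0 + df)
  }

  se <- sqrt(s_post * (1 / stats$n_case + 1 / stats$n_control))
  t_mod <- stats$delta_beta / se
  t_mod[stats$delta_beta == 0 & se == 0] <- 0
  p <- 2 * stats::pt(-abs(t_mod), df = d0 + df)

  out <- stats
  out$s_sq_post <- s_post
  out$t_mod <- t_mod
  out$p_value <- p
  list(params = list(d0 = d0, s0_sq = s0_sq), stats = out)
}

#' One-step per-probe differential methylation
#'
#' Convenience wrapper: [group_difference()] followed by
#' [ebayes_moderate()], with chromosome and position merged in for the
#' region caller.
#'
#' @inheritParams group_difference
#' @param ... passed to [ebayes_moderate()].
#' @return `list(params, stats)`; `stats` gains `chrom` and `pos` columns.
#' @export
probe_stats <- function(dataset, case_group = "NLRP7_RHM",
                        control_groups = c("PLACENTA_FIRST", "PLACENTA_TERM"),
                        ...) {
  gd <- group_difference(dataset, case_group, control_groups)
  mod <- ebayes_moderate(gd, ...)
  idx <- match(mod$stats$probe_id, dataset$annotation$probe_id)
  mod$stats$chrom <- dataset$annotation$chrom[idx]
  mod$stats$pos <- dataset$annotation$pos[idx]
  mod
}

#' Export a probe-statistic table as TSV
#'
#' @param stats stats data.frame from [probe_stats()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_probe_stats <- function(stats, path) {
  cols <- intersect(c("probe_id", "chrom", "pos", "delta_beta", "s_sq",
                      "s_sq_post", "t_mod", "p_value"), names(stats))
  write.table(stats[, cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
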