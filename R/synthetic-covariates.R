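# Covariate synthesis with planted feature-covariate correlations.

#' Generate per-subject covariates
#'
#' Draws each covariate so that its per-group mean and SD match the
#' configured specification, clipped to the configured bounds (and rounded
#' for integer-valued scales). For every planted correlation, the
#' standardized covariate is a linear blend of the standardized realized
#' EEG feature(s) and independent Gaussian noise, with blend weights chosen
#' so that the population correlation with each named feature equals its
#' target `r`; several targets on one covariate are solved jointly.
#' Configured missing rates are applied per group, missing at random.
#'
#' @param config An [effect_config()].
#' @param features Subject-level feature summary (one row per subject,
#'   columns `subject`, `group` plus feature columns such as
#'   `rel_theta_ec`). Required when `planted_correlations` is non-empty;
#'   may be `NULL` otherwise.
#' @param seed Integer seed; defaults to the config seed offset by a fixed
#'   stream so recordings and covariates are independent draws.
#' @return A tibble with one row per subject: `subject`, `group` and one
#'   column per covariate; `NA` marks missing entries.
#' @export
generate_covariates <- function(config, features = NULL, seed = NULL) {
  stopifnot(inherits(config, "effect_config"))
  spec <- config$covariate_spec
  planted <- config$planted_correlations
  subjects <- cohort_subjects(config)
  seed <- seed %||% child_seed(config$seed, 1L, stream = 9L)

  if (nrow(planted)) {
    if (any(abs(planted$r) >= 1)) {
      abort_bad_input("Planted correlation targets must satisfy |r| < 1.")
    }
    if (is.null(features)) {
      abort_bad_input("`features` is required when correlations are planted.")
    }
    missing_feats <- setdiff(unique(planted$feature), names(features))
    if (length(missing_feats)) {
      abort_unknown_label(sprintf(
        "Planted correlation requested against absent feature(s): %s.",
        paste(missing_feats, collapse = ", ")
      ))
    }
  }

  with_seed(seed, {
    out <- subjects[, c("subject", "group")]
    for (cov_name in unique(spec$covariate)) {
      cov_spec <- spec[spec$covariate == cov_name, ]
      applicable <- out$group %in% cov_spec$group
      n_app <- sum(applicable)
      values <- rep(NA_real_, nrow(out))

      idx_app <- which(applicable)
      grp_app <- out$group[idx_app]
      mu_vec <- cov_spec$mean[match(grp_app, cov_spec$group)]
      sd_vec <- cov_spec$sd[match(grp_app, cov_spec$group)]

      targets <- if (nrow(planted)) planted[planted$covariate == cov_name, ] else planted
      if (!is.null(targets) && nrow(targets)) {
        feat <- features[match(out$subject[idx_app], features$subject),
          targets$feature,
          drop = FALSE
        ]
        z <- scale(as.matrix(feat))
        if (all(!is.finite(z))) {
          abort_degenerate(sprintf(
            "No finite feature values available to plant a correlation for '%s'.",
            cov_name
          ))
        }
        if (any(!is.finite(apply(z, 2, stats::sd, na.rm = TRUE))) ||
          any(apply(z, 2, stats::sd, na.rm = TRUE) == 0)) {
          abort_degenerate(sprintf(
            "Feature(s) for '%s' have zero variance; cannot plant a correlation.",
            cov_name
          ))
        }
        # subjects lacking a feature (e.g. excluded in that condition) get a
        # pure-noise draw; the blend is solved on the complete rows
        ok <- stats::complete.cases(z)
        sigma <- stats::cor(z[ok, , drop = FALSE])
        eps <- stats::rnorm(n_app)
        # The covariate is mu_g + sd_g * (Z a + s * eps). Group-mean structure
        # in both the covariate and the features contributes to the pooled
        # correlation, so the blend weights `a` are solved numerically so
        # that the realized pooled correlation with each target feature
        # equals its target r (clipping/rounding below may attenuate it).
        blend <- function(a, resid_sd) {
          cz <- eps
          cz[ok] <- drop(z[ok, , drop = FALSE] %*% a) + resid_sd * eps[ok]
          cz
        }
        achieved <- function(a) {
          s2 <- 1 - drop(crossprod(a, sigma %*% a))
          v <- mu_vec + sd_vec * blend(a, sqrt(max(s2, 1e-8)))
          drop(stats::cor(v[ok], z[ok, , drop = FALSE]))
        }
        obj <- function(a) sum((achieved(a) - targets$r)^2)
        a0 <- solve(sigma, targets$r)
        opt <- stats::optim(a0, obj, method = "BFGS")
        a <- opt$par
        resid_var <- 1 - drop(crossprod(a, sigma %*% a))
        if (resid_var <= 0 || opt$value > 0.01) {
          abort_bad_input(sprintf(
            "Planted correlations for '%s' are jointly infeasible.", cov_name
          ))
        }
        std <- blend(a, sqrt(resid_var))
      } else {
        std <- stats::rnorm(n_app)
      }

      for (g in cov_spec$group) {
        row <- cov_spec[cov_spec$group == g, ]
        sel_local <- which(grp_app == g)
        v <- row$mean + row$sd * std[sel_local]
        v <- pmin(pmax(v, row$lower), row$upper)
        if (isTRUE(row$integer)) v <- round(v)
        if (row$missing_rate > 0) {
          v[stats::runif(length(v)) < row$missing_rate] <- NA_real_
        }
        values[idx_app[sel_local]] <- v
      }
      out[[cov_name]] <- values
    }
    out
  })
}
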