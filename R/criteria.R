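#' Log multivariate beta function
#'
#' `log B(x) = sum_m log Gamma(x_m) - log Gamma(sum_m x_m)`, the log
#' normalizing constant of the Dirichlet density.  Every marginal criterion
#' decomposes into differences of this primitive, evaluated in log space.
#'
#' @param x positive numeric vector.
#' @return Scalar `log B(x)`.
#' @examples
#' log_multivariate_beta(c(1, 1))   # 0:  B(1,1) = 1
#' @export
log_multivariate_beta <- function(x) {
  if (!length(x) || any(!is.finite(x)) || any(x <= 0))
    stop("log_multivariate_beta needs strictly positive components")
  sum(lgamma(x)) - lgamma(sum(x))
}

#' Stirling expansion of the log multivariate beta function
#'
#' Asymptotic expansion through the 1/(12 x) terms,
#' `sum_m x_m log(x_m / sum(x)) - (1/2)(sum_m log(x_m / 2 pi) -
#' log(sum(x) / 2 pi)) + (1/12)(sum_m 1/x_m - 1/sum(x))`,
#' with error of order `sum(x)^-3`.  Intended for large components (all
#' components >= 100 gives relative agreement with the exact value better
#' than 1e-6); it is deliberately not guarded against small inputs, where it
#' is simply inaccurate.
#'
#' @param x positive numeric vector.
#' @return Scalar approximation to `log B(x)`.
#' @export
stirling_log_beta <- function(x) {
  s <- sum(x)
  sum(x * log(x / s)) -
    0.5 * (sum(log(x / (2 * pi))) - log(s / (2 * pi))) +
    (sum(1 / x) - 1 / s) / 12
}

# row-wise log B(mat[i, ])
lbeta_rows <- function(mat) rowSums(lgamma(mat)) - lgamma(rowSums(mat))

criterion_names <- c("AIC", "BIC", "nLML", "nLPD", "nLPPD",
                     "WAIC1", "WAIC2", "DIC1", "DIC2", "LOO", "LHO")

# Closed-form evaluation of the requested criteria from a count table.
# Returns a named list of criterion values plus effective sizes
# k_WAIC1/k_WAIC2/k_DIC1/k_DIC2 and the raw LML/LPD/LPPD when computed.
criteria_core <- function(counts, alpha = 1,
                          which = criterion_names, k_mode = "literal") {
  Np <- counts$pooled
  M <- n_states(counts$alphabet)
  X <- nrow(Np)
  a <- check_alpha(alpha, M)
  a0 <- sum(a)
  A <- outer(rep(1, X), a)  # X x M prior matrix; also valid when X = 0
  Nx <- rowSums(Np)
  out <- list()

  if (any(c("AIC", "BIC") %in% which)) {
    ab <- aic_bic(counts, k_mode = k_mode)
    out$AIC <- ab$AIC; out$BIC <- ab$BIC; out$k_param <- ab$k
  }

  lbeta_post <- lbeta_rows(Np + A)           # log B(N_x + alpha) per context
  lB_alpha <- sum(lgamma(a)) - lgamma(a0)

  if ("nLML" %in% which) {
    out$LML <- sum(lbeta_post) - X * lB_alpha
    out$nLML <- -2 * out$LML
  }
  if ("nLPD" %in% which) {
    out$LPD <- sum(lbeta_rows(2 * Np + A)) - sum(lbeta_post)
    out$nLPD <- -2 * out$LPD
  }

  need_lppd <- any(c("nLPPD", "WAIC1", "WAIC2") %in% which)
  need_loo <- "LOO" %in% which
  need_w2 <- "WAIC2" %in% which
  if (need_lppd || need_loo) {
    lppd <- loo_sum <- kW2 <- 0
    for (ptj in counts$per_traj) {
      idx <- match(rownames(ptj), rownames(Np))
      Ns <- Np[idx, , drop = FALSE]
      Aj <- matrix(a, nrow(ptj), M, byrow = TRUE)
      Nxs <- Nx[idx]
      Nxj <- rowSums(ptj)
      base <- sum(lbeta_post[idx])
      if (need_lppd)
        lppd <- lppd +
          sum(lgamma(Ns + ptj + Aj)) - sum(lgamma(Nxs + Nxj + a0)) - base
      if (need_loo)
        loo_sum <- loo_sum +
          base - (sum(lgamma(Ns - ptj + Aj)) - sum(lgamma(Nxs - Nxj + a0)))
      if (need_w2)
        kW2 <- kW2 + sum(ptj^2 * trigamma(Ns + Aj)) -
          sum(Nxj^2 * trigamma(Nxs + a0))
    }
    if (need_lppd) { out$LPPD <- lppd; out$nLPPD <- -2 * lppd }
    if (need_loo) out$LOO <- -2 * loo_sum
    if (need_w2) out$k_WAIC2 <- kW2
  }

  if (any(c("WAIC1", "DIC1", "DIC2") %in% which)) {
    # posterior expectation of the log-likelihood (digamma identity) and
    # plug-in log-likelihood at the posterior mean, both as single sums
    e_loglik <- sum(Np * digamma(Np + A)) - sum(Nx * digamma(Nx + a0))
    plug <- sum(Np * log(Np + A)) - sum(Nx * log(Nx + a0))
    if ("WAIC1" %in% which) {
      out$k_WAIC1 <- 2 * out$LPPD - 2 * e_loglik
      out$WAIC1 <- -2 * out$LPPD + 2 * out$k_WAIC1
    }
    if (any(c("DIC1", "DIC2") %in% which)) {
      plugdev <- -2 * plug
      if ("DIC1" %in% which) {
        out$k_DIC1 <- 2 * (plug - e_loglik)
        out$DIC1 <- plugdev + 2 * out$k_DIC1
      }
      if ("DIC2" %in% which) {
        out$k_DIC2 <- 2 * (sum(Np^2 * trigamma(Np + A)) -
                             sum(Nx^2 * trigamma(Nx + a0)))
        out$DIC2 <- plugdev + 2 * out$k_DIC2
      }
    }
  }
  if ("WAIC2" %in% which)
    out$WAIC2 <- -2 * out$LPPD + 2 * out$k_WAIC2

  if ("LHO" %in% which && n_trajectories(counts) >= 2L)
    out$LHO <- lho(counts, alpha)

  out
}

#' AIC and BIC for a multistep Markov model
#'
#' Deviance term `-2 sum_x sum_m N_x,m log(N_x,m / N_x.)` (MLE plug-in, with
#' 0 log 0 = 0) plus the complexity penalty.  Two parameter-counting
#' conventions are supported: `"literal"` uses `k = M^h (M - 1)` for a
#' fixed-order-h model (boundary contexts not counted), `"contexts"` counts
#' the observed contexts (or blocks, for merged tables) times `(M - 1)`.
#' The BIC penalty is `log(total transitions) * k`.
#'
#' @param counts a [count_transitions()] table.
#' @param k_mode `"literal"` or `"contexts"`.  Merged (variable-length)
#'   tables require `"contexts"`.
#' @return List with elements `AIC`, `BIC`, `k`.
#' @export
aic_bic <- function(counts, k_mode = c("literal", "contexts")) {
  k_mode <- match.arg(k_mode)
  M <- n_states(counts$alphabet)
  if (k_mode == "literal") {
    if (counts$merged)
      stop("literal parameter counting is undefined for merged (variable-length) tables")
    k <- M^counts$h * (M - 1)
  } else {
    k <- sum(rowSums(counts$pooled) > 0) * (M - 1)
  }
  Np <- counts$pooled
  Nx <- rowSums(Np)
  pos <- Np > 0
  dev <- -2 * sum(Np[pos] * log(sweep(Np, 1L, pmax(Nx, 1), "/")[pos]))
  total <- sum(Nx)
  list(AIC = dev + 2 * k,
       BIC = dev + if (total > 0) log(total) * k else 0,
       k = k)
}

#' Marginal-likelihood family criteria (closed form)
#'
#' The log marginal likelihood `LML = sum_x log(B(N_x + alpha) / B(alpha))`,
#' the expected log predictive density
#' `LPD = sum_x log(B(2 N_x + alpha) / B(N_x + alpha))`, and its pointwise
#' (per-trajectory) version
#' `LPPD = sum_j sum_x log(B(N_x + N_x^(j) + alpha) / B(N_x + alpha))`.
#' Each is returned both raw and on the deviance scale (`-2 x`, prefixed
#' `n`), so that lower is better and values are comparable with the AIC.
#'
#' @inheritParams posterior_params
#' @return List with `nLML`, `nLPD`, `nLPPD` (deviance scale) and `LML`,
#'   `LPD`, `LPPD` (raw).
#' @export
marginal_criteria <- function(counts, alpha = 1) {
  r <- criteria_core(counts, alpha, which = c("nLML", "nLPD", "nLPPD"))
  r[c("nLML", "nLPD", "nLPPD", "LML", "LPD", "LPPD")]
}

#' Widely applicable information criterion (closed form)
#'
#' `WAIC = -2 LPPD + 2 k_WAIC`, with the effective model size computed
#' exactly: variant 1 from the gap between the LPPD and the posterior
#' expectation of the log-likelihood (digamma form), variant 2 from posterior
#' variances (trigamma form).
#'
#' @inheritParams posterior_params
#' @param variant 1 or 2.
#' @return List with `WAIC` and `k_eff`.
#' @export
waic <- function(counts, alpha = 1, variant = 1) {
  variant <- match.arg(as.character(variant), c("1", "2"))
  nm <- paste0("WAIC", variant)
  r <- criteria_core(counts, alpha, which = nm)
  list(WAIC = r[[nm]], k_eff = r[[paste0("k_WAIC", variant)]])
}

#' Deviance information criterion (closed form)
#'
#' `DIC = -2 log p(N | posterior-mean p) + 2 k_DIC`.  Variant 1 computes the
#' effective size from the gap between the plug-in log-likelihood and the
#' posterior expectation of the log-likelihood; variant 2 is twice the
#' posterior variance of the log-likelihood (trigamma form).
#'
#' @inheritParams waic
#' @return List with `DIC` and `k_eff`.
#' @export
dic <- function(counts, alpha = 1, variant = 1) {
  variant <- match.arg(as.character(variant), c("1", "2"))
  nm <- paste0("DIC", variant)
  r <- criteria_core(counts, alpha, which = nm)
  list(DIC = r[[nm]], k_eff = r[[paste0("k_DIC", variant)]])
}

#' Leave-one-out cross-validation (closed form)
#'
#' `LOO = -2 sum_j sum_x log(B(N_x + alpha) / B(N_x - N_x^(j) + alpha))`:
#' each trajectory is scored against the posterior trained on the other
#' J - 1 trajectories.  Already on the deviance scale.
#'
#' @inheritParams posterior_params
#' @return Scalar LOO.
#' @export
loo <- function(counts, alpha = 1) {
  criteria_core(counts, alpha, which = "LOO")$LOO
}

#' Leave-half-out (twofold) cross-validation (closed form)
#'
#' The trajectory set is split into the first ceiling(J/2) trajectories and
#' the remainder; each trajectory is scored against the posterior trained on
#' the opposite block,
#' `LHO = -2 sum_j sum_x log(B(N_x^other + N_x^(j) + alpha) /
#' B(N_x^other + alpha))`.  Deviance scale.
#'
#' @inheritParams posterior_params
#' @return Scalar LHO.
#' @export
lho <- function(counts, alpha = 1) {
  J <- n_trajectories(counts)
  if (J < 2L) stop("LHO undefined: need at least two trajectories (J >= 2)")
  M <- n_states(counts$alphabet)
  a <- check_alpha(alpha, M)
  a0 <- sum(a)
  halves <- split_half(counts)
  score_block <- function(per_block, other_pooled) {
    s <- 0
    for (ptj in per_block) {
      idx <- match(rownames(ptj), rownames(other_pooled))
      C <- matrix(0, nrow(ptj), M)
      hit <- !is.na(idx)
      if (any(hit)) C[hit, ] <- other_pooled[idx[hit], , drop = FALSE]
      Aj <- matrix(a, nrow(ptj), M, byrow = TRUE)
      s <- s + sum(lgamma(C + ptj + Aj)) -
        sum(lgamma(rowSums(C) + rowSums(ptj) + a0)) -
        (sum(lgamma(C + Aj)) - sum(lgamma(rowSums(C) + a0)))
    }
    s
  }
  -2 * (score_block(halves$first$per_traj, halves$second$pooled) +
          score_block(halves$second$per_traj, halves$first$pooled))
}

#' Evaluate all selection criteria for a set of candidate memory models
#'
#' For each candidate memory specification, counts are computed once (and
#' merged for variable-length specs) and all requested criteria are evaluated
#' in closed form.  Results are returned as a data frame with one row per
#' candidate, on the deviance scale throughout (lower is better).  For
#' variable-length candidates AIC/BIC always use context counting, whatever
#' `k_mode` says, since the literal convention is undefined for them.
#'
#' @param trajs a [trajectory_set()].
#' @param specs list of [memory_spec()] objects (or a numeric vector of
#'   orders, converted for convenience).
#' @param alpha Dirichlet prior vector or scalar (default 1, uniform).
#' @param k_mode parameter counting for AIC/BIC of fixed-order candidates:
#'   `"literal"` (`M^h (M - 1)`) or `"contexts"` (observed contexts times
#'   `M - 1`).
#' @param criteria character vector of criteria to compute (default all
#'   eleven).  LHO is omitted, with a warning, when J = 1.
#' @param pad history padding symbol passed to [count_transitions()]
#'   (default: the alphabet's boundary marker).
#' @return A data frame of class `"criteria_report"` with columns `model`,
#'   `h`, `k_param`, the criterion columns, and effective sizes `k_WAIC1`,
#'   `k_WAIC2`, `k_DIC1`, `k_DIC2` when computed.  The candidate specs are
#'   attached as attribute `"specs"`, the prior as `"alpha"`.
#' @examples
#' ab <- alphabet("-+")
#' ts <- parse_trajectories("+-++-++\n+--+-+++++-", ab)
#' evaluate_all(ts, 0:1)[, c("model", "AIC", "LOO")]
#' @export
evaluate_all <- function(trajs, specs, alpha = 1,
                         k_mode = c("literal", "contexts"),
                         criteria = criterion_names, pad = NULL) {
  k_mode <- match.arg(k_mode)
  if (is.numeric(specs)) specs <- lapply(specs, function(h) memory_spec(order = h))
  if (inherits(specs, "memory_spec")) specs <- list(specs)
  if (!length(specs)) stop("need at least one candidate memory spec")
  bad <- !vapply(specs, inherits, logical(1L), "memory_spec")
  if (any(bad)) stop("'specs' must be memory_spec objects or orders")
  criteria <- match.arg(criteria, criterion_names, several.ok = TRUE)
  J <- length(trajs$sequences)
  if ("LHO" %in% criteria && J < 2L) {
    warning("J = 1: LHO is undefined and omitted")
    criteria <- setdiff(criteria, "LHO")
  }
  rows <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    ct <- count_transitions(trajs, spec_base_order(sp), pad = pad)
    if (sp$kind == "partition") ct <- merge_contexts(ct, sp)
    km <- if (sp$kind == "partition") "contexts" else k_mode
    r <- criteria_core(ct, alpha, which = criteria, k_mode = km)
    if (!("AIC" %in% criteria))
      r$k_param <- aic_bic(ct, k_mode = km)$k
    rows[[i]] <- data.frame(
      model = sp$label, h = spec_base_order(sp),
      c(r[intersect(c("k_param", criteria,
                      "k_WAIC1", "k_WAIC2", "k_DIC1", "k_DIC2"), names(r))]),
      stringsAsFactors = FALSE)
  }
  rep_df <- do.call(rbind, rows)
  rownames(rep_df) <- NULL
  structure(rep_df, specs = specs, alpha = alpha, J = J, k_mode = k_mode,
            total_transitions = sum(lengths(trajs$sequences)),
            class = c("criteria_report", "data.frame"))
}

#' @export
print.criteria_report <- function(x, digits = 4, ...) {
  cat(sprintf("Model selection criteria (deviance scale; J = %d, %d transitions)\n",
              attr(x, "J"), attr(x, "total_transitions")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], round, digits = digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Select the best model from a criteria report
#'
#' The candidate with the smallest value of the named criterion wins; ties
#' are broken toward the simplest model (fewest parameters, then lowest
#' order).
#'
#' @param report a [evaluate_all()] report.
#' @param criterion criterion column name, e.g. `"LOO"`.
#' @return The winning [memory_spec()].
#' @export
select_model <- function(report, criterion) {
  if (!(criterion %in% names(report)))
    stop(sprintf("criterion '%s' not present in report", criterion))
  v <- report[[criterion]]
  if (all(is.na(v))) stop(sprintf("criterion '%s' has no values", criterion))
  o <- order(v, report$k_param, report$h, na.last = TRUE)
  attr(report, "specs")[[o[1L]]]
}

#' Write a criteria report to CSV
#'
#' Fixed column order (as produced by [evaluate_all()]), one row per model.
#'
#' @param report a [evaluate_all()] report.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}

#' Write a criteria report to JSON
#'
#' One object per model, plus the prior and sample metadata.
#'
#' @param report a [evaluate_all()] report.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(
    list(alpha = attr(report, "alpha"), J = attr(report, "J"),
         total_transitions = attr(report, "total_transitions"),
         k_mode = attr(report, "k_mode"),
         models = as.data.frame(report)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
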