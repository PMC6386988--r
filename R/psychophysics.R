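#' Classify responses against the phantom ground truth
#'
#' Each key press is matched to the nearest inclusion centre by Euclidean
#' distance in the X-Y plane. A press within `tolerance_mm` of that centre
#' (inclusive: a press at exactly the tolerance counts) is a true positive
#' (TP), otherwise a false positive (FP). With an inclusion-free phantom
#' every response is an FP.
#'
#' @param responses data.frame with `x_mm`, `y_mm` (one row per press).
#' @param phantom a `telepalp_phantom`.
#' @param tolerance_mm admitted centre-to-centre distance, mm (default 10,
#'   the inclusion diameter).
#' @return a list of class `telepalp_classified`: data.frame `detail`
#'   (`label`, `inclusion_id`, `distance_mm`), plus `tp_count`, `fp_count`,
#'   `tolerance_mm`.
#' @export
classify_responses <- function(responses, phantom, tolerance_mm = 10) {
  check_scalar_num(tolerance_mm, "tolerance_mm", 0, strict_lower = TRUE)
  inc <- phantom$inclusions
  n <- nrow(responses)
  if (!nrow(inc)) {
    detail <- data.frame(label = rep("FP", n), inclusion_id = rep(NA_integer_, n),
                         distance_mm = rep(NA_real_, n),
                         stringsAsFactors = FALSE)
  } else {
    nearest <- t(vapply(seq_len(n), function(i) {
      d <- sqrt((inc$x - responses$x_mm[i])^2 +
                (inc$y - responses$y_mm[i])^2)
      j <- which.min(d)
      c(inc$id[j], d[j])
    }, numeric(2)))
    if (n == 0) nearest <- matrix(numeric(0), ncol = 2)
    tp <- nearest[, 2] <= tolerance_mm
    detail <- data.frame(label = ifelse(tp, "TP", "FP"),
                         inclusion_id = ifelse(tp, as.integer(nearest[, 1]),
                                               NA_integer_),
                         distance_mm = nearest[, 2],
                         stringsAsFactors = FALSE)
  }
  structure(list(detail = detail,
                 tp_count = sum(detail$label == "TP"),
                 fp_count = sum(detail$label == "FP"),
                 tolerance_mm = tolerance_mm),
            class = "telepalp_classified")
}

#' Accuracy of classified responses
#'
#' By default the fraction of presses that landed on an inclusion,
#' `TP / (TP + FP)`. The alternative `"positives"` definition divides TP by
#' the count of collected responses minus FP (which for this two-label
#' scheme equals TP, making the ratio degenerate at 1 whenever any TP
#' exists); it is provided for completeness but not recommended.
#'
#' @param c a `telepalp_classified` (from [classify_responses()]).
#' @param definition `"responses"` (default, TP/(TP+FP)) or `"positives"`.
#' @return accuracy in `[0, 1]`.
#' @export
accuracy <- function(c, definition = c("responses", "positives")) {
  definition <- match.arg(definition)
  total <- c$tp_count + c$fp_count
  if (total == 0) abort("accuracy undefined with zero responses")
  if (definition == "responses") return(c$tp_count / total)
  p <- total - c$fp_count
  if (p == 0) abort("accuracy undefined: zero positives under this definition")
  c$tp_count / p
}

#' Sweep the classification tolerance
#'
#' Classifies every session at each tolerance and averages TP count, FP
#' count and accuracy across sessions, reproducing the tolerance curve
#' analysis (default tolerances 5, 10, 15, 20 mm).
#'
#' @param sessions a response data.frame or a list of them (one per
#'   session).
#' @param phantom a `telepalp_phantom`.
#' @param tolerances tolerances to sweep, mm.
#' @return data.frame `tolerance_mm`, `mean_tp`, `mean_fp`, `mean_accuracy`.
#' @export
tolerance_sweep <- function(sessions, phantom,
                            tolerances = c(5, 10, 15, 20)) {
  if (is.data.frame(sessions)) sessions <- list(sessions)
  if (!length(sessions)) abort("need at least one session")
  rows <- lapply(tolerances, function(tol) {
    cls <- lapply(sessions, classify_responses, phantom = phantom,
                  tolerance_mm = tol)
    acc <- vapply(cls, function(cc)
      if (cc$tp_count + cc$fp_count > 0) accuracy(cc) else NA_real_,
      numeric(1))
    data.frame(tolerance_mm = tol,
               mean_tp = mean(vapply(cls, `[[`, numeric(1), "tp_count")),
               mean_fp = mean(vapply(cls, `[[`, numeric(1), "fp_count")),
               mean_accuracy = mean(acc, na.rm = TRUE))
  })
  do.call(rbind, rows)
}

#' Identification rate per material
#'
#' Within a session an inclusion counts as identified when at least one TP
#' press matches it; the session's rate for a material is the identified
#' fraction of that material's inclusions. Rates are then averaged across
#' sessions, with the interquartile range as spread.
#'
#' @param sessions a response data.frame or list of them.
#' @param phantom a `telepalp_phantom` with at least one inclusion of each
#'   queried material.
#' @param tolerance_mm classification tolerance, mm.
#' @param materials materials to report (default: all in the phantom, in
#'   increasing stiffness order).
#' @return data.frame `material`, `stiffness_k`, `mean_rate`, `iqr`,
#'   `n_sessions`.
#' @export
identification_rate_by_material <- function(sessions, phantom,
                                            tolerance_mm = 10,
                                            materials = NULL) {
  if (is.data.frame(sessions)) sessions <- list(sessions)
  inc <- phantom$inclusions
  if (is.null(materials)) {
    if (!nrow(inc)) abort("phantom has no inclusions")
    materials <- names(sort(tapply(inc$stiffness_k, inc$material, unique)))
  }
  missing <- setdiff(materials, inc$material)
  if (length(missing))
    abort("material(s) absent from phantom: %s",
          paste(missing, collapse = ", "))
  per_session <- vapply(sessions, function(s) {
    cls <- classify_responses(s, phantom, tolerance_mm)
    hit <- unique(cls$detail$inclusion_id[cls$detail$label == "TP"])
    vapply(materials, function(mat) {
      ids <- inc$id[inc$material == mat]
      mean(ids %in% hit)
    }, numeric(1))
  }, numeric(length(materials)))
  per_session <- matrix(per_session, nrow = length(materials))
  data.frame(
    material = materials,
    stiffness_k = vapply(materials, function(mat)
      unique(inc$stiffness_k[inc$material == mat])[1], numeric(1)),
    mean_rate = apply(per_session, 1, mean),
    iqr = apply(per_session, 1, IQR),
    n_sessions = length(sessions),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Fit the logistic psychometric function
#'
#' Nonlinear least-squares fit of the logistic CDF
#' `G(x) = 1 / (1 + exp(-(x - a) / b))` to identification rates observed at
#' a set of stiffness values. `a` is the perceptual threshold (the stiffness
#' at which the fitted detection probability is 0.5) and `b > 0` the scale.
#' Fitting uses Levenberg-Marquardt with `b` bounded below; non-convergence
#' and unidentifiable inputs (all rates equal, or fewer than two distinct
#' stiffness levels) are flagged, not raised.
#'
#' @param stiffness_values stimulus stiffness levels, N/mm.
#' @param rates observed identification rates in `[0, 1]`, one per level.
#' @param init optional `c(a, b)` start; defaults to the median stiffness
#'   and half the stiffness range.
#' @return a list of class `telepalp_psychfit`: `a_thr`, `b_scale`, `rss`,
#'   `converged`, `fitted`.
#' @export
fit_cdf <- function(stiffness_values, rates, init = NULL) {
  if (length(stiffness_values) != length(rates))
    abort("stiffness_values and rates must have equal length")
  if (any(rates < 0 | rates > 1)) abort("rates must lie in [0, 1]")
  if (length(unique(stiffness_values)) < 2)
    abort("need at least 2 distinct stiffness values")
  if (length(unique(rates)) == 1L) {
    return(structure(list(a_thr = NA_real_, b_scale = NA_real_,
                          rss = 0, converged = FALSE,
                          reason = "unidentifiable: all rates equal",
                          fitted = rates),
                     class = "telepalp_psychfit"))
  }
  if (is.null(init)) {
    init <- c(a = median(stiffness_values),
              b = max(diff(range(stiffness_values)) / 2, 1e-3))
  } else {
    init <- c(a = init[[1]], b = init[[2]])
  }
  x <- stiffness_values
  resid_fn <- function(par) rates - 1 / (1 + exp(-(x - par[1]) / par[2]))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = init, fn = resid_fn,
                       lower = c(a = -Inf, b = 1e-6),
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(structure(list(a_thr = NA_real_, b_scale = NA_real_,
                          rss = NA_real_, converged = FALSE,
                          reason = conditionMessage(fit), fitted = NULL),
                     class = "telepalp_psychfit"))
  }
  est <- fit$par
  # Levenberg-Marquardt info codes 1-3 indicate convergence
  structure(list(a_thr = unname(est["a"]), b_scale = unname(est["b"]),
                 rss = fit$deviance,
                 converged = fit$info %in% 1:3,
                 fitted = 1 / (1 + exp(-(x - est["a"]) / est["b"]))),
            class = "telepalp_psychfit")
}

#' @export
print.telepalp_psychfit <- function(x, ...) {
  if (is.na(x$a_thr)) {
    cat("<telepalp_psychfit> not converged:",
        if (!is.null(x$reason)) x$reason else "", "\n")
  } else {
    cat(sprintf(
      "<telepalp_psychfit> threshold a = %.3f N/mm, scale b = %.3f N/mm (rss %.3g)\n",
      x$a_thr, x$b_scale, x$rss))
  }
  invisible(x)
}

#' Full psychophysical analysis report
#'
#' Bundles the tolerance sweep, per-material identification rates and the
#' psychometric fit into one report, and optionally writes it as JSON.
#'
#' @param sessions a response data.frame or list of them.
#' @param phantom a `telepalp_phantom`.
#' @param tolerance_mm tolerance for the per-material rates, mm.
#' @param tolerances tolerances for the sweep, mm.
#' @param file optional JSON output path.
#' @return a list with `tolerance_curve`, `material_rates`, `fit`.
#' @export
analyze_sessions <- function(sessions, phantom, tolerance_mm = 10,
                             tolerances = c(5, 10, 15, 20), file = NULL) {
  curve <- tolerance_sweep(sessions, phantom, tolerances)
  rates <- identification_rate_by_material(sessions, phantom, tolerance_mm)
  fit <- fit_cdf(rates$stiffness_k, rates$mean_rate)
  out <- list(tolerance_curve = curve, material_rates = rates,
              fit = list(a_thr = fit$a_thr, b_scale = fit$b_scale,
                         rss = fit$rss, converged = fit$converged))
  if (!is.null(file))
    jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  out
}
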