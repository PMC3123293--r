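#' Conflict success function
#'
#' Probability that the attacking side wins a battle, as a function of the
#' resources each side commits. Write the attacker's share of all committed
#' resources as share `= ra / (ra + rt)`; then:
#'
#' * `form = "log_odds"` (default): `p = plogis(k * (logit(r) - logit(r0)))`,
#'   a logistic in the log-odds of the share. At `r0 = 0.5` this is exactly
#'   the ratio contest `ra^k / (ra^k + rt^k)`, with asymptotes 0 and 1 as the
#'   resource ratio goes to 0 or infinity.
#' * `form = "share_linear"`: `p = plogis(k * (r - r0))`, a logistic in the
#'   share itself (range bounded away from 0 and 1 for finite `k`).
#'
#' Both forms give `p = 0.5` when the share equals `r0`, are strictly increasing in `ra`
#' and decreasing in `rt`, and are complementary at `r0 = 0.5`:
#' `p(a, b) + p(b, a) = 1`.
#'
#' @param r_attacker,r_target Positive resources committed by the attacker
#'   and the target. Vectorised with recycling.
#' @param k Decisiveness (slope), `k > 0`.
#' @param r0 Share at which the odds are equal, in (0, 1).
#' @param form CSF form, see Details.
#' @return Win probabilities in (0, 1).
#' @examples
#' success_probability(20, 10, k = 5)              # 32/33
#' success_probability(10, 10, k = 5)              # 0.5 exactly
#' success_probability(20, 10, k = 5, form = "share_linear")
#' @export
success_probability <- function(r_attacker, r_target, k = 5, r0 = 0.5,
                                form = c("log_odds", "share_linear")) {
  form <- match.arg(form)
  if (any(r_attacker <= 0) || any(r_target <= 0))
    abort("committed resources must be strictly positive")
  if (k <= 0) abort("`k` must be positive")
  if (r0 <= 0 || r0 >= 1) abort("`r0` must lie in (0, 1)")
  r <- r_attacker / (r_attacker + r_target)
  if (form == "log_odds") {
    stats::plogis(k * (log(r / (1 - r)) - log(r0 / (1 - r0))))
  } else {
    stats::plogis(k * (r - r0))
  }
}

#' Perceived win probability under a confidence factor
#'
#' A state with confidence factor `alpha` judges its chances against an
#' opponent by feeding its *perceived* resources `alpha * r_attacker` into
#' the conflict success function, while seeing the opponent's true stock.
#' The perception is strictly increasing in `alpha` and equals the true win
#' probability exactly when `alpha = 1` (an unbiased state). Only decisions
#' use the perceived value; battle outcomes always use true resources.
#'
#' @param alpha Positive confidence factor; `alpha > 1` overconfident,
#'   `alpha < 1` underconfident.
#' @inheritParams success_probability
#' @return Perceived win probabilities in (0, 1).
#' @examples
#' perceived_success_probability(1, 10, 10)   # unbiased: exactly 0.5
#' perceived_success_probability(4, 10, 10)   # 1024/1025
#' @export
perceived_success_probability <- function(alpha, r_attacker, r_target,
                                          k = 5, r0 = 0.5,
                                          form = c("log_odds", "share_linear")) {
  if (any(alpha <= 0)) abort("`alpha` must be strictly positive")
  success_probability(alpha * r_attacker, r_target, k = k, r0 = r0,
                      form = match.arg(form))
}

#' Perceived win probability as a function of confidence
#'
#' Sweeps the confidence factor for a hypothetical contest between equals
#' (`r_attacker = r_target`), tracing how over- and underconfidence distort
#' the perceived chance of victory away from the true value 0.5.
#'
#' @param alpha Vector of confidence factors to evaluate.
#' @param k,r0,form CSF parameters, see [success_probability()].
#' @return A tibble with columns `alpha` and `p_perceived`.
#' @examples
#' csf_confidence_curve(alpha = c(0.25, 1, 4))
#' @export
csf_confidence_curve <- function(alpha = exp(seq(log(0.05), log(20), length.out = 201)),
                                 k = 5, r0 = 0.5,
                                 form = c("log_odds", "share_linear")) {
  form <- match.arg(form)
  tibble::tibble(
    alpha = alpha,
    p_perceived = perceived_success_probability(alpha, 1, 1, k = k, r0 = r0,
                                                form = form)
  )
}

#' Plot the confidence-perception curve
#'
#' @param curve Output of [csf_confidence_curve()].
#' @return A ggplot object.
#' @export
plot_csf_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$alpha, y = .data$p_perceived)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(alpha), y = "perceived win probability",
                  title = "Perceived chance of victory against an equal opponent") +
    ggplot2::theme_minimal()
}
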