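#' Panel plot of a per-trial summary
#'
#' Renders the four headline panels of a run with base graphics: performance
#' and uncertainty, habitised fraction per choice point, maximum expected
#' cached policy probability against the habitisation threshold, and the
#' deliberation-cost proxy.
#'
#' @param x A `tmaze_summary` from [summarize_metrics()].
#' @param p_th Habitisation threshold drawn as a reference line.
#' @param ... Ignored.
#' @return `x`, invisibly.
#' @export
plot.tmaze_summary <- function(x, p_th = 0.90, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$trial, x$reward_rate, type = "l", ylim = c(0, 1),
                 xlab = "trial", ylab = "", main = "performance / uncertainty")
  graphics::lines(x$trial, x$context_entropy, col = "red")
  graphics::legend("right", legend = c("reward rate", "context entropy"),
                   col = c("black", "red"), lty = 1, bty = "n", cex = 0.8)
  graphics::matplot(x$trial,
                    cbind(x$habit_fraction_1, x$habit_fraction_2,
                          x$habit_fraction_3, x$habit_fraction_4),
                    type = "l", lty = 1, ylim = c(0, 1),
                    col = c("blue", "skyblue", "gold", "red"),
                    xlab = "trial", ylab = "fraction habitised",
                    main = "habitisation by choice point")
  graphics::plot(x$trial, x$max_expected_prob, type = "l", ylim = c(0, 1),
                 xlab = "trial", ylab = "max E[P(pi|s)]",
                 main = "best cached policy")
  graphics::abline(h = p_th, lty = 2)
  graphics::plot(x$trial, x$n_efe_evals, type = "l",
                 xlab = "trial", ylab = "policy evaluations",
                 main = "deliberation cost")
  invisible(x)
}
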