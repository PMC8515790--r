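#' Two-parameter phase-diagram sweep
#'
#' For every grid point: runs the linear stability analysis and, where the
#' stationary state is unstable to oscillations, integrates the limit cycle
#' and measures period, amplitude and (optionally) the cycle-averaged
#' entropy production rate. Non-oscillating points carry
#' `oscillating = FALSE` and `NA` observables -- the "white region" of the
#' phase diagrams. Per-point failures are caught, recorded as `NA` and
#' reported in the `failures` attribute rather than aborting the sweep.
#'
#' @param params Base [kai_params()] object (the fixed-parameter context).
#' @param var1,var2 Parameter names to vary (must be `kai_params` fields).
#' @param grid1,grid2 Numeric grids (nonempty).
#' @param entropy Also compute the entropy production rate (slower).
#' @param n_periods Simulated periods per oscillatory point.
#' @return A data frame with columns `var1`, `var2` (named after the swept
#'   parameters), `oscillating`, `leading_re`, `predicted_period`, `period`,
#'   `amplitude`, and `sigma_dot` when requested.
#' @export
run_sweep <- function(params, var1, grid1, var2 = NULL, grid2 = NULL,
                      entropy = FALSE, n_periods = 30) {
  if (!length(grid1)) stop("grid1 must be nonempty")
  fields <- names(unclass(params))
  if (!var1 %in% fields) stop("unknown parameter name: ", var1)
  if (!is.null(var2) && !var2 %in% fields) stop("unknown parameter name: ", var2)
  if (is.null(var2)) {
    pts <- data.frame(v1 = grid1)
  } else {
    if (!length(grid2)) stop("grid2 must be nonempty")
    pts <- expand.grid(v1 = grid1, v2 = grid2)
  }
  res <- vector("list", nrow(pts))
  failures <- character(0)
  for (i in seq_len(nrow(pts))) {
    upd <- stats::setNames(list(pts$v1[i]), var1)
    if (!is.null(var2)) upd <- c(upd, stats::setNames(list(pts$v2[i]), var2))
    row <- tryCatch({
      p <- do.call(kai_set, c(list(params), upd))
      rep <- stability_report(p)
      out <- list(oscillating = rep$oscillating,
                  leading_re = Re(rep$leading),
                  predicted_period = rep$predicted_period,
                  period = NA_real_, amplitude = NA_real_,
                  sigma_dot = NA_real_)
      if (rep$oscillating) {
        sim <- simulate_cycles(p, n_periods = n_periods)
        out$period <- sim$cycles$period
        out$amplitude <- sim$cycles$amplitude
        if (entropy) {
          out$sigma_dot <- entropy_production_cycle(p, sim$trajectory)$sigma_dot
        }
      } else if (entropy) {
        out$sigma_dot <-
          entropy_production_stationary(p, rep$fixed_point)$sigma_dot
      }
      out
    }, error = function(e) {
      failures <<- c(failures, sprintf("point %d: %s", i, conditionMessage(e)))
      list(oscillating = NA, leading_re = NA_real_, predicted_period = NA_real_,
           period = NA_real_, amplitude = NA_real_, sigma_dot = NA_real_)
    })
    res[[i]] <- row
  }
  out <- cbind(pts, do.call(rbind, lapply(res, as.data.frame)))
  names(out)[1] <- var1
  if (!is.null(var2)) names(out)[2] <- var2
  if (!entropy) out$sigma_dot <- NULL
  attr(out, "failures") <- failures
  out
}
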