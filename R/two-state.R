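#' Log-probability of a temporal two-state sequence
#'
#' The sequence prior of the two-state model: a first-order Markov chain
#' over states `H` (high effect) and `L` (low effect) with a fixed
#' transition probability `lambda`, the *penalty*. The chain starts with
#' initial state probability `pi` for `H` and switches state with
#' probability `lambda` (stays with `1 - lambda`) at each step. With
#' `lambda = 0.5` all `2^T` sequences are equiprobable (no penalty); the
#' smaller `lambda`, the more state switches are penalised.
#'
#' @param states Character vector over `"H"`/`"L"`, or a single pattern
#'   string such as `"LLHH"`.
#' @param lambda Transition probability in `(0, 0.5]`.
#' @param pi Initial probability of the `H` state (default `0.5`).
#' @return The log-probability of the sequence.
#' @export
#' @examples
#' sequence_log_prob("LLHH", lambda = 0.1)  # log(0.5 * 0.9 * 0.1 * 0.9)
sequence_log_prob <- function(states, lambda, pi = 0.5) {
  states <- parse_states(states)
  check_lambda(lambda)
  lp <- ifelse(states[1] == "H", log(pi), log1p(-pi))
  if (length(states) > 1) {
    sw <- states[-1] != states[-length(states)]
    lp <- lp + sum(ifelse(sw, log(lambda), log1p(-lambda)))
  }
  lp
}

check_lambda <- function(lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda <= 0 ||
      lambda > 0.5)
    abort("`lambda` (transition penalty) must lie in (0, 0.5]; 0.5 applies no penalty")
  invisible(lambda)
}

parse_states <- function(states) {
  if (length(states) == 1 && is.character(states) && nchar(states) > 1)
    states <- strsplit(states, "")[[1]]
  states <- as.character(states)
  if (length(states) == 0 || !all(states %in% c("H", "L")))
    abort("states must be a nonempty sequence over {H, L}")
  states
}

#' Log-probability of observed effects given a state sequence
#'
#' Gaussian emission term of the two-state model: each observed effect at
#' time point `t` is an independent draw from `N(mu[s_t], sigma[s_t])`,
#' with one `(mu, sigma)` pair per state shared across all time points in
#' that state.
#'
#' @param effects A tibble with columns `time` and `effect` (the observed
#'   effect sample, e.g. from [observed_effects()]).
#' @param states One state per retained time point (sorted unique times in
#'   `effects`), as for [sequence_log_prob()].
#' @param mu,sigma Named numeric vectors with elements `H` and `L`.
#' @return The summed Gaussian log-density.
#' @export
emissions_log_prob <- function(effects, states, mu, sigma) {
  states <- parse_states(states)
  times <- sort(unique(effects$time))
  if (length(states) != length(times))
    abort("need one state per retained time point")
  st <- states[match(effects$time, times)]
  sum(dnorm(effects$effect, mu[st], sigma[st], log = TRUE))
}

#' Fit the temporal two-state model to an observed-effect sample
#'
#' Maximises the joint likelihood of a state sequence and Gaussian emission
#' parameters over the per-time-point observed effects, using Baum-Welch
#' expectation-maximisation with the transition penalty `lambda` held fixed.
#' The default initialisation is deterministic and low-effect-like: both
#' states start at the pooled standard deviation with means at the pooled
#' mean plus/minus half the pooled standard deviation. After convergence
#' (log-likelihood gain below `tol` or `max_iter` iterations) the hidden
#' sequence is Viterbi-decoded and the emission parameters are refit in
#' closed form given that sequence; the reported `log_likelihood` is the
#' resulting joint sequence-plus-emissions objective. States are then
#' labelled `H`/`L` by absolute mean (see [label_states()]).
#'
#' @inheritParams emissions_log_prob
#' @param lambda Transition penalty in `(0, 0.5]`; `0.5` leaves state
#'   sequences unpenalised.
#' @param pi Initial probability of the `H` state.
#' @param tol Convergence tolerance on the marginal log-likelihood gain.
#' @param max_iter Maximum EM iterations.
#' @param sigma_floor Lower bound on emission standard deviations,
#'   preventing degenerate zero-variance collapse.
#' @param restarts Number of additional random initialisations; the best
#'   joint log-likelihood wins. `0` (default) uses the single deterministic
#'   start.
#' @return A `two_state_fit` object: fields `pattern` (time-ordered state
#'   string, e.g. `"LLHH"`), `states`, `times`, `mu`, `sigma` (named `H`,
#'   `L`), `log_likelihood`, `marginal_log_likelihood`, `trace` (per-EM
#'   -iteration marginal log-likelihood), `n_iter`, `converged`.
#'   Supports [tidy()], [glance()], [autoplot()].
#' @export
fit_two_state <- function(effects, lambda = 0.5, pi = 0.5, tol = 1e-8,
                          max_iter = 500, sigma_floor = 1e-6, restarts = 0) {
  check_lambda(lambda)
  st <- effect_stats_tbl(effects)
  keep <- st$n > 0
  if (sum(keep) < 1) abort("no time points with observed effects")
  fit <- cpp_fit_stats(st$n[keep], st$s1[keep], st$s2[keep], lambda, pi,
                       tol, max_iter, sigma_floor)
  if (restarts > 0) {
    pooled_m <- sum(st$s1) / sum(st$n)
    pooled_s <- max(sqrt(max(sum(st$s2) / sum(st$n) - pooled_m^2, 0)),
                    sigma_floor)
    for (r in seq_len(restarts)) {
      cand <- cpp_fit_stats(st$n[keep], st$s1[keep], st$s2[keep], lambda, pi,
                            tol, max_iter, sigma_floor,
                            init_mu = pooled_m + pooled_s * rnorm(2),
                            init_sigma = pooled_s * runif(2, 0.25, 2))
      if (cand$log_likelihood > fit$log_likelihood) fit <- cand
    }
  }
  new_two_state_fit(fit, times = st$time[keep], lambda = lambda, pi = pi,
                    n_obs = st$n[keep])
}

new_two_state_fit <- function(fit, times, lambda, pi, n_obs,
                              method = "baum-welch") {
  labs <- state_labels(fit$mu, fit$sigma)
  states <- labs[fit$path + 1L]
  mu <- stats::setNames(fit$mu, labs)[c("H", "L")]
  sigma <- stats::setNames(fit$sigma, labs)[c("H", "L")]
  structure(
    list(pattern = paste(states, collapse = ""), states = states,
         times = times, mu = mu, sigma = sigma,
         log_likelihood = fit$log_likelihood,
         marginal_log_likelihood = fit$marginal_log_likelihood %||% NA_real_,
         trace = fit$trace %||% numeric(), n_iter = fit$n_iter %||% NA_integer_,
         converged = fit$converged %||% TRUE, lambda = lambda, pi = pi,
         n_obs = n_obs, method = method),
    class = "two_state_fit")
}

# H is the state with the larger |mu|; ties broken by larger sigma, then by
# internal state order (deterministic)
state_labels <- function(mu, sigma) {
  h <- order(-abs(mu), -sigma)[1]
  labs <- c("L", "L")
  labs[h] <- "H"
  labs
}

#' Relabel the states of a fitted two-state model
#'
#' Assigns the `H` label to the state whose mean has the larger absolute
#' value (the rule is sign-free: a strong negative effect is still the
#' high-effect state), `L` to the other. Exact ties are broken by the larger
#' standard deviation, then deterministically. Idempotent.
#'
#' @param fit A `two_state_fit` object.
#' @return The fit with labels (and pattern string) reassigned.
#' @export
label_states <- function(fit) {
  labs <- state_labels(unname(fit$mu), unname(fit$sigma))
  map <- stats::setNames(labs, names(fit$mu))
  fit$states <- unname(map[fit$states])
  fit$pattern <- paste(fit$states, collapse = "")
  names(fit$mu) <- labs
  names(fit$sigma) <- labs
  fit$mu <- fit$mu[c("H", "L")]
  fit$sigma <- fit$sigma[c("H", "L")]
  fit
}

#' Exact maximum-likelihood fit by exhaustive enumeration
#'
#' Independent reference optimiser for the two-state model: enumerates all
#' `2^T` state sequences, fits the two Gaussian emission parameter pairs in
#' closed form for each sequence, and returns the global maximum of the
#' joint likelihood. Exponential in `T`; refuses `T > 12`. Intended as a
#' test oracle for [fit_two_state()].
#'
#' @inheritParams fit_two_state
#' @return A `two_state_fit` object (with `method = "enumeration"`).
#' @export
enumerate_ml_oracle <- function(effects, lambda = 0.5, pi = 0.5,
                                sigma_floor = 1e-6) {
  check_lambda(lambda)
  st <- effect_stats_tbl(effects)
  keep <- st$n > 0
  n <- st$n[keep]; s1 <- st$s1[keep]; s2 <- st$s2[keep]
  T <- length(n)
  if (T > 12) abort("enumeration oracle refuses T > 12")
  best <- NULL
  best_ll <- -Inf
  for (mask in 0:(2^T - 1)) {
    path <- as.integer(intToBits(mask)[1:T])  # 1 = state H, 0 = state L
    ll_em <- 0
    mu <- c(0, 0); sg <- c(sigma_floor, sigma_floor)
    for (k in 0:1) {
      sel <- path == k
      if (!any(sel)) next
      Nk <- sum(n[sel]); S1k <- sum(s1[sel]); S2k <- sum(s2[sel])
      m <- S1k / Nk
      v <- max(S2k / Nk - m^2, 0)
      s <- max(sqrt(v), sigma_floor)
      mu[k + 1] <- m; sg[k + 1] <- s
      ll_em <- ll_em + sum(-0.5 * n[sel] * (log(2 * base::pi) + 2 * log(s)) -
                             (s2[sel] - 2 * m * s1[sel] + n[sel] * m^2) /
                               (2 * s^2))
    }
    lp <- ifelse(path[1] == 1, log(pi), log1p(-pi))
    if (T > 1) {
      sw <- path[-1] != path[-T]
      lp <- lp + sum(ifelse(sw, log(lambda), log1p(-lambda)))
    }
    ll <- ll_em + lp
    if (ll > best_ll) {
      best_ll <- ll
      best <- list(mu = c(mu[1], mu[2]), sigma = c(sg[1], sg[2]),
                   path = path, log_likelihood = ll,
                   marginal_log_likelihood = NA_real_, trace = numeric(),
                   n_iter = NA_integer_, converged = TRUE)
    }
  }
  new_two_state_fit(best, times = st$time[keep], lambda = lambda, pi = pi,
                    n_obs = n, method = "enumeration")
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat("Temporal two-state model fit (", x$method, ")\n", sep = "")
  cat("  pattern: ", x$pattern, "  (", length(x$times), " time points)\n",
      sep = "")
  cat(sprintf("  mu_H = %.4g (sd %.4g), mu_L = %.4g (sd %.4g)\n",
              x$mu["H"], x$sigma["H"], x$mu["L"], x$sigma["L"]))
  cat(sprintf("  log-likelihood = %.6g, lambda = %g\n",
              x$log_likelihood, x$lambda))
  invisible(x)
}

#' @export
tidy.two_state_fit <- function(x, ...) {
  tibble(time = x$times, state = x$states,
         mu = unname(x$mu[x$states]), sigma = unname(x$sigma[x$states]),
         n_obs = as.numeric(x$n_obs))
}

#' @export
glance.two_state_fit <- function(x, ...) {
  tibble(pattern = x$pattern, log_likelihood = x$log_likelihood,
         mu_H = unname(x$mu["H"]), mu_L = unname(x$mu["L"]),
         sigma_H = unname(x$sigma["H"]), sigma_L = unname(x$sigma["L"]),
         lambda = x$lambda, n_iter = as.integer(x$n_iter),
         converged = isTRUE(x$converged))
}

#' @export
autoplot.two_state_fit <- function(object, effects = NULL, ...) {
  td <- tidy(object)
  p <- ggplot2::ggplot(td, ggplot2::aes(x = .data$time, y = .data$mu))
  if (!is.null(effects)) {
    p <- p + ggplot2::geom_jitter(
      data = as_tibble(effects),
      ggplot2::aes(x = .data$time, y = .data$effect),
      width = 0.1, alpha = 0.2, colour = "grey50", inherit.aes = FALSE)
  }
  p +
    ggplot2::geom_step(colour = "grey30") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$state), size = 3) +
    ggplot2::scale_colour_manual(values = c(H = "#c0392b", L = "#2980b9")) +
    ggplot2::labs(x = "time point", y = "state mean effect",
                  colour = "state")
}
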