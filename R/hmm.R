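#' Two-state HMM parameter set
#'
#' @param trans 2x2 row-stochastic transition matrix (state 1 = hypo).
#' @param init_p initial state distribution.
#' @param emission `"betabinom"` or `"binomial"`.
#' @param alpha,beta beta-binomial shape parameters per state (hypo, hyper);
#'   used when `emission = "betabinom"`.
#' @param p success probabilities per state; used when
#'   `emission = "binomial"`.
#' @return An `hmm_params` list.
#' @export
hmm_params <- function(trans = matrix(c(0.99, 0.01, 0.01, 0.99), 2,
                                      byrow = TRUE),
                       init_p = c(0.5, 0.5),
                       emission = c("betabinom", "binomial"),
                       alpha = c(1, 8), beta = c(9, 2),
                       p = c(0.1, 0.8)) {
  emission <- match.arg(emission)
  if (any(abs(rowSums(trans) - 1) > 1e-8))
    stop("transition matrix rows must sum to 1")
  if (emission == "betabinom" && any(c(alpha, beta) <= 0))
    stop("beta-binomial shapes must be positive")
  means <- if (emission == "betabinom") alpha / (alpha + beta) else p
  if (means[1] >= means[2])
    stop("state 1 (hypo) must have the smaller emission mean")
  structure(list(trans = trans, init_p = init_p / sum(init_p),
                 emission = emission, alpha = alpha, beta = beta, p = p),
            class = "hmm_params")
}

emission_means <- function(params) {
  if (params$emission == "betabinom")
    params$alpha / (params$alpha + params$beta)
  else params$p
}

# log emission probability matrix (n x 2) for counts (meth, total)
emission_loglik <- function(meth, total, params) {
  lc <- lchoose(total, meth)
  if (params$emission == "betabinom") {
    cbind(lc + lbeta(meth + params$alpha[1], total - meth + params$beta[1]) -
            lbeta(params$alpha[1], params$beta[1]),
          lc + lbeta(meth + params$alpha[2], total - meth + params$beta[2]) -
            lbeta(params$alpha[2], params$beta[2]))
  } else {
    cbind(dbinom(meth, total, params$p[1], log = TRUE),
          dbinom(meth, total, params$p[2], log = TRUE))
  }
}

# split covered CpG sites of a track into decoding chains:
# new chain at each chromosome change or inter-CpG gap > gap_limit
covered_chains <- function(track, gap_limit) {
  x <- as.data.frame(track)
  x <- x[x$context == "CpG" & x$total > 0, , drop = FALSE]
  if (!nrow(x)) return(list(sites = x, chain = integer(0)))
  new_chain <- c(TRUE, x$chrom[-1] != x$chrom[-nrow(x)] |
                   diff(x$pos) > gap_limit)
  list(sites = x, chain = cumsum(new_chain))
}

# scaled forward-backward for one chain; le is the n x 2 log emission matrix
forward_backward <- function(le, trans, init_p) {
  n <- nrow(le)
  shift <- apply(le, 1, max)
  e <- exp(le - shift)
  a <- matrix(0, n, 2)
  cs <- numeric(n)
  v <- init_p * e[1, ]
  cs[1] <- sum(v)
  a[1, ] <- v / cs[1]
  if (n > 1) {
    for (t in 2:n) {
      v <- (a[t - 1, ] %*% trans) * e[t, ]
      cs[t] <- sum(v)
      a[t, ] <- v / cs[t]
    }
  }
  b <- matrix(1, n, 2)
  xi <- matrix(0, 2, 2)
  if (n > 1) {
    for (t in (n - 1):1) {
      w <- e[t + 1, ] * b[t + 1, ]
      x <- outer(a[t, ], w) * trans / cs[t + 1]
      xi <- xi + x / sum(x)
      b[t, ] <- (trans %*% w) / cs[t + 1]
    }
  }
  g <- a * b
  g <- g / rowSums(g)
  list(gamma = g, xi = xi, loglik = sum(log(cs)) + sum(shift))
}

# one E-step over all chains
e_step <- function(sites, chain, params) {
  le <- emission_loglik(sites$meth, sites$total, params)
  gamma <- matrix(0, nrow(sites), 2)
  xi <- matrix(0, 2, 2)
  first <- c(0, 0)
  ll <- 0
  for (k in unique(chain)) {
    idx <- which(chain == k)
    fb <- forward_backward(le[idx, , drop = FALSE], params$trans,
                           params$init_p)
    gamma[idx, ] <- fb$gamma
    xi <- xi + fb$xi
    first <- first + fb$gamma[1, ]
    ll <- ll + fb$loglik
  }
  list(gamma = gamma, xi = xi, first = first, loglik = ll)
}

# weighted beta-binomial M-step for one state (generalized EM: the update is
# kept only if it improves the weighted log-likelihood)
update_betabinom <- function(meth, total, w, a0, b0, maxit = 25) {
  if (sum(w) < 1e-8) return(c(a0, b0))
  q <- function(la) {
    a <- exp(la[1]); b <- exp(la[2])
    if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0) return(1e10)
    -sum(w * (lbeta(meth + a, total - meth + b) - lbeta(a, b)))
  }
  opt <- optim(log(c(a0, b0)), q, method = "Nelder-Mead",
               control = list(maxit = maxit))
  if (opt$value < q(log(c(a0, b0)))) exp(opt$par) else c(a0, b0)
}

#' Fit a two-state hidden Markov model to a methylome track
#'
#' Segmentation model behind HMR calling: covered CpGs form chains (split at
#' chromosome boundaries and inter-CpG gaps longer than `gap_limit`), and a
#' two-state HMM with beta-binomial emissions (binomial available) is fitted
#' by Baum-Welch EM. The beta-binomial emission absorbs the overdispersion
#' of low-coverage bisulfite counts. State 1 is the hypomethylated state;
#' states are relabelled after fitting so its mean is the smaller one.
#'
#' The M-step for the beta-binomial shapes is a generalized EM update
#' (a short Nelder-Mead ascent accepted only when it improves the weighted
#' likelihood), so the log-likelihood trace is non-decreasing.
#'
#' @param track a [methylome_track()] with at least 2 covered CpGs.
#' @param init an [hmm_params()] initialisation.
#' @param tol stop when the log-likelihood improves by at most `tol`;
#'   `tol = Inf` returns the initial parameters after a single E-step.
#' @param max_iter maximum EM iterations.
#' @param gap_limit chain-splitting gap in bp.
#' @param n_restarts number of jittered EM restarts (best likelihood wins).
#' @param seed seed for restart jitter.
#' @return A `meth_hmm` model object with components `params`,
#'   `loglik_trace`, `loglik`, `converged`, `n_sites`, `gap_limit`, `track`.
#' @export
meth_hmm <- function(track, init = hmm_params(), tol = 1e-3,
                     max_iter = 100L, gap_limit = 1000, n_restarts = 1L,
                     seed = NULL) {
  cc <- covered_chains(track, gap_limit)
  if (nrow(cc$sites) < 2)
    stop("need at least 2 covered CpGs to fit the HMM")
  if (!is.null(seed)) set.seed(seed)

  run_em <- function(params) {
    trace <- numeric(0)
    prev <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      es <- e_step(cc$sites, cc$chain, params)
      trace <- c(trace, es$loglik)
      if (es$loglik - prev <= tol) { converged <- TRUE; break }
      prev <- es$loglik
      # M-step
      trans <- es$xi / rowSums(es$xi)
      trans[!is.finite(trans)] <- params$trans[!is.finite(trans)]
      params$trans <- trans
      params$init_p <- es$first / sum(es$first)
      if (params$emission == "betabinom") {
        for (s in 1:2) {
          ab <- update_betabinom(cc$sites$meth, cc$sites$total,
                                 es$gamma[, s],
                                 params$alpha[s], params$beta[s])
          params$alpha[s] <- ab[1]; params$beta[s] <- ab[2]
        }
      } else {
        for (s in 1:2) {
          wtot <- sum(es$gamma[, s] * cc$sites$total)
          if (wtot > 0)
            params$p[s] <- min(1 - 1e-6, max(1e-6,
              sum(es$gamma[, s] * cc$sites$meth) / wtot))
        }
      }
    }
    list(params = params, trace = trace, converged = converged)
  }

  best <- NULL
  for (r in seq_len(n_restarts)) {
    p0 <- init
    if (r > 1) {  # seed-controlled jitter around the supplied init
      if (p0$emission == "betabinom") {
        p0$alpha <- p0$alpha * exp(stats::rnorm(2, 0, 0.2))
        p0$beta <- p0$beta * exp(stats::rnorm(2, 0, 0.2))
      } else {
        p0$p <- pmin(0.99, pmax(0.01, p0$p + stats::rnorm(2, 0, 0.05)))
      }
    }
    fit <- run_em(p0)
    if (is.null(best) || max(fit$trace) > max(best$trace)) best <- fit
  }

  params <- best$params
  means <- emission_means(params)
  if (means[1] > means[2]) {  # relabel so state 1 is the hypo state
    sw <- c(2, 1)
    params$trans <- params$trans[sw, sw]
    params$init_p <- params$init_p[sw]
    params$alpha <- params$alpha[sw]
    params$beta <- params$beta[sw]
    params$p <- params$p[sw]
  }
  structure(list(params = params, loglik_trace = best$trace,
                 loglik = best$trace[length(best$trace)],
                 converged = best$converged, n_sites = nrow(cc$sites),
                 n_chains = length(unique(cc$chain)),
                 gap_limit = gap_limit, track = track,
                 call = match.call()),
            class = "meth_hmm")
}

#' @export
print.meth_hmm <- function(x, ...) {
  m <- emission_means(x$params)
  cat(sprintf(paste0("two-state %s HMM over %d covered CpGs (%d chains)\n",
                     "  state means: hypo %.3f, hyper %.3f\n",
                     "  self-transitions: %.4f / %.4f\n",
                     "  log-likelihood %.2f after %d EM iteration(s)%s\n"),
              x$params$emission, x$n_sites, x$n_chains, m[1], m[2],
              x$params$trans[1, 1], x$params$trans[2, 2],
              x$loglik, length(x$loglik_trace),
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @export
summary.meth_hmm <- function(object, ...) {
  post <- predict(object)
  occ <- mean(post$posterior_hypo)
  out <- list(model = object, hypo_occupancy = occ,
              n_iter = length(object$loglik_trace))
  class(out) <- "summary.meth_hmm"
  out
}

#' @export
print.summary.meth_hmm <- function(x, ...) {
  print(x$model)
  cat(sprintf("  expected hypo-state occupancy: %.4f\n", x$hypo_occupancy))
  invisible(x)
}

#' @export
coef.meth_hmm <- function(object, ...) {
  p <- object$params
  m <- emission_means(p)
  c(hypo_mean = m[1], hyper_mean = m[2],
    p_stay_hypo = p$trans[1, 1], p_stay_hyper = p$trans[2, 2],
    if (p$emission == "betabinom")
      c(alpha_hypo = p$alpha[1], beta_hypo = p$beta[1],
        alpha_hyper = p$alpha[2], beta_hyper = p$beta[2]))
}

#' @export
logLik.meth_hmm <- function(object, ...) {
  df <- 3L + if (object$params$emission == "betabinom") 4L else 2L
  structure(object$loglik, df = df, nobs = object$n_sites,
            class = "logLik")
}

#' Posterior decoding of a methylome track
#'
#' Runs forward-backward with the fitted parameters and returns, per covered
#' CpG, the posterior probability of the hypomethylated state and the
#' posterior state call (`posterior_hypo > 0.5`).
#'
#' @param object a fitted [meth_hmm()].
#' @param track methylome track to decode; defaults to the training track.
#' @param ... unused.
#' @return Data frame `chrom, pos, meth, total, posterior_hypo, state`.
#' @export
predict.meth_hmm <- function(object, track = object$track, ...) {
  cc <- covered_chains(track, object$gap_limit)
  if (!nrow(cc$sites))
    return(data.frame(chrom = character(), pos = integer(),
                      meth = integer(), total = integer(),
                      posterior_hypo = numeric(), state = character()))
  es <- e_step(cc$sites, cc$chain, object$params)
  data.frame(chrom = cc$sites$chrom, pos = cc$sites$pos,
             meth = cc$sites$meth, total = cc$sites$total,
             posterior_hypo = es$gamma[, 1],
             state = ifelse(es$gamma[, 1] > 0.5, "hypo", "hyper"),
             chain = cc$chain)
}

#' Simulate counts from a fitted methylome HMM
#'
#' Draws a state path from the fitted Markov chain over the supplied
#' positions and emits beta-binomial (or binomial) counts.
#'
#' @param object a fitted [meth_hmm()].
#' @param nsim number of tracks to simulate.
#' @param seed optional seed.
#' @param positions data frame `chrom, pos` (defaults to the training
#'   track's covered CpGs).
#' @param coverage_mean mean Poisson coverage.
#' @param ... unused.
#' @return A [methylome_track()] (or a list of them if `nsim > 1`).
#' @export
simulate.meth_hmm <- function(object, nsim = 1, seed = NULL,
                              positions = NULL, coverage_mean = 10, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(positions)) {
    cc <- covered_chains(object$track, object$gap_limit)
    positions <- cc$sites[, c("chrom", "pos")]
  }
  p <- object$params
  one <- function(i) {
    n <- nrow(positions)
    st <- integer(n)
    st[1] <- sample(1:2, 1, prob = p$init_p)
    for (t in seq_len(n - 1))
      st[t + 1] <- sample(1:2, 1, prob = p$trans[st[t], ])
    total <- rpois(n, coverage_mean)
    level <- if (p$emission == "betabinom")
      stats::rbeta(n, p$alpha[st], p$beta[st]) else p$p[st]
    methylome_track(
      data.frame(chrom = positions$chrom, pos = positions$pos,
                 strand = "+", context = "CpG",
                 meth = rbinom(n, total, level), total = total),
      sample_id = sprintf("sim_%d", i))
  }
  out <- lapply(seq_len(nsim), one)
  if (nsim == 1) out[[1]] else out
}

#' @export
residuals.meth_hmm <- function(object, track = object$track, ...) {
  post <- predict(object, track)
  m <- emission_means(object$params)
  fitted_level <- post$posterior_hypo * m[1] + (1 - post$posterior_hypo) * m[2]
  post$meth / post$total - fitted_level
}

#' @export
plot.meth_hmm <- function(x, ...) {
  plot(seq_along(x$loglik_trace), x$loglik_trace, type = "b",
       xlab = "EM iteration", ylab = "log-likelihood",
       main = "Baum-Welch log-likelihood trace", ...)
  invisible(x)
}

#' Call hypomethylated regions from a fitted HMM
#'
#' Posterior-decodes the track and converts maximal runs of hypo-state CpGs
#' into HMRs. An HMR spans the first CpG's position to the last CpG's
#' position + 2 (covering the CpG dyad); runs never cross chain boundaries
#' (chromosome changes or gaps over `gap_limit`).
#'
#' @param track a [methylome_track()].
#' @param fit a fitted [meth_hmm()] (fitted on `track` by default usage).
#' @param min_cpgs discard HMRs spanning fewer covered CpGs.
#' @return Data frame `chrom, start, end, n_cpgs, mean_meth, length`.
#' @export
call_hmrs <- function(track, fit, min_cpgs = 1L) {
  post <- predict(fit, track)
  if (!nrow(post))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_cpgs = integer(),
                      mean_meth = numeric(), length = integer()))
  hypo <- post$state == "hypo"
  grp <- cumsum(c(TRUE, diff(post$chain) != 0 | diff(hypo) != 0))
  keep <- which(hypo)
  if (!length(keep))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_cpgs = integer(),
                      mean_meth = numeric(), length = integer()))
  runs <- split(keep, grp[keep])
  out <- lapply(runs, function(idx) {
    data.frame(chrom = post$chrom[idx[1]],
               start = post$pos[idx[1]],
               end = post$pos[idx[length(idx)]] + 2L,
               n_cpgs = length(idx),
               mean_meth = sum(post$meth[idx]) / sum(post$total[idx]))
  })
  out <- do.call(rbind, out)
  out <- out[out$n_cpgs >= min_cpgs, , drop = FALSE]
  out$length <- out$end - out$start
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter HMRs to methylation canyons
#'
#' Canyons are HMRs at least `min_length` bp long (default 3500, the
#' "3.5 kb or longer" convention). Pure threshold filter; input order is
#' preserved.
#'
#' @param hmrs HMR data frame from [call_hmrs()].
#' @param min_length minimum length in bp.
#' @return The subset of `hmrs` with `length >= min_length`.
#' @export
call_canyons <- function(hmrs, min_length = 3500) {
  if (min_length < 0) stop("min_length must be non-negative")
  len <- if ("length" %in% names(hmrs)) hmrs$length else hmrs$end - hmrs$start
  out <- hmrs[len >= min_length, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summary statistics of an HMR set
#'
#' @param hmrs HMR data frame.
#' @param genome_size total genome size in bp (optional; enables the genome
#'   fraction).
#' @return List with `n`, `median_length`, `total_bp` and (if `genome_size`
#'   given) `genome_fraction`.
#' @export
hmr_length_stats <- function(hmrs, genome_size = NULL) {
  if (!nrow(hmrs)) stop("empty HMR set")
  len <- if ("length" %in% names(hmrs)) hmrs$length else hmrs$end - hmrs$start
  out <- list(n = nrow(hmrs), median_length = median(len),
              total_bp = sum(len))
  if (!is.null(genome_size))
    out$genome_fraction <- sum(len) / genome_size
  out
}

#' Two-sample Kolmogorov-Smirnov comparison of HMR length distributions
#'
#' @param lengths_a,lengths_b numeric vectors of HMR lengths.
#' @return List with `statistic` (sup ECDF difference) and `p_value`.
#' @export
hmr_ks_stat <- function(lengths_a, lengths_b) {
  kt <- suppressWarnings(ks.test(lengths_a, lengths_b))
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}
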