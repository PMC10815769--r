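#' Hardy-Weinberg population model for one biallelic autosomal locus
#'
#' Frequencies of a presence/absence allele pair (A with frequency `p`, a with
#' frequency `q = 1 - p`) and the implied Hardy-Weinberg genotype frequencies
#' `(p^2, 2pq, q^2)` for AA, Aa and aa. This is the population assumed by the
#' pseudo-marker error-rate models: in a ZW species, a female that happens to be
#' Aa at an autosomal locus while all sampled males are homozygous mimics a
#' W-linked presence/absence marker.
#'
#' @param p Frequency of allele A, in `[0, 1]`.
#' @return An object of class `population_model`: a list with elements `p`, `q`
#'   and `genotype_freqs` (named numeric vector `AA`, `Aa`, `aa`).
#' @examples
#' population_model(0.3)
#' @export
population_model <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("'p' must be a single number in [0, 1]")
  q <- 1 - p
  structure(
    list(p = p, q = q,
         genotype_freqs = c(AA = p^2, Aa = 2 * p * q, aa = q^2)),
    class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat("Hardy-Weinberg biallelic locus: p =", format(x$p),
      " q =", format(x$q), "\n")
  print(round(x$genotype_freqs, 6))
  invisible(x)
}

.match_system <- function(system) {
  match.arg(system, c("combined", "ZW", "XY"))
}

#' Autosomal pseudo-marker error rate for an n-versus-n sampling design
#'
#' Probability that a biallelic autosomal locus with allele frequency `p`
#' masquerades as a sex-specific presence/absence marker when `n` individuals
#' of each sex are screened: every heterogametic-candidate individual is
#' heterozygous Aa while every individual of the other sex is homozygous
#' (all AA or all aa). For a single known system (ZW or XY) the rate is
#'
#'   `P_E = (pq)^n * ((p^2/2)^n + (q^2/2)^n)`
#'
#' and for the combined case, where either chromosomal system would be
#' accepted, the rate is doubled. Note the model's homozygote term uses
#' `p^2/2` (the table form evaluated literally); the population simulator in
#' [simulate_population()] uses canonical Hardy-Weinberg `(p^2, 2pq, q^2)` for
#' genotypes - the two facts are independent and both intentional.
#'
#' @param p Allele-A frequency (vectorised), each value in `[0, 1]`.
#' @param n Individuals per sex, a single integer `>= 1`.
#' @param system `"combined"` (default; either ZW or XY accepted), `"ZW"` or
#'   `"XY"`. The ZW and XY single-system expressions are identical.
#' @return Numeric vector of error probabilities in `[0, 1]`, symmetric under
#'   `p <-> 1 - p`.
#' @examples
#' pseudo_marker_rate(0.5, 3)              # 1.220703125e-4
#' pseudo_marker_rate(0.5, 1)              # 0.125
#' @seealso [expected_rate_closed_form()] for the exact mean over uniform `p`.
#' @export
pseudo_marker_rate <- function(p, n, system = c("combined", "ZW", "XY")) {
  system <- .match_system(system)
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("'p' must be numeric in [0, 1]")
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != round(n))
    stop("'n' must be a single integer >= 1")
  q <- 1 - p
  single <- (p * q)^n * ((p^2 / 2)^n + (q^2 / 2)^n)
  if (system == "combined") 2 * single else single
}

#' Exact mean pseudo-marker rate under uniformly distributed allele frequency
#'
#' Closed-form expectation of the combined-system [pseudo_marker_rate()] when
#' `p ~ Uniform(0, 1)` and `q = 1 - p`:
#'
#'   `E[P_E] = 2^(2 - n) * B(3n + 1, n + 1)`
#'
#' with `B` the Beta function. This is the analytic oracle for the Monte-Carlo
#' design simulation; for `n = 3` it equals `1/5720 = 1.748e-4`, i.e. 0.0175%.
#'
#' @param n Individuals per sex (vectorised), integers `>= 1`.
#' @return Numeric vector of expected rates; strictly decreasing in `n`.
#' @examples
#' expected_rate_closed_form(1:5)
#' @export
expected_rate_closed_form <- function(n) {
  if (!is.numeric(n) || any(is.na(n)) || any(n < 1) || any(n != round(n)))
    stop("'n' must be integer(s) >= 1")
  2^(2 - n) * beta(3 * n + 1, n + 1)
}

#' Pseudo-marker error rate with an additional single-sex mixed pool
#'
#' Extends the single-system pseudo-marker rate with a pool of `N` individuals
#' of the homogametic sex: a pseudo marker additionally requires every pool
#' member to be homozygous absent, which multiplies the rate by `r^(2N)` where
#' `r^2` is the per-individual probability of the disproving-free genotype:
#'
#'   `P_E-Pool = (pq)^n * ((p^2/2)^n + (q^2/2)^n) * r^(2N)`
#'
#' `N = 0` reduces exactly to the non-pool single-system expression. When `r`
#' has length `N` (one value per pool member, the
#' `independent_per_individual` policy) the multiplier is `prod(r_i^2)`.
#'
#' @param p Allele-A frequency in `[0, 1]`.
#' @param r Pool genotype frequency parameter in `[0, 1]`; scalar, or length
#'   `N` for per-individual values.
#' @param n Individuals per sex in the original groups.
#' @param N Pool size, integer `>= 0`.
#' @param system `"ZW"` (default) or `"XY"`; the expressions coincide.
#' @return A single probability in `[0, 1]`, never exceeding
#'   `pseudo_marker_rate(p, n, system)`.
#' @examples
#' pool_error_rate(0.5, r = 0.5, n = 3, N = 15)   # 2^-44
#' @export
pool_error_rate <- function(p, r, n, N, system = c("ZW", "XY")) {
  system <- match.arg(system)
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N < 0 || N != round(N))
    stop("'N' must be a single integer >= 0")
  if (!is.numeric(r) || any(is.na(r)) || any(r < 0) || any(r > 1))
    stop("'r' must be numeric in [0, 1]")
  if (!(length(r) == 1L || length(r) == N))
    stop("'r' must be a scalar or have one value per pool member")
  base <- pseudo_marker_rate(p, n, system)
  mult <- if (length(r) == 1L) r^(2 * N) else prod(r^2)
  base * mult
}

.rate_summary <- function(x) {
  c(mean = mean(x), median = stats::median(x), min = min(x), max = max(x))
}

#' Monte-Carlo simulation of the pseudo-marker rate over sampling designs
#'
#' For each group size `n`, draws `iterations` allele frequencies
#' `p ~ Uniform(0, 1)` (with `q = 1 - p`), evaluates [pseudo_marker_rate()]
#' and summarises the sampled distribution. With the defaults this reproduces
#' the design simulation behind the "at least three of each sex" sample-size
#' recommendation: the mean for `n = 3` is about 0.0175% (closed form
#' `1.748e-4`).
#'
#' @param group_sizes Integer vector of per-sex group sizes `n` to evaluate.
#' @param iterations Draws per group size (default `1e6`).
#' @param seed Integer seed; identical seed and parameters give identical
#'   summaries. The global RNG state is left untouched.
#' @param system Passed to [pseudo_marker_rate()]; default `"combined"`.
#' @return A `data.frame` of class `design_summary` with one row per group
#'   size and columns `group_size`, `system`, `iterations`, `seed`, `mean`,
#'   `median`, `min`, `max`.
#' @examples
#' simulate_design(1:3, iterations = 1e4, seed = 1)
#' @export
simulate_design <- function(group_sizes, iterations = 1e6, seed,
                            system = c("combined", "ZW", "XY")) {
  system <- .match_system(system)
  if (length(group_sizes) < 1L) stop("'group_sizes' must be non-empty")
  if (!is.numeric(iterations) || iterations < 1) stop("'iterations' must be >= 1")
  if (missing(seed)) stop("'seed' is required for reproducibility")
  iterations <- as.integer(iterations)
  rows <- withr::with_seed(seed, {
    lapply(group_sizes, function(n) {
      p <- stats::runif(iterations)
      s <- .rate_summary(pseudo_marker_rate(p, n, system))
      data.frame(group_size = as.integer(n), system = system,
                 iterations = iterations, seed = as.integer(seed),
                 mean = s[["mean"]], median = s[["median"]],
                 min = s[["min"]], max = s[["max"]])
    })
  })
  out <- do.call(rbind, rows)
  class(out) <- c("design_summary", "data.frame")
  out
}

.r_policies <- c("literal_choice", "matched", "independent_per_individual")

#' Monte-Carlo simulation of the pooled pseudo-marker rate
#'
#' For each pool size `N`, draws allele frequencies `p ~ Uniform(0, 1)`,
#' resolves the pool parameter `r` under the chosen policy and evaluates the
#' pooled error rate. Draws of `p` (and of `r`, where applicable) are shared
#' across the pool sizes within one call, so the sampled rates are
#' element-wise non-increasing in `N`.
#'
#' The wording "r randomly selected the value of p (or q)" under-determines
#' `r`; three readings are provided:
#' \describe{
#'   \item{`literal_choice`}{per iteration, `r` is set to `p` or `q` with
#'     equal probability and multiplies the whole rate (`r^(2N)`). Default.}
#'   \item{`matched`}{term-wise: the `(p^2/2)^n` term is multiplied by
#'     `p^(2N)` and the `(q^2/2)^n` term by `q^(2N)`, i.e. `r` matches the
#'     allele of each term's homozygote class.}
#'   \item{`independent_per_individual`}{each pool member gets a fresh
#'     `r_i ~ Uniform(0, 1)`; the multiplier is `prod(r_i^2)`.}
#' }
#'
#' @param pool_sizes Integer vector of pool sizes `N >= 0`.
#' @param n Individuals per sex in the original groups (default 3).
#' @param r_policy One of `"literal_choice"`, `"matched"`,
#'   `"independent_per_individual"`.
#' @param iterations Draws per pool size (default `1e6`).
#' @param seed Integer seed.
#' @param system Single-system base expression; `"ZW"` or `"XY"` (identical).
#' @return A `data.frame` of class `pool_design_summary` with columns
#'   `pool_size`, `group_size`, `r_policy`, `iterations`, `seed`, `mean`,
#'   `median`, `min`, `max`.
#' @examples
#' simulate_pool_design(c(0, 5, 15), n = 3, iterations = 1e4, seed = 1)
#' @export
simulate_pool_design <- function(pool_sizes, n = 3,
                                 r_policy = c("literal_choice", "matched",
                                              "independent_per_individual"),
                                 iterations = 1e6, seed,
                                 system = c("ZW", "XY")) {
  r_policy <- match.arg(r_policy)
  system <- match.arg(system)
  if (length(pool_sizes) < 1L) stop("'pool_sizes' must be non-empty")
  if (any(pool_sizes < 0) || any(pool_sizes != round(pool_sizes)))
    stop("'pool_sizes' must be integers >= 0")
  if (!is.numeric(iterations) || iterations < 1) stop("'iterations' must be >= 1")
  if (missing(seed)) stop("'seed' is required for reproducibility")
  iterations <- as.integer(iterations)
  N_max <- max(pool_sizes)
  rows <- withr::with_seed(seed, {
    p <- stats::runif(iterations)
    q <- 1 - p
    single <- pseudo_marker_rate(p, n, system)
    # shared r draws across pool sizes => element-wise monotone in N
    log_mult_per_N <- switch(r_policy,
      literal_choice = {
        r <- ifelse(stats::runif(iterations) < 0.5, p, q)
        function(N) 2 * N * log(r)
      },
      independent_per_individual = {
        if (N_max > 0) {
          lr <- matrix(log(stats::runif(iterations * N_max)),
                       nrow = N_max, ncol = iterations)
          for (i in seq_len(N_max)[-1L])        # row-wise running sum
            lr[i, ] <- lr[i, ] + lr[i - 1L, ]
          function(N) if (N == 0) rep(0, iterations) else 2 * lr[N, ]
        } else function(N) rep(0, iterations)
      },
      matched = NULL)
    lapply(pool_sizes, function(N) {
      rates <- if (r_policy == "matched") {
        (p * q)^n * ((p^2 / 2)^n * p^(2 * N) + (q^2 / 2)^n * q^(2 * N))
      } else {
        single * exp(log_mult_per_N(N))
      }
      s <- .rate_summary(rates)
      data.frame(pool_size = as.integer(N), group_size = as.integer(n),
                 r_policy = r_policy, iterations = iterations,
                 seed = as.integer(seed),
                 mean = s[["mean"]], median = s[["median"]],
                 min = s[["min"]], max = s[["max"]])
    })
  })
  out <- do.call(rbind, rows)
  class(out) <- c("pool_design_summary", "data.frame")
  out
}

#' Recommend group and pool sizes from the error-rate simulations
#'
#' Searches for the smallest per-sex group size `n` whose chosen statistic of
#' the simulated pseudo-marker rate falls below `rate_threshold_group`, and
#' the smallest pool size `N` (at that group size) whose statistic of the
#' pooled rate falls below `rate_threshold_pool`, for each requested `r`
#' policy. With mean statistics and the default thresholds this yields the
#' "three of each sex" group recommendation; for the pool, only the
#' `independent_per_individual` policy attains a mean below `1e-10` at
#' realistic pool sizes (N = 13) - under the other policies the mean decays
#' polynomially in `N` and the search reports "not reached".
#'
#' @param rate_threshold_group Threshold for the group-stage rate, in (0, 1).
#' @param rate_threshold_pool Threshold for the pooled rate, in (0, 1).
#' @param statistic `"mean"` (default) or `"max"` of the simulated rates.
#' @param policies Character vector of `r` policies to evaluate for the pool.
#' @param iterations Monte-Carlo draws per candidate size (default `1e5`).
#' @param seed Integer seed.
#' @param max_n,max_N Upper bounds of the searches.
#' @return A list of class `design_recommendation`: `n_star` (integer or `NA`
#'   if not reached), `group_reached`, and a `data.frame` `pool` with one row
#'   per policy (`r_policy`, `N_star`, `reached`), plus the `statistic`,
#'   thresholds and search bounds used.
#' @examples
#' recommend_design(iterations = 2e4, seed = 1, max_N = 15)
#' @export
recommend_design <- function(rate_threshold_group = 1e-3,
                             rate_threshold_pool = 1e-10,
                             statistic = c("mean", "max"),
                             policies = .r_policies,
                             iterations = 1e5, seed,
                             max_n = 10, max_N = 30) {
  statistic <- match.arg(statistic)
  policies <- match.arg(policies, .r_policies, several.ok = TRUE)
  stopifnot(rate_threshold_group > 0, rate_threshold_group < 1,
            rate_threshold_pool > 0, rate_threshold_pool < 1)
  if (missing(seed)) stop("'seed' is required for reproducibility")

  grp <- simulate_design(seq_len(max_n), iterations = iterations, seed = seed)
  ok <- grp[[statistic]] < rate_threshold_group
  n_star <- if (any(ok)) grp$group_size[which(ok)[1L]] else NA_integer_
  n_for_pool <- if (is.na(n_star)) 3L else n_star

  pool <- do.call(rbind, lapply(seq_along(policies), function(i) {
    sim <- simulate_pool_design(0:max_N, n = n_for_pool, r_policy = policies[i],
                                iterations = iterations, seed = seed + i)
    ok <- sim[[statistic]] < rate_threshold_pool
    data.frame(r_policy = policies[i],
               N_star = if (any(ok)) sim$pool_size[which(ok)[1L]] else NA_integer_,
               reached = any(ok))
  }))

  structure(list(n_star = n_star, group_reached = !is.na(n_star),
                 pool = pool, statistic = statistic,
                 rate_threshold_group = rate_threshold_group,
                 rate_threshold_pool = rate_threshold_pool,
                 group_size_for_pool = n_for_pool,
                 iterations = as.integer(iterations), seed = as.integer(seed),
                 max_n = as.integer(max_n), max_N = as.integer(max_N)),
            class = "design_recommendation")
}

#' @export
print.design_recommendation <- function(x, ...) {
  cat("Sampling-design recommendation (statistic:", x$statistic, ")\n")
  if (x$group_reached)
    cat("  group size n* =", x$n_star,
        sprintf("(first %s(P_E) < %g)\n", x$statistic, x$rate_threshold_group))
  else
    cat("  group threshold not reached within n <=", x$max_n, "\n")
  for (i in seq_len(nrow(x$pool))) {
    row <- x$pool[i, ]
    if (row$reached)
      cat(sprintf("  pool [%s]: N* = %d (first %s(P_E-Pool) < %g)\n",
                  row$r_policy, row$N_star, x$statistic, x$rate_threshold_pool))
    else
      cat(sprintf("  pool [%s]: not reached within N <= %d\n",
                  row$r_policy, x$max_N))
  }
  invisible(x)
}
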