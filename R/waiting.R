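# Birth-death waiting-time models of active-site evolution.
#
# States count the number of wild-type residues acquired (0..n); state n is
# absorbing. The "mean waiting time" quoted alongside results follows the
# half-time convention, ln(2) x the mean first-passage time, by analogy to
# a first-order reaction's half-time; the raw MFPT is always reported too.

#' Construct a birth-death chain
#'
#' @param forward Forward (gain) rates lambda_k for states k = 0..n-1; all
#'   must be positive.
#' @param backward Backward (loss) rates mu_k for states k = 0..n-1, i.e.
#'   mu_0..mu_{n-1} with \code{mu_0 = 0}; losses from the absorbing state
#'   are irrelevant and not represented.
#' @return A \code{bd_chain} with fields \code{n_states}, \code{forward},
#'   \code{backward}, \code{absorbing_state}.
#' @export
birth_death_chain <- function(forward, backward = rep(0, length(forward))) {
  stopifnot(is.numeric(forward), is.numeric(backward),
            length(backward) == length(forward), length(forward) >= 1L)
  if (any(forward <= 0)) stop("all forward rates must be positive", call. = FALSE)
  if (backward[1] != 0) stop("mu_0 must be zero", call. = FALSE)
  if (any(backward < 0)) stop("backward rates must be non-negative", call. = FALSE)
  n <- length(forward)
  structure(list(n_states = n + 1L, forward = forward, backward = backward,
                 absorbing_state = n),
            class = "bd_chain")
}

#' @export
print.bd_chain <- function(x, ...) {
  cat(sprintf("Birth-death chain on states 0..%d (absorbing at %d)\n",
              x$absorbing_state, x$absorbing_state))
  cat("  forward: ", paste(signif(x$forward, 4), collapse = ", "), "\n")
  cat("  backward:", paste(signif(x$backward, 4), collapse = ", "), "\n")
  invisible(x)
}

#' The fully cooperative residue-acquisition chain
#'
#' Models an active site in which no partial combination confers any
#' selective advantage, so residues drift in and out neutrally until all n
#' are present simultaneously. With per-position mutation rate 1, a vacant
#' position acquires the single advantageous residue with probability
#' \code{p} (one residue out of the twenty amino acids gives p = 1/20) and
#' an acquired residue is lost with probability \code{1 - p}: from state k,
#' the gain rate is \code{(n - k) p} and the loss rate \code{k (1 - p)}.
#'
#' @param n Number of residues (default 5).
#' @param p Per-position acquisition probability in (0, 1) (default 1/20).
#' @return A \code{bd_chain}.
#' @export
#' @examples
#' cooperative_chain(5, 1/20)
cooperative_chain <- function(n = 5L, p = 1 / 20) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1) {
    stop("p must lie strictly between 0 and 1", call. = FALSE)
  }
  k <- 0:(n - 1)
  birth_death_chain(forward = (n - k) * p, backward = k * (1 - p))
}

#' The forward-only (stepwise) residue-acquisition chain
#'
#' Every acquisition confers a selective advantage and is treated as
#' irreversible: gain rate \code{(n - k) p} from state k, no losses.
#'
#' @inheritParams cooperative_chain
#' @return A \code{bd_chain} with zero backward rates.
#' @export
stepwise_chain <- function(n = 5L, p = 1 / 20) {
  stopifnot(n >= 1, p > 0, p < 1)
  k <- 0:(n - 1)
  birth_death_chain(forward = (n - k) * p)
}

.waiting_time <- function(mfpt, method, se = NA_real_) {
  structure(list(mfpt = mfpt, half_time = log(2) * mfpt, method = method,
                 se = se),
            class = "waiting_time")
}

#' @export
print.waiting_time <- function(x, ...) {
  cat(sprintf("Mean first-passage time %.4g (half-time %.4g) [%s]%s\n",
              x$mfpt, x$half_time, x$method,
              if (is.finite(x$se)) sprintf(", sim SE %.3g", x$se) else ""))
  cat("  (arbitrary time units)\n")
  invisible(x)
}

#' Mean first-passage time of a birth-death chain
#'
#' Expected time to first reach the absorbing state n starting from state 0,
#' computed by the standard birth-death summation
#' \deqn{T = \sum_{k=0}^{n-1} \sum_{i=0}^{k} \frac{1}{\lambda_i}
#'   \prod_{j=i+1}^{k} \frac{\mu_j}{\lambda_j}}
#' or, equivalently, by solving the first-step linear system
#' \eqn{(\lambda_k + \mu_k) t_k = 1 + \lambda_k t_{k+1} + \mu_k t_{k-1}}.
#' \code{method = "both"} computes both and errors if they disagree beyond
#' 1e-10 relative tolerance.
#'
#' @param chain A \code{bd_chain}.
#' @param method \code{"closed_form"}, \code{"linear_solve"} or
#'   \code{"both"}.
#' @return A \code{waiting_time} with \code{mfpt}, \code{half_time}
#'   (\code{log(2) * mfpt}), and \code{method}.
#' @export
#' @examples
#' mfpt_birth_death(cooperative_chain(5, 1/20))   # ~6.8e5
#' mfpt_birth_death(stepwise_chain(5, 1/20))      # ~45.7, half-time ~32
mfpt_birth_death <- function(chain,
                             method = c("closed_form", "linear_solve", "both")) {
  method <- match.arg(method)
  stopifnot(inherits(chain, "bd_chain"))
  lam <- chain$forward
  mu <- chain$backward
  n <- length(lam)

  closed <- function() {
    total <- 0
    for (k in 0:(n - 1)) {
      for (i in 0:k) {
        t <- 1 / lam[i + 1]
        if (i < k) for (j in (i + 1):k) t <- t * mu[j + 1] / lam[j + 1]
        total <- total + t
      }
    }
    total
  }

  linear <- function() {
    # unknowns t_0..t_{n-1}; t_n = 0
    A <- matrix(0, n, n)
    b <- rep(1, n)
    for (k in 0:(n - 1)) {
      i <- k + 1
      A[i, i] <- lam[i] + mu[i]
      if (k > 0) A[i, i - 1] <- -mu[i]
      if (k < n - 1) A[i, i + 1] <- -lam[i]
    }
    solve(A, b)[1]
  }

  if (method == "closed_form") return(.waiting_time(closed(), method))
  if (method == "linear_solve") return(.waiting_time(linear(), method))
  tc <- closed(); tl <- linear()
  if (abs(tc - tl) > 1e-10 * max(abs(tc), abs(tl))) {
    stop(sprintf("closed form (%.12g) and linear solve (%.12g) disagree", tc, tl),
         call. = FALSE)
  }
  .waiting_time(tc, "both")
}

#' Waiting time for a single irreversible pathway
#'
#' n successive irreversible steps, each an exponential waiting time at rate
#' p: MFPT = n / p. With n = 5 and p = 1/20 the effective rate constant is
#' 1/100 and the half-time is 100 ln 2 ~ 69.
#'
#' @inheritParams cooperative_chain
#' @return A \code{waiting_time}.
#' @export
#' @examples
#' single_path_time(5, 1/20)
single_path_time <- function(n = 5L, p = 1 / 20) {
  stopifnot(n >= 1)
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p > 1) {
    stop("p must lie in (0, 1]", call. = FALSE)
  }
  .waiting_time(n / p, "closed_form")
}

#' Kinetic Monte Carlo simulation of a birth-death chain
#'
#' Gillespie-style simulation: exponential holding times at the total rate
#' out of the current state, transitions chosen with probability
#' proportional to their rates. Serves as a stochastic oracle for the
#' deterministic solvers; given a seed, the output is fully reproducible
#' (the global RNG state is restored on exit).
#'
#' @param chain A \code{bd_chain}.
#' @param n_replicates Number of independent absorption times (>= 1).
#' @param seed Integer seed; required.
#' @return A \code{waiting_time}; \code{mfpt} is the replicate mean and
#'   \code{se} its standard error.
#' @export
#' @examples
#' simulate_chain(stepwise_chain(5, 1/20), 200, seed = 1)
simulate_chain <- function(chain, n_replicates, seed) {
  stopifnot(inherits(chain, "bd_chain"), n_replicates >= 1)
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lam <- chain$forward
  mu <- chain$backward
  n <- length(lam)
  times <- vapply(seq_len(n_replicates), function(r) {
    k <- 0L
    t <- 0
    while (k < n) {
      up <- lam[k + 1]
      down <- if (k > 0) mu[k + 1] else 0
      rate <- up + down
      t <- t + stats::rexp(1, rate)
      k <- if (stats::runif(1) < up / rate) k + 1L else k - 1L
    }
    t
  }, numeric(1))
  .waiting_time(mean(times), "simulation",
                se = stats::sd(times) / sqrt(n_replicates))
}

#' Mean waiting time on a landscape's accessible-path chain
#'
#' Builds the continuous-time chain over the 32 genotypes in which each
#' passing edge (strict fold increase > \code{threshold}) is an
#' irreversible transition at rate \code{p}. Transitions are restricted to
#' edges lying on at least one fully accessible monotonic path, i.e. edges
#' whose endpoints are both forward-reachable from the minimal enzyme and
#' backward-reachable from WT through passing edges; this keeps the
#' absorbing state reachable from every visited state, matching the premise
#' that trajectories stalling short of WT carry negligible probability.
#'
#' @inheritParams classify_edges
#' @param p Per-edge rate (default 1/20, one advantageous residue among the
#'   twenty amino acids).
#' @param wt_convention WT reference convention (default
#'   \code{"observed"}, the landscape as displayed).
#' @return A \code{waiting_time} (method \code{"linear_solve"}).
#' @export
#' @examples
#' mfpt_general(builtin_table1(), threshold = 3)
mfpt_general <- function(landscape, threshold, wt_convention = "observed",
                         p = 1 / 20) {
  stopifnot(p > 0)
  pass <- classify_edges(landscape, threshold, wt_convention)
  # forward reachability from minimal
  reach <- "00000"
  repeat {
    grown <- union(reach, pass$to[pass$from %in% reach])
    if (length(grown) == length(reach)) break
    reach <- grown
  }
  # backward reachability from WT
  back <- "11111"
  repeat {
    grown <- union(back, pass$from[pass$to %in% back])
    if (length(grown) == length(back)) break
    back <- grown
  }
  states <- intersect(reach, back)
  if (!("11111" %in% reach) || !("00000" %in% states)) {
    stop("WT is not reachable from the minimal enzyme through passing edges",
         call. = FALSE)
  }
  keep <- pass$from %in% states & pass$to %in% states
  e <- pass[keep, , drop = FALSE]
  # process states by decreasing number of residues: the DAG's reverse
  # topological order, so t(to) is known before t(from)
  ord <- states[order(-.n_present(states))]
  t <- stats::setNames(numeric(length(states)), ord)
  for (s in ord) {
    if (s == "11111") next
    outs <- e$to[e$from == s]
    t[[s]] <- 1 / (length(outs) * p) + mean(t[outs])
  }
  .waiting_time(t[["00000"]], "linear_solve")
}
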