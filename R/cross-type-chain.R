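#' Cross-type distribution for haplodiploid full sib-mating
#'
#' A mated female sampled from a haplodiploid population carries at most three
#' distinct alleles per locus (two of her own plus her mate's), so every
#' sib-mated pair falls into one of four cross types:
#'
#' * `A` — heterozygous female, mate shares no allele (e.g. \[xy\] x \[z\])
#' * `B` — heterozygous female, mate shares one allele (e.g. \[xy\] x \[x\])
#' * `C` — homozygous female, mate carries a different allele (\[xx\] x \[y\])
#' * `D` — homozygous female, mate carries the same allele (\[xx\] x \[x\]);
#'   the absorbing, fully inbred state.
#'
#' `cross_type_distribution()` builds the state vector of the four-type chain
#' at a given generation. In `"exact"` mode frequencies are stored as dyadic
#' rationals (integer numerators over a common power-of-two denominator);
#' every chain update is a halving or quartering, so iteration is exact.
#'
#' @param A,B,C,D Frequencies of the four cross types; must be non-negative
#'   and sum to 1 (to within `1e-9` in floating mode).
#' @param generation Number of completed sib-mating generations (default 0).
#' @param mode `"exact"` for dyadic-rational arithmetic (the default; requires
#'   frequencies exactly representable as `n / 2^k`), `"floating"` for plain
#'   double precision.
#' @return An object of class `"cross_type_dist"`: a list with elements
#'   `generation`, `freq` (named numeric of length 4) and, in exact mode,
#'   `num` (integer numerators) and `k` (the common denominator is `2^k`).
#' @examples
#' d0 <- cross_type_distribution(1, 0, 0, 0)   # most-heterozygotic founding
#' step_cross_types(d0)
#' @seealso [step_cross_types()], [inbreeding_trajectory()]
#' @export
cross_type_distribution <- function(A, B, C, D, generation = 0L,
                                    mode = c("exact", "floating")) {
  mode <- match.arg(mode)
  freq <- c(A = A, B = B, C = C, D = D)
  if (anyNA(freq) || !is.numeric(freq)) {
    stop("cross-type frequencies must be numeric and non-missing")
  }
  if (any(freq < 0)) {
    stop("cross-type frequencies must be non-negative")
  }
  if (abs(sum(freq) - 1) > 1e-9) {
    stop("cross-type frequencies must sum to 1 (got ", sum(freq), ")")
  }
  generation <- as.integer(generation)
  if (length(generation) != 1L || is.na(generation) || generation < 0L) {
    stop("'generation' must be a single non-negative integer")
  }
  obj <- list(generation = generation, freq = freq, num = NULL, k = NULL)
  if (mode == "exact") {
    dy <- .as_dyadic(freq)
    if (is.null(dy)) {
      stop("exact mode requires frequencies representable as n / 2^k; ",
           "use mode = \"floating\" for arbitrary values")
    }
    obj$num <- dy$num
    obj$k <- dy$k
    obj$freq <- dy$num / 2^dy$k
  }
  class(obj) <- "cross_type_dist"
  obj
}

# Find integer numerators over a common 2^k denominator, or NULL if the
# values are not dyadic within k <= 32 (the cap leaves ~20 bits of headroom
# for iteration before numerators approach the 2^53 exactness limit; it also
# keeps near-dyadic doubles like 1/3 out of exact mode).
.as_dyadic <- function(x) {
  for (k in 0:32) {
    scaled <- x * 2^k
    if (all(scaled == round(scaled))) {
      return(list(num = round(scaled), k = k))
    }
  }
  NULL
}

#' @export
print.cross_type_dist <- function(x, ...) {
  cat("Sib-mating cross-type distribution (generation ", x$generation, ")\n",
      sep = "")
  mode <- if (is.null(x$num)) "floating" else "exact dyadic"
  cat("  arithmetic: ", mode, "\n", sep = "")
  print(round(x$freq, 6))
  pt <- inbreeding_from_distribution(x)
  cat(sprintf("  f = %.6f  P(fully inbred) = %.6f\n", pt$f, pt$p_fully_inbred))
  invisible(x)
}

.is_exact <- function(dist) !is.null(dist$num)

.check_dist <- function(dist) {
  if (!inherits(dist, "cross_type_dist")) {
    stop("expected a 'cross_type_dist' object; see cross_type_distribution()")
  }
  if (any(dist$freq < 0) || abs(sum(dist$freq) - 1) > 1e-9) {
    stop("invalid cross-type distribution: frequencies must be non-negative ",
         "and sum to 1")
  }
  invisible(dist)
}

#' Advance the cross-type chain by one sib-mating generation
#'
#' Applies the one-generation recurrence of the four-type chain:
#' \deqn{A' = A/2, \quad B' = A/2 + B/2 + C, \quad C' = B/4, \quad D' = B/4 + D.}
#' Type A crosses yield half type A and half type B broods; type B yield half
#' B, a quarter C and a quarter D; type C always yields B; type D is
#' absorbing. In exact mode the update is carried out on integer numerators
#' (denominator grows by at most 2^2 per step, then is reduced).
#'
#' @param dist A [cross_type_distribution()].
#' @return The distribution one generation later (`generation + 1`).
#' @examples
#' step_cross_types(cross_type_distribution(0, 1, 0, 0))  # B -> (0, 1/2, 1/4, 1/4)
#' @export
step_cross_types <- function(dist) {
  .check_dist(dist)
  if (.is_exact(dist)) {
    n <- dist$num
    # common denominator 2^(k+2)
    num <- c(A = 2 * n[["A"]],
             B = 2 * n[["A"]] + 2 * n[["B"]] + 4 * n[["C"]],
             C = n[["B"]],
             D = n[["B"]] + 4 * n[["D"]])
    k <- dist$k + 2L
    while (k > 0L && all(num %% 2 == 0)) {
      num <- num / 2
      k <- k - 1L
    }
    if (max(num) >= 2^53) {
      stop("exact dyadic numerators exceed 2^53; rerun in floating mode")
    }
    dist$num <- num
    dist$k <- k
    dist$freq <- num / 2^k
  } else {
    f <- dist$freq
    dist$freq <- c(A = f[["A"]] / 2,
                   B = f[["A"]] / 2 + f[["B"]] / 2 + f[["C"]],
                   C = f[["B"]] / 4,
                   D = f[["B"]] / 4 + f[["D"]])
  }
  dist$generation <- dist$generation + 1L
  dist
}

#' Inbreeding summary of a cross-type distribution
#'
#' The coefficient of inbreeding is the probability that the two alleles at a
#' locus are identical by descent; under the four-type chain it equals the
#' combined frequency of crosses with a homozygous mother, `f = C + D`. The
#' probability that the line is fully inbred at the locus is the frequency of
#' the absorbing type, `D`.
#'
#' @param dist A [cross_type_distribution()].
#' @return A list of class `"inbreeding_point"` with elements `generation`,
#'   `f` and `p_fully_inbred`.
#' @examples
#' inbreeding_from_distribution(cross_type_distribution(0.25, 0.5, 0.125, 0.125,
#'                                                      generation = 2))
#' @export
inbreeding_from_distribution <- function(dist) {
  .check_dist(dist)
  out <- list(generation = dist$generation,
              f = dist$freq[["C"]] + dist$freq[["D"]],
              p_fully_inbred = dist$freq[["D"]])
  class(out) <- "inbreeding_point"
  out
}

#' @export
print.inbreeding_point <- function(x, ...) {
  cat(sprintf("generation %d: f = %.6f (%.1f%%), P(fully inbred) = %.6f (%.1f%%)\n",
              x$generation, x$f, 100 * x$f,
              x$p_fully_inbred, 100 * x$p_fully_inbred))
  invisible(x)
}

#' Iterate the sib-mating chain and record the inbreeding trajectory
#'
#' Starting from an initial cross-type distribution (by default the
#' most-heterozygotic founding cross, a \[xy\] female mated to a \[z\] male,
#' i.e. `A = 1` at generation 0 — the conservative assumption when founder
#' genotypes are unknown), iterates [step_cross_types()] for the requested
#' number of generations and tabulates the four frequencies together with the
#' inbreeding coefficient `f = C + D` and the probability of a fully inbred
#' line `D`. After 15 generations from `A = 1`, `f` reaches 95.1% and `D`
#' 93.6%.
#'
#' @param generations Number of sib-mating generations to iterate (>= 1).
#' @param initial Starting [cross_type_distribution()]; its `generation` field
#'   labels the first row.
#' @param mode Optional override of the initial distribution's arithmetic
#'   mode.
#' @return A data frame of class `"inbreeding_trajectory"` with columns
#'   `generation`, `freq_A` .. `freq_D`, `f`, `p_fully_inbred`, one row per
#'   generation from the initial one to the horizon. Attributes `mode` and
#'   `initial` record provenance.
#' @examples
#' tr <- inbreeding_trajectory(15)
#' tail(tr, 1)  # f = 0.951263..., p_fully_inbred = 0.936218...
#' @export
inbreeding_trajectory <- function(generations,
                                  initial = cross_type_distribution(1, 0, 0, 0),
                                  mode = NULL) {
  generations <- as.integer(generations)
  if (length(generations) != 1L || is.na(generations) || generations < 1L) {
    stop("'generations' must be a single integer >= 1")
  }
  .check_dist(initial)
  if (!is.null(mode)) {
    mode <- match.arg(mode, c("exact", "floating"))
    initial <- cross_type_distribution(initial$freq[["A"]], initial$freq[["B"]],
                                       initial$freq[["C"]], initial$freq[["D"]],
                                       generation = initial$generation,
                                       mode = mode)
  }
  rows <- vector("list", generations + 1L)
  d <- initial
  for (i in seq_len(generations + 1L)) {
    pt <- inbreeding_from_distribution(d)
    rows[[i]] <- data.frame(generation = d$generation,
                            freq_A = d$freq[["A"]], freq_B = d$freq[["B"]],
                            freq_C = d$freq[["C"]], freq_D = d$freq[["D"]],
                            f = pt$f, p_fully_inbred = pt$p_fully_inbred)
    if (i <= generations) d <- step_cross_types(d)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "mode") <- if (.is_exact(initial)) "exact" else "floating"
  attr(out, "initial") <- initial$freq
  class(out) <- c("inbreeding_trajectory", "data.frame")
  out
}

#' Plot an inbreeding trajectory
#'
#' Draws `f` (dashed) and the probability of a fully inbred line (solid)
#' against generation, mirroring the usual presentation of sib-mating
#' inbreeding curves.
#'
#' @param x An [inbreeding_trajectory()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.inbreeding_trajectory <- function(x, ...) {
  graphics::plot(x$generation, x$f, type = "l", lty = 2, ylim = c(0, 1),
                 xlab = "generation of sib-mating", ylab = "probability", ...)
  graphics::lines(x$generation, x$p_fully_inbred, lty = 1)
  graphics::legend("bottomright", lty = c(2, 1),
                   legend = c(expression(f[t]), expression(D[t])), bty = "n")
  invisible(x)
}

#' Direct inbreeding-coefficient recurrence for haplodiploid full sib-mating
#'
#' The coefficient can also be computed without tracking cross types, via
#' \deqn{f_t = \tfrac14 + \tfrac14 f_{t-2} + \tfrac12 f_{t-1},
#'       \qquad f_1 = f_2 = 0:}
#' with probability 1/2 both of a female's alleles descend from her
#' grandmother (identical with probability 1/2, otherwise IBD with
#' probability \eqn{f_{t-2}}), and with probability 1/2 one comes from the
#' grandfather (IBD with probability \eqn{f_{t-1}}).
#'
#' Indexing differs between the two methods: the recurrence value at index
#' `t + 1` equals the cross-type chain value at generation `t` (the chain's
#' generation count — completed sib-mating generations since the founding
#' cross — is the canonical one in this package; only that convention
#' reproduces f = 95.1% "after 15 generations").
#'
#' @param horizon Largest index to compute (>= 3).
#' @return Named numeric vector `f_3 .. f_<horizon>` (values at indices 1 and
#'   2 are 0 by definition). Computed in exact dyadic arithmetic.
#' @examples
#' direct_f_recurrence(16)[["f_16"]]  # 0.951263..., the chain's generation-15 value
#' @export
direct_f_recurrence <- function(horizon) {
  horizon <- as.integer(horizon)
  if (length(horizon) != 1L || is.na(horizon) || horizon < 3L) {
    stop("'horizon' must be a single integer >= 3")
  }
  # dyadic pairs (num, k): f = num / 2^k
  fm2 <- c(0, 0)  # f_{t-2}
  fm1 <- c(0, 0)  # f_{t-1}
  out <- numeric(horizon - 2L)
  for (t in 3:horizon) {
    # 1/4 + fm2/4 + fm1/2 over common denominator 2^(max(k)+2)
    k <- max(fm2[2], fm1[2]) + 2
    num <- 2^(k - 2) + fm2[1] * 2^(k - 2 - fm2[2]) + fm1[1] * 2^(k - 1 - fm1[2])
    while (k > 0 && num %% 2 == 0) {
      num <- num / 2
      k <- k - 1
    }
    if (num >= 2^53) stop("exact dyadic numerator exceeds 2^53")
    out[t - 2L] <- num / 2^k
    fm2 <- fm1
    fm1 <- c(num, k)
  }
  names(out) <- paste0("f_", 3:horizon)
  out
}

#' First generation at which an inbreeding statistic reaches a threshold
#'
#' Planning aid for choosing a sib-mating horizon: scans the exact trajectory
#' from the initial distribution and returns the smallest generation at which
#' the chosen statistic is at least `threshold`. Both statistics converge to
#' 1 (type D is absorbing), so any threshold below 1 is reached in finite
#' time; a threshold of 1 or more is rejected as unreachable from any
#' not-yet-inbred start.
#'
#' @param threshold Probability in `[0, 1)`.
#' @param statistic `"f"` (coefficient of inbreeding) or `"p_fully_inbred"`.
#' @param initial Starting [cross_type_distribution()].
#' @return The generation number (non-negative integer).
#' @examples
#' generations_to_threshold(0.95, "f")              # 15
#' generations_to_threshold(0.9, "p_fully_inbred")  # 13
#' @export
generations_to_threshold <- function(threshold,
                                     statistic = c("f", "p_fully_inbred"),
                                     initial = cross_type_distribution(1, 0, 0, 0)) {
  statistic <- match.arg(statistic)
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold < 0) {
    stop("'threshold' must be a single probability")
  }
  if (threshold >= 1) {
    stop("threshold >= 1 is unreachable in finite time; choose a value below 1")
  }
  .check_dist(initial)
  d <- initial
  repeat {
    pt <- inbreeding_from_distribution(d)
    val <- if (statistic == "f") pt$f else pt$p_fully_inbred
    if (val >= threshold) return(d$generation)
    d <- step_cross_types(d)
  }
}
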