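#' Simulate attrition of a panel of inbred lines
#'
#' Models the inbred-line creation protocol: each line is propagated on
#' `replicates_per_line` replicate patches per generation (replication is
#' survival insurance only — the next generation always continues from a
#' single patch, so it carries no genetic branching). Each replicate
#' independently fails with probability `failure_prob` per generation (death
#' of the female, null fecundity, no egg hatching, or a single-sex brood);
#' the line is lost only when all replicates fail.
#'
#' @param n_lines Lines founded at generation 0 (default 450, the protocol's
#'   panel size).
#' @param generations Sib-mating generations (default 15).
#' @param replicates_per_line Replicate patches per line per generation
#'   (default 3).
#' @param failure_prob Marginal per-replicate, per-generation failure
#'   probability in `[0, 1]`.
#' @param cause_probs Optional named numeric decomposing `failure_prob` by
#'   cause (e.g. `c(female_death = .., null_fecundity = .., no_hatching = ..,
#'   single_sex_brood = ..)`); must sum to `failure_prob`. Causes are
#'   attributed to failed replicates proportionally; they do not change the
#'   survival dynamics.
#' @param seed Optional integer seed; recorded in the output.
#' @return A list of class `"panel_trajectory"`: `survivors` (integer vector,
#'   generations 0..`generations`, non-increasing), `alive` (logical line
#'   survival flags at the horizon), `cause_counts` (if `cause_probs` given),
#'   plus the configuration and seed.
#' @examples
#' p <- simulate_line_panel(450, failure_prob = 0.5, seed = 1)
#' p$survivors
#' @export
simulate_line_panel <- function(n_lines = 450L, generations = 15L,
                                replicates_per_line = 3L, failure_prob,
                                cause_probs = NULL, seed = NULL) {
  n_lines <- as.integer(n_lines)
  generations <- as.integer(generations)
  replicates_per_line <- as.integer(replicates_per_line)
  if (is.na(n_lines) || n_lines < 1L) stop("'n_lines' must be >= 1")
  if (is.na(generations) || generations < 1L) stop("'generations' must be >= 1")
  if (is.na(replicates_per_line) || replicates_per_line < 1L) {
    stop("'replicates_per_line' must be >= 1")
  }
  if (!is.numeric(failure_prob) || length(failure_prob) != 1L ||
      is.na(failure_prob) || failure_prob < 0 || failure_prob > 1) {
    stop("'failure_prob' must be a probability in [0, 1]")
  }
  if (!is.null(cause_probs)) {
    if (is.null(names(cause_probs)) || any(cause_probs < 0)) {
      stop("'cause_probs' must be a named non-negative numeric vector")
    }
    if (abs(sum(cause_probs) - failure_prob) > 1e-9) {
      stop("'cause_probs' must sum to 'failure_prob'")
    }
  }
  if (!is.null(seed)) set.seed(seed)

  alive <- rep(TRUE, n_lines)
  survivors <- integer(generations + 1L)
  survivors[1] <- n_lines
  cause_counts <- if (is.null(cause_probs)) NULL else
    stats::setNames(integer(length(cause_probs)), names(cause_probs))
  for (g in seq_len(generations)) {
    idx <- which(alive)
    if (length(idx)) {
      # replicate-level failure events for every live line
      fails <- matrix(stats::runif(length(idx) * replicates_per_line) < failure_prob,
                      nrow = length(idx))
      if (!is.null(cause_probs) && any(fails)) {
        drawn <- sample(names(cause_probs), sum(fails), replace = TRUE,
                        prob = cause_probs / failure_prob)
        tab <- table(factor(drawn, levels = names(cause_probs)))
        cause_counts <- cause_counts + as.integer(tab)
      }
      alive[idx[rowSums(!fails) == 0L]] <- FALSE
    }
    survivors[g + 1L] <- sum(alive)
  }
  structure(list(survivors = survivors, alive = alive,
                 cause_counts = cause_counts,
                 n_lines = n_lines, generations = generations,
                 replicates_per_line = replicates_per_line,
                 failure_prob = failure_prob, seed = seed),
            class = "panel_trajectory")
}

#' @export
print.panel_trajectory <- function(x, ...) {
  cat(sprintf("Line-panel attrition: %d lines, %d generations, %d replicates/line, q = %.4f\n",
              x$n_lines, x$generations, x$replicates_per_line, x$failure_prob))
  cat("  survivors:", paste(x$survivors, collapse = " "), "\n")
  invisible(x)
}

#' Monte-Carlo replication of line-panel attrition
#'
#' Repeats the panel simulation many times and summarises the surviving-line
#' trajectory. Per generation, each live line is lost when all
#' `replicates_per_line` replicates fail, i.e. with probability
#' `failure_prob ^ replicates_per_line`; losses are drawn as binomial counts
#' over live lines, which is distributionally identical to replicate-level
#' draws and fast enough for tens of thousands of panels.
#'
#' @inheritParams simulate_line_panel
#' @param n_panels Number of independent panel replicates.
#' @return A list: `mean_trajectory` (mean survivors per generation),
#'   `final_survivors` (vector over panels), `mean_final`, `se_final`
#'   (standard error of the mean final count), and the configuration.
#' @export
replicate_line_panels <- function(n_panels, n_lines = 450L, generations = 15L,
                                  replicates_per_line = 3L, failure_prob,
                                  seed = NULL) {
  n_panels <- as.integer(n_panels)
  if (is.na(n_panels) || n_panels < 1L) stop("'n_panels' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  p_loss <- failure_prob^replicates_per_line
  counts <- matrix(0L, generations + 1L, n_panels)
  counts[1, ] <- n_lines
  cur <- rep(n_lines, n_panels)
  for (g in seq_len(generations)) {
    cur <- cur - stats::rbinom(n_panels, size = cur, prob = p_loss)
    counts[g + 1L, ] <- cur
  }
  list(mean_trajectory = rowMeans(counts),
       final_survivors = counts[generations + 1L, ],
       mean_final = mean(cur),
       se_final = stats::sd(cur) / sqrt(n_panels),
       n_panels = n_panels, n_lines = n_lines, generations = generations,
       replicates_per_line = replicates_per_line, failure_prob = failure_prob,
       seed = seed)
}

#' Calibrate the per-replicate failure probability from panel endpoints
#'
#' Inverts the expected-survival relation
#' \deqn{(1 - q^{r})^{g} = S/N}
#' for the per-replicate, per-generation failure probability `q`, given that
#' `N` founded lines left `S` survivors after `g` generations with `r`
#' replicates per line. The left side is strictly decreasing in `q` on
#' `[0, 1]`, so the root is unique; it is found numerically.
#'
#' @param initial_lines Lines founded (`N > 0`).
#' @param surviving_lines Lines remaining (`0 < S <= N`). A target of zero is
#'   rejected: no failure probability below 1 drives the expectation exactly
#'   to zero.
#' @param generations Number of generations `g >= 1`.
#' @param replicates_per_line Replicates per line `r >= 1`.
#' @param tol Root-finding tolerance.
#' @return The failure probability `q`.
#' @examples
#' calibrate_failure_prob(450, 59, 15, 3)  # ~0.502
#' @export
calibrate_failure_prob <- function(initial_lines, surviving_lines, generations,
                                   replicates_per_line = 3L, tol = 1e-10) {
  if (initial_lines <= 0) stop("'initial_lines' must be positive")
  if (surviving_lines > initial_lines) {
    stop("'surviving_lines' cannot exceed 'initial_lines'")
  }
  if (surviving_lines <= 0) {
    stop("a survival target of 0 is unattainable: no failure probability ",
         "below 1 gives expected survival exactly 0")
  }
  if (generations < 1) stop("'generations' must be >= 1")
  target <- surviving_lines / initial_lines
  if (target == 1) return(0)
  fn <- function(q) (1 - q^replicates_per_line)^generations - target
  stats::uniroot(fn, c(0, 1), tol = tol)$root
}
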