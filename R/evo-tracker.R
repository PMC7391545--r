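#' Plan one serial-transfer census
#'
#' At each transfer of an experimental-evolution replicate, a fixed number of
#' mated females (220 by default in the protocol, ensuring >200 survive
#' transfer mortality) must be collected. Sourcing follows a strict
#' priority: first the current experimental box, then the previous
#' generation's backup box, and any remaining shortfall from the base
#' outbred population, which is treated as inexhaustible.
#'
#' @param available_current Females available in the current box.
#' @param available_backup Females available in the t-1 backup box.
#' @param target Total females to transfer (default 220).
#' @return A list of class `"transfer_record"` with counts `n_current`,
#'   `n_backup`, `n_base` and `n_total` (always summing to `target`).
#' @examples
#' plan_transfer(180, 60)   # 180 from current, 40 from backup, 0 from base
#' plan_transfer(100, 50)   # 100 / 50 / 70
#' @export
plan_transfer <- function(available_current, available_backup, target = 220L) {
  if (target < 1) stop("'target' must be >= 1")
  if (available_current < 0 || available_backup < 0) {
    stop("availabilities must be non-negative")
  }
  n_cur <- min(available_current, target)
  n_back <- min(available_backup, target - n_cur)
  n_base <- target - n_cur - n_back
  structure(list(n_current = n_cur, n_backup = n_back, n_base = n_base,
                 n_total = target),
            class = "transfer_record")
}

#' @export
print.transfer_record <- function(x, ...) {
  cat(sprintf("Transfer of %d females: %d current + %d backup + %d base\n",
              x$n_total, x$n_current, x$n_backup, x$n_base))
  invisible(x)
}

#' Effective number of generations of selection after a transfer
#'
#' Individuals replenished from the backup or base populations have
#' experienced fewer generations of selection than the resident population,
#' so replicates that receive migrants accumulate selection more slowly. The
#' transfer-weighted mean is
#' \deqn{Gen_{t+1} = 1 + \frac{N_t \, Gen_t + N_{t-1} \, Gen_{t-1} +
#'       N_0 \cdot 0}{N_{total}},}
#' where \eqn{N_t, N_{t-1}, N_0} are the counts drawn from the current box,
#' the t-1 backup and the base population, and \eqn{Gen_t, Gen_{t-1}} their
#' effective-generation values (the base population is not adapting, so its
#' value is 0). The result is kept fractional. It always lies in
#' `[1, 1 + max(gen_current, gen_backup)]` — a weighted mean of the source
#' values plus one — and equals `gen_current + 1` exactly when sourced
#' entirely from the current box. Only while the backup never outranks the
#' current box (as in uninterrupted operation) does the tighter familiar
#' bound `gen_current + 1` hold.
#'
#' @param record A [plan_transfer()] result, or a list with fields
#'   `n_current`, `n_backup`, `n_base`, `n_total`.
#' @param gen_current Effective generations of the current box.
#' @param gen_backup Effective generations of the backup box (one transfer
#'   older).
#' @return The effective-generation value after this transfer.
#' @examples
#' effective_generations(plan_transfer(110, 55), gen_current = 5, gen_backup = 4)  # 4.5
#' @export
effective_generations <- function(record, gen_current, gen_backup = 0) {
  need <- c("n_current", "n_backup", "n_base", "n_total")
  if (!is.list(record) || !all(need %in% names(record))) {
    stop("'record' must carry counts n_current, n_backup, n_base, n_total")
  }
  counts <- unlist(record[need])
  if (any(counts < 0)) stop("transfer counts must be non-negative")
  if (record$n_current + record$n_backup + record$n_base != record$n_total) {
    stop("transfer counts must sum to n_total")
  }
  if (gen_current < 0 || gen_backup < 0) {
    stop("effective-generation values must be non-negative")
  }
  1 + (record$n_current * gen_current + record$n_backup * gen_backup) /
    record$n_total
}

#' Track effective generations across a replicate's transfer history
#'
#' Chains [plan_transfer()] and [effective_generations()] over a history of
#' per-transfer availabilities. The current box entering transfer t carries
#' the effective-generation value computed at transfer t-1, and the backup
#' box carries the value from transfer t-2 (the backup is simply the
#' previous generation's box kept until the next transfer); both start at 0,
#' the base population's value, at the founding of the replicate.
#'
#' @param history Data frame with columns `available_current` and
#'   `available_backup`, one row per transfer in chronological order.
#' @param target Females per transfer (default 220).
#' @param label Optional replicate/regime label, carried through.
#' @return A data frame of class `"regime_history"` with columns
#'   `generation`, `n_current`, `n_backup`, `n_base`, `n_total`,
#'   `effective_generations`; attribute `label`.
#' @examples
#' h <- data.frame(available_current = c(250, 100, 0),
#'                 available_backup = c(0, 50, 0))
#' track_regime(h)
#' @export
track_regime <- function(history, target = 220L, label = NULL) {
  if (!is.data.frame(history) || !nrow(history) ||
      !all(c("available_current", "available_backup") %in% names(history))) {
    stop("'history' must be a non-empty data frame with columns ",
         "'available_current' and 'available_backup'")
  }
  gen_cur <- 0   # value of the current box (set at the previous transfer)
  gen_back <- 0  # value of the backup box (one transfer older)
  out <- vector("list", nrow(history))
  for (t in seq_len(nrow(history))) {
    rec <- plan_transfer(history$available_current[t],
                         history$available_backup[t], target)
    val <- effective_generations(rec, gen_cur, gen_back)
    out[[t]] <- data.frame(generation = t,
                           n_current = rec$n_current, n_backup = rec$n_backup,
                           n_base = rec$n_base, n_total = rec$n_total,
                           effective_generations = val)
    gen_back <- gen_cur
    gen_cur <- val
  }
  res <- do.call(rbind, out)
  attr(res, "label") <- label
  class(res) <- c("regime_history", "data.frame")
  res
}
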