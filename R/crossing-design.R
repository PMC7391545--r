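#' Define a controlled interpopulation crossing design
#'
#' Two designs for building a fully hybrid outbred population in a
#' haplodiploid are supported, matching the two protocols actually used:
#'
#' * `"matched-pairs-4"` — four founder populations in two fixed pairs;
#'   reciprocal parental crosses within each pair, then reciprocal
#'   hybrid-by-hybrid crosses across pairs. Yields 8 fully hybrid
#'   combinations.
#' * `"round-robin-3"` — three founder populations; reciprocal parental
#'   crosses among all pairs, each F1 hybrid female then mated to males from
#'   the population absent from her parental cross. Yields 6 combinations.
#'
#' Because males develop from unfertilized eggs, hybrid males must be
#' produced by isolating virgin hybrid females and raising their sons — the
#' scheduling constraint handled by [build_schedule()]. Other population
#' counts are rejected rather than extrapolated. Populations showing hybrid
#' breakdown should be excluded by the user before constructing the design.
#'
#' @param kind Design kind.
#' @param populations Character vector of unique single-letter population
#'   labels: exactly 4 for matched pairs, 3 for round robin. For matched
#'   pairs the first two labels form one parental pair and the last two the
#'   other.
#' @param crosses_per_type Individual crosses performed per cross type
#'   (default 200, chosen so each combination yields comfortably more than
#'   the >70 mated females a representative founding requires).
#' @return A list of class `"crossing_design"`.
#' @examples
#' crossing_design("matched-pairs-4", LETTERS[1:4])
#' crossing_design("round-robin-3", c("E", "F", "G"))
#' @export
crossing_design <- function(kind = c("matched-pairs-4", "round-robin-3"),
                            populations, crosses_per_type = 200L) {
  kind <- match.arg(kind)
  populations <- as.character(populations)
  want <- if (kind == "matched-pairs-4") 4L else 3L
  if (length(populations) != want) {
    stop("design '", kind, "' requires exactly ", want,
         " founder populations (other counts are not supported)")
  }
  if (anyDuplicated(populations)) stop("population labels must be unique")
  if (any(nchar(populations) != 1L)) {
    stop("population labels must be single characters (combination labels ",
         "concatenate them)")
  }
  crosses_per_type <- as.integer(crosses_per_type)
  if (is.na(crosses_per_type) || crosses_per_type < 1L) {
    stop("'crosses_per_type' must be >= 1")
  }
  structure(list(kind = kind, populations = populations,
                 crosses_per_type = crosses_per_type),
            class = "crossing_design")
}

#' @export
print.crossing_design <- function(x, ...) {
  cat(sprintf("Crossing design '%s' over populations %s (%d crosses per type)\n",
              x$kind, paste(x$populations, collapse = ", "), x$crosses_per_type))
  invisible(x)
}

# Female offspring of a cross inherit the maternal lineage label first;
# a female's label therefore starts with her mitochondrial origin.
.offspring_label <- function(mother, father) paste0(mother, father)

# Parental cross table for a design: reciprocal within pairs (matched pairs)
# or among all pairs (round robin).
.parental_crosses <- function(design) {
  p <- design$populations
  if (design$kind == "matched-pairs-4") {
    data.frame(mother = c(p[1], p[2], p[3], p[4]),
               father = c(p[2], p[1], p[4], p[3]))
  } else {
    pairs <- utils::combn(p, 2)
    data.frame(mother = c(pairs[1, ], pairs[2, ]),
               father = c(pairs[2, ], pairs[1, ]))
  }
}

# Hybrid cross table: F1 x F1 across pairs (matched pairs) or F1 female x
# excluded-founder male (round robin).
.hybrid_crosses <- function(design) {
  p <- design$populations
  par <- .parental_crosses(design)
  f1 <- .offspring_label(par$mother, par$father)
  if (design$kind == "matched-pairs-4") {
    pair1 <- f1[par$mother %in% p[1:2]]
    pair2 <- f1[par$mother %in% p[3:4]]
    expand <- rbind(expand.grid(mother = pair1, father = pair2,
                                stringsAsFactors = FALSE),
                    expand.grid(mother = pair2, father = pair1,
                                stringsAsFactors = FALSE))
    expand
  } else {
    excluded <- vapply(f1, function(lbl) {
      setdiff(p, strsplit(lbl, "")[[1]])
    }, character(1))
    data.frame(mother = f1, father = unname(excluded))
  }
}

#' Enumerate the fully hybrid combinations of a design
#'
#' A combination label records the maternal-lineage history: the first letter
#' is the mother's mother's (... ) population and hence the mitochondrial
#' origin; each founder label appears exactly once. The matched-pairs design
#' over A-D yields the 8 combinations ABCD, ABDC, BACD, BADC, CDAB, CDBA,
#' DCAB, DCBA; the round-robin design over 3 populations yields 6.
#'
#' @param design A [crossing_design()].
#' @return Character vector of combination labels with attribute
#'   `mito_origin` (first letter of each).
#' @examples
#' enumerate_combinations(crossing_design("matched-pairs-4", LETTERS[1:4]))
#' @export
enumerate_combinations <- function(design) {
  if (!inherits(design, "crossing_design")) {
    stop("expected a 'crossing_design' object")
  }
  h <- .hybrid_crosses(design)
  combos <- .offspring_label(h$mother, h$father)
  attr(combos, "mito_origin") <- substr(combos, 1, 1)
  combos
}

#' Mitochondrial representation of founder populations
#'
#' Counts how many combinations carry each founder as their mitochondrial
#' origin (first label). Both supported designs are balanced: every founder
#' is the maternal-lineage root of exactly two combinations, ensuring equal
#' mitochondrial (as well as nuclear) representation.
#'
#' @param combos Character vector of combination labels (as from
#'   [enumerate_combinations()]).
#' @return A list with `counts` (named integer per founder) and `balanced`
#'   (logical).
#' @export
mito_representation <- function(combos) {
  if (!length(combos)) stop("combination list must be non-empty")
  founders <- sort(unique(unlist(strsplit(combos, ""))))
  counts <- table(factor(substr(combos, 1, 1), levels = founders))
  list(counts = stats::setNames(as.integer(counts), founders),
       balanced = length(unique(as.integer(counts))) == 1L)
}

#' Build the generation-by-generation crossing schedule
#'
#' Expands a design into ordered generation blocks of crosses and husbandry
#' steps, honouring the two haplodiploid constraints: every hybrid male used
#' in a cross must descend from a virgin hybrid female isolated one block
#' earlier (males come from unfertilized eggs), and every hybrid female used
#' must come from a cross performed one block earlier. Generations are kept
#' synchronized by repeating each set of matings one generation later, so
#' hybrid females and hybrid males of matching age meet. The terminal block
#' pools all combinations into the founding population.
#'
#' @param design A [crossing_design()].
#' @return A list of class `"cross_schedule"`; each element is a block with
#'   fields `block`, `crosses` (data frame `mother`, `father`, `count`),
#'   `isolate_virgin` (labels of females isolated for male production) and
#'   `note`. The final block instead carries `pool` (the combination
#'   labels).
#' @export
build_schedule <- function(design) {
  if (!inherits(design, "crossing_design")) {
    stop("expected a 'crossing_design' object")
  }
  n <- design$crosses_per_type
  par <- .parental_crosses(design)
  par$count <- n
  hyb <- .hybrid_crosses(design)
  hyb$count <- n
  f1 <- .offspring_label(par$mother, par$father)
  combos <- .offspring_label(hyb$mother, hyb$father)
  blk <- function(block, crosses = NULL, isolate = character(0),
                  note = "", pool = NULL) {
    list(block = block, crosses = crosses, isolate_virgin = isolate,
         note = note, pool = pool)
  }
  if (design$kind == "matched-pairs-4") {
    sched <- list(
      blk(1L, par, note = "reciprocal parental crosses within each pair"),
      blk(2L, par, isolate = f1,
          note = paste("isolate virgin F1 females for hybrid male production;",
                       "repeat parental crosses to synchronize")),
      blk(3L, rbind(hyb, par), isolate = f1,
          note = paste("hybrid x hybrid crosses across pairs;",
                       "repeat parental crosses and F1 isolation")),
      blk(4L, hyb, isolate = combos,
          note = paste("isolate virgin fully hybrid females for male",
                       "production; repeat hybrid crosses to synchronize")),
      blk(5L, pool = combos,
          note = "mix all fully hybrid combinations into the founding pool"))
  } else {
    sched <- list(
      blk(1L, par, note = "reciprocal parental crosses among all pairs"),
      blk(2L, rbind(hyb, par),
          note = paste("F1 hybrid females x males from the excluded",
                       "population; repeat parental crosses to synchronize")),
      blk(3L, hyb, isolate = combos,
          note = paste("repeat F1 x founder crosses; isolate virgin fully",
                       "hybrid females for male production")),
      blk(4L, pool = combos,
          note = "mix all fully hybrid combinations into the founding pool"))
  }
  structure(sched, class = "cross_schedule",
            populations = design$populations, kind = design$kind)
}

#' @export
print.cross_schedule <- function(x, ...) {
  cat("Crossing schedule (", attr(x, "kind"), ")\n", sep = "")
  for (b in x) {
    cat(sprintf("block %d: %s\n", b$block, b$note))
    if (!is.null(b$crosses)) {
      cat(sprintf("  %d cross types x %d crosses\n",
                  nrow(b$crosses), b$crosses$count[1]))
    }
    if (length(b$isolate_virgin)) {
      cat("  isolate virgin:", paste(b$isolate_virgin, collapse = " "), "\n")
    }
    if (!is.null(b$pool)) {
      cat("  pool:", paste(b$pool, collapse = " "), "\n")
    }
  }
  invisible(x)
}

#' Validate provenance constraints of a crossing schedule
#'
#' Checks, block by block, that the schedule is realizable in a
#' haplodiploid:
#' * every hybrid (multi-letter) male used at block g stems from a virgin
#'   female of that genotype isolated at block g-1;
#' * every hybrid female used or isolated at block g was produced by a cross
#'   listed at block g-1;
#' * founder-labelled individuals come from stock and are always available;
#' * the terminal pool's females were produced, and its males' mothers
#'   isolated, at the preceding block.
#'
#' @param schedule A [build_schedule()] result (possibly modified).
#' @return `TRUE` if valid, otherwise `FALSE` with attribute `"violations"`
#'   listing the failures.
#' @export
validate_schedule <- function(schedule) {
  pops <- attr(schedule, "populations")
  violations <- character(0)
  prev_produced <- character(0)   # female genotypes emerging this block
  prev_isolated <- character(0)   # virgin females isolated previous block
  for (b in schedule) {
    is_hybrid <- function(lbl) nchar(lbl) > 1L
    if (!is.null(b$crosses)) {
      for (i in seq_len(nrow(b$crosses))) {
        mo <- b$crosses$mother[i]
        fa <- b$crosses$father[i]
        if (is_hybrid(mo) && !(mo %in% prev_produced)) {
          violations <- c(violations, sprintf(
            "block %d: hybrid mother %s not produced at block %d",
            b$block, mo, b$block - 1L))
        }
        if (!is_hybrid(mo) && !(mo %in% pops)) {
          violations <- c(violations, sprintf(
            "block %d: unknown founder mother %s", b$block, mo))
        }
        if (is_hybrid(fa) && !(fa %in% prev_isolated)) {
          violations <- c(violations, sprintf(
            "block %d: hybrid father %s has no virgin %s female isolated at block %d",
            b$block, fa, fa, b$block - 1L))
        }
        if (!is_hybrid(fa) && !(fa %in% pops)) {
          violations <- c(violations, sprintf(
            "block %d: unknown founder father %s", b$block, fa))
        }
      }
    }
    bad_iso <- b$isolate_virgin[nchar(b$isolate_virgin) > 1L &
                                  !(b$isolate_virgin %in% prev_produced)]
    if (length(bad_iso)) {
      violations <- c(violations, sprintf(
        "block %d: cannot isolate %s: not produced at block %d",
        b$block, paste(bad_iso, collapse = ","), b$block - 1L))
    }
    if (!is.null(b$pool)) {
      missing_f <- setdiff(b$pool, prev_produced)
      if (length(missing_f)) {
        violations <- c(violations, sprintf(
          "block %d: pooled females %s not produced at block %d",
          b$block, paste(missing_f, collapse = ","), b$block - 1L))
      }
      missing_m <- setdiff(b$pool, prev_isolated)
      if (length(missing_m)) {
        violations <- c(violations, sprintf(
          "block %d: pooled males %s lack isolated virgin mothers at block %d",
          b$block, paste(missing_m, collapse = ","), b$block - 1L))
      }
    }
    prev_produced <- if (is.null(b$crosses)) character(0) else
      unique(.offspring_label(b$crosses$mother, b$crosses$father))
    prev_isolated <- b$isolate_virgin
  }
  if (length(violations)) {
    return(structure(FALSE, violations = violations))
  }
  TRUE
}

#' Founding census under the equal-representation rule
#'
#' Some crosses fail to produce viable offspring of both sexes, so the
#' combinations yield unequal numbers. To keep every combination (and hence
#' every founder population) equally represented, the `"minimum"` rule founds
#' the population with the minimum available count from each combination.
#' The `"as-available"` rule passes counts through unchanged — used e.g. for
#' a scarce male pool where all available males are taken even though counts
#' are uneven.
#'
#' @param available Named numeric vector of available counts per combination.
#' @param rule `"minimum"` or `"as-available"`.
#' @return A list of class `"founding_census"`: `per_combination` (named
#'   counts actually used), `total`, `rule`.
#' @examples
#' founding_census(setNames(c(80, 72, 90, 75, 88, 74, 101, 72),
#'                          c("ABCD","ABDC","BACD","BADC","CDAB","CDBA","DCAB","DCBA")))
#' @export
founding_census <- function(available, rule = c("minimum", "as-available")) {
  rule <- match.arg(rule)
  if (!length(available)) stop("combination set must be non-empty")
  if (any(available < 0)) stop("available counts must be non-negative")
  per <- if (rule == "minimum") {
    stats::setNames(rep(min(available), length(available)), names(available))
  } else {
    available
  }
  structure(list(per_combination = per, total = sum(per), rule = rule),
            class = "founding_census")
}

#' @export
print.founding_census <- function(x, ...) {
  cat(sprintf("Founding census (%s rule): total %d\n", x$rule, x$total))
  print(x$per_combination)
  invisible(x)
}
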