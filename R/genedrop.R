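#' Found a sib-mating line
#'
#' Creates the founding mated pair of an inbred line. Under the default
#' most-heterozygotic scheme the female is heterozygous `x/y` at every locus
#' and her mate carries a third allele `z` — the conservative assumption used
#' when founder genotypes are unknown (it underestimates inbreeding). A
#' user-specified scheme supplies explicit allele labels instead, e.g. to
#' start from a known (possibly already inbred) pair.
#'
#' @param scheme `"most-heterozygotic"`, or a list with elements `female`
#'   (character vector of 2 allele labels, recycled across loci, or a list of
#'   length `n_loci` of such pairs) and `male` (a single allele label, or a
#'   list of length-1 vectors per locus).
#' @param n_loci Number of independent loci (>= 1).
#' @return A list with elements `female` and `male`, each an individual as
#'   built by [new_individual()]. Founders have no recorded parents.
#' @examples
#' found_line()                     # [x/y] female x [z] male
#' found_line(list(female = c("x", "x"), male = "x"))  # fully inbred start
#' @export
found_line <- function(scheme = "most-heterozygotic", n_loci = 1L) {
  n_loci <- as.integer(n_loci)
  if (is.na(n_loci) || n_loci < 1L) stop("'n_loci' must be >= 1")
  if (identical(scheme, "most-heterozygotic")) {
    fem <- rep(list(c("x", "y")), n_loci)
    mal <- rep(list("z"), n_loci)
  } else if (is.list(scheme) && all(c("female", "male") %in% names(scheme))) {
    fem <- scheme$female
    mal <- scheme$male
    if (!is.list(fem)) fem <- rep(list(fem), n_loci)
    if (!is.list(mal)) mal <- rep(list(mal), n_loci)
    if (length(fem) != n_loci || length(mal) != n_loci) {
      stop("founder genotypes must cover all ", n_loci, " loci")
    }
  } else {
    stop("'scheme' must be \"most-heterozygotic\" or a list(female=, male=)")
  }
  list(female = new_individual("F0", "female", fem),
       male = new_individual("M0", "male", mal))
}

#' Construct a pedigree individual
#'
#' Individuals carry sex-dependent ploidy: females are diploid (two allele
#' labels per locus), males haploid (one label; arrhenotoky — males develop
#' from unfertilized eggs and have no father).
#'
#' @param id Unique identifier token.
#' @param sex `"female"` or `"male"`.
#' @param genotype List with one element per locus: a length-2 character
#'   vector for females, length-1 for males.
#' @param mother_id,father_id Parent identifiers; `NA` for founders, and
#'   `father_id` is always `NA` for males.
#' @return A list of class `"hb_individual"`.
#' @export
new_individual <- function(id, sex = c("female", "male"), genotype,
                           mother_id = NA_character_, father_id = NA_character_) {
  sex <- match.arg(sex)
  if (!is.list(genotype)) genotype <- list(genotype)
  want <- if (sex == "female") 2L else 1L
  ok <- vapply(genotype, function(g) is.character(g) && length(g) == want,
               logical(1))
  if (!all(ok)) {
    stop("a ", sex, " genotype needs exactly ", want, " allele label(s) per locus")
  }
  if (sex == "male" && !is.na(father_id)) {
    stop("males develop from unfertilized eggs and cannot have a father")
  }
  structure(list(id = id, sex = sex, genotype = genotype,
                 mother_id = mother_id, father_id = father_id),
            class = "hb_individual")
}

#' @export
print.hb_individual <- function(x, ...) {
  g <- vapply(x$genotype, paste, character(1), collapse = "/")
  cat(sprintf("<%s %s [%s] mother=%s father=%s>\n", x$sex, x$id,
              paste(g, collapse = "; "), x$mother_id, x$father_id))
  invisible(x)
}

#' Produce one offspring under haplodiploid transmission
#'
#' Daughters develop from fertilized eggs: at each locus they receive one
#' uniformly chosen maternal allele plus the paternal allele. Sons develop
#' from unfertilized eggs: one uniformly chosen maternal allele, no paternal
#' contribution. Loci segregate independently.
#'
#' @param mother A female [new_individual()].
#' @param father A male individual (required for daughters, forbidden for
#'   sons — all of a female's fertilized offspring share her single mate
#'   under first-male sperm precedence).
#' @param sex Offspring sex.
#' @param id Identifier for the offspring.
#' @return A new individual.
#' @examples
#' p <- found_line()
#' set.seed(1)
#' produce_offspring(p$female, p$male, "female")  # [x/z] or [y/z]
#' @export
produce_offspring <- function(mother, father = NULL,
                              sex = c("female", "male"), id = "offspring") {
  sex <- match.arg(sex)
  if (!inherits(mother, "hb_individual") || mother$sex != "female") {
    stop("'mother' must be a female individual")
  }
  if (sex == "female") {
    if (is.null(father)) stop("a daughter requires a father (fertilized egg)")
    if (!inherits(father, "hb_individual") || father$sex != "male") {
      stop("'father' must be a male individual")
    }
  } else if (!is.null(father)) {
    stop("a son stems from an unfertilized egg; no father may be specified")
  }
  n_loci <- length(mother$genotype)
  geno <- vector("list", n_loci)
  for (l in seq_len(n_loci)) {
    maternal <- mother$genotype[[l]][sample.int(2L, 1L)]
    geno[[l]] <- if (sex == "female") c(maternal, father$genotype[[l]]) else maternal
  }
  new_individual(id, sex, geno,
                 mother_id = mother$id,
                 father_id = if (sex == "female") father$id else NA_character_)
}

#' Advance a sib-mating line by one generation
#'
#' From the current mated pair, draws one daughter and one son (independent
#' allele draws from the same brood distribution) and returns the daughter
#' mated to her brother — the next generation's pair.
#'
#' @param pair List with elements `female` and `male` (a mated pair, as from
#'   [found_line()] or a previous call).
#' @param ids Character vector of length 2 giving the daughter's and son's
#'   identifiers.
#' @return A list with elements `female` and `male`.
#' @export
advance_line <- function(pair, ids = c("daughter", "son")) {
  daughter <- produce_offspring(pair$female, pair$male, "female", id = ids[[1]])
  son <- produce_offspring(pair$female, sex = "male", id = ids[[2]])
  list(female = daughter, male = son)
}

#' Classify a mated pair into a sib-mating cross type
#'
#' Vectorised over lines: given the female's two allele codes and the male's
#' single code at one locus, returns the cross type — `A` (heterozygous
#' female, no shared allele), `B` (heterozygous, shared), `C` (homozygous,
#' not shared), `D` (homozygous, shared; fully inbred).
#'
#' @param a1,a2 Female allele codes (vectors).
#' @param m Male allele codes (vector).
#' @return Factor with levels `A`, `B`, `C`, `D`.
#' @export
classify_cross_type <- function(a1, a2, m) {
  het <- a1 != a2
  share <- m == a1 | m == a2
  type <- ifelse(het, ifelse(share, "B", "A"), ifelse(share, "D", "C"))
  factor(type, levels = c("A", "B", "C", "D"))
}

#' Monte-Carlo gene dropping through sib-mating lines
#'
#' Simulates many independent sib-mating lines forward from a founding pair
#' and estimates, per generation, the inbreeding coefficient (proportion of
#' lines whose current female is homozygous at the focal locus), the
#' probability of a fully inbred line (proportion of current crosses of type
#' D) and the full cross-type frequency vector, each with binomial standard
#' errors. This is the stochastic counterpart of the analytic chain in
#' [inbreeding_trajectory()] and serves to verify it.
#'
#' Randomness is drawn as a line-major stream from the single seed: each
#' line's trajectory consumes a fixed block of deviates, so enlarging
#' `n_lines` under the same seed leaves existing lines' trajectories
#' unchanged.
#'
#' @param n_lines Number of replicate lines.
#' @param generations Sib-mating generations to simulate (default 15).
#' @param n_loci Independent loci per line (default 1; the focal locus is the
#'   first).
#' @param seed Integer seed; recorded in the output.
#' @param founder Founder scheme as in [found_line()].
#' @return A data frame of class `"genedrop_mc"` with one row per generation
#'   0..`generations`: columns `generation`, `freq_A`..`freq_D`, `f_hat`,
#'   `f_se`, `p_fully_inbred_hat`, `p_se`, `n`. Attributes: `seed`,
#'   `per_locus_f` (final-generation f-hat per locus),
#'   `genomewide_fully_inbred` (proportion of lines homozygous at all loci in
#'   the final generation — a genome-wide view under locus independence) and
#'   `final_type` (per-line cross type at the horizon, focal locus).
#' @examples
#' mc <- estimate_inbreeding_mc(2000, generations = 15, seed = 1)
#' mc[mc$generation == 15, c("f_hat", "f_se")]
#' @export
estimate_inbreeding_mc <- function(n_lines, generations = 15L, n_loci = 1L,
                                   seed = NULL,
                                   founder = "most-heterozygotic") {
  n_lines <- as.integer(n_lines)
  generations <- as.integer(generations)
  n_loci <- as.integer(n_loci)
  if (is.na(n_lines) || n_lines < 1L) stop("'n_lines' must be >= 1")
  if (is.na(generations) || generations < 1L) stop("'generations' must be >= 1")
  if (is.na(n_loci) || n_loci < 1L) stop("'n_loci' must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  # founder allele codes per locus
  pair <- found_line(founder, n_loci)
  codes <- lapply(seq_len(n_loci), function(l) {
    labs <- unique(c(pair$female$genotype[[l]], pair$male$genotype[[l]]))
    list(a1 = match(pair$female$genotype[[l]][1], labs),
         a2 = match(pair$female$genotype[[l]][2], labs),
         m = match(pair$male$genotype[[l]], labs))
  })

  # line-major uniform stream: per line, 2 draws per generation per locus
  per_line <- 2L * generations * n_loci
  U <- array(stats::runif(per_line * n_lines) < 0.5,
             dim = c(2L * generations, n_loci, n_lines))

  a1 <- matrix(0L, n_loci, n_lines)
  a2 <- matrix(0L, n_loci, n_lines)
  m <- matrix(0L, n_loci, n_lines)
  for (l in seq_len(n_loci)) {
    a1[l, ] <- codes[[l]]$a1
    a2[l, ] <- codes[[l]]$a2
    m[l, ] <- codes[[l]]$m
  }

  summarise <- function(gen) {
    type <- classify_cross_type(a1[1, ], a2[1, ], m[1, ])
    freq <- as.vector(table(type)) / n_lines
    f_hat <- mean(a1[1, ] == a2[1, ])
    p_hat <- freq[4]
    data.frame(generation = gen,
               freq_A = freq[1], freq_B = freq[2],
               freq_C = freq[3], freq_D = freq[4],
               f_hat = f_hat,
               f_se = sqrt(f_hat * (1 - f_hat) / n_lines),
               p_fully_inbred_hat = p_hat,
               p_se = sqrt(p_hat * (1 - p_hat) / n_lines),
               n = n_lines)
  }

  rows <- vector("list", generations + 1L)
  rows[[1]] <- summarise(0L)
  for (g in seq_len(generations)) {
    for (l in seq_len(n_loci)) {
      u_d <- U[2L * g - 1L, l, ]  # daughter's maternal allele
      u_s <- U[2L * g, l, ]       # son's allele
      dm <- ifelse(u_d, a1[l, ], a2[l, ])
      son <- ifelse(u_s, a1[l, ], a2[l, ])
      a1[l, ] <- dm
      a2[l, ] <- m[l, ]
      m[l, ] <- son
    }
    rows[[g + 1L]] <- summarise(g)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  attr(out, "per_locus_f") <- rowMeans(a1 == a2)
  attr(out, "genomewide_fully_inbred") <- mean(colSums(a1 == a2) == n_loci)
  attr(out, "final_type") <- classify_cross_type(a1[1, ], a2[1, ], m[1, ])
  class(out) <- c("genedrop_mc", "data.frame")
  out
}

#' Simulate a full pedigree of one sib-mating line
#'
#' Runs [advance_line()] for the requested number of generations, recording
#' every individual, and returns the pedigree as a data frame suitable for
#' [write_pedigree_tsv()]. Allele labels let identity by descent be read off
#' directly.
#'
#' @param generations Number of sib-mating generations.
#' @param scheme Founder scheme as in [found_line()].
#' @param n_loci Number of loci.
#' @param seed Optional integer seed.
#' @return Data frame with columns `id`, `sex`, `mother_id`, `father_id`,
#'   `generation` and one `locus_<i>` column per locus with slash-separated
#'   allele labels (`"x/z"` for females, `"x"` for males).
#' @export
simulate_pedigree <- function(generations, scheme = "most-heterozygotic",
                              n_loci = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pair <- found_line(scheme, n_loci)
  record <- function(ind, gen) {
    g <- vapply(ind$genotype, paste, character(1), collapse = "/")
    cbind(data.frame(id = ind$id, sex = ind$sex,
                     mother_id = ind$mother_id, father_id = ind$father_id,
                     generation = gen),
          stats::setNames(as.data.frame(as.list(g)),
                          paste0("locus_", seq_along(g))))
  }
  rows <- list(record(pair$female, 0L), record(pair$male, 0L))
  for (g in seq_len(generations)) {
    pair <- advance_line(pair, ids = c(sprintf("F%d", g), sprintf("M%d", g)))
    rows <- c(rows, list(record(pair$female, g), record(pair$male, g)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
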