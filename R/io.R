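#' Write a tabular artifact as TSV
#'
#' All tabular outputs share one dialect: tab-separated, header row, `"."`
#' for missing values, no quoting, no row names.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_artifact <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, na = ".",
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV artifact
#'
#' @param path Input path.
#' @return Data frame.
#' @export
read_tsv_artifact <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = ".",
                    stringsAsFactors = FALSE)
}

#' Write an inbreeding trajectory
#'
#' TSV columns: `generation`, `freq_A`..`freq_D`, `f`, `p_fully_inbred`; the
#' JSON variant additionally records the arithmetic mode and initial state.
#'
#' @param trajectory An [inbreeding_trajectory()].
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write_tsv_artifact(as.data.frame(trajectory), path)
  } else {
    jsonlite::write_json(
      list(mode = attr(trajectory, "mode"),
           initial = as.list(attr(trajectory, "initial")),
           trajectory = as.data.frame(trajectory)),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Write a pedigree as TSV
#'
#' Columns `id`, `sex`, `mother_id`, `father_id`, `generation` and one
#' `locus_<i>` column per locus with slash-separated allele labels (`"x/z"`
#' for diploid females, `"x"` for haploid males). This is a package-specific
#' dialect: standard 6-column pedigree formats assume two parents per
#' individual and cannot encode fatherless haploid males unambiguously.
#'
#' @param pedigree Data frame from [simulate_pedigree()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree_tsv <- function(pedigree, path) {
  write_tsv_artifact(pedigree, path)
}

#' Write a line-panel trajectory
#'
#' TSV form: columns `generation`, `surviving_lines`. JSON form: survivors
#' plus the full configuration and seed.
#'
#' @param panel A [simulate_line_panel()] result.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_panel_trajectory <- function(panel, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- data.frame(generation = seq_along(panel$survivors) - 1L,
                   surviving_lines = panel$survivors)
  if (format == "tsv") {
    write_tsv_artifact(df, path)
  } else {
    cfg <- panel[c("n_lines", "generations", "replicates_per_line",
                   "failure_prob", "seed")]
    jsonlite::write_json(list(config = cfg, trajectory = df),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Write a crossing schedule
#'
#' TSV columns: `block`, `cross_type`, `mother_label`, `father_label`,
#' `count`, `husbandry_note`; virgin-isolation and pooling steps appear as
#' rows with `"."` in the cross columns. A JSON form mirrors the block
#' structure for programmatic use.
#'
#' @param schedule A [build_schedule()] result.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    blocks <- lapply(schedule, function(b) {
      list(block = b$block, crosses = b$crosses,
           isolate_virgin = as.list(b$isolate_virgin),
           pool = as.list(b$pool), note = b$note)
    })
    jsonlite::write_json(list(kind = attr(schedule, "kind"),
                              populations = as.list(attr(schedule, "populations")),
                              blocks = blocks),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(path))
  }
  rows <- list()
  for (b in schedule) {
    if (!is.null(b$crosses)) {
      rows[[length(rows) + 1L]] <- data.frame(
        block = b$block, cross_type = "cross",
        mother_label = b$crosses$mother, father_label = b$crosses$father,
        count = b$crosses$count, husbandry_note = b$note)
    }
    if (length(b$isolate_virgin)) {
      rows[[length(rows) + 1L]] <- data.frame(
        block = b$block, cross_type = "isolate_virgin",
        mother_label = b$isolate_virgin, father_label = NA_character_,
        count = NA_integer_, husbandry_note = "virgin female for male production")
    }
    if (!is.null(b$pool)) {
      rows[[length(rows) + 1L]] <- data.frame(
        block = b$block, cross_type = "pool",
        mother_label = b$pool, father_label = NA_character_,
        count = NA_integer_, husbandry_note = b$note)
    }
  }
  write_tsv_artifact(do.call(rbind, rows), path)
}

#' Read or write a regime transfer log
#'
#' The on-disk form is TSV with columns `generation`, `n_current`,
#' `n_backup`, `n_base`, `n_total`, `effective_generations`. The reader also
#' accepts availability histories (columns `available_current`,
#' `available_backup`) as input to [track_regime()].
#'
#' @param x A [track_regime()] result.
#' @param path File path.
#' @return The data frame (reader) or `path` invisibly (writer).
#' @export
write_regime_log <- function(x, path) {
  write_tsv_artifact(as.data.frame(x), path)
}

#' @rdname write_regime_log
#' @export
read_regime_log <- function(path) {
  read_tsv_artifact(path)
}
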