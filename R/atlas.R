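#' Construct a region atlas
#'
#' The parcellation used throughout the pipeline: 90 ordered regions, of which
#' exactly 78 are cortical and 12 subcortical. In the packaged default ordering
#' the cortical regions occupy positions 1--78 and the subcortical regions
#' positions 79--90. Indices reported to the user are 1-based.
#'
#' @param labels Character vector of 90 unique region names.
#' @param group Character vector of per-region flags, `"cortical"` or
#'   `"subcortical"`.
#' @return An object of class `region_atlas` with elements `labels` and
#'   `group`.
#' @seealso [load_atlas()], [region_groups()]
#' @export
region_atlas <- function(labels, group) {
  labels <- as.character(labels)
  group <- as.character(group)
  if (length(labels) != length(group))
    stop("labels and group must have equal length", call. = FALSE)
  if (length(labels) != 90L)
    stop(sprintf("atlas must define exactly 90 regions, got %d", length(labels)),
         call. = FALSE)
  bad <- which(!group %in% c("cortical", "subcortical"))
  if (length(bad))
    stop(sprintf("unknown group flag '%s' for region %d ('%s')",
                 group[bad[1L]], bad[1L], labels[bad[1L]]), call. = FALSE)
  dup <- unique(labels[duplicated(labels)])
  if (length(dup))
    stop("duplicate region labels: ", paste(dup, collapse = ", "), call. = FALSE)
  n_c <- sum(group == "cortical")
  n_s <- sum(group == "subcortical")
  if (n_c != 78L || n_s != 12L)
    stop(sprintf("expected 78 cortical and 12 subcortical regions, got %d and %d",
                 n_c, n_s), call. = FALSE)
  structure(list(labels = labels, group = group), class = "region_atlas")
}

#' @export
print.region_atlas <- function(x, ...) {
  cat(sprintf("<region_atlas> %d regions (%d cortical, %d subcortical)\n",
              length(x$labels), sum(x$group == "cortical"),
              sum(x$group == "subcortical")))
  invisible(x)
}

#' Load a region atlas
#'
#' Reads a plain-text atlas file with one region per line,
#' `<label><TAB><cortical|subcortical>`, 90 lines. With no argument the
#' packaged default is used: standard AAL-style labels with the 78 cortical
#' regions first (positions 1--78) and the 12 subcortical regions
#' (hippocampus, amygdala, caudate, putamen, pallidum, thalamus; left/right)
#' last (positions 79--90). Ordering is preserved from the source file.
#'
#' @param source Optional path to an atlas file; `NULL` for the packaged
#'   default.
#' @return A [region_atlas()].
#' @examples
#' atlas <- load_atlas()
#' table(atlas$group)
#' @export
load_atlas <- function(source = NULL) {
  if (is.null(source))
    source <- system.file("extdata", "aal90.tsv", package = "megslow",
                          mustWork = TRUE)
  lines <- readLines(source)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != 90L)
    stop(sprintf("atlas file must contain exactly 90 regions, got %d lines: %s",
                 length(lines), source), call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(parts, length, integer(1))
  if (any(nf != 2L)) {
    i <- which(nf != 2L)[1L]
    stop(sprintf("malformed atlas line %d: '%s' (expected <label>TAB<flag>)",
                 i, lines[i]), call. = FALSE)
  }
  region_atlas(vapply(parts, `[[`, character(1), 1L),
               trimws(vapply(parts, `[[`, character(1), 2L)))
}

#' Write a region atlas
#'
#' Inverse of [load_atlas()]: writes `<label><TAB><flag>` lines so that
#' `load_atlas(write_atlas(a, f))` round-trips.
#'
#' @param atlas A [region_atlas()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "region_atlas"))
  writeLines(paste(atlas$labels, atlas$group, sep = "\t"), path)
  invisible(path)
}

#' Cortical and subcortical index sets
#'
#' Splits the atlas into the two disjoint 1-based index sets whose union is
#' all 90 regions; every downstream cortical/subcortical average is an
#' unweighted mean over these sets.
#'
#' @param atlas A [region_atlas()].
#' @return A list with integer vectors `cortical` (length 78) and
#'   `subcortical` (length 12).
#' @examples
#' g <- region_groups(load_atlas())
#' lengths(g)
#' @export
region_groups <- function(atlas) {
  stopifnot(inherits(atlas, "region_atlas"))
  list(cortical = which(atlas$group == "cortical"),
       subcortical = which(atlas$group == "subcortical"))
}
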