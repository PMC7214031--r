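XRAY_METHOD_LABELS <- c("X-RAY DIFFRACTION", "X-RAY")

#' Keep only X-ray diffraction entries
#'
#' Entries solved by NMR, powder diffraction, cryo-electron microscopy,
#' neutron diffraction — or carrying an unrecognised method label — are
#' excluded (the last with a warning, conservatively), preserving order.
#'
#' @param entries A tibble with columns `pdb_id`, `method`, `resolution`,
#'   `protein_name` (an entry list, see [read_entry_list()]).
#' @return The filtered entry tibble.
#' @export
filter_by_method <- function(entries) {
  if (nrow(entries) == 0) return(entries)
  m <- toupper(trimws(dplyr::coalesce(entries$method, "")))
  known_other <- c("SOLUTION NMR", "SOLID-STATE NMR", "POWDER DIFFRACTION",
                   "ELECTRON MICROSCOPY", "ELECTRON CRYSTALLOGRAPHY",
                   "NEUTRON DIFFRACTION", "SOLUTION SCATTERING", "FIBER DIFFRACTION")
  is_xray <- m %in% XRAY_METHOD_LABELS
  unknown <- !is_xray & !m %in% known_other
  if (any(unknown)) {
    warning(sprintf("excluding %d entr%s with unrecognised method label (e.g. '%s')",
                    sum(unknown), if (sum(unknown) == 1) "y" else "ies",
                    entries$method[unknown][1]), call. = FALSE)
  }
  entries[is_xray, , drop = FALSE]
}

#' Keep only high-resolution entries
#'
#' Entries whose resolution is numerically at or below the cutoff (better or
#' equal quality) are kept; entries with no resolution recorded are excluded.
#'
#' @inheritParams filter_by_method
#' @param cutoff Resolution cutoff in angstrom (default 2.0).
#' @return The filtered entry tibble.
#' @export
filter_by_resolution <- function(entries, cutoff = 2.0) {
  stopifnot(cutoff > 0)
  if (nrow(entries) == 0) return(entries)
  entries[!is.na(entries$resolution) & entries$resolution <= cutoff, , drop = FALSE]
}

#' One entry per protein name, best resolution wins
#'
#' For entries sharing a normalized protein name, retains the one with the
#' numerically smallest (best) resolution; exact ties go to the
#' lexicographically smallest `pdb_id`.
#'
#' @inheritParams filter_by_method
#' @return The deduplicated entry tibble, input order of survivors kept.
#' @export
deduplicate_by_name <- function(entries) {
  if (nrow(entries) == 0) return(entries)
  stopifnot(!anyNA(entries$resolution))
  entries$.ord <- seq_len(nrow(entries))
  out <- entries |>
    dplyr::group_by(.data$protein_name) |>
    dplyr::arrange(.data$resolution, .data$pdb_id, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.ord)
  out$.ord <- NULL
  out
}

#' Apply the full entry curation
#'
#' Method filter, then resolution filter, then same-name deduplication —
#' the census's strict selection of non-redundant high-quality X-ray entries.
#'
#' @inheritParams filter_by_method
#' @param params A [census_params()] supplying the resolution cutoff.
#' @return The curated entry tibble.
#' @export
curate_entries <- function(entries, params = census_params()) {
  entries |>
    filter_by_method() |>
    filter_by_resolution(params$resolution_cutoff) |>
    deduplicate_by_name()
}

#' Read / write an entry list
#'
#' The offline entry-list contract: a TSV with columns `pdb_id`, `method`,
#' `resolution`, `protein_name`. Protein names are normalized (case-folded,
#' whitespace-collapsed, trailing punctuation stripped) on read.
#'
#' @param path Path to the TSV.
#' @return A tibble of entries.
#' @export
read_entry_list <- function(path) {
  e <- readr::read_tsv(
    path,
    col_types = readr::cols(
      pdb_id = readr::col_character(),
      method = readr::col_character(),
      resolution = readr::col_double(),
      protein_name = readr::col_character()
    ),
    progress = FALSE
  )
  e$protein_name <- normalize_protein_name(dplyr::coalesce(e$protein_name, ""))
  e
}

#' @rdname read_entry_list
#' @param entries The entry tibble to write.
#' @export
write_entry_list <- function(entries, path) {
  readr::write_tsv(entries[, c("pdb_id", "method", "resolution", "protein_name")],
                   path, progress = FALSE)
  invisible(entries)
}

#' Entry metadata from parsed structures
#'
#' Convenience builder of the entry-list tibble from parsed structures, e.g.
#' when curating a local directory of PDB files without a prebuilt list.
#'
#' @param structures A list of `halide_structure` objects.
#' @return An entry tibble.
#' @export
entries_from_structures <- function(structures) {
  dplyr::bind_rows(purrr::map(structures, function(s) {
    tibble::tibble(
      pdb_id = s$pdb_id, method = s$method,
      resolution = s$resolution, protein_name = s$protein_name
    )
  }))
}
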