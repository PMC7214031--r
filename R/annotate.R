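# (res_seq, i_code) falls inside an inclusive range; blank insertion codes
# order before lettered ones, matching PDB residue ordering (52 < 52A < 53)
icode_rank <- function(i_code) {
  ifelse(i_code == "", 0L, match(toupper(i_code), LETTERS))
}

residue_in_range <- function(res_seq, i_code, start_seq, start_icode, end_seq, end_icode) {
  r <- icode_rank(i_code)
  after_start <- res_seq > start_seq |
    (res_seq == start_seq & r >= icode_rank(start_icode))
  before_end <- res_seq < end_seq |
    (res_seq == end_seq & r <= icode_rank(end_icode))
  after_start & before_end
}

ss_label_for_residue <- function(chain_id, res_seq, i_code, structure) {
  in_ranges <- function(rng) {
    if (nrow(rng) == 0) return(FALSE)
    any(rng$chain_id == chain_id &
          residue_in_range(res_seq, i_code, rng$start_seq, rng$start_icode,
                           rng$end_seq, rng$end_icode))
  }
  in_helix <- in_ranges(structure$helix_ranges)
  in_sheet <- in_ranges(structure$sheet_ranges)
  if (in_helix && in_sheet) {
    warning(sprintf("residue %s:%d%s lies in both helix and sheet ranges; helix wins",
                    chain_id, res_seq, i_code), call. = FALSE)
  }
  if (in_helix) "helix" else if (in_sheet) "strand" else "none"
}

#' Secondary-structure labels of a site's coordinating residues
#'
#' Labels each unique coordinating residue `helix`, `strand` or `none` from
#' the structure's HELIX/SHEET header ranges. A residue claimed by both a
#' helix and a sheet range is labelled `helix` (with a warning). Backbone-only
#' contacts are labelled like any other contact.
#'
#' @param site A one-row `halide_sites` tibble.
#' @param structure The `halide_structure` carrying helix/sheet ranges.
#' @return Character vector of labels aligned with the site's `residues`.
#' @export
assign_ss_labels <- function(site, structure) {
  r <- site$residues[[1]]
  if (nrow(r) == 0) return(character())
  purrr::map_chr(seq_len(nrow(r)), function(i) {
    ss_label_for_residue(r$chain_id[i], r$res_seq[i], r$i_code[i], structure)
  })
}

#' Residue composition of a site
#'
#' Counts residue names over the unique coordinating residues: a residue
#' contributes once no matter how many of its atoms coordinate the halide;
#' waters are excluded.
#'
#' @param site A one-row `halide_sites` tibble.
#' @return A named integer vector of residue-name counts (sorted by name).
#' @examples
#' # two atoms of one Arg plus a Gly backbone N -> c(ARG = 1, GLY = 1)
#' @export
site_composition <- function(site) {
  r <- site$residues[[1]]
  if (nrow(r) == 0) return(integer())
  tab <- table(r$res_name)
  stats::setNames(as.integer(tab), names(tab))
}

#' Fraction of main-chain coordinating atoms
#'
#' The fraction of a site's coordinating polymer atoms that are backbone
#' atoms (`N`, `O`, `OXT`); side-chain atoms are the complement. Carbon
#' backbone atoms never appear since carbons are excluded from coordination.
#'
#' @param site A one-row `halide_sites` tibble.
#' @return A fraction in \[0, 1\], or `NA` for an empty coordinating set.
#' @export
mainchain_fraction <- function(site) {
  co <- site$coord[[1]]
  co <- co[co$record_class == "polymer", , drop = FALSE]
  if (nrow(co) == 0) return(NA_real_)
  mean(co$atom_name %in% BACKBONE_ATOM_NAMES)
}

#' Annotate sites with secondary structure and composition
#'
#' Adds `ss_labels` (per-residue helix/strand/none), `composition` (residue
#' multiset key, e.g. `"ARG+SER"`) and `mainchain_frac` columns.
#'
#' @param sites A `halide_sites` tibble.
#' @param structure The `halide_structure` the sites came from.
#' @return The annotated sites tibble.
#' @export
annotate_sites <- function(sites, structure) {
  if (nrow(sites) == 0) {
    sites$ss_labels <- list()
    sites$composition <- character()
    sites$mainchain_frac <- double()
    return(sites)
  }
  sites$ss_labels <- purrr::map(seq_len(nrow(sites)), function(i) {
    assign_ss_labels(sites[i, ], structure)
  })
  sites$composition <- purrr::map_chr(sites$residues, function(r) {
    paste(sort(r$res_name), collapse = "+")
  })
  sites$mainchain_frac <- purrr::map_dbl(seq_len(nrow(sites)), function(i) {
    mainchain_fraction(sites[i, ])
  })
  sites
}
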