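NUCLEOTIDE_CODES <- c("A", "C", "G", "U", "DA", "DC", "DG", "DT")

KNOWN_ELEMENTS <- c(
  "H", "D", "C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "Se",
  "Fe", "Zn", "Mg", "Mn", "Na", "K", "Ca", "Cu", "Ni", "Co", "Cd", "Hg", "B"
)

# normalize an element symbol to title case ("CL" -> "Cl")
normalize_element <- function(x) {
  x <- toupper(trimws(x))
  paste0(substr(x, 1, 1), tolower(substr(x, 2, nchar(x))))
}

# Element from the atom-name field (PDB columns 13-16) when columns 77-78
# are blank. A symbol occupying column 13 is read as a two-letter element
# when valid; otherwise the first alphabetic character (digits stripped,
# deuterium kept distinct) decides.
infer_element <- function(name_raw, line_no) {
  two <- normalize_element(substr(name_raw, 1, 2))
  if (!grepl("^\\s", name_raw) && nchar(two) == 2 && two %in% KNOWN_ELEMENTS) {
    return(two)
  }
  letters_only <- gsub("[^A-Za-z]", "", name_raw)
  if (nchar(letters_only) == 0) {
    stop(sprintf("cannot infer element from atom name '%s' at line %d",
                 name_raw, line_no), call. = FALSE)
  }
  one <- normalize_element(substr(letters_only, 1, 1))
  if (!one %in% KNOWN_ELEMENTS) {
    stop(sprintf("cannot infer element from atom name '%s' at line %d",
                 name_raw, line_no), call. = FALSE)
  }
  one
}

parse_num_field <- function(x, what, line_no) {
  v <- suppressWarnings(as.numeric(x))
  bad <- is.na(v) & trimws(x) != ""
  if (any(bad)) {
    stop(sprintf("malformed %s field at line %d: '%s'",
                 what, line_no[bad][1], x[bad][1]), call. = FALSE)
  }
  v
}

#' Parse a PDB-format structure
#'
#' Reads fixed-column PDB text into the census data model: an atom table with
#' every atom classified as `polymer`, `water`, `halide` or `ligand`, plus
#' entry metadata (experimental method, resolution, normalized molecule name)
#' and helix/sheet ranges from the header. Only the first MODEL is retained.
#'
#' Classification rules: `ATOM` records are polymer unless the residue code is
#' a nucleotide (`A`, `C`, `G`, `U`, `DA`, `DC`, `DG`, `DT`), which are classed
#' `ligand` so that sites contacting DNA/RNA are rejected downstream. `HETATM`
#' records are `halide` when the residue code matches a configured halide code,
#' `water` for `HOH`/`DOD`/`WAT`, and `ligand` otherwise.
#'
#' @param text Character scalar (whole file) or vector of lines of PDB text.
#' @param params A [census_params()] object.
#' @param pdb_id Optional 4-character identifier; when missing it is taken
#'   from the HEADER record, else `"XXXX"`.
#' @return An object of class `halide_structure`: a list with `pdb_id`,
#'   `method`, `resolution` (angstrom, `NA` if absent), `protein_name`,
#'   `atoms` (a tibble, one row per atom), and `helix_ranges`/`sheet_ranges`
#'   tibbles with `chain_id`, `start_seq`, `start_icode`, `end_seq`,
#'   `end_icode`.
#' @examples
#' txt <- c(
#'   "ATOM      1  N   GLY A   1       0.000   0.000   3.200  1.00 10.00           N",
#'   "HETATM    2 CL    CL A 101       0.000   0.000   0.000  1.00 10.00          CL"
#' )
#' s <- parse_structure(txt)
#' s$atoms$record_class
#' @export
parse_structure <- function(text, params = census_params(), pdb_id = NULL) {
  lines <- if (length(text) == 1L && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    text
  }
  rec <- substr(lines, 1, 6)
  line_no <- seq_along(lines)

  # first model only
  model_starts <- which(trimws(rec) == "MODEL")
  if (length(model_starts) > 0) {
    endmdl <- which(trimws(rec) == "ENDMDL")
    stop_at <- if (length(endmdl) > 0) endmdl[1] else length(lines) + 1L
    in_model <- line_no > model_starts[1] & line_no < stop_at
    atom_sel <- (rec == "ATOM  " | rec == "HETATM") & in_model
  } else {
    atom_sel <- rec == "ATOM  " | rec == "HETATM"
  }

  if (!any(atom_sel)) {
    stop("no ATOM or HETATM records found: empty structure", call. = FALSE)
  }

  al <- lines[atom_sel]
  ano <- line_no[atom_sel]
  # pad short lines so fixed-column extraction is safe
  al <- formatC(al, width = 80, flag = "-")

  name_raw <- substr(al, 13, 16)
  elem_field <- trimws(substr(al, 77, 78))
  element <- character(length(al))
  for (i in seq_along(al)) {
    if (nchar(elem_field[i]) > 0 && elem_field[i] != "D") {
      e <- normalize_element(elem_field[i])
      if (!e %in% KNOWN_ELEMENTS) e <- infer_element(name_raw[i], ano[i])
      element[i] <- e
    } else if (elem_field[i] == "D") {
      element[i] <- "D"
    } else {
      element[i] <- infer_element(name_raw[i], ano[i])
    }
  }

  occ_raw <- substr(al, 55, 60)
  occ <- parse_num_field(occ_raw, "occupancy", ano)
  occ[is.na(occ)] <- 1.0
  bf <- parse_num_field(substr(al, 61, 66), "b-factor", ano)
  bf[is.na(bf)] <- 0.0

  atoms <- tibble::tibble(
    element = element,
    atom_name = trimws(name_raw),
    alt_loc = trimws(substr(al, 17, 17)),
    res_name = trimws(substr(al, 18, 20)),
    chain_id = substr(al, 22, 22),
    res_seq = as.integer(parse_num_field(substr(al, 23, 26), "residue number", ano)),
    i_code = trimws(substr(al, 27, 27)),
    x = parse_num_field(substr(al, 31, 38), "x coordinate", ano),
    y = parse_num_field(substr(al, 39, 46), "y coordinate", ano),
    z = parse_num_field(substr(al, 47, 54), "z coordinate", ano),
    occupancy = occ,
    b_factor = bf,
    is_hetatm = substr(al, 1, 6) == "HETATM"
  )
  if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z)) {
    bad <- ano[which(is.na(atoms$x) | is.na(atoms$y) | is.na(atoms$z))[1]]
    stop(sprintf("malformed coordinate fields at line %d", bad), call. = FALSE)
  }

  halide_codes <- unlist(params$halide_residue_codes, use.names = FALSE)
  atoms$record_class <- dplyr::case_when(
    atoms$is_hetatm & atoms$res_name %in% halide_codes ~ "halide",
    atoms$is_hetatm & atoms$res_name %in% params$water_residue_codes ~ "water",
    atoms$is_hetatm ~ "ligand",
    atoms$res_name %in% NUCLEOTIDE_CODES ~ "ligand",
    TRUE ~ "polymer"
  )
  atoms$is_hetatm <- NULL

  # header metadata
  resolution <- NA_real_
  rem2 <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(rem2) > 0) {
    m <- regmatches(rem2[1], regexpr("[0-9]+\\.?[0-9]*(?=\\s*ANGSTROM)", rem2[1], perl = TRUE))
    if (length(m) == 1) resolution <- as.numeric(m)
  }
  method <- NA_character_
  expdta <- grep("^EXPDTA", lines, value = TRUE)
  if (length(expdta) > 0) method <- trimws(substr(expdta[1], 11, nchar(expdta[1])))

  protein_name <- NA_character_
  mol <- grep("^COMPND.*MOLECULE:", lines, value = TRUE)
  if (length(mol) > 0) {
    nm <- sub(".*MOLECULE:", "", mol[1])
    nm <- sub(";.*$", "", nm)
    protein_name <- normalize_protein_name(nm)
  }

  if (is.null(pdb_id)) {
    hdr <- grep("^HEADER", lines, value = TRUE)
    pdb_id <- if (length(hdr) > 0 && nchar(trimws(substr(hdr[1], 63, 66))) == 4) {
      trimws(substr(hdr[1], 63, 66))
    } else {
      "XXXX"
    }
  }

  helix <- lines[rec == "HELIX "]
  helix_ranges <- if (length(helix) > 0) {
    helix <- formatC(helix, width = 80, flag = "-")
    tibble::tibble(
      chain_id = substr(helix, 20, 20),
      start_seq = as.integer(trimws(substr(helix, 22, 25))),
      start_icode = trimws(substr(helix, 26, 26)),
      end_seq = as.integer(trimws(substr(helix, 34, 37))),
      end_icode = trimws(substr(helix, 38, 38))
    )
  } else {
    empty_ss_ranges()
  }
  sheet <- lines[rec == "SHEET "]
  sheet_ranges <- if (length(sheet) > 0) {
    sheet <- formatC(sheet, width = 80, flag = "-")
    tibble::tibble(
      chain_id = substr(sheet, 22, 22),
      start_seq = as.integer(trimws(substr(sheet, 23, 26))),
      start_icode = trimws(substr(sheet, 27, 27)),
      end_seq = as.integer(trimws(substr(sheet, 34, 37))),
      end_icode = trimws(substr(sheet, 38, 38))
    )
  } else {
    empty_ss_ranges()
  }

  structure(
    list(
      pdb_id = pdb_id,
      method = method,
      resolution = resolution,
      protein_name = protein_name,
      atoms = atoms,
      helix_ranges = helix_ranges,
      sheet_ranges = sheet_ranges
    ),
    class = "halide_structure"
  )
}

empty_ss_ranges <- function() {
  tibble::tibble(
    chain_id = character(), start_seq = integer(), start_icode = character(),
    end_seq = integer(), end_icode = character()
  )
}

# case-fold, collapse whitespace, strip trailing punctuation
normalize_protein_name <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("\\s+", " ", x)
  sub("[[:punct:]]+$", "", x)
}

#' Read a PDB file from disk
#'
#' @param path Path to a PDB-format file.
#' @inheritParams parse_structure
#' @return A `halide_structure`; `pdb_id` falls back to the file name (minus
#'   extension) when the HEADER record carries no identifier.
#' @export
read_pdb <- function(path, params = census_params()) {
  lines <- readLines(path, warn = FALSE)
  id <- toupper(sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE))
  s <- parse_structure(lines, params)
  if (identical(s$pdb_id, "XXXX") && nchar(id) == 4) s$pdb_id <- id
  s
}

#' @export
print.halide_structure <- function(x, ...) {
  tab <- table(x$atoms$record_class)
  cat(sprintf("<halide_structure %s> %s, %.2f A\n", x$pdb_id,
              ifelse(is.na(x$method), "method unknown", x$method),
              x$resolution))
  cat("  atoms:", paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " "), "\n")
  invisible(x)
}

#' Resolve alternate atom locations
#'
#' For every (chain, residue, insertion code, atom name) group modelled in
#' multiple alternate locations, keeps the single copy with the highest
#' occupancy; exact ties go to the alphabetically smallest altloc indicator.
#' Atoms with zero occupancy are dropped.
#'
#' @param structure A `halide_structure`.
#' @return The structure with a deduplicated atom table, original order kept.
#' @export
select_altlocs <- function(structure) {
  a <- structure$atoms
  a$.ord <- seq_len(nrow(a))
  a <- a[a$occupancy > 0, , drop = FALSE]
  a <- a |>
    dplyr::group_by(.data$chain_id, .data$res_seq, .data$i_code, .data$atom_name) |>
    dplyr::arrange(dplyr::desc(.data$occupancy), .data$alt_loc, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.ord)
  a$.ord <- NULL
  structure$atoms <- a
  structure
}

SITE_TABLE_COLS <- c(
  "pdb_id", "halide_species", "chain", "res_seq", "n_coord",
  "min_dist_A", "median_dist_A", "distances_A", "angles_deg",
  "n_waters", "fasa", "ss_labels", "residues"
)

#' Flatten sites to the serialized census table
#'
#' Converts a site tibble (one row per halide, list-columns for the
#' coordinating atoms) into the flat per-halide table that [write_site_table()]
#' serializes: distances and angles are semicolon-joined with three decimals,
#' coordinating residues are rendered `res_name:chain:res_seq`, and rows are
#' ordered by (`pdb_id`, `chain`, `res_seq`).
#'
#' @param sites A site tibble from [extract_sites()] (annotated or not).
#' @return A tibble with columns `pdb_id`, `halide_species`, `chain`,
#'   `res_seq`, `n_coord`, `min_dist_A`, `median_dist_A`, `distances_A`,
#'   `angles_deg`, `n_waters`, `fasa`, `ss_labels`, `residues`.
#' @export
as_site_table <- function(sites) {
  if (nrow(sites) == 0) {
    return(tibble::tibble(
      pdb_id = character(), halide_species = character(), chain = character(),
      res_seq = integer(), n_coord = integer(),
      min_dist_A = double(), median_dist_A = double(),
      distances_A = character(), angles_deg = character(),
      n_waters = integer(), fasa = double(),
      ss_labels = character(), residues = character()
    ))
  }
  fmt3 <- function(v) round(v, 3)
  join3 <- function(v) paste(sprintf("%.3f", v), collapse = ";")
  tab <- tibble::tibble(
    pdb_id = sites$pdb_id,
    halide_species = sites$species,
    chain = sites$chain,
    res_seq = sites$res_seq,
    n_coord = sites$cn,
    min_dist_A = fmt3(purrr::map_dbl(sites$coord, \(d) {
      if (nrow(d) == 0) NA_real_ else min(d$distance)
    })),
    median_dist_A = fmt3(purrr::map_dbl(sites$coord, \(d) {
      if (nrow(d) == 0) NA_real_ else stats::median(d$distance)
    })),
    distances_A = purrr::map_chr(sites$coord, \(d) join3(d$distance)),
    angles_deg = purrr::map_chr(sites$coord, \(d) join3(d$angle)),
    n_waters = sites$n_waters,
    fasa = if ("fasa" %in% names(sites)) fmt3(sites$fasa) else NA_real_,
    ss_labels = if ("ss_labels" %in% names(sites)) {
      purrr::map_chr(sites$ss_labels, paste, collapse = ";")
    } else {
      NA_character_
    },
    residues = purrr::map_chr(sites$residues, \(r) {
      paste(sprintf("%s:%s:%d%s", r$res_name, r$chain_id, r$res_seq, r$i_code),
            collapse = ";")
    })
  )
  dplyr::arrange(tab, .data$pdb_id, .data$chain, .data$res_seq)
}

#' Write the per-halide census table
#'
#' Serializes sites to a UTF-8, LF-terminated TSV with a fixed column order
#' and three-decimal floats; row order is deterministic
#' (`pdb_id`, `chain`, `res_seq`) so identical inputs give identical bytes.
#'
#' @inheritParams as_site_table
#' @param path Output file path.
#' @return The flattened table, invisibly.
#' @seealso [read_site_table()] for the inverse.
#' @export
write_site_table <- function(sites, path) {
  tab <- if (is.data.frame(sites) && "coord" %in% names(sites) || nrow(sites) == 0) {
    as_site_table(sites)
  } else {
    sites[, SITE_TABLE_COLS]
  }
  out <- tab
  for (col in c("min_dist_A", "median_dist_A", "fasa")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "", sprintf("%.3f", out[[col]]))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(SITE_TABLE_COLS, collapse = "\t"), con, sep = "\n")
  if (nrow(out) > 0) {
    body <- do.call(paste, c(lapply(out, as.character), sep = "\t"))
    writeLines(body, con, sep = "\n")
  }
  invisible(tab)
}

#' Read a census table written by [write_site_table()]
#'
#' @param path Path to the TSV.
#' @return A tibble in the flat site-table layout.
#' @export
read_site_table <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      pdb_id = readr::col_character(),
      halide_species = readr::col_character(),
      chain = readr::col_character(),
      res_seq = readr::col_integer(),
      n_coord = readr::col_integer(),
      min_dist_A = readr::col_double(),
      median_dist_A = readr::col_double(),
      distances_A = readr::col_character(),
      angles_deg = readr::col_character(),
      n_waters = readr::col_integer(),
      fasa = readr::col_double(),
      ss_labels = readr::col_character(),
      residues = readr::col_character()
    ),
    progress = FALSE
  ) |>
    dplyr::mutate(dplyr::across(
      c("distances_A", "angles_deg", "ss_labels", "residues"),
      \(v) dplyr::coalesce(v, "")
    ))
}
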