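# most frequent value; exact ties broken toward the smaller value
modal_value <- function(x) {
  if (length(x) == 0) return(NA_integer_)
  tab <- table(x)
  vals <- as.numeric(names(tab))
  vals[order(-as.integer(tab), vals)][1]
}

# pooled per-site angle values: the nearest atom's reference 0 is dropped
pooled_angles <- function(coord) {
  if (nrow(coord) < 2) return(double())
  a <- coord$angle
  a[-which(a == 0)[1]]
}

#' Histogram with half-open bins
#'
#' Bins values into half-open intervals `[origin + k*w, origin + (k+1)*w)`;
#' the counts conserve the total number of observations.
#'
#' @param values Numeric vector.
#' @param bin_width Positive bin width.
#' @param origin Left edge of bin 0 (default 0).
#' @return A tibble with `bin_start`, `bin_end`, `count`; empty input gives
#'   an empty tibble. Bins between the smallest and largest occupied bin are
#'   included with zero counts.
#' @examples
#' histogram_counts(c(0.1, 0.9, 1.1), 1) # bin [0,1): 2, bin [1,2): 1
#' @export
histogram_counts <- function(values, bin_width, origin = 0) {
  stopifnot(bin_width > 0)
  if (length(values) == 0) {
    return(tibble::tibble(bin_start = double(), bin_end = double(),
                          count = integer()))
  }
  k <- floor((values - origin) / bin_width)
  rng <- seq(min(k), max(k))
  counts <- as.integer(table(factor(k, levels = rng)))
  tibble::tibble(
    bin_start = origin + rng * bin_width,
    bin_end = origin + (rng + 1) * bin_width,
    count = counts
  )
}

#' Summarize a halide census
#'
#' Aggregates annotated sites into the census-level statistics: per-species
#' site counts, the pooled anion-atom distance distribution and its median,
#' the nearest-atom angle distribution, fractional-ASA mean and distribution,
#' water-count and coordination-number distributions with their modes,
#' residue composition and per-site residue combinations, the
#' CN-by-residue contingency table, and secondary-structure preference
#' counts.
#'
#' Medians are taken over the pooled per-atom distances of all sites of a
#' species (the standard interpolated middle order statistic); set
#' `nearest_only = TRUE` to pool only each site's nearest-atom distance.
#' Modes break ties toward the smaller value. Combination counts key each
#' site by its sorted residue-name multiset.
#'
#' @param sites An annotated `halide_sites` tibble (any number of entries).
#' @param nearest_only Pool only nearest-atom distances for the distance
#'   summary (default `FALSE`: all in-sphere distances).
#' @return An object of class `halide_census` (see [glance.halide_census()]
#'   and [tidy.halide_census()]). Empty input yields an empty summary.
#' @export
summarize_census <- function(sites, nearest_only = FALSE) {
  comps <- list()
  if (nrow(sites) == 0) {
    per_species <- tibble::tibble(
      species = character(), n_sites = integer(), n_distances = integer(),
      median_distance = double(), mean_fasa = double(),
      modal_cn = integer(), modal_waters = integer()
    )
    return(structure(list(
      per_species = per_species,
      distances = tibble::tibble(species = character(), value = double()),
      angles = tibble::tibble(species = character(), value = double()),
      fasa = tibble::tibble(species = character(), value = double()),
      cn = tibble::tibble(species = character(), cn = integer(), n = integer()),
      waters = tibble::tibble(species = character(), n_waters = integer(), n = integer()),
      composition = tibble::tibble(species = character(), res_name = character(), n = integer()),
      combinations = tibble::tibble(species = character(), combination = character(), n = integer()),
      cn_residue = tibble::tibble(species = character(), cn = integer(),
                                  res_name = character(), n = integer()),
      ss = tibble::tibble(species = character(), label = character(), n = integer()),
      nearest_only = nearest_only
    ), class = "halide_census"))
  }

  has_fasa <- "fasa" %in% names(sites)
  has_ss <- "ss_labels" %in% names(sites)

  comps$distances <- sites |>
    dplyr::mutate(.vals = purrr::map(.data$coord, function(co) {
      if (nrow(co) == 0) return(double())
      if (nearest_only) min(co$distance) else co$distance
    })) |>
    dplyr::select("species", ".vals") |>
    tidyr::unnest_longer(".vals", values_to = "value") |>
    dplyr::select("species", "value")

  comps$angles <- sites |>
    dplyr::mutate(.vals = purrr::map(.data$coord, pooled_angles)) |>
    dplyr::select("species", ".vals") |>
    tidyr::unnest_longer(".vals", values_to = "value") |>
    dplyr::select("species", "value")

  comps$fasa <- if (has_fasa) {
    tibble::tibble(species = sites$species, value = sites$fasa)
  } else {
    tibble::tibble(species = character(), value = double())
  }

  comps$cn <- sites |>
    dplyr::count(.data$species, .data$cn, name = "n") |>
    dplyr::arrange(.data$species, .data$cn)

  comps$waters <- sites |>
    dplyr::count(.data$species, .data$n_waters, name = "n") |>
    dplyr::arrange(.data$species, .data$n_waters)

  comps$composition <- sites |>
    dplyr::mutate(.res = purrr::map(.data$residues, "res_name")) |>
    dplyr::select("species", ".res") |>
    tidyr::unnest_longer(".res", values_to = "res_name") |>
    dplyr::count(.data$species, .data$res_name, name = "n") |>
    dplyr::arrange(.data$species, .data$res_name)

  combo <- if ("composition" %in% names(sites)) {
    sites$composition
  } else {
    purrr::map_chr(sites$residues, \(r) paste(sort(r$res_name), collapse = "+"))
  }
  comps$combinations <- tibble::tibble(species = sites$species, combination = combo) |>
    dplyr::count(.data$species, .data$combination, name = "n") |>
    dplyr::arrange(.data$species, dplyr::desc(.data$n), .data$combination)

  comps$cn_residue <- sites |>
    dplyr::mutate(.res = purrr::map(.data$residues, "res_name")) |>
    dplyr::select("species", "cn", ".res") |>
    tidyr::unnest_longer(".res", values_to = "res_name") |>
    dplyr::count(.data$species, .data$cn, .data$res_name, name = "n") |>
    dplyr::arrange(.data$species, .data$cn, .data$res_name)

  comps$ss <- if (has_ss) {
    sites |>
      dplyr::select("species", "ss_labels") |>
      tidyr::unnest_longer("ss_labels", values_to = "label") |>
      dplyr::count(.data$species, .data$label, name = "n") |>
      dplyr::arrange(.data$species, .data$label)
  } else {
    tibble::tibble(species = character(), label = character(), n = integer())
  }

  per_species <- sites |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      n_sites = dplyr::n(),
      modal_cn = as.integer(modal_value(.data$cn)),
      modal_waters = as.integer(modal_value(.data$n_waters)),
      mean_fasa = if (has_fasa) mean(.data$fasa, na.rm = TRUE) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::left_join(
      comps$distances |>
        dplyr::group_by(.data$species) |>
        dplyr::summarise(n_distances = dplyr::n(),
                         median_distance = stats::median(.data$value),
                         .groups = "drop"),
      by = "species"
    ) |>
    dplyr::mutate(
      n_distances = dplyr::coalesce(.data$n_distances, 0L)
    ) |>
    dplyr::select("species", "n_sites", "n_distances", "median_distance",
                  "mean_fasa", "modal_cn", "modal_waters") |>
    dplyr::arrange(.data$species)

  structure(
    c(list(per_species = per_species), comps, list(nearest_only = nearest_only)),
    class = "halide_census"
  )
}

#' @export
print.halide_census <- function(x, ...) {
  cat("<halide_census>\n")
  print(x$per_species)
  invisible(x)
}

#' Tidiers for census summaries
#'
#' `glance()` returns the one-row-per-species overview (site counts, pooled
#' median distance, mean fractional ASA, modal coordination number and modal
#' water count). `tidy()` returns a chosen component of the summary as a long
#' tibble. `tidy()` on a [superpose()] result returns its RMSD, rotation
#' determinant and translation.
#'
#' @param x A `halide_census` (or `superposition`) object.
#' @param component One of `"distances"`, `"angles"`, `"fasa"`, `"cn"`,
#'   `"waters"`, `"composition"`, `"combinations"`, `"cn_residue"`, `"ss"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.halide_census <- function(x, component = "distances", ...) {
  component <- match.arg(component, c("distances", "angles", "fasa", "cn",
                                      "waters", "composition", "combinations",
                                      "cn_residue", "ss"))
  x[[component]]
}

#' @rdname tidy.halide_census
#' @export
glance.halide_census <- function(x, ...) {
  x$per_species
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

DEFAULT_BIN_WIDTHS <- c(distances = 0.1, angles = 5, fasa = 0.05)

#' Plot a census summary
#'
#' `autoplot()` draws one distribution (distances, angles, fASA,
#' coordination numbers, water counts or residue composition), faceted by
#' species. `plot_census()` writes the four per-species distribution plots
#' (distance, angle, fASA, CN) as image files with deterministic names
#' `<type>_<species>.<format>` into `outdir`.
#'
#' @param object A `halide_census`.
#' @param type Which distribution to draw.
#' @param ... Unused.
#' @return A ggplot object (`autoplot`); invisibly, the written file paths
#'   (`plot_census`).
#' @export
autoplot.halide_census <- function(object, type = "distances", ...) {
  type <- match.arg(type, c("distances", "angles", "fasa", "cn", "waters",
                            "composition"))
  lab <- c(distances = "distance (Å)", angles = "angle (°)",
           fasa = "fractional ASA", cn = "coordination number",
           waters = "waters in sphere", composition = "residue")
  if (type %in% names(DEFAULT_BIN_WIDTHS)) {
    dat <- object[[type]]
    p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$value)) +
      ggplot2::geom_histogram(binwidth = DEFAULT_BIN_WIDTHS[[type]],
                              boundary = 0, closed = "left",
                              fill = "steelblue", colour = NA)
  } else if (type == "cn") {
    p <- ggplot2::ggplot(object$cn, ggplot2::aes(x = .data$cn, y = .data$n)) +
      ggplot2::geom_col(fill = "steelblue")
  } else if (type == "waters") {
    p <- ggplot2::ggplot(object$waters,
                         ggplot2::aes(x = .data$n_waters, y = .data$n)) +
      ggplot2::geom_col(fill = "steelblue")
  } else {
    p <- ggplot2::ggplot(object$composition,
                         ggplot2::aes(x = .data$res_name, y = .data$n)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
  }
  p + ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = lab[[type]], y = "count") +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname autoplot.halide_census
#' @param summary A `halide_census`.
#' @param outdir Output directory (created if missing).
#' @param format `"png"` or `"svg"` (`"svg"` requires the svglite package).
#' @export
plot_census <- function(summary, outdir, format = "png") {
  if (nrow(summary$per_species) == 0) {
    warning("empty census summary: no plots written", call. = FALSE)
    return(invisible(character()))
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  for (sp in summary$per_species$species) {
    for (type in c("distances", "angles", "fasa", "cn")) {
      dat <- summary[[type]]
      dat <- dat[dat$species == sp, , drop = FALSE]
      if (nrow(dat) == 0) next
      sub <- structure(summary, class = "halide_census")
      for (nm in c("distances", "angles", "fasa", "cn", "waters", "composition")) {
        sub[[nm]] <- sub[[nm]][sub[[nm]]$species == sp, , drop = FALSE]
      }
      p <- autoplot.halide_census(sub, type = type)
      path <- file.path(outdir, sprintf("%s_%s.%s", type, sp, format))
      suppressMessages(ggplot2::ggsave(path, p, width = 5, height = 4, dpi = 150))
      written <- c(written, path)
    }
  }
  invisible(written)
}
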