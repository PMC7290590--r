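#' Spherical lysosome volume from mean cross-sectional area
#'
#' Treats each lysosome as a sphere: the radius is derived from the mean
#' imaged area via `A = pi * r^2`, and the volume follows as
#' `V = 4/3 * pi * r^3`, i.e. `V = (4/3) * A^(3/2) / sqrt(pi)`.
#'
#' @param mean_area mean lysosomal area(s) in square micrometres; must be
#'   non-negative.
#' @return per-lysosome volume(s) in cubic micrometres.
#' @examples
#' volume_from_area(pi)   # unit radius: 4*pi/3
#' volume_from_area(3.03) # ~3.97 um^3
#' @export
volume_from_area <- function(mean_area) {
  if (any(!is.finite(mean_area)) || any(mean_area < 0))
    stop_data("mean_area must be finite and non-negative")
  r <- sqrt(mean_area / pi)
  (4 / 3) * pi * r^3
}

#' Total cellular lysosomal volume and derived columns
#'
#' Augments a per-condition lysosome summary table with the derived radius,
#' per-lysosome volume and total volume per cell (per-lysosome volume times
#' the number of lysosomes per cell).
#'
#' @param table data.frame with columns `condition`, `n_lysosomes_per_cell`
#'   and `mean_area` (um^2); other columns (e.g. `mean_intensity`) pass
#'   through.
#' @return the table with added `radius` (um), `per_lysosome_volume` (um^3)
#'   and `total_volume_per_cell` (um^3).
#' @export
total_cell_volume <- function(table) {
  need <- c("condition", "n_lysosomes_per_cell", "mean_area")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop_format(paste0("lysosome table missing column(s): ",
                       paste(miss, collapse = ", ")))
  if (any(table$n_lysosomes_per_cell < 0))
    stop_data("lysosome counts must be non-negative")
  table$radius <- sqrt(table$mean_area / pi)
  table$per_lysosome_volume <- volume_from_area(table$mean_area)
  table$total_volume_per_cell <- table$per_lysosome_volume *
    table$n_lysosomes_per_cell
  table
}

#' Fold change in total lysosomal volume versus a control condition
#'
#' @param table a lysosome table (see [total_cell_volume()]; derived columns
#'   are computed if absent).
#' @param control_label the control condition (e.g. `"DMSO"`).
#' @return the table with an added `fold_change` column; the control row has
#'   fold change 1.
#' @export
fold_change <- function(table, control_label) {
  if (is.null(table$total_volume_per_cell)) table <- total_cell_volume(table)
  ctrl <- table$total_volume_per_cell[table$condition == control_label]
  if (!length(ctrl))
    stop_data(paste0("control condition '", control_label, "' not found"))
  if (length(ctrl) > 1)
    stop_data("control condition appears more than once")
  if (ctrl <= 0)
    stop_data("control total volume must be > 0 for fold changes")
  table$fold_change <- table$total_volume_per_cell / ctrl
  table
}

#' Read / write lysosome morphometry tables
#'
#' Plain TSV with columns `condition`, `n_lysosomes_per_cell`, `mean_area`
#' and optionally `mean_intensity`.
#'
#' @param path file path.
#' @return `read_lysosome_table()`: a data.frame.
#' @export
read_lysosome_table <- function(path) {
  if (!file.exists(path)) stop_format(paste0("file not found: ", path))
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("condition", "n_lysosomes_per_cell", "mean_area")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop_format(paste0("lysosome table missing column(s): ",
                       paste(miss, collapse = ", ")))
  tab
}

#' @rdname read_lysosome_table
#' @param table a lysosome table.
#' @export
write_lysosome_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
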