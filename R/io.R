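#' Read a tetramer table
#'
#' Canonical CSV schema: header \code{id,x_nm,y_nm,theta_deg,tomogram,group}.
#' Rows are grouped by tomogram into one \code{\link{tetramer_array}} each;
#' angles are reduced modulo 90 degrees on input.
#'
#' @param path CSV file path.
#' @param side square edge in nm (27).
#' @param overlap_tol footprint-overlap tolerance passed to the array
#'   constructor, nm^2.
#' @return named list of \code{\link{tetramer_array}} objects (one per
#'   tomogram).
#' @export
read_tetramer_table <- function(path, side = 27, overlap_tol = 15) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "x_nm", "y_nm", "theta_deg", "tomogram", "group")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("tetramer table is missing columns: ", paste(miss, collapse = ", "))
  for (col in c("x_nm", "y_nm", "theta_deg")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad))
      stop(sprintf("non-numeric %s in tetramer table row %d", col, bad[1]))
    df[[col]] <- as.numeric(df[[col]])
  }
  dup <- df$id[duplicated(paste(df$tomogram, df$id))]
  if (length(dup))
    stop("duplicate tetramer id within a tomogram: ", dup[1])
  out <- lapply(split(df, df$tomogram), function(sub)
    tetramer_array(data.frame(id = sub$id, x = sub$x_nm, y = sub$y_nm,
                              theta = sub$theta_deg),
                   side = side, tomogram = sub$tomogram[1],
                   group = sub$group[1], overlap_tol = overlap_tol))
  out[order(names(out))]
}

#' Write tetramer arrays to the canonical CSV schema
#'
#' @param arrays a \code{\link{tetramer_array}} or list of them.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_tetramer_table <- function(arrays, path) {
  if (inherits(arrays, "tetramer_array")) arrays <- list(arrays)
  rows <- lapply(arrays, function(a)
    data.frame(id = a$id, x_nm = a$x, y_nm = a$y, theta_deg = a$theta,
               tomogram = attr(a, "tomogram"), group = attr(a, "group")))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a localization table
#'
#' Canonical schema: \code{x_nm,y_nm,z_nm,sigma_xy_nm,sigma_z_nm,gof,frame}.
#' Supported dialects map other common localization-table layouts onto it:
#' \describe{
#'   \item{\code{canonical}}{the schema above, nm units.}
#'   \item{\code{canonical_um}}{same columns suffixed \code{_um}, values in
#'     micrometres (converted to nm).}
#'   \item{\code{thunderstorm}}{columns \code{x [nm]}, \code{y [nm]},
#'     \code{z [nm]}, \code{uncertainty_xy [nm]}, \code{uncertainty_z [nm]},
#'     \code{chi2}/goodness column \code{gof}, \code{frame}.}
#' }
#' A missing z column is treated as z = 0 with a warning (z filtering is
#' then effectively disabled by passing an infinite slice).
#'
#' @param path CSV file path.
#' @param dialect one of the supported dialect names.
#' @return data.frame with columns \code{x, y, z, sigma_xy, sigma_z, gof,
#'   frame} (nm units).
#' @export
read_localizations <- function(path, dialect = "canonical") {
  if (!file.exists(path)) stop("file not found: ", path)
  dialects <- c("canonical", "canonical_um", "thunderstorm")
  if (!dialect %in% dialects)
    stop("unknown dialect '", dialect, "'; supported: ",
         paste(dialects, collapse = ", "))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  map <- switch(dialect,
    canonical = c(x = "x_nm", y = "y_nm", z = "z_nm",
                  sigma_xy = "sigma_xy_nm", sigma_z = "sigma_z_nm",
                  gof = "gof", frame = "frame"),
    canonical_um = c(x = "x_um", y = "y_um", z = "z_um",
                     sigma_xy = "sigma_xy_um", sigma_z = "sigma_z_um",
                     gof = "gof", frame = "frame"),
    thunderstorm = c(x = "x [nm]", y = "y [nm]", z = "z [nm]",
                     sigma_xy = "uncertainty_xy [nm]",
                     sigma_z = "uncertainty_z [nm]",
                     gof = "gof", frame = "frame"))
  out <- data.frame(row.names = seq_len(nrow(df)))
  scale <- if (dialect == "canonical_um") 1000 else 1
  for (f in names(map)) {
    src <- map[[f]]
    if (!src %in% names(df)) {
      if (f == "z") {
        warning("no z column; treating z as 0 (z filtering disabled)")
        out$z <- 0
        next
      }
      if (f == "frame") { out$frame <- seq_len(nrow(df)); next }
      stop("localization table is missing column: ", src)
    }
    v <- suppressWarnings(as.numeric(df[[src]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("malformed value in column '%s', row %d", src, bad[1]))
    out[[f]] <- if (f %in% c("gof", "frame")) v else v * scale
  }
  out
}

#' Write localizations in the canonical schema
#'
#' @param locs data.frame with columns \code{x, y, z, sigma_xy, sigma_z,
#'   gof, frame}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_localizations <- function(locs, path) {
  out <- data.frame(x_nm = locs$x, y_nm = locs$y, z_nm = locs$z,
                    sigma_xy_nm = locs$sigma_xy, sigma_z_nm = locs$sigma_z,
                    gof = locs$gof, frame = locs$frame)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spark table
#'
#' Schema: \code{rat,cell,group,amplitude,fdhm_ms,fwhm_um}.
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_spark_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("rat", "cell", "group", "amplitude", "fdhm_ms", "fwhm_um")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("spark table is missing columns: ", paste(miss, collapse = ", "))
  df
}

#' Write a cluster table
#'
#' Stable column order \code{cluster_id,area_nm2,n_pixels,n_tetramers}
#' (the count column is filled with NA when coverage was not set).
#'
#' @param clusters a \code{cluster_table}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_cluster_table <- function(clusters, path) {
  nt <- if ("n_tetramers" %in% names(clusters)) clusters$n_tetramers
        else rep(NA_integer_, nrow(clusters))
  out <- data.frame(cluster_id = clusters$cluster_id,
                    area_nm2 = clusters$area_nm2,
                    n_pixels = clusters$n_pixels,
                    n_tetramers = nt)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
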