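#' Particle table columns
#'
#' The canonical per-particle record: source tomogram, position,
#' current transform, keep/exclude flag with reason code.
#' @keywords internal
particle_table_cols <- c("particle_id", "tomo_id", "x", "y", "z",
                         "phi", "theta", "psi", "dx", "dy", "dz",
                         "cc", "at_window_limit", "keep", "reason")

#' Build a particle table from a particle list
#'
#' @param particles list of particle lists (`transform`, `particle_id`,
#'   optional `cc`, `at_window_limit`, `keep`, `reason`).
#' @param positions optional n x 3 matrix of positions (voxels).
#' @param tomo_id tomogram identifier.
#' @return data frame with the standard columns.
#' @export
particle_table <- function(particles, positions = NULL, tomo_id = 1L) {
  rows <- lapply(seq_along(particles), function(i) {
    p <- particles[[i]]
    tr <- p$transform
    data.frame(particle_id = p$particle_id %||% i, tomo_id = tomo_id,
               x = if (is.null(positions)) NA_real_ else positions[i, 1],
               y = if (is.null(positions)) NA_real_ else positions[i, 2],
               z = if (is.null(positions)) NA_real_ else positions[i, 3],
               phi = tr$phi, theta = tr$theta, psi = tr$psi,
               dx = tr$shift[1], dy = tr$shift[2], dz = tr$shift[3],
               cc = p$cc %||% NA_real_,
               at_window_limit = isTRUE(p$at_window_limit),
               keep = !isFALSE(p$keep),
               reason = p$reason %||% "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a particle table as UTF-8 TSV
#'
#' @param table particle data frame.
#' @param path file path.
#' @return `path` / the table.
#' @export
write_particle_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_particle_table
#' @export
read_particle_table <- function(path) {
  t_ <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   fileEncoding = "UTF-8")
  if ("reason" %in% names(t_)) t_$reason[is.na(t_$reason)] <- ""
  t_
}

#' Push table-level keep/exclude state back onto a particle list
#'
#' @param particles particle list.
#' @param table particle table with matching `particle_id`s.
#' @return the updated particle list.
#' @export
apply_table_flags <- function(particles, table) {
  for (i in seq_along(particles)) {
    row <- match(particles[[i]]$particle_id, table$particle_id)
    if (!is.na(row)) {
      particles[[i]]$keep <- table$keep[row]
      particles[[i]]$reason <- table$reason[row]
    }
  }
  particles
}
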