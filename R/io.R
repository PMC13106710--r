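#' Read and write the package's delimited formats
#'
#' Track tables are tab-separated with header `fly_id genotype t x y`;
#' ERG tables are tab-separated `batch genotype_a genotype_b amplitude
#' is_control` (`genotype_b` empty for controls and singles); partitions
#' are two-column `genotype group` TSVs.
#'
#' @param path File path.
#' @param x Object to write.
#' @return Readers return `data.table`s ([read_partition()] a named
#'   character vector); writers return `path` invisibly.
#' @name ethoscreen-io
NULL

#' @rdname ethoscreen-io
#' @export
write_tracks <- function(x, path) {
  fwrite(as.data.table(x)[, .(fly_id, genotype, t, x, y)], path, sep = "\t")
  invisible(path)
}

#' @rdname ethoscreen-io
#' @export
read_tracks <- function(path) {
  dt <- fread(path, sep = "\t")
  stopifnot(all(c("fly_id", "genotype", "t", "x", "y") %in% names(dt)))
  dt
}

#' @rdname ethoscreen-io
#' @export
write_erg <- function(x, path) {
  fwrite(
    as.data.table(x)[, .(batch, genotype_a, genotype_b, amplitude, is_control)],
    path,
    sep = "\t"
  )
  invisible(path)
}

#' @rdname ethoscreen-io
#' @export
read_erg <- function(path) {
  dt <- fread(path, sep = "\t", na.strings = c("", "NA"))
  stopifnot(all(
    c("batch", "genotype_a", "genotype_b", "amplitude", "is_control") %in%
      names(dt)
  ))
  dt[, genotype_b := as.character(genotype_b)]
  dt
}

#' @rdname ethoscreen-io
#' @export
write_partition <- function(x, path) {
  fwrite(
    data.table(genotype = names(x), group = unname(x)), path,
    sep = "\t"
  )
  invisible(path)
}

#' @rdname ethoscreen-io
#' @export
read_partition <- function(path) {
  dt <- fread(path, sep = "\t")
  setNames(as.character(dt$group), dt$genotype)
}
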