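# Particle/alignment metadata I/O. STAR is the cryo-EM lingua franca for
# tabular metadata; a TSV mirror keeps the assay-side tooling simple. One
# data block, loop_ format, whitespace-separated rows.

star_block_name <- "particles"

#' Write a metadata table as STAR or TSV
#'
#' Format is chosen by file extension (`.star` or `.tsv`). Column names,
#' row order and unknown columns are preserved on a round trip.
#'
#' @param table A data frame.
#' @param path Output path ending in `.star` or `.tsv`.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "star") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("", sprintf("data_%s", star_block_name), "", "loop_"), con)
    writeLines(sprintf("_%s #%d", names(table), seq_along(table)), con)
    fmt <- vapply(table, function(col) {
      if (is.numeric(col)) format(col, digits = 12, trim = TRUE,
                                  scientific = FALSE)
      else as.character(col)
    }, FUN.VALUE = character(nrow(table)))
    fmt <- matrix(fmt, nrow = nrow(table))
    writeLines(apply(fmt, 1, paste, collapse = "  "), con)
  } else if (ext == "tsv") {
    utils::write.table(table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    abort("write_table supports .star and .tsv")
  }
  invisible(path)
}

#' Read a metadata table from STAR or TSV
#'
#' @param path Input path (`.star` or `.tsv`).
#' @param required Character vector of mandatory columns; missing ones are
#'   listed by name in the error.
#' @return A tibble.
#' @export
read_table <- function(path, required = NULL) {
  ext <- tolower(tools::file_ext(path))
  out <- if (ext == "star") {
    lines <- readLines(path)
    lines <- trimws(lines)
    loop_at <- which(lines == "loop_")
    if (!length(loop_at)) abort(sprintf("no loop_ block in %s", path))
    i <- loop_at[1] + 1
    cols <- character()
    while (i <= length(lines) && startsWith(lines[i], "_")) {
      cols <- c(cols, sub("^_", "", sub("\\s+#\\d+$", "", lines[i])))
      i <- i + 1
    }
    rows <- lines[i:length(lines)]
    rows <- rows[nzchar(rows)]
    mat <- do.call(rbind, strsplit(rows, "\\s+"))
    if (ncol(mat) != length(cols))
      abort(sprintf("malformed STAR rows in %s", path))
    df <- as.data.frame(mat, stringsAsFactors = FALSE)
    names(df) <- cols
    df[] <- lapply(df, utils::type.convert, as.is = TRUE)
    as_tibble(df)
  } else if (ext == "tsv") {
    as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE))
  } else {
    abort("read_table supports .star and .tsv")
  }
  if (!is.null(required)) {
    miss <- setdiff(required, names(out))
    if (length(miss))
      abort(sprintf("missing mandatory column(s) in %s: %s", path,
                    paste(miss, collapse = ", ")))
  }
  out
}

# canonical alignment-table columns
alignment_columns <- c("segment_id", "filament_id", "segment_index",
                       "rot", "tilt", "psi", "shift_x", "shift_y",
                       "cc_score", "pf_assignment")

#' Expand segment alignment metadata to protofilament-particle metadata
#'
#' The metadata counterpart of [extract_pf_particles()]: every segment row
#' becomes `n_pf` particle rows (one per tubulin dimer imaged in that
#' segment), carrying provenance and the symmetry-composed initial view
#' angle. Useful for bookkeeping ahead of (or without) image extraction —
#' e.g. a 19,128-segment table at 14 protofilaments expands to 267,792
#' particle rows.
#'
#' @param table An alignment table (see [projection_match()]).
#' @param n_pf Protofilament count.
#' @param twist_deg Per-step view-angle increment; default
#'   `-360 / n_pf` (left-handed lattice).
#' @return A tibble with `n_pf` rows per input row: `segment_id`,
#'   `pf_index`, `rot` (composed), plus the carried-through columns.
#' @export
expand_pf_metadata <- function(table, n_pf, twist_deg = -360 / n_pf) {
  out <- tidyr::expand_grid(table, pf_index = seq_len(n_pf) - 1L)
  out$rot <- wrap360(out$rot + out$pf_index * twist_deg)
  out$particle_id <- seq_len(nrow(out))
  out
}

#' Read an alignment table, enforcing the canonical column set
#'
#' @param path `.star` or `.tsv` path.
#' @return A tibble with at least the canonical alignment columns.
#' @export
read_alignment_table <- function(path) {
  read_table(path, required = alignment_columns)
}
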