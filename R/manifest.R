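# The fragment manifest: the "written" form of data. An unordered multiset of
# oligomer sequences; order and duplication never carry information.

new_manifest <- function(sequences, cfg = NULL) {
  structure(as.character(sequences),
            config = if (!is.null(cfg))
              list(base = cfg$base, capacity = cfg$capacity,
                   index_width = cfg$index_width, index_radix = cfg$index_radix,
                   length_record = cfg$length_record, pad = cfg$pad,
                   spacer = cfg$spacer),
            class = "fragment_manifest")
}

#' Construct a fragment manifest from plain sequences
#'
#' @param sequences Character vector of oligomer sequence strings.
#' @return A `fragment_manifest`.
#' @export
fragment_manifest <- function(sequences) new_manifest(sequences)

#' @export
print.fragment_manifest <- function(x, ...) {
  cen <- census(x)
  cat("<fragment_manifest> ", length(x), " fragment(s); length census: ",
      if (length(cen)) paste0(names(cen), ":", cen, collapse = " ") else "(empty)",
      "\n", sep = "")
  utils::head(as.character(x), 10L) |>
    (\(h) cat(paste0("  ", h, collapse = "\n"),
              if (length(x) > 10L) "\n  ..." else "", "\n"))()
  invisible(x)
}

#' @export
`[.fragment_manifest` <- function(x, i, ...) {
  new_manifest(NextMethod())
}

#' Write / read a fragment manifest
#'
#' Two on-disk twins: JSON (an array of records with a `sequence` string and,
#' when a mass model and alphabet are supplied, the computed precursor `mz`)
#' and flat CSV (`fragment_id,sequence`). Output is sorted lexicographically
#' so that repeated runs diff cleanly; ordering carries no information.
#'
#' @param manifest A `fragment_manifest` or character vector.
#' @param path Output path; format follows the extension unless `format` is
#'   given.
#' @param format `"json"` or `"csv"`.
#' @param model,alphabet Optional [mass_model()] and [alphabet()]; when both
#'   are given the JSON records include each fragment's precursor m/z.
#' @return `write_manifest()` returns `path` invisibly; `read_manifest()`
#'   returns a `fragment_manifest`.
#' @export
write_manifest <- function(manifest, path, format = NULL,
                           model = NULL, alphabet = NULL) {
  seqs <- sort(as.character(manifest))
  format <- format %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  if (format == "csv") {
    utils::write.csv(data.frame(fragment_id = seq_along(seqs), sequence = seqs),
                     path, row.names = FALSE, quote = FALSE)
  } else {
    recs <- data.frame(sequence = seqs)
    if (!is.null(model) && !is.null(alphabet))
      recs$mz <- vapply(seqs, oligomer_mass, numeric(1),
                        model = model, alphabet = alphabet, USE.NAMES = FALSE)
    jsonlite::write_json(recs, path, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path, format = NULL) {
  format <- format %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  seqs <- if (format == "csv") {
    df <- utils::read.csv(path, colClasses = "character")
    if (!"sequence" %in% names(df)) stop_data("manifest CSV lacks a `sequence` column")
    df$sequence
  } else {
    df <- jsonlite::fromJSON(path)
    if (is.null(df$sequence)) stop_data("manifest JSON lacks `sequence` fields")
    df$sequence
  }
  new_manifest(seqs)
}
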