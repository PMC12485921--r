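#' Read a protein FASTA file into a tibble
#'
#' @param path FASTA file path.
#' @return Tibble: `id`, `sequence` (case preserved).
#' @export
read_fasta <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             set.attributes = FALSE)
  tibble(id = names(seqs), sequence = unname(unlist(seqs)))
}

#' Write sequences to FASTA
#'
#' @param x Tibble with `id`/`sequence` columns (the first column is used
#'   as the id when no `id` column exists, e.g. `protein`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  id <- if ("id" %in% names(x)) x$id else x[[1]]
  seqinr::write.fasta(as.list(x$sequence), names = id, file.out = path,
                      nbchar = 60)
  invisible(path)
}

#' Read/write tab-separated tables with empty-string missing values
#'
#' Empty optional cells round-trip as empty strings, never as literal
#' `"NA"`.
#'
#' @param path File path.
#' @return A tibble with character columns ([read_tsv_cells()]) or `path`
#'   invisibly ([write_tsv_cells()]).
#' @export
read_tsv_cells <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
}

#' @rdname read_tsv_cells
#' @param x Data frame to write.
#' @export
write_tsv_cells <- function(x, path) {
  readr::write_tsv(x, path, na = "")
  invisible(path)
}

#' Verify lossless read/write round-trips for pipeline file formats
#'
#' Each file is read, written back out, and re-read; the report records
#' whether the two reads agree (sequence ids and residues for FASTA,
#' topology and branch lengths to 1e-9 for newick, all cells for TSV,
#' parsed objects for JSON). Malformed files are reported with their parse
#' diagnostic instead of aborting the run.
#'
#' @param paths Character vector of file paths (`.fasta`/`.fa`, `.nwk` /
#'   `.newick`, `.tsv`, `.json`).
#' @return Tibble: `path`, `format`, `ok`, `detail`.
#' @export
roundtrip_formats <- function(paths) {
  list_rbind(lapply(paths, function(path) {
    ext <- tolower(tools::file_ext(path))
    format <- dplyr::case_when(
      ext %in% c("fasta", "fa", "faa", "afa") ~ "fasta",
      ext %in% c("nwk", "newick", "tre") ~ "newick",
      ext == "tsv" ~ "tsv",
      ext == "json" ~ "json",
      TRUE ~ "unknown"
    )
    res <- tryCatch(
      {
        ok <- switch(format,
          fasta = {
            a <- read_fasta(path)
            tmp <- tempfile(fileext = ".fasta")
            on.exit(unlink(tmp), add = TRUE)
            write_fasta(a, tmp)
            identical(a, read_fasta(tmp))
          },
          newick = {
            a <- suppressWarnings(ape::read.tree(path))
            if (!inherits(a, "phylo") && !inherits(a, "multiPhylo")) {
              abort("malformed newick: no tree could be parsed")
            }
            tmp <- tempfile(fileext = ".nwk")
            on.exit(unlink(tmp), add = TRUE)
            ape::write.tree(a, tmp)
            b <- ape::read.tree(tmp)
            isTRUE(ape::all.equal.phylo(a, b, tolerance = 1e-9,
                                        use.edge.length = TRUE))
          },
          tsv = {
            a <- read_tsv_cells(path)
            tmp <- tempfile(fileext = ".tsv")
            on.exit(unlink(tmp), add = TRUE)
            write_tsv_cells(a, tmp)
            identical(as.data.frame(a), as.data.frame(read_tsv_cells(tmp)))
          },
          json = {
            a <- jsonlite::read_json(path)
            tmp <- tempfile(fileext = ".json")
            on.exit(unlink(tmp), add = TRUE)
            jsonlite::write_json(a, tmp, auto_unbox = TRUE, digits = NA)
            identical(a, jsonlite::read_json(tmp))
          },
          abort(sprintf("unsupported format for '%s'", path))
        )
        list(ok = ok, detail = if (ok) "round-trip identical"
             else "round-trip altered content")
      },
      error = function(e) list(ok = FALSE, detail = conditionMessage(e))
    )
    tibble(path = path, format = format, ok = res$ok, detail = res$detail)
  }))
}
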