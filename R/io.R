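#' Read and write GMT gene-set collections
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#'
#' @param path File path.
#' @return `read_gmt()`: a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1L)
  assert_that(!anyDuplicated(names(sets)), "duplicate set names in GMT")
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param description Optional per-set description column.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  description <- description %||% rep(".", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read and write BED6 interval files (0-based half-open)
#'
#' @param path File path.
#' @return `read_bed()`: tibble with chrom, start, end and any of
#'   name/score/strand present.
#' @export
read_bed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  names(x) <- cols[seq_len(ncol(x))]
  tibble::as_tibble(x)
}

#' @rdname read_bed
#' @param x Interval tibble (chrom/start/end, optional name/score/strand).
#' @export
write_bed <- function(x, path) {
  check_intervals(x)
  x <- dplyr::arrange(x, chrom, start)
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"), names(x))
  ## BED requires contiguous leading columns; fill gaps with defaults
  col_or <- function(nm, default) if (nm %in% names(x)) x[[nm]] else default
  out <- tibble::tibble(chrom = x$chrom, start = x$start, end = x$end,
                        name = col_or("name", "."),
                        score = col_or("score", 0),
                        strand = col_or("strand", "."))
  n_keep <- max(3L, match(cols[length(cols)], names(out)))
  utils::write.table(out[seq_len(n_keep)], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a JASPAR-format position frequency matrix
#'
#' Accepts the JASPAR text layout: a `>ID name` header followed by four
#' lines `A [ 1 2 ... ]` etc. Returns the raw count matrix (4 x width,
#' rows A/C/G/T).
#'
#' @param path File path.
#' @return Numeric matrix with rownames A, C, G, T.
#' @export
read_jaspar_pfm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lines <- lines[!startsWith(lines, ">")]
  assert_that(length(lines) == 4, "expected four base rows in PFM")
  base <- toupper(substr(trimws(lines), 1, 1))
  nums <- lapply(lines, function(l) {
    l <- gsub("^[ACGTacgt]\\s*\\[?", "", l)
    l <- gsub("\\]\\s*$", "", l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  })
  m <- do.call(rbind, nums)
  dimnames(m) <- list(base, NULL)
  m[c("A", "C", "G", "T"), , drop = FALSE]
}

#' Write all synthetic fixtures to disk with a checksum manifest
#'
#' Serialises a [generate_cell_population()] result as MatrixMarket MTX
#' plus features/barcodes/cell-metadata TSVs, a
#' [generate_regulatory_landscape()] as per-mark BED files, a TSS TSV and
#' a region-count TSV, planted modules as a GMT, the intensity table as
#' TSV, and all truth tables as one JSON file. The manifest lists every
#' file with its MD5 checksum.
#'
#' @param population A `cell_population` (or NULL to skip).
#' @param landscape A `regulatory_landscape` (or NULL).
#' @param intensity_table Tibble from [generate_intensity_table()] (or NULL).
#' @param out_dir Output directory (created if absent).
#' @return Tibble manifest (file, md5), invisibly written to
#'   `manifest.tsv` as well.
#' @export
write_fixtures <- function(population = NULL, landscape = NULL,
                           intensity_table = NULL, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character()
  emit <- function(path) { written <<- c(written, path); path }

  if (!is.null(population)) {
    Matrix::writeMM(population$counts, emit(file.path(out_dir, "counts.mtx")))
    writeLines(rownames(population$counts), emit(file.path(out_dir, "features.tsv")))
    writeLines(colnames(population$counts), emit(file.path(out_dir, "barcodes.tsv")))
    readr::write_tsv(population$cell_meta, emit(file.path(out_dir, "cell_meta.tsv")))
    readr::write_tsv(population$gene_meta, emit(file.path(out_dir, "gene_meta.tsv")))
    modules <- split(population$gene_meta$gene[!is.na(population$gene_meta$module)],
                     population$gene_meta$module[!is.na(population$gene_meta$module)])
    if (length(modules)) {
      write_gmt(modules, emit(file.path(out_dir, "planted_modules.gmt")))
    }
  }
  if (!is.null(landscape)) {
    for (mark in names(landscape$peaks)) {
      write_bed(landscape$peaks[[mark]],
                emit(file.path(out_dir, paste0("peaks_", mark, ".bed"))))
    }
    write_bed(landscape$tad_boundaries, emit(file.path(out_dir, "tad_boundaries.bed")))
    readr::write_tsv(landscape$tss, emit(file.path(out_dir, "tss.tsv")))
    rc <- tibble::as_tibble(landscape$region_counts, rownames = "region")
    readr::write_tsv(rc, emit(file.path(out_dir, "region_counts.tsv")))
  }
  if (!is.null(intensity_table)) {
    readr::write_tsv(intensity_table, emit(file.path(out_dir, "intensity.tsv")))
  }

  truth <- list()
  if (!is.null(population)) {
    truth$population <- list(senescent = population$truth$s,
                             marker = population$gene_meta$gene[population$gene_meta$is_marker])
  }
  if (!is.null(landscape)) {
    truth$landscape <- list(ctcf = landscape$ctcf_truth,
                            promoters = landscape$promoter_truth,
                            enhancers = landscape$enhancer_truth,
                            genes = landscape$gene_truth,
                            condition = as.character(landscape$condition))
  }
  if (!is.null(intensity_table)) {
    truth$intensity <- list(senescent = intensity_table$senescent)
  }
  jsonlite::write_json(truth, emit(file.path(out_dir, "truth.json")),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)

  manifest <- tibble::tibble(
    file = basename(written),
    md5 = unname(tools::md5sum(written))
  )
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  manifest
}
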