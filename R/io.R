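# Readers/writers for the plain-text interchange formats: counts as TSV or
# MatrixMarket triples, sample metadata TSV, orthology TSV, limiting-dilution
# CSV, truth JSON, and GMT gene-set collections.

#' Write a counts matrix as TSV
#'
#' Genes in rows; first column `gene_id`, remaining columns one per sample.
#' Tab-delimited, UTF-8, no quoting.
#'
#' @param counts matrix with gene row names and sample column names.
#' @param path output file.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV counts matrix written by [write_counts_tsv()]
#' @param path input file.
#' @return integer matrix with dimnames.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write a counts matrix as a MatrixMarket triple
#'
#' Writes `<prefix>.mtx` (1-based coordinate format), `<prefix>_genes.txt`
#' and `<prefix>_samples.txt`.
#'
#' @param counts matrix with dimnames.
#' @param prefix path prefix for the three files.
#' @export
write_counts_mtx <- function(counts, prefix) {
  Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "generalMatrix"),
                  paste0(prefix, ".mtx"))
  writeLines(rownames(counts), paste0(prefix, "_genes.txt"))
  writeLines(colnames(counts), paste0(prefix, "_samples.txt"))
  invisible(prefix)
}

#' Read a MatrixMarket triple written by [write_counts_mtx()]
#' @param prefix path prefix used when writing.
#' @return integer matrix with dimnames.
#' @export
read_counts_mtx <- function(prefix) {
  m <- as.matrix(Matrix::readMM(paste0(prefix, ".mtx")))
  rownames(m) <- readLines(paste0(prefix, "_genes.txt"))
  colnames(m) <- readLines(paste0(prefix, "_samples.txt"))
  storage.mode(m) <- "integer"
  m
}

#' Write a simulated bundle to a directory of plain-text files
#'
#' Counts go out as TSV (and, with `format = "mtx"`, as MatrixMarket
#' triples), sample metadata as TSV with columns `sample_id`, `sex`,
#' orthology as TSV with columns `mouse_gene`, `human_gene`, and the
#' planted truth as JSON. [read_fixture()] round-trips the bundle.
#'
#' @param bundle a `paired_expression` object from
#'   [generate_paired_expression()].
#' @param dir output directory (created if missing).
#' @param format `"tsv"` (default) or `"mtx"` for the count matrices.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(bundle, dir, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (!inherits(bundle, "paired_expression")) {
    stop_field("bundle", "must come from generate_paired_expression()")
  }
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop(sprintf("cannot create directory '%s'", dir), call. = FALSE)
  }
  for (sp in c("mouse", "human")) {
    ds <- bundle[[sp]]
    if (format == "tsv") {
      write_counts_tsv(ds$counts, file.path(dir, paste0(sp, "_counts.tsv")))
    } else {
      write_counts_mtx(ds$counts, file.path(dir, paste0(sp, "_counts")))
    }
    utils::write.table(
      data.frame(sample_id = ds$sample_ids, sex = ds$sex,
                 stringsAsFactors = FALSE),
      file.path(dir, paste0(sp, "_samples.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  }
  utils::write.table(bundle$map, file.path(dir, "orthology.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  tr <- bundle$truth
  jsonlite::write_json(
    list(de_flags = unname(tr$de_flags),
         mouse_sign = unname(tr$mouse_sign),
         human_sign = unname(tr$human_sign),
         gene_ids_mouse = names(tr$mouse_sign),
         gene_ids_human = names(tr$human_sign),
         planted_concordance = tr$planted_concordance,
         seed = tr$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  writeLines(format, file.path(dir, "format.txt"))
  invisible(dir)
}

#' Read a bundle written by [write_fixture()]
#' @param dir directory containing the fixture files.
#' @return A `paired_expression` list with `mouse`, `human`, `map`, `truth`
#'   (the simulation config itself is not round-tripped).
#' @export
read_fixture <- function(dir) {
  format <- readLines(file.path(dir, "format.txt"))[1]
  read_one <- function(sp) {
    counts <- if (format == "tsv") {
      read_counts_tsv(file.path(dir, paste0(sp, "_counts.tsv")))
    } else {
      read_counts_mtx(file.path(dir, paste0(sp, "_counts")))
    }
    meta <- utils::read.delim(file.path(dir, paste0(sp, "_samples.tsv")),
                              stringsAsFactors = FALSE)
    stopifnot(identical(meta$sample_id, colnames(counts)))
    expression_dataset(counts, meta$sex, sp)
  }
  mouse <- read_one("mouse")
  human <- read_one("human")
  mp <- utils::read.delim(file.path(dir, "orthology.tsv"),
                          stringsAsFactors = FALSE)
  map <- orthology_map(mp$mouse_gene, mp$human_gene)
  tj <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  truth <- structure(
    list(de_flags = stats::setNames(as.logical(tj$de_flags),
                                    tj$gene_ids_mouse),
         mouse_sign = stats::setNames(as.integer(tj$mouse_sign),
                                      tj$gene_ids_mouse),
         human_sign = stats::setNames(as.integer(tj$human_sign),
                                      tj$gene_ids_human),
         planted_concordance = tj$planted_concordance,
         seed = tj$seed),
    class = "synthetic_truth"
  )
  structure(list(mouse = mouse, human = human, map = map, truth = truth,
                 config = NULL),
            class = "paired_expression")
}

#' Write a limiting-dilution design as CSV
#'
#' Columns `dose`, `wells`, `positive` and, when any design carries a
#' group label, `group`.
#'
#' @param designs an [ld_design()] or a list of them.
#' @param path output file.
#' @export
write_ld_csv <- function(designs, path) {
  if (inherits(designs, "ld_design")) designs <- list(designs)
  rows <- do.call(rbind, lapply(designs, function(d) {
    out <- as.data.frame(d)
    grp <- attr(d, "group")
    out$group <- if (is.null(grp)) NA_character_ else grp
    out
  }))
  if (all(is.na(rows$group))) rows$group <- NULL
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a limiting-dilution CSV written by [write_ld_csv()]
#' @param path input file.
#' @return A single [ld_design()] (no `group` column) or a named list of
#'   designs, one per group.
#' @export
read_ld_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(df$group)) {
    return(ld_design(df$dose, df$wells, df$positive))
  }
  out <- lapply(split(df, df$group), function(g) {
    ld_design(g$dose, g$wells, g$positive, group = g$group[1])
  })
  out[unique(df$group)]
}

#' Write a gene-set collection in GMT format
#'
#' One set per line: name, description, then tab-separated member ids.
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param description description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  if (is.null(names(sets)) || anyDuplicated(names(sets)) ||
      any(!nzchar(names(sets)))) {
    stop_field("sets", "must be a named list with unique non-empty names")
  }
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file path.
#' @return A `gene_set_collection`: named list of character vectors with a
#'   `source` attribute.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  gene_set_collection(sets, source = basename(path))
}

#' Validate a named list of gene sets
#' @param sets named list of character vectors.
#' @param source label recorded on the collection.
#' @return The validated list, classed `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, source = "user") {
  if (!is.list(sets) || is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop_field("sets", "must be a named list with unique names")
  }
  if (any(lengths(sets) == 0L)) {
    stop_field("sets", "sets must be nonempty")
  }
  structure(lapply(sets, as.character), source = source,
            class = "gene_set_collection")
}
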